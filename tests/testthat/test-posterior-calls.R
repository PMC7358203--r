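test_that("probDE counts same-sign mass with boundary conventions", {
    expect_equal(suppressWarnings(probDE(c(0.5, 1, 2))), 1)
    # mean of {-1, 2, 3, 4} is positive: 3 of 4 draws count
    expect_equal(suppressWarnings(probDE(c(-1, 2, 3, 4))), 3 / 4)
    # symmetric draws: mean 0 convention
    expect_equal(suppressWarnings(probDE(c(-2, -1, 1, 2))), 0.5)
    # zeros count to neither side
    expect_equal(suppressWarnings(probDE(c(0, 0, 1, 3))), 2 / 4)
    expect_error(probDE(numeric()), "empty")
    expect_warning(probDE(rnorm(50)), "fewer than 100")
})

test_that("probDSGene uses the 1/T null and the max-over-isoforms rule", {
    # all draws exactly at 1/T: probability 0
    flat <- matrix(1 / 3, 200, 3)
    expect_equal(probDSGene(flat)$gene, 0)
    # hand-counted two-isoform case
    a1 <- c(0.6, 0.7, 0.55, 0.4)
    expect_equal(probDSGene(cbind(a1, 1 - a1))$isoform[[1]], 3 / 4)
    # one isoform always above 1/T forces gene probability 1
    up <- cbind(runif(300, 0.6, 0.9))
    up <- cbind(up, (1 - up) / 2, (1 - up) / 2)
    expect_equal(probDSGene(up)$gene, 1)
    expect_error(probDSGene(matrix(1, 10, 1)), "at least 2")
})

test_that("probDSIsoform uses the draw-wise dot-product null", {
    # uniform alpha in every draw reduces to the gene-level null
    T <- 4
    aU <- matrix(1 / T, 150, T)
    pAny <- t(vapply(seq_len(150), function(i) {
        w <- rgamma(T, 1); w / sum(w)
    }, numeric(T)))
    expect_equal(unname(probDSIsoform(aU, pAny)), rep(0, T))
    # single-draw hand calculation: c = 0.5, alpha1 above
    a <- matrix(c(0.8, 0.2), 1)
    p <- matrix(c(0.5, 0.5), 1)
    expect_equal(unname(probDSIsoform(a, p)), c(1, 1))
    # permutation equivariance
    set.seed(6)
    a <- t(vapply(1:200, function(i) {
        w <- rgamma(3, 1); w / sum(w)
    }, numeric(3)))
    p <- t(vapply(1:200, function(i) {
        w <- rgamma(3, 1); w / sum(w)
    }, numeric(3)))
    perm <- c(3, 1, 2)
    expect_equal(unname(probDSIsoform(a[, perm], p[, perm])),
                 unname(probDSIsoform(a, p))[perm])
    expect_error(probDSIsoform(a, p[1:10, ]), "matching dimensions")
})

test_that("fold changes follow the perturbation-ratio definition", {
    d <- list(beta = rep(1, 200),
              p = matrix(rep(c(0.4, 0.6), each = 200), 200),
              alpha = matrix(rep(c(0.6, 0.4), each = 200), 200))
    fc <- foldChanges(d)
    expect_equal(fc$expr_log2fc, 1)
    expect_equal(unname(fc$splicing_fc), c(0.5 / 0.4, 0.5 / 0.6))
    # uniform alpha: all splicing fold changes are 1
    d$alpha <- matrix(0.5, 200, 2)
    expect_equal(unname(foldChanges(d)$splicing_fc), c(1, 1))
    # splicing fold changes times control fractions stay on the simplex
    set.seed(11)
    for (i in 1:10) {
        T <- sample(2:6, 1)
        d <- list(beta = rnorm(100),
                  p = t(vapply(1:100, function(.) {
                      w <- rgamma(T, 1); w / sum(w)
                  }, numeric(T))),
                  alpha = t(vapply(1:100, function(.) {
                      w <- rgamma(T, 1); w / sum(w)
                  }, numeric(T))))
        fc <- foldChanges(d)
        pBar <- simplexNormalize(colMeans(d$p))
        expect_equal(sum(fc$splicing_fc * pBar), 1, tolerance = 1e-9)
    }
})

test_that("classification respects both thresholds and partitions genes", {
    expect_equal(classifyComparison(1.0, 0.0), "DGE")
    expect_equal(classifyComparison(1.0, 1.0), "DAST/DGE")
    expect_equal(classifyComparison(0.5, 0.5), "static")
    expect_equal(classifyComparison(0.98, 0.995), "DAST")
    expect_equal(classifyComparison(0.99, 0.5, threshDE = 0.99), "DGE")
    # single-isoform genes can only be DGE or static
    expect_equal(classifyComparison(1.0, NA), "DGE")
    expect_equal(classifyComparison(0.2, NA), "static")
    expect_error(classifyComparison(1, 1, threshDE = 0.4), "0.5")
    # exactly one category for any probability pair
    for (pde in c(0, 0.5, 0.99, 1)) {
        for (pds in c(0, 0.5, 0.99, 1)) {
            expect_length(classifyComparison(pde, pds), 1L)
        }
    }
})

test_that("cohort aggregation applies the min-cohort and dominance rules", {
    mk <- function(gene, comparison, nDE, nDS, nCoh = 3) {
        # nDE / nDS sub-cohorts called in this comparison
        do.call(rbind, lapply(seq_len(nCoh), function(i) data.frame(
            gene = gene, comparison = comparison, cohort = i,
            category = if (i <= min(nDE, nDS)) "DAST/DGE"
            else if (i <= nDE) "DGE"
            else if (i <= nDS) "DAST" else "static")))
    }
    # s = 6, d = 2 across 8 comparisons -> DAST (6 >= 2*2)
    calls <- do.call(rbind, c(
        lapply(1:6, function(k) mk("gA", paste0("cmp", k), 0, 3)),
        lapply(7:8, function(k) mk("gA", paste0("cmp", k), 3, 0))))
    out <- aggregateCohorts(calls)
    expect_equal(out$group, "DAST")
    expect_equal(out$n_ds, 6); expect_equal(out$n_de, 2)
    # boundary of the 2x rule: d = 6, s = 3 -> DGE
    calls <- do.call(rbind, c(
        lapply(1:6, function(k) mk("gB", paste0("cmp", k), 3, 0)),
        lapply(7:9, function(k) mk("gB", paste0("cmp", k), 0, 3))))
    expect_equal(aggregateCohorts(calls)$group, "DGE")
    # neither dominates -> DAST/DGE
    calls <- do.call(rbind, c(
        lapply(1:3, function(k) mk("gC", paste0("cmp", k), 3, 0)),
        lapply(4:5, function(k) mk("gC", paste0("cmp", k), 0, 3))))
    expect_equal(aggregateCohorts(calls)$group, "DAST/DGE")
    # nothing called -> static; sub-threshold cohorts don't count
    calls <- rbind(mk("gD", "cmp1", 2, 2), mk("gD", "cmp2", 1, 0))
    expect_equal(aggregateCohorts(calls)$group, "static")
})

test_that("the results table has the documented shape", {
    sim <- simulateDataset(simulationConfig(nGenes = 25, seed = 17))
    res <- duetAnalysis(sim$counts, warmup = 150, steps = 600, seed = 17)
    tab <- resultsTable(res)
    expect_named(tab, c("Gene", "Isoform", "log2FC_or_FC",
                        "PosteriorProb", "Category"))
    gl <- tab[tab$Isoform == "Expression", ]
    expect_equal(sort(unique(tab$Gene)), sort(gl$Gene))
    expect_true(all(tab$PosteriorProb >= 0 & tab$PosteriorProb <= 1))
    expect_true(all(tab$Category %in%
                    c("DGE", "DAST", "DAST/DGE", "static")))
    iso <- tab[tab$Isoform != "Expression", ]
    expect_true(all(iso$log2FC_or_FC > 0))
    # isoform rows appear exactly for the retained multi-isoform genes
    x <- filterLowCounts(sim$counts)
    gid <- geneIds(x)
    multiIso <- isoformIds(x)[gid %in% names(which(table(gid) >= 2))]
    expect_setequal(iso$Isoform, multiIso)
    # determinism end to end
    res2 <- duetAnalysis(sim$counts, warmup = 150, steps = 600, seed = 17)
    expect_identical(tab, resultsTable(res2))
})
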