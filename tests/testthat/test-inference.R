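test_that("model inputs carry trends, variances and expression-only blocks", {
    sim <- simulateDataset(simulationConfig(nGenes = 40, seed = 3))
    x <- filterLowCounts(sim$counts)
    mi <- buildModelInputs(x)
    expect_s4_class(mi$geneTrend, "VarianceTrend")
    expect_s4_class(mi$isoformTrend, "VarianceTrend")
    gi <- mi$genes[[1]]
    expect_true(all(gi$vg > 0))
    expect_equal(gi$mu1, mean(gi$yg[!gi$isCase]))
    # a gene reduced to one isoform carries an expression-only block
    one <- x[geneIds(x) == geneIds(x)[1], ][1, ]
    rest <- x[geneIds(x) != geneIds(x)[1], ]
    both <- IsoformExperiment(
        rbind(SummarizedExperiment::assay(one, "counts"),
              SummarizedExperiment::assay(rest, "counts")),
        geneIds = c(geneIds(one), geneIds(rest)),
        condition = as.character(conditionLabels(x)))
    mi1 <- buildModelInputs(both)
    expect_equal(mi1$genes[[1]]$T, 1L)
    expect_equal(nrow(mi1$genes[[1]]$tr), 0L)
})

test_that("chain initialization follows the observed-fractions rule", {
    sim <- simulateDataset(simulationConfig(nGenes = 20, seed = 5))
    mi <- buildModelInputs(filterLowCounts(sim$counts))
    for (gi in mi$genes[1:5]) {
        init <- initializeChain(gi)
        expect_equal(init$beta, 0)
        expect_equal(init$beta0, gi$mu1)
        expect_equal(sum(init$alpha), 1)
        expect_equal(init$alpha, rep(1 / gi$T, gi$T))
        trBar <- rowMeans(gi$tr[, !gi$isCase, drop = FALSE])
        expect_equal(init$p, 2^trBar / sum(2^trBar))
    }
    # worked fraction examples: equal levels and a 2-unit gap
    gi <- mi$genes[[1]]
    gi$T <- 2L
    gi$tr <- matrix(c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3,
                      3, 3, 3, 3, 3, 3, 3, 3, 3, 3), 2, 10, byrow = TRUE)
    gi$isCase <- rep(c(FALSE, TRUE), each = 5)
    expect_equal(initializeChain(gi)$p, c(0.5, 0.5))
    gi$tr[1, ] <- 4; gi$tr[2, ] <- 2
    expect_equal(initializeChain(gi)$p, c(0.8, 0.2))
})

test_that("runMCMC is deterministic given the seed and draws stay on the simplex", {
    sim <- simulateDataset(simulationConfig(nGenes = 15, seed = 8))
    mi <- buildModelInputs(filterLowCounts(sim$counts))
    pd1 <- runMCMC(mi, warmup = 100, steps = 400, seed = 11)
    pd2 <- runMCMC(mi, warmup = 100, steps = 400, seed = 11)
    expect_identical(pd1@draws, pd2@draws)
    pd3 <- runMCMC(mi, warmup = 100, steps = 400, seed = 12)
    expect_false(identical(pd1@draws[[1]]$beta, pd3@draws[[1]]$beta))
    expect_equal(nDraws(pd1), 300L)
    for (d in pd1@draws) {
        expect_length(d$beta, 300L)
        if (!is.null(d$p)) {
            expect_equal(unname(rowSums(d$p)), rep(1, 300),
                         tolerance = 1e-12)
            expect_equal(unname(rowSums(d$alpha)), rep(1, 300),
                         tolerance = 1e-12)
            expect_true(all(d$p > 0) && all(d$alpha > 0))
        }
    }
    expect_error(runMCMC(mi, warmup = 400, steps = 400), "steps > warmup")
})

test_that("the sampler recovers known expression shifts and nulls", {
    # data generated from the model itself: calibration is exact up to MC
    miDE <- modelSimulatedInputs(20, beta = 1, seed = 21)
    pd <- runMCMC(miDE, warmup = 300, steps = 1500, seed = 1)
    postMeans <- vapply(pd@draws, function(d) mean(d$beta), 0)
    expect_lt(abs(mean(postMeans) - 1), 0.1)

    miNull <- modelSimulatedInputs(20, beta = 0, seed = 22)
    pdN <- runMCMC(miNull, warmup = 300, steps = 1500, seed = 1)
    cover <- vapply(pdN@draws, function(d) {
        q <- quantile(d$beta, c(0.005, 0.995))
        q[1] < 0 && q[2] > 0
    }, TRUE)
    expect_gte(sum(cover), 18L)
})

test_that("a known splicing perturbation shifts the alpha posterior", {
    a <- c(0.55, 0.25, 0.20)
    mi <- modelSimulatedInputs(12, beta = 0, alpha = a, sigmaIso = 0.3,
                               seed = 31)
    pd <- runMCMC(mi, warmup = 500, steps = 2500, seed = 2)
    aBar <- colMeans(do.call(rbind, lapply(pd@draws, function(d)
        colMeans(d$alpha))))
    expect_equal(unname(aBar), a, tolerance = 0.08)
})

test_that("the posterior matches an independent JAGS fit of the same model", {
    skip_if_not_installed("rjags")
    mi <- modelSimulatedInputs(1, n = 6L, beta = 0.8, Tiso = 3L,
                               sigmaGene = 0.3, sigmaIso = 0.4, seed = 41)
    gi <- mi$genes[[1]]
    pd <- runMCMC(mi, warmup = 1000, steps = 9000, seed = 3)
    d <- pd@draws[[1]]

    model <- "
    model {
      beta ~ dnorm(0, 0.2)
      beta0 ~ dnorm(mu1, 0.2)
      for (s in 1:n) {
        yg[s] ~ dnorm(beta0 + beta * case[s], 1 / vg[s])
      }
      p ~ ddirch(ones)
      alpha ~ ddirch(ones)
      for (i in 1:T) {
        pk[i] <- p[i] * alpha[i] / inprod(p, alpha)
        for (s in 1:n) {
          m[i, s] <- (case[s] * log(pk[i]) +
                      (1 - case[s]) * log(p[i])) / log(2)
          dIso[i, s] ~ dnorm(m[i, s], 1 / viso[i, s])
        }
      }
    }"
    dIso <- gi$tr - rep(gi$yg, each = gi$T)
    jd <- list(yg = gi$yg, vg = gi$vg, dIso = dIso, viso = gi$viso,
               case = as.numeric(gi$isCase), n = length(gi$yg),
               T = gi$T, mu1 = gi$mu1, ones = rep(1, gi$T))
    jm <- rjags::jags.model(textConnection(model), data = jd,
                            inits = list(.RNG.name = "base::Wichmann-Hill",
                                         .RNG.seed = 7),
                            n.chains = 1, n.adapt = 1000, quiet = TRUE)
    js <- rjags::jags.samples(jm, c("beta", "beta0", "p", "alpha"),
                              n.iter = 8000, progress.bar = "none")
    expect_equal(mean(d$beta), mean(as.vector(js$beta)), tolerance = 0.05)
    expect_equal(sd(d$beta), sd(as.vector(js$beta)), tolerance = 0.05)
    expect_equal(mean(d$beta0), mean(as.vector(js$beta0)),
                 tolerance = 0.05)
    expect_equal(colMeans(d$p), apply(js$p, 1, mean),
                 tolerance = 0.04, ignore_attr = TRUE)
    expect_equal(colMeans(d$alpha), apply(js$alpha, 1, mean),
                 tolerance = 0.04, ignore_attr = TRUE)
})

test_that("the Geweke diagnostic separates stationary from drifting chains", {
    set.seed(9)
    # iid chains: |z| moderate, p roughly uniform
    zs <- ps <- numeric(100)
    for (r in 1:100) {
        g <- gewekeDiagnostic(rnorm(10000))
        zs[r] <- g$z; ps[r] <- g$p
    }
    expect_true(all(abs(zs) < 4.5))
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
    # linear drift is detected emphatically
    drift <- gewekeDiagnostic(seq(0, 5, length.out = 10000) + rnorm(10000))
    expect_lt(drift$p, 1e-6)
    # constant chain: NA with warning
    expect_warning(out <- gewekeDiagnostic(rep(1, 1000)), "degenerate")
    expect_true(is.na(out$z))
    expect_error(gewekeDiagnostic(rnorm(1000), 0.6, 0.5), "firstFrac")
})

test_that("Geweke summary over PosteriorDraws reports a BH fraction", {
    sim <- simulateDataset(simulationConfig(nGenes = 10, seed = 13))
    mi <- buildModelInputs(filterLowCounts(sim$counts))
    pd <- runMCMC(mi, warmup = 500, steps = 3000, seed = 4)
    g <- gewekeDiagnostic(pd)
    expect_true(all(c("gene", "parameter", "z", "p") %in%
                    colnames(g$table)))
    expect_gte(g$nTested, 10L)
    expect_true(g$fracSignificant >= 0 && g$fracSignificant <= 1)
})
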