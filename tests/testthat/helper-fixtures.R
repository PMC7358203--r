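# Small fixtures built in code, shared across test files.

# deterministic toy experiment: 2 genes (3 + 2 isoforms), 2 + 2 samples
toyExperiment <- function() {
    cts <- matrix(c(10, 12, 30, 28,
                    20, 18, 10, 12,
                    5,  6,  5,  7,
                    40, 38, 42, 39,
                    15, 14, 60, 55),
                  nrow = 5, byrow = TRUE,
                  dimnames = list(paste0("iso", 1:5),
                                  c("c1", "c2", "k1", "k2")))
    IsoformExperiment(cts,
                      geneIds = c("g1", "g1", "g1", "g2", "g2"),
                      condition = c("control", "control", "case", "case"))
}

# write a toy counts TSV and return its path
toyCountsTsv <- function(dir = tempdir()) {
    path <- file.path(dir, "toy_counts.tsv")
    writeLines(c("Gene\tIsoform\ts1\ts2\ts3\ts4",
                 "g1\ti1\t10\t12\t30\t28",
                 "g1\ti2\t20\t18\t10\t12",
                 "g2\ti3\t5\t6\t5\t7"), path)
    path
}

# model inputs for synthetic genes generated FROM the model itself:
# Normal observations with known variances, beta/alpha as requested.
# Used for sampler-calibration checks.
modelSimulatedInputs <- function(nGenes, n = 5L, beta = 0, Tiso = 3L,
                                 sigmaGene = 0.3, sigmaIso = 0.5,
                                 alpha = NULL, seed = 1L) {
    set.seed(seed)
    isCase <- rep(c(FALSE, TRUE), each = n)
    genes <- lapply(seq_len(nGenes), function(k) {
        mu <- runif(1, 5, 12)
        p <- as.vector(rgamma(Tiso, 2))
        p <- p / sum(p)
        a <- if (is.null(alpha)) rep(1 / Tiso, Tiso) else alpha
        pk <- p * a / sum(p * a)
        yg <- mu + beta * isCase + rnorm(2L * n, 0, sigmaGene)
        frac <- outer(log2(p), rep(1, n))
        frack <- outer(log2(pk), rep(1, n))
        tr <- cbind(rep(yg[!isCase], each = Tiso) + frac,
                    rep(yg[isCase], each = Tiso) + frack) +
            rnorm(Tiso * 2L * n, 0, sigmaIso)
        tr <- matrix(tr, nrow = Tiso)
        list(gene = sprintf("g%03d", k), T = Tiso,
             isoform_ids = sprintf("g%03d.i%d", k, seq_len(Tiso)),
             yg = yg, vg = rep(sigmaGene^2, 2L * n),
             tr = tr, viso = matrix(sigmaIso^2, Tiso, 2L * n),
             mu1 = mean(yg[!isCase]), isCase = isCase,
             true = list(beta = beta, p = p, alpha = a))
    })
    names(genes) <- vapply(genes, `[[`, "", "gene")
    list(genes = genes, condition = factor(
        rep(c("control", "case"), each = n),
        levels = c("control", "case")))
}
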