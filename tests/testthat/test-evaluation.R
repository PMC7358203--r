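test_that("isoform proportions divide by the rest of the gene", {
    cts <- matrix(c(2, 4, 1, 8,
                    2, 1, 3, 2,
                    0, 5, 5, 5,
                    7, 7, 7, 7), nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("i", 1:4), NULL))
    ie <- IsoformExperiment(cts, geneIds = c("a", "a", "a", "b"),
                            condition = c("control", "control",
                                          "case", "case"))
    pr <- isoformProportions(ie)
    # counts (2, 2, 0) in sample 1: 2/2, 2/2, 0/4
    expect_equal(unname(pr[, 1]), c(2 / 2, 2 / 2, 0 / 4))
    # single-isoform gene b is excluded
    expect_false("i4" %in% rownames(pr))
    # zero complement yields NA
    cts2 <- matrix(c(3, 3, 3, 3,
                     0, 0, 2, 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c("x1", "x2"), NULL))
    ie2 <- IsoformExperiment(cts2, geneIds = c("g", "g"),
                             condition = c("control", "control",
                                           "case", "case"))
    pr2 <- isoformProportions(ie2)
    expect_true(all(is.na(pr2["x1", 1:2])))
    expect_equal(unname(pr2["x2", 1:2]), c(0, 0))
    # permuting isoform order permutes rows identically
    prP <- isoformProportions(ie[c(2, 1, 3, 4), ])
    expect_equal(prP[c("i1", "i2", "i3"), ], pr[c("i1", "i2", "i3"), ])
})

test_that("grid PR curve matches the brute-force oracle", {
    # hand-enumerable 6-item instance
    scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
    flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
    pc <- prCurve(scores, flags)
    expect_equal(auprc(pc), bruteForcePR(scores, flags))
    # hand value: envelope points (1/3,1), (2/3,1), (3/4? ...) checked
    # against cumulative counts at the six cuts
    expect_equal(auprc(pc), 1 / 3 * 1 + 1 / 3 * 1 +
                     1 / 3 * (1 + 3 / 4) / 2, tolerance = 1e-12)
    # random instances up to 100 items agree exactly
    set.seed(14)
    for (i in 1:20) {
        n <- sample(10:100, 1)
        s <- round(runif(n), 3)   # scores on the 1e-4 grid
        f <- runif(n) < 0.3
        if (!any(f)) f[1] <- TRUE
        expect_equal(auprc(prCurve(s, f)), bruteForcePR(s, f),
                     tolerance = 1e-12)
    }
    # degenerate cases
    expect_error(prCurve(c(0.1, 0.2), c(FALSE, FALSE)),
                 "no true positives")
    expect_error(prCurve(c(2, 0.5), c(TRUE, FALSE)), "0, 1")
    flat <- prCurve(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
    # all scores identical: single operating point at prevalence
    expect_equal(max(flat@precision, na.rm = TRUE), 0.3)
    # perfect scores: area 1
    expect_equal(auprc(prCurve(as.numeric(flags), flags)), 1)
})

test_that("OSTP picks the best cutoff per false-positive count", {
    sim <- simulateDataset(simulationConfig(nGenes = 150, seed = 31))
    x <- filterLowCounts(sim$counts)
    oc <- ostpCurve(x, sim$truth)
    expect_s4_class(oc, "PRCurve")
    expect_true(all(oc@precision >= 0 & oc@precision <= 1))
    expect_true(auprc(oc) > 0 && auprc(oc) <= 1)
    # brute-force oracle: enumerate every |t| cutoff, take the maximum
    # TP for each achievable FP count
    set.seed(33)
    for (i in 1:10) {
        n <- sample(20:100, 1)
        s <- c(abs(rnorm(n)), abs(rnorm(5)))          # with ties
        s <- sample(round(s, 1))
        f <- runif(length(s)) < 0.3
        if (!any(f)) f[1] <- TRUE
        op <- duet:::ostpOperatingPoints(s, f)
        brute <- t(vapply(sort(unique(s)), function(thr) {
            called <- s >= thr
            c(tp = sum(called & f), fp = sum(called & !f))
        }, c(tp = 0, fp = 0)))
        bruteBest <- tapply(brute[, "tp"], brute[, "fp"], max)
        expect_equal(unname(op$tp),
                     as.numeric(bruteBest[as.character(op$fp)]))
        # every achievable FP count of the enumeration is represented
        expect_setequal(op$fp, unique(brute[, "fp"]))
    }
    # perfectly separated statistics: precision 1 at recall 1
    sep <- duet:::ostpOperatingPoints(c(10, 10, 0.1, 0.1),
                                      c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(sep$tp[sep$fp == 0], 2)
})

test_that("permuted labels drive OSTP precision to prevalence", {
    sim <- simulateDataset(simulationConfig(nGenes = 300, seed = 41))
    x <- filterLowCounts(sim$counts)
    real <- auprc(ostpCurve(x, sim$truth))
    set.seed(42)
    prev <- mean(duet:::truthSplicingFlags(sim$truth)[
        rownames(isoformProportions(x))], na.rm = TRUE)
    perms <- replicate(5, {
        xp <- x[, sample(ncol(x))]
        xp$condition <- conditionLabels(x)  # labels fixed, data permuted
        suppressWarnings(auprc(ostpCurve(xp, sim$truth)))
    })
    expect_gt(real, max(perms))
    expect_lt(mean(perms), prev * 3)
})

test_that("mean PR curve smooths, imputes and averages", {
    mkCurve <- function(prec, rec)
        new("PRCurve", threshold = numeric(), precision = prec,
            recall = rec, auprc = duet:::trapezoidAuprc(rec, prec))
    r <- seq(0, 1, by = 0.05)
    c1 <- mkCurve(rep(0.8, length(r)), r)
    c2 <- mkCurve(rep(0.4, length(r)), r)
    m <- meanPRCurve(list(c1, c2))
    expect_equal(unname(m@precision), rep(0.6, length(m@recall)),
                 tolerance = 1e-6)
    # identical inputs: mean equals the (smoothed) input
    m2 <- meanPRCurve(list(c1, c1))
    expect_equal(unname(m2@precision), rep(0.8, length(m2@recall)),
                 tolerance = 1e-6)
    # imputation carries the nearest lower recall value
    rShort <- seq(0, 0.8, by = 0.05)
    c3 <- mkCurve(0.9 - 0.5 * rShort, rShort)
    m3 <- meanPRCurve(list(c3, c3), recallGrid = c(0.5, 0.9))
    expect_equal(m3@precision[2], m3@precision[1] -
                     0.5 * 0.3, tolerance = 0.05)
    expect_error(meanPRCurve(list(c1)), "length")
})

test_that("t-test scores rank a strong expression shift first", {
    sim <- simulateDataset(simulationConfig(nGenes = 200, seed = 51))
    x <- filterLowCounts(sim$counts)
    sc <- deTTestScores(x)
    tg <- truthGenes(sim$truth)
    flags <- tg$is_de[match(names(sc), tg$gene)]
    expect_true(all(sc >= 0 & sc <= 1, na.rm = TRUE))
    expect_gt(auprc(prCurve(sc[!is.na(sc)], flags[!is.na(sc)])), 0.7)
})
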