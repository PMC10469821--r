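test_that("the differential abundance test behaves at its edges", {
    # identical groups: one-sided p >= 0.5
    expect_gte(diffAbundanceTest(c(1, 2, 3), c(1, 2, 3)), 0.5)
    # constant equal values: p = 1 by convention
    expect_identical(diffAbundanceTest(c(5, 5, 5), c(5, 5, 5)), 1)
    # strong separation with low variance
    expect_lt(diffAbundanceTest(c(100, 110, 105), c(1, 1.1, 0.9)), 0.01)
    # wrong-direction shift is not significant
    expect_gt(diffAbundanceTest(c(1, 1.1, 0.9), c(100, 110, 105)), 0.5)
    expect_error(diffAbundanceTest(1, c(1, 2)), "at least 2")
})

sim_for_windows <- function(seed = 21, cv = 0.1, afe = 0.32) {
    g <- defaultGenomePanel(nUnlabeled = 8, labeledAfe = afe)
    sim <- simulateSipExperiment(simConfig(genomes = g,
                                           coverageNoiseCv = cv,
                                           seed = seed))
    scaleToAbsolute(sim, fitScalingModels(sim))
}

test_that("HR-SIP labels the shifted genome and not the unshifted ones", {
    ab <- sim_for_windows()
    d <- validateDesign(ab)
    calls <- hrSip(ab, d)
    expect_true(calls$labeled[calls$genome_id == "FOCAL"])
    expect_identical(calls$window_low[1], 1.71)
    expect_equal(calls$window_high[1], 1.77)  # max treatment density
    expect_error(hrSip(ab, d, window = c(1.80, 1.85)), "empty heavy window")
})

test_that("sparsity filtering excludes genomes below the presence cutoff", {
    # gA present in 20% of window fractions -> untestable at s = 0.25
    set.seed(1)
    cov <- matrix(stats::rexp(40) + 1, 2, 20,
                  dimnames = list(c("gA", "gB"),
                                  c(sprintf("C1_F%02d", 1:5),
                                    sprintf("C2_F%02d", 1:5),
                                    sprintf("T1_F%02d", 1:5),
                                    sprintf("T2_F%02d", 1:5))))
    cov["gA", ] <- 0
    cov["gA", c("C1_F01", "C2_F01", "T1_F01", "T2_F01")] <- 1  # 4/20
    fm <- do.call(rbind, mapply(function(s, cond)
        make_fraction_meta(s, cond, K = 5,
                           densities = seq(1.71, 1.76, length.out = 5)),
        c("C1", "C2", "T1", "T2"),
        c("control", "control", "treatment", "treatment"),
        SIMPLIFY = FALSE))
    se <- sipExperiment(cov, fm, assayName = "abundance")
    d <- validateDesign(se)
    calls <- hrSip(se, d, window = c(1.71, 1.76), sparsityGrid = 0.25)
    expect_true(is.na(calls$p_adj[calls$genome_id == "gA"]))
    expect_false(is.na(calls$p_adj[calls$genome_id == "gB"]))
})

test_that("MW-HR-SIP finds the labeled genome and records its window", {
    ab <- sim_for_windows()
    d <- validateDesign(ab)
    calls <- mwHrSip(ab, d)
    hit <- calls[calls$genome_id == "FOCAL", ]
    expect_true(hit$labeled)
    expect_false(is.na(hit$window_low))
    expect_false(any(calls$labeled[calls$genome_id != "FOCAL"]))

    # agreement with HR-SIP on a strongly labeled, low-noise genome
    hr <- hrSip(ab, d)
    expect_identical(hr$labeled[hr$genome_id == "FOCAL"],
                     hit$labeled)
})

test_that("coverage filtering is inclusive and monotone", {
    cov <- matrix(0, 2, 12,
                  dimnames = list(c("gA", "gB"),
                                  c(sprintf("C1_F%02d", 1:4),
                                    sprintf("C2_F%02d", 1:4),
                                    sprintf("C3_F%02d", 1:4))))
    # per-sample totals gA: 12, 8, 10 (mean 10); gB: 1, 1, 1
    cov["gA", c(1, 5, 9)] <- c(12, 8, 10)
    cov["gB", c(1, 5, 9)] <- 1
    fm <- do.call(rbind, lapply(c("C1", "C2", "C3"), function(s)
        make_fraction_meta(s, "control", K = 4)))
    fm$condition[fm$sample_id == "C3"] <- "treatment"
    se <- sipExperiment(cov, fm)
    d <- validateDesign(se)
    expect_identical(coverageFilter(se, d, 10), "gA")  # boundary inclusive
    expect_identical(coverageFilter(se, d, 0), c("gA", "gB"))
    # raising the threshold never grows the kept set
    k1 <- coverageFilter(se, d, 5); k2 <- coverageFilter(se, d, 11)
    expect_true(all(k2 %in% k1))
})

test_that("the minimum-AFE labeling rule compares the lower CI bound", {
    est <- data.frame(genome_id = c("a", "b", "c"),
                      ci_low = c(0.03, -0.01, 0.03),
                      ci_high = c(0.09, 0.05, 0.09))
    expect_identical(unname(afeThresholdCall(est, 0.02)),
                     c(TRUE, FALSE, TRUE))
    expect_identical(unname(afeThresholdCall(est, 0)[2]), FALSE)
    expect_identical(unname(afeThresholdCall(est, 0.06)),
                     c(FALSE, FALSE, FALSE))
})

test_that("the sequential workflow confirms true positives both ways", {
    ab <- sim_for_windows(seed = 31, cv = 0.15)
    d <- validateDesign(ab)
    res <- sequentialWorkflow(ab, d, nBoot = 300, seed = 5)
    expect_identical(res$genome_id[res$labeled], "FOCAL")
    expect_true(res$stage1_labeled[res$genome_id == "FOCAL"])

    # stage-2 intervals under reduced-set adjustment are no wider than
    # under full-set FCR adjustment with the same draws
    full <- adjustCI(estimateAFE(ab, d, nBoot = 300, seed = 5),
                     "fcr", q = 0.05)
    i <- which(res$genome_id == "FOCAL")
    j <- which(full$genome_id == "FOCAL")
    expect_lte(res$ci_high[i] - res$ci_low[i],
               full$ci_high[j] - full$ci_low[j] + 1e-12)
})

test_that("an all-unlabeled community yields an empty sequential call set", {
    empty <- 0L
    for (sd in 1:6) {
        g <- defaultGenomePanel(nUnlabeled = 14, labeledAfe = 0)
        sim <- simulateSipExperiment(simConfig(genomes = g,
                                               coverageNoiseCv = 0.2,
                                               seed = 40 + sd))
        ab <- scaleToAbsolute(sim, fitScalingModels(sim))
        res <- sequentialWorkflow(ab, validateDesign(ab), nBoot = 200,
                                  seed = sd)
        if (!any(res$labeled)) empty <- empty + 1L
        if (!any(res$stage1_labeled))
            expect_match(attr(res, "note"), "no candidates")
    }
    expect_gte(empty, 5L)
})

test_that("consensus combines call sets by intersection or union", {
    a <- data.frame(genome_id = c("x", "y", "z"),
                    labeled = c(TRUE, TRUE, FALSE))
    b <- data.frame(genome_id = c("z", "y", "x"),
                    labeled = c(TRUE, TRUE, FALSE))
    expect_identical(consensusCalls(a, b)$labeled, c(FALSE, TRUE, FALSE))
    expect_identical(consensusCalls(a, b, "union")$labeled,
                     c(TRUE, TRUE, TRUE))
    none <- a; none$labeled <- FALSE
    expect_false(any(consensusCalls(a, none)$labeled))
    expect_error(consensusCalls(a, b[1:2, ]), "different genomes")
})

test_that("performance metrics reproduce direct confusion counting", {
    calls <- data.frame(genome_id = paste0("g", 1:4),
                        labeled = c(TRUE, TRUE, FALSE, FALSE))
    pm <- performanceMetrics(calls, truth = c("g1", "g3"))
    expect_identical(pm$true_positives, 1L + 0L)
    expect_equal(pm$specificity, 1 / 2)
    expect_equal(pm$sensitivity, 1 / 2)
    expect_equal(pm$balanced_accuracy, 0.5)

    # perfect calls
    pm2 <- performanceMetrics(calls, truth = c("g1", "g2"))
    expect_equal(unlist(pm2[, c("specificity", "sensitivity",
                                "balanced_accuracy")]),
                 c(specificity = 1, sensitivity = 1,
                   balanced_accuracy = 1))

    # all-negative calls with a positive truth
    none <- calls; none$labeled <- FALSE
    pm3 <- performanceMetrics(none, truth = "g1")
    expect_equal(pm3$sensitivity, 0)
    expect_equal(pm3$specificity, 1)
    expect_equal(pm3$balanced_accuracy, 0.5)

    # identities hold on random confusion tables (oracle: direct counting)
    set.seed(17)
    for (i in 1:20) {
        n <- sample(5:60, 1)
        lab <- stats::runif(n) < 0.4
        tru <- stats::runif(n) < 0.3
        ids <- paste0("g", seq_len(n))
        pm <- performanceMetrics(
            data.frame(genome_id = ids, labeled = lab),
            truth = ids[tru])
        tp <- sum(lab & tru); fp <- sum(lab & !tru)
        fn <- sum(!lab & tru); tn <- sum(!lab & !tru)
        expect_identical(c(pm$true_positives, pm$false_positives,
                           pm$true_negatives, pm$false_negatives),
                         c(tp, fp, tn, fn))
        if (fp + tn > 0) expect_equal(pm$specificity, tn / (fp + tn))
        if (tp + fn > 0) expect_equal(pm$sensitivity, tp / (tp + fn))
    }
})
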