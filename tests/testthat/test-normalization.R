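test_that("the CoV gate keeps and removes concentration groups correctly", {
    # identical coverages: CoV 0, retained
    cv0 <- c(a = 5, b = 5, c = 5)
    expect_identical(filterSequinsByCoV(cv0, rep("g1", 3)),
                     c("a", "b", "c"))

    # CoV({1,1,100}) = 100*sd/mean = 168.1% <= 250: retained
    cvA <- c(a = 1, b = 1, c = 100)
    expect_identical(filterSequinsByCoV(cvA, rep("g1", 3)),
                     c("a", "b", "c"))

    # seven-member group {0,...,0,50}: CoV = 264.6% > 250: removed;
    # the surviving group keeps the fit alive
    cvB <- c(stats::setNames(c(rep(0, 6), 50), paste0("z", 1:7)),
             d = 10, e = 11, f = 9)
    groups <- c(rep("bad", 7), rep("good", 3))
    expect_identical(filterSequinsByCoV(cvB, groups), c("d", "e", "f"))
    # oracle arithmetic for the removed group
    expect_gt(100 * stats::sd(cvB[1:7]) / mean(cvB[1:7]), 250)

    expect_error(
        filterSequinsByCoV(stats::setNames(c(rep(0, 6), 50),
                                           paste0("z", 1:7)),
                           rep("bad", 7)),
        "insufficient sequins")
})

test_that("sequin regression recovers exact linear data", {
    cov <- c(s1 = 1, s2 = 2, s3 = 4, s4 = 8, s5 = 16)
    m <- fitSequinRegression(cov, 2 * cov, logTransform = FALSE)
    expect_equal(m@slope, 2, tolerance = 1e-12)
    expect_equal(m@intercept, 0, tolerance = 1e-12)
    expect_equal(m@rSquared, 1)
    expect_identical(m@nPointsUsed, 5L)

    # log-log fit recovers an exact power law
    ml <- fitSequinRegression(cov, 3 * cov, logTransform = TRUE)
    expect_equal(ml@slope, 1, tolerance = 1e-10)
    expect_equal(10^ml@intercept, 3, tolerance = 1e-10)
})

test_that("Cook's-distance filtering removes a gross outlier and refits", {
    cov <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 5, s6 = 6, s7 = 7,
             out = 6)
    conc <- 2 * cov
    conc["out"] <- 42  # +30 off the conc = 2*cov line; Cook D ~ 0.86
    m <- fitSequinRegression(cov, conc, cooksFilter = TRUE,
                             logTransform = FALSE)
    expect_true("out" %in% m@removedSequinIds)
    expect_equal(m@slope, 2, tolerance = 1e-10)
    expect_equal(m@intercept, 0, tolerance = 1e-9)

    # without the filter the fit is dragged off the line
    m0 <- fitSequinRegression(cov, conc, cooksFilter = FALSE,
                              logTransform = FALSE)
    expect_gt(abs(m0@slope - 2) + abs(m0@intercept), 0.5)

    # the alternative n/4 cutoff reading removes nothing here
    m2 <- fitSequinRegression(cov, conc, cooksFilter = TRUE,
                              cooksCutoff = "n/4", logTransform = FALSE)
    expect_length(m2@removedSequinIds, 0)
})

test_that("degenerate regressions are refused", {
    expect_error(fitSequinRegression(c(a = 1, b = 2), c(2, 4)),
                 "at least 3")
    expect_error(fitSequinRegression(c(a = 1, b = 1, c = 1), c(1, 2, 3),
                                     logTransform = FALSE),
                 "zero variance")
})

test_that("scaleToAbsolute applies models, clamps, and drops standards", {
    cov <- matrix(c(0, 2, 10, 0.1,
                    4, 1, 10, 0.1), 4, 2,
                  dimnames = list(c("gA", "gB", "SEQ1", "SPK1"),
                                  c("C1_F01", "C1_F02")))
    fm <- make_fraction_meta("C1", K = 2)
    se <- sipExperiment(cov, fm,
        sequinRef = data.frame(sequin_id = "SEQ1", concentration = 1,
                               group = "g"),
        spikeinRef = data.frame(spikein_id = "SPK1",
                                expected_peak_density = 1.71, gc = 0.5,
                                label_fraction = 0))
    mk <- function(lib, slope, b) new("ScalingModel", libraryId = lib,
        slope = slope, intercept = b, rSquared = 1, nPointsUsed = 3L,
        removedSequinIds = character(0), method = "ols",
        logTransform = FALSE)
    models <- list(C1_F01 = mk("C1_F01", 2, 0),
                   C1_F02 = mk("C1_F02", 1, -2))
    ab <- scaleToAbsolute(se, models)
    expect_identical(rownames(ab), c("gA", "gB"))  # standards dropped
    expect_identical(abundanceMethod(ab), "sequin")
    expect_equal(abundanceMatrix(ab)["gA", "C1_F01"], 0)   # 2*0 + 0
    expect_equal(abundanceMatrix(ab)["gB", "C1_F01"], 4)   # 2*2 + 0
    expect_equal(abundanceMatrix(ab)["gA", "C1_F02"], 2)   # 1*4 - 2
    expect_equal(abundanceMatrix(ab)["gB", "C1_F02"], 0)   # 1*1 - 2 clamped

    expect_error(scaleToAbsolute(se, models["C1_F01"]), "no scaling model")
})

test_that("positive-slope scaling preserves within-library rank order", {
    set.seed(11)
    cov <- matrix(stats::rexp(40), 10, 4,
                  dimnames = list(paste0("g", 1:10),
                                  sprintf("C1_F%02d", 1:4)))
    se <- make_tiny_experiment(cov, samples = list(C1 = "control"), K = 4)
    models <- lapply(sprintf("C1_F%02d", 1:4), function(l)
        new("ScalingModel", libraryId = l, slope = stats::runif(1, 0.5, 3),
            intercept = stats::runif(1, 0, 1), rSquared = 1,
            nPointsUsed = 3L, removedSequinIds = character(0),
            method = "ols", logTransform = FALSE))
    names(models) <- sprintf("C1_F%02d", 1:4)
    ab <- scaleToAbsolute(se, models)
    for (l in colnames(cov))
        expect_identical(order(abundanceMatrix(ab)[, l]),
                         order(cov[, l]))
})

test_that("relative coverage sums to one over genomes", {
    cov <- matrix(c(3, 1, 5,
                    2, 2, 4), 3, 2,
                  dimnames = list(c("gA", "gB", "SEQ1"),
                                  c("C1_F01", "C1_F02")))
    fm <- make_fraction_meta("C1", K = 2)
    se <- sipExperiment(cov, fm,
        sequinRef = data.frame(sequin_id = "SEQ1", concentration = 1,
                               group = "g"))
    rc <- relativeCoverage(se)
    expect_equal(abundanceMatrix(rc)[, "C1_F01"], c(gA = 0.75, gB = 0.25))
    expect_equal(unname(colSums(abundanceMatrix(rc))), c(1, 1))
    expect_identical(abundanceMethod(rc), "rel_coverage")

    set.seed(3)
    for (i in 1:5) {
        r <- matrix(stats::rexp(12) * rbinom(12, 1, 0.8), 3, 4,
                    dimnames = list(paste0("g", 1:3),
                                    sprintf("C1_F%02d", 1:4)))
        r[1, ] <- r[1, ] + 0.01   # keep columns non-degenerate
        ser <- make_tiny_experiment(r, samples = list(C1 = "control"))
        expect_equal(unname(colSums(abundanceMatrix(
            relativeCoverage(ser)))), rep(1, 4))
    }

    covz <- cov; covz[c(1, 2), 2] <- 0
    sez <- sipExperiment(covz, fm,
        sequinRef = data.frame(sequin_id = "SEQ1", concentration = 1,
                               group = "g"))
    expect_error(relativeCoverage(sez), "C1_F02")
})

test_that("DNA-based abundance uses the right weights", {
    cov <- matrix(c(2, 2), 2, 1, dimnames = list(c("gA", "gB"), "C1_F01"))
    fm <- make_fraction_meta("C1", K = 1, densities = 1.71, dna_conc = 8)
    gm <- data.frame(genome_id = c("gA", "gB"), gc = 0.5,
                     length_bp = c(1e6, 3e6))
    se <- sipExperiment(cov, fm, genomeMeta = gm)

    # equal coverage, lengths 1:3 -> relative abundance weights 0.25/0.75
    ra <- abundanceByDNA(se, basis = "relative_abundance")
    expect_equal(abundanceMatrix(ra)[, 1], c(gA = 2, gB = 6))
    expect_identical(abundanceMethod(ra), "relabund_x_dna")

    # relative coverage 0.5 each x dna 8 -> 4 each
    rc <- abundanceByDNA(se, basis = "relative_coverage")
    expect_equal(abundanceMatrix(rc)[, 1], c(gA = 4, gB = 4))
    expect_identical(abundanceMethod(rc), "relcov_x_dna")

    # worked example: relative coverage 0.25 at dna_conc 8 -> 2
    cov2 <- matrix(c(1, 3), 2, 1,
                   dimnames = list(c("gA", "gB"), "C1_F01"))
    se2 <- sipExperiment(cov2, fm, genomeMeta = gm)
    expect_equal(
        abundanceMatrix(abundanceByDNA(se2, "relative_coverage"))["gA", 1],
        2)

    # zero dna_conc zeroes the library
    fm0 <- fm; fm0$dna_conc <- 0
    se0 <- sipExperiment(cov, fm0, genomeMeta = gm)
    expect_equal(unname(
        abundanceMatrix(abundanceByDNA(se0, "relative_coverage"))[, 1]),
        c(0, 0))
})

test_that("noiseless simulated data is recovered exactly by sequin scaling", {
    cfg <- simConfig(seed = 5)  # coverageNoiseCv 0
    sim <- simulateSipExperiment(cfg)
    ab <- scaleToAbsolute(sim, fitScalingModels(sim))
    # per-sample abundance totals equal each genome's configured total mass
    fm <- fractionData(ab)
    m <- abundanceMatrix(ab)
    for (s in unique(fm$sample_id)) {
        tot <- rowSums(m[, fm$library_id[fm$sample_id == s]])
        expect_equal(unname(tot), cfg$genomes$total_abundance,
                     tolerance = 1e-8)
    }
})
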