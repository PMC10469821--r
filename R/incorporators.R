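#' One-sided differential abundance test between treatment and control
#'
#' Default backend for HR-SIP style window testing: a one-sided Welch
#' (unequal-variance) two-sample t-test for treatment > control on
#' log1p-transformed abundances. If both groups are constant the test is
#' degenerate: p = 1 when the treatment mean does not exceed the control
#' mean, p = 0 otherwise. The backend is pluggable: any function taking
#' two numeric vectors (treatment, control) and returning a p-value for the
#' one-sided greater alternative can replace it.
#'
#' @param treat,ctrl abundances (e.g. per-sample totals over the heavy
#'   window) in treatment and control.
#' @return p-value in \[0, 1\].
#' @examples
#' diffAbundanceTest(c(100, 120, 110), c(1, 2, 1.5))
#' @export
diffAbundanceTest <- function(treat, ctrl) {
    if (length(treat) < 2L || length(ctrl) < 2L)
        stop("need at least 2 values per group")
    lt <- log1p(treat); lc <- log1p(ctrl)
    if (stats::sd(lt) == 0 && stats::sd(lc) == 0)
        return(if (mean(lt) > mean(lc)) 0 else 1)
    tryCatch(
        stats::t.test(lt, lc, alternative = "greater",
                      var.equal = FALSE)$p.value,
        error = function(e) {
            # numerically constant data: fall back to the mean comparison
            if (grepl("constant", conditionMessage(e)))
                return(if (mean(lt) > mean(lc)) 0 else 1)
            stop(e)
        })
}

.window_libs <- function(fm, window) {
    fm$library_id[fm$density >= window[1L] & fm$density <= window[2L]]
}

# per-genome presence fraction and per-sample window totals for one window
.window_stats <- function(ab, fm, design, window) {
    libs <- .window_libs(fm, window)
    if (!length(libs))
        stop(sprintf("empty heavy window [%.3f, %.3f]: no fraction falls ",
                     window[1L], window[2L]), "inside it")
    samples <- c(controlSamples(design), treatmentSamples(design))
    for (s in samples)
        if (!length(intersect(libs, fm$library_id[fm$sample_id == s])))
            stop(sprintf("window [%.3f, %.3f] overlaps no fraction of %s",
                         window[1L], window[2L], s))
    m <- ab[, libs, drop = FALSE]
    presence <- rowMeans(m > 0)
    totals <- vapply(samples, function(s) {
        sl <- intersect(libs, fm$library_id[fm$sample_id == s])
        rowSums(m[, sl, drop = FALSE])
    }, numeric(nrow(m)))
    list(presence = presence, totals = totals)
}

.window_pvalues <- function(ws, design, testFun) {
    trt <- treatmentSamples(design); ctrl <- controlSamples(design)
    if (length(trt) < 2L || length(ctrl) < 2L)   # untestable design
        return(rep(NA_real_, nrow(ws$totals)))
    apply(ws$totals, 1L, function(tot)
        testFun(tot[trt], tot[ctrl]))
}

#' HR-SIP: incorporator identification in a single heavy window
#'
#' Tests each genome for higher absolute abundance in the heavy
#' buoyant-density window of the treatment gradients than of the control
#' gradients. Genomes must be present (abundance > 0) in more than the
#' sparsity threshold's share of window fractions to be tested; the whole
#' sparsity grid is scanned and the threshold yielding the greatest number
#' of Benjamini-Hochberg rejections is selected for the final calls.
#'
#' @param x a [SipExperiment-class] holding an abundance assay.
#' @param design a [SampleDesign-class].
#' @param window `c(low, high)` heavy window in g/mL. Default: 1.71 to the
#'   maximum observed density among treatment fractions.
#' @param sparsityGrid presence thresholds scanned (fractions, default 0 to
#'   0.30 by 0.05).
#' @param alpha BH-adjusted significance threshold.
#' @param testFun two-group test backend, see [diffAbundanceTest()].
#' @return data.frame per genome: `genome_id`, `method`, `p_value`,
#'   `p_adj` (`NA` when untestable at the chosen sparsity), `labeled`,
#'   `sparsity_used`, `window_low`, `window_high`.
#' @export
hrSip <- function(x, design, window = NULL,
                  sparsityGrid = seq(0, 0.30, by = 0.05), alpha = 0.05,
                  testFun = diffAbundanceTest) {
    fm <- fractionData(x)
    if (is.null(window)) {
        trt_libs <- fm$sample_id %in% treatmentSamples(design)
        window <- c(1.71, max(fm$density[trt_libs]))
    }
    ab <- abundanceMatrix(x, type = "genome")
    ws <- .window_stats(ab, fm, design, window)
    p <- .window_pvalues(ws, design, testFun)

    best <- NULL
    for (s in sparsityGrid) {
        testable <- ws$presence > s
        if (!any(testable)) next
        padj <- rep(NA_real_, length(p))
        padj[testable] <- stats::p.adjust(p[testable], method = "BH")
        nrej <- sum(padj <= alpha, na.rm = TRUE)
        if (is.null(best) || nrej > best$nrej)
            best <- list(s = s, padj = padj, nrej = nrej)
    }
    if (is.null(best))
        stop("no genome testable at any sparsity threshold")
    data.frame(genome_id = rownames(ab), method = "hrsip", p_value = p,
               p_adj = best$padj,
               labeled = !is.na(best$padj) & best$padj <= alpha,
               sparsity_used = best$s, window_low = window[1L],
               window_high = window[2L], row.names = NULL)
}

#' MW-HR-SIP: incorporator identification over overlapping heavy windows
#'
#' Runs the HR-SIP test in several overlapping heavy windows (defaults:
#' 1.71-1.74, 1.72-1.75 and 1.73-1.76 g/mL). For each sparsity threshold,
#' p-values are BH-adjusted across the testable genomes of each window
#' separately; the threshold with the greatest number of significant
#' genomes is selected. A genome is labeled when significant in any window;
#' the most significant window is recorded.
#'
#' @inheritParams hrSip
#' @param windows list of `c(low, high)` windows in g/mL.
#' @return data.frame per genome: `genome_id`, `method`, `p_value` (best
#'   across windows), `p_adj`, `labeled`, `sparsity_used`, `window_low`,
#'   `window_high` (the most significant window; `NA` when untestable).
#' @export
mwHrSip <- function(x, design,
                    windows = list(c(1.71, 1.74), c(1.72, 1.75),
                                   c(1.73, 1.76)),
                    sparsityGrid = seq(0, 0.30, by = 0.05), alpha = 0.05,
                    testFun = diffAbundanceTest) {
    fm <- fractionData(x)
    ab <- abundanceMatrix(x, type = "genome")
    per_win <- lapply(windows, function(w) {
        ws <- .window_stats(ab, fm, design, w)
        list(window = w, presence = ws$presence,
             p = .window_pvalues(ws, design, testFun))
    })
    nw <- length(windows); ng <- nrow(ab)

    best <- NULL
    for (s in sparsityGrid) {
        padj <- matrix(NA_real_, ng, nw)
        any_testable <- FALSE
        for (w in seq_len(nw)) {
            testable <- per_win[[w]]$presence > s
            if (!any(testable)) next
            any_testable <- TRUE
            padj[testable, w] <- stats::p.adjust(per_win[[w]]$p[testable],
                                                 method = "BH")
        }
        if (!any_testable) next
        nrej <- sum(apply(padj, 1L, function(r) any(r <= alpha,
                                                    na.rm = TRUE)))
        if (is.null(best) || nrej > best$nrej)
            best <- list(s = s, padj = padj, nrej = nrej)
    }
    if (is.null(best))
        stop("no genome testable in any window at any sparsity threshold")

    padj <- best$padj
    hit <- apply(padj, 1L, function(r)
        if (all(is.na(r))) NA_integer_ else which.min(r))
    pmin_adj <- vapply(seq_len(ng), function(i)
        if (is.na(hit[i])) NA_real_ else padj[i, hit[i]], numeric(1))
    praw <- vapply(seq_len(ng), function(i)
        if (is.na(hit[i])) NA_real_ else per_win[[hit[i]]]$p[i], numeric(1))
    wlo <- vapply(seq_len(ng), function(i)
        if (is.na(hit[i])) NA_real_ else per_win[[hit[i]]]$window[1L],
        numeric(1))
    whi <- vapply(seq_len(ng), function(i)
        if (is.na(hit[i])) NA_real_ else per_win[[hit[i]]]$window[2L],
        numeric(1))
    data.frame(genome_id = rownames(ab), method = "mwhrsip",
               p_value = praw, p_adj = pmin_adj,
               labeled = !is.na(pmin_adj) & pmin_adj <= alpha,
               sparsity_used = best$s, window_low = wlo, window_high = whi,
               row.names = NULL)
}

#' Filter genomes by mean total coverage
#'
#' Mean total coverage of a genome is the mean over samples of its summed
#' per-fraction coverage within the sample. Genomes at or above the
#' threshold are retained (inclusive boundary).
#'
#' @param x a [SipExperiment-class] holding raw coverage.
#' @param design a [SampleDesign-class].
#' @param minMeanTotalCoverage threshold in x-fold coverage (default 10).
#' @return character vector of retained genome IDs.
#' @export
coverageFilter <- function(x, design, minMeanTotalCoverage = 10) {
    if (minMeanTotalCoverage < 0) stop("threshold must be non-negative")
    fm <- fractionData(x)
    covm <- coverageMatrix(x, type = "genome")
    samples <- c(controlSamples(design), treatmentSamples(design))
    totals <- vapply(samples, function(s)
        rowSums(covm[, fm$library_id[fm$sample_id == s], drop = FALSE]),
        numeric(nrow(covm)))
    rownames(covm)[rowMeans(totals) >= minMeanTotalCoverage]
}

#' Minimum-enrichment labeling rule
#'
#' A genome is labeled when the lower bound of its AFE confidence interval
#' exceeds the minimum AFE threshold (0 recovers the default "significantly
#' above zero" rule; larger values trade sensitivity for specificity).
#'
#' @param estimates result of [estimateAFE()] (or any data.frame with
#'   `genome_id` and `ci_low`).
#' @param minAfe minimum atom fraction excess.
#' @return named logical vector of labels.
#' @export
afeThresholdCall <- function(estimates, minAfe = 0) {
    if (is.null(estimates$ci_low)) stop("estimates lack a ci_low column")
    stats::setNames(!is.na(estimates$ci_low) & estimates$ci_low > minAfe,
                    estimates$genome_id)
}

#' Sequential MW-HR-SIP then qSIP incorporator workflow
#'
#' Stage 1 applies [mwHrSip()] as a high-specificity first-pass filter.
#' Stage 2 re-analyzes only the stage-1 positives with bootstrap qSIP
#' ([estimateAFE()]), with the multiplicity adjustment computed over the
#' reduced candidate set, which tightens the adjusted intervals relative to
#' full-set adjustment. The final labeled set is the genomes positive in
#' both stages.
#'
#' @inheritParams mwHrSip
#' @param params,iMax,nBoot,ciLevel,seed,minAfe passed to the stage-2 AFE
#'   estimation and labeling rule.
#' @param adjust interval adjustment for stage 2: `"fcr"`, `"bonferroni"`
#'   or `"none"`.
#' @param q FCR level / Bonferroni alpha for stage 2.
#' @param method stage-2 AFE model, `"qsip"` or `"deltabd"`.
#' @return data.frame per genome: `genome_id`, `method` = `"sequential"`,
#'   `stage1_labeled`, `afe`, `ci_low`, `ci_high`, `labeled`. The stage-2
#'   estimate columns are `NA` for genomes not passing stage 1. When stage
#'   1 yields no candidate the result carries a `"note"` attribute.
#' @export
sequentialWorkflow <- function(x, design,
                               windows = list(c(1.71, 1.74), c(1.72, 1.75),
                                              c(1.73, 1.76)),
                               sparsityGrid = seq(0, 0.30, by = 0.05),
                               alpha = 0.05, q = 0.05,
                               adjust = c("fcr", "bonferroni", "none"),
                               method = c("qsip", "deltabd"),
                               params = isotopeParams("13C"), iMax = NULL,
                               nBoot = 1000, ciLevel = 0.95, seed = 1,
                               minAfe = 0, testFun = diffAbundanceTest) {
    adjust <- match.arg(adjust)
    method <- match.arg(method)
    stage1 <- mwHrSip(x, design, windows = windows,
                      sparsityGrid = sparsityGrid, alpha = alpha,
                      testFun = testFun)
    out <- data.frame(genome_id = stage1$genome_id, method = "sequential",
                      stage1_labeled = stage1$labeled, afe = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      labeled = FALSE, row.names = NULL)
    cand <- stage1$genome_id[stage1$labeled]
    if (!length(cand)) {
        attr(out, "note") <- "stage 1 (MW-HR-SIP) returned no candidates"
        return(out)
    }
    est <- estimateAFE(x, design, method = method, params = params,
                       iMax = iMax, nBoot = nBoot, ciLevel = ciLevel,
                       seed = seed, threshold = minAfe, genomes = cand)
    if (adjust != "none") est <- adjustCI(est, method = adjust, q = q)
    i <- match(est$genome_id, out$genome_id)
    out$afe[i] <- est$afe
    out$ci_low[i] <- est$ci_low
    out$ci_high[i] <- est$ci_high
    out$labeled[i] <- afeThresholdCall(est, minAfe)
    out
}

#' Combine incorporator calls from two methods
#'
#' `"intersection"` (the default) labels only genomes labeled by both
#' methods — since different methods tend to produce non-overlapping false
#' positives, requiring agreement eliminates them; `"union"` labels genomes
#' labeled by either.
#'
#' @param callsA,callsB data.frames with `genome_id` and `labeled` over the
#'   same genome universe.
#' @param mode `"intersection"` or `"union"`.
#' @return data.frame with `genome_id`, `method` = `"consensus"`,
#'   `labeled`.
#' @export
consensusCalls <- function(callsA, callsB,
                           mode = c("intersection", "union")) {
    mode <- match.arg(mode)
    if (!setequal(callsA$genome_id, callsB$genome_id))
        stop("the two call sets cover different genomes")
    b <- callsB$labeled[match(callsA$genome_id, callsB$genome_id)]
    lab <- if (mode == "intersection") callsA$labeled & b
           else callsA$labeled | b
    data.frame(genome_id = callsA$genome_id, method = "consensus",
               labeled = lab, row.names = NULL)
}

#' Confusion-matrix performance of incorporator calls against known truth
#'
#' Counts true/false positives/negatives of a call set against the known
#' labeled genomes and reports specificity = TN / (FP + TN), sensitivity =
#' TP / (TP + FN) and balanced accuracy = (specificity + sensitivity) / 2.
#'
#' @param calls data.frame with `genome_id` and `labeled`, or a named
#'   logical vector.
#' @param truth character vector of truly labeled genome IDs, or a named
#'   logical vector covering every called genome.
#' @return one-row data.frame with the four counts and the three ratios.
#' @examples
#' calls <- data.frame(genome_id = c("a", "b", "c"),
#'                     labeled = c(TRUE, FALSE, FALSE))
#' performanceMetrics(calls, truth = "a")
#' @export
performanceMetrics <- function(calls, truth) {
    if (is.data.frame(calls))
        calls <- stats::setNames(calls$labeled, calls$genome_id)
    if (is.logical(truth)) {
        if (!all(names(calls) %in% names(truth)))
            stop("truth undefined for genome(s): ",
                 paste(setdiff(names(calls), names(truth)), collapse = ", "))
        truth <- names(truth)[truth]
    }
    pos <- names(calls) %in% truth
    tp <- sum(calls & pos); fp <- sum(calls & !pos)
    fn <- sum(!calls & pos); tn <- sum(!calls & !pos)
    spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    data.frame(true_positives = tp, false_positives = fp,
               true_negatives = tn, false_negatives = fn,
               specificity = spec, sensitivity = sens,
               balanced_accuracy = (spec + sens) / 2)
}
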