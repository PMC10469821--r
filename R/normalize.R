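#' Coefficient-of-variation gate on sequin concentration groups
#'
#' Sequins are dosed in concentration groups; within one fraction library a
#' group whose coverages scatter wildly carries no calibration information.
#' For every group the percent coefficient of variation,
#' CoV = 100 * sd / mean, of the member coverages is computed and groups
#' exceeding the threshold are removed before the scaling regression.
#'
#' @param coverages named numeric vector of per-sequin coverage within one
#'   library.
#' @param groups concentration-group labels, parallel to `coverages`.
#' @param covThreshold maximum tolerated CoV in percent (default 250).
#' @return character vector of retained sequin IDs.
#' @export
filterSequinsByCoV <- function(coverages, groups, covThreshold = 250) {
    if (covThreshold <= 0) stop("covThreshold must be positive")
    if (length(coverages) != length(groups))
        stop("coverages and groups differ in length")
    ids <- names(coverages)
    if (is.null(ids)) stop("coverages must be named by sequin ID")
    keep <- unlist(lapply(split(ids, groups), function(g) {
        x <- coverages[g]
        if (length(x) < 2L) return(g)   # CoV undefined; keep
        m <- mean(x)
        cv <- if (m == 0) Inf else 100 * stats::sd(x) / m
        if (cv > covThreshold) character(0) else g
    }), use.names = FALSE)
    if (!length(keep))
        stop("insufficient sequins for scaling: all concentration groups ",
             "failed the CoV gate")
    ids[ids %in% keep]
}

.cooks_cutoff <- function(spec, n) {
    if (is.numeric(spec)) return(spec)
    switch(match.arg(spec, c("4/n", "n/4")),
           "4/n" = 4 / n, "n/4" = n / 4)
}

#' Fit a sequin scaling regression for one fraction library
#'
#' Calibrates coverage against known sequin concentration,
#' `concentration = slope * coverage + intercept`. With
#' `method = "ols"` and `cooksFilter = TRUE` (the default workflow), points
#' whose Cook's distance exceeds the cutoff (conventionally 4/n) are removed
#' and the model refit once; `method = "robust"` instead downweights
#' outliers by iteratively reweighted least squares (Huber M-estimation).
#' An optional log10-log10 fit is available, as is common practice with
#' sequin standards spanning orders of magnitude.
#'
#' @param coverages named numeric vector of sequin coverages.
#' @param concentrations known concentrations, parallel to `coverages`.
#' @param method `"ols"` or `"robust"`.
#' @param cooksFilter apply one pass of Cook's-distance outlier removal
#'   (OLS only).
#' @param cooksCutoff `"4/n"` (default), `"n/4"`, or a number.
#' @param logTransform fit on log10(coverage) vs log10(concentration)
#'   (the default, as is standard with sequin standards spanning orders of
#'   magnitude; it avoids an additive intercept floor leaking into empty
#'   fractions); zero-coverage points are dropped first. `FALSE` fits on
#'   the untransformed scale.
#' @param libraryId identifier recorded on the model.
#' @return a [ScalingModel-class].
#' @examples
#' cov <- c(s1 = 1, s2 = 2, s3 = 4, s4 = 8)
#' fitSequinRegression(cov, 2 * cov, libraryId = "L1")
#' @export
fitSequinRegression <- function(coverages, concentrations,
                                method = c("ols", "robust"),
                                cooksFilter = TRUE, cooksCutoff = "4/n",
                                logTransform = TRUE, libraryId = "library") {
    method <- match.arg(method)
    if (length(coverages) != length(concentrations))
        stop("coverages and concentrations differ in length")
    ids <- names(coverages)
    if (is.null(ids)) ids <- paste0("sequin", seq_along(coverages))
    removed <- character(0)
    x <- as.numeric(coverages); y <- as.numeric(concentrations)
    if (logTransform) {
        pos <- x > 0 & y > 0
        removed <- ids[!pos]
        ids <- ids[pos]; x <- log10(x[pos]); y <- log10(y[pos])
    }
    if (length(x) < 3L)
        stop("need at least 3 sequin points to fit a scaling model")
    if (stats::sd(x) == 0)
        stop("degenerate regression: zero variance in sequin coverage")

    if (method == "robust") {
        fit <- MASS::rlm(y ~ x, maxit = 100)
        used <- ids
        tag <- "robust"
    } else {
        fit <- stats::lm(y ~ x)
        tag <- "ols"
        used <- ids
        if (cooksFilter) {
            cutoff <- .cooks_cutoff(cooksCutoff, length(x))
            bad <- which(stats::cooks.distance(fit) > cutoff)
            if (length(bad)) {
                if (length(x) - length(bad) < 3L)
                    stop("fewer than 3 sequin points remain after ",
                         "Cook's-distance filtering")
                removed <- c(removed, ids[bad])
                used <- ids[-bad]
                x <- x[-bad]; y <- y[-bad]
                if (stats::sd(x) == 0)
                    stop("degenerate regression after outlier removal")
                fit <- stats::lm(y ~ x)
            }
            tag <- "ols_cooks"
        }
    }
    cf <- stats::coef(fit)
    resid <- y - (cf[2L] * x + cf[1L])
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(resid^2) / tss
    new("ScalingModel", libraryId = libraryId,
        slope = unname(cf[2L]), intercept = unname(cf[1L]),
        rSquared = r2, nPointsUsed = length(x),
        removedSequinIds = removed, method = tag,
        logTransform = logTransform)
}

#' Fit sequin scaling models for every library of a SipExperiment
#'
#' Applies the per-library CoV gate ([filterSequinsByCoV()]) to the sequin
#' concentration groups, then fits [fitSequinRegression()] per fraction
#' library.
#'
#' @param x a [SipExperiment-class] with a sequin reference.
#' @param covThreshold CoV gate in percent; `NULL` disables the gate.
#' @param doseFactors optional named per-library multipliers of the sequin
#'   reference concentrations, for designs where some fractions receive a
#'   larger sequin dose; defaults to `metadata(x)$sequin_dose` when
#'   present (as set by the simulator), otherwise 1.
#' @inheritParams fitSequinRegression
#' @return named list of [ScalingModel-class], one per library.
#' @export
fitScalingModels <- function(x, method = c("ols", "robust"),
                             cooksFilter = TRUE, cooksCutoff = "4/n",
                             covThreshold = 250, logTransform = TRUE,
                             doseFactors = NULL) {
    method <- match.arg(method)
    sq <- as.data.frame(sequinRef(x))
    if (!nrow(sq)) stop("no sequin reference on this SipExperiment")
    if (is.null(doseFactors))
        doseFactors <- S4Vectors::metadata(x)$sequin_dose
    covm <- coverageMatrix(x, type = "sequin")
    sq <- sq[match(rownames(covm), sq$sequin_id), ]
    models <- lapply(colnames(covm), function(lib) {
        cv <- stats::setNames(covm[, lib], rownames(covm))
        keep <- if (is.null(covThreshold)) names(cv) else
            filterSequinsByCoV(cv, sq$group, covThreshold)
        i <- match(keep, sq$sequin_id)
        dose <- if (is.null(doseFactors)) 1 else doseFactors[[lib]]
        fitSequinRegression(cv[keep], sq$concentration[i] * dose,
                            method = method, cooksFilter = cooksFilter,
                            cooksCutoff = cooksCutoff,
                            logTransform = logTransform, libraryId = lib)
    })
    stats::setNames(models, colnames(covm))
}

.predict_conc <- function(model, cov) {
    if (model@logTransform) {
        out <- numeric(length(cov))
        pos <- cov > 0
        out[pos] <- 10^(model@slope * log10(cov[pos]) + model@intercept)
        out
    } else model@slope * cov + model@intercept
}

.drop_standards <- function(x, m, methodTag) {
    genome <- featureType(x) == "genome"
    out <- x[genome, ]
    SummarizedExperiment::assays(out) <- list(abundance = m[genome, ,
                                                            drop = FALSE])
    S4Vectors::metadata(out)$abundance_method <- methodTag
    out
}

#' Scale coverage to absolute abundance with sequin models
#'
#' Applies each library's [ScalingModel-class] to the genome coverages,
#' producing absolute per-fraction abundance in the units of the sequin
#' reference. Negative predictions (possible with a negative intercept) are
#' clamped to zero, since the weighted-density model requires non-negative
#' abundance. Sequin and spike-in rows are dropped from the result.
#'
#' @param x a [SipExperiment-class] holding raw coverage.
#' @param models named list of [ScalingModel-class] per library, e.g. from
#'   [fitScalingModels()].
#' @return a [SipExperiment-class] with assay `"abundance"` and method tag
#'   `"sequin"`.
#' @export
scaleToAbsolute <- function(x, models) {
    covm <- coverageMatrix(x)
    missing_m <- setdiff(colnames(covm), names(models))
    if (length(missing_m))
        stop("no scaling model for library(ies): ",
             paste(missing_m, collapse = ", "))
    ab <- covm
    for (lib in colnames(covm))
        ab[, lib] <- pmax(.predict_conc(models[[lib]], covm[, lib]), 0)
    .drop_standards(x, ab, "sequin")
}

#' Relative-coverage abundance
#'
#' Divides each genome's coverage by the summed genome coverage of its
#' library (sequins and spike-ins are excluded before the sum), so columns
#' sum to one over genomes.
#'
#' @param x a [SipExperiment-class] holding raw coverage.
#' @return a [SipExperiment-class] with assay `"abundance"` and method tag
#'   `"rel_coverage"`.
#' @export
relativeCoverage <- function(x) {
    covm <- coverageMatrix(x, type = "genome")
    tot <- colSums(covm)
    zero <- colnames(covm)[tot == 0]
    if (length(zero))
        stop("all-zero genome coverage in library(ies): ",
             paste(zero, collapse = ", "))
    .drop_standards(x, sweep(coverageMatrix(x), 2, c(tot)[
        match(colnames(covm), names(tot))], "/"), "rel_coverage")
}

#' DNA-concentration-based abundance
#'
#' Multiplies a per-library proportion by the library's measured DNA
#' concentration. With `basis = "relative_coverage"` the proportion is the
#' relative coverage; with `basis = "relative_abundance"` it is a
#' reads-proportional weight, coverage x genome length normalized to sum to
#' one over genomes.
#'
#' @param x a [SipExperiment-class] holding raw coverage; genome metadata
#'   with `length_bp` is required for the `relative_abundance` basis.
#' @param basis `"relative_abundance"` or `"relative_coverage"`.
#' @return a [SipExperiment-class] with assay `"abundance"` and method tag
#'   `"relabund_x_dna"` or `"relcov_x_dna"`.
#' @export
abundanceByDNA <- function(x, basis = c("relative_abundance",
                                        "relative_coverage")) {
    basis <- match.arg(basis)
    fm <- fractionData(x)
    if (any(is.na(fm$dna_conc)))
        stop("dna_conc missing for library(ies): ",
             paste(fm$library_id[is.na(fm$dna_conc)], collapse = ", "))
    covm <- coverageMatrix(x, type = "genome")
    if (basis == "relative_abundance") {
        len <- genomeData(x)$length_bp
        if (is.null(len) || any(is.na(len)))
            stop("genome length_bp required for the relative_abundance basis")
        w <- covm * len
        tag <- "relabund_x_dna"
    } else {
        w <- covm
        tag <- "relcov_x_dna"
    }
    tot <- colSums(w)
    zero <- colnames(w)[tot == 0]
    if (length(zero))
        stop("all-zero genome coverage in library(ies): ",
             paste(zero, collapse = ", "))
    prop <- sweep(w, 2, tot, "/")
    ab <- sweep(prop, 2, fm$dna_conc[match(colnames(prop), fm$library_id)],
                "*")
    full <- coverageMatrix(x)
    full[rownames(ab), ] <- ab
    .drop_standards(x, full, tag)
}

#' Unscaled-coverage abundance
#'
#' Uses raw mean coverage directly as the abundance measure (the simplest
#' alternative normalization), dropping sequin and spike-in rows.
#'
#' @param x a [SipExperiment-class] holding raw coverage.
#' @return a [SipExperiment-class] with assay `"abundance"` and method tag
#'   `"unscaled"`.
#' @export
unscaledCoverage <- function(x)
    .drop_standards(x, coverageMatrix(x), "unscaled")
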