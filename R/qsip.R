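#' Isotope-specific constants of the qSIP model
#'
#' Bundles the natural-abundance correction of the atom-fraction-excess
#' (AFE) equations and the coefficients of the maximum-labeling molecular
#' weight. Defaults: the natural-abundance term is 0.01111233 for 13C and
#' 0.002000429 for 18O; the heavy-maximum molecular weight is
#' `mLight(G) + 9.974564 - 0.4987282 * G`. All constants are overridable,
#' e.g. to adapt the heavy-maximum coefficients (published for the carbon
#' formulation) to another isotope.
#'
#' @param isotope `"13C"` or `"18O"`.
#' @param naturalAbundance override the natural-abundance term.
#' @param heavyMaxOffset,heavyMaxGcCoeff override the heavy-maximum
#'   coefficients (g/mol and g/mol per GC unit).
#' @return list with elements `isotope`, `naturalAbundance`,
#'   `heavyMaxOffset`, `heavyMaxGcCoeff`.
#' @export
isotopeParams <- function(isotope = c("13C", "18O"),
                          naturalAbundance = NULL,
                          heavyMaxOffset = 9.974564,
                          heavyMaxGcCoeff = 0.4987282) {
    isotope <- match.arg(isotope)
    if (is.null(naturalAbundance))
        naturalAbundance <- switch(isotope, "13C" = 0.01111233,
                                   "18O" = 0.002000429)
    if (naturalAbundance <= 0 || naturalAbundance >= 1)
        stop("naturalAbundance must lie in (0, 1)")
    list(isotope = isotope, naturalAbundance = naturalAbundance,
         heavyMaxOffset = heavyMaxOffset, heavyMaxGcCoeff = heavyMaxGcCoeff)
}

.check_gc <- function(G) {
    if (any(!is.finite(G)) || any(G < 0) || any(G > 1))
        stop("GC content must lie in [0, 1]")
    G
}

#' Molecular weight of unlabeled (light) DNA
#'
#' Average molecular weight per nucleotide pair of DNA at natural isotopic
#' abundance, as a linear function of GC content:
#' `M_Light = 0.496 * G + 307.691` g/mol.
#'
#' @param G GC content in \[0, 1\] (vectorized).
#' @return g/mol.
#' @examples
#' mLight(0)      # 307.691
#' mLight(0.504)  # 307.940984
#' @export
mLight <- function(G) 0.496 * .check_gc(G) + 307.691

#' Theoretical maximum molecular weight under full heavy labeling
#'
#' `M_Heavymax = M_Light + offset - gcCoeff * G`, with the default offset
#' 9.974564 g/mol and GC coefficient 0.4987282 g/mol.
#'
#' @inheritParams mLight
#' @param params an [isotopeParams()] list.
#' @return g/mol.
#' @export
mHeavyMax <- function(G, params = isotopeParams("13C"))
    mLight(G) + params$heavyMaxOffset - params$heavyMaxGcCoeff * .check_gc(G)

#' Molecular weight of DNA in the labeled treatment
#'
#' Infers the treatment-condition molecular weight from the relative shift
#' of the weighted mean buoyant density:
#' `M_Lab = M_Light * ((W_lab - W_light) / W_light + 1)`.
#'
#' @param MLight light molecular weight (g/mol).
#' @param WLab,WLight weighted mean buoyant densities in treatment and
#'   control (g/mL).
#' @return g/mol.
#' @export
mLab <- function(MLight, WLab, WLight) {
    if (any(WLight <= 0, na.rm = TRUE))
        stop("WLight must be strictly positive")
    MLight * ((WLab - WLight) / WLight + 1)
}

#' Abundance-weighted mean buoyant density of one replicate
#'
#' `W_ij = sum_k rho_jk * y_ijk / sum_k y_ijk`. A single summary value is
#' produced whether the distribution along the gradient is monomodal or
#' multimodal.
#'
#' @param y non-negative abundances over the fractions of one replicate.
#' @param rho fraction buoyant densities (g/mL), parallel to `y`.
#' @return g/mL, or `NA` if the genome is absent (`sum(y) == 0`).
#' @examples
#' weightedMeanBD(c(1, 3), c(1.70, 1.74))  # 1.73
#' @export
weightedMeanBD <- function(y, rho) {
    if (length(y) != length(rho)) stop("y and rho differ in length")
    if (any(y < 0)) stop("abundances must be non-negative")
    s <- sum(y)
    if (s == 0) return(NA_real_)
    sum(rho * y) / s
}

#' Atom fraction excess from the qSIP model
#'
#' `AFE = (M_Lab - M_Light) / (M_Heavymax - M_Light) * (1 - a)` where `a`
#' is the natural-abundance term of the isotope. The point estimate is not
#' clamped at zero; incorporator calling is done on confidence-interval
#' bounds.
#'
#' @param WLab,WLight weighted mean buoyant densities (g/mL; vectorized).
#' @param G GC content in \[0, 1\].
#' @param params an [isotopeParams()] list.
#' @return atom fraction excess (dimensionless).
#' @examples
#' qsipAFE(WLab = 1.726859, WLight = 1.709392, G = 0.504)  # ~0.32
#' @export
qsipAFE <- function(WLab, WLight, G, params = isotopeParams("13C")) {
    ML <- mLight(G)
    MH <- mHeavyMax(G, params)
    if (any(MH == ML)) stop("degenerate model: M_Heavymax equals M_Light")
    (mLab(ML, WLab, WLight) - ML) / (MH - ML) * (1 - params$naturalAbundance)
}

#' Atom fraction excess from the delta-BD model
#'
#' `AFE = (W_lab - W_light) / I_max`, where `I_max` is the maximum linear
#' buoyant-density shift at 100% labeling. No default for `I_max` is
#' provided; it is gradient- and isotope-specific (see Birnie & Rickwood on
#' isopycnic centrifugation for measured values).
#'
#' @inheritParams qsipAFE
#' @param iMax maximum density shift at full labeling (g/mL), required.
#' @return atom fraction excess.
#' @export
deltaBDAFE <- function(WLab, WLight, iMax) {
    if (missing(iMax) || is.null(iMax)) stop("iMax is required for delta-BD")
    if (iMax <= 0) stop("iMax must be positive")
    (WLab - WLight) / iMax
}

#' Theoretical buoyant density of unlabeled DNA from GC content
#'
#' The standard linear GC-density relation for CsCl gradients,
#' `rho = 1.660 + 0.098 * G` g/mL; used for heavy-window defaults and as
#' the simulator's unlabeled peak position.
#'
#' @inheritParams mLight
#' @return g/mL.
#' @examples
#' theoreticalDensity(0.504)  # ~1.709
#' @export
theoreticalDensity <- function(G) 1.660 + 0.098 * .check_gc(G)

#' Per-replicate weighted buoyant densities of every genome
#'
#' Computes `W_ij` ([weightedMeanBD()]) for every genome in every
#' non-excluded sample, plus each genome's total abundance per sample.
#'
#' @param x a [SipExperiment-class] holding an abundance assay.
#' @param design a [SampleDesign-class].
#' @return list with `W` (genomes x samples matrix of weighted densities,
#'   `NA` where a genome is absent from a replicate) and `totals` (matching
#'   matrix of summed abundances).
#' @export
weightedBD <- function(x, design) {
    fm <- fractionData(x)
    samples <- c(controlSamples(design), treatmentSamples(design))
    ab <- abundanceMatrix(x, type = "genome")
    W <- tot <- matrix(NA_real_, nrow(ab), length(samples),
                       dimnames = list(rownames(ab), samples))
    for (s in samples) {
        libs <- fm$library_id[fm$sample_id == s]
        rho <- fm$density[match(libs, fm$library_id)]
        m <- ab[, libs, drop = FALSE]
        ts <- rowSums(m)
        tot[, s] <- ts
        W[, s] <- ifelse(ts > 0, (m %*% rho) / ts, NA_real_)
    }
    list(W = W, totals = tot)
}

#' Condition means of per-replicate weighted densities
#'
#' Arithmetic mean of `W_ij` over the replicates of each condition,
#' skipping replicates where the genome is absent. Genomes absent from all
#' replicates of a condition get `NA` (estimate unavailable).
#'
#' @param W genomes x samples matrix from [weightedBD()].
#' @param design a [SampleDesign-class].
#' @return list with numeric vectors `WLight` and `WLab` (named by genome).
#' @export
conditionMeanBD <- function(W, design) {
    mean_over <- function(cols) {
        m <- W[, cols, drop = FALSE]
        out <- rowMeans(m, na.rm = TRUE)
        out[!is.finite(out)] <- NA_real_
        out
    }
    list(WLight = mean_over(controlSamples(design)),
         WLab = mean_over(treatmentSamples(design)))
}

.local_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Estimate per-genome atom fraction excess with bootstrap intervals
#'
#' Point estimates come from the original data: per-replicate weighted
#' densities are averaged within condition and fed to the qSIP
#' ([qsipAFE()]) or delta-BD ([deltaBDAFE()]) model. Uncertainty is
#' quantified by resampling whole replicates with replacement,
#' independently within control and treatment, recomputing the condition
#' means and AFE each draw, and taking percentile intervals. Draws in which
#' a genome is absent from every resampled replicate of a condition are
#' discarded and counted; a genome with more than 50% discarded draws is
#' flagged unstable.
#'
#' The bootstrap draws are retained on the result (attribute `"boot"`) so
#' that [adjustCI()] can recompute intervals at multiplicity-adjusted
#' levels without re-running.
#'
#' @param x a [SipExperiment-class] holding an abundance assay.
#' @param design a [SampleDesign-class].
#' @param method `"qsip"` or `"deltabd"`.
#' @param params an [isotopeParams()] list (qSIP).
#' @param iMax maximum density shift at 100% labeling (delta-BD only).
#' @param nBoot number of bootstrap draws (default 1000, minimum 100).
#' @param ciLevel two-sided confidence level of the percentile interval.
#' @param seed integer seed; identical seeds give identical intervals.
#' @param threshold minimum AFE for the `labeled` flag: labeled iff the
#'   lower CI bound exceeds it.
#' @param genomes optional subset of genome IDs to estimate.
#' @return data.frame with one row per genome: `genome_id`, `method`,
#'   `afe`, `ci_low`, `ci_high`, `ci_level_used`, `n_boot`, `n_discarded`,
#'   `unstable`, `labeled`, `threshold_used`; bootstrap draws in
#'   `attr(, "boot")`.
#' @examples
#' sim <- simulateSipExperiment(simConfig(seed = 1))
#' ab <- scaleToAbsolute(sim, fitScalingModels(sim))
#' est <- estimateAFE(ab, validateDesign(ab), nBoot = 200, seed = 1)
#' head(est)
#' @export
estimateAFE <- function(x, design, method = c("qsip", "deltabd"),
                        params = isotopeParams("13C"), iMax = NULL,
                        nBoot = 1000, ciLevel = 0.95, seed = 1,
                        threshold = 0, genomes = NULL) {
    method <- match.arg(method)
    if (nBoot < 100) stop("nBoot must be at least 100")
    wbd <- weightedBD(x, design)
    W <- wbd$W
    if (!is.null(genomes)) W <- W[genomes, , drop = FALSE]
    gc <- genomeData(x)$gc[match(rownames(W), rownames(genomeData(x)))]
    if (method == "qsip" && any(is.na(gc)))
        stop("gc missing for genome(s): ",
             paste(rownames(W)[is.na(gc)], collapse = ", "))
    ctrl <- controlSamples(design)
    trt <- treatmentSamples(design)
    cm <- conditionMeanBD(W, design)

    afe_fun <- if (method == "qsip")
        function(wl, wc, g) qsipAFE(wl, wc, g, params)
    else
        function(wl, wc, g) deltaBDAFE(wl, wc, iMax)

    point <- afe_fun(cm$WLab, cm$WLight, gc)

    nc <- length(ctrl); nt <- length(trt)
    boot <- matrix(NA_real_, nrow(W), nBoot,
                   dimnames = list(rownames(W), NULL))
    .local_seed(seed, {
        idxC <- matrix(sample.int(nc, nBoot * nc, replace = TRUE), nBoot)
        idxT <- matrix(sample.int(nt, nBoot * nt, replace = TRUE), nBoot)
        for (i in seq_len(nrow(W))) {
            if (is.na(point[i])) next
            wc <- W[i, ctrl]; wt <- W[i, trt]
            mc <- matrix(wc[idxC], nBoot)
            mt <- matrix(wt[idxT], nBoot)
            wcb <- rowMeans(mc, na.rm = TRUE)
            wtb <- rowMeans(mt, na.rm = TRUE)
            ok <- is.finite(wcb) & is.finite(wtb)
            boot[i, ok] <- afe_fun(wtb[ok], wcb[ok],
                                   rep(if (is.na(gc[i])) 0 else gc[i],
                                       sum(ok)))
        }
    })
    n_disc <- rowSums(is.na(boot))
    n_disc[is.na(point)] <- nBoot
    alpha <- 1 - ciLevel
    qs <- t(apply(boot, 1L, function(b) {
        b <- b[!is.na(b)]
        if (!length(b)) return(c(NA_real_, NA_real_))
        stats::quantile(b, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    }))
    out <- data.frame(genome_id = rownames(W), method = method,
                      afe = unname(point), ci_low = qs[, 1L],
                      ci_high = qs[, 2L], ci_level_used = ciLevel,
                      n_boot = nBoot, n_discarded = n_disc,
                      unstable = n_disc > nBoot / 2,
                      labeled = !is.na(qs[, 1L]) & qs[, 1L] > threshold,
                      threshold_used = threshold, row.names = NULL)
    attr(out, "boot") <- boot
    attr(out, "seed") <- seed
    out
}

#' Multiplicity-adjusted confidence intervals for AFE estimates
#'
#' Recomputes the bootstrap percentile intervals of [estimateAFE()] output
#' at a level adjusted for the number of genomes tested. `"bonferroni"`
#' widens every interval to level `1 - alpha/m`. `"fcr"` (false coverage
#' rate) first selects the `R` genomes whose unadjusted interval excludes
#' the labeling threshold, then recomputes the selected intervals at level
#' `1 - R*q/m`, the interval analogue of Benjamini-Hochberg. `labeled`
#' flags are refreshed from the adjusted intervals.
#'
#' @param estimates result of [estimateAFE()] (must carry its `"boot"`
#'   attribute).
#' @param method `"fcr"` or `"bonferroni"`.
#' @param q FCR level or Bonferroni family alpha (default 0.05).
#' @return the estimates data.frame with adjusted `ci_low`, `ci_high`,
#'   `ci_level_used` and `labeled`.
#' @export
adjustCI <- function(estimates, method = c("fcr", "bonferroni"), q = 0.05) {
    method <- match.arg(method)
    boot <- attr(estimates, "boot")
    if (is.null(boot)) stop("estimates lack the bootstrap draws attribute")
    m <- nrow(estimates)
    if (!m) stop("no estimates to adjust")
    thr <- estimates$threshold_used[1L]

    requant <- function(rows, level) {
        a <- 1 - level
        for (i in rows) {
            b <- boot[i, ]
            b <- b[!is.na(b)]
            if (!length(b)) next
            qs <- stats::quantile(b, c(a / 2, 1 - a / 2), names = FALSE)
            estimates$ci_low[i] <<- qs[1L]
            estimates$ci_high[i] <<- qs[2L]
            estimates$ci_level_used[i] <<- level
        }
    }
    if (method == "bonferroni") {
        requant(seq_len(m), 1 - q / m)
    } else {
        sel <- which(!is.na(estimates$ci_low) &
                     (estimates$ci_low > thr | estimates$ci_high < thr))
        R <- length(sel)
        if (R) requant(sel, 1 - R * q / m)
    }
    estimates$labeled <- !is.na(estimates$ci_low) & estimates$ci_low > thr
    attr(estimates, "boot") <- boot
    estimates
}
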