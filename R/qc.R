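#' Spike-in quality control of density gradients
#'
#' Pre-centrifugation spike-ins have distinct, predictable peak positions
#' along the buoyant-density gradient. For every sample, each spike-in's
#' observed peak is the density of the fraction where its coverage (or
#' sequin-scaled abundance, if models are supplied) is maximal. A sample
#' passes when every spike-in is detected and the observed peak densities,
#' walked in expected-peak order, never strictly decrease (a tie between
#' neighbouring spike-ins is tolerated; a strict inversion is not). Disturbed gradients (swapped or
#' shuffled fractions) violate the order and are flagged for exclusion.
#'
#' @param x a [SipExperiment-class] with a spike-in reference.
#' @param models optional named list of [ScalingModel-class]; when given,
#'   spike-in coverages are scaled before peak detection.
#' @return data.frame with one row per sample: `sample_id`, `pass`,
#'   `observed_order`, `expected_order` (comma-separated spike-in IDs) and
#'   `notes`.
#' @examples
#' sim <- simulateSipExperiment(simConfig(seed = 1))
#' spikeinQC(sim)
#' @export
spikeinQC <- function(x, models = NULL) {
    ref <- as.data.frame(spikeinRef(x))
    if (nrow(ref) < 2L)
        stop("need at least 2 spike-ins in the reference for order QC")
    ref <- ref[order(ref$expected_peak_density), ]
    expected <- ref$spikein_id
    covm <- coverageMatrix(x, type = "spikein")
    if (!all(expected %in% rownames(covm)))
        stop("spike-in(s) missing from the coverage table: ",
             paste(setdiff(expected, rownames(covm)), collapse = ", "))
    covm <- covm[expected, , drop = FALSE]
    if (!is.null(models))
        for (lib in colnames(covm))
            covm[, lib] <- pmax(.predict_conc(models[[lib]], covm[, lib]), 0)
    fm <- fractionData(x)

    res <- lapply(unique(fm$sample_id), function(s) {
        libs <- fm$library_id[fm$sample_id == s]
        dens <- fm$density[fm$sample_id == s]
        m <- covm[, libs, drop = FALSE]
        notes <- character(0)
        undetected <- rownames(m)[rowSums(m) == 0]
        if (length(undetected))
            notes <- c(notes, paste0("spike-in not detected: ",
                                     paste(undetected, collapse = ", ")))
        obs <- dens[apply(m, 1L, which.max)]
        names(obs) <- rownames(m)
        # ties (two spike-ins peaking in the same fraction) are not treated
        # as violations; only a strict inversion of the expected order is
        ordered_ok <- all(diff(obs) >= 0)
        if (!ordered_ok)
            notes <- c(notes, "observed peak order differs from expected")
        pass <- ordered_ok && !length(undetected)
        data.frame(sample_id = s, pass = pass,
                   observed_order = paste(names(sort(obs)), collapse = ","),
                   expected_order = paste(expected, collapse = ","),
                   notes = paste(notes, collapse = "; "))
    })
    do.call(rbind, res)
}
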