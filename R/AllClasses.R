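#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

REQUIRED_FRACTION_COLS <- c("library_id", "sample_id", "replicate", "condition",
                            "isotope", "fraction_index", "density", "dna_conc")

#' SipExperiment: coverage or abundance across density-gradient fractions
#'
#' The central container of the package. It extends
#' \linkS4class{SummarizedExperiment}: rows are features (genomes, sequins or
#' pre-centrifugation spike-ins), columns are fraction libraries, and the
#' single assay holds either mean coverage (raw input) or per-fraction
#' abundance (after normalization; see [scaleToAbsolute()]).
#'
#' Column metadata (one row per fraction library) must carry
#' `library_id`, `sample_id`, `replicate`, `condition` (`"control"` or
#' `"treatment"`), `isotope` (`"13C"` or `"18O"`), `fraction_index`,
#' `density` (buoyant density of the fraction, g/mL) and `dna_conc`
#' (measured DNA concentration of the fraction).
#'
#' Row metadata carries `feature_type` (`"genome"`, `"sequin"`, `"spikein"`)
#' and, for genomes, `gc` (GC fraction in \[0,1\]), `length_bp` and optional
#' `completeness`/`contamination`.
#'
#' @slot sequinRef `DataFrame` with `sequin_id`, `concentration` (known
#'   amount per fraction aliquot) and `group` (concentration-group tag).
#' @slot spikeinRef `DataFrame` with `spikein_id`, `expected_peak_density`
#'   (g/mL), `gc` and `label_fraction`.
#' @slot truth named numeric of ground-truth atom fraction excess per
#'   genome; empty for real data, populated by [simulateSipExperiment()].
#'
#' @seealso [sipExperiment()] for construction from plain tables,
#'   [readSipExperiment()] for construction from TSV files on disk.
#' @aliases SipExperiment
#' @exportClass SipExperiment
setClass("SipExperiment",
    contains = "SummarizedExperiment",
    slots = c(sequinRef = "DataFrame", spikeinRef = "DataFrame",
              truth = "numeric"),
    prototype = prototype(sequinRef = S4Vectors::DataFrame(),
                          spikeinRef = S4Vectors::DataFrame(),
                          truth = numeric(0)))

setValidity("SipExperiment", function(object) {
    msgs <- character(0)
    if (length(SummarizedExperiment::assays(object)) >= 1L) {
        a <- SummarizedExperiment::assay(object)
        if (any(!is.finite(a)))
            msgs <- c(msgs, "assay contains non-finite values")
        else if (any(a < 0))
            msgs <- c(msgs, "assay contains negative values")
    }
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(REQUIRED_FRACTION_COLS, colnames(cd))
    if (length(missing_cols))
        msgs <- c(msgs, paste0("fraction metadata lacks column(s): ",
                               paste(missing_cols, collapse = ", ")))
    if (!length(msgs) && ncol(object)) {
        if (any(!is.finite(cd$density)) || any(cd$density <= 0))
            msgs <- c(msgs, "fraction densities must be strictly positive")
        key <- paste(cd$sample_id, cd$fraction_index)
        if (anyDuplicated(key))
            msgs <- c(msgs, "(sample_id, fraction_index) pairs must be unique")
        bad <- setdiff(unique(cd$condition), c("control", "treatment"))
        if (length(bad))
            msgs <- c(msgs, paste0("unknown condition label(s): ",
                                   paste(bad, collapse = ", ")))
    }
    rd <- SummarizedExperiment::rowData(object)
    if ("gc" %in% colnames(rd)) {
        gc <- rd$gc[!is.na(rd$gc)]
        if (length(gc) && (any(gc < 0) || any(gc > 1)))
            msgs <- c(msgs, "gc values must lie in [0, 1]")
    }
    if (anyDuplicated(rownames(object)))
        msgs <- c(msgs, "feature IDs must be unique")
    if (length(object@truth)) {
        if (is.null(names(object@truth)))
            msgs <- c(msgs, "truth vector must be named by genome ID")
    }
    if (length(msgs)) msgs else TRUE
})

#' Experimental design of a SIP comparison
#'
#' Maps sample IDs to the unlabeled control and isotope treatment conditions,
#' records the isotope, excluded samples, and any validation warnings.
#' Construct with [validateDesign()].
#'
#' @slot isotope character, `"13C"` or `"18O"`.
#' @slot controlSamples,treatmentSamples character vectors of sample IDs.
#' @slot excluded character vector of excluded sample IDs.
#' @slot notes character vector of warnings recorded during validation.
#' @aliases SampleDesign
#' @exportClass SampleDesign
setClass("SampleDesign",
    slots = c(isotope = "character", controlSamples = "character",
              treatmentSamples = "character", excluded = "character",
              notes = "character"))

setValidity("SampleDesign", function(object) {
    msgs <- character(0)
    if (!length(object@controlSamples))
        msgs <- c(msgs, "no control condition samples")
    if (!length(object@treatmentSamples))
        msgs <- c(msgs, "no treatment condition samples")
    if (length(intersect(object@controlSamples, object@treatmentSamples)))
        msgs <- c(msgs, "samples assigned to both conditions")
    if (length(msgs)) msgs else TRUE
})

#' Per-library sequin scaling model
#'
#' Linear calibration of coverage against known sequin concentration within
#' one fraction library, as fitted by [fitSequinRegression()]. Predicted
#' concentration is `slope * coverage + intercept` (on log10 scales when
#' `logTransform` is `TRUE`).
#'
#' @slot libraryId library the model belongs to.
#' @slot slope,intercept,rSquared regression coefficients and fit quality.
#' @slot nPointsUsed number of sequin points in the final fit.
#' @slot removedSequinIds sequins dropped by the CoV gate or Cook's filter.
#' @slot method `"ols"`, `"ols_cooks"` or `"robust"`.
#' @slot logTransform whether the fit is on log10(coverage)/log10(conc).
#' @aliases ScalingModel
#' @exportClass ScalingModel
setClass("ScalingModel",
    slots = c(libraryId = "character", slope = "numeric",
              intercept = "numeric", rSquared = "numeric",
              nPointsUsed = "integer", removedSequinIds = "character",
              method = "character", logTransform = "logical"))

setValidity("ScalingModel", function(object) {
    msgs <- character(0)
    if (object@nPointsUsed < 3L)
        msgs <- c(msgs, "a scaling model needs at least 3 points")
    if (!is.finite(object@slope))
        msgs <- c(msgs, "slope must be finite")
    if (length(msgs)) msgs else TRUE
})
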