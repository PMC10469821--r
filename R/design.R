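#' Validate the experimental design of a SIP comparison
#'
#' Groups the fraction libraries into unlabeled control and isotope
#' treatment samples and checks the design is analyzable: at least one
#' sample per condition, the requested isotope throughout, and at least two
#' fractions per sample (fewer yields a warning note rather than an error,
#' since a weighted-density estimate from a single fraction is technically
#' defined but uninformative).
#'
#' @param x a [SipExperiment-class] or a data.frame of fraction metadata.
#' @param requiredIsotope isotope the analysis expects, `"13C"` or `"18O"`.
#' @param exclude sample IDs to exclude (e.g. spike-in QC failures).
#' @return a [SampleDesign-class].
#' @examples
#' sim <- simulateSipExperiment(simConfig(seed = 1))
#' validateDesign(sim)
#' @export
validateDesign <- function(x, requiredIsotope = NULL, exclude = character(0)) {
    fm <- if (is(x, "SipExperiment")) fractionData(x) else as.data.frame(x)
    if (!nrow(fm)) stop("empty fraction metadata")
    fm <- fm[!(fm$sample_id %in% exclude), , drop = FALSE]
    if (!nrow(fm)) stop("all samples excluded")
    notes <- character(0)

    iso <- unique(fm$isotope)
    if (length(iso) > 1L)
        stop("mixed isotopes in one design: ", paste(iso, collapse = ", "))
    if (!is.null(requiredIsotope) && iso != requiredIsotope)
        stop("design isotope is ", iso, ", expected ", requiredIsotope)

    smp <- unique(fm[c("sample_id", "condition")])
    if (anyDuplicated(smp$sample_id))
        stop("sample(s) assigned to more than one condition: ",
             paste(unique(smp$sample_id[duplicated(smp$sample_id)]),
                   collapse = ", "))
    ctrl <- smp$sample_id[smp$condition == "control"]
    trt <- smp$sample_id[smp$condition == "treatment"]
    if (!length(ctrl)) stop("no control condition samples in design")
    if (!length(trt)) stop("no treatment condition samples in design")

    nfrac <- table(fm$sample_id)
    thin <- names(nfrac)[nfrac < 2L]
    if (length(thin))
        notes <- c(notes, paste0("sample(s) with <2 fractions: ",
                                 paste(thin, collapse = ", ")))
    new("SampleDesign", isotope = iso, controlSamples = sort(ctrl),
        treatmentSamples = sort(trt), excluded = exclude, notes = notes)
}
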