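#' @rdname SipExperiment-accessors
#' @export
setGeneric("coverageMatrix", function(x, ...) standardGeneric("coverageMatrix"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("abundanceMatrix", function(x, ...) standardGeneric("abundanceMatrix"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("fractionData", function(x, ...) standardGeneric("fractionData"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("genomeData", function(x, ...) standardGeneric("genomeData"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("sequinRef", function(x) standardGeneric("sequinRef"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("spikeinRef", function(x) standardGeneric("spikeinRef"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("truthAFE", function(x) standardGeneric("truthAFE"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("featureType", function(x) standardGeneric("featureType"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname SipExperiment-accessors
#' @export
setGeneric("abundanceMethod", function(x) standardGeneric("abundanceMethod"))

#' @rdname SampleDesign
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname SampleDesign
#' @export
setGeneric("treatmentSamples", function(x) standardGeneric("treatmentSamples"))

#' @rdname SampleDesign
#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))

#' @rdname SampleDesign
#' @export
setGeneric("designIsotope", function(x) standardGeneric("designIsotope"))
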