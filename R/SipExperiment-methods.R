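#' Construct a SipExperiment from plain tables
#'
#' Assembles the coverage matrix, fraction metadata and optional genome,
#' sequin and spike-in references into a validated [SipExperiment-class]
#' object. Feature type is decided by ID membership in the sequin and
#' spike-in references, never by naming convention: a row whose ID appears in
#' `sequinRef` is a sequin, one in `spikeinRef` a spike-in, everything else a
#' genome.
#'
#' @param coverage numeric matrix of mean coverage (features x libraries),
#'   with feature IDs as rownames and library IDs as colnames.
#' @param fractionMeta data.frame with one row per library; must contain
#'   columns `library_id`, `sample_id`, `replicate`, `condition`, `isotope`,
#'   `fraction_index`, `density`, `dna_conc`.
#' @param genomeMeta optional data.frame with `genome_id`, `gc`, `length_bp`
#'   and optional `completeness`, `contamination`.
#' @param sequinRef optional data.frame with `sequin_id`, `concentration`,
#'   `group`.
#' @param spikeinRef optional data.frame with `spikein_id`,
#'   `expected_peak_density`, `gc`, `label_fraction`.
#' @param truth optional named numeric vector of true atom fraction excess.
#' @param assayName name of the assay, `"coverage"` for raw input.
#' @return a [SipExperiment-class] object.
#' @examples
#' cov <- matrix(c(5, 1, 0, 3), 2, 2,
#'               dimnames = list(c("gA", "gB"), c("L1", "L2")))
#' fm <- data.frame(library_id = c("L1", "L2"), sample_id = "S1",
#'                  replicate = 1L, condition = "control", isotope = "13C",
#'                  fraction_index = 1:2, density = c(1.70, 1.72),
#'                  dna_conc = c(8, 6))
#' se <- sipExperiment(cov, fm)
#' coverageMatrix(se)
#' @export
sipExperiment <- function(coverage, fractionMeta, genomeMeta = NULL,
                          sequinRef = NULL, spikeinRef = NULL, truth = NULL,
                          assayName = "coverage") {
    coverage <- as.matrix(coverage)
    if (is.null(rownames(coverage)) || is.null(colnames(coverage)))
        stop("coverage matrix needs feature IDs as rownames and ",
             "library IDs as colnames")
    fractionMeta <- as.data.frame(fractionMeta)
    missing_cols <- setdiff(REQUIRED_FRACTION_COLS, colnames(fractionMeta))
    if (length(missing_cols))
        stop("fraction metadata lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    if (!all(colnames(coverage) %in% fractionMeta$library_id))
        stop("coverage library(ies) without fraction metadata: ",
             paste(setdiff(colnames(coverage), fractionMeta$library_id),
                   collapse = ", "))
    fm <- fractionMeta[match(colnames(coverage), fractionMeta$library_id), ,
                       drop = FALSE]
    rownames(fm) <- fm$library_id

    sq <- if (is.null(sequinRef)) S4Vectors::DataFrame() else
        S4Vectors::DataFrame(as.data.frame(sequinRef))
    sp <- if (is.null(spikeinRef)) S4Vectors::DataFrame() else
        S4Vectors::DataFrame(as.data.frame(spikeinRef))

    type <- rep("genome", nrow(coverage))
    if (nrow(sq)) type[rownames(coverage) %in% sq$sequin_id] <- "sequin"
    if (nrow(sp)) type[rownames(coverage) %in% sp$spikein_id] <- "spikein"
    rd <- S4Vectors::DataFrame(feature_type = type,
                               row.names = rownames(coverage))
    if (!is.null(genomeMeta)) {
        genomeMeta <- as.data.frame(genomeMeta)
        idx <- match(rownames(coverage), genomeMeta$genome_id)
        for (col in setdiff(colnames(genomeMeta), "genome_id"))
            rd[[col]] <- genomeMeta[[col]][idx]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = stats::setNames(list(coverage), assayName),
        rowData = rd,
        colData = S4Vectors::DataFrame(fm))
    new("SipExperiment", se, sequinRef = sq, spikeinRef = sp,
        truth = if (is.null(truth)) numeric(0) else truth)
}

#' Accessors for SipExperiment objects
#'
#' `coverageMatrix()`/`abundanceMatrix()` return the assay restricted to a
#' feature type (all features with `type = NULL`); `fractionData()` the
#' per-library metadata; `genomeData()` the genome row metadata;
#' `sequinRef()`/`spikeinRef()` the internal-standard references;
#' `truthAFE()` the simulation ground truth (empty for real data);
#' `genomeIds()` the genome feature IDs; `abundanceMethod()` the
#' normalization tag (`NA` for raw coverage).
#'
#' @param x a [SipExperiment-class].
#' @param type restrict rows to a feature type (`"genome"`, `"sequin"`,
#'   `"spikein"`) or `NULL` for all.
#' @param ... unused.
#' @return see Description.
#' @name SipExperiment-accessors
NULL

.assay_by_type <- function(x, type) {
    a <- SummarizedExperiment::assay(x)
    if (is.null(type)) return(a)
    a[featureType(x) == type, , drop = FALSE]
}

#' @rdname SipExperiment-accessors
#' @export
setMethod("coverageMatrix", "SipExperiment", function(x, type = NULL, ...)
    .assay_by_type(x, type))

#' @rdname SipExperiment-accessors
#' @export
setMethod("abundanceMatrix", "SipExperiment", function(x, type = "genome", ...)
    .assay_by_type(x, type))

#' @rdname SipExperiment-accessors
#' @export
setMethod("fractionData", "SipExperiment", function(x, ...)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname SipExperiment-accessors
#' @export
setMethod("genomeData", "SipExperiment", function(x, ...) {
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    rd[rd$feature_type == "genome", , drop = FALSE]
})

#' @rdname SipExperiment-accessors
#' @export
setMethod("sequinRef", "SipExperiment", function(x) x@sequinRef)

#' @rdname SipExperiment-accessors
#' @export
setMethod("spikeinRef", "SipExperiment", function(x) x@spikeinRef)

#' @rdname SipExperiment-accessors
#' @export
setMethod("truthAFE", "SipExperiment", function(x) x@truth)

#' @rdname SipExperiment-accessors
#' @export
setMethod("featureType", "SipExperiment", function(x)
    SummarizedExperiment::rowData(x)$feature_type)

#' @rdname SipExperiment-accessors
#' @export
setMethod("genomeIds", "SipExperiment", function(x)
    rownames(x)[featureType(x) == "genome"])

#' @rdname SipExperiment-accessors
#' @export
setMethod("abundanceMethod", "SipExperiment", function(x) {
    m <- S4Vectors::metadata(x)$abundance_method
    if (is.null(m)) NA_character_ else m
})

setMethod("show", "SipExperiment", function(object) {
    ft <- table(factor(featureType(object),
                       levels = c("genome", "sequin", "spikein")))
    cd <- SummarizedExperiment::colData(object)
    cat("SipExperiment:", nrow(object), "features x", ncol(object),
        "fraction libraries\n")
    cat("  genomes:", ft[["genome"]], "| sequins:", ft[["sequin"]],
        "| spike-ins:", ft[["spikein"]], "\n")
    if (ncol(object)) {
        cat("  samples:", length(unique(cd$sample_id)),
            sprintf("(%d control, %d treatment)",
                    length(unique(cd$sample_id[cd$condition == "control"])),
                    length(unique(cd$sample_id[cd$condition == "treatment"]))),
            "\n")
        cat("  density range:", sprintf("%.4f-%.4f g/mL",
            min(cd$density), max(cd$density)), "\n")
    }
    m <- abundanceMethod(object)
    cat("  assay:", SummarizedExperiment::assayNames(object)[1],
        if (!is.na(m)) sprintf("(method: %s)", m) else "", "\n")
    if (length(object@truth))
        cat("  ground-truth AFE available for", length(object@truth),
            "genomes\n")
})

#' @rdname SampleDesign
#' @export
setMethod("controlSamples", "SampleDesign", function(x) x@controlSamples)

#' @rdname SampleDesign
#' @export
setMethod("treatmentSamples", "SampleDesign", function(x) x@treatmentSamples)

#' @rdname SampleDesign
#' @export
setMethod("excludedSamples", "SampleDesign", function(x) x@excluded)

#' @rdname SampleDesign
#' @export
setMethod("designIsotope", "SampleDesign", function(x) x@isotope)

setMethod("show", "SampleDesign", function(object) {
    cat("SampleDesign (", object@isotope, "):\n", sep = "")
    cat("  control  :", paste(object@controlSamples, collapse = ", "), "\n")
    cat("  treatment:", paste(object@treatmentSamples, collapse = ", "), "\n")
    if (length(object@excluded))
        cat("  excluded :", paste(object@excluded, collapse = ", "), "\n")
    for (n in object@notes) cat("  note:", n, "\n")
})

setMethod("show", "ScalingModel", function(object) {
    cat(sprintf("ScalingModel [%s] %s%s: conc = %.4g*cov %+.4g (r2 %.3f, n %d",
                object@libraryId, object@method,
                if (object@logTransform) " (log10)" else "",
                object@slope, object@intercept, object@rSquared,
                object@nPointsUsed))
    if (length(object@removedSequinIds))
        cat(", removed:", paste(object@removedSequinIds, collapse = ","))
    cat(")\n")
})
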