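#' Read and write the tab-separated input tables
#'
#' All inputs are plain TSV with a header row. The coverage matrix has
#' feature IDs in the first column and one numeric column per fraction
#' library; duplicate feature IDs and non-numeric cells are rejected with
#' messages naming the offender. `writeCoverageTable()` is the exact inverse
#' of `readCoverageTable()` up to numeric formatting.
#'
#' @param path path to a TSV file.
#' @return `readCoverageTable()`: numeric matrix with feature rownames and
#'   library colnames, column order preserved. The metadata readers return
#'   data.frames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("L1", "L2")))
#' writeCoverageTable(m, tf)
#' stopifnot(identical(readCoverageTable(tf), m + 0))
#' @export
readCoverageTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop("coverage table needs an ID column plus at ",
                            "least one library column")
    ids <- df[[1L]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate feature ID(s): ", paste(dup, collapse = ", "))
    m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                dimnames = list(ids, colnames(df)[-1L]))
    for (j in seq_len(ncol(m))) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                         df[[j + 1L]][bad[1L]], ids[bad[1L]], colnames(m)[j]))
        m[, j] <- v
    }
    m
}

#' @rdname readCoverageTable
#' @param x numeric matrix as returned by `readCoverageTable()`.
#' @param idColumn header of the feature-ID column on write.
#' @export
writeCoverageTable <- function(x, path, idColumn = "feature_id") {
    df <- data.frame(rownames(x), x, check.names = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.read_meta <- function(path, required, what) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    missing_cols <- setdiff(required, colnames(df))
    if (length(missing_cols))
        stop(what, " table lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    df
}

#' @rdname readCoverageTable
#' @export
readFractionMeta <- function(path)
    .read_meta(path, REQUIRED_FRACTION_COLS, "fraction metadata")

#' @rdname readCoverageTable
#' @export
readGenomeMeta <- function(path)
    .read_meta(path, c("genome_id", "gc", "length_bp"), "genome metadata")

#' @rdname readCoverageTable
#' @export
readSequinRef <- function(path)
    .read_meta(path, c("sequin_id", "concentration", "group"),
               "sequin reference")

#' @rdname readCoverageTable
#' @export
readSpikeinRef <- function(path)
    .read_meta(path, c("spikein_id", "expected_peak_density", "gc",
                       "label_fraction"), "spike-in reference")

#' @rdname readCoverageTable
#' @export
readPairwiseSimilarity <- function(path)
    .read_meta(path, c("id_a", "id_b", "gani", "af"), "pairwise similarity")

#' Read or write a full SipExperiment as a directory of TSV files
#'
#' The on-disk layout is the set of delimited tables the package consumes:
#' `coverage.tsv`, `fractions.tsv`, `genomes.tsv` and, when present,
#' `sequins.tsv`, `spikeins.tsv` and `truth.tsv` (simulator ground truth).
#'
#' @param dir directory containing (or to receive) the tables.
#' @return `readSipExperiment()`: a [SipExperiment-class];
#'   `writeSipExperiment()`: `dir`, invisibly.
#' @export
readSipExperiment <- function(dir) {
    p <- function(f) file.path(dir, f)
    cov <- readCoverageTable(p("coverage.tsv"))
    fm <- readFractionMeta(p("fractions.tsv"))
    gm <- if (file.exists(p("genomes.tsv"))) readGenomeMeta(p("genomes.tsv"))
    sq <- if (file.exists(p("sequins.tsv"))) readSequinRef(p("sequins.tsv"))
    sp <- if (file.exists(p("spikeins.tsv")))
        readSpikeinRef(p("spikeins.tsv"))
    tr <- NULL
    if (file.exists(p("truth.tsv"))) {
        td <- utils::read.delim(p("truth.tsv"), sep = "\t")
        tr <- stats::setNames(td$true_afe, td$genome_id)
    }
    se <- sipExperiment(cov, fm, genomeMeta = gm, sequinRef = sq,
                        spikeinRef = sp, truth = tr)
    if ("sequin_dose" %in% colnames(fm))
        S4Vectors::metadata(se)$sequin_dose <-
            stats::setNames(fm$sequin_dose, fm$library_id)
    se
}

#' @rdname readSipExperiment
#' @param x a [SipExperiment-class] to serialize.
#' @export
writeSipExperiment <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.table(df, file.path(dir, f),
        sep = "\t", quote = FALSE, row.names = FALSE)
    writeCoverageTable(SummarizedExperiment::assay(x),
                       file.path(dir, "coverage.tsv"))
    fm <- fractionData(x)
    dose <- S4Vectors::metadata(x)$sequin_dose
    if (!is.null(dose)) fm$sequin_dose <- unname(dose[fm$library_id])
    w(fm, "fractions.tsv")
    gd <- genomeData(x)
    if (nrow(gd)) {
        gd <- data.frame(genome_id = rownames(gd),
                         gd[setdiff(colnames(gd), "feature_type")],
                         check.names = FALSE)
        w(gd, "genomes.tsv")
    }
    if (nrow(sequinRef(x))) w(as.data.frame(sequinRef(x)), "sequins.tsv")
    if (nrow(spikeinRef(x))) w(as.data.frame(spikeinRef(x)), "spikeins.tsv")
    if (length(truthAFE(x)))
        w(data.frame(genome_id = names(truthAFE(x)),
                     true_afe = unname(truthAFE(x))), "truth.tsv")
    invisible(dir)
}
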