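#' Run the full SIP analysis pipeline from a configuration
#'
#' Orchestrates the workflow end to end: spike-in quality control (failed
#' samples are excluded before anything else), abundance normalization, AFE
#' estimation with bootstrap intervals and multiplicity adjustment,
#' incorporator identification, and — when the input carries ground truth —
#' performance scoring. All tabular outputs are written as TSV into the
#' output directory together with a config snapshot, its md5 hash, the
#' package version and the seed, so a rerun with the same config and inputs
#' is fully reproducible.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognized entries (defaults in parentheses):
#'   `input_dir` (required) — directory of TSV inputs, see
#'   [readSipExperiment()]; `output_dir` (required on write);
#'   `normalization` (`"sequin"`; also `"rel_coverage"`,
#'   `"relabund_x_dna"`, `"relcov_x_dna"`, `"unscaled"`);
#'   `regression`: `method` (`"ols"`), `cooks_filter` (TRUE),
#'   `cooks_cutoff` (`"4/n"`), `cov_threshold` (250), `log_transform`
#'   (TRUE); `isotope` (`"13C"`); `afe_method` (`"qsip"`); `i_max`
#'   (delta-BD only); `n_boot` (1000); `ci_level` (0.95); `seed` (1);
#'   `identify` (`c("qsip", "mwhrsip", "sequential")`); `windows`
#'   (MW-HR-SIP defaults); `hr_window` (HR-SIP default); `alpha` (0.05);
#'   `adjust` (`"fcr"`); `q` (0.05); `min_afe` (0); `min_coverage` (0).
#' @param outputDir overrides `config$output_dir`; `NULL` suppresses
#'   writing.
#' @return invisibly, a list with `qc`, `design`, `abundance`, `models`,
#'   `afe`, `calls` (named list per method) and `performance` (if truth
#'   available).
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- function(name, default) {
        v <- config[[name]]
        if (is.null(v)) default else v
    }
    if (is.null(config$input_dir)) stop("config lacks input_dir")
    if (is.null(outputDir)) outputDir <- config$output_dir
    seed <- cfg("seed", 1L)

    x <- readSipExperiment(config$input_dir)

    # 1. spike-in QC before anything touches the data
    qc <- NULL
    excluded <- character(0)
    if (nrow(spikeinRef(x)) >= 2L) {
        qc <- spikeinQC(x)
        excluded <- qc$sample_id[!qc$pass]
        if (length(excluded))
            message("excluding QC-failed sample(s): ",
                    paste(excluded, collapse = ", "))
    }
    design <- validateDesign(x, requiredIsotope = cfg("isotope", NULL),
                             exclude = excluded)
    keep_libs <- fractionData(x)$sample_id %in%
        c(controlSamples(design), treatmentSamples(design))
    x <- x[, keep_libs]

    # 2. coverage filter (inclusive >=)
    min_cov <- cfg("min_coverage", 0)
    kept_genomes <- coverageFilter(x, design, min_cov)
    if (length(kept_genomes) < length(genomeIds(x)))
        x <- x[rownames(x) %in% c(kept_genomes,
                                  rownames(x)[featureType(x) != "genome"]), ]

    # 3. normalization
    norm <- cfg("normalization", "sequin")
    reg <- cfg("regression", list())
    rcfg <- function(name, default) {
        v <- reg[[name]]
        if (is.null(v)) default else v
    }
    models <- NULL
    ab <- switch(norm,
        sequin = {
            models <- fitScalingModels(
                x, method = rcfg("method", "ols"),
                cooksFilter = rcfg("cooks_filter", TRUE),
                cooksCutoff = rcfg("cooks_cutoff", "4/n"),
                covThreshold = rcfg("cov_threshold", 250),
                logTransform = rcfg("log_transform", TRUE))
            scaleToAbsolute(x, models)
        },
        rel_coverage = relativeCoverage(x),
        relabund_x_dna = abundanceByDNA(x, "relative_abundance"),
        relcov_x_dna = abundanceByDNA(x, "relative_coverage"),
        unscaled = unscaledCoverage(x),
        stop("unknown normalization method: ", norm))

    # 4. AFE estimation
    params <- isotopeParams(designIsotope(design))
    afe_method <- cfg("afe_method", "qsip")
    est <- estimateAFE(ab, design, method = afe_method, params = params,
                       iMax = cfg("i_max", NULL),
                       nBoot = cfg("n_boot", 1000),
                       ciLevel = cfg("ci_level", 0.95), seed = seed,
                       threshold = cfg("min_afe", 0))
    adj <- cfg("adjust", "fcr")
    if (adj != "none") est <- adjustCI(est, method = adj, q = cfg("q", 0.05))

    # 5. incorporator identification
    alpha <- cfg("alpha", 0.05)
    windows <- cfg("windows", list(c(1.71, 1.74), c(1.72, 1.75),
                                   c(1.73, 1.76)))
    windows <- lapply(windows, as.numeric)
    calls <- list()
    for (m in cfg("identify", c("qsip", "mwhrsip", "sequential"))) {
        calls[[m]] <- switch(m,
            qsip = data.frame(genome_id = est$genome_id, method = "qsip",
                              labeled = afeThresholdCall(est,
                                  cfg("min_afe", 0)), row.names = NULL),
            deltabd = data.frame(genome_id = est$genome_id,
                                 method = "deltabd",
                                 labeled = afeThresholdCall(est,
                                     cfg("min_afe", 0)), row.names = NULL),
            hrsip = hrSip(ab, design,
                          window = cfg("hr_window", NULL), alpha = alpha),
            mwhrsip = mwHrSip(ab, design, windows = windows,
                              alpha = alpha),
            sequential = sequentialWorkflow(
                ab, design, windows = windows, alpha = alpha,
                q = cfg("q", 0.05), adjust = adj, method = afe_method,
                params = params, iMax = cfg("i_max", NULL),
                nBoot = cfg("n_boot", 1000),
                ciLevel = cfg("ci_level", 0.95), seed = seed,
                minAfe = cfg("min_afe", 0)),
            stop("unknown identification method: ", m))
    }

    # 6. score against truth when available
    perf <- NULL
    if (length(truthAFE(x))) {
        truth_pos <- names(truthAFE(x))[truthAFE(x) > 0]
        perf <- do.call(rbind, lapply(names(calls), function(m)
            cbind(method = m, performanceMetrics(calls[[m]], truth_pos))))
    }

    res <- list(qc = qc, design = design, models = models, abundance = ab,
                afe = est, calls = calls, performance = perf)
    if (!is.null(outputDir)) .write_bundle(res, config, outputDir, seed)
    invisible(res)
}

.write_bundle <- function(res, config, outputDir, seed) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.table(df, file.path(outputDir, f),
        sep = "\t", quote = FALSE, row.names = FALSE)
    snap <- file.path(outputDir, "config_snapshot.yaml")
    yaml::write_yaml(config, snap)
    info <- data.frame(
        tool = "SIPquant",
        version = as.character(utils::packageVersion("SIPquant")),
        config_md5 = unname(tools::md5sum(snap)),
        seed = seed)
    w(info, "run_info.tsv")
    if (!is.null(res$qc)) w(res$qc, "qc_report.tsv")
    writeCoverageTable(abundanceMatrix(res$abundance),
                       file.path(outputDir, "abundance.tsv"),
                       idColumn = "genome_id")
    w(cbind(res$afe, seed = seed), "afe_estimates.tsv")
    for (m in names(res$calls))
        w(res$calls[[m]], sprintf("calls_%s.tsv", m))
    if (!is.null(res$performance)) w(res$performance, "performance.tsv")
    invisible(outputDir)
}

#' Score incorporator calls against a ground-truth table
#'
#' Convenience wrapper over [performanceMetrics()] accepting the TSV files
#' the pipeline writes: a calls table (`genome_id`, `labeled`) and a truth
#' table (`genome_id`, `true_afe`); a genome is truly labeled when its true
#' AFE exceeds zero.
#'
#' @param calls path to a calls TSV or a data.frame.
#' @param truth path to a truth TSV or a data.frame.
#' @return one-row data.frame of counts, specificity, sensitivity and
#'   balanced accuracy.
#' @export
evaluatePerformance <- function(calls, truth) {
    if (is.character(calls)) calls <- utils::read.delim(calls, sep = "\t")
    if (is.character(truth)) truth <- utils::read.delim(truth, sep = "\t")
    missing_t <- setdiff(calls$genome_id, truth$genome_id)
    if (length(missing_t))
        stop("truth table lacks genome(s): ",
             paste(missing_t, collapse = ", "))
    performanceMetrics(calls, truth$genome_id[truth$true_afe > 0])
}
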