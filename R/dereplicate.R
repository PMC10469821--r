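#' Dereplicate MAGs by single-linkage clustering of pairwise similarity
#'
#' Groups genomes into species-level clusters from a precomputed table of
#' pairwise genome-wide average nucleotide identity (gANI) and alignment
#' fraction (AF). For each pair the lowest value across the two comparison
#' orientations is used; an edge joins two genomes when that minimum gANI
#' and minimum AF both reach their (inclusive) thresholds; clusters are the
#' connected components of the resulting graph, so linkage is single.
#' Genomes with no qualifying edge are singletons.
#'
#' One representative is picked per cluster: highest completeness, ties
#' broken by lowest contamination, then by greatest total length.
#'
#' @param sim data.frame with columns `id_a`, `id_b`, `gani` (0-100) and
#'   `af` (0-100), as read by [readPairwiseSimilarity()].
#' @param ids character vector of all genome IDs to cluster (the similarity
#'   table need not mention singletons).
#' @param ganiMin,afMin inclusive thresholds; defaults are the species-level
#'   delineation of 96.5 gANI and 30 AF.
#' @param quality data.frame with `genome_id`, `completeness`,
#'   `contamination`, `length_bp` used for representative selection.
#' @return data.frame with one row per genome: `genome_id`, `cluster`
#'   (integer label), `representative` (logical).
#' @examples
#' sim <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
#'                   gani = c(98, 97), af = c(50, 40))
#' q <- data.frame(genome_id = c("A", "B", "C"),
#'                 completeness = c(95, 80, 99), contamination = c(1, 2, 5),
#'                 length_bp = c(3e6, 2e6, 4e6))
#' clusterMAGs(sim, c("A", "B", "C"), quality = q)
#' @export
clusterMAGs <- function(sim, ids, ganiMin = 96.5, afMin = 30, quality) {
    if (ganiMin < 0 || ganiMin > 100 || afMin < 0 || afMin > 100)
        stop("thresholds must lie in [0, 100]")
    sim <- as.data.frame(sim)
    unknown <- setdiff(unique(c(sim$id_a, sim$id_b)), ids)
    if (length(unknown))
        stop("similarity table mentions unknown genome ID(s): ",
             paste(unknown, collapse = ", "))
    quality <- as.data.frame(quality)
    if (!all(ids %in% quality$genome_id))
        stop("quality metrics missing for: ",
             paste(setdiff(ids, quality$genome_id), collapse = ", "))

    # min over the two orientations of each unordered pair
    if (nrow(sim)) {
        key <- ifelse(sim$id_a < sim$id_b,
                      paste(sim$id_a, sim$id_b, sep = "\r"),
                      paste(sim$id_b, sim$id_a, sep = "\r"))
        gani <- tapply(sim$gani, key, min)
        af <- tapply(sim$af, key, min)
        keep <- gani >= ganiMin & af >= afMin
        pairs <- do.call(rbind, strsplit(names(gani)[keep], "\r", fixed = TRUE))
    } else pairs <- NULL

    g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
        igraph::vertices(ids)
    if (!is.null(pairs) && length(pairs))
        g <- igraph::add_edges(g, t(pairs))
    comp <- igraph::components(g)
    membership <- comp$membership[ids]

    q <- quality[match(ids, quality$genome_id), ]
    rep_flag <- logical(length(ids))
    for (cl in unique(membership)) {
        i <- which(membership == cl)
        o <- order(-q$completeness[i], q$contamination[i], -q$length_bp[i])
        rep_flag[i[o[1L]]] <- TRUE
    }
    data.frame(genome_id = ids, cluster = as.integer(membership),
               representative = rep_flag, row.names = NULL)
}
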