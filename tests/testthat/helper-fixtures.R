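# shared fixture builders; everything is generated in code, no files

# minimal fraction metadata: one sample, K fractions on an even density grid
make_fraction_meta <- function(sample_id = "S1", condition = "control",
                               K = 4, densities = seq(1.70, 1.76,
                                                      length.out = K),
                               replicate = 1L, dna_conc = 5) {
    data.frame(library_id = sprintf("%s_F%02d", sample_id, seq_len(K)),
               sample_id = sample_id, replicate = replicate,
               condition = condition, isotope = "13C",
               fraction_index = seq_len(K), density = densities,
               dna_conc = dna_conc)
}

# a tiny multi-sample SipExperiment with hand-set genome coverages
make_tiny_experiment <- function(cov, samples = list(C1 = "control",
                                                     T1 = "treatment"),
                                 K = 4,
                                 densities = seq(1.70, 1.76, length.out = K),
                                 genomeMeta = NULL, dna_conc = 5) {
    fm <- do.call(rbind, lapply(names(samples), function(s)
        make_fraction_meta(s, samples[[s]], K = K, densities = densities,
                           dna_conc = dna_conc)))
    sipExperiment(cov, fm, genomeMeta = genomeMeta)
}

# independent brute-force connected components by breadth-first search
# over the thresholded min-orientation similarity graph
bfs_components <- function(ids, sim, gani_min, af_min) {
    adj <- matrix(FALSE, length(ids), length(ids),
                  dimnames = list(ids, ids))
    if (nrow(sim)) {
        # min over every record of an unordered pair, both orientations
        for (a in ids) for (b in ids) {
            if (a >= b) next
            hit <- (sim$id_a == a & sim$id_b == b) |
                   (sim$id_a == b & sim$id_b == a)
            if (!any(hit)) next
            if (min(sim$gani[hit]) >= gani_min &&
                min(sim$af[hit]) >= af_min)
                adj[a, b] <- adj[b, a] <- TRUE
        }
    }
    comp <- rep(NA_integer_, length(ids)); names(comp) <- ids
    cl <- 0L
    for (v in ids) {
        if (!is.na(comp[v])) next
        cl <- cl + 1L
        queue <- v
        while (length(queue)) {
            u <- queue[1L]; queue <- queue[-1L]
            if (!is.na(comp[u])) next
            comp[u] <- cl
            queue <- c(queue, ids[adj[u, ] & is.na(comp)])
        }
    }
    comp
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x, digits) {
    sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
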