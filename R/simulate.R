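#' Mass-weighted effective atom fraction excess of a DNA mixture
#'
#' Mixing unlabeled and labeled DNA of the same organism emulates an
#' intermediate enrichment level: because the weighted mean buoyant density
#' is linear in mass, a mixture behaves exactly like uniformly labeled DNA
#' with the mass-weighted mean AFE (e.g. 20 mass units at 0% plus 30 at
#' 54% gives 32.4%, i.e. 32% to the nearest percent).
#'
#' @param mass positive masses of the components.
#' @param afe atom fraction excess of each component, parallel to `mass`.
#' @return effective atom fraction excess.
#' @examples
#' effectiveMixtureAFE(c(20, 30), c(0, 0.54))  # 0.324
#' @export
effectiveMixtureAFE <- function(mass, afe) {
    if (!length(mass)) stop("empty mixture")
    if (length(mass) != length(afe)) stop("mass and afe differ in length")
    if (any(mass <= 0)) stop("masses must be positive")
    sum(mass * afe) / sum(mass)
}

#' Buoyant density of the labeled peak for a given enrichment
#'
#' Inverts the qSIP model: for GC content `G` and atom fraction excess
#' `afe`, the labeled molecular weight is
#' `M_Lab = M_Light + afe / (1 - a) * (M_Heavymax - M_Light)` and the peak
#' density is `theoreticalDensity(G) * M_Lab / M_Light`. Placing simulated
#' DNA at this density guarantees that the qSIP pipeline recovers `afe`
#' exactly on noiseless data.
#'
#' @param gc GC content in \[0, 1\].
#' @param afe atom fraction excess in \[0, 1 - naturalAbundance\].
#' @param params an [isotopeParams()] list.
#' @return g/mL (vectorized over `gc`/`afe`).
#' @examples
#' labeledCenterDensity(0.504, 0.32)  # ~1.726859
#' @export
labeledCenterDensity <- function(gc, afe, params = isotopeParams("13C")) {
    amax <- 1 - params$naturalAbundance
    if (any(afe < 0) || any(afe > amax))
        stop("afe must lie in [0, ", format(amax), "]")
    ML <- mLight(gc)
    MLabv <- ML + afe / amax * (mHeavyMax(gc, params) - ML)
    theoreticalDensity(gc) * MLabv / ML
}

#' Default genome panel for simulated SIP experiments
#'
#' Emulates the study design of an environmental community amended with an
#' isotopically labeled organism: `nUnlabeled` community genomes (AFE 0, GC
#' spread 0.30-0.70, log-spread total abundances) plus one labeled focal
#' genome of GC 0.504 at the given enrichment.
#'
#' @param nUnlabeled number of unlabeled community genomes.
#' @param labeledAfe true AFE of the focal genome (0 for an all-null
#'   community; the genome is still included).
#' @param labeledAbundance total abundance of the focal genome.
#' @return data.frame with columns `genome_id`, `gc`, `length_bp`,
#'   `total_abundance`, `true_afe`.
#' @export
defaultGenomePanel <- function(nUnlabeled = 10, labeledAfe = 0.32,
                               labeledAbundance = 1) {
    i <- seq_len(nUnlabeled)
    comm <- data.frame(
        genome_id = sprintf("MAG%02d", i),
        gc = seq(0.30, 0.70, length.out = max(nUnlabeled, 2L))[i],
        length_bp = round(seq(2e6, 6e6, length.out = max(nUnlabeled, 2L)))[i],
        total_abundance = round(2^seq(-2, 2,
                                      length.out = max(nUnlabeled, 2L)),
                                4)[i],
        true_afe = rep(0, nUnlabeled))
    rbind(comm,
          data.frame(genome_id = "FOCAL", gc = 0.504, length_bp = 4.6e6,
                     total_abundance = labeledAbundance,
                     true_afe = labeledAfe))
}

#' Configuration of a simulated SIP metagenomics experiment
#'
#' Collects the experimental conditions the simulator reproduces: the
#' genome panel with true enrichments, replicate structure (3 control + 3
#' treatment by default), a 16-fraction density grid spanning 1.67-1.77
#' g/mL, the within-gradient Gaussian spread, multiplicative coverage
#' noise, sequencing depth, and the sequin and spike-in references. Sequins
#' default to 12 standards in 4 four-fold concentration groups, dosed 300
#' units into the middle eight fractions and 100 units into the four
#' fractions on either tail; six spike-ins tile the gradient in close
#' pairs so that any local reordering of fractions perturbs their expected
#' peak order.
#'
#' @param genomes genome panel data.frame (see [defaultGenomePanel()]).
#' @param mixtures optional named list: `genome_id` -> data.frame with
#'   `mass`, `afe` describing an unlabeled/labeled DNA mixture for that
#'   genome (overrides its `true_afe` with the effective mixture AFE).
#' @param nControlReps,nTreatmentReps biological replicates per condition.
#' @param isotope `"13C"` or `"18O"`.
#' @param densityGrid strictly increasing fraction densities (g/mL).
#' @param peakSd within-gradient Gaussian spread (g/mL); the default 0.006
#'   makes a genome span roughly 4-6 fractions of the default grid.
#' @param coverageNoiseCv coefficient of variation of multiplicative
#'   lognormal coverage noise (0 = noiseless).
#' @param depthFactor mean coverage per unit abundance per library.
#' @param depthLogSd lognormal spread of per-library depth (sequins absorb
#'   it during scaling).
#' @param sequinSpec data.frame `sequin_id`, `concentration`, `group`.
#' @param sequinDose per-fraction dose multipliers (length of
#'   `densityGrid`); known to the scaling step via the dataset metadata.
#' @param spikeinSpec data.frame `spikein_id`, `expected_peak_density`,
#'   `gc`, `label_fraction`.
#' @param spikeinAbundance total abundance of each spike-in.
#' @param seed integer seed making the dataset deterministic.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(genomes = defaultGenomePanel(), mixtures = NULL,
                      nControlReps = 3, nTreatmentReps = 3,
                      isotope = c("13C", "18O"),
                      densityGrid = seq(1.67, 1.77, length.out = 16),
                      peakSd = 0.006, coverageNoiseCv = 0,
                      depthFactor = 100, depthLogSd = 0.1,
                      sequinSpec = NULL, sequinDose = NULL,
                      spikeinSpec = NULL, spikeinAbundance = 0.05,
                      seed = 1) {
    isotope <- match.arg(isotope)
    if (any(diff(densityGrid) <= 0))
        stop("densityGrid must be strictly increasing")
    if (peakSd <= 0) stop("peakSd must be positive")
    if (coverageNoiseCv < 0) stop("coverageNoiseCv must be non-negative")
    K <- length(densityGrid)
    if (is.null(sequinSpec))
        sequinSpec <- data.frame(
            sequin_id = sprintf("SEQ%02d", 1:12),
            concentration = rep(c(0.5, 2, 8, 32), each = 3),
            group = rep(paste0("grp", 1:4), each = 3))
    if (is.null(sequinDose)) {
        sequinDose <- rep(100, K)
        mid <- seq_len(K) > ceiling(K / 4) & seq_len(K) <= K - floor(K / 4)
        sequinDose[mid] <- 300
    }
    if (length(sequinDose) != K)
        stop("sequinDose must match the density grid length")
    if (is.null(spikeinSpec)) {
        pk <- pmin(c(3L, 4L, 7L, 8L, 11L, 12L), K - 1L)
        d <- densityGrid[pk]
        spikeinSpec <- data.frame(
            spikein_id = sprintf("SPK%d", seq_along(pk)),
            expected_peak_density = d,
            gc = round(pmin(pmax((d - 1.66) / 0.098, 0), 1), 3),
            label_fraction = 0)
    }
    genomes <- as.data.frame(genomes)
    if (!is.null(mixtures)) {
        for (g in names(mixtures)) {
            i <- match(g, genomes$genome_id)
            if (is.na(i)) stop("mixture for unknown genome: ", g)
            genomes$true_afe[i] <-
                effectiveMixtureAFE(mixtures[[g]]$mass, mixtures[[g]]$afe)
        }
    }
    structure(list(genomes = genomes, mixtures = mixtures,
                   nControlReps = nControlReps,
                   nTreatmentReps = nTreatmentReps, isotope = isotope,
                   densityGrid = densityGrid, peakSd = peakSd,
                   coverageNoiseCv = coverageNoiseCv,
                   depthFactor = depthFactor, depthLogSd = depthLogSd,
                   sequinSpec = sequinSpec, sequinDose = sequinDose,
                   spikeinSpec = spikeinSpec,
                   spikeinAbundance = spikeinAbundance, seed = seed),
              class = "SimConfig")
}

# Gaussian weights on the truncated grid, tilted so the discretized
# abundance-weighted mean equals `center` exactly (closed-form first-order
# moment correction); total mass is conserved by renormalization.
.gradient_weights <- function(grid, center, sd) {
    w <- stats::dnorm(grid, center, sd)
    if (sum(w) == 0) { # center far off-grid: put everything at the edge
        w[which.min(abs(grid - center))] <- 1
        return(w)
    }
    w <- w / sum(w)
    m1 <- sum(w * grid)
    m2 <- sum(w * grid^2)
    denom <- m2 - 2 * center * m1 + center^2
    if (denom > 0) {
        lam <- (center - m1) / denom
        w <- w * (1 + lam * (grid - center))
        w[w < 0] <- 0
    }
    w / sum(w)
}

#' Simulate a SIP metagenomics dataset with known ground truth
#'
#' Generates a full [SipExperiment-class] — genome, sequin and spike-in
#' coverage across density-gradient fractions of replicated control and
#' treatment samples — from a [simConfig()]. Per genome and replicate, DNA
#' mass is spread over the density grid as a renormalized Gaussian centered
#' at [labeledCenterDensity()] (control replicates at enrichment 0;
#' mixtures as mass-weighted sums of component Gaussians); coverage is mass
#' times a per-library depth factor times multiplicative lognormal noise.
#' Sequins respond linearly to their known dosed concentrations through the
#' same library depth, and spike-ins sit at their expected peak densities.
#' The ground-truth AFE of every genome is recorded on the object.
#'
#' @param config a [simConfig()] list.
#' @return a [SipExperiment-class] with raw `"coverage"` assay, references
#'   and `truthAFE()`; per-library sequin dose factors are stored in
#'   `metadata(x)$sequin_dose`.
#' @examples
#' sim <- simulateSipExperiment(simConfig(seed = 7))
#' sim
#' @export
simulateSipExperiment <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    .local_seed(config$seed, {
        grid <- config$densityGrid
        K <- length(grid)
        params <- isotopeParams(config$isotope)
        samples <- c(sprintf("C%d", seq_len(config$nControlReps)),
                     sprintf("T%d", seq_len(config$nTreatmentReps)))
        condition <- rep(c("control", "treatment"),
                         c(config$nControlReps, config$nTreatmentReps))
        replicate <- c(seq_len(config$nControlReps),
                       seq_len(config$nTreatmentReps))
        fm <- do.call(rbind, lapply(seq_along(samples), function(s)
            data.frame(library_id = sprintf("%s_F%02d", samples[s],
                                            seq_len(K)),
                       sample_id = samples[s], replicate = replicate[s],
                       condition = condition[s], isotope = config$isotope,
                       fraction_index = seq_len(K), density = grid,
                       dna_conc = 0)))
        depth <- config$depthFactor *
            stats::rlnorm(nrow(fm), -config$depthLogSd^2 / 2,
                          config$depthLogSd)
        names(depth) <- fm$library_id

        g <- config$genomes
        noise <- function(n) {
            cv <- config$coverageNoiseCv
            if (cv == 0) return(rep(1, n))
            sdl <- sqrt(log(1 + cv^2))
            stats::rlnorm(n, -sdl^2 / 2, sdl)
        }
        genome_mass <- function(gc, afe, total) {
            # mixtures: mass-weighted sum of per-component placements
            comps <- data.frame(mass = total, afe = afe)
            w <- rowSums(vapply(seq_len(nrow(comps)), function(ci)
                comps$mass[ci] * .gradient_weights(
                    grid, labeledCenterDensity(gc, comps$afe[ci], params),
                    config$peakSd), numeric(K)))
            w
        }

        nfeat <- nrow(g) + nrow(config$sequinSpec) +
            nrow(config$spikeinSpec)
        cov <- matrix(0, nfeat, nrow(fm),
                      dimnames = list(c(g$genome_id,
                                        config$sequinSpec$sequin_id,
                                        config$spikeinSpec$spikein_id),
                                      fm$library_id))
        dose <- config$sequinDose / 100   # relative to tail dose
        for (s in seq_along(samples)) {
            libs <- fm$library_id[fm$sample_id == samples[s]]
            treat <- condition[s] == "treatment"
            total_mass <- numeric(K)
            for (i in seq_len(nrow(g))) {
                afe_i <- if (treat) g$true_afe[i] else 0
                mx <- config$mixtures[[g$genome_id[i]]]
                mass <- if (treat && !is.null(mx))
                    genome_mass(g$gc[i],
                                mx$afe,
                                mx$mass / sum(mx$mass) *
                                    g$total_abundance[i])
                else genome_mass(g$gc[i], afe_i, g$total_abundance[i])
                total_mass <- total_mass + mass
                cov[g$genome_id[i], libs] <-
                    mass * depth[libs] * noise(K)
            }
            fm$dna_conc[fm$sample_id == samples[s]] <- total_mass
            for (i in seq_len(nrow(config$sequinSpec)))
                cov[config$sequinSpec$sequin_id[i], libs] <-
                    config$sequinSpec$concentration[i] * dose *
                    depth[libs] * noise(K)
            for (i in seq_len(nrow(config$spikeinSpec))) {
                w <- .gradient_weights(
                    grid, config$spikeinSpec$expected_peak_density[i],
                    config$peakSd)
                cov[config$spikeinSpec$spikein_id[i], libs] <-
                    config$spikeinAbundance * w * depth[libs] * noise(K)
            }
        }
        se <- sipExperiment(
            cov, fm,
            genomeMeta = data.frame(genome_id = g$genome_id, gc = g$gc,
                                    length_bp = g$length_bp,
                                    completeness = 100, contamination = 0),
            sequinRef = config$sequinSpec,
            spikeinRef = config$spikeinSpec,
            truth = stats::setNames(g$true_afe, g$genome_id))
        S4Vectors::metadata(se)$sequin_dose <-
            stats::setNames(rep(dose, length(samples)), fm$library_id)
        S4Vectors::metadata(se)$sim_seed <- config$seed
        se
    })
}

#' Disturb the density gradient of one simulated sample
#'
#' Permutes the assignment of feature abundances to fractions within one
#' sample while leaving the recorded fraction densities untouched —
#' emulating an accidentally disturbed or mishandled gradient.
#' `"swap_adjacent"` transposes every adjacent pair of fractions (an
#' involution: applying it twice restores the data); `"shuffle"` applies a
#' random permutation.
#'
#' @param x a [SipExperiment-class].
#' @param sampleId sample whose gradient is disturbed.
#' @param mode `"swap_adjacent"` or `"shuffle"`.
#' @param seed seed for `"shuffle"`.
#' @return the modified [SipExperiment-class].
#' @export
disturbGradient <- function(x, sampleId,
                            mode = c("swap_adjacent", "shuffle"),
                            seed = 1) {
    mode <- match.arg(mode)
    fm <- fractionData(x)
    libs <- fm$library_id[fm$sample_id == sampleId]
    if (!length(libs)) stop("unknown sample: ", sampleId)
    K <- length(libs)
    perm <- if (mode == "swap_adjacent") {
        p <- seq_len(K)
        for (i in seq(1L, K - 1L, by = 2L)) p[c(i, i + 1L)] <- p[c(i + 1L, i)]
        p
    } else .local_seed(seed, sample.int(K))
    a <- SummarizedExperiment::assay(x)
    a[, libs] <- a[, libs[perm]]
    SummarizedExperiment::assay(x) <- a
    x
}

#' Thin a genome's coverage to emulate read subsampling
#'
#' Replaces a genome's coverage values by Poisson draws with mean
#' `factor * coverage`, expressed through the implied read count
#' (`coverage * length / readLength`), reproducing the effect of
#' subsampling that genome's reads to a given percentage before coverage
#' calculation.
#'
#' @param x a [SipExperiment-class] holding raw coverage.
#' @param genomeId genome to thin.
#' @param factor retention fraction in (0, 1\].
#' @param seed integer seed.
#' @param readLength nominal read length (bp) for the coverage-to-reads
#'   conversion.
#' @return the modified [SipExperiment-class].
#' @export
diluteCoverage <- function(x, genomeId, factor, seed = 1,
                           readLength = 150) {
    if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]")
    if (!genomeId %in% rownames(x)) stop("unknown genome: ", genomeId)
    if (factor == 1) return(x)
    len <- SummarizedExperiment::rowData(x)[genomeId, "length_bp"]
    if (is.null(len) || is.na(len))
        stop("genome length required for coverage thinning")
    a <- SummarizedExperiment::assay(x)
    reads <- a[genomeId, ] * len / readLength
    a[genomeId, ] <- .local_seed(seed,
        stats::rpois(length(reads), factor * reads)) * readLength / len
    SummarizedExperiment::assay(x) <- a
    x
}
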