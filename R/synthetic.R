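# Multi-cohort synthetic data with the statistical structure the analysis
# assumes: a latent co-regulator drives a planted HMT module, a methyl-sink
# gene is coupled (negatively) to standardized total HMT expression, a
# metabolite tracks sink activity, and per-locus chromatin signal is
# coupled to sink expression. Ground truth is returned for
# parameter-recovery tests.

#' Simulation configuration
#'
#' Encodes the generative assumptions of the synthetic multi-cohort world.
#' Defaults describe a realistic bulk RNA-seq setting: three cohorts of
#' 100 samples, a 40-gene co-regulated module among 1,000 genes,
#' negative-binomial counts with moderate overdispersion, log-normal
#' library sizes, donors contributing 1-3 samples across cohorts, and a
#' sink coupling chosen so that pooled-module/sink correlations land in
#' the -0.3 to -0.5 range typical of the real data this emulates.
#'
#' @param n_cohorts Number of cohorts (tissue/cancer types).
#' @param samples_per_cohort Samples per cohort.
#' @param n_genes Total genes, including the module and the sink.
#' @param n_hmt Size of the planted co-regulated (HMT-like) module.
#' @param regulator_sd Spread of the latent regulator R across samples.
#' @param hmt_loading_mean,hmt_loading_sd Per-module-gene coupling a_i to
#'   R, drawn Normal(mean, sd).
#' @param sink_coupling Coupling b (must be <= 0) of the sink gene's
#'   log-mean to the z-score of summed module pseudocounts.
#' @param metabolite_coupling Coupling of the tracked metabolite to the
#'   sink expression z-score.
#' @param nb_dispersion Negative-binomial dispersion phi (> 0);
#'   variance = mu + phi * mu^2.
#' @param library_size_sd SD of log library-size factors (log-normal).
#' @param cohort_effect_sd SD of per-gene, per-cohort baseline offsets
#'   (tissue-specific expression).
#' @param covariate_effects Named numeric vector: each named covariate is
#'   drawn standard normal per sample and shifts every gene's log-mean by
#'   effect * value.
#' @param mutation_fraction Fraction of samples carrying the mutation.
#' @param mutation_regulator_shift Additive shift of R in mutant samples
#'   (the regulator-mediated, "chain" path).
#' @param mutation_sink_shift Additive shift of the sink log-mean in
#'   mutant samples (a direct, "independent-arms" path; default 0).
#' @param max_samples_per_donor Donors contribute 1..k samples spread
#'   across cohorts.
#' @param chip_effect_mean,chip_effect_sd Per-locus coupling beta_l of
#'   chromatin signal to sink expression, drawn Normal and truncated at 0
#'   so that marked loci get beta_l <= 0.
#' @param chip_noise_sd Residual SD of per-locus signal.
#' @param chip_donor_sd SD of per-locus donor random intercepts.
#' @param n_loci Number of genomic loci.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3L,
                       samples_per_cohort = 100L,
                       n_genes = 1000L,
                       n_hmt = 40L,
                       regulator_sd = 1,
                       hmt_loading_mean = 0.5,
                       hmt_loading_sd = 0.1,
                       sink_coupling = -0.3,
                       metabolite_coupling = 1,
                       nb_dispersion = 0.15,
                       library_size_sd = 0.2,
                       cohort_effect_sd = 0.5,
                       covariate_effects = c(batch = 0.1),
                       mutation_fraction = 0.2,
                       mutation_regulator_shift = 1,
                       mutation_sink_shift = 0,
                       max_samples_per_donor = 3L,
                       chip_effect_mean = -0.5,
                       chip_effect_sd = 0.1,
                       chip_noise_sd = 0.5,
                       chip_donor_sd = 0.25,
                       n_loci = 200L,
                       seed = 1L) {
  cfg <- list(
    n_cohorts = check_count(n_cohorts, "n_cohorts"),
    samples_per_cohort = check_count(samples_per_cohort,
                                     "samples_per_cohort", 2L),
    n_genes = check_count(n_genes, "n_genes", 3L),
    n_hmt = check_count(n_hmt, "n_hmt"),
    regulator_sd = check_scalar_number(regulator_sd, "regulator_sd", 0,
                                       strict_lower = TRUE),
    hmt_loading_mean = check_scalar_number(hmt_loading_mean,
                                           "hmt_loading_mean"),
    hmt_loading_sd = check_scalar_number(hmt_loading_sd, "hmt_loading_sd",
                                         0),
    sink_coupling = check_scalar_number(sink_coupling, "sink_coupling",
                                        upper = 0),
    metabolite_coupling = check_scalar_number(metabolite_coupling,
                                              "metabolite_coupling"),
    nb_dispersion = check_scalar_number(nb_dispersion, "nb_dispersion", 0,
                                        strict_lower = TRUE),
    library_size_sd = check_scalar_number(library_size_sd,
                                          "library_size_sd", 0),
    cohort_effect_sd = check_scalar_number(cohort_effect_sd,
                                           "cohort_effect_sd", 0),
    covariate_effects = covariate_effects,
    mutation_fraction = check_scalar_number(mutation_fraction,
                                            "mutation_fraction", 0, 1),
    mutation_regulator_shift = check_scalar_number(mutation_regulator_shift,
                                                   "mutation_regulator_shift"),
    mutation_sink_shift = check_scalar_number(mutation_sink_shift,
                                              "mutation_sink_shift"),
    max_samples_per_donor = check_count(max_samples_per_donor,
                                        "max_samples_per_donor"),
    chip_effect_mean = check_scalar_number(chip_effect_mean,
                                           "chip_effect_mean"),
    chip_effect_sd = check_scalar_number(chip_effect_sd, "chip_effect_sd",
                                         0),
    chip_noise_sd = check_scalar_number(chip_noise_sd, "chip_noise_sd", 0),
    chip_donor_sd = check_scalar_number(chip_donor_sd, "chip_donor_sd", 0),
    n_loci = check_count(n_loci, "n_loci"),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$n_hmt + 1L > cfg$n_genes) {
    stop_config("n_hmt", "module plus sink must fit inside n_genes")
  }
  if (!is.null(covariate_effects) && length(covariate_effects) &&
      is.null(names(covariate_effects))) {
    stop_config("covariate_effects", "must be a named numeric vector")
  }
  structure(cfg, class = "sim_config")
}

# Donor assignment: donors contribute 1..k samples, each in a distinct
# cohort, exercising the random-intercept path downstream.
assign_donors <- function(n_cohorts, per_cohort, k) {
  remaining <- rep(per_cohort, n_cohorts)
  donor_of <- matrix(NA_character_, n_cohorts, per_cohort)
  next_slot <- rep(1L, n_cohorts)
  donor_id <- 0L
  while (any(remaining > 0L)) {
    donor_id <- donor_id + 1L
    open <- which(remaining > 0L)
    size <- min(sample.int(k, 1L), length(open))
    chosen <- if (length(open) == 1L) open else sample(open, size)
    for (co in chosen) {
      donor_of[co, next_slot[co]] <- sprintf("d%04d", donor_id)
      next_slot[co] <- next_slot[co] + 1L
      remaining[co] <- remaining[co] - 1L
    }
  }
  as.vector(t(donor_of))
}

#' Simulate a multi-cohort expression and metabolite dataset
#'
#' Counts are negative binomial around log-linear means: gene baseline +
#' per-cohort offset + covariate effects + a_i * R for module genes; the
#' sink gene's log-mean additionally receives
#' `sink_coupling * z(total module pseudocounts)` and any direct mutation
#' shift. One metabolite tracks the sink expression z-score; further
#' metabolites are pure noise. Mutation carriers receive a shift of the
#' latent regulator.
#'
#' @param config A [sim_config()].
#' @return list of class `methylsink_sim` with elements `counts` (matrix,
#'   genes x samples), `metadata` (data.frame: sample_id, cohort, donor,
#'   covariates, mutant), `metabolites` (matrix, metabolites x samples),
#'   `hmt_set` (the planted [gene_set()]), `sink_gene`, and `truth`
#'   (regulator values, loadings, sink coupling, sink z-scores, locus
#'   betas, mutation status).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created by sim_config()")
  }
  with_seed(config$seed, {
    n_c <- config$n_cohorts
    spc <- config$samples_per_cohort
    n <- n_c * spc
    n_g <- config$n_genes
    n_h <- config$n_hmt

    cohorts <- rep(sprintf("cohort%02d", seq_len(n_c)), each = spc)
    sample_ids <- sprintf("s%04d", seq_len(n))
    donors <- assign_donors(n_c, spc, config$max_samples_per_donor)
    mutant <- runif(n) < config$mutation_fraction

    covs <- list()
    for (nm in names(config$covariate_effects)) {
      covs[[nm]] <- rnorm(n)
    }

    regulator <- rnorm(n, 0, config$regulator_sd) +
      config$mutation_regulator_shift * mutant

    gene_ids <- c(sprintf("HMT%02d", seq_len(n_h)), "SINK",
                  sprintf("G%04d", seq_len(n_g - n_h - 1L)))
    baseline <- c(rep(log(500), n_h), log(1000),
                  rnorm(n_g - n_h - 1L, log(200), 1))
    loadings <- rnorm(n_h, config$hmt_loading_mean, config$hmt_loading_sd)

    cohort_offsets <- matrix(rnorm(n_g * n_c, 0, config$cohort_effect_sd),
                             n_g, n_c)
    lib <- exp(rnorm(n, 0, config$library_size_sd))

    log_mu <- baseline + cohort_offsets[, rep(seq_len(n_c), each = spc)]
    for (nm in names(config$covariate_effects)) {
      log_mu <- log_mu +
        rep(config$covariate_effects[[nm]] * covs[[nm]], each = n_g)
    }
    hmt_rows <- seq_len(n_h)
    log_mu[hmt_rows, ] <- log_mu[hmt_rows, ] + outer(loadings, regulator)

    size <- 1 / config$nb_dispersion
    mu <- exp(log_mu) * rep(lib, each = n_g)
    counts <- matrix(rnbinom(n_g * n, mu = mu, size = size), n_g, n,
                     dimnames = list(gene_ids, sample_ids))

    # Sink responds to realized, library-corrected module totals.
    total_hmt <- colSums(counts[hmt_rows, , drop = FALSE]) / lib
    z_tot <- as.numeric(scale(total_hmt))
    sink_row <- n_h + 1L
    sink_mu <- exp(log_mu[sink_row, ] + config$sink_coupling * z_tot +
                     config$mutation_sink_shift * mutant) * lib
    counts[sink_row, ] <- rnbinom(n, mu = sink_mu, size = size)

    sink_z <- as.numeric(scale(log1p(counts[sink_row, ] / lib)))
    metab <- rbind(
      MET_sink = config$metabolite_coupling * sink_z + rnorm(n),
      matrix(rnorm(4L * n), 4L, n,
             dimnames = list(sprintf("MET_noise%d", 1:4), NULL))
    )
    colnames(metab) <- sample_ids

    locus_betas <- pmin(0, rnorm(config$n_loci, config$chip_effect_mean,
                                 config$chip_effect_sd))

    metadata <- data.frame(sample_id = sample_ids, cohort = cohorts,
                           donor = donors, mutant = mutant,
                           stringsAsFactors = FALSE)
    for (nm in names(covs)) metadata[[nm]] <- covs[[nm]]

    truth <- list(regulator_values = setNames(regulator, sample_ids),
                  hmt_loadings = setNames(loadings, gene_ids[hmt_rows]),
                  sink_coupling = config$sink_coupling,
                  sink_z = setNames(sink_z, sample_ids),
                  locus_betas = locus_betas,
                  library_factors = setNames(lib, sample_ids),
                  mutation_status = setNames(mutant, sample_ids))

    structure(list(counts = counts, metadata = metadata,
                   metabolites = metab,
                   hmt_set = gene_set("HMT", gene_ids[hmt_rows]),
                   sink_gene = "SINK", truth = truth),
              class = "methylsink_sim")
  })
}

#' Simulate per-locus chromatin signal coupled to sink expression
#'
#' Per-locus mean log2 fold-change-over-input signal is
#' `mu_l + beta_l * z(sink expression) + donor intercept + noise`, where
#' the planted `beta_l <= 0` come from the truth produced by
#' [simulate_cohort()]. Peak presence per (locus, sample) is Bernoulli
#' with probability increasing in the realized signal, yielding
#' per-sample BED-style peak sets.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result (or
#'   the result itself).
#' @param config The same [sim_config()] used to generate the truth.
#' @return list with `signal` (matrix, loci x samples), `regions`
#'   (data.frame: chrom, start, end, strand, id, class), `peaks` (named
#'   list of per-sample BED data.frames), `donors` (per-sample donor IDs).
#' @export
simulate_chip_signal <- function(truth, config) {
  if (inherits(truth, "methylsink_sim")) {
    donors <- truth$metadata$donor
    truth <- truth$truth
  } else {
    donors <- NULL
  }
  n <- length(truth$sink_z)
  if (n != config$n_cohorts * config$samples_per_cohort) {
    stop("truth sample set does not match config dimensions")
  }
  if (length(truth$locus_betas) != config$n_loci) {
    stop("truth locus set does not match config n_loci")
  }
  with_seed(derive_seed(config$seed, 7L), {
    n_l <- config$n_loci
    sample_ids <- names(truth$sink_z)
    if (is.null(donors)) donors <- sample_ids
    locus_ids <- sprintf("locus%04d", seq_len(n_l))
    regions <- data.frame(chrom = "chr1",
                          start = (seq_len(n_l) - 1L) * 10000L,
                          end = (seq_len(n_l) - 1L) * 10000L + 1000L,
                          strand = "+", id = locus_ids,
                          class = "promoter", stringsAsFactors = FALSE)
    mu_l <- rnorm(n_l, 1, 0.5)
    donor_levels <- unique(donors)
    donor_eff <- matrix(rnorm(n_l * length(donor_levels), 0,
                              config$chip_donor_sd),
                        n_l, length(donor_levels),
                        dimnames = list(NULL, donor_levels))
    signal <- mu_l + outer(truth$locus_betas, truth$sink_z) +
      donor_eff[, donors, drop = FALSE] +
      matrix(rnorm(n_l * n, 0, config$chip_noise_sd), n_l, n)
    dimnames(signal) <- list(locus_ids, sample_ids)
    present <- matrix(runif(n_l * n) < plogis(2 * signal), n_l, n)
    peaks <- lapply(seq_len(n), function(j) {
      idx <- which(present[, j])
      data.frame(chrom = "chr1", start = regions$start[idx],
                 end = regions$end[idx], name = locus_ids[idx],
                 stringsAsFactors = FALSE)
    })
    names(peaks) <- sample_ids
    list(signal = signal, regions = regions, peaks = peaks,
         donors = setNames(donors, sample_ids))
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits counts, metadata, metabolites and the ground truth as TSV under
#' `dir` (creating it), and, when chromatin output is supplied, a
#' per-region signal TSV plus one BED peak file per sample.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory.
#' @param chip Optional [simulate_chip_signal()] result.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, chip = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_matrix_tsv(sim$metabolites, file.path(dir, "metabolites.tsv"),
                   id_column = "metabolite_id")
  write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- data.frame(sample_id = names(sim$truth$regulator_values),
                      regulator = sim$truth$regulator_values,
                      sink_z = sim$truth$sink_z,
                      mutant = sim$truth$mutation_status)
  write.table(truth, file.path(dir, "truth_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sim$hmt_set$members, file.path(dir, "hmt_set.txt"))
  if (!is.null(chip)) {
    write_matrix_tsv(chip$signal, file.path(dir, "signal.tsv"),
                     id_column = "region_id")
    write_bed(chip$regions, file.path(dir, "regions.bed"))
    peak_dir <- file.path(dir, "peaks")
    dir.create(peak_dir, showWarnings = FALSE)
    for (s in names(chip$peaks)) {
      write_bed(chip$peaks[[s]], file.path(peak_dir, paste0(s, ".bed")))
    }
  }
  invisible(dir)
}
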