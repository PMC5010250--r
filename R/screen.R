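#' Simulate and analyse a full selection-screen timecourse
#'
#' End-to-end pipeline on synthetic data: build the variant library (in
#' haploid mode, apply the viability bottleneck before T0), propagate it
#' through successive passages under selection with bottleneck drift,
#' sequence every timepoint plus a wild-type background sample (all samples
#' share one per-locus error profile, as they would share one amplicon and
#' chemistry), fit the hierarchical model to each sample, call variants of
#' each timepoint against the background for the diversity score and
#' against T0 for the timecourse call set.
#'
#' @param config a [sim_config()]; for screens at reduced scale lower
#'   `n_alleles` and `loci` here.
#' @param mode `"diploid"` (no viability filter) or `"haploid"` (viability
#'   filter applied before T0).
#' @param n_timepoints number of sampled timepoints including T0.
#' @param mcmc an [mcmc_params()] (its `seed` is ignored; the screen is
#'   driven by `seed`).
#' @param cfg a [somatic_config()].
#' @param wt_replicates replicates for the background sample.
#' @param seed integer seed for the whole screen.
#' @param keep_fits keep the fitted posteriors in the result (memory-heavy).
#' @return A list with `mode`, `diversity` (data frame: timepoint, number of
#'   called variants, D or NA when undefined), `timecourse` (the
#'   [call_timecourse()] result against T0), `n_variant_positions`, `truth`
#'   (per-timepoint truth tables) and optionally `fits`.
#' @export
simulate_screen <- function(config, mode = c("diploid", "haploid"),
                            n_timepoints = 4, mcmc = mcmc_params(),
                            cfg = somatic_config(),
                            wt_replicates = config$n_replicates,
                            seed = NULL, keep_fits = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"), n_timepoints >= 2)
  if (!is.null(seed)) set.seed(seed)
  mcmc$seed <- NULL
  cfg$seed <- NULL

  pool <- build_library(config)
  if (mode == "haploid")
    pool <- apply_viability_filter(pool, config$viability_fraction)

  # one locus-error profile shared by all samples of the screen
  a <- config$error_model$shape1
  b <- a * (1 - config$error_model$mean) / config$error_model$mean
  locus_error <- rbeta(config$loci, a, b)

  labels <- paste0("T", seq_len(n_timepoints) - 1L)
  tensors <- list()
  truth <- list()
  sq <- sequence_pool(pool, config, locus_error = locus_error, sample = "T0")
  tensors$T0 <- sq$tensor; truth$T0 <- sq$truth
  for (t in labels[-1]) {
    pool <- propagate(pool, g = config$generations_per_passage,
                      bottleneck_size = config$bottleneck_size)
    sq <- sequence_pool(pool, config, locus_error = locus_error, sample = t)
    tensors[[t]] <- sq$tensor; truth[[t]] <- sq$truth
  }
  wt <- sequence_background(config, ref = pool$ref, locus_error = locus_error,
                            n_replicates = wt_replicates, sample = "WT")
  tensors$WT <- wt$tensor

  fits <- lapply(tensors, fit_vaf, mcmc = mcmc, keep_theta = FALSE)

  # diversity: variants of each timepoint called against the background,
  # scored with the timepoint's own VAF estimates
  div <- lapply(labels, function(t) {
    st <- somatic_test(fits[[t]], fits$WT, cfg)
    prov <- st[st$provisional & st$direction == "gain", , drop = FALSE]
    flt <- suppressMessages(
      nonuniformity_filter(tensors[[t]], prov$pos, cfg$alpha_chisq))
    vafs <- fits[[t]]$mu_hat[match(flt$pos, fits[[t]]$pos)]
    ds <- diversity_score(vafs)
    data.frame(timepoint = t, n_called = nrow(flt),
               D = if (ds$defined) ds$value else NA_real_,
               stringsAsFactors = FALSE)
  })
  diversity <- do.call(rbind, div)

  tc <- suppressMessages(
    call_timecourse(fits[labels], tensors[labels], control = "T0", cfg))

  out <- list(mode = mode, diversity = diversity, timecourse = tc,
              n_variant_positions = tc$n_union, truth = truth)
  if (keep_fits) out$fits <- fits
  out
}

#' Estimate the caller's detection limit by spike-in simulation
#'
#' Simulates a control tensor (baseline error only) and a case tensor with
#' `loci_per_level` loci spiked at each VAF level (plus `n_null` unspiked
#' loci), both at the configured depth and replicate structure and sharing
#' one per-locus error profile; fits both samples, runs the somatic test and
#' the chi-squared filter, and reports per-level sensitivity (the fraction
#' of spiked loci called) and the smallest level with sensitivity at least
#' `min_sensitivity`.
#'
#' @param levels spiked VAF levels, as fractions.
#' @param loci_per_level spiked loci per level.
#' @param n_null unspiked loci (used to report the false-positive rate).
#' @param n_replicates technical replicates.
#' @param depth_model,error_model as in [sim_config()].
#' @param mcmc an [mcmc_params()].
#' @param cfg a [somatic_config()].
#' @param min_sensitivity sensitivity threshold defining the limit.
#' @param seed integer seed.
#' @return A list with `sensitivity` (data frame: level, percent, n_called,
#'   sensitivity), `detection_limit_pct` (smallest qualifying level in
#'   percent, `Inf` when no level qualifies), `fpr` and `n_loci`.
#' @export
estimate_detection_limit <- function(levels = c(0.0005, 0.001, 0.002, 0.005, 0.01),
                                     loci_per_level = 50, n_null = 50,
                                     n_replicates = 3,
                                     depth_model = list(median = 20000, dispersion = 10),
                                     error_model = list(mean = 2e-4, shape1 = 0.5),
                                     mcmc = mcmc_params(),
                                     cfg = somatic_config(),
                                     min_sensitivity = 0.8,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mcmc$seed <- NULL
  cfg$seed <- NULL
  levels <- sort(levels)
  J <- loci_per_level * length(levels) + n_null
  vaf <- c(rep(levels, each = loci_per_level), rep(0, n_null))
  ref <- sample(DNA_BASES, J, replace = TRUE)
  a <- error_model$shape1
  b <- a * (1 - error_model$mean) / error_model$mean
  locus_error <- rbeta(J, a, b)

  case <- simulate_counts(vaf, ref, n_replicates = n_replicates,
                          depth_model = depth_model, error_model = error_model,
                          locus_error = locus_error, sample = "case",
                          chrom = "sim", region_start = 1L)
  ctrl <- simulate_counts(rep(0, J), ref, n_replicates = n_replicates,
                          depth_model = depth_model, error_model = error_model,
                          locus_error = locus_error, sample = "control",
                          chrom = "sim", region_start = 1L)

  fit_case <- fit_vaf(case$tensor, mcmc, keep_theta = FALSE)
  fit_ctrl <- fit_vaf(ctrl$tensor, mcmc, keep_theta = FALSE)
  st <- somatic_test(fit_case, fit_ctrl, cfg)
  prov <- st[st$provisional & st$direction == "gain", , drop = FALSE]
  flt <- suppressMessages(
    nonuniformity_filter(case$tensor, prov$pos, cfg$alpha_chisq))
  called <- case$tensor$pos %in% flt$pos

  sens <- vapply(levels, function(lv) mean(called[vaf == lv]), numeric(1))
  fpr <- if (n_null > 0) mean(called[vaf == 0]) else NA_real_
  pass <- levels[sens >= min_sensitivity]
  list(sensitivity = data.frame(level = levels, percent = 100 * levels,
                                n_called = vapply(levels, function(lv)
                                  sum(called[vaf == lv]), numeric(1)),
                                sensitivity = sens),
       detection_limit_pct = if (length(pass)) 100 * min(pass) else Inf,
       fpr = fpr, n_loci = J)
}

#' Published reference outcomes of the original region-wide screen
#'
#' Variant-position counts and diversity scores reported for the deposited
#' methotrexate-selection screen of the dihydrofolate reductase amplicon
#' (raw reads: NCBI SRA accession SRP072709). These are integration targets
#' for a full re-analysis of the deposited data — reproducing them requires
#' downloading the reads, running the documented upstream trimming /
#' alignment / mpileup commands over chrXV:780367-782084, and fitting every
#' sample with default MCMC settings; they are not reproducible from the
#' package's desk-scale simulations. `NA` marks timepoints where fewer than
#' two variants were called and the diversity score is undefined ("-").
#'
#' @return A data frame with one row per pool (diploid, haploid): the
#'   variant-position count over the timecourse and the diversity score at
#'   each timepoint.
#' @export
screen_reference_values <- function() {
  data.frame(pool = c("diploid", "haploid"),
             n_variant_positions = c(66L, 49L),
             D_T0 = c(NA, 1.37),
             D_T1 = c(9.20, NA),
             D_T2 = c(7.13, NA),
             D_T3 = c(4.66, NA),
             stringsAsFactors = FALSE)
}
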