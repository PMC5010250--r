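#' Simulation configuration for a pooled variant-library selection screen
#'
#' Bundles every knob of the synthetic screen: the variant library itself,
#' the passaging regime, and the sequencing noise model. Defaults emulate a
#' plasmid-borne variomics pool of 2e5 point-mutation alleles over a 1,718-bp
#' amplicon, passaged in triplicate for 8 generations per timepoint under
#' lethal drug selection with an 11% haploid-viability bottleneck, and
#' sequenced at a median depth of 20,000x with per-locus baseline error of
#' mean 2e-4.
#'
#' @param n_alleles number of independent library alleles.
#' @param loci number of positions in the amplicon region.
#' @param chrom,region_start chromosome label and 1-based start of the region.
#' @param initial_vaf_model list; `dist` is `"uniform"` (equal starting
#'   frequencies) or `"dirichlet"` (symmetric Dirichlet with
#'   `concentration`, emulating uneven clone representation).
#' @param fitness_model list with `resistant_fraction` (share of alleles with
#'   relative fitness above 1 under drug) and lognormal location/scale for
#'   resistant and sensitive alleles. The true distribution of resistance
#'   effects is unknown; these defaults are deliberately simple and fully
#'   configurable.
#' @param muts_per_allele point mutations carried by each allele.
#' @param generations_per_passage generations of growth between samplings.
#' @param bottleneck_size cells sampled at each passage dilution; default
#'   `10 * n_alleles` (10-fold variant coverage at the dilution).
#' @param viability_fraction fraction of alleles surviving haploid conversion.
#' @param n_replicates technical sequencing replicates per timepoint.
#' @param depth_model list with `median` depth and negative-binomial
#'   `dispersion` (size); `dispersion = Inf` gives constant depth.
#' @param error_model list with `mean` locus baseline error and Beta `shape1`;
#'   shape2 is solved from the mean.
#' @param seed optional integer seed applied by the generator functions.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_alleles = 2e5,
                       loci = 1718,
                       chrom = "chrXV",
                       region_start = 780367L,
                       initial_vaf_model = list(dist = "dirichlet", concentration = 5),
                       fitness_model = list(resistant_fraction = 0.01,
                                            resistant_meanlog = log(1.5),
                                            resistant_sdlog = 0.15,
                                            sensitive_meanlog = log(0.5),
                                            sensitive_sdlog = 0.2),
                       muts_per_allele = 1L,
                       generations_per_passage = 8L,
                       bottleneck_size = NULL,
                       viability_fraction = 0.11,
                       n_replicates = 3L,
                       depth_model = list(median = 20000, dispersion = 10),
                       error_model = list(mean = 2e-4, shape1 = 0.5),
                       seed = NULL) {
  stopifnot(n_alleles >= 1, loci >= 1, muts_per_allele >= 1,
            generations_per_passage >= 1, n_replicates >= 1)
  if (!(viability_fraction > 0 && viability_fraction <= 1))
    stop("viability_fraction must be in (0, 1]")
  if (muts_per_allele > loci)
    stop("muts_per_allele cannot exceed the number of loci")
  if (!initial_vaf_model$dist %in% c("uniform", "dirichlet"))
    stop("unknown initial_vaf_model dist: ", initial_vaf_model$dist)
  if (initial_vaf_model$dist == "dirichlet" &&
      (is.null(initial_vaf_model$concentration) || initial_vaf_model$concentration <= 0))
    stop("dirichlet initial_vaf_model needs a positive concentration")
  if (depth_model$median < 0 || (is.finite(depth_model$dispersion) && depth_model$dispersion <= 0))
    stop("invalid depth_model")
  if (error_model$mean < 0 || error_model$mean >= 1 || error_model$shape1 <= 0)
    stop("invalid error_model")
  fm <- fitness_model
  if (fm$resistant_fraction < 0 || fm$resistant_fraction > 1)
    stop("resistant_fraction must be in [0, 1]")
  structure(list(n_alleles = as.integer(n_alleles), loci = as.integer(loci),
                 chrom = chrom, region_start = as.integer(region_start),
                 initial_vaf_model = initial_vaf_model, fitness_model = fm,
                 muts_per_allele = as.integer(muts_per_allele),
                 generations_per_passage = as.integer(generations_per_passage),
                 bottleneck_size = as.integer(bottleneck_size %||% (10 * n_alleles)),
                 viability_fraction = viability_fraction,
                 n_replicates = as.integer(n_replicates),
                 depth_model = depth_model, error_model = error_model,
                 seed = seed),
            class = "sim_config")
}

new_pool_state <- function(timepoint, freqs, fitness, mutations, ref, config) {
  stopifnot(length(freqs) == length(fitness), all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("pool frequencies must sum to 1")
  structure(list(timepoint = timepoint, freqs = freqs, fitness = fitness,
                 mutations = mutations, ref = ref,
                 loci = config$loci, chrom = config$chrom,
                 region_start = config$region_start),
            class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("<pool_state> %s: %d alleles (%d with freq > 0), %d loci\n",
              x$timepoint, length(x$freqs), sum(x$freqs > 0), x$loci))
  cat(sprintf("  fitness range [%.3g, %.3g]; %d mutations mapped\n",
              min(x$fitness), max(x$fitness), nrow(x$mutations)))
  invisible(x)
}

#' Draw a variant library at its starting timepoint
#'
#' Generates the T0 pool: starting allele frequencies, per-allele relative
#' fitness under selection (a configurable minority is resistant, w > 1), a
#' random reference sequence for the amplicon, and the allele-to-locus map
#' assigning each allele `muts_per_allele` distinct (locus, alt base)
#' substitutions.
#'
#' @param config a [sim_config()].
#' @return A `pool_state` at timepoint `"T0"`.
#' @export
build_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_alleles
  ref <- sample(DNA_BASES, config$loci, replace = TRUE)

  freqs <- switch(config$initial_vaf_model$dist,
    uniform = rep(1 / n, n),
    dirichlet = {
      g <- rgamma(n, shape = config$initial_vaf_model$concentration, rate = 1)
      g / sum(g)
    })

  fm <- config$fitness_model
  resistant <- runif(n) < fm$resistant_fraction
  fitness <- numeric(n)
  fitness[resistant] <- rlnorm(sum(resistant), fm$resistant_meanlog, fm$resistant_sdlog)
  fitness[!resistant] <- rlnorm(sum(!resistant), fm$sensitive_meanlog, fm$sensitive_sdlog)

  m <- config$muts_per_allele
  if (m == 1L) {
    locus <- sample.int(config$loci, n, replace = TRUE)
  } else {
    locus <- as.vector(vapply(seq_len(n),
                              function(i) sample.int(config$loci, m),
                              integer(m)))
  }
  allele <- rep(seq_len(n), each = m)
  # each substitution picks one of the three non-reference bases
  alt_tbl <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b), character(3)))
  alt <- alt_tbl[cbind(match(ref[locus], DNA_BASES), sample.int(3, n * m, replace = TRUE))]
  mutations <- data.frame(allele = allele, locus = locus, alt = alt,
                          stringsAsFactors = FALSE)
  new_pool_state("T0", freqs, fitness, mutations, ref, config)
}

#' Apply a viability (haploid-conversion) bottleneck to a pool
#'
#' Retains approximately `fraction` of the alleles, with survival biased
#' against low-fitness alleles: allele i survives with probability
#' `c * min(1, w_i / max(w))`, where the constant `c` is set so the expected
#' retained fraction equals `fraction`. Frequencies of survivors are
#' renormalised to sum to 1.
#'
#' @param pool a `pool_state`.
#' @param fraction fraction of alleles to retain, in (0, 1].
#' @param seed optional integer seed.
#' @return A `pool_state` containing the surviving alleles.
#' @export
apply_viability_filter <- function(pool, fraction = 0.11, seed = NULL) {
  stopifnot(inherits(pool, "pool_state"))
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  w <- pool$fitness
  u <- pmin(1, w / max(w))
  # survival probability proportional to u, rescaled so the expected
  # retained fraction equals `fraction` even when the proportionality
  # constant clips some probabilities at 1
  gap <- function(cc) mean(pmin(1, cc * u)) - fraction
  cc <- fraction / mean(u)
  if (gap(cc) < 0) {
    hi <- cc
    while (gap(hi) < 0 && hi < 1e12) hi <- hi * 2
    if (gap(hi) >= 0) cc <- stats::uniroot(gap, c(cc, hi), tol = 1e-12)$root
    else cc <- hi
  }
  p <- pmin(1, cc * u)
  keep <- which(runif(length(w)) < p)
  if (length(keep) == 0L)
    stop("no alleles survived the viability filter")
  f <- pool$freqs[keep]
  out <- pool
  out$freqs <- f / sum(f)
  out$fitness <- w[keep]
  out$mutations <- pool$mutations[pool$mutations$allele %in% keep, , drop = FALSE]
  out$mutations$allele <- match(out$mutations$allele, keep)
  out
}

#' Propagate a pool for g generations of growth under selection
#'
#' Deterministic selection update `f'_i = f_i w_i^g / sum_k f_k w_k^g`,
#' optionally followed (stochastic mode) by multinomial resampling of
#' `bottleneck_size` cells at the passage dilution, the simulator's source
#' of genetic drift.
#'
#' @param pool a `pool_state`.
#' @param g generations of growth (>= 1).
#' @param bottleneck_size cells sampled at the dilution (stochastic mode).
#' @param seed optional integer seed.
#' @param deterministic if `TRUE`, skip the bottleneck resampling.
#' @return The propagated `pool_state`; its timepoint label is advanced
#'   (`"T0"` to `"T1"`, etc.).
#' @export
propagate <- function(pool, g = 8, bottleneck_size = NULL, seed = NULL,
                      deterministic = FALSE) {
  stopifnot(inherits(pool, "pool_state"), g >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- pool$freqs * pool$fitness^g
  s <- sum(f)
  if (s <= 0) stop("all alleles are lethal: nothing survives propagation")
  f <- f / s
  if (!deterministic) {
    if (is.null(bottleneck_size))
      stop("stochastic propagation requires bottleneck_size")
    cnt <- rmultinom(1, size = bottleneck_size, prob = f)[, 1]
    f <- cnt / sum(cnt)
  }
  out <- pool
  out$freqs <- f
  tp <- suppressWarnings(as.integer(sub("^T", "", pool$timepoint)))
  out$timepoint <- if (!is.na(tp)) sprintf("T%d", tp + 1L)
                   else paste0(pool$timepoint, "+")
  out
}

#' Per-locus, per-base true variant allele frequencies of a pool
#'
#' Sums allele frequencies over the allele-to-locus map, giving the marginal
#' frequency of each alt base at each locus (a 4 x loci matrix with zero rows
#' for reference bases).
#'
#' @param pool a `pool_state`.
#' @return Numeric matrix `[4, loci]` with rownames A, C, G, T.
#' @export
locus_vaf_matrix <- function(pool) {
  v <- matrix(0, nrow = 4, ncol = pool$loci, dimnames = list(DNA_BASES, NULL))
  mt <- pool$mutations
  if (nrow(mt)) {
    f <- pool$freqs[mt$allele]
    idx <- cbind(match(mt$alt, DNA_BASES), mt$locus)
    for (i in seq_along(f)) v[idx[i, 1], idx[i, 2]] <- v[idx[i, 1], idx[i, 2]] + f[i]
  }
  v
}

#' Simulate replicate sequencing counts for known per-locus VAFs
#'
#' The low-level count generator behind [sequence_pool()]. For each replicate
#' n and locus j it draws a depth from the negative-binomial depth model, a
#' non-reference count `r_nj ~ Binomial(d_nj, vaf_j + e_j - vaf_j * e_j)`
#' where `e_j` is the locus baseline error (Beta-distributed, shared across
#' replicates), and spreads non-reference reads over the three non-reference
#' bases (true signal proportional to the per-base VAF, error split evenly).
#'
#' @param vaf either a numeric vector of total non-reference signal per locus
#'   (signal assigned to one randomly chosen alt base per locus) or a
#'   `[4, loci]` per-base matrix as from [locus_vaf_matrix()].
#' @param ref reference base per locus.
#' @param n_replicates technical replicates.
#' @param depth_model,error_model as in [sim_config()].
#' @param locus_error optional per-locus baseline error (length `loci` or a
#'   scalar); overrides drawing from `error_model`, e.g. to share the same
#'   locus error profile between a case and a control tensor sequenced on
#'   the same amplicon.
#' @param sample sample label.
#' @param chrom,region_start coordinates of the first locus.
#' @param seed optional integer seed.
#' @return A list with `tensor` (a [read_count_tensor()]) and `truth`, a
#'   data frame of per-locus true VAF, locus error and true non-reference
#'   rate.
#' @export
simulate_counts <- function(vaf, ref, n_replicates = 3,
                            depth_model = list(median = 20000, dispersion = 10),
                            error_model = list(mean = 2e-4, shape1 = 0.5),
                            locus_error = NULL, sample = "S",
                            chrom = "chrXV", region_start = 780367L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(vaf)) {
    stopifnot(nrow(vaf) == 4)
    vmat <- vaf
  } else {
    J0 <- length(vaf)
    vmat <- matrix(0, 4, J0, dimnames = list(DNA_BASES, NULL))
    alt_choice <- vapply(seq_len(J0), function(j) {
      sample(setdiff(DNA_BASES, ref[j]), 1)
    }, character(1))
    vmat[cbind(match(alt_choice, DNA_BASES), seq_len(J0))] <- vaf
  }
  J <- ncol(vmat)
  stopifnot(length(ref) == J)
  # true signal must not sit on the reference base
  ref_idx <- match(ref, DNA_BASES)
  if (any(vmat[cbind(ref_idx, seq_len(J))] > 0))
    stop("vaf assigns signal to the reference base")
  vtot <- colSums(vmat)
  if (any(vtot > 1)) stop("per-locus VAF exceeds 1")

  if (is.null(locus_error)) {
    a <- error_model$shape1
    b <- a * (1 - error_model$mean) / error_model$mean
    locus_error <- rbeta(J, a, b)
  } else {
    locus_error <- rep_len(locus_error, J)
  }
  p_nonref <- pmin(1, pmax(0, vtot + locus_error - vtot * locus_error))

  N <- n_replicates
  depth <- if (is.infinite(depth_model$dispersion)) {
    matrix(as.integer(depth_model$median), N, J)
  } else if (depth_model$median == 0) {
    matrix(0L, N, J)
  } else {
    matrix(rnbinom(N * J, size = depth_model$dispersion, mu = depth_model$median),
           N, J)
  }
  r <- matrix(rbinom(N * J, as.vector(depth), rep(p_nonref, each = N)), N, J)

  counts <- array(0L, dim = c(N, J, 4), dimnames = list(NULL, NULL, DNA_BASES))
  for (j in seq_len(J)) {
    wj <- vmat[, j] * (1 - locus_error[j])
    wj[-ref_idx[j]] <- wj[-ref_idx[j]] + locus_error[j] / 3
    wj[ref_idx[j]] <- 0
    for (n in seq_len(N)) {
      if (r[n, j] > 0) {
        if (sum(wj) <= 0) { # r > 0 can only occur when p_nonref > 0, but guard
          counts[n, j, -ref_idx[j]] <- as.integer(rmultinom(1, r[n, j], rep(1, 3))[, 1])
        } else {
          counts[n, j, ] <- as.integer(rmultinom(1, r[n, j], wj)[, 1])
        }
      }
      counts[n, j, ref_idx[j]] <- depth[n, j] - r[n, j]
    }
  }
  tensor <- read_count_tensor(counts, depth, pos = region_start + seq_len(J) - 1L,
                              ref = ref, chrom = chrom, sample = sample)
  truth <- data.frame(chrom = chrom, pos = region_start + seq_len(J) - 1L,
                      ref = ref, true_vaf = vtot, locus_error = locus_error,
                      true_nonref_rate = p_nonref, stringsAsFactors = FALSE)
  list(tensor = tensor, truth = truth)
}

#' Sequence a simulated pool
#'
#' Computes the pool's marginal per-locus VAFs and simulates replicate
#' sequencing counts under the configured depth and error models.
#'
#' @inheritParams simulate_counts
#' @param pool a `pool_state`.
#' @param config a [sim_config()].
#' @return As [simulate_counts()].
#' @export
sequence_pool <- function(pool, config, locus_error = NULL,
                          sample = pool$timepoint, seed = NULL) {
  stopifnot(inherits(pool, "pool_state"), inherits(config, "sim_config"))
  simulate_counts(locus_vaf_matrix(pool), ref = pool$ref,
                  n_replicates = config$n_replicates,
                  depth_model = config$depth_model,
                  error_model = config$error_model,
                  locus_error = locus_error, sample = sample,
                  chrom = pool$chrom, region_start = pool$region_start,
                  seed = seed)
}

#' Sequence a wild-type background sample (no variant alleles)
#'
#' Emulates the strain carrying only the wild-type allele: every
#' non-reference read is sequencing error.
#'
#' @inheritParams simulate_counts
#' @param config a [sim_config()].
#' @param n_replicates replicates for the background sample (the background
#'   strain may be sequenced with fewer replicates than the pools).
#' @export
sequence_background <- function(config, ref, locus_error = NULL,
                                n_replicates = config$n_replicates,
                                sample = "WT", seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(ref) == config$loci)
  simulate_counts(rep(0, config$loci), ref = ref,
                  n_replicates = n_replicates,
                  depth_model = config$depth_model,
                  error_model = config$error_model,
                  locus_error = locus_error, sample = sample,
                  chrom = config$chrom, region_start = config$region_start,
                  seed = seed)
}
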