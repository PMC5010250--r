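#' MCMC schedule for the hierarchical VAF model
#'
#' Defaults follow the screen's analysis settings: 4000 Gibbs sweeps, 10
#' Metropolis-Hastings updates of each locus VAF per sweep, 20% warm-up and
#' a thinning rate of 2, retaining `floor(n_gibbs * (1 - warmup_frac) / thin)`
#' samples.
#'
#' @param n_gibbs total Gibbs sweeps (>= 10).
#' @param n_mh MH updates of each mu_j per sweep.
#' @param warmup_frac fraction of sweeps discarded as warm-up, in [0, 1).
#' @param thin thinning rate (>= 1).
#' @param seed optional integer seed; identical seeds give identical chains.
#' @return An object of class `mcmc_params`.
#' @export
mcmc_params <- function(n_gibbs = 4000, n_mh = 10, warmup_frac = 0.2,
                        thin = 2, seed = NULL) {
  stopifnot(n_gibbs >= 10, n_mh >= 1, thin >= 1,
            warmup_frac >= 0, warmup_frac < 1)
  n_keep <- floor(n_gibbs * (1 - warmup_frac) / thin)
  if (n_keep < 1) stop("schedule retains no samples")
  structure(list(n_gibbs = as.integer(n_gibbs), n_mh = as.integer(n_mh),
                 warmup_frac = warmup_frac, thin = as.integer(thin),
                 n_keep = as.integer(n_keep), seed = seed),
            class = "mcmc_params")
}

#' Method-of-moments hyperparameters for the hierarchical VAF model
#'
#' Empirical-Bayes initialisation of the model
#' `r_nj ~ Binomial(d_nj, theta_nj)`, `theta_nj ~ Beta(mu_j, M_j)`,
#' `mu_j ~ Beta(mu0, M0)` (mean/precision parameterisation):
#' `mu0` is the mean of `r/d` over all loci and replicates; `M0` comes from
#' the between-locus variance of the per-locus pooled rates; `M_j` from the
#' cross-replicate variance at locus j, after subtracting the expected
#' binomial sampling variance (otherwise depth noise masquerades as
#' replicate overdispersion). `M_j` is clamped to `[m_floor, m_ceiling]`;
#' zero residual variance maps to the ceiling. Single-replicate tensors get
#' `M_j = M0`. A tensor with no non-reference reads at all gets the
#' pseudocount floor `mu0 = 1 / (total reads + 2)` so all Beta parameters
#' stay proper.
#'
#' @param tensor a [read_count_tensor()] with at least one locus of
#'   positive depth.
#' @param m_floor,m_ceiling clamp for the per-locus precision `M_j`.
#' @return An object of class `model_hyperparams` with `mu0`, `M0` and the
#'   vector `M`.
#' @export
estimate_moments <- function(tensor, m_floor = 1, m_ceiling = 1e6) {
  stopifnot(inherits(tensor, "read_count_tensor"))
  d <- tensor$depth; r <- tensor$nonref
  J <- length(tensor$pos); N <- nrow(d)
  if (J < 1 || sum(d) == 0)
    stop("tensor has no sequenced loci: hyperparameters are not estimable")
  obs <- d > 0
  rate <- r / d # NaN where d == 0
  mu0 <- mean(rate[obs])
  if (mu0 <= 0) mu0 <- 1 / (sum(d) + 2)
  if (mu0 >= 1) mu0 <- 1 - 1 / (sum(d) + 2)

  pooled <- colSums(r) / pmax(1, colSums(d))
  pooled[colSums(d) == 0] <- NA

  # between-locus prior precision
  M0 <- 1
  if (sum(!is.na(pooled)) >= 2) {
    v <- var(pooled, na.rm = TRUE)
    noise <- mean(pooled * (1 - pooled) / pmax(1, colSums(d)), na.rm = TRUE)
    vb <- v - noise
    M0 <- if (!is.finite(vb) || vb <= 0) 1e4
          else min(1e4, max(0.1, mu0 * (1 - mu0) / vb - 1))
  }

  # per-locus replicate precision
  M <- rep(m_ceiling, J)
  if (N >= 2) {
    for (j in seq_len(J)) {
      dj <- d[, j]; use <- dj > 0
      if (sum(use) < 2 || is.na(pooled[j]) || pooled[j] <= 0 || pooled[j] >= 1) next
      v <- var(rate[use, j])
      noise <- mean(pooled[j] * (1 - pooled[j]) / dj[use])
      vtheta <- v - noise
      if (is.finite(vtheta) && vtheta > 0)
        M[j] <- min(m_ceiling, max(m_floor, pooled[j] * (1 - pooled[j]) / vtheta - 1))
    }
  } else {
    M[] <- M0
  }
  structure(list(mu0 = mu0, M0 = M0, M = M,
                 m_floor = m_floor, m_ceiling = m_ceiling),
            class = "model_hyperparams")
}

#' @export
print.model_hyperparams <- function(x, ...) {
  cat(sprintf("<model_hyperparams> mu0 = %.4g, M0 = %.4g, M_j in [%.3g, %.3g]\n",
              x$mu0, x$M0, min(x$M), max(x$M)))
  invisible(x)
}

#' Fit the hierarchical VAF model by Metropolis-within-Gibbs MCMC
#'
#' Each sweep draws every replicate rate from its conjugate conditional,
#' `theta_nj ~ Beta(r_nj + mu_j M_j, d_nj - r_nj + (1 - mu_j) M_j)`, then
#' applies `n_mh` Metropolis-Hastings updates to each locus VAF `mu_j`,
#' targeting the `Beta(mu0, M0)` prior times the product of Beta likelihoods
#' of the replicate rates, with a symmetric random-walk proposal on the
#' logit scale whose step size is adapted during warm-up to a 0.2-0.5
#' acceptance band. All density arithmetic is in log space. Loci with zero
#' total depth get prior-driven posteriors and are flagged.
#'
#' @param tensor a [read_count_tensor()].
#' @param mcmc an [mcmc_params()].
#' @param hyper optional [estimate_moments()] result; estimated from the
#'   tensor when `NULL`.
#' @param keep_theta retain the per-replicate rate samples (needed for the
#'   per-replicate point estimates in [vaf_point_estimates()]).
#' @return An object of class `vaf_posterior`: retained `mu` samples
#'   (matrix, samples x loci), optional `theta` samples (samples x
#'   replicates x loci), posterior means `mu_hat` and `theta_hat`, central
#'   95% credible intervals `ci` (2 x loci), MH acceptance rates, the
#'   hyperparameters and schedule used, and the sample label.
#' @export
fit_vaf <- function(tensor, mcmc = mcmc_params(), hyper = NULL,
                    keep_theta = TRUE) {
  stopifnot(inherits(tensor, "read_count_tensor"), inherits(mcmc, "mcmc_params"))
  if (length(tensor$pos) < 1) stop("empty tensor")
  if (is.null(hyper)) hyper <- estimate_moments(tensor)
  stopifnot(inherits(hyper, "model_hyperparams"))
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  J <- length(tensor$pos); N <- nrow(tensor$depth)
  n_warm <- mcmc$n_gibbs - mcmc$n_keep * mcmc$thin
  res <- .gibbs_vaf(matrix(as.integer(tensor$nonref), N, J),
                    matrix(as.integer(tensor$depth), N, J),
                    hyper$mu0, hyper$M0, hyper$M,
                    mcmc$n_gibbs, mcmc$n_mh, n_warm, mcmc$thin,
                    keep_theta)
  mu <- res$mu
  colnames(mu) <- tensor$pos
  theta <- if (keep_theta) array(res$theta, dim = c(mcmc$n_keep, N, J)) else NULL
  ci <- apply(mu, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(mu = mu, theta = theta,
                 mu_hat = colMeans(mu),
                 theta_hat = if (keep_theta) colMeans(theta) else NULL,
                 ci = ci,
                 accept_rate = res$accept_rate,
                 proposal_sd = res$proposal_sd,
                 hyper = hyper, mcmc = mcmc,
                 region = tensor$region, pos = tensor$pos, ref = tensor$ref,
                 sample = tensor$sample,
                 zero_depth = colSums(tensor$depth) == 0),
            class = "vaf_posterior")
}

#' @export
print.vaf_posterior <- function(x, ...) {
  cat(sprintf("<vaf_posterior> sample %s: %d loci, %d retained samples\n",
              x$sample, length(x$pos), nrow(x$mu)))
  cat(sprintf("  mu_hat range [%.3g, %.3g]; mean MH acceptance %.2f\n",
              min(x$mu_hat), max(x$mu_hat), mean(x$accept_rate)))
  if (any(x$zero_depth))
    cat(sprintf("  %d zero-depth loci with prior-driven posteriors\n",
                sum(x$zero_depth)))
  invisible(x)
}

#' Per-locus VAF point estimates and credible intervals
#'
#' The plotted quantities of a fitted sample: the posterior mean VAF, its
#' central 95% credible interval (2.5 and 97.5 empirical percentiles of the
#' retained samples), and the per-replicate rate estimates.
#'
#' @param posterior a [fit_vaf()] result.
#' @return A data frame with one row per locus: `chrom`, `pos`, `ref`,
#'   `mu_hat`, `ci_lo`, `ci_hi` and one `theta_<n>` column per replicate.
#' @export
vaf_point_estimates <- function(posterior) {
  stopifnot(inherits(posterior, "vaf_posterior"))
  out <- data.frame(chrom = posterior$region$chrom,
                    pos = posterior$pos, ref = posterior$ref,
                    mu_hat = posterior$mu_hat,
                    ci_lo = posterior$ci[1, ], ci_hi = posterior$ci[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(posterior$theta_hat)) {
    th <- t(posterior$theta_hat)
    colnames(th) <- paste0("theta_", seq_len(ncol(th)))
    out <- cbind(out, th)
  }
  out
}

# internal constructor used in tests to build posteriors with known samples
new_vaf_posterior <- function(mu, pos, ref = NULL, sample = "S",
                              chrom = "chrS") {
  mu <- as.matrix(mu)
  stopifnot(ncol(mu) == length(pos))
  structure(list(mu = mu, theta = NULL, mu_hat = colMeans(mu),
                 theta_hat = NULL,
                 ci = apply(mu, 2, quantile, probs = c(0.025, 0.975),
                            names = FALSE),
                 accept_rate = rep(NA_real_, ncol(mu)),
                 hyper = NULL, mcmc = NULL,
                 region = list(chrom = chrom, start = min(pos), end = max(pos)),
                 pos = as.integer(pos),
                 ref = ref %||% rep("A", length(pos)),
                 sample = sample,
                 zero_depth = rep(FALSE, ncol(mu))),
            class = "vaf_posterior")
}
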