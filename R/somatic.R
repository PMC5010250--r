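#' Configuration for the posterior-difference (somatic) variant test
#'
#' The test calls a provisional variant at a locus when the posterior
#' probability that the VAF difference between case and control lies in the
#' admissible interval exceeds `1 - alpha`. Defaults follow the screen's
#' settings: interval \[0.001, 1\] (i.e. a difference between 0.1% and 100%,
#' expressed as fractions since a difference of two frequencies cannot
#' exceed 1), alpha 0.05, and 1000 posterior draws. The test is two-sided:
#' both the gain direction (case above control) and the loss direction are
#' tested against the positive interval. `adjust = "bonferroni"` divides
#' alpha by the locus count; the default, matching the original analysis,
#' applies no multiple-testing adjustment.
#'
#' @param tau_low,tau_high admissible VAF-difference interval, as fractions.
#' @param alpha significance level of the posterior test.
#' @param n_draws posterior draws used to estimate the probability (>= 100).
#' @param alpha_chisq significance level of the alt-base non-uniformity
#'   filter applied after the posterior test.
#' @param adjust multiple-testing adjustment, `"none"` or `"bonferroni"`.
#' @param seed optional integer seed for the posterior resampling.
#' @return An object of class `somatic_config`.
#' @export
somatic_config <- function(tau_low = 0.001, tau_high = 1.0, alpha = 0.05,
                           n_draws = 1000, alpha_chisq = 0.05,
                           adjust = c("none", "bonferroni"), seed = NULL) {
  stopifnot(tau_low > 0, tau_low < tau_high, tau_high <= 1,
            alpha > 0, alpha < 1, n_draws >= 100,
            alpha_chisq > 0, alpha_chisq < 1)
  structure(list(tau_low = tau_low, tau_high = tau_high, alpha = alpha,
                 n_draws = as.integer(n_draws), alpha_chisq = alpha_chisq,
                 adjust = match.arg(adjust), seed = seed),
            class = "somatic_config")
}

#' Bayesian posterior-difference test between a case and a control sample
#'
#' For each locus, draws `n_draws` independent pairs (with replacement) from
#' the retained VAF samples of the case and control posteriors, forms the
#' difference `delta = mu_case - mu_control`, and estimates
#' `p_gain = P(delta in [tau_low, tau_high])` and
#' `p_loss = P(-delta in [tau_low, tau_high])`. A provisional variant is
#' called when `max(p_gain, p_loss) > 1 - alpha`, with the direction
#' recorded.
#'
#' @param case,control [fit_vaf()] posteriors over the same region.
#' @param cfg a [somatic_config()].
#' @return A data frame with one row per locus: positions, point estimates
#'   and credible intervals for both samples, `p_gain`, `p_loss`, `prob`
#'   (the larger of the two), `direction` and `provisional`.
#' @export
somatic_test <- function(case, control, cfg = somatic_config()) {
  stopifnot(inherits(case, "vaf_posterior"), inherits(control, "vaf_posterior"),
            inherits(cfg, "somatic_config"))
  if (nrow(case$mu) == 0 || nrow(control$mu) == 0)
    stop("empty posterior")
  if (!identical(case$pos, control$pos) ||
      !identical(case$region$chrom, control$region$chrom))
    stop("case and control posteriors cover different regions")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  J <- length(case$pos)
  K1 <- nrow(case$mu); K2 <- nrow(control$mu)
  p_gain <- p_loss <- numeric(J)
  for (j in seq_len(J)) {
    delta <- case$mu[sample.int(K1, cfg$n_draws, replace = TRUE), j] -
             control$mu[sample.int(K2, cfg$n_draws, replace = TRUE), j]
    p_gain[j] <- mean(delta >= cfg$tau_low & delta <= cfg$tau_high)
    p_loss[j] <- mean(-delta >= cfg$tau_low & -delta <= cfg$tau_high)
  }
  alpha <- if (cfg$adjust == "bonferroni") cfg$alpha / J else cfg$alpha
  prob <- pmax(p_gain, p_loss)
  data.frame(chrom = case$region$chrom, pos = case$pos, ref = case$ref,
             mu_case = case$mu_hat, ci_lo_case = case$ci[1, ],
             ci_hi_case = case$ci[2, ],
             mu_control = control$mu_hat, ci_lo_control = control$ci[1, ],
             ci_hi_control = control$ci[2, ],
             p_gain = p_gain, p_loss = p_loss, prob = prob,
             direction = ifelse(p_gain >= p_loss, "gain", "loss"),
             provisional = prob > 1 - alpha,
             case = case$sample, control = control$sample,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Alt-base non-uniformity filter for provisional variant calls
#'
#' Pools the non-reference base counts of the case sample across its
#' replicates at each provisional position and tests them against a uniform
#' 1/3 split over the three substitution bases (chi-squared goodness of fit,
#' 2 degrees of freedom). True substitutions concentrate reads on one alt
#' base, while generally elevated sequencing error spreads over all three,
#' so positions are retained only when the distribution is non-uniform
#' (p < `alpha`). Positions with zero non-reference reads are dropped with a
#' message (the test is undefined there).
#'
#' @param tensor the case sample's [read_count_tensor()].
#' @param positions positions (1-based) of provisional calls.
#' @param alpha significance level of the chi-squared filter.
#' @return A data frame of retained positions with the pooled alt-base
#'   spectrum, chi-squared statistic and p-value, the dominant alt base
#'   (ties broken alphabetically and flagged), and the reference base.
#' @export
nonuniformity_filter <- function(tensor, positions, alpha = 0.05) {
  stopifnot(inherits(tensor, "read_count_tensor"))
  positions <- as.integer(positions)
  if (!all(positions %in% tensor$pos))
    stop("positions absent from the tensor")
  rows <- lapply(positions, function(p) {
    j <- match(p, tensor$pos)
    ref <- tensor$ref[j]
    pooled <- colSums(matrix(tensor$counts[, j, ], nrow = nrow(tensor$depth),
                             dimnames = list(NULL, DNA_BASES)))
    alt <- pooled[setdiff(DNA_BASES, ref)]
    if (sum(alt) == 0) return(NULL)
    ht <- suppressWarnings(chisq.test(alt, p = rep(1 / 3, 3)))
    tie <- sum(alt == max(alt)) > 1
    data.frame(pos = p, ref = ref,
               alt = names(alt)[which.max(alt)],  # lexicographic tie-break
               alt_tie = tie,
               n_alt_1 = unname(alt[1]), n_alt_2 = unname(alt[2]),
               n_alt_3 = unname(alt[3]),
               chisq_stat = unname(ht$statistic),
               chisq_p = unname(ht$p.value),
               retained = unname(ht$p.value) < alpha,
               stringsAsFactors = FALSE)
  })
  dropped <- positions[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    message(sprintf("nonuniformity_filter: %d position(s) dropped (no non-reference reads, test undefined): %s%s",
                    length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", "),
                    if (length(dropped) > 10) ", ..." else ""))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), alt_tie = logical(0),
                         n_alt_1 = integer(0), n_alt_2 = integer(0),
                         n_alt_3 = integer(0), chisq_stat = numeric(0),
                         chisq_p = numeric(0), retained = logical(0))
  out <- out[out$retained, setdiff(names(out), "retained"), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Call variants at every timepoint against a common control
#'
#' Runs [somatic_test()] and [nonuniformity_filter()] for each case sample
#' against the designated control and collects the per-pair call tables and
#' the union of called positions across pairs (the screen's "variant
#' positions" count).
#'
#' @param posteriors named list of [fit_vaf()] posteriors (one per sample).
#' @param tensors named list of the matching [read_count_tensor()]s (used by
#'   the chi-squared filter on the case sample).
#' @param control name of the control sample within `posteriors`.
#' @param cfg a [somatic_config()].
#' @return A list with `calls` (named list of per-pair call tables),
#'   `union` (sorted called positions) and `n_union`.
#' @export
call_timecourse <- function(posteriors, tensors, control = "T0",
                            cfg = somatic_config()) {
  stopifnot(control %in% names(posteriors))
  cases <- setdiff(names(posteriors), control)
  calls <- lapply(cases, function(cs) {
    st <- somatic_test(posteriors[[cs]], posteriors[[control]], cfg)
    prov <- st[st$provisional, , drop = FALSE]
    flt <- nonuniformity_filter(tensors[[cs]], prov$pos, cfg$alpha_chisq)
    merge(prov, flt[, setdiff(names(flt), "ref"), drop = FALSE],
          by = "pos", sort = TRUE)
  })
  names(calls) <- cases
  union_pos <- sort(unique(unlist(lapply(calls, `[[`, "pos"))))
  list(calls = calls, union = union_pos, n_union = length(union_pos))
}

#' Export a call table as tab-separated text or minimal VCF
#'
#' The VCF export writes a site-only VCFv4.2 with INFO fields VAF_CASE,
#' VAF_CTRL, PROB, DIR and CHI2_P.
#'
#' @param calls a call table as produced by [call_timecourse()] (one
#'   element of `$calls`).
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=VAF_CASE,Number=1,Type=Float,Description=\"Posterior mean VAF in the case sample\">",
           "##INFO=<ID=VAF_CTRL,Number=1,Type=Float,Description=\"Posterior mean VAF in the control sample\">",
           "##INFO=<ID=PROB,Number=1,Type=Float,Description=\"Posterior probability that the VAF difference lies in the test interval\">",
           "##INFO=<ID=DIR,Number=1,Type=String,Description=\"Direction of change relative to the control\">",
           "##INFO=<ID=CHI2_P,Number=1,Type=Float,Description=\"Alt-base non-uniformity chi-squared p-value\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF_CASE=%.6g;VAF_CTRL=%.6g;PROB=%.4g;DIR=%s;CHI2_P=%.4g",
            calls$chrom, calls$pos, calls$ref, calls$alt,
            calls$mu_case, calls$mu_control, calls$prob,
            calls$direction, calls$chisq_p)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
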