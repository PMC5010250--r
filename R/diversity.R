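#' Kullback-Leibler divergence between two Bernoulli distributions
#'
#' `D_KL(p || q) = p log(p/q) + (1-p) log((1-p)/(1-q))`, in nats. The
#' divergence is zero if and only if `q == p`, and is `+Inf` when `q` is 0
#' or 1 while `p` is interior (absolute-continuity failure).
#'
#' @param p reference success probability, strictly inside (0, 1).
#' @param q comparison probability (or vector of probabilities) in \[0, 1\].
#' @return Numeric vector of divergences, recycled over `q`.
#' @export
#' @examples
#' bernoulli_kl(0.5, 0.1) # 0.5108
bernoulli_kl <- function(p, q) {
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1)
    stop("p must be a single probability strictly inside (0, 1)")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  ifelse(q <= 0 | q >= 1, Inf,
         p * log(p / q) + (1 - p) * log((1 - p) / (1 - q)))
}

#' Pool-diversity score of a called-variant set
#'
#' For a set V of called variants with estimated VAFs `mu_hat_j`, sets
#' `p = 1/|V|` (the share each variant would hold in a perfectly uniform
#' all-variant pool) and scores
#' `D = sum_j (1 - tanh(D_KL(p || mu_hat_j)))`. Each term is 1 when the
#' variant holds exactly the uniform share and decays to 0 as its VAF
#' diverges from it, so D is high when many variants are near-uniformly
#' represented: it captures both the number of variants and the evenness of
#' their frequencies. With fewer than two called variants the score is
#' undefined and recorded as `"-"`.
#'
#' The term is written `1 - tanh` so that it is 1 at zero divergence and 0
#' at infinite divergence, the stated limiting behaviour of the statistic;
#' `literal = TRUE` instead applies `1 + tanh` (terms in \[1, 2\]), kept
#' only for comparison.
#'
#' @param vafs estimated VAFs `mu_hat_j` of the called variants, in \[0, 1\].
#' @param literal use the `1 + tanh` transform instead of `1 - tanh`.
#' @return An object of class `diversity_score` with fields `value` (the
#'   score, `NA` when undefined), `defined`, `n_variants`, `p` and the
#'   per-variant `terms`.
#' @export
#' @examples
#' diversity_score(rep(0.25, 4)) # uniform pool of 4: D = 4
#' diversity_score(c(0.5, 0.1)) # D = 1.530
#' diversity_score(0.2) # undefined: "-"
diversity_score <- function(vafs, literal = FALSE) {
  if (any(vafs < 0 | vafs > 1)) stop("VAFs must lie in [0, 1]")
  n <- length(vafs)
  if (n < 2) {
    return(structure(list(value = NA_real_, defined = FALSE, n_variants = n,
                          p = NA_real_, terms = numeric(0)),
                     class = "diversity_score"))
  }
  p <- 1 / n
  kl <- bernoulli_kl(p, vafs)
  terms <- if (literal) 1 + tanh(kl) else 1 - tanh(kl)
  structure(list(value = sum(terms), defined = TRUE, n_variants = n,
                 p = p, terms = terms),
            class = "diversity_score")
}

#' @export
format.diversity_score <- function(x, digits = 3, ...) {
  if (!x$defined) "-" else formatC(x$value, digits = digits, format = "f")
}

#' @export
print.diversity_score <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<diversity_score> undefined (-): %d variant(s) called\n",
                x$n_variants))
  } else {
    cat(sprintf("<diversity_score> D = %s over %d variants (p = %.4g)\n",
                format(x), x$n_variants, x$p))
  }
  invisible(x)
}
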