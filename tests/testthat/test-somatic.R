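test_that("somatic-test configuration enforces its invariants", {
  expect_error(somatic_config(tau_low = 0), "tau_low")
  expect_error(somatic_config(tau_low = 0.5, tau_high = 0.2))
  expect_error(somatic_config(tau_high = 1.5))
  expect_error(somatic_config(n_draws = 10), "n_draws")
  expect_error(somatic_config(alpha = 0))
})

test_that("the posterior-difference test calls gains, losses and nulls correctly", {
  set.seed(90)
  K <- 1600
  jitter <- function(m, s = 2e-5) pmax(0, m + rnorm(K, 0, s))
  # locus 1: identical tiny rates (null); locus 2: case far above control
  # (gain); locus 3: difference constant 0.0005, below tau_low; locus 4:
  # case far below control (loss)
  case <- cbind(jitter(2e-4), jitter(0.05, 2e-3), jitter(7e-4),
                jitter(2e-4))
  ctrl <- cbind(jitter(2e-4), jitter(2e-4), jitter(2e-4),
                jitter(0.04, 2e-3))
  pc <- make_posterior(case, pos = 1:4, sample = "T1")
  p0 <- make_posterior(ctrl, pos = 1:4, sample = "T0")
  st <- somatic_test(pc, p0, somatic_config(seed = 91))

  expect_false(st$provisional[1])
  expect_true(st$provisional[2])
  expect_equal(st$direction[2], "gain")
  expect_gt(st$p_gain[2], 0.99)
  expect_false(st$provisional[3]) # constant delta 0.0005 < tau_low = 0.001
  expect_true(st$provisional[4])
  expect_equal(st$direction[4], "loss")

  # direct Monte-Carlo oracle on the known sample sets for locus 2
  set.seed(92)
  d <- sample(case[, 2], 4000, TRUE) - sample(ctrl[, 2], 4000, TRUE)
  expect_equal(st$p_gain[2], mean(d >= 0.001 & d <= 1), tolerance = 0.02)

  # identical seeds give identical probabilities
  st2 <- somatic_test(pc, p0, somatic_config(seed = 91))
  expect_identical(st[c("p_gain", "p_loss")], st2[c("p_gain", "p_loss")])

  # mismatched regions are refused
  p_other <- make_posterior(ctrl, pos = 5:8, sample = "T0")
  expect_error(somatic_test(pc, p_other, somatic_config()), "different regions")
})

test_that("provisional-call rate rises with the true VAF difference", {
  set.seed(95)
  K <- 800
  n_loci <- 40
  rate_at <- function(delta) {
    case <- vapply(seq_len(n_loci), function(i)
      pmax(0, rnorm(K, 2e-4 + delta, 4e-4)), numeric(K))
    ctrl <- vapply(seq_len(n_loci), function(i)
      pmax(0, rnorm(K, 2e-4, 4e-4)), numeric(K))
    st <- somatic_test(make_posterior(case, pos = seq_len(n_loci)),
                       make_posterior(ctrl, pos = seq_len(n_loci)),
                       somatic_config(seed = 96))
    mean(st$provisional)
  }
  rates <- vapply(c(0.001, 0.003, 0.01), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("the chi-squared filter keeps concentrated and rejects uniform alt spectra", {
  tn <- make_tensor(depth = 1000, ref = rep("A", 4),
                    alt_counts = list(c(G = 10), # (30,0,0) pooled over 3 reps
                                      c(C = 4, G = 3, T = 3), # near-uniform
                                      NULL, # zero non-reference reads
                                      c(C = 2, G = 1, T = 2))) # (6,3,6)
  expect_message(
    flt <- nonuniformity_filter(tn, positions = 1:4, alpha = 0.05),
    "dropped")
  expect_equal(flt$pos, 1L)
  expect_equal(flt$alt[1], "G")
  expect_equal(flt$chisq_stat[1], 60, tolerance = 1e-12)
  expect_equal(flt$chisq_p[1], pchisq(60, df = 2, lower.tail = FALSE))
  expect_lt(flt$chisq_p[1], 1e-12)
  expect_equal(attr(flt, "dropped"), 3L)

  # hand-checked chi-squared values: (10,10,10) -> 0, p = 1; (5,4,3) -> 0.5
  tn2 <- make_tensor(depth = 1000, ref = c("A", "A"),
                     alt_counts = list(c(C = 10, G = 10, T = 10),
                                       c(C = 5, G = 4, T = 3)))
  flt2 <- nonuniformity_filter(tn2, positions = 1:2, alpha = 0.05)
  expect_equal(nrow(flt2), 0)
  # with alpha = 1 everything except exact uniformity (p = 1) is retained;
  # counts pool over the 3 replicates: (30,30,30) is dropped, (15,12,9) kept
  all2 <- nonuniformity_filter(tn2, positions = 1:2, alpha = 1)
  expect_equal(all2$pos, 2L)
  expect_equal(all2$chisq_stat, 1.5, tolerance = 1e-12)
  expect_equal(all2$chisq_p, pchisq(1.5, 2, lower.tail = FALSE))

  # filtering is idempotent
  again <- nonuniformity_filter(tn, flt$pos, alpha = 0.05)
  expect_equal(again$pos, flt$pos)
  expect_equal(again$chisq_stat, flt$chisq_stat)

  # ties are broken alphabetically and flagged
  tn3 <- make_tensor(depth = 1000, ref = "A",
                     alt_counts = list(c(C = 20, T = 20)))
  all3 <- nonuniformity_filter(tn3, positions = 1, alpha = 0.05)
  expect_equal(all3$alt, "C")
  expect_true(all3$alt_tie)

  expect_error(nonuniformity_filter(tn, positions = 99), "absent")
})

test_that("timecourse calling unions positions across case/control pairs", {
  set.seed(101)
  ref <- sample(c("A", "C", "G", "T"), 30, TRUE)
  err <- rep(2e-4, 30)
  base_vaf <- rep(0, 30)
  v2 <- base_vaf; v2[c(7, 19)] <- 0.05 # gains at T2 only
  sims <- list(
    T0 = simulate_counts(base_vaf, ref, locus_error = err, seed = 102,
                         depth_model = list(median = 8000, dispersion = 10),
                         chrom = "sim", region_start = 1L, sample = "T0"),
    T1 = simulate_counts(base_vaf, ref, locus_error = err, seed = 103,
                         depth_model = list(median = 8000, dispersion = 10),
                         chrom = "sim", region_start = 1L, sample = "T1"),
    T2 = simulate_counts(v2, ref, locus_error = err, seed = 104,
                         depth_model = list(median = 8000, dispersion = 10),
                         chrom = "sim", region_start = 1L, sample = "T2"))
  tensors <- lapply(sims, `[[`, "tensor")
  fits <- lapply(tensors, fit_vaf, mcmc = mcmc_params(n_gibbs = 1000, seed = 105),
                 keep_theta = FALSE)
  tc <- call_timecourse(fits, tensors, control = "T0",
                        cfg = somatic_config(seed = 106))
  expect_named(tc$calls, c("T1", "T2"))
  expect_equal(nrow(tc$calls$T1), 0)
  expect_equal(sort(tc$calls$T2$pos), c(7L, 19L))
  expect_equal(tc$union, c(7L, 19L))
  expect_equal(tc$n_union, 2L)
  expect_equal(tc$n_union,
               length(unique(unlist(lapply(tc$calls, `[[`, "pos")))))
  expect_true(all(tc$calls$T2$prob > 0.95 & tc$calls$T2$chisq_p < 0.05))
})

test_that("call tables export as TSV and minimal VCF", {
  calls <- data.frame(chrom = "chrXV", pos = c(780501L, 780777L),
                      ref = c("A", "C"), alt = c("G", "T"),
                      mu_case = c(0.02, 0.3), mu_control = c(1e-4, 2e-4),
                      prob = c(0.99, 1), direction = c("gain", "gain"),
                      chisq_p = c(1e-8, 1e-12))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls_tsv(calls, tsv)
  expect_equal(nrow(read.delim(tsv)), 2)
  write_calls_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_equal(sum(grepl("^##", lines)), 6)
  expect_equal(sum(!grepl("^#", lines)), 2)
  body <- strsplit(lines[!grepl("^#", lines)][1], "\t")[[1]]
  expect_equal(body[c(1, 2, 4, 5)], c("chrXV", "780501", "A", "G"))
  expect_match(body[8], "VAF_CASE=0.02;")
})
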