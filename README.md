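# poolvar

Pooled variant fitness profiling from replicate deep amplicon sequencing.

A variomics screen passages a pooled library of ~2×10⁵ plasmid-borne
point-mutation alleles of one gene under lethal drug selection, sampling
every ~8 generations and sequencing the amplicon in technical triplicate at
10,000–20,000× median depth. Resistant alleles — often starting below 0.1%
frequency — enrich; everything else collapses. `poolvar` is for the people
analysing such screens: it estimates per-locus variant allele frequencies
(VAF) below the raw error rate, calls emergent/depleted variants between
timepoints, scores the pool's allelic diversity, and annotates coding
consequences. A generative simulator with known ground truth backs every
stage.

## The model and tests at the core

For replicates *n* and loci *j*, with depth *d* and non-reference count *r*:

    r_nj ~ Binomial(d_nj, θ_nj)
    θ_nj ~ Beta(μ_j M_j)            (mean/precision parameterisation)
    μ_j  ~ Beta(μ0 M0)

fitted per sample by Metropolis-within-Gibbs MCMC (conjugate θ draws; 10
logit-scale random-walk MH updates of each μ_j per sweep; 4000 sweeps, 20%
warm-up, thinning 2 by default), with empirical-Bayes moment estimates for
(μ0, M0, M_j). Technical replicates let the model learn a per-locus error
baseline and separate it from real VAF differences.

Variants between a case and a control sample are called by a Bayesian
posterior-difference ("somatic") test — P(μ_case − μ_control ∈ [0.001, 1])
from 1000 posterior draws, called at probability > 0.95, both directions
tested — followed by a chi-squared filter requiring the case sample's
non-reference reads to be non-uniform over the three substitution bases.

Pool diversity over a called set V with uniform share p = 1/|V|:

    D = Σ_{j∈V} (1 − tanh D_KL(p ‖ μ̂_j)),    D_KL = Bernoulli KL divergence

which is |V| for a perfectly even variant pool, shrinks toward 0 as the
pool skews, and is recorded as "-" when |V| < 2.

## Worked example

Simulate two timepoints of a screen, fit both, call variants and score
diversity:

```r
library(poolvar)
cfg <- sim_config(n_alleles = 2000, loci = 300, chrom = "sim", region_start = 1L,
                  depth_model = list(median = 20000, dispersion = 10), seed = 7)
pool <- build_library(cfg)
err  <- rbeta(cfg$loci, 0.5, 0.5 * (1 - 2e-4) / 2e-4)  # shared error profile
t0   <- sequence_pool(pool, cfg, locus_error = err, sample = "T0")
pool1 <- propagate(pool, g = 8, bottleneck_size = cfg$bottleneck_size)
t1   <- sequence_pool(pool1, cfg, locus_error = err, sample = "T1")

fit0 <- fit_vaf(t0$tensor, mcmc_params(seed = 1))
fit1 <- fit_vaf(t1$tensor, mcmc_params(seed = 2))
fit1
#> <vaf_posterior> sample T1: 300 loci, 1600 retained samples
#>   mu_hat range [1.84e-06, 0.241]; mean MH acceptance 0.33

st    <- somatic_test(fit1, fit0, somatic_config(seed = 3))
prov  <- st[st$provisional, ]
calls <- nonuniformity_filter(t1$tensor, prov$pos)
nrow(calls)
#> [1] 109
```

After one passage under lethal selection most library alleles are depleted
(`direction == "loss"`) while the resistant minority has enriched. Scoring
the enriched variants:

```r
gains <- calls$pos[calls$pos %in% st$pos[st$direction == "gain"]]
diversity_score(fit1$mu_hat[match(gains, fit1$pos)])
#> <diversity_score> D = 16.583 over 17 variants (p = 0.05882)
```

17 enriched variants with fairly even frequencies give D ≈ 16.6, close to
its maximum |V| = 17; as selection concentrates the pool onto the fittest
alleles over later passages, D falls. `simulate_screen()` wraps this whole
loop (library → optional haploid-viability bottleneck → T0..T3 →
background sample → fits → calls → diversity), and `annotate_calls()` /
`vaf_change_matrix()` turn call tables into amino-acid effects and
timecourse heatmap matrices.

Real data enter through `parse_pileup()` (samtools mpileup text over the
amplicon region, e.g. `chrXV:780367-782084`) or the TSV dialect of
`read_count_table()`; upstream read trimming, alignment and pileup
generation are standard tooling and are not reimplemented here. The raw
reads of the original region-wide screen are deposited at NCBI SRA
accession SRP072709; `screen_reference_values()` carries its published
outcome numbers as integration targets for a full re-analysis, which needs
that download and full MCMC over all samples (not desk-scale).

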