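---
title: "Pooled variant fitness profiling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled variant fitness profiling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A variomics screen propagates a pooled library of ~2×10⁵ plasmid-borne
point-mutation alleles of a single gene through serial passages under lethal
drug selection, sampling the pool every ~8 generations and sequencing the
amplicon in technical triplicate at 10,000–20,000× median depth. Resistant
alleles — often starting below 0.1% frequency — enrich over the timecourse;
everything else collapses. The analysis problem is to estimate each
position's variant allele frequency (VAF) far below the raw sequencing error
rate, decide which positions changed between timepoints, summarise how much
allelic diversity the pool retains, and translate called positions into
amino-acid consequences.

`poolvar` implements that pipeline end to end, together with a generative
simulator that provides ground truth for validating every stage.

## The hierarchical VAF model

For one sample with replicates $n = 1,\dots,N$ and loci $j = 1,\dots,J$, let
$d_{nj}$ be the depth and $r_{nj}$ the non-reference read count. The model is
a beta-binomial hierarchy in mean/precision parameterisation:

$$
r_{nj} \sim \mathrm{Binomial}(d_{nj}, \theta_{nj}), \qquad
\theta_{nj} \sim \mathrm{Beta}(\mu_j M_j), \qquad
\mu_j \sim \mathrm{Beta}(\mu_0 M_0).
$$

$\mu_j$ is the locus VAF (signal plus baseline error); $\theta_{nj}$ absorbs
replicate-to-replicate variation; $M_j$ is the per-locus replicate precision
and $(\mu_0, M_0)$ a global prior. The replicate layer is the point of the
design: triplicates of the *same* library let the model learn a per-locus
error baseline and separate it from true VAF differences between samples.

**Empirical-Bayes moments.** $\mu_0$, $M_0$ and $M_j$ are point-estimated
(`estimate_moments()`), not sampled, keeping the sampler to its two blocks.
$M_j$ inverts the cross-replicate variance of $r/d$ *after subtracting the
expected binomial sampling variance*; without that subtraction, depth noise
would masquerade as replicate overdispersion and flatten every posterior.
With ≤3 replicates the residual variance estimate is noisy, so $M_j$ is
clamped to $[1, 10^6]$ (zero residual variance maps to the ceiling), and an
all-zero tensor receives the pseudocount floor $\mu_0 = 1/(\text{total
reads} + 2)$ so all Beta parameters stay proper.

**Sampler.** `fit_vaf()` runs Metropolis-within-Gibbs (Rcpp core): each
sweep draws every $\theta_{nj}$ from its conjugate conditional
$\mathrm{Beta}(r_{nj} + \mu_j M_j,\; d_{nj} - r_{nj} + (1-\mu_j) M_j)$, then
applies 10 Metropolis-Hastings updates to each $\mu_j$ with a symmetric
random-walk proposal on the logit scale. The proposal step is adapted per
locus during warm-up toward a 0.2–0.5 acceptance band and then frozen.
Defaults are 4000 sweeps, 20% warm-up and thinning 2, retaining
$\lfloor n_{\text{gibbs}}(1 - \text{warmup})/\text{thin} \rfloor = 1600$
samples. All density arithmetic is in log space; within a sweep the
sufficient statistics $\sum_n \log\theta_{nj}$ and $\sum_n \log(1 -
\theta_{nj})$ make each proposal cost three `lgamma` calls.

A known behaviour worth stating: when $M_j$ sits at its ceiling the chain
moves along a tight $\mu \approx \theta$ ridge and the per-sweep
autocorrelation approaches $1 - d/(M_j + d)$. At the default 4000 sweeps the
posterior mean is accurate to a fraction of a posterior standard deviation
and interval coverage is nominal (the calibration test measures ~94% for
95% intervals over 200 loci), but effective sample sizes at such loci are
tens, not thousands — a deliberate trade against the fixed two-block
structure of the sampler.

## Variant calling

`somatic_test()` compares two *separately fitted* samples. For each locus it
resamples `n_draws = 1000` independent pairs from the two retained chains,
forms $\Delta = \mu^{\text{case}}_j - \mu^{\text{control}}_j$, and estimates
$p_{\text{gain}} = P(\Delta \in [\tau_{\text{low}}, \tau_{\text{high}}])$
and the mirrored $p_{\text{loss}}$. A provisional call requires
$\max(p_{\text{gain}}, p_{\text{loss}}) > 1 - \alpha$ with $\alpha = 0.05$.

Two interface decisions:

* **Interval units.** The admissible difference interval is
  $[0.001, 1.0]$ *as fractions* (0.1% to 100%): a difference of two
  frequencies cannot exceed 1, so an upper bound of "100" is only coherent
  as 100%. Both bounds are exposed.
* **Two-sidedness** is implemented as testing $\Delta$ and $-\Delta$
  against the positive interval with the direction recorded, since both
  enrichment and depletion are biologically meaningful over a selection
  timecourse. No multiple-testing adjustment is applied by default
  (matching the original analysis); a Bonferroni option exists.

`nonuniformity_filter()` then pools the case sample's non-reference base
counts across replicates at each provisional position and keeps it only if
the spectrum over the three substitution bases is non-uniform (chi-squared
goodness of fit, df 2, $\alpha = 0.05$): true substitutions concentrate on
one alt base, generic error does not. Pooling uses the case sample only —
the filter targets error uniformity in the sample being called. Positions
with zero non-reference reads are dropped (the statistic is undefined) and
reported; note this removes loss-direction calls whose variant vanished
completely, a conservative consequence of the contract.

## The diversity score

For the called set $V$ with estimates $\hat\mu_j$ and uniform share
$p = 1/|V|$:

$$
D = \sum_{j \in V} \left(1 - \tanh D_{KL}(p \,\|\, \hat\mu_j)\right),
\qquad
D_{KL}(p \| q) = p \ln\frac{p}{q} + (1-p)\ln\frac{1-p}{1-q},
$$

each term being 1 when the variant holds exactly the uniform share and 0 at
infinite divergence, so $D$ grows with both the number of variants and the
evenness of their frequencies. Two readings required a decision:

* The transform must be $1 - \tanh$: the statistic's stated limits (term
  → 0 as $D_{KL} \to \infty$, → 1 at 0) are only satisfied with the minus
  sign, since $\tanh$ is non-negative on $[0, \infty)$. The $1 + \tanh$
  variant (terms in $[1,2]$, maximum $2|V|$) is kept behind
  `literal = TRUE` for comparison only.
* The KL term is the *Bernoulli* divergence per variant — the only reading
  consistent with a per-$j$ summation and with "zero iff $\hat\mu_j = p$".

With fewer than two called variants the score is undefined and printed as
`"-"`. The call set feeding the score is the timepoint-versus-background
comparison (the background strain carries only the wild-type allele), with
$\hat\mu_j$ taken from the timepoint's own posterior.

## The simulator

`build_library()` → `apply_viability_filter()` → `propagate()` →
`sequence_pool()` emulate the screen's population structure:

* **Starting frequencies**: symmetric Dirichlet (concentration 5) over the
  alleles, emulating uneven clone representation; `"uniform"` available.
* **Fitness**: a configurable minority (default 1%) is resistant with
  $w \sim \mathrm{Lognormal}(\log 1.5, 0.15)$; the sensitive rest follow
  $\mathrm{Lognormal}(\log 0.5, 0.2)$, i.e. they decay under lethal
  selection. The true distribution of resistance effects is unknown — these
  are deliberately simple, stated defaults, chosen once and exposed in
  `sim_config()`, not tuned.
* **Viability bottleneck** (haploid conversion): allele $i$ survives with
  probability $\propto \min(1, w_i / w_{\max})$, rescaled to retain ~11% in
  expectation; only the realised fraction is known from the screen, so the
  weight is the simplest fitness-monotone choice.
* **Passaging**: deterministic $f_i' \propto f_i w_i^g$ with $g = 8$
  generations, plus multinomial resampling of `bottleneck_size` cells
  (default 10× the allele count, the screen's dilution coverage) for drift.
* **Sequencing**: negative-binomial depth around the configured median
  (amplicon coverage is overdispersed; the screen states only medians), a
  Beta-distributed per-locus baseline error (mean 2×10⁻⁴) shared across
  replicates — and, within one simulated screen, across samples, as a real
  amplicon's error profile would be — and binomial non-reference counts at
  $v + e - ve$, spread over alt bases with signal mass on the allele's
  substitution and error split evenly.
* **Ploidy modes**: one flag — haploid applies the viability filter before
  T0, diploid does not. Alleles carry one mutation by default
  (configurable); multi-mutation linkage exists in the truth table but the
  observed tensors are per-position marginals, matching the per-position
  analysis.

What the simulator does *not* model: PCR chimeras and cycle artefacts,
read-level qualities, alignment error, indels, batch effects between
sequencing runs, and epistasis between co-carried mutations. Passing tests
therefore validate the statistical machinery under the model's own
assumptions plus the stated population dynamics — not robustness to every
artefact of real libraries.

## Annotation

`classify_region()` partitions the region into promoter / CDS / terminator
by CDS interval and strand. `cds_effect()` translates reference and mutated
codons with the standard genetic code, labelling effects in the
conventional `S63A` style; minus-strand genes are handled by complementing
bases and counting CDS positions from the genomic end. The CDS coordinates
and sequence are a *required input* (`gene_annotation()` /
`read_gene_annotation()`): the screen's amplicon coordinates are printed
but the CDS placement within them is not, so the package refuses to
hard-code an unverifiable genome detail; the packaged
`inst/extdata/synthetic_annotation.yaml` is a synthetic fixture.
Conservation flags come from a user-supplied residue list — no alignment is
computed. `vaf_change_matrix()` reports $\hat\mu_j(t) - \hat\mu_j(T_0)$
(difference, with fold change as an option — "relative change" admits both
readings, and differences keep depleted variants finite).

## Problem sizes and numerical choices

The shipped tests exercise: single-locus exact-posterior recovery (depth
10,000 × 3); CI calibration over 200 loci at depth 10,000; type-I error on
200 null loci at depth 20,000; a spike-in detection grid of 300 loci
(50 per level at 0.05–1% plus 50 null) at depth 20,000 with full MCMC
defaults; and 20 seeded full screens per ploidy mode at a reduced scale of
2,000 alleles, 500 loci and 1,000 Gibbs sweeps. These sizes were chosen as
the smallest at which the corresponding statistical statements are stable.

Numerical details: chains are seeded and bit-reproducible (R's RNG drives
the C++ core); $\mu$ and $\theta$ are clamped to $[10^{-12}, 1-10^{-12}]$;
non-finite proposal log-densities are rejected; zero-depth loci produce
prior-driven posteriors and are flagged rather than dropped; alt-base ties
in the filter break alphabetically and carry a flag; credible intervals are
the 2.5/97.5 empirical percentiles of the retained samples.

## Known limitations

* At the detection limit itself, the interval test is inherently
  conservative: a spike exactly at $\tau_{\text{low}}$ leaves ~half the
  posterior mass of $\Delta$ inside the interval, so sensitivity at that
  exact level cannot approach 1; detection becomes reliable from about
  twice the lower bound (the spike-in grid measures this directly).
* Samples are fitted independently; there is no joint multi-timepoint
  model and no haplotype linkage of co-occurring mutations.
* The chi-squared filter cannot assess complete losses (zero alt reads).
* No indel calling; the pileup reader consumes and discards indel symbols.
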