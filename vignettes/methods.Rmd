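---
title: "Methods: mapping resistance alleles from crosses and pooled capture sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping resistance alleles from crosses and pooled capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experimental design this package models

A multi-resistant mosquito founder population (F0) is exposed, per
insecticide (deltamethrin, bendiocarb, fenitrothion), to a dose killing 80%
of individuals. Surviving females are mass-crossed with a fully susceptible
laboratory strain; their F1 offspring mate freely, and F2 females are
segregated with two further doses of the same insecticide (LD25 and LD75).
Thirteen pools of 100 females are sequenced with a targeted capture panel:
the shared unexposed F0 sample and, per line, the F0 LD80 survivors, unexposed
F2, F2 LD25 survivors and F2 LD75 survivors. The cross dilutes every
resistance allele towards one half of its survivor frequency and breaks up
genetic backgrounds, so alleles that rise under selection, fall after
outcrossing, and rise again with dose in F2 survivors are specifically
associated with resistance to that line's insecticide.

`poolcross` implements the full computational side of this design: a forward
simulator with known ground truth, copy-number detection from capture
coverage, an allele-frequency trajectory filter, a Bayesian F_ST outlier
scan, and the integration rule that combines them.

## The tolerance (phenotype) model

Individual log10-tolerance is `mu0 + sum(beta_l * g_l) + e`, with
`e ~ N(0, sigma^2)`. An individual survives dose `d` with probability
`pnorm((mu0 + score - log10 d) / sigma)` — the probit dose-mortality model
used to analyse bioassays, read at the individual level. Consequences:

* an individual's LD50 is `10^(mu0 + score)`, so `beta = log10(3)` is a
  3-fold LD50 shift per allele copy;
* `find_ld()` root-finds the dose at which expected cohort mortality equals
  a target (LD25/LD75/LD80), to relative tolerance 1e-6;
* dominance is configurable per locus (`h = 0.5` additive default;
  heterozygote contribution `2*h*beta`).

The residual `sigma` defaults to 0.3 log10-dose units, i.e. a probit slope
around 3.3 — the steep dose-mortality response typical of single-compound
mosquito bioassays. Amplification (`cnv_gene`) alleles segregate as single
Mendelian alleles of fixed per-haplotype copy number `k`; tandem-array
mutation dynamics are out of scope.

Census sizes default to 2,000 per generation (configurable). F2 females not
taken for the unexposed pool are split 35/65 between the LD25 and LD75
exposures so both survivor cohorts comfortably exceed one pool of 100 at the
default census (the LD75 batch kills three quarters, so it gets the larger
share). Only females are exposed and sequenced; sex is tracked.
Founder haplotypes are drawn in linkage equilibrium; linkage acts in
transmission through per-locus recombination fractions (0.5 = unlinked
default).

## Sequencing models

Read counts at a SNP: depth ~ NegBin(mean, size) per locus and condition
(capture variability is super-Poisson; size defaults to 20), alt reads ~
Binomial(depth, f') with `f' = f (1 - e) + (1 - f) e` for pool frequency `f`
and error rate `e` (default 0.001).

Capture coverage of an exon region: NegBin with expectation
`base_depth * library_factor * region_factor * (pool mean copy number / 2)`.
Library factors (lognormal, shared by all regions of a sample) emulate
library-size differences and are removable by library-size normalization;
region factors (lognormal, shared by all samples at a region) emulate
capture-efficiency differences and cancel in the common-reference ratio.

Neutral intergenic loci draw founder frequencies uniform on [0.05, 0.95] and
independent susceptible-strain frequencies uniform on [0, 1] (a lab strain
fixed or divergent at arbitrary loci); causal alleles are absent from the
susceptible strain by construction, which is the premise of the cross design.

## CNV detection

1. QC: a region is kept iff length > 45 bp and mean depth within [30, 800]
   reads/bp in all 13 samples (bounds inclusive, length strict).
2. Normalization: depths are scaled by (mean library size / sample library
   size), then each region is divided by its across-sample mean, so
   normalized values average exactly 1 per region.
3. Profiles: region values are averaged per gene (unweighted) and
   centre-reduced across the 13 conditions with the population (denominator
   n) standard deviation; spreads below 1e-12 are flagged degenerate.
4. Pass rule per line, strict inequalities:
   `(v[F0_LD80] - v[F0]) > 0.3 AND (v[F0_LD80] - v[F2]) > 0 AND
   ((v[F2_LD25] - v[F2]) > 0.2 OR (v[F2_LD75] - v[F2]) > 0.2)`.

**Which scale the rule reads, and why both are supported.** The rule was
stated for centre-reduced profiles, and `scale = "z"` is the default.
Centre-reduction standardizes each gene's profile to unit spread — on real
capture data, where profiles carry genuine inter-population copy-number
structure, that removes amplitude differences between genes. But for a gene
whose true profile is flat, the same standardization amplifies pure noise to
sd 1, and a fixed 0.3 threshold then passes roughly a fifth of such genes by
chance. On synthetic data whose non-causal genes are strictly diploid, the
normalized-ratio scale (`scale = "ratio"`, thresholds read as ratio
differences) is the meaningful configuration, and it is what
`run_pipeline()` and the recovery analyses use. This is a property of the
rule itself, not of the implementation; both scales share the same code
path and oracle tests.

## Variant QC and the trajectory filter

Loci enter the trajectory analysis when depth > 30 in all 13 conditions, the
largest pairwise frequency difference is at least 0.05, and the minor allele
has at least 4% of reads in at least one condition (the supporting-read rule
is applied per condition — "in at least one condition" — since pooled
application would hide conditions where the allele is absent).

Trajectory verdicts per line use initial-frequency bands over f(F0):
[0.30, 0.85) for deltamethrin ([0.15, 0.85) for the other two lines,
whose founders are less resistant) requiring a rise of at least 0.15 from F0
to F0_LD80; [0.85, 0.90) requiring 0.10; [0.90, 0.95) requiring 0.05; and
[0.95, 1] requiring any strict increase. Bands are left-closed right-open
(top band closed); printed "+15%" is read as "at least 15 points". The
trajectory must then fall from F0_LD80 to F2, rise from F2 to F2_LD25, rise
again to F2_LD75, and gain at least the band's minimum from F2 to F2_LD75
(the final-rise minimum mirrors the initial band's). Deleterious alleles are
detected as the exact complement: a locus is deleterious iff `1 - f`
satisfies the resistance conditions, which makes the two verdicts mutually
exclusive by construction. Stages with depth < 30 are flagged and disqualify
a locus rather than being imputed.

## The Bayesian F_ST scan

Per line, two contrasts are scanned: F0 (unexposed vs LD80 survivors) and F2
(unexposed vs LD25 vs LD75 survivors). Locus-by-population differentiation
is decomposed as `logit(F_ij) = alpha_i + beta_j`: `beta_j` captures
population-wide drift/sampling, `alpha_i` is a locus-specific selection
effect carried by a spike-and-slab prior with prior odds 10 for the neutral
(alpha excluded) model. Allele counts enter a Dirichlet-multinomial
likelihood with uniform ancestral frequencies; pooled read counts are
collapsed to effective haploid samples of `min(2 * pool_size, depth)`
alleles — a standard pool-seq compromise (how the original scan consumed
pooled counts is not specified; this choice is flagged for sensitivity
analysis, not asserted). Only substitutions enter the scan; indels remain
eligible for the trajectory filter.

The reversible-jump MCMC updates ancestral frequencies (logit random walk),
included alphas (random walk), betas (random walk), and toggles each
locus's inclusion with an independence proposal calibrated during pilot runs
executed with all alphas included; random-walk widths adapt to acceptance in
[0.25, 0.45]. Priors: alpha ~ N(0, 1), beta ~ N(-1, 1.8), following the
cited method's convention. The published schedule (20 x 2,000 pilot,
100,000 burn-in, 500,000 iterations thinned by 50) is the `"paper"` preset;
the `"desk"` preset divides chain lengths by 10 (configurable) and is used
throughout the tests — at a few hundred loci the posterior inclusion
frequencies are stable well below the published lengths. A split-chain
disagreement check on beta warns (without suppressing output) when the two
halves of the retained samples disagree by more than 0.5.

Posterior selection probability = inclusion frequency across retained
samples. q-values follow the posterior-error-probability convention: sort by
decreasing probability; q at rank r is the mean of (1 - prob) over ranks
1..r, enforced non-decreasing. "Low Q-value" defaults to q < 0.05.

Power depends on the neutral background: in this design the members of a
contrast are pools drawn from the same generation, so neutral
differentiation is at pool-plus-read sampling level (F_ST ~ 0.01), and
planted differences of 0.5 at depth 200+ are recovered essentially always.
If the background itself is strongly differentiated (island-model F_ST of
0.05-0.1 between only two populations), such outliers become genuinely
marginal under the model and posterior probabilities sit in mid-range — a
property of two-population scans, not an implementation artifact.

## Integration

A selection region is seeded by each trajectory hit whose locus reaches
q < 0.05 in both of its line's contrasts (the strictest literal reading:
the differential polymorphism itself must show low Q, not merely its
region); windows of +/- 50 kb are merged per line and chromosome. Regions
list overlapping candidate genes (any annotated family other than "other");
regions with none are kept and flagged anonymous rather than dropped, since
intergenic scan signal is informative. The protein-altering hit table
restricts trajectory hits to nonsynonymous/frameshift variants on candidate
genes and flags co-location with selection regions. `venn_counts()` gives
the seven-class overlap of per-line hit sets, and `truth_eval()` scores any
call set against the simulator's ground truth (sensitivity, false positives,
FDR, enrichment over the neutral hit rate).

## What the synthetic data do and do not show

The generator reproduces the design's structure — Mendelian segregation
through the cross, probit selection, pool sampling, negative-binomial
sequencing noise, dosage-driven coverage — with known truth, so it can
measure recovery and false-positive behaviour of every printed rule. It does
not emulate linkage blocks around real resistance loci (hitchhiking), mapping
bias, repeat-driven coverage artifacts, population structure in the founder
composite, or tandem-array CNV evolution. Passing recovery tests therefore
demonstrate the correctness and calibration of the decision rules under the
design's own noise model, not field performance.

Two quantitative limits of the design itself, measured with this package and
worth knowing:

* At 100x depth with pools of 100, a stage-to-stage frequency difference has
  a sampling sd of about 0.086. With ten causal loci sharing a 3-fold LD50
  shift each, the per-locus selection response at the F2 doses (~0.06-0.08
  at LD25, ~0.2 at LD75) sits close to these noise and threshold scales, so
  the trajectory filter recovers roughly half to two-thirds of such loci per
  experiment — with essentially no neutral hits (enrichment in the
  hundreds). Larger effects, fewer loci, or deeper sequencing push
  sensitivity up quickly.
* The centre-reduced CNV rule is scale-free for flat genes (see above);
  choose the scale to match what "no CNV" looks like in your data.
* When two or more amplified genes confer resistance to the same insecticide,
  the LD80 selection response per gene saturates: for two genes at founder
  frequency 0.3 the survivor allele frequency cannot exceed ~0.615 however
  strong the effect, because the survivors are selected on the joint score.
  The expected common-reference ratio rise (~0.41) then sits about one
  noise-sd above the strict 0.3 threshold, so a same-line amplified gene is
  recovered with probability ~0.8 per experiment rather than certainty; a
  gene that is its line's only strong locus is recovered essentially always.

A note on permutation nulls: the five stages of a line are exchangeable
under "no selection" only if the susceptible strain matches the founder
allele frequencies — otherwise outcrossing dilution gives the stages
genuinely different expectations and permuting condition labels manufactures
rise-fall-rise patterns out of real differences. The null-integrity test
builds its no-selection simulation accordingly.

## Problem sizes used by the test suite

Unit and property tests run on purpose-built small fixtures. The recovery
analyses use the study's own scales: pools of 100, census 2,000, 100x depth,
200 neutral genes + 5 amplified (20 seeds), 5,000 neutral SNPs + 10 causal
(20 seeds), 500-1,000 loci per scan at the desk MCMC preset. The acceptance
script repeats the same computations with fewer seeds (3-5) to keep a single
run within minutes.
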