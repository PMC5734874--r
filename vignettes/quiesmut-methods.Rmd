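---
title: "Methods: estimating total mutation rates from a phenotypic reporter screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating total mutation rates from a phenotypic reporter screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quiesmut)
```

# The measurement and its bias

A quiescent yeast population assayed on 5-FOA reports only mutations that
inactivate the *ura4*/*ura5* reporter. Synonymous SNVs are never seen;
STOP gains essentially always are; non-synonymous SNVs are seen only when
they hit a functionally essential residue. The package's job is to turn
the biased phenotypic record into estimates of the total mutational flux.
Everything hinges on one unknown, `f`: the fraction of potential
non-synonymous SNVs that produce the phenotype.

# Spectrum conventions

`mutation_records()` normalises alleles (case, U→T) and types each row as
SNV, insertion, deletion or *complex* (equal-length multi-nucleotide
substitution). Complex events are counted but enter neither SNV nor indel
statistics: the source data flag such events without prescribing a
treatment, and mixing them into either class would distort both.

`deduplicate()` collapses identical mutations within a clonal population
to a single representative (earliest day, then input order) rather than
removing them outright: repeated sightings within one culture reflect
lineage expansion of a single event, but the event itself did happen once
and belongs in the non-redundant spectrum. Identical mutations in
*different* populations are independent events and are all kept.

SNV classification is strand-symmetric: each of the 12 ordered
substitutions maps to one of six base-pair classes by normalising the
reference to its pyrimidine representative. The AT bias is
(GC→AT + GC→TA)/(AT→GC + AT→CG); the two direction-neutral classes
(AT→TA, GC→CG) enter neither side of the ratio. Ratios with a zero
denominator are reported as `NaN`, never silently dropped. Indel size
histogram bins (±1, ±2–3, ±4–10, ±>10 by default in
`bin_indel_sizes()`) are a reporting choice only; all statistics are
computed from exact signed sizes.

# The occupancy model

Both likelihood-based estimators reduce to the same abstraction: `m`
mutations fall independently and uniformly on `k` exchangeable targets,
and we observe only the histogram `k_1, ..., k_max` of targets hit
1, 2, ... times, with `k_0 = k - sum(k_i)` targets unseen. The
probability of the histogram is

$$P(k_1,\dots,k_{max}\mid k)
  = \frac{m!\,k!}{\prod_{i=0}^{max} k_i!\,(i!)^{k_i}}\cdot\frac{1}{k^m}.$$

`log_likelihood()` evaluates this through `lgamma()`, keeping every term
(including those constant in `k`) so that `exp()` of the result is the
exact probability — the test suite verifies this against exhaustive
enumeration of all `k^m` assignments for every achievable histogram with
`m, k <= 6`.

## Numerical choices in `mle_k()`

* **Integer grid scan**, no continuous relaxation: `k` is a count; the
  scan over `[occupied, k_max]` is exact and cheap at this scale
  (vectorised log-gamma, ~10^4–10^6 grid points).
* **Tie-break**: smallest `k` at equal log-likelihood (`which.max`),
  for determinism.
* **Credibility interval**: central (equal-tail) 95% interval of the
  likelihood normalised to sum to one over the integer grid — a flat
  prior. Equal-tail is reproducible and captures the asymmetry of the
  profile. Highest-density intervals would differ in the heavy-tailed
  regime (few recurrences); the construction used by the original
  analysis is not stated, so exact reproduction of its printed intervals
  is treated as a soft check.
* **Search bound**: starts at `200 * occupied` and doubles until the
  posterior mass in the upper half of the grid is below `1e-6`.
  **Caveat:** when `m - occupied <= 2` the normalised likelihood decays
  like `1/k` or `1/k^2`, and no finite grid captures its tail (with a
  single recurrence the flat-prior posterior is not even normalisable).
  The bound is therefore capped (`k_cap = 1e6`) and a warning reports
  that the interval's upper end is truncated; the point estimate is
  unaffected because the mode lies far inside the grid.
* **Unbounded detection**: if every target was hit exactly once
  (`max == 1`) the likelihood increases monotonically in `k`; the
  estimate is flagged `unbounded` rather than returning the search
  bound as a fake maximiser.

## The three estimators of `f`

* **Method 1** builds the distribution of *different* amino-acid-changing
  mutations per residue; `f = k_hat / n_aa`. Only non-synonymous
  (non-STOP) changes are counted as residue hits — whether STOP gains
  were included upstream in the original residue distributions is not
  decidable from the printed inputs, which are used verbatim when
  supplied directly.
* **Method 2** builds the distribution of *independent recurrent* hits
  per distinct non-synonymous SNV; `f = k_hat / n_NS,potential`. At the
  saturation typical of a reporter screen (~130 hits on several hundred
  targets) only the handful of recurrences carries information about
  `k`, so this estimator has intrinsically high variance — its interval,
  not just its point estimate, should be read.
* **Method 3** equates the saturation of phenotype-causing
  non-synonymous SNVs with that of STOPs:
  `s = obs_STOP / pot_STOP`, `f = obs_NS / (s * pot_NS)`. It uses only
  four counts and no likelihood.

All three assume no mutational bias across sites — mutational hotspots
violate the uniformity assumption and bias `k_hat` downward (a hot target
absorbs recurrences that the model reads as saturation).

# Codon enumeration

`enumerate_potential_snvs()` classifies all `9 * n_aa` single-nucleotide
substitutions under the standard genetic code. Deliberate conventions:
the initiator codon is an ordinary codon (the published potential-SNV
totals equal `9 * n_aa` exactly, implying no special-casing); a trailing
stop codon is excluded from the protein, putting STOP-loss out of scope;
ambiguity codes are rejected rather than expanded, because inputs are
curated Sanger calls; internal stop codons warn by default
(configurable to error).

# Rate correction

The phenotypic share of potential SNVs is `phi = P_STOP + f * P_NS`, and
the total SNV rate is `observed / phi`. For indels, out-of-frame events
are assumed always phenotypic; in-frame events are seen with probability
`f` (3 nt) or `1 - (1-f)^2` (6 nt, either of two residues essential).
The default correction is the multiplier
`1 + P_3nt/f + P_6nt/(1-(1-f)^2)` applied to the observed indel rate,
with `P_3nt`, `P_6nt` the in-frame fractions among observed indels. An
alternative reading — inflating only the observed in-frame classes,
multiplier `1 + P_3nt(1/f - 1) + P_6nt(1/(1-(1-f)^2) - 1)` — is arguably
more self-consistent, but the first form is what reproduces the published
corrected slopes, so it is the default and the alternative sits behind
`method = "inflate_observed"`. When several reporter genes are pooled the
pipeline uses the pooled `f` (configurable per method via `f_method`);
how the original analysis combined per-gene multipliers is unstated, so
the pooled default is flagged in the output.

Genome extrapolation is a plain linearity assumption: the per-nucleotide
rate measured on ~1.4 kb of reporter sequence is taken to hold across
the 14 Mb genome. Regional rate variation, chromatin context and the
reporter's 50%-coding bias all violate this to unknown degree; the
extrapolated figure is an order-of-magnitude statement.

# Accumulation and homogeneity

`fit_slope()` is ordinary least squares of frequency on day with a free
intercept — day-1 cultures already carry the replicative mutation load of
outgrowth, so forcing the line through zero would bias the slope. Points
from parallel experiments are pooled into a single fit.

`poisson_gof()` tests whether per-genome mutation counts are compatible
with a single homogeneous mutational force: counts binned at 0, 1, 2, …,
right tail merged until every expected count is ≥ 5 (the textbook
threshold; the binning is recorded in the output), chi-square with
`#bins - 2` degrees of freedom (one lost to the estimated mean).
Because the published p-value depends on an unstated binning, it is not
an acceptance target; instead the test's calibration (type-I error at
5%) and its power against negative-binomial overdispersion are verified
by simulation in the test suite.

# What the generator emulates — and what it does not

The synthetic module generates exactly the world the estimators assume:

* `simulate_target_hits()` — uniform multinomial placement of `m` hits
  on `k` targets; zero-hit targets unobserved.
* `simulate_phenotypic_assay()` — a random CDS, a uniformly chosen
  essential-residue subset of size `round(f_true * n_aa)` (chosen
  without regard to codon degeneracy, matching the estimators'
  uniformity assumption), candidates drawn uniformly over all potential
  SNVs, retained iff STOP or essential-residue non-synonymous. Default
  recovery configuration: 300-codon CDS, `f_true = 0.35`, `m` set so
  ~130 non-synonymous SNVs are observed — the input size of the pooled
  published analysis.
* `simulate_accumulation()` — a line with multiplicative Gaussian noise
  (default cv 5%, slope 0.55e-7/day, intercept 1e-7: the scale of the
  real assay).
* `simulate_genome_counts()` — i.i.d. Poisson (default mean 0.6 over
  237 genomes, the scale of the whole-genome arm).

It deliberately does **not** emulate: mutational bias and hotspots,
homopolymer-run indel enrichment, CpG effects, clonal redundancy
dynamics, selection during outgrowth, or sequencing error. A green
recovery test therefore establishes that the estimators invert their own
generative model at realistic sample sizes — not that the model is true
of real data. Method 2's recovery sits at the edge of its stated
tolerance for exactly this reason: with ~15 recurrences among ~130
hits, the sampling noise of `k_hat` is of the same order as the
tolerance itself.

# Known limitations

* The credibility interval is flat-prior over `[occupied, k_max]`; with
  very few recurrences the upper bound is truncated (warned) and should
  be read as "effectively unbounded".
* `f` is assumed identical across pooled genes; per-gene analysis is
  available but the headline pooled numbers inherit this assumption.
* The spectrum module does not annotate homopolymer context, and
  genome-coordinate↔CDS mapping is out of scope (positions are 1-based
  within the CDS).
* All randomness flows through R's global Mersenne-Twister stream,
  seeded once per generator call; byte-identical reproducibility is
  guaranteed for a fixed seed and R version.
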