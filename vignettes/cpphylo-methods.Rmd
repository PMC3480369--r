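---
title: "Methods: chloroplast haplotype phylogeography with cpphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloroplast haplotype phylogeography with cpphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chloroplast DNA in oaks (and most angiosperms) is maternally inherited and
non-recombining, so every tree carries a single cpDNA haplotype and the
geographic arrangement of haplotypes records seed-mediated range history:
where populations persisted through glacial cycles, where they expanded
from, and how strongly they are differentiated today. `cpphylo` implements
the full desk analysis for such a survey: haplotype calling from an aligned
set of intergenic spacers, diversity and differentiation statistics,
variance partitioning, network construction, and expansion dating. The
packaged worked example is a 528-tree, 50-population survey of *Quercus
variabilis* across East Asia (26 haplotypes in 1670 aligned bp), shipped as
a plain-text count table (`load_table1_fixture()`).

## Haplotype calling and gap handling

Aligned sequences are collapsed with `call_haplotypes()`. Gap handling is
the one genuinely open design choice, because published tables show
populations with two haplotypes yet zero nucleotide diversity — which can
only happen when haplotypes are distinguished by indels that the
nucleotide-diversity calculation ignores. The package therefore uses two
conventions at once:

* **Calling** uses `simple_indel`: a contiguous gap run is a single
  mutational event, so indels distinguish haplotypes (and contribute one
  step each to network and NST distances).
* **Substitution statistics** (π, Tajima's D, mismatch distributions) use
  `site_deletion` distances, which count substitution columns only.

This reproduces the `Hd > 0, π = 0` pattern in the fixture. Missing data
(`N`, and any non-ACGT ambiguity code) matches any base and never founds a
haplotype; representatives are completed when a later member resolves an
`N`. Haplotypes are numbered `H1, H2, ...` by order of first appearance;
any published labelling is unknowable from counts alone, so the mapping to
published haplotype names lives only in the fixture.

## Diversity and differentiation

Per-population haplotype diversity is Nei's unbiased estimator
`Hd = n/(n−1)(1 − Σ p_i²)`; nucleotide diversity is the mean number of
pairwise substitution differences per site.

The differentiation framework is Pons & Petit's. Within-population
diversity `HS` is the unweighted mean of the per-population unbiased
diversities. Total diversity `HT` is estimated from the unweighted mean
haplotype frequencies with two corrections:

$$\hat h_{T,\text{plug}} = 1 - \sum_i \bar x_i^2 + \frac{\hat h_S}{\tilde n K},
\qquad
\hat h_T = \hat h_S + \frac{K}{K-1}\left(\hat h_{T,\text{plug}} - \hat h_S\right),$$

with `ñ` the harmonic mean sample size and `K` the number of populations.
The `K/(K−1)` factor on the between-population component matters: without
it the estimator overshoots badly on real survey data (0.976 instead of
0.888 on the fixture). The chosen form reproduces all eleven published
regional `HT` values of the worked example to ±0.001, which is how it was
validated and frozen. `GST = (HT − HS)/HT`. `NST` applies the identical
estimator with each haplotype pair weighted by its mutational distance
`d_ij`; when all off-diagonal distances are equal the weighting is a
constant rescaling and `NST = GST` exactly (a test asserts this).

The `NST > GST` test (`nst_gst_test()`) permutes haplotype identities on
the distance matrix, leaving frequencies untouched, and reports the
one-sided `P` with the `+1/(n_perm+1)` correction; 1000 permutations is
the default. Standard errors are delete-one jackknives over populations.
Populations with `n < 2` cannot contribute an unbiased within-population
term and are dropped with a warning; degenerate configurations (all
populations fixed for one haplotype) report `NC` rather than a silent 0.
`Nm = (1 − GST)/(2 GST)` is the haploid, maternally inherited island-model
conversion; the factor 2 (not the nuclear 4) was adopted because it is the
convention for organelle markers and reproduces both published `Nm` values
from their `GST`s.

## AMOVA, pairwise divergence, isolation by distance

`amova()` partitions the sum of squared inter-haplotype distances (counts
of differences used directly as squared distances, the ARLEQUIN
convention; a frequency-only mode is available) into among-group,
among-population-within-group and within-population components with the
standard unequal-sample-size coefficients. Negative variance components
are reported as computed, never truncated. Permutation schemes follow the
usual design: individuals among populations within groups for `F_SC`,
whole populations among groups for `F_CT`, individuals among all
populations for `F_ST`. `pairwise_fct()` runs a two-group AMOVA per group
pair (the unit diagonal in its report is a formatting convention), and
`fst_matrix()` a two-population AMOVA per population pair.

`mantel_ibd()` correlates linearised genetic distance `F_ST/(1 − F_ST)`
with great-circle distance (haversine, Earth radius fixed at 6371.0 km —
the conventional mean radius; the choice is immaterial at the test's
resolution) and permutes rows/columns jointly for a one-sided `P`. Any
`F_ST = 1` pair makes the linearisation infinite and is reported as an
error naming the pair.

## Median-joining networks

`build_msn()` keeps every edge that lies in some minimum spanning tree
(characterised by minimax path weights, so ties are retained), plus —
for `ε > 0` — feasible links within `ε` of the connection threshold. The
default `ε = 0` because the original study does not state its setting.
`median_joining()` recodes the variable columns to binary indicators
(multistate columns get one indicator per state — a simplification of the
quasi-median rule that is exact for infinite-sites data, where every
column carries at most one mutation), then repeatedly inserts the majority
(consensus) vector of a node triple whenever it strictly lowers the total
network cost (MST weight), and finally prunes median vectors that are
obsolete or of degree < 3. Insertions are accepted only when they reduce
cost, so the cost sequence is non-increasing by construction. MST
tie-breaking is deterministic (ordered by steps, then node ids).

## Neutrality tests and expansion dating

`tajimas_d()` uses the 1989 constants on substitution sites only.
Calibration note: `D` is not mean-zero at finite sample size; at `n = 30`,
`θ = 5` an independent simulator (msprime/tskit, run once during
development) gives `E[D] ≈ −0.14`, and the test suite checks our generator
against that value, not against zero.

`fus_fs()` evaluates `S' = Pr(K ≥ k_obs | θ = θ̂_π)` under the Ewens
sampling formula with unsigned Stirling numbers of the first kind computed
by a log-space recurrence (stable to `n` in the hundreds; the fixture's
`n = 528` works). `FS = ln(S'/(1−S'))`. `k_obs = 1` makes `S' = 1` and
`FS` unbounded; this is guarded with an informative error. Significance,
where needed, is assessed against a simulated constant-size null at the
observed `θ̂_π`, since no closed-form null exists.

`expected_mismatch_demographic()` is the closed-form sudden-expansion
expectation built on the equilibrium geometric
`F_i(θ) = θ^i/(θ+1)^{i+1}`: pairs coalescing since the expansion
contribute a gamma-truncated equilibrium term at `θ1`, earlier pairs a
Poisson(τ)-shifted equilibrium at `θ0`. The spatial variant treats the
sample as one deme of an infinite-island system (parameters τ, θ, M,
ancestral deme size = θ) and is labelled experimental: the reference
implementation's exact numerical scheme is not public, so the package
derives the mixture form exactly and verifies it against numerical
quadrature. `fit_expansion()` minimises the SSD between observed and
expected relative frequencies by a coarse grid (τ to 20 in steps of 0.5,
log-spaced θ values; θ1 capped at 1e5 where the expectation goes flat)
followed by Nelder–Mead on square-root-transformed parameters — the SSD
surface is multimodal, so the grid matters more than the polish.
Goodness-of-fit `P`s and the τ CI come from a parametric bootstrap that
re-simulates genealogies under the fitted model with the package's own
coalescent engine.

`expansion_time()` computes `T = τ/(2u)` with `u = µ k g`. Strictly this
yields generations, but the literature convention reports it as years
(so τ ≈ 2.2 with µ = 7.905×10⁻¹⁰, k = 1670, g = 50 prints as ≈ 17 kyr);
the function reproduces that arithmetic and attaches the caveat as an
attribute rather than silently changing the published convention.

## The synthetic-data generator: what it emulates, what it does not

`cp_sim_config()` defaults state the world the analyses assume: 528
individuals in 50 populations over 7 regions, 1670 bp, sudden expansion
`θ0 = 0.1 → θ1 = 1000` at `τ = 2.2` (the scale of the fitted history).
`simulate_expansion_coalescent()` is a Kingman coalescent with
exponential waiting times rescaled across the size change and
infinite-sites mutations mapped to distinct alignment columns (a run that
needs more mutations than columns errors rather than violating the
model). Its truth record carries tree length, the exact pairwise mismatch
histogram and per-individual haplotype labels, so haplotype recovery and
estimator checks score against ground truth. `simulate_structured()` is
an equilibrium structured coalescent (island or ring stepping-stone) with
per-deme `deme_theta` and scaled migrant number `M = 2Nm`; with
`structured_mutations` 99% of migration stays within a deme's region,
which makes related haplotypes co-occur geographically — the signal
`NST > GST` detects. `simulate_planted_haplotypes()` builds an exact
26-haplotype, 23-substitution-site, 528-individual survey by placing
mutations on a random topology and splitting residual duplicates with
private indels (so some haplotypes differ by indels only, as in the real
data).

What the generator does **not** emulate: recombination (cpDNA is assumed
a single linkage block), selection, sequencing error, homoplasy (every
column mutates at most once) and the geographic irregularity of real
sampling (coordinates are synthetic grid points). A green simulation test
therefore establishes estimator correctness under the stated model, not
robustness to artefacts the model excludes.

## Numerical choices and degenerate inputs

* Permutation tests use the `+1/(n_perm+1)` correction and a mandatory
  seed; defaults are 1000 permutations and 1000 bootstrap replicates
  (tests and the worked scripts scale these down where runtime matters
  and say so).
* Jackknife SEs use only finite leave-one-out replicates; with fewer than
  two they are `NA`.
* Distances of zero variance (all off-diagonal equal) short-circuit the
  `NST` permutation test with `P = 1` and a warning.
* `F_ST` estimates can be negative; they are kept raw in computation and
  clamped only at reporting layers that need a bounded display.
* Stirling rows and the fitted-θ1 cap are cached/bounded to keep Fu's FS
  and the mismatch fit stable at survey scale.

## Known limitations

Counts-only input (the usual published form) supports `Hd`, `HS`, `HT`,
`GST` and `Nm` only; π, `NST`, AMOVA, networks and demography need
sequences and are reported `NC` by `run_pipeline()` rather than silently
zero. The spatial expansion model is the exact infinite-island mixture,
which may differ in detail from other implementations' numerics. The
median-joining reduction to binary indicators can produce chimeric median
vectors on multistate columns with three or more observed states; for
infinite-sites-like cpDNA data this case does not arise.
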