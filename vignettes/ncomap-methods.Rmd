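---
title: "Detecting and analysing crossovers and non-crossover gene conversions in hybrid mouse pedigrees"
author: "ncomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ncomap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncomap)
```

## The problem

During meiosis, programmed DNA double-strand breaks (DSBs) at
PRDM9-positioned hotspots repair from the homologous chromosome either
as crossovers (COs, reciprocal exchanges visible as ancestry switches)
or, far more often, as non-crossovers (NCOs): short gene-conversion
tracts in which a handful of bases are copied from the donor homologue
onto the broken (recipient) homologue. In a cross between two diverged
inbred strains (here labelled B6 and CAST, with the B6 line carrying a
humanised *Prdm9* allele), dense diagnostic SNPs (~1 per 170 bp) make
both event types detectable in deep-sequenced offspring: a CO is a
change of background ancestry along a chromosome, and an NCO is an
isolated cluster of genotype calls conflicting with the local
background.

`ncomap` implements this full analysis as a reusable pipeline:
background-ancestry inference by HMM, CO/NCO calling with a
false-positive filter cascade, composite-likelihood estimation of mean
conversion-tract length, estimation of total homologue-templated DSBs
per meiosis, Poisson-noise-corrected correlations of binned event
rates, hotspot-symmetry analyses from allele-specific ChIP read
counts, a two-pathway model of GC-biased gene conversion, and a
detection-power simulation. A synthetic-data generator reproduces the
statistical structure of the cross so every stage is testable without
any external data.

## The synthetic intercross generator

`sim_config()` collects the generative constants. The defaults are the
study conditions the pipeline targets:

* SNP spacing: geometric inter-SNP gaps with mean 170 bp; alleles are
  uniform distinct base pairs, classified strong (S = G/C) or weak
  (W = A/T).
* Pedigree: two inbred founders, two F1 hybrids, 11 sequenced F2
  offspring, an (unsequenced) F3 generation, 36 F4 parents in 18
  pairs, and 72 F5 offspring (4 per family).
* Meiosis: Poisson(300) homologue-templated DSB repairs per meiosis,
  10% resolving as CO; one obligate CO per chromosome is enforced by
  resampling (crossover interference is not modelled, since no
  downstream analysis depends on it). Hotspots receive DSBs with
  probability proportional to heat times the binding ratio of the
  recipient homologue.
* NCO tracts: exponential lengths with mean 30 bp at Cast-controlled
  and 41 bp at humanised-allele hotspots, centred on the hotspot motif
  plus a zero-mean normal displacement (sd 200 bp).
* Heteroduplex repair: the donor-biased pathway converts every
  mismatch; the GC-restoring pathway blocks single-mismatch tracts
  whose recipient base is G or C with probability `p_block = 0.53`,
  and interior G/C-recipient markers of multi-SNP tracts at a small
  rate (`complex_block_rate`), generating rare complex events with
  blocked markers.
* Sequencing: Poisson depth (10x founders/F4, 20x F2/F5), binomial
  allele reads with per-read errors, maximum-likelihood genotype
  calls, plus injected artifact modes (skewed-allele-balance false
  hets, low-depth false homs) to exercise the filter cascade.
* Hotspots: truncated Pareto heats (tail index 1.3, cap 300) so that
  the hottest sixth of hotspots carries over half the total heat — the
  only constraint available on the real heat distribution — while no
  single hotspot dominates; a configurable fraction is asymmetric
  (binding ratio x near 0 or 1), and 96% of asymmetric hotspots carry
  a motif-disrupting variant (the motif interval is placed over an
  actual SNP of the map; intact motifs avoid SNPs where possible).

The default genome is a scaled twin: 75 Mb over three autosomes
(tests and the shipped experiments use 10–40 Mb), not 2.5 Gb. All
other constants are kept at the study's values. One scale interaction
matters: with a full per-meiosis DSB count on a small genome, distinct
events collide in the same hotspot far more often than they would on
a full-size genome. The experiments below therefore use hotspot
counts near the 2-kb packing capacity, and accuracy claims exclude
the residual collisions, which are identifiability limits rather than
caller errors (see *Known limitations*).

Truth bookkeeping records every event per meiosis, tracks inherited
events through later transmissions, and supports exact recall and
precision measurement. All DSB repairs of a meiosis are placed on the
transmitted chromatid, so truth counts per meiosis are on the same
scale as the per-meiosis estimators; chromatid sampling within the
tetrad is deliberately not modelled.

## Background inference and event calling

`infer_background()` runs a three-state HMM (BB, BC, CC background)
along each chromosome. Emissions give the concordant call probability
1 − ε and split ε over the two discordant calls; missing calls are
uninformative. Transitions over a gap of d bp leave the current state
with probability 1 − exp(−r·d), and direct BB↔CC moves are disallowed
(they pass through BC). Defaults ε = 0.002 and r = 10⁻⁷/bp recover
truth at the generator's noise levels; both are exposed in
`hmm_params()`. Decoding is by per-SNP posterior argmax
(forward–backward, implemented in C++), because the analysis assigns
a state to every SNP rather than one best path; SNPs below a
posterior threshold (default 0.9) stay unassigned. The
forward–backward kernel is verified against exhaustive enumeration of
all 3^n paths on small inputs.

`call_crossovers()` emits one call per adjacent segment pair with
different states, with the breakpoint interval spanning the last and
first flanking SNPs; A→B→A excursions spanning at most a couple of
SNPs are flagged `nco_like`. `call_nco_candidates()` emits every SNP
whose call conflicts with its background, with the implied conversion
direction. The recipient *allele* (the founder allele replaced) is
always known from the direction; the recipient *homologue* is known
in homozygous segments and unknown in heterozygous ones, where phase
is ambiguous.

`apply_filters()` applies an ordered cascade modelled on the study's
description (the exact thresholds live in an unavailable supplement,
so the defaults here are this package's own, chosen from the error
model of the calls and exposed in `filter_config()`):

1. sites heterozygous or discordant in the founders;
2. heterozygous candidates: two-sided binomial allele-balance
   p ≥ 0.01, depth ≥ 10 and ≥ 2 reads of the rarer allele (singleton
   discordant reads are typical sequencing errors);
3. homozygous candidates: depth ≥ 12, ≥ 10 supporting reads and no
   reads of the other allele (false homozygotes are overwhelmingly
   moderate-depth heterozygous sites whose minor allele was missed by
   sampling);
4. configured exclusion regions;
5. an optional guard distance around called crossovers (off by
   default);
6. merging of surviving candidates within 2,000 bp (the hotspot
   scale) into NCO calls with minimal/maximal tracts and a
   complexity flag (an unconverted SNP strictly inside the minimal
   tract).

The report conserves counts exactly (input = removed + surviving).
`classify_inheritance()` marks an offspring event inherited when a
parent carries an identical event — same converted SNP set for NCOs,
same breakpoint interval for COs, the strictest reading — and
collapses sibling-shared events. Parent of origin is assigned by the
heterozygous-parent rule for NCOs, and by the same rule applied to
the flanking boundary SNPs for COs; a dedicated phasing HMM for CO
origin is intentionally out of scope, and undetermined cases are
labelled unknown.

## Tract lengths and total DSBs

Conversion tracts are summarised by an exponential length model with
rate λ. For each converted (focal) site, every other SNP within a
1-kb window contributes a pair (d, x): distance and co-conversion
indicator. Conditioning on SNP positions makes the estimator
independent of SNP density — verified directly by halving the
density in tests. The composite likelihood multiplies
exp(−λd)^x (1 − exp(−λd))^(1−x) over pairs and is maximised by grid
search over mean tract lengths 1–1000 bp in 0.1-bp steps (ties to the
smaller mean; boundary maxima flagged). The grid maximiser matches a
continuous optimiser within one grid step, and the two-pair closed
form (one co-converted, one not, both at 50 bp) gives 50/ln 2 ≈
72.1 bp. Uncertainty comes from a length-weighted block bootstrap
(10-Mb blocks, percentile intervals; the percentile choice is the
simplest consistent one). Parameter-recovery experiments at the
study's event counts (409 and 815 events at 1 SNP/170 bp) recover
30 bp and 41 bp within the study's printed confidence intervals.

`estimate_total_dsbs()` scales observed counts to total
homologue-templated DSBs per meiosis:
total = [NCO/(power × p) + CO/co_detect]/n_meioses, with every
component recorded for audit. The observability p is computed by
Monte-Carlo placement of exponential tracts at hotspot motifs —
either the plain probability of containing a SNP
(`prob_tract_contains_snp()`) or, under the two-pathway repair model,
the probability of yielding at least one *observable* conversion
(`prob_tract_observable()`), which also discounts single-mismatch
G/C-recipient tracts restored by the GC-restoring pathway. The
end-to-end experiment (11 noise-free F2 samples, 22 meioses)
recovers a simulated truth of 300 DSBs per meiosis within 15%.

## Rate correlations and positional profiles

Observed binned counts N are modelled as Poisson around latent binned
rates W, so Var(N) = E(W) + Var(W) and Cov(N_j, N_k) = Cov(W_j, W_k).
The corrected correlation divides the count covariance by the
geometric mean of the variance excesses Var(N) − mean(N), using
unbiased sample moments. When an excess is non-positive there is no
detectable rate variation and the estimate is flagged invalid rather
than silently reported; finite-sample estimates outside [−1, 1]
(e.g. for identical overdispersed vectors) are clipped with the raw
value retained. Intervals come from bootstrap resampling of bins;
invalid resamples are dropped and counted. Bins are unweighted, with
partial-bin lengths recorded. `end_distance_profile()` bins events by
distance to the nearer chromosome end against a null that scrambles
positions uniformly per chromosome (preserving per-chromosome counts
exactly), with 90% bootstrap bands.

## Hotspot symmetry

From homologue-assignable read counts, `b6_ratio()` computes the B6
fraction x (requiring ≥ 10 informative reads; an optional linear
input subtraction stands in for the full H3K4me3 background
correction), and `symmetry()` computes 4x(1 − x). Homologous heat is
the heat attributed to the repair-template homologue: x·h for a
CAST-recipient event and (1 − x)·h for a B6-recipient event. (The
source description of this quantity assigns both cases to the same
chromosome, which is internally inconsistent; the template-homologue
convention adopted here is the one under which the quantity measures
how well the intact homologue is bound.) Average homologous heat is
2hx(1 − x).

`bin_by_symmetry()` orders hotspots by symmetry and cuts the
cumulative predicted-event mass into equal-mass bins;
`observed_vs_expected()` compares per-class observed fractions with
the enrichment-predicted expectation by chi-square (no continuity
correction; the equal-mass construction keeps expected counts large).
With the generator's asymmetric-repair deficit switched on, the
asymmetric bin shows the expected depletion; with it off, p-values
are null-like. `glm_symmetry_vs_density()` fits the binomial GLM of
event occurrence on symmetry, log H3K4me3 enrichment (incremented by
1e-4) and SNP densities at ±100/±500/±800 bp, with optional
power-weight resampling of hotspots for NCOs; simulation tests
confirm it attributes the signal to whichever driver generated it.
`event_motif_distance()` reports both distance definitions (motif
centre to nearest converted marker, zero inside the motif; and
minimal-tract midpoint to motif centre) with SNP-density-normalised
histograms.

## GC-biased gene conversion

`classify_conversions()` labels each converted site by recipient and
donor base, collapsing strand-equivalent pairs, with the event's
tract-size class and the site's nearest-SNP distance. Because the S/W
status of a conversion is determined by its direction alone, records
are informative even when the recipient homologue is unknown.
`gc_bias_fraction()`, `single_vs_multi_test()` and
`distance_stratified_bias()` quantify the weak-to-strong bias overall,
between single- and multi-SNP tracts (Fisher exact), and across
nearest-SNP distance strata. Under the two-pathway model the observed
weak-to-strong fraction among single-mismatch conversions is
1/(2 − p_block): 68% at p_block = 0.53, capped at 2/3 if restoration
acts at only one of the two strong bases. `blocked_marker_tally()`
counts G/C-recipient blocked markers inside complex events with an
exact two-sided binomial test (minimum-likelihood convention, equal to
twice the smaller tail at p₀ = 0.5). Exact tests are delegated to
`binom.test()`/`fisher.test()` and verified against full enumeration
in the test suite.

## Detection power

`run_power_simulation()` re-creates the study's spliced-genotype
power estimate: hotspots sampled proportional to H3K4me3 enrichment,
tract centres from the motif-displacement distribution, exponential
lengths over a grid of means (10–100 by 10, 150–300 by 50); tracts
with no SNP are not potentially detectable; a donor sample with a
conversion-consistent background supplies call-level GT/DP/AD fields
which are spliced onto the recipient, and the filter cascade decides
survival. Power is survival among detectable tracts with an eligible
donor (donor-less tracts are skipped and counted). The splice copies
call-level fields rather than reads; that is sufficient for every
implemented filter. `detection_weights()` turns the same tract model
into per-hotspot detection probabilities normalised to mean 1, used
for the power-corrected analyses.

## Numerical choices and degenerate inputs

Grid ties break toward the smaller mean; boundary maxima are flagged
rather than silently returned. Composite-likelihood terms with
1 − exp(−λd) ≤ 0 are floored with a warning. All-missing chromosomes
leave states unassigned with a warning; unsorted SNP positions are an
error. The allele-balance p-value uses the exact symmetric-binomial
form 2·P(X ≤ min(k, n−k)), capped at 1. Bootstrap intervals are
percentile throughout. Every generator function is deterministic
under `sim_config(seed = )`.

## What the tests do and do not show

All accuracy claims are made on the generator, which emulates SNP
density, pedigree structure, heavy-tailed hotspot usage, exponential
tracts, allele-specific binding, depth/error-bearing calls and
artifact modes — but not alignment artifacts, indels, structural
variation, reference bias, recurrent systematic error sites, X-linked
inheritance or crossover interference. Passing tests therefore show
the statistical machinery is correct under the stated model, not that
the filters would achieve the same false-positive rate on real
sequencing data. Two identifiability limits are intrinsic rather than
implementation flaws, and event-level recall/precision tests exclude
them: an NCO whose tract lies within the resolution interval of a
crossover is absorbed into the background switch, and two events in
the same hotspot merge into one call (both are also limits of the
original method; they matter here only because a scaled genome packs
events more densely).

The command-line wrapper (`inst/cli/ncomap`) covers the two batch
entry points, dataset simulation and tract-length fitting; all other
operations are library calls documented on their help pages.
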