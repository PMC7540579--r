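---
title: "Shared genomic segment analysis: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared genomic segment analysis: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segshare)
```

## The statistical model

`segshare` addresses gene mapping for dominantly inherited traits with high
locus and allelic heterogeneity, where the classical "linkage with
homogeneity" null is the wrong starting point. The package reverses the
hypotheses (equivalence testing): the null H0 is *heterogeneity* — each
individual's candidate disease-variant positions can fall anywhere in the
genome — and evidence against H0 is that several individuals place
candidates at approximately the same position.

**Candidate generation.** A rare dominant disease allele with population
minor allele frequency *f* forces its immediate neighbourhood to be
heterozygous in carriers with probability P(H) > 1 − *f*, whereas an
arbitrary variant with frequency *f* is heterozygous with only
2*f*(1 − *f*). The scan exploits this contrast: for each individual, a
window of 2*m* + 1 adjacent variants slides one variant at a time along the
chromosome and H = *h*/(*g* + *h*) is recorded at the window centre, where
*h* and *g* count heterozygous and homozygous genotypes in the window.
Missing genotypes are excluded from numerator and denominator (they shrink
the window rather than being imputed); H is undefined where no genotype is
called, and such positions are dropped before peak detection. Runs of
increasing H up to a maximum H_max followed by decreasing H mark candidate
locations; each individual contributes the positions of its H_max values —
*k* candidates, however many emerge.

**Sharing statistic.** For every variant v and half-width *d* (kb), N_f(v)
counts the individuals with at least one candidate within ±*d*·1000 bp of v
(closed interval, so a candidate exactly *d* kb away counts). An individual
contributes at most one to any variant no matter how many of its candidates
fall in the window; internally each individual's candidate windows are
merged into disjoint intervals before coverage is stamped, which is what
makes the count match its brute-force definition.

**Null distribution.** Under H0, each individual's *k* candidate positions
are re-drawn uniformly *without replacement* from the positions of the
variant universe, independently across individuals. This is equivalent to
randomly permuting the position labels of the variants for that individual
and reading off where its candidates land, and it preserves each
individual's *k*. Candidates are restricted to variant positions (not
arbitrary base pairs): the statistic is only ever evaluated at variants, and
the observed candidates are themselves variant positions. Each permutation
sample yields a pseudo-N_f value at every variant; the exceedance
probability P(N_f ≥ t) is estimated by pooling pseudo-N_f over all variants
and samples, giving one p per (t, *d*) pair — a single genome-wide
significance table, which is also why two variants with equal N_f always
receive equal p. A per-variant mode (`mode = "per_variant"`), which draws
one pseudo-N_f at a single target variant per sample, is available for the
alternative reading in which the permutation count applies to one variant
at a time; the pooled mode is the default because its N_f = 1 row matches
the marginal capture probability of a random variant, which is how the
published significance tables behave.

When the observed candidate set is supplied it is counted as one of the
`n_perm` samples, so the smallest attainable p is 1/`n_perm` (0.0001 at the
default 10,000) and values at the floor are reported as "< 1/n_perm". In
pooled mode p is floored at 1/`n_perm` for the same reason even though the
pooled denominator is larger.

**Runs.** N_crit(*d*) is the smallest t with p(t, *d*) < 0.05, floored at 3
so that a "significant" region is never driven by only two individuals.
Maximal stretches of consecutive variants with N_f ≥ N_crit are reported as
runs; strict adjacency defines a run (no gap tolerance) because that is the
minimal reading of a run of variants, and a run breaks at chromosome
boundaries. A run's length is the bp span from its first to its last
variant, so single-variant runs have length 0 but still count. Run lengths
are reported in kb throughout; published run-length tables for this kind of
analysis are ambiguous between kb and Mb, and we emit kb rather than match
any particular table.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 50 variants | window half-width; the window spans 2m+1 variants. A fixed, user-configurable value is used; dynamic per-position window optimisation is deliberately out of scope, and a per-position `m` can be emulated by rerunning the scan. |
| `maf_max` | 0.05 | variants with sample MAF strictly above this are removed, after removing monomorphic ones; a variant at exactly 0.05 is kept. |
| `min_rise`, `min_fall` | 3 variants | minimum strict increases (decreases) before (after) a peak. Peak emergence criteria for this scan are not fully standardised; these defaults suppress one-variant jitter while keeping genuine peaks, and both are tunable. |
| `min_prominence` | 0.1 | peak H minus the larger endpoint H must reach this; filters shallow bumps on a high baseline. |
| `d` grid | 2, 5, 10, 20, 50, 100, 200, 500 kb | half-widths for the sharing statistic. Small d gives few, precise captures; large d captures more individuals but needs a larger N_f for significance. |
| `n_perm` | 10,000 | permutation samples, including the observed data when supplied. |
| `n_crit_floor` | 3 | minimum N_crit. |

Coordinates are 1-based base pairs (VCF convention) everywhere; *d* is
converted exactly as *d*·1000 bp; BED output converts to 0-based half-open
intervals. Duplicate (chrom, pos) records keep the first occurrence with a
warning, and unsorted input is sorted with a warning, because the scan
needs a strictly increasing position vector per chromosome.

**MAF estimation.** From VCF input, MAF is the allele-dosage minor
frequency with all alternate alleles collapsed and missing alleles excluded
from the denominator. The TSV genotype dialect carries only HOM/HET/missing
codes, so its MAF is estimated as #HET/(2·#called); this is exact when no
individual is homozygous for the minor allele — the regime the method
targets — and is documented on `read_genotypes()`. Note that a MAF
estimated from a handful of carriers is too coarse for a 0.05 filter (the
shared core itself approaches 0.5); in carrier-only analyses the filter
threshold should be relaxed or frequencies taken from a population panel,
which is why the simulator records each variant's generating population
frequency in the variant table.

## The synthetic-data generator

`simulate_genotypes()` emulates exactly the structure the method assumes:
a chromosome of M rare variants (uniform grid or uniform-random positions),
per-variant population frequencies f drawn uniformly from `maf_range`
(capped at 0.05, the post-filter regime), and N carriers whose genotypes
are independently HET with probability 2f(1−f) in the background and
`p_het_near` (default 1) within ±`elevation_halfwidth_bp` of the implanted
disease position. The config validates the heterozygote-excess inequality
`p_het_near > 1 − max f`. `simulate_candidates()` skips the genotype level
and draws candidate sets directly under the null, optionally implanting a
candidate shared by the first `n_true_shared` individuals — the fixture for
null-calibration tests.

Genotypes are i.i.d. across variants: no linkage disequilibrium is
simulated, deliberately, because the sharing statistic works one variant at
a time and does not appeal to LD (permuting positions destroys LD anyway).
Only carriers are simulated — the sharing stage never uses controls. The
step-function heterozygosity elevation (constant `p_het_near` inside ±w) is
the minimal model; real carrier haplotypes decay with recombination
distance, so passing tests demonstrate correctness of the machinery on data
satisfying the model's assumptions, not the method's power on real cohorts,
where segment widths, penetrance, and allele frequencies all matter.

## Numerical and design choices

- **Determinism.** Every stochastic entry point takes a `seed` and calls
  `set.seed` once; permutations are drawn in a fixed individual-then-sample
  order and are never parallelised, so identical seeds give bit-identical
  null tables, and the pipeline's manifest (parameters + input/output
  checksums) makes reruns verifiable.
- **Interval conventions.** All windows and the region-of-interest overlap
  are closed intervals; touching endpoints overlap. Cross-chromosome
  candidates never match variants on another chromosome.
- **Degenerate inputs.** Chromosomes shorter than 2m+1 variants are skipped
  with a warning; an all-missing window yields undefined H; a constant H
  profile yields no peaks (a segment requires at least one strict rise and
  fall); filtering that removes every variant is an error rather than an
  empty analysis.
- **Peak plateaus.** The window average changes by at most two genotypes
  between adjacent positions, so flat stretches are common; a segment
  allows non-strict monotonicity and the peak is the first variant of the
  maximal plateau, a deterministic tie-break.
- **Pooled-null self-consistency.** On a uniform grid with fixed k per
  individual, an individual's k draws capture a given variant v with
  probability q_v = 1 − C(M−w_v, k)/C(M, k), where w_v is the number of
  variants within ±d of v, so N_f(v) is Binomial(N, q_v) under the null.
  The test suite and the acceptance script verify the pooled permutation
  estimates against the variant-averaged form of this closed expression
  (averaging over v handles chromosome ends exactly) within Monte-Carlo
  error; the closed form is an oracle only and is never used in the
  analysis path, since real variant grids are neither uniform nor
  fixed-k.
- **No additional multiple-testing correction** is applied beyond the
  permutation construction itself, and candidate H_max values are used only
  through their positions — the sizes of the peaks are not used as weights.

## Problem sizes used in validation

The packaged checks run at desk scale, chosen to keep Monte-Carlo error
well below the effects being verified: the closed-form comparison uses
M = 50,000 grid variants (50 Mb), N = 20 individuals, k = 10, d = 50 kb and
2,000 permutation samples; end-to-end recovery uses 20 replicates of 5
carriers on 20,000 variants (20 Mb) with a ±1 Mb fully heterozygous core,
in which the implanted region is recovered as a significant run in every
replicate; null calibration uses 20 individuals on 5,000 variants with
1,000 samples. The brute-force oracles (per-window recount, O(M·N·k)
sharing count, linear-scan run detection) run on hundreds of random
instances up to M = 2,000.

## Known limitations

- The heterozygosity scan targets dominant traits; there is no
  recessive-trait (homozygosity-run) mode.
- Candidate peaks on real data can be wide and overlapping; this
  implementation defines segments as strict unimodal runs and does not
  reproduce overlapping-segment behaviour, which depends on a peak
  criterion internal to other scan implementations.
- Sample-MAF filtering assumes a population-scale sample (see above).
- No gene annotation: regions of interest are supplied explicitly as
  coordinates.
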