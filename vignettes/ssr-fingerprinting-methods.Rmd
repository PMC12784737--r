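---
title: "Methods: SSR fingerprinting and duplicate detection in polyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR fingerprinting and duplicate detection in polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrclone)
```

## Scope and data model

`ssrclone` analyses SSR genotypes of polyploid samples scored in binary
presence/absence form. The central object is the `ssr_matrix`: samples ×
allele columns, columns grouped into loci, cell values 1 (band present),
0 (absent) or `NA` (missing). Two modelling commitments shape everything
downstream:

* **Missingness is locus-level.** Amplification and gel lanes fail per
  locus, not per band, so a sample is either fully scored or fully missing
  at a locus. Mixed cells are a validation error on input.
* **Dosage is unobservable.** A hexaploid sample showing the allele set
  {A, B} may be AAAAAB through ABBBBB; all statistics must work from the
  presence set alone. Validation rejects more than *ploidy* present
  alleles per sample-locus.

When two panels scored at different times are merged, allele columns are
matched within a locus by exact fragment-size label, and a sample whose
panel never scored some size receives 0 (not `NA`) there when its locus
amplified: presence/absence scoring registers every detected band, so an
unreported size is an observed absence. An optional ±1 bp binning
tolerance was considered and rejected: the reference panels this package
targets use fixed calibrated bins, and silent re-binning can merge truly
distinct alleles. Unshared loci follow an explicit `drop`/`keep` policy.

## Allele frequencies without dosage

Two estimators are provided.

**Uniform split** (`simple_freq`). A sample with *k* distinct alleles at a
locus credits *ploidy/k* copies to each. Fast, deterministic, and exact
when every genotype is unambiguous (e.g. diploid heterozygotes), but it
systematically underestimates common alleles and overestimates rare ones,
because a balanced and a nearly homozygous genotype contribute identically.

**EM under polysomic inheritance with selfing** (`em_freq`). Each observed
presence set is an incomplete observation of a latent dosage genotype. The
genotype prior is an exchangeable mixture: with probability 1 − *F* the
*m* = ploidy copies are independent draws from the frequency vector *p*
(multinomial), and with probability *F* all copies collapse to a single
draw (identical by descent). *F* = *s*/(2 − *s*) is the equilibrium
inbreeding coefficient implied by selfing rate *s*. The E-step enumerates
every composition of *m* copies over the observed alleles (each observed
allele ≥ 1 copy — at most C(5, k−1) ≤ 10 compositions for *m* = 6, so
enumeration is cheap), weights them by the prior at the current *p*, and
accumulates expected draw counts; a collapsed genotype contributes one
draw, an independent-copies genotype its copy counts. The M-step
renormalises. This is a standard EM on the complete-data likelihood, so
the observed-data log-likelihood is non-decreasing by construction — the
trajectory is stored per locus and asserted in the tests.

Choices the literature leaves open, fixed here: initialisation is the
uniform-split estimate (already close, and strictly positive on every
observed allele); convergence is L∞ change < `tol` (default 1e-8, on the
scale of frequencies); `max_iter` 500 with a `converged` flag and warning
rather than an error on exhaustion; loci are estimated independently
(the analysis assumes no linkage); samples with a locus missing are
excluded from that locus rather than imputed. The selfing rate is an
*input* (default 0.07, the value used with this marker panel in practice);
estimating it from identity disequilibrium is out of scope.

The same mixture prior drives the simulator's genotype draws, so
parameter recovery is well-posed: `em_freq` on data from
`simulate_dataset` estimates the very quantity the generator used. The
acceptance suite checks recovery within ±0.05 per allele at 500 samples,
*p* = (0.5, 0.3, 0.2), *s* = 0.07.

## Diversity and informativeness

Per locus, with *p* the frequency vector and *n* allele copies behind it:
*H* = 1 − Σpᵢ², corrected *n/(n−1)·H*; *PIC* = 1 − Σpᵢ² − Σᵢ<ⱼ2pᵢ²pⱼ²
(computed via the algebraic identity Σᵢ<ⱼ2pᵢ²pⱼ² = (Σpᵢ²)² − Σpᵢ⁴). Both
are permutation-invariant and unaffected by zero-frequency padding, and
PIC ≤ H < corrected H on any polymorphic locus — all property-tested.

The *n* used in the finite-sample correction is the total number of
observed allele presences at the locus. No published per-locus *n* is
available for the reference panel, and the printed percent-change column
there is not consistent with any single global *n*; the presence-count
definition reproduces the printed changes for the high-diversity loci.
The residual mismatch on low-allele-count loci is a known open point, so
percent-change values are reported but never asserted against published
numbers. Aggregate rows are unweighted arithmetic means over loci; the
correlation analysis pairs the per-locus overall mean allele number with
corrected *H* and with EM-frequency PIC, which reproduces both published
correlation coefficients (0.902, 0.816) from the fixture columns.

## Discriminating power and panel selection

A locus's banding patterns are its distinct presence/absence vectors over
scored samples. The confusion probability
*C* = Σ pᵢ(N pᵢ − 1)/(N − 1) equals exactly the fraction of unordered
sample pairs sharing a pattern (Σ cᵢ(cᵢ−1)/(N(N−1)), the form computed
here to avoid cancellation); *D* = 1 − *C*; the large-N limit is
*DL* = 1 − Σpᵢ², linked by *D = N·DL/(N−1)* to machine precision. The
formula-vs-enumeration equality is property-tested on 1000 random
profiles.

For multi-locus panels the pattern is the tuple of per-locus patterns. A
missing locus contributes a distinct sentinel symbol instead of dropping
the sample: N stays constant across locus subsets, keeping cumulative D
values comparable along the curve (the alternative — per-subset sample
exclusion — makes steps incommensurable; the original workflow's policy
is not documented). Greedy selection starts from the best single locus
and at each step adds the remaining locus maximising combined D, with
ties broken by input order for determinism; the distinct-pattern count is
non-decreasing by refinement, and the plateau index is the first step
reaching the curve's final pattern count. The greedy choice is verified
against exhaustive enumeration on a 3-locus toy. The published 11-locus
plateau at D = 0.951 depends on the unpublished 65-sample matrix and is
therefore not a reproducible target; the machinery is validated by oracle
instead.

## Clustering and duplicate detection

Jaccard dissimilarity treats allele columns as independent dominant
markers: per pair, columns are restricted to loci scored in both samples,
*d* = 1 − a/(a + b + c). Pairs with no co-scored locus have no defined
distance; they are excluded from duplicate flagging and reported
separately. On missing-free data this matches `vegan`'s binary Jaccard
(cross-checked in the tests) and is a metric (triangle inequality
property-tested).

Trees are unweighted neighbor-joining (via `ape::nj`), which reproduces
the 3-taxon closed form and recovers additive matrices exactly — both
asserted. Negative branch lengths are retained by default (`clamp_negative`
truncates for display). Bootstrap resamples *loci* with replacement —
allele columns travel with their locus, preserving within-locus dependence;
resampling individual columns would treat alleles of one locus as
independent, which they are not. Support is the percentage of replicates
containing each internal bipartition of the reference tree. In a
replicate, a pair left with no co-scored locus is imputed with the mean
defined distance so NJ stays defined; at realistic missing rates (2%)
this is rare. Newick export quotes labels containing metacharacters;
parsing relies on `ape`, which handles quoted labels with spaces but not
embedded quote characters — a documented limitation.

Duplicate flagging uses a *strict* threshold (*d* < 0.05, the operational
cut-off for clonal duplicates in genebank practice — "less than", so a
pair at exactly 0.05 is not flagged), and groups are connected components
of the flagged-pair graph (single linkage). Flagged pairs can be verified
locus by locus (`verify_profiles`). `threshold_roc` sweeps the flagging
threshold over observed distances against known clone labels; AUC is the
Mann–Whitney pair-ranking probability with ties at 1/2, cross-checked
against `pROC`.

## What the simulator emulates — and what it does not

`simulate_dataset` draws per-locus frequency vectors from a symmetric
Dirichlet, founder genotypes from the partial-selfing mixture above,
collapses dosage to presence sets (clones of one founder share the
identical pre-error phenotype, as vegetative propagation implies), and
corrupts the result with three independent error processes.

Defaults mirror the curated sweetpotato panel the package is designed
around: 19 loci; 3–12 alleles per locus (published range; mean 8.2);
Dirichlet concentration 1, which at k = 8 alleles gives expected gene
diversity 1 − 2/(k+1) ≈ 0.78, matching the observed ≈ 0.80 and
a realistic mean of ≈ 3 bands per individual; ploidy 6; 20 founders with
2–4 clones each (genebank duplicate groups are small); selfing rate 0.07.
The error rates are simulation choices, not published values (none were
reported for the reference panel): allele dropout 0.01 per present band,
false allele 0.005 per absent band, whole-locus failure 0.02 — the order
of magnitude fingerprinting labs typically quote. Two guard rules keep
generated data valid: a scored sample-locus emptied by dropout gets one
original band re-instated (a bandless lane would have been scored as
failed), and false alleles never push a genotype past ploidy presences.

Not emulated: stutter and size-shift artifacts, linkage between loci,
population structure among founders, and generational selfing dynamics
(the equilibrium mixture stands in for the full machinery). Passing tests
therefore demonstrate correctness of the estimators and detection logic
under the stated model, not robustness to systematic scoring artifacts in
real gels.

All randomness flows from a single integer seed; per-locus frequency
draws are keyed on (seed, locus index) so they are reproducible in
isolation, and `simulate_dataset` is byte-reproducible.

## A note on the duplicate-detection operating point

At the package's default noise rates, two clones of one founder differ in
expectation by about 2 bands (2 × (0.01 × ~60 presences + 0.005 × ~80
absences)) over a ~60-band union, so their expected Jaccard distance is
≈ 0.035 — close to the 0.05 threshold. The strict cut-off therefore
misses a noticeable minority of true clone pairs at 19 loci (connected
components recover some of them transitively), while precision stays at 1
because unrelated founders sit at d ≈ 0.5–0.8. This is a property of the
threshold-and-noise operating point itself, visible in the acceptance
suite's synthetic clone benchmark, not an implementation artifact: recall
at d < 0.05 rises with more loci or lower dropout, and the ROC (AUC ≈ 1)
shows the two distance populations are in fact almost perfectly
separable.

## Problem sizes used by the test suite

Simulated checks run at deliberately modest sizes chosen to make the
statistical assertions sharp but cheap: frequency-recovery at 400–500
samples on one locus; oracle sweeps at 200–1000 random profiles or
triples; bootstrap tests at 25–200 replicates on 15–70 samples; pipeline
round-trips on 8–20 founders. The full pipeline on a 65 × 156 panel with
1000 bootstrap replicates runs in well under a minute.
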