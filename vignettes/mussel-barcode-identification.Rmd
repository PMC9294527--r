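---
title: "Barcode species identification and method agreement in smooth-shelled mussels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode species identification and method agreement in smooth-shelled mussels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselid)
```

## The setting

*Mytilus chilensis* and *M. galloprovincialis* are so closely related that
a ~400 bp nuclear barcode (here modelled on the histone *H1C* fragment)
separates them at only a handful of alignment columns. Where both species
are farmed they hybridize, and an F1 hybrid carries one allele from each
parent: its Sanger chromatogram shows a double peak at every site that is
fixed for different bases in the two species, which base-callers encode as
an IUPAC ambiguity code (`Y` for C/T, `R` for A/G, `M` for A/C).

This combination — tiny interspecific divergence, hybrids sitting between
the species — is close to a worst case for every standard barcode
identification method, and different commercial methods can return
different answers for the same animal. The package implements the five
standard sequence-analysis methods, the hybrid-detection step, and
chance-corrected agreement statistics between methods, so the whole
comparison can be run, audited and re-run on new data.

## Distances and site policies

All methods start from pairwise comparisons of aligned sequences, and
the single most consequential modelling choice is what to do with IUPAC
ambiguity codes, because hybrids are made of them. `site_policy()` makes
the choice explicit and records it in every matrix:

* `intersect` — a site matches when the two base sets overlap. A hybrid's
  `Y` matches both a parental `C` and a parental `T`. This is the right
  view for percent-similarity questions ("how close is this animal to
  each species?"), and it is the default for the `similarity` model:
  under it hybrids are >98% similar to *both* parental species, which is
  exactly what the chromatograms say.
* `mismatch` — strict character comparison; a `Y` against a `C` counts as
  a difference. This is how classical barcoding tools count, it is the
  default for the model-corrected distances, and it is what makes the
  best-close-match threshold informative: with hybrids present, the
  pooled "intraspecific" distance list acquires a heavy tail of
  hybrid-versus-pure pairs at ~5/397 ≈ 1.3%, and the 95th percentile
  lands there; after hybrid exclusion it collapses to ~0.25%. Fractional
  mismatch counts are apportioned between transitions and transversions
  by enumerating the differing resolutions of the two base sets.
* `exclude` — ambiguity codes are treated as missing data and the column
  is dropped from the pair, which is what barcode-gap tools conventionally
  do. Under this policy a hybrid is at distance ≈ 0 from *both* species —
  the mechanism behind the single-cluster behaviour described below.
* `fractional` — the probability that random resolutions differ; offered
  for sensitivity analyses.

Gaps are removed pairwise by default (`complete` deletion is available for
reproducibility studies). Distances come as p (with transition/transversion
split), JC69, K2P and TN93; the TN93 closed form estimates base
frequencies per pair by default (the whole-alignment option exists),
since composition can drift between taxa. Saturated pairs (a log argument
≤ 0) are flagged, not fatal.

## The five identification methods

**DSC** (direct sequence comparison) aggregates the query's similarities
to each species' references (`all` = every reference must clear the
threshold, the default; `mean` and `max` are options) and assigns the
best-scoring species above the threshold (98% by default). We deliberately
depart from a strictly exclusive rule ("any second species above the
threshold means ambiguous"): with markers this conserved, heterospecific
similarities routinely exceed 98%, so an exclusive rule would call
*everything* ambiguous and the method would carry no information — whereas
assignment in practice goes to the most similar species, with ambiguity
reserved for ties. The exclusive rule is retained as `rule = "exclusive"`.
Queries already flagged by the diagnostic-site analysis bypass the
comparison and are reported as putative hybrids.

**BCM** (best close match) assigns the species of the closest
reference(s), provided the closest distance lies within the threshold —
the 95th percentile, with linear interpolation, of all intraspecific
pairwise distances in the reference set. Ties across species are
ambiguous; a best match beyond the threshold is a no-match.

**AB** (all barcodes) additionally requires every conspecific reference
to outrank every heterospecific one (ties count as interleaving), at
least two conspecific references, and the best match within the
threshold. The threshold applies to the best match, not to every
conspecific pair: a method whose own threshold is by construction
exceeded by 5% of intraspecific pairs could otherwise never return a
clean identification. Hybrids in the reference panel interleave every
ranked list, which is why this method collapses to all-ambiguous when
they are present.

**ABGD** (simplified) sorts all pairwise distances, finds the first step
above the prior intraspecific divergence `P` that is wider than `X`
times the mean step among the smaller distances (`X = 1.5`), clusters by
single linkage below that gap, and recurses. Two properties matter in
practice. First, at small priors the candidate steps include the discrete
1-substitution increments inside species, and the partition shatters into
haplotype clusters — real barcode-gap sweeps show exactly this, which is
why calls default to the conventional prior `P = 0.01` while
`abgd_sweep()` exposes the whole grid (0.001–0.1). Second, the detected
gap only partitions if single linkage actually separates groups below the
cut-off: hybrids at distance ≈ 0 from both species (ambiguity-excluded
policy) chain the two species into one cluster, so with hybrids present
the method returns a single group even though the sorted distance list
has a numeric gap — precisely the "no gap with hybrids, clean gap without
them" behaviour that motivates the dataset split. Group-to-species calls
use the majority label of each group; a single group means every call is
ambiguous.

**FINS** builds a neighbour-joining tree (TN93 distances by default) with
bootstrap supports, and assigns the species of the smallest clade that
contains the query and at least one labelled reference — only if the
clade is single-species and its support reaches `min_support` (70% by
default; tree-based identification conventionally requires at least
that). NJ is implemented with deterministic lexicographic tie-breaking so
results are invariant to record order, and negative branch-length
estimates are clamped to zero with the deficit moved to the sibling
branch, preserving the joined pair's distance. Bootstrap supports come
from column resampling under a fixed seed; the default 100 replicates
keep a 61-sequence run interactive, and the replicate count is a
parameter for publication-grade runs.

## Agreement statistics

Two methods' calls over the same individuals are cross-tabulated over the
union of their categories, so a category only one method can emit (the
hybrid category, or AB's no-match) enters as an ordinary category with a
zero marginal for the other method — this is required for the κ values to
mean what they appear to mean. Cohen's κ uses the large-sample standard
error `sqrt(po(1−po)/(n(1−pe)²))` for its 95% interval and the Fleiss
null-SE one-sided normal test for its p-value (when both methods are
constant the null SE is zero; κ = 0 is then reported with p = 0.5, and
two constant *identical* raters give an undefined κ). p-values across the
pairwise matrix are Benjamini–Hochberg corrected. The multiclass Matthews
correlation is Gorodkin's R_K, which reduces to the familiar binary MCC
on 2×2 tables. Verbal interpretation uses the Landis–Koch bands, with
"perfect" reserved for κ = 1 exactly.

## What the synthetic data emulate — and what they do not

`simulate_dataset()` draws a random ancestral sequence, derives two
species consensuses separated at exactly `n_diagnostic_sites` fixed sites
plus additional fixed differences (Poisson, so that the *total* consensus
divergence has expectation `interspecific_divergence` substitutions per
site), gives each species a small pool of segregating sites at
minor-allele frequency `minor_allele_freq`, and samples individuals from
those pools. F1 hybrids carry the combined IUPAC code at every
consensus-difference site and a parental consensus elsewhere (which
parent alternates by default and is configurable).

Intraspecific variation is modelled as *shared* segregating sites rather
than independent private mutations per individual, with the pool sized so
the expected pairwise intraspecific p-distance equals
`intraspecific_theta`. This is a deliberate choice: population samples
share their polymorphism, which bounds the maximum intraspecific pairwise
distance at the pool size. Independent per-individual Poisson mutations
of the same expected diversity produce an unbounded right tail that
erases the barcode gap in a noticeable fraction of runs — a property of
that noise model, not of the biology the generator is meant to emulate,
where the 95th-percentile intraspecific distance (~0.25%) sits far below
the minimum interspecific distance (~1.26%).

`simulate_paperlike()` is the fixed-seed reference dataset used
throughout the tests: 61 individuals (7 + 42 pure, 12 all-site
heterozygous F1s labelled 2/10 by an independent "HRM" scheme, hence 9/52
scheme counts), consensus divergence of exactly the five diagnostic sites
(5/397 ≈ 1.26%), `theta = 0.001`, `maf = 0.1`. These rates were
calibrated once against the regime sketched above — interspecific
similarities in the high 97s–98s, intraspecific 95th percentile of a few
tenths of a percent — and give interspecific similarity 98.2–98.7% and
intraspecific thresholds of 1.27%/0.25% (with/without hybrids) on the
default seed.

Known gaps between simulation and real data: real hybrids are not all
perfect F1s (field chromatograms show individuals heterozygous at only a
subset of the diagnostic sites — the `min_het_sites = 1` default flags
those too, at the cost of treating rare shared polymorphism as evidence
of hybridity); real reference panels contain mislabelled database
records and additional congeneric species; and there are no indels, so
gap handling is exercised only by constructed tests. Passing the
simulation-based tests therefore demonstrates the machinery and the
qualitative failure modes, not field-accuracy of any method.

## Numerical conventions

* Percentile with linear interpolation (R's default type 7) for the BCM
  threshold; thresholds are inclusive (`distance ≤ threshold` passes).
* Distance ties use a 1e-12 absolute tolerance; NJ ties break towards the
  lexicographically smallest id pair; DSC score ties of qualifying
  species are ambiguous.
* Alignment columns are reported 1-based.
* `U` and lower case are normalised on input; any character outside the
  IUPAC + gap alphabet is a hard error naming the record and column,
  never silently treated as `N`.
* All randomness (simulation, bootstrap) flows from explicit integer
  seeds; identical seed and input give byte-identical outputs.

## Problem sizes used in the test suite

The shipped tests run the full 61-sequence pipeline without FINS (seconds),
exercise NJ recovery exhaustively on random additive trees of 4–6 taxa,
and use 60–100 bootstrap replicates on 8–16 sequence alignments; the
simulation checks average over a handful of seeds. These sizes were chosen
so the whole suite stays interactive while still covering every method on
datasets with the study's structure.

## Limitations

A single nuclear marker cannot separate F1 hybrids from backcrosses or
later generations — `het_sites` is reported but deliberately not
interpreted beyond "putative hybrid". The simplified ABGD reproduces the
recursive gap/no-gap logic, not the original's coalescent-calibrated
prior inference, and its partition can depend on the prior in the way the
sweep makes visible. FINS inherits every known weakness of tree-based
identification when divergence is this shallow; it is included because
the comparison is the point.
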