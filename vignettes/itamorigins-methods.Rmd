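---
title: "Methods: from degenerate ITAM screening to clock-dated signaling"
author: "itamorigins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from degenerate ITAM screening to clock-dated signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itamorigins)
```

## The scientific setting

Immune receptors signal through immunoreceptor tyrosine-based activation
motifs (ITAMs): two Y-x-x-(L/I) half-sites whose phosphorylated tyrosines
recruit the kinases Syk or ZAP70. Phagocytes, however, also engulf bare
solid particles for which no receptor can exist. A candidate explanation is
an ITAM-like sequence carried not by a receptor but by a membrane-anchored
cytoskeletal linker: particle contact concentrates the inner-leaflet lipid
PIP2, PIP2 recruits and opens the ERM-family protein Moesin, and the
two-tyrosine motif inside its FERM domain (Y191/Y205, a 10-residue spacer)
recruits Syk.

This package implements the computational side of that investigation as a
reproducible pipeline: a degenerate-motif proteome screen with
expression-based shortlisting, distance-based molecular-clock phylogenetics
that dates the duplication of the Syk/ZAP70 paralog pair, the fluorescence
quantification operators used for contact-site enrichment, and the
contact-mechanics and nonparametric statistics tying target stiffness to
uptake. Every stage is driven by synthetic data with known ground truth, so
the whole chain is testable offline.

## Motif screen

### The probe and its matching rules

The screen uses the deliberately loose probe

```
Y - x - x - (L/I) - x(6..12) - Y - x - x - (L/I)
```

`scan_sequence()` reports **every** `(start, spacer)` combination,
including overlapping and nested matches. The choice to report all matches
is deliberate: the probe is degenerate, and any dedup at match level would
be arbitrary. "Independent hits" are instead defined at protein level by
`scan_proteome()`, which collapses a protein's matches to one row with a
hit count. Coordinates are 1-based and inclusive, matching standard residue
numbering (a Moesin-like arrangement scans as `start = 191`, `spacer = 10`,
`end = 208`).

Unknown symbols (`X`, `B`, `Z`, `*`) can never satisfy an anchor or tail
position, but are allowed in the unconstrained positions — the conservative
reading for low-quality sequence.

Under a uniform residue model the per-start match probability is
`7 * (1/20) * (2/20) * (1/20) * (2/20)` (seven admissible spacers), about
`1.75e-4`; the test suite confirms the decoy hit rate over more than a
million random positions within three binomial standard errors, and checks
the scanner against a brute-force enumeration of every `(start, spacer)`
pair.

### Ranking and exclusion

Expression datasets differ in units (counts, FPKM, TPM), so
`rank_candidates()` works entirely in within-dataset percentile ranks,
which are invariant to any monotone rescaling of a single dataset. The
aggregate score is the mean percentile rank across datasets; a gene missing
from a dataset contributes rank 0 rather than being dropped, which is
conservative (absence of evidence of expression ranks below any observed
expression). Ties in the aggregate are broken lexicographically so output
order is deterministic. The default shortlisting depth is 25 candidates.

Exclusion criteria (secreted, nuclear-only, sterically inaccessible motif,
already-known ITAM receptor, ...) are prose judgments, so
`apply_exclusions()` treats them as *data*: a boolean annotation table
whose columns are rule names, with precedence given by column order or an
explicit `rules` argument. Each excluded row carries exactly one primary
reason — the highest-precedence failing rule. An editable example table
ships in `inst/extdata/example_exclusion_annotations.tsv`.

## Clock phylogenetics

### Distances and trees

Branch lengths come from pairwise amino-acid distances
(`aa_distance_matrix()`): p-distance with pairwise deletion of gap/unknown
columns, optionally corrected by the Poisson formula `-ln(1 - p)` or the
gamma formula `alpha * ((1 - p)^(-1/alpha) - 1)` (default `alpha = 1`,
user-settable; empirical-matrix likelihood models are out of scope — the
quantities of interest here, rates and ages, are functions of branch
lengths, which the distance surrogate estimates). Pairwise deletion is used
because ortholog sets differ in coverage; a column is dropped only for the
pair it is unusable in.

Trees are built by neighbor joining. NJ on noisy distances can propose
slightly negative branch lengths; these are clamped to zero with a warning,
since a negative substitutions-per-site length is meaningless downstream.
On additive metrics NJ recovers the generating tree exactly, which the
suite verifies over random 6–10-tip trees.

Bootstrap supports (`bootstrap_support()`, default 100 replicates) resample
alignment columns with replacement under a fixed seed; the support of each
internal bipartition of the point tree is the percentage of replicate trees
containing it. A replicate that saturates (p-distance of 1 under a
corrected model) is skipped and logged; more than 20% skips aborts the run,
at which point the p-distance model is the appropriate fallback.

### Calibration and dating

`root_by_outgroup()` places the root at the midpoint of the branch
separating the outgroup from the rest, preserving patristic distances.
Species divergence times (TimeTree-style `taxonA, taxonB, time_mya` rows)
then calibrate the tree in `fit_clock()`:

* clade rate `r` = mean over calibrated in-clade tip pairs of
  `patristic(i, j) / (2 * t_ij)` — the factor 2 because both lineages
  accumulate substitutions for `t_ij` million years;
* clade root age = mean root-to-tip patristic distance of the clade's tips
  divided by `r`.

For a paralog pair such as ZAP70/Syk the two clades date the *same*
duplication node independently; `fit_clock()` therefore reports the
per-clade estimates and their `[min, max]` interval, never an average —
disagreement between clades is information about rate heterogeneity, not
noise to smooth away. Using all calibrated in-clade pairs (rather than a
root-to-tip regression) was an open choice; the pairwise mean uses every
calibration and has a closed-form expectation under the clock, which makes
the estimator directly testable.

`rate_profile()` is the machine-readable form of a calibrated
distance-versus-time plot for one focal taxon: points `(t_i, d_i)` sorted
by divergence time with per-segment slopes. Because `d_i` spans both
diverging lineages, a strict clock with per-lineage rate `r` gives constant
slopes of `2r`. When several taxa share a calibration time, each tied
point's slope is computed against the last strictly earlier point. By
default distances are read off the tree (patristic); passing the alignment
switches to direct corrected pairwise distances, which is how such plots
are usually drawn, and both options are exposed because the choice is not
neutral on non-clocklike trees.

### What the simulator shows — and what it cannot

`evolve_alignment()` uses the 20-state symmetric (Poisson) substitution
process, chosen because it admits a closed-form expected p-distance,
`E[p] = (19/20)(1 - exp(-(20/19) * 2 r t))`, against which the simulator
itself is validated. The dating recovery study (two four-tip clades, root
800 Mya, rate `5e-4` substitutions/site/Mya, 2000 sites, 20 seeds — sizes
chosen so the whole study runs in seconds) shows interval midpoints within
±15% of truth in at least 90% of seeds.

Real protein evolution is not symmetric-Poisson: amino-acid exchangeabilities
are highly structured, site rates are correlated, and published divergence
dates additionally depend on which orthologs a database search returns and
which calibration studies one adopts. Passing recoveries therefore certify
the *estimator chain* (distances → NJ → rooting → calibration → dating),
not any particular published date; reproducing literature dates would
require the original retrieval, which is deliberately out of scope.

## Imaging quantification

All operators take plain numeric arrays (`H x W x T`, row = y, 0-based
pixel coordinates with x to the right and y down, matching image-viewer
conventions). Line sampling (`line_profile()`) uses unit-pixel spacing with
bilinear interpolation and averages across a perpendicular band of `width`
pixels; `kymograph()` is by construction row-for-row identical to per-frame
line profiles, and the suite asserts that compositionality.

`normalized_fluorescence()` implements the contact-site enrichment readout:
per frame, mean intensity over an explicit contact mask divided by the mean
over a non-contact membrane (reference) mask, with optional background
subtraction of a third mask's mean from both. Masks are explicit inputs
because how the original measurements delimited "non-contact membrane" is
not recorded; any reasonable choice can be expressed as a mask. A frame
whose denominator falls below `1e-6` times the global mean intensity
reports `NA` rather than an unstable spike. `pattern_fold_change()` is the
single-image analogue for vesicles settling on fabricated micropatterns
(pattern-contacting over non-contacting mean, the assay in which PIP2 shows
about 3-fold enrichment), and `gp_ratio()` computes the generalized
polarization index `(I_o - I_d)/(I_o + I_d)`, with the channel identities
left to configuration since band choices vary between setups.

The stack generator (`gen_cell_stack()`) builds a membrane ring with a
contact arc whose intensity is `fold × base` from the onset frame onward,
optionally blurred with a small separable Gaussian kernel and Poisson
sampled. With blur disabled the expected normalized fluorescence plateau is
*exactly* the planted fold, giving sharp tests; with blur the contact and
reference regions mix at their boundary, which is realistic but makes the
plateau an underestimate — tests therefore plant the sharp geometry and
treat blur as an option. Synthetic stacks have uniform rings and
stationary contacts; they do not emulate cell motion, photobleaching, or
uneven illumination, so passing tests certify the operators, not
robustness to those artifacts.

TIFF I/O uses the 16-bit unsigned multi-page convention standard in
microscopy: integer photon counts in `[0, 65535]` round-trip
voxel-identically, and non-integer data is rejected rather than silently
quantized.

## Mechanics and statistics

### Hertz fitting

`hertz_force()` is the spherical-indenter Hertz relation
`F = (4/3) (E/(1-nu^2)) sqrt(R) delta^(3/2)`; `fit_hertz()` estimates `E`
and the contact-point offset `delta0` by Levenberg–Marquardt least squares
on `F = (4/3)(E/(1-nu^2)) sqrt(R) max(delta - delta0, 0)^(3/2)`. The
contact point is fitted jointly by default because instrument zeroing is
rarely exact, and can be pinned via `fix_delta0`. Internally the fit runs
in nanometre/nanonewton/GPa units so both parameters are order one — in SI
units the Jacobian columns differ by ~18 orders of magnitude and the
normal equations are numerically singular. I/O stays at the instrument's
nm/nN convention with a logged conversion. Defaults mirror stiff-bead
nanoindentation: Poisson ratio 0.33 (bulk polystyrene), micron-scale probe,
indentation depths of a few nanometres.

### Exact Spearman test

`spearman_exact()` computes the rank correlation and, for `n <= 9` untied
data, enumerates all `n!` permutations of the y-ranks: the one-sided p is
the fraction of permutations with statistic at least the observed one.
Five perfectly concordant pairs give `r = 1` and one-sided
`p = 1/120 ≈ 0.0083` — exactly the value printed for the
stiffness–phagocytosis correlation, which is why the one-sided exact p is
treated as primary (the printed value identifies it); the two-sided value
is always reported alongside. Beyond `n = 9` (or with ties) the test falls
back to the large-sample t approximation with an explicit notice; ties
with exact requested are an error rather than a silent midrank
approximation. The suite checks the implementation against an independent
brute-force enumeration, against `cor.test()`'s exact distribution, and
for the defining calibration property of an exact test,
`P(p <= u) = u` at every achievable level.

`internalized_geometry()` and `phagocytosis_efficiency()` are the
bookkeeping ends of the uptake assays: sphere volume/surface totals, and
both candidate definitions of "efficiency" (fraction of cells with at
least one internalized bead, and mean beads per cell) since the operational
definition varies between assays — reporting both avoids committing to one
silently.

## Pipeline and reproducibility

`run_pipeline()` executes stages in dependency order from a YAML or list
configuration, rejecting unknown keys before anything runs. A single
global seed is expanded into per-stage streams by a counter-based scheme
(stage index times a fixed prime, modulo `2^31`), so adding or removing a
stage never perturbs another stage's randomness. Every run writes a
resolved-config copy, a seed record, and a manifest of MD5 content hashes;
identical configuration and seed give identical data-artifact hashes. All
generators are pure functions of `(parameters, seed)` — repeated calls are
byte-identical — and each returns a truth record sufficient to recompute
its expected downstream outputs.

A thin command-line wrapper ships in `inst/cli/itamorigins`; the package
functions remain the primary interface.

## Numerical choices and known limitations

* Corrected distances are undefined at `p = 1`; saturation is an explicit
  error (or a skipped, logged bootstrap replicate), never a clamp.
* The gamma correction converges to the Poisson correction as
  `alpha -> infinity` with residual `ln^2(1-p)/(2 alpha)`; the property is
  tested at moderate divergence where the residual is far below the
  tolerance, because at near-saturated distances the residual itself is
  the dominant term.
* NJ tie-breaking follows the lowest-index pair, so tree topology is
  deterministic for a given input ordering; bootstrap supports are tested
  to be invariant to taxon order under a fixed seed.
* The NF denominator floor (`1e-6` of global mean intensity) and the GP
  total-intensity floor trade a small amount of coverage for stability;
  affected pixels/frames are `NA`, visible to the caller.
* Exact permutation enumeration is capped at `n = 9` (`9! = 362880`
  statistics); beyond that the t approximation is used and announced.
* The screen's candidate counts (25 top expressers, 18 exclusions, 7
  shortlisted) are properties of a given proteome, expression panel and
  annotation table; the package reproduces the *funnel logic* on synthetic
  inputs of the same shape, not the specific gene list, which depends on
  proteome version and database retrieval.
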