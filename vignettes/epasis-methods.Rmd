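---
title: "Sub-complex deconvolution from SDS-destabilization elution profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-complex deconvolution from SDS-destabilization elution profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epasis)
```

## The experimental model

A bait protein and its native complex are immobilised on an affinity resin
and exposed to a short series of increasing SDS concentrations — 0.001%,
0.005%, 0.01% and 0.02% w/v — with a final FLAG-peptide elution releasing
whatever remains bound. Sub-complexes dissociate as units: all subunits of a
sub-module leave the resin at the same destabilization step, whereas the
larger assembly falls apart progressively. Each fraction is quantified by
label-free LC-MS/MS, so each protein acquires an intensity trace over the
five ordered steps, replicated across (by default) seven biological
replicates.

Two modelling commitments follow from this design:

* **The elution axis is ordinal.** The SDS concentrations are treated as
  ordered categories (step index 0–4), not as a numeric dose axis: the
  response to SDS is strongly nonlinear and the final FLAG step is not an
  SDS concentration at all.
* **Profiles are per-replicate normalized.** A replicate's trace is
  converted to *cumulative relative abundance* — the running fraction of
  that replicate's total recovered intensity — before averaging across
  replicates. Averaging raw intensities instead would let high-yield
  replicates dominate the profile shape; after normalization every
  replicate carries equal weight, and profiles are invariant to
  per-replicate rescaling (a tested property).

A replicate in which a protein has zero total intensity carries no shape
information; it is flagged as undefined and excluded from the mean rather
than entering as a row of zeros. Missing cells inside an otherwise
quantified replicate are counted as zero intensity, which is the natural
reading for label-free data where absence of signal is absence of evidence
of elution at that step.

## Presence filtering

Proteins must be detected (at least one positive intensity) in at least a
fraction `min_fraction` of replicates; the default is 4/7, applied as
`ceiling(min_fraction * n_replicates)` so that with seven replicates
exactly four are required. The filter is idempotent and retains the input
protein order.

## EPD and consensus profiles

Each curated sub-complex (for the dynein/dynactin system: the dynactin
module `DCTN` and the cytoplasmic dynein 1 module `DYN`) gets a consensus
profile, the unweighted mean of its members' averaged profiles. The
unweighted mean matches how group-average elution curves are usually
displayed and makes no assumption about member stoichiometry. Members that
fell to the presence filter are reported by a warning, never silently
dropped.

The elution profile distance is the plain Euclidean (L2) distance between
cumulative profile vectors. Because the published EPD scale for this assay
cannot be pinned down without the underlying raw data, a normalized dialect
(L2 divided by `sqrt(n_steps)`, making values comparable across designs
with different step counts) is available behind `normalized = TRUE`;
everything downstream is dialect-agnostic. Likewise, whether a curated
member should contribute to its own consensus when scored against it is not
decidable from first principles; the default includes it (simplest, and
stable for modules of realistic size), with `leave_one_out = TRUE`
available. Under leave-one-out a single-member module is an error, not a
silent fallback.

Per protein, the nearest module is the EPD argmin with ties broken toward
the lexicographically smallest module name, and all outputs are ordered by
accession — both choices exist purely so that runs are deterministic.

## Threshold calibration

The assignment cutoff is calibrated by a stepwise search over `n_steps`
(default 1000) equally spaced thresholds between 0 and the largest
calibration EPD. Positives are curated members scored against their own
module; negatives are curated members scored against the *other* modules.
Unlabelled proteins are deliberately excluded from calibration: their
membership is the unknown the threshold will be used to infer, so letting
them into the sensitivity/specificity counts would be circular.

Sensitivity (fraction of positives at or below the threshold) is
non-decreasing and specificity (fraction of negatives above it)
non-increasing along the grid — tested invariants. The operating point
maximizes Youden's J = sensitivity + specificity − 1, the standard
threshold choice when neither error direction is privileged; ties are
resolved toward the smaller threshold, which keeps candidate lists
conservative (on perfectly separated data the selected threshold sits at
the near edge of the separating interval, just above the largest member
EPD).

At the threshold, category semantics follow the curated labels: a curated
member below threshold on its own module is a *reference* protein and keeps
the bare module label even if the data place it nearer another module (the
`nearest_module` column keeps the data-driven reading visible — relevant
for real cases where a curated subunit elutes with a different module); a
non-member below threshold becomes `<module>_cand` of its nearest module;
everything else is `unknown`. Raising the threshold never unassigns a
protein (tested monotonicity).

## Ordination and replicate QC

NMDS (global nonmetric model, Kruskal stress-1 with primary tie handling,
via `vegan::monoMDS`) summarizes the pairwise profile distance matrix in
two dimensions. NMDS is non-convex, so the fit takes the best of
`n_restarts = 8` starts: one metric principal-coordinate start plus seven
random configurations drawn from a user seed, making results exactly
reproducible for a fixed `(seed, n_restarts)`. Stress is non-increasing in
the embedding dimension and invariant under relabeling (tested); distances
generated from an exact 2-D configuration embed with stress below 1e-3.

Replicate reproducibility uses per-protein intensities summed across the
five fractions within each replicate (one point per protein per replicate
pair), log2-transformed; zero totals are excluded pairwise since log2 is
undefined there. Each pair gets Pearson's r with a Fisher-z 95% confidence
interval and an orthogonal (total-least-squares) regression — appropriate
because both replicates carry comparable measurement error, and symmetric:
regressing (x, y) and (y, x) gives reciprocal slopes. Pairs sharing fewer
than three quantified proteins are reported as undefined rather than
producing meaningless coefficients. Step-level reproducibility is the
Spearman matrix of per-step log2 intensities (summed across replicates),
rank-based because step totals differ by orders of magnitude.

## Evidence filters and significance A

Two standard AP-MS evidence rules are provided for the surrounding
interactome work: the pull-down replicate/control rule (retain proteins
detected in ≥ 3 of 4 bait runs and in 0 control runs, both configurable —
the control rule is read strictly, any control detection removes the
protein) and the two-unique-peptide rule applied per run.

Significance A flags outliers in a SILAC log2-ratio distribution. The
spread on each side of the median is estimated from the 15.87th and 84.13th
percentiles — the points one standard deviation from the mean under
normality — giving a robust, asymmetry-tolerant z-score; the p-value is the
outward normal tail `0.5 * erfc(z / sqrt(2))`. This one-sided form (the
default) lives on (0, 0.5]: the value 0.5 marks the median and small values
mark either tail. For null calibration checks the `tail = "two.sided"`
option doubles the tail probability, which is the form that is uniformly
distributed on (0, 1) under a null ratio distribution (tested by
Kolmogorov–Smirnov at n = 10,000). No multiple-testing correction is
applied by default; `adjust = TRUE` adds Benjamini–Hochberg. At least five
finite ratios are required, and a degenerate spread (percentile equal to
the median) is an error rather than an infinite z.

## The synthetic generator

`simulate_experiment()` emulates the study design so the whole chain is
testable without any deposited data: by default 7 replicates × 5 steps,
two true modules of 10 members and 20 background proteins. Module release
curves are logistic CDFs over the ordinal step axis — the simplest monotone
family that reproduces the qualitative signatures of an early-eluting
module (dynein-like, midpoint 1.0, i.e. released across the low-SDS steps)
versus a later, more stably bound one (dynactin-like, midpoint 2.0);
`sharpness` (default 6) controls how step-like the release is, with the
all-in-one-step and uniform limits recovered at the extremes. Background
proteins draw individual symmetric Dirichlet(1) step fractions — maximally
uninformative elution. Per-protein totals are log-normal (meanlog 16,
sdlog 1, i.e. a median total near 10^7 arbitrary LFQ units, a realistic
magnitude for label-free protein intensities); each cell is multiplied by
`exp(N(0, sigma^2))` noise (default sigma 0.2, roughly ±20% cell-level
variation); dropout removes a protein from a whole replicate with
probability 0.1.

All randomness flows from one seed through a per-protein stream split
(`seed + 104729 * protein_index`, reduced mod 2^31 − 1), so extending the
configuration with more proteins never changes the draws of existing ones,
and a fixed config reproduces its output bit for bit.

What the generator does *not* emulate: peptide-level sampling and protein
inference, intensity-dependent (left-censored) missingness — dropout here
is whole-replicate and intensity-independent — correlated noise between
co-eluting proteins, contaminants, and partial co-membership of proteins in
several sub-modules. Passing tests on synthetic data therefore demonstrate
correctness of the algorithms under the stated statistical model, not
robustness to every pathology of real AP-MS data.

## Numerical choices and degenerate inputs

* Profiles end at exactly 1 up to floating-point rounding; tests use a
  1e-9 terminal tolerance and treat EPDs below ~1e-12 as the exact-zero
  noise-free limit.
* The threshold grid includes 0; with noise-free members (EPD ≈ 1e-16) the
  first grid point gives J = 0, so selection lands on the second point —
  effectively zero but numerically safe.
* Zero-total replicates, empty member lists, calibration without positives
  or negatives, all-zero distance matrices, fewer points than embedding
  dimensions, and degenerate ratio spreads are all explicit errors, not
  silent results.
* The pipeline writes a provenance JSON (config, seed, package version,
  per-stage protein counts) sufficient to reproduce every output file.

## Problem sizes

The bundled tests and the acceptance script run the generator at its
default size (40 proteins × 7 replicates × 5 steps) with 1000-point
threshold grids, and the noise-degradation study at four noise levels × 20
seeds; these sizes give stable statistics for the properties being checked
while keeping a full run of the suite in the low minutes on a laptop.

## Known limitations

* The statistical test for splitting a module into further sub-modules is
  not implemented: the source analysis mentions a tendency of the dynein
  module to split further but reports it as not statistically significant
  and does not describe the test, so this package only reports per-module
  distances and leaves sub-splitting to the user.
* EPD absolute scales depend on the dialect (plain vs normalized) and on
  step count; thresholds calibrated under one dialect do not transfer.
* Calibration needs at least two curated modules (or external negatives);
  with a single module the sensitivity/specificity trade-off is undefined.
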