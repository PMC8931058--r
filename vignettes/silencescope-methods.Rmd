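---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model behind the synthetic-data
module, the numerical choices inside each pipeline stage, and the design
decisions that were genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

Each reporter mRNA is a diffraction-limited smFISH spot; translation is read
out as a SunTag immunofluorescence spot colocalized with the mRNA (within
500 nm in 3D), and RISC occupancy as an AGO spot within 250 nm. The tighter
AGO gate compensates for the much denser AGO background (~2000 IF spots per
cell against ~250 SunTag spots), which otherwise inflates chance
colocalization. All downstream quantities are ratios over per-cell spot
counts and summed on-mRNA intensities; bulk versions are ratios of pooled
sums over the analyzed cell population (the default batch is 50 cells), not
means of per-cell ratios — the two differ whenever denominators vary across
cells, which the test suite checks with an explicit counterexample.

## The synthetic generator

`sim_config()` encodes the study conditions; the defaults are the model, not
tuning knobs.

* **Expression level.** mRNAs per cell follow a negative binomial
  (size 6, mean 42) truncated at 100, which has median exactly 40 — chosen
  to match the reported expression summaries for this reporter system
  (median ~40, maximum ~100 mRNAs per cell). The truncation mirrors the deliberate minimization of
  reporter expression relative to the ~4000 miR-21-loaded RISC per cell
  (15,000 AGO copies x 25% occupancy).
* **Export.** A single-rate model,
  P(cytoplasmic) = 1 − exp(−k_export (t + t0)), with k_export = 0.03/min
  and offset t0 = 10 min. The offset accounts for the 30-min transcription
  pulse preceding chase time 0: some mRNAs are already cytoplasmic when the
  chase starts, which is what makes immediate RISC binding observable at
  t = 0. The defaults put roughly a quarter of mRNAs in the cytoplasm at
  0 min rising to ~90% at 60 min, so the export-efficiency metric E is
  monotone in time (a property test).
* **RISC binding.** Cytoplasmic reporters are bound with probability
  `p_risc_bind` (default 0.35) in the miR-21 condition from the earliest
  time point, and with `p_risc_false` (default 0) in the mutant. The true
  bound fraction is unobservable experimentally, so `p_risc_bind` is a
  free parameter of the generator, not a literature value; the default is
  chosen so that the *measured* RISC-positive fraction (true binding plus
  chance colocalization) lands near the ~30% such experiments report.
  Mutant RISC-positives arise purely from chance matches
  against the dense free-AGO field; with the default cell geometry this
  baseline is of the same order as the ~10% such experiments attribute to chance.
* **Repression and decay.** Translation is a Bernoulli flag
  (p = 0.6 active) with Poisson ribosome loads (mean 8, floor 1). At and
  after 30 min, RISC-bound mRNAs switch to the repressed regime (p = 0.15,
  mean 2 ribosomes) as a step — the experiment resolves only 0/30/60 min,
  so a step is the most parsimonious model the data could distinguish.
  Decay is likewise a single survival fraction (0.5) applied to cytoplasmic
  copies of the decay reporter (the construct without the anti-decay
  element) at t >= 60 min, matching the 0/30/60-min granularity such pulse-chase
  designs resolve.
* **Partner spots.** On-mRNA SunTag/AGO spots sit at the mRNA position plus
  isotropic Gaussian jitter (sigma 60 nm), resampled so the displacement
  stays 50 nm inside the relevant gate — partners colocalize by
  construction, as the measurement model assumes. On-mRNA SunTag intensity
  is ribosome count x a lognormal single-peptide unit (median 1500 a.u.,
  sdlog 0.3), the same law as free SunTag spots, so the ribosome estimator
  R = i / median(free) is consistent by construction. Free AGO/SunTag spots
  are uniform in the cytoplasm.
* **Geometry.** Cells are 2D ellipses (semi-axes 11 x 9 um, nucleus
  4.5 x 3.5 um) extruded over z, on a fixed-pitch grid; outlines from projection-based
  segmentation are 2D, so compartment assignment uses
  (y, x) only. These dimensions give a spread U2OS-like cell of ~310 um^2
  and, with ~2000 free AGO spots, a chance-colocalization rate at the
  250 nm gate in the 10–20% range.
* **Rendering.** Spots become anisotropic 3D Gaussians (sigma 150 nm
  lateral, 300 nm axial) whose voxel sum equals the spot's intensity, on a
  constant offset of 100 counts; Poisson shot noise is applied first, then
  additive Gaussian read noise (sd 2). Voxels are 107.5 nm in XY and
  200 nm in Z, with the centre of 0-based voxel i at (i + 0.5) x size.
* **Reproducibility.** Every cell draws from its own seed derived
  deterministically from the global seed, so identical (config, seed) pairs
  are bit-identical and single cells can be regenerated in isolation.

What the generator does *not* emulate: optical aberrations, channel
bleed-through, autofluorescence structure, nuclear AGO pools, partial
nascent peptides (so simulated R recovers the true ribosome count, whereas
in real data R is a lower bound), transcription-site spots containing
multiple nascent mRNAs, and gradual (rate-like) repression or decay.
Passing tests therefore demonstrate correctness of the *analysis* under the
stated measurement model, not robustness to every artifact of real
microscopy.

## Numerical choices in the pipeline

* **Background subtraction** subtracts a large-sigma Gaussian blur
  (1500 nm lateral, 1200 nm axial) and clamps negatives.
* **Candidate detection** uses a difference of Gaussians at the PSF scale
  (1x vs 1.6x), strict 26-neighbourhood maxima, and a threshold of
  mean + 5 sd of the filter response. The threshold is deliberately an
  explicit, overridable parameter: pre-detection settings of the
  established single-molecule tools are not standardized.
* **Fitting** minimizes least squares for an elliptical Gaussian
  (shared sigma_xy, separate sigma_z — widefield PSF symmetry) over a
  9 x 9 x 5 window, shrunk at stack borders, with log-parameterized
  amplitude and widths for positivity, BFGS, and moment-based starts.
  Integrated intensity is the analytic integral
  A (2 pi)^{3/2} sigma_xy^2 sigma_z / voxel volume, in voxel-sum units.
  Downstream metrics use integrated intensity, not amplitude: amplitude is
  confounded with PSF width, and established single-molecule pipelines report the
  integral. Quality filtering bounds sigma_xy to [50, 400] nm, sigma_z to
  [100, 800] nm, caps the normalized residual, and collapses fits that
  converged within one voxel of a brighter fit (the brighter wins). The
  single-emitter model is not a deconvolver: spots closer than roughly two
  PSF widths fuse, which is why detection benchmarks use resolvable
  (>= 1 um apart) emitters.
* **Segmentation** runs on maximum-intensity projections: Gaussian
  smoothing, Otsu threshold (overridable, since no single
  thresholding rule is canonical), hole filling and distance-transform watershed
  for nuclei; seeded propagation of nucleus labels through the probe-haze
  mask for cells. Cells touching the field border are flagged and excluded
  from per-cell metrics, since partial cells bias counts.
* **Drift** is a single average vector per field (mutual nearest neighbours
  within 500 nm, mean displacement, one refinement pass), applied globally;
  no chromatic field map is fit; a single average vector is the standard
  correction for zero-pixel-shift filter sets.
* **Matching** is greedy one-to-one in ascending distance, ties broken by
  lower spot id. One-to-one assignment is a policy choice; greedy is deterministic, near-optimal at these densities, and
  checkable against a brute-force implementation of the same rule (an
  oracle-equivalence test covers 1000 random instances).
* **Undefined ratios** (zero denominators) are `NA` flags, never errors,
  and exclude the cell from that metric only.
* **Free-SunTag calibration** (the denominator of R) uses the per-cell
  median when the cell has >= 10 free spots, else the pooled median. Per-cell versus pooled is genuinely open; per-cell respects
  cell-to-cell staining variation while the fallback keeps sparse cells
  usable.
* **Normalization** divides by the control's *bulk* (pooled) stability, not
  its median: a control reference should be a single pooled number, matching
  the bulk-metric definition. Time courses normalize within
  each time point.
* **Statistics.** The Mann–Whitney p is exact by full enumeration of rank
  assignments when the pooled sample is <= 20 and tie-free (C(20,10) =
  184,756 arrangements at worst), else a normal approximation with tie and
  continuity corrections; the two paths agree within 0.01 at n = 10 + 10.
  Tail directions are explicit arguments; the pipeline presets encode the
  directional hypotheses (miR-21 lowers S, T_eff, T_fra and raises A_eff,
  A_fra). Dunn's z uses pooled ranks with the tie term
  sum(t^3 − t) / (12 (N − 1)) and Bonferroni over the comparisons actually
  performed — in time courses, the miR-21-vs-mutant pair within each time
  point. Significance bands are `***` (p < 0.001), `*` (p < 0.05), `n.s.`
  otherwise, with strict inequalities: an exact p of 0.05 is n.s.
* **Site scanning** treats "7mer" as both 7mer-m8 and 7mer-A1 and "6mer" as
  the nt 2–7 match, per the canonical site taxonomy; overlapping matches of
  one miRNA deduplicate longest-type-wins, keyed on the position of the
  seed hexamer. Coordinates are 0-based on the forward strand. UTR
  *rewriting* is out of scope; only scanning, pairing verification and auditing are
  provided.

## Validation problem sizes

The test suite exercises: parameter recovery on ~2000 cytoplasmic mRNAs
(50 cells); drift recovery on 20 cells with a tenfold excess of unrelated
spots in the moving channel; detection on one 256 x 256 x 15 field with 100
resolvable spots at SNR >= 5; time courses with 50 cells per condition at
0/30/60 min; oracle equivalence on 1000 random matching instances (up to
200 spots) and 100 random 1-kb UTRs; Mann–Whitney null calibration with
10,000 replicates of 40-vs-40 samples (the asymptotic path, the one a
50-cell analysis would exercise); and Dunn familywise error with 1200
three-group null replicates. These sizes were chosen to keep Monte-Carlo
error well below each check's tolerance.

## Known limitations

Compartment assignment is 2D, so spots above or below a nucleus are called
nuclear. The greedy matcher is a policy choice among equally defensible
assignment rules. The ribosome estimator inherits the partial-peptide bias of the
SunTag method in real data. The simulator's repression/decay steps cannot
test inference of *rates*, only of before/after contrasts. Exact
Mann–Whitney p-values are not available under ties (the corrected normal
approximation is used instead).
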