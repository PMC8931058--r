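# silencescope

Single-molecule image quantification of miRNA-mediated gene silencing.

miRNAs loaded into RISC (an Argonaute protein guided by a ~22-nt RNA) bind
complementary mRNAs and silence them by translational repression followed by
mRNA decay. In single-molecule experiments each of those steps is imaged
directly: smFISH renders every reporter mRNA as one diffraction-limited spot,
SunTag/anti-GCN4 immunofluorescence renders the nascent peptides on a
translating mRNA as a bright spot (and each released single peptide as a dim
"free" spot), and anti-AGO2 immunofluorescence marks RISC. An mRNA is called
**translated** when a SunTag spot lies within 500 nm of it in 3D, and
**RISC-positive** when an AGO spot lies within 250 nm, giving a 2x2
classification of every cytoplasmic mRNA. `silencescope` implements the full
analysis chain for such experiments, plus a ground-truthed synthetic
microscopy generator to validate every stage:

* **Synthetic data** — a generative model of the pulse-chase reporter system
  (nuclear export, RISC binding, step repression at 30 min, decay at 60 min,
  PSF rendering, shot/read noise, inter-channel drift), emitted either as
  noisy spot tables or as rendered 3D TIFF stacks.
* **Spot detection** — background subtraction, difference-of-Gaussians
  candidate detection, and sub-pixel 3D Gaussian fitting returning positions
  in nm and integrated intensities.
* **Segmentation** — DAPI nuclei (Otsu + distance-transform watershed) and
  probe-background cell outlines (seeded propagation), with
  nuclear/cytoplasmic spot assignment.
* **Colocalization** — average inter-channel drift estimation by mutual
  nearest neighbours, greedy one-to-one distance-gated matching
  (mRNA–SunTag 500 nm, mRNA–AGO 250 nm), four-class mRNA classification.
* **Quantification** — the per-cell metrics

  S(k) = M_Sun,cyto(k) / M_Fluc,cyto(k)                (mRNA stability)
  T_eff(k) = I_Sun,coloc,cyto(k) / M_Sun,cyto(k)       (translational efficiency)
  T_fra(k) = M_Sun,coloc,cyto(k) / M_Sun,cyto(k)       (fraction translated)
  A_eff(k) = I_AGO,coloc,cyto(k) / M_Sun,cyto(k)       (RISC-binding efficiency)
  A_fra(k) = M_AGO,coloc,cyto(k) / M_Sun,cyto(k)       (fraction RISC-positive)
  E(k) = M_Sun,cyto(k) / M_Sun,nuc(k)                  (export efficiency)

  their bulk ratio-of-sums counterparts (S_bulk, T_eff,bulk, A_eff,bulk over
  the pooled 50-cell population), ribosome numbers
  R = i_Sun,coloc,cyto / median(i_Sun,free,cyto), and control-normalized
  stability S_norm.
* **Statistics** — one-tailed Mann–Whitney (exact by enumeration at pooled
  n ≤ 20, tie- and continuity-corrected normal approximation otherwise),
  Dunn's multiple comparisons with Bonferroni adjustment, Pearson r with
  simple linear regression; significance bands `***` / `*` / `n.s.` at
  0.001 / 0.05.
* **Site scanner** — canonical miRNA target sites (8mer, 7mer-m8, 7mer-A1,
  6mer), seed / 3'-supplemental pairing verification for designed sites, and
  auditing of "cleaned" reporter UTRs against a miRNA list.

## Worked example

Simulate one triple-channel experiment (mRNA + SunTag + AGO, 50 cells per
condition, fixation right after the transcription pulse), run the whole
pipeline, and compare conditions:

```r
library(silencescope)

cfg <- sim_config(n_cells = 50, seed = 2024)
ex  <- run_experiment("triple", cfg, time_points_min = 0)
ex
#> <silence_experiment> triple design, miR21/mutant at 0 min
#> # A tibble: 2 x 6
#>   condition time_min S_bulk T_eff_bulk A_eff_bulk n_cells
#>   <chr>        <dbl>  <dbl>      <dbl>      <dbl>   <int>
#> 1 miR21            0     NA      8085.      1188.      50
#> 2 mutant           0     NA      7230.       329.      50

dplyr::select(ex$tests_mw, metric, alternative, statistic, p_value, band)
#>   metric alternative statistic  p_value band
#> 1 T_eff  less             1533 9.75e- 1 n.s.
#> 2 T_fra  less             1368 7.93e- 1 n.s.
#> 3 A_eff  greater          2282 5.57e-13 ***
#> 4 A_fra  greater          2119 1.02e- 9 ***
```

At time 0 the miR-21 condition already shows strongly elevated RISC binding
(A_eff 1188 vs 329 intensity units per mRNA, one-tailed Mann–Whitney
p ≈ 6e-13) while translation is still untouched (T_eff n.s.) — binding
precedes repression. `S_bulk` is `NA` here because the triple design carries
no Fluc internal-control channel; stability comes from the decay design
(`run_experiment("decay", ...)`), which also adds `S_norm`, the per-cell
stability normalized to the mutant control within each time point.
`plot_metric(ex, "A_eff")` and `plot_classes(ex)` draw the standard
single-cell scatter-with-median and stacked four-class views, and
`tidy()` / `glance()` return the test and bulk tables.

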