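---
title: "Methods: quantifying pS6 immunostaining and validating the analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pS6 immunostaining and validating the analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ps6quant)
```

## The measurement problem

Phosphorylated ribosomal protein S6 (pS6) marks recently activated neurons.
In bright-field sections developed with DAB-Ni, activated cells carry a deep
greyish reaction product confined to the cell body: the cytoplasm around the
unstained nucleus is dark, while unstained tissue shows only a slight,
smooth, unspecific background staining. The activation measure for a brain
region is the **stained-area fraction**

$$F \;=\; \frac{A_\text{stained}}{A_\text{total}},$$

the stained area divided by the total area segmented for that region. One
region is typically segmented as several regions of interest (ROIs) — both
hemispheres, several sections — which are pooled to a single value per
animal and region. Group comparisons are rank-based: each learning group is
compared with the control group per region by a two-sided Mann–Whitney
U test, and relative activation is reported as
$\log_{10}(\bar F_\text{group}/\bar F_\text{control})$.

`ps6quant` implements this chain end to end, together with the behavioral
scheduling computations of the corresponding operant visual-learning
paradigm, and validates everything against a synthetic-histology generator
with known ground truth.

## Synthetic section model

`generate_section()` simulates one single-channel bright-field view on the
normalized intensity scale $[0,1]$ (1 = white):

1. a constant background at `background_level`, plus a smooth unspecific
   staining field (a coarse iid Gaussian grid, bilinearly interpolated;
   correlation length 32 px) with standard deviation `background_stain_sd`;
2. cells placed by a homogeneous Poisson process at `cell_density` per mm²;
   each cell is an annulus — cytoplasm between `nucleus_radius_um` and
   `cell_radius_um` — whose pixels are darkened by `stain_level`; the
   nucleus disc stays at background. Overlapping cells are merged by mask
   union;
3. iid Gaussian pixel noise (`noise_sd`), clipping to $[0,1]$, and
   quantization to 16-bit levels so in-memory images match their TIFF
   round-trips bit for bit.

The ground truth records exactly the stained cytoplasm pixels; background
variation and noise never enter the mask, so the true fraction is an exact
pixel count by construction.

### Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `resolution_um` | 1.6 | µm/px | slide-scanner resolution of the assay |
| `image_shape` | 200 × 200 | px | one ROI field (~320 µm square, ~0.1 mm²) |
| `background_level` | 0.85 | intensity | light tissue background in bright field |
| `background_stain_sd` | 0.02 | intensity | visible but slight unspecific staining |
| `cell_density` | 200 | cells/mm² | yields baseline fractions near 0.03 |
| `cell_radius_um` / `nucleus_radius_um` | 8 / 4 | µm | mid-sized teleost neuron soma; annulus ≈ 151 µm² |
| `stain_level` | 0.35 | intensity | deep grey product, well separated from background |
| `noise_sd` | 0.02 | intensity | scanner/staining pixel noise |

Cell radii are fixed rather than jittered: radius dispersion adds realism
but changes none of the contracts the package validates, and a fixed
annulus keeps the ground-truth geometry exactly interpretable.

`cohort_spec()` scales this model to a study: by default 4 groups
(control, avoidance, trained, novelty) × 10 animals × 19 brain regions ×
4 ROIs per animal and region (two sides on two sections), i.e. 3040 ROIs —
the "more than 3000 segmented areas" scale of a real data set. Group- and
region-specific activation is a positive multiplier on cell density;
control multipliers are pinned at 1.

### What the generator does and does not emulate

It emulates the features the measurement chain must cope with: annular
stained cells, smooth unspecific background, pixel noise, per-ROI polygon
variability, group structure with known effect sizes, and blinded IDs. It
does **not** emulate realistic neuron morphology, cutting/staining
artifacts, section deformation, within-animal spatial correlation, or
between-animal biological variability beyond Poisson sampling of cell
counts. Passing the validation suite therefore demonstrates that the
measurement and inference chain is accurate and calibrated under the stated
model — not that it is robust to every failure mode of real histology
(artifact exclusion, in particular, remains a manual step in practice).

## Quantification

All detection happens on the inverted scale $1 - \text{intensity}$ (stain
up). Per ROI:

* **Background**: median of the ROI's inverted intensities; spread as the
  normal-consistent MAD. The median is robust while stained pixels cover
  well under half the ROI (baseline fractions here are a few percent).
* **Threshold**: a pixel is stained iff its inverted intensity exceeds
  `background + k·MAD`, with `k = 5` by default. At the default noise this
  places the threshold ≈ 0.15 intensity units above background, versus a
  stain depression of 0.35 — large margins on both sides. In the noise-free
  limit the rule recovers the ground-truth mask exactly. Both background
  and spread can be supplied explicitly (e.g. from a cell-free reference
  region) for nearly fully stained ROIs, where a per-ROI estimate would be
  biased.
* **Pooling**: the per-animal, per-region value is area-weighted,
  $\sum A_\text{stained} / \sum A_\text{total}$ over the ROIs — the single
  stained-over-total ratio for that brain part — not a mean of per-ROI
  ratios, so larger segmented areas carry proportionally more weight.

ROIs are polygons in 0-based pixel coordinates; a pixel belongs to the ROI
iff its center lies inside the polygon (even-odd rule). Polygon vertices
are continuously jittered, so pixel centers lie on edges with probability
zero and rasterization is unambiguous and bit-reproducible. A polygon
reaching outside the image is a hard error, never clipped silently.

Blinding is structural: `blind_order()` returns a seeded uniformly random
permutation of the records that exposes only the blinded ID and file
references, plus a separately held key for post-hoc unblinding. The
presentation schema cannot leak group or animal identity.

## Statistics

`mann_whitney_u()` computes $U_x = \#\{(i,j): x_i > y_j\}$ (ties counting
one half; $U_x + U_y = n_1 n_2$ always). For tie-free samples with
$n_1 + n_2 \le 20$ the two-sided p-value is **exact**: the null
distribution of $U$ over all $\binom{n_1+n_2}{n_1}$ label assignments is
obtained from a subset rank-sum counting recursion, and $p$ is the null
probability of a $U$ at least as far from $n_1 n_2/2$ as observed. This
covers the 10-vs-10 design (184 756 assignments) exactly. With ties, or
beyond the exact limit, a normal approximation with tie-corrected variance
and continuity correction is used and flagged in the output. The test
suite checks the exact path against full `combn` enumeration for **every**
tie-free input with $n_1+n_2 \le 12$ and spot-checks 10-vs-10 against the
complete enumeration.

Design choices made here (the upstream analysis convention leaves them
open) and their rationale:

* **Two-sided** p-values: activation differences are reported in both
  directions.
* **Animal-level** inference: ROIs are pooled to one value per animal and
  region before testing, so the test's exchangeable units are animals.
* **Log base 10** for activation ratios (configurable); zero or negative
  means raise an error rather than being patched with a pseudo-count — a
  zero group mean signals a degenerate configuration.
* **No multiple-testing correction by default**, matching per-region
  decisions at $p < 0.05$; Benjamini–Hochberg is available via
  `adjust = "BH"`.

`error_calibration()` closes the loop: it pushes replicate two-group
cohorts through the *entire* chain (generate → measure → pool → test) and
reports the rejection rate — the empirical type-I error under the null
multiplier 1, or power under an effect multiplier. Note the exact test is
discrete: at $n_1=n_2=10$ the largest attainable two-sided level below
0.05 is ≈ 0.043, so a well-calibrated chain rejects slightly less often
than 5%.

## Behavioral scheduling

A rotational scheme is the predetermined side sequence of the rewarded
stimulus over a 10-trial session: 5 left / 5 right, never more than twice
consecutively on one side. `generate_scheme()` samples uniformly from the
valid set by rejection from balanced permutations; exhaustive enumeration
(`count_valid_schemes()`) shows the valid set has 84 of the 252 balanced
sequences, and a χ² test over large draw counts confirms empirical
uniformity. Four schemes are cycled consecutively over every four sessions
(`schedule_sessions()`, two sessions a day). The learning criterion —
seven or more correct out of ten in three consecutive sessions — is
evaluated online by `criterion_met()`, which returns the *first* session
index closing a qualifying window; it is verified against a brute-force
sliding-window oracle on all $2^{10}$ session-outcome patterns.
`habituation_schedule()` encodes the novelty-group design (4 trials per
session, 3 sessions per day, one session on the final day, then a single
30 s dishabituation presentation; 30 s stimulus-to-food, 2 min stimulus-off
after food, 5 min between trials) as schedule metadata; choice behavior
itself is not modelled beyond the Bernoulli test harness
`simulate_learner()`.

## Pipeline and reproducibility

`run_pipeline()` executes the full chain into one directory: cohort
(TIFF + ROI JSON + CSV), blind order and sealed key, per-ROI and per-animal
measurement CSVs, the activation report (CSV + JSON), and a manifest with
the configuration, derived stage seeds, versions and file checksums. The
master seed deterministically derives per-stage seeds
(`derive_seed()`, a multiplicative-congruential split modulo $2^{31}-1$),
so any stage can be replayed in isolation from the manifest, and an
identical configuration reproduces byte-identical measurement and report
files.

## Validation problem sizes

The validation suite uses compact frames for Monte-Carlo loops — 96–128 px
ROIs for recovery and calibration (standard noise settings throughout),
200 replicate cohorts for recovery and detection checks, 1000 replicates
for type-I calibration, 100 000 draws for scheme uniformity — and the full
default design (3040 ROIs, two complete runs) for the byte-identity check.
These sizes give stable rates while keeping the suite comfortably
re-runnable; all of them are driven from fixed seeds.

## Known limitations

* The stain detector is a per-ROI robust threshold; real workflows may add
  smoothing, artifact exclusion and operator review, which are out of scope
  here.
* The generator's between-animal variability is purely Poisson; real
  cohorts add biological and staining-batch variance components, which
  would widen group distributions without changing the rank-test machinery.
* ROI-level spatial correlation within an animal is not modelled; pooling
  to animal level (as done before testing) makes inference insensitive to
  this simplification.
* Fractions are rational with denominators of ~10⁴ pixels, so occasional
  exact ties occur between animals; these replicates fall back to the
  tie-corrected normal approximation and are flagged as such.
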