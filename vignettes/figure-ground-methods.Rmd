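---
title: "Figure-ground segmentation stimuli, encoding models, and modulation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Figure-ground segmentation stimuli, encoding models, and modulation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figground)
```

## The problem this package addresses

When an object moves against its background, pixels of the background are
revealed and hidden at the object's edges (accretion-deletion). This is the
one segmentation cue that occurs *only* at true object borders, regardless
of the textures involved. Whether a visual system can exploit it —
segmenting a figure whose texture is identical to the background and which
is defined purely by opponent motion — is a sharp test that separates
texture segregation from genuine surface segmentation.

`figground` packages the machinery needed to run that test *in silico* and
to analyze recordings made with it:

1. **Stimulus synthesis** (`figure_ground_spec()`, `render_trial_movie()`,
   `build_figure_map_session()`): square figures on full-field carriers —
   orthogonal gratings (Cross), same-orientation gratings (Iso),
   naturalistic 1/f noise (Nat) — with figure and background translating in
   counterphase (sinusoid, 3.5 deg half-range, 1 cycle/s).
2. **A synthetic population** (`sample_gabor_population()`,
   `simulate_session()`): the feedforward linear-nonlinear (LN) simple-cell
   model, an optional divisive orientation-tuned surround, and a
   mean-scaled Gaussian noise model, producing response matrices with known
   ground truth so every downstream statistic can be validated.
3. **Receptive-field mapping** (`make_sparse_noise_session()`,
   `compute_sta()`, `fit_gaussian_rf()`, `assess_and_select()`).
4. **Figure maps and cross-session matching** (`build_figure_map()`,
   `correlate_maps()`, `match_cells_across_sessions()`).
5. **Modulation indices** (`modulation_index()`, figure-ground FGM and
   border-ownership BOM) with bootstrap nulls and the Binomial chance curve
   for multi-condition significance counts.
6. **Population decoding** (`fit_position_decoder()`, `decoding_curve()`):
   cross-validated ridge regression of figure azimuth.
7. **Orchestration** (`pipeline_config()`, `run_pipeline()`,
   `write_session()`/`read_session()`).

## Stimulus model

A stimulus is a square figure of side 27 deg (configurable) on a full-field
carrier. The background, shifted by its displacement, is drawn first; the
figure patch — its texture rigidly attached to its aperture — is pasted
over it at the displaced figure location. Accretion-deletion then emerges
at the trailing/leading edges without further modeling. Displacements
follow `A sin(2 pi f t)` with the figure and background in counterphase
(equal and opposite), so the relative displacement peaks at `2A`.

Conventions worth knowing:

* **Luminance** is kept in `[0, 1]` with mean 0.5 end to end; 8-bit
  quantization happens only in `write_movie_tiff()`. This keeps contrast
  algebra (for instance the morph-stage checks below) exact.
* **Rendering resolution** defaults to 1 px/deg; displacements are
  quantized to whole pixels at that resolution, mirroring the pixel
  quantization of any real display. `px_per_deg` refines this if needed.
* **Condition semantics.** `Cross`: figure grating orthogonal to the
  background. `Iso` (behavioral): same orientation, phase offset (half
  period by default; the offset is configurable).
  `Nat`: figure and background are the *same* noise sample, so at zero
  relative displacement the figure-present frame is pixel-identical to the
  background-only frame (a property the tests assert bit-exactly).
* **Session Iso pops out by motion.** In the recording sessions the Iso
  figure is generated from the very texture that defines the background —
  no phase offset — so within Iso and Nat the figure is defined only by
  opponent motion. `standard_conditions()` therefore sets `pop_out = TRUE`;
  the phase-offset variant remains the behavioral default in
  `figure_ground_spec()`. This distinction matters: with a phase-offset
  figure interior, a linear population reads the figure's position from
  phase contrast alone and the condition ordering studied below cannot
  arise.
* **Morph schedule.** `make_morph_stimulus(stage, ...)` blends carrier
  textures as `(1 - s/10) grating + (s/10) noise`, stage 3 giving the
  70%/30% split; the figure patch is flipped vertically and placed at one
  of three heights to discourage local-cue strategies.
* **Geometry.** `angular_geometry()` maps movie pixels to visual angle
  through the physical screen with the exact arctangent (a freely moving
  animal can be centimeters from the screen): a 50 px figure in a 200 px
  movie on the 24 cm touchscreen spans ~15 deg at 23 cm and ~143 deg at
  1 cm. Head-fixed conversions use the small-angle map at the screen
  center (`deg_per_px()`, tangent-corrected option available).

A figure-map session (`build_figure_map_session()`) flashes the figure over
a 16 x 8 grid of positions (45 x 23 deg, ~3 deg steps), 10 repeats per
position and condition-variant, 250 ms dwell. Condition order is
pseudo-random with the two within-condition variants presented
consecutively; positions are shuffled within each block.

## The synthetic population

The generator's defaults *are* the study conditions; they are not tuning
knobs.

**Feedforward LN model.** Each cell is a Gabor filter
`g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) cos(2 pi x' / lambda + omega)`
followed by rectification. Parameters are i.i.d. uniform: orientation on
`[0, pi)`, envelope `sigma` on 2-7 deg, spatial frequency on 0.05-0.3 cpd,
phase on `[0, pi)`, aspect ratio 1. RF centers are uniform over the grid
span (the center distribution is not pinned down anywhere; uniform over the
sampled positions is the neutral choice). Filters are truncated at 3
envelope SDs (<1% mass discarded). Frames are mean-centered (the 0.5
pedestal removed) before filtering, otherwise DC leakage of the cosine
Gabor dominates at low frequencies.

**Trial responses sample the motion phase.** The displacement sine runs
continuously during a session while 250 ms trials tile it, so the repeats
of a position start at different motion phases. `simulate_session()`
therefore computes per-frame rectified rates over one full cycle (16
frames) and averages each trial over the quarter-cycle window starting at
that trial's onset phase (`onset_s` mod the period). Two consequences are
worth spelling out. First, the *expected* per-position rate is the
full-cycle phase average, under which a same-texture (pop-out) figure
interior is invisible to rectified linear filters: the figure-attached
texture sweeps displacements `+s(t)` while the background sweeps `-s(t)`,
and the two symmetric sweeps average to the same rate. Second, edge
responses — the only linear signature of a motion-defined figure — vary
strongly with onset phase, and that stimulus-driven variability is carried
into the trial responses rather than being averaged away.

**Divisive surround.** `response = feedforward / (1 + beta * rho)` with
`beta = 0.95`, where `rho` is the Pearson correlation between mean
orientation-energy vectors inside the RF (< 2 sigma) and in the annulus
(2-5 sigma), evaluated at the middle frame of each trial-onset phase
window so the surround modulation samples the motion phase exactly as the
feedforward responses do (a single fixed-frame rho would hand the decoder
a deterministic seam cue in the motion-defined conditions). The
energy bank is a set of quadrature Gabor pairs at orientations evenly
spaced on `[0, pi)` and a carrier-matched spatial frequency (0.06 cpd
default): a phase-invariant local orientation spectrum. An earlier design
sampled the bank from the LN parameter ranges with rectified outputs, but
the frequency/size diversity of such a bank induces a common energy profile
in both regions and the center-surround correlation comes out positive even
for orthogonal textures; the orientation-spectrum bank restores the
intended behavior — iso-oriented surrounds give `rho > 0` (suppression),
orthogonal surrounds `rho < 0` (facilitation). Note the sign statement
applies to cells whose annulus actually samples the ground; a small-sigma
cell sitting wholly inside a 27 deg figure sees figure texture in both
regions, which is the physically correct outcome, not an artifact. Energy
maps use circular FFT convolution (the noise textures are
Fourier-periodic by construction; gratings are near-periodic), and a cell
with a zero-variance energy vector is flagged and left unmodulated.

**Noise model.** Zero-mean Gaussian noise with variance
`noise_factor x popmean` is added per trial and rectified, `popmean` being
the mean response over all neurons and trials of the trial's condition.
The variance-proportional-to-mean law is scale-covariant only once a
response scale is fixed, and there is no canonical scale; the
generator normalizes LN rates so the session grand mean is 1 before noise,
making `noise_factor = 1` Poisson-like at unit rate and `noise_factor = 2`
(the reference condition for the model-comparison run) twice that.

**Archetypes.** Three idealized cells interpret figure maps: a figure cell
(fires iff the figure intersects its RF disc — its map is the square
dilated by the RF, side `figure + RF diameter`), a border cell (fires iff
an edge of its preferred orientation falls on the RF with the figure on its
preferred side — its map is an edge stripe), and an ON simple cell
(rectified zero-mean Gaussian kernel — its map tracks the carrier phase and
so cannot be texture-invariant).

## Receptive-field estimation

Sparse noise (18 x 32 grid of 3.5 deg squares, one black or white square
per frame, strict polarity alternation, 8000 frames at 10 Hz) is analyzed
by spike-triggered averaging in a 30-100 ms window. Black events are
sign-flipped so a single signed map results (separate ON/OFF maps via
`combine`). A 5-parameter axis-aligned 2D Gaussian plus offset is fit by
Levenberg-Marquardt from multiple starts (absolute peak and centroid, both
amplitude signs; lowest MSE wins; a rotation term is deliberately omitted
— nothing in the data model requires it and it destabilizes small maps).
Fit quality is `GOF = 1 - MSE / Var(RF)`, which is 1 exactly at zero
residual and 0 when the fit is the map's mean. Cells enter analyses when
GOF > 0.1, total response mass >= 100, the observed GOF beats at least
99/100 position-shuffled refits, and the fitted center lies in the central
window — either the 15 x 10 deg box or the 4 deg radius variant, two
conventions in experimental use; neither is asserted as canonical
(`center_window` chooses).

## Modulation indices

`FGM = (R_fig - R_back) / (R_fig + R_back)` and
`BOM = (R_left - R_right) / (R_left + R_right)` on zone means of trial
means, averaged across the condition's two patterns. Zone conventions:

* `results`: figure zone = central 2 x 2 positions (40 trials at 10
  repeats), background = outermost columns (160 trials), border zones =
  single columns (defaults 4 and 12; 80 trials each).
* `methods`: figure zone = the 2 x 2 block nearest the fitted RF center;
  background = positions farther than 1.5 x the RF width (taken as twice
  the geometric mean of the fitted sigmas — the width is not defined in
  print, and this is full width at ~60% height).

The figure zone's angular size is quoted sometimes as 6 x 6 deg and
sometimes as 10 x 10 deg for
the same 2 x 2 block; with ~3 deg grid spacing the 6 deg reading is
self-consistent, but the package treats the block definition, not the
degree label, as normative. Significance is a 500-shuffle bootstrap of
trial identity with a two-sided criterion on `|index|` and the `+1/(n+1)`
small-sample correction ("significantly different from zero" is read as
two-sided). Per-cell counts of significant conditions across the six
variants are compared against the Binomial(6, 0.05) false-positive curve.

## Decoding

Azimuth (bin index 1-16) is decoded as a continuous target by ridge
regression: 50/50 train/test splits; the penalty picked per split on a
10-point log grid spanning six decades by an internal 50/50 split of the
training half; both the neuron subsample and the trial split are redrawn
each of 100 iterations (whether trials, neurons, or both should be
resampled is underdetermined by convention; both are, and the seed pins
it down).
Performance is the held-out coefficient of determination
`1 - SS_res / SS_tot` — negative values are possible and are evidence of
overfitting, not an error. Within a condition the two pattern variants are
pooled before splitting, so the decoder must generalize across carriers
within the texture class. The glmnet ridge path is used as the solver; the
procedure around it is owned by this package.

`side_generalization_test()` is the population analogue of the behavioral
transfer test: a ridge linear readout of figure side trained on responses
to a set of training patterns, evaluated on novel patterns (chance 0.5).

## Problem sizes and what passing tests show

The test suite and the acceptance script run the full pipeline at sizes a
laptop handles comfortably: 200 model neurons (the reference
model-comparison population; full-scale simulations of this paradigm use
tens of thousands of cells with decoding subsamples up to 200, so 200 is
the size actually entering the decoder), 100 decoder iterations, 500 bootstrap shuffles, and >= 500 null
cells for calibration checks. The generator emulates trial structure,
motion-phase sampling, condition texture relations, and mean-scaled
Gaussian variability. It does not emulate spiking dynamics, adaptation,
recurrence, eye movements, or neuropil contamination; passing tests
therefore validate the *statistics and the model implementation*, not
claims about biological tissue. Calibration results (false-positive rates,
null decoding) transfer to real data only insofar as trial
exchangeability holds there too.

## Numerical choices and degenerate inputs

* Constant maps make Pearson r and GOF undefined: both are hard errors,
  never NA-silent.
* `compute_fgm(0, 0)` (both zone means zero) is an error; zone means are
  validated nonnegative.
* Bootstrap and shuffle p-values use the `+1/(n+1)` correction, so no
  p-value is ever exactly 0.
* Ties in `make_static_frame()` resolve to the earliest frame; the
  greedy cross-session matcher breaks overlap ties by scan order after
  sorting by descending Jaccard index.
* All stochastic stages derive their seeds from one global seed
  (`derive_seed`), and every generator is reproducible byte-for-byte under
  a fixed seed; the pipeline manifest records the config hash and per-stage
  seeds, while wall-clock timings go to a log file so manifests stay
  reproducible.

## Known limitations

* The LN and surround models are rate models; Poisson spike generation is
  out of scope (the quantitative noise description covers only the
  Gaussian model, which is what is implemented).
* A divisive orientation-energy surround is intrinsically sensitive to the
  texture seams that opponent motion creates at a motion-defined figure's
  border, so the surround model retains a small positional signal in the
  Nat condition (held-out r^2 ~ 0.1 at the reference noise level, versus
  ~0.05 feedforward and ~0.7 for Cross). The rank ordering
  Cross > Iso > Nat, with Nat far below the decodable conditions, is the
  robust model prediction; the exact Nat floor depends on rho's phase
  sampling and the noise-free divisive path.
* The drifting-Gabor-patch RF protocol used for imaging is not
  implemented; the STA path is the estimator.
* The session container is plain CSV/JSON. It mirrors the logical schema
  of the archival deposit (responses x trials, trial table, cell metadata,
  provenance) rather than its binary layout.
* VGG-style network activations are not computed here;
  `decode_feature_matrix()` accepts any units x trials matrix so
  externally computed layer activations can be decoded with the identical
  pipeline.
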