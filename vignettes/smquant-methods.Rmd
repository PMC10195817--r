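---
title: "Methods and design notes for smquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for smquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smquant)
```

smquant quantifies single-molecule experiments on nuclear proteins across
five measurement modalities: SMLM (STORM) point patterns, two-channel
coordinate-based colocalization, 3D single-particle tracking, FRAP, and
equilibrium titrations, plus AFM grain morphometrics.  This vignette
explains the models behind each pipeline, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## SMLM cluster analysis

**Linearised Ripley's K.**  For a point pattern in a polygonal ROI of area
$A$, the estimator is

$$\hat K(r) = A \, \frac{\sum_{i \in C} n_i(r)}{|C| \, (n-1)},
\qquad L(r) - r = \sqrt{\hat K(r)/\pi} - r,$$

where $n_i(r)$ counts other localizations within $r$ of point $i$ and $C$
is the set of *guard-band centres*: points at least $\max(r)$ from the ROI
boundary.  Guard-band exclusion was chosen over analytic isotropic edge
correction because ROIs here are free-hand nuclear outlines — arbitrary
polygons for which the analytic correction is awkward, while the guard
band is unbiased for any shape.  Its cost is that the largest usable
radius must stay well inside the ROI (the estimator refuses radii beyond a
quarter of the ROI's minimum caliper width by default).  $L(r)-r$ is zero
in expectation under complete spatial randomness (CSR), positive under
clustering; because $\sqrt{\cdot}$ is concave the estimate carries a small
negative bias that a Monte-Carlo envelope built with the same estimator
shares, which is why significance should always be read against such an
envelope rather than against the zero line.

**DBSCAN.**  Cluster maps use standard DBSCAN semantics with the field's
conventions: `min_pts = 5` molecules, and `eps` equal to the mean
localization precision of the channel (typically 20 nm for far-red and
30 nm for green dyes; the table's own precision column supplies the value
when present).  Determinism is pinned down explicitly — clusters are
numbered by their first member's row index and a border point reachable
from two clusters joins the lower label — so results are reproducible
across runs and match the naive reference implementation point for point.

**Cluster areas.**  Per-cluster area is the convex hull of member
coordinates.  The software this analysis descends from derives areas from
smoothed density contours controlled by a "smoothing" setting; that
setting's geometric meaning is not published, so the hull — parameter-free
and exactly testable — is used instead, and the smoothing value is merely
carried through for provenance.  Hull areas are systematically smaller
than contour areas for diffuse clusters; comparisons should therefore stay
within one convention.  Clusters with collinear members get zero area and
are excluded from mean-area summaries (their count is reported).

## Coordinate-based colocalization (DoC)

For each point $i$ of channel A, neighbour counts $N_A(i,r)$ and
$N_B(i,r)$ are taken on a linear ladder of `n_radii` radii up to `r_max`
(defaults 10 and 500 nm).  Each series becomes a density gradient
$G(r) = \frac{N(i,r)/r^2}{N(i,r_{\max})/r_{\max}^2}$, and

$$\mathrm{DoC}_i \;=\; \rho_s\!\left(G_A, G_B\right)\,
e^{-d_i/r_{\max}},$$

with $\rho_s$ the Spearman rank correlation across the ladder and $d_i$
the distance to the nearest channel-B point.  Scores live in $[-1, 1]$:
+1 for molecules whose two-channel density landscapes rise and fall
together at zero separation, negative values for segregation.  A point
with no same-channel or no cross-channel neighbour within `r_max` has no
defined gradient pair; its score is set to 0 and counted, a convention
that leaves sparse background molecules neutral rather than forcing a
sign.  The colocalization threshold is 0.4, the conventional cutoff for
this score; cluster-level calls require at least `min_coloc_points = 5`
above-threshold members, mirroring the minimum cluster size.

Dense nuclei are sometimes analysed in quadrants for memory reasons.  The
implementation here is chunked rather than tiled, so no tile-boundary rule
is needed; if external tiling is ever used, scores near tile edges should
be computed against the full point set, not the tile.

## Single-particle tracking

Per track, the time-averaged MSD at lag $k\,\Delta t$ averages squared
displacements over all ordered frame pairs, summing the three axes.  The
anomalous-diffusion fit is linear least squares in log–log space,

$$\log \mathrm{MSD} = \log(2\,d\,D) + \alpha \log t,$$

over the first 4 lags by default ($d = 3$ dimensions for 3D tracks).  The
short window trades variance for bias: at longer lags time-averaged MSDs
of confined motion flatten, biasing $\alpha$ down, while the first lags
are the best-sampled.  Mobility classes follow the fixed thresholds
(static $D < 0.1$, slow $0.1 \le D \le 1$, diffuse $D > 1$ µm²/s);
boundary values go to "slow" because the printed outer inequalities are
strict.  No localization-noise offset is subtracted by default; a static
emitter with noise $\sigma$ per axis shows an MSD plateau near
$6\sigma^2$, which for the defaults here sits well below the static band's
scale.

**Why the track generator uses fractional Brownian motion.**  Two Gaussian
processes both have ensemble MSD $6 D t^\alpha$: scaled Brownian motion
(independent increments whose variance ages as $t^\alpha$) and fractional
Brownian motion (stationary, correlated increments).  They are *not*
interchangeable for this pipeline: sBm's time-averaged MSD is nearly
linear in lag regardless of $\alpha$ (weak ergodicity breaking), so
per-track fits on sBm tracks return $\alpha \approx 1$, not the generating
exponent — we measured exactly that before switching.  fBm's time-averaged
MSD follows $6 D\,\Delta t^{\alpha}$, matching what per-track fitting
assumes, so `simulate_tracks()` defaults to fBm (exact simulation via one
Cholesky factor per mixture component, reused across tracks); sBm remains
available as `model = "sbm"` for studying exactly this discrepancy.

**Composition studies and boundary leakage.**  Per-track $\hat D$ from a
4-lag fit on a 30-frame track is broad on the log scale, so a mixture with
a static component at $D = 0.05$ loses a few percent of its static tracks
across the 0.1 µm²/s boundary — with 55% generated static, roughly 51%
is recovered at 30 frames.  The composition study in the acceptance script
therefore uses 1000 tracks of 60 frames (about 2 s of a typical 30 s
acquisition), where the leakage in and out of the static band roughly
cancels; the parameter-recovery study keeps 200 tracks of 30 frames.
When comparing real acquisitions of different track-length distributions,
this leakage is a genuine confounder to keep in mind.

## FRAP

Normalization is the double/full-scale convention: background-subtracted
double normalization
$I_{dn}(t) = \frac{\mathrm{ref}_{pre}}{\mathrm{ref}(t)}
\cdot \frac{\mathrm{frap}(t)}{\mathrm{frap}_{pre}}$
corrects acquisition photobleaching through the reference ROI, then
full-scale normalization pins the bleach frame to 0 and the pre-bleach
level to 1, so the recovery plateau *is* the mobile fraction.  The
recovery fit is the single-exponential $I(t) = M(1 - e^{-kt})$ with
$t_{1/2} = \ln 2 / k$; a single component suffices for the data this
models, and a two-component extension is out of scope.  Initial guesses
are data-driven ($M$ from the final-quartile mean, $k$ from the linear
interpolated half-rise), which converges without manual seeding across
the noise range the generator covers.  Whether a mobile fraction should
come from the full-scale plateau or from an end-value formula is a genuine
convention fork; the plateau convention is used and stated, and the
simulator adopts the same convention so the two ends meet exactly.

## Binding titrations

The quadratic ("tight-binding", ligand-depletion) isotherm gives the
bound-complex concentration

$$[PD] = \tfrac12\!\left(S - \sqrt{S^2 - 4 P_t D_t}\right),
\qquad S = P_t + D_t + K_d,$$

evaluated as $2 P_t D_t / (S + \sqrt{S^2 - 4P_tD_t})$ to avoid
cancellation at tight binding.  Signals are linear in the bound fraction
of the fixed partner.  Self-association (the MST design: a 16-step
two-fold dilution from 10 µM titrated onto 50 nM labelled material) is
modelled as a bimolecular labelled–unlabelled association with the
labelled species in the fixed-partner role; the quadratic is symmetric in
its two totals, so it does not matter which species is called "partner".
Higher-order self-assembly is deliberately not modelled.

The modified model adds a linear baseline $a + b\,[\mathrm{DNA}]_t$ as
printed.  Two caveats, both documented rather than silently "fixed":
with the partner held constant the printed term is a constant offset, so
`eq2_signal()` exposes a `linear_in = "titrant"` variant that produces the
non-saturating tail such curves actually show, and `fit_kd()` defaults to
that variant because it is the identifiable one.  Second, a free-state
signal level is structurally collinear with the intercept $a$ (shifting
$a$ equals shifting both plateau levels), so the modified-model fit fixes
$f_{free} = 0$ and lets $a$ absorb it — otherwise the Jacobian is
rank-deficient and the fit aborts.

## AFM morphometrics

Grain masks threshold the lightly smoothed map (Gaussian, 1.5 px) at
`mean + k_sigma * SD`, with the multiplier chosen per molecule type
(published values 0.57–1.5 for the proteins this emulates); grains are
4-connected components.  Filters then drop border-touching grains, grains
under 50 nm², and grains outside a configurable multiple-of-median-area
window, with per-rule drop counts.  Bounding sizes are caliper widths
(width of support) of the mask's convex hull built from pixel *corners*,
so a w×h-pixel block measures exactly w×h pixels across; the maximum
width of support of a convex body equals its diameter, which is why a
rectangle's "length" reads as its diagonal.  A single-pixel grain reports
both bounds as one pixel by convention.  Size distributions are
summarised as the KDE mode ± sample SD (Gaussian kernel, Silverman
bandwidth, 512-point grid, ties to the lower value).

For the synthetic rod-recovery study, the threshold multiplier is derived
from first principles rather than reused from the protein defaults: a hard
edge blurred by a symmetric kernel crosses *half* its height exactly at
the true boundary, so the study sets `k_sigma` such that the threshold
sits at half the rod height.  Protein-default multipliers applied to these
hard-edged synthetic rods would dilate the mask by 1–2 px and bias widths
upward — an artefact of the synthetic edge profile, not of the estimator.

Binding positions along a DNA contour are arc-length projections onto the
ground-truth polyline, reported as % distance from the nearer end (0–50%),
with the edge/middle split at 25% (the two edge regions jointly cover half
the molecule; exactly 25% counts as middle).  Sites farther than a capture
radius (default 15 nm) from the contour are left unassigned and counted —
the manual measurement protocol this mirrors does not publish its capture
rule, so the default is a documented choice, not a claim about the
original analysis.

## Synthetic data: what it does and does not emulate

The generators provide every downstream stage with inputs of known ground
truth: Thomas-type two-channel cluster scenes with a controllable shared-
centre fraction and per-point truncated-normal precision; fBm/sBm mobility
mixtures; exponential FRAP recovery with an immobile fraction; quadratic
titration signals with Gaussian noise; worm-like-chain DNA contours
(tangent-angle variance step/persistence length) rendered as ~2 px ridges
with max-combined Gaussian blobs, plus hard-edged rods for bounding-size
studies.  Every generator is a pure function of its parameters and seed.

They deliberately do **not** emulate: camera/PSF-level SMLM frame
formation, fluorophore blinking and the repeated-localization artefacts it
causes, drift, chromatic misalignment between channels, motion blur or
detection dropout in tracking, bleach-spot diffusion during FRAP,
thermophoresis physics, or AFM tip convolution.  Passing recovery tests on
these generators therefore demonstrates that the estimators are correct
and unbiased under each stage's own model assumptions — not that those
assumptions hold for any particular instrument's raw data.  Noise models
and their default levels are stand-ins chosen at realistic magnitudes
(e.g. 20–30 nm localization precision, 2% titration noise) and stay
configurable.

## Numerical conventions and degenerate inputs

* Lengths are nm for SMLM/AFM, µm for tracking; times in s,
  concentrations in µM.  Readers convert on ingest.
* Point-in-polygon uses the even–odd rule with boundary points counted
  inside, making ROI membership a deterministic total function.
* The ridge renderer combines heights by maximum, so a noiseless chain
  peaks at the nominal ridge height up to grid quantization (< 2% at the
  default half-pixel sampling).
* Empty localization tables cluster to an empty result, not an error;
  empty masks give empty grain sets; failed fits carry an `ok` flag and an
  "unclassified" mobility class excluded from percentages.
* JSON reports are written with 17 significant digits so a round trip
  reproduces doubles bit for bit.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
these sizes, chosen to keep every statistical check's sampling error small
relative to its tolerance band: 5000-point CSR patterns with a 39-run
Monte-Carlo envelope; two-channel scenes of 15–20 clusters × ~30
molecules; 200 × 30-frame tracks for (D, α) recovery and 1000 × 60-frame
tracks for composition; 30 FRAP traces; 3 × 16-point titrations; 60 rods
and ≥ 20 random fixtures per brute-force oracle comparison.
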