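---
title: "Models and methods: simulating and quantifying pheromone-guided polarity-site movement"
author: "pherotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and quantifying pheromone-guided polarity-site movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pherotrack)
```

## The biological problem

Haploid *Saccharomyces cerevisiae* cells of opposite mating type (MATa,
MATalpha) find each other by decoding pheromone gradients. Each cell carries
a single mobile cortical polarity site (a cluster of active Cdc42 and
effectors, conveniently marked by Spa2 fusions) that wanders over the cell
cortex in an apparent search. Because pheromone is secreted at the polarity
site itself, each partner's site acts as a moving point source, and the
other cell's site is biased to move up the resulting gradient. The search
ends when the two sites come face to face ("encounter"), after which they
may stabilize ("commitment") or move on ("kiss-and-run").

pherotrack packages the complete quantitative workflow for studying this
process in silico: a ground-truth simulator of biased walks on touching
spherical cells, a renderer producing synthetic confocal z-stack movies, a
tracking pipeline, the tangent-plane direction statistic theta, encounter
detection and outcome classification, and two-sample Kolmogorov-Smirnov
(KS) comparisons.

## The gradient model

A polarity site emitting S molecules per second into a medium with
diffusion constant D produces, at steady state with free diffusion and no
degradation, the concentration field

$$ c(r) = \frac{S}{4 \pi D r} $$

at distance $r$ from the source. Degradation is deliberately omitted: for a
small peptide (D of order 150-300 um^2/s) diffusional escape outpaces any
plausible extracellular proteolysis, and the package's scope is the spatial
information carried by the gradient, not pheromone metabolism. Only the
*direction* of the gradient enters the simulation — `bias_direction()`
projects the direction from a site to the source onto the receiving cell's
tangent plane — so the absolute magnitudes of S and D are irrelevant to the
walk; the strength of chemotropic guidance is a separate dimensionless
parameter kappa. With several partners the summed gradient vectors (each
with magnitude $S/(4\pi D r^2)$) are projected and normalized, which
reduces to the single-partner direction when only one partner is present.

The `concentration()` formula is validated in the test suite against an
independent Monte-Carlo free-diffusion oracle: particle ages are sampled
uniformly over an emission horizon, positions after age $t$ are isotropic
Gaussians with variance $2Dt$ per axis, and radial binning of the standing
population reproduces the $1/r$ profile.

## The walk generator

Each cell carries one site confined to its spherical surface (radius 2.5 um
by default, a typical haploid cell). Per 2-minute frame the tangential step
direction is the renormalized mixture

```
persistence * previous direction + kappa * gradient direction
                                 + (1 - persistence) * isotropic noise
```

and the step arclength is a folded-normal draw. Motion uses the
exponential map (great-circle steps), so positions are on-sphere to
machine precision rather than reprojected chords. Design notes:

* **The mixture model is the simplest generator** able to produce both the
  "indecisive" wandering seen in unstimulated cells (kappa = 0) and
  gradient-following (kappa > 0). The literature does not quantify real
  step-length or persistence parameters for polarity-patch motion, so the
  defaults — step 0.5 +/- 0.25 um per 2-min frame, persistence 0.3 — are
  illustrative values in the range suggested by published patch
  trajectories; kappa is meant to be *recovered* from data (below), not
  asserted.
* **kappa = 0 is the genotype dial.** Receptorless (*ste2*/*ste3* deletion),
  Galpha-null (*gpa1*) and Far1-pathway-broken (*cdc24-m1*) cells all lack
  gradient decoding; in the model they are all `kappa = 0` / `sensing =
  FALSE`, which is why the package's three "signaling-dead" scenarios are
  statistically exchangeable by construction.
* **Commitment** is modeled as a full stop of both sites once a pair of
  *mutually sensing* cells comes within `commitment_distance` (1 um
  default). Requiring mutual sensing is a deliberate biological choice:
  unilateral mixes then produce only kiss-and-run encounters, matching the
  observation that a cell with no receptors has no way to know the sites
  are aligned. Partial slowdown is not modeled.
* **Randomness**: each cell consumes its own RNG substream whose seed is
  drawn sequentially from the master stream, so adding a cell to an arena
  does not perturb the other cells' draws. (An earlier arithmetic seed
  derivation produced detectably correlated Mersenne-Twister streams
  between the two cells of a pair — a reminder that substream seeds should
  be drawn, not computed.)

## Rendering synthetic movies

`render_movie()` emulates spinning-disk acquisition: 15 z-planes of 0.48 um
at 2-minute intervals, 0.16 um lateral pixels (100x/1.4-class sampling;
the true pixel pitch of any given microscope is configurable). Sites become
anisotropic 3D Gaussians (sigma 0.25 um lateral, 0.5 um axial, integrated
intensity 2000 counts by default) over a constant background; a brighter
fiducial bead is rendered in a corner lane of the field, clear of every
cell's tracking region; stage drift displaces everything; optional Poisson
shot noise plus Gaussian read noise completes the camera model. Movies
round-trip through 16-bit multi-page TIFFs with a YAML sidecar carrying
voxel geometry, so the tracking pipeline can equally be pointed at files
on disk.

The renderer does not model photobleaching, a realistic PSF beyond the
Gaussian, cell-shape change, or multiple polarity clusters per cell —
passing tests therefore demonstrate correctness of the pipeline's
geometry and statistics, not robustness to every artifact of real
microscopy.

## Tracking

`detect_sites()` thresholds each region of interest at a fraction (default
0.5) of its maximum intensity (Otsu's method is available), groups voxels
into 26-connected 3D components, discards components below 2 voxels (hot
pixels), and takes intensity-weighted centroids in physical microns.
Voxel (i, j, k) has its center at ((i-0.5)dx, (j-0.5)dy, (k-0.5)dz) from
the stack origin. Frames with zero or multiple candidates are excluded
with a recorded reason, never interpolated. Drift correction subtracts the
bead displacement relative to a reference frame; cell ROIs follow the
measured bead displacement so that drifting fields stay trackable. Tracks
of partner cells are truncated at the first frame where their corrected
centroids fall within 0.5 um (`track_until_overlap()`): below that
separation the two thresholded components merge and a joint blob centroid
would silently corrupt both tracks.

## The direction statistic theta

For each retained step, the tangent plane is fitted through the current
position and its nearest retained neighbors before and after (the actual
time span is recorded when excluded frames are bridged). The partner's
site, taken at the step-start frame (or the nearest retained frame within
one frame), is orthogonally projected onto the plane; the in-plane unit
vector from the current site to that projection is the *optimal*
direction, and theta is the angle between it and the in-plane projection
of the actual step. theta is 0 for a step straight at the partner, 180 for
a step straight away, and uniform on [0, 180] for an unbiased walk.
Numerical choices:

* a collinear triplet (cross product below 1e-9 of scale) falls back to
  the outward radial normal and is flagged; coincident points skip the
  step;
* a partner projecting onto the anchor itself (radially aligned) skips the
  step;
* the actual step is plane-projected before measuring the angle (a mixed
  3D-vs-in-plane angle would not be well defined); the raw-step variant is
  available behind `project_step = FALSE`;
* steps at or after the pair's first encounter are dropped — once the
  sites have met, "direction toward the partner" is no longer meaningful;
* the distance gate (default 4 um, applied to the 3D inter-site distance
  at the step start) restricts the statistic to the regime where guidance
  operates.

One estimator property deserves emphasis: fitted from three points on a
sphere, the plane is a *secant* plane that tilts slightly along the chord
of motion. This leaks a fraction of the partner's radial component into
alignment with the step and gives the ungated estimator a small positive
bias in cos(theta) that grows with step length (about +0.03 at the default
step length for an unbiased walk). Within the 4 um gate the geometry
suppresses the effect to below detectability at realistic sample sizes.
The package's null-calibration test therefore mirrors the gated protocol;
analyses of ungated angles should interpret small mean biases accordingly.

## Recovering kappa

Because kappa has no direct experimental counterpart, `calibrate_kappa()`
builds a simulation calibration curve mapping kappa to the mean of
cos(theta) over a grid (0 to 4 by 0.25, 3000 pooled steps per point,
commitment off so the walk never freezes), enforces monotonicity, and
interpolates with a monotone (Hyman) spline; `estimate_kappa()` inverts
the curve at an observed mean cos(theta). The curve saturates above kappa
of roughly 2.5 — mean cos(theta) approaches its ceiling — so recovered
values near the top of the grid should be read as "at least". The
acceptance suite demonstrates recovery within 25 percent for kappa in
{0.5, 1, 2} from 300 observed steps.

## Encounters, outcomes, strata

The distance series of a partner pair (3D centroid distance by default;
the image-space alternative — maximum projection, a 10-pixel-wide averaged
line scan through both sites, distance between the two most prominent
profile peaks — is provided for validation against the visual protocol)
is scanned for *maximal runs* below 1 um; each run is one encounter, and
the time to encounter is (start frame - 1) x 2 min from the start of the
movie (mixing). Peak detection uses topographic prominence of at least 20
percent of the profile's dynamic range, an explicit stand-in for the
by-eye peak calls of interactive analysis; a profile with a single
qualifying peak means the sites are unresolvable and is flagged "merged".

An encounter is classified *commitment* if the pair stays below 1 um for
at least K = 5 consecutive frames (10 min) or through the end of the
movie, *kiss-and-run* otherwise, and *censored* if it starts on the final
frame. K is a package choice — no duration criterion exists in the
literature — and is exposed as a parameter. Encounter times are stratified
by the number of touching opposite-type partners (1, 2, more than 2);
pairs that never meet contribute right-censored observations at the movie
end and are reported, not dropped.

## KS testing

`ks_two_sample()` evaluates D at the pooled unique sample values (which
handles ties), computes the p-value exactly for pooled sizes up to 16 by
lattice-path counting over tie blocks in integer arithmetic — the same
distribution that explicit enumeration of all C(n1+n2, n1) splits yields,
verified against such an enumeration in the tests — and otherwise uses
the asymptotic Kolmogorov tail at sqrt(ne) D with ne = n1 n2/(n1+n2). At
the exact/asymptotic boundary (n1 = n2 = 8) the two disagree by at most
about 0.03-0.05 because the exact distribution is discrete there; the
null rejection rate of the asymptotic branch at alpha = 0.05, n = 50 per
sample, sits near 0.04. No multiple-testing correction is applied
anywhere; p-values are reported raw, as is conventional for these
figure-level comparisons.

## Problem sizes and reproducibility

The shipped experiments are sized to run comfortably on a single CPU:
direction-bias batches pool 10-20 pairs of 100-150 frames; the null
calibration uses 100 runs of 296 gated steps pooled from about ten pairs
each; encounter-scenario comparisons use 20 pairs per scenario at 120
frames; rendered-movie round-trips use 12-frame movies of an isolated
pair. Every simulation seed derives deterministically from a single master
seed, the report embeds that seed plus a hash of the configuration, and
rerunning any entry point with the same seed reproduces its numbers
exactly.

## Known limitations

* Cells are rigid, non-growing spheres; real mating cells polarize their
  shape toward the partner.
* The motion model has a single persistence scale and no waiting states;
  real patches intermittently vanish and reappear.
* The gradient is quasi-static (recomputed from current positions each
  frame); finite diffusion time and receptor binding kinetics are not
  modeled.
* Commitment is all-or-none and deterministic at the trigger distance.
* The renderer's Gaussian PSF and constant background are idealized.

These are scope boundaries, not accidents: the package quantifies the
search statistics of the guidance model, and each limitation marks a seam
where a more detailed biophysical model could be plugged in without
changing the analysis surface.
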