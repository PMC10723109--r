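---
title: "Modeling a CZT Compton-enhanced PET prototype: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a CZT Compton-enhanced PET prototype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cztpet` models a small-animal PET prototype built from four panels of
3-D position-sensitive cadmium zinc telluride (CZT) detectors, each panel
a 2 x 2 array of 2.2 x 2.2 x 1.0 cm crystals with 11 x 11 anode pixels of
1.9 mm pitch, opposite front faces 80 mm apart. Such detectors resolve
individual gamma-ray interactions in 3-D with ~0.5 mm FWHM and ~1% energy
resolution at 511 keV, which makes two things possible that conventional
scintillator PET cannot do: depth-of-interaction (DOI) binning of the
coincidence response, and Compton-kinematic screening of coincidences —
when one annihilation photon scatters once and is then photoabsorbed, the
two measured energies and positions constrain the photon's incoming
direction to a cone, and a coincidence whose partner photon is
inconsistent with every admissible cone is very likely a random (or
in-object-scattered) pairing.

This vignette records the models implemented, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data tests
do and do not demonstrate.

## Photon interaction physics

Attenuation coefficients for Cd~0.9~Zn~0.1~Te (density 5.9 g/cm^3^,
molecular density 1.51e22 cm^-3^) are tabulated on a 50–1500 keV grid in
`inst/extdata/czt_attenuation.tsv` and interpolated log-log by
`cross_sections()`. The incoherent component is Klein–Nishina theory with
a smooth incoherent-scattering-function correction; photoelectric and
coherent components are log-log parametric fits anchored to published CZT
values. At 511 keV the table gives a total of 0.504 cm^-1^ with an 83%
incoherent share — the two facts that drive everything downstream: a
511 keV photon crossing 1 cm of CZT interacts with probability ~0.39, and
five of six interactions begin with a Compton scatter.

Monte-Carlo transport (`transport_photon()`, and the batch engine behind
the simulators) samples exponential free paths with the interaction
coefficient (photoelectric + incoherent). Coherent scattering is excluded
from transport: it is ~2% of the total at 511 keV, deposits no energy,
and deflects by small angles; `cross_sections()` still reports it. The
same interaction coefficient is used in the analytic response model so
that model and simulator describe the same physics — using the full
attenuation coefficient there would make the analytic model overstate
detection by the coherent share. Compton chains are followed until
photoelectric absorption, escape from the crystal, or a five-site cap
(at which point the remainder is deposited locally, so absorbed histories
conserve energy exactly). Scattered photons below the 50 keV table floor
are absorbed on the spot (their range in CZT is below 0.2 mm), and
scattered photons that leave their panel are not followed into other
panels — cross-panel single-photon coincidences are rare and would
complicate the event model for little realism gain.

### Doppler broadening

At fixed scattering angle the deposited energy is broadened by the bound
electron's momentum. The sampler implements the impulse approximation: a
momentum component `p_z` is drawn and the scattered energy solved from
the Compton relation for a moving electron (four Newton iterations from
the static line). Without offline Hartree–Fock Compton-profile tables we
use a five-component Gaussian mixture, one component per shell group of
the average Z ≈ 49 constituent, with electron-share weights and widths
`sigma = Z_eff / (n sqrt(3))` atomic units from Slater-screened
hydrogenic shells (`czt_compton_profile()`). The narrow valence
components reproduce the few-keV core Doppler width at 511 keV / 90°
(~2° angular); the L- and K-shell components supply the heavy tails that
measured Compton profiles show and that matter for the rejection
statistics below (the tail mass is exactly what falls under the rejection
threshold). This is the package's main approximation to the interaction
physics: tabulated profiles would change the tail weights at the tens of
percent level, which propagates to a few points of the false-rejection
probability.

## Detector response

`detector_model()` carries the measured resolution anchors — 3 keV FWHM
at 200 keV, 4.5 at 450, 5.4 at 511, interpolated monotonically, with
square-root scaling outside the anchored range — an isotropic 0.5 mm FWHM
position blur, and a 50 keV per-site trigger threshold. The threshold is
not part of the published detector description but is essential to
reproduce the observed event statistics: Klein–Nishina scattering at
511 keV is strongly forward-peaked, so a large fraction of first
interactions deposit a few tens of keV, which a real pixel readout does
not register as a separate site. 50 keV is a typical anode trigger level
for this detector class; with it, the simulated single/double/triple
site shares after pixel merging land near the measured 80/18/2 split.

`apply_detector_model()` merges true sites sharing an anode pixel
(energy-weighted centroid, summed energy) *before* blurring, drops
sub-threshold merged sites, then applies independent Gaussian energy and
position blur. Blurred positions are clamped into the crystal volume;
events whose detector-voxel index lands on the grid edge are therefore
slightly biased, which is why the calibration likelihood excludes
edge-voxel events (below).

## Analytic coincidence response and sensitivity

The probability that a coincidence is detected in a given pair of
detector voxels on opposite panels is the sublayer-pair sum of (solid
angle x attenuation x interaction probability) for the first photon times
a conditional term for the second, whose geometric factor is the overlap
between the first sublayer slice back-projected through the source and
the second voxel's slice. `p_coincidence()` computes the overlap by exact
convex-polygon clipping (a small C++ kernel); the back-projection follows
the published construction, including its normalization by the target
slice area rather than the projected area.

`sensitivity_map()` sums this model over all detector-voxel pairs, each
unordered pair counted once, on a configurable depth discretization
(`D` sublayers across the 1 cm thickness; `D = 10` is the reference).
Two numerical choices matter:

* the lateral sum is aggregated per back-projection plane (overlap with
  the whole opposite-panel active area rather than voxel by voxel), with
  the attenuation factor evaluated at the projection centre; on a smooth
  integrand this matches the literal pair sum to better than 2% (tested),
  at ~1000x less work;
* the lateral integration covers the full 22 mm crystal width, not just
  the 20.9 mm anode footprint — interactions in the margin are collected
  by edge pixels, and only with the full width does the analytic model
  agree with the Monte-Carlo coincidence fraction (the map equals half
  the physical MC coincidence probability, since the map counts each
  voxel pair once).

At `D = 10` the nominal geometry gives a peak of ~1.93% at the centre of
the field of view, converging to ~2.0% as `D` grows; the printed value
for the prototype is ~2.2%. The residual discrepancy is not explained by
any convention we could vary without breaking the model-vs-MC agreement,
and we report the model's own number rather than tune toward the printed
one. An optional full-energy window acceptance (estimated once per
geometry by Monte Carlo) converts the interaction sensitivity into an
in-window detected-coincidence sensitivity for reconstruction use.

## Near-field Compton response matrix

`build_response_matrix()` fires a normal pencil beam into an idealized
4 x 4 x 1 cm slab and keeps histories with exactly one Compton scatter
followed by photoelectric absorption (full energy). True sites are
blurred by the detector model; no pixel merge is applied, so the matrix
covers sub-pitch inter-interaction distances; the trigger threshold is
applied, matching the events the selector sees downstream. Each kept
event contributes its observed (first-site energy, geometric scattering
angle, inter-interaction distance) triple to a sparse 3-D histogram
normalized to unit mass; distances beyond 20 mm pool in an overflow bin
that participates in the normalization but not in angular fits. The
first-site energy is assigned at the *true* first interaction — the
matrix encodes the forward response; sequence ambiguity is handled
downstream by evaluating both orderings.

The reference bin widths are 1/3 keV x 1/3° x 0.25 mm. They are,
however, only meaningful with ~10^9^ events: the package's desk-scale
default is 10^7^ histories (~7.5e5 kept events), and the estimate of the
below-threshold slice mass is biased low whenever the occupied
(energy, distance) slices are statistically starved. We therefore use
2 keV x 2° x 2 mm for the headline false-rejection numbers, the
coarsest setting that still resolves the angular structure (the core
angular width is >2.5° everywhere); at these bins the estimate is stable
from 1e7 to 2e7 histories. Finer bins at desk scale *look* better for
rejection — slice maxima become noisy, bands collapse to single bins and
the rejection rate soars — but the same noise collapses the model
false-rejection probability to a few percent; we treat that regime as an
artifact and do not use it.

`angular_uncertainty_map()` fits a Gaussian to each slice's angle
distribution (moment start, nonlinear refinement; slices under 50 events
flagged invalid, never extrapolated). The map shows the defining
near-field feature: at 90° the angular FWHM falls from tens of degrees
at 2 mm inter-interaction distance to under 10° beyond 8 mm — which is
why marginalizing the distance axis (`marginalize_d2()`) costs real
discrimination.

## Sequencing, rejection and the NECR threshold

For a coincidence with a two-site photon, `sequence_probabilities()`
evaluates both candidate orderings: each fixes the energy and distance
bins, takes the line from the opposite photon (its site, or its
energy-weighted centroid if it has several) through the assumed first
site as the incoming direction, reads the matrix at the implied angle and
normalizes by the slice maximum. `reject_events()` accepts an event when
any (side, ordering) candidate reaches the threshold; single-single
events pass untouched. Events with Compton photons on both sides are
evaluated side by side and rejected only if every candidate fails.
A "cathode-nearest" fallback ordering (first interaction = site closer to
the cathode) is available for reconstruction without Compton processing.

The false-rejection probability of true Compton events is computed
directly from the matrix: per slice, the mass in angle bins below
threshold x slice maximum, combined across slices by their mass share.
The NECR gain of rejection is `(1 - false rejection)^2 / (1 - rejection
rate)`; `optimize_threshold()` scans thresholds at 0.01 resolution with
the empirical rejection rate of the supplied Compton-containing stream
(that stream, not the full dataset, is the denominator — the share of
Compton-containing events in the prototype's accounting indicates this
convention) and the model false-rejection probability.

On a clean simulated mixture of true and random coincidences with the
known-random share matched to the prototype's accounting (~half the
in-window Compton stream), the gain curve is nearly flat with an optimum
of ~1.0–1.3 depending on binning: the simulated randoms are too easily
accepted at the broad small-distance slices for rejection to pay off
strongly. The prototype's reported optimum (~1.85 at threshold 0.2)
implies that ~64% of its Compton stream was rejectable at 18% true loss —
a stream dominated by noise beyond pure randoms (in-object scatter,
pileup combinations), which this package deliberately does not simulate
(phantoms are ≤1.4 cm of water-equivalent material; self-attenuation and
scatter are off by default). The package reports the curve its own
stream produces.

## Simulation and list-mode data

`simulate_coincidences()` emits back-to-back photon pairs from a
voxelized phantom (isotropic, perfectly collinear — positron range and
acollinearity are not modeled at this FOV scale), transports them,
applies the detector model, timestamps detected photons with 100 ns FWHM
Gaussian jitter, and pairs singles by time clustering within a ±250 ns
window: clusters of two on opposite panels become events (same-decay =
true, different-decay = random), larger clusters are discarded as
pileup. Acquisitions rotate the object over angle-step subsets, with
isotope decay (Cu-64 12.7 h, Na-22 2.6 y) thinning later subsets; the
decay-adjusted subset sensitivities follow the per-subset counts.

Because random coincidence rates scale with activity squared while
pileup losses explode at the same time, composition-controlled studies
use `simulate_photon_pool()` plus `coincidence_stream()`: true pairs are
formed from same-decay photons and randoms by re-pairing photons from
different decays (the delayed-window idiom), at an explicit
randoms-per-true ratio. This is how the rejection studies set the
known-random share to the published accounting.

List-mode datasets are wide per-event tables (per side: site count, up
to two observed sites, summed energy, centroid, panel/module ids) with a
versioned header (format version, units, seed, geometry hash,
acquisition settings); the simulation ground truth (emission point,
true/random label, true site order) is a separable block so
experimental-style files round-trip without it. Files use R's
serialization; a CSV export is provided.

## Reconstruction

`osem_reconstruct()` is list-mode OS-EM over angle subsets. System-matrix
rows are evaluated on the fly from the analytic response model at the
configured DOI binning (one sublayer per DOI bin), with a
tube-of-response cutoff at 3 voxel sizes from the LOR axis — dense
evaluation per event is intractable and contributions beyond the tube
are negligible against the solid-angle factors. Sensitivity is evaluated
on a coarse lattice (2.5 mm default) and interpolated trilinearly;
voxels with zero sensitivity stay zero; iterates are non-negative by
construction, and the subset update makes the sensitivity-weighted total
intensity exactly equal to the subset event count, so total intensity is
conserved across iterations. Two-site photons are positioned by the
kinematics-predicted first site, the energy-weighted centroid, or the
cathode-nearest site, so the published dataset-processing variants are
all expressible. A 0.40 mm FWHM Gaussian post-filter (edge-renormalized,
intensity-preserving) and the standard metrics (Gaussian-fit profile
FWHM, peak-to-valley ratio, activity-weighted normalized SD over ROIs)
complete the chain.

Iteration counts for cross-dataset comparisons are chosen by matching
noise (normalized SD) or resolution rather than hard-coding counts,
since they depend on the realized data.

## Geometry calibration

The pose state is a 130-entry vector: 6 pose parameters per panel, 6 per
module within its panel, 7 for the rotation stage, 3 for the vertical
stage. `calibrate_geometry()` maximizes the list-mode likelihood of
full-energy single-site coincidences from a known 0.25 mm point source
(a uniform sphere integrated by 8-point cube quadrature) over a masked
parameter subset — by default one panel's six pose parameters; the
likelihood supports all 130, but global optimization of the full vector
is an experiment-scale task and out of scope. Three numerical choices
were decisive, and all are deliberate:

* the second-photon overlap is convolved with the position blur
  (closed-form integrated-Gaussian overlap, separable per axis — valid
  for the sub-degree rotations targeted). The observed voxel is itself a
  blurred observation; without the convolution the likelihood is
  corrugated at the 0.2 mm voxel scale and every local optimizer stalls
  in a grid groove;
* edge detector voxels are excluded: clamping blurred positions at the
  crystal boundary biases them inward, and since pose rotations have
  maximal leverage at panel edges, keeping those events biases the
  recovered rotations by ~0.1–0.2°;
* Nelder–Mead with fresh-simplex restarts (up to five, until the
  improvement drops below 0.25 nats) — the surface is smooth after the
  convolution but strongly anisotropic across translations and
  rotations.

With 24 projections (8 angles x 3 axial positions) and a few thousand
events, a panel pose perturbed by up to 1 mm / 1° is recovered to better
than 0.1 mm / 0.1° (tested at ~0.03 typical error).

## Phantoms

`make_phantom()` rasterizes analytic phantom definitions with 4 x 4
in-plane supersampling and normalizes to the specified activity: a
0.25 mm point source; two 0.65 mm capillary line sources; the hot-rod
resolution phantom (four sectors of 0.35/0.5/0.75/1.0 mm rods at
0.7/1.0/1.5/1.6 mm pitches, triangular lattice, inside a 14 mm x 10 mm
cylinder); a 70%-scaled NU-4-style image-quality phantom (rods
0.50/0.80/1.10/1.50/1.80 mm at 4.9 mm radius under a uniform chamber);
and a uniform cylinder. Rasterization requires the voxel to be at most
half the smallest feature and converges to better than 1% in sector
activity when the voxel is halved.

## What the synthetic tests do and do not show

The generator reproduces the geometry, interaction physics, resolution
blurs, pixel merging, trigger threshold, timing jitter and decay of the
prototype — so tests against it validate the *model chain*: the analytic
response against the transport MC, the rejection formulas against direct
event processing, OS-EM against a dense MLEM oracle, calibration against
known perturbations, and the orderings (DOI binning sharpens off-centre
sources; at matched counts, clean singles localize a point source better
than kinematics-sequenced Compton events, which beat centroid-positioned
ones). It
does not reproduce in-object scatter, charge-induction physics, sub-pixel
position decoding, depth-dependent trigger delay, or detector dead time;
quantities dominated by the experimental noise composition (the absolute
NECR gain above all) or by sub-0.5 mm experimental resolution effects are
reproduced in ordering but not in absolute value, and the package reports
its own computed values in those cases.

Desk-scale problem sizes used throughout: 10^6^–10^7^ Monte-Carlo
histories, 10^5^–10^6^ simulated decays per study, response matrices at
2 keV / 2° / 2 mm bins, reconstructions on ~30–50 voxel grids — each
chosen as the smallest size at which the corresponding statistical
assertion is stable, and stated alongside the numbers they produce.
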