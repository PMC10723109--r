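# cztpet

Simulation, Compton-kinematics event processing and list-mode OS-EM
reconstruction for a four-panel CZT Compton-enhanced PET prototype.

3-D position-sensitive cadmium zinc telluride (CZT) detectors resolve
individual gamma-ray interactions with ~0.5 mm and ~1% (at 511 keV)
position and energy resolution. In a PET geometry this enables two things
scintillator systems cannot do: depth-of-interaction (DOI) binning of the
coincidence response, and **Compton-kinematic screening of coincidences**.
When an annihilation photon Compton-scatters once and is then
photoabsorbed, the observed first-interaction energy E&#x302;₁, scattering
angle θ&#x302; and inter-interaction distance d&#x302;₂ constrain the photon's
incoming direction; a coincidence whose partner photon is inconsistent
with every admissible interaction ordering is, with high probability, a
random pairing and can be rejected.

The package implements the full model chain for such a system on purely
synthetic data:

* **Physics / Monte Carlo** — tabulated CZT attenuation
  (`cross_sections()`), Klein–Nishina sampling with impulse-approximation
  Doppler broadening (`sample_compton()`), photon transport through the
  four-panel geometry (`transport_photon()`), anode-pixel merging with
  trigger threshold and Gaussian blurs (`apply_detector_model()`).
* **Analytic system model** — the coincidence-response probability
  p(A|i) over detector-voxel sublayer pairs, with back-projected slice
  overlap by exact polygon clipping (`p_coincidence()`), and the system
  sensitivity map (`sensitivity_map()`).
* **Near-field Compton response** — the 3-D histogram F over
  (E&#x302;₁, θ&#x302;, d&#x302;₂) from pencil-beam simulation
  (`build_response_matrix()`), angular-uncertainty maps and the
  conventional distance-marginalized variant.
* **Sequencing and rejection** — relative ordering probabilities
  normalized by the slice maximum (`sequence_probabilities()`),
  threshold rejection (`reject_events()`), the slice-mass
  false-rejection probability, and NECR′/NECR threshold optimization
  (`optimize_threshold()`), where NECR′/NECR =
  (1 − false rejection rate)² / (1 − rejection rate).
* **Calibration** — maximum-likelihood recovery of panel poses from a
  rotating point source over the 130-parameter geometry vector
  (`calibrate_geometry()`).
* **Reconstruction** — list-mode OS-EM with on-the-fly system-matrix
  rows at configurable DOI binning, decay-adjusted subset sensitivities,
  Gaussian post-filter and image-quality metrics
  (`osem_reconstruct()`, `profile_fwhm()`, `peak_to_valley()`,
  `normalized_sd()`).
* **Phantoms and list-mode I/O** — point/line/hot-rod/NU-4-style/uniform
  phantoms (`make_phantom()`), the coincidence simulator
  (`simulate_coincidences()`, `simulate_photon_pool()` +
  `coincidence_stream()`), versioned list-mode files
  (`write_listmode()`), and a thin CLI
  (`inst/cli/cztpet.R`, subcommands `simulate`, `build-response`,
  `reject`, `reconstruct`, `metrics`, `demo`).

## A worked example

Simulate a point source, build the response matrix, screen the stream,
and reconstruct:

```r
library(cztpet)
set.seed(1)

geom <- system_geometry()                      # nominal 4-panel setup
ph   <- make_phantom(phantom_spec("point", activity = 1e5,
                                  center = c(3, 1, 0)), voxel_size = 0.1)
pool <- simulate_photon_pool(ph, geom, 5e5, n_subsets = 3)
lm   <- coincidence_stream(pool, geom, randoms_per_true = 1)

F    <- build_response_matrix(2e6, bins = c(2, 2, 2))
ev   <- events_wide(lm)
dec  <- reject_events(ev, F, threshold = 0.2)
mean(dec$accepted[ev$label == "true"])         # 0.905 trues kept
mean(dec$accepted[ev$label == "random"])       # 0.845 randoms kept

false_rejection_probability(F, 0.2)            # 0.149 model false rejection

inw <- ev$a_esum >= 500 & ev$a_esum <= 540 &
       ev$b_esum >= 500 & ev$b_esum <= 540
lm$events <- ev[inw & ev$a_n == 1 & ev$b_n == 1, ]
cfg <- recon_config(doi_bin_size = 1, voxel_size = 0.25,
                    dims = c(49, 49, 25), iterations = 3,
                    positioning = "first_site")
rec <- osem_reconstruct(lm, geom, cfg)
rec$total_intensity                            # constant across iterations
```

The rejection numbers above say: at the 0.2 threshold the screening keeps
90.5% of true coincidences in this stream (single-site events pass
untouched; the matrix-level false-rejection probability for true Compton
events is 14.9%) while randoms are kept at a visibly lower rate — the
discrimination that the NECR′/NECR scan in `optimize_threshold()` turns
into a threshold choice. The total reconstructed intensity is constant
across iterations (886.7 for this stream), and the peak analytic
sensitivity of the nominal geometry is 1.93% at the centre of the field
of view (`sensitivity_map(geom, rbind(c(0,0,0)), D = 10)`), consistent
with the transport Monte Carlo within counting error.

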