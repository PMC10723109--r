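# Shared fixtures, built once per test run. Sizes are desk-scale: large
# enough for the statistical assertions, small enough to keep the suite
# fast. Everything is generated in code under fixed seeds.

fx <- new.env()

fx_geom <- function() {
  if (is.null(fx$geom)) fx$geom <- system_geometry()
  fx$geom
}

# blur-free detector model (no position/energy blur, no threshold)
fx_model0 <- function() {
  detector_model(position_fwhm = 0, threshold = 0,
                 energy_anchors = data.frame(energy = c(200, 450, 511),
                                             fwhm = c(0, 0, 0)))
}

# default-blur Compton response matrix, coarse bins
fx_F <- function() {
  if (is.null(fx$F)) {
    set.seed(1001)
    fx$F <- build_response_matrix(2e6, model = detector_model(),
                                  bins = c(2, 2, 2))
  }
  fx$F
}

# blur-free, Doppler-free response matrix. Bin widths are kinematically
# matched (a 1 keV energy bin maps inside a 3-degree angle bin over most
# of the Compton line), so the blur-free matrix is near-diagonal in
# (energy bin -> angle bin).
fx_F0 <- function() {
  if (is.null(fx$F0)) {
    set.seed(1002)
    fx$F0 <- build_response_matrix(1.5e6, model = fx_model0(),
                                   bins = c(1, 3, 1), doppler = FALSE)
  }
  fx$F0
}

# hot-rod photon pool and a mixed true+random coincidence stream
fx_stream <- function() {
  if (is.null(fx$stream)) {
    set.seed(1003)
    ph <- make_phantom(phantom_spec("hot_rod", activity = 1e6),
                       voxel_size = 0.125)
    pool <- simulate_photon_pool(ph, fx_geom(), 6e5, chunk = 2e5)
    lm <- coincidence_stream(pool, fx_geom(), randoms_per_true = 3)
    ev <- events_wide(lm)
    inw <- ev$a_esum >= 500 & ev$a_esum <= 540 &
      ev$b_esum >= 500 & ev$b_esum <= 540
    fx$stream <- ev[inw & (ev$a_n == 2L | ev$b_n == 2L), ]
  }
  fx$stream
}

# point-source acquisition for reconstruction tests
fx_point_lm <- function() {
  if (is.null(fx$point_lm)) {
    set.seed(1004)
    ph <- make_phantom(phantom_spec("point", activity = 1e5,
                                    center = c(3, 1, 0)), voxel_size = 0.1)
    pool <- simulate_photon_pool(ph, fx_geom(), 5e5, n_subsets = 3)
    lm <- coincidence_stream(pool, fx_geom())
    ev <- events_wide(lm)
    keep <- ev$a_n == 1L & ev$b_n == 1L &
      ev$a_esum >= 500 & ev$a_esum <= 540 &
      ev$b_esum >= 500 & ev$b_esum <= 540
    lm$events <- ev[keep, ]
    fx$point_lm <- lm
  }
  fx$point_lm
}

# draw observation triples from a response matrix (multinomial over cells)
fx_draw_from_F <- function(F, n) {
  tr <- methods::as(F$counts, "TsparseMatrix")
  pick <- sample.int(length(tr@x), n, replace = TRUE, prob = tr@x)
  list(j = tr@i[pick] + 1L, s = tr@j[pick] + 1L, value = tr@x[pick])
}
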