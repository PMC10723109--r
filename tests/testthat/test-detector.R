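test_that("energy resolution curve reproduces its anchors monotonically", {
  m <- detector_model()
  expect_equal(m$energy_fwhm(200), 3)
  expect_equal(m$energy_fwhm(450), 4.5)
  expect_equal(m$energy_fwhm(511), 5.4)
  e <- seq(100, 600, by = 5)
  expect_true(all(diff(m$energy_fwhm(e)) >= 0))
})

test_that("sites in one anode pixel merge to an energy-weighted centroid", {
  m0 <- fx_model0()
  sites <- data.frame(x = c(0.10, 0.40), y = c(0.2, 0.2),
                      z = c(2, 5), energy = c(100, 300), site = 1:2)
  obs <- apply_detector_model(sites, m0)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$energy, 400)
  expect_equal(obs$x, (0.1 * 100 + 0.4 * 300) / 400)
  expect_equal(obs$n_merged, 2L)
  # sites in different pixels stay separate
  sites2 <- data.frame(x = c(-3, 3), y = c(0, 0), z = c(2, 5),
                       energy = c(100, 300), site = 1:2)
  expect_equal(nrow(apply_detector_model(sites2, m0)), 2L)
})

test_that("merging is idempotent and order-independent", {
  m0 <- fx_model0()
  set.seed(74)
  sites <- data.frame(x = runif(6, -8, 8), y = runif(6, -8, 8),
                      z = runif(6, 0, 10), energy = runif(6, 60, 200),
                      site = 1:6)
  a <- apply_detector_model(sites, m0)
  b <- apply_detector_model(sites[sample(6), ], m0)
  expect_equal(a[order(a$x), c("x", "y", "z", "energy")],
               b[order(b$x), c("x", "y", "z", "energy")],
               tolerance = 1e-12, ignore_attr = TRUE)
  # re-observing merged sites changes nothing
  a2 <- apply_detector_model(
    data.frame(x = a$x, y = a$y, z = a$z, energy = a$energy, site = a$site), m0)
  expect_equal(sort(a2$energy), sort(a$energy))
})

test_that("zero-blur observation is the identity on a single site", {
  m0 <- fx_model0()
  s <- data.frame(x = 1.23, y = -4.56, z = 7.89, energy = 321, site = 1)
  obs <- apply_detector_model(s, m0)
  expect_equal(obs$x, 1.23); expect_equal(obs$energy, 321)
})

test_that("sub-threshold merged sites are dropped", {
  m <- detector_model()   # 50 keV threshold
  s <- data.frame(x = c(-3, 3), y = c(0, 0), z = c(1, 2),
                  energy = c(30, 481), site = 1:2)
  set.seed(75)
  obs <- apply_detector_model(s, m)
  expect_equal(nrow(obs), 1L)
  expect_error(apply_detector_model(s[0, ], m), "empty")
})

test_that("broad-beam single-site fraction is near the measured 80%", {
  set.seed(76)
  n <- 2e5
  o <- cbind(runif(n, -11, 11), runif(n, -11, 11), rep(-1, n))
  d <- cbind(0, 0, rep(1, n))
  s <- cztpet:::transport_in_box(o, d, 511, 11, 11, 10)
  s$pid <- s$id
  obs <- cztpet:::observe_photon_sites(s, detector_model())
  frac <- as.vector(table(table(obs$pid)))
  frac <- frac / sum(frac)
  expect_gt(frac[1], 0.70)
  expect_lt(frac[1], 0.88)
  expect_gt(frac[2], 0.10)   # double-site share
})
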