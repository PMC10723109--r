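test_that("first-photon term follows the inverse-square law", {
  g <- fx_geom()
  # two sources on the voxel normal, distances in ratio 2 (66.25 too far:
  # keep both inside the FOV side of the panel)
  ctr <- cztpet:::voxel_center_local(g, 50, 50, 1, 10)
  f <- g$frames$modules[[1]]
  cglob <- as.vector(f$o + f$R %*% ctr[1, ])
  nrm <- f$R[, 3]
  s1 <- cglob - 20 * nrm
  s2 <- cglob - 40 * nrm
  p1 <- p_first_photon(g, s1, 1, 50, 50, 1, 10)
  p2 <- p_first_photon(g, s2, 1, 50, 50, 1, 10)
  expect_equal(p1 / p2, 4, tolerance = 1e-6)
  expect_gt(p1, 0); expect_lt(p1, 1)
  # a source behind the anode cannot be seen through the cathode face
  expect_equal(p_first_photon(g, cglob + 20 * nrm, 1, 50, 50, 1, 10), 0)
})

test_that("first-photon term matches a Monte-Carlo estimate", {
  set.seed(91)
  g <- system_geometry(lateral_voxels = 10)   # 2.09 mm voxels for MC yield
  p_model <- sum(vapply(1:10, function(n)
    p_first_photon(g, c(0, 0, 0), 1, 5, 5, n, 10), 0))
  n <- 2e6
  d <- random_directions(n)
  s <- cztpet:::transport_photons(g, matrix(0, n, 3), d, doppler = FALSE)
  first <- s[s$site == 1L & s$module == 1L, ]
  vi <- detector_voxel_index(g, first$mx, first$my, first$mz, 1)
  hits <- sum(vi$u == 5 & vi$v == 5)
  p_mc <- hits / n
  expect_lt(abs(p_mc - p_model), 3 * sqrt(p_mc / n) + 1e-7)
})

test_that("coincidence probability refines with sublayer count", {
  g <- fx_geom()
  I1 <- list(module = 1, u = 50, v = 50)
  I2 <- list(module = 11, u = 50, v = 51)
  p <- vapply(c(1, 2, 10, 20), function(D)
    p_coincidence(g, c(0, 0, 0), I1, I2, D = D), 0)
  expect_true(all(p > 0 & p < 1))
  expect_lt(abs(p[3] - p[4]), abs(p[1] - p[4]))
  expect_error(p_coincidence(g, c(0, 0, 0), I1,
                             list(module = 2, u = 1, v = 1)), "opposite")
})

test_that("off-line sources give zero coincidence probability", {
  g <- fx_geom()
  I1 <- list(module = 1, u = 50, v = 50)
  I2 <- list(module = 11, u = 50, v = 51)
  expect_equal(p_coincidence(g, c(0, 18, 0), I1, I2, D = 2), 0)
})

test_that("pair-summed coincidence model equals the sensitivity sum", {
  g <- system_geometry(lateral_voxels = 6)
  src <- c(0.4, -0.3, 0.2)
  # literal sum over all voxel pairs of one opposite panel pair, D = 1
  total <- 0
  for (m1 in 1:4) for (m2 in 9:12) for (u1 in 1:6) for (v1 in 1:6) {
    for (u2 in 1:6) for (v2 in 1:6) {
      total <- total + p_coincidence(g, src, list(module = m1, u = u1, v = v1),
                                     list(module = m2, u = u2, v = v2), D = 1)
    }
  }
  agg <- cztpet:::.sens_pair(g, src, axis = 1, sgn = 1, D = 1, step = 1,
                             extent = 20.9) +
    cztpet:::.sens_pair(g, src, axis = 1, sgn = -1, D = 1, step = 1,
                        extent = 20.9)
  expect_equal(total, agg, tolerance = 0.02)
})

test_that("sensitivity peaks at the centre and respects 90-degree symmetry", {
  g <- fx_geom()
  pts <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(-6, 0, 0), c(0, -6, 0),
               c(0, 0, 100))
  s <- sensitivity_map(g, pts, D = 4, lateral_step = 5)
  expect_true(all(s[1] >= s[2:5]))
  expect_equal(s[2], s[3], tolerance = 1e-6)
  expect_equal(s[2], s[4], tolerance = 1e-6)
  expect_equal(s[6], 0)
})
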