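test_that("response matrix is a normalized histogram with configured bins", {
  F <- fx_F()
  expect_s3_class(F, "compton_response")
  expect_equal(sum(F$counts) / F$N, 1)
  expect_equal(c(F$de, F$dth, F$dd2), c(2, 2, 2))
  expect_true(all(F$counts@x >= 0))
  expect_gt(F$N, 1e5)
})

test_that("blur-free matrix concentrates on the kinematic line", {
  F0 <- fx_F0()
  tr <- methods::as(F0$counts, "TsparseMatrix")
  ib <- tr@j %% F0$nE          # energy bin (0-based) of each occupied cell
  jb <- tr@i                   # angle bin (0-based)
  e_mid <- (ib + 0.5) * F0$de
  edge <- compton_deposit(511, pi)
  th_kin <- kinematic_angle(pmin(e_mid, edge - 1e-6), 511)
  th_cell <- (jb + 0.5) * F0$dth
  # within-bin kinematic slack: angle change across the energy bin
  dth_de <- abs(kinematic_angle(pmin(e_mid + F0$de / 2, edge - 1e-6), 511) -
                  kinematic_angle(pmax(e_mid - F0$de / 2, 1e-3), 511))
  tol <- F0$dth + dth_de
  expect_true(all(abs(th_cell - th_kin) <= tol + 1e-9))
  # every occupied energy bin maps to a narrow band of angle bins
  span <- tapply(jb, ib, function(x) diff(range(x)))
  expect_lte(median(span), 1)
  expect_true(all(span <= 3))
})

test_that("inter-interaction distances show an attenuation-limited tail", {
  F <- fx_F()
  tr <- methods::as(F$counts, "TsparseMatrix")
  k <- tr@j %/% F$nE           # distance bin (0-based, last = overflow)
  mass <- tapply(tr@x, k, sum) / F$N
  finite <- mass[as.integer(names(mass)) < F$nk]
  tail <- finite[as.integer(names(finite)) >= 2]   # beyond ~4 mm
  expect_true(all(diff(tail) < 0))
  # overflow distances are rare but included in the normalization
  expect_lt(mass[as.character(F$nk)], 0.05)
})

test_that("distance marginalization renormalizes and preserves profiles", {
  F <- fx_F()
  Fc <- marginalize_d2(F)
  expect_true(Fc$marginalized)
  expect_equal(sum(Fc$counts) / Fc$N, 1)
  # marginal lookups ignore the distance argument
  v1 <- cztpet:::response_value(Fc, 30L, 45L, 1L)
  v2 <- cztpet:::response_value(Fc, 30L, 45L, 7L)
  expect_equal(v1, v2)
  # a distance-independent synthetic matrix keeps per-angle profiles
  Fs <- F
  base <- Matrix::sparseMatrix(i = c(10, 11, 12), j = c(1, 1, 1),
                               x = c(1, 2, 1), dims = c(F$nth, 1))
  Fs$counts <- do.call(cbind, rep(list(base), F$nE * (F$nk + 1)))
  Fs$N <- sum(Fs$counts)
  Fs <- cztpet:::.response_cache(Fs)
  Fm <- marginalize_d2(Fs)
  prof <- as.numeric(Fm$counts[10:12, 5]) / sum(Fm$counts[10:12, 5])
  expect_equal(prof, c(0.25, 0.5, 0.25))
})

test_that("angular uncertainty grows as the interaction distance shrinks", {
  F <- fx_F()
  am <- angular_uncertainty_map(F, min_events = 60)
  am <- am[which(am$valid & abs(am$theta_kin - 90) < 15), ]
  near <- median(am$fwhm[am$d2 <= 3])
  far <- median(am$fwhm[am$d2 >= 7])
  expect_gt(near, far)
  # blur-free matrix: width limited by the binning alone
  F0 <- fx_F0()
  am0 <- angular_uncertainty_map(F0, min_events = 60)
  expect_lt(median(am0$fwhm[am0$valid]), 2 * F0$dth)
})

test_that("compton event probability combines its three factors", {
  g <- fx_geom()
  F <- fx_F()
  obs <- list(E1 = 150, theta = 60, d2 = 3)
  # doubling the source-element distance quarters the interaction factor
  f <- g$frames$modules[[1]]
  ctr <- as.vector(f$o + f$R %*% cztpet:::voxel_center_local(g, 50, 50, 1, 10)[1, ])
  nrm <- f$R[, 3]
  p20 <- compton_event_probability(g, ctr - 20 * nrm, 1, 50, 50, 1, F, obs)
  p40 <- compton_event_probability(g, ctr - 40 * nrm, 1, 50, 50, 1, F, obs)
  expect_equal(p20 / p40, 4, tolerance = 1e-6)
  # empty response cell gives zero
  obs0 <- list(E1 = 2, theta = 179, d2 = 19)
  expect_equal(compton_event_probability(g, c(0, 0, 0), 1, 50, 50, 1, F, obs0), 0)
})

test_that("response matrices persist bit-exactly", {
  F <- fx_F()
  tf <- tempfile(fileext = ".rds")
  write_response(F, tf)
  F2 <- read_response(tf)
  expect_identical(F2$counts@x, F$counts@x)
  expect_identical(F2$N, F$N)
  expect_identical(F2$blur, F$blur)
  saveRDS(list(format = "other"), tf)
  expect_error(read_response(tf), "format")
})
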