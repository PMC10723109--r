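test_that("a single event only updates voxels in its response tube", {
  g <- fx_geom()
  lm <- fx_point_lm()
  one <- lm; one$events <- lm$events[1, ]
  cfg <- recon_config(doi_bin_size = 2.5, voxel_size = 0.5,
                      dims = c(25, 25, 9), iterations = 1,
                      positioning = "first_site")
  sens <- rep(1, prod(cfg$dims))
  rec <- osem_reconstruct(one, g, cfg, sens = sens)
  img <- rec$images[[1]]
  nz <- which(img > 1e-12)      # voxels retaining support after the update
  expect_gt(length(nz), 0)
  # every raised voxel lies within the tube cutoff of the event's LOR
  ep <- cztpet:::position_events(one$events, g, "first_site")
  a <- c(ep$ax, ep$ay, ep$az); b <- c(ep$bx, ep$by, ep$bz)
  ai <- arrayInd(nz, cfg$dims)
  ctr <- sweep((ai - 1) * cfg$voxel_size, 2, -rec$origin)
  w <- b - a
  tpar <- as.vector(sweep(ctr, 2, a) %*% w) / sum(w^2)
  perp <- sweep(ctr, 2, a) - outer(tpar, w)
  expect_true(all(sqrt(rowSums(perp^2)) <=
                    cfg$tube_radius * cfg$voxel_size + 1e-9))
})

test_that("point source reconstructs at its true position", {
  g <- fx_geom()
  lm <- fx_point_lm()
  cfg <- recon_config(doi_bin_size = 1, voxel_size = 0.25,
                      dims = c(49, 49, 25), iterations = 3,
                      positioning = "first_site")
  rec <- osem_reconstruct(lm, g, cfg)
  img <- rec$images[[3]]
  expect_true(all(img >= 0))
  idx <- which(img > 0.2 * max(img))
  ai <- arrayInd(idx, cfg$dims)
  w <- img[idx]
  cen <- colSums(sweep(ai - 1, 1, w, "*")) / sum(w) * cfg$voxel_size +
    rec$origin
  expect_lt(max(abs(cen - c(3, 1, 0))), 0.25)   # within one voxel
  # total intensity is conserved across iterations
  ti <- rec$total_intensity
  expect_lt(max(abs(ti - ti[1])) / ti[1], 0.02)
})

test_that("one full pass with one subset equals dense MLEM on a toy grid", {
  g <- fx_geom()
  lm <- fx_point_lm()
  lm$events <- head(lm$events, 60)
  lm$events$subset <- 1L
  lm$header$n_subsets <- 1L
  cfg <- recon_config(doi_bin_size = 5, voxel_size = 1,
                      dims = c(9, 9, 9), iterations = 1,
                      positioning = "first_site", tube_radius = 12)
  sens <- rep(0.01, prod(cfg$dims))
  rec <- osem_reconstruct(lm, g, cfg, sens = sens, decay_adjust = FALSE)
  # dense oracle: build the full system matrix row by row and apply the
  # textbook MLEM update from the same uniform start
  origin <- -(cfg$dims - 1) / 2 * cfg$voxel_size
  nvox <- prod(cfg$dims)
  ep <- cztpet:::position_events(lm$events, g, "first_site")
  vox <- cbind(origin[1] + ((seq_len(nvox) - 1) %% 9) * 1,
               origin[2] + (((seq_len(nvox) - 1) %/% 9) %% 9) * 1,
               origin[3] + ((seq_len(nvox) - 1) %/% 81) * 1)
  P <- t(vapply(seq_len(nrow(ep)), function(r)
    cztpet:::.lor_row(g, ep[r, ], vox, cztpet:::mu511(), 2),
    numeric(nvox)))
  f0 <- rep(1, nvox)
  q <- as.vector(P %*% f0)
  f1 <- f0 / sens * as.vector(t(P) %*% ifelse(q > 0, 1 / q, 0))
  f1[sens <= 0] <- 0
  expect_equal(as.vector(rec$images[[1]]), f1, tolerance = 1e-8)
})

test_that("decay-adjusted sensitivity rescales subsets by their counts", {
  s <- c(0.1, 0.2, 0.3)
  m <- decay_adjusted_sensitivity(s, c(100, 100, 100))
  expect_equal(m[, 2], s)
  m2 <- decay_adjusted_sensitivity(s, c(100, 50, 25))
  expect_equal(m2[, 2], s / 2)
  expect_equal(m2[, 3], s / 4)
  expect_error(decay_adjusted_sensitivity(s, c(0, 1)), "positive")
})

test_that("gaussian post-filter preserves intensity at the stated width", {
  img <- array(0, c(21, 21, 21)); img[11, 11, 11] <- 1
  out <- gaussian_postfilter(img, fwhm = 0.40, spacing = 0.25)
  expect_equal(sum(out), 1, tolerance = 1e-3)
  expect_equal(profile_fwhm(out[, 11, 11], x = (0:20) * 0.25), 0.40,
               tolerance = 0.05)
  expect_identical(gaussian_postfilter(img, 0, 0.25), img)
})

test_that("profile metrics behave on analytic fixtures", {
  x <- seq(0, 10, by = 0.1)
  y <- exp(-(x - 5)^2 / (2 * 0.5^2))
  expect_equal(profile_fwhm(y, x), 2 * sqrt(2 * log(2)) * 0.5,
               tolerance = 1e-3)
  expect_error(profile_fwhm(rep(1, 50)), "peak")
  expect_equal(peak_to_valley(c(0, 1.13, 1.0, 1.50, 0), c(2, 4), 3), 1.13)
  expect_equal(peak_to_valley(c(0, 2, 1, 2, 0), c(2, 4), 3), 2)
  expect_true(is.infinite(peak_to_valley(c(0, 1, 0, 1, 0), c(2, 4), 3)))
})

test_that("normalized SD weights regions by mean activity", {
  img <- array(1, c(10, 10, 1))
  expect_equal(normalized_sd(img, list(1:20)), 0)
  img2 <- array(c(rep(c(1, 3), 25), rep(2, 50)), c(10, 10, 1))
  r1 <- 1:50; r2 <- 51:100
  m1 <- mean(img2[r1]); m2 <- mean(img2[r2])
  manual <- (sd(img2[r1]) / m1) * m1 / (m1 + m2) +
    (sd(img2[r2]) / m2) * m2 / (m1 + m2)
  expect_equal(normalized_sd(img2, list(r1, r2)), manual)
  expect_error(normalized_sd(array(0, c(4, 4, 1)), list(1:4)), "zero")
})
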