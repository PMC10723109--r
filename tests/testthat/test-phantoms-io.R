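test_that("phantom rasterization normalizes activity and honours support", {
  sp <- phantom_spec("point", activity = 3.7e4)
  img <- make_phantom(sp, voxel_size = 0.1)
  expect_equal(sum(img$data), 3.7e4, tolerance = 1e-6)
  # nonzero voxels only within the 0.25 mm sphere (plus half-voxel margin)
  nz <- which(img$data > 0, arr.ind = TRUE)
  ctr <- sweep((nz - 1) * img$spacing[1], 2, -img$origin)
  r <- sqrt(rowSums(ctr^2))
  expect_true(all(r <= 0.125 + 0.1))
  expect_error(make_phantom(sp, voxel_size = 0.2), "coarse")
})

test_that("hot-rod phantom has four sectors at the specified pitches", {
  sp <- phantom_spec("hot_rod")
  rods <- cztpet:::hot_rod_centers(sp$geometry)
  expect_setequal(unique(rods$sector), 1:4)
  expect_equal(sort(unique(rods$diam)), c(0.35, 0.5, 0.75, 1.0))
  for (s in 1:4) {
    rs <- rods[rods$sector == s, ]
    expect_gt(nrow(rs), 3)
    # nearest-neighbour spacing equals the sector pitch
    dmat <- as.matrix(dist(rs[, c("x", "y")]))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1, min)
    expect_equal(median(nn), sp$geometry$rod_pitch[s], tolerance = 1e-6)
    # all rods inside the 14 mm cylinder
    expect_true(all(sqrt(rs$x^2 + rs$y^2) + rs$diam / 2 <= 7 + 1e-9))
  }
})

test_that("rasterization converges as the voxel shrinks", {
  sp <- phantom_spec("hot_rod")
  f <- function(vs) {
    img <- make_phantom(sp, voxel_size = vs,
                        dims = c(ceiling(15 / vs), ceiling(15 / vs), 4))
    d <- dim(img$data)
    x <- img$origin[1] + (seq_len(d[1]) - 1) * vs
    right <- sweep(img$data, 1, as.numeric(x > 0), "*")
    sum(right) / sum(img$data)   # activity share of the x > 0 half
  }
  expect_lt(abs(f(0.125) - f(0.0625)), 0.01)
})

test_that("image-quality phantom carries the five scaled rod sizes", {
  sp <- phantom_spec("iq")
  expect_equal(sp$geometry$rod_diam, c(0.50, 0.80, 1.10, 1.50, 1.80))
  img <- make_phantom(sp, voxel_size = 0.2)
  expect_gt(sum(img$data > 0), 1000)
})

test_that("list-mode files round-trip bit-exactly with header validation", {
  set.seed(111)
  g <- fx_geom()
  ph <- make_phantom(phantom_spec("point", activity = 1e4), voxel_size = 0.1)
  lm <- simulate_coincidences(ph, g, duration = 0.3, seed = 9)
  tf <- tempfile(fileext = ".rds")
  write_listmode(lm, tf)
  lm2 <- read_listmode(tf)
  expect_identical(lm2$events, lm$events)
  expect_identical(lm2$header$seed, 9)
  expect_true(lm2$header$has_truth)
  # experimental-style file: truth dropped, loads with labels unavailable
  write_listmode(strip_truth(lm), tf)
  lm3 <- read_listmode(tf)
  expect_false(lm3$header$has_truth)
  expect_null(lm3$events$label)
  # corrupted / mismatching files give named errors
  saveRDS(list(events = data.frame()), tf)
  expect_error(read_listmode(tf), "header")
  bad <- unclass(lm); bad$header$format_version <- "cztpet-listmode-99"
  saveRDS(bad, tf)
  expect_error(read_listmode(tf), "version")
  bad$header$format_version <- "cztpet-listmode-1"
  bad$header$units$length <- "cm"
  saveRDS(bad, tf)
  expect_error(read_listmode(tf), "unit")
  writeLines("not rds", tf)
  expect_error(read_listmode(tf), "list-mode")
})

test_that("the command-line front end validates its arguments", {
  cli <- system.file("cli", "cztpet.R", package = "cztpet")
  expect_true(nchar(cli) > 0)
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, cli, stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(out, "status")))   # no command -> usage + error
  expect_true(any(grepl("usage", out)))
})
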