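#' Phantom specifications
#'
#' Builds the specification of one of the study phantoms: a 0.25-mm point
#' source, two 0.65-mm inner-diameter capillary line sources, the
#' custom hot-rod resolution phantom (four sectors of 0.35/0.5/0.75/1.0 mm
#' rods with centre-to-centre pitches 0.7/1.0/1.5/1.6 mm inside a 14-mm
#' cylinder), the NU-4-style image-quality phantom scaled to 70% (rod
#' diameters 0.50/0.80/1.10/1.50/1.80 mm), or a uniform cylinder.
#'
#' @param kind one of \code{"point"}, \code{"two_lines"}, \code{"hot_rod"},
#'   \code{"iq"}, \code{"uniform_cylinder"}
#' @param activity total activity, Bq
#' @param isotope \code{"Cu64"}, \code{"Na22"} or \code{"none"} (no decay)
#' @param center phantom centre in the object frame, mm
#' @param ... kind-specific geometry overrides (see Details)
#' @return object of class \code{phantom_spec}
#' @export
phantom_spec <- function(kind = c("point", "two_lines", "hot_rod", "iq",
                                  "uniform_cylinder"),
                         activity = 1e6,
                         isotope = c("Cu64", "Na22", "none"),
                         center = c(0, 0, 0), ...) {
  kind <- match.arg(kind)
  isotope <- match.arg(isotope)
  half_life <- switch(isotope, Cu64 = 12.7 * 3600, Na22 = 2.6 * 3.156e7,
                      none = Inf)
  geo <- switch(kind,
    point = list(diameter = 0.25),
    two_lines = list(diameter = 0.65, length = 10, separation = 5),
    hot_rod = list(diameter = 14, length = 10,
                   rod_diam = c(0.35, 0.5, 0.75, 1.0),
                   rod_pitch = c(0.7, 1.0, 1.5, 1.6)),
    iq = list(body_diameter = 15.75, body_length = 9.8,
              rod_diam = c(0.50, 0.80, 1.10, 1.50, 1.80),
              rod_radius = 4.9, rod_length = 9.8),
    uniform_cylinder = list(diameter = 14, length = 10))
  over <- list(...)
  geo[names(over)] <- over
  structure(list(kind = kind, activity = activity, isotope = isotope,
                 half_life = half_life, center = center, geometry = geo),
            class = "phantom_spec")
}

# triangular-lattice rod centres for one quadrant sector of a Derenzo-style
# phantom; sector bisector along `angle0` degrees, rods inside radius R
.sector_rods <- function(diam, pitch, R, angle0, margin) {
  r_rod <- diam / 2
  dy <- pitch * sqrt(3) / 2
  pts <- NULL
  for (row in 0:40) {
    y <- margin + r_rod + row * dy
    if (y > R - r_rod) break
    xoff <- (row %% 2) * pitch / 2
    xs <- seq(-20 * pitch, 20 * pitch, by = pitch) + xoff
    pts <- rbind(pts, cbind(xs, y))
  }
  if (is.null(pts)) return(NULL)
  keep <- sqrt(pts[, 1]^2 + pts[, 2]^2) <= R - r_rod
  # stay inside the 90-degree wedge about +y with a margin off the sector
  # boundaries so neighbouring sectors do not touch
  ang <- atan2(pts[, 1], pts[, 2]) * 180 / pi
  keep <- keep & abs(ang) <= 45 - (margin + r_rod) / pmax(sqrt(rowSums(pts^2)), 1e-6) * 57.3
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(NULL)
  th <- angle0 * pi / 180
  rot <- cbind(pts[, 1] * cos(th) + pts[, 2] * sin(th),
               -pts[, 1] * sin(th) + pts[, 2] * cos(th))
  rot
}

# rod centre list for the hot-rod phantom: sectors at +y, +x, -y, -x
hot_rod_centers <- function(geo) {
  out <- list()
  for (s in 1:4) {
    ctr <- .sector_rods(geo$rod_diam[s], geo$rod_pitch[s],
                        geo$diameter / 2, (s - 1) * 90, margin = 0.6)
    if (!is.null(ctr) && nrow(ctr))
      out[[s]] <- data.frame(x = ctr[, 1], y = ctr[, 2], sector = s,
                             diam = geo$rod_diam[s])
  }
  do.call(rbind, out)
}

#' Rasterize a phantom to a voxelized activity image
#'
#' Partial-volume-aware rasterization: every voxel is supersampled 16x
#' (4 x 4 in-plane) against the analytic phantom geometry and the image is
#' normalized so that its sum equals the specified total activity.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param voxel_size isotropic voxel size, mm (must be at most half the
#'   smallest phantom feature)
#' @param dims optional grid dimensions (defaults fit the phantom)
#' @return object of class \code{activity_image}: list with 3-D
#'   \code{data}, \code{origin} (centre of the first voxel), \code{spacing}
#' @export
make_phantom <- function(spec, voxel_size = 0.25, dims = NULL) {
  g <- spec$geometry
  feature <- switch(spec$kind,
    point = g$diameter, two_lines = g$diameter,
    hot_rod = min(g$rod_diam), iq = min(g$rod_diam),
    uniform_cylinder = g$diameter)
  if (voxel_size > feature / 2)
    stop(sprintf("voxel size %.3g mm too coarse for the %.3g mm feature",
                 voxel_size, feature))
  ext <- switch(spec$kind,
    point = rep(g$diameter + 6 * voxel_size, 3),
    two_lines = c(g$separation + g$diameter + 2, g$diameter + 2, g$length),
    hot_rod = c(g$diameter + 1, g$diameter + 1, g$length),
    iq = c(g$body_diameter + 1, g$body_diameter + 1, g$body_length * 2),
    uniform_cylinder = c(g$diameter + 1, g$diameter + 1, g$length))
  if (is.null(dims)) dims <- pmax(4L, as.integer(ceiling(ext / voxel_size)))
  half <- (dims - 1) / 2 * voxel_size
  origin <- spec$center - half
  cx <- origin[1] + (seq_len(dims[1]) - 1) * voxel_size
  cy <- origin[2] + (seq_len(dims[2]) - 1) * voxel_size
  cz <- origin[3] + (seq_len(dims[3]) - 1) * voxel_size
  ss <- (seq_len(4) - 2.5) / 4 * voxel_size       # 4x4 in-plane subsamples
  vol <- array(0, dims)
  ind_fun <- .phantom_indicator(spec)
  for (ox in ss) for (oy in ss) {
    X <- rep(cx + ox, times = dims[2])
    Y <- rep(cy + oy, each = dims[1])
    for (iz in seq_len(dims[3])) {
      vol[, , iz] <- vol[, , iz] + ind_fun(X, Y, rep(cz[iz], length(X)))
    }
  }
  tot <- sum(vol)
  if (tot == 0) stop("phantom does not intersect the grid")
  vol <- vol * (spec$activity / tot)
  structure(list(data = vol, origin = origin, spacing = rep(voxel_size, 3),
                 spec = spec), class = "activity_image")
}

.phantom_indicator <- function(spec) {
  g <- spec$geometry
  c0 <- spec$center
  switch(spec$kind,
    point = function(x, y, z)
      ((x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 <= (g$diameter / 2)^2) + 0,
    two_lines = function(x, y, z) {
      r <- g$diameter / 2; s <- g$separation / 2
      inz <- abs(z - c0[3]) <= g$length / 2
      l1 <- (x - c0[1] - s)^2 + (y - c0[2])^2 <= r^2
      l2 <- (x - c0[1] + s)^2 + (y - c0[2])^2 <= r^2
      (inz & (l1 | l2)) + 0
    },
    hot_rod = {
      rods <- hot_rod_centers(g)
      function(x, y, z) {
        inz <- abs(z - c0[3]) <= g$length / 2
        hit <- rep(FALSE, length(x))
        for (ri in seq_len(nrow(rods))) {
          hit <- hit | ((x - c0[1] - rods$x[ri])^2 +
                          (y - c0[2] - rods$y[ri])^2 <=
                          (rods$diam[ri] / 2)^2)
        }
        (inz & hit) + 0
      }
    },
    iq = {
      nrod <- length(g$rod_diam)
      ang <- (seq_len(nrod) - 1) * 2 * pi / nrod + pi / 2
      rx <- g$rod_radius * cos(ang); ry <- g$rod_radius * sin(ang)
      function(x, y, z) {
        zl <- z - c0[3]
        un <- (x - c0[1])^2 + (y - c0[2])^2 <= (g$body_diameter / 2)^2 &
          zl > 0 & zl <= g$body_length
        hit <- rep(FALSE, length(x))
        for (ri in seq_len(nrod)) {
          hit <- hit | ((x - c0[1] - rx[ri])^2 + (y - c0[2] - ry[ri])^2 <=
                          (g$rod_diam[ri] / 2)^2)
        }
        (un | (hit & zl <= 0 & zl > -g$rod_length)) + 0
      }
    },
    uniform_cylinder = function(x, y, z)
      ((x - c0[1])^2 + (y - c0[2])^2 <= (g$diameter / 2)^2 &
         abs(z - c0[3]) <= g$length / 2) + 0)
}

#' @export
print.activity_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("activity image %d x %d x %d voxels of %g mm, total %.4g Bq\n",
              d[1], d[2], d[3], x$spacing[1], sum(x$data)))
  invisible(x)
}

# draw emission positions from the voxelized activity, jittered uniformly
# within each voxel
sample_emissions <- function(img, n) {
  p <- as.vector(img$data)
  idx <- sample.int(length(p), n, replace = TRUE, prob = p)
  d <- dim(img$data)
  i1 <- (idx - 1) %% d[1]
  i2 <- ((idx - 1) %/% d[1]) %% d[2]
  i3 <- (idx - 1) %/% (d[1] * d[2])
  jit <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
  cbind(img$origin[1] + (i1 + jit[, 1]) * img$spacing[1],
        img$origin[2] + (i2 + jit[, 2]) * img$spacing[2],
        img$origin[3] + (i3 + jit[, 3]) * img$spacing[3])
}
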