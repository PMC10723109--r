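# List-mode OS-EM reconstruction with on-the-fly system-matrix rows from
# the analytic coincidence-response model, DOI binning, decay-adjusted
# subset sensitivity, Gaussian post-filtering and image-quality metrics.

#' Reconstruction configuration
#'
#' @param doi_bin_size depth-of-interaction bin size, mm; must divide the
#'   10 mm crystal thickness (1, 2.5, 5 or 10 = no DOI)
#' @param voxel_size image voxel size, mm (isotropic)
#' @param dims image dimensions (3 integers)
#' @param iterations OS-EM iterations (one pass over all subsets each)
#' @param positioning rule locating two-site Compton photons on the LOR:
#'   \code{"predicted"} (kinematics-predicted first site),
#'   \code{"centroid"} (energy-weighted), \code{"cathode"} (site nearest
#'   the cathode), or \code{"first_site"} (stored order; simulation truth)
#' @param post_filter_fwhm Gaussian post-filter FWHM, mm (0.40 default)
#' @param tube_radius system-matrix cutoff: voxels farther than this many
#'   voxel sizes from the LOR axis are treated as zero
#' @return list of class \code{recon_config}
#' @export
recon_config <- function(doi_bin_size = 2.5, voxel_size = 0.25,
                         dims = c(66, 66, 80), iterations = 4,
                         positioning = c("predicted", "centroid",
                                         "cathode", "first_site"),
                         post_filter_fwhm = 0.40, tube_radius = 3) {
  if (abs(10 / doi_bin_size - round(10 / doi_bin_size)) > 1e-9)
    stop("DOI bin size must divide the 10 mm thickness evenly")
  positioning <- match.arg(positioning)
  structure(list(doi_bin_size = doi_bin_size, voxel_size = voxel_size,
                 dims = as.integer(dims), iterations = iterations,
                 positioning = positioning,
                 post_filter_fwhm = post_filter_fwhm,
                 tube_radius = tube_radius), class = "recon_config")
}

#' Position coincidence events on their line of response
#'
#' Resolves each photon of every event to a single endpoint according to
#' the positioning rule. Single-site photons always use their site.
#'
#' @param events wide event table
#' @param geom a \code{\link{system_geometry}}
#' @param rule positioning rule (see \code{\link{recon_config}})
#' @param F response matrix, required for \code{rule = "predicted"}
#' @return data.frame of endpoints: \code{ax..az, amod, bx..bz, bmod}
#' @export
position_events <- function(events, geom,
                            rule = c("predicted", "centroid", "cathode",
                                     "first_site"), F = NULL) {
  rule <- match.arg(rule)
  n <- nrow(events)
  pred <- NULL
  if (rule == "predicted") {
    if (is.null(F)) stop("rule 'predicted' needs a response matrix")
    pred <- reject_events(events, F, threshold = 0)
  }
  out <- data.frame(row.names = seq_len(n))
  for (side in c("a", "b")) {
    gx <- events[[paste0(side, "_x1")]]
    gy <- events[[paste0(side, "_y1")]]
    gz <- events[[paste0(side, "_z1")]]
    gm <- events[[paste0(side, "_m1")]]
    two <- events[[paste0(side, "_n")]] == 2L
    pick2 <- rep(FALSE, n)
    if (rule == "centroid") {
      # energy-weighted centroid; module of the higher-energy site
      sel <- two
      gx[sel] <- events[[paste0(side, "_cx")]][sel]
      gy[sel] <- events[[paste0(side, "_cy")]][sel]
      gz[sel] <- events[[paste0(side, "_cz")]][sel]
      hi2 <- sel & events[[paste0(side, "_e2")]] > events[[paste0(side, "_e1")]]
      gm[hi2] <- events[[paste0(side, "_m2")]][hi2]
    } else if (rule == "cathode") {
      # site with the smaller module-local depth
      z1l <- .local_depth(geom, events[[paste0(side, "_m1")]],
                          cbind(events[[paste0(side, "_x1")]],
                                events[[paste0(side, "_y1")]],
                                events[[paste0(side, "_z1")]]))
      z2l <- .local_depth(geom, events[[paste0(side, "_m2")]],
                          cbind(events[[paste0(side, "_x2")]],
                                events[[paste0(side, "_y2")]],
                                events[[paste0(side, "_z2")]]))
      pick2 <- two & !is.na(z2l) & z2l < z1l
    } else if (rule == "predicted") {
      pick2 <- two & pred$best_side == side & pred$best_ordering == 2L
    }                                     # first_site: keep site 1
    if (any(pick2)) {
      gx[pick2] <- events[[paste0(side, "_x2")]][pick2]
      gy[pick2] <- events[[paste0(side, "_y2")]][pick2]
      gz[pick2] <- events[[paste0(side, "_z2")]][pick2]
      gm[pick2] <- events[[paste0(side, "_m2")]][pick2]
    }
    out[[paste0(side, "x")]] <- gx
    out[[paste0(side, "y")]] <- gy
    out[[paste0(side, "z")]] <- gz
    out[[paste0(side, "mod")]] <- gm
  }
  out
}

.local_depth <- function(geom, module, pts) {
  z <- rep(NA_real_, nrow(pts))
  ok <- !is.na(module)
  for (mod in unique(module[ok])) {
    sel <- which(ok & module == mod)
    z[sel] <- global_to_module(geom, mod, pts[sel, , drop = FALSE])[, 3]
  }
  z
}

# system-matrix row for one event: probabilities over candidate image
# voxels near the LOR (one sublayer per DOI bin)
.lor_row <- function(geom, ep, vox, mu, doi_bins) {
  pitch <- 20.9 / geom$lateral_voxels
  tz <- geom$thickness / doi_bins
  f1 <- geom$frames$modules[[ep$amod]]
  f2 <- geom$frames$modules[[ep$bmod]]
  l1 <- global_to_module(geom, ep$amod, matrix(c(ep$ax, ep$ay, ep$az), 1))
  l2 <- global_to_module(geom, ep$bmod, matrix(c(ep$bx, ep$by, ep$bz), 1))
  vi1 <- detector_voxel_index(geom, l1[1], l1[2], l1[3], doi_bins)
  vi2 <- detector_voxel_index(geom, l2[1], l2[2], l2[3], doi_bins)
  c1l <- voxel_center_local(geom, vi1$u, vi1$v, vi1$doi, doi_bins)[1, ]
  c2l <- voxel_center_local(geom, vi2$u, vi2$v, vi2$doi, doi_bins)[1, ]
  c1 <- as.vector(f1$o + f1$R %*% c1l)
  hw <- pitch / 2
  corners <- rbind(c(-hw, -hw), c(hw, -hw), c(hw, hw), c(-hw, hw))
  qg <- t(vapply(1:4, function(i)
    as.vector(f1$o + f1$R %*% c(c1l[1] + corners[i, 1],
                                c1l[2] + corners[i, 2], c1l[3])),
    numeric(3)))
  nvx <- nrow(vox)
  dvec <- sweep(-vox, 2, c1, "+")         # vox -> slice1 centre
  d2 <- rowSums(dvec^2)
  proj <- dvec %*% f1$R[, 3]
  cphi <- abs(proj) / sqrt(d2)
  p1 <- pitch^2 * cphi / (4 * pi * d2) * exp(-mu * c1l[3] / cphi * 0.1) *
    (1 - exp(-mu * tz / cphi * 0.1))
  p1[proj <= 0] <- 0
  # project slice-1 corners through each voxel onto slice-2 plane
  s2 <- sweep(vox, 2, f2$o) %*% f2$R
  q2 <- sweep(qg, 2, f2$o) %*% f2$R
  px <- matrix(0, nvx, 4); py <- matrix(0, nvx, 4)
  bad <- rep(FALSE, nvx)
  for (i in 1:4) {
    den <- q2[i, 3] - s2[, 3]
    uu <- (c2l[3] - s2[, 3]) / den
    bad <- bad | uu >= 0 | !is.finite(uu)
    px[, i] <- s2[, 1] + uu * (q2[i, 1] - s2[, 1])
    py[, i] <- s2[, 2] + uu * (q2[i, 2] - s2[, 2])
  }
  Sp <- clip_quad_rect_area(px, py, c2l[1] - hw, c2l[1] + hw,
                            c2l[2] - hw, c2l[2] + hw)
  ctrx <- rowMeans(px); ctry <- rowMeans(py)
  dir2 <- cbind(ctrx - s2[, 1], ctry - s2[, 2], c2l[3] - s2[, 3])
  cphi2 <- abs(dir2[, 3]) / sqrt(rowSums(dir2^2))
  g2 <- exp(-mu * c2l[3] / cphi2 * 0.1) * (1 - exp(-mu * tz / cphi2 * 0.1))
  p <- p1 * (Sp / pitch^2) * g2
  p[bad] <- 0
  p
}

#' List-mode OS-EM reconstruction
#'
#' Ordered-subset expectation maximization over angle-step subsets with
#' system-matrix rows evaluated from the analytic coincidence-response
#' model at the configured DOI binning (voxels beyond the tube-of-response
#' cutoff contribute zero). Events whose endpoints do not map into the
#' geometry are skipped and counted. Voxels with zero sensitivity stay
#' zero. Subset sensitivities are scaled by the per-subset event counts to
#' compensate source decay.
#'
#' @param lm a \code{cztpet_listmode} (or wide event table with an
#'   \code{attr "header"}-free default subset column)
#' @param geom a \code{\link{system_geometry}}
#' @param config a \code{\link{recon_config}}
#' @param F response matrix for predicted-first-site positioning
#' @param sens optional precomputed per-voxel sensitivity vector
#' @param origin image origin (centre of first voxel), mm; default centres
#'   the grid on the FOV
#' @param decay_adjust logical; scale subset sensitivities by N_sub / N_1
#' @param verbose print per-iteration totals
#' @return list of class \code{osem_result}: \code{images} (list of 3-D
#'   arrays, one per iteration), \code{total_intensity}, \code{sens},
#'   \code{skipped}, \code{config}
#' @export
osem_reconstruct <- function(lm, geom, config = recon_config(), F = NULL,
                             sens = NULL, origin = NULL,
                             decay_adjust = TRUE, verbose = FALSE) {
  events <- if (inherits(lm, "cztpet_listmode")) lm$events else lm
  header <- if (inherits(lm, "cztpet_listmode")) lm$header else
    list(n_subsets = max(events$subset), angle_step_deg = 0)
  if (!nrow(events)) stop("no events to reconstruct")
  cfg <- config
  dims <- cfg$dims; vs <- cfg$voxel_size
  if (is.null(origin)) origin <- -(dims - 1) / 2 * vs
  ep <- position_events(events, geom, cfg$positioning, F)
  subs <- sort(unique(events$subset))
  ang <- (match(events$subset, subs) - 1) * header$angle_step_deg * pi / 180
  # rotate LOR endpoints back into the object frame
  rot_back <- function(x, y, a) cbind(cos(a) * x + sin(a) * y,
                                      -sin(a) * x + cos(a) * y)
  pa <- rot_back(ep$ax, ep$ay, ang); pb <- rot_back(ep$bx, ep$by, ang)
  epo <- data.frame(ax = pa[, 1], ay = pa[, 2], az = ep$az,
                    bx = pb[, 1], by = pb[, 2], bz = ep$bz)
  doi_bins <- as.integer(round(10 / cfg$doi_bin_size))
  mu <- mu511()
  nvox <- prod(dims)
  # sensitivity on the image grid (coarse analytic evaluation, interpolated)
  if (is.null(sens)) sens <- sensitivity_on_grid(geom, dims, origin, vs)
  Plist <- vector("list", length(subs))
  skipped <- 0L
  for (si in seq_along(subs)) {
    rows <- which(events$subset == subs[si])
    trip <- vector("list", length(rows))
    for (ri in seq_along(rows)) {
      r <- rows[ri]
      cand <- .tube_voxels(epo[r, ], dims, origin, vs, cfg$tube_radius)
      if (!length(cand)) { skipped <- skipped + 1L; next }
      vox_obj <- cbind(origin[1] + ((cand - 1) %% dims[1]) * vs,
                       origin[2] + (((cand - 1) %/% dims[1]) %% dims[2]) * vs,
                       origin[3] + ((cand - 1) %/% (dims[1] * dims[2])) * vs)
      # voxel centres rotated into the lab frame of this subset
      a <- ang[r]
      vox_lab <- cbind(cos(a) * vox_obj[, 1] - sin(a) * vox_obj[, 2],
                       sin(a) * vox_obj[, 1] + cos(a) * vox_obj[, 2],
                       vox_obj[, 3])
      p <- .lor_row(geom, ep[r, ], vox_lab, mu, doi_bins)
      ok <- p > 0
      if (!any(ok)) { skipped <- skipped + 1L; next }
      trip[[ri]] <- cbind(ri, cand[ok], p[ok])
    }
    tr <- do.call(rbind, trip[!vapply(trip, is.null, TRUE)])
    if (is.null(tr)) { Plist[si] <- list(NULL); next }
    Plist[[si]] <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2],
                                        x = tr[, 3],
                                        dims = c(length(rows), nvox))
  }
  nsub_counts <- vapply(subs, function(s) sum(events$subset == s), 0)
  w <- if (decay_adjust) nsub_counts / nsub_counts[1] else rep(1, length(subs))
  f <- rep(1, nvox)
  f[sens <= 0] <- 0
  images <- vector("list", cfg$iterations)
  totals <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    for (si in seq_along(subs)) {
      P <- Plist[[si]]
      if (is.null(P)) next
      q <- as.vector(P %*% f)
      ratio <- ifelse(q > 0, 1 / q, 0)
      bp <- as.vector(Matrix::crossprod(P, ratio))
      ssub <- sens * w[si] / length(subs)
      upd <- ifelse(ssub > 0, bp / ssub, 0)
      f <- f * upd
    }
    images[[it]] <- array(f, dims)
    totals[it] <- sum(f * sens)
    if (verbose)
      message(sprintf("iteration %d: total intensity %.6g", it, totals[it]))
  }
  structure(list(images = images, total_intensity = totals, sens = sens,
                 skipped = skipped, config = cfg, origin = origin),
            class = "osem_result")
}

#' @export
print.osem_result <- function(x, ...) {
  cat(sprintf("OS-EM reconstruction: %d iterations, %d x %d x %d voxels of %g mm\n",
              length(x$images), x$config$dims[1], x$config$dims[2],
              x$config$dims[3], x$config$voxel_size))
  cat(sprintf("  total intensity by iteration: %s\n",
              paste(signif(x$total_intensity, 4), collapse = ", ")))
  invisible(x)
}

# linear voxel indices within `radius` voxels of the LOR segment
.tube_voxels <- function(ep, dims, origin, vs, radius) {
  p <- c(ep$ax, ep$ay, ep$az); q <- c(ep$bx, ep$by, ep$bz)
  w <- q - p
  len <- sqrt(sum(w^2))
  if (!is.finite(len) || len == 0) return(integer(0))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len / (vs / 2))))
  pts <- cbind(p[1] + ts * w[1], p[2] + ts * w[2], p[3] + ts * w[3])
  iv <- sweep(pts, 2, origin) / vs
  keep <- iv[, 1] > -radius - 1 & iv[, 1] < dims[1] + radius &
    iv[, 2] > -radius - 1 & iv[, 2] < dims[2] + radius &
    iv[, 3] > -radius - 1 & iv[, 3] < dims[3] + radius
  iv <- unique(round(iv[keep, , drop = FALSE]))
  if (!nrow(iv)) return(integer(0))
  r <- ceiling(radius)
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  off <- off[rowSums(off^2) <= (radius + 0.5)^2, , drop = FALSE]
  nh <- nrow(off); nv <- nrow(iv)
  ox <- rep(iv[, 1], each = nh) + rep(off[, 1], nv)
  oy <- rep(iv[, 2], each = nh) + rep(off[, 2], nv)
  oz <- rep(iv[, 3], each = nh) + rep(off[, 3], nv)
  # walk voxels can sit up to r+1 outside the grid, plus +-r offsets
  s0 <- 2 * r + 2
  b1 <- dims[1] + 2 * s0; b2 <- dims[2] + 2 * s0
  key <- (ox + s0) + b1 * ((oy + s0) + b2 * (oz + s0))
  u <- !duplicated(key)
  ox <- ox[u]; oy <- oy[u]; oz <- oz[u]
  ok <- ox >= 0 & ox < dims[1] & oy >= 0 & oy < dims[2] &
    oz >= 0 & oz < dims[3]
  ii <- cbind(ox[ok], oy[ok], oz[ok])
  if (!nrow(ii)) return(integer(0))
  # exact perpendicular distance cutoff
  ctr <- cbind(origin[1] + ii[, 1] * vs, origin[2] + ii[, 2] * vs,
               origin[3] + ii[, 3] * vs)
  ap <- sweep(ctr, 2, p)
  tpar <- (ap %*% w) / sum(w^2)
  perp <- ap - tpar %*% t(w)
  dperp <- sqrt(rowSums(perp^2))
  ii <- ii[dperp <= radius * vs, , drop = FALSE]
  if (!nrow(ii)) return(integer(0))
  unique(1L + ii[, 1] + dims[1] * (ii[, 2] + dims[2] * ii[, 3]))
}

#' Sensitivity evaluated on an image grid by coarse interpolation
#'
#' Evaluates the analytic sensitivity on a coarse lattice spanning the
#' image and interpolates trilinearly to every voxel.
#' @inheritParams osem_reconstruct
#' @param dims,origin,vs image grid definition
#' @param coarse coarse lattice spacing, mm
#' @param D depth sublayers for the coarse evaluation
#' @param lateral_step lateral coarsening of the detector sum
#' @export
sensitivity_on_grid <- function(geom, dims, origin, vs, coarse = 2.5,
                                D = 2, lateral_step = 10) {
  ends <- origin + (dims - 1) * vs
  gx <- unique(c(seq(origin[1], ends[1], by = coarse), ends[1]))
  gy <- unique(c(seq(origin[2], ends[2], by = coarse), ends[2]))
  gz <- unique(c(seq(origin[3], ends[3], by = coarse), ends[3]))
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sv <- sensitivity_map(geom, grid, D = D, lateral_step = lateral_step)
  sarr <- array(sv, c(length(gx), length(gy), length(gz)))
  # trilinear interpolation onto the voxel grid
  vx <- origin[1] + (seq_len(dims[1]) - 1) * vs
  vy <- origin[2] + (seq_len(dims[2]) - 1) * vs
  vz <- origin[3] + (seq_len(dims[3]) - 1) * vs
  ix <- .interp_index(vx, gx); iy <- .interp_index(vy, gy)
  iz <- .interp_index(vz, gz)
  out <- array(0, dims)
  for (k in seq_len(dims[3])) {
    w3 <- iz$w[k]; k0 <- iz$i[k]
    sl <- sarr[, , k0] * (1 - w3) + sarr[, , min(k0 + 1, dim(sarr)[3])] * w3
    a00 <- sl[ix$i, iy$i, drop = FALSE]
    a10 <- sl[pmin(ix$i + 1, nrow(sl)), iy$i, drop = FALSE]
    a01 <- sl[ix$i, pmin(iy$i + 1, ncol(sl)), drop = FALSE]
    a11 <- sl[pmin(ix$i + 1, nrow(sl)), pmin(iy$i + 1, ncol(sl)), drop = FALSE]
    wx <- matrix(ix$w, dims[1], dims[2])
    wy <- matrix(iy$w, dims[1], dims[2], byrow = TRUE)
    out[, , k] <- a00 * (1 - wx) * (1 - wy) + a10 * wx * (1 - wy) +
      a01 * (1 - wx) * wy + a11 * wx * wy
  }
  as.vector(out)
}

.interp_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  w <- (x - grid[i]) / (grid[pmin(i + 1, length(grid))] - grid[i])
  w[!is.finite(w)] <- 0
  list(i = i, w = clamp(w, 0, 1))
}

#' Decay-adjusted per-subset sensitivity
#'
#' Scales the sensitivity of each subset by its event-count ratio to the
#' first subset, compensating source decay across angle steps.
#' @param s per-voxel sensitivity vector
#' @param counts per-subset event counts (N1 first)
#' @return matrix with one column per subset
#' @export
decay_adjusted_sensitivity <- function(s, counts) {
  if (counts[1] <= 0) stop("first-subset count must be positive")
  vapply(counts / counts[1], function(w) s * w, numeric(length(s)))
}

#' Gaussian post-filter
#'
#' Separable Gaussian convolution with edge renormalization (total
#' intensity preserved).
#' @param img 3-D array or \code{activity_image}
#' @param fwhm filter FWHM, mm
#' @param spacing voxel size, mm
#' @return filtered array (same type as input)
#' @export
gaussian_postfilter <- function(img, fwhm = 0.40, spacing = 0.25) {
  arr <- if (inherits(img, "activity_image")) img$data else img
  if (fwhm <= 0) return(img)
  sdv <- fwhm_to_sd(fwhm) / spacing
  r <- max(1L, ceiling(4 * sdv))
  k <- stats::dnorm(-r:r, 0, sdv)
  for (dm in 1:3) {
    arr <- .conv_dim(arr, k, dm)
  }
  if (inherits(img, "activity_image")) { img$data <- arr; img } else arr
}

.conv_dim <- function(arr, k, dm) {
  d <- dim(arr)
  perm <- c(dm, setdiff(1:3, dm))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- prod(dim(a)[2:3])
  A <- matrix(a, n, m)
  r <- (length(k) - 1) / 2
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1, j - r); hi <- min(n, j + r)
    kk <- k[(lo - j + r + 1):(hi - j + r + 1)]
    K[lo:hi, j] <- kk / sum(kk)          # edge renormalization
  }
  B <- K %*% A
  aperm(array(B, dim(a)), order(perm))
}

#' FWHM of a 1-D profile by Gaussian fit
#'
#' @param y profile values (one dominant peak)
#' @param x positions, mm (defaults to 0-based index)
#' @return fitted FWHM in the units of \code{x}
#' @export
profile_fwhm <- function(y, x = seq_along(y) - 1) {
  if (max(y) - min(y) <= 0 || !is.finite(max(y)))
    stop("profile has no peak to fit")
  y0 <- y - min(y)
  mu0 <- sum(x * y0) / sum(y0)
  sd0 <- sqrt(sum((x - mu0)^2 * y0) / sum(y0))
  if (!is.finite(sd0) || sd0 <= 0) stop("degenerate profile")
  fit <- try(suppressWarnings(
    stats::nls(y ~ b + a * exp(-(x - m)^2 / (2 * s^2)),
               start = list(a = max(y0), m = x[which.max(y)],
                            s = sd0, b = min(y)),
               control = stats::nls.control(maxiter = 100,
                                            warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) stop("Gaussian fit failed on profile")
  s <- abs(stats::coef(fit)["s"])
  if (!is.finite(s) || s <= 0) stop("Gaussian fit failed on profile")
  unname(sd_to_fwhm(s))
}

#' Peak-to-valley ratio of a two-peak profile
#'
#' The ratio of the lower peak height to the valley height between them.
#' @param y profile values
#' @param peaks indices (or positions if \code{x} given) of the two peaks
#' @param valley index of the valley between them
#' @param x optional positions matching \code{y}
#' @return the P/V ratio (Inf flagged if the valley is zero)
#' @export
peak_to_valley <- function(y, peaks, valley, x = NULL) {
  if (!is.null(x)) {
    peaks <- vapply(peaks, function(p) which.min(abs(x - p)), 0L)
    valley <- which.min(abs(x - valley))
  }
  lower <- min(y[peaks])
  v <- y[valley]
  if (v <= 0) return(Inf)
  lower / v
}

#' Activity-weighted normalized standard deviation over ROIs
#'
#' Per-ROI SD over mean, combined with weights proportional to each ROI's
#' mean reconstructed activity.
#' @param img 3-D array
#' @param rois list of integer index vectors (voxel indices) or logical
#'   masks
#' @return scalar normalized SD
#' @export
normalized_sd <- function(img, rois) {
  if (!length(rois)) stop("no ROIs supplied")
  vals <- lapply(rois, function(r) as.vector(img[r]))
  mus <- vapply(vals, mean, 0)
  if (any(mus == 0)) stop("ROI with zero mean activity")
  sds <- vapply(vals, stats::sd, 0)
  sum((sds / mus) * (mus / sum(mus)))
}
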