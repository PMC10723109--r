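# Analytic coincidence-detection response: solid angle x attenuation x
# interaction probability per detector-voxel sublayer, with the conditional
# second-photon term evaluated through back-projected slice overlap.
# Attenuation uses the interaction coefficient (photoelectric + incoherent),
# consistent with the Monte-Carlo transport.

mu511 <- function() {
  if (is.null(.cztpet$mu511)) .cztpet$mu511 <- czt_mu_parts(511)$tot
  .cztpet$mu511
}

# overlap length of [c-h, c+h] with the active lateral area (two module
# strips [-21.45,-0.55] and [0.55,21.45] for the default 20.9 mm footprint)
.strip_overlap <- function(c0, h, inner, outer) {
  a <- c0 - h; b <- c0 + h
  pmax(0, pmin(b, -inner) - pmax(a, -outer)) +
    pmax(0, pmin(b, outer) - pmax(a, inner))
}

#' Probability that the first annihilation photon is detected in a given
#' detector-voxel sublayer
#'
#' Evaluates the solid-angle / attenuation / interaction product
#' S1 cos(phi) / (4 pi d^2) * exp(-mu l) * (1 - exp(-mu l0)) for the central
#' slice of sublayer \code{n} of the detector voxel \code{(module, u, v)}.
#'
#' @param geom a \code{\link{system_geometry}}
#' @param src source position, mm (global frame), vector of length 3
#' @param module module id (1..16)
#' @param u,v lateral detector-voxel indices (1-based)
#' @param n sublayer index (1..D) across the crystal thickness
#' @param D number of sublayers
#' @return probability in [0, 1); 0 when the sublayer faces away from the
#'   source
#' @export
p_first_photon <- function(geom, src, module, u, v, n, D = 10) {
  dz <- geom$thickness / D
  ctr_l <- voxel_center_local(geom, u, v, n, D)
  f <- geom$frames$modules[[module]]
  ctr <- as.vector(f$o + f$R %*% ctr_l[1, ])
  nrm <- f$R[, 3]
  dvec <- ctr - src
  d <- sqrt(sum(dvec^2))
  cphi <- abs(sum(nrm * dvec)) / d
  if (sum(nrm * dvec) <= 0) return(0)   # source behind the cathode face
  pitch <- 20.9 / geom$lateral_voxels
  mu <- mu511()
  l <- ctr_l[1, 3] / cphi
  l0 <- dz / cphi
  pitch^2 * cphi / (4 * pi * d^2) * exp(-mu * l * 0.1) *
    (1 - exp(-mu * l0 * 0.1))
}

#' Coincidence detection probability for a detector-voxel pair
#'
#' Implements the sublayer-pair sum: the first-photon term times the
#' conditional second-photon term, whose geometric factor is the exact
#' overlap area between the first slice back-projected through the source
#' and the second voxel's central slice (convex polygon clipping).
#'
#' @inheritParams p_first_photon
#' @param I1,I2 lists with fields \code{module}, \code{u}, \code{v} and
#'   optionally \code{doi}, \code{doi_bins} (depth-of-interaction bin of the
#'   detector voxel; default one bin spanning the full thickness)
#' @param D sublayers per detector voxel
#' @return probability p(A | i)
#' @export
p_coincidence <- function(geom, src, I1, I2, D = 10) {
  pan <- function(I) geom$frames$modules[[I$module]]$panel
  if (abs(pan(I1) - pan(I2)) != 2)
    stop("I1 and I2 must lie on opposite panels")
  db1 <- if (is.null(I1$doi_bins)) 1L else I1$doi_bins
  db2 <- if (is.null(I2$doi_bins)) 1L else I2$doi_bins
  d1 <- if (is.null(I1$doi)) 1L else I1$doi
  d2 <- if (is.null(I2$doi)) 1L else I2$doi
  tz1 <- geom$thickness / db1; tz2 <- geom$thickness / db2
  z1 <- (d1 - 1) * tz1 + (seq_len(D) - 0.5) * tz1 / D
  z2 <- (d2 - 1) * tz2 + (seq_len(D) - 0.5) * tz2 / D
  total <- 0
  for (n in seq_len(D)) for (m in seq_len(D)) {
    total <- total + .p_pair_term(geom, src, I1, z1[n], tz1 / D,
                                  I2, z2[m], tz2 / D)
  }
  total
}

# one (n, m) sublayer-pair term; z1c/z2c slice-center depths, dz1/dz2
# sublayer thicknesses (module-local mm)
.p_pair_term <- function(geom, src, I1, z1c, dz1, I2, z2c, dz2) {
  pitch <- 20.9 / geom$lateral_voxels
  mu <- mu511()
  f1 <- geom$frames$modules[[I1$module]]
  f2 <- geom$frames$modules[[I2$module]]
  c1l <- voxel_center_local(geom, I1$u, I1$v, 1, 1)
  c1l <- c(c1l[1, 1], c1l[1, 2], z1c)
  c1 <- as.vector(f1$o + f1$R %*% c1l)
  dvec <- c1 - src
  d <- sqrt(sum(dvec^2))
  proj_n <- sum(f1$R[, 3] * dvec)
  if (proj_n <= 0) return(0)
  cphi <- proj_n / d
  p1 <- pitch^2 * cphi / (4 * pi * d^2) * exp(-mu * z1c / cphi * 0.1) *
    (1 - exp(-mu * dz1 / cphi * 0.1))
  # corners of slice 1 in module-1 frame, projected through src onto the
  # plane of slice 2 (module-2 frame)
  hw <- pitch / 2
  cor <- rbind(c(-hw, -hw), c(hw, -hw), c(hw, hw), c(-hw, hw))
  qg <- t(apply(cor, 1, function(cc)
    as.vector(f1$o + f1$R %*% c(c1l[1] + cc[1], c1l[2] + cc[2], z1c))))
  s2 <- as.vector((src - f2$o) %*% f2$R)
  q2 <- sweep(qg, 2, f2$o) %*% f2$R
  den <- q2[, 3] - s2[3]
  if (any(abs(den) < 1e-9)) return(0)
  uu <- (z2c - s2[3]) / den
  if (any(uu >= 0)) return(0)   # must project through the source (opposite side)
  px <- s2[1] + uu * (q2[, 1] - s2[1])
  py <- s2[2] + uu * (q2[, 2] - s2[2])
  c2l <- voxel_center_local(geom, I2$u, I2$v, 1, 1)
  S2 <- pitch^2
  Sp <- clip_quad_rect_area(matrix(px, 1), matrix(py, 1),
                            c2l[1, 1] - hw, c2l[1, 1] + hw,
                            c2l[1, 2] - hw, c2l[1, 2] + hw)
  if (Sp <= 0) return(0)
  ctr2 <- c(mean(px), mean(py), z2c)
  dir2 <- c(ctr2[1] - s2[1], ctr2[2] - s2[2], z2c - s2[3])
  cphi2 <- abs(dir2[3]) / sqrt(sum(dir2^2))
  g2 <- exp(-mu * z2c / cphi2 * 0.1) * (1 - exp(-mu * dz2 / cphi2 * 0.1))
  p1 * (Sp / S2) * g2
}

#' System sensitivity map from the analytic response model
#'
#' Sums the coincidence-response model over all detector-voxel pairs on
#' opposite panels (each unordered pair counted once) for every source
#' position in \code{grid}. The lateral detector-voxel sum may be coarsened
#' by \code{lateral_step} (the summand varies on centimetre scales, so
#' moderate coarsening changes the result by well under 1%); sublayer count
#' \code{D} controls the depth discretization. Optionally multiplies by the
#' squared full-energy window acceptance estimated by Monte Carlo, giving
#' the in-window detected-coincidence sensitivity instead of the
#' interaction sensitivity.
#'
#' @param geom a \code{\link{system_geometry}} (nominal panel orientations)
#' @param grid data.frame or matrix of source points (x, y, z in mm)
#' @param D number of depth sublayers
#' @param lateral_step coarsening factor for the lateral detector-voxel sum
#' @param efficiency \code{"none"} (interaction sensitivity, the quantity
#'   the response model defines) or \code{"window"} (multiply by the squared
#'   MC-estimated full-energy acceptance)
#' @param eff_value optional precomputed per-photon window acceptance
#' @param model detector model used when estimating the window acceptance
#' @param n_eff Monte-Carlo histories for the acceptance estimate
#' @param extent lateral integration extent per module, mm. The default is
#'   the full crystal width: interactions in the margin outside the anode
#'   footprint are collected by the edge pixels, so the whole crystal
#'   contributes to sensitivity. Set to 20.9 to restrict the sum to the
#'   nominal detector-voxel footprint (matching a literal per-voxel pair
#'   sum with \code{\link{p_coincidence}}).
#' @return numeric vector of per-point sensitivities (probabilities)
#' @export
sensitivity_map <- function(geom, grid, D = 10, lateral_step = 2,
                            efficiency = c("none", "window"),
                            eff_value = NULL, model = detector_model(),
                            n_eff = 2e5, extent = geom$module_size) {
  efficiency <- match.arg(efficiency)
  grid <- as.matrix(grid)
  eta2 <- 1
  if (efficiency == "window") {
    if (is.null(eff_value))
      eff_value <- full_energy_efficiency(geom, model, n_eff)
    eta2 <- eff_value^2
  }
  out <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- 0
    for (axis in 1:2) for (sgn in c(1, -1))
      s <- s + .sens_pair(geom, grid[i, ], axis, sgn, D, lateral_step,
                          extent)
    out[i] <- 0.5 * s * eta2
  }
  out
}

# ordered-pair sum for elements on the panel at `sgn` end of `axis`
# (1 = x pair, 2 = y pair), aggregated over the opposite panel's active area
.sens_pair <- function(geom, src, axis, sgn, D, step,
                       extent = geom$module_size) {
  nv <- max(2L, round(geom$lateral_voxels / step))
  pitch <- extent / nv
  half_face <- geom$face_distance / 2
  th <- geom$thickness
  mu <- mu511()
  moff <- geom$module_size / 2
  ctrs <- (seq_len(nv) - 0.5) * pitch - extent / 2
  lat <- c(ctrs - moff, ctrs + moff)
  zc <- (seq_len(D) - 0.5) * (th / D)
  Gl1 <- rep(lat, times = length(lat) * D)
  Gl2 <- rep(rep(lat, each = length(lat)), times = D)
  Gz <- rep(zc, each = length(lat)^2)
  sa <- src[axis]
  lat_axes <- if (axis == 1) c(2, 3) else c(1, 3)
  sl1 <- src[lat_axes[1]]; sl2 <- src[lat_axes[2]]
  xe <- sgn * (half_face + Gz)
  da <- xe - sa
  d2 <- da^2 + (Gl1 - sl1)^2 + (Gl2 - sl2)^2
  d <- sqrt(d2)
  cphi <- abs(da) / d
  ok <- sgn * da > 0
  p1 <- ifelse(ok,
               pitch^2 * cphi / (4 * pi * d2) * exp(-mu * Gz / cphi * 0.1) *
                 (1 - exp(-mu * (th / D) / cphi * 0.1)), 0)
  inner <- max(0, moff - extent / 2)   # inter-module dead gap, none at 22 mm
  outer <- moff + extent / 2
  P2 <- numeric(length(Gz))
  for (m in seq_len(D)) {
    xm <- -sgn * (half_face + zc[m])
    u <- (xm - sa) / da
    C1 <- sl1 + u * (Gl1 - sl1)
    C2 <- sl2 + u * (Gl2 - sl2)
    h <- abs(u) * pitch / 2
    A <- .strip_overlap(C1, h, inner, outer) *
      .strip_overlap(C2, h, inner, outer)
    dd2 <- (xm - sa)^2 + (C1 - sl1)^2 + (C2 - sl2)^2
    cphi2 <- abs(xm - sa) / sqrt(dd2)
    g <- exp(-mu * zc[m] / cphi2 * 0.1) *
      (1 - exp(-mu * (th / D) / cphi2 * 0.1))
    P2 <- P2 + (A / pitch^2) * g
  }
  sum(p1 * P2)
}

#' Full-energy window acceptance of one detected photon
#'
#' Monte-Carlo estimate of the probability that a 511 keV photon which
#' interacts in a panel is observed (after site thresholding, pixel merging
#' and resolution blurring) with summed energy inside \code{window}.
#'
#' @inheritParams sensitivity_map
#' @param n number of emitted histories
#' @param window energy window, keV
#' @return scalar acceptance estimate
#' @export
full_energy_efficiency <- function(geom, model = detector_model(), n = 2e5,
                                   window = c(500, 540)) {
  o <- matrix(0, n, 3)
  d <- random_directions(n)
  sites <- transport_photons(geom, o, d, 511)
  if (!nrow(sites)) stop("no interactions in efficiency estimate")
  n_int <- length(unique(sites$id))
  sites$pid <- sites$id
  obs <- observe_photon_sites(
    data.frame(pid = sites$pid, x = sites$mx, y = sites$my, z = sites$mz,
               energy = sites$energy, site = sites$site), model)
  esum <- rowsum(obs$energy, obs$pid)
  mean(esum >= window[1] & esum <= window[2]) * nrow(esum) / n_int
}
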