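# Maximum-likelihood geometry calibration from point-source coincidences.
#
# The detector reports interaction positions in module-local coordinates;
# the parameter vector alpha maps them into the global frame. Calibration
# maximizes the list-mode likelihood of full-energy single-site
# coincidences from a known point source (a uniform 250-um sphere,
# integrated by an 8-point cube quadrature) over a masked subset of alpha.

# strip events to module-local observation records using the geometry the
# data were acquired with (i.e. recover the raw detector readout)
calib_prepare <- function(events, geom_data, doi_bins = 10) {
  ok <- events$a_n == 1L & events$b_n == 1L
  ev <- events[ok, , drop = FALSE]
  l1 <- .batch_local(geom_data, ev$a_m1, cbind(ev$a_x1, ev$a_y1, ev$a_z1))
  l2 <- .batch_local(geom_data, ev$b_m1, cbind(ev$b_x1, ev$b_y1, ev$b_z1))
  v1 <- detector_voxel_index(geom_data, l1[, 1], l1[, 2], l1[, 3], doi_bins)
  v2 <- detector_voxel_index(geom_data, l2[, 1], l2[, 2], l2[, 3], doi_bins)
  rec <- data.frame(subset = ev$subset, m1 = ev$a_m1, u1 = v1$u, v1 = v1$v,
                    d1 = v1$doi, m2 = ev$b_m1, u2 = v2$u, v2 = v2$v,
                    d2 = v2$doi)
  # edge detector-voxels collect positions clamped at the crystal boundary,
  # which the response model does not describe and which bias pose
  # rotations; drop them
  nv <- geom_data$lateral_voxels
  inner <- function(u) u > 1L & u < nv
  rec[inner(rec$u1) & inner(rec$v1) & inner(rec$u2) & inner(rec$v2), ,
      drop = FALSE]
}

.batch_local <- function(geom, module, pts) {
  out <- matrix(NA_real_, nrow(pts), 3)
  for (mod in unique(module)) {
    sel <- module == mod
    out[sel, ] <- global_to_module(geom, mod, pts[sel, , drop = FALSE])
  }
  out
}

# expected overlap length of the interval [c-h, c+h] with [a, b] when the
# interval centre is Gaussian-blurred with sd `s` (integrated-Gaussian psi)
.smeared_overlap <- function(c0, h, a, b, s) {
  psi <- function(t) t * stats::pnorm(t) + stats::dnorm(t)
  lo <- c0 - h; hi <- c0 + h
  s * (psi((hi - a) / s) - psi((lo - a) / s) -
         psi((hi - b) / s) + psi((lo - b) / s))
}

# log-likelihood of prepared calibration records under geometry `geom`.
#
# The second-photon term uses the back-projected slice overlap convolved
# with the position-resolution blur (separable per axis, closed form):
# without the convolution the likelihood is corrugated at the 0.2 mm
# detector-voxel scale and local optimization stalls in grid grooves;
# physically, the observed voxel is itself a blurred observation, so the
# smeared overlap is the correct forward model. The separable (axis-
# aligned) approximation of the projected slice holds for the sub-degree
# rotations this calibration targets.
.calib_loglik <- function(geom, rec, src_centers, doi_bins = 10,
                          quad_radius = 0.125 / sqrt(3), blur_sd = 0.30,
                          floor_p = 1e-14) {
  pitch <- 20.9 / geom$lateral_voxels
  tz <- geom$thickness / doi_bins
  hw <- pitch / 2
  mu <- mu511()
  n <- nrow(rec)
  c1l <- voxel_center_local(geom, rec$u1, rec$v1, rec$d1, doi_bins)
  c2l <- voxel_center_local(geom, rec$u2, rec$v2, rec$d2, doi_bins)
  g1 <- .gather_frames(geom, rec$m1)
  g2 <- .gather_frames(geom, rec$m2)
  c1g <- .apply_frame(g1, c1l)
  qoff <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))) *
    quad_radius
  src0 <- src_centers[rec$subset, , drop = FALSE]
  psum <- numeric(n)
  for (qi in seq_len(nrow(qoff))) {
    s <- src0 + matrix(qoff[qi, ], n, 3, byrow = TRUE)
    dvec <- c1g - s
    d2 <- rowSums(dvec^2)
    proj <- rowSums(dvec * g1$R3)
    cphi <- pmax(abs(proj) / sqrt(d2), 1e-6)
    p1 <- pitch^2 * cphi / (4 * pi * d2) * exp(-mu * c1l[, 3] / cphi * 0.1) *
      (1 - exp(-mu * tz / cphi * 0.1))
    p1[proj <= 0] <- 0
    s2 <- .to_frame(g2, s)
    q2 <- .to_frame(g2, c1g)              # slice-1 centre in module-2 frame
    den <- q2[, 3] - s2[, 3]
    uu <- (c2l[, 3] - s2[, 3]) / den
    bad <- uu >= 0 | !is.finite(uu)
    cx <- s2[, 1] + uu * (q2[, 1] - s2[, 1])
    cy <- s2[, 2] + uu * (q2[, 2] - s2[, 2])
    hproj <- abs(uu) * hw
    ovx <- .smeared_overlap(cx, hproj, c2l[, 1] - hw, c2l[, 1] + hw, blur_sd)
    ovy <- .smeared_overlap(cy, hproj, c2l[, 2] - hw, c2l[, 2] + hw, blur_sd)
    dir2 <- cbind(cx - s2[, 1], cy - s2[, 2], c2l[, 3] - s2[, 3])
    cphi2 <- pmax(abs(dir2[, 3]) / sqrt(rowSums(dir2^2)), 1e-6)
    g2f <- exp(-mu * c2l[, 3] / cphi2 * 0.1) *
      (1 - exp(-mu * tz / cphi2 * 0.1))
    pq <- p1 * (ovx * ovy / pitch^2) * g2f
    pq[bad] <- 0
    psum <- psum + pq
  }
  p <- psum / nrow(qoff)
  if (any(!is.finite(p))) stop("non-finite likelihood")
  sum(log(pmax(p, floor_p)))
}

.gather_frames <- function(geom, module) {
  n <- length(module)
  R1 <- R2 <- R3 <- o <- matrix(0, n, 3)
  for (mod in unique(module)) {
    f <- geom$frames$modules[[mod]]
    sel <- module == mod
    R1[sel, ] <- matrix(f$R[, 1], sum(sel), 3, byrow = TRUE)
    R2[sel, ] <- matrix(f$R[, 2], sum(sel), 3, byrow = TRUE)
    R3[sel, ] <- matrix(f$R[, 3], sum(sel), 3, byrow = TRUE)
    o[sel, ] <- matrix(f$o, sum(sel), 3, byrow = TRUE)
  }
  list(R1 = R1, R2 = R2, R3 = R3, o = o)
}
.apply_frame <- function(g, local) {
  g$o + g$R1 * local[, 1] + g$R2 * local[, 2] + g$R3 * local[, 3]
}
.to_frame <- function(g, global) {
  d <- global - g$o
  cbind(rowSums(d * g$R1), rowSums(d * g$R2), rowSums(d * g$R3))
}

#' Calibrate system geometry from point-source list-mode data
#'
#' Maximizes the list-mode likelihood of full-energy single-site
#' coincidences acquired from a known 0.25-mm point source over a masked
#' subset of the 130-entry geometry parameter vector (by default the six
#' pose parameters of panel 1), by derivative-free local optimization from
#' the initial geometry.
#'
#' @param lm a \code{cztpet_listmode} of full-energy single-site
#'   coincidences (other events are dropped)
#' @param geom_init starting geometry (defines the raw detector readout
#'   frame mapping used to decode the events and the optimizer start)
#' @param geom_data geometry the data were encoded with; defaults to
#'   \code{geom_init}. Only used to recover module-local readout values.
#' @param src_centers matrix (n_subsets x 3) of known source positions per
#'   angle step, mm
#' @param mask integer indices into alpha to optimize (default: panel 1
#'   pose, \code{1:6})
#' @param maxit optimizer iteration budget
#' @return list with \code{alpha} (full calibrated vector), \code{geom},
#'   \code{nll} (final negative log-likelihood), \code{convergence}
#' @export
calibrate_geometry <- function(lm, geom_init, src_centers,
                               geom_data = geom_init, mask = 1:6,
                               maxit = 1500) {
  events <- if (inherits(lm, "cztpet_listmode")) lm$events else lm
  rec <- calib_prepare(events, geom_data)
  if (nrow(rec) < 10 * length(mask))
    warning("fewer events than 10x the number of free parameters")
  a0 <- geom_init$alpha
  nll <- function(theta) {
    a <- a0; a[mask] <- theta
    -.calib_loglik(set_alpha(geom_init, a), rec, src_centers)
  }
  # Nelder-Mead with fresh-simplex restarts: the likelihood is strongly
  # anisotropic across translations and rotations and a single simplex run
  # routinely stalls short of the optimum
  par <- a0[mask]
  val <- Inf
  fit <- NULL
  for (rs in 1:5) {
    fit <- stats::optim(par, nll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    done <- val - fit$value < 0.25
    val <- fit$value; par <- fit$par
    if (done) break
  }
  a <- a0; a[mask] <- par
  list(alpha = a, geom = set_alpha(geom_init, a), nll = fit$value,
       convergence = fit$convergence, mask = mask)
}
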