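# package-wide unit conventions: mm, keV, ns, Bq; attenuation tables in cm^-1

.cztpet <- new.env(parent = emptyenv())

FWHM2SD <- 1 / (2 * sqrt(2 * log(2)))

#' Convert a full width at half maximum to a Gaussian standard deviation
#' @param fwhm full width at half maximum (any unit)
#' @return standard deviation in the same unit
#' @export
fwhm_to_sd <- function(fwhm) fwhm * FWHM2SD

#' @rdname fwhm_to_sd
#' @param sd Gaussian standard deviation
#' @export
sd_to_fwhm <- function(sd) sd / FWHM2SD

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# rotation matrix from intrinsic z-y-x Euler angles in degrees
rotation_matrix <- function(rx = 0, ry = 0, rz = 0) {
  d <- pi / 180
  cx <- cos(rx * d); sx <- sin(rx * d)
  cy <- cos(ry * d); sy <- sin(ry * d)
  cz <- cos(rz * d); sz <- sin(rz * d)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# isotropic unit vectors, n x 3
random_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotate unit vectors `dir` (n x 3) by polar angle theta about themselves with
# uniform azimuth phi: returns the scattered directions
deflect_directions <- function(dir, theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi);   sp <- sin(phi)
  # build an orthonormal frame (u, v, w=dir) per row
  w <- dir
  # pick helper axis least aligned with w
  ax <- abs(w)
  h <- matrix(0, nrow(w), 3)
  m1 <- ax[, 1] <= ax[, 2] & ax[, 1] <= ax[, 3]
  m2 <- !m1 & ax[, 2] <= ax[, 3]
  h[m1, 1] <- 1; h[m2, 2] <- 1; h[!(m1 | m2), 3] <- 1
  u <- cbind(h[, 2] * w[, 3] - h[, 3] * w[, 2],
             h[, 3] * w[, 1] - h[, 1] * w[, 3],
             h[, 1] * w[, 2] - h[, 2] * w[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(w[, 2] * u[, 3] - w[, 3] * u[, 2],
             w[, 3] * u[, 1] - w[, 1] * u[, 3],
             w[, 1] * u[, 2] - w[, 2] * u[, 1])
  st * cp * u + st * sp * v + ct * w
}

vec_norm <- function(m) sqrt(rowSums(m^2))

# angle (degrees) between row vectors of a and b
vec_angle_deg <- function(a, b) {
  ca <- rowSums(a * b) / (vec_norm(a) * vec_norm(b))
  acos(clamp(ca, -1, 1)) * 180 / pi
}
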