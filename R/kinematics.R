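ME_C2 <- 511.0  # electron rest energy, keV

#' Compton scattering kinematics
#'
#' \code{compton_scatter} gives the scattered-photon energy for a photon of
#' energy \code{E0} scattering through polar angle \code{theta};
#' \code{compton_deposit} gives the energy left with the recoil electron;
#' \code{kinematic_angle} inverts the relation, recovering the scattering
#' angle from the deposited energy.
#'
#' @param E0 incident photon energy, keV (> 0)
#' @param theta scattering angle in radians, in [0, pi]
#' @return \code{compton_scatter}: scattered photon energy in keV, in
#'   (E0 / (1 + 2 E0 / 511), E0].
#' @export
compton_scatter <- function(E0, theta) {
  stopifnot(all(E0 > 0), all(theta >= 0), all(theta <= pi))
  E0 / (1 + (E0 / ME_C2) * (1 - cos(theta)))
}

#' @rdname compton_scatter
#' @export
compton_deposit <- function(E0, theta) E0 - compton_scatter(E0, theta)

#' @rdname compton_scatter
#' @param E1 deposited (recoil electron) energy, keV
#' @return \code{kinematic_angle}: scattering angle in degrees, or \code{NA}
#'   where \code{E1} exceeds the Compton edge (kinematically forbidden, as
#'   happens for Doppler-broadened observations).
#' @export
kinematic_angle <- function(E1, E0) {
  stopifnot(all(E0 > 0))
  ct <- 1 - ME_C2 * (1 / (E0 - E1) - 1 / E0)
  ct[E1 <= 0 | E1 >= E0] <- NA_real_
  ct[!is.na(ct) & (ct < -1 | ct > 1)] <- NA_real_
  acos(ct) * 180 / pi
}

# Klein-Nishina differential cross section in theta (per unit polar angle,
# i.e. including the sin(theta) Jacobian), unnormalized
klein_nishina_theta <- function(theta, E0) {
  k <- E0 / ME_C2
  r <- 1 / (1 + k * (1 - cos(theta)))   # E'/E0
  sin(theta) * r^2 * (r + 1 / r - sin(theta)^2)
}

# Klein-Nishina polar-angle sampler (Kahn's composition-rejection method),
# vectorized over a vector of incident energies
sample_kn_theta <- function(E0) {
  n <- length(E0)
  theta <- rep(NA_real_, n)
  todo <- seq_len(n)
  a <- E0 / ME_C2
  while (length(todo)) {
    at <- a[todo]
    r1 <- stats::runif(length(todo))
    r2 <- stats::runif(length(todo))
    r3 <- stats::runif(length(todo))
    b1 <- r1 <= (1 + 2 * at) / (9 + 2 * at)
    eta <- ifelse(b1, 1 + 2 * at * r2, (1 + 2 * at) / (1 + 2 * at * r2))
    ct <- 1 - (eta - 1) / at
    ok <- ifelse(b1, r3 <= 4 * (eta - 1) / eta^2,
                 r3 <= (ct^2 + 1 / eta) / 2)
    ok <- ok & ct >= -1 & ct <= 1
    theta[todo[ok]] <- acos(clamp(ct[ok], -1, 1))
    todo <- todo[!ok]
  }
  theta
}

#' Sample Compton scattering angles and energy deposits
#'
#' Draws scattering angles from the Klein-Nishina differential cross section.
#' With \code{doppler = FALSE} the deposited energy is the exact Compton-line
#' value for the drawn angle. With \code{doppler = TRUE} the scattered-photon
#' energy is additionally broadened following the impulse approximation,
#' sampling the bound-electron momentum from the mixture profile.
#'
#' @param n number of draws
#' @param E0 incident photon energy, keV
#' @param doppler logical; apply Doppler broadening of the Compton line
#' @param profile momentum profile, a data.frame(weight, sd_au) mixture of
#'   Gaussian components with widths in atomic units; the default
#'   \code{czt_compton_profile()} approximates the shell structure of
#'   Cd/Zn/Te
#' @return data.frame with columns \code{theta} (radians), \code{E1}
#'   (deposited energy, keV) and \code{Escat} (scattered photon energy, keV)
#' @export
sample_compton <- function(n, E0, doppler = TRUE,
                           profile = czt_compton_profile()) {
  sample_compton_multi(rep_len(E0, n), doppler, profile)
}

#' Effective Compton (momentum) profile of CZT
#'
#' Gaussian-mixture approximation to the atomic Compton profile of
#' Cd0.9Zn0.1Te under the impulse approximation: one component per shell
#' (O through K), weighted by the shell's electron share for the average
#' Z ~ 49 constituent and with momentum widths sigma = Z_eff / (n sqrt(3))
#' atomic units from Slater-screened hydrogenic shells (virial
#' \code{<p^2> = (Z_eff/n)^2}). The narrow valence components set a
#' few-degree core angular Doppler width at 511 keV / 90 deg; the L and K
#' components supply the heavy tails characteristic of measured Compton
#' profiles.
#' @return data.frame with columns \code{weight} and \code{sd_au}
#' @export
czt_compton_profile <- function() {
  data.frame(weight = c(0.042, 0.387, 0.367, 0.163, 0.041),
             sd_au = c(0.5, 2.0, 6.0, 12.7, 27.5))
}

AU_PZ <- 7.2973525693e-3   # one atomic unit of momentum, in m_e c

# vectorized over an energy vector
sample_compton_multi <- function(E0, doppler = TRUE,
                                 profile = czt_compton_profile()) {
  n <- length(E0)
  theta <- sample_kn_theta(E0)
  Es <- compton_scatter(E0, theta)
  if (doppler && n > 0) {
    comp <- sample.int(nrow(profile), n, replace = TRUE,
                       prob = profile$weight)
    pz <- stats::rnorm(n, 0, profile$sd_au[comp] * AU_PZ) * ME_C2 # p_z c, keV
    ct <- cos(theta)
    Ep <- Es
    for (it in 1:4) {  # Newton iterations on the impulse-approximation root
      q <- sqrt(pmax(E0^2 + Ep^2 - 2 * E0 * Ep * ct, 1e-9))
      g <- E0 * Ep * (1 - ct) - ME_C2 * (E0 - Ep) - pz * q
      dg <- E0 * (1 - ct) + ME_C2 - pz * (Ep - E0 * ct) / q
      Ep <- Ep - g / dg
      Ep <- clamp(Ep, 1e-6, E0 - 1e-6)
    }
    Es <- Ep
  }
  data.frame(theta = theta, E1 = E0 - Es, Escat = Es)
}
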