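#' CZT detector module response model
#'
#' Describes one 2.2 x 2.2 x 1.0 cm CZT imaging-spectrometer module: an
#' 11 x 11 array of 1.9-mm anode pixels, a per-site trigger threshold, and
#' Gaussian energy and position resolution. The energy resolution
#' interpolates monotonically through the measured anchors 3 keV FWHM at
#' 200 keV, 4.5 keV at 450 keV and 5.4 keV at 511 keV (square-root scaling
#' outside the anchored range).
#'
#' @param position_fwhm isotropic 3-D position resolution, mm FWHM
#' @param pixel_pitch anode pixel pitch, mm
#' @param n_pixels pixels per side
#' @param crystal crystal dimensions (x, y, depth), mm
#' @param threshold per-site trigger threshold on true deposited energy, keV.
#'   Deposits below it are not registered (their energy is lost).
#' @param timing_fwhm coincidence timing resolution, ns FWHM
#' @param energy_anchors data.frame(energy, fwhm) through which the energy
#'   resolution curve passes exactly
#' @return an object of class \code{detector_model}
#' @export
detector_model <- function(position_fwhm = 0.5, pixel_pitch = 1.9,
                           n_pixels = 11, crystal = c(22, 22, 10),
                           threshold = 50, timing_fwhm = 100,
                           energy_anchors = data.frame(
                             energy = c(200, 450, 511),
                             fwhm = c(3, 4.5, 5.4))) {
  a <- energy_anchors[order(energy_anchors$energy), ]
  sf <- stats::splinefun(a$energy, a$fwhm, method = "monoH.FC")
  lo <- min(a$energy); hi <- max(a$energy)
  flo <- a$fwhm[1]; fhi <- a$fwhm[nrow(a)]
  efun <- function(E) {
    out <- numeric(length(E))
    low <- E < lo; high <- E > hi; mid <- !(low | high)
    out[low] <- flo * sqrt(E[low] / lo)
    out[high] <- fhi * sqrt(E[high] / hi)
    out[mid] <- sf(E[mid])
    out
  }
  structure(list(energy_fwhm = efun, energy_anchors = a,
                 position_fwhm = position_fwhm, pixel_pitch = pixel_pitch,
                 n_pixels = n_pixels, crystal = crystal,
                 threshold = threshold, timing_fwhm = timing_fwhm),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("CZT detector module model\n")
  cat(sprintf("  crystal %g x %g x %g mm, %d x %d pixels of %g mm pitch\n",
              x$crystal[1], x$crystal[2], x$crystal[3],
              x$n_pixels, x$n_pixels, x$pixel_pitch))
  cat(sprintf("  energy FWHM %.2f keV @511, position FWHM %g mm, threshold %g keV\n",
              x$energy_fwhm(511), x$position_fwhm, x$threshold))
  invisible(x)
}

# anode pixel index (0-based) from module-local lateral coordinate
pixel_index <- function(x, model) {
  half <- model$pixel_pitch * model$n_pixels / 2
  clamp(floor((x + half) / model$pixel_pitch), 0, model$n_pixels - 1)
}

#' Apply the detector model to true interaction sites
#'
#' Converts the true interaction sites of one photon history into the
#' observed photon event: sites sharing an anode pixel are merged
#' (energy-weighted centroid, summed energy) before any blurring, merged
#' sites below the trigger threshold are dropped, and the surviving sites
#' receive independent Gaussian energy blur and isotropic 3-D Gaussian
#' position blur. The number of sites after merging defines the
#' single/double/triple classification.
#'
#' @param sites data.frame of true sites in module-local coordinates with
#'   columns \code{x, y, z} (mm; z is depth from the cathode face),
#'   \code{energy} (keV) and optionally \code{site} (chain order)
#' @param model a \code{\link{detector_model}}
#' @return data.frame of observed sites, ordered by true chain order, with
#'   columns \code{x, y, z, energy, n_merged}
#' @export
apply_detector_model <- function(sites, model = detector_model()) {
  if (nrow(sites) == 0) stop("empty site list")
  if (is.null(sites$site)) sites$site <- seq_len(nrow(sites))
  sites$pid <- 1L
  obs <- observe_photon_sites(sites, model)
  obs[order(obs$site), c("x", "y", "z", "energy", "n_merged", "site")]
}

# vectorized core: `sites` has pid (photon id), x, y, z (module-local),
# energy, site (chain order). Returns merged+thresholded+blurred sites.
observe_photon_sites <- function(sites, model) {
  sites <- sites[order(sites$pid, sites$site), , drop = FALSE]
  u <- pixel_index(sites$x, model)
  v <- pixel_index(sites$y, model)
  key <- paste(sites$pid, u, v)
  keep <- !duplicated(key)
  g <- match(key, key[keep])           # group ids in first-appearance order
  w <- sites$energy
  esum <- as.vector(rowsum(w, g, reorder = FALSE))
  x <- as.vector(rowsum(w * sites$x, g, reorder = FALSE)) / esum
  y <- as.vector(rowsum(w * sites$y, g, reorder = FALSE)) / esum
  z <- as.vector(rowsum(w * sites$z, g, reorder = FALSE)) / esum
  out <- data.frame(pid = sites$pid[keep], x = x, y = y, z = z,
                    energy = esum, n_merged = tabulate(g),
                    site = sites$site[keep])
  out <- out[out$energy >= model$threshold, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  psd <- fwhm_to_sd(model$position_fwhm)
  if (psd > 0) {
    n <- nrow(out)
    out$x <- out$x + stats::rnorm(n, 0, psd)
    out$y <- out$y + stats::rnorm(n, 0, psd)
    out$z <- out$z + stats::rnorm(n, 0, psd)
    out$x <- clamp(out$x, -model$crystal[1] / 2, model$crystal[1] / 2)
    out$y <- clamp(out$y, -model$crystal[2] / 2, model$crystal[2] / 2)
    out$z <- clamp(out$z, 0, model$crystal[3])
  }
  esd <- fwhm_to_sd(model$energy_fwhm(out$energy))
  if (any(esd > 0))
    out$energy <- pmax(out$energy + stats::rnorm(nrow(out), 0, esd), 0.1)
  out
}
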