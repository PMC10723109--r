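#' Photon interaction coefficients for CZT
#'
#' Linear attenuation coefficients of Cd0.9Zn0.1Te (density 5.9 g/cm^3)
#' interpolated log-log from the table shipped in
#' \code{inst/extdata/czt_attenuation.tsv}. The incoherent component is
#' Klein-Nishina theory with an incoherent-scattering-function correction;
#' photoelectric and coherent components are parametric fits anchored to
#' published CZT attenuation values (see \code{tools/make_attenuation.R}).
#'
#' @param energy photon energy in keV, in [50, 1500]; vectorized
#' @return a data.frame with columns \code{energy} (keV),
#'   \code{photoelectric}, \code{incoherent}, \code{coherent}, \code{total}
#'   (all cm^-1) and \code{molecular_density} (cm^-3)
#' @examples
#' xs <- cross_sections(511)
#' xs$incoherent / xs$total   # Compton share at 511 keV, ~0.83
#' @export
cross_sections <- function(energy) {
  if (any(!is.finite(energy)) || any(energy < 50) || any(energy > 1500))
    stop("energy must lie within the tabulated range [50, 1500] keV")
  tab <- czt_attenuation_table()
  le <- log(energy)
  out <- data.frame(
    energy        = energy,
    photoelectric = exp(stats::approx(tab$log_e, log(tab$photoelectric_cm1), le)$y),
    incoherent    = exp(stats::approx(tab$log_e, log(tab$incoherent_cm1), le)$y),
    coherent      = exp(stats::approx(tab$log_e, log(tab$coherent_cm1), le)$y)
  )
  out$total <- out$photoelectric + out$incoherent + out$coherent
  out$molecular_density <- attr(tab, "molecular_density")
  out
}

czt_attenuation_table <- function() {
  if (is.null(.cztpet$atten)) {
    path <- system.file("extdata", "czt_attenuation.tsv", package = "cztpet")
    if (path == "") path <- file.path("inst", "extdata", "czt_attenuation.tsv")
    hdr <- readLines(path, n = 8)
    n0 <- as.numeric(sub(".*molecular_density_cm3: ", "",
                         grep("molecular_density_cm3", hdr, value = TRUE)))
    tab <- utils::read.delim(path, comment.char = "#")
    tab$log_e <- log(tab$energy_keV)
    attr(tab, "molecular_density") <- n0
    .cztpet$atten <- tab
  }
  .cztpet$atten
}

# fast internal accessors (cm^-1); transport ignores coherent scattering
czt_mu_total <- function(energy) {
  xs <- cross_sections(energy)
  xs$photoelectric + xs$incoherent
}
czt_mu_parts <- function(energy) {
  xs <- cross_sections(energy)
  list(pe = xs$photoelectric, inc = xs$incoherent, tot = xs$photoelectric + xs$incoherent)
}

# attenuation coefficient including coherent, as used in the analytic
# coincidence-response model (Beer-Lambert survival)
czt_mu_atten <- function(energy) cross_sections(energy)$total
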