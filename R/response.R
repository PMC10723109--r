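#' Near-field Compton response matrix
#'
#' \code{build_response_matrix} constructs the 3-D probability histogram F
#' over (observed first-interaction energy, observed scattering angle,
#' observed inter-interaction distance) from Monte-Carlo pencil-beam
#' histories in an idealized 4 x 4 x 1 cm CZT slab: photons enter normally
#' through the centre of the front face; only histories with exactly one
#' Compton scattering followed by a photoelectric absorption (full energy
#' deposit) are kept. True positions and energies are blurred by the
#' detector resolution model; the first-interaction energy is taken at the
#' true first site (sequence ambiguity is handled downstream by evaluating
#' both orderings). No anode-pixel merging is applied in the slab so that F
#' covers small inter-interaction distances; the per-site trigger threshold
#' is applied, matching the events the selector sees downstream.
#'
#' Distances beyond \code{d2max} accumulate in an overflow bin that is
#' included in the normalization (the matrix sums to one over all detected
#' two-site events) but excluded from angular-uncertainty fits.
#'
#' @param n number of pencil-beam histories (>= 1e5)
#' @param E0 beam energy, keV
#' @param model a \code{\link{detector_model}} supplying the blur and
#'   threshold; set \code{position_fwhm = 0} and a zero-FWHM energy curve
#'   for an unblurred matrix
#' @param bins bin widths \code{c(energy keV, angle deg, distance mm)}; the
#'   reference setting is \code{c(1/3, 1/3, 0.25)}
#' @param d2max largest finite distance bin edge, mm
#' @param doppler logical; Doppler-broaden Compton deposits
#' @param chunk histories per Monte-Carlo batch
#' @return object of class \code{compton_response}
#' @export
build_response_matrix <- function(n, E0 = 511, model = detector_model(),
                                  bins = c(1 / 3, 1 / 3, 0.25), d2max = 20,
                                  doppler = TRUE, chunk = 1e6) {
  stopifnot(n >= 1e5)
  de <- bins[1]; dth <- bins[2]; dd2 <- bins[3]
  emax <- ceiling((compton_deposit(E0, pi) + 25) / de) * de
  nE <- as.integer(round(emax / de))
  nth <- as.integer(ceiling(180 / dth))
  nk <- as.integer(round(d2max / dd2))
  nslice <- nE * (nk + 1L)                # + overflow distance bin
  acc <- NULL
  left <- n
  while (left > 0) {
    m <- min(chunk, left); left <- left - m
    o <- cbind(rep(0, m), 0, -1)
    d <- cbind(rep(0, m), 0, 1)
    s <- transport_in_box(o, d, E0, 20, 20, 10, doppler = doppler)
    ns <- tabulate(s$id, nbins = m)
    two <- which(ns[s$id] == 2L)
    s2 <- s[two, , drop = FALSE]
    a <- s2[!duplicated(s2$id), , drop = FALSE]        # first site
    b <- s2[rev(!duplicated(rev(s2$id))), , drop = FALSE] # second site
    okk <- a$kind == "compton" & b$kind == "photoelectric"
    a <- a[okk, , drop = FALSE]; b <- b[okk, , drop = FALSE]
    thr <- model$threshold
    keep <- a$energy >= thr & b$energy >= thr
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    if (!nrow(a)) next
    psd <- fwhm_to_sd(model$position_fwhm)
    blur3 <- function(df) {
      k <- nrow(df)
      if (psd > 0) {
        df$x <- df$x + stats::rnorm(k, 0, psd)
        df$y <- df$y + stats::rnorm(k, 0, psd)
        df$z <- df$z + stats::rnorm(k, 0, psd)
      }
      esd <- fwhm_to_sd(model$energy_fwhm(df$energy))
      df$energy <- pmax(df$energy + stats::rnorm(k, 0, esd), 0.1)
      df
    }
    a <- blur3(a); b <- blur3(b)
    dx <- b$x - a$x; dy <- b$y - a$y; dz <- b$z - a$z
    d2hat <- sqrt(dx^2 + dy^2 + dz^2)
    that <- acos(clamp(dz / pmax(d2hat, 1e-12), -1, 1)) * 180 / pi
    i <- clamp(floor(a$energy / de), 0, nE - 1)
    j <- clamp(floor(that / dth), 0, nth - 1)
    k <- pmin(floor(d2hat / dd2), nk)     # nk = overflow
    lin <- 1 + i + nE * k                 # slice index (1-based)
    idx <- j + nth * (lin - 1)            # within (nth x nslice)
    tb <- sort(idx)
    r <- rle(tb)
    add <- cbind(r$values, r$lengths)
    acc <- if (is.null(acc)) add else rbind(acc, add)
    if (!is.null(acc) && nrow(acc) > 8e6) {
      ordi <- order(acc[, 1])
      acc <- acc[ordi, , drop = FALSE]
      rr <- rle(acc[, 1])
      acc <- cbind(rr$values, as.vector(rowsum(acc[, 2], rep(seq_along(rr$lengths), rr$lengths))))
    }
  }
  if (is.null(acc) || !nrow(acc)) stop("no surviving two-interaction events")
  ordi <- order(acc[, 1])
  acc <- acc[ordi, , drop = FALSE]
  rr <- rle(acc[, 1])
  cnt <- as.vector(rowsum(acc[, 2], rep(seq_along(rr$lengths), rr$lengths)))
  idx0 <- rr$values
  jrow <- (idx0 %% nth) + 1L
  scol <- (idx0 %/% nth) + 1L
  counts <- Matrix::sparseMatrix(i = jrow, j = scol, x = cnt,
                                 dims = c(nth, nslice))
  F <- structure(list(counts = counts, N = sum(cnt), E0 = E0,
                      de = de, dth = dth, dd2 = dd2, d2max = d2max,
                      nE = nE, nth = nth, nk = nk,
                      doppler = doppler,
                      blur = list(position_fwhm = model$position_fwhm,
                                  energy_fwhm_511 = model$energy_fwhm(511),
                                  threshold = model$threshold),
                      marginalized = FALSE),
                 class = "compton_response")
  .response_cache(F)
}

.response_cache <- function(F) {
  M <- F$counts
  F$slice_sum <- Matrix::colSums(M)
  F$slice_max <- col_max_sparse(M@p, M@x, ncol(M))
  F
}

#' @export
print.compton_response <- function(x, ...) {
  cat(sprintf("Compton response matrix: %s events at %g keV\n",
              format(x$N, big.mark = ","), x$E0))
  if (x$marginalized)
    cat(sprintf("  bins %.3g keV x %.3g deg (distance marginalized), %d occupied cells\n",
                x$de, x$dth, length(x$counts@x)))
  else
    cat(sprintf("  bins %.3g keV x %.3g deg x %.3g mm, %d occupied cells\n",
                x$de, x$dth, x$dd2, length(x$counts@x)))
  invisible(x)
}

# slice (energy, distance) -> column index; marginalized matrices ignore k
.slice_index <- function(F, i, k) {
  if (F$marginalized) i else i + F$nE * (k - 1L) + 0L
}

# bin helpers (1-based; values outside return NA)
.bin_E <- function(F, e) {
  i <- floor(e / F$de) + 1L
  i[e < 0 | i > F$nE] <- NA_integer_
  i
}
.bin_th <- function(F, th) clamp(floor(th / F$dth) + 1L, 1L, F$nth)
.bin_d2 <- function(F, d2) pmin(floor(d2 / F$dd2) + 1L, F$nk + 1L)

# normalized value F(i, j, k), vectorized; NA bins give 0
response_value <- function(F, i, j, k) {
  s <- .slice_index(F, i, k)
  ok <- !is.na(s) & !is.na(j)
  out <- numeric(length(s))
  if (any(ok)) out[ok] <- F$counts[cbind(j[ok], s[ok])] / F$N
  out
}

#' Marginalize the distance axis of a Compton response matrix
#'
#' Sums the matrix over the inter-interaction-distance axis, producing the
#' conventional response over (energy, angle) alone, renormalized to one.
#' @param F a \code{compton_response}
#' @return a \code{compton_response} with \code{marginalized = TRUE}
#' @export
marginalize_d2 <- function(F) {
  if (F$marginalized) return(F)
  M <- F$counts
  tr <- methods::as(M, "TsparseMatrix")
  i2 <- ((tr@j) %% F$nE) + 1L           # energy slice of each cell
  counts <- Matrix::sparseMatrix(i = tr@i + 1L, j = i2,
                                 x = tr@x, dims = c(F$nth, F$nE))
  F$counts <- counts
  F$marginalized <- TRUE
  F$nk <- 1L
  .response_cache(F)
}

#' Angular uncertainty map of a Compton response matrix
#'
#' For each (energy, distance) slice with at least \code{min_events}
#' events, fits a Gaussian to the observed scattering-angle distribution
#' and reports its FWHM, indexed by the kinematic angle of the slice's
#' energy-bin centre and the distance-bin centre. Overflow-distance slices
#' and cells failing the fit are flagged invalid rather than extrapolated.
#'
#' @param F a \code{compton_response}
#' @param min_events minimum events per slice for a fit
#' @return data.frame with columns \code{E1}, \code{theta_kin}, \code{d2},
#'   \code{fwhm}, \code{n}, \code{valid}
#' @export
angular_uncertainty_map <- function(F, min_events = 50) {
  ks <- if (F$marginalized) 1L else seq_len(F$nk)  # finite-distance slices
  res <- vector("list", 2048); ri <- 0L
  th_centers <- (seq_len(F$nth) - 0.5) * F$dth
  for (k in ks) {
    for (i in seq_len(F$nE)) {
      s <- .slice_index(F, i, k)
      cnt <- F$counts[, s]
      ntot <- sum(cnt)
      if (ntot < min_events) next
      w <- as.numeric(cnt)
      mu <- sum(w * th_centers) / ntot
      sdv <- sqrt(sum(w * (th_centers - mu)^2) / ntot)
      fwhm <- sd_to_fwhm(sdv)
      valid <- TRUE
      fit <- try(suppressWarnings(stats::nls(
        w ~ a * exp(-(th_centers - m)^2 / (2 * s2^2)),
        start = list(a = max(w), m = mu, s2 = max(sdv, F$dth)),
        control = stats::nls.control(maxiter = 50, warnOnly = TRUE))),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        cf <- stats::coef(fit)
        if (is.finite(cf["s2"]) && cf["s2"] > 0) fwhm <- sd_to_fwhm(abs(cf["s2"]))
        else valid <- FALSE
      }
      e1 <- (i - 0.5) * F$de
      ri <- ri + 1L
      res[[ri]] <- data.frame(E1 = e1,
                              theta_kin = kinematic_angle(e1, F$E0),
                              d2 = if (F$marginalized) NA_real_ else (k - 0.5) * F$dd2,
                              fwhm = fwhm, n = ntot, valid = valid)
    }
  }
  if (ri == 0L) return(data.frame(E1 = numeric(), theta_kin = numeric(),
                                  d2 = numeric(), fwhm = numeric(),
                                  n = numeric(), valid = logical()))
  do.call(rbind, res[seq_len(ri)])
}

#' Probability of one observed near-field Compton event
#'
#' Combines the penetration factor to the detector element, the
#' Compton-interaction probability of the element (molecular density times
#' Compton cross-section times element volume over 4 pi d1^2), and the
#' response-matrix probability of the observed (energy, angle, distance)
#' signature.
#'
#' @param geom a \code{\link{system_geometry}}
#' @param src source position, mm (global)
#' @param module,u,v,doi,doi_bins detector element (see
#'   \code{\link{detector_voxel_index}})
#' @param obs list with \code{E1} (keV), \code{theta} (deg), \code{d2} (mm)
#' @param F a \code{compton_response}
#' @return probability (dimensionless)
#' @export
compton_event_probability <- function(geom, src, module, u, v, doi, F,
                                      obs, doi_bins = 10) {
  xs <- cross_sections(F$E0)
  sigma <- xs$incoherent / xs$molecular_density          # cm^2 per molecule
  tz <- geom$thickness / doi_bins
  ctr_l <- voxel_center_local(geom, u, v, doi, doi_bins)
  fmod <- geom$frames$modules[[module]]
  ctr <- as.vector(fmod$o + fmod$R %*% ctr_l[1, ])
  dvec <- ctr - src
  d1 <- sqrt(sum(dvec^2)) * 0.1                          # cm
  cphi <- abs(sum(fmod$R[, 3] * dvec)) / sqrt(sum(dvec^2))
  pitch <- 20.9 / geom$lateral_voxels
  V <- pitch^2 * tz * 1e-3                               # cm^3
  p_pre <- exp(-(xs$photoelectric + xs$incoherent) * ctr_l[1, 3] / cphi * 0.1)
  p1 <- xs$molecular_density * sigma / (4 * pi * d1^2) * V
  p2 <- response_value(F, .bin_E(F, obs$E1), .bin_th(F, obs$theta),
                       .bin_d2(F, obs$d2))
  p_pre * p1 * p2
}

#' Persist / load a Compton response matrix
#'
#' The matrix is stored bit-exactly, with bin metadata, total event count
#' and the blur configuration, in R's serialization container.
#' @param F a \code{compton_response}
#' @param path file path
#' @export
write_response <- function(F, path) {
  saveRDS(list(format = "cztpet-response-1", F = unclass(F)), path)
  invisible(path)
}

#' @rdname write_response
#' @export
read_response <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cztpet-response-1"))
    stop("not a cztpet response file (format field mismatch)")
  structure(obj$F, class = "compton_response")
}
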