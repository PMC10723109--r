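# Monte-Carlo photon transport in CZT.
#
# Free paths are exponential with the interaction coefficient
# (photoelectric + incoherent); coherent scattering is excluded from
# transport (about 2% of the total at 511 keV) though cross_sections()
# still reports it. Compton chains are followed until photoelectric
# absorption, escape from the crystal, or a chain-length cap (5 sites),
# at which point the remaining energy is deposited locally so absorbed
# histories conserve energy exactly. Scattered photons that fall below the
# 50 keV table floor are absorbed on the spot (their range in CZT is
# < 0.2 mm).

# entry/exit parameters of rays through the box [-hx,hx] x [-hy,hy] x [0,th]
ray_box <- function(o, d, hx, hy, th) {
  t0 <- rep(-Inf, nrow(o)); t1 <- rep(Inf, nrow(o))
  lims <- list(c(-hx, hx), c(-hy, hy), c(0, th))
  for (ax in 1:3) {
    lo <- lims[[ax]][1]; hi <- lims[[ax]][2]
    da <- d[, ax]; oa <- o[, ax]
    par <- abs(da) < 1e-12
    ta <- (lo - oa) / da; tb <- (hi - oa) / da
    tmin <- pmin(ta, tb); tmax <- pmax(ta, tb)
    inside <- oa >= lo & oa <= hi
    tmin[par] <- ifelse(inside[par], -Inf, Inf)
    tmax[par] <- ifelse(inside[par], Inf, -Inf)
    t0 <- pmax(t0, tmin); t1 <- pmin(t1, tmax)
  }
  list(t0 = t0, t1 = t1)
}

# Vectorized transport of photons into one crystal box (local frame).
# o, d: N x 3 origins and unit directions; E0: scalar or length-N keV.
# Returns true interaction sites: id (photon row), site (chain order),
# x, y, z (local mm), energy (keV deposited), kind.
transport_in_box <- function(o, d, E0, hx, hy, th,
                             doppler = TRUE,
                             max_chain = 5L) {
  n <- nrow(o)
  E <- rep_len(E0, n)
  cm <- 0.1                              # mm -> cm for attenuation
  rb <- ray_box(o, d, hx, hy, th)
  pos <- o; dir <- d
  tstart <- pmax(rb$t0, 0); tend <- rb$t1
  active <- which(is.finite(tstart) & tend > tstart)
  out <- vector("list", max_chain)
  for (gen in seq_len(max_chain)) {
    if (!length(active)) break
    mu <- czt_mu_parts(E[active])
    s <- stats::rexp(length(active), mu$tot * cm)
    tint <- tstart[active] + s
    hit <- tint < tend[active]
    if (!any(hit)) break
    hi <- active[hit]
    p_int <- pos[hi, , drop = FALSE] + dir[hi, , drop = FALSE] * tint[hit]
    photo <- stats::runif(length(hi)) < (mu$pe[hit] / mu$tot[hit])
    last <- gen == max_chain
    dep <- E[hi]                         # default: full local absorption
    kind <- rep("photoelectric", length(hi))
    cm_i <- which(!photo)
    newE <- numeric(length(hi))
    if (length(cm_i) && !last) {
      smp <- sample_compton_multi(E[hi][cm_i], doppler)
      absorb <- smp$Escat < 50
      dep[cm_i] <- ifelse(absorb, E[hi][cm_i], smp$E1)
      kind[cm_i][!absorb] <- "compton"
      newE[cm_i] <- ifelse(absorb, 0, smp$Escat)
      phi <- stats::runif(length(cm_i), 0, 2 * pi)
      nd <- deflect_directions(dir[hi[cm_i], , drop = FALSE], smp$theta, phi)
    }
    out[[gen]] <- data.frame(id = hi, site = gen,
                             x = p_int[, 1], y = p_int[, 2], z = p_int[, 3],
                             energy = dep, kind = kind)
    cont <- which(newE > 0)
    if (length(cont) && !last) {
      ci <- hi[cont]
      pos[ci, ] <- p_int[cont, , drop = FALSE]
      sel <- match(cont, cm_i)
      dir[ci, ] <- nd[sel, , drop = FALSE]
      E[ci] <- newE[cont]
      rb2 <- ray_box(pos[ci, , drop = FALSE], dir[ci, , drop = FALSE],
                     hx, hy, th)
      tstart[ci] <- 0
      tend[ci] <- rb2$t1
      active <- ci[rb2$t1 > 1e-9]
    } else active <- integer(0)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(id = integer(), site = integer(), x = numeric(),
                      y = numeric(), z = numeric(), energy = numeric(),
                      kind = character())
  res[order(res$id, res$site), , drop = FALSE]
}

#' Transport one photon through the four-panel system
#'
#' Samples the Monte-Carlo interaction chain of a single photon emitted at
#' \code{origin} along \code{direction}: panel entry by ray tracing,
#' exponential free paths, interaction type by cross-section ratio,
#' Klein-Nishina Compton scattering (optionally Doppler-broadened) followed
#' until photoelectric absorption or escape. Scattered photons leaving
#' their panel are not followed into other panels.
#'
#' @param geom a \code{\link{system_geometry}}
#' @param origin emission point, mm (global frame)
#' @param direction unit direction vector
#' @param E0 photon energy, keV
#' @param doppler logical; Doppler-broaden Compton deposits
#' @return data.frame of true interaction sites with global coordinates
#'   (\code{x, y, z}), \code{energy}, \code{kind}, \code{panel},
#'   \code{module} and module-local coordinates (\code{mx, my, mz});
#'   zero rows if the photon misses or escapes undetected
#' @export
transport_photon <- function(geom, origin, direction, E0 = 511,
                             doppler = TRUE) {
  direction <- direction / sqrt(sum(direction^2))
  transport_photons(geom, matrix(origin, 1), matrix(direction, 1), E0,
                    doppler = doppler)
}

# Batch transport through the panel system. o, d: N x 3 global.
# Returns site table with id = photon row index.
transport_photons <- function(geom, o, d, E0 = 511, doppler = TRUE) {
  n <- nrow(o)
  half <- geom$panel_size / 2
  th <- geom$thickness
  best_t <- rep(Inf, n); best_p <- rep(0L, n)
  loc_o <- vector("list", 4); loc_d <- vector("list", 4)
  for (p in 1:4) {
    ol <- global_to_panel(geom, p, o)
    f <- geom$frames$panels[[p]]
    dl <- d %*% f$R
    rb <- ray_box(ol, dl, half, half, th)
    hit <- is.finite(rb$t0) & rb$t1 > pmax(rb$t0, 0) & rb$t0 > 0
    sel <- hit & rb$t0 < best_t
    best_t[sel] <- rb$t0[sel]
    best_p[sel] <- p
    loc_o[[p]] <- ol; loc_d[[p]] <- dl
  }
  res <- vector("list", 4)
  for (p in 1:4) {
    idx <- which(best_p == p)
    if (!length(idx)) next
    sites <- transport_in_box(loc_o[[p]][idx, , drop = FALSE],
                              loc_d[[p]][idx, , drop = FALSE],
                              if (length(E0) > 1) E0[idx] else E0,
                              half, half, th, doppler)
    if (!nrow(sites)) next
    sites$id <- idx[sites$id]
    sites$panel <- p
    sites$module <- module_from_panel_xy(p, sites$x, sites$y)
    mo <- geom$module_size / 2
    sites$mx <- sites$x - ifelse(sites$x >= 0, mo, -mo)
    sites$my <- sites$y - ifelse(sites$y >= 0, mo, -mo)
    sites$mz <- sites$z
    g <- panel_to_global(geom, p, cbind(sites$x, sites$y, sites$z))
    sites$x <- g[, 1]; sites$y <- g[, 2]; sites$z <- g[, 3]
    res[[p]] <- sites
  }
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(id = integer(), site = integer(), x = numeric(),
                      y = numeric(), z = numeric(), energy = numeric(),
                      kind = character(), panel = integer(),
                      module = integer(), mx = numeric(), my = numeric(),
                      mz = numeric())
  res[order(res$id, res$site), , drop = FALSE]
}
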