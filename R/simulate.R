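#' Simulate a list-mode coincidence acquisition
#'
#' Emits back-to-back 511 keV photon pairs from the voxelized phantom
#' (isotropic directions, perfect collinearity), transports each photon
#' through the four-panel system, applies the detector model (pixel
#' merging, trigger threshold, energy and position blur) and timestamps
#' detected photons with Gaussian timing jitter. Coincidences are formed in
#' post-processing from the single-photon timestamps: clusters of exactly
#' two photons within the pairing window on opposite panels become events
#' (same-decay pairs are true coincidences, different-decay pairs randoms);
#' larger clusters are discarded as pileup. The acquisition is divided into
#' \code{n_subsets} angle steps over which the object rotates and the
#' source decays.
#'
#' @param phantom an \code{\link{activity_image}}
#' @param geom a \code{\link{system_geometry}}
#' @param duration acquisition time, s
#' @param window pairing half-window, ns (timestamps closer than this are
#'   clustered)
#' @param model a \code{\link{detector_model}}
#' @param n_subsets number of angle steps / OS-EM subsets
#' @param angle_step rotation between subsets, degrees
#' @param doppler logical; Doppler broadening in transport
#' @param seed optional integer seed recorded in the header
#' @param chunk decays per transport batch
#' @return a \code{cztpet_listmode} object: \code{header} (format version,
#'   seed, geometry hash, units, acquisition settings, counters) and the
#'   wide per-event table \code{events} with per-side observed sites and
#'   the simulation ground-truth block (emission point in the object
#'   frame, true/random label; site order within a photon is the true
#'   chain order)
#' @export
simulate_coincidences <- function(phantom, geom, duration,
                                  window = 250, model = detector_model(),
                                  n_subsets = 3,
                                  angle_step = 360 / n_subsets,
                                  doppler = TRUE, seed = NULL,
                                  chunk = 2e5) {
  if (!is.null(seed)) set.seed(seed)
  A0 <- sum(phantom$data)
  if (A0 <= 0) stop("phantom has no activity")
  lam <- log(2) / phantom$spec$half_life
  n_exp <- if (lam > 0) A0 / lam * (1 - exp(-lam * duration))
           else A0 * duration
  n_dec <- stats::rpois(1, n_exp)
  if (n_dec == 0)
    return(.listmode(data.frame(), geom, seed, duration, window, n_subsets,
                     angle_step, counters = c(decays = 0)))
  # decay-weighted emission times
  u <- stats::runif(n_dec)
  t_s <- if (lam > 0) -log(1 - u * (1 - exp(-lam * duration))) / lam
         else u * duration
  t_s <- sort(t_s)
  subset <- pmin(floor(t_s / (duration / n_subsets)), n_subsets - 1) + 1L
  ph_list <- vector("list", ceiling(n_dec / chunk))
  ci <- 0L
  for (start in seq(1, n_dec, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_dec)
    m <- length(idx)
    pos0 <- sample_emissions(phantom, m)            # object frame
    ang <- (subset[idx] - 1) * angle_step * pi / 180
    ca <- cos(ang); sa <- sin(ang)
    pos <- cbind(ca * pos0[, 1] - sa * pos0[, 2],
                 sa * pos0[, 1] + ca * pos0[, 2], pos0[, 3])
    dirs <- random_directions(m)
    ph <- .detect_photons(geom, rbind(pos, pos), rbind(dirs, -dirs),
                          model, doppler)
    if (nrow(ph)) {
      ph$decay <- idx[(ph$pid - 1L) %% m + 1L]
      ph$time <- t_s[ph$decay] * 1e9 +
        stats::rnorm(nrow(ph), 0, fwhm_to_sd(model$timing_fwhm))
      ph$subset <- subset[ph$decay]
      ph$ox <- pos0[(ph$pid - 1L) %% m + 1L, 1]
      ph$oy <- pos0[(ph$pid - 1L) %% m + 1L, 2]
      ph$oz <- pos0[(ph$pid - 1L) %% m + 1L, 3]
      ci <- ci + 1L
      ph$pid <- NULL
      ph_list[[ci]] <- ph
    }
  }
  if (ci == 0L)
    return(.listmode(data.frame(), geom, seed, duration, window, n_subsets,
                     angle_step, counters = c(decays = n_dec)))
  ph <- do.call(rbind, ph_list[seq_len(ci)])
  ph <- ph[order(ph$time), ]
  # time clustering: break where the gap to the previous photon > window
  newc <- c(TRUE, diff(ph$time) > window)
  clid <- cumsum(newc)
  csz <- tabulate(clid)
  pair <- which(csz[clid] == 2L & newc)   # first photon of each pair
  n_pileup <- sum(csz >= 3)
  a <- ph[pair, ]; b <- ph[pair + 1L, ]
  opp <- abs(a$panel - b$panel) == 2L
  n_not_opposite <- sum(!opp)
  a <- a[opp, ]; b <- b[opp, ]
  ev <- data.frame(event = seq_len(nrow(a)),
                   time = (a$time + b$time) / 2, dt = b$time - a$time,
                   subset = a$subset,
                   label = ifelse(a$decay == b$decay, "true", "random"),
                   true_x = a$ox, true_y = a$oy, true_z = a$oz)
  for (side in c("a", "b")) {
    src <- if (side == "a") a else b
    cols <- c("n", "ntrue", "x1", "y1", "z1", "e1", "m1", "x2", "y2", "z2", "e2",
              "m2", "esum", "cx", "cy", "cz", "panel")
    for (cc in cols) ev[[paste0(side, "_", cc)]] <- src[[cc]]
  }
  .listmode(ev, geom, seed, duration, window, n_subsets, angle_step,
            counters = c(decays = n_dec, singles = nrow(ph),
                         pileup_clusters = n_pileup,
                         not_opposite = n_not_opposite))
}

# transport a batch of photons and summarize each detected photon:
# observed sites (true-chain order), counts, summed energy, centroid
.detect_photons <- function(geom, pos, dirs, model, doppler) {
  sites <- transport_photons(geom, pos, dirs, 511, doppler = doppler)
  if (!nrow(sites))
    return(data.frame(pid = integer(0)))
  obs <- observe_photon_sites(
    data.frame(pid = sites$id, x = sites$mx, y = sites$my, z = sites$mz,
               energy = sites$energy, site = sites$site,
               module = sites$module, panel = sites$panel), model)
  if (!nrow(obs)) return(data.frame(pid = integer(0)))
  # module/panel of each merged site: module of its first true site
  key <- paste(obs$pid, obs$site)
  skey <- paste(sites$id, sites$site)
  mi <- match(key, skey)
  obs$module <- sites$module[mi]
  obs$panel <- sites$panel[mi]
  ntrue_tab <- table(sites$id)
  obs$ntrue <- as.integer(ntrue_tab[as.character(obs$pid)])
  gl <- module_to_global_batch(geom, obs$module, cbind(obs$x, obs$y, obs$z))
  obs$gx <- gl[, 1]; obs$gy <- gl[, 2]; obs$gz <- gl[, 3]
  obs <- obs[order(obs$pid, obs$site), ]
  first <- !duplicated(obs$pid)
  fi <- which(first)
  g <- match(obs$pid, obs$pid[fi])
  nsites <- tabulate(g)
  w <- obs$energy
  esum <- as.vector(rowsum(w, g, reorder = FALSE))
  cx <- as.vector(rowsum(w * obs$gx, g, reorder = FALSE)) / esum
  cy <- as.vector(rowsum(w * obs$gy, g, reorder = FALSE)) / esum
  cz <- as.vector(rowsum(w * obs$gz, g, reorder = FALSE)) / esum
  o1 <- obs[fi, ]
  cand <- fi + 1L                  # second observed site, if present
  has2 <- cand <= nrow(obs) & obs$pid[pmin(cand, nrow(obs))] == obs$pid[fi]
  o2 <- obs[ifelse(has2, cand, NA_integer_), ]
  data.frame(pid = o1$pid, panel = o1$panel, n = nsites,
             ntrue = o1$ntrue,
             x1 = o1$gx, y1 = o1$gy, z1 = o1$gz, e1 = o1$energy,
             m1 = o1$module,
             x2 = o2$gx, y2 = o2$gy, z2 = o2$gz, e2 = o2$energy,
             m2 = o2$module,
             esum = esum, cx = cx, cy = cy, cz = cz)
}

# batch module-local -> global for mixed module ids
module_to_global_batch <- function(geom, module, pts) {
  out <- matrix(NA_real_, nrow(pts), 3)
  for (mod in unique(module)) {
    sel <- module == mod
    out[sel, ] <- module_to_global(geom, mod, pts[sel, , drop = FALSE])
  }
  out
}

.listmode <- function(events, geom, seed, duration, window, n_subsets,
                      angle_step, counters) {
  structure(list(
    header = list(format_version = "cztpet-listmode-1",
                  units = list(length = "mm", energy = "keV", time = "ns"),
                  seed = if (is.null(seed)) NA_integer_ else seed,
                  geometry_hash = geometry_hash(geom),
                  duration_s = duration, window_ns = window,
                  n_subsets = n_subsets, angle_step_deg = angle_step,
                  counters = counters,
                  has_truth = TRUE),
    events = events), class = "cztpet_listmode")
}

#' @export
print.cztpet_listmode <- function(x, ...) {
  h <- x$header
  cat(sprintf("list-mode dataset: %d coincidence events, %d subsets (%g deg steps)\n",
              nrow(x$events), h$n_subsets, h$angle_step_deg))
  if (nrow(x$events) && !is.null(x$events$label))
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s %d", names(table(x$events$label)),
                              as.vector(table(x$events$label))),
                      collapse = ", ")))
  invisible(x)
}

#' Wide per-event table of a list-mode dataset
#' @param lm a \code{cztpet_listmode}
#' @return the wide event data.frame
#' @export
events_wide <- function(lm) lm$events

#' Simulate a pool of detected single photons
#'
#' Transports \code{n_decays} back-to-back photon pairs from the phantom
#' (rotating over angle-step subsets) and returns every detected photon
#' with its decay id and observed sites, without timing or pairing. Pools
#' feed \code{\link{coincidence_stream}}, which builds labeled true and
#' random coincidences at a controlled mixture - the delayed-window idiom
#' for studying random rejection without simulating the full count-rate
#' regime.
#'
#' @inheritParams simulate_coincidences
#' @param n_decays number of annihilations to transport
#' @return data.frame of detected photons (decay, subset, object-frame
#'   emission point, panel, observed sites)
#' @export
simulate_photon_pool <- function(phantom, geom, n_decays,
                                 model = detector_model(), n_subsets = 3,
                                 angle_step = 360 / n_subsets,
                                 doppler = TRUE, chunk = 2e5) {
  subset <- sample.int(n_subsets, n_decays, replace = TRUE)
  out <- list()
  for (start in seq(1, n_decays, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_decays)
    m <- length(idx)
    pos0 <- sample_emissions(phantom, m)
    ang <- (subset[idx] - 1) * angle_step * pi / 180
    ca <- cos(ang); sa <- sin(ang)
    pos <- cbind(ca * pos0[, 1] - sa * pos0[, 2],
                 sa * pos0[, 1] + ca * pos0[, 2], pos0[, 3])
    dirs <- random_directions(m)
    ph <- .detect_photons(geom, rbind(pos, pos), rbind(dirs, -dirs),
                          model, doppler)
    if (nrow(ph)) {
      di <- (ph$pid - 1L) %% m + 1L
      ph$decay <- idx[di]
      ph$subset <- subset[ph$decay]
      ph$ox <- pos0[di, 1]; ph$oy <- pos0[di, 2]; ph$oz <- pos0[di, 3]
      ph$pid <- NULL
      out[[length(out) + 1L]] <- ph
    }
  }
  res <- do.call(rbind, out)
  attr(res, "angle_step") <- angle_step
  res
}

#' Build a labeled coincidence stream from a photon pool
#'
#' True coincidences pair the two detected photons of the same decay;
#' random coincidences pair detected photons of different decays. Only
#' opposite-panel pairs are kept (the coincidence-response model is
#' defined for opposite panels). \code{randoms_per_true} sets the mixture;
#' use \code{\link{lor_misses_object}} on the result to match a printed
#' known-randoms share.
#'
#' @param pool result of \code{\link{simulate_photon_pool}}
#' @param geom a \code{\link{system_geometry}}
#' @param randoms_per_true ratio of random to true coincidences in the
#'   output stream
#' @return a \code{cztpet_listmode} with labeled events
#' @export
coincidence_stream <- function(pool, geom, randoms_per_true = 0) {
  pool <- pool[order(pool$decay), ]
  dup <- pool$decay %in% pool$decay[duplicated(pool$decay)]
  pp <- pool[dup, ]
  firsts <- which(!duplicated(pp$decay))
  # decays with exactly two detected photons on opposite panels
  cnt <- tabulate(match(pp$decay, pp$decay[firsts]))
  ok2 <- cnt[match(pp$decay, pp$decay[firsts])] == 2L
  pp <- pp[ok2, ]
  ia <- which(!duplicated(pp$decay)); ib <- ia + 1L
  opp <- abs(pp$panel[ia] - pp$panel[ib]) == 2L
  a <- pp[ia[opp], ]; b <- pp[ib[opp], ]
  ev_true <- .assemble_events(a, b, "true")
  n_rand <- round(nrow(ev_true) * randoms_per_true)
  ev <- ev_true
  if (n_rand > 0) {
    got <- 0L; parts <- list()
    guard <- 0L
    while (got < n_rand && guard < 50L) {
      guard <- guard + 1L
      need <- (n_rand - got) * 5L
      i <- sample.int(nrow(pool), need, replace = TRUE)
      j <- sample.int(nrow(pool), need, replace = TRUE)
      keep <- pool$decay[i] != pool$decay[j] &
        abs(pool$panel[i] - pool$panel[j]) == 2L &
        pool$subset[i] == pool$subset[j]
      i <- i[keep]; j <- j[keep]
      take <- seq_len(min(length(i), n_rand - got))
      if (length(take)) {
        parts[[length(parts) + 1L]] <-
          .assemble_events(pool[i[take], ], pool[j[take], ], "random")
        got <- got + length(take)
      }
    }
    ev <- rbind(ev_true, do.call(rbind, parts))
  }
  ev$event <- seq_len(nrow(ev))
  .listmode(ev, geom, seed = NA, duration = NA, window = NA,
            n_subsets = max(pool$subset), angle_step = attr(pool, "angle_step"),
            counters = c(pool_photons = nrow(pool), trues = nrow(ev_true),
                         randoms = nrow(ev) - nrow(ev_true)))
}

# build the wide event table from matched photon rows a / b
.assemble_events <- function(a, b, label) {
  ev <- data.frame(event = seq_len(nrow(a)), time = NA_real_, dt = NA_real_,
                   subset = a$subset, label = label,
                   true_x = a$ox, true_y = a$oy, true_z = a$oz)
  for (side in c("a", "b")) {
    src <- if (side == "a") a else b
    cols <- c("n", "ntrue", "x1", "y1", "z1", "e1", "m1", "x2", "y2", "z2", "e2",
              "m2", "esum", "cx", "cy", "cz", "panel")
    for (cc in cols) ev[[paste0(side, "_", cc)]] <- src[[cc]]
  }
  ev
}
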