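# Compton-kinematics interaction sequencing and random/scattered
# coincidence rejection.
#
# Coincidence events are handled in a wide per-event table (one row per
# coincidence) with, for each side a/b: the observed site count, up to two
# observed sites (position and energy, ordered by the true chain order when
# simulated - algorithms only ever use them symmetrically), the summed
# energy and the energy-weighted centroid. See events_wide().

.side_cols <- function(side) {
  paste0(side, "_", c("n", "x1", "y1", "z1", "e1", "x2", "y2", "z2", "e2",
                      "esum", "cx", "cy", "cz", "panel"))
}

# relative sequence probabilities for every (event, side, ordering)
# candidate; returns data.frame(row, side, ordering, rel)
.seq_candidates <- function(ev, F) {
  out <- list()
  for (side in c("a", "b")) {
    other <- if (side == "a") "b" else "a"
    two <- which(ev[[paste0(side, "_n")]] == 2L)
    if (!length(two)) next
    # reference point on the opposite photon: its only site, or the
    # energy-weighted centroid when it has several
    rx <- ev[[paste0(other, "_cx")]][two]
    ry <- ev[[paste0(other, "_cy")]][two]
    rz <- ev[[paste0(other, "_cz")]][two]
    for (ord in 1:2) {
      f <- if (ord == 1) "1" else "2"; s <- if (ord == 1) "2" else "1"
      fx <- ev[[paste0(side, "_x", f)]][two]
      fy <- ev[[paste0(side, "_y", f)]][two]
      fz <- ev[[paste0(side, "_z", f)]][two]
      sx <- ev[[paste0(side, "_x", s)]][two]
      sy <- ev[[paste0(side, "_y", s)]][two]
      sz <- ev[[paste0(side, "_z", s)]][two]
      E1 <- ev[[paste0(side, "_e", f)]][two]
      v1 <- cbind(fx - rx, fy - ry, fz - rz)   # assumed incoming direction
      v2 <- cbind(sx - fx, sy - fy, sz - fz)   # first -> second
      theta <- vec_angle_deg(v1, v2)
      d2 <- vec_norm(v2)
      i <- .bin_E(F, E1)
      j <- .bin_th(F, theta)
      k <- .bin_d2(F, d2)
      val <- response_value(F, i, j, k)
      s_idx <- .slice_index(F, i, k)
      mx <- rep(0, length(val))
      ok <- !is.na(s_idx)
      mx[ok] <- F$slice_max[s_idx[ok]] / F$N
      rel <- ifelse(mx > 0, val / mx, 0)
      out[[length(out) + 1L]] <-
        data.frame(row = two, side = side, ordering = ord, rel = rel)
    }
  }
  if (!length(out))
    return(data.frame(row = integer(), side = character(),
                      ordering = integer(), rel = numeric()))
  do.call(rbind, out)
}

#' Relative interaction-sequence probabilities for one coincidence event
#'
#' For a coincidence with a two-site Compton photon, evaluates both
#' candidate interaction orderings: each fixes the observed
#' first-interaction energy bin and the inter-interaction distance bin,
#' forms the line from the opposite photon's position through the assumed
#' first site, reads the response matrix at the implied scattering angle,
#' and normalizes by the maximum of that (energy, distance) slice, so the
#' best attainable value is 1.
#'
#' @param event one-row wide event record (see \code{\link{events_wide}})
#' @param F a \code{\link{build_response_matrix}} result
#' @return data.frame with one row per (side, ordering) candidate and its
#'   relative probability in [0, 1]
#' @export
sequence_probabilities <- function(event, F) {
  stopifnot(nrow(event) == 1)
  if (all(event$a_n != 2L) && all(event$b_n != 2L))
    stop("event has no two-site Compton photon")
  .seq_candidates(event, F)[, c("side", "ordering", "rel")]
}

#' Accept or reject coincidence events by Compton kinematics
#'
#' An event with at least one two-site Compton photon is accepted when the
#' best relative sequence probability over all (side, ordering) candidates
#' reaches \code{threshold}; the chosen ordering is the argmax.
#' Single-single events pass through untouched.
#'
#' @param events wide event table (\code{\link{events_wide}})
#' @param F a \code{compton_response}
#' @param threshold rejection threshold on the relative probability
#' @return data.frame with \code{accepted}, \code{best_rel},
#'   \code{best_side}, \code{best_ordering}, \code{is_compton},
#'   \code{threshold}
#' @export
reject_events <- function(events, F, threshold = 0.2) {
  n <- nrow(events)
  cand <- .seq_candidates(events, F)
  best <- data.frame(accepted = rep(TRUE, n), best_rel = rep(NA_real_, n),
                     best_side = rep(NA_character_, n),
                     best_ordering = rep(NA_integer_, n),
                     is_compton = events$a_n == 2L | events$b_n == 2L,
                     threshold = threshold)
  if (nrow(cand)) {
    o <- order(cand$row, -cand$rel)
    cand <- cand[o, ]
    top <- cand[!duplicated(cand$row), ]
    best$best_rel[top$row] <- top$rel
    best$best_side[top$row] <- top$side
    best$best_ordering[top$row] <- top$ordering
    best$accepted[top$row] <- top$rel >= threshold
  }
  best
}

#' @rdname reject_events
#' @param event a one-row wide event record
#' @export
reject_event <- function(event, F, threshold = 0.2) {
  as.list(reject_events(event, F, threshold))
}

#' False-rejection probability of true Compton coincidences
#'
#' Slice-wise below-threshold mass of the response matrix combined by the
#' law of total probability: within each (energy, distance) slice the
#' rejected mass is the sum over angle bins whose value falls below
#' \code{threshold} times the slice maximum, divided by the slice sum;
#' slices are weighted by their share of the total matrix mass.
#'
#' @param F a \code{compton_response}
#' @param threshold rejection threshold in [0, 1]
#' @return probability that a true Compton coincidence drawn from F is
#'   rejected
#' @export
false_rejection_probability <- function(F, threshold = 0.2) {
  stopifnot(threshold >= 0, threshold <= 1)
  M <- F$counts
  below <- col_mass_below(M@p, M@x, ncol(M), threshold)
  sum(below) / F$N
}

#' Noise-equivalent count-rate gain of Compton-based rejection
#'
#' The ratio NECR'/NECR = (1 - false rejection rate)^2 / (1 - rejection
#' rate): the squared retained-trues fraction over the retained-stream
#' fraction. Scale-free - absolute count rates cancel.
#'
#' @param false_rejection_rate fraction of true coincidences rejected
#' @param rejection_rate fraction of the whole stream rejected (< 1)
#' @return the NECR gain factor
#' @export
necr_gain <- function(false_rejection_rate, rejection_rate) {
  stopifnot(all(false_rejection_rate >= 0), all(false_rejection_rate < 1),
            all(rejection_rate >= 0))
  if (any(rejection_rate >= 1)) stop("rejection_rate must be < 1")
  (1 - false_rejection_rate)^2 / (1 - rejection_rate)
}

#' Optimize the rejection threshold by NECR gain
#'
#' Scans thresholds on a grid, computing the empirical rejection rate of
#' the supplied Compton-containing event stream and the model
#' false-rejection probability from the response matrix, and returns the
#' threshold maximizing \code{\link{necr_gain}}.
#'
#' @param F a \code{compton_response}
#' @param events wide event table; only rows with a two-site Compton photon
#'   enter the rejection-rate denominator
#' @param grid thresholds to scan
#' @return list with \code{threshold}, \code{gain}, and the full
#'   \code{curve} (threshold, rejection_rate, false_rejection, gain)
#' @export
optimize_threshold <- function(F, events, grid = seq(0, 1, by = 0.01)) {
  ev <- events[events$a_n == 2L | events$b_n == 2L, , drop = FALSE]
  if (!nrow(ev)) stop("no Compton-containing events in stream")
  dec <- reject_events(ev, F, threshold = 0)
  rel <- dec$best_rel
  M <- F$counts
  curve <- data.frame(threshold = grid)
  curve$rejection_rate <- vapply(grid, function(th) mean(rel < th), 0)
  curve$false_rejection <- vapply(grid, function(th)
    sum(col_mass_below(M@p, M@x, ncol(M), th)) / F$N, 0)
  curve$gain <- ifelse(curve$rejection_rate < 1,
                       (1 - curve$false_rejection)^2 /
                         (1 - curve$rejection_rate), NA_real_)
  best <- which.max(curve$gain)
  list(threshold = grid[best], gain = curve$gain[best], curve = curve)
}

#' True-rejection rate on known-random coincidences
#'
#' Fraction of labeled random coincidences rejected at the given
#' threshold. Labels come from simulator ground truth or from the
#' line-of-response surrogate (\code{\link{lor_misses_object}}).
#'
#' @inheritParams reject_events
#' @return scalar rejection fraction
#' @export
true_rejection_rate <- function(events, F, threshold = 0.2) {
  if (!nrow(events)) stop("empty known-random event set")
  dec <- reject_events(events, F, threshold)
  mean(!dec$accepted[dec$is_compton])
}

#' Line-of-response surrogate label for random coincidences
#'
#' An event is flagged known-random when none of its candidate
#' lines-of-response (all pairings of candidate first-interaction sites on
#' the two sides) passes within the hot-object cylinder (radius
#' \code{radius}, half-length \code{half_length}, axis z through the FOV
#' centre).
#'
#' @param events wide event table
#' @param radius object cylinder radius, mm
#' @param half_length object cylinder half-length, mm
#' @return logical vector, TRUE where every candidate LOR misses the object
#' @export
lor_misses_object <- function(events, radius = 7, half_length = 5) {
  n <- nrow(events)
  miss <- rep(TRUE, n)
  for (ia in 1:2) for (ib in 1:2) {
    pa <- cbind(events[[paste0("a_x", ia)]], events[[paste0("a_y", ia)]],
                events[[paste0("a_z", ia)]])
    pb <- cbind(events[[paste0("b_x", ib)]], events[[paste0("b_y", ib)]],
                events[[paste0("b_z", ib)]])
    ok <- !is.na(pa[, 1]) & !is.na(pb[, 1])
    w <- pb - pa
    # closest approach of the 3-D line to the z axis
    wxy2 <- w[, 1]^2 + w[, 2]^2
    t0 <- ifelse(wxy2 > 0, -(pa[, 1] * w[, 1] + pa[, 2] * w[, 2]) / wxy2, 0)
    cx <- pa[, 1] + t0 * w[, 1]
    cy <- pa[, 2] + t0 * w[, 2]
    cz <- pa[, 3] + t0 * w[, 3]
    hits <- sqrt(cx^2 + cy^2) <= radius & abs(cz) <= half_length
    miss[ok & hits] <- FALSE
  }
  miss
}

#' Tabulate coincidence events by interaction type and energy window
#'
#' Counts events in the four categories (single-site interactions on both
#' sides; an observed two-site Compton on exactly one side; two-site
#' Compton on both sides; everything else, e.g. three or more sites),
#' split by whether both photons' summed energies fall inside the energy
#' window, with column proportions.
#'
#' @param events wide event table
#' @param window energy window, keV
#' @return list with the count matrix \code{counts} (rows: out-of-window,
#'   in-window, total) and matching \code{proportions}
#' @export
classify_and_tabulate <- function(events, window = c(500, 540)) {
  cat_of <- function(na, nb) {
    ifelse(na >= 3 | nb >= 3, "other",
           ifelse(na == 2 & nb == 2, "compton_both",
                  ifelse(na == 2 | nb == 2, "compton_one", "single_single")))
  }
  cats <- c("single_single", "compton_one", "compton_both", "other")
  cl <- factor(cat_of(events$a_n, events$b_n), levels = cats)
  inw <- events$a_esum >= window[1] & events$a_esum <= window[2] &
    events$b_esum >= window[1] & events$b_esum <= window[2]
  tab <- rbind(out_of_window = table(cl[!inw]),
               in_window = table(cl[inw]))
  tab <- rbind(tab, total = colSums(tab))
  prop <- sweep(tab, 2, pmax(tab["total", ], 1), "/")
  list(counts = tab, proportions = prop)
}

#' Rates from printed coincidence count tables
#'
#' Appends the true-rejection rate (rejected known-randoms over
#' known-randoms) to a table of per-subset counts shaped like the
#' prototype's accounting: columns \code{randoms} and
#' \code{rejected_randoms} are required.
#'
#' @param counts data.frame of per-subset event counts
#' @return the table with a \code{true_rejection_rate} column appended
#' @export
coincidence_table_rates <- function(counts) {
  stopifnot(all(c("randoms", "rejected_randoms") %in% names(counts)))
  counts$true_rejection_rate <- counts$rejected_randoms / counts$randoms
  counts
}
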