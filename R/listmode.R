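#' Read and write list-mode coincidence files
#'
#' List-mode datasets are stored in a versioned serialized container: a
#' header (format version, units, seed, geometry hash, acquisition
#' settings) followed by the wide per-event table. The round trip
#' \code{read_listmode(write_listmode(x))} is the identity on all fields.
#' Experimental-style files may omit the ground-truth columns (emission
#' point, true/random label); they load with \code{has_truth = FALSE}.
#' A CSV export is provided for interoperability.
#'
#' @param lm a \code{cztpet_listmode}
#' @param path file path
#' @export
write_listmode <- function(lm, path) {
  stopifnot(inherits(lm, "cztpet_listmode"))
  saveRDS(unclass(lm), path)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("truncated or unreadable list-mode file: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$header))
    stop("corrupted list-mode file: missing header block")
  h <- obj$header
  if (is.null(h$format_version))
    stop("corrupted list-mode header: missing field 'format_version'")
  if (!identical(h$format_version, "cztpet-listmode-1"))
    stop("list-mode format version mismatch: found ", h$format_version)
  if (is.null(h$units) || !identical(h$units$length, "mm") ||
      !identical(h$units$energy, "keV") || !identical(h$units$time, "ns"))
    stop("list-mode unit mismatch: expected mm / keV / ns")
  obj$header$has_truth <- !is.null(obj$events$label)
  structure(obj, class = "cztpet_listmode")
}

#' Drop the simulation ground truth from a dataset
#'
#' Produces an experimental-style dataset: the true/random labels and true
#' emission coordinates are removed.
#' @param lm a \code{cztpet_listmode}
#' @return the dataset without ground-truth columns
#' @export
strip_truth <- function(lm) {
  drop <- intersect(c("label", "true_x", "true_y", "true_z", "a_ntrue", "b_ntrue"),
                    names(lm$events))
  lm$events <- lm$events[, setdiff(names(lm$events), drop), drop = FALSE]
  lm$header$has_truth <- FALSE
  lm
}

#' @rdname write_listmode
#' @export
write_listmode_csv <- function(lm, path) {
  utils::write.csv(lm$events, path, row.names = FALSE)
  invisible(path)
}
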