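#' Four-panel CZT coincidence system geometry
#'
#' Builds the prototype geometry: four CZT detector panels (each 2 x 2
#' modules of 2.2 x 2.2 x 1.0 cm) arranged around the field of view with
#' opposite front faces \code{face_distance} apart, panel normals in the
#' x-y plane and the rotation axis along z. Depth of interaction is measured
#' from the cathode (front) face, increasing toward the anode.
#'
#' The full pose state is the 130-entry parameter vector \code{alpha}:
#' for each of the 4 panels, 6 pose parameters (3 translations in mm, 3
#' rotations in degrees about the panel axes) followed by 6 such parameters
#' for each of its 4 modules (within the panel frame); then 7 parameters for
#' the sample rotation stage (position, axis direction, radius) and 3 for
#' the vertical translation stage direction. The nominal geometry has all
#' pose perturbations zero.
#'
#' @param face_distance distance between opposite panel front faces, mm
#' @param panel_size lateral panel extent, mm
#' @param module_size lateral module extent, mm
#' @param thickness crystal thickness, mm
#' @param lateral_voxels detector voxels per module side (209 um at 100)
#' @param alpha optional 130-entry parameter vector
#' @return object of class \code{system_geometry}
#' @export
system_geometry <- function(face_distance = 80, panel_size = 44,
                            module_size = 22, thickness = 10,
                            lateral_voxels = 100, alpha = NULL) {
  if (is.null(alpha)) {
    alpha <- numeric(130)
    alpha[121:130] <- c(0, 0, 0, 0, 0, 1, 5, 0, 0, 1)  # stage defaults
  }
  stopifnot(length(alpha) == 130)
  g <- structure(list(face_distance = face_distance, panel_size = panel_size,
                      module_size = module_size, thickness = thickness,
                      lateral_voxels = lateral_voxels, alpha = alpha),
                 class = "system_geometry")
  g$frames <- compute_frames(g)
  g
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf(paste0("CZT coincidence system: 4 panels of %g x %g x %g mm ",
                     "(4 modules each),\n  opposite faces %g mm apart, ",
                     "%d x %d detector voxels per module\n"),
              x$panel_size, x$panel_size, x$thickness, x$face_distance,
              x$lateral_voxels, x$lateral_voxels))
  if (any(x$alpha[1:120] != 0)) cat("  (pose perturbations present)\n")
  invisible(x)
}

# base frame of panel 1 (+x): local x,y lateral -> global y,z; local z
# (depth) -> global +x
.panel_base <- matrix(c(0, 1, 0,  0, 0, 1,  1, 0, 0), 3, 3)

panel_alpha <- function(alpha, p) alpha[(p - 1) * 30 + 1:6]
module_alpha <- function(alpha, p, m) alpha[(p - 1) * 30 + 6 + (m - 1) * 6 + 1:6]

# per-panel and per-module rotation matrices and origins (global frame)
compute_frames <- function(g) {
  half <- g$face_distance / 2
  frames <- list(panels = vector("list", 4), modules = vector("list", 16))
  moff <- g$module_size / 2   # nominal module centers at (+-11, +-11)
  mlat <- rbind(c(-moff, -moff), c(moff, -moff), c(-moff, moff), c(moff, moff))
  for (p in 1:4) {
    Rz <- rotation_matrix(0, 0, (p - 1) * 90)
    Rnom <- Rz %*% .panel_base
    onom <- Rz %*% c(half, 0, 0)
    pa <- panel_alpha(g$alpha, p)
    Rp <- Rnom %*% rotation_matrix(pa[4], pa[5], pa[6])
    op <- as.vector(onom + Rnom %*% pa[1:3])
    frames$panels[[p]] <- list(R = Rp, o = op)
    for (m in 1:4) {
      ma <- module_alpha(g$alpha, p, m)
      Rm <- Rp %*% rotation_matrix(ma[4], ma[5], ma[6])
      om <- as.vector(op + Rp %*% c(mlat[m, 1] + ma[1], mlat[m, 2] + ma[2], ma[3]))
      frames$modules[[(p - 1) * 4 + m]] <-
        list(R = Rm, o = om, panel = p, lat = mlat[m, ])
    }
  }
  frames
}

#' Replace the geometry parameter vector
#' @param geom a \code{system_geometry}
#' @param alpha new 130-entry parameter vector
#' @return updated geometry with recomputed frames
#' @export
set_alpha <- function(geom, alpha) {
  stopifnot(length(alpha) == 130)
  geom$alpha <- alpha
  geom$frames <- compute_frames(geom)
  geom
}

# transform global points (n x 3) into panel-local / module-local frames
global_to_panel <- function(geom, p, pts) {
  f <- geom$frames$panels[[p]]
  sweep(pts, 2, f$o) %*% f$R
}
panel_to_global <- function(geom, p, pts) {
  f <- geom$frames$panels[[p]]
  sweep(pts %*% t(f$R), 2, f$o, "+")
}
global_to_module <- function(geom, mod, pts) {
  f <- geom$frames$modules[[mod]]
  sweep(pts, 2, f$o) %*% f$R
}
module_to_global <- function(geom, mod, pts) {
  f <- geom$frames$modules[[mod]]
  sweep(pts %*% t(f$R), 2, f$o, "+")
}

# module id (1..16) from panel id and panel-local lateral coordinates
module_from_panel_xy <- function(p, lx, ly) {
  (p - 1) * 4 + 1 + (lx >= 0) + 2 * (ly >= 0)
}

#' Detector-voxel indexing
#'
#' Maps module-local interaction coordinates to the detector-voxel grid used
#' by the analytic response model: \code{lateral_voxels} x
#' \code{lateral_voxels} voxels of 209 um (at the default 100) covering the
#' anode-pixel footprint, and \code{D} depth-of-interaction sublayers across
#' the crystal thickness.
#'
#' @param geom a \code{system_geometry}
#' @param x,y module-local lateral coordinates, mm
#' @param z module-local depth from the cathode, mm
#' @param D number of DOI bins (1, 2, 4 or 10 supported; any divisor works)
#' @return data.frame with integer columns \code{u}, \code{v} (1-based
#'   lateral indices) and \code{doi} (1-based DOI bin)
#' @export
detector_voxel_index <- function(geom, x, y, z, D = 10) {
  nv <- geom$lateral_voxels
  extent <- 20.9                      # anode footprint, mm
  pitch <- extent / nv
  u <- clamp(floor((x + extent / 2) / pitch), 0, nv - 1) + 1L
  v <- clamp(floor((y + extent / 2) / pitch), 0, nv - 1) + 1L
  dz <- geom$thickness / D
  doi <- clamp(floor(z / dz), 0, D - 1) + 1L
  data.frame(u = as.integer(u), v = as.integer(v), doi = as.integer(doi))
}

# center of a detector voxel / sublayer slice in module-local coordinates
voxel_center_local <- function(geom, u, v, doi, D) {
  nv <- geom$lateral_voxels
  pitch <- 20.9 / nv
  dz <- geom$thickness / D
  cbind((u - 0.5) * pitch - 20.9 / 2, (v - 0.5) * pitch - 20.9 / 2,
        (doi - 0.5) * dz)
}

#' Serialize a geometry to JSON (and back)
#'
#' The file stores the construction dimensions and the full parameter vector
#' \code{alpha} with units (mm, degrees); \code{alpha} round-trips
#' losslessly.
#' @param geom a \code{system_geometry}
#' @param path file path
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(list(
    format = "cztpet-geometry-1", units = list(length = "mm", angle = "deg"),
    face_distance = geom$face_distance, panel_size = geom$panel_size,
    module_size = geom$module_size, thickness = geom$thickness,
    lateral_voxels = geom$lateral_voxels, alpha = geom$alpha),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "cztpet-geometry-1"))
    stop("not a cztpet geometry file (format field mismatch)")
  system_geometry(face_distance = j$face_distance, panel_size = j$panel_size,
                  module_size = j$module_size, thickness = j$thickness,
                  lateral_voxels = j$lateral_voxels, alpha = j$alpha)
}

geometry_hash <- function(geom) {
  v <- c(geom$face_distance, geom$panel_size, geom$module_size,
         geom$thickness, geom$lateral_voxels, geom$alpha)
  sprintf("%08x", sum(as.integer(abs(v * 1000) %% 97) * seq_along(v)) %% .Machine$integer.max)
}
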