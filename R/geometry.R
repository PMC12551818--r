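#' Voxel geometry of an axial slice stack
#'
#' Describes the acquisition grid of a 3D axial stack: field of view in the
#' three anatomical directions (centimetres, as entered on the scanner console)
#' and the reconstruction matrix. Pixel area and slice thickness are derived
#' exactly from FOV/matrix rather than taken from rounded resolution figures:
#' only the exact pixel pitch (e.g. 2 cm / 256 = 78.125 um) makes reported
#' cross-sectional areas integer multiples of the pixel area.
#'
#' @param fov_lr_cm Field of view left-right, cm.
#' @param fov_dv_cm Field of view dorsal-ventral, cm.
#' @param fov_rc_cm Field of view rostral-caudal (slab thickness), cm.
#' @param n_lr,n_dv Matrix size in the left-right / dorsal-ventral direction.
#' @param n_slices Number of axial slices.
#'
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry()
#' pixel_area(g)        # 0.0061035... mm^2
#' slice_thickness(g)   # 0.29166... mm
#' @export
voxel_geometry <- function(fov_lr_cm = 2, fov_dv_cm = 1.5, fov_rc_cm = 0.7,
                           n_lr = 256L, n_dv = 192L, n_slices = 24L) {
  stopifnot(
    is.numeric(fov_lr_cm), is.numeric(fov_dv_cm), is.numeric(fov_rc_cm),
    length(fov_lr_cm) == 1, length(fov_dv_cm) == 1, length(fov_rc_cm) == 1,
    fov_lr_cm > 0, fov_dv_cm > 0, fov_rc_cm > 0
  )
  n_lr <- as.integer(n_lr); n_dv <- as.integer(n_dv); n_slices <- as.integer(n_slices)
  if (n_lr < 8L || n_dv < 8L)
    stop("matrix sizes n_lr and n_dv must be integers >= 8", call. = FALSE)
  if (n_slices < 5L)
    stop("n_slices must be >= 5 (two reference slices plus at least one DRG slice)",
         call. = FALSE)
  structure(
    list(fov_lr_cm = fov_lr_cm, fov_dv_cm = fov_dv_cm, fov_rc_cm = fov_rc_cm,
         n_lr = n_lr, n_dv = n_dv, n_slices = n_slices),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> FOV %g x %g x %g cm, matrix %d x %d x %d\n  pixel %g x %g mm, slice thickness %g mm, pixel area %g mm^2\n",
    x$fov_lr_cm, x$fov_dv_cm, x$fov_rc_cm, x$n_lr, x$n_dv, x$n_slices,
    pixel_pitch(x)["lr"], pixel_pitch(x)["dv"], slice_thickness(x), pixel_area(x)))
  invisible(x)
}

#' In-plane pixel pitch in millimetres
#'
#' @param geometry A [voxel_geometry()].
#' @return Named vector `c(dv = , lr = )` of pixel sizes in mm.
#' @export
pixel_pitch <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  c(dv = 10 * geometry$fov_dv_cm / geometry$n_dv,
    lr = 10 * geometry$fov_lr_cm / geometry$n_lr)
}

#' In-plane pixel area in mm^2
#'
#' `(10 * fov_lr / n_lr) * (10 * fov_dv / n_dv)`. Every cross-sectional area
#' measured by the pipeline is an integer multiple of this quantity.
#'
#' @param geometry A [voxel_geometry()].
#' @return Pixel area in mm^2.
#' @export
pixel_area <- function(geometry) {
  p <- pixel_pitch(geometry)
  unname(p["dv"] * p["lr"])
}

#' Axial slice thickness in millimetres
#'
#' @param geometry A [voxel_geometry()].
#' @return `10 * fov_rc_cm / n_slices`, mm.
#' @export
slice_thickness <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  10 * geometry$fov_rc_cm / geometry$n_slices
}

#' Default acquisition geometry with a reduced slice count
#'
#' The full acquisition covers 24 slices; the delineation operates on a short
#' window (two cord-only reference slices rostral to the ganglion plus the
#' slices containing it). This helper returns a geometry with `n_slices`
#' slices at the same in-plane pitch and the same slice thickness, i.e. the
#' rostral-caudal FOV is scaled with the slice count.
#'
#' @param n_slices Number of slices (default 5, the analysis window).
#' @return A [voxel_geometry()].
#' @export
analysis_window_geometry <- function(n_slices = 5L) {
  g <- voxel_geometry()
  voxel_geometry(fov_lr_cm = g$fov_lr_cm, fov_dv_cm = g$fov_dv_cm,
                 fov_rc_cm = g$fov_rc_cm * n_slices / g$n_slices,
                 n_lr = g$n_lr, n_dv = g$n_dv, n_slices = n_slices)
}
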