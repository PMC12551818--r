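#' Rasterize an ellipse onto the imaging grid
#'
#' A pixel belongs to the region when its centre lies inside the ellipse
#' (the pixel-centre form of the >= 50% partial-volume rule). This is the
#' analytic oracle used throughout: phantom truth counts, recovery bounds, and
#' tests all rasterize with the same rule, so expected pixel counts are exact.
#'
#' Pixel `(i, j)` (1-based, `[dv, lr]`) has its centre at
#' `((i - 0.5) * pitch_dv, (j - 0.5) * pitch_lr)` millimetres.
#'
#' @param center_dv,center_lr Ellipse centre, mm.
#' @param a_dv,a_lr Semi-axes, mm.
#' @param geometry A [voxel_geometry()].
#' @return Logical matrix `[n_dv, n_lr]`.
#' @export
rasterize_ellipse <- function(center_dv, center_lr, a_dv, a_lr, geometry) {
  stopifnot(a_dv > 0, a_lr > 0)
  p <- pixel_pitch(geometry)
  dv <- (seq_len(geometry$n_dv) - 0.5) * p["dv"]
  lr <- (seq_len(geometry$n_lr) - 0.5) * p["lr"]
  u <- (dv - center_dv) / a_dv
  v <- (lr - center_lr) / a_lr
  outer(u^2, v^2, `+`) <= 1
}

#' Boundary perimeter of a pixel region, in pixels
#'
#' Number of region pixels with at least one 4-neighbour outside the region
#' (image border counts as outside). Used as the partial-volume tolerance
#' band: re-rasterizing a region after a sub-pixel move can change its count
#' by at most its boundary pixel count.
#'
#' @param mask Logical matrix.
#' @return Integer perimeter pixel count.
#' @export
region_perimeter_px <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  up    <- pad[1:nrow(mask), 2:(ncol(mask) + 1), drop = FALSE]
  down  <- pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1), drop = FALSE]
  left  <- pad[2:(nrow(mask) + 1), 1:ncol(mask), drop = FALSE]
  right <- pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2), drop = FALSE]
  sum(core & !(up & down & left & right))
}

# internal: point on an ellipse boundary along direction (u_dv, u_lr) from its
# centre; returns distance t with (t*u_dv/a)^2 + (t*u_lr/b)^2 = 1
.ellipse_ray <- function(u_dv, u_lr, a_dv, a_lr) {
  1 / sqrt((u_dv / a_dv)^2 + (u_lr / a_lr)^2)
}

# internal: fast pixel count of (DRG ellipse) \ (cord ellipse), evaluated only
# on the DRG's bounding box; identical result to full-grid rasterization
.count_ellipse_minus_cord <- function(ctr, a, cord_center, cord_a, geometry) {
  p <- pixel_pitch(geometry)
  i0 <- max(1L, floor((ctr[1] - a[1]) / p["dv"] + 0.5))
  i1 <- min(geometry$n_dv, ceiling((ctr[1] + a[1]) / p["dv"] + 0.5))
  j0 <- max(1L, floor((ctr[2] - a[2]) / p["lr"] + 0.5))
  j1 <- min(geometry$n_lr, ceiling((ctr[2] + a[2]) / p["lr"] + 0.5))
  dv <- (i0:i1 - 0.5) * p["dv"]
  lr <- (j0:j1 - 0.5) * p["lr"]
  inside <- outer(((dv - ctr[1]) / a[1])^2, ((lr - ctr[2]) / a[2])^2, `+`) <= 1
  in_cord <- outer(((dv - cord_center[1]) / cord_a[1])^2,
                   ((lr - cord_center[2]) / cord_a[2])^2, `+`) <= 1
  sum(inside & !in_cord)
}
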