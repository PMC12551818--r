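#' Solve DRG in-plane semi-axes for a target cross-sectional area
#'
#' The ganglion's maximal axial cross-section is modelled as an ellipse; this
#' returns semi-axes with fixed aspect ratio whose analytic area
#' `pi * a_dv * a_lr` equals the target CSA. Used by the cohort generator to
#' dial anatomy to a prescribed CSA trajectory.
#'
#' @param csa_mm2 Target area, mm^2.
#' @param aspect Ratio `a_dv / a_lr` (default 0.8: ganglia are slightly
#'   flattened dorso-ventrally).
#' @return Named vector `c(a_dv =, a_lr =)`, mm.
#' @export
drg_semi_axes_for_csa <- function(csa_mm2, aspect = 0.8) {
  stopifnot(csa_mm2 > 0, aspect > 0)
  a_lr <- sqrt(csa_mm2 / (pi * aspect))
  c(a_dv = aspect * a_lr, a_lr = a_lr)
}

#' Specify a synthetic DRG phantom
#'
#' Describes one scan's anatomy on the imaging grid: an elliptic spinal cord
#' constant across slices, a partially suppressed peri-ganglion fat ring, and
#' per-side DRG ellipsoids attached to the ventral-lateral cord surface
#' (mouse DRGs sit against the cord, on its lateral-ventral aspect, and appear
#' hyperintense on T2-weighted images). The ganglion's rostral-caudal span
#' (2 * `a_rc`, default 0.9 mm) covers three 0.29 mm slices; the two most
#' rostral slices contain cord only, mirroring the acquisition layout the
#' delineation assumes.
#'
#' Intensities are arbitrary units (the scanner scale is not calibrated);
#' defaults: background 100, cord 400, DRG 650, fat 900 suppressed by 0.85,
#' Rician noise sigma 40 (SNR ~ 10 for the cord).
#'
#' @param geometry A [voxel_geometry()]; default the 5-slice analysis window.
#' @param cord_center `(dv, lr)` mm; default image centre.
#' @param cord_semi_axes `(a_dv, a_lr)` mm.
#' @param cord_intensity,background_intensity,drg_intensity Signal levels,
#'   must satisfy `drg > cord > background`.
#' @param drg_sides Character subset of `c("left", "right")`; default both.
#' @param drg_semi_axes `(a_dv, a_lr, a_rc)` mm; default in-plane axes solve
#'   to a 50-pixel analytic area with `a_rc = 0.45`.
#' @param drg_center_offset Optional `(dv, lr)` mm offset of the DRG centre
#'   from its default attachment point on the ventral-lateral cord surface
#'   (45 degrees); `NULL` places the ellipsoid externally tangent there.
#' @param drg_center_rc Rostral-caudal DRG centre, mm; default the centre of
#'   slice `n_slices - 1` so the ganglion occupies the last three slices.
#' @param fat_ring `list(standoff, thickness, intensity, suppression_factor)`:
#'   an elliptic annulus `standoff` mm off the cord surface (the epidural
#'   space and dura separate cord from peri-ganglion fat) rendered at
#'   `intensity * (1 - suppression_factor)`.
#' @param noise_sigma Rician noise scale (per quadrature channel), >= 0.
#' @param seed Integer seed; fully determines the rendered stack.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = analysis_window_geometry(5L),
                         cord_center = NULL,
                         cord_semi_axes = c(0.7, 0.9),
                         cord_intensity = 400,
                         background_intensity = 100,
                         drg_intensity = 650,
                         drg_sides = c("left", "right"),
                         drg_semi_axes = NULL,
                         drg_center_offset = NULL,
                         drg_center_rc = NULL,
                         fat_ring = list(standoff = 0.35, thickness = 0.15,
                                         intensity = 900,
                                         suppression_factor = 0.85),
                         noise_sigma = 40,
                         seed = 1L) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (is.null(cord_center))
    cord_center <- c(dv = geometry$fov_dv_cm * 10 / 2,
                     lr = geometry$fov_lr_cm * 10 / 2)
  if (is.null(drg_semi_axes))
    drg_semi_axes <- c(drg_semi_axes_for_csa(50 * pixel_area(geometry)),
                       a_rc = 0.45)
  if (is.null(drg_center_rc))
    drg_center_rc <- (geometry$n_slices - 1.5) * slice_thickness(geometry)
  if (length(drg_sides) && !all(drg_sides %in% c("left", "right")))
    stop("drg_sides must be a subset of c('left', 'right')", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!(drg_intensity > cord_intensity && cord_intensity > background_intensity))
    stop("intensity ordering violated: need drg > cord > background",
         call. = FALSE)
  stopifnot(fat_ring$suppression_factor >= 0, fat_ring$suppression_factor <= 1)
  spec <- structure(
    list(geometry = geometry, cord_center = cord_center,
         cord_semi_axes = cord_semi_axes, cord_intensity = cord_intensity,
         background_intensity = background_intensity,
         drg_intensity = drg_intensity, drg_sides = drg_sides,
         drg_semi_axes = drg_semi_axes, drg_center_offset = drg_center_offset,
         drg_center_rc = drg_center_rc, fat_ring = fat_ring,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec")
  .check_attachment(spec)
  spec
}

# internal: DRG centre for one side (dv, lr) in mm; default placement puts the
# ellipsoid externally tangent to the cord boundary along the 45-degree
# ventral-lateral ray (dv increases ventrally; left = smaller lr)
.drg_center <- function(spec, side, size_factor = 1) {
  u_dv <- 1 / sqrt(2)
  u_lr <- if (side == "left") -1 / sqrt(2) else 1 / sqrt(2)
  t_cord <- .ellipse_ray(u_dv, u_lr, spec$cord_semi_axes[1], spec$cord_semi_axes[2])
  surface <- spec$cord_center + t_cord * c(u_dv, u_lr)
  if (is.null(spec$drg_center_offset)) {
    a <- spec$drg_semi_axes[1:2] * sqrt(size_factor)
    t_drg <- .ellipse_ray(u_dv, u_lr, a[1], a[2])
    offset <- t_drg * c(u_dv, u_lr)
  } else {
    offset <- spec$drg_center_offset * c(1, if (side == "left") -1 else 1)
  }
  unname(surface + offset)
}

# internal: DRG must sit ventral-lateral and attached (tangent or overlapping
# within a small gap tolerance along the centre ray)
.check_attachment <- function(spec) {
  for (side in spec$drg_sides) {
    ctr <- .drg_center(spec, side)
    d <- ctr - spec$cord_center
    if (d[1] <= 0 || (side == "left" && d[2] >= 0) || (side == "right" && d[2] <= 0))
      stop("DRG centre must lie in the ventral-lateral quadrant of the cord",
           call. = FALSE)
    u <- d / sqrt(sum(d^2))
    t_cord <- .ellipse_ray(u[1], u[2], spec$cord_semi_axes[1], spec$cord_semi_axes[2])
    t_drg <- .ellipse_ray(u[1], u[2], spec$drg_semi_axes[1], spec$drg_semi_axes[2])
    gap <- sqrt(sum(d^2)) - t_cord - t_drg
    if (gap > 0.1)
      stop("DRG detached from the cord surface (gap ", signif(gap, 3), " mm)",
           call. = FALSE)
  }
  invisible(TRUE)
}

# internal: noiseless rendering of one slice at rostral-caudal position z_mm,
# with all structure centres shifted by dv_off_mm; returns intensity matrix
.render_slice <- function(spec, z_mm, dv_off_mm = 0, size_factors = NULL) {
  g <- spec$geometry
  img <- matrix(spec$background_intensity, g$n_dv, g$n_lr)
  cc <- spec$cord_center + c(dv_off_mm, 0)
  fr <- spec$fat_ring
  ring_out <- rasterize_ellipse(cc[1], cc[2],
                                spec$cord_semi_axes[1] + fr$standoff + fr$thickness,
                                spec$cord_semi_axes[2] + fr$standoff + fr$thickness, g)
  ring_in <- rasterize_ellipse(cc[1], cc[2],
                               spec$cord_semi_axes[1] + fr$standoff,
                               spec$cord_semi_axes[2] + fr$standoff, g)
  img[ring_out & !ring_in] <- fr$intensity * (1 - fr$suppression_factor)
  cord <- rasterize_ellipse(cc[1], cc[2], spec$cord_semi_axes[1],
                            spec$cord_semi_axes[2], g)
  img[cord] <- spec$cord_intensity
  for (side in spec$drg_sides) {
    sf <- if (is.null(size_factors)) 1 else size_factors[[side]]
    dz <- (z_mm - spec$drg_center_rc) / spec$drg_semi_axes[3]
    if (abs(dz) >= 1) next
    f <- sqrt(1 - dz^2)
    a <- spec$drg_semi_axes[1:2] * sqrt(sf) * f
    ctr <- .drg_center(spec, side, size_factor = sf) + c(dv_off_mm, 0)
    sec <- rasterize_ellipse(ctr[1], ctr[2], a[1], a[2], g)
    if (any(sec[1, ]) || any(sec[g$n_dv, ]) || any(sec[, 1]) || any(sec[, g$n_lr]))
      stop("DRG cross-section touches the image border", call. = FALSE)
    img[sec] <- pmax(img[sec], spec$drg_intensity)
  }
  img
}

# internal: noiseless anatomy + truth for a spec under a global integer dv
# shift (pixels), per-side size factors and intensity scale
.render_noiseless <- function(spec, dv_shift_px = 0L, intensity_scale = 1,
                              size_factors = NULL) {
  g <- spec$geometry
  p <- pixel_pitch(g)
  dv_off <- dv_shift_px * unname(p["dv"])
  cc <- spec$cord_center + c(dv_off, 0)
  cord <- rasterize_ellipse(cc[1], cc[2], spec$cord_semi_axes[1],
                            spec$cord_semi_axes[2], g)
  edge_margin_px <- 5
  rows <- which(apply(cord, 1, any)); cols <- which(apply(cord, 2, any))
  if (length(rows) == 0 ||
      min(rows) <= edge_margin_px || max(rows) > g$n_dv - edge_margin_px ||
      min(cols) <= edge_margin_px || max(cols) > g$n_lr - edge_margin_px)
    stop("anatomy shifted out of frame: cord within 5 px of the image edge",
         call. = FALSE)
  th <- slice_thickness(g)
  arr <- array(0, c(g$n_slices, g$n_dv, g$n_lr))
  for (i in seq_len(g$n_slices))
    arr[i, , ] <- .render_slice(spec, (i - 0.5) * th, dv_off, size_factors)
  truth_sides <- list()
  for (side in spec$drg_sides) {
    sf <- if (is.null(size_factors)) 1 else size_factors[[side]]
    a <- spec$drg_semi_axes[1:2] * sqrt(sf)
    ctr <- .drg_center(spec, side, size_factor = sf) + c(dv_off, 0)
    full <- rasterize_ellipse(ctr[1], ctr[2], a[1], a[2], g)
    region <- full & !cord
    truth_sides[[side]] <- list(
      true_pixel_count = sum(region),
      true_csa = sum(region) * pixel_area(g),
      region = region,
      perimeter_px = region_perimeter_px(region))
  }
  list(intensities = arr * intensity_scale, cord_mask = cord,
       sides = truth_sides)
}

#' Render a synthetic phantom stack with ground truth
#'
#' Produces the stack plus a truth object carrying, per side, the exact
#' pixel count of the DRG's maximal cross-section on the analysis grid
#' (pixel-centre rasterization, cord pixels excluded — the delineation
#' measures the ganglion outside the zeroed cord) and the corresponding
#' quantized CSA. Rician noise is applied as the magnitude of the noiseless
#' signal plus complex Gaussian noise of scale `noise_sigma`; the spec's seed
#' fully determines the output.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `stack` (a [slice_stack()]) and `truth` (list
#'   with `sides` — per side `true_pixel_count`, `true_csa`, `region`,
#'   `perimeter_px` —, `cord_mask`, `applied_shift_px`, `seed`).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  base <- .render_noiseless(spec)
  arr <- .apply_rician(base$intensities, spec$noise_sigma, spec$seed)
  list(stack = slice_stack(arr, spec$geometry),
       truth = list(sides = base$sides, cord_mask = base$cord_mask,
                    applied_shift_px = 0L, seed = spec$seed))
}

# internal: magnitude of (S + sigma Z1) + i sigma Z2
.apply_rician <- function(arr, sigma, seed) {
  if (sigma == 0) return(arr)
  set.seed(seed)
  n <- length(arr)
  sqrt((arr + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
}

#' Render a test-retest phantom pair under repositioning jitter
#'
#' Re-renders one animal's anatomy twice: the retest arm applies a rigid
#' integer dorso-ventral shift (the repositioning error the pipeline's
#' alignment step corrects), a global intensity scale (receiver gain /
#' coil-loading change, applied to signal and noise alike), fresh noise in
#' both arms, and — when `size_cv > 0` — an independent per-arm, per-side
#' log-normal scan-to-scan size factor emulating physiological and
#' partial-volume variation in the apparent cross-section.
#'
#' @param spec A [phantom_spec()] describing the animal.
#' @param jitter List with `dv_shift_px` (integer range, length 2),
#'   `intensity_scale` (range), `size_cv` (coefficient of variation of the
#'   apparent CSA per scan, default 0).
#' @param seed Integer seed for the jitter draws and both noise fields.
#' @return List with elements `test` and `retest`, each as [render_phantom()].
#' @export
render_test_retest <- function(spec,
                               jitter = list(dv_shift_px = c(-3L, 3L),
                                             intensity_scale = c(0.95, 1.05),
                                             size_cv = 0),
                               seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  size_cv <- if (is.null(jitter$size_cv)) 0 else jitter$size_cv
  set.seed(seed)
  shift <- sample(seq(jitter$dv_shift_px[1], jitter$dv_shift_px[2]), 1)
  scale <- runif(1, jitter$intensity_scale[1], jitter$intensity_scale[2])
  sf <- function() {
    if (size_cv == 0) return(list(left = 1, right = 1))
    sdlog <- sqrt(log(1 + size_cv^2))
    list(left = rlnorm(1, -sdlog^2 / 2, sdlog),
         right = rlnorm(1, -sdlog^2 / 2, sdlog))
  }
  sf_test <- sf(); sf_retest <- sf()
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  arm <- function(dv_shift, int_scale, sfac, arm_seed) {
    base <- .render_noiseless(spec, dv_shift_px = dv_shift,
                              intensity_scale = int_scale, size_factors = sfac)
    arr <- .apply_rician(base$intensities, spec$noise_sigma * int_scale, arm_seed)
    list(stack = slice_stack(arr, spec$geometry),
         truth = list(sides = base$sides, cord_mask = base$cord_mask,
                      applied_shift_px = as.integer(dv_shift), seed = arm_seed))
  }
  list(test = arm(0L, 1, sf_test, seeds[1]),
       retest = arm(shift, scale, sf_retest, seeds[2]))
}
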