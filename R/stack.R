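#' Axial slice stack
#'
#' A 3D array of non-negative magnitude-MRI intensities indexed
#' `[slice, dv, lr]` (0-based slice index in all log output maps to the
#' 1-based "slice No." convention of scanner print-outs). The slice axis runs
#' rostral to caudal, the dv axis dorsal to ventral, the lr axis subject-left
#' to subject-right. One fixed convention avoids silent axis flips.
#'
#' @param intensities Numeric 3D array `[slice, dv, lr]`, finite and >= 0.
#' @param geometry A [voxel_geometry()] whose matrix sizes match the array.
#' @return An object of class `slice_stack` with elements `intensities` and
#'   `geometry`.
#' @export
slice_stack <- function(intensities, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("intensities must be a 3D array [slice, dv, lr]", call. = FALSE)
  expected <- c(geometry$n_slices, geometry$n_dv, geometry$n_lr)
  if (!identical(dim(intensities), as.integer(expected)))
    stop(sprintf("array dim (%s) does not match geometry (%s)",
                 paste(dim(intensities), collapse = "x"),
                 paste(expected, collapse = "x")), call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (any(intensities < 0))
    stop("negative intensities: not magnitude MRI data", call. = FALSE)
  structure(list(intensities = intensities, geometry = geometry),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d slices of %d x %d (dv x lr), range [%g, %g]\n",
              dim(x$intensities)[1], dim(x$intensities)[2], dim(x$intensities)[3],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Extract one axial slice as a 2D image
#'
#' @param stack A [slice_stack()].
#' @param i 1-based slice index.
#' @return Matrix `[dv, lr]`.
#' @export
get_slice <- function(stack, i) {
  stopifnot(inherits(stack, "slice_stack"))
  stack$intensities[i, , ]
}

# internal: geometry from NIfTI pixdims + dims (fov derived as n * pitch)
.geometry_from_nifti <- function(dims, pd) {
  voxel_geometry(
    fov_lr_cm = dims[1] * pd[1] / 10, fov_dv_cm = dims[2] * pd[2] / 10,
    fov_rc_cm = dims[3] * pd[3] / 10,
    n_lr = dims[1], n_dv = dims[2], n_slices = dims[3]
  )
}

.check_header_geometry <- function(pd, geometry, tol = 0.01) {
  want <- c(pixel_pitch(geometry)["lr"], pixel_pitch(geometry)["dv"],
            slice_thickness(geometry))
  rel <- abs(pd - want) / want
  if (any(rel > tol))
    stop(sprintf(
      "header voxel sizes (%s mm) disagree with declared geometry (%s mm) by more than %g%%",
      paste(signif(pd, 6), collapse = ", "),
      paste(signif(want, 6), collapse = ", "), 100 * tol), call. = FALSE)
  invisible(TRUE)
}

#' Write a slice stack to NIfTI-1 or multi-page TIFF
#'
#' NIfTI is the primary format and stores intensities in their native units
#' with voxel sizes in the header. TIFF (32-bit float pages, one per slice)
#' only stores values in \[0, 1\], so intensities are divided by a scale
#' factor recorded, together with the voxel geometry, in a JSON sidecar
#' (`<path>.json`).
#'
#' @param stack A [slice_stack()].
#' @param path Output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  g <- stack$geometry
  if (grepl("\\.nii(\\.gz)?$", path)) {
    # NIfTI stores [x, y, z] fastest-first = [lr, dv, slice]
    arr <- aperm(stack$intensities, c(3, 2, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(pixel_pitch(g)["lr"], pixel_pitch(g)["dv"],
                             slice_thickness(g))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    scale <- max(stack$intensities, 1)
    pages <- lapply(seq_len(g$n_slices),
                    function(i) stack$intensities[i, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    sidecar <- list(
      intensity_scale = scale,
      geometry = list(fov_lr_cm = g$fov_lr_cm, fov_dv_cm = g$fov_dv_cm,
                      fov_rc_cm = g$fov_rc_cm, n_lr = g$n_lr, n_dv = g$n_dv,
                      n_slices = g$n_slices))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported extension (use .nii, .nii.gz, .tif or .tiff): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Read a slice stack from NIfTI-1 or multi-page TIFF
#'
#' For NIfTI the geometry is derived from the header voxel sizes; when a
#' `geometry_override` is supplied the header must agree with it within 1% in
#' every voxel dimension. TIFF stacks require the JSON sidecar written by
#' [write_stack()] (TIFF carries no voxel-size metadata).
#'
#' @param path File path.
#' @param geometry_override Optional [voxel_geometry()] declaring the intended
#'   FOV/matrix; checked against the header.
#' @return A [slice_stack()].
#' @export
read_stack <- function(path, geometry_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3)
      stop("expected a 3D NIfTI volume, got ", length(dim(img)), "D", call. = FALSE)
    pd <- RNifti::pixdim(img)[1:3]
    if (is.null(geometry_override)) {
      geometry <- .geometry_from_nifti(dim(img), pd)
    } else {
      stopifnot(inherits(geometry_override, "voxel_geometry"))
      .check_header_geometry(pd, geometry_override)
      geometry <- geometry_override
    }
    arr <- aperm(as.array(img), c(3, 2, 1))
  } else if (grepl("\\.tiff?$", path)) {
    sidecar_path <- paste0(path, ".json")
    if (!file.exists(sidecar_path))
      stop("TIFF stack requires its JSON sidecar: ", sidecar_path, call. = FALSE)
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    gl <- sc$geometry
    geometry <- voxel_geometry(gl$fov_lr_cm, gl$fov_dv_cm, gl$fov_rc_cm,
                               gl$n_lr, gl$n_dv, gl$n_slices)
    if (!is.null(geometry_override)) {
      stopifnot(inherits(geometry_override, "voxel_geometry"))
      pd <- c(pixel_pitch(geometry)["lr"], pixel_pitch(geometry)["dv"],
              slice_thickness(geometry))
      .check_header_geometry(pd, geometry_override)
      geometry <- geometry_override
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(geometry$n_slices, geometry$n_dv, geometry$n_lr))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * sc$intensity_scale
  } else {
    stop("unsupported extension: ", path, call. = FALSE)
  }
  if (any(arr < 0))
    stop("negative intensities in ", path, ": not magnitude MRI data",
         call. = FALSE)
  slice_stack(arr, geometry)
}
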