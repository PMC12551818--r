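#' Build a table of CSA measurement records
#'
#' A CSA record is the tabular unit flowing from segmentation into the
#' reliability and cohort statistics: one delineated DRG on one scan.
#' Cross-sectional area is pixel-quantized: `csa_mm2` must equal
#' `pixel_count * pixel_area(geometry)` exactly, so every reported CSA is an
#' integer multiple of the pixel area.
#'
#' @param animal_id Character animal labels.
#' @param side `"left"` or `"right"`.
#' @param timepoint Age in weeks.
#' @param group Group label.
#' @param pixel_count Non-negative integer delineated pixel counts.
#' @param geometry A [voxel_geometry()] supplying the pixel area.
#' @return A tibble with columns `animal_id, side, timepoint, group,
#'   pixel_count, csa_mm2`.
#' @export
csa_records <- function(animal_id, side, timepoint, group, pixel_count,
                        geometry = voxel_geometry()) {
  side <- as.character(side)
  if (!all(side %in% c("left", "right")))
    stop("side must be 'left' or 'right'", call. = FALSE)
  pixel_count <- as.integer(pixel_count)
  stopifnot(all(pixel_count >= 0))
  tibble::tibble(
    animal_id = as.character(animal_id), side = side,
    timepoint = as.numeric(timepoint), group = as.character(group),
    pixel_count = pixel_count,
    csa_mm2 = pixel_count * pixel_area(geometry)
  )
}

#' Write CSA measurement records to CSV
#'
#' Columns `animal_id,side,timepoint,group,pixel_count,csa_mm2`; areas are
#' written with full precision so the pixel-quantization invariant survives a
#' round trip.
#'
#' @param records Tibble as produced by [csa_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  need <- c("animal_id", "side", "timepoint", "group", "pixel_count", "csa_mm2")
  stopifnot(all(need %in% names(records)))
  out <- records[need]
  out$csa_mm2 <- sprintf("%.9f", out$csa_mm2)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read CSA measurement records from CSV
#'
#' Each row is checked against the quantization invariant
#' `csa_mm2 == pixel_count * pixel_area(geometry)` (to half a pixel area, i.e.
#' allowing only rounding in the stored decimal representation); offending row
#' indices are reported.
#'
#' @param path CSV path written by [write_measurements()].
#' @param geometry The [voxel_geometry()] the areas were computed under.
#' @return A tibble of records.
#' @export
read_measurements <- function(path, geometry = voxel_geometry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           animal_id = readr::col_character(),
                           side = readr::col_character(),
                           timepoint = readr::col_double(),
                           group = readr::col_character(),
                           pixel_count = readr::col_integer(),
                           csa_mm2 = readr::col_double()))
  pa <- pixel_area(geometry)
  bad <- which(abs(tab$csa_mm2 - tab$pixel_count * pa) > pa / 2 + 1e-9)
  if (length(bad))
    stop("rows violating csa = pixel_count x pixel_area: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # snap to the exact quantized value (CSV stores finite decimals)
  tab$csa_mm2 <- tab$pixel_count * pa
  tab
}

#' Bundled wild-type test-retest CSA measurements
#'
#' L4 DRG cross-sectional areas (mm^2) from a five-mouse wild-type
#' repeatability experiment: each animal was scanned, repositioned (or
#' re-scanned the next day), and scanned again, and both DRGs were delineated
#' on each scan, giving ten DRG units with a test and a retest CSA. The
#' `rel_diff_pct` column is the recorded per-unit relative difference in
#' percent. Acquired at the default [voxel_geometry()], so all areas are
#' integer multiples of `pixel_area(voxel_geometry())`.
#'
#' @return A tibble with columns `mouse, side, csa_test_mm2, csa_retest_mm2,
#'   rel_diff_pct`.
#' @export
testretest_csa <- function() {
  path <- system.file("extdata", "testretest_csa.csv", package = "drgvol",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    mouse = readr::col_character(),
                    side = readr::col_character(),
                    csa_test_mm2 = readr::col_double(),
                    csa_retest_mm2 = readr::col_double(),
                    rel_diff_pct = readr::col_double()))
}
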