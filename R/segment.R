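#' Slice selection for the delineation pipeline
#'
#' Two cord-only reference slices immediately rostral to a contiguous run of
#' DRG-bearing slices. Indices are 1-based, matching the "slice No." labels
#' on scanner print-outs.
#'
#' @param reference Two slice indices (cord only, rostral of the ganglion).
#' @param drg One or more contiguous slice indices containing the ganglion.
#' @param n_slices Total slices in the stack, for bounds checking.
#' @return Object of class `slice_selection`.
#' @export
slice_selection <- function(reference, drg, n_slices) {
  reference <- as.integer(reference); drg <- as.integer(drg)
  if (length(reference) != 2)
    stop("exactly two reference slices are required", call. = FALSE)
  if (length(drg) < 1 || (length(drg) > 1 && any(diff(sort(drg)) != 1)))
    stop("drg slices must be a non-empty contiguous run", call. = FALSE)
  if (length(intersect(reference, drg)))
    stop("reference and DRG slice sets must be disjoint", call. = FALSE)
  if (any(c(reference, drg) < 1) || any(c(reference, drg) > n_slices))
    stop("slice indices out of range 1..", n_slices, call. = FALSE)
  if (!identical(sort(reference), c(min(drg) - 2L, min(drg) - 1L)))
    stop("reference slices must be the two slices immediately rostral to the DRG run",
         call. = FALSE)
  structure(list(reference = sort(reference), drg = sort(drg)),
            class = "slice_selection")
}

# internal: 8-connected labeling (EBImage::bwlabel is 4-connected; merge
# labels that touch diagonally via union-find)
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nr - 1), if (sh[2] == 1) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr, if (sh[2] == 1) 2:nc else 1:(nc - 1)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      for (k in which(sel)) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# internal: foreground threshold. Otsu alone fails on these images: the
# background vastly outnumbers the cord, so under noise Otsu splits the
# background mode instead of background vs cord. Guard it with a robust
# background ceiling (median + 5 MAD); both terms scale with receiver gain.
.fg_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(NULL)
  max(EBImage::otsu(EBImage::Image(img), range = rng),
      stats::median(img) + 5 * stats::mad(img))
}

# internal: provisional cord = foreground-thresholded component whose
# centroid is nearest the image centre; list(mask, centroid = c(dv, lr))
.provisional_cord <- function(img) {
  thr <- .fg_threshold(img)
  if (is.null(thr)) return(NULL)
  lab <- EBImage::bwlabel((img > thr) * 1)
  n <- max(lab)
  if (n == 0) return(NULL)
  ctr <- c(nrow(img), ncol(img)) / 2
  best <- NULL; best_d <- Inf
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 10) next    # speckle
    cen <- colMeans(idx)
    d <- sum((cen - ctr)^2)
    if (d < best_d) { best_d <- d; best <- k }
  }
  if (is.null(best)) return(NULL)
  mask <- lab == best
  idx <- which(mask, arr.ind = TRUE)
  list(mask = mask, centroid = c(dv = mean(idx[, 1]), lr = mean(idx[, 2])))
}

#' Identify the DRG-bearing slices
#'
#' Mouse ganglia lie against the cord with no intensity contrast between the
#' two, so on DRG-bearing slices the Otsu foreground is a single cord+DRG
#' component. In `auto` mode each slice's cord core is therefore recovered by
#' a morphological opening (disc of `cord_brush_px`, small enough to erase a
#' ganglion-sized bulge but not the cord) and the slice is scored by the
#' summed intensity of above-Otsu pixels outside that core (beyond its
#' gradient skirt), ventral of its centroid — the ventral-lateral quadrants
#' where mouse DRGs appear. The maximal contiguous run of slices scoring more
#' than 1.25 times the minimum-scoring slice (plus a tenth of the score
#' range, guarding against isolated noise pixels) is taken as the DRG run,
#' with the two slices rostral of it as the cord-only references. In `config` mode
#' a supplied selection is validated and passed through.
#'
#' @param stack A [slice_stack()].
#' @param mode `"auto"` or `"config"`.
#' @param config_selection A [slice_selection()] (config mode).
#' @param cord_brush_px Odd disc diameter for the cord-core opening
#'   (default 11 px: larger than a ganglion cross-section, smaller than the
#'   cord).
#' @return A [slice_selection()].
#' @export
select_drg_slices <- function(stack, mode = c("auto", "config"),
                              config_selection = NULL, cord_brush_px = 11L) {
  stopifnot(inherits(stack, "slice_stack"))
  mode <- match.arg(mode)
  ns <- stack$geometry$n_slices
  if (mode == "config") {
    if (is.null(config_selection))
      stop("config mode requires a slice_selection", call. = FALSE)
    stopifnot(inherits(config_selection, "slice_selection"))
    if (max(config_selection$drg) > ns)
      stop("selection exceeds stack", call. = FALSE)
    return(config_selection)
  }
  brush <- EBImage::makeBrush(as.integer(cord_brush_px), "disc")
  scores <- vapply(seq_len(ns), function(i) {
    img <- get_slice(stack, i)
    thr <- .fg_threshold(img)
    if (is.null(thr)) return(0)
    pc <- .provisional_cord(img)
    if (is.null(pc)) return(0)
    # heal noise holes and ragged edges before the opening, or the disc
    # cannot fit inside the cord and the core vanishes
    solid <- EBImage::fillHull(EBImage::closing(pc$mask * 1,
                                                EBImage::makeBrush(3, "box")))
    core <- EBImage::opening(solid, brush) > 0
    if (!any(core)) return(0)
    idx <- which(core, arr.ind = TRUE)
    dist <- EBImage::distmap((!core) * 1)
    sel <- img > thr & !core & dist > 2 & row(img) > mean(idx[, 1])
    sum(img[sel])
  }, 0)
  # 1.25x the minimum slice, plus a tenth of the score range: with a near-zero
  # minimum the multiplicative rule alone would let isolated noise pixels
  # qualify a cord-only slice
  qualifies <- scores > 1.25 * min(scores) + 0.1 * diff(range(scores)) &
    scores > 0
  if (!any(qualifies))
    stop("no DRG-bearing slice run found: lateral-ventral signal is flat across slices",
         call. = FALSE)
  runs <- rle(qualifies)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  run_score <- vapply(cand, function(r) sum(scores[starts[r]:ends[r]]), 0)
  r <- cand[which.max(run_score)]
  drg <- starts[r]:ends[r]
  if (min(drg) < 3)
    stop("DRG run touches the rostral stack boundary: fewer than 2 reference slices available",
         call. = FALSE)
  slice_selection(c(min(drg) - 2L, min(drg) - 1L), drg, ns)
}

# internal: shift a matrix s rows down (dv direction), zero fill
.shift_rows <- function(m, s) {
  if (s == 0) return(m)
  out <- matrix(0, nrow(m), ncol(m))
  if (s > 0) out[(1 + s):nrow(m), ] <- m[1:(nrow(m) - s), ]
  else out[1:(nrow(m) + s), ] <- m[(1 - s):nrow(m), ]
  out
}

#' Align slices in the dorso-ventral direction
#'
#' Axial slices may be vertically offset against each other when the cord is
#' not perfectly parallel to the magnet axis. Each slice is shifted by the
#' integer dorso-ventral offset that maximizes the binary overlap of its
#' provisional cord component with that of the first reference slice
#' (search range +/- `max_shift` pixels, ties broken toward zero shift).
#'
#' @param stack A [slice_stack()].
#' @param selection A [slice_selection()].
#' @param max_shift Search half-range in pixels (default 10).
#' @return List with `stack` (aligned) and `shifts` (integer per slice, the
#'   applied dv offsets).
#' @export
align_dorsoventral <- function(stack, selection, max_shift = 10L) {
  stopifnot(inherits(stack, "slice_stack"), inherits(selection, "slice_selection"))
  ref <- .provisional_cord(get_slice(stack, selection$reference[1]))
  if (is.null(ref)) stop("no cord component in the first reference slice",
                         call. = FALSE)
  ns <- stack$geometry$n_slices
  shifts <- integer(ns)
  arr <- stack$intensities
  cand <- seq(-max_shift, max_shift)
  cand <- cand[order(abs(cand), -sign(cand))]   # 0, 1, -1, 2, -2, ...
  for (i in seq_len(ns)) {
    pc <- .provisional_cord(arr[i, , ])
    if (is.null(pc)) next
    ov <- vapply(cand, function(s) sum(.shift_rows(pc$mask, s) & ref$mask), 0L)
    best <- cand[which.max(ov)]   # first max in candidate order = nearest zero
    if (abs(best) == max_shift)
      stop("optimal shift at the search-range boundary (slice ", i,
           "): gross misalignment", call. = FALSE)
    shifts[i] <- best
    if (best != 0) arr[i, , ] <- .shift_rows(arr[i, , ], best)
  }
  list(stack = slice_stack(arr, stack$geometry), shifts = shifts)
}

#' Average the two cord-only reference slices
#'
#' @param stack An aligned [slice_stack()].
#' @param selection A [slice_selection()].
#' @return 2D matrix, the pixelwise mean of the two reference slices.
#' @export
average_reference <- function(stack, selection) {
  stopifnot(inherits(stack, "slice_stack"), inherits(selection, "slice_selection"))
  (get_slice(stack, selection$reference[1]) +
     get_slice(stack, selection$reference[2])) / 2
}

#' Detect the spinal cord edge on the averaged reference image
#'
#' 3x3 smoothed-gradient (Sobel) magnitude, thresholded (automatic threshold:
#' 4x the mean gradient magnitude), followed by a 3x3 morphological closing
#' that seals gaps of up to one pixel. Among the resulting edge components
#' the one forming the innermost closed contour around the provisional cord
#' (the Otsu component nearest the image centre) is returned; fat-rim or
#' other peripheral contours enclosing the cord from further out are thereby
#' ignored.
#'
#' @param reference_image 2D matrix from [average_reference()].
#' @param threshold `"auto"` or a numeric gradient-magnitude threshold.
#' @return Object of class `cord_outline`: list with `edge` (logical matrix),
#'   `interior` (logical matrix strictly inside the edge), `closed` (flag).
#' @export
detect_cord_edge <- function(reference_image, threshold = "auto") {
  stopifnot(is.matrix(reference_image))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/d(lr), smoothed over dv
  ky <- t(kx)
  gx <- EBImage::filter2(EBImage::Image(reference_image), kx, boundary = "replicate")
  gy <- EBImage::filter2(EBImage::Image(reference_image), ky, boundary = "replicate")
  gm <- sqrt(as.matrix(gx)^2 + as.matrix(gy)^2)
  thr <- if (identical(threshold, "auto")) 4 * mean(gm) else threshold
  edge <- gm > thr
  if (!any(edge))
    stop("no closed cord contour: gradient magnitude below threshold everywhere",
         call. = FALSE)
  pc <- .provisional_cord(reference_image)
  if (is.null(pc))
    stop("no cord-like bright region in the reference image", call. = FALSE)
  anchor <- round(pc$centroid)
  # close each edge component separately: the 3x3 closing heals <= 1 px gaps
  # in a contour without welding it to a neighbouring structure's contour
  lab <- .label8(edge)
  brush <- EBImage::makeBrush(3, "box")
  best <- NULL; best_area <- Inf
  for (k in seq_len(max(lab))) {
    comp <- EBImage::closing((lab == k) * 1, brush) > 0
    filled <- EBImage::fillHull(comp * 1) > 0
    interior <- filled & !comp
    if (!any(interior)) next
    if (!interior[anchor[1], anchor[2]] && !comp[anchor[1], anchor[2]]) next
    if (sum(filled) < best_area) {
      best <- list(edge = comp, interior = interior)
      best_area <- sum(filled)
    }
  }
  if (is.null(best))
    stop("no closed cord contour after gap closing", call. = FALSE)
  structure(c(best, list(closed = TRUE)), class = "cord_outline")
}

#' Fill the cord outline into a binary cord mask
#'
#' Interior fill of a closed outline, edge pixels included. The mask must be
#' a single connected component without holes and of anatomically plausible
#' size.
#'
#' @param outline A closed [detect_cord_edge()] result.
#' @param area_bounds Plausible mask area in pixels at the default geometry.
#' @return Logical matrix (`TRUE` = cord).
#' @export
fill_cord <- function(outline, area_bounds = c(200, 3000)) {
  stopifnot(inherits(outline, "cord_outline"))
  if (!isTRUE(outline$closed))
    stop("outline is not closed: cord mask undefined", call. = FALSE)
  mask <- (outline$edge | outline$interior)
  mask <- EBImage::fillHull(mask * 1) > 0
  lab <- .label8(mask)
  if (max(lab) != 1)
    stop("cord mask is not a single connected component", call. = FALSE)
  a <- sum(mask)
  if (a < area_bounds[1] || a > area_bounds[2])
    stop(sprintf("cord mask area %d px outside plausible bounds [%d, %d]",
                 a, area_bounds[1], area_bounds[2]), call. = FALSE)
  mask
}

#' Maximum intensity projection over the DRG slices
#'
#' @param stack An aligned [slice_stack()].
#' @param selection A [slice_selection()].
#' @return 2D matrix, the pixelwise maximum over the DRG slices.
#' @export
project_max <- function(stack, selection) {
  stopifnot(inherits(stack, "slice_stack"), inherits(selection, "slice_selection"))
  sub <- stack$intensities[selection$drg, , , drop = FALSE]
  apply(sub, c(2, 3), max)
}

#' Zero the cord region of the projection
#'
#' @param mip 2D matrix from [project_max()].
#' @param mask Cord mask from [fill_cord()].
#' @return `mip` with exactly the mask pixels set to zero.
#' @export
mask_cord <- function(mip, mask) {
  if (!identical(dim(mip), dim(mask)))
    stop("mip and mask shapes disagree", call. = FALSE)
  mip[mask] <- 0
  mip
}

#' Delineate the DRGs on the cord-masked projection
#'
#' The ganglion is the hyperintense structure left after cord zeroing. In
#' `auto` mode pixels brighter than `rel_threshold` times the mean projection
#' intensity inside the cord mask are grouped by 8-connectivity, and per side
#' the component adjacent to the cord's ventral-lateral quadrant with the
#' largest overlap of that quadrant is selected (components further than
#' `adjacency_px` from the cord are only considered when no adjacent one
#' exists). Components below `min_px` are rejected; components above
#' `max_px` are kept but flagged. In `manual_roi` mode the same thresholding
#' is restricted to supplied per-side rectangles. An absent DRG on a side is
#' a legal outcome, reported as `NULL` with a note.
#'
#' @param masked_mip Projection with the cord zeroed ([mask_cord()]).
#' @param mask Cord mask.
#' @param mip The projection before masking (supplies the cord mean
#'   intensity for the threshold).
#' @param rel_threshold Threshold as a fraction of the cord mean (default 1.10).
#' @param min_px,max_px Component size limits (defaults 5 and 200).
#' @param adjacency_px Maximum pixel distance from the cord for a component
#'   to count as adjacent (default 10).
#' @param roi Optional `list(left =, right =)` of rectangles
#'   `c(dv0, dv1, lr0, lr1)` switching to manual-ROI mode.
#' @return Object of class `drg_delineation`: per side a logical pixel mask
#'   or `NULL`, plus `mode`, `threshold`, `flags`, `notes`.
#' @export
delineate_drg <- function(masked_mip, mask, mip, rel_threshold = 1.10,
                          min_px = 5L, max_px = 200L, adjacency_px = 10,
                          roi = NULL) {
  stopifnot(identical(dim(masked_mip), dim(mask)),
            identical(dim(mip), dim(mask)))
  mode <- if (is.null(roi)) "auto" else "manual_roi"
  thr <- rel_threshold * mean(mip[mask])
  cand <- masked_mip > thr & !mask
  idx <- which(mask, arr.ind = TRUE)
  cen <- c(dv = mean(idx[, 1]), lr = mean(idx[, 2]))
  dist_to_cord <- EBImage::distmap((!mask) * 1)
  out <- list(left = NULL, right = NULL)
  flags <- character(); notes <- character()
  for (side in c("left", "right")) {
    cside <- cand
    if (mode == "manual_roi") {
      r <- roi[[side]]
      if (is.null(r)) { notes <- c(notes, paste0(side, ": no ROI supplied")); next }
      keep <- matrix(FALSE, nrow(cand), ncol(cand))
      keep[r[1]:r[2], r[3]:r[4]] <- TRUE
      cside <- cand & keep
    }
    lab <- .label8(cside)
    if (max(lab) == 0) {
      notes <- c(notes, paste0(side, ": no suprathreshold component"))
      next
    }
    lateral <- if (side == "left") col(cand) < cen["lr"] else col(cand) > cen["lr"]
    quadrant <- row(cand) > cen["dv"] & lateral
    comps <- seq_len(max(lab))
    overlap <- vapply(comps, function(k) sum(lab == k & quadrant), 0L)
    comps <- comps[overlap > 0]
    if (!length(comps)) {
      notes <- c(notes, paste0(side, ": no component in the ventral-lateral quadrant"))
      next
    }
    adj <- vapply(comps, function(k) min(dist_to_cord[lab == k]) <= adjacency_px,
                  TRUE)
    if (any(adj)) comps <- comps[adj]
    k <- comps[which.max(overlap[comps])]
    comp <- lab == k
    sz <- sum(comp)
    if (sz < min_px) {
      notes <- c(notes, sprintf("%s: component of %d px below min_px, rejected",
                                side, sz))
      next
    }
    if (sz > max_px)
      flags <- c(flags, sprintf("%s: component of %d px exceeds max_px", side, sz))
    out[[side]] <- comp
  }
  structure(list(left = out$left, right = out$right, mode = mode,
                 threshold = thr, flags = flags, notes = notes),
            class = "drg_delineation")
}

#' Measure cross-sectional areas from a delineation
#'
#' The delineated pixels of each side are summed; CSA is the pixel count
#' times the pixel area, i.e. the maximal axial cross-section of the
#' ganglion, the scalar surrogate for its volume.
#'
#' @param delineation A [delineate_drg()] result.
#' @param geometry The stack's [voxel_geometry()].
#' @param animal_id,timepoint,group Identifiers for the emitted records.
#' @return Tibble of [csa_records()], one row per present side.
#' @export
measure_csa <- function(delineation, geometry, animal_id = "animal",
                        timepoint = NA_real_, group = "unknown") {
  stopifnot(inherits(delineation, "drg_delineation"))
  sides <- c("left", "right")[!vapply(delineation[c("left", "right")], is.null, TRUE)]
  if (!length(sides)) {
    return(csa_records(character(), character(), numeric(), character(),
                       integer(), geometry))
  }
  counts <- vapply(sides, function(s) sum(delineation[[s]]), 0L)
  csa_records(rep(animal_id, length(sides)), sides,
              rep(timepoint, length(sides)), rep(group, length(sides)),
              counts, geometry)
}

#' Run the full DRG delineation pipeline on one stack
#'
#' Composes slice selection, dorso-ventral alignment, reference averaging,
#' cord edge detection, interior fill, maximum intensity projection, cord
#' zeroing, DRG delineation and CSA measurement. All intermediates are
#' returned for audit; a cord-only stack (no DRG-bearing slices found in
#' auto selection) yields an empty record table with a log note rather than
#' an error. Other stage failures propagate with the stage name attached.
#'
#' @param stack A [slice_stack()].
#' @param selection_mode `"auto"` or `"config"`.
#' @param config_selection A [slice_selection()] for config mode.
#' @param edge_threshold `"auto"` or numeric, see [detect_cord_edge()].
#' @param rel_threshold,min_px,max_px,adjacency_px,roi See [delineate_drg()].
#' @param animal_id,timepoint,group Identifiers for the emitted records.
#' @return List with `records` (tibble) and `intermediates` (list: selection,
#'   shifts, reference, outline, mask, mip, masked_mip, delineation, log).
#' @export
run_pipeline <- function(stack, selection_mode = c("auto", "config"),
                         config_selection = NULL, edge_threshold = "auto",
                         rel_threshold = 1.10, min_px = 5L, max_px = 200L,
                         adjacency_px = 10, roi = NULL,
                         animal_id = "animal", timepoint = NA_real_,
                         group = "unknown") {
  stopifnot(inherits(stack, "slice_stack"))
  selection_mode <- match.arg(selection_mode)
  log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  selection <- tryCatch(
    select_drg_slices(stack, selection_mode, config_selection),
    error = function(e) {
      if (grepl("no DRG-bearing slice run", conditionMessage(e))) NULL
      else stop(sprintf("stage select: %s", conditionMessage(e)), call. = FALSE)
    })
  if (is.null(selection)) {
    log <- c(log, "no DRG slices: empty measurement set")
    empty <- csa_records(character(), character(), numeric(), character(),
                         integer(), stack$geometry)
    return(list(records = empty,
                intermediates = list(selection = NULL, log = log)))
  }
  log <- c(log, sprintf("selection: reference %s, drg %s",
                        paste(selection$reference, collapse = ","),
                        paste(selection$drg, collapse = ",")))
  ali <- stage("align", align_dorsoventral(stack, selection))
  log <- c(log, paste("shifts:", paste(ali$shifts, collapse = ",")))
  ref <- stage("average", average_reference(ali$stack, selection))
  outline <- stage("edge", detect_cord_edge(ref, threshold = edge_threshold))
  mask <- stage("fill", fill_cord(outline))
  mip <- stage("mip", project_max(ali$stack, selection))
  mmip <- stage("mask", mask_cord(mip, mask))
  del <- stage("delineate",
               delineate_drg(mmip, mask, mip, rel_threshold = rel_threshold,
                             min_px = min_px, max_px = max_px,
                             adjacency_px = adjacency_px, roi = roi))
  log <- c(log, sprintf("delineation threshold: %.3f", del$threshold),
           del$notes, del$flags)
  records <- stage("measure",
                   measure_csa(del, stack$geometry, animal_id, timepoint, group))
  list(records = records,
       intermediates = list(selection = selection, shifts = ali$shifts,
                            reference = ref, outline = outline, mask = mask,
                            mip = mip, masked_mip = mmip, delineation = del,
                            log = log))
}
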