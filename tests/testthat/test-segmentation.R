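test_that("slice selection finds the DRG run with its rostral references", {
  ph <- noiseless_phantom()
  sel <- select_drg_slices(ph$stack)
  expect_identical(sel$reference, c(1L, 2L))
  expect_identical(sel$drg, c(3L, 4L, 5L))

  cord_only <- render_phantom(phantom_spec(noise_sigma = 0,
                                           drg_sides = character(0)))
  expect_error(select_drg_slices(cord_only$stack), "no DRG-bearing slice run")

  # single-slice ganglion (0.3 mm span)
  base <- phantom_spec(noise_sigma = 0)
  short <- render_phantom(phantom_spec(
    noise_sigma = 0, drg_semi_axes = c(base$drg_semi_axes[1:2], a_rc = 0.15)))
  expect_length(select_drg_slices(short$stack)$drg, 1)

  # config mode validates its selection
  expect_error(slice_selection(c(1, 2), c(3, 5), 5), "contiguous")
  expect_error(slice_selection(c(1, 3), c(4, 5), 5), "immediately rostral")
  expect_error(slice_selection(c(2, 3), 3:5, 5), "disjoint")
  expect_identical(select_drg_slices(ph$stack, "config",
                                     slice_selection(c(1, 2), 3:5, 5))$drg,
                   c(3L, 4L, 5L))
})

test_that("dorso-ventral alignment inverts constructed shifts and is exact under noise", {
  ph <- noiseless_phantom()
  sel <- slice_selection(c(1, 2), 3:5, 5)
  ali0 <- align_dorsoventral(ph$stack, sel)
  expect_identical(ali0$shifts, integer(5))

  arr <- ph$stack$intensities
  pre <- c(0L, 0L, 3L, 3L, 3L)
  for (i in 1:5) arr[i, , ] <- drgvol:::.shift_rows(arr[i, , ], pre[i])
  ali <- align_dorsoventral(slice_stack(arr, ph$stack$geometry), sel)
  expect_identical(ali$shifts, -pre)

  # noisy recovery: shifts drawn in +/-5 px at cord SNR 10
  hits <- 0; trials <- 30
  for (s in seq_len(trials)) {
    set.seed(1000 + s)
    drawn <- c(0L, sample(-5:5, 4, replace = TRUE))
    phn <- render_phantom(phantom_spec(noise_sigma = 40, seed = 2000 + s))
    arr <- phn$stack$intensities
    for (i in 1:5) arr[i, , ] <- drgvol:::.shift_rows(arr[i, , ], drawn[i])
    ali <- align_dorsoventral(slice_stack(arr, phn$stack$geometry), sel)
    if (identical(ali$shifts, -drawn)) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * trials))

  # a shift at the search boundary signals gross misalignment
  arr <- ph$stack$intensities
  arr[3, , ] <- drgvol:::.shift_rows(arr[3, , ], 15L)
  expect_error(align_dorsoventral(slice_stack(arr, ph$stack$geometry), sel),
               "search-range boundary")
})

test_that("reference averaging is the pixelwise mean and suppresses noise by sqrt(2)", {
  g <- voxel_geometry(fov_lr_cm = 1, fov_dv_cm = 1, fov_rc_cm = 0.15,
                      n_lr = 128, n_dv = 128, n_slices = 5)
  arr <- array(10, c(5, 128, 128)); arr[2, , ] <- 20
  st <- slice_stack(arr, g)
  sel <- slice_selection(c(1, 2), c(3, 4), 5)
  expect_true(all(average_reference(st, sel) == 15))

  set.seed(11)
  arr <- array(1000 + rnorm(5 * 128 * 128, sd = 30), c(5, 128, 128))
  st <- slice_stack(arr, g)
  avg <- average_reference(st, sel)
  expect_equal(sd(avg) / sd(arr[1, , ]), 1 / sqrt(2), tolerance = 0.1)
})

test_that("cord edge detection hugs the analytic boundary and rejects flat images", {
  spec <- phantom_spec(noise_sigma = 0)
  ph <- noiseless_phantom()
  sel <- slice_selection(c(1, 2), 3:5, 5)
  ref <- average_reference(ph$stack, sel)
  o <- detect_cord_edge(ref)
  expect_true(o$closed)
  # radial offset of every edge pixel from the analytic cord ellipse
  p <- pixel_pitch(spec$geometry)
  idx <- which(o$edge, arr.ind = TRUE)
  dv <- (idx[, 1] - 0.5) * p["dv"]; lr <- (idx[, 2] - 0.5) * p["lr"]
  rn <- sqrt(((dv - spec$cord_center[1]) / spec$cord_semi_axes[1])^2 +
               ((lr - spec$cord_center[2]) / spec$cord_semi_axes[2])^2)
  offset_px <- (rn - 1) * sqrt(prod(spec$cord_semi_axes)) / mean(p)
  expect_lte(max(abs(offset_px)), 1.5)

  expect_error(detect_cord_edge(matrix(7, 64, 64)), "no closed cord contour|bright")
})

test_that("cord masks stay within the analytic area plus the edge band under noise", {
  true_px <- sum(noiseless_phantom()$truth$cord_mask)
  perim <- region_perimeter_px(noiseless_phantom()$truth$cord_mask)
  sel <- slice_selection(c(1, 2), 3:5, 5)
  for (s in 1:10) {
    ph <- render_phantom(phantom_spec(noise_sigma = 40, seed = 300 + s))
    ref <- average_reference(align_dorsoventral(ph$stack, sel)$stack, sel)
    m <- fill_cord(detect_cord_edge(ref))
    expect_gte(sum(m), true_px)
    expect_lte(sum(m), true_px + 2 * perim)
  }
})

test_that("outline filling includes the edge, bounds the area, and needs closure", {
  # constructed circular outline of radius 10 px
  ring <- matrix(FALSE, 64, 64)
  th <- seq(0, 2 * pi, length.out = 200)
  ring[cbind(round(32 + 10 * sin(th)), round(32 + 10 * cos(th)))] <- TRUE
  outline <- structure(list(edge = ring, interior = matrix(FALSE, 64, 64),
                            closed = TRUE), class = "cord_outline")
  area <- sum(fill_cord(outline, area_bounds = c(100, 3000)))
  expect_gte(area, pi * 9^2)
  expect_lte(area, pi * 11^2)

  open_outline <- structure(list(edge = ring, interior = matrix(FALSE, 64, 64),
                                 closed = FALSE), class = "cord_outline")
  expect_error(fill_cord(open_outline), "not closed")
})

test_that("maximum intensity projection is the pixelwise slice maximum", {
  ph <- noiseless_phantom()
  one <- slice_selection(c(2, 3), 4, 5)
  expect_identical(project_max(ph$stack, one), get_slice(ph$stack, 4))
  sel <- slice_selection(c(1, 2), 3:5, 5)
  mip <- project_max(ph$stack, sel)
  for (i in 3:5) expect_true(all(mip >= get_slice(ph$stack, i)))
  # the ganglion's maximal section lives in the middle slice, so the MIP
  # equals that slice wherever the ganglion appears
  mid <- get_slice(ph$stack, 4)
  region <- noiseless_phantom()$truth$sides$left$region
  expect_identical(mip[region], mid[region])
})

test_that("cord zeroing changes exactly the mask pixels", {
  set.seed(12)
  mip <- matrix(runif(64 * 48, 1, 10), 48, 64)
  mask <- matrix(FALSE, 48, 64); mask[10:20, 30:40] <- TRUE
  out <- mask_cord(mip, mask)
  expect_true(all(out[mask] == 0))
  expect_identical(out[!mask], mip[!mask])
  expect_equal(sum(out), sum(mip) - sum(mip[mask]))
  expect_identical(mask_cord(mip, matrix(FALSE, 48, 64)), mip)
  expect_true(all(mask_cord(mip, matrix(TRUE, 48, 64)) == 0))
  expect_error(mask_cord(mip, mask[1:10, ]), "disagree")
})

test_that("delineation recovers phantom ganglia and prefers cord-adjacent components", {
  ph <- noiseless_phantom()
  res <- run_pipeline(ph$stack)
  for (side in c("left", "right")) {
    tr <- ph$truth$sides[[side]]
    got <- res$records$pixel_count[res$records$side == side]
    expect_length(got, 1)
    expect_lte(abs(got - tr$true_pixel_count), tr$perimeter_px)
  }

  # constructed two-blob scene: a decoy further from the cord wins on
  # quadrant overlap but the adjacent component must be chosen
  mask <- matrix(FALSE, 96, 96)
  mask[40:56, 40:56] <- TRUE          # square "cord"
  mip <- matrix(100, 96, 96); mip[mask] <- 400
  mip[58:62, 30:34] <- 650            # adjacent blob, ventral-left, 25 px
  mip[80:88, 5:13] <- 650             # decoy far away, ventral-left, 81 px
  del <- delineate_drg(mask_cord(mip, mask), mask, mip)
  expect_equal(sum(del$left), 25)

  # no suprathreshold signal: both sides legally absent
  flat <- matrix(100, 96, 96); flat[mask] <- 400
  del2 <- delineate_drg(mask_cord(flat, mask), mask, flat)
  expect_null(del2$left); expect_null(del2$right)
  expect_length(del2$notes, 2)

  # min_px rejection and max_px flagging
  tiny <- flat; tiny[60:61, 30:31] <- 650
  del3 <- delineate_drg(mask_cord(tiny, mask), mask, tiny)
  expect_null(del3$left)
  big <- flat; big[58:80, 10:38] <- 650
  del4 <- delineate_drg(mask_cord(big, mask), mask, big)
  expect_false(is.null(del4$left))
  expect_match(del4$flags, "max_px")

  # manual ROI mode only sees the supplied rectangle
  del5 <- delineate_drg(mask_cord(mip, mask), mask, mip,
                        roi = list(left = c(57, 63, 28, 36)))
  expect_equal(sum(del5$left), 25)
  expect_identical(del5$mode, "manual_roi")
})

test_that("the pipeline is deterministic, shift-equivariant, and logs cord-only stacks", {
  ph <- noiseless_phantom()
  r1 <- run_pipeline(ph$stack)
  r2 <- run_pipeline(ph$stack)
  expect_identical(r1$records, r2$records)

  # translating the whole stack by an integer dv offset changes nothing:
  # analytic anatomy shifted by whole pixels re-rasterizes identically
  arr <- ph$stack$intensities
  for (i in 1:5) arr[i, , ] <- drgvol:::.shift_rows(arr[i, , ], 4L)
  r3 <- run_pipeline(slice_stack(arr, ph$stack$geometry))
  expect_identical(r3$records$pixel_count, r1$records$pixel_count)

  cord_only <- render_phantom(phantom_spec(noise_sigma = 0,
                                           drg_sides = character(0)))
  r4 <- run_pipeline(cord_only$stack)
  expect_equal(nrow(r4$records), 0)
  expect_match(r4$intermediates$log, "no DRG slices", all = FALSE)
})

test_that("pipeline CSAs agree with cohort truth under noise", {
  # rendered scans at generator defaults: per-DRG recovery within the
  # 10% mean absolute relative error budget at this SNR
  cs <- cohort_spec(groups = tibble::tibble(name = "wildtype", n_animals = 2L),
                    weeks = c(8, 12), base_spec = phantom_spec(noise_sigma = 40),
                    seed = 9)
  out <- render_cohort(cs, render_stacks = TRUE)
  measured <- c(); truth <- c()
  for (nm in names(out$stacks)) {
    r <- run_pipeline(out$stacks[[nm]])
    for (side in c("left", "right")) {
      v <- r$records$csa_mm2[r$records$side == side]
      if (length(v)) {
        measured <- c(measured, v)
        key <- strsplit(nm, "_w")[[1]]
        truth <- c(truth, out$truth$csa_mm2[
          out$truth$animal_id == key[1] & out$truth$timepoint == as.numeric(key[2]) &
            out$truth$side == side])
      }
    }
  }
  expect_gte(length(measured), 6)
  expect_lte(mean(abs(measured - truth) / truth), 0.10)
})
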