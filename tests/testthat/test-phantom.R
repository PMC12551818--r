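test_that("equal seeds render bit-identical phantoms, unequal seeds differ", {
  a <- render_phantom(phantom_spec(seed = 3))
  b <- render_phantom(phantom_spec(seed = 3))
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_identical(a$truth$sides$left$true_pixel_count,
                   b$truth$sides$left$true_pixel_count)
  c <- render_phantom(phantom_spec(seed = 4))
  expect_false(identical(a$stack$intensities, c$stack$intensities))
})

test_that("cord-only noiseless phantom has identical slices capped at cord intensity", {
  spec <- phantom_spec(noise_sigma = 0, drg_sides = character(0))
  ph <- render_phantom(spec)
  for (i in 2:5)
    expect_identical(get_slice(ph$stack, i), get_slice(ph$stack, 1))
  expect_equal(max(ph$stack$intensities), spec$cord_intensity)
})

test_that("phantom truth matches the analytic rasterization oracle", {
  spec <- phantom_spec(noise_sigma = 0)
  ph <- noiseless_phantom()
  g <- spec$geometry
  # default semi-axes solve to a 50-pixel analytic area
  expect_equal(pi * spec$drg_semi_axes[1] * spec$drg_semi_axes[2] / pixel_area(g),
               50, tolerance = 1e-9, ignore_attr = TRUE)
  for (side in c("left", "right")) {
    tr <- ph$truth$sides[[side]]
    expect_lte(abs(tr$true_pixel_count - 50), tr$perimeter_px)
    expect_equal(tr$true_csa, tr$true_pixel_count * pixel_area(g))
    expect_identical(tr$true_pixel_count, sum(tr$region))
  }
  # cord mask: one connected component, no holes
  lab <- drgvol:::.label8(ph$truth$cord_mask)
  expect_equal(max(lab), 1)
  filled <- EBImage::fillHull(ph$truth$cord_mask * 1) > 0
  expect_identical(filled, ph$truth$cord_mask)
})

test_that("the DRG occupies exactly the slices its ellipsoid intersects", {
  spec <- phantom_spec(noise_sigma = 0)
  with_drg <- render_phantom(spec)$stack
  cord_only <- render_phantom(phantom_spec(noise_sigma = 0,
                                           drg_sides = character(0)))$stack
  differs <- vapply(1:5, function(i)
    !identical(get_slice(with_drg, i), get_slice(cord_only, i)), TRUE)
  expect_identical(differs, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # a 0.3 mm span (a_rc = 0.15) fits a single 0.29 mm slice
  short <- phantom_spec(noise_sigma = 0,
                        drg_semi_axes = c(spec$drg_semi_axes[1:2], a_rc = 0.15))
  with_short <- render_phantom(short)$stack
  differs <- vapply(1:5, function(i)
    !identical(get_slice(with_short, i), get_slice(cord_only, i)), TRUE)
  expect_equal(sum(differs), 1)
})

test_that("growing the DRG strictly grows its true pixel count", {
  px <- pixel_pitch(voxel_geometry())["dv"]
  base <- phantom_spec(noise_sigma = 0)
  counts <- vapply(0:3, function(k) {
    ax <- base$drg_semi_axes + c(k * px, k * px, 0)
    sp <- phantom_spec(noise_sigma = 0, drg_semi_axes = ax)
    render_phantom(sp)$truth$sides$left$true_pixel_count
  }, 0L)
  expect_true(all(diff(counts) > 0))
})

test_that("Rician rendering preserves mean intensity in uniform regions at high SNR", {
  spec <- phantom_spec(noise_sigma = 40, seed = 8, drg_sides = character(0))
  ph <- render_phantom(spec)
  core <- EBImage::erode(ph$truth$cord_mask * 1, EBImage::makeBrush(5, "disc")) > 0
  vals <- c()
  for (i in 1:5) vals <- c(vals, get_slice(ph$stack, i)[core])
  expect_equal(mean(vals), spec$cord_intensity, tolerance = 0.02)
})

test_that("test-retest rendering reproduces anatomy up to jitter", {
  spec <- phantom_spec(noise_sigma = 0)
  still <- render_test_retest(spec, jitter = list(dv_shift_px = c(0L, 0L),
                                                  intensity_scale = c(1, 1),
                                                  size_cv = 0), seed = 2)
  expect_identical(still$test$stack$intensities, still$retest$stack$intensities)

  pa <- pixel_area(spec$geometry)
  for (s in 1:5) {
    pr <- render_test_retest(spec, seed = s)
    for (side in c("left", "right")) {
      dcsa <- abs(pr$test$truth$sides[[side]]$true_csa -
                    pr$retest$truth$sides[[side]]$true_csa)
      expect_lte(dcsa, pr$test$truth$sides[[side]]$perimeter_px * pa)
    }
  }
  again <- render_test_retest(spec, seed = 3)
  first <- render_test_retest(spec, seed = 3)
  expect_identical(first$retest$stack$intensities, again$retest$stack$intensities)
})

test_that("cohort truth is quantized and deterministic in the degenerate limit", {
  cs <- cohort_spec(between_animal_cv = 0, within_animal_cv = 0, seed = 5)
  tr <- render_cohort(cs)$truth
  pa <- pixel_area(cs$base_spec$geometry)
  expect_equal(tr$csa_mm2, tr$pixel_count * pa)
  # zero CVs: every animal of a group has the same true CSA at each week
  spread <- tapply(tr$pixel_count, interaction(tr$group, tr$timepoint),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("cohort group means land on the prescribed trajectories", {
  tr <- render_cohort(cohort_spec(seed = 1))$truth
  per_animal <- stats::aggregate(
    csa_mm2 ~ animal_id + group, data = tr[tr$timepoint == 24, ], FUN = mean)
  for (case in list(list(g = c("fabry", "fabry_null"), target = 0.35),
                    list(g = "wildtype", target = 0.28),
                    list(g = "fabry_gla", target = 0.28))) {
    v <- per_animal$csa_mm2[per_animal$group %in% case$g]
    sem <- sd(v) / sqrt(length(v))
    expect_lte(abs(mean(v) - case$target), 2 * sem)
  }
})
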