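#' Default longitudinal CSA trajectories (mm^2) per group
#'
#' Calibrated to the study conditions the cohort generator emulates:
#' wild-type L4 DRG CSA is flat at 0.28 mm^2 from week 8 on; untreated Fabry
#' animals (with or without a null vector) start mildly enlarged at week 8 and
#' rise to 0.35 mm^2 by week 24 (~25% above wild type); gene-therapy-treated
#' Fabry animals start at the Fabry baseline and track the wild-type level
#' after week 8 (treatment at week 8 normalizes the enlargement).
#'
#' @return Named list of `week -> mm^2` numeric vectors for groups
#'   `wildtype`, `fabry`, `fabry_null`, `fabry_gla`.
#' @export
default_csa_trajectories <- function() {
  weeks <- c(8, 12, 16, 20, 24)
  traj <- function(v) stats::setNames(v, weeks)
  fabry <- traj(c(0.300, 0.315, 0.330, 0.340, 0.350))
  list(wildtype = traj(rep(0.280, 5)),
       fabry = fabry,
       fabry_null = fabry,
       fabry_gla = traj(c(0.300, 0.285, 0.280, 0.280, 0.280)))
}

#' Specify a synthetic longitudinal cohort
#'
#' Groups of animals scanned at a fixed week grid, each group following a
#' mean CSA trajectory. Each animal carries a persistent log-normal
#' between-animal size factor (biological spread); each scan of each DRG
#' additionally draws a within-animal factor (scan-to-scan repeatability).
#' Log-normal factors are mean-corrected so group means land on the
#' trajectory. Group sizes default to the study design: 5 wild-type, 3 Fabry,
#' 5 Fabry + null vector, 5 Fabry + gene therapy.
#'
#' @param groups Data frame / tibble with columns `name`, `n_animals`;
#'   default the four study groups.
#' @param trajectories Named list `group -> (week -> mm^2)`; default
#'   [default_csa_trajectories()]. Weeks off the grid are piecewise-linearly
#'   interpolated.
#' @param weeks Strictly increasing scan weeks, default `c(8, 12, 16, 20, 24)`.
#' @param between_animal_cv,within_animal_cv Coefficients of variation, in
#'   `[0, 0.5]`; defaults 0.10 and 0.06.
#' @param base_spec A [phantom_spec()] supplying anatomy, noise and geometry.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, trajectories = default_csa_trajectories(),
                        weeks = c(8, 12, 16, 20, 24),
                        between_animal_cv = 0.10, within_animal_cv = 0.06,
                        base_spec = phantom_spec(noise_sigma = 0), seed = 1L) {
  if (is.null(groups))
    groups <- tibble::tibble(
      name = c("wildtype", "fabry", "fabry_null", "fabry_gla"),
      n_animals = c(5L, 3L, 5L, 5L))
  stopifnot(all(c("name", "n_animals") %in% names(groups)),
            all(groups$n_animals >= 1),
            all(diff(weeks) > 0),
            between_animal_cv >= 0, between_animal_cv <= 0.5,
            within_animal_cv >= 0, within_animal_cv <= 0.5,
            all(groups$name %in% names(trajectories)),
            inherits(base_spec, "phantom_spec"))
  structure(list(groups = groups, trajectories = trajectories, weeks = weeks,
                 between_animal_cv = between_animal_cv,
                 within_animal_cv = within_animal_cv,
                 base_spec = base_spec, seed = as.integer(seed)),
            class = "cohort_spec")
}

# internal: mean-corrected log-normal factors
.lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws every animal's size factors, solves the DRG in-plane semi-axes
#' (isotropic scaling) so the analytic cross-section equals each scan's target
#' CSA, rasterizes the resulting region on the imaging grid to obtain the
#' quantized ground-truth pixel count, and — optionally — renders the full
#' noisy stacks for pipeline-recovery studies. With `render_stacks = FALSE`
#' only the truth table is produced, which is cheap enough for large
#' simulation studies of the downstream statistics.
#'
#' @param cohort A [cohort_spec()].
#' @param render_stacks Render noisy image stacks per animal/week (slow) or
#'   only emit the truth table (fast).
#' @return List with `truth` (a tibble of per-DRG records: `animal_id, side,
#'   timepoint, group, pixel_count, csa_mm2, target_csa_mm2`) and `stacks`
#'   (named list `animal_week -> slice_stack`, or `NULL`).
#' @export
render_cohort <- function(cohort, render_stacks = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$seed)
  spec <- cohort$base_spec
  g <- spec$geometry
  pa <- pixel_area(g)
  acc <- list(animal_id = character(), side = character(),
              timepoint = numeric(), group = character(),
              pixel_count = integer(), target = numeric())
  stacks <- if (render_stacks) list() else NULL
  for (gi in seq_len(nrow(cohort$groups))) {
    gname <- cohort$groups$name[gi]
    tr <- cohort$trajectories[[gname]]
    tw <- as.numeric(names(tr))
    for (ai in seq_len(cohort$groups$n_animals[gi])) {
      aid <- sprintf("%s_%02d", gname, ai)
      fb <- .lnorm_factor(1, cohort$between_animal_cv)
      for (wk in cohort$weeks) {
        mu <- stats::approx(tw, tr, xout = wk, rule = 2)$y
        fw <- .lnorm_factor(2, cohort$within_animal_cv)
        targets <- mu * fb * fw  # left, right
        names(targets) <- c("left", "right")
        base_area <- pi * spec$drg_semi_axes[1] * spec$drg_semi_axes[2]
        sfac <- as.list(targets / base_area)
        scan_seed <- sample.int(.Machine$integer.max - 1L, 1)
        if (render_stacks) {
          base <- .render_noiseless(spec, size_factors = sfac)
          counts <- vapply(spec$drg_sides,
                           function(s) base$sides[[s]]$true_pixel_count, 0L)
          arr <- .apply_rician(base$intensities, spec$noise_sigma, scan_seed)
          stacks[[sprintf("%s_w%02d", aid, wk)]] <- slice_stack(arr, g)
        } else {
          counts <- vapply(spec$drg_sides, function(s) {
            a <- spec$drg_semi_axes[1:2] * sqrt(sfac[[s]])
            ctr <- .drg_center(spec, s, size_factor = sfac[[s]])
            as.integer(.count_ellipse_minus_cord(
              ctr, a, spec$cord_center, spec$cord_semi_axes, g))
          }, 0L)
        }
        ns <- length(spec$drg_sides)
        acc$animal_id <- c(acc$animal_id, rep(aid, ns))
        acc$side <- c(acc$side, spec$drg_sides)
        acc$timepoint <- c(acc$timepoint, rep(wk, ns))
        acc$group <- c(acc$group, rep(gname, ns))
        acc$pixel_count <- c(acc$pixel_count, unname(counts[spec$drg_sides]))
        acc$target <- c(acc$target, unname(targets[spec$drg_sides]))
      }
    }
  }
  truth <- tibble::tibble(
    animal_id = acc$animal_id, side = acc$side, timepoint = acc$timepoint,
    group = acc$group, pixel_count = acc$pixel_count,
    csa_mm2 = acc$pixel_count * pa, target_csa_mm2 = acc$target)
  list(truth = truth, stacks = stacks)
}
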