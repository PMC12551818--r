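#' Build test-retest pairs from CSA measurements
#'
#' Each row pairs the test and retest CSA of one DRG (one animal-side unit;
#' the two ganglia of an animal are treated as separate units, a caveat
#' documented in the methods vignette since their sizes are not strictly
#' independent). Integer pixel counts are recovered from the areas via the
#' pixel area; a CSA that is not an integer pixel multiple (to rounding of
#' the stored decimals) is rejected.
#'
#' @param unit_id Character unit labels (animal + side).
#' @param test_csa,retest_csa CSA in mm^2.
#' @param geometry The [voxel_geometry()] the areas were measured under.
#' @param tol_px Tolerance, in pixels, for recovering integer counts from
#'   rounded areas (default 0.13 px, ample for 3-decimal rounding).
#' @return Tibble with `unit_id, test_csa, retest_csa, test_px, retest_px`.
#' @export
test_retest_pairs <- function(unit_id, test_csa, retest_csa,
                              geometry = voxel_geometry(), tol_px = 0.13) {
  stopifnot(length(unit_id) == length(test_csa),
            length(test_csa) == length(retest_csa))
  pa <- pixel_area(geometry)
  px <- function(csa, label) {
    raw <- csa / pa
    k <- round(raw)
    bad <- which(abs(raw - k) > tol_px)
    if (length(bad))
      stop(label, " CSA not an integer pixel multiple at rows: ",
           paste(bad, collapse = ", "), call. = FALSE)
    as.integer(k)
  }
  tibble::tibble(unit_id = as.character(unit_id),
                 test_csa = test_csa, retest_csa = retest_csa,
                 test_px = px(test_csa, "test"),
                 retest_px = px(retest_csa, "retest"))
}

#' One-way random-effects intraclass correlation (single measure)
#'
#' Units (DRGs) are random; the two scans per unit are indistinguishable
#' replicates, so the one-way model applies: with k measurements per unit,
#' `ICC = (MS_between - MS_within) / (MS_between + (k-1) MS_within)`.
#' Mean squares come from the one-way ANOVA of measurement on unit
#' (between df `n - 1`, within df `n (k - 1)`).
#'
#' @param pairs Tibble from [test_retest_pairs()].
#' @return List with `icc`, `ms_between`, `ms_within`, `n_units`, `k`, and
#'   `undefined` (TRUE when total variance is zero, in which case `icc` is
#'   `NA` — agreement is not estimable from constant data).
#' @export
icc_oneway <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2) stop("at least 2 units are required", call. = FALSE)
  if (anyNA(pairs[c("test_csa", "retest_csa")]))
    stop("missing values are not allowed", call. = FALSE)
  y <- c(pairs$test_csa, pairs$retest_csa)
  unit <- factor(rep(pairs$unit_id, 2))
  if (stats::var(y) == 0)
    return(list(icc = NA_real_, ms_between = 0, ms_within = 0,
                n_units = n, k = 2L, undefined = TRUE))
  fit <- stats::lm(y ~ unit)
  msb <- sum((stats::fitted(fit) - mean(y))^2) / (n - 1)
  msw <- stats::deviance(fit) / stats::df.residual(fit)
  k <- 2
  list(icc = (msb - msw) / (msb + (k - 1) * msw),
       ms_between = msb, ms_within = msw, n_units = n, k = 2L,
       undefined = FALSE)
}

#' Bland-Altman agreement statistics
#'
#' Differences are test minus retest; the bias is their mean, `sd_diff` the
#' sample standard deviation (n - 1 denominator), and the 95% limits of
#' agreement are `bias +/- 1.96 sd_diff`. Per-unit means and differences are
#' returned for plotting.
#'
#' @param pairs Tibble from [test_retest_pairs()].
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`, and `points`
#'   (tibble `unit_id, mean, difference`).
#' @export
bland_altman <- function(pairs) {
  if (nrow(pairs) < 2) stop("at least 2 units are required", call. = FALSE)
  d <- pairs$test_csa - pairs$retest_csa
  m <- (pairs$test_csa + pairs$retest_csa) / 2
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       points = tibble::tibble(unit_id = pairs$unit_id, mean = m,
                               difference = d))
}

#' Relative difference of a test-retest pair, percent
#'
#' `100 (test_px - retest_px) / ((test_px + retest_px) / 2)`, computed on the
#' integer pixel counts rather than rounded areas — only the pixel-count form
#' reproduces recorded per-unit relative differences exactly, since areas are
#' pixel-quantized.
#'
#' @param test_px,retest_px Integer pixel counts (vectorized).
#' @return Relative difference(s), percent.
#' @export
relative_difference <- function(test_px, retest_px) {
  if (any(test_px + retest_px <= 0))
    stop("both pixel counts are zero: relative difference undefined",
         call. = FALSE)
  100 * (test_px - retest_px) / ((test_px + retest_px) / 2)
}

#' Full test-retest reliability report
#'
#' Aggregates the ICC, Bland-Altman, and relative-difference statistics, plus
#' the summary cells of the standard repeatability table (means and SDs of
#' both arms, of the pair means, of the differences, and of the relative
#' differences).
#'
#' @param pairs Tibble from [test_retest_pairs()].
#' @return Object of class `reliability_result` (a list).
#' @export
reliability_report <- function(pairs) {
  icc <- icc_oneway(pairs)
  ba <- bland_altman(pairs)
  rd <- relative_difference(pairs$test_px, pairs$retest_px)
  structure(list(
    n_units = nrow(pairs), k = 2L,
    icc = icc$icc, icc_undefined = icc$undefined,
    ms_between = icc$ms_between, ms_within = icc$ms_within,
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    mean_test = mean(pairs$test_csa), sd_test = stats::sd(pairs$test_csa),
    mean_retest = mean(pairs$retest_csa), sd_retest = stats::sd(pairs$retest_csa),
    mean_of_means = mean((pairs$test_csa + pairs$retest_csa) / 2),
    sd_of_means = stats::sd((pairs$test_csa + pairs$retest_csa) / 2),
    rel_diff_per_unit = rd,
    mean_rel_diff = mean(rd), sd_rel_diff = stats::sd(rd),
    points = ba$points, pairs = pairs),
    class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    paste0("<reliability_result> n = %d DRG units, k = %d\n",
           "  mean CSA: test %.3f, retest %.3f mm^2\n",
           "  ICC (one-way random effects): %s\n",
           "  bias %.3f mm^2, SD of differences %.3f, LoA [%.3f, %.3f] mm^2\n",
           "  mean relative difference %.3f%%\n"),
    x$n_units, x$k, x$mean_test, x$mean_retest,
    if (x$icc_undefined) "undefined (zero variance)" else sprintf("%.3f", x$icc),
    x$bias, x$sd_diff, x$loa_low, x$loa_high, x$mean_rel_diff))
  invisible(x)
}

#' Scatter and Bland-Altman plots for a reliability report
#'
#' The scatterplot shows retest against test CSA with the identity line; the
#' Bland-Altman plot shows per-unit differences against means with the bias
#' line (solid) and the 95% limits of agreement (dashed).
#'
#' @param report A [reliability_report()] result.
#' @return Named list of two ggplot objects, `scatter` and `bland_altman`.
#' @export
reliability_plots <- function(report) {
  stopifnot(inherits(report, "reliability_result"))
  pairs <- report$pairs
  rng <- range(c(pairs$test_csa, pairs$retest_csa))
  scatter <- ggplot2::ggplot(pairs,
                             ggplot2::aes(x = .data$test_csa, y = .data$retest_csa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = rng, ylim = rng) +
    ggplot2::labs(x = "CSA, test scan (mm^2)", y = "CSA, retest scan (mm^2)",
                  title = "L4 DRG CSA: test vs retest") +
    ggplot2::theme_classic()
  ba <- ggplot2::ggplot(report$points,
                        ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = report$bias, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean of test and retest CSA (mm^2)",
                  y = "Difference, test - retest (mm^2)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_classic()
  list(scatter = scatter, bland_altman = ba)
}
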