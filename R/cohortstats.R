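#' Pool groups in a longitudinal table
#'
#' Relabels the rows of the listed groups to a common name (e.g. pooling
#' untreated and null-vector Fabry animals, whose trajectories do not differ,
#' before comparison against wild type); everything else is unchanged.
#'
#' @param table Longitudinal tibble with a `group` column.
#' @param groups_to_pool Character vector of existing group labels.
#' @param pooled_name Label for the pooled group.
#' @return The relabelled table (row count preserved).
#' @export
pool_groups <- function(table, groups_to_pool, pooled_name) {
  stopifnot("group" %in% names(table))
  missing <- setdiff(groups_to_pool, unique(table$group))
  if (length(missing))
    stop("unknown group(s): ", paste(missing, collapse = ", "), call. = FALSE)
  table$group[table$group %in% groups_to_pool] <- pooled_name
  table
}

#' Two-sample Student's t-test
#'
#' Classical pooled-variance (equal-variance) two-sided t-test with
#' `df = n_a + n_b - 2`; a Welch variant is available behind a flag. When
#' both samples are constant and equal the statistic is undefined; by
#' convention `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
student_t <- function(sample_a, sample_b, welch = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2,
                  p = 1, degenerate = TRUE))
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf,
                df = length(sample_a) + length(sample_b) - 2,
                p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

# internal: per-week samples for one group; unit = "animal" averages the two
# DRGs of each animal per week, unit = "drg" keeps them separate
.week_sample <- function(table, group, week, unit) {
  rows <- table[table$group == group & table$timepoint == week, ]
  if (!nrow(rows)) return(numeric())
  if (unit == "animal") {
    agg <- stats::aggregate(csa_mm2 ~ animal_id, data = rows, FUN = mean)
    agg$csa_mm2
  } else rows$csa_mm2
}

#' Closed testing procedure for a longitudinal group comparison
#'
#' Tests the group difference at a pre-specified endpoint week (chosen a
#' priori as the week of maximal predicted difference, by default the last).
#' Only if the endpoint is significant at `alpha` does testing step backwards
#' in time, week by week, while significance holds; the earliest week of the
#' unbroken significant run ending at the endpoint is reported. The endpoint
#' gate keeps the procedure's type-I error at the endpoint level without
#' further multiplicity correction. By default the two DRGs of an animal are
#' averaged so each animal contributes one value per week.
#'
#' @param table Longitudinal tibble of CSA records (`animal_id, side,
#'   timepoint, group, csa_mm2`).
#' @param group_a,group_b Group labels to compare.
#' @param weeks_ordered Increasing week grid; default the weeks in `table`.
#' @param endpoint_week Endpoint (default: last week).
#' @param alpha Significance level (default 0.05).
#' @param unit `"animal"` (per-animal means, default) or `"drg"`.
#' @param welch Use Welch's t instead of the pooled-variance form.
#' @param scan_all_weeks Sensitivity variant: when the endpoint is
#'   significant, compute p at every week (not just the unbroken run) —
#'   reported for audit, the earliest-week rule is unchanged.
#' @return Object of class `closed_test_result`: list with `endpoint_week`,
#'   `endpoint_p`, `earliest_significant_week` (or `NA`), `per_week_p`
#'   (named vector of every p actually computed), `alpha`, `groups`, `unit`.
#' @export
closed_testing <- function(table, group_a, group_b, weeks_ordered = NULL,
                           endpoint_week = NULL, alpha = 0.05,
                           unit = c("animal", "drg"), welch = FALSE,
                           scan_all_weeks = FALSE) {
  unit <- match.arg(unit)
  if (is.null(weeks_ordered)) weeks_ordered <- sort(unique(table$timepoint))
  if (is.null(endpoint_week)) endpoint_week <- max(weeks_ordered)
  if (!endpoint_week %in% weeks_ordered)
    stop("endpoint_week must be on the week grid", call. = FALSE)
  test_week <- function(wk) {
    a <- .week_sample(table, group_a, wk, unit)
    b <- .week_sample(table, group_b, wk, unit)
    if (length(a) < 2 || length(b) < 2)
      stop("missing group-week cell at week ", wk, call. = FALSE)
    student_t(a, b, welch = welch)$p
  }
  per_week_p <- c()
  endpoint_p <- test_week(endpoint_week)
  per_week_p[as.character(endpoint_week)] <- endpoint_p
  earliest <- NA_real_
  if (endpoint_p < alpha) {
    earliest <- endpoint_week
    run_unbroken <- TRUE
    prior <- rev(weeks_ordered[weeks_ordered < endpoint_week])
    for (wk in prior) {
      if (!run_unbroken && !scan_all_weeks) break
      p <- test_week(wk)
      per_week_p[as.character(wk)] <- p
      if (p < alpha && run_unbroken) earliest <- wk
      else run_unbroken <- FALSE
    }
  }
  structure(list(groups = c(group_a, group_b), unit = unit,
                 endpoint_week = endpoint_week, endpoint_p = endpoint_p,
                 earliest_significant_week = earliest,
                 per_week_p = per_week_p[order(as.numeric(names(per_week_p)))],
                 alpha = alpha),
            class = "closed_test_result")
}

#' @export
print.closed_test_result <- function(x, ...) {
  cat(sprintf("<closed_test_result> %s vs %s (unit: %s)\n",
              x$groups[1], x$groups[2], x$unit))
  cat(sprintf("  endpoint week %g: p = %.4g (alpha %.3g)\n",
              x$endpoint_week, x$endpoint_p, x$alpha))
  if (is.na(x$earliest_significant_week))
    cat("  endpoint not significant; no earlier weeks tested\n")
  else
    cat(sprintf("  earliest significant week: %g\n", x$earliest_significant_week))
  invisible(x)
}

#' Staining positivity, percent
#'
#' `100 * positive_px / total_px`: the stained fraction of an analysed
#' histology area from a positive-pixel-count algorithm.
#'
#' @param positive_px,total_px Pixel counts, `0 <= positive_px <= total_px`,
#'   `total_px > 0` (vectorized).
#' @return Positivity in percent.
#' @export
positivity_percent <- function(positive_px, total_px) {
  if (any(total_px <= 0)) stop("total_px must be positive", call. = FALSE)
  if (any(positive_px < 0) || any(positive_px > total_px))
    stop("need 0 <= positive_px <= total_px", call. = FALSE)
  100 * positive_px / total_px
}
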