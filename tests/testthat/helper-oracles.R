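# Independent definitional oracles, kept free of package internals.

# one-way random-effects ICC from raw sums of squares (k = 2)
ss_icc_oracle <- function(test, retest) {
  n <- length(test)
  grand <- mean(c(test, retest))
  unit_means <- (test + retest) / 2
  ssb <- 2 * sum((unit_means - grand)^2)
  ssw <- sum((test - unit_means)^2 + (retest - unit_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / n
  list(icc = (msb - msw) / (msb + msw), ms_between = msb, ms_within = msw)
}

# pooled-variance two-sample t from the definitional formula
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# noiseless default phantom, memoised: several tests reuse it
noiseless_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- render_phantom(phantom_spec(noise_sigma = 0))
    cache
  }
})

# longitudinal table with exact group separation for construction tests:
# per-animal CSA = group mean at that week + small fixed within-group offsets
constructed_cohort_table <- function(means_by_week_a, means_by_week_b,
                                     n_a = 5, n_b = 5, spread = 0.002) {
  weeks <- as.numeric(names(means_by_week_a))
  offs <- function(n) spread * scale(seq_len(n), scale = FALSE)
  rows <- list()
  for (w in weeks) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      animal_id = sprintf("a%02d", seq_len(n_a)), side = "left",
      timepoint = w, group = "grp_a",
      csa_mm2 = means_by_week_a[[as.character(w)]] + as.numeric(offs(n_a)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      animal_id = sprintf("b%02d", seq_len(n_b)), side = "left",
      timepoint = w, group = "grp_b",
      csa_mm2 = means_by_week_b[[as.character(w)]] + as.numeric(offs(n_b)))
  }
  dplyr::bind_rows(rows)
}
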