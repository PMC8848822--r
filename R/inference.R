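# Permutation significance, bootstrap difference Z-test, interpretation.

#' Permutation significance of an effect size
#'
#' Builds the null distribution of the effect size by shuffling the y values
#' against the fixed x values `n_permutations` times and recomputing d each
#' time. The returned p-value is the add-one-smoothed upper tail
#' (count of permuted d >= observed d, plus one, over `n_permutations + 1`),
#' so p is never exactly zero. The scope is invariant under permutation
#' because the value multisets are unchanged.
#'
#' @param sample An [nca_sample()].
#' @param direction `"necessity"` (default) or `"sufficiency"`; the latter is
#'   evaluated as necessity on the axis-swapped sample.
#' @param technique `"ce_fdh"` or `"cr_fdh"`.
#' @param n_permutations Number of random permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `nca_perm` with `d_obs`, `p`,
#'   `n_permutations`, `seed`, `direction` and `technique`.
#' @export
permutation_p <- function(sample,
                          direction = c("necessity", "sufficiency"),
                          technique = c("ce_fdh", "cr_fdh"),
                          n_permutations = 10000, seed = NULL) {
  direction <- match.arg(direction)
  technique <- match.arg(technique)
  if (n_permutations < 1)
    .ncax_error("ncax_invalid_input", "n_permutations must be at least 1")
  work <- if (direction == "sufficiency") swap_sample(sample) else sample
  scope <- compute_scope(work)
  d_obs <- necessity_effect(work, technique)$d
  if (!is.null(seed)) set.seed(seed)
  x <- work$x
  y <- work$y
  n <- work$n
  ord <- order(x)
  xs <- x[ord]
  dx <- diff(xs)
  y_max <- max(y)
  area <- scope$area
  count <- 0L
  if (technique == "ce_fdh") {
    for (k in seq_len(n_permutations)) {
      yp <- y[sample.int(n)]
      cm <- cummax(yp[ord])
      dk <- sum(dx * (y_max - cm[-n])) / area
      if (dk >= d_obs - 1e-12) count <- count + 1L
    }
  } else {
    for (k in seq_len(n_permutations)) {
      dk <- .d_necessity(x, y[sample.int(n)], technique)
      if (dk >= d_obs - 1e-12) count <- count + 1L
    }
  }
  structure(list(d_obs = d_obs,
                 p = (count + 1) / (n_permutations + 1),
                 n_permutations = n_permutations,
                 seed = seed,
                 direction = direction,
                 technique = technique),
            class = "nca_perm")
}

#' @export
print.nca_perm <- function(x, ...) {
  cat(sprintf("%s effect d = %.4f, permutation p = %.4g (%d permutations)\n",
              x$direction, x$d_obs, x$p, x$n_permutations))
  invisible(x)
}

#' Bootstrap Z-test for the necessity-sufficiency difference
#'
#' Draws `n_bootstrap` resamples of the rows with replacement and computes
#' the difference d_necessity - d_sufficiency in each. The reported
#' difference is the mean of these bootstrap differences; its standard error
#' is their sample standard deviation; Z = mean / SE, with a two-sided
#' standard-normal p-value. The plug-in difference on the observed sample is
#' reported alongside. Resamples with a degenerate scope (zero range in x or
#' y) are skipped and counted.
#'
#' @inheritParams permutation_p
#' @param n_bootstrap Number of bootstrap resamples (default 10000).
#' @return An object of class `nca_bootdiff` with `mean_diff`, `se_diff`,
#'   `z`, `p`, `plugin_diff`, `n_bootstrap`, `n_effective`, `skipped`,
#'   `constant` (TRUE when the difference did not vary across resamples, in
#'   which case Z is undefined and p is reported as 1), `seed`, and the
#'   vector `diffs` of retained bootstrap differences.
#' @export
bootstrap_difference <- function(sample, technique = c("ce_fdh", "cr_fdh"),
                                 n_bootstrap = 10000, seed = NULL) {
  technique <- match.arg(technique)
  if (n_bootstrap < 2)
    .ncax_error("ncax_invalid_input", "n_bootstrap must be at least 2")
  compute_scope(sample)  # fail early on degenerate input
  plugin_diff <- necessity_effect(sample, technique)$d -
    sufficiency_effect(sample, technique)$d
  if (!is.null(seed)) set.seed(seed)
  x <- sample$x
  y <- sample$y
  n <- sample$n
  diffs <- numeric(n_bootstrap)
  kept <- 0L
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]
    yb <- y[idx]
    if (min(xb) == max(xb) || min(yb) == max(yb)) next
    kept <- kept + 1L
    diffs[kept] <- .d_necessity(xb, yb, technique) -
      .d_necessity(yb, xb, technique)
  }
  skipped <- n_bootstrap - kept
  if (skipped > 0L)
    message(sprintf("bootstrap_difference: skipped %d degenerate resample(s)",
                    skipped))
  diffs <- diffs[seq_len(kept)]
  if (kept < 2L)
    .ncax_error("ncax_insufficient_data",
                "fewer than 2 non-degenerate bootstrap resamples")
  mean_diff <- mean(diffs)
  se_diff <- stats::sd(diffs)
  constant <- se_diff == 0
  z <- if (constant) NA_real_ else mean_diff / se_diff
  p <- if (constant) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(mean_diff = mean_diff, se_diff = se_diff, z = z, p = p,
                 plugin_diff = plugin_diff,
                 n_bootstrap = n_bootstrap, n_effective = kept,
                 skipped = skipped, constant = constant, seed = seed,
                 technique = technique, diffs = diffs),
            class = "nca_bootdiff")
}

#' @export
print.nca_bootdiff <- function(x, ...) {
  cat(sprintf("Bootstrap difference: %.4f (SE %.4f), Z = %s, p = %.4g\n",
              x$mean_diff, x$se_diff,
              if (x$constant) "undefined (constant)" else sprintf("%.3f", x$z),
              x$p))
  invisible(x)
}

#' Interpret the necessity/sufficiency/difference pattern
#'
#' Encodes the logical reading of the three results. If neither effect is
#' permutation-significant the association shows no detectable
#' non-randomness. Otherwise a non-significant difference means equal
#' degrees of necessity and sufficiency, and a significant difference is
#' read by the sign of the bootstrap mean. The guard flag records whether
#' the stronger of the two effects is itself permutation-significant; a
#' difference should not be interpreted without it. When the sufficiency
#' effect of x on y (equivalently, the necessity effect of y on x) is
#' significant, a note records that this contradicts a "x is necessary but
#' not sufficient for y" reading.
#'
#' @param necessity,sufficiency [permutation_p()] results for the two
#'   directions.
#' @param difference A [bootstrap_difference()] result.
#' @param alpha Significance level for the guard and the pattern (default
#'   0.05).
#' @return A list with `interpretation` (one of `"necessity_dominant"`,
#'   `"sufficiency_dominant"`, `"equal_degrees"`, `"no_nonrandomness"`),
#'   `guard_ok`, and `note` (character or `NULL`).
#' @export
interpret_pattern <- function(necessity, sufficiency, difference,
                              alpha = 0.05) {
  nec_sig <- necessity$p < alpha
  suf_sig <- sufficiency$p < alpha
  stronger_p <- if (necessity$d_obs >= sufficiency$d_obs) necessity$p else sufficiency$p
  guard_ok <- stronger_p < alpha
  interpretation <-
    if (!nec_sig && !suf_sig) "no_nonrandomness"
    else if (difference$p >= alpha) "equal_degrees"
    else if (difference$mean_diff > 0) "necessity_dominant"
    else "sufficiency_dominant"
  note <- NULL
  if (suf_sig)
    note <- paste("the necessity effect in the reverse direction (y on x) is",
                  "significant, which is not logically compatible with x being",
                  "necessary but not sufficient for y")
  list(interpretation = interpretation, guard_ok = guard_ok, note = note)
}

#' Run the full extended analysis
#'
#' Computes both effect sizes, their permutation p-values, the bootstrap
#' difference Z-test, and the interpretation, in one reproducible call.
#' Sub-seeds for the permutation tests and the bootstrap are derived
#' deterministically from the master seed; the same master seed yields a
#' bit-identical report. Both permutation tests share one sub-seed so that
#' swapping the input axes exactly swaps the necessity and sufficiency
#' blocks of the report.
#'
#' @inheritParams permutation_p
#' @inheritParams bootstrap_difference
#' @param alpha Significance level for the interpretation (default 0.05).
#' @return An object of class `nca_report`: a list with `labels`,
#'   `technique`, `alpha`, `seed`, `necessity` and `sufficiency` (each an
#'   effect plus permutation result), `difference`, `guard_ok`,
#'   `interpretation` and `note`.
#' @export
run_extended_nca <- function(sample, technique = c("ce_fdh", "cr_fdh"),
                             n_permutations = 10000, n_bootstrap = 10000,
                             seed = 1, alpha = 0.05) {
  technique <- match.arg(technique)
  seeds <- local({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, 2)
  })
  nec_eff <- necessity_effect(sample, technique)
  suf_eff <- sufficiency_effect(sample, technique)
  nec_perm <- permutation_p(sample, "necessity", technique,
                            n_permutations, seeds[1])
  suf_perm <- permutation_p(sample, "sufficiency", technique,
                            n_permutations, seeds[1])
  boot <- bootstrap_difference(sample, technique, n_bootstrap, seeds[2])
  interp <- interpret_pattern(nec_perm, suf_perm, boot, alpha)
  structure(list(labels = sample$labels,
                 technique = technique,
                 alpha = alpha,
                 seed = seed,
                 n = sample$n,
                 necessity = list(effect = nec_eff, perm = nec_perm),
                 sufficiency = list(effect = suf_eff, perm = suf_perm),
                 difference = boot,
                 guard_ok = interp$guard_ok,
                 interpretation = interp$interpretation,
                 note = interp$note),
            class = "nca_report")
}

#' @export
print.nca_report <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 3)
  fmtp <- function(p) if (p < 0.001) "<0.001" else fmt(p)
  cat(sprintf("Extended NCA: %s -> %s (technique %s, n = %d)\n",
              x$labels[1], x$labels[2], x$technique, x$n))
  cat(sprintf("  Necessity   d = %s, p = %s\n",
              fmt(x$necessity$effect$d), fmtp(x$necessity$perm$p)))
  cat(sprintf("  Sufficiency d = %s, p = %s\n",
              fmt(x$sufficiency$effect$d), fmtp(x$sufficiency$perm$p)))
  cat(sprintf("  Difference  %s (%s), p = %s\n",
              fmt(x$difference$mean_diff), fmt(x$difference$se_diff),
              fmtp(x$difference$p)))
  cat(sprintf("  Interpretation: %s (guard %s)\n",
              x$interpretation, if (x$guard_ok) "ok" else "NOT met"))
  if (!is.null(x$note)) cat("  Note:", x$note, "\n")
  invisible(x)
}
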