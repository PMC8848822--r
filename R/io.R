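# CSV ingestion with cleaning, report serialization, diagnostic plot.

#' Load a paired sample from a CSV file
#'
#' Reads a comma-separated file with a header row, selects two columns,
#' coerces them to numeric, and drops rows with a missing or non-numeric
#' entry in either column (listwise deletion). The number of rows read and
#' dropped and per-column descriptive statistics (n, mean, sd) are reported
#' via [message()] and attached to the result as the `"cleaning_log"`
#' attribute.
#'
#' @param path Path to a CSV file (comma-separated, header row, UTF-8).
#' @param x_column,y_column Column names for the determinant and the outcome.
#' @return An [nca_sample()] with attribute `cleaning_log`, a list with
#'   `n_read`, `n_dropped`, `n`, and `descriptives` (mean/sd per column).
#' @export
load_sample <- function(path, x_column, y_column) {
  if (!file.exists(path))
    .ncax_error("ncax_missing_file", paste("file not found:", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  for (col in c(x_column, y_column))
    if (!col %in% names(df))
      .ncax_error("ncax_missing_column",
                  sprintf("column '%s' not found in %s", col, path))
  xv <- suppressWarnings(as.numeric(df[[x_column]]))
  yv <- suppressWarnings(as.numeric(df[[y_column]]))
  keep <- !is.na(xv) & !is.na(yv)
  n_read <- nrow(df)
  n_dropped <- n_read - sum(keep)
  if (sum(keep) < 3L)
    .ncax_error("ncax_insufficient_data",
                "fewer than 3 complete rows after cleaning")
  s <- nca_sample(xv[keep], yv[keep], labels = c(x_column, y_column))
  log <- list(n_read = n_read, n_dropped = n_dropped, n = s$n,
              descriptives = data.frame(
                column = c(x_column, y_column),
                n = s$n,
                mean = c(mean(s$x), mean(s$y)),
                sd = c(stats::sd(s$x), stats::sd(s$y))))
  message(sprintf("load_sample: read %d rows, dropped %d, n = %d",
                  n_read, n_dropped, s$n))
  message(sprintf("  %s: mean = %.3f, sd = %.3f; %s: mean = %.3f, sd = %.3f",
                  x_column, mean(s$x), stats::sd(s$x),
                  y_column, mean(s$y), stats::sd(s$y)))
  attr(s, "cleaning_log") <- log
  s
}

#' Write a paired sample to CSV
#'
#' Writes the two columns (named by the sample's labels) with full double
#' precision, so that [load_sample()] recovers the sample bit-exactly.
#'
#' @param sample An [nca_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  stopifnot(inherits(sample, "nca_sample"))
  lines <- c(paste(sample$labels, collapse = ","),
             paste(sprintf("%.17g", sample$x),
                   sprintf("%.17g", sample$y), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

.fmt3 <- function(v) formatC(v, format = "f", digits = 3)
.fmtp <- function(p) ifelse(p < 0.001, "<0.001", .fmt3(p))

#' Serialize an extended report
#'
#' `format = "tsv"` mirrors the one-row tabular layout (d and p for
#' necessity; d and p for sufficiency; bootstrap difference mean with its SE
#' in parentheses, and p) at 3 decimal places, rendering p-values below
#' 0.001 as `<0.001`, followed by a comment footer with the interpretation.
#' `format = "json"` carries full precision plus the seed, technique,
#' plug-in difference and guard flag. TSV and JSON agree after rounding.
#'
#' @param report An [run_extended_nca()] report.
#' @param path Output file, or `NULL` to return the serialized text.
#' @param format `"tsv"` or `"json"`.
#' @return The serialized report as a character vector (invisibly when
#'   written to `path`).
#' @export
write_report <- function(report, path = NULL, format = c("tsv", "json")) {
  stopifnot(inherits(report, "nca_report"))
  format <- match.arg(format)
  out <- if (format == "tsv") .report_tsv(report) else .report_json(report)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

.report_tsv <- function(r) {
  header <- paste("variables", "necessity_d", "necessity_p",
                  "sufficiency_d", "sufficiency_p",
                  "difference_d_se", "difference_p", sep = "\t")
  row <- paste(paste(r$labels, collapse = " -> "),
               .fmt3(r$necessity$effect$d), .fmtp(r$necessity$perm$p),
               .fmt3(r$sufficiency$effect$d), .fmtp(r$sufficiency$perm$p),
               sprintf("%s (%s)", .fmt3(r$difference$mean_diff),
                       .fmt3(r$difference$se_diff)),
               .fmtp(r$difference$p), sep = "\t")
  footer <- sprintf("# interpretation: %s (guard %s)", r$interpretation,
                    if (r$guard_ok) "ok" else "not met")
  c(header, row, footer,
    if (!is.null(r$note)) paste("# note:", r$note))
}

.report_json <- function(r) {
  obj <- list(
    variables = r$labels,
    technique = r$technique,
    n = r$n,
    seed = r$seed,
    alpha = r$alpha,
    necessity = list(d = r$necessity$effect$d,
                     ceiling_zone = r$necessity$effect$ceiling_zone,
                     scope_area = r$necessity$effect$scope_area,
                     p = r$necessity$perm$p,
                     n_permutations = r$necessity$perm$n_permutations),
    sufficiency = list(d = r$sufficiency$effect$d,
                       ceiling_zone = r$sufficiency$effect$ceiling_zone,
                       scope_area = r$sufficiency$effect$scope_area,
                       p = r$sufficiency$perm$p,
                       n_permutations = r$sufficiency$perm$n_permutations),
    difference = list(mean_diff = r$difference$mean_diff,
                      se_diff = r$difference$se_diff,
                      z = r$difference$z,
                      p = r$difference$p,
                      plugin_diff = r$difference$plugin_diff,
                      n_bootstrap = r$difference$n_bootstrap,
                      n_effective = r$difference$n_effective,
                      skipped = r$difference$skipped,
                      constant = r$difference$constant),
    guard_ok = r$guard_ok,
    interpretation = r$interpretation,
    note = r$note)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

.draw_step <- function(knots, x_max, swap = FALSE) {
  xs <- c(knots$x, x_max)
  for (i in seq_len(nrow(knots))) {
    if (swap) {
      graphics::segments(knots$level[i], xs[i], knots$level[i], xs[i + 1],
                         col = "blue", lwd = 2)
      if (i > 1)
        graphics::segments(knots$level[i - 1], xs[i], knots$level[i], xs[i],
                           col = "blue", lwd = 2)
    } else {
      graphics::segments(xs[i], knots$level[i], xs[i + 1], knots$level[i],
                         col = "blue", lwd = 2)
      if (i > 1)
        graphics::segments(xs[i], knots$level[i - 1], xs[i], knots$level[i],
                           col = "blue", lwd = 2)
    }
  }
}

#' Two-panel diagnostic plot
#'
#' Upper panel: the scatter with the scope rectangle, the ceiling line
#' (upper-left boundary) and the floor line (lower-right boundary) for the
#' report's technique. Lower panel: histogram of the retained bootstrap
#' differences with zero marked. The device is chosen from the file
#' extension (`.png` or `.svg`). Plotting failures are logged and do not
#' raise.
#'
#' @param sample The analyzed [nca_sample()].
#' @param report The matching [run_extended_nca()] report (its stored
#'   bootstrap differences feed the histogram).
#' @param path Output image path.
#' @return `path` invisibly, or `NULL` if plotting failed.
#' @export
render_diagnostics <- function(sample, report, path) {
  tryCatch({
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           png = grDevices::png(path, width = 800, height = 900),
           svg = grDevices::svg(path, width = 7, height = 8),
           .ncax_error("ncax_parameter_error",
                       paste("unsupported plot format:", ext)))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    sc <- compute_scope(sample)
    graphics::plot(sample$x, sample$y, pch = 16, col = "grey40",
         xlab = sample$labels[1], ylab = sample$labels[2],
         main = sprintf("Ceiling and floor (%s)", report$technique))
    graphics::rect(sc$x_min, sc$y_min, sc$x_max, sc$y_max, border = "red",
                   lwd = 2)
    if (report$technique == "ce_fdh") {
      .draw_step(ce_fdh_ceiling(sample, sc)$knots, sc$x_max)
      sw <- swap_sample(sample)
      .draw_step(ce_fdh_ceiling(sw, compute_scope(sw))$knots, sc$y_max,
                 swap = TRUE)
    } else {
      cl <- cr_fdh_ceiling(sample, sc, warn_fallback = FALSE)
      if (inherits(cl, "nca_cr_line"))
        graphics::abline(cl$intercept, cl$slope, col = "blue", lwd = 2)
      fl <- cr_fdh_ceiling(swap_sample(sample), warn_fallback = FALSE)
      if (inherits(fl, "nca_cr_line") && fl$slope != 0)
        graphics::abline(-fl$intercept / fl$slope, 1 / fl$slope,
                         col = "blue", lwd = 2)
    }
    graphics::hist(report$difference$diffs,
                   breaks = 40, col = "grey80",
                   main = "Bootstrap differences",
                   xlab = "necessity d - sufficiency d")
    graphics::abline(v = 0, col = "red", lwd = 2)
    invisible(path)
  }, error = function(e) {
    message("render_diagnostics failed: ", conditionMessage(e))
    invisible(NULL)
  })
}
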