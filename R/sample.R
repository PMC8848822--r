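# Paired bivariate sample: the unit every computation consumes.

.ncax_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "ncax_error", "error", "condition")))
}

#' Construct a paired bivariate sample
#'
#' Bundles two equal-length numeric vectors into the observation set that all
#' effect-size and inference functions consume. Cleaning (removal of missing
#' or non-numeric entries) happens upstream, typically in [load_sample()];
#' this constructor refuses incomplete data.
#'
#' @param x Numeric vector of determinant values.
#' @param y Numeric vector of outcome values, same length as `x`.
#' @param labels Character vector of length 2 with display names for the two
#'   variables, in (x, y) order.
#'
#' @return An object of class `nca_sample`: a list with elements `x`, `y`,
#'   `n` (number of pairs) and `labels`.
#'
#' @examples
#' s <- nca_sample(c(1, 2, 3, 4, 5), c(2, 3, 3, 5, 4))
#' s$n
#' @export
nca_sample <- function(x, y, labels = c("x", "y")) {
  if (!is.numeric(x) || !is.numeric(y))
    .ncax_error("ncax_invalid_input", "x and y must be numeric vectors")
  if (length(x) != length(y))
    .ncax_error("ncax_invalid_input", "x and y must have equal length")
  if (anyNA(x) || anyNA(y))
    .ncax_error("ncax_invalid_input",
                "missing values are not allowed; clean the data first (see load_sample)")
  if (length(x) < 3L)
    .ncax_error("ncax_insufficient_data",
                "insufficient data: at least 3 complete pairs are required")
  labels <- as.character(labels)
  if (length(labels) != 2L)
    .ncax_error("ncax_invalid_input", "labels must have length 2")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 n = length(x), labels = labels),
            class = "nca_sample")
}

#' Swap the axes of a paired sample
#'
#' Exchanges the roles of the two variables. The sufficiency effect of x on y
#' is, by construction, the necessity effect computed on the swapped sample.
#'
#' @param sample An [nca_sample()].
#' @return An `nca_sample` with `x` and `y` (and the labels) exchanged.
#' @export
swap_sample <- function(sample) {
  stopifnot(inherits(sample, "nca_sample"))
  nca_sample(sample$y, sample$x, labels = rev(sample$labels))
}

#' @export
print.nca_sample <- function(x, ...) {
  cat(sprintf("Paired sample: %s vs %s, n = %d\n",
              x$labels[1], x$labels[2], x$n))
  invisible(x)
}

#' Empirical scope of a paired sample
#'
#' The scope is the bounding rectangle spanned by the observed minima and
#' maxima of both variables. Effect sizes are empty-corner areas expressed
#' relative to the area of this rectangle.
#'
#' @param sample An [nca_sample()].
#' @return An object of class `nca_scope` with elements `x_min`, `x_max`,
#'   `y_min`, `y_max` and `area`.
#' @export
compute_scope <- function(sample) {
  stopifnot(inherits(sample, "nca_sample"))
  rx <- range(sample$x)
  ry <- range(sample$y)
  if (rx[1] == rx[2] || ry[1] == ry[2])
    .ncax_error("ncax_degenerate_scope",
                "degenerate scope: zero range in x or y, effect size undefined")
  structure(list(x_min = rx[1], x_max = rx[2],
                 y_min = ry[1], y_max = ry[2],
                 area = (rx[2] - rx[1]) * (ry[2] - ry[1])),
            class = "nca_scope")
}

#' @export
print.nca_scope <- function(x, ...) {
  cat(sprintf("Scope: x in [%g, %g], y in [%g, %g], area = %g\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$area))
  invisible(x)
}
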