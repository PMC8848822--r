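# Ceiling estimation: CE-FDH step function and CR-FDH regression line.

#' CE-FDH ceiling: the free-disposal-hull step function
#'
#' The ceiling-envelopment free-disposal-hull (CE-FDH) ceiling is the lowest
#' non-decreasing, right-continuous step function with no observation
#' strictly above it: c(x) = max\{y_i : x_i <= x\}. The observations that
#' generate its steps (the non-dominated upper-left points) are the peers.
#'
#' @param sample An [nca_sample()].
#' @param scope The sample's [compute_scope()]; recomputed when omitted.
#' @return An object of class `nca_ceiling` with `knots` (data frame of step
#'   break `x` and `level`), `peers` (data frame of the generating points),
#'   and the scope bounds it was built against.
#' @export
ce_fdh_ceiling <- function(sample, scope = compute_scope(sample)) {
  ord <- order(sample$x, -sample$y)
  xs <- sample$x[ord]
  ys <- sample$y[ord]
  first <- !duplicated(xs)        # ys is max within each x-tie group here
  gx <- xs[first]
  gy <- ys[first]
  lev <- cummax(gy)
  keep <- !duplicated(lev)        # strict increases of the running max
  structure(list(knots = data.frame(x = gx[keep], level = lev[keep]),
                 peers = data.frame(x = gx[keep], y = gy[keep]),
                 x_max = scope$x_max, y_max = scope$y_max),
            class = "nca_ceiling")
}

#' Evaluate a CE-FDH ceiling
#'
#' Right-continuous step evaluation of the ceiling at arbitrary x positions
#' within the scope.
#'
#' @param ceiling An `nca_ceiling` from [ce_fdh_ceiling()].
#' @param x Numeric vector of positions, each >= the first knot.
#' @return Numeric vector of ceiling levels.
#' @export
eval_ceiling <- function(ceiling, x) {
  stopifnot(inherits(ceiling, "nca_ceiling"))
  idx <- findInterval(x, ceiling$knots$x)
  if (any(idx < 1L))
    .ncax_error("ncax_invalid_input", "x below the ceiling's domain")
  ceiling$knots$level[idx]
}

#' Area of the empty zone above a ceiling
#'
#' Exact area of \{(x, y) in the scope : y > c(x)\}, the empty upper-left
#' corner. For the CE-FDH step this is a finite sum of rectangles; for the
#' CR-FDH line it is trapezoid geometry with the line clamped to the scope.
#'
#' @param ceiling An `nca_ceiling` or `nca_cr_line`.
#' @param scope The [compute_scope()] rectangle.
#' @return Non-negative area in data units, at most `scope$area`.
#' @export
ceiling_zone_area <- function(ceiling, scope) UseMethod("ceiling_zone_area")

#' @export
ceiling_zone_area.nca_ceiling <- function(ceiling, scope) {
  k <- ceiling$knots
  w <- diff(c(k$x, scope$x_max))
  sum(w * (scope$y_max - k$level))
}

#' @export
ceiling_zone_area.nca_cr_line <- function(ceiling, scope) {
  .area_above_line(ceiling$intercept, ceiling$slope, scope)
}

# Exact area of {y > b0 + b1*x} within the scope rectangle: the integrand
# y_max - clamp(line, y_min, y_max) is piecewise linear, so trapezoids
# between the crossings of the line with y_min and y_max are exact.
.area_above_line <- function(b0, b1, scope) {
  f <- function(x) {
    scope$y_max - pmin(pmax(b0 + b1 * x, scope$y_min), scope$y_max)
  }
  xs <- c(scope$x_min, scope$x_max)
  if (b1 != 0)
    xs <- c(xs, (scope$y_min - b0) / b1, (scope$y_max - b0) / b1)
  xs <- sort(unique(pmin(pmax(xs, scope$x_min), scope$x_max)))
  lo <- xs[-length(xs)]
  hi <- xs[-1]
  sum((hi - lo) * (f(lo) + f(hi)) / 2)
}

#' CR-FDH ceiling: least-squares line through the CE-FDH peers
#'
#' The ceiling-regression (CR-FDH) ceiling is the ordinary least-squares line
#' fitted to the CE-FDH peers. Its empty zone is the part of the scope
#' rectangle strictly above the line, computed exactly with the line clamped
#' to the rectangle. With fewer than two distinct peers no line can be
#' fitted and the CE-FDH step is returned instead, with a warning.
#'
#' @inheritParams ce_fdh_ceiling
#' @param warn_fallback Emit the fallback warning (internal resampling loops
#'   disable it).
#' @return An object of class `nca_cr_line` with `intercept`, `slope` and
#'   `peers`, or the CE-FDH `nca_ceiling` when the fit is impossible.
#' @export
cr_fdh_ceiling <- function(sample, scope = compute_scope(sample),
                           warn_fallback = TRUE) {
  ce <- ce_fdh_ceiling(sample, scope)
  p <- unique(ce$peers)
  if (nrow(p) < 2L) {
    if (warn_fallback)
      warning("fewer than 2 distinct CE-FDH peers; falling back to the CE-FDH ceiling",
              call. = FALSE)
    return(ce)
  }
  co <- stats::lm.fit(cbind(1, p$x), p$y)$coefficients
  structure(list(intercept = unname(co[1]), slope = unname(co[2]), peers = p),
            class = "nca_cr_line")
}

#' @export
print.nca_ceiling <- function(x, ...) {
  cat(sprintf("CE-FDH ceiling: %d step(s), %d peer(s)\n",
              nrow(x$knots), nrow(x$peers)))
  invisible(x)
}

#' @export
print.nca_cr_line <- function(x, ...) {
  cat(sprintf("CR-FDH ceiling: y = %g + %g x (%d peers)\n",
              x$intercept, x$slope, nrow(x$peers)))
  invisible(x)
}
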