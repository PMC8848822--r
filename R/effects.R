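# Effect sizes: relative empty-corner areas in the two directions.

#' Necessity effect size
#'
#' The necessity effect of x on y is the area of the empty upper-left corner
#' above the ceiling line, divided by the scope area: the degree to which a
#' low value of x precludes a high value of y. d = 0 means no empty corner;
#' d = 1 would mean a fully empty scope.
#'
#' @param sample An [nca_sample()].
#' @param technique `"ce_fdh"` (step ceiling, default) or `"cr_fdh"`
#'   (regression line through the CE-FDH peers).
#' @return An object of class `nca_effect` with `direction`, `technique`,
#'   `d`, `ceiling_zone`, `scope_area` and `labels`.
#' @examples
#' s <- nca_sample(c(1, 2, 3, 4, 5), c(2, 3, 3, 5, 4))
#' necessity_effect(s)$d   # 7/12
#' @export
necessity_effect <- function(sample, technique = c("ce_fdh", "cr_fdh")) {
  technique <- match.arg(technique)
  scope <- compute_scope(sample)
  ceil <- switch(technique,
                 ce_fdh = ce_fdh_ceiling(sample, scope),
                 cr_fdh = cr_fdh_ceiling(sample, scope))
  zone <- ceiling_zone_area(ceil, scope)
  structure(list(direction = "necessity_x_on_y",
                 technique = technique,
                 d = zone / scope$area,
                 ceiling_zone = zone,
                 scope_area = scope$area,
                 labels = sample$labels),
            class = "nca_effect")
}

#' Sufficiency effect size
#'
#' The sufficiency effect of x on y is the relative area of the empty
#' lower-right corner below the floor line. It is identical to the necessity
#' effect of y on x, and is computed exactly that way: the sample's axes are
#' swapped and [necessity_effect()] applied.
#'
#' @inheritParams necessity_effect
#' @return An `nca_effect` with `direction = "sufficiency_x_on_y"`.
#' @examples
#' s <- nca_sample(c(1, 2, 3, 4, 5), c(2, 3, 3, 5, 4))
#' sufficiency_effect(s)$d   # 6/12
#' @export
sufficiency_effect <- function(sample, technique = c("ce_fdh", "cr_fdh")) {
  technique <- match.arg(technique)
  eff <- necessity_effect(swap_sample(sample), technique)
  eff$direction <- "sufficiency_x_on_y"
  eff$labels <- sample$labels
  eff
}

#' @export
print.nca_effect <- function(x, ...) {
  dir <- if (x$direction == "necessity_x_on_y") "Necessity" else "Sufficiency"
  cat(sprintf("%s effect of %s on %s (%s): d = %.4f\n",
              dir, x$labels[1], x$labels[2], x$technique, x$d))
  invisible(x)
}

# Fast scalar d for resampling loops: same quantity as necessity_effect()
# but without object construction. Correct under x ties because the running
# max at the last element of a tie group is the group max and the widths of
# the other elements are zero.
.d_necessity <- function(x, y, technique = "ce_fdh") {
  ord <- order(x, -y)   # within x ties the group max comes first
  xs <- x[ord]
  n <- length(xs)
  x_rng <- xs[n] - xs[1]
  y_min <- min(y)
  y_max <- max(y)
  area <- x_rng * (y_max - y_min)
  cm <- cummax(y[ord])
  if (technique == "ce_fdh")
    return(sum(diff(xs) * (y_max - cm[-n])) / area)
  # cr_fdh: peers are the first attainments of each new running max
  ys <- y[ord]
  is_new <- ys == cm & !duplicated(cm)
  px <- xs[is_new]
  py <- ys[is_new]
  if (length(px) < 2L) {  # silent CE-FDH fallback inside resampling
    return(sum(diff(xs) * (y_max - cm[-n])) / area)
  }
  mx <- mean(px); my <- mean(py)
  b1 <- sum((px - mx) * (py - my)) / sum((px - mx)^2)
  b0 <- my - b1 * mx
  scope <- list(x_min = xs[1], x_max = xs[n], y_min = y_min, y_max = y_max)
  .area_above_line(b0, b1, scope) / area
}
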