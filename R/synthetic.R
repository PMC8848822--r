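# Seeded generators with known empty-corner structure.

#' Specify a synthetic bivariate sample
#'
#' Describes a seeded generator on the unit square with controllable
#' empty-corner structure:
#'
#' * `necessity_only`: points uniform below a straight ceiling line whose
#'   excluded upper-left triangle has area `ceiling_fraction`; the points
#'   (0, 0) and (1, 1 - 2*ceiling_fraction) are pinned so the x-range and the
#'   y-minimum of the empirical scope are stable.
#' * `sufficiency_only`: the axis swap of `necessity_only` at the same seed.
#' * `both`: points uniform on a parallelogram band around the diagonal whose
#'   excluded upper-left and lower-right triangles each have area
#'   `ceiling_fraction`; (0, 0) and (1, 1) pinned.
#' * `independent`: points uniform on the unit square with all four corners
#'   pinned (the pinned corners make both empty-corner areas exactly zero).
#' * `swap_symmetric`: the union of a uniform random set and its axis-swap
#'   image, so the necessity and sufficiency effects are equal by
#'   construction.
#'
#' `ceiling_fraction` is the asymptotic empty-corner area relative to the
#' unit square; it must be at most 0.5 for `necessity_only` /
#' `sufficiency_only` (a straight line cannot exclude more than half the
#' square) and below 0.5 for `both`.
#'
#' @param model One of `"necessity_only"`, `"sufficiency_only"`, `"both"`,
#'   `"independent"`, `"swap_symmetric"`.
#' @param n Number of observations (>= 3; >= 4 for `independent`).
#' @param seed Integer seed; the same spec always generates the same sample.
#' @param ceiling_fraction Target asymptotic empty-corner area fraction in
#'   `[0, 1)`; ignored by `independent` and `swap_symmetric`.
#' @return An object of class `nca_generator_spec`.
#' @export
generator_spec <- function(model = c("necessity_only", "sufficiency_only",
                                     "both", "independent", "swap_symmetric"),
                           n, seed, ceiling_fraction = 0) {
  model <- match.arg(model)
  if (n < 3)
    .ncax_error("ncax_parameter_error", "n must be at least 3")
  if (model == "independent" && n < 4)
    .ncax_error("ncax_parameter_error",
                "independent model pins four corners and needs n >= 4")
  if (ceiling_fraction < 0 || ceiling_fraction >= 1)
    .ncax_error("ncax_parameter_error", "ceiling_fraction must be in [0, 1)")
  if (model %in% c("necessity_only", "sufficiency_only") &&
      ceiling_fraction > 0.5)
    .ncax_error("ncax_parameter_error",
                "a straight ceiling line cannot exclude more than half the square: ceiling_fraction must be <= 0.5")
  if (model == "both" && ceiling_fraction >= 0.5)
    .ncax_error("ncax_parameter_error",
                "both-corners band requires ceiling_fraction < 0.5")
  structure(list(model = model, n = as.integer(n), seed = as.integer(seed),
                 ceiling_fraction = ceiling_fraction),
            class = "nca_generator_spec")
}

# Uniform points on the accepted subregion of the unit square.
.rejection_unit <- function(m, accept) {
  ox <- numeric(0)
  oy <- numeric(0)
  while (length(ox) < m) {
    k <- max(1000L, 2L * (m - length(ox)))
    cx <- stats::runif(k)
    cy <- stats::runif(k)
    ok <- accept(cx, cy)
    ox <- c(ox, cx[ok])
    oy <- c(oy, cy[ok])
  }
  list(x = ox[seq_len(m)], y = oy[seq_len(m)])
}

#' Generate a synthetic sample
#'
#' Draws the sample described by a [generator_spec()]. Identical specs
#' (including the seed) produce identical samples.
#'
#' @param spec An `nca_generator_spec`.
#' @return An [nca_sample()] with labels `c("x", "y")`.
#' @examples
#' s <- generate_sample(generator_spec("necessity_only", n = 200, seed = 7,
#'                                     ceiling_fraction = 0.5))
#' necessity_effect(s)$d
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "nca_generator_spec"))
  if (spec$model == "sufficiency_only") {
    base <- generator_spec("necessity_only", spec$n, spec$seed,
                           spec$ceiling_fraction)
    return(swap_sample(generate_sample(base)))
  }
  set.seed(spec$seed)
  n <- spec$n
  f <- spec$ceiling_fraction
  switch(spec$model,
    necessity_only = {
      h <- 2 * f  # ceiling line y = (1 - h) + h * x
      pts <- .rejection_unit(n - 2L, function(cx, cy) cy <= (1 - h) + h * cx)
      nca_sample(c(0, 1, pts$x), c(0, 1 - h, pts$y))
    },
    both = {
      t <- 1 - sqrt(2 * f)  # band |y - x| <= t
      pts <- .rejection_unit(n - 2L, function(cx, cy) abs(cy - cx) <= t)
      nca_sample(c(0, 1, pts$x), c(0, 1, pts$y))
    },
    independent = {
      nca_sample(c(0, 0, 1, 1, stats::runif(n - 4L)),
                 c(0, 1, 0, 1, stats::runif(n - 4L)))
    },
    swap_symmetric = {
      k <- n %/% 2L
      px <- stats::runif(k)
      py <- stats::runif(k)
      x <- c(px, py)
      y <- c(py, px)
      if (n %% 2L == 1L) {
        u <- stats::runif(1)
        x <- c(x, u)
        y <- c(y, u)
      }
      nca_sample(x, y)
    })
}
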