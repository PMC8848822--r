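# Independent oracles used across the suite.

# Grid oracle: fraction of G x G cell centers lying strictly above the
# ceiling. For CE-FDH the ceiling is evaluated directly from the data
# (max y over x_i <= x), independently of the package's step representation.
grid_d <- function(sample, technique = "ce_fdh", G = 2000) {
  sc <- compute_scope(sample)
  hx <- (sc$x_max - sc$x_min) / G
  hy <- (sc$y_max - sc$y_min) / G
  xc <- sc$x_min + (seq_len(G) - 0.5) * hx
  cvals <- if (technique == "ce_fdh") {
    vapply(xc, function(x0) max(sample$y[sample$x <= x0]), numeric(1))
  } else {
    cl <- cr_fdh_ceiling(sample, sc, warn_fallback = FALSE)
    if (inherits(cl, "nca_cr_line"))
      pmin(pmax(cl$intercept + cl$slope * xc, sc$y_min), sc$y_max)
    else
      vapply(xc, function(x0) max(sample$y[sample$x <= x0]), numeric(1))
  }
  cnt <- G - floor((cvals - sc$y_min) / hy + 0.5)
  cnt <- pmin(pmax(cnt, 0), G)
  sum(cnt) / G^2
}

# Direct lower-right empty-corner area: integrates x_max - max{x_i : y_i <= y}
# over y, without going through swap_sample().
lower_right_d <- function(sample) {
  sc <- compute_scope(sample)
  ord <- order(sample$y, -sample$x)
  ys <- sample$y[ord]
  cm <- cummax(sample$x[ord])
  n <- length(ys)
  sum(diff(ys) * (sc$x_max - cm[-n])) / sc$area
}

# All permutations of 1..n as rows (n <= 7).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[p], nrow = nrow(p)))
  }))
}

# Exact (unsmoothed) permutation p for the necessity effect by exhaustive
# enumeration of all n! re-pairings; uses the slow effect-size path.
exact_perm_p <- function(sample, technique = "ce_fdh") {
  d_obs <- suppressWarnings(necessity_effect(sample, technique)$d)
  pm <- all_perms(sample$n)
  dvals <- apply(pm, 1, function(idx) {
    suppressWarnings(
      necessity_effect(nca_sample(sample$x, sample$y[idx]), technique)$d)
  })
  mean(dvals >= d_obs - 1e-12)
}

random_sample <- function(n) nca_sample(stats::runif(n), stats::runif(n))
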