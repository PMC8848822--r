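# Permutation test, bootstrap difference Z-test, interpretation logic.

five_pt <- function() nca_sample(c(1, 2, 3, 4, 5), c(2, 3, 3, 5, 4))

test_that("observed d of zero gives permutation p of exactly 1", {
  corners <- nca_sample(c(0, 0, 1, 1), c(0, 1, 0, 1))
  pr <- permutation_p(corners, n_permutations = 50, seed = 1)
  expect_identical(pr$p, 1)
  expect_identical(pr$d_obs, 0)
})

test_that("sampled permutation p matches exhaustive enumeration for small n", {
  s4 <- nca_sample(c(1, 2, 3, 4), c(1, 3, 2, 4))
  for (tech in c("ce_fdh", "cr_fdh")) {
    p_exact <- exact_perm_p(s4, tech)
    K <- 2000
    p_hat <- permutation_p(s4, technique = tech,
                           n_permutations = K, seed = 21)$p
    expect_lt(abs(p_hat - (K * p_exact + 1) / (K + 1)),
              2 * sqrt(p_exact * (1 - p_exact) / K) + 1e-9)
  }
})

test_that("permutation p is never zero and add-one smoothed", {
  # a sample whose observed pairing maximizes d among permutations
  s <- nca_sample(c(0, 0.5, 1), c(0, 0.5, 1))
  K <- 200
  pr <- permutation_p(s, n_permutations = K, seed = 3)
  expect_gte(pr$p, 1 / (K + 1))
  expect_lte(pr$p, 1)
})

test_that("bootstrap difference is symmetric about zero for swap-symmetric data", {
  ss <- generate_sample(generator_spec("swap_symmetric", n = 100, seed = 8))
  b <- bootstrap_difference(ss, n_bootstrap = 400, seed = 9)
  expect_lt(abs(b$mean_diff), 3 * b$se_diff / sqrt(b$n_effective))
  expect_gt(b$p, 0.5)
  expect_equal(b$plugin_diff, 0)
})

test_that("constant bootstrap difference is flagged with p = 1", {
  s <- nca_sample(c(0, 0, 1), c(0, 0, 1))
  b <- bootstrap_difference(s, n_bootstrap = 100, seed = 5)
  expect_true(b$constant)
  expect_identical(b$se_diff, 0)
  expect_true(is.na(b$z))
  expect_identical(b$p, 1)
})

test_that("plug-in difference is exact and diffs are retained", {
  b <- bootstrap_difference(five_pt(), n_bootstrap = 300, seed = 13)
  expect_equal(b$plugin_diff, 7 / 12 - 6 / 12)
  expect_identical(length(b$diffs), b$n_effective)
  expect_identical(b$n_effective + b$skipped, b$n_bootstrap)
  if (!b$constant) {
    expect_equal(b$z, b$mean_diff / b$se_diff)
    expect_equal(b$p, 2 * pnorm(-abs(b$z)))
  }
})

test_that("interpretation encodes the guard and the logical pattern", {
  boot <- function(p, m) list(p = p, mean_diff = m)
  perm <- function(d, p) list(d_obs = d, p = p)

  # both effects detected, difference flat: equal degrees
  r <- interpret_pattern(perm(0.121, 0.0005), perm(0.137, 0.008),
                         boot(0.991, 0.0003))
  expect_identical(r$interpretation, "equal_degrees")
  expect_true(r$guard_ok)
  expect_match(r$note, "not logically compatible")

  # necessity detected, significant positive difference
  r <- interpret_pattern(perm(0.117, 0.003), perm(0.032, 0.474),
                         boot(0.0005, 0.088))
  expect_identical(r$interpretation, "necessity_dominant")
  expect_true(r$guard_ok)
  expect_null(r$note)

  # neither effect detected: no claim regardless of the difference
  r <- interpret_pattern(perm(0.05, 0.6), perm(0.04, 0.7), boot(0.001, 0.2))
  expect_identical(r$interpretation, "no_nonrandomness")
  expect_false(r$guard_ok)

  # significant negative difference
  r <- interpret_pattern(perm(0.02, 0.6), perm(0.30, 0.001),
                         boot(0.0001, -0.25))
  expect_identical(r$interpretation, "sufficiency_dominant")
  expect_true(r$guard_ok)
})

test_that("the full report is reproducible and composes its parts", {
  s <- five_pt()
  r1 <- run_extended_nca(s, n_permutations = 300, n_bootstrap = 300, seed = 17)
  r2 <- run_extended_nca(s, n_permutations = 300, n_bootstrap = 300, seed = 17)
  expect_identical(r1, r2)

  expect_equal(r1$necessity$effect$d, 7 / 12)
  expect_equal(r1$sufficiency$effect$d, 6 / 12)
  expect_equal(r1$difference$plugin_diff, 1 / 12)
  expect_identical(r1$necessity$perm$n_permutations, 300)

  # four-corner data: nothing non-random anywhere
  corners <- nca_sample(c(0, 0, 1, 1), c(0, 1, 0, 1))
  rc <- run_extended_nca(corners, n_permutations = 100, n_bootstrap = 100,
                         seed = 2)
  expect_identical(rc$necessity$effect$d, 0)
  expect_identical(rc$sufficiency$effect$d, 0)
  expect_identical(rc$necessity$perm$p, 1)
  expect_identical(rc$interpretation, "no_nonrandomness")
})

test_that("axis swap exchanges the report blocks and negates the difference", {
  set.seed(55)
  s <- random_sample(40)
  r <- run_extended_nca(s, n_permutations = 200, n_bootstrap = 200, seed = 7)
  rs <- run_extended_nca(swap_sample(s), n_permutations = 200,
                         n_bootstrap = 200, seed = 7)
  expect_identical(rs$necessity$effect$d, r$sufficiency$effect$d)
  expect_identical(rs$sufficiency$effect$d, r$necessity$effect$d)
  expect_identical(rs$necessity$perm$p, r$sufficiency$perm$p)
  expect_identical(rs$sufficiency$perm$p, r$necessity$perm$p)
  expect_identical(rs$difference$mean_diff, -r$difference$mean_diff)
  expect_identical(rs$difference$z, -r$difference$z)
  expect_identical(rs$difference$p, r$difference$p)
})
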