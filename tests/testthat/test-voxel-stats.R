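# independent slow oracle: per-voxel t by explicit formula, per-permutation
# recomputation in a plain loop
oracle_tmap <- function(X, y) {
  apply(X, 2, function(v) {
    if (sd(v) == 0) return(NA_real_)
    r <- cor(y, v)
    r * sqrt((length(y) - 2) / (1 - r^2))
  })
}

# minimal independent permutation enumerator (lexicographic)
gtools_style_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_style_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}


test_that("voxel-wise t statistics match the closed form", {
  set.seed(31)
  n <- 6
  X <- matrix(rnorm(n * 10), n)
  y <- rnorm(n)
  expect_equal(voxelwise_glm(X, y), oracle_tmap(X, y))
  # constant voxel is untestable
  X2 <- cbind(X, 5)
  expect_true(is.na(voxelwise_glm(X2, y)[11]))
  # perfect linear relation reports the cap
  X3 <- cbind(y * 2 + 1, X)
  expect_equal(voxelwise_glm(X3, y)[1], 1e8)
  expect_error(voxelwise_glm(X, rep(1, n)), "constant severity")
  expect_error(voxelwise_glm(X[1:2, ], y[1:2]), "at least 3")
})

test_that("exhaustive permutation threshold matches explicit enumeration", {
  set.seed(32)
  n <- 6
  X <- matrix(rnorm(n * 8), n)
  y <- rnorm(n)
  res <- max_stat_fwe(X, y, alpha = 0.05, tails = "two", exhaustive = TRUE)
  expect_equal(res$n_perm, factorial(n))
  # brute-force enumeration with an independent permutation generator
  perms <- gtools_style_perms(n)
  maxima <- apply(perms, 1, function(p) max(abs(oracle_tmap(X, y[p]))))
  expect_equal(sort(res$perm_max), sort(maxima))
  expect_equal(res$fwe_threshold, sort(maxima)[ceiling(0.95 * length(maxima))])
})

test_that("a single-voxel map reduces to an ordinary permutation test", {
  set.seed(33)
  n <- 12
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.5)
  set.seed(99)
  res <- max_stat_fwe(matrix(x, ncol = 1), y, n_perm = 500, alpha = 0.05)
  # manual permutation test of the correlation with the same draws
  set.seed(99)
  t_obs <- abs(oracle_tmap(matrix(x, ncol = 1), y))
  t_perm <- replicate(500, abs(oracle_tmap(matrix(x, ncol = 1),
                                           y[sample.int(n)])))
  expect_equal(res$perm_max, t_perm)
  expect_equal(res$p_fwe[1], (1 + sum(t_perm >= t_obs)) / 501)
  expect_equal(unname(res$sig_mask[1]),
               t_obs > sort(t_perm)[ceiling(0.95 * 500)])
})

test_that("permutation p-values are strictly positive and thresholds grow with map size", {
  set.seed(34)
  n <- 10
  y <- rnorm(n)
  X <- matrix(rnorm(n * 200), n)
  set.seed(1); r_small <- max_stat_fwe(X[, 1:10], y, n_perm = 300)
  set.seed(1); r_large <- max_stat_fwe(X, y, n_perm = 300)
  expect_gte(r_large$fwe_threshold, r_small$fwe_threshold)
  expect_true(all(r_small$p_fwe >= 1 / 301))
})

test_that("Bayes factors match adaptive numerical integration", {
  ref_bf <- function(t, n, s = sqrt(2) / 2) {
    num <- integrate(function(d)
      suppressWarnings(dt(t, n - 2, ncp = d * sqrt(n))) * dcauchy(d, 0, s),
      -Inf, Inf, rel.tol = 1e-10)$value
    num / dt(t, n - 2)
  }
  for (t in c(-4, -1, 0, 0.8, 2.5, 7))
    expect_equal(bf10_from_t(t, 40), ref_bf(t, 40), tolerance = 1e-6)
  # prior scale matters and is honoured
  expect_equal(bf10_from_t(2, 20, prior_scale = 1),
               ref_bf(2, 20, s = 1), tolerance = 1e-6)
})

test_that("Bayes factors separate null from strong effects and grow with n", {
  set.seed(35)
  n <- 40
  x <- rnorm(n)
  y_null <- rnorm(n)
  t_null <- voxelwise_glm(matrix(x, ncol = 1), y_null)
  r <- 0.9
  t_eff <- r * sqrt((n - 2) / (1 - r^2))
  expect_lt(bf10_from_t(t_null, n), 1)
  expect_gt(bf10_from_t(t_eff, n), 30)
  # monotone in n at fixed r, both under H1 and towards H0 under the null
  r_fix <- 0.5
  bfs <- sapply(c(10, 40, 160), function(m)
    bf10_from_t(r_fix * sqrt((m - 2) / (1 - r_fix^2)), m))
  expect_true(all(diff(bfs) > 0))
  bfs0 <- sapply(c(10, 40, 160), function(m) bf10_from_t(0, m))
  expect_true(all(diff(bfs0) < 0))
})

test_that("evidence binning follows the conventional thresholds", {
  bf <- c(0.2, 0.5, 1, 2, 5, 10.5, 40, NA)
  got <- bin_bayes_factors(bf)
  expect_equal(as.character(got$bins),
               c("h0_moderate_or_more", "h0_anecdotal", "h1_anecdotal",
                 "h1_anecdotal", "h1_moderate", "h1_strong",
                 "h1_very_strong", NA))
  expect_equal(sum(got$proportions), 1)
  expect_error(bin_bayes_factors(c(1, -2)), "positive")
  # boundary cases: 3 is still moderate's lower neighbour, 1/3 not yet h0+
  b2 <- bin_bayes_factors(c(3, 3.0001, 1 / 3, 1 / 3 - 1e-9))
  expect_equal(as.character(b2$bins),
               c("h1_anecdotal", "h1_moderate", "h0_anecdotal",
                 "h0_moderate_or_more"))
})

test_that("bayes_factor_map handles stacks and reports proportions", {
  set.seed(36)
  n <- 30
  y <- rnorm(n)
  X <- cbind(y + rnorm(n, sd = 0.2), matrix(rnorm(n * 5), n), rep(1, n))
  bm <- bayes_factor_map(X, y)
  expect_gt(bm$bfmap[1], 30)
  expect_true(is.na(bm$bfmap[7]))       # constant voxel propagates NA
  expect_equal(sum(bm$bin_proportions), 1)
  expect_error(bayes_factor_map(X[1:4, ], y[1:4]), "at least 5")
})
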