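test_that("tract binarisation is inclusive at the threshold", {
  dims <- c(4, 4, 4)
  p <- array(0, dims)
  p[1, 1, 1] <- 0.3; p[2, 1, 1] <- 0.29; p[3, 1, 1] <- 1
  prob <- volume3d(p)
  b <- binarize_tract(prob, 0.3)
  expect_equal(b$data[1, 1, 1], 1)       # p = 0.3 is kept (>= rule)
  expect_equal(b$data[2, 1, 1], 0)
  b1 <- binarize_tract(prob, 1.0)
  expect_equal(sum(b1$data), 1)
  low <- volume3d(array(0.2, dims))
  expect_error(binarize_tract(low, 0.3, name = "SLF"), "SLF")
  expect_error(binarize_tract(prob, 0), "threshold")
})

test_that("lesion loads match brute-force voxel enumeration", {
  set.seed(51)
  dims <- c(6, 6, 6)
  for (rep in 1:25) {
    lesion <- volume3d(array(rbinom(prod(dims), 1, 0.3) + 0, dims))
    tract <- volume3d(array(rbinom(prod(dims), 1, 0.4) + 0, dims))
    prob <- volume3d(array(runif(prod(dims)), dims))
    # brute force by explicit triple loop
    inter <- 0; tsize <- 0; wsum <- 0; wmass <- 0
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
      tsize <- tsize + (tract$data[i, j, k] > 0)
      inter <- inter + (tract$data[i, j, k] > 0 && lesion$data[i, j, k] > 0)
      wmass <- wmass + prob$data[i, j, k]
      if (lesion$data[i, j, k] > 0) wsum <- wsum + prob$data[i, j, k]
    }
    if (tsize > 0)
      expect_identical(lesion_load(lesion, tract), inter / tsize)
    expect_identical(weighted_lesion_load(lesion, prob), wsum / wmass)
  }
})

test_that("load measures are bounded, monotone, and consistent on binary maps", {
  set.seed(52)
  dims <- c(8, 8, 8)
  tract <- volume3d(array(rbinom(prod(dims), 1, 0.2) + 0, dims))
  lesion <- volume3d(array(rbinom(prod(dims), 1, 0.15) + 0, dims))
  l1 <- lesion_load(lesion, tract)
  expect_gte(l1, 0); expect_lte(l1, 1)
  # weighted load on a binary probability map equals the binary load
  expect_equal(weighted_lesion_load(lesion, tract), l1)
  # growing the lesion never decreases either load
  grown <- lesion
  grown$data[tract$data > 0] <- 1
  expect_gte(lesion_load(grown, tract), l1)
  expect_equal(lesion_load(grown, tract), 1)     # lesion now covers tract
  none <- volume3d(array(0, dims))
  expect_equal(lesion_load(none, tract), 0)
  expect_equal(weighted_lesion_load(none, tract), 0)
  expect_error(lesion_load(lesion, none), "empty tract")
})

test_that("kendall tau matches brute-force pair counting with ties", {
  brute_tau <- function(x, y) {
    n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx * dy > 0) C <- C + 1 else D <- D + 1
    }
    n0 <- n * (n - 1) / 2
    (C - D) / sqrt((n0 - tx) * (n0 - ty))
  }
  set.seed(53)
  for (rep in 1:10) {
    x <- sample(0:3, 8, replace = TRUE)     # plenty of ties
    y <- rnorm(8) + x
    if (sd(x) == 0) next
    expect_equal(kendall_tau(x, y)$tau, brute_tau(x, y))
  }
  # tie-free extremes
  x <- 1:6
  expect_equal(kendall_tau(x, x + runif(6, 0, 0.1) + 1:6)$tau, 1)
  expect_equal(kendall_tau(x, rev(x) + 0.01 * rnorm(6))$tau, -1)
  expect_error(kendall_tau(rep(1, 6), rnorm(6)), "constant")
})

test_that("bonferroni is the capped multiple of the raw p-values", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.08, 0.12, 0.16))
  expect_equal(bonferroni(c(0.5, 0.5, 0.5, 0.5)), rep(1, 4))
  expect_equal(bonferroni(0.2), 0.2)
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("presence chi-square reproduces closed forms and the reference worked example", {
  # reconstruction from the reference cohort marginals: 43 patients, 28 with
  # load, 14 neglect patients of whom 12 with load
  tab <- rbind(c(12, 2), c(16, 13))
  res <- presence_chi_square(tab)
  expect_equal(res$df, 1)
  expect_equal(round(res$chi2, 2), 3.88)
  expect_lt(res$p, 0.05)
  # independence gives exactly zero
  expect_equal(presence_chi_square(rbind(c(5, 5), c(5, 5)))$chi2, 0)
  # perfect association gives chi2 = N
  expect_equal(presence_chi_square(rbind(c(10, 0), c(0, 10)))$chi2, 20)
  # transpose invariance
  expect_equal(presence_chi_square(t(tab))$chi2, res$chi2)
  expect_error(presence_chi_square(rbind(c(0, 0), c(3, 4))), "zero margin")
})

test_that("the load table and association summary hold together", {
  fx <- small_anatomy()
  cfg <- fx$cfg
  les <- make_lesions(cfg, fx$anatomy)
  loads_b <- lesion_load_table(les$lesions, fx$anatomy$atlas)
  loads_w <- lesion_load_table(les$lesions, fx$anatomy$atlas,
                               weighted = TRUE)
  expect_true(all(as.matrix(loads_b) >= 0 & as.matrix(loads_b) <= 1))
  expect_equal(loads_b$total,
               unname(rowSums(loads_b[, fx$anatomy$atlas$names])))
  expect_false(attr(loads_b, "weighted"))
  expect_true(attr(loads_w, "weighted"))
  beh <- make_behaviour(cfg, loads_b)
  assoc <- tract_load_association(loads_b, beh$behaviour$mean_coc,
                                  beh$behaviour$neglect)
  expect_equal(nrow(assoc$per_tract), 4)
  expect_true(all(assoc$per_tract$p_bonf >= assoc$per_tract$p,
                  na.rm = TRUE))
  if (!is.null(assoc$presence))
    expect_equal(sum(assoc$presence$table), nrow(loads_b))
})
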