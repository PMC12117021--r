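tiny_ts <- function(dims = c(3, 3, 2), nt = 12, seed = 21) {
  set.seed(seed)
  volume4d(array(rnorm(prod(dims) * nt), c(dims, nt)))
}

test_that("seed time course averages the seed voxels", {
  ts <- tiny_ts()
  one <- array(0, c(3, 3, 2)); one[2, 1, 1] <- 1
  expect_equal(seed_timecourse(ts, volume3d(one)), ts$data[2, 1, 1, ])
  two <- one; two[3, 3, 2] <- 1
  expect_equal(seed_timecourse(ts, volume3d(two)),
               (ts$data[2, 1, 1, ] + ts$data[3, 3, 2, ]) / 2)
  # whole-volume seed equals the global mean series
  all1 <- volume3d(array(1, c(3, 3, 2)))
  expect_equal(seed_timecourse(ts, all1),
               apply(ts$data, 4, mean))
  expect_error(seed_timecourse(ts, volume3d(array(0, c(3, 3, 2)))),
               "does not overlap")
})

test_that("correlation map matches the Pearson formula and flags constants", {
  set.seed(22)
  nt <- 10
  arr <- array(rnorm(2 * 1 * 1 * nt), c(2, 1, 1, nt))
  arr[2, 1, 1, ] <- 3                    # constant voxel
  ts <- volume4d(arr)
  tc <- rnorm(nt)
  cm <- correlation_map(ts, tc)
  x <- arr[1, 1, 1, ]
  r_hand <- sum((x - mean(x)) * (tc - mean(tc))) /
    sqrt(sum((x - mean(x))^2) * sum((tc - mean(tc))^2))
  expect_equal(cm$data[1, 1, 1], r_hand)
  expect_true(is.na(cm$data[2, 1, 1]))
  # perfect correlation and anticorrelation
  arr2 <- array(0, c(2, 1, 1, nt))
  arr2[1, 1, 1, ] <- tc; arr2[2, 1, 1, ] <- -tc
  cm2 <- correlation_map(volume4d(arr2), tc)
  expect_equal(cm2$data[1, 1, 1], 1)
  expect_equal(cm2$data[2, 1, 1], -1)
  expect_error(correlation_map(ts, rep(1, nt)), "constant seed")
})

test_that("fisher z is the clipped atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.5), "> 1")
})

test_that("lesion-network maps average per-subject z maps", {
  set.seed(23)
  dims <- c(4, 4, 3)
  seed_m <- array(0, dims); seed_m[2, 2, 2] <- 1
  seed <- volume3d(seed_m)
  subs <- lapply(1:3, function(s) tiny_ts(dims, 15, seed = 100 + s))
  # mean of one equals that subject's z map (unmasked)
  m1 <- lesion_network_map(seed, subs[1], mask_cortex = FALSE)
  z1 <- fisher_z(correlation_map(subs[[1]],
                                 seed_timecourse(subs[[1]], seed)))
  expect_equal(m1$zmap$data, z1$data)
  # duplicating a subject changes nothing
  m11 <- lesion_network_map(seed, subs[c(1, 1)], mask_cortex = FALSE)
  expect_equal(m11$zmap$data, m1$zmap$data)
  # three subjects: voxel-wise mean of independently computed z maps
  m3 <- lesion_network_map(seed, subs, mask_cortex = FALSE)
  zs <- sapply(subs, function(sv)
    as.vector(fisher_z(correlation_map(sv,
                                       seed_timecourse(sv, seed)))$data))
  expect_equal(as.vector(m3$zmap$data), rowMeans(zs))
  # the seed voxel itself carries the clipped transform of r = 1
  expect_equal(m1$zmap$data[2, 2, 2], atanh(1 - 1e-7))
})

test_that("masking and averaging commute, and masked maps are cortex-only", {
  set.seed(24)
  dims <- c(4, 4, 3)
  labs <- array(0L, dims)
  labs[1, , ] <- 101L; labs[4, , ] <- 102L; labs[2, 2, 2] <- 1L
  parc <- parcellation(labs, cortical_ids = c(101L, 102L))
  seed_m <- array(0, dims); seed_m[2, 2, 2] <- 1
  seed <- volume3d(seed_m)
  subs <- lapply(1:3, function(s) tiny_ts(dims, 15, seed = 200 + s))
  m_mask <- lesion_network_map(seed, subs, parc, mask_cortex = TRUE)
  m_nomask <- lesion_network_map(seed, subs, parc, mask_cortex = FALSE)
  cortical <- labs %in% c(101L, 102L)
  manual <- m_nomask$zmap$data
  manual[!array(cortical, dims)] <- NA
  expect_equal(m_mask$zmap$data, manual)
  expect_true(all(is.na(m_mask$zmap$data[!array(cortical, dims)])))
})

test_that("a planted seed-to-cortex network is recovered as the top parcel", {
  fx <- small_anatomy()
  cn <- make_connectome(fx$cfg, fx$anatomy)
  seed <- fx$anatomy$roi_masks$basal_ganglia
  parc <- fx$anatomy$parcellation
  m <- lesion_network_map(seed, cn$subjects, parc, mask_cortex = TRUE)
  labs <- as.integer(parc$labels)
  mean_z <- vapply(parc$cortical_ids, function(id)
    mean(m$zmap$data[labs == id], na.rm = TRUE), numeric(1))
  expect_equal(parc$cortical_ids[which.max(mean_z)], cn$planted_parcel)
})
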