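lesion_with_voxels <- function(dims, vox) {
  a <- array(0, dims)
  a[vox] <- 1
  volume3d(a)
}

test_that("streamline intersection covers vertices, misses, and fine crossings", {
  dims <- c(10, 10, 10)
  les <- lesion_with_voxels(dims, cbind(5, 5, 5))   # voxel centre (4,4,4) mm
  # vertex inside the lesion voxel
  hit <- matrix(c(4.1, 4, 4, 8, 8, 8), 2, 3, byrow = TRUE)
  expect_true(streamline_intersects(les, hit))
  # entirely outside the lesion's bounding box
  miss <- matrix(c(0, 0, 0, 1, 1, 0), 2, 3, byrow = TRUE)
  expect_false(streamline_intersects(les, miss))
  # segment crossing the voxel between two coarse vertices: the vertex-only
  # test misses it, arc-length resampling at 0.5 mm catches it, and the
  # decision agrees with near-continuous 0.01 mm sampling
  crossing <- matrix(c(4, 4, 1, 4, 4, 7), 2, 3, byrow = TRUE)
  vertex_only <- any(les$data[world_to_voxel(les, crossing)] > 0)
  expect_false(vertex_only)
  expect_true(streamline_intersects(les, crossing, step_mm = 0.5))
  expect_true(streamline_intersects(les, crossing, step_mm = 0.01))
})

test_that("coarse and dense sampling agree on the synthetic suite, and growth is monotone", {
  fx <- small_anatomy()
  sset <- fx$anatomy$streamlines
  lines <- sset$streamlines[seq(1, length(sset), by = 12)]
  cfg <- fx$cfg
  les <- make_lesions(cfg, fx$anatomy)$lesions[1:4]
  for (l in les) {
    for (ln in lines) {
      coarse <- streamline_intersects(l, ln, step_mm = 0.5)
      dense <- streamline_intersects(l, ln, step_mm = 0.01)
      expect_identical(coarse, dense)
    }
    # dilate the lesion: intersections never flip true -> false
    grown <- l
    idx <- which(grown$data > 0, arr.ind = TRUE)
    for (d in 1:3) {
      up <- idx; up[, d] <- pmin(up[, d] + 1L, dim(grown$data)[d])
      dn <- idx; dn[, d] <- pmax(dn[, d] - 1L, 1L)
      grown$data[up] <- 1; grown$data[dn] <- 1
    }
    for (ln in lines)
      if (streamline_intersects(l, ln))
        expect_true(streamline_intersects(grown, ln))
  }
})

test_that("the disconnection matrix matches per-pair brute force", {
  set.seed(41)
  dims <- c(12, 12, 12)
  lesions <- list(
    lesion_with_voxels(dims, as.matrix(expand.grid(4:6, 4:6, 4:6))),
    lesion_with_voxels(dims, as.matrix(expand.grid(8:10, 8:10, 8:10))),
    lesion_with_voxels(dims, cbind(1, 1, 1)))
  sset <- streamline_set(lapply(1:4, function(i)
    matrix(runif(9, 0, 11), 3, 3)))
  m <- build_disconnection_matrix(lesions, sset)
  brute <- sapply(seq_len(4), function(j)
    vapply(lesions, function(l)
      as.integer(streamline_intersects(l, sset$streamlines[[j]])), 0L))
  expect_equal(unname(m$matrix), unname(brute))
  # empty lesion row is all zero
  expect_true(all(m$matrix[3, ] %in% c(0L, 1L)))
  empty <- lesion_with_voxels(dims, cbind(12, 12, 12))
  m2 <- build_disconnection_matrix(list(empty), sset)
  expect_equal(sum(m2$matrix), 0)
})

test_that("prevalence filtering keeps columns by count", {
  M <- cbind(c(1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 0, 0),
             c(1, 1, 1, 1, 1, 1, 1))
  m <- structure(list(matrix = M, patient_ids = paste0("p", 1:7),
                      streamline_index = 1:3, sset = NULL),
                 class = "disconnection_matrix")
  expect_equal(ncol(filter_prevalence(m, 5)$matrix), 2)
  expect_equal(filter_prevalence(m, 5)$streamline_index, 2:3)
  expect_equal(ncol(filter_prevalence(m, 1)$matrix), 3)
  expect_equal(ncol(filter_prevalence(m, 8)$matrix), 0)
  # filtering before inference leaves the surviving columns' statistics
  # identical to running on the filtered matrix directly
  set.seed(42)
  y <- rnorm(7)
  mf <- filter_prevalence(m, 5)
  set.seed(7); a <- streamline_glm(mf, y, n_perm = 200)
  set.seed(7); b <- streamline_glm(filter_prevalence(mf, 1), y, n_perm = 200)
  expect_equal(a$t_obs, b$t_obs)
  expect_equal(a$fwe_threshold, b$fwe_threshold)
})

test_that("a single-column GLM reduces to a one-tailed permutation t-test", {
  set.seed(43)
  n <- 14
  g <- c(rep(1L, 5), rep(0L, 9))
  y <- rnorm(n) + 1.5 * g
  m <- structure(list(matrix = matrix(g, ncol = 1), patient_ids = paste0("p", 1:n),
                      streamline_index = 1L, sset = NULL),
                 class = "disconnection_matrix")
  set.seed(11)
  res <- streamline_glm(m, y, n_perm = 400)
  t_obs <- unname(t.test(y[g == 1], y[g == 0], var.equal = TRUE)$statistic)
  expect_equal(res$t_obs, t_obs)
  set.seed(11)
  t_perm <- replicate(400, {
    yp <- y[sample.int(n)]
    unname(t.test(yp[g == 1], yp[g == 0], var.equal = TRUE)$statistic)
  })
  expect_equal(res$perm_max, t_perm)
  expect_equal(length(res$sig_index) == 1,
               t_obs > sort(t_perm)[ceiling(0.95 * 400)])
})

test_that("planted disconnection effects are detected and constants excluded", {
  set.seed(44)
  n <- 50
  planted <- integer(n); planted[sample.int(n, 15)] <- 1L
  y <- rnorm(n) + 2 * planted
  M <- cbind(planted, sapply(1:30, function(j) {
    v <- integer(n); v[sample.int(n, sample(5:20, 1))] <- 1L; v
  }), rep(1L, n))
  m <- structure(list(matrix = M, patient_ids = paste0("p", 1:n),
                      streamline_index = seq_len(ncol(M)), sset = NULL),
                 class = "disconnection_matrix")
  expect_message(res <- streamline_glm(m, y, n_perm = 500), "constant")
  expect_true(1L %in% res$sig_index)
  expect_equal(unname(res$excluded), ncol(M))
})

test_that("tract assignment counts labels and buckets missing ones", {
  s <- streamline_set(lapply(1:5, function(i) matrix(runif(6), 2, 3)),
                      tract_label = c("a", "a", "b", NA, "a"))
  expect_equal(assign_tracts(c(1, 2, 3), s), c(a = 2L, b = 1L))
  expect_equal(assign_tracts(integer(), s), setNames(integer(), character()))
  expect_equal(assign_tracts(c(1, 4), s), c(a = 1L, unlabelled = 1L))
  s2 <- streamline_set(s$streamlines)
  expect_equal(assign_tracts(1:2, s2), c(unlabelled = 2L))
})
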