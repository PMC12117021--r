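test_that("the generator is a pure function of config and seed", {
  cfg <- synth_config(n_patients = 8, n_subjects = 2, n_timepoints = 30,
                      seed = 99)
  a1 <- make_anatomy(cfg); a2 <- make_anatomy(cfg)
  expect_identical(a1$parcellation$labels, a2$parcellation$labels)
  expect_identical(a1$atlas$tracts$SLF$data, a2$atlas$tracts$SLF$data)
  expect_identical(a1$streamlines$streamlines, a2$streamlines$streamlines)
  l1 <- make_lesions(cfg, a1); l2 <- make_lesions(cfg, a2)
  expect_identical(lapply(l1$lesions, `[[`, "data"),
                   lapply(l2$lesions, `[[`, "data"))
  c1 <- make_connectome(cfg, a1); c2 <- make_connectome(cfg, a2)
  expect_identical(c1$subjects[[1]]$data, c2$subjects[[1]]$data)
})

test_that("tract maps are proper probability maps hosting their streamlines", {
  fx <- small_anatomy()
  an <- fx$anatomy
  for (nm in an$atlas$names) {
    v <- an$atlas$tracts[[nm]]$data
    expect_gte(min(v), 0); expect_lte(max(v), 1)
    expect_gt(sum(v), 0)
  }
  # every streamline lies inside the p >= 0.3 core of its own tract
  for (i in seq_along(an$streamlines$streamlines)) {
    nm <- an$streamlines$tract_label[i]
    if (!nm %in% an$atlas$names) next        # distractor bundle has no map
    vol <- an$atlas$tracts[[nm]]
    idx <- world_to_voxel(vol, an$streamlines$streamlines[[i]])
    probs <- vol$data[idx]
    expect_gte(min(probs), 0.3)
  }
})

test_that("lesions are subcortical, sized within range, and load-graded", {
  fx <- small_anatomy()
  cfg <- fx$cfg
  les <- make_lesions(cfg, fx$anatomy)
  rng <- cfg$lesion_size_range
  for (i in seq_along(les$lesions)) {
    vol <- sum(les$lesions[[i]]$data)
    expect_gte(vol, rng[1]); expect_lte(vol, rng[2])
    roi <- fx$anatomy$roi_masks[[les$groups[i]]]
    expect_gt(sum(les$lesions[[i]]$data * roi$data), 0)
  }
  # larger lesions tend to produce larger tract loads
  loads <- lesion_load_table(les$lesions, fx$anatomy$atlas)
  sizes <- vapply(les$lesions, function(l) sum(l$data), numeric(1))
  expect_gt(cor(sizes, loads$total, method = "spearman"), 0)
})

test_that("behaviour tracks total load with the requested effect", {
  fx <- small_anatomy()
  an <- fx$anatomy
  cfg_big <- synth_config(n_patients = 43, seed = 7711)
  les <- make_lesions(cfg_big, an)
  loads <- lesion_load_table(les$lesions, an$atlas)
  # noiseless limit: severity is a monotone function of total load, and
  # tie-free totals give tau exactly 1
  cfg0 <- cfg_big; cfg0$noise_sd <- 0
  beh0 <- make_behaviour(cfg0, loads)
  keep <- !duplicated(loads$total)
  if (sum(keep) >= 4)
    expect_equal(suppressWarnings(
      cor(loads$total[keep], beh0$severity[keep], method = "kendall")), 1)
  # zero effect: severity independent of load (tau centred on 0)
  cfg_null <- cfg_big; cfg_null$effect_size <- 0
  taus <- vapply(1:30, function(r) {
    cfgr <- cfg_null; cfgr$seed <- 5000L + r
  # nolint: lesions fixed, only behaviour resampled
    kendall_tau(loads$total, make_behaviour(cfgr, loads)$severity)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus)), 0.08)
  # the realised cancellation sheets reproduce the intended severity
  beh <- make_behaviour(cfg_big, loads)
  expect_lt(max(abs(beh$behaviour$coc_letters - beh$severity)), 0.02)
  expect_lt(max(abs(beh$behaviour$coc_bells - beh$severity)), 0.02)
  expect_true(all(abs(beh$behaviour$mean_coc) <= 1))
})

test_that("cohorts round-trip through the on-disk format", {
  cfg <- synth_config(n_patients = 6, bg_fraction = 0.5, n_subjects = 2,
                      n_timepoints = 24, seed = 31)
  coh <- simulate_cohort(cfg, with_connectome = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir, with_connectome = TRUE)
  expect_equal(length(back$lesions), length(coh$lesions))
  for (i in seq_along(coh$lesions))
    expect_identical(back$lesions[[i]]$data, coh$lesions[[i]]$data)
  expect_identical(back$anatomy$parcellation$labels,
                   coh$anatomy$parcellation$labels)
  for (nm in coh$anatomy$atlas$names)
    expect_identical(back$anatomy$atlas$tracts[[nm]]$data,
                     coh$anatomy$atlas$tracts[[nm]]$data)
  expect_equal(back$anatomy$streamlines$tract_label,
               coh$anatomy$streamlines$tract_label)
  for (i in seq_along(coh$anatomy$streamlines$streamlines))
    expect_lt(max(abs(back$anatomy$streamlines$streamlines[[i]] -
                      coh$anatomy$streamlines$streamlines[[i]])), 1e-4)
  # behaviour recomputed from the raw sheets matches the generator
  expect_equal(back$behaviour$mean_coc, coh$behaviour$mean_coc,
               tolerance = 1e-12)
  expect_equal(back$behaviour$neglect, coh$behaviour$neglect)
  expect_equal(back$groups, coh$groups)
  expect_identical(back$connectome[[1]]$data, coh$connectome[[1]]$data)
  expect_equal(back$ground_truth$planted_network_parcel,
               coh$ground_truth$planted_network_parcel)
})

test_that("abstract calibration generators have the advertised structure", {
  set.seed(71)
  nm <- make_null_maps(n_patients = 15, n_voxels = 60)
  expect_equal(dim(nm$X), c(15, 60))
  # neighbouring voxels are autocorrelated, distant ones are not
  r_near <- mean(sapply(1:50, function(v) cor(nm$X[, v], nm$X[, v + 1])))
  expect_gt(r_near, 0.3)
  nd <- make_null_disconnection(n_patients = 20, n_streamlines = 50)
  expect_true(all(colSums(nd$m$matrix) >= 5))
  pl <- make_planted_disconnection(n_patients = 40, n_null = 30,
                                   n_planted = 8)
  expect_equal(ncol(pl$m$matrix), 38)
  expect_equal(pl$planted_cols, 1:8)
})
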