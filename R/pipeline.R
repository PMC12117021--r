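# Orchestration of the three experiments over a cohort (synthetic or
# user-supplied), with seeding, structured per-stage counts, and
# deterministic JSON serialisation of results. Per-group analyses reuse
# the identical code path with a patient filter.

#' Run configuration for the three-experiment pipeline
#'
#' @param alpha FWE level for both mapping experiments.
#' @param n_perm_voxel,n_perm_streamline permutation counts.
#' @param prevalence_min minimum disconnection prevalence (patients) for a
#'   streamline to be tested.
#' @param tract_threshold probability cutoff for binary tract loads.
#' @param prior_scale Cauchy scale of the Bayes-factor maps.
#' @param classifier a [classifier_config()].
#' @param groups run group-wise analyses in addition to the whole cohort.
#' @param seed top-level RNG seed; fully determines every stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, n_perm_voxel = 10000,
                       n_perm_streamline = 10000, prevalence_min = 5,
                       tract_threshold = 0.3, prior_scale = sqrt(2) / 2,
                       classifier = classifier_config(),
                       groups = TRUE, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_perm_voxel >= 1, n_perm_streamline >= 1,
            prevalence_min >= 1)
  structure(list(alpha = alpha, n_perm_voxel = as.integer(n_perm_voxel),
                 n_perm_streamline = as.integer(n_perm_streamline),
                 prevalence_min = as.integer(prevalence_min),
                 tract_threshold = tract_threshold,
                 prior_scale = prior_scale, classifier = classifier,
                 groups = groups, seed = as.integer(seed)),
            class = "run_config")
}

group_subsets <- function(cohort, cfg) {
  subsets <- list(all = seq_along(cohort$lesions))
  if (isTRUE(cfg$groups)) {
    for (g in unique(cohort$groups))
      subsets[[g]] <- which(cohort$groups == g)
  }
  subsets
}

#' Experiment 1: lesion-network symptom mapping
#'
#' Builds cortex-masked lesion-network maps for every patient, then runs
#' per group (and for the whole cohort) the frequentist voxel-wise GLM
#' with maximum-statistic permutation FWE correction and the Bayes-factor
#' map with evidence binning against mean CoC severity. Groups with fewer
#' than 3 patients (5 for the Bayesian map) are skipped with a recorded
#' reason.
#'
#' @param cohort a `synth_cohort` (with connectome) or an equivalently
#'   shaped list.
#' @param cfg a [run_config()].
#' @return Nested list per group: `stat` ([max_stat_fwe()] result), `bf`
#'   ([bayes_factor_map()] result), `n_patients`, `n_voxels_tested`, or
#'   `skipped` with a reason.
#' @export
run_experiment1 <- function(cohort, cfg = run_config()) {
  if (is.null(cohort$connectome))
    stop("run_experiment1: cohort has no connectome")
  set.seed(cfg$seed + 10L)
  stack <- lesion_network_stack(cohort$lesions, cohort$connectome,
                                cohort$anatomy$parcellation,
                                mask_cortex = TRUE)
  y_all <- cohort$behaviour$mean_coc
  out <- list()
  for (g in names(group_subsets(cohort, cfg))) {
    idx <- group_subsets(cohort, cfg)[[g]]
    if (length(idx) < 3) {
      out[[g]] <- list(skipped = "fewer than 3 patients")
      next
    }
    Xg <- stack$X[idx, , drop = FALSE]
    yg <- y_all[idx]
    res <- list(n_patients = length(idx), n_voxels_tested = ncol(Xg))
    res$stat <- max_stat_fwe(Xg, yg, n_perm = cfg$n_perm_voxel,
                             alpha = cfg$alpha, tails = "two")
    res$bf <- if (length(idx) >= 5)
      bayes_factor_map(Xg, yg, prior_scale = cfg$prior_scale)
    else NULL
    out[[g]] <- res
  }
  list(groups = out, voxels = stack$voxels, dim = stack$dim, maps = stack$maps)
}

#' Experiment 2: streamline disconnection analysis
#'
#' Disconnection matrix, prevalence filter, one-tailed permutation GLM,
#' tract assignment of the significant streamlines — per group and for
#' the whole cohort.
#'
#' @inheritParams run_experiment1
#' @return Nested list per group: `glm` ([streamline_glm()] result),
#'   `tract_counts`, stage counts.
#' @export
run_experiment2 <- function(cohort, cfg = run_config()) {
  set.seed(cfg$seed + 20L)
  m_full <- build_disconnection_matrix(cohort$lesions,
                                       cohort$anatomy$streamlines)
  y_all <- cohort$behaviour$mean_coc
  out <- list()
  for (g in names(group_subsets(cohort, cfg))) {
    idx <- group_subsets(cohort, cfg)[[g]]
    m_g <- structure(list(matrix = m_full$matrix[idx, , drop = FALSE],
                          patient_ids = m_full$patient_ids[idx],
                          streamline_index = m_full$streamline_index,
                          sset = m_full$sset),
                     class = "disconnection_matrix")
    m_f <- filter_prevalence(m_g, cfg$prevalence_min)
    res <- list(n_patients = length(idx),
                n_streamlines_total = ncol(m_g$matrix),
                n_streamlines_tested = ncol(m_f$matrix))
    if (ncol(m_f$matrix) == 0) {
      res$glm <- NULL
      res$tract_counts <- setNames(integer(), character())
      res$note <- "no streamline passed the prevalence filter"
    } else {
      res$glm <- streamline_glm(m_f, y_all[idx],
                                n_perm = cfg$n_perm_streamline,
                                alpha = cfg$alpha)
      res$tract_counts <- assign_tracts(res$glm$sig_index,
                                        cohort$anatomy$streamlines)
    }
    out[[g]] <- res
  }
  list(groups = out, matrix = m_full)
}

#' Experiment 3: tract-wise lesion load analysis
#'
#' Binary and probability-weighted load tables, per-tract and total-load
#' Kendall tau with Bonferroni correction, the presence chi-square, and
#' the random-forest classification with permutation test — for all
#' patients combined and per group (the classifier only for the whole
#' cohort, where group-wise samples are too small for model training; it
#' is skipped with a reason when
#' labels are single-class).
#'
#' @inheritParams run_experiment1
#' @return List with `loads_binary`, `loads_weighted`, per-group
#'   `association` results, and `classifier`.
#' @export
run_experiment3 <- function(cohort, cfg = run_config()) {
  set.seed(cfg$seed + 30L)
  loads_b <- lesion_load_table(cohort$lesions, cohort$anatomy$atlas,
                               threshold = cfg$tract_threshold,
                               weighted = FALSE,
                               patient_ids = cohort$behaviour$patient_id)
  loads_w <- lesion_load_table(cohort$lesions, cohort$anatomy$atlas,
                               weighted = TRUE,
                               patient_ids = cohort$behaviour$patient_id)
  y <- cohort$behaviour$mean_coc
  neglect <- cohort$behaviour$neglect
  assoc <- list()
  for (g in names(group_subsets(cohort, cfg))) {
    idx <- group_subsets(cohort, cfg)[[g]]
    if (length(idx) < 4) {
      assoc[[g]] <- list(skipped = "fewer than 4 patients")
      next
    }
    assoc[[g]] <- list(
      n_patients = length(idx),
      binary = tract_load_association(loads_b[idx, ], y[idx], neglect[idx]),
      weighted = tract_load_association(loads_w[idx, ], y[idx],
                                        neglect[idx]))
  }
  cls <- if (length(unique(neglect)) < 2 || min(table(neglect)) < 2)
    list(skipped = "labels single-class or near-degenerate")
  else {
    ccfg <- cfg$classifier
    ccfg$seed <- cfg$seed + 31L
    feats <- loads_b[, setdiff(names(loads_b), "total"), drop = FALSE]
    permutation_test_auc(feats, neglect, ccfg)
  }
  list(loads_binary = loads_b, loads_weighted = loads_w,
       association = assoc, classifier = cls)
}

#' Run all three experiments and serialise JSON reports
#'
#' A single top-level seed determines every stage. Reports are plain
#' deterministic JSON (config echo, seed, per-stage counts and statistics;
#' MD5 hashes of any input files listed in `input_files`), so two runs
#' with the same cohort, config and seed produce byte-identical files.
#'
#' @param cohort a `synth_cohort`; experiment 1 is skipped (with reason)
#'   when it carries no connectome.
#' @param cfg a [run_config()].
#' @param out_dir output directory for the JSON reports; created if
#'   needed. `NULL` skips serialisation.
#' @param input_files optional named character vector of files to hash
#'   into the provenance block.
#' @return List with `experiment1`, `experiment2`, `experiment3`,
#'   `report` (the serialisable summary), invisibly the paths written.
#' @export
run_all <- function(cohort, cfg = run_config(), out_dir = NULL,
                    input_files = character()) {
  exp1 <- if (!is.null(cohort$connectome)) run_experiment1(cohort, cfg)
  else NULL
  exp2 <- run_experiment2(cohort, cfg)
  exp3 <- run_experiment3(cohort, cfg)
  report <- build_report(cohort, cfg, exp1, exp2, exp3, input_files)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(experiment1 = exp1, experiment2 = exp2, experiment3 = exp3,
       report = report)
}

build_report <- function(cohort, cfg, exp1, exp2, exp3, input_files) {
  prov <- list(seed = cfg$seed,
               n_patients = length(cohort$lesions),
               groups = as.list(table(cohort$groups)))
  if (length(input_files))
    prov$input_md5 <- as.list(tools::md5sum(input_files))
  cfg_echo <- unclass(cfg)
  cfg_echo$classifier <- unclass(cfg_echo$classifier)
  rep1 <- if (is.null(exp1)) list(skipped = "no connectome") else
    lapply(exp1$groups, function(r) {
      if (!is.null(r$skipped)) return(list(skipped = r$skipped))
      out <- list(n_patients = r$n_patients,
                  n_voxels_tested = r$n_voxels_tested,
                  fwe_threshold = r$stat$fwe_threshold,
                  n_significant = sum(r$stat$sig_mask))
      if (!is.null(r$bf))
        out$bf_bin_proportions <- as.list(r$bf$bin_proportions)
      out
    })
  rep2 <- lapply(exp2$groups, function(r) {
    out <- list(n_patients = r$n_patients,
                n_streamlines_total = r$n_streamlines_total,
                n_streamlines_tested = r$n_streamlines_tested)
    if (!is.null(r$glm)) {
      out$fwe_threshold <- r$glm$fwe_threshold
      out$n_significant <- length(r$glm$sig_index)
      out$tract_counts <- as.list(r$tract_counts)
    } else out$note <- r$note
    out
  })
  rep3 <- list(association = lapply(exp3$association, function(a) {
    if (!is.null(a$skipped)) return(list(skipped = a$skipped))
    fmt <- function(x) list(per_tract = x$per_tract,
                            total_tau = x$total$tau, total_p = x$total$p)
    out <- list(n_patients = a$n_patients,
                binary = fmt(a$binary), weighted = fmt(a$weighted))
    if (!is.null(a$binary$presence))
      out$presence <- list(chi2 = a$binary$presence$chi2,
                           df = a$binary$presence$df,
                           p = a$binary$presence$p,
                           table = a$binary$presence$table)
    out
  }))
  rep3$classifier <- if (!is.null(exp3$classifier$skipped))
    list(skipped = exp3$classifier$skipped)
  else list(mean_auc = exp3$classifier$mean_auc,
            p_value = exp3$classifier$p_value,
            n_splits = exp3$classifier$config$n_splits,
            n_perm = exp3$classifier$config$n_perm)
  list(provenance = prov, config = cfg_echo,
       experiment1 = rep1, experiment2 = rep2, experiment3 = rep3)
}

# ---- Cohort serialisation --------------------------------------------------

#' Write a synthetic cohort to a self-contained directory
#'
#' NIfTI volumes (lesions, parcellation, brain mask, tract maps), TRK
#' streamlines, behavioural CSV (raw cancellation sheets), YAML manifest
#' and ground-truth JSON. 4D connectome subjects are written only when
#' present.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "atlas"), showWarnings = FALSE)
  lesion_files <- character(length(cohort$lesions))
  for (i in seq_along(cohort$lesions)) {
    lesion_files[i] <- file.path("lesions", sprintf("P%03d.nii.gz", i))
    write_volume(cohort$lesions[[i]], file.path(dir, lesion_files[i]))
  }
  parc <- cohort$anatomy$parcellation
  write_volume(volume3d(parc$labels + 0, parc$affine),
               file.path(dir, "parcellation.nii.gz"))
  write_volume(cohort$anatomy$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  tract_files <- character()
  for (nm in cohort$anatomy$atlas$names) {
    tract_files[nm] <- file.path("atlas", paste0(nm, ".nii.gz"))
    write_volume(cohort$anatomy$atlas$tracts[[nm]],
                 file.path(dir, tract_files[nm]))
  }
  write_streamlines(cohort$anatomy$streamlines,
                    file.path(dir, "streamlines.trk"),
                    affine = cohort$anatomy$affine,
                    dim = dim(cohort$anatomy$brain_mask$data))
  writeLines(yaml::as.yaml(list(tract_label =
                                  cohort$anatomy$streamlines$tract_label)),
             file.path(dir, "streamline_labels.yaml"))
  beh <- do.call(rbind, lapply(seq_along(cohort$sheets), function(i) {
    sh <- cohort$sheets[[i]]
    do.call(rbind, lapply(names(sh), function(tn)
      data.frame(patient_id = cohort$behaviour$patient_id[i],
                 test_name = tn,
                 group = cohort$groups[i],
                 target_x = paste(sh[[tn]]$target_x, collapse = ";"),
                 hit_flags = paste(as.integer(sh[[tn]]$hit_flags),
                                   collapse = ";"),
                 stringsAsFactors = FALSE)))
  }))
  utils::write.csv(beh, file.path(dir, "behaviour.csv"), row.names = FALSE)
  connectome_files <- character()
  if (!is.null(cohort$connectome)) {
    dir.create(file.path(dir, "connectome"), showWarnings = FALSE)
    for (s in seq_along(cohort$connectome)) {
      connectome_files[s] <- file.path("connectome",
                                       sprintf("sub%03d.nii.gz", s))
      write_volume(cohort$connectome[[s]],
                   file.path(dir, connectome_files[s]))
    }
  }
  manifest <- list(
    grid = as.integer(cohort$config$grid),
    seed = cohort$config$seed,
    neglect_cutoffs = as.list(cohort$config$neglect_cutoffs),
    lesions = as.list(lesion_files),
    parcellation = "parcellation.nii.gz",
    cortical_ids = as.integer(parc$cortical_ids),
    tracts = as.list(tract_files),
    streamlines = "streamlines.trk",
    streamline_labels = "streamline_labels.yaml",
    behaviour = "behaviour.csv",
    connectome = as.list(connectome_files))
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  jsonlite::write_json(
    list(true_loads = cohort$ground_truth$true_loads,
         true_severity_signal = cohort$ground_truth$true_severity_signal,
         severity = cohort$ground_truth$severity,
         planted_network_parcel = cohort$ground_truth$planted_network_parcel,
         planted_streamline_ids = cohort$ground_truth$planted_streamline_ids),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.yaml`.
#' @param with_connectome also load the 4D connectome volumes.
#' @return A `synth_cohort`-shaped list (without the generator's internal
#'   ground-truth signal fields unless present on disk).
#' @export
read_cohort <- function(dir, with_connectome = TRUE) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  lesions <- lapply(manifest$lesions, function(f)
    read_volume(file.path(dir, f), expect_binary = TRUE))
  parc_vol <- read_volume(file.path(dir, manifest$parcellation))
  labels <- array(as.integer(round(parc_vol$data)), dim(parc_vol$data))
  parc <- parcellation(labels, parc_vol$affine,
                       cortical_ids = manifest$cortical_ids)
  tracts <- lapply(manifest$tracts, function(f)
    read_volume(file.path(dir, f)))
  names(tracts) <- names(manifest$tracts)
  labels_y <- yaml::read_yaml(file.path(dir, manifest$streamline_labels))
  sset <- read_streamlines(file.path(dir, manifest$streamlines))
  sset$tract_label <- unlist(labels_y$tract_label)
  cutoffs <- unlist(manifest$neglect_cutoffs)
  beh <- read_behaviour(file.path(dir, manifest$behaviour), cutoffs)
  groups <- beh$group
  connectome <- NULL
  if (with_connectome && length(manifest$connectome))
    connectome <- lapply(seq_along(manifest$connectome), function(s)
      read_volume4d(file.path(dir, manifest$connectome[[s]]),
                    subject_id = sprintf("sub%03d", s)))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
  else NULL
  structure(list(config = list(grid = manifest$grid, seed = manifest$seed,
                               neglect_cutoffs = cutoffs),
                 anatomy = list(parcellation = parc,
                                atlas = tract_atlas(tracts),
                                streamlines = sset,
                                affine = parc$affine),
                 lesions = lesions, groups = groups,
                 behaviour = beh, connectome = connectome,
                 ground_truth = gt),
            class = "synth_cohort")
}
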