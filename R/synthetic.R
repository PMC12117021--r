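# Synthetic cohorts with known ground truth.
#
# Everything the pipeline consumes is generated on a small template grid
# (default 32^3 voxels at 1 mm): two subcortical grey-matter blobs
# (pseudo basal ganglia and pseudo thalamus), a shell of cortical parcels,
# four named probabilistic tract maps whose centrelines pass the
# subcortical blobs at varying distance (plus a corticospinal-like
# distractor bundle that pierces the thalamus blob), streamlines jittered
# around those centrelines, a normative 4D "connectome" with a planted
# seed-to-cortex network, subcortically centred lesions of randomised size
# and anisotropy, and behaviour generated as a noisy monotone function of
# total tract lesion load, emitted both as CoC scores and as realised
# cancellation sheets.
#
# All generators are pure functions of (config, seed): a fixed seed gives
# bit-identical cohorts.

#' Synthetic cohort configuration
#'
#' Defaults reproduce the reference cohort conditions
#' (43 patients in a roughly 27:16 basal-ganglia:thalamus split, 100
#' normative subjects, a target rank effect of tau = 0.3 between total
#' tract lesion load and severity); grid-dependent quantities (lesion
#' sizes, tract geometry) are scaled to the 32^3 template.
#'
#' @param grid template extents in voxels (1 mm isotropic).
#' @param n_patients cohort size.
#' @param bg_fraction share of patients with basal-ganglia (vs thalamic)
#'   lesions.
#' @param n_subjects normative connectome size.
#' @param n_timepoints time series length per subject.
#' @param effect_size target Kendall tau between total tract lesion load
#'   and severity, in `[0, 1)`; 0 plants no effect.
#' @param noise_sd base standard deviation of the Gaussian severity noise;
#'   0 gives noiseless severity.
#' @param lesion_size_range admissible lesion volume range (voxels).
#' @param neglect_cutoffs named per-test CoC cutoffs used for the binary
#'   neglect label of the synthetic cohort.
#' @param n_streamlines_per_tract streamlines sampled per bundle.
#' @param seed RNG seed; every generated structure is a deterministic
#'   function of the config including this seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(grid = c(32L, 32L, 32L),
                         n_patients = 43L,
                         bg_fraction = 27 / 43,
                         n_subjects = 100L,
                         n_timepoints = 100L,
                         effect_size = 0.3,
                         noise_sd = 1,
                         lesion_size_range = c(10, 80),
                         neglect_cutoffs = c(letters = 0.08, bells = 0.08),
                         n_streamlines_per_tract = 60L,
                         seed = 1L) {
  stopifnot(length(grid) == 3, all(grid >= 24),
            n_patients >= 4, n_subjects >= 1, n_timepoints >= 10,
            effect_size >= 0, effect_size < 1, noise_sd >= 0,
            length(lesion_size_range) == 2,
            lesion_size_range[1] > 0,
            diff(lesion_size_range) > 0,
            bg_fraction > 0, bg_fraction < 1)
  structure(list(grid = as.integer(grid), n_patients = as.integer(n_patients),
                 bg_fraction = bg_fraction,
                 n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 effect_size = effect_size, noise_sd = noise_sd,
                 lesion_size_range = lesion_size_range,
                 neglect_cutoffs = neglect_cutoffs,
                 n_streamlines_per_tract = as.integer(n_streamlines_per_tract),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# world coordinates of all voxel centres (identity affine: 0-based mm)
grid_coords <- function(grid) {
  cbind(rep(seq_len(grid[1]) - 1, times = grid[2] * grid[3]),
        rep(rep(seq_len(grid[2]) - 1, each = grid[1]), times = grid[3]),
        rep(seq_len(grid[3]) - 1, each = grid[1] * grid[2]))
}

# quadratic Bezier curve sampled at m points
bezier3 <- function(p0, p1, p2, m = 80) {
  t <- seq(0, 1, length.out = m)
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  b
}

TRACT_SIGMA <- 1.4  # mm, Gaussian profile of the tract probability maps

# bundle geometry on a unit 32-grid, rescaled to the actual grid
bundle_specs <- function(grid) {
  s <- grid / 32
  sc <- function(p) p * s
  list(
    SLF = list(p0 = sc(c(8, 26, 18)), p1 = sc(c(7, 15.5, 17)),
               p2 = sc(c(8, 5, 18)), atlas = TRUE),
    IOF = list(p0 = sc(c(12, 27, 10)), p1 = sc(c(13, 15.5, 11)),
               p2 = sc(c(12, 4, 10)), atlas = TRUE),
    SOF = list(p0 = sc(c(14, 26, 21)), p1 = sc(c(14.5, 15.5, 21)),
               p2 = sc(c(14, 5, 21)), atlas = TRUE),
    UF = list(p0 = sc(c(7, 24, 9)), p1 = sc(c(6, 18, 11)),
              p2 = sc(c(10, 26, 17)), atlas = TRUE),
    CST = list(p0 = sc(c(17, 13, 28)), p1 = sc(c(18, 13, 15)),
               p2 = sc(c(19, 13, 3)), atlas = FALSE))
}

roi_specs <- function(grid) {
  s <- grid / 32
  list(basal_ganglia = list(centre = c(11, 17, 15) * s, radius = 3.0 * mean(s)),
       thalamus = list(centre = c(18, 13, 15) * s, radius = 2.5 * mean(s)))
}

#' Synthetic anatomy: parcellation, subcortical ROIs, tract atlas,
#' streamlines
#'
#' Builds the template anatomy: a spherical brain mask, two subcortical
#' blobs (labels 1 = pseudo basal ganglia, 2 = pseudo thalamus), twelve
#' cortical shell parcels (labels 101..112), four probabilistic
#' association-tract maps (SLF, IOF, SOF, UF; Gaussian profile around a
#' curved centreline, peak 1 at the centreline) and a corticospinal-like
#' distractor bundle, plus labelled streamlines jittered inside each
#' bundle's p >= 0.3 core.
#'
#' @param cfg a [synth_config()].
#' @return List with `parcellation`, `brain_mask`, `roi_masks` (named
#'   binary volumes), `atlas` (a [tract_atlas()] of the four association
#'   tracts), `streamlines` (a labelled [streamline_set()] including the
#'   distractor bundle), `affine`.
#' @export
make_anatomy <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  grid <- cfg$grid
  affine <- diag(4)
  W <- grid_coords(grid)
  centre <- (grid - 1) / 2
  rel <- sweep(W, 2, centre)
  d_centre <- sqrt(rowSums(rel^2))
  r_brain <- min(grid) / 2 - 1.5
  brain <- d_centre <= r_brain

  labels <- array(0L, grid)
  # subcortical blobs
  rois <- roi_specs(grid)
  roi_masks <- list()
  for (i in seq_along(rois)) {
    rs <- rois[[i]]
    inside <- sqrt(rowSums(sweep(W, 2, rs$centre)^2)) <= rs$radius
    labels[inside] <- i
    roi_masks[[names(rois)[i]]] <-
      volume3d(array(as.numeric(inside), grid), affine)
  }
  # cortical shell parcels: 4 azimuthal x 3 polar sectors
  shell <- brain & d_centre >= r_brain - 3
  az <- atan2(rel[, 2], rel[, 1])
  pol <- acos(pmin(pmax(rel[, 3] / pmax(d_centre, 1e-9), -1), 1))
  az_bin <- pmin(floor((az + pi) / (2 * pi) * 4), 3)
  pol_bin <- pmin(floor(pol / pi * 3), 2)
  parcel <- 101L + az_bin + 4L * pol_bin
  labels[shell] <- parcel[shell]
  cortical_ids <- sort(unique(parcel[shell]))
  label_table <- c(setNames(names(rois), seq_along(rois)),
                   setNames(paste0("cortex_", cortical_ids), cortical_ids))
  parc <- parcellation(array(labels, grid), affine, label_table,
                       cortical_ids)

  # tract maps and streamlines
  specs <- bundle_specs(grid)
  tracts <- list()
  streamlines <- list()
  tract_label <- character()
  r_core <- TRACT_SIGMA * sqrt(2 * log(1 / 0.3))   # p >= 0.3 tube radius
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    cl <- bezier3(sp$p0, sp$p1, sp$p2, m = 160)
    d2 <- rep(Inf, nrow(W))
    for (i in seq_len(nrow(cl)))
      d2 <- pmin(d2, (W[, 1] - cl[i, 1])^2 + (W[, 2] - cl[i, 2])^2 +
                     (W[, 3] - cl[i, 3])^2)
    prob <- exp(-d2 / (2 * TRACT_SIGMA^2))
    prob[prob < 0.01] <- 0
    if (sp$atlas)
      tracts[[nm]] <- volume3d(array(prob, grid), affine)
    vol_prob <- array(prob, grid)
    for (k in seq_len(cfg$n_streamlines_per_tract)) {
      repeat {
        off <- rnorm(3, 0, 0.45)
        if (sqrt(sum(off^2)) > r_core - 1.0) next
        pts <- sweep(bezier3(sp$p0, sp$p1, sp$p2, m = 40), 2, off, "+")
        fi <- flat_index(grid, floor(pts + 0.5) + 1)
        if (all(fi > 0L) && all(vol_prob[fi] >= 0.3)) break
      }
      streamlines[[length(streamlines) + 1L]] <- pts
      tract_label <- c(tract_label, nm)
    }
  }
  list(parcellation = parc,
       brain_mask = volume3d(array(as.numeric(brain), grid), affine),
       roi_masks = roi_masks,
       atlas = tract_atlas(tracts),
       streamlines = streamline_set(streamlines, tract_label),
       affine = affine)
}

#' Synthetic normative connectome with a planted seed-to-cortex network
#'
#' Per subject, every voxel's time series is white noise; voxels of the
#' subcortical blobs and of one designated cortical parcel additionally
#' share a latent signal (so the seed region co-fluctuates with exactly
#' that parcel), every other cortical parcel shares its own private
#' latent, and a light separable spatial smoothing induces local
#' autocorrelation.
#'
#' @param cfg a [synth_config()].
#' @param anatomy output of [make_anatomy()].
#' @param coupling share of variance carried by the region latents.
#' @return List with `subjects` (list of [volume4d()]) and
#'   `planted_parcel` (cortical label id).
#' @export
make_connectome <- function(cfg, anatomy, coupling = 0.6) {
  set.seed(cfg$seed + 1L)
  grid <- cfg$grid
  labels <- as.integer(anatomy$parcellation$labels)
  cortical_ids <- anatomy$parcellation$cortical_ids
  planted <- cortical_ids[1]
  seed_vox <- which(labels %in% c(1L, 2L))
  a <- sqrt(coupling); b <- sqrt(1 - coupling)
  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    g <- rnorm(cfg$n_timepoints)
    mat <- matrix(rnorm(prod(grid) * cfg$n_timepoints),
                  nrow = prod(grid)) * b
    mat[seed_vox, ] <- mat[seed_vox, ] +
      matrix(a * g, length(seed_vox), cfg$n_timepoints, byrow = TRUE)
    for (pid in cortical_ids) {
      vox <- which(labels == pid)
      l <- if (pid == planted) g else rnorm(cfg$n_timepoints)
      mat[vox, ] <- mat[vox, ] +
        matrix(a * l, length(vox), cfg$n_timepoints, byrow = TRUE)
    }
    arr <- array(mat, c(grid, cfg$n_timepoints))
    arr <- smooth3d_light(arr)
    subjects[[s]] <- volume4d(arr, anatomy$affine,
                              subject_id = sprintf("sub%03d", s))
  }
  list(subjects = subjects, planted_parcel = planted)
}

# separable nearest-neighbour smoothing (kernel 1/4, 1/2, 1/4 per axis),
# applied to each timepoint of a 4D array
smooth3d_light <- function(arr) {
  d <- dim(arr)
  sm_axis <- function(x, axis) {
    idx_lo <- pmax(seq_len(d[axis]) - 1L, 1L)
    idx_hi <- pmin(seq_len(d[axis]) + 1L, d[axis])
    pick <- function(i) switch(axis,
                               x[i, , , , drop = FALSE],
                               x[, i, , , drop = FALSE],
                               x[, , i, , drop = FALSE])
    0.5 * x + 0.25 * pick(idx_lo) + 0.25 * pick(idx_hi)
  }
  for (ax in 1:3) arr <- sm_axis(arr, ax)
  arr
}

#' Synthetic subcortically centred lesions
#'
#' One anisotropic ellipsoidal blob per patient, centred in the assigned
#' subcortical blob with a small positional jitter, with volume drawn from
#' `cfg$lesion_size_range` and clipped to the brain mask. Lesions that
#' miss their blob or leave the admissible volume range are resampled.
#'
#' @param cfg a [synth_config()].
#' @param anatomy output of [make_anatomy()].
#' @return List with `lesions` (list of binary [volume3d()]), `groups`
#'   (character vector: `"basal_ganglia"` / `"thalamus"`).
#' @export
make_lesions <- function(cfg, anatomy) {
  set.seed(cfg$seed + 2L)
  grid <- cfg$grid
  W <- grid_coords(grid)
  brain <- as.vector(anatomy$brain_mask$data) > 0
  rois <- roi_specs(grid)
  n_bg <- round(cfg$bg_fraction * cfg$n_patients)
  groups <- rep(c("basal_ganglia", "thalamus"),
                c(n_bg, cfg$n_patients - n_bg))
  rng <- cfg$lesion_size_range
  lesions <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    rs <- rois[[groups[i]]]
    roi_vox <- sqrt(rowSums(sweep(W, 2, rs$centre)^2)) <= rs$radius
    for (try in 1:100) {
      ctr <- rs$centre + pmin(pmax(rnorm(3, 0, 1.2), -2.5), 2.5)
      target <- runif(1, rng[1] + 0.2 * diff(rng), rng[2] - 0.2 * diff(rng))
      r0 <- (3 * target / (4 * pi))^(1 / 3)
      aniso <- exp(rnorm(3, 0, 0.25))
      aniso <- aniso / prod(aniso)^(1 / 3)
      radii <- r0 * aniso
      inside <- (W[, 1] - ctr[1])^2 / radii[1]^2 +
        (W[, 2] - ctr[2])^2 / radii[2]^2 +
        (W[, 3] - ctr[3])^2 / radii[3]^2 <= 1
      inside <- inside & brain
      vol <- sum(inside)
      if (vol >= rng[1] && vol <= rng[2] && any(inside & roi_vox)) break
      if (try == 100) stop("make_lesions: could not place lesion ", i)
    }
    lesions[[i]] <- volume3d(array(as.numeric(inside), grid),
                             anatomy$affine)
  }
  list(lesions = lesions, groups = groups)
}

# expected Kendall tau-b between x and a*s + noise_sd*N(0,1), where s is
# the [0,1]-scaled x signal: closed form over pairs via the normal CDF
expected_tau_b <- function(s, a, noise_sd) {
  n <- length(s)
  ij <- utils::combn(n, 2)
  d <- s[ij[1, ]] - s[ij[2, ]]
  untied <- d != 0
  conc <- sum(2 * pnorm(a * abs(d[untied]) / (noise_sd * sqrt(2))) - 1)
  n0 <- n * (n - 1) / 2
  n1 <- sum(!untied)
  conc / sqrt((n0 - n1) * n0)
}

#' Synthetic behaviour from tract lesion loads
#'
#' Severity is a linear function of the `[0, 1]`-scaled total tract lesion
#' load plus Gaussian noise; the signal amplitude is calibrated (via the
#' closed-form expected tau over patient pairs) so the realised Kendall
#' tau between total load and severity matches `cfg$effect_size` in
#' expectation. The severity scale is then anchored at the reference cohort's
#' moments (mean 0.16, SD 0.27) and clipped to `[-1, 1]`. Each patient
#' additionally receives realised letter and bells cancellation sheets
#' whose hit patterns reproduce the intended per-test CoC to within the
#' sheet's granularity (< 0.02), so the CoC scoring path is exercised end
#' to end.
#'
#' @param cfg a [synth_config()].
#' @param loads a [lesion_load_table()] for the cohort.
#' @return List with `behaviour` (data.frame: per-test CoC, `mean_coc`,
#'   `neglect`), `sheets` (per patient, per test: `target_x`, `hit_flags`),
#'   `severity` (the clipped severity actually encoded in the sheets' CoC
#'   targets), `signal` (noiseless severity signal), `noise_amplitude`.
#' @export
make_behaviour <- function(cfg, loads) {
  set.seed(cfg$seed + 3L)
  total <- loads$total
  n <- length(total)
  if (max(total) == min(total))
    stop("make_behaviour: degenerate all-equal total loads")
  s <- (total - min(total)) / (max(total) - min(total))
  if (cfg$noise_sd == 0) {
    a <- 1
    sev_raw <- s
  } else if (cfg$effect_size == 0) {
    a <- 0
    sev_raw <- cfg$noise_sd * rnorm(n)
  } else {
    tau_max <- expected_tau_b(s, 1e6, cfg$noise_sd)
    if (cfg$effect_size >= tau_max) {
      warning("make_behaviour: target tau unattainable with these loads; ",
              "using maximal signal share")
      a <- 1e6
    } else {
      a <- uniroot(function(a) expected_tau_b(s, a, cfg$noise_sd) -
                     cfg$effect_size,
                   lower = 1e-8, upper = 1e6, tol = 1e-10)$root
    }
    sev_raw <- a * s + cfg$noise_sd * rnorm(n)
  }
  sev <- 0.16 + 0.27 * (sev_raw - mean(sev_raw)) / max(sd(sev_raw), 1e-12)
  sev <- pmin(pmax(sev, -1), 1)
  signal <- 0.16 + 0.27 * (a * s - mean(sev_raw)) / max(sd(sev_raw), 1e-12)

  sheets <- lapply(seq_len(n), function(i)
    list(letters = make_sheet(cancellation_layout("letters"), sev[i]),
         bells = make_sheet(cancellation_layout("bells"), sev[i])))
  coc_letters <- vapply(sheets, function(sh)
    compute_coc(sh$letters$target_x, sh$letters$hit_flags), numeric(1))
  coc_bells <- vapply(sheets, function(sh)
    compute_coc(sh$bells$target_x, sh$bells$hit_flags), numeric(1))
  behaviour <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    coc_letters = coc_letters,
    coc_bells = coc_bells,
    stringsAsFactors = FALSE)
  behaviour$mean_coc <- (coc_letters + coc_bells) / 2
  behaviour$neglect <- vapply(seq_len(n), function(i)
    classify_neglect(c(letters = coc_letters[i], bells = coc_bells[i]),
                     cfg$neglect_cutoffs), logical(1))
  list(behaviour = behaviour, sheets = sheets, severity = sev,
       signal = signal, noise_amplitude = cfg$noise_sd / max(a, 1e-12))
}

#' Cancellation sheet layouts
#'
#' Symmetric column layouts on a 29.7 cm-wide landscape sheet: 60 targets
#' in 10 columns for the letters test, 35 targets in 7 columns for the
#' bells test.
#'
#' @param test `"letters"` or `"bells"`.
#' @return Numeric vector of horizontal target positions (cm, midline 0).
#' @export
cancellation_layout <- function(test = c("letters", "bells")) {
  test <- match.arg(test)
  if (test == "letters") rep(seq(-13.5, 13.5, length.out = 10), each = 6)
  else rep(seq(-13.5, 13.5, length.out = 7), each = 5)
}

# choose a hit pattern whose CoC best matches the target score: cancel the
# k rightmost (leftmost for negative targets) targets, k chosen to
# minimise the CoC error; granularity of the layouts keeps the error
# below 0.02
make_sheet <- function(target_x, coc_target) {
  p <- target_x / max(abs(target_x))
  flip <- coc_target < 0
  if (flip) { p <- -p; coc_target <- -coc_target }
  ord <- order(p, decreasing = TRUE)
  means <- cumsum(p[ord]) / seq_along(ord)
  k <- which.min(abs(means - coc_target))
  hits <- logical(length(p))
  hits[ord[seq_len(k)]] <- TRUE
  list(target_x = target_x, hit_flags = hits)
}

#' Simulate a full synthetic cohort
#'
#' Chains [make_anatomy()], optionally [make_connectome()],
#' [make_lesions()], [lesion_load_table()] and [make_behaviour()] into a
#' self-consistent cohort with ground truth.
#'
#' @param cfg a [synth_config()].
#' @param with_connectome also generate the normative 4D time series (the
#'   memory-heavy part; only needed for lesion-network analyses).
#' @return List of class `synth_cohort` with `anatomy`, `lesions`,
#'   `groups`, `loads` (binary-mode table at threshold 0.3), `behaviour`,
#'   `sheets`, `connectome` (or `NULL`), and `ground_truth`
#'   (`true_loads`, `true_severity_signal`, `planted_network_parcel`,
#'   `planted_streamline_ids`).
#' @export
simulate_cohort <- function(cfg = synth_config(), with_connectome = FALSE) {
  anatomy <- make_anatomy(cfg)
  les <- make_lesions(cfg, anatomy)
  loads <- lesion_load_table(les$lesions, anatomy$atlas, threshold = 0.3)
  beh <- make_behaviour(cfg, loads)
  connectome <- NULL
  planted_parcel <- anatomy$parcellation$cortical_ids[1]
  if (with_connectome) {
    cn <- make_connectome(cfg, anatomy)
    connectome <- cn$subjects
    planted_parcel <- cn$planted_parcel
  }
  atlas_tracts <- anatomy$atlas$names
  planted_ids <- which(anatomy$streamlines$tract_label %in% atlas_tracts)
  structure(list(config = cfg, anatomy = anatomy,
                 lesions = les$lesions, groups = les$groups,
                 loads = loads, behaviour = beh$behaviour,
                 sheets = beh$sheets, connectome = connectome,
                 ground_truth = list(
                   true_loads = loads,
                   true_severity_signal = beh$signal,
                   severity = beh$severity,
                   planted_network_parcel = planted_parcel,
                   planted_streamline_ids = planted_ids)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", length(x$lesions), " patients (",
      sum(x$groups == "basal_ganglia"), " basal ganglia, ",
      sum(x$groups == "thalamus"), " thalamus), ",
      length(x$anatomy$streamlines), " streamlines, ",
      if (is.null(x$connectome)) "no connectome"
      else paste0(length(x$connectome), "-subject connectome"),
      "\n", sep = "")
  invisible(x)
}

# ---- Abstract calibration cohorts -----------------------------------------
# Matrix-level generators for the statistical calibration suites: they
# bypass the image-domain machinery and directly emit the patients x
# features structures the inference code consumes.

#' Null map stack for FWER calibration
#'
#' Patients x voxels matrix of spatially autocorrelated Gaussian maps
#' (moving-average smoothing across the voxel index) with a severity
#' vector drawn independently of the maps, so any detection is a false
#' positive.
#'
#' @param n_patients,n_voxels dimensions.
#' @param smooth half-width of the moving-average autocorrelation window.
#' @return List with `X` and `y`.
#' @export
make_null_maps <- function(n_patients = 20, n_voxels = 500, smooth = 2) {
  E <- matrix(rnorm(n_patients * (n_voxels + 2 * smooth)), n_patients)
  k <- 2 * smooth + 1
  X <- sapply(seq_len(n_voxels), function(v)
    rowMeans(E[, v:(v + 2 * smooth), drop = FALSE]))
  list(X = X * sqrt(k), y = rnorm(n_patients))
}

#' Null disconnection matrix for FWER calibration
#'
#' Binary patients x streamlines indicators with random prevalence and an
#' independent severity vector.
#'
#' @param n_patients,n_streamlines dimensions.
#' @param min_prev,max_prev per-column disconnection count range.
#' @return List with `m` (a `disconnection_matrix`) and `y`.
#' @export
make_null_disconnection <- function(n_patients = 20, n_streamlines = 500,
                                    min_prev = 5,
                                    max_prev = floor(n_patients / 2)) {
  M <- sapply(seq_len(n_streamlines), function(j) {
    k <- sample(min_prev:max_prev, 1)
    v <- integer(n_patients)
    v[sample.int(n_patients, k)] <- 1L
    v
  })
  m <- structure(list(matrix = M,
                      patient_ids = sprintf("P%03d", seq_len(n_patients)),
                      streamline_index = seq_len(n_streamlines),
                      sset = NULL),
                 class = "disconnection_matrix")
  list(m = m, y = rnorm(n_patients))
}

#' Planted-effect disconnection cohort
#'
#' A driver subset of patients receives a severity shift (in units of the
#' noise SD); planted streamline columns are noisy copies of the driver
#' indicator (a small per-entry flip probability makes them distinct),
#' null columns are random subsets. Used to measure the sensitivity of
#' the one-tailed streamline GLM at a known effect.
#'
#' @param n_patients cohort size.
#' @param n_null,n_planted column counts.
#' @param shift severity shift of disconnected patients, in noise-SD units.
#' @param driver_size patients in the driver subset.
#' @param flip_prob per-entry flip probability for planted columns.
#' @return List with `m`, `y`, `planted_cols` (column indices of `m`).
#' @export
make_planted_disconnection <- function(n_patients = 50, n_null = 200,
                                       n_planted = 20, shift = 2,
                                       driver_size = 15, flip_prob = 0.05) {
  driver <- sample.int(n_patients, driver_size)
  d_ind <- integer(n_patients); d_ind[driver] <- 1L
  planted <- sapply(seq_len(n_planted), function(j) {
    v <- d_ind
    fl <- runif(n_patients) < flip_prob
    v[fl] <- 1L - v[fl]
    v
  })
  nulls <- sapply(seq_len(n_null), function(j) {
    v <- integer(n_patients)
    v[sample.int(n_patients, sample(5:floor(n_patients / 2), 1))] <- 1L
    v
  })
  M <- cbind(planted, nulls)
  y <- shift * d_ind + rnorm(n_patients)
  m <- structure(list(matrix = M,
                      patient_ids = sprintf("P%03d", seq_len(n_patients)),
                      streamline_index = seq_len(ncol(M)),
                      sset = NULL),
                 class = "disconnection_matrix")
  list(m = m, y = y, planted_cols = seq_len(n_planted))
}
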