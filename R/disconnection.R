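# Streamline-level structural disconnection: which normative streamlines
# does each lesion interrupt? A streamline counts as disconnected when any
# point of its dense arc-length resampling falls inside a lesion voxel
# (covering both streamlines terminating in and passing through the
# lesion). Indicators are binary; columns (streamlines) disconnected in
# fewer than k patients are filtered before inference; the association
# with severity is a one-tailed two-sample t per streamline with
# maximum-statistic permutation FWE correction across streamlines.

#' Does a streamline intersect a lesion?
#'
#' The polyline is resampled at arc-length intervals of at most `step_mm`
#' (original vertices kept) and each sample is mapped to its nearest voxel;
#' the streamline intersects if any sample lands on a lesion voxel. The
#' default step of 0.5 mm is half a 1 mm template voxel, so no voxel can be
#' skipped between samples at typical curvature.
#'
#' @param lesion binary [volume3d()] lesion mask.
#' @param line n x 3 matrix of polyline points (world mm).
#' @param step_mm sampling step (> 0).
#' @return Logical.
#' @export
streamline_intersects <- function(lesion, line, step_mm = 0.5) {
  pts <- resample_polyline(line, step_mm)
  idx <- world_to_voxel(lesion, pts)
  fi <- flat_index(dim(lesion$data), idx)
  fi <- fi[fi > 0L]
  if (!length(fi)) return(FALSE)
  v <- lesion$data[fi]
  any(v > 0 & !is.na(v))
}

#' Patients x streamlines disconnection matrix
#'
#' @param lesions list of binary [volume3d()] masks sharing one grid.
#' @param sset a [streamline_set()].
#' @param step_mm resampling step passed to [streamline_intersects()].
#' @param patient_ids optional row names.
#' @return Object of class `disconnection_matrix`: binary `matrix`
#'   (patients x streamlines), `patient_ids`, `streamline_index` (column ->
#'   index into `sset`), and the `sset` carried along for tract assignment.
#' @export
build_disconnection_matrix <- function(lesions, sset, step_mm = 0.5,
                                       patient_ids = NULL) {
  stopifnot(inherits(sset, "streamline_set"))
  if (length(lesions) > 1)
    do.call(check_same_grid, lesions)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_along(lesions))
  dims <- dim(lesions[[1]]$data)
  # voxel footprint of each streamline on the shared grid, computed once
  footprints <- lapply(sset$streamlines, function(line) {
    pts <- resample_polyline(line, step_mm)
    fi <- flat_index(dims, world_to_voxel(lesions[[1]], pts))
    unique(fi[fi > 0L])
  })
  m <- matrix(0L, length(lesions), length(footprints),
              dimnames = list(patient_ids, NULL))
  for (i in seq_along(lesions)) {
    les <- as.vector(lesions[[i]]$data) > 0
    les[is.na(les)] <- FALSE
    m[i, ] <- vapply(footprints, function(fp) as.integer(any(les[fp])), 0L)
  }
  structure(list(matrix = m, patient_ids = patient_ids,
                 streamline_index = seq_along(footprints), sset = sset),
            class = "disconnection_matrix")
}

#' @export
print.disconnection_matrix <- function(x, ...) {
  cat("<disconnection_matrix> ", nrow(x$matrix), " patients x ",
      ncol(x$matrix), " streamlines, ",
      sum(x$matrix), " disconnections\n", sep = "")
  invisible(x)
}

#' Filter streamlines by disconnection prevalence
#'
#' Keeps streamlines disconnected in at least `k` patients. Applied before
#' forming the permutation null, so filtered columns never enter the
#' maximum-statistic distribution.
#'
#' @param m a `disconnection_matrix`.
#' @param k minimum patient count (>= 1); the conventional choice is 5.
#' @return A `disconnection_matrix` with the surviving columns;
#'   `streamline_index` still refers to the original streamline set.
#' @export
filter_prevalence <- function(m, k = 5) {
  stopifnot(inherits(m, "disconnection_matrix"), k >= 1)
  keep <- colSums(m$matrix) >= k
  structure(list(matrix = m$matrix[, keep, drop = FALSE],
                 patient_ids = m$patient_ids,
                 streamline_index = m$streamline_index[keep],
                 sset = m$sset),
            class = "disconnection_matrix")
}

#' Streamline-wise permutation GLM
#'
#' Per streamline, the two-sample t statistic (pooled variance) comparing
#' severity between disconnected and spared patients, signed disconnected
#' minus spared; family-wise error control by the maximum t over
#' streamlines across permutations of the severity vector. One-tailed by
#' design: damage is expected to produce more severe, not less severe,
#' deficits.
#'
#' @param m a `disconnection_matrix` (typically prevalence-filtered).
#' @param y severity vector, one per patient.
#' @param n_perm permutation count.
#' @param alpha FWE level.
#' @param exhaustive enumerate all permutations (n <= 8).
#' @return Object of class `streamline_glm`: `sig_index` (indices into the
#'   original streamline set), `sig_cols` (columns of `m`), `t_obs`,
#'   `fwe_threshold`, `perm_max`, `excluded` (columns constant across
#'   patients, dropped with a message), `n_perm`, `alpha`.
#' @export
streamline_glm <- function(m, y, n_perm = 10000, alpha = 0.05,
                           exhaustive = FALSE) {
  stopifnot(inherits(m, "disconnection_matrix"))
  M <- m$matrix
  n <- nrow(M)
  if (length(y) != n) stop("streamline_glm: length(y) != n_patients")
  if (ncol(M) == 0)
    return(structure(list(sig_index = integer(), sig_cols = integer(),
                          t_obs = numeric(), fwe_threshold = NA_real_,
                          perm_max = numeric(), excluded = integer(),
                          n_perm = n_perm, alpha = alpha),
                     class = "streamline_glm"))
  n1 <- colSums(M)
  usable <- n1 > 0 & n1 < n
  excluded <- which(!usable)
  if (length(excluded))
    message("streamline_glm: excluding ", length(excluded),
            " constant column(s)")
  M <- M[, usable, drop = FALSE]
  if (ncol(M) == 0)
    return(structure(list(sig_index = integer(), sig_cols = integer(),
                          t_obs = numeric(), fwe_threshold = NA_real_,
                          perm_max = numeric(), excluded = excluded,
                          n_perm = n_perm, alpha = alpha),
                     class = "streamline_glm"))
  t_obs <- as.vector(two_sample_t(M, matrix(y, ncol = 1)))
  Yp <- permutation_matrix(y, n_perm, exhaustive)
  n_perm <- ncol(Yp)
  Tm <- two_sample_t(M, Yp)
  perm_max <- apply(Tm, 2, max)
  thr <- sort(perm_max)[ceiling((1 - alpha) * n_perm)]
  sig <- t_obs > thr
  cols <- which(usable)[sig]
  structure(list(sig_index = m$streamline_index[cols], sig_cols = cols,
                 t_obs = t_obs, fwe_threshold = thr, perm_max = perm_max,
                 excluded = excluded, n_perm = n_perm, alpha = alpha),
            class = "streamline_glm")
}

# pooled-variance two-sample t for every binary column of M against every
# column of Y, in two matrix products: group sums of y and of y^2 are
# linear in the indicator columns, and the total sum/SS are permutation
# invariant.
two_sample_t <- function(M, Y) {
  n <- nrow(M)
  n1 <- colSums(M)
  n0 <- n - n1
  Sy <- colSums(Y)                    # per permutation (constant across M)
  Syy <- colSums(Y^2)
  S1 <- crossprod(M, Y)               # streamlines x perms: sum y in group 1
  mean1 <- S1 / n1
  mean0 <- sweep(-S1, 2, Sy, "+") / n0
  ss_within <- sweep(-(n1 * mean1^2 + n0 * mean0^2), 2, Syy, "+")
  sp2 <- pmax(ss_within, 0) / (n - 2)
  (mean1 - mean0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

#' @export
print.streamline_glm <- function(x, ...) {
  cat("<streamline_glm> ", length(x$t_obs), " streamlines tested, ",
      length(x$sig_index), " significant (one-tailed FWE alpha = ",
      x$alpha, ", ", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Count significant streamlines per tract
#'
#' @param indices streamline indices (into `sset`) declared significant.
#' @param sset a [streamline_set()] carrying `tract_label`; unlabelled
#'   streamlines are counted under `"unlabelled"`.
#' @return Named integer vector of counts per tract (empty for an empty
#'   index set).
#' @export
assign_tracts <- function(indices, sset) {
  stopifnot(inherits(sset, "streamline_set"))
  if (!length(indices)) return(setNames(integer(), character()))
  labs <- if (is.null(sset$tract_label))
    rep("unlabelled", length(sset$streamlines))
  else {
    l <- sset$tract_label
    l[is.na(l) | l == ""] <- "unlabelled"
    l
  }
  tab <- table(labs[indices])
  setNames(as.integer(tab), names(tab))
}
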