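# Tract-wise lesion load from probabilistic tract atlases, and the
# association statistics applied to it: Kendall rank correlation with
# Bonferroni correction, and a Pearson chi-square on the presence table
# (lesion load yes/no x neglect yes/no).

#' Probabilistic tract atlas
#'
#' @param tracts named list of [volume3d()] probabilistic maps with values
#'   in `[0, 1]`; each tract must carry positive total probability mass.
#' @return An object of class `tract_atlas`.
#' @export
tract_atlas <- function(tracts) {
  if (!length(tracts) || is.null(names(tracts)) || any(names(tracts) == ""))
    stop("tract_atlas: 'tracts' must be a named list of volumes")
  for (nm in names(tracts)) {
    v <- tracts[[nm]]$data
    if (min(v, na.rm = TRUE) < 0 || max(v, na.rm = TRUE) > 1)
      stop("tract_atlas: tract '", nm, "' has values outside [0, 1]")
    if (sum(v, na.rm = TRUE) <= 0)
      stop("tract_atlas: tract '", nm, "' has zero probability mass")
  }
  structure(list(tracts = tracts, names = names(tracts)),
            class = "tract_atlas")
}

#' Binarise a probabilistic tract map
#'
#' @param prob a [volume3d()] probabilistic map in `[0, 1]`.
#' @param threshold probability cutoff in `(0, 1]`; voxels with probability
#'   `>= threshold` (inclusive) are retained. The conventional cutoff for
#'   histological tract atlases is 0.3.
#' @param name tract name used in error messages.
#' @return A binary [volume3d()] region of interest.
#' @export
binarize_tract <- function(prob, threshold = 0.3, name = "tract") {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("binarize_tract: threshold must be in (0, 1]")
  m <- (prob$data >= threshold) + 0
  m[is.na(prob$data)] <- 0
  if (sum(m) == 0)
    stop("binarize_tract: tract '", name, "' vanishes at threshold ",
         threshold)
  volume3d(m, affine = prob$affine, space = prob$space)
}

#' Binary tract-wise lesion load
#'
#' Proportional overlap of the lesion with the binarised tract: the damaged
#' fraction of the tract, `|lesion ∩ tract| / |tract|`. The denominator is
#' the tract size, making loads comparable across lesion sizes.
#'
#' @param lesion binary [volume3d()] lesion mask.
#' @param tract_mask binary [volume3d()] tract region of interest.
#' @return Load fraction in `[0, 1]`.
#' @export
lesion_load <- function(lesion, tract_mask) {
  check_same_grid(lesion, tract_mask)
  tract_n <- sum(tract_mask$data > 0, na.rm = TRUE)
  if (tract_n == 0) stop("lesion_load: empty tract mask")
  inter <- sum(lesion$data > 0 & tract_mask$data > 0, na.rm = TRUE)
  inter / tract_n
}

#' Probability-weighted tract-wise lesion load
#'
#' Each lesioned voxel contributes its probability of belonging to the
#' tract; the sum is normalised by the tract's total probability mass so
#' the weighted load shares the `[0, 1]` scale of the binary load (and the
#' two coincide when the probability map is itself binary).
#'
#' @param lesion binary [volume3d()] lesion mask.
#' @param prob probabilistic [volume3d()] tract map.
#' @return Weighted load fraction in `[0, 1]`.
#' @export
weighted_lesion_load <- function(lesion, prob) {
  check_same_grid(lesion, prob)
  mass <- sum(prob$data, na.rm = TRUE)
  if (mass <= 0) stop("weighted_lesion_load: tract has zero probability mass")
  p <- prob$data
  p[is.na(p)] <- 0
  sum(p[lesion$data > 0 & !is.na(lesion$data)]) / mass
}

#' Patients x tracts lesion-load table
#'
#' @param lesions list of binary [volume3d()] lesion masks.
#' @param atlas a [tract_atlas()].
#' @param threshold binarisation cutoff for the binary mode.
#' @param weighted compute probability-weighted loads instead of binary
#'   thresholded loads.
#' @param patient_ids optional patient identifiers (row names).
#' @return A data.frame with one column per tract plus `total` (row sum),
#'   and attribute `weighted`.
#' @export
lesion_load_table <- function(lesions, atlas, threshold = 0.3,
                              weighted = FALSE, patient_ids = NULL) {
  stopifnot(inherits(atlas, "tract_atlas"))
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_along(lesions))
  masks <- if (!weighted)
    lapply(names(atlas$tracts), function(nm)
      binarize_tract(atlas$tracts[[nm]], threshold, name = nm))
  else atlas$tracts
  names(masks) <- atlas$names
  out <- matrix(0, length(lesions), length(masks),
                dimnames = list(patient_ids, atlas$names))
  for (i in seq_along(lesions)) {
    for (nm in atlas$names) {
      out[i, nm] <- if (weighted)
        weighted_lesion_load(lesions[[i]], masks[[nm]])
      else lesion_load(lesions[[i]], masks[[nm]])
    }
  }
  df <- as.data.frame(out)
  df$total <- rowSums(out)
  attr(df, "weighted") <- weighted
  df
}

#' Kendall rank correlation (tau-b) with tie-adjusted normal p-value
#'
#' Tau-b with tie correction in the denominator; the two-sided p-value uses
#' the normal approximation with tie-adjusted variance (the appropriate
#' choice here because lesion-load vectors typically contain ties at zero).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with elements `tau` and `p`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("kendall_tau: need equal-length vectors of length >= 4")
  if (sd(x) == 0 || sd(y) == 0)
    stop("kendall_tau: constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, `min(1, m * p)` with `m = length(p_values)`.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("bonferroni: p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni")
}

#' Pearson chi-square on a 2x2 presence table
#'
#' Tests whether the presence of any tract lesion load differs between
#' patients with and without spatial neglect. No continuity correction is
#' applied.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `chi2`, `df` (always 1) and `p`.
#' @export
presence_chi_square <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("presence_chi_square: need 2x2 table")
  if (any(tab < 0)) stop("presence_chi_square: negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("presence_chi_square: zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Tract-load association statistics
#'
#' Per-tract and total-load Kendall tau against severity with Bonferroni
#' correction over the per-tract tests, plus the presence chi-square
#' comparing load presence between neglect and non-neglect patients.
#'
#' @param loads a [lesion_load_table()] (tract columns + `total`).
#' @param severity numeric severity (mean CoC) per patient.
#' @param neglect logical neglect label per patient (for the presence test;
#'   omit to skip it).
#' @return List with a per-tract data.frame (`tau`, `p`, `p_bonf`), the
#'   total-load test, and the presence test (or `NULL`).
#' @export
tract_load_association <- function(loads, severity, neglect = NULL) {
  tracts <- setdiff(names(loads), "total")
  tau_or_na <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) list(tau = NA_real_, p = NA_real_)
    else kendall_tau(x, y)
  }
  per <- lapply(tracts, function(nm) tau_or_na(loads[[nm]], severity))
  tab <- data.frame(tract = tracts,
                    tau = vapply(per, `[[`, 0, "tau"),
                    p = vapply(per, `[[`, 0, "p"))
  tab$p_bonf <- bonferroni(tab$p)
  total <- tau_or_na(loads$total, severity)
  presence <- NULL
  if (!is.null(neglect)) {
    has_load <- loads$total > 0
    counts <- rbind(c(sum(has_load & neglect), sum(!has_load & neglect)),
                    c(sum(has_load & !neglect), sum(!has_load & !neglect)))
    presence <- if (all(rowSums(counts) > 0) && all(colSums(counts) > 0))
      c(presence_chi_square(counts), list(table = counts))
    else NULL
  }
  list(per_tract = tab, total = total, presence = presence)
}
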