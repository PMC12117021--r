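# Centre-of-Cancellation (CoC) scoring of cancellation tests.
#
# Cancellation sheets present targets left and right of the patient's
# sagittal midline (horizontal coordinate 0 cm). The CoC is the mean
# normalised horizontal position of the successfully cancelled targets:
# -1 (all the way left, i.e. neglect of right stimuli) through 0
# (symmetrical performance) to +1 (neglect of left stimuli). Positions are
# normalised by the largest absolute target position on the sheet so the
# extremes are attained at the outermost targets.

#' Centre of Cancellation for one cancellation test
#'
#' @param target_x numeric vector of horizontal target positions (cm,
#'   midline = 0); must contain at least one target strictly left and one
#'   strictly right of the midline.
#' @param hit_flags logical (or 0/1) vector, same length: was the target
#'   cancelled?
#' @return CoC score in `[-1, 1]`; positive = rightward deviation of the
#'   cancelled set (left neglect).
#' @export
compute_coc <- function(target_x, hit_flags) {
  target_x <- as.numeric(target_x)
  hit_flags <- as.logical(hit_flags)
  if (!length(target_x)) stop("compute_coc: no targets")
  if (length(hit_flags) != length(target_x))
    stop("compute_coc: hit_flags length mismatch")
  if (!any(target_x < 0) || !any(target_x > 0))
    stop("compute_coc: targets must flank the midline on both sides")
  if (!any(hit_flags))
    stop("compute_coc: no cancelled targets; CoC undefined")
  mean(target_x[hit_flags]) / max(abs(target_x))
}

#' Mean CoC across the available cancellation tests
#'
#' The severity measure is the average CoC of the letter and bells tests;
#' when only one test is available its score is used as the sole measure.
#'
#' @param scores named numeric vector or list of per-test CoC scores;
#'   `NA` entries are treated as unavailable.
#' @return Arithmetic mean of the available scores.
#' @export
mean_coc <- function(scores) {
  s <- unlist(scores, use.names = FALSE)
  s <- s[!is.na(s)]
  if (!length(s)) stop("mean_coc: no scores available")
  mean(s)
}

#' Binary spatial-neglect classification from per-test CoC scores
#'
#' A patient is classified as exhibiting spatial neglect if the CoC in at
#' least one available test is strictly above that test's empirically
#' established cutoff. Cutoffs are configuration, not constants: supply
#' them explicitly (e.g. `c(letters = 0.08, bells = 0.08)`).
#'
#' @param scores named numeric per-test CoC scores (`NA` = unavailable).
#' @param cutoffs named numeric cutoffs; a cutoff must be present for every
#'   available test.
#' @return Logical: neglect or not. A score exactly at the cutoff does not
#'   count ("above" is read as strict).
#' @export
classify_neglect <- function(scores, cutoffs) {
  s <- unlist(scores)
  s <- s[!is.na(s)]
  if (!length(s)) stop("classify_neglect: no scores available")
  cuts <- unlist(cutoffs)
  missing_cut <- setdiff(names(s), names(cuts))
  if (length(missing_cut))
    stop("classify_neglect: missing cutoff for test(s): ",
         paste(missing_cut, collapse = ", "))
  any(s > cuts[names(s)])
}

#' Read a behavioural table from CSV
#'
#' Accepts one row per patient-test with either raw cancellation data
#' (columns `target_x` and `hit_flags`, each a semicolon-joined list) or a
#' precomputed `coc` column, and derives per-patient mean CoC and the
#' binary neglect label. Zero-hit raw records yield a missing (`NA`) CoC
#' for that test rather than an extreme score.
#'
#' @param path CSV with columns `patient_id`, `test_name` and either
#'   `coc` or `target_x` + `hit_flags`; an optional `group` column is
#'   carried through.
#' @param cutoffs named per-test cutoffs passed to [classify_neglect()].
#' @return A data.frame with one row per patient: `patient_id`,
#'   one `coc_<test>` column per test, `mean_coc`, `neglect`, and `group`
#'   if present.
#' @export
read_behaviour <- function(path, cutoffs) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "test_name")
  if (!all(need %in% names(raw)))
    stop("read_behaviour: required columns missing: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  raw$coc_value <- NA_real_
  if ("coc" %in% names(raw)) raw$coc_value <- as.numeric(raw$coc)
  if (all(c("target_x", "hit_flags") %in% names(raw))) {
    for (i in seq_len(nrow(raw))) {
      if (!is.na(raw$coc_value[i])) next
      tx <- as.numeric(strsplit(raw$target_x[i], ";")[[1]])
      hf <- as.integer(strsplit(raw$hit_flags[i], ";")[[1]])
      raw$coc_value[i] <- if (any(hf == 1L)) compute_coc(tx, hf) else NA_real_
    }
  }
  behaviour_table(raw$patient_id, raw$test_name, raw$coc_value, cutoffs,
                  group = if ("group" %in% names(raw)) raw$group else NULL)
}

#' Assemble a per-patient behavioural table from per-test CoC scores
#'
#' @param patient_id,test_name,coc parallel vectors, one entry per
#'   patient-test record.
#' @param cutoffs named per-test cutoffs for [classify_neglect()].
#' @param group optional per-record patient group (constant within patient).
#' @return A data.frame, one row per patient, in first-appearance order.
#' @export
behaviour_table <- function(patient_id, test_name, coc, cutoffs,
                            group = NULL) {
  pid <- as.character(patient_id)
  ids <- unique(pid)
  tests <- unique(as.character(test_name))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (tn in tests) out[[paste0("coc_", tn)]] <- NA_real_
  for (i in seq_along(pid)) {
    r <- match(pid[i], ids)
    out[r, paste0("coc_", test_name[i])] <- coc[i]
  }
  out$mean_coc <- NA_real_
  out$neglect <- NA
  for (r in seq_len(nrow(out))) {
    s <- setNames(as.numeric(out[r, paste0("coc_", tests)]), tests)
    if (all(is.na(s))) next
    out$mean_coc[r] <- mean_coc(s)
    out$neglect[r] <- classify_neglect(s, cutoffs)
  }
  if (!is.null(group))
    out$group <- as.character(group)[match(ids, pid)]
  out
}
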