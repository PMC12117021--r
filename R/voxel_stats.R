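# Voxel-wise association mapping between lesion-network connectivity and
# neglect severity: a single-regressor GLM per voxel (t statistic of the
# slope, equivalent to the Pearson-r t with n - 2 df), family-wise error
# corrected by maximum-statistic permutation thresholding, plus a Bayesian
# replication mapping Bayes factors under a Cauchy prior on the
# standardised effect, binned into conventional evidence categories.
#
# All heavy computation works on a patients x voxels matrix; permutations
# are evaluated in one matrix product (standardised maps crossed with a
# matrix of permuted, standardised severity vectors), which keeps the
# calibration suites (hundreds of cohorts x hundreds of permutations)
# inside seconds.

T_CAP <- 1e8  # reported |t| for numerically perfect fits (1 - r^2 -> 0)

#' Per-voxel t statistics of the severity slope
#'
#' @param X patients x voxels matrix of map values (complete cases: columns
#'   with any `NA` are returned as `NA`).
#' @param y severity vector (mean CoC), non-constant, length `nrow(X)`.
#' @return Numeric vector of t statistics with `n - 2` df; `NA` at voxels
#'   with zero variance or missing values; perfect fits are capped at
#'   `1e8` in magnitude.
#' @export
voxelwise_glm <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("voxelwise_glm: need at least 3 patients")
  if (length(y) != n) stop("voxelwise_glm: length(y) != nrow(X)")
  if (sd(y) == 0) stop("voxelwise_glm: constant severity")
  r <- as.vector(suppressWarnings(cor(y, X)))
  t_from_r(r, n)
}

t_from_r <- function(r, n) {
  denom <- 1 - r^2
  t <- r * sqrt((n - 2) / pmax(denom, 0))
  t[!is.na(denom) & denom <= .Machine$double.eps] <-
    sign(r[!is.na(denom) & denom <= .Machine$double.eps]) * T_CAP
  pmin(pmax(t, -T_CAP), T_CAP)
}

# n x n_perm matrix of permuted y; exhaustive enumerates all n!
# permutations (identity included), feasible for n <= 8
permutation_matrix <- function(y, n_perm, exhaustive = FALSE) {
  n <- length(y)
  if (exhaustive) {
    perms <- all_permutations(n)
    return(matrix(y[perms], nrow = n))
  }
  vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
}

all_permutations <- function(n) {
  if (n > 8) stop("exhaustive permutation only supported for n <= 8")
  rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(rec(v[-i]), function(p) c(v[i], p)))
    out
  }
  do.call(cbind, rec(seq_len(n)))
}

#' Maximum-statistic permutation FWE thresholding of a voxel-wise GLM
#'
#' For each permutation the severity vector is shuffled, the voxel-wise t
#' map recomputed, and the maximum over voxels of `|t|` (two-tailed) or `t`
#' (one-tailed) recorded. The family-wise critical value is the `1 - alpha`
#' empirical quantile of that maximum distribution; the observed map is
#' thresholded strictly above it. Per-voxel FWE p-values use
#' `p = (1 + #permutation maxima >= observed) / (1 + n_perm)`, so p is
#' never zero.
#'
#' @param X patients x voxels matrix; columns with missing values or zero
#'   variance are excluded from both the observed map and the permutation
#'   null.
#' @param y severity vector.
#' @param n_perm permutation count (>= 1; >= 100 recommended).
#' @param alpha family-wise error level in (0, 1).
#' @param tails `"two"` (default) or `"one"` (positive slope).
#' @param exhaustive enumerate all `n!` permutations instead of sampling
#'   (n <= 8).
#' @return Object of class `stat_map`: `tmap` (full-length t vector, `NA`
#'   at excluded voxels), `fwe_threshold`, `sig_mask` (logical vector),
#'   `p_fwe`, `perm_max`, `n_perm`, `tails`, `alpha`.
#' @export
max_stat_fwe <- function(X, y, n_perm = 10000, alpha = 0.05,
                         tails = c("two", "one"), exhaustive = FALSE) {
  tails <- match.arg(tails)
  if (!exhaustive && (!is.numeric(n_perm) || n_perm < 1))
    stop("max_stat_fwe: n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("max_stat_fwe: alpha must be in (0, 1)")
  X <- as.matrix(X)
  n <- nrow(X)
  t_obs <- voxelwise_glm(X, y)
  ok <- !is.na(t_obs)
  if (!any(ok)) stop("max_stat_fwe: no testable voxels")
  Z <- scale(X[, ok, drop = FALSE])          # n x V, unit-sd columns
  Yp <- permutation_matrix(y, n_perm, exhaustive)
  n_perm <- ncol(Yp)
  Zy <- scale(Yp)
  R <- crossprod(Z, Zy) / (n - 1)            # V x n_perm correlations
  Tm <- t_from_r(R, n)
  stat_obs <- if (tails == "two") abs(t_obs) else t_obs
  perm_stat <- if (tails == "two") abs(Tm) else Tm
  perm_max <- apply(perm_stat, 2, max)
  thr <- sort(perm_max)[ceiling((1 - alpha) * n_perm)]
  sig <- !is.na(stat_obs) & stat_obs > thr
  p_fwe <- rep(NA_real_, length(t_obs))
  p_fwe[ok] <- vapply(stat_obs[ok],
                      function(s) (1 + sum(perm_max >= s)) / (1 + n_perm),
                      numeric(1))
  structure(list(tmap = t_obs, fwe_threshold = thr, sig_mask = sig,
                 p_fwe = p_fwe, perm_max = perm_max, n_perm = n_perm,
                 tails = tails, alpha = alpha),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", sum(!is.na(x$tmap)), " voxels tested, ",
      sum(x$sig_mask), " significant (", x$tails, "-tailed FWE alpha = ",
      x$alpha, ", threshold ", signif(x$fwe_threshold, 4), ", ",
      x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

# ---- Bayes factors ---------------------------------------------------------

#' Bayes factor for a nonzero standardised slope, from a t statistic
#'
#' BF10 for the two-sided test of slope != 0 in the simple regression of
#' severity on map value, with a zero-centred Cauchy prior on the
#' standardised effect size delta (scale `prior_scale`). The marginal
#' likelihood under H1 is obtained by numerical integration of the
#' noncentral-t density of the observed statistic over the prior,
#' `BF10 = \int t_df(t | delta sqrt(n)) Cauchy(delta; 0, s) d delta /
#' t_df(t | 0)`.
#'
#' @param t observed t statistic(s) with `n - 2` df.
#' @param n sample size.
#' @param prior_scale Cauchy scale; default `sqrt(2)/2`, the common default
#'   for standardised-slope priors.
#' @return BF10 value(s); `NA` (with a warning) where integration fails.
#' @export
bf10_from_t <- function(t, n, prior_scale = sqrt(2) / 2) {
  df <- n - 2
  # |t| beyond 40 underflows the central-t density; BF10 is astronomically
  # large there anyway, so clip before integrating (bins are unaffected)
  tc <- sign(t) * pmin(abs(t), 40)
  # substitute delta = prior_scale * tan(theta): the Cauchy-weighted
  # integral becomes (1/pi) * int_{-pi/2}^{pi/2} f(delta(theta)) d theta,
  # evaluated by composite Simpson on a fixed grid — smooth integrand,
  # vanishing at the endpoints, vectorises over voxels
  m <- 129L
  theta <- seq(-pi / 2, pi / 2, length.out = m)
  w <- c(1, rep(c(4, 2), length.out = m - 2L), 1)
  w[m - 1L] <- 4
  h <- theta[2] - theta[1]
  ncp <- prior_scale * tan(theta) * sqrt(n)
  ncp[c(1, m)] <- sign(theta[c(1, m)]) * 1e8      # tan(+-pi/2): density -> 0
  ok <- !is.na(tc)
  out <- rep(NA_real_, length(t))
  if (any(ok)) {
    G <- suppressWarnings(
      outer(tc[ok], ncp, function(ti, d) dt(ti, df, ncp = d)))
    G[!is.finite(G)] <- 0
    num <- as.vector(G %*% w) * h / 3 / pi
    den <- dt(tc[ok], df)
    bf <- num / den
    bad <- !is.finite(bf) | bf <= 0
    if (any(bad))
      warning("bf10_from_t: non-finite Bayes factor at ", sum(bad),
              " value(s)")
    bf[bad] <- NA_real_
    out[ok] <- bf
  }
  out
}

#' Voxel-wise Bayes-factor map
#'
#' @param X patients x voxels matrix (complete cases per column).
#' @param y severity vector; `nrow(X) >= 5`.
#' @param prior_scale Cauchy prior scale on the standardised effect.
#' @return Object of class `bf_map`: `bfmap` (BF10 per voxel, `NA` where
#'   untestable), `bins` (see [bin_bayes_factors()]), `bin_proportions`,
#'   `prior_scale`.
#' @export
bayes_factor_map <- function(X, y, prior_scale = sqrt(2) / 2) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("bayes_factor_map: need at least 5 patients")
  if (sd(y) == 0) stop("bayes_factor_map: constant severity")
  t_obs <- voxelwise_glm(X, y)
  bf <- bf10_from_t(t_obs, nrow(X), prior_scale)
  binned <- bin_bayes_factors(bf)
  structure(list(bfmap = bf, bins = binned$bins,
                 bin_proportions = binned$proportions,
                 prior_scale = prior_scale),
            class = "bf_map")
}

BF_BIN_LEVELS <- c("h0_moderate_or_more", "h0_anecdotal", "h1_anecdotal",
                   "h1_moderate", "h1_strong", "h1_very_strong")

#' Bin Bayes factors into conventional evidence categories
#'
#' Categories follow the usual conventions: BF10 > 30 very strong and
#' BF10 > 10 strong and BF10 > 3 moderate evidence for H1; 1 <= BF10 <= 3
#' anecdotal evidence for H1; 1/3 <= BF10 < 1 anecdotal evidence for H0;
#' BF10 < 1/3 at least moderate evidence for H0. A BF of exactly 1 (a
#' measure-zero tie) falls in the anecdotal-H1 bin.
#'
#' @param bf positive BF10 values (`NA` allowed and ignored).
#' @return List with `bins` (factor over the six categories, `NA`
#'   propagated) and `proportions` (named fractions of tested voxels,
#'   summing to 1).
#' @export
bin_bayes_factors <- function(bf) {
  if (any(bf <= 0, na.rm = TRUE))
    stop("bin_bayes_factors: Bayes factors must be positive")
  cut_one <- function(b) {
    if (is.na(b)) return(NA_character_)
    if (b < 1 / 3) "h0_moderate_or_more"
    else if (b < 1) "h0_anecdotal"
    else if (b <= 3) "h1_anecdotal"
    else if (b <= 10) "h1_moderate"
    else if (b <= 30) "h1_strong"
    else "h1_very_strong"
  }
  bins <- factor(vapply(bf, cut_one, character(1)), levels = BF_BIN_LEVELS)
  tab <- table(bins)
  n_tested <- sum(tab)
  if (n_tested == 0) stop("bin_bayes_factors: no tested voxels")
  list(bins = bins,
       proportions = setNames(as.numeric(tab) / n_tested, BF_BIN_LEVELS))
}
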