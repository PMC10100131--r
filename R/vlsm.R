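#' Voxelwise lesion-symptom statistic map
#'
#' For every tested voxel, fits ordinary least squares of the outcome on
#' \[lesion indicator, covariates, intercept\] and reports the t statistic of
#' the lesion coefficient (for a binary outcome this is a linear probability
#' model, the default continuous machinery of VLSM).  Voxels lesioned in
#' fewer than `min_coverage` patients, or in more than `N - min_coverage`,
#' are excluded, as are voxels whose design is rank deficient (logged, not a
#' crash).
#'
#' Implementation note: with the covariate design shared across voxels, the
#' lesion-coefficient t is computed through the Frisch-Waugh decomposition
#' (residualize outcome and lesion indicator against the covariates, then a
#' simple regression per voxel), which is algebraically identical to the
#' full per-voxel OLS fit and fully vectorized.
#'
#' @param cohort A [lesion_cohort()].
#' @param outcome Numeric per-patient outcome (complete; no NA).
#' @param covariates Optional numeric matrix (patients x covariates).
#' @param min_coverage Minimum patients lesioned (and spared) per voxel;
#'   at least 2.
#' @return List with `t_map` (3-D array, NA outside tested voxels),
#'   `coverage_map` (integer 3-D array) and `tested_mask` (logical 3-D
#'   array).
#' @export
voxelwise_stat <- function(cohort, outcome, covariates = NULL,
                           min_coverage = 5) {
  eng <- vlsm_engine(cohort, outcome, covariates, min_coverage)
  list(t_map = eng$t_map, coverage_map = eng$coverage_map,
       tested_mask = eng$tested_mask)
}

# Internal workhorse shared by voxelwise_stat and permutation_threshold.
vlsm_engine <- function(cohort, outcome, covariates, min_coverage) {
  n <- cohort_size(cohort)
  stopifnot(length(outcome) == n, min_coverage >= 2)
  if (anyNA(outcome)) stop("outcome contains NA; pass a complete-case subset")
  Z <- cbind(intercept = rep(1, n), covariates)
  if (anyNA(Z)) stop("covariates contain NA; pass a complete-case subset")
  if (qr(Z)$rank < ncol(Z)) stop("covariate design is rank deficient")

  space <- cohort$space
  coverage <- array(0L, dim = space$dims)
  for (m in cohort$masks) coverage <- coverage + m
  tested <- coverage >= min_coverage & coverage <= n - min_coverage &
    space$brain_mask
  tested_idx <- which(tested)
  if (length(tested_idx) == 0) stop("no voxels meet min_coverage")

  L <- vapply(cohort$masks, function(m) as.numeric(m[tested_idx]),
              numeric(length(tested_idx)))
  ZtZ <- crossprod(Z)
  My <- outcome - Z %*% solve(ZtZ, crossprod(Z, outcome))
  Lres <- L - (L %*% Z) %*% solve(ZtZ, t(Z))
  sxx <- rowSums(Lres^2)
  df <- n - ncol(Z) - 1

  rank_ok <- sxx > 1e-10 * n
  if (any(!rank_ok)) {
    gf_log("vlsm: %d voxel(s) excluded for rank deficiency", sum(!rank_ok))
  }
  beta <- as.numeric(Lres %*% My) / sxx
  sse <- pmax(sum(My^2) - beta^2 * sxx, 0)
  tval <- beta / sqrt(sse / df / sxx)
  tval[!rank_ok] <- NA_real_
  tval[is.nan(tval)] <- 0  # 0/0: zero effect with zero residual variance

  t_map <- array(NA_real_, dim = space$dims)
  t_map[tested_idx] <- tval
  tested[tested_idx[!rank_ok]] <- FALSE

  list(t_map = t_map, coverage_map = coverage, tested_mask = tested,
       tested_idx = tested_idx, t = tval, rank_ok = rank_ok,
       Z = Z, ZtZ = ZtZ, My = as.numeric(My), Lres = Lres, sxx = sxx,
       df = df, n = n, outcome = outcome)
}

#' Permutation-thresholded VLSM
#'
#' Computes the observed voxelwise t map and a permutation null under the
#' Freedman-Lane scheme: the reduced (covariate-only) model's residuals are
#' permuted, refitted per voxel, and the resulting t maps form the null.
#' In `maxstat` mode the threshold is the `1 - alpha` quantile of the
#' per-permutation maximum statistic over tested voxels (familywise error
#' control); in `voxelwise` mode each voxel is thresholded at the
#' `1 - alpha` quantile of its own null.  The direction selects which tail
#' is of interest: `"two"` uses |t|, `"positive"`/`"negative"` use signed t.
#'
#' @inheritParams voxelwise_stat
#' @param n_perm Number of permutations, at least 20 (default 500).
#' @param alpha Significance level (default 0.05).
#' @param mode `"maxstat"` (default) or `"voxelwise"`.
#' @param direction `"two"`, `"positive"` or `"negative"`.
#' @param scheme `"freedman-lane"` (default) or `"naive"` outcome
#'   permutation.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return A `vlsm_result` with the t map, coverage map, tested mask,
#'   stored null maxima, threshold, significant mask and config.
#' @export
permutation_threshold <- function(cohort, outcome, covariates = NULL,
                                  n_perm = 500, alpha = 0.05,
                                  mode = c("maxstat", "voxelwise"),
                                  direction = c("two", "positive", "negative"),
                                  scheme = c("freedman-lane", "naive"),
                                  min_coverage = 5, seed = 1L) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  scheme <- match.arg(scheme)
  if (n_perm < 20) stop("n_perm must be at least 20 for a stable quantile")
  eng <- vlsm_engine(cohort, outcome, covariates, min_coverage)
  n <- eng$n

  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  base <- if (scheme == "freedman-lane") eng$My else eng$outcome
  E <- matrix(base[perms], nrow = n)
  ME <- E - eng$Z %*% solve(eng$ZtZ, crossprod(eng$Z, E))
  numer <- eng$Lres %*% ME
  beta_null <- numer / eng$sxx
  sse_null <- pmax(sweep(-beta_null^2 * eng$sxx, 2L, colSums(ME^2), `+`), 0)
  t_null <- beta_null / sqrt(sse_null / eng$df / eng$sxx)
  t_null[!eng$rank_ok, ] <- NA_real_
  t_null[is.nan(t_null)] <- 0

  dirstat <- switch(direction,
    two = abs,
    positive = identity,
    negative = function(x) -x
  )
  s_obs <- dirstat(eng$t)
  s_null <- dirstat(t_null)
  null_maxima <- apply(s_null, 2L, max, na.rm = TRUE)

  sig <- array(FALSE, dim = cohort$space$dims)
  if (mode == "maxstat") {
    threshold <- unname(quantile(null_maxima, 1 - alpha, type = 7))
    sig[eng$tested_idx] <- eng$rank_ok & !is.na(s_obs) & s_obs > threshold
  } else {
    thr_vox <- apply(s_null, 1L, quantile, probs = 1 - alpha, type = 7,
                     na.rm = TRUE)
    threshold <- thr_vox
    sig[eng$tested_idx] <- eng$rank_ok & !is.na(s_obs) & s_obs > thr_vox
  }
  gf_log("vlsm permutation: seed %d, %d perms, mode %s, %d significant voxels",
         seed, n_perm, mode, sum(sig))
  structure(list(
    t_map = eng$t_map, coverage_map = eng$coverage_map,
    tested_mask = eng$tested_mask, null_maxima = null_maxima,
    threshold = threshold, significant_mask = sig,
    config = list(n_perm = n_perm, alpha = alpha, mode = mode,
                  direction = direction, scheme = scheme,
                  min_coverage = min_coverage, seed = seed)
  ), class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat(sprintf(
    "<vlsm_result> %d tested voxels, %d significant (%s, %s, alpha=%.3g, %d perms)\n",
    sum(x$tested_mask), sum(x$significant_mask), x$config$mode,
    x$config$direction, x$config$alpha, x$config$n_perm))
  invisible(x)
}

#' Derive grade-associated (ROI1) and short-survival (ROI2) masks
#'
#' ROI1 is the significant mask of a VLSM run with outcome = GBM indicator
#' (positive direction: voxels whose lesioning associates with GBM rather
#' than LGG); ROI2 is the significant mask of a VLSM run on overall survival
#' among GBM patients, negative direction (voxels associated with shorter
#' survival).  Both runs control for age, sex and tumor volume and use
#' complete-case subsets (exclusions logged).
#'
#' @param cohort A [lesion_cohort()] containing both grade groups.
#' @param n_perm,alpha,mode,min_coverage,seed Passed to
#'   [permutation_threshold()].
#' @return List with logical masks `roi1` and `roi2` plus the two full
#'   `vlsm_result`s (`fit1`, `fit2`).  Empty masks are returned with a
#'   warning.
#' @export
derive_rois <- function(cohort, n_perm = 500, alpha = 0.05,
                        mode = "maxstat", min_coverage = 5, seed = 1L) {
  rec <- cohort$records
  vox_cm3 <- voxel_volume_cm3(cohort$space)
  volume <- vapply(cohort$masks, sum, numeric(1))[rec$patient_id] * vox_cm3

  ok1 <- !is.na(rec$grade) & !is.na(rec$age) & !is.na(rec$sex)
  if (sum(!ok1) > 0) gf_log("derive_rois: ROI1 excludes %d incomplete rows",
                            sum(!ok1))
  co1 <- subset_cohort(cohort, ids = rec$patient_id[ok1])
  r1 <- co1$records
  cov1 <- cbind(age = r1$age, sex = as.numeric(r1$sex == "male"),
                volume = volume[r1$patient_id])
  fit1 <- permutation_threshold(co1, as.numeric(r1$grade == "GBM"),
                                covariates = cov1, n_perm = n_perm,
                                alpha = alpha, mode = mode,
                                direction = "positive",
                                min_coverage = min_coverage, seed = seed)

  ok2 <- rec$grade %in% "GBM" & !is.na(rec$survival_time) &
    !is.na(rec$age) & !is.na(rec$sex)
  co2 <- subset_cohort(cohort, ids = rec$patient_id[ok2])
  r2 <- co2$records
  cov2 <- cbind(age = r2$age, sex = as.numeric(r2$sex == "male"),
                volume = volume[r2$patient_id])
  fit2 <- permutation_threshold(co2, r2$survival_time,
                                covariates = cov2, n_perm = n_perm,
                                alpha = alpha, mode = mode,
                                direction = "negative",
                                min_coverage = min_coverage,
                                seed = seed + 1L)

  if (!any(fit1$significant_mask)) warning("ROI1 is empty")
  if (!any(fit2$significant_mask)) warning("ROI2 is empty")
  list(roi1 = fit1$significant_mask, roi2 = fit2$significant_mask,
       fit1 = fit1, fit2 = fit2)
}
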