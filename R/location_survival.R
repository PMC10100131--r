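#' Euclidean distance map to a target mask
#'
#' Exact Euclidean distance transform (anisotropic voxel sizes respected):
#' each voxel's value is the mm distance to the nearest target voxel, zero
#' inside the target.  Applied to the ventricle mask this yields the
#' concentric periventricular (SVZ) distance map.
#'
#' @param space A [brain_space()].
#' @param target_mask Nonempty logical 3-D array on `space`.
#' @return Numeric 3-D array of mm distances.
#' @export
distance_map <- function(space, target_mask) {
  stopifnot(identical(dim(target_mask), space$dims))
  if (!any(target_mask)) stop("empty target mask")
  .edt_cpp(target_mask, space$dims, space$voxel_size)
}

#' Spherical mask at the mass center of an ROI
#'
#' Places a sphere of radius `radius_mm` at the ROI's voxel-rounded center
#' of mass, clipped to the brain mask.  If the center of mass falls outside
#' the brain mask (e.g. for a C-shaped ROI) the nearest in-mask voxel is
#' used and a warning is issued.  The default radius of twice the largest
#' voxel size keeps the center mask point-like but nonempty.
#'
#' @param roi_mask Nonempty logical ROI mask.
#' @param space A [brain_space()].
#' @param radius_mm Sphere radius in mm.
#' @return Logical 3-D mask.
#' @export
roi_center_mask <- function(roi_mask, space,
                            radius_mm = 2 * max(space$voxel_size)) {
  if (!any(roi_mask)) stop("empty ROI mask")
  idx0 <- arrayInd(which(roi_mask), space$dims) - 1L
  com_vox <- round(colMeans(idx0))
  com_mm <- space$origin + com_vox * space$voxel_size
  ci <- as.integer(com_vox) + 1L
  if (!space$brain_mask[ci[1], ci[2], ci[3]]) {
    warning("ROI center of mass outside brain mask; using nearest in-mask voxel")
    xyz <- mask_coords_mm(space$brain_mask, space)
    d2 <- rowSums(sweep(xyz, 2L, com_mm, `-`)^2)
    com_mm <- xyz[which.min(d2), ]
  }
  xyz_all <- voxel_grid_mm(space)
  d2 <- rowSums(sweep(xyz_all, 2L, com_mm, `-`)^2)
  mask <- array(d2 <= radius_mm^2, dim = space$dims) & space$brain_mask
  if (!any(mask)) {
    # radius below voxel size: keep the single center voxel
    mask <- array(seq_len(prod(space$dims)) == which.min(d2),
                  dim = space$dims)
  }
  mask
}

#' Mean distance of a tumor to a target
#'
#' @param lesion Nonempty logical lesion mask.
#' @param dist_map Distance map from [distance_map()].
#' @return Mean of the distance map over lesion voxels (mm).
#' @export
mean_tumor_distance <- function(lesion, dist_map) {
  stopifnot(identical(dim(lesion), dim(dist_map)))
  if (!any(lesion)) stop("empty lesion mask")
  mean(dist_map[lesion])
}

#' Per-patient tumor-location feature table
#'
#' Assembles, for every patient: tumor volume (cm^3); overlap volume and
#' proportion with the predilection mask, ROI1 and ROI2; and mean mm
#' distance to the ROI1 center mask, ROI2 center mask and SVZ (ventricle
#' mask).  Distances to ROI centers use spheres at the ROI mass centers
#' (see [roi_center_mask()]).  If an ROI is empty its columns are filled
#' with `NA` and flagged in the `"empty_rois"` attribute.
#'
#' @param cohort A [lesion_cohort()].
#' @param predilection Predilection mask (logical array or
#'   `predilection_mask`).
#' @param roi1,roi2 Logical ROI masks (possibly empty).
#' @param svz_mask Logical ventricle mask (defaults to the space's).
#' @param radius_mm Radius of the ROI center spheres.
#' @return Data.frame with one row per patient.
#' @export
build_feature_table <- function(cohort, predilection, roi1, roi2,
                                svz_mask = cohort$space$ventricle_mask,
                                radius_mm = 2 * max(cohort$space$voxel_size)) {
  space <- cohort$space
  if (inherits(predilection, "predilection_mask")) {
    predilection <- predilection$mask
  }
  vox <- voxel_volume_cm3(space)
  targets <- list(pred = predilection, roi1 = roi1, roi2 = roi2)
  empty <- names(targets)[!vapply(targets, any, logical(1))]
  if (length(empty) > 0) {
    gf_log("build_feature_table: empty ROI(s): %s",
           paste(empty, collapse = ", "))
  }
  dmaps <- list(
    roi1 = if (any(roi1)) distance_map(space, roi_center_mask(roi1, space,
                                                              radius_mm)),
    roi2 = if (any(roi2)) distance_map(space, roi_center_mask(roi2, space,
                                                              radius_mm)),
    svz = distance_map(space, svz_mask)
  )
  ids <- cohort$records$patient_id
  one <- function(id) {
    m <- cohort$masks[[id]]
    ov <- lapply(targets, function(tg) {
      if (any(tg)) overlap_metrics(m, tg, space) else
        list(overlap_volume_cm3 = NA_real_, overlap_proportion = NA_real_)
    })
    data.frame(
      patient_id = id,
      tumor_volume_cm3 = sum(m) * vox,
      overlap_pred_cm3 = ov$pred$overlap_volume_cm3,
      overlap_pred_prop = ov$pred$overlap_proportion,
      overlap_roi1_cm3 = ov$roi1$overlap_volume_cm3,
      overlap_roi1_prop = ov$roi1$overlap_proportion,
      overlap_roi2_cm3 = ov$roi2$overlap_volume_cm3,
      overlap_roi2_prop = ov$roi2$overlap_proportion,
      dist_roi1_mm = if (is.null(dmaps$roi1)) NA_real_ else
        mean_tumor_distance(m, dmaps$roi1),
      dist_roi2_mm = if (is.null(dmaps$roi2)) NA_real_ else
        mean_tumor_distance(m, dmaps$roi2),
      dist_svz_mm = mean_tumor_distance(m, dmaps$svz),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(ids, one))
  rownames(out) <- NULL
  attr(out, "empty_rois") <- empty
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right-censoring; the curve starts at
#' survival 1 at time 0.
#'
#' @param times Nonnegative survival times.
#' @param events Event indicators (1 died, 0 censored).
#' @return Data.frame with `time` and `surv` columns (step function,
#'   including the leading `(0, 1)` point).
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(all(times >= 0), length(events) == length(times))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic with simultaneous risk sets at
#' tied event times, on one degree of freedom.
#'
#' @param times_a,events_a Times and event flags for group A.
#' @param times_b,events_b Times and event flags for group B.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be nonempty")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("no events in either group: log-rank undefined")
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = unname(sd$chisq), p = pchisq(sd$chisq, df = 1,
                                           lower.tail = FALSE))
}

#' Top- and bottom-quartile groups of a feature
#'
#' Splits patients at the first and third quartiles (linear-interpolation,
#' type-7 quantiles): the top group has values `>= Q3`, the bottom group
#' `<= Q1`.  Ties at a boundary are included in the corresponding group
#' (and logged when they inflate the group beyond 25%).
#'
#' @param feature Named per-patient numeric vector (at least 8 patients,
#'   non-constant); names are patient ids.
#' @return List with `top` and `bottom` character vectors of patient ids.
#' @export
quartile_groups <- function(feature) {
  stopifnot(!is.null(names(feature)))
  n <- length(feature)
  if (n < 8) stop("need at least 8 patients for quartile groups")
  if (sd(feature) == 0) stop("constant feature: quartiles undefined")
  qs <- quantile(feature, c(0.25, 0.75), type = 7, names = FALSE)
  top <- names(feature)[feature >= qs[2]]
  bottom <- names(feature)[feature <= qs[1]]
  if (length(top) > ceiling(n / 4) || length(bottom) > ceiling(n / 4)) {
    gf_log("quartile_groups: boundary ties inflate groups to %d/%d of %d",
           length(top), length(bottom), n)
  }
  list(top = top, bottom = bottom)
}

#' Fixed-coefficient gene-expression risk model
#'
#' The default model is the published six-gene GBM prognostic signature
#' fitted by LASSO-selected Cox regression on TCGA-GBM expression:
#' `risk score = 0.1507*SNCB - 0.2949*GRIN1 + 0.0044*HPCA + 0.1415*CPNE6 +
#' 0.2997*GABRD - 0.081*ATP2B3`.  The score is a linear combination of
#' expression values and is agnostic to the expression scale (raw or
#' log-scale), which simply rescales the score distribution.
#'
#' @param coefficients Named numeric vector of gene coefficients; the
#'   default is the six-gene model above.
#' @return A `risk_model` (named coefficient vector).
#' @export
risk_model <- function(coefficients = c(SNCB = 0.1507, GRIN1 = -0.2949,
                                        HPCA = 0.0044, CPNE6 = 0.1415,
                                        GABRD = 0.2997, ATP2B3 = -0.081)) {
  if (length(coefficients) == 0 || is.null(names(coefficients))) {
    stop("risk model needs a nonempty named coefficient vector")
  }
  structure(coefficients, class = "risk_model")
}

#' Per-patient risk score
#'
#' `risk score = sum(coefficient * gene expression)` over the model's
#' genes.
#'
#' @param expression Patients x genes numeric matrix or data.frame with
#'   gene-id column names.
#' @param model A [risk_model()] (default: the six-gene model).
#' @return Numeric per-patient score vector (named by rownames of
#'   `expression` if present).
#' @export
risk_score <- function(expression, model = risk_model()) {
  expression <- as.matrix(expression)
  missing_genes <- setdiff(names(model), colnames(expression))
  if (length(missing_genes) > 0) {
    stop("expression is missing model gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  as.numeric(expression[, names(model), drop = FALSE] %*%
               as.numeric(model))
}

#' Median split of risk scores
#'
#' Scores strictly above the median form the high-risk group; scores at or
#' below it the low-risk group, so ties at the median land deterministically
#' in the low group.  With distinct scores the group sizes differ by at
#' most 1.
#'
#' @param scores Named numeric score vector.
#' @return List with `high` and `low` character vectors of names, plus
#'   `median`.
#' @export
median_split <- function(scores) {
  stopifnot(!is.null(names(scores)))
  med <- median(scores)
  list(high = names(scores)[scores > med],
       low = names(scores)[scores <= med],
       median = med)
}

#' Time-dependent AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Area under the time-dependent ROC curve at a horizon: cases are
#' patients with an observed event by the horizon, controls those still at
#' risk beyond it, weighted by inverse probability of censoring from the
#' Kaplan-Meier estimator of the censoring distribution.  With no
#' censoring this reduces to the plain rank-sum AUC of the indicator
#' `T <= horizon`.
#'
#' @param scores Per-patient risk scores (higher = higher risk).
#' @param times Observed survival times (months).
#' @param events Event flags (1 died, 0 censored).
#' @param horizon_months Evaluation horizon (e.g. 12 or 36).
#' @return Scalar AUC.
#' @export
time_dependent_auc <- function(scores, times, events, horizon_months) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  is_case <- times <= horizon_months & events == 1
  is_ctrl <- times > horizon_months
  if (!any(is_case)) stop("no cases by the horizon")
  if (!any(is_ctrl)) stop("no controls at the horizon")
  # censoring survivor function G(t) by Kaplan-Meier on the censoring times
  cfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  g_case <- vapply(times[is_case], function(t) {
    gv <- G(t - 1e-9)  # left limit G(t-)
    if (gv <= 0) NA_real_ else gv
  }, numeric(1))
  g_ctrl <- G(horizon_months)
  if (is.na(g_ctrl) || g_ctrl <= 0) stop("censoring weight at horizon is zero")
  w_case <- 1 / g_case
  w_case[is.na(w_case)] <- 0
  w_ctrl <- rep(1 / g_ctrl, sum(is_ctrl))
  sc <- scores[is_case]
  sk <- scores[is_ctrl]
  num <- 0
  for (i in seq_along(sc)) {
    num <- num + w_case[i] * sum(w_ctrl * ((sc[i] > sk) + 0.5 * (sc[i] == sk)))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Quartile-group log-rank survival comparison
#'
#' Convenience wrapper: split patients into top and bottom quartile groups
#' of a location feature and compare their survival with the log-rank test.
#'
#' @param feature Named per-patient feature vector.
#' @param records Clinical data.frame with `patient_id`, `survival_time`,
#'   `event`.
#' @return List with `groups` (from [quartile_groups()]), `chi2`, `p`.
#' @export
quartile_logrank <- function(feature, records) {
  rownames(records) <- records$patient_id
  keep <- names(feature)[names(feature) %in% records$patient_id &
                           !is.na(records[names(feature), "survival_time"]) &
                           !is.na(records[names(feature), "event"])]
  if (length(keep) < length(feature)) {
    gf_log("quartile_logrank: excluding %d patients with missing survival",
           length(feature) - length(keep))
  }
  grp <- quartile_groups(feature[keep])
  a <- records[grp$top, ]
  b <- records[grp$bottom, ]
  lr <- logrank_test(a$survival_time, a$event, b$survival_time, b$event)
  c(list(groups = grp), lr)
}
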