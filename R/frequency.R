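#' Voxelwise tumor frequency map
#'
#' The frequency map of a cohort (optionally restricted to a grade subset)
#' is, at each voxel, the proportion of patients whose lesion mask covers
#' that voxel: the sum of binary lesion masks divided by the number of
#' patients.
#'
#' @param cohort A [lesion_cohort()].
#' @param grades Optional character vector of grades defining the subset
#'   (`NULL` uses every patient).
#' @return A `frequency_map` with fields `space`, `values` (3-D array in
#'   \[0, 1\]) and `n_patients`.
#' @export
build_frequency_map <- function(cohort, grades = NULL) {
  sub <- if (is.null(grades)) cohort else subset_cohort(cohort, grades = grades)
  n <- cohort_size(sub)
  acc <- array(0, dim = sub$space$dims)
  for (m in sub$masks) acc <- acc + m
  gf_log("build_frequency_map: %d patients, %d lesioned voxels",
         n, sum(acc > 0))
  structure(list(space = sub$space, values = acc / n, n_patients = n),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> n=%d patients, %d nonzero voxels, max %.3f\n",
              x$n_patients, sum(x$values > 0), max(x$values)))
  invisible(x)
}

#' Predilection-site mask: top fraction of the frequency map
#'
#' Selects the `ceiling(q * V)` highest-valued voxels among the V voxels
#' with nonzero frequency (with `q = 0.10`, the "top 10%" predilection
#' site).  All voxels tied with the cutoff value are included, so the
#' realized fraction can exceed `q`; the base set is the nonzero-frequency
#' voxels, not the whole brain, so the mask does not depend on brain-mask
#' size.  Set `base = "brain"` to take the fraction over all brain voxels
#' instead.
#'
#' @param fmap A `frequency_map` with at least 10 nonzero voxels.
#' @param q Fraction in (0, 1], default 0.10.
#' @param base `"nonzero"` (default) or `"brain"`.
#' @return A `predilection_mask` with fields `space`, `mask`, `fraction_q`.
#' @export
top_fraction_mask <- function(fmap, q = 0.10, base = c("nonzero", "brain")) {
  base <- match.arg(base)
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  vals <- fmap$values
  idx <- if (base == "nonzero") which(vals > 0) else which(fmap$space$brain_mask)
  if (base == "nonzero" && length(idx) < 10) {
    stop("fewer than 10 nonzero voxels")
  }
  k <- ceiling(q * length(idx))
  v <- vals[idx]
  cutoff <- sort(v, decreasing = TRUE)[k]
  sel <- idx[v >= cutoff]
  if (length(sel) > k) {
    gf_log("top_fraction_mask: ties at cutoff, realized fraction %.4f > q=%.4f",
           length(sel) / length(idx), q)
  }
  mask <- array(FALSE, dim = fmap$space$dims)
  mask[sel] <- TRUE
  structure(list(space = fmap$space, mask = mask, fraction_q = q,
                 cutoff = cutoff),
            class = "predilection_mask")
}

#' Overlap of a lesion with a target mask
#'
#' @param lesion Nonempty logical lesion mask.
#' @param target Logical target mask (e.g. a predilection mask's `mask`).
#' @param space A [brain_space()] shared by both masks.
#' @param denominator `"lesion"` (default: the individual tumor's volume) or
#'   `"target"`.
#' @return List with `overlap_volume_cm3` and `overlap_proportion`.
#' @export
overlap_metrics <- function(lesion, target, space,
                            denominator = c("lesion", "target")) {
  denominator <- match.arg(denominator)
  stopifnot(identical(dim(lesion), space$dims),
            identical(dim(target), space$dims))
  n_lesion <- sum(lesion)
  if (n_lesion == 0) stop("empty lesion mask")
  n_int <- sum(lesion & target)
  denom <- if (denominator == "lesion") n_lesion else sum(target)
  list(overlap_volume_cm3 = n_int * voxel_volume_cm3(space),
       overlap_proportion = n_int / denom)
}

#' Rank patients by overlap with a target mask
#'
#' Orders patients by descending overlap volume or proportion with a target
#' mask (ties broken deterministically by `patient_id`) and flags the top
#' and bottom 20%.
#'
#' @param cohort A [lesion_cohort()] with at least 5 patients.
#' @param target Logical target mask.
#' @param metric `"volume"` or `"proportion"`.
#' @param fraction Flagged fraction at each end, default 0.20.
#' @return Data.frame with `patient_id`, `value`, `rank`, `top`, `bottom`,
#'   ordered by descending value.
#' @export
rank_by_overlap <- function(cohort, target, metric = c("volume", "proportion"),
                            fraction = 0.20) {
  metric <- match.arg(metric)
  n <- cohort_size(cohort)
  if (n < 5) stop("need at least 5 patients to rank")
  vals <- vapply(cohort$records$patient_id, function(id) {
    om <- overlap_metrics(cohort$masks[[id]], target, cohort$space)
    if (metric == "volume") om$overlap_volume_cm3 else om$overlap_proportion
  }, numeric(1))
  ord <- order(-vals, cohort$records$patient_id)
  k <- ceiling(fraction * n)
  out <- data.frame(
    patient_id = cohort$records$patient_id[ord],
    value = unname(vals[ord]),
    rank = seq_len(n),
    top = c(rep(TRUE, k), rep(FALSE, n - k)),
    bottom = c(rep(FALSE, n - k), rep(TRUE, k)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Parcellate a voxel map to a regional vector
#'
#' Averages a 3-D map over each parcellation region, producing the R-vector
#' used by the regional (transcriptomic / receptor) analyses.
#'
#' @param map Numeric 3-D array on `space` (or a `frequency_map`).
#' @param space A [brain_space()].
#' @return Named numeric vector of per-region means, length R.
#' @export
parcellate <- function(map, space = NULL) {
  if (inherits(map, "frequency_map")) {
    space <- map$space
    map <- map$values
  }
  stopifnot(!is.null(space), identical(dim(map), space$dims))
  labs <- space$parcellation[space$brain_mask]
  vals <- map[space$brain_mask]
  counts <- tabulate(labs, nbins = n_regions(space))
  if (any(counts == 0)) {
    stop("parcellation region(s) with zero voxels: ",
         paste(which(counts == 0), collapse = ", "))
  }
  out <- as.numeric(rowsum(vals, labs)) / counts
  names(out) <- as.character(seq_len(n_regions(space)))
  out
}
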