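#' Clinical record table schema
#'
#' Clinical tables carry one row per patient with columns `patient_id`,
#' `age` (years), `sex` (`"male"`/`"female"`), `kps` (Karnofsky Performance
#' Status, 0-100), `grade` (`"GBM"`, `"astrocytoma"`, `"oligodendroglioma"`),
#' `survival_time` (months), `event` (1 = died, 0 = censored) and
#' `dataset_id`.  Missing values are allowed and flagged, never silently
#' dropped; each analysis stage works on its own complete-case subset.
#'
#' @param records A data.frame to validate/coerce.
#' @return The validated data.frame with a logical `complete` column
#'   flagging rows with all required fields present.
#' @export
clinical_records <- function(records) {
  required <- c("patient_id", "age", "sex", "kps", "grade",
                "survival_time", "event", "dataset_id")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  records$patient_id <- as.character(records$patient_id)
  if (anyDuplicated(records$patient_id)) {
    stop("duplicate patient_id in clinical table: ",
         paste(unique(records$patient_id[duplicated(records$patient_id)]),
               collapse = ", "))
  }
  ok_grade <- records$grade %in%
    c("GBM", "astrocytoma", "oligodendroglioma") | is.na(records$grade)
  if (!all(ok_grade)) stop("grade outside {GBM, astrocytoma, oligodendroglioma}")
  ok_sex <- records$sex %in% c("male", "female") | is.na(records$sex)
  if (!all(ok_sex)) stop("sex outside {male, female}")
  if (any(records$survival_time < 0, na.rm = TRUE)) {
    stop("negative survival_time")
  }
  if (any(records$kps < 0 | records$kps > 100, na.rm = TRUE)) {
    stop("kps outside [0, 100]")
  }
  if (!all(records$event %in% c(0, 1) | is.na(records$event))) {
    stop("event must be 0 or 1")
  }
  records$complete <- stats::complete.cases(records[required])
  gf_log("clinical table: %d rows, %d complete", nrow(records),
         sum(records$complete))
  records
}

#' Construct a lesion cohort
#'
#' Pairs per-patient binary lesion masks with clinical records on one
#' reference space.  Masks and records are aligned one-to-one by
#' `patient_id`; each mask must be nonempty and contained in the brain mask.
#'
#' @param space A [brain_space()].
#' @param masks Named list of logical 3-D arrays (names are patient ids).
#' @param records Clinical data.frame (see [clinical_records()]).
#' @return An object of class `lesion_cohort`.
#' @export
lesion_cohort <- function(space, masks, records) {
  records <- clinical_records(records)
  if (is.null(names(masks)) || !setequal(names(masks), records$patient_id)) {
    stop("mask names must match clinical patient_id one-to-one")
  }
  masks <- masks[records$patient_id]
  for (id in names(masks)) {
    m <- masks[[id]]
    if (!identical(dim(m), space$dims)) {
      stop(sprintf("mask for patient %s does not match space dims", id))
    }
    if (!any(m)) stop(sprintf("mask for patient %s is empty", id))
    n_out <- sum(m & !space$brain_mask)
    if (n_out > 0) {
      stop(sprintf("mask for patient %s has %d voxels outside brain_mask",
                   id, n_out))
    }
  }
  structure(list(space = space, masks = masks, records = records),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  tab <- table(factor(x$records$grade,
                      c("GBM", "astrocytoma", "oligodendroglioma")))
  cat(sprintf("<lesion_cohort> %d patients (GBM %d, astro %d, oligo %d)\n",
              nrow(x$records), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A [lesion_cohort()].
#' @return Integer patient count.
#' @export
cohort_size <- function(cohort) nrow(cohort$records)

#' Subset a cohort by patient id or grade
#'
#' @param cohort A [lesion_cohort()].
#' @param ids Character vector of patient ids to keep, or `NULL`.
#' @param grades Character vector of grades to keep (e.g. `"GBM"` or
#'   `c("astrocytoma", "oligodendroglioma")`), or `NULL`.
#' @return A new, smaller [lesion_cohort()].
#' @export
subset_cohort <- function(cohort, ids = NULL, grades = NULL) {
  keep <- rep(TRUE, cohort_size(cohort))
  if (!is.null(grades)) keep <- keep & cohort$records$grade %in% grades
  if (!is.null(ids)) keep <- keep & cohort$records$patient_id %in% ids
  if (!any(keep)) stop("cohort subset is empty")
  rec <- cohort$records[keep, , drop = FALSE]
  rec$complete <- NULL
  rownames(rec) <- NULL
  lesion_cohort(cohort$space, cohort$masks[rec$patient_id], rec)
}

# ---------------------------------------------------------------------------
# NIfTI readers/writers (RNifti behind the scenes)

nifti_template <- function(arr, space) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- space$voxel_size
  img
}

#' Write a binary mask as NIfTI-1
#' @param mask Logical 3-D array on `space`.
#' @param space A [brain_space()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, space, path) {
  stopifnot(identical(dim(mask), space$dims))
  arr <- array(as.integer(mask), dim = space$dims)
  RNifti::writeNifti(nifti_template(arr, space), path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#' @param path Input path.
#' @param space A [brain_space()]; dimensions are checked.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path, space) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!identical(dim(arr), space$dims)) {
    stop(sprintf("mask %s has dims %s, expected %s", path,
                 paste(dim(arr), collapse = "x"),
                 paste(space$dims, collapse = "x")))
  }
  array(arr != 0, dim = space$dims)
}

#' Write a real-valued map (frequency, t, distance) as NIfTI-1
#' @inheritParams write_mask
#' @param map Numeric 3-D array on `space`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, space, path) {
  stopifnot(identical(dim(map), space$dims))
  RNifti::writeNifti(nifti_template(map, space), path, datatype = "double")
  invisible(path)
}

#' Read a real-valued map from NIfTI-1
#' @inheritParams read_mask
#' @return Numeric 3-D array.
#' @export
read_map <- function(path, space) {
  arr <- as.array(RNifti::readNifti(path))
  if (!identical(dim(arr), space$dims)) {
    stop(sprintf("map %s has dims %s, expected %s", path,
                 paste(dim(arr), collapse = "x"),
                 paste(space$dims, collapse = "x")))
  }
  array(as.numeric(arr), dim = space$dims)
}

#' Write a cohort to a directory
#'
#' Masks go to `<dir>/masks/<patient_id>.nii.gz`, the clinical table to
#' `<dir>/clinical.csv`.
#'
#' @param cohort A [lesion_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$records$patient_id) {
    write_mask(cohort$masks[[id]], cohort$space,
               file.path(mask_dir, paste0(id, ".nii.gz")))
  }
  rec <- cohort$records
  rec$complete <- NULL
  write.csv(rec, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from masks and a clinical table
#'
#' Every clinical row must have a mask file named `<patient_id>.nii.gz` (or
#' `.nii`) under `mask_dir`; all masks must share the space's grid.
#' Dimension mismatches and duplicate ids are hard errors naming the
#' offender; rows with missing clinical fields are flagged in the `complete`
#' column, not dropped.
#'
#' @param mask_dir Directory of per-patient mask NIfTIs.
#' @param clinical_table Path to the clinical CSV.
#' @param space A [brain_space()].
#' @return A [lesion_cohort()].
#' @export
read_cohort <- function(mask_dir, clinical_table, space) {
  records <- read.csv(clinical_table, stringsAsFactors = FALSE)
  records$patient_id <- as.character(records$patient_id)
  masks <- list()
  for (id in records$patient_id) {
    path <- file.path(mask_dir, paste0(id, ".nii.gz"))
    if (!file.exists(path)) path <- file.path(mask_dir, paste0(id, ".nii"))
    if (!file.exists(path)) stop("no mask file for patient ", id)
    masks[[id]] <- read_mask(path, space)
  }
  gf_log("read cohort: %d patients from %s", length(masks), mask_dir)
  lesion_cohort(space, masks, records)
}

# ---------------------------------------------------------------------------
# Run configuration

#' Read / write a run configuration
#'
#' A single flat key-value YAML file holds seeds, thresholds and permutation
#' counts for a pipeline run, so a run is reproducible from its config copy.
#'
#' @param path Config file path.
#' @param config Named list of scalar values.
#' @return `read_run_config` returns the named list; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Contingency statistics

#' Pearson chi-square test for a 2x2 contingency table
#'
#' The uncorrected Pearson chi-square on one degree of freedom, as used for
#' baseline-characteristics tables comparing GBM against LGG (no Yates
#' continuity correction).
#'
#' @param tab 2x2 matrix of nonnegative integer counts; all four marginals
#'   must be positive.
#' @return List with `statistic` (chi-square) and `p_value` (upper tail,
#'   1 df).
#' @examples
#' chi_square_2x2(matrix(c(117, 87, 86, 85), nrow = 2))
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: zero marginal")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}
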