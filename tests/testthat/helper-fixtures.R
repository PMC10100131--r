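# Shared fixtures: small hand-built spaces and cohorts, constructed in code.

# A fully rectangular "brain" where geometry is easy to reason about:
# brain mask everywhere, parcellation in four slabs along x, a small
# central ventricle box.
cube_space <- function(dims = c(12, 12, 12), voxel = c(1, 1, 1)) {
  dims <- as.integer(dims)
  brain <- array(TRUE, dims)
  parc <- array(0L, dims)
  slab <- ceiling(seq_len(dims[1]) / (dims[1] / 4))
  for (x in seq_len(dims[1])) parc[x, , ] <- slab[x]
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  mm <- sweep(idx, 2L, voxel, `*`)
  centroids <- t(vapply(1:4, function(r) {
    colMeans(mm[as.vector(parc) == r, , drop = FALSE])
  }, numeric(3)))
  vent <- array(FALSE, dims)
  mid <- pmax(dims %/% 2, 1L)
  vent[mid[1] + (0:1), mid[2] + (0:1), mid[3] + (0:1)] <- TRUE
  brain_space(dims, voxel, c(0, 0, 0), brain, parc, centroids, vent)
}

# Axis-aligned box mask given inclusive 1-based index ranges.
box_mask <- function(space, xr, yr, zr) {
  m <- array(FALSE, space$dims)
  m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  m
}

# Minimal clinical table for n patients.
toy_records <- function(n, grade = "GBM", seed = 1) {
  withr::with_seed(seed, data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = round(stats::runif(n, 30, 80), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    kps = sample(seq(40, 100, 10), n, replace = TRUE),
    grade = rep_len(grade, n),
    survival_time = round(stats::rexp(n, 1 / 15), 2),
    event = stats::rbinom(n, 1, 0.8),
    dataset_id = "d1",
    stringsAsFactors = FALSE
  ))
}

# Cohort of random box lesions on a cube space.
toy_cohort <- function(n = 6, space = cube_space(), grade = "GBM", seed = 1) {
  rec <- toy_records(n, grade = grade, seed = seed)
  masks <- withr::with_seed(seed + 100, lapply(seq_len(n), function(i) {
    lo <- sapply(space$dims, function(d) sample.int(d - 3, 1))
    box_mask(space, c(lo[1], lo[1] + 2), c(lo[2], lo[2] + 2),
             c(lo[3], lo[3] + 2))
  }))
  names(masks) <- rec$patient_id
  lesion_cohort(space, masks, rec)
}

# One shared synthetic world for tests that need a realistic space/field.
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- make_brain_space(c(16, 16, 16), voxel_size = c(3, 3, 3),
                             n_regions = 8, seed = 42)
      fld <- make_occurrence_field(sp, n_foci = 2, autocorr_length = 12,
                                   seed = 2)
      cache <<- list(space = sp, field = fld)
    }
    cache
  }
})
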