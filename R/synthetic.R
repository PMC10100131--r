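#' Simulation configuration for synthetic cohorts
#'
#' Bundles every generative parameter of [sample_cohort()].  Defaults follow
#' the pooled marginals of a typical multi-center glioma series: 396 GBM and
#' 190 LGG patients, log-normal lesion volumes with mean about 30 cm^3,
#' male fraction 0.54, KPS approximately normal (mean 82, sd 14), GBM ages
#' around 60 years and LGG around 43, and exponential survival with median
#' overall survival near 14 months for GBM and several times longer for LGG.
#'
#' @param n_gbm,n_lgg Patient counts per grade group.
#' @param volume_lognormal `(mu, sigma)` of log lesion volume in cm^3.
#' @param grade_location_beta Log-odds increase of GBM per mm closer to the
#'   ventricles; positive values pull GBM lesions toward the SVZ.
#' @param survival_betas Named coefficients of the log-hazard on centered
#'   `(volume, distance, age)` where `distance` is the mean lesion-to-SVZ
#'   distance in mm.
#' @param censor_rate Fraction of patients independently right-censored.
#' @param n_genes,n_assoc_genes Total genes and planted frequency-associated
#'   genes in [make_expression()].
#' @param assoc_effect Correlation of planted genes with regional frequency.
#' @param autocorr_length Spatial autocorrelation length scale, mm.
#' @param seed Master RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_gbm = 396, n_lgg = 190,
                              volume_lognormal = c(mu = 3.1, sigma = 0.75),
                              grade_location_beta = 0.05,
                              survival_betas = c(volume = 0.02,
                                                 distance = -0.04,
                                                 age = 0.02),
                              censor_rate = 0.2,
                              n_genes = 1000, n_assoc_genes = 20,
                              assoc_effect = 0.5,
                              autocorr_length = 10,
                              seed = 1L) {
  stopifnot(n_gbm > 0, n_lgg > 0,
            censor_rate >= 0, censor_rate < 1,
            abs(assoc_effect) < 1,
            n_assoc_genes <= n_genes,
            autocorr_length > 0)
  structure(list(
    n_gbm = as.integer(n_gbm), n_lgg = as.integer(n_lgg),
    volume_lognormal = volume_lognormal,
    grade_location_beta = grade_location_beta,
    survival_betas = survival_betas,
    censor_rate = censor_rate,
    n_genes = as.integer(n_genes),
    n_assoc_genes = as.integer(n_assoc_genes),
    assoc_effect = assoc_effect,
    autocorr_length = autocorr_length,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Build a toy brain space
#'
#' Constructs an ellipsoidal brain mask, a parcellation of exactly
#' `n_regions` contiguous regions (Voronoi cells of seeded points, which are
#' convex and hence connected inside the convex brain mask), and two
#' ellipsoidal lateral ventricles.  Deterministic given `seed`.
#'
#' @param dims Integer triple, each at least 16.
#' @param voxel_size mm triple (default 2 mm isotropic).
#' @param n_regions Number of parcellation regions, at least 4.
#' @param seed RNG seed.
#' @return A [brain_space()].
#' @export
make_brain_space <- function(dims, voxel_size = c(2, 2, 2), n_regions = 60,
                             seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 16L), n_regions >= 4L)
  origin <- c(0, 0, 0)
  extent <- (dims - 1) * voxel_size
  center <- extent / 2

  skeleton <- structure(list(
    dims = dims, voxel_size = as.numeric(voxel_size), origin = origin
  ), class = "brain_space")
  xyz <- voxel_grid_mm(skeleton)
  rel <- sweep(xyz, 2L, center, `-`)

  semi <- 0.45 * extent
  brain <- array(rowSums(sweep(rel, 2L, semi, `/`)^2) <= 1, dim = dims)
  n_in <- sum(brain)
  if (n_regions > n_in) {
    stop(sprintf("n_regions (%d) exceeds the %d in-mask voxels",
                 n_regions, n_in))
  }

  # two lateral ventricles: elongated ellipsoids offset left/right of midline
  vent <- array(FALSE, dim = dims)
  vsemi <- pmax(c(0.06, 0.22, 0.10) * extent, 1.5 * voxel_size)
  for (s in c(-1, 1)) {
    vcen <- center + c(s * 0.13 * extent[1], 0, 0.05 * extent[3])
    relv <- sweep(xyz, 2L, vcen, `-`)
    vent <- vent | array(rowSums(sweep(relv, 2L, vsemi, `/`)^2) <= 1,
                         dim = dims)
  }
  vent <- vent & brain

  with_seed(seed, {
    in_idx <- which(brain)
    seeds <- sample(in_idx, n_regions)
    seed_xyz <- xyz[seeds, , drop = FALSE]
    # nearest-seed (Voronoi) assignment in world mm
    lab <- integer(n_in)
    best <- rep(Inf, n_in)
    in_xyz <- xyz[in_idx, , drop = FALSE]
    for (r in seq_len(n_regions)) {
      d2 <- (in_xyz[, 1] - seed_xyz[r, 1])^2 +
            (in_xyz[, 2] - seed_xyz[r, 2])^2 +
            (in_xyz[, 3] - seed_xyz[r, 3])^2
      upd <- d2 < best
      lab[upd] <- r
      best[upd] <- d2[upd]
    }
    parc <- array(0L, dim = dims)
    parc[in_idx] <- lab
    centroids <- t(vapply(seq_len(n_regions), function(r) {
      colMeans(in_xyz[lab == r, , drop = FALSE])
    }, numeric(3)))
    gf_log("make_brain_space: seed %d, %d regions, %d brain voxels",
           seed, n_regions, n_in)
    brain_space(dims, voxel_size, origin, brain, parc, centroids, vent)
  })
}

#' Smooth multi-focal lesion occurrence field
#'
#' A nonnegative relative lesion-seed propensity: the sum of isotropic
#' Gaussian kernels (scale `autocorr_length` mm) centered on `n_foci` voxels
#' drawn uniformly inside the brain mask, zeroed outside the mask and
#' normalized to sum to one.  Emulates the smooth spatial predilection that
#' concentrates tumor occurrence in a handful of hotspots.
#'
#' @param space A [brain_space()].
#' @param n_foci Number of Gaussian foci, at least 1.
#' @param autocorr_length Kernel scale in mm, positive.
#' @param seed RNG seed.
#' @return An `occurrence_field` with fields `space` and `intensity`.
#' @export
make_occurrence_field <- function(space, n_foci = 3, autocorr_length = 12,
                                  seed = 1L) {
  stopifnot(n_foci >= 1)
  if (autocorr_length <= 0) stop("autocorr_length must be positive")
  xyz <- voxel_grid_mm(space)
  in_idx <- which(space$brain_mask)
  with_seed(seed, {
    foci <- sample(in_idx, n_foci, replace = n_foci > length(in_idx))
    intensity <- numeric(prod(space$dims))
    for (f in foci) {
      d2 <- (xyz[, 1] - xyz[f, 1])^2 + (xyz[, 2] - xyz[f, 2])^2 +
            (xyz[, 3] - xyz[f, 3])^2
      intensity <- intensity + exp(-d2 / (2 * autocorr_length^2))
    }
    intensity[-in_idx] <- 0
    intensity <- intensity / sum(intensity)
    structure(list(space = space,
                   intensity = array(intensity, dim = space$dims),
                   foci = foci),
              class = "occurrence_field")
  })
}

#' Sample a single connected lesion mask
#'
#' Draws a seed voxel with probability proportional to the occurrence field,
#' then grows the lesion by stochastic dilation (each boundary voxel accepted
#' with probability proportional to the field), restricted to the brain mask,
#' until the target volume is reached.  The result is 6-connected and within
#' one voxel of the target volume.
#'
#' @param space A [brain_space()].
#' @param field An `occurrence_field` (or bare intensity array).
#' @param target_volume_cm3 Target lesion volume in cm^3 (at least 1 voxel).
#' @param seed RNG seed.
#' @return Logical 3-D lesion mask.
#' @export
sample_lesion <- function(space, field, target_volume_cm3, seed = 1L) {
  intensity <- if (inherits(field, "occurrence_field")) field$intensity else field
  stopifnot(identical(dim(intensity), space$dims))
  n_target <- max(1L, as.integer(round(target_volume_cm3 /
                                         voxel_volume_cm3(space))))
  n_brain <- sum(space$brain_mask)
  if (n_target > n_brain) {
    stop(sprintf("target volume (%d voxels) exceeds brain volume (%d voxels)",
                 n_target, n_brain))
  }
  in_idx <- which(space$brain_mask)
  w <- intensity[in_idx] + 1e-12
  with_seed(seed, {
    seed_vox <- in_idx[sample.int(length(in_idx), 1L, prob = w)]
    .grow_lesion_cpp(as.numeric(intensity), space$brain_mask, space$dims,
                     seed_vox, n_target)
  })
}

#' Sample a full synthetic lesion cohort
#'
#' Generates grade labels by the configured counts, lesion masks grown from
#' grade-specific occurrence fields, demographics from the configured
#' marginal distributions, and exponential survival times whose log-hazard
#' is a linear function of centered lesion volume, mean SVZ distance and
#' age, with independent right-censoring at the configured rate.  A positive
#' `grade_location_beta` tilts the GBM field toward the ventricles by the
#' factor `exp(-beta * d_SVZ)`, so GBM lesions sit closer to the SVZ than
#' LGG lesions.
#'
#' @param space A [brain_space()].
#' @param field_gbm,field_lgg `occurrence_field`s for the two grade groups.
#' @param config A [simulation_config()].
#' @return A [lesion_cohort()] with attribute `"sim"` holding the SVZ
#'   distance map and per-patient true mean SVZ distances.
#' @export
sample_cohort <- function(space, field_gbm, field_lgg, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_gbm + config$n_lgg
  n_astro <- round(config$n_lgg * 115 / 190)
  grade <- c(rep("GBM", config$n_gbm), rep("astrocytoma", n_astro),
             rep("oligodendroglioma", config$n_lgg - n_astro))

  svz_dist <- distance_map(space, space$ventricle_mask)
  tilt <- function(intensity, sgn) {
    out <- intensity * exp(sgn * config$grade_location_beta * svz_dist)
    out[!space$brain_mask] <- 0
    out / sum(out)
  }
  f_gbm <- tilt(field_gbm$intensity, -1)
  f_lgg <- field_lgg$intensity

  seeds <- derive_seeds(config$seed, n + 1L)
  masks <- vector("list", n)
  vol_cm3 <- numeric(n)
  mean_svz <- numeric(n)
  demo <- with_seed(seeds[n + 1L], {
    vols <- rlnorm(n, config$volume_lognormal[["mu"]],
                   config$volume_lognormal[["sigma"]])
    vols <- pmin(vols, 0.25 * sum(space$brain_mask) * voxel_volume_cm3(space))
    age <- ifelse(grade == "GBM", rnorm(n, 60.02, 13.17),
                  rnorm(n, 43.29, 14.16))
    age <- round(pmin(pmax(age, 18), 90), 1)
    sex <- ifelse(runif(n) < 0.54, "male", "female")
    kps <- as.integer(pmin(pmax(round(rnorm(n, 82, 14) / 10) * 10, 40), 100))
    cens <- rbinom(n, 1, config$censor_rate)
    list(vols = vols, age = age, sex = sex, kps = kps, cens = cens)
  })

  for (i in seq_len(n)) {
    fld <- if (grade[i] == "GBM") f_gbm else f_lgg
    masks[[i]] <- sample_lesion(space, fld, demo$vols[i], seed = seeds[i])
    vol_cm3[i] <- sum(masks[[i]]) * voxel_volume_cm3(space)
    mean_svz[i] <- mean(svz_dist[masks[[i]]])
  }

  b <- config$survival_betas
  base_rate <- ifelse(grade == "GBM", log(2) / 14, log(2) / 14 * exp(-1.1))
  loghaz <- log(base_rate) +
    b[["volume"]] * (vol_cm3 - 25) +
    b[["distance"]] * (mean_svz - 20) +
    b[["age"]] * (demo$age - 55)
  surv <- with_seed((seeds[n + 1L] - 1L) %% (.Machine$integer.max - 1L) + 1L, {
    true_t <- rexp(n, exp(loghaz))
    obs_t <- ifelse(demo$cens == 1, runif(n) * true_t, true_t)
    list(obs_t = obs_t, event = 1L - demo$cens)
  })

  ids <- sprintf("P%04d", seq_len(n))
  names(masks) <- ids
  records <- data.frame(
    patient_id = ids,
    age = demo$age,
    sex = demo$sex,
    kps = demo$kps,
    grade = grade,
    survival_time = round(surv$obs_t, 2),
    event = surv$event,
    dataset_id = ifelse(seq_len(n) %% 7 == 0, "dataset2", "dataset1"),
    stringsAsFactors = FALSE
  )
  gf_log("sample_cohort: seed %d, n=%d (GBM %d / LGG %d), censor_rate %.2f",
         config$seed, n, config$n_gbm, config$n_lgg, config$censor_rate)
  cohort <- lesion_cohort(space, masks, records)
  attr(cohort, "sim") <- list(svz_dist = svz_dist, mean_svz = mean_svz,
                              config = config)
  cohort
}

#' Synthetic region-by-gene expression matrix
#'
#' Plants `n_assoc` genes equal to the effect-scaled standardized regional
#' frequency plus Gaussian noise; the remaining genes are spatially smooth
#' noise, obtained by kernel-smoothing independent region-level noise over
#' the region-centroid distance matrix at the configured length scale.  All
#' columns are z-scored.
#'
#' @param space A [brain_space()] supplying region centroids.
#' @param regional_frequency Vector of per-region tumor frequency (length R).
#' @param n_genes Total gene count.
#' @param n_assoc Number of planted associated genes (`<= n_genes`).
#' @param effect Correlation of planted genes with the frequency, in (-1, 1).
#' @param seed RNG seed.
#' @param autocorr_length Length scale (mm) of the smooth noise genes.
#' @return R x n_genes numeric matrix with gene-id column names and an
#'   attribute `"planted_genes"` naming the associated genes.
#' @export
make_expression <- function(space, regional_frequency, n_genes = 1000,
                            n_assoc = 20, effect = 0.5, seed = 1L,
                            autocorr_length = 10) {
  R <- length(regional_frequency)
  if (R < 4) stop("need at least 4 regions")
  stopifnot(R == n_regions(space), n_assoc <= n_genes, abs(effect) < 1)
  if (sd(regional_frequency) == 0 && effect != 0) {
    stop("constant regional frequency: planted association undefined")
  }
  zf <- if (sd(regional_frequency) > 0) {
    as.numeric(scale(regional_frequency))
  } else {
    numeric(R)
  }
  D <- as.matrix(dist(space$region_centroids))
  W <- exp(-D^2 / (2 * autocorr_length^2))
  W <- W / rowSums(W)
  with_seed(seed, {
    expr <- W %*% matrix(rnorm(R * n_genes), R, n_genes)
    planted <- sort(sample.int(n_genes, n_assoc))
    expr[, planted] <- effect * zf +
      sqrt(1 - effect^2) * matrix(rnorm(R * n_assoc), R, n_assoc)
    expr <- scale(expr)
    attr(expr, "scaled:center") <- NULL
    attr(expr, "scaled:scale") <- NULL
    colnames(expr) <- sprintf("gene%04d", seq_len(n_genes))
    rownames(expr) <- as.character(seq_len(R))
    attr(expr, "planted_genes") <- colnames(expr)[planted]
    gf_log("make_expression: seed %d, %d regions x %d genes, %d planted at effect %.2f",
           seed, R, n_genes, n_assoc, effect)
    expr
  })
}

#' Synthetic regional receptor map with controlled Spearman correlation
#'
#' Gaussian-copula construction: the frequency ranks are mapped to normal
#' scores and mixed with independent noise at the Pearson correlation
#' `2*sin(pi*rho/6)` that corresponds to the requested Spearman `rho` for a
#' bivariate normal.  Draws are retried (deterministically under `seed`)
#' until the realized Spearman correlation is within 0.075 of the target,
#' so the contract |observed - target| <= 0.1 holds for R >= 100.
#'
#' @param regional_frequency Non-constant vector of per-region frequency.
#' @param rho_target Target Spearman correlation, |rho| < 1.
#' @param seed RNG seed.
#' @return Numeric vector of length R.
#' @export
make_receptor_map <- function(regional_frequency, rho_target, seed = 1L) {
  R <- length(regional_frequency)
  stopifnot(abs(rho_target) < 1)
  if (sd(regional_frequency) == 0) {
    stop("constant regional frequency: correlation undefined")
  }
  r <- 2 * sin(pi * rho_target / 6)
  z1 <- qnorm((rank(regional_frequency) - 0.5) / R)
  with_seed(seed, {
    best <- NULL
    best_err <- Inf
    for (try in 1:50) {
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(R)
      err <- abs(cor(regional_frequency, z2, method = "spearman") - rho_target)
      if (err < best_err) {
        best <- z2
        best_err <- err
      }
      if (best_err <= 0.075) break
    }
    gf_log("make_receptor_map: seed %d, target %.2f, realized err %.3f",
           seed, rho_target, best_err)
    best
  })
}
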