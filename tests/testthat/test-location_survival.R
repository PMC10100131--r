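test_that("distance maps are exact against brute-force nearest-voxel search", {
  sp <- cube_space(dims = c(12, 12, 12), voxel = c(1, 2, 3))
  target <- withr::with_seed(5, {
    m <- array(FALSE, sp$dims)
    m[sample(prod(sp$dims), 6)] <- TRUE
    m
  })
  dm <- distance_map(sp, target)
  expect_true(all(dm[target] == 0))

  idx0 <- arrayInd(which(target), sp$dims) - 1L
  tmm <- sweep(idx0, 2L, sp$voxel_size, `*`)
  all0 <- arrayInd(seq_len(prod(sp$dims)), sp$dims) - 1L
  amm <- sweep(all0, 2L, sp$voxel_size, `*`)
  brute <- apply(amm, 1L, function(p) {
    sqrt(min(colSums((t(tmm) - p)^2)))
  })
  expect_equal(as.numeric(dm), brute, tolerance = 1e-9)

  # isotropic 2 mm: offset (1,2,2) from a lone target voxel is 6 mm
  sp2 <- cube_space(dims = c(12, 12, 12), voxel = c(2, 2, 2))
  lone <- array(FALSE, sp2$dims)
  lone[4, 4, 4] <- TRUE
  dm2 <- distance_map(sp2, lone)
  expect_equal(dm2[5, 6, 6], 6)
  expect_error(distance_map(sp2, array(FALSE, sp2$dims)), "empty")
})

test_that("ROI center masks sit at the brute-force mass center", {
  sp <- cube_space(dims = c(13, 13, 13), voxel = c(2, 2, 2))
  roi <- box_mask(sp, c(3, 7), c(3, 7), c(3, 7))  # symmetric cube
  cm <- roi_center_mask(roi, sp, radius_mm = 2)
  ctr <- which(cm)
  expect_true(cm[5, 5, 5])

  # center of mass equals the mean of voxel coordinates
  idx0 <- arrayInd(which(roi), sp$dims) - 1L
  expect_equal(round(colMeans(idx0)), c(4, 4, 4))

  # radius below the voxel size still yields a nonempty (single-voxel) mask
  tiny <- roi_center_mask(roi, sp, radius_mm = 0.5)
  expect_equal(sum(tiny), 1)
  expect_true(tiny[5, 5, 5])
  expect_error(roi_center_mask(array(FALSE, sp$dims), sp), "empty")
})

test_that("mean tumor distance averages the distance map over the lesion", {
  sp <- cube_space(voxel = c(2, 2, 2))
  target <- box_mask(sp, c(1, 4), c(1, 4), c(1, 4))
  dm <- distance_map(sp, target)
  inside <- box_mask(sp, c(2, 3), c(2, 3), c(2, 3))
  expect_equal(mean_tumor_distance(inside, dm), 0)
  lone <- array(FALSE, sp$dims)
  lone[9, 9, 9] <- TRUE
  expect_equal(mean_tumor_distance(lone, dm), dm[9, 9, 9])
  rnd <- box_mask(sp, c(5, 9), c(2, 8), c(3, 6))
  expect_equal(mean_tumor_distance(rnd, dm),
               sum(dm[rnd]) / sum(rnd), tolerance = 1e-12)
})

test_that("the feature table composes the per-operation metrics verbatim", {
  co <- toy_cohort(n = 5, seed = 12)
  sp <- co$space
  pred <- box_mask(sp, c(1, 6), c(1, 6), c(1, 6))
  roi1 <- box_mask(sp, c(2, 5), c(2, 5), c(2, 5))
  roi2 <- box_mask(sp, c(7, 10), c(7, 10), c(7, 10))
  ft <- build_feature_table(co, pred, roi1, roi2, radius_mm = 2)
  expect_equal(nrow(ft), 5)
  expect_true(all(!is.na(as.matrix(ft[-1]))))

  dm1 <- distance_map(sp, roi_center_mask(roi1, sp, 2))
  dsvz <- distance_map(sp, sp$ventricle_mask)
  for (i in c(1, 4)) {
    id <- ft$patient_id[i]
    m <- co$masks[[id]]
    om <- overlap_metrics(m, pred, sp)
    expect_equal(ft$overlap_pred_cm3[i], om$overlap_volume_cm3)
    expect_equal(ft$overlap_pred_prop[i], om$overlap_proportion)
    expect_equal(ft$dist_roi1_mm[i], mean_tumor_distance(m, dm1))
    expect_equal(ft$dist_svz_mm[i], mean_tumor_distance(m, dsvz))
    expect_equal(ft$tumor_volume_cm3[i], sum(m) * voxel_volume_cm3(sp))
  }
  # determinism and the lesion == ROI special case
  expect_identical(ft, build_feature_table(co, pred, roi1, roi2,
                                           radius_mm = 2))
  rec1 <- toy_records(1)
  small_roi <- box_mask(sp, c(6, 7), c(6, 7), c(6, 7))
  co1 <- lesion_cohort(sp, list(P001 = small_roi), rec1)
  ft1 <- build_feature_table(co1, pred, small_roi, roi2, radius_mm = 4)
  expect_equal(ft1$overlap_roi1_prop, 1)
  expect_lt(ft1$dist_roi1_mm, 2)

  # empty ROI: sentinel columns plus a flag
  ft2 <- build_feature_table(co, pred, array(FALSE, sp$dims), roi2,
                             radius_mm = 2)
  expect_true(all(is.na(ft2$dist_roi1_mm)))
  expect_equal(attr(ft2, "empty_rois"), "roi1")
})

test_that("Kaplan-Meier curves match the hand-computed product limit", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(km$time, c(0, 1, 2, 3, 4))

  flat <- km_curve(c(5, 8, 11), c(0, 0, 0))
  expect_true(all(flat$surv == 1))

  # mixed worked example: times 1+, 2, 2, 3+, 4
  # at t=2: 4 at risk, 2 events -> S = 1/2; at t=4: 1 at risk, 1 event -> 0
  km2 <- km_curve(c(1, 2, 2, 3, 4), c(0, 1, 1, 0, 1))
  s_at <- function(t) km2$surv[max(which(km2$time <= t))]
  expect_equal(s_at(1.5), 1)
  expect_equal(s_at(2.5), 0.5)
  expect_equal(s_at(4), 0)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("log-rank matches the risk-set-table computation exactly", {
  brute_logrank <- function(ta, ea, tb, eb) {
    time <- c(ta, tb)
    event <- c(ea, eb)
    grp <- rep(c(1, 2), c(length(ta), length(tb)))
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
      n <- sum(time >= t)
      n1 <- sum(time >= t & grp == 1)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & grp == 1)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  withr::with_seed(61, {
    for (i in 1:20) {
      ta <- round(rexp(15, 0.1), 1)
      ea <- rbinom(15, 1, 0.8)
      tb <- round(rexp(18, 0.15), 1)
      eb <- rbinom(18, 1, 0.8)
      if (sum(ea) + sum(eb) == 0) next
      got <- logrank_test(ta, ea, tb, eb)
      expect_equal(got$chi2, brute_logrank(ta, ea, tb, eb),
                   tolerance = 1e-10)
    }
  })
  ident <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_lt(ident$chi2, 1e-10)
  expect_gt(ident$p, 0.99)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("quartile groups follow type-7 boundaries with tie inclusion", {
  x <- setNames(c(10, 20, 30, 40, 50, 60, 70, 80), paste0("P", 1:8))
  qg <- quartile_groups(x)
  expect_setequal(qg$top, c("P7", "P8"))       # >= Q3 = 62.5
  expect_setequal(qg$bottom, c("P1", "P2"))    # <= Q1 = 27.5

  # sort-based oracle on random features, plus translation invariance
  withr::with_seed(71, {
    for (i in 1:20) {
      v <- setNames(rnorm(23), paste0("P", 1:23))
      qg2 <- quartile_groups(v)
      qs <- quantile(v, c(0.25, 0.75), type = 7)
      expect_setequal(qg2$top, names(v)[v >= qs[2]])
      expect_setequal(qg2$bottom, names(v)[v <= qs[1]])
      qg3 <- quartile_groups(v + 100)
      expect_identical(qg2, qg3)
    }
  })
  expect_error(quartile_groups(setNames(rep(1, 10), paste0("P", 1:10))),
               "constant")
  expect_error(quartile_groups(setNames(1:5, paste0("P", 1:5))), "at least 8")
})

test_that("the six-gene risk score and median split behave as printed", {
  rm <- risk_model()
  expect_equal(unname(rm["SNCB"]), 0.1507)
  zero <- matrix(0, 3, 6, dimnames = list(NULL, names(rm)))
  expect_equal(risk_score(zero), c(0, 0, 0))
  one <- zero
  one[, "SNCB"] <- 1
  expect_equal(risk_score(one), rep(0.1507, 3))

  withr::with_seed(81, {
    expr <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("P", 1:10),
                                                     names(rm)))
    sc <- setNames(risk_score(expr), rownames(expr))
    hand <- as.numeric(expr %*% as.numeric(rm))
    expect_equal(unname(sc), hand, tolerance = 1e-12)
    ms <- median_split(sc)
    expect_lte(abs(length(ms$high) - length(ms$low)), 1)
    expect_true(all(sc[ms$high] > ms$median))
  })
  bad <- matrix(0, 2, 5, dimnames = list(NULL, names(rm)[-1]))
  expect_error(risk_score(bad), "SNCB")
})

test_that("time-dependent AUC reduces to the rank-sum AUC without censoring", {
  # perfect separation
  t1 <- c(2, 4, 6, 20, 25, 30)
  e1 <- rep(1, 6)
  s1 <- c(9, 8, 7, 1, 2, 3)
  expect_equal(time_dependent_auc(s1, t1, e1, 12), 1.0)

  withr::with_seed(91, {
    for (i in 1:10) {
      n <- 80
      t <- rexp(n, 1 / 15)
      s <- rnorm(n) + (t < 12)
      lab <- as.numeric(t <= 12)
      plain <- (sum(rank(s)[lab == 1]) - sum(lab) * (sum(lab) + 1) / 2) /
        (sum(lab) * sum(1 - lab))
      expect_equal(time_dependent_auc(s, t, rep(1, n), 12), plain,
                   tolerance = 1e-12)
    }
    # null behavior at n = 500: random scores give AUC ~ 0.5
    n <- 500
    t <- rexp(n, 1 / 15)
    s <- rnorm(n)
    expect_lt(abs(time_dependent_auc(s, t, rep(1, n), 12) - 0.5), 0.05)
  })
  expect_error(time_dependent_auc(c(1, 2), c(20, 30), c(1, 1), 12),
               "no cases")
})

test_that("quartile log-rank wrapper ties features to survival records", {
  withr::with_seed(95, {
    n <- 60
    rec <- toy_records(n)
    # hazard increases with the feature: top quartile should die earlier
    feat <- setNames(runif(n, 0, 10), rec$patient_id)
    rec$survival_time <- round(rexp(n, 0.02 * exp(0.4 * feat)), 2)
    rec$event <- 1L
    out <- quartile_logrank(feat, rec)
    expect_lt(out$p, 0.05)
    expect_setequal(names(out), c("groups", "chi2", "p"))
  })
})
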