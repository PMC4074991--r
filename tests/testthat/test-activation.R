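timing <- scan_timing()  # 70 x 6 s, control 1-25, stimulation 26-50

test_that("scan timing defaults describe the 7-minute session and reject bad windows", {
  expect_identical(timing$duration_s, 420)
  expect_error(scan_timing(control_window = c(1, 25), stimulation_window = c(20, 50)),
               "overlap")
  expect_error(scan_timing(40, 6, c(1, 25), c(26, 50)), "within")
})

test_that("percent change follows the two-window mean formula", {
  x <- c(rep(100, 25), rep(102, 25), rep(100, 20))
  expect_equal(percent_change(x, timing), 2.0)
  expect_equal(percent_change(rep(5, 70), timing), 0.0)
  # direct two-mean oracle on a seeded noisy series
  set.seed(21)
  y <- rnorm(70, 100, 3)
  oracle <- 100 * (mean(y[26:50]) - mean(y[1:25])) / mean(y[1:25])
  expect_equal(percent_change(y, timing), oracle, tolerance = 1e-12)
  # invariance under positive rescaling
  expect_equal(percent_change(7.3 * y, timing), percent_change(y, timing),
               tolerance = 1e-10)
  # non-positive control mean is masked, not an error
  expect_true(is.na(percent_change(c(rep(0, 25), rep(1, 45)), timing)))
})

test_that("per-voxel Welch t matches the formula oracle and stats::t.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  tm <- scan_timing(10, 6, c(1, 5), c(6, 10))
  got <- voxel_t_test(c(x, y), tm)
  orc <- welch_oracle(x, y)
  expect_equal(got$t, orc$t, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)
  tt <- t.test(y, x, var.equal = FALSE)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)
  # identical windows give t = 0, p = 1
  same <- voxel_t_test(c(x, x), tm)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  # seeded random series, vectorised path vs per-voxel t.test
  set.seed(3)
  arr <- array(rnorm(4 * 3 * 2 * 70, 100, 2), c(4, 3, 2, 70))
  got4 <- voxel_t_test(arr, timing)
  for (v in c(1, 9, 24)) {
    ijk <- arrayInd(v, c(4, 3, 2))
    ts <- arr[ijk[1], ijk[2], ijk[3], ]
    tt <- t.test(ts[26:50], ts[1:25], var.equal = FALSE)
    expect_equal(got4$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got4$p[v], tt$p.value, tolerance = 1e-10)
  }
})

test_that("null p-values are uniform", {
  set.seed(17)
  arr <- array(rnorm(10000 * 50, 100, 1), c(100, 100, 1, 50))
  tm <- scan_timing(50, 6, c(1, 25), c(26, 50))
  p <- as.vector(voxel_t_test(arr, tm)$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH filter reproduces the enumerated step-up rule", {
  got <- fdr_filter(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(got, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdr_filter(rep(1, 20), q = 0.05)))
  # property: random small arrays on a 0.01 grid agree with the oracle
  set.seed(5)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    p <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(fdr_filter(p, q), bh_oracle(p, q))
  }
  # lowering q never enlarges the rejection set
  set.seed(6)
  p <- runif(100)^2
  r1 <- fdr_filter(p, 0.05); r2 <- fdr_filter(p, 0.01)
  expect_true(all(r1[r2]))
  expect_message(fdr_filter(c(0.1, 0.2), mask = c(FALSE, FALSE)), "empty mask")
})

test_that("activation maps detect a sustained 8% signal and respect the threshold", {
  atlas <- tiny_atlas(6, c(24, 24, 8), seed = 2)
  spec <- session_spec(active_regions = c(1, 2), seed = 11)
  s <- simulate_session(atlas, spec, "WT")  # 8% amplitude
  mask <- atlas$labels > 0L
  m <- activation_map(s$series, mask, timing)
  active <- array(atlas$labels %in% c(1, 2), dim(atlas$labels))
  expect_gt(mean(m$significant[active]), 0.90)
  expect_lt(mean(m$significant[mask & !active]), 0.01)
  expect_false(any(m$significant[!mask]))
  # sub-threshold signal with tiny p still yields no significant voxels
  base <- array(100, c(6, 6, 2, 70))
  base[, , , 26:50] <- 101.5  # 1.5% < 2% threshold, p ~ 0
  m2 <- activation_map(base + array(rnorm(length(base), 0, 0.01), dim(base)),
                       array(TRUE, c(6, 6, 2)), timing)
  expect_identical(sum(m2$significant), 0L)
  # raising the baseline threshold never increases the significant count
  m3 <- activation_map(s$series, mask, timing, baseline_threshold = 5)
  expect_lte(sum(m3$significant), sum(m$significant))
})

test_that("composite maps average subjects and locate the true activation centroid", {
  atlas <- tiny_atlas(6, c(20, 20, 8), seed = 4)
  spec <- session_spec(active_regions = 1, seed = 9)
  s <- simulate_session(atlas, spec, "WT")
  mask <- atlas$labels > 0L
  m <- activation_map(s$series, mask, timing)
  id <- affine_transform(moving_geom = atlas$geometry)
  # single subject, identity transform: composite equals the subject map
  cm1 <- composite_map(list(m), list(id), atlas)
  pc <- m$percent_change; pc[is.na(pc)] <- 0
  expect_equal(cm1$mean_percent_change, pc, tolerance = 1e-6)
  expect_equal(cm1$n_significant, array(as.integer(m$significant), dim(mask)))
  # two identical subjects: mean equals the shared map
  cm2 <- composite_map(list(m, m), list(id, id), atlas)
  expect_equal(cm2$mean_percent_change, cm1$mean_percent_change, tolerance = 1e-12)
  expect_error(composite_map(list(m, m), list(id), atlas), "contract")
  # three subjects with known non-identity transforms: centroid within 1 voxel
  trs <- list(affine_transform(c(0.3, 0, 0), moving_geom = atlas$geometry),
              affine_transform(c(0, -0.3, 0), moving_geom = atlas$geometry),
              affine_transform(c(0, 0, 0.2), moving_geom = atlas$geometry))
  maps <- lapply(1:3, function(i) {
    sub <- simulate_session(atlas, session_spec(active_regions = 1, seed = 30 + i), "WT")
    series_sub <- array(0, dim(sub$series))
    for (t in seq_len(dim(sub$series)[4]))
      series_sub[, , , t] <- apply_transform(sub$series[, , , t], trs[[i]],
                                             "linear", direction = "inverse",
                                             fill = 1000)
    mask_sub <- apply_transform(atlas$labels, trs[[i]], "nearest",
                                direction = "inverse", fill = 0L) > 0L
    activation_map(series_sub, mask_sub, timing)
  })
  cm3 <- composite_map(maps, trs, atlas)
  w <- which(cm3$n_significant >= 2, arr.ind = TRUE)
  truth <- which(atlas$labels == 1, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(w) - colMeans(truth))), 1)
})
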