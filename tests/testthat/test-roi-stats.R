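test_that("normalized volume of activation follows the counting formula", {
  atlas <- tiny_atlas(5, c(16, 16, 8), seed = 1)
  none <- array(FALSE, dim(atlas$labels))
  voa0 <- volume_of_activation(none, atlas)
  expect_true(all(voa0$normalized_voa == 0))
  # random significance mask vs exhaustive per-voxel tally
  set.seed(8)
  sig <- array(runif(length(atlas$labels)) < 0.3, dim(atlas$labels))
  voa <- volume_of_activation(sig, atlas)
  for (k in voa$id) {
    act <- sum(sig & atlas$labels == k)
    tot <- sum(atlas$labels == k)
    expect_identical(voa$activated_voxels[voa$id == k], act)
    expect_equal(voa$normalized_voa[voa$id == k], 100 * act / tot)
  }
  expect_true(all(voa$normalized_voa >= 0 & voa$normalized_voa <= 100))
  expect_true(all(voa$activated_voxels <= voa$total_voxels))
})

test_that("50 activated of 200 total gives 25% and voxel splitting leaves it unchanged", {
  g <- voxel_geometry(1, 1, 1, grid_shape = c(10, 10, 2))
  labels <- array(0L, c(10, 10, 2)); labels[1:200] <- 1L
  atlas <- segmented_atlas(labels, data.frame(id = 1, name = "roi"), g)
  sig <- array(FALSE, c(10, 10, 2)); sig[1:50] <- TRUE
  expect_equal(volume_of_activation(sig, atlas)$normalized_voa, 25.0)
  # split every voxel into 8: normalized VOA is invariant on nested masks
  g2 <- voxel_geometry(0.5, 0.5, 0.5, grid_shape = c(20, 20, 4))
  up <- function(a) a[rep(1:10, each = 2), rep(1:10, each = 2), rep(1:2, each = 2)]
  atlas2 <- segmented_atlas(up(labels), data.frame(id = 1, name = "roi"), g2)
  expect_equal(volume_of_activation(up(sig), atlas2)$normalized_voa, 25.0)
})

test_that("Mann-Whitney matches enumeration and large-sample oracles", {
  mw <- mousebold:::mann_whitney_u
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1 by full enumeration
  got <- mw(c(1, 2, 3), c(4, 5, 6))
  expect_identical(got$U, 0)
  expect_equal(got$p, 0.1, tolerance = 1e-12)
  expect_equal(got$p, mw_enum_oracle(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  # random small samples against the enumeration oracle
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    pool <- sample(100, n1 + n2)  # tie-free draw across both samples
    x <- pool[seq_len(n1)]; y <- pool[n1 + seq_len(n2)]
    expect_equal(mw(x, y)$p, mw_enum_oracle(x, y), tolerance = 1e-10)
  }
  # tied / larger samples against the normal-approximation formula oracle
  set.seed(13)
  for (i in 1:10) {
    x <- sample(1:5, 8, replace = TRUE); y <- sample(2:6, 9, replace = TRUE)
    expect_equal(mw(x, y)$p, mw_normal_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  set.seed(14)
  for (i in 1:10) {
    g <- rep(c("a", "b", "c"), times = c(4, 3, 4))
    v <- sample(1:8, length(g), replace = TRUE)
    if (length(unique(v)) == 1) next
    got <- mousebold:::kruskal_omnibus(v, g)
    expect_equal(got$H, kw_h_oracle(v, g), tolerance = 1e-10)
  }
})

test_that("group comparison ranks regions and handles identical groups", {
  atlas <- tiny_atlas(4, c(12, 12, 6), seed = 5)
  mk <- function(voa_by_region) {
    rv <- compute_region_volumes(atlas)
    data.frame(id = rv$id, name = rv$name,
               activated_voxels = round(voa_by_region / 100 * rv$voxel_count),
               total_voxels = rv$voxel_count, normalized_voa = voa_by_region)
  }
  # three identical groups: H ~ 0, p ~ 1
  tabs <- lapply(1:6, function(i) mk(c(10, 20, 30, 40)))
  res <- suppressWarnings(group_compare(tabs, rep(c("WT", "HET", "HOM"), each = 2)))
  expect_true(all(res$p_value == 1))
  # graded groups: affected region ranks first, ties broken by id
  set.seed(20)
  tabs2 <- lapply(1:9, function(i) {
    gi <- (i - 1) %/% 3 + 1  # 1 = WT, 2 = HET, 3 = HOM
    v <- c(c(60, 40, 10)[gi] + runif(1), 5 + runif(3))
    mk(v)
  })
  res2 <- group_compare(tabs2, rep(c("WT", "HET", "HOM"), each = 3))
  expect_identical(res2$id[1], 1L)
  expect_true(!is.unsorted(res2$p_value))
  expect_true(all(c("WT_median", "HET_max", "HOM_min", "p_WT_vs_HOM") %in% names(res2)))
  # medians bracketed by min/max
  expect_true(all(res2$WT_min <= res2$WT_median & res2$WT_median <= res2$WT_max))
  expect_error(group_compare(tabs2[1:3], c("WT", "HET", "HOM")), ">= 2")
})

test_that("under the null the omnibus rejects at close to the nominal rate", {
  set.seed(31)
  n_reg <- 400
  p <- replicate(n_reg, {
    v <- rnorm(12)
    mousebold:::kruskal_omnibus(v, rep(c("a", "b", "c"), each = 4))$p
  })
  frac <- mean(p < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / n_reg)
  expect_lt(abs(frac - 0.05), ci + 0.02)
})

test_that("Fisher's protected LSD matches the hand-computed contrast oracle", {
  set.seed(42)
  v <- c(rnorm(4, 10), rnorm(4, 12), rnorm(4, 15))
  g <- rep(c("WT", "HET", "HOM"), each = 4)
  lsd <- mousebold:::fisher_lsd(v, g)
  for (pr in list(c("WT", "HET"), c("WT", "HOM"), c("HET", "HOM"))) {
    orc <- lsd_oracle(v, g, pr[1], pr[2])
    hit <- grepl(pr[1], lsd$pairwise$contrast) & grepl(pr[2], lsd$pairwise$contrast)
    row <- lsd$pairwise[hit, ]
    # factor level order may flip the sign; compare magnitudes and p
    expect_equal(abs(row$t), abs(orc$t), tolerance = 1e-10)
    expect_equal(row$p, orc$p, tolerance = 1e-10)
    expect_identical(row$df, orc$df)
  }
  ref <- anova(lm(v ~ factor(g)))
  expect_equal(lsd$omnibus_p, ref[1, "Pr(>F)"], tolerance = 1e-12)
})

test_that("volume comparison detects simulated atrophy and protects contrasts", {
  g <- voxel_geometry(0.097, 0.097, 0.75, grid_shape = c(8, 8, 4))
  vv <- compute_voxel_volume(g)
  mk_tab <- function(vols) data.frame(id = seq_along(vols), name = paste0("r", seq_along(vols)),
                                      voxel_count = round(vols / vv), volume_mm3 = vols)
  # identical volumes: nothing significant
  same <- lapply(1:9, function(i) mk_tab(c(5, 10, 15)))
  res0 <- volume_compare(same, rep(c("WT", "HET", "HOM"), each = 3))
  expect_true(all(res0$p_value == 1))
  expect_true(all(is.na(res0$p_WT_vs_HOM)))
  # power simulation: 15% HOM atrophy, 5% between-subject noise, n = 10/10/10
  set.seed(55)
  hits <- 0L
  for (r in 1:50) {
    tabs <- lapply(1:30, function(i) {
      hom <- i > 20
      v1 <- 10 * (1 - 0.15 * hom) * (1 + rnorm(1, 0, 0.05))
      mk_tab(c(v1, 5 * (1 + rnorm(1, 0, 0.05))))
    })
    res <- volume_compare(tabs, rep(c("WT", "HET", "HOM"), each = 10))
    row <- res[res$id == 1, ]
    hit <- !is.na(row$p_WT_vs_HOM) && row$p_WT_vs_HOM < 0.05 &&
           !is.na(row$p_HET_vs_HOM) && row$p_HET_vs_HOM < 0.05
    hits <- hits + hit
  }
  expect_gte(hits / 50, 0.8)
})

test_that("ROI time courses are baseline-anchored and recover an injected boxcar", {
  atlas <- tiny_atlas(4, c(16, 16, 6), seed = 3)
  id <- affine_transform(moving_geom = atlas$geometry)
  # constant series: flat zero trace
  const <- array(500, c(16, 16, 6, 30))
  tc <- extract_timecourse(const, id, atlas, 1, baseline_window = c(1, 10))
  expect_equal(tc$pct_change, rep(0, 30))
  # injected +5% boxcar from acquisition 26, averaged over 10 seeds
  timing <- scan_timing()
  spec0 <- session_spec(active_regions = 1, amplitudes = c(WT = 5),
                        gene_dose = FALSE, seed = 1)
  prof <- 5 * mousebold:::activation_profile(timing)
  traces <- sapply(1:10, function(s) {
    sp <- spec0; sp$seed <- s
    ses <- simulate_session(atlas, sp, "WT")
    tcs <- extract_timecourse(ses$series, id, atlas, 1, baseline_window = c(1, 25))
    # baseline window of the output averages to 0 exactly
    expect_equal(mean(tcs$pct_change[1:25]), 0, tolerance = 1e-12)
    tcs$pct_change
  })
  expect_lt(max(abs(rowMeans(traces) - prof)), 0.5)
  expect_error(extract_timecourse(const, id, atlas, 999), "unknown region")
})

test_that("mixed repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(71)
  d <- expand.grid(subject = 1:12, acquisition = 1:5)
  d$group <- c("WT", "HET", "HOM")[(d$subject - 1) %/% 4 + 1]
  d$pct_change <- rnorm(nrow(d)) +
    ifelse(d$group == "WT", 0.2, 0) * d$acquisition
  got <- timecourse_anova(d)
  orc <- mixed_anova_oracle(d$pct_change, d$group, d$subject, d$acquisition)
  expect_equal(got$main$F, orc$F_group, tolerance = 1e-8)
  expect_equal(got$time$F, orc$F_time, tolerance = 1e-8)
  expect_equal(got$interaction$F, orc$F_interaction, tolerance = 1e-8)
  expect_equal(got$interaction$p, orc$p_interaction, tolerance = 1e-8)
  expect_error(timecourse_anova(d[-1, ]), "unbalanced")
})

test_that("the interaction test holds its size under the null", {
  set.seed(99)
  n_sims <- 200
  rej <- 0L
  for (i in 1:n_sims) {
    d <- expand.grid(subject = 1:12, acquisition = 1:8)
    d$group <- c("a", "b", "c")[(d$subject - 1) %/% 4 + 1]
    subj_fx <- rnorm(12, 0, 0.5)
    d$pct_change <- subj_fx[d$subject] + rnorm(nrow(d))
    rej <- rej + (timecourse_anova(d)$interaction$p < 0.05)
  }
  ci <- 1.96 * sqrt(0.05 * 0.95 / n_sims)
  expect_lt(abs(rej / n_sims - 0.05), ci + 0.02)
})

test_that("non-responders are subjects with zero activated voxels in the target ROI", {
  tabs <- list(
    data.frame(id = 1:2, name = c("a", "b"), activated_voxels = c(0L, 5L),
               total_voxels = c(10L, 10L), normalized_voa = c(0, 50)),
    data.frame(id = 1:2, name = c("a", "b"), activated_voxels = c(3L, 0L),
               total_voxels = c(10L, 10L), normalized_voa = c(30, 0)))
  expect_identical(non_responders(tabs, 1), c(TRUE, FALSE))
  expect_identical(non_responders(tabs, 2), c(FALSE, TRUE))
})
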