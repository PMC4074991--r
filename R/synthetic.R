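# Synthetic phantom atlases and awake-mouse BOLD sessions with known ground
# truth. The generator emulates the study conditions: 70 acquisitions at 6 s
# (2.5 min baseline, 2.5 min stimulus window), a multi-region label atlas
# (default 116 regions), genotype-graded activation amplitudes (WT > HET >
# HOM), Gaussian voxel noise, slow linear drift, and optional sub-voxel
# rigid motion.

#' Generate a phantom label atlas
#'
#' Builds an ellipsoidal brain mask on the given grid and partitions it into
#' `n_regions` contiguous regions by nearest-seed (Voronoi) assignment of
#' seeded interior points; every region is non-empty by construction and the
#' result is deterministic per seed.
#'
#' @param n_regions number of regions (default 116).
#' @param grid grid shape in voxels (default `c(48, 48, 16)`).
#' @param geometry optional [voxel_geometry()]; defaults to a 25 mm in-plane
#'   field of view over the grid with 0.75 mm slices.
#' @param seed integer seed.
#' @return a [segmented_atlas()] with regions named `region_001`, ...
#' @export
make_phantom_atlas <- function(n_regions = 116L, grid = c(48L, 48L, 16L),
                               geometry = NULL, seed = 1L) {
  grid <- as.integer(grid)
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (is.null(geometry))
    geometry <- voxel_geometry(slice_thickness = 0.75, grid_shape = grid,
                               field_of_view = 25)
  idx <- index_grid(grid)
  semi <- pmax((grid - 1) / 2 * 0.9, 0.5)
  ctr <- (grid - 1) / 2
  inside <- rowSums(sweep(sweep(idx, 2, ctr, `-`), 2, semi, `/`)^2) <= 1
  n_in <- sum(inside)
  if (n_in < n_regions) {
    min_grid <- ceiling((n_regions / 0.38)^(1 / 3))
    stop(sprintf("infeasible packing: %d mask voxels for %d regions; need a grid of at least ~%d^3",
                 n_in, n_regions, min_grid))
  }
  labels <- array(0L, dim = grid)
  if (n_regions == 1L) {
    labels[inside] <- 1L
  } else {
    set.seed(seed)
    seeds <- idx[sample(which(inside), n_regions), , drop = FALSE]
    # physical-space nearest seed
    vs <- voxel_sizes(geometry)
    pts <- sweep(idx[inside, , drop = FALSE], 2, vs, `*`)
    sp <- sweep(seeds, 2, vs, `*`)
    d2 <- matrix(0, nrow(pts), n_regions)
    for (k in seq_len(n_regions))
      d2[, k] <- (pts[, 1] - sp[k, 1])^2 + (pts[, 2] - sp[k, 2])^2 + (pts[, 3] - sp[k, 3])^2
    labels[inside] <- max.col(-d2, ties.method = "first")
  }
  regions <- data.frame(id = seq_len(n_regions),
                        name = sprintf("region_%03d", seq_len(n_regions)),
                        stringsAsFactors = FALSE)
  segmented_atlas(labels, regions, geometry)
}

#' Smooth anatomical phantom from a label atlas
#'
#' Assigns each region a seeded random intensity and smooths the volume with
#' a separable Gaussian kernel, yielding a structured "anatomy" suitable for
#' intensity-based registration tests.
#'
#' @param atlas a [segmented_atlas()].
#' @param sigma Gaussian smoothing in voxels.
#' @param seed integer seed for the region intensities.
#' @return 3D numeric array.
#' @export
make_phantom_anatomy <- function(atlas, sigma = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(atlas$regions)
  intens <- stats::runif(n, 200, 1000)
  img <- array(0, dim = dim(atlas$labels))
  pos <- atlas$labels > 0L
  img[pos] <- intens[atlas$labels[pos]]
  gaussian_smooth3(img, sigma)
}

# separable 3D Gaussian smoothing (reflecting boundaries)
gaussian_smooth3 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- dp[1]
    pad <- rbind(m[pmin(r:1, n), , drop = FALSE], m, m[pmax(n - (1:r) + 1, 1), , drop = FALSE])
    sm <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) sm <- sm + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    ap2 <- array(sm, dp)
    aperm(ap2, order(perm))
  }
  for (ax in 1:3) img <- smooth_axis(img, ax)
  img
}

#' Session specification for the synthetic generator
#'
#' The defaults are the emulated study conditions: 70 x 6 s acquisitions
#' with control window 1-25 and stimulation window 26-50, gene-dose
#' activation amplitudes WT 8, HET 5, HOM 2 (% BOLD), Gaussian voxel noise
#' of 1% of baseline, a slow linear drift of 0.5% across the session, and no
#' rigid motion (set `motion_sd > 0` to inject sub-voxel motion).
#'
#' @param timing a [scan_timing()].
#' @param active_regions integer vector of activated region ids.
#' @param amplitudes named per-genotype % BOLD amplitudes; in gene-dose mode
#'   they must be ordered non-increasing over the given genotype order.
#' @param noise_sd Gaussian noise SD, percent of baseline (> 0).
#' @param drift_amplitude peak-to-peak linear drift, percent per session.
#' @param motion_sd per-frame rigid translation SD in mm (0 = off).
#' @param baseline_intensity baseline signal, arbitrary units.
#' @param nonresponder_fraction named per-genotype fraction of subjects whose
#'   amplitude is forced to 0 (default none).
#' @param gene_dose enforce the non-increasing amplitude ordering.
#' @param seed integer seed.
#' @return object of class `session_spec`.
#' @export
session_spec <- function(timing = scan_timing(),
                         active_regions = integer(0),
                         amplitudes = c(WT = 8, HET = 5, HOM = 2),
                         noise_sd = 1,
                         drift_amplitude = 0.5,
                         motion_sd = 0,
                         baseline_intensity = 1000,
                         nonresponder_fraction = c(HOM = 0),
                         gene_dose = TRUE,
                         seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (gene_dose && is.unsorted(rev(as.numeric(amplitudes))))
    stop("gene-dose mode requires non-increasing amplitudes across genotypes")
  structure(list(timing = timing, active_regions = as.integer(active_regions),
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, motion_sd = motion_sd,
                 baseline_intensity = baseline_intensity,
                 nonresponder_fraction = nonresponder_fraction,
                 gene_dose = gene_dose, seed = as.integer(seed)),
            class = "session_spec")
}

# activation time profile: boxcar over the stimulation window with a
# 2-acquisition exponential rise, normalized so its stimulation-window mean
# is exactly 1 (so the recovered window-mean contrast equals the requested
# amplitude by construction).
activation_profile <- function(timing, rise_tau = 2) {
  prof <- numeric(timing$n_acquisitions)
  si <- window_idx(timing$stimulation_window)
  k <- seq_along(si)
  rise <- 1 - exp(-k / rise_tau)
  prof[si] <- rise / mean(rise)
  prof
}

#' Simulate one BOLD session
#'
#' Baseline intensity plus a rise-smoothed boxcar activation in the active
#' regions at the genotype's amplitude, plus linear drift (random sign),
#' Gaussian voxel noise, and optional per-frame sub-voxel rigid motion.
#' The ground truth (active voxel set, amplitude, motion trace, transform,
#' seed) is returned alongside; regeneration from the same spec and seed is
#' bit-identical.
#'
#' @param atlas a [segmented_atlas()].
#' @param spec a [session_spec()].
#' @param genotype one of `names(spec$amplitudes)`.
#' @param amplitude_override optional amplitude replacing the genotype's
#'   (used for non-responders).
#' @return list with `series` (4D array), `ground_truth` (list), `geometry`.
#' @export
simulate_session <- function(atlas, spec, genotype = "WT",
                             amplitude_override = NULL) {
  stopifnot(inherits(atlas, "segmented_atlas"), inherits(spec, "session_spec"))
  if (!genotype %in% names(spec$amplitudes)) stop("unknown genotype: ", genotype)
  amp <- if (is.null(amplitude_override)) unname(spec$amplitudes[genotype])
         else amplitude_override
  if (amp > 0 && amp < spec$noise_sd)
    warning("requested amplitude below the noise floor; recovery will be unreliable")
  timing <- spec$timing
  d <- dim(atlas$labels)
  nt <- timing$n_acquisitions
  set.seed(spec$seed)
  active_mask <- array(atlas$labels %in% spec$active_regions, dim = d)
  prof <- activation_profile(timing) * (amp / 100)
  drift_sign <- sample(c(-1, 1), 1)
  drift <- drift_sign * (spec$drift_amplitude / 100) *
    (seq_len(nt) - 1) / (nt - 1) - drift_sign * spec$drift_amplitude / 200
  base <- spec$baseline_intensity
  series <- array(0, dim = c(d, nt))
  nvox <- prod(d)
  motion <- matrix(0, nt, 6)
  if (spec$motion_sd > 0) {
    motion[, 1:3] <- stats::rnorm(3 * nt, sd = spec$motion_sd)
    motion[, 4:6] <- stats::rnorm(3 * nt, sd = spec$motion_sd * 0.5)
    motion[1, ] <- 0  # frame 1 is the reference
  }
  # brain voxels carry the signal; the background (air) is dark
  brain <- atlas$labels > 0L
  clean_frame <- function(t) {
    f <- array(0, dim = d)
    f[brain] <- base * (1 + drift[t])
    if (prof[t] != 0 && any(active_mask)) {
      f[active_mask] <- base * (1 + drift[t] + prof[t])
    }
    f
  }
  noise <- array(stats::rnorm(nvox * nt, sd = spec$noise_sd / 100 * base),
                 dim = c(d, nt))
  for (t in seq_len(nt)) {
    f <- clean_frame(t)
    if (spec$motion_sd > 0 && any(motion[t, ] != 0)) {
      tr <- rigid_transform(motion[t, 1:3], motion[t, 4:6],
                            moving_geom = as_grid_geom(atlas$geometry))
      f <- apply_transform(f, tr, "linear", fill = 0)
    }
    series[, , , t] <- f + noise[, , , t]
  }
  gt <- list(transform = affine_transform(moving_geom = atlas$geometry),
             active_voxels = which(active_mask),
             amplitude = amp, genotype = genotype,
             motion = motion, seed = spec$seed)
  list(series = series, ground_truth = gt, geometry = atlas$geometry)
}

# documented master-seed splitting rule: subject k of a cohort generated with
# master seed s simulates with seed (s * 1009 + k * 9973) mod (2^31 - 1)
subject_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 1009 + k * 9973) %% 2147483647)
}

#' Simulate a genotype cohort
#'
#' Generates one session per subject with independent seeds derived from the
#' master seed by a documented splitting rule, and a manifest of subject id,
#' genotype, seed. Within each genotype a fixed fraction of subjects
#' (`spec$nonresponder_fraction`) is generated with amplitude 0
#' (non-responders), chosen deterministically as the last subjects of the
#' group.
#'
#' @param atlas a [segmented_atlas()].
#' @param spec a [session_spec()].
#' @param n_per_group named integer vector, subjects per genotype
#'   (default `c(WT = 9, HET = 9, HOM = 8)`).
#' @param seed master integer seed.
#' @return list with `sessions` (list of [simulate_session()] results) and
#'   `manifest` (data.frame: subject, genotype, seed, nonresponder).
#' @export
simulate_cohort <- function(atlas, spec, n_per_group = c(WT = 9, HET = 9, HOM = 8),
                            seed = 1L) {
  if (any(n_per_group < 1L)) stop("counts must be >= 1")
  sessions <- list()
  manifest <- NULL
  k <- 0L
  for (g in names(n_per_group)) {
    n_g <- n_per_group[[g]]
    frac <- if (g %in% names(spec$nonresponder_fraction))
      spec$nonresponder_fraction[[g]] else 0
    n_nonresp <- floor(frac * n_g)
    for (i in seq_len(n_g)) {
      k <- k + 1L
      sspec <- spec
      sspec$seed <- subject_seed(seed, k)
      nonresp <- i > n_g - n_nonresp
      sessions[[k]] <- simulate_session(atlas, sspec, genotype = g,
                                        amplitude_override = if (nonresp) 0 else NULL)
      manifest <- rbind(manifest,
                        data.frame(subject = sprintf("sub-%03d", k),
                                   genotype = g, seed = sspec$seed,
                                   nonresponder = nonresp,
                                   stringsAsFactors = FALSE))
    }
  }
  list(sessions = sessions, manifest = manifest)
}

#' Null-session calibration of the voxel-wise false discovery rate
#'
#' Generates seeded null sessions (no active regions, generator-default
#' Gaussian noise and drift) on an ellipsoidal single-region phantom, runs
#' the full voxel-wise activation pipeline (Welch t-tests, BH filter at rate
#' `q`, baseline threshold) on each, and returns the per-replicate false
#' discovery proportion: false discoveries over max(1, total discoveries).
#' With no true activation every discovery is false.
#'
#' @param n_replicates number of null sessions.
#' @param grid grid shape of the phantom.
#' @param seed master seed; replicate r uses the documented split rule.
#' @param timing a [scan_timing()].
#' @param baseline_threshold,q activation-map parameters.
#' @return list with `mean_fdp`, per-replicate `fdp`, and `n_replicates`.
#' @export
null_fdr_calibration <- function(n_replicates = 200L, grid = c(32L, 32L, 10L),
                                 seed = 1L, timing = scan_timing(),
                                 baseline_threshold = 2.0, q = 0.05) {
  atlas <- make_phantom_atlas(n_regions = 1L, grid = grid, seed = seed)
  mask <- atlas$labels > 0L
  fdp <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- session_spec(timing = timing, active_regions = integer(0),
                         seed = subject_seed(seed, r))
    s <- simulate_session(atlas, spec, "WT")
    m <- activation_map(s$series, mask, timing,
                        baseline_threshold = baseline_threshold, q = q)
    n_disc <- sum(m$significant)
    fdp[r] <- n_disc / max(1L, n_disc)
  }
  list(mean_fdp = mean(fdp), fdp = fdp, n_replicates = n_replicates)
}
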