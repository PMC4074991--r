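#' Scan timing of a block-design session
#'
#' Defaults match a 7-minute odor session: 70 whole-brain acquisitions with a
#' period of 6 s each (420 s total), a control window over the first 25 scan
#' repetitions (2.5 min baseline) and a stimulation window over repetitions
#' 26-50. Windows are 1-based inclusive scan-index ranges and must be
#' disjoint; post-stimulation scans (51-70 by default) take part in neither
#' window.
#'
#' @param n_acquisitions total number of acquisitions.
#' @param period_s acquisition period in seconds.
#' @param control_window inclusive 1-based `c(first, last)` control range.
#' @param stimulation_window inclusive 1-based `c(first, last)` stimulation
#'   range.
#' @return object of class `scan_timing` with the validated fields plus
#'   `duration_s = n_acquisitions * period_s`.
#' @export
scan_timing <- function(n_acquisitions = 70L, period_s = 6,
                        control_window = c(1L, 25L),
                        stimulation_window = c(26L, 50L)) {
  n <- as.integer(n_acquisitions)
  cw <- as.integer(control_window); sw <- as.integer(stimulation_window)
  errs <- validate_timing(n, period_s, cw, sw)
  if (length(errs)) stop("configuration error: ", paste(errs, collapse = "; "))
  structure(list(n_acquisitions = n, period_s = period_s,
                 control_window = cw, stimulation_window = sw,
                 duration_s = n * period_s),
            class = "scan_timing")
}

validate_timing <- function(n, period_s, cw, sw) {
  errs <- character(0)
  if (is.na(n) || n < 2L) errs <- c(errs, "n_acquisitions must be >= 2")
  if (!is.finite(period_s) || period_s <= 0) errs <- c(errs, "period_s must be positive")
  for (w in list(control = cw, stimulation = sw)) {
    if (length(w) != 2L || any(is.na(w)) || w[1] > w[2] || w[1] < 1L || (!is.na(n) && w[2] > n))
      errs <- c(errs, "windows must be inclusive 1-based ranges within [1, n_acquisitions]")
  }
  if (length(errs) == 0 && max(cw[1], sw[1]) <= min(cw[2], sw[2]))
    errs <- c(errs, "control and stimulation windows overlap")
  errs
}

# 1-based inclusive window -> index vector
window_idx <- function(w) seq.int(w[1], w[2])

# coerce a 4D array / niftiImage / vector to voxels x time matrix + dims
as_voxel_matrix <- function(series) {
  series <- as.array(series)
  d <- dim(series)
  if (is.null(d)) { d <- c(length(series)); dim(series) <- d }
  if (length(d) == 1L) return(list(mat = matrix(series, nrow = 1), spatial = NULL))
  if (length(d) != 4L) stop("series must be a per-voxel vector or a 4D array")
  list(mat = matrix(series, nrow = prod(d[1:3]), ncol = d[4]), spatial = d[1:3])
}

#' Percent BOLD signal change between stimulation and control windows
#'
#' 100 x (stimulation-window mean - control-window mean) / control-window
#' mean, per voxel. Voxels whose control mean is zero or negative cannot be
#' expressed as a percent change and are returned as `NA` (masked out, not an
#' error).
#'
#' @param series a single voxel's time series (numeric vector) or a 4D array.
#' @param timing a [scan_timing()].
#' @return numeric scalar for a vector input; 3D array for a 4D input.
#' @export
percent_change <- function(series, timing) {
  vm <- as_voxel_matrix(series)
  if (timing$n_acquisitions > ncol(vm$mat))
    stop("configuration error: timing windows exceed series length")
  m_ctrl <- rowMeans(vm$mat[, window_idx(timing$control_window), drop = FALSE])
  m_stim <- rowMeans(vm$mat[, window_idx(timing$stimulation_window), drop = FALSE])
  pc <- 100 * (m_stim - m_ctrl) / m_ctrl
  pc[m_ctrl <= 0] <- NA_real_
  if (is.null(vm$spatial)) as.numeric(pc) else array(pc, dim = vm$spatial)
}

# Vectorised Welch statistics for voxels x time matrices.
welch_rows <- function(x_ctrl, x_stim) {
  n1 <- ncol(x_ctrl); n2 <- ncol(x_stim)
  m1 <- rowMeans(x_ctrl); m2 <- rowMeans(x_stim)
  v1 <- rowSums((x_ctrl - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_stim - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate voxels: zero variance in both windows
  degen <- se2 == 0
  eq <- degen & (m1 == m2)
  t[eq] <- 0; p[eq] <- 1
  ne <- degen & (m1 != m2)
  t[ne] <- sign(m2 - m1)[ne] * Inf; p[ne] <- 0
  list(t = t, p = p, df = df)
}

#' Per-voxel Welch t-test between stimulation and control windows
#'
#' Two-sample t-test with two-tailed p-values and heteroscedastic
#' (unequal-variance, Welch-Satterthwaite) variance assumptions, comparing
#' the stimulation-window samples against the control-window samples of each
#' voxel. By convention a voxel with zero variance in both windows and equal
#' means gets t = 0, p = 1.
#'
#' @inheritParams percent_change
#' @return for a vector input, a list with `t`, `p`, `df`; for a 4D input, a
#'   list of 3D arrays `t` and `p` (and `df`).
#' @export
voxel_t_test <- function(series, timing) {
  vm <- as_voxel_matrix(series)
  if (timing$n_acquisitions > ncol(vm$mat))
    stop("configuration error: timing windows exceed series length")
  ci <- window_idx(timing$control_window); si <- window_idx(timing$stimulation_window)
  if (length(ci) < 2L || length(si) < 2L)
    stop("both windows need >= 2 samples")
  w <- welch_rows(vm$mat[, ci, drop = FALSE], vm$mat[, si, drop = FALSE])
  if (is.null(vm$spatial))
    list(t = as.numeric(w$t), p = as.numeric(w$p), df = as.numeric(w$df))
  else
    list(t = array(w$t, vm$spatial), p = array(w$p, vm$spatial),
         df = array(w$df, vm$spatial))
}

#' Benjamini-Hochberg false discovery rate filter
#'
#' Step-up FDR control over the in-mask p-values: the filter guarantees
#' that, on average, the false-positive detection rate among rejected voxels
#' is below the cutoff `q`.
#'
#' @param p_values numeric vector or array of p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @param mask optional logical vector/array; out-of-mask entries are never
#'   rejected and do not enter the correction.
#' @return logical rejection flags, same shape as `p_values`.
#' @export
fdr_filter <- function(p_values, q = 0.05, mask = NULL) {
  if (q <= 0 || q > 1) stop("rate out of range: q must be in (0, 1]")
  p <- as.vector(p_values)
  keep <- if (is.null(mask)) rep(TRUE, length(p)) else as.vector(mask)
  keep <- keep & !is.na(p)
  rej <- rep(FALSE, length(p))
  if (!any(keep)) {
    message("fdr_filter: empty mask, nothing to test")
  } else {
    rej[keep] <- stats::p.adjust(p[keep], method = "BH") <= q
  }
  if (!is.null(dim(p_values))) dim(rej) <- dim(p_values)
  rej
}

#' Voxel-wise activation map for one subject
#'
#' Combines the percent-change contrast, per-voxel Welch t-tests, the
#' Benjamini-Hochberg FDR filter at rate `q`, and a baseline threshold on
#' percent BOLD change (default 2%, accounting for normal fluctuation of the
#' BOLD signal in the awake rodent brain). A voxel is significant when it is
#' inside the brain mask, survives the FDR filter, and its percent change
#' exceeds the baseline threshold (positive activations only).
#'
#' @param subject_series 4D array (x, y, z, time) in subject space.
#' @param mask 3D logical brain mask matching the spatial grid.
#' @param timing a [scan_timing()].
#' @param baseline_threshold minimum percent BOLD change (default 2).
#' @param q FDR cutoff (default 0.05).
#' @param geometry optional [voxel_geometry()] carried along for export.
#' @return object of class `voxel_activation_map` with 3D fields
#'   `percent_change`, `t_stat`, `p_value`, `significant`, `mask`.
#' @export
activation_map <- function(subject_series, mask, timing,
                           baseline_threshold = 2.0, q = 0.05,
                           geometry = NULL) {
  series <- as.array(subject_series)
  d <- dim(series)
  if (length(d) != 4L) stop("subject_series must be 4D")
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape does not match series")
  if (timing$n_acquisitions > d[4])
    stop("configuration error: timing windows exceed series length")
  pc <- percent_change(series, timing)
  tt <- voxel_t_test(series, timing)
  usable <- mask & !is.na(pc)
  rej <- fdr_filter(tt$p, q = q, mask = usable)
  sig <- rej & usable & !is.na(pc) & (pc > baseline_threshold)
  sig[is.na(sig)] <- FALSE
  structure(list(percent_change = pc, t_stat = tt$t, p_value = tt$p,
                 significant = sig, mask = mask, geometry = geometry,
                 baseline_threshold = baseline_threshold, q = q),
            class = "voxel_activation_map")
}

#' @export
print.voxel_activation_map <- function(x, ...) {
  cat(sprintf("voxel_activation_map: %d/%d in-mask voxels significant (q = %g, threshold %g%%)\n",
              sum(x$significant), sum(x$mask), x$q, x$baseline_threshold))
  invisible(x)
}

#' Composite group map in atlas space
#'
#' Resamples each subject's percent-change map (trilinear) and significance
#' flags (nearest-neighbour) into atlas space through the subject's affine
#' transform, then averages percent change and counts, per voxel, how many
#' subjects were significant there.
#'
#' @param maps list of [activation_map()] results, one per subject, in
#'   subject space.
#' @param transforms list of [affine_transform()]s (subject to atlas), same
#'   length as `maps`.
#' @param atlas a [segmented_atlas()] defining the target grid.
#' @param group optional group label stored in the result.
#' @return object of class `composite_map` with 3D fields
#'   `mean_percent_change` and `n_significant`, plus `n_subjects` and
#'   `group`.
#' @export
composite_map <- function(maps, transforms, atlas, group = NA_character_) {
  if (length(maps) != length(transforms))
    stop("contract violation: one transform per subject map required")
  if (length(maps) == 0L) stop("no subject maps supplied")
  d <- dim(atlas$labels)
  acc_pc <- array(0, d); acc_n <- array(0, d); acc_sig <- array(0L, d)
  for (i in seq_along(maps)) {
    pc <- maps[[i]]$percent_change
    pc[is.na(pc)] <- 0
    pc_a <- apply_transform(pc, transforms[[i]], "linear", fill = 0)
    sig_a <- apply_transform(array(as.integer(maps[[i]]$significant),
                                   dim(maps[[i]]$significant)),
                             transforms[[i]], "nearest", fill = 0L)
    acc_pc <- acc_pc + pc_a
    acc_sig <- acc_sig + sig_a
    acc_n <- acc_n + 1
  }
  structure(list(mean_percent_change = acc_pc / acc_n,
                 n_significant = acc_sig,
                 n_subjects = length(maps), group = group,
                 geometry = atlas$geometry),
            class = "composite_map")
}
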