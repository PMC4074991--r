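# Intensity-based registration: negative normalized cross-correlation cost,
# derivative-free cyclic pattern search, multiresolution pyramid.

# 1 - Pearson correlation between fixed and resampled moving intensities over
# the overlap; large penalty when the overlap is too small to be meaningful.
ncc_cost <- function(fixed_vals, moving_vals, min_overlap) {
  ok <- !is.na(moving_vals)
  if (sum(ok) < min_overlap) return(2)
  f <- fixed_vals[ok]; m <- moving_vals[ok]
  sf <- stats::sd(f); sm <- stats::sd(m)
  if (sf == 0 || sm == 0) return(2)
  1 - stats::cor(f, m)
}

# block-mean downsampling by an integer factor (per-axis, truncating edges)
downsample_block <- function(img, factor) {
  if (factor == 1L) return(img)
  d <- dim(img)
  nd <- pmax(d %/% factor, 1L)
  img <- img[seq_len(nd[1] * factor), seq_len(nd[2] * factor), seq_len(nd[3] * factor), drop = FALSE]
  # average over factor^3 blocks
  a <- array(img, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dim = nd)
}

image_geom_of <- function(img, pixdim = NULL) {
  if (inherits(img, "niftiImage") && is.null(pixdim)) pixdim <- RNifti::pixdim(img)[1:3]
  if (is.null(pixdim)) pixdim <- c(1, 1, 1)
  list(grid_shape = as.integer(dim(as.array(img))[1:3]), voxel_sizes = pixdim)
}

# Derivative-free cyclic pattern search: for each parameter try +/- the
# current step, keep improvements, halve all steps once a full sweep yields
# none. Deterministic, and robust on the nearly flat NCC landscapes that
# defeat simplex methods when two images are already highly correlated.
optimize_level <- function(par, cost_fn, steps, maxit, step_tol = 1e-4) {
  value <- cost_fn(par)
  initial <- value
  evals <- 1L
  cur <- steps
  while (evals < maxit && any(cur > step_tol * steps)) {
    improved_any <- FALSE
    for (j in seq_along(par)) {
      if (cur[j] <= step_tol * steps[j]) next
      repeat {
        cand <- list(`+` = par, `-` = par)
        cand$`+`[j] <- par[j] + cur[j]
        cand$`-`[j] <- par[j] - cur[j]
        v <- c(cost_fn(cand$`+`), cost_fn(cand$`-`))
        evals <- evals + 2L
        k <- which.min(v)
        if (v[k] < value) {
          par <- cand[[k]]; value <- v[k]; improved_any <- TRUE
          if (evals >= maxit) break
        } else break
      }
      if (evals >= maxit) break
    }
    if (!improved_any) cur <- cur / 2
  }
  list(par = par, value = value, initial = initial,
       convergence = if (any(cur > step_tol * steps)) 1L else 0L,
       evals = evals)
}

# shared machinery: cost of parameter vector p on a given pyramid level
level_cost_fn <- function(moving, fixed, mg, fg, rigid, min_overlap_frac = 0.25) {
  grid <- index_grid(fg$grid_shape)
  world <- sweep(grid, 2, fg$voxel_sizes, `*`)
  fixed_vals <- as.vector(fixed)
  min_overlap <- max(20, round(min_overlap_frac * length(fixed_vals)))
  cm <- (mg$grid_shape - 1) / 2 * mg$voxel_sizes
  cf <- (fg$grid_shape - 1) / 2 * fg$voxel_sizes
  function(p) {
    s <- if (rigid) c(1, 1, 1) else p[7:9]
    if (any(s <= 0.5) || any(s >= 2)) return(3)
    A <- rot3(p[4], p[5], p[6]) %*% diag(s)
    b <- cf + p[1:3] - A %*% cm
    Minv <- solve(rbind(cbind(A, b), c(0, 0, 0, 1)))
    src <- world %*% t(Minv[1:3, 1:3]) + matrix(Minv[1:3, 4], nrow(world), 3, byrow = TRUE)
    src_idx <- sweep(src, 2, mg$voxel_sizes, `/`)
    mv <- resample3d(moving, src_idx, method = "linear", fill = NA_real_)
    ncc_cost(fixed_vals, mv, min_overlap)
  }
}

#' Affine subject-to-atlas registration
#'
#' Estimates a 9-parameter transform (translation, rotation, and scaling
#' independently in all three dimensions) mapping `moving` into the space of
#' `fixed`, by minimizing 1 - normalized cross-correlation with a
#' derivative-free cyclic pattern search over a multiresolution pyramid. The
#' returned transform carries its inverse matrix.
#'
#' @param moving,fixed 3D arrays or `niftiImage`s sharing a world-coordinate
#'   convention (RAS+, origin at the grid corner).
#' @param moving_pixdim,fixed_pixdim voxel sizes in mm (taken from the NIfTI
#'   header when the input is a `niftiImage`).
#' @param init optional [affine_transform()] used as the starting point.
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param maxit cost-evaluation cap per pyramid level.
#' @param rigid if `TRUE`, scales are fixed at 1 (6-DOF rigid pre-step).
#' @return an [affine_transform()] (or [rigid_transform()]) with an attached
#'   `cost_trace` attribute: initial and final cost per pyramid level, coarse
#'   to fine (the search never increases the cost within a level).
#' @export
register_affine <- function(moving, fixed, moving_pixdim = NULL,
                            fixed_pixdim = NULL, init = NULL,
                            pyramid = c(4L, 2L, 1L), maxit = 2000L,
                            rigid = FALSE) {
  mg0 <- image_geom_of(moving, moving_pixdim)
  fg0 <- image_geom_of(fixed, fixed_pixdim)
  moving <- as.array(moving); storage.mode(moving) <- "double"
  fixed <- as.array(fixed); storage.mode(fixed) <- "double"
  npar <- if (rigid) 6L else 9L
  par <- if (is.null(init)) c(rep(0, 6), rep(1, 3))[seq_len(npar)]
         else c(init$translations, init$rotations, init$scales)[seq_len(npar)]
  steps <- c(rep(0.4, 3), rep(0.04, 3), rep(0.04, 3))[seq_len(npar)]
  pyramid <- as.integer(pyramid)
  # drop coarse levels whose downsampled grid would be degenerate
  pyramid <- pyramid[vapply(pyramid, function(f)
    f == 1L || all(fg0$grid_shape %/% f >= 4L), logical(1))]
  trace <- NULL
  fit <- NULL
  for (f in pyramid) {
    mv <- downsample_block(moving, f)
    fx <- downsample_block(fixed, f)
    mg <- list(grid_shape = dim(mv), voxel_sizes = mg0$voxel_sizes * f)
    fg <- list(grid_shape = dim(fx), voxel_sizes = fg0$voxel_sizes * f)
    cost <- level_cost_fn(mv, fx, mg, fg, rigid)
    fit <- optimize_level(par, cost, steps, maxit)
    par <- fit$par
    trace <- rbind(trace, data.frame(factor = f, initial_cost = fit$initial,
                                     final_cost = fit$value, evals = fit$evals))
  }
  if (!is.null(fit$convergence) && fit$convergence != 0 && fit$value > 0.5)
    stop(sprintf("registration failed to converge; final cost %.4f", fit$value))
  out <- if (rigid)
    rigid_transform(par[1:3], par[4:6], moving_geom = mg0, fixed_geom = fg0)
  else
    affine_transform(par[1:3], par[4:6], par[7:9], moving_geom = mg0, fixed_geom = fg0)
  attr(out, "cost_trace") <- trace
  out
}

#' Rigid-body motion estimation within a 4D series
#'
#' Estimates, for every frame, a 3D rigid body model with 6 degrees of
#' freedom (3 translations, 3 rotations) relative to a reference frame, by
#' minimizing 1 - normalized cross-correlation. Displacement is the Euclidean
#' norm of the translation vector, reported in micrometres; rotations are
#' reported separately.
#'
#' @param series 4D array (x, y, z, time) or `niftiImage`.
#' @param reference_index 1-based index of the reference frame (default 1).
#' @param pixdim voxel sizes in mm.
#' @param maxit cost-evaluation cap per frame.
#' @return data.frame of class `motion_trace`: one row per frame with columns
#'   `frame`, `tx_mm`, `ty_mm`, `tz_mm`, `rx_rad`, `ry_rad`, `rz_rad`,
#'   `displacement_um`.
#' @export
estimate_motion <- function(series, reference_index = 1L, pixdim = NULL,
                            maxit = 800L) {
  geom <- image_geom_of(series, pixdim)
  series <- as.array(series)
  if (length(dim(series)) != 4L || dim(series)[4] < 2L)
    stop("series must be 4D with at least 2 frames")
  nt <- dim(series)[4]
  if (reference_index < 1L || reference_index > nt)
    stop("reference_index out of range")
  if (any(apply(series, 4, stats::sd) == 0))
    stop("degenerate input: constant (zero-variance) frame in series")
  ref <- series[, , , reference_index]
  steps <- c(rep(0.05, 3), rep(0.01, 3))
  pars <- matrix(0, nt, 6)
  prev <- rep(0, 6)
  for (t in seq_len(nt)) {
    if (t == reference_index) { pars[t, ] <- 0; next }
    frame <- series[, , , t]
    cost <- level_cost_fn(frame, ref, geom, geom, rigid = TRUE)
    fit <- optimize_level(prev, cost, steps, maxit)
    # identical frames: the zero start is already the global optimum
    if (cost(rep(0, 6)) <= fit$value) fit$par <- rep(0, 6)
    pars[t, ] <- fit$par
    prev <- fit$par
  }
  out <- data.frame(frame = seq_len(nt),
                    tx_mm = pars[, 1], ty_mm = pars[, 2], tz_mm = pars[, 3],
                    rx_rad = pars[, 4], ry_rad = pars[, 5], rz_rad = pars[, 6],
                    displacement_um = sqrt(rowSums(pars[, 1:3, drop = FALSE]^2)) * 1000)
  class(out) <- c("motion_trace", "data.frame")
  out
}
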