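# Spatial transforms and resampling.
#
# World coordinates are RAS+ mm with the origin at the corner of voxel
# (0,0,0): x_world = index_0based * voxel_size. Rotations are intrinsic,
# about x then y then z (R = Rx %*% Ry %*% Rz), applied about the physical
# centre of each grid so that zero parameters map grid centres onto each
# other. The forward matrix maps moving-space world coordinates into
# fixed-space world coordinates; the inverse is stored alongside.

rot3 <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

grid_center <- function(geom) (geom$grid_shape - 1) / 2 * voxel_sizes(geom)

# minimal geometry stored inside transforms
as_grid_geom <- function(geometry) {
  list(grid_shape = as.integer(geometry$grid_shape),
       voxel_sizes = voxel_sizes(geometry))
}

#' Nine-parameter affine transform
#'
#' Translation, rotation, and per-axis scaling in all three dimensions,
#' mapping a moving image's physical space into a fixed (atlas) space.
#' The 4x4 homogeneous matrix and its inverse are stored; rotations and
#' scalings act about the grid centres, so all-zero parameters align the two
#' grid centres.
#'
#' @param translations length-3 numeric, mm.
#' @param rotations length-3 numeric, radians (intrinsic x, then y, then z).
#' @param scales length-3 strictly positive numeric.
#' @param moving_geom,fixed_geom [voxel_geometry()] of the moving and fixed
#'   grids (fixed defaults to moving).
#' @return object of class `affine_transform` with fields `translations`,
#'   `rotations`, `scales`, `matrix`, `inverse_matrix`, `moving`, `fixed`.
#' @export
affine_transform <- function(translations = c(0, 0, 0),
                             rotations = c(0, 0, 0),
                             scales = c(1, 1, 1),
                             moving_geom, fixed_geom = moving_geom) {
  if (any(scales <= 0)) stop("scales must be strictly positive")
  mg <- if (inherits(moving_geom, "voxel_geometry")) as_grid_geom(moving_geom) else moving_geom
  fg <- if (inherits(fixed_geom, "voxel_geometry")) as_grid_geom(fixed_geom) else fixed_geom
  A <- rot3(rotations[1], rotations[2], rotations[3]) %*% diag(scales)
  cm <- (mg$grid_shape - 1) / 2 * mg$voxel_sizes
  cf <- (fg$grid_shape - 1) / 2 * fg$voxel_sizes
  b <- cf + translations - A %*% cm
  M <- rbind(cbind(A, b), c(0, 0, 0, 1))
  structure(list(translations = as.numeric(translations),
                 rotations = as.numeric(rotations),
                 scales = as.numeric(scales),
                 matrix = M, inverse_matrix = solve(M),
                 moving = mg, fixed = fg),
            class = "affine_transform")
}

#' Six-parameter rigid-body transform
#'
#' A 3D rigid body model with 6 degrees of freedom (3 translations, 3
#' rotations); a special case of [affine_transform()] with unit scales.
#'
#' @inheritParams affine_transform
#' @return object of class `c("rigid_transform", "affine_transform")`.
#' @export
rigid_transform <- function(translations = c(0, 0, 0), rotations = c(0, 0, 0),
                            moving_geom, fixed_geom = moving_geom) {
  t <- affine_transform(translations, rotations, c(1, 1, 1),
                        moving_geom, fixed_geom)
  class(t) <- c("rigid_transform", class(t))
  t
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("%s: t = (%s) mm, r = (%s) rad, s = (%s)\n",
              if (inherits(x, "rigid_transform")) "rigid_transform" else "affine_transform",
              paste(signif(x$translations, 4), collapse = ", "),
              paste(signif(x$rotations, 4), collapse = ", "),
              paste(signif(x$scales, 4), collapse = ", ")))
  invisible(x)
}

#' Invert an affine transform
#'
#' Swaps the roles of moving and fixed space; the parameter fields are
#' re-derived by decomposing the inverted matrix.
#'
#' @param transform an [affine_transform()].
#' @return the inverse `affine_transform`.
#' @export
invert_transform <- function(transform) {
  p <- decompose_affine(transform$inverse_matrix, transform$fixed, transform$moving)
  out <- affine_transform(p$translations, p$rotations, p$scales,
                          transform$fixed, transform$moving)
  # keep the numerically exact inverse rather than the re-composed one
  out$matrix <- transform$inverse_matrix
  out$inverse_matrix <- transform$matrix
  out
}

# recover (t, r, s) from a 4x4 matrix under this package's conventions
decompose_affine <- function(M, moving, fixed) {
  A <- M[1:3, 1:3]
  s <- sqrt(colSums(A^2))
  R <- A %*% diag(1 / s)
  ry <- asin(max(-1, min(1, R[1, 3])))
  rz <- atan2(-R[1, 2], R[1, 1])
  rx <- atan2(-R[2, 3], R[3, 3])
  cm <- (moving$grid_shape - 1) / 2 * moving$voxel_sizes
  cf <- (fixed$grid_shape - 1) / 2 * fixed$voxel_sizes
  t <- M[1:3, 4] - cf + A %*% cm
  list(translations = as.numeric(t), rotations = c(rx, ry, rz), scales = s)
}

#' Serialize a transform to a JSON text file
#'
#' Writes the parameter list and 4x4 matrices with full precision; reading
#' back reproduces the object bit-exactly.
#'
#' @param transform an [affine_transform()].
#' @param path output file path.
#' @export
write_transform <- function(transform, path) {
  obj <- list(type = if (inherits(transform, "rigid_transform")) "rigid" else "affine",
              translations = transform$translations,
              rotations = transform$rotations,
              scales = transform$scales,
              matrix = transform$matrix,
              inverse_matrix = transform$inverse_matrix,
              moving = transform$moving, fixed = transform$fixed)
  writeLines(jsonlite::serializeJSON(obj, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_transform
#' @return `read_transform` returns the deserialized transform.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  out <- structure(list(translations = obj$translations,
                        rotations = obj$rotations,
                        scales = obj$scales,
                        matrix = obj$matrix,
                        inverse_matrix = obj$inverse_matrix,
                        moving = obj$moving, fixed = obj$fixed),
                   class = "affine_transform")
  if (identical(obj$type, "rigid")) class(out) <- c("rigid_transform", class(out))
  out
}

# Gather values of a 3D array at fractional 0-based voxel coordinates.
# idx: N x 3 matrix. Out-of-grid coordinates return `fill`.
resample3d <- function(img, idx, method = c("linear", "nearest"), fill = NA_real_) {
  method <- match.arg(method)
  d <- dim(img)
  n <- nrow(idx)
  out <- rep(fill, n)
  if (method == "nearest") {
    r <- round(idx)
    ok <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
          r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
          r[, 3] >= 0 & r[, 3] <= d[3] - 1
    lin <- r[ok, 1] + d[1] * (r[ok, 2] + d[2] * r[ok, 3]) + 1
    out[ok] <- img[lin]
    return(out)
  }
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  i0 <- floor(p)
  f <- p - i0
  i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(p)), ncol = 3))
  lin <- function(ix, iy, iz) img[ix + d[1] * (iy + d[2] * iz) + 1]
  v000 <- lin(i0[, 1], i0[, 2], i0[, 3]); v100 <- lin(i1[, 1], i0[, 2], i0[, 3])
  v010 <- lin(i0[, 1], i1[, 2], i0[, 3]); v110 <- lin(i1[, 1], i1[, 2], i0[, 3])
  v001 <- lin(i0[, 1], i0[, 2], i1[, 3]); v101 <- lin(i1[, 1], i0[, 2], i1[, 3])
  v011 <- lin(i0[, 1], i1[, 2], i1[, 3]); v111 <- lin(i1[, 1], i1[, 2], i1[, 3])
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# 0-based voxel index grid of a geometry, as an N x 3 matrix (x fastest)
index_grid <- function(grid_shape) {
  as.matrix(expand.grid(x = seq_len(grid_shape[1]) - 1,
                        y = seq_len(grid_shape[2]) - 1,
                        z = seq_len(grid_shape[3]) - 1,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Resample an image through an affine transform
#'
#' `direction = "forward"` treats `image` as living in the transform's moving
#' space and resamples it onto the fixed grid (subject into atlas).
#' `direction = "inverse"` treats `image` as living in fixed space and
#' resamples it onto the moving grid through the stored inverse matrix
#' (atlas labels back into subject space). Nearest-neighbour interpolation is
#' mandatory for integer label volumes.
#'
#' @param image 3D numeric array.
#' @param transform an [affine_transform()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @param direction `"forward"` or `"inverse"` (see Details).
#' @param fill value for voxels mapping outside the input grid (default 0).
#' @return 3D array on the output grid.
#' @export
apply_transform <- function(image, transform,
                            interpolation = c("linear", "nearest"),
                            direction = c("forward", "inverse"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  direction <- match.arg(direction)
  image <- as.array(image)
  if (interpolation == "linear" && is.integer(image))
    stop("contract violation: linear interpolation requested on an integer label volume")
  if (direction == "forward") {
    out_geom <- transform$fixed; in_geom <- transform$moving
    M <- transform$inverse_matrix
  } else {
    out_geom <- transform$moving; in_geom <- transform$fixed
    M <- transform$matrix
  }
  grid <- index_grid(out_geom$grid_shape)
  world <- sweep(grid, 2, out_geom$voxel_sizes, `*`)
  src <- world %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(world), 3, byrow = TRUE)
  src_idx <- sweep(src, 2, in_geom$voxel_sizes, `/`)
  vals <- resample3d(image, src_idx, method = interpolation, fill = fill)
  out <- array(vals, dim = out_geom$grid_shape)
  if (interpolation == "nearest" && is.integer(image)) storage.mode(out) <- "integer"
  out
}
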