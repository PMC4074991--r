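#' Voxel geometry of an acquisition grid
#'
#' Describes the physical sampling of a 3D image: in-plane voxel width and
#' height, slice thickness, the grid shape in voxels, and (optionally) the
#' in-plane field of view it was derived from. When constructed from
#' acquisition parameters, width = FOV_x / n_x and height = FOV_y / n_y.
#'
#' @param width voxel width in mm (x). Ignored if `field_of_view` is given.
#' @param height voxel height in mm (y). Ignored if `field_of_view` is given.
#' @param slice_thickness slice thickness in mm (z).
#' @param grid_shape integer vector of length 3: voxels along x, y, z.
#' @param field_of_view optional in-plane field of view in mm, length 1
#'   (square) or 2 `(x, y)`; when supplied, in-plane voxel dimensions are
#'   derived as FOV / matrix size.
#' @return An object of class `voxel_geometry` with elements `width`,
#'   `height`, `slice_thickness`, `grid_shape`, `field_of_view`.
#' @examples
#' voxel_geometry(0.097, 0.097, 0.75, grid_shape = c(256, 256, 20))
#' # functional grid: FOV 25 mm, 96 x 96 matrix, 0.75 mm slices
#' voxel_geometry(slice_thickness = 0.75, grid_shape = c(96, 96, 20),
#'                field_of_view = 25)
#' @export
voxel_geometry <- function(width = NULL, height = NULL, slice_thickness,
                           grid_shape, field_of_view = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 1L))
    stop("invalid geometry: grid_shape must be 3 positive integers")
  if (!is.null(field_of_view)) {
    if (length(field_of_view) == 1L) field_of_view <- rep(field_of_view, 2L)
    if (any(field_of_view <= 0)) stop("invalid geometry: field_of_view must be positive")
    width <- field_of_view[1L] / grid_shape[1L]
    height <- field_of_view[2L] / grid_shape[2L]
  }
  if (is.null(width) || is.null(height))
    stop("invalid geometry: supply width and height, or field_of_view")
  dims <- c(width = width, height = height, slice_thickness = slice_thickness)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid geometry: all voxel dimensions must be strictly positive")
  structure(list(width = width, height = height,
                 slice_thickness = slice_thickness,
                 grid_shape = grid_shape,
                 field_of_view = field_of_view),
            class = "voxel_geometry")
}

#' Physical volume of a single voxel
#'
#' Volume of voxel = voxel width x voxel height x slice thickness, in mm^3.
#'
#' @param geometry a [voxel_geometry()] object.
#' @return single numeric, mm^3.
#' @examples
#' g <- voxel_geometry(0.097, 0.097, 0.75, grid_shape = c(256, 256, 20))
#' compute_voxel_volume(g)  # 0.00706 mm^3 to 3 significant figures
#' @export
compute_voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$width * geometry$height * geometry$slice_thickness
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %g x %g x %g mm, grid %s\n",
              x$width, x$height, x$slice_thickness,
              paste(x$grid_shape, collapse = " x ")))
  invisible(x)
}

# mm size per voxel along each axis, as a length-3 vector
voxel_sizes <- function(geometry) {
  c(geometry$width, geometry$height, geometry$slice_thickness)
}
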