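#' Segmented, annotated label atlas
#'
#' Bundles a 3D integer label volume (0 = background / non-brain, k > 0 = the
#' region with id k), a region annotation table, and the voxel geometry. Every
#' nonzero label present in the volume must appear in the region table and
#' region ids must be unique.
#'
#' @param labels 3D array of nonnegative integers.
#' @param regions data.frame with columns `id` (unique positive integers) and
#'   `name` (character).
#' @param geometry a [voxel_geometry()] describing the grid.
#' @return An object of class `segmented_atlas`.
#' @export
segmented_atlas <- function(labels, regions, geometry) {
  labels <- unclass(labels)
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(labels)) != 3L)
    stop("format error: label volume must be a 3D array")
  if (any(abs(labels - round(labels)) > 0))
    stop("format error: label volume must be integer-valued")
  if (any(labels < 0))
    stop("format error: labels must be nonnegative (0 = background)")
  storage.mode(labels) <- "integer"
  if (!all(c("id", "name") %in% names(regions)))
    stop("annotation error: region table needs columns id, name")
  if (anyDuplicated(regions$id))
    stop("annotation error: duplicate region ids in region table")
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, regions$id)
  if (length(missing) > 0L)
    stop("annotation mismatch: labels present in volume but absent from region table: ",
         paste(missing, collapse = ", "))
  if (!identical(as.integer(geometry$grid_shape), as.integer(dim(labels))))
    stop("invalid geometry: grid_shape does not match label volume dimensions")
  regions <- data.frame(id = as.integer(regions$id),
                        name = as.character(regions$name),
                        stringsAsFactors = FALSE)
  structure(list(labels = labels, regions = regions, geometry = geometry),
            class = "segmented_atlas")
}

#' @export
print.segmented_atlas <- function(x, ...) {
  cat(sprintf("segmented_atlas: %d regions, grid %s, %d labelled voxels\n",
              nrow(x$regions), paste(dim(x$labels), collapse = " x "),
              sum(x$labels > 0L)))
  invisible(x)
}

#' Per-region voxel counts and volumes
#'
#' Counts voxels by exact label equality and converts counts to mm^3 with the
#' single-voxel volume from [compute_voxel_volume()]. Regions listed in the
#' annotation table but absent from the volume get a count of zero.
#'
#' @param atlas a [segmented_atlas()].
#' @return data.frame with columns `id`, `name`, `voxel_count`, `volume_mm3`,
#'   one row per region, ordered by region id.
#' @export
compute_region_volumes <- function(atlas) {
  stopifnot(inherits(atlas, "segmented_atlas"))
  vv <- compute_voxel_volume(atlas$geometry)
  lab <- atlas$labels[atlas$labels > 0L]
  counts <- tabulate(lab, nbins = max(c(atlas$regions$id, 1L)))
  ord <- order(atlas$regions$id)
  ids <- atlas$regions$id[ord]
  data.frame(id = ids,
             name = atlas$regions$name[ord],
             voxel_count = counts[ids],
             volume_mm3 = counts[ids] * vv,
             stringsAsFactors = FALSE)
}

#' Read / write a segmented atlas
#'
#' The label volume is stored as an int32 NIfTI-1 image (RAS+ orientation
#' assumed); the region table as a CSV with columns `id,name`. Voxel geometry
#' is taken from the NIfTI header `pixdim` unless an explicit `geometry` is
#' supplied, which then wins with a warning on conflict.
#'
#' @param label_path path to a `.nii`/`.nii.gz` integer label volume.
#' @param region_table_path path to a CSV with columns `id,name`.
#' @param geometry optional [voxel_geometry()] overriding the header.
#' @return a [segmented_atlas()].
#' @export
read_atlas <- function(label_path, region_table_path, geometry = NULL) {
  img <- RNifti::readNifti(label_path)
  arr <- as.array(img)
  if (any(abs(arr - round(arr)) > 1e-6))
    stop("format error: label image is not integer-valued")
  pd <- RNifti::pixdim(img)[1:3]
  hdr_geom <- voxel_geometry(pd[1], pd[2], pd[3], grid_shape = dim(arr))
  if (is.null(geometry)) {
    geometry <- hdr_geom
  } else if (max(abs(voxel_sizes(geometry) - pd)) > 1e-6) {
    warning("explicit geometry conflicts with NIfTI header pixdim; using explicit geometry")
  }
  regions <- utils::read.csv(region_table_path, stringsAsFactors = FALSE)
  segmented_atlas(round(arr), regions, geometry)
}

#' @rdname read_atlas
#' @param atlas a [segmented_atlas()] to write.
#' @export
write_atlas <- function(atlas, label_path, region_table_path) {
  stopifnot(inherits(atlas, "segmented_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- voxel_sizes(atlas$geometry)
  RNifti::writeNifti(img, label_path, datatype = "int32")
  utils::write.csv(atlas$regions, region_table_path, row.names = FALSE)
  invisible(c(label_path, region_table_path))
}

# write a numeric 3D/4D array as NIfTI with the atlas/session voxel sizes
write_volume <- function(arr, geometry, path, datatype = "auto") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_sizes(geometry)[seq_len(min(3L, length(dim(arr))))]
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
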