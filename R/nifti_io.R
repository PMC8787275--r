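# NIfTI-1 input/output, via RNifti. The TR is carried in pixdim[4] as the
# NIfTI standard prescribes; label atlases are written as int16, maps and
# BOLD volumes as float32.

#' Read and write 4D BOLD volumes as NIfTI-1
#'
#' @param volume A [volume4d()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_bold_nifti()` returns `path` invisibly;
#'   `read_bold_nifti()` returns a [volume4d()] with TR taken from
#'   `pixdim[4]` of the header.
#' @export
write_bold_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "volume4d"))
  arr <- volume$data
  attr(arr, "pixdim") <- c(volume$voxel_size, volume$tr)
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("expected a 4D NIfTI volume", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  tr <- pd[4]
  if (!is.finite(tr) || tr <= 0) {
    stop("NIfTI header carries no usable TR in pixdim[4]", call. = FALSE)
  }
  volume4d(array(as.numeric(img), d), tr = tr, voxel_size = pd[1:3])
}

#' Read and write label atlases as NIfTI-1
#'
#' @param atlas A [label_atlas()].
#' @param path File path.
#' @param legend Legend to attach on read; defaults to the package's
#'   8-region convention.
#' @return `write_atlas_nifti()` returns `path` invisibly;
#'   `read_atlas_nifti()` returns a [label_atlas()].
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "label_atlas"))
  img <- RNifti::asNifti(atlas$labels, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(path, legend = default_region_legend()) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D NIfTI label volume", call. = FALSE)
  }
  label_atlas(array(as.integer(img), d), legend = legend)
}

#' Write a 3D voxel map (H', ALFF, SD) as NIfTI-1 float32
#'
#' @param map 3D numeric array (NaN allowed as out-of-mask sentinel).
#' @param path File path.
#' @param voxel_size mm per axis, stored in pixdim.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size = c(1.3, 1.3, 1.3)) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  arr <- array(as.numeric(map), dim(map))
  attr(arr, "pixdim") <- voxel_size
  attr(arr, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}
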