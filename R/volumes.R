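#' 4D BOLD volume
#'
#' A voxel grid with one time series per voxel, plus the acquisition
#' geometry the estimators need: the repetition time (TR, seconds) and the
#' voxel size (mm per axis).
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param tr Repetition time in seconds.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a
#'   diagonal scaling by `voxel_size`.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, tr, voxel_size = c(1.3, 1.3, 1.3), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (x, y, z, time)", call. = FALSE)
  }
  stop_if_not_scalar_number(tr, "tr", positive = TRUE)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(data = data, tr = tr, voxel_size = voxel_size, affine = affine),
    class = "volume4d"
  )
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume4d> %dx%dx%d voxels x %d frames, TR = %g s, voxel %s mm\n",
    d[1], d[2], d[3], d[4], x$tr, paste(signif(x$voxel_size, 3), collapse = "x")
  ))
  invisible(x)
}

#' Integer label atlas
#'
#' Region labels on a voxel grid: 0 is background, positive integers are
#' regions. The legend maps labels to region names; the default follows the
#' pipeline's convention of gray matter plus the seven canonical resting
#' state networks.
#'
#' @param labels 3D integer array.
#' @param legend Named integer vector mapping region names to labels; must
#'   cover every nonzero label present.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, legend = default_region_legend()) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, legend)
  if (length(missing) > 0) {
    stop(sprintf(
      "legend does not cover label(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  structure(list(labels = labels, legend = legend), class = "label_atlas")
}

#' @rdname label_atlas
#' @details `default_region_legend()` returns the 8-region convention used
#'   throughout: 1 = non-network gray matter ("GMother"), 2-8 the seven
#'   networks (visual, somatomotor, dorsal attention, ventral attention,
#'   limbic, frontoparietal, default).
#' @export
default_region_legend <- function() {
  c(
    GMother = 1L, Vis = 2L, SoM = 3L, DAtt = 4L,
    VAtt = 5L, Lim = 6L, FP = 7L, DN = 8L
  )
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  n_in <- sum(x$labels != 0L)
  cat(sprintf(
    "<label_atlas> %dx%dx%d grid, %d labelled voxels, regions: %s\n",
    d[1], d[2], d[3], n_in, paste(names(x$legend), collapse = ", ")
  ))
  invisible(x)
}

# Coerce a mask argument (label_atlas, logical or numeric array) to a
# logical 3D array; any nonzero label counts as in-mask.
as_mask_array <- function(mask) {
  if (inherits(mask, "label_atlas")) {
    return(mask$labels != 0L)
  }
  if (is.array(mask) && length(dim(mask)) == 3L) {
    return(array(as.logical(mask != 0), dim(mask)))
  }
  stop("`mask` must be a label_atlas or a 3D array", call. = FALSE)
}

# Extract the n x V matrix of in-mask voxel time series (V = sum(mask)).
voxel_matrix <- function(volume, mask_arr) {
  n <- dim(volume$data)[4]
  idx <- which(mask_arr)
  matrix(aperm(volume$data, c(4, 1, 2, 3)), nrow = n)[, idx, drop = FALSE]
}
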