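# Binary segmentation masks: the container every stereological operation
# consumes, plus NIfTI-1 round-trip I/O.

#' Create a binary segmentation mask
#'
#' Wraps a 3D array and its voxel spacing into the container used by the
#' point-counting and phantom machinery. Non-zero values are treated as
#' foreground. All downstream geometry works in physical units (mm): voxel
#' `(i, j, k)` (1-based) occupies the half-open box
#' `[(i-1) * spacing, i * spacing)` along each axis.
#'
#' @param data A 3D array (logical, integer or numeric); non-zero = foreground.
#' @param spacing Numeric length-3, voxel edge lengths in mm (anisotropic
#'   spacing is honored by all physical-coordinate computations).
#' @return An object of class `seg_mask` with elements `data` (logical array),
#'   `spacing` and `dim`.
#' @seealso [mask_volume()], [read_mask()], [count_points()]
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes (mm)", call. = FALSE)
  }
  structure(
    list(data = data != 0, spacing = spacing, dim = dim(data)),
    class = "seg_mask"
  )
}

#' Voxel-count volume of a mask
#'
#' @param mask A [seg_mask()].
#' @return Volume in mm^3: number of foreground voxels times voxel volume.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$data) * prod(mask$spacing)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf(
    "<seg_mask> %d x %d x %d voxels, spacing %s mm, %d foreground (%.1f mm^3)\n",
    x$dim[1], x$dim[2], x$dim[3],
    paste(format(x$spacing, trim = TRUE), collapse = " x "),
    sum(x$data), mask_volume(x)
  ))
  invisible(x)
}

# one 6-neighbour dilation step, used by the flood fill
dilate6 <- function(b) {
  d <- dim(b)
  out <- b
  if (d[1] > 1) {
    out[-1, , ] <- out[-1, , ] | b[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | b[-1, , ]
  }
  if (d[2] > 1) {
    out[, -1, ] <- out[, -1, ] | b[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | b[, -1, ]
  }
  if (d[3] > 1) {
    out[, , -1] <- out[, , -1] | b[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | b[, , -1]
  }
  out
}

#' Is the mask foreground a single 6-connected component?
#'
#' Flood fill by iterated 6-neighbour dilation from one foreground voxel.
#' An empty mask is not connected.
#'
#' @param mask A [seg_mask()].
#' @return Logical scalar.
#' @export
is_connected <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  a <- mask$data
  n_fg <- sum(a)
  if (n_fg == 0L) return(FALSE)
  # crop to the foreground bounding box: the fill never leaves it
  bb <- lapply(1:3, function(ax) range(which(apply(a, ax, any))))
  a <- a[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2], bb[[3]][1]:bb[[3]][2],
         drop = FALSE]
  start <- which(a, arr.ind = TRUE)[1L, ]
  comp <- array(FALSE, dim(a))
  comp[start[1], start[2], start[3]] <- TRUE
  n_prev <- 1L
  repeat {
    comp <- dilate6(comp) & a
    n_now <- sum(comp)
    if (n_now == n_prev) break
    n_prev <- n_now
  }
  n_prev == n_fg
}

#' Read a binary segmentation mask from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header `pixdim`. Non-binary input is
#' binarized (non-zero to 1) with a warning.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop("mask file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D mask volume in ", path, call. = FALSE)
  }
  if (!all(arr %in% c(0, 1))) {
    warning("non-binary mask values in ", path, ": binarizing non-zero to 1")
  }
  seg_mask(arr != 0, spacing = RNifti::pixdim(img)[1:3])
}

#' Write a binary segmentation mask to a NIfTI-1 file
#'
#' @param mask A [seg_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), mask$dim))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
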