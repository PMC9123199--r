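# NIfTI volume I/O and the intensity transforms that bracket the network:
# per-volume min-max normalization to [-1, 1], its exact inverse, display
# rescaling to [0, 1], and symmetric zero-padding to the grid the stride-2
# U-Net requires.

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric 3D array with a `voxel_size` attribute (mm per axis).
#'   Volumes containing non-finite voxels are rejected.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '",
                                           path, "': ", conditionMessage(e)))
  v <- as.array(img)
  if (length(dim(v)) != 3L) {
    stop("expected a 3D volume in '", path, "', got ",
         length(dim(v)), " dimensions")
  }
  if (any(!is.finite(v))) {
    stop("volume '", path, "' contains non-finite voxel values")
  }
  v <- array(as.double(v), dim = dim(v))
  attr(v, "voxel_size") <- RNifti::pixdim(img)[1:3]
  v
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Data are stored as 32-bit floats; the voxel size is recorded in the header.
#'
#' @param v Numeric 3D array (a `voxel_size` attribute is used if present).
#' @param path Output file path.
#' @param voxel_size Numeric length-3, mm per axis; overrides the attribute.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, voxel_size = NULL) {
  if (is.null(voxel_size)) voxel_size <- attr(v, "voxel_size")
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  stopifnot(length(dim(v)) == 3L, length(voxel_size) == 3L)
  if (any(!is.finite(v))) stop("refusing to write non-finite voxel values")
  arr <- array(as.double(v), dim = dim(v))
  attr(arr, "pixdim") <- as.numeric(voxel_size)
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min--max normalization to the network range [-1, 1]
#'
#' Maps a volume A to `2 * (A - m) / d` with `m = (max + min) / 2` and
#' `d = max - min`, so the minimum lands exactly on -1 and the maximum on +1.
#' `m` and `d` are kept for exact inversion by [denormalize()].
#'
#' @param A Numeric array with `max(A) > min(A)`.
#' @return A `normalized_volume`: list with `data`, `m`, `d`.
#' @export
#' @examples
#' nv <- normalize_minmax(array(c(2, 10, 6, 4), c(2, 2, 1)))
#' range(nv$data) # -1 1
normalize_minmax <- function(A) {
  if (any(!is.finite(A))) stop("cannot normalize non-finite voxel values")
  mx <- max(A)
  mn <- min(A)
  d <- mx - mn
  if (d <= 0) {
    stop("degenerate input: constant volume has zero intensity range (d = 0)")
  }
  m <- (mx + mn) / 2
  out <- 2 * (A - m) / d
  structure(list(data = out, m = m, d = d), class = "normalized_volume")
}

#' Invert the min--max normalization
#'
#' @param nv A `normalized_volume` from [normalize_minmax()].
#' @return The original-scale array.
#' @export
denormalize <- function(nv) {
  stopifnot(inherits(nv, "normalized_volume"))
  nv$data * nv$d / 2 + nv$m
}

#' Rescale a [-1, 1] volume to [0, 1] for display and evaluation
#'
#' The affine map `0.5 * x + 0.5`.
#'
#' @param x A numeric array in `[-1, 1]` or a `normalized_volume`.
#' @return Array in `[0, 1]`.
#' @export
rescale_display <- function(x) {
  if (inherits(x, "normalized_volume")) x <- x$data
  0.5 * x + 0.5
}

#' Zero-pad a volume to the grid a depth-level network requires
#'
#' Symmetric zero padding (extra voxel on the upper side when odd) to the next
#' multiple of `2^depth` per axis. The padding is recorded so
#' [crop_to_original()] can restore the original shape exactly.
#'
#' @param v Numeric 3D array.
#' @param depth Number of stride-2 levels the volume must survive.
#' @return List with `data` (padded array) and `padding` (3x2 matrix of
#'   low/high pad counts).
#' @export
#' @examples
#' p <- fit_to_network_grid(array(0, c(60, 64, 15)), 4)
#' dim(p$data) # 64 64 16
fit_to_network_grid <- function(v, depth) {
  stopifnot(length(dim(v)) == 3L, depth >= 1)
  d <- dim(v)
  fac <- 2^depth
  target <- ceiling(d / fac) * fac
  extra <- target - d
  lo <- floor(extra / 2)
  hi <- extra - lo
  out <- array(0, dim = target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- v
  padding <- cbind(low = lo, high = hi)
  rownames(padding) <- c("x", "y", "z")
  list(data = out, padding = padding)
}

#' @rdname fit_to_network_grid
#' @param x Padded array.
#' @param padding The 3x2 padding matrix recorded by [fit_to_network_grid()].
#' @export
crop_to_original <- function(x, padding) {
  d <- dim(x)
  lo <- padding[, "low"]
  hi <- padding[, "high"]
  x[lo[1] + seq_len(d[1] - lo[1] - hi[1]),
    lo[2] + seq_len(d[2] - lo[2] - hi[2]),
    lo[3] + seq_len(d[3] - lo[3] - hi[3]), drop = FALSE]
}
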