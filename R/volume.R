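#' Volumetric scalar map with affine and analysis mask
#'
#' A `volume_map` bundles a 3-D scalar array, a 4x4 affine mapping 0-based
#' voxel indices to MNI millimetre coordinates, and a logical analysis mask
#' of the same shape. All spatial operations in the package (kernel map
#' reconstruction, sphere sampling, cluster labelling) work in MNI mm and
#' convert through the affine only.
#'
#' @param data numeric 3-D array of voxel values.
#' @param affine numeric 4x4 matrix; `affine %*% c(i, j, k, 1)` gives the mm
#'   coordinate of the centre of 0-based voxel `(i, j, k)`.
#' @param mask logical array with the same dimensions as `data`; `TRUE`
#'   marks voxels inside the analysis mask. Defaults to all-`TRUE`.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(data, affine, mask = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimensions")
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data))
  if (!identical(dim(mask), dim(data)))
    stop("`mask` dimensions must match `data`")
  structure(list(data = data, affine = affine, mask = array(as.logical(mask), dim(mask))),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$data)
  cat("volume_map:", paste(d, collapse = " x "),
      "voxels,", sum(x$mask), "in mask\n")
  cat("voxel size (mm):", paste(signif(voxel_size(x), 4), collapse = " x "), "\n")
  invisible(x)
}

#' @export
dim.volume_map <- function(x) dim(x$data)

voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Convert between voxel indices and MNI mm coordinates
#'
#' Voxel indices are 0-based, following the NIfTI convention.
#'
#' @param ijk integer matrix (n x 3) of 0-based voxel indices (a vector is
#'   taken as one point).
#' @param affine 4x4 voxel-to-mm affine.
#' @return n x 3 matrix of mm coordinates (or voxel indices for the inverse).
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- rbind2mat(ijk)
  xyz <- cbind(ijk, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_mm
#' @param xyz numeric matrix (n x 3) of mm coordinates.
#' @param round logical; round to the nearest voxel index.
#' @export
mm_to_voxel <- function(xyz, affine, round = TRUE) {
  xyz <- rbind2mat(xyz)
  ijk <- cbind(xyz, 1) %*% t(solve(affine))
  ijk <- ijk[, 1:3, drop = FALSE]
  if (round) ijk <- round(ijk)
  ijk
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  x
}

# 0-based voxel indices (V x 3) of in-mask voxels, in array order
mask_voxels <- function(vol) {
  idx <- which(vol$mask)
  arrayInd(idx, dim(vol$mask)) - 1L
}

#' MNI mm coordinates of in-mask voxel centres
#'
#' @param vol a [volume_map].
#' @return V x 3 matrix of mm coordinates, one row per in-mask voxel in
#'   array (column-major) order — the ordering used by all per-voxel vectors
#'   in [meta_result] objects.
#' @export
mask_coordinates <- function(vol) {
  voxel_to_mm(mask_voxels(vol), vol$affine)
}

# expand a per-in-mask-voxel vector to a full array (0 outside mask)
values_to_array <- function(values, vol, fill = 0) {
  stopifnot(length(values) == sum(vol$mask))
  arr <- array(fill, dim = dim(vol$mask))
  arr[vol$mask] <- values
  arr
}

#' Is an MNI mm point inside the analysis mask?
#'
#' A point is in-mask when its nearest voxel index lies inside the grid and
#' that voxel's mask value is `TRUE`.
#'
#' @param xyz n x 3 matrix of mm coordinates.
#' @param vol a [volume_map].
#' @return logical vector of length n.
#' @export
in_mask <- function(xyz, vol) {
  ijk <- mm_to_voxel(xyz, vol$affine)
  d <- dim(vol$mask)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  out <- rep(FALSE, nrow(ijk))
  if (any(ok)) {
    lin <- 1L + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])
    out[ok] <- vol$mask[lin]
  }
  out
}

#' Read and write volumes as NIfTI-1
#'
#' Round-trips preserve data, affine and shape for finite double data.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume_map] (all-`TRUE` mask);
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume in ", path, ", got ",
         length(dim(arr)), " dimensions")
  volume_map(arr, matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' @rdname read_volume
#' @param vol a [volume_map]; the mask is not stored (write it as its own
#'   volume if needed).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_map"))
  arr <- vol$data
  attr(arr, "pixdim") <- voxel_size(vol)   # so the scaling survives the qform
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
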