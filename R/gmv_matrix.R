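#' Masked subject-by-voxel gray matter volume matrix
#'
#' `gmv_matrix()` bundles a numeric subject x voxel data matrix with the 3D
#' brain mask it was extracted from, the mapping from matrix columns back to
#' mask coordinates, and the image geometry (affine, voxel dimensions).  All
#' Scaled Subprofile Model computation operates on this object.
#'
#' Columns follow a fixed raster order over the true mask voxels (x fastest,
#' then y, then z — the storage order of an R array), so column identity is
#' reproducible across runs, platforms, and subject file orderings.
#'
#' @param data numeric matrix, subjects in rows, masked voxels in columns.
#' @param subject_ids character vector of unique subject labels, one per row.
#' @param mask 3D logical array; `sum(mask)` must equal `ncol(data)`.
#' @param affine 4x4 voxel-to-world affine matrix.
#'
#' @return An object of class `"gmv_matrix"` with elements `data`,
#'   `subject_ids`, `mask`, `voxel_index` (n_voxels x 3 integer matrix of
#'   1-based mask coordinates in raster order), and `geometry` (list with
#'   `affine`, `pixdim`, `dim`).
#' @export
gmv_matrix <- function(data, subject_ids, mask, affine = diag(4)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  n_vox <- sum(mask)
  if (n_vox == 0L) stop("empty mask: no true voxels")
  if (ncol(data) != n_vox)
    stop(sprintf("data has %d columns but mask has %d true voxels",
                 ncol(data), n_vox))
  if (!all(is.finite(data)))
    stop("non-finite values in masked data")
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(data))
    stop("length of subject_ids must equal nrow(data)")
  if (anyDuplicated(subject_ids))
    stop("duplicated subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  rownames(data) <- subject_ids
  structure(
    list(
      data        = data,
      subject_ids = subject_ids,
      mask        = mask,
      voxel_index = mask_voxel_index(mask),
      geometry    = list(affine = affine,
                         pixdim = sqrt(colSums(affine[1:3, 1:3]^2)),
                         dim    = dim(mask))
    ),
    class = "gmv_matrix"
  )
}

#' @export
print.gmv_matrix <- function(x, ...) {
  cat("Masked GMV matrix:", nrow(x$data), "subjects x", ncol(x$data),
      "voxels\n")
  cat("Grid:", paste(x$geometry$dim, collapse = " x "),
      " voxel size:", paste(signif(x$geometry$pixdim, 4), collapse = " x "),
      "mm\n")
  cat("Value range:", paste(signif(range(x$data), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.gmv_matrix <- function(x) dim(x$data)

# Raster-order (x fastest) coordinates of the true mask voxels.
mask_voxel_index <- function(mask) {
  idx <- which(mask)
  arrayInd(idx, dim(mask))
}

# Linear array indices of the mask voxels in raster order.
mask_linear_index <- function(mask) which(mask)

#' Load a set of NIfTI gray matter maps into a masked matrix
#'
#' Reads one NIfTI volume per subject plus a binary mask, checks that every
#' image shares the mask's grid and affine (within an absolute tolerance on
#' affine entries), and extracts the masked voxels into a subject x voxel
#' matrix in fixed raster order.  Values are taken as stored (NIfTI
#' scl_slope/scl_inter scaling is honoured by the reader; no further
#' rescaling is applied, as the model is scale-sensitive before the log
#' transform).
#'
#' @param image_paths character vector of NIfTI file paths, one per subject.
#' @param mask_path path to the NIfTI mask volume (voxels > 0.5 are in-mask).
#' @param subject_ids subject labels; defaults to image file names without
#'   extension.
#' @param affine_tol absolute tolerance for affine agreement (default 1e-4).
#' @return A [gmv_matrix] object.
#' @export
load_gmv_dataset <- function(image_paths, mask_path, subject_ids = NULL,
                             affine_tol = 1e-4) {
  mask_img <- RNifti::readNifti(mask_path)
  if (length(dim(mask_img)) != 3L)
    stop("mask must be a 3D volume: ", mask_path)
  mask <- array(as.array(mask_img) > 0.5, dim = dim(mask_img))
  if (!any(mask)) stop("empty mask: ", mask_path)
  mask_affine <- unclass(RNifti::xform(mask_img))[1:4, 1:4]
  lin <- mask_linear_index(mask)

  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  n <- length(image_paths)
  data <- matrix(NA_real_, n, length(lin))
  for (i in seq_len(n)) {
    img <- RNifti::readNifti(image_paths[i])
    if (!identical(dim(img), dim(mask)))
      stop(sprintf("grid mismatch for %s: image %s vs mask %s",
                   image_paths[i], paste(dim(img), collapse = "x"),
                   paste(dim(mask), collapse = "x")))
    aff <- unclass(RNifti::xform(img))[1:4, 1:4]
    if (max(abs(aff - mask_affine)) > affine_tol)
      stop("affine mismatch (tolerance ", affine_tol, ") for ",
           image_paths[i])
    vals <- as.array(img)[lin]
    if (any(!is.finite(vals)))
      stop("non-finite values inside mask in ", image_paths[i])
    data[i, ] <- vals
  }
  gmv_matrix(data, subject_ids, mask, mask_affine)
}

#' Write a masked voxel vector back out as a 3D NIfTI volume
#'
#' Scatters a per-voxel vector (e.g. a component loading or a bootstrap
#' Z-map) to the mask coordinates of a reference [gmv_matrix], zero outside
#' the mask, preserving the reference affine.
#'
#' @param values numeric vector of length `n_voxels` of the reference.
#' @param reference a [gmv_matrix] supplying mask and geometry.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype (default `"double"` for lossless
#'   round trips; use `"float"` for smaller files).
#' @return The path, invisibly.
#' @export
save_voxel_map <- function(values, reference, path, datatype = "double") {
  stopifnot(inherits(reference, "gmv_matrix"))
  values <- as.numeric(values)
  n_vox <- ncol(reference$data)
  if (length(values) != n_vox)
    stop(sprintf("values has length %d but reference has %d voxels",
                 length(values), n_vox))
  vol <- array(0, dim = reference$geometry$dim)
  vol[mask_linear_index(reference$mask)] <- values
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(reference$geometry$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Read a voxel map written by save_voxel_map back into a masked vector.
#' Extract the masked voxel vector from a NIfTI volume
#'
#' Inverse of [save_voxel_map()]: reads a volume on the reference grid and
#' returns the values at the reference mask voxels in raster order.
#'
#' @inheritParams save_voxel_map
#' @param path NIfTI file to read.
#' @export
load_voxel_map <- function(path, reference) {
  stopifnot(inherits(reference, "gmv_matrix"))
  img <- RNifti::readNifti(path)
  if (!identical(dim(img), dim(reference$mask)))
    stop("grid mismatch between ", path, " and reference mask")
  as.array(img)[mask_linear_index(reference$mask)]
}
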