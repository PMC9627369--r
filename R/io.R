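# NIfTI-1, TSV, and JSON interfaces.

# diagonal affine from voxel size (mm), origin at 0
.nifti_image <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep_len(voxel_size, length(dim(arr)))
  img
}

#' Write a 3D map as NIfTI-1
#'
#' In-mask values are embedded on the grid; out-of-mask voxels are `NaN`
#' (missing marker, never zero-filled). The affine is diagonal with the
#' voxel size.
#'
#' @param values in-mask value vector, or a full 3D array.
#' @param file output path (`.nii` or `.nii.gz`).
#' @param mask_idx,grid_dims,voxel_size grid description (ignored when
#'   `values` is already an array).
#' @return the file path, invisibly.
#' @export
write_nifti_map <- function(values, file, mask_idx = NULL,
                            grid_dims = NULL, voxel_size = c(2, 2, 2)) {
  arr <- if (is.null(dim(values)) || length(dim(values)) < 3) {
    embed_map(values, mask_idx, grid_dims)
  } else {
    values
  }
  arr[is.na(arr)] <- NaN
  RNifti::writeNifti(.nifti_image(arr, voxel_size), file)
  invisible(file)
}

#' Write one subject's seed connectivity map as NIfTI-1
#'
#' File name follows the pattern `<subject>_<seed>_zmap.nii`.
#'
#' @param map an `fc_map`.
#' @param dir output directory.
#' @param voxel_size mm per axis.
#' @param gzip write `.nii.gz` instead of `.nii`.
#' @return the file path, invisibly.
#' @export
write_fc_map <- function(map, dir, voxel_size = c(2, 2, 2), gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, paste0(map$subject_id, "_", map$seed_name, "_zmap.nii",
                             if (gzip) ".gz" else ""))
  write_nifti_map(map$values, f, map$mask_idx, map$grid_dims, voxel_size)
  invisible(f)
}

#' Write an atlas (probability maps + brain mask) as NIfTI-1 files
#'
#' @param atlas a `prob_atlas`.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(atlas$rois)) {
    f <- file.path(dir, paste0("roi_", nm, ".nii"))
    RNifti::writeNifti(.nifti_image(atlas$rois[[nm]], atlas$voxel_size), f)
    paths <- c(paths, f)
  }
  f <- file.path(dir, "brain_mask.nii")
  RNifti::writeNifti(.nifti_image(atlas$brain_mask * 1, atlas$voxel_size), f)
  invisible(c(paths, f))
}

#' Read an atlas written by [write_atlas()]
#' @param dir directory containing `roi_*.nii` and `brain_mask.nii`.
#' @return a `prob_atlas`.
#' @export
read_atlas <- function(dir) {
  mask_img <- RNifti::readNifti(file.path(dir, "brain_mask.nii"))
  vx <- RNifti::pixdim(mask_img)[1:3]
  mask <- array(as.array(mask_img) > 0.5, dim(mask_img))
  roi_files <- list.files(dir, pattern = "^roi_.*\\.nii(\\.gz)?$",
                          full.names = TRUE)
  rois <- list()
  for (f in roi_files) {
    nm <- sub("^roi_(.*)\\.nii(\\.gz)?$", "\\1", basename(f))
    rois[[nm]] <- array(as.array(RNifti::readNifti(f)), dim(mask))
  }
  prob_atlas(rois, mask, vx)
}

#' Write a BOLD series as 4D NIfTI-1
#' @param bold a `bold_series`.
#' @param file output path.
#' @param voxel_size mm per axis.
#' @return the path, invisibly.
#' @export
write_bold <- function(bold, file, voxel_size = c(2, 2, 2)) {
  arr <- bold_to_array(bold)
  arr[is.na(arr)] <- NaN
  img <- .nifti_image(arr, c(voxel_size, bold$tr))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write / read the cohort table as TSV
#' @param tab cohort table.
#' @param file TSV path.
#' @return the path (write) or the table (read).
#' @export
write_cohort <- function(tab, file) {
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Serialize a simulation spec (or any result list) as JSON
#' @param x list-like object.
#' @param file JSON path.
#' @return the path, invisibly.
#' @export
write_json_file <- function(x, file) {
  jsonlite::write_json(unclass(x), file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(file)
}
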