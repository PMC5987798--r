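#' Construct a parcellation object
#'
#' A parcellation is an integer label volume (0 = background) together with a
#' voxel-to-world affine and an optional region table describing each label.
#'
#' @param labels 3-D integer array of region labels; 0 marks background.
#' @param affine 4 x 4 voxel-to-world matrix (mm).
#' @param regions optional data frame with columns `id`, `name`, `hemisphere`
#'   (one of "left", "right", "midline") and `homologue_id` (`NA` for
#'   unpaired/midline regions); every nonzero label in `labels` must appear
#'   exactly once.
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(labels, affine, regions = NULL) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D array")
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stopf("label volume must contain integer values")
  }
  storage.mode(labels) <- "integer"
  check_affine(affine)
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!is.null(regions)) {
    regions <- validate_region_table(regions)
    missing <- setdiff(present, regions$id)
    if (length(missing)) {
      stopf("labels present in volume but absent from region table: %s",
            paste(missing, collapse = ", "))
    }
  }
  structure(
    list(labels = labels, affine = affine, regions = regions),
    class = "parcellation"
  )
}

validate_region_table <- function(regions) {
  need <- c("id", "name", "hemisphere", "homologue_id")
  if (!all(need %in% names(regions))) {
    stopf("region table needs columns: %s", paste(need, collapse = ", "))
  }
  regions <- as.data.frame(regions)[, need]
  regions$id <- as.integer(regions$id)
  regions$homologue_id <- as.integer(regions$homologue_id)
  if (anyDuplicated(regions$id)) stopf("duplicate region ids")
  if (!all(regions$hemisphere %in% c("left", "right", "midline"))) {
    stopf("hemisphere must be left, right or midline")
  }
  paired <- !is.na(regions$homologue_id)
  if (any(paired)) {
    mate <- match(regions$homologue_id[paired], regions$id)
    if (anyNA(mate)) stopf("homologue_id refers to an unknown region")
    back <- regions$homologue_id[mate]
    if (!all(back == regions$id[paired])) {
      stopf("homologue pairing is not symmetric")
    }
  }
  regions
}

#' @export
print.parcellation <- function(x, ...) {
  n <- length(setdiff(unique(as.integer(x$labels)), 0L))
  cat(sprintf("Parcellation: %s grid, %d labelled regions%s\n",
              paste(dim(x$labels), collapse = " x "), n,
              if (is.null(x$regions)) " (no region table)" else ""))
  invisible(x)
}

#' Construct a binary resection mask
#'
#' @param values 3-D array with values in \{0, 1\} (continuous inputs are
#'   binarised at > 0.5), aligned to the parcellation grid.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return an object of class `resection_mask`.
#' @export
resection_mask <- function(values, affine) {
  if (length(dim(values)) != 3L) stopf("mask must be a 3-D array")
  if (any(!is.finite(values))) stopf("mask contains non-finite values")
  values <- array(as.integer(values > 0.5), dim = dim(values))
  check_affine(affine)
  structure(list(values = values, affine = affine), class = "resection_mask")
}

#' @export
print.resection_mask <- function(x, ...) {
  cat(sprintf("Resection mask: %s grid, %d voxels set\n",
              paste(dim(x$values), collapse = " x "), sum(x$values)))
  invisible(x)
}

#' Read an integer label volume from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file with integer voxel values.
#' @param regions optional region table (see [parcellation()]), or a path to
#'   a sidecar TSV readable by [read_region_table()].
#' @return a [parcellation()] object.
#' @export
read_label_volume <- function(path, regions = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  labels <- array(as.vector(img), dim = dim(img))
  if (any(labels != round(labels))) {
    stopf("label volume %s contains non-integer voxel values", path)
  }
  if (is.character(regions)) regions <- read_region_table(regions)
  parcellation(labels, nifti_affine(img), regions)
}

#' Write a parcellation's label volume to NIfTI
#'
#' @param parc a [parcellation()] object.
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(parc, path) {
  write_nifti_volume(parc$labels, parc$affine, path)
}

#' Read a binary resection mask from NIfTI
#'
#' Values are binarised at > 0.5 on load.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [resection_mask()] object.
#' @export
read_resection_mask <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  resection_mask(array(as.vector(img), dim = dim(img)), nifti_affine(img))
}

#' Write a resection mask to NIfTI
#' @param mask a [resection_mask()] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_resection_mask <- function(mask, path) {
  write_nifti_volume(mask$values, mask$affine, path)
}

write_nifti_volume <- function(arr, affine, path) {
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_affine <- function(img) {
  aff <- RNifti::xform(img)
  structure(as.matrix(aff)[1:4, 1:4], dimnames = NULL)
}

#' Read a region table from a sidecar TSV
#'
#' Columns: `id`, `name`, `hemisphere` (left/right/midline), `homologue_id`
#' (empty or NA when unpaired). Label volumes carry no names, so region
#' metadata travels in this sidecar.
#'
#' @param path TSV path.
#' @return validated region data frame.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  validate_region_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a region table to TSV
#' @param regions region data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  write.table(validate_region_table(regions), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
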