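sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a label volume as NIfTI-1 plus a JSON sidecar
#'
#' The voxel grid is stored as integer NIfTI-1 (`int16`) with the physical
#' spacing in the header; the label map and any extra metadata (condition,
#' resection, seed, ...) go into a JSON sidecar next to the image, so a
#' round trip preserves grid values, spacing (to float32 precision) and the
#' label map exactly.
#'
#' @param volume A [label_volume].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path, meta = list()) {
  stopifnot(inherits(volume, "label_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("path must end in .nii or .nii.gz", call. = FALSE)
  img <- RNifti::asNifti(volume$grid)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  sidecar <- c(list(label_map = as.list(volume$label_map),
                    spacing = volume$spacing), meta)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' Rejects non-integer image data, a missing sidecar, and grid labels not
#' present in the sidecar's label map.
#'
#' @param path Path to the `.nii`/`.nii.gz` file.
#' @return A [label_volume]; sidecar metadata beyond the label map is
#'   attached as attribute `"meta"`.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar: ", sc, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (any(arr != round(arr)))
    stop("image contains non-integer data; label volumes must be integer",
         call. = FALSE)
  if (any(arr < 0))
    stop("image contains negative values; labels must be nonnegative",
         call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$label_map))
    stop("sidecar has no label_map", call. = FALSE)
  label_map <- vapply(meta$label_map, as.integer, integer(1))
  spacing <- RNifti::pixdim(img)[1:3]
  vol <- label_volume(array(as.integer(arr), dim(arr)), spacing, label_map)
  attr(vol, "meta") <- meta[setdiff(names(meta), c("label_map", "spacing"))]
  vol
}
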