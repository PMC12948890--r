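# NIfTI and tabular I/O wrappers (RNifti-backed). The pipeline contract
# starts at NIfTI magnitude series plus integer label maps; these helpers
# exist for the script interface and for interoperability, while the core
# functions work on plain arrays.

#' Read a 4-D MESE image series from NIfTI
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`) with echoes on the 4th axis.
#' @return List with `voxels` (4-D array), `voxel_size` (mm) and the RNifti
#'   `image` for affine-preserving writes.
#' @export
read_image_series <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 4L)
    stop("expected a 4-D NIfTI series (X x Y x Z x echoes)", call. = FALSE)
  list(voxels = a, voxel_size = RNifti::pixdim(img)[1:3], image = img)
}

#' Read an integer label map from NIfTI
#'
#' @param path NIfTI file of integer base-label codes.
#' @return 3-D integer array.
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.integer(round(as.numeric(img))), dim(img))
  a
}

#' Write fitted quantitative maps as NIfTI plus a JSON provenance sidecar
#'
#' Writes `<prefix>_t2.nii.gz`, `<prefix>_b1.nii.gz`,
#' `<prefix>_score.nii.gz`, `<prefix>_valid.nii.gz` and
#' `<prefix>_provenance.json` (dictionary hash, package version).
#'
#' @param maps A `quant_maps` object from [fit_map()].
#' @param prefix Output path prefix.
#' @param dict The `emc_dictionary` used (for the provenance hash).
#' @param template Optional RNifti image whose affine/header to reuse.
#' @export
write_quant_maps <- function(maps, prefix, dict = NULL, template = NULL) {
  wr <- function(a, suffix) {
    path <- paste0(prefix, "_", suffix, ".nii.gz")
    if (is.null(template)) RNifti::writeNifti(a, path)
    else RNifti::writeNifti(RNifti::asNifti(a, reference = template), path)
    path
  }
  wr(maps$t2_map, "t2")
  wr(maps$b1_map, "b1")
  wr(maps$score_map, "score")
  wr(maps$validity_mask * 1, "valid")
  jsonlite::write_json(
    list(dictionary_hash = if (!is.null(dict)) dict$hash else NULL,
         package_version = as.character(utils::packageVersion("emcT2"))),
    paste0(prefix, "_provenance.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Export a synthetic study to disk
#'
#' Writes, per participant/knee/timepoint, the rendered series, label map
#' and truth maps as NIfTI, plus `manifest.csv`.
#'
#' @param study A `synthetic_study` from [make_study()].
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$images)) {
    img <- study$images[[nm]]
    RNifti::writeNifti(img$series, file.path(dir, paste0(nm, "_series.nii.gz")))
    RNifti::writeNifti(img$labels, file.path(dir, paste0(nm, "_labels.nii.gz")))
    RNifti::writeNifti(img$truth_t2, file.path(dir, paste0(nm, "_truth_t2.nii.gz")))
  }
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
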