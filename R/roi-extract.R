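#' Mean regional uptake from an intensity volume and a label atlas
#'
#' Averages voxel intensities within each atlas region, producing one row of
#' an SUV table.  Voxels are grouped by the exact integer label they carry in
#' `atlas`; no partial-volume weighting is applied, and the background label
#' 0 never forms an ROI.  Spatial preprocessing (alignment to a template,
#' masking, smoothing) is assumed to have happened upstream.
#'
#' @param volume 3-D numeric array of uptake values.
#' @param atlas 3-D array of non-negative integer ROI codes, same shape as
#'   `volume`.
#' @param roi_codes integer vector of codes to treat as ROIs, in output
#'   order.  Defaults to all positive codes present in `atlas`, sorted.
#' @return Named numeric vector of per-ROI mean uptake, one entry per code in
#'   `roi_codes`, names `"roi<code>"`.
#' @examples
#' vol <- array(1:8, c(2, 2, 2))
#' atl <- array(c(1, 1, 2, 2, 1, 1, 2, 2), c(2, 2, 2))
#' roi_mean_suv(vol, atl)
#' @export
roi_mean_suv <- function(volume, atlas, roi_codes = NULL) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3-D array")
  if (!identical(dim(volume), dim(atlas)))
    stop("volume and atlas shapes differ: ",
         paste(dim(volume), collapse = "x"), " vs ",
         paste(dim(atlas), collapse = "x"))
  if (!all(is.finite(volume))) stop("`volume` contains non-finite values")
  lab <- as.integer(round(atlas))
  if (any(lab < 0L)) stop("atlas labels must be non-negative integers")
  if (is.null(roi_codes)) roi_codes <- sort(unique(lab[lab > 0L]))
  roi_codes <- as.integer(roi_codes)
  if (any(roi_codes == 0L)) stop("background label 0 cannot be an ROI code")
  v <- as.vector(volume)
  means <- vapply(roi_codes, function(code) {
    sel <- lab == code
    if (!any(sel)) stop("ROI code ", code, " has no voxels in the atlas")
    mean(v[sel])
  }, numeric(1))
  names(means) <- paste0("roi", roi_codes)
  means
}

#' Build an SUV table from NIfTI volumes
#'
#' Reads one or more NIfTI-1 intensity volumes plus an integer-label atlas
#' volume and extracts per-ROI mean uptake for each subject via
#' [roi_mean_suv()].
#'
#' @param volume_paths character vector of NIfTI file paths, one per subject.
#' @param atlas_path NIfTI file with integer ROI labels on the same grid.
#' @param roi_codes optional integer vector of ROI codes (see
#'   [roi_mean_suv()]).
#' @param subject_ids subject identifiers; defaults to file base names.
#' @param group group label for the resulting table.
#' @return An [suv_table] with one row per volume.
#' @export
suv_table_from_nifti <- function(volume_paths, atlas_path, roi_codes = NULL,
                                 subject_ids = NULL, group = "ungrouped") {
  atlas <- as.array(RNifti::readNifti(atlas_path))
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  rows <- lapply(volume_paths, function(p)
    roi_mean_suv(as.array(RNifti::readNifti(p)), atlas, roi_codes))
  vals <- do.call(rbind, rows)
  suv_table(vals, subject_ids = subject_ids, roi_labels = colnames(vals),
            group = group)
}
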