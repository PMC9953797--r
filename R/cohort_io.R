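# On-disk cohort layout: one directory per patient containing
# {BL,C2,C4}.nii.gz (4D series), {BL,C2,C4}_mask.nii.gz, and {BL,C2,C4}.json
# sidecars ({"phase_times_s": [...], "spacing_mm": [...]}) -- NIfTI-1 has no
# standard field for DCE phase timing, so timing and spacing travel in the
# sidecar -- plus a top-level cohort.csv (patient_id, label).

#' Write one DCE study (and optional mask) to NIfTI + sidecar JSON
#'
#' @param study a [dce_study()].
#' @param mask optional [tumor_mask()] on the same grid.
#' @param dir patient directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_study <- function(study, mask = NULL, dir) {
  stopifnot(inherits(study, "dce_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, study$timepoint)
  img_path <- paste0(base, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(study$volumes), img_path)
  jsonlite::write_json(
    list(phase_times_s = study$phase_times,
         spacing_mm = study$voxel_spacing),
    paste0(base, ".json"), digits = NA)
  paths <- c(img_path, paste0(base, ".json"))
  if (!is.null(mask)) {
    mask_path <- paste0(base, "_mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask$mask),
                                             dim = dim(mask$mask))),
                       mask_path)
    paths <- c(paths, mask_path)
  }
  invisible(paths)
}

#' Read one DCE study (and mask) from a patient directory
#'
#' @param dir patient directory.
#' @param timepoint `"BL"`, `"C2"`, or `"C4"`.
#' @param patient_id identifier to attach (defaults to the directory name).
#' @param mask_source provenance recorded on the mask.
#' @return list with `study` and `mask` (`NULL` if no mask file exists).
#' @export
read_study <- function(dir, timepoint, patient_id = basename(dir),
                       mask_source = "manual") {
  base <- file.path(dir, timepoint)
  img_path <- paste0(base, ".nii.gz")
  if (!file.exists(img_path)) stop("missing image: ", img_path)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(img_path)
  vols <- array(as.numeric(img), dim = dim(img))
  study <- dce_study(vols, meta$phase_times_s, meta$spacing_mm,
                     patient_id = patient_id, timepoint = timepoint)
  mask <- NULL
  mask_path <- paste0(base, "_mask.nii.gz")
  if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- tumor_mask(array(as.numeric(m) > 0.5, dim = dim(m)),
                       source = mask_source)
  }
  list(study = study, mask = mask)
}

#' Write a synthetic cohort to the on-disk layout
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(cohort$patients)) {
    p <- cohort$patients[[id]]
    for (tp in c("BL", "C2", "C4"))
      write_study(p$studies[[tp]], p$masks[[tp]], file.path(dir, id))
  }
  utils::write.csv(
    data.frame(patient_id = names(cohort$labels),
               label = ifelse(cohort$labels == 1L, "pCR", "non-pCR")),
    file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read the cohort table of an on-disk cohort
#'
#' @param dir cohort directory containing `cohort.csv`.
#' @return data frame with `patient_id` and `label` (`"pCR"`/`"non-pCR"`).
#' @export
read_cohort_table <- function(dir) {
  path <- file.path(dir, "cohort.csv")
  if (!file.exists(path)) stop("missing cohort table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% names(tab)))
    stop("cohort.csv must have columns patient_id and label")
  if (!all(tab$label %in% c("pCR", "non-pCR")))
    stop("labels must be 'pCR' or 'non-pCR'")
  tab
}
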