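# Core DCE containers and voxel-wise enhancement mapping.
#
# A DCE study is stored as a 4D array indexed [row, col, slice, phase] in
# arbitrary intensity units, with phase times in seconds relative to the
# start of contrast injection (pre-contrast phases have time <= 0).

#' Cap applied to SER where the late-phase denominator vanishes
#'
#' Voxels that enhance early but return exactly to the pre-contrast level by
#' the late phase (complete wash-out) have an undefined SER ratio. They are
#' exactly the fast-washout tissue SER is designed to flag, so they are
#' assigned this cap, which sits above the top of the threshold grid (2.0)
#' and therefore passes every SER threshold.
#' @export
SER_CAP <- 10

#' Construct a DCE study
#'
#' @param volumes 4D numeric array indexed `[row, col, slice, phase]`;
#'   arbitrary signal-intensity units.
#' @param phase_times numeric vector, one entry per phase, in seconds
#'   relative to contrast-injection start. Pre-contrast phases have times
#'   `<= 0`. Must be strictly increasing and contain at least one
#'   pre-contrast phase.
#' @param voxel_spacing numeric length-3: (row mm, col mm, slice-increment
#'   mm). The slice component is the per-slice table advance, not the slice
#'   thickness (overlapping-slice protocols make the two differ).
#' @param patient_id opaque identifier string.
#' @param timepoint one of `"BL"`, `"C2"`, `"C4"`.
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(volumes, phase_times, voxel_spacing,
                      patient_id = "unknown",
                      timepoint = c("BL", "C2", "C4")) {
  timepoint <- match.arg(timepoint)
  if (length(dim(volumes)) != 4L)
    stop("`volumes` must be a 4D array [row, col, slice, phase]")
  phase_times <- as.numeric(phase_times)
  if (dim(volumes)[4] != length(phase_times))
    stop("number of phases (", dim(volumes)[4],
         ") does not match length(phase_times) (", length(phase_times), ")")
  if (any(diff(phase_times) <= 0))
    stop("`phase_times` must be strictly increasing")
  if (!any(phase_times <= 0))
    stop("at least one pre-contrast phase (phase_time <= 0) is required")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be 3 positive values (row, col, slice) in mm")
  structure(
    list(volumes = volumes, phase_times = phase_times,
         voxel_spacing = voxel_spacing, patient_id = patient_id,
         timepoint = timepoint),
    class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<dce_study> patient %s, %s: %dx%dx%d voxels, %d phases\n",
              x$patient_id, x$timepoint, d[1], d[2], d[3], d[4]))
  cat("  phase times (s):", paste(x$phase_times, collapse = ", "), "\n")
  cat("  spacing (mm):", paste(x$voxel_spacing, collapse = " x "), "\n")
  invisible(x)
}

spatial_dim <- function(study) dim(study$volumes)[1:3]

phase_volume <- function(study, phase) {
  array(study$volumes[, , , phase, drop = FALSE],
        dim = dim(study$volumes)[1:3])
}

#' Index of the last pre-contrast phase
#' @param study a [dce_study()].
#' @return integer phase index.
#' @export
precontrast_phase <- function(study) {
  max(which(study$phase_times <= 0))
}

#' Select the acquired phase closest to a nominal post-injection time
#'
#' DCE protocols acquire phases every few seconds, so no phase lands exactly
#' on a nominal label like "1 min". The phase with time nearest to
#' `nominal_time` is returned; a pre-contrast request (`nominal_time <= 0`)
#' returns the last pre-contrast phase.
#'
#' @param study a [dce_study()].
#' @param nominal_time target time in seconds after injection.
#' @return integer phase index.
#' @export
select_phase <- function(study, nominal_time) {
  stopifnot(inherits(study, "dce_study"), length(nominal_time) == 1L)
  if (nominal_time <= 0) return(precontrast_phase(study))
  gaps <- diff(study$phase_times)
  tol <- max(gaps) / 2
  d <- abs(study$phase_times - nominal_time)
  if (min(d) > tol)
    stop(sprintf(
      "no acquired phase within %.1f s of nominal time %.1f s for patient %s (%s)",
      tol, nominal_time, study$patient_id, study$timepoint))
  which.min(d)
}

#' Subtraction image for a post-contrast phase
#'
#' Voxelwise difference between a post-contrast phase and the (last)
#' pre-contrast phase.
#'
#' @param study a [dce_study()].
#' @param phase post-contrast phase index.
#' @return 3D numeric array on the study grid.
#' @export
subtraction_image <- function(study, phase) {
  stopifnot(inherits(study, "dce_study"))
  if (study$phase_times[phase] <= 0)
    stop("`phase` must be a post-contrast phase")
  phase_volume(study, phase) - phase_volume(study, precontrast_phase(study))
}

#' Percentage-enhancement (PE) map
#'
#' PE = (S_early - S_pre) / S_pre x 100 per voxel. Undefined where the
#' pre-contrast signal is non-positive; such voxels are flagged invalid,
#' never raised as errors.
#'
#' @param study a [dce_study()].
#' @param early_phase post-contrast phase index for the early phase.
#' @return list with `pe` (3D array, percent; NA where invalid) and `valid`
#'   (3D logical).
#' @export
compute_pe_map <- function(study, early_phase) {
  stopifnot(inherits(study, "dce_study"))
  if (study$phase_times[early_phase] <= 0)
    stop("`early_phase` must be post-contrast")
  pre <- phase_volume(study, precontrast_phase(study))
  early <- phase_volume(study, early_phase)
  valid <- pre > 0
  pe <- array(NA_real_, dim = dim(pre))
  pe[valid] <- (early[valid] - pre[valid]) / pre[valid] * 100
  list(pe = pe, valid = valid)
}

#' Signal-enhancement-ratio (SER) map
#'
#' SER = (S_early - S_pre) / (S_late - S_pre) per voxel. Voxels that do not
#' enhance early (S_early <= S_pre) are flagged invalid. Voxels that enhance
#' early but whose late-phase signal has returned to (or below) the
#' pre-contrast level have a vanishing denominator and are assigned
#' [SER_CAP] with `valid = TRUE`: complete wash-out is the high-SER extreme,
#' not missing data. The degeneracy cutoff is `1e-6` of the study's dynamic
#' range.
#'
#' @param study a [dce_study()].
#' @param early_phase,late_phase post-contrast phase indices, late after
#'   early.
#' @return list with `ser` (3D array, dimensionless; NA where invalid) and
#'   `valid` (3D logical).
#' @export
compute_ser_map <- function(study, early_phase, late_phase) {
  stopifnot(inherits(study, "dce_study"))
  if (study$phase_times[early_phase] <= 0 || study$phase_times[late_phase] <= 0)
    stop("early and late phases must be post-contrast")
  if (study$phase_times[late_phase] <= study$phase_times[early_phase])
    stop("`late_phase` must be acquired after `early_phase`")
  pre <- phase_volume(study, precontrast_phase(study))
  early <- phase_volume(study, early_phase)
  late <- phase_volume(study, late_phase)
  eps <- 1e-6 * diff(range(study$volumes))
  num <- early - pre
  den <- late - pre
  valid <- num > 0
  ser <- array(NA_real_, dim = dim(pre))
  degen <- valid & den <= eps
  ok <- valid & den > eps
  ser[ok] <- num[ok] / den[ok]
  ser[degen] <- SER_CAP
  list(ser = ser, valid = valid)
}

#' Combined PE/SER enhancement maps for one study
#'
#' Computes PE and SER on the phases nearest the requested nominal times and
#' combines their validity flags (`valid` is TRUE only where both maps are
#' defined). Downstream functional-tumor-volume counts use only valid
#' voxels.
#'
#' @param study a [dce_study()].
#' @param early_min nominal early-phase time in minutes (1 or 2.5).
#' @param late_min nominal late-phase time in minutes (default 7).
#' @return object of class `enhancement_maps` with fields `pe`, `ser`,
#'   `valid`, `early_phase_label`.
#' @export
enhancement_maps <- function(study, early_min = 1, late_min = 7) {
  early_phase <- select_phase(study, early_min * 60)
  late_phase <- select_phase(study, late_min * 60)
  p <- compute_pe_map(study, early_phase)
  s <- compute_ser_map(study, early_phase, late_phase)
  structure(
    list(pe = p$pe, ser = s$ser, valid = p$valid & s$valid,
         early_phase_label = early_min),
    class = "enhancement_maps")
}

#' @export
print.enhancement_maps <- function(x, ...) {
  cat(sprintf("<enhancement_maps> early phase %g min: %s voxels, %d valid\n",
              x$early_phase_label, paste(dim(x$pe), collapse = "x"),
              sum(x$valid)))
  invisible(x)
}

#' Construct a tumor mask
#'
#' @param mask logical (or 0/1) 3D array on the study grid.
#' @param source provenance: `"manual"`, `"refined"`, or `"synthetic"`.
#' @return object of class `tumor_mask`.
#' @export
tumor_mask <- function(mask, source = c("manual", "refined", "synthetic")) {
  source <- match.arg(source)
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  m <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(m)) stop("`mask` must not contain NA")
  structure(list(mask = m, source = source), class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %s voxels, %d in mask (%s)\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask), x$source))
  invisible(x)
}

check_same_grid <- function(a_dim, b_dim, what) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(what, ": grids do not match (",
         paste(a_dim, collapse = "x"), " vs ", paste(b_dim, collapse = "x"), ")")
  invisible(TRUE)
}
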