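# Synthetic DCE cohort generator. Axis-aligned ellipsoidal tumors on a
# uniform background, with per-voxel wash-in/wash-out kinetics
# S(t) = S0 * (1 + A * w(t)), where w rises linearly to 1 at the first
# early phase and decays linearly to (1 - W) at the late phase. Ground
# truth (enhancing-voxel counts, diameters, per-voxel A and W) is recorded
# so every pipeline stage can be checked exactly in the zero-noise limit.

#' Configuration for a synthetic DCE cohort
#'
#' Defaults encode the study conditions the generator emulates: a cohort
#' with a 49% pathologic-complete-response (pCR) rate, one pre-contrast
#' phase plus post-injection phases near 1, 2.5 and 7 minutes, and
#' enhancing tumors whose volume shrinks over treatment with far larger
#' shrinkage in the pCR arm (multiplicative volume factors at C2/C4: pCR
#' 0.35/0.02, non-pCR 0.75/0.45), so that on-treatment functional tumor
#' volume separates the arms while baseline volume does not.
#'
#' @param n_patients cohort size.
#' @param pcr_rate probability a patient is in the pCR arm.
#' @param grid_shape voxel grid dimensions (row, col, slice).
#' @param spacing_mm voxel spacing in mm (row, col, slice-increment).
#' @param phase_times_s acquisition times in seconds relative to injection;
#'   must include one pre-contrast phase (`<= 0`).
#' @param radius_mm_mean,radius_mm_sd normal mean/SD of each baseline tumor
#'   semi-axis, mm (per-axis independent draws give unequal diameters).
#' @param shrinkage named list `pCR`/`non_pCR`, each `c(C2 = , C4 = )`
#'   multiplicative volume factors relative to baseline, in `[0, 1]`; the
#'   pCR C4 factor must be below the non-pCR C4 factor.
#' @param washin named list of per-arm `c(min, max)` wash-in amplitude A
#'   ranges (fractional enhancement; A = 0.6 gives PE 60%). The default is
#'   identical in both arms: response status shows in volume shrinkage, not
#'   in a baseline kinetic signature, which keeps baseline FTV
#'   non-discriminative as in the emulated cohort.
#' @param washout named list of per-arm `c(min, max)` washout fraction W
#'   ranges in `[0, 1]`; W = 1 means complete wash-out by the late phase.
#'   Arm-identical by default for the same reason.
#' @param s0 pre-contrast background intensity (arbitrary units).
#' @param noise_sd SD of additive Gaussian intensity noise (same units as
#'   `s0`); 0 gives noiseless phantoms with exact closed-form PE/SER.
#' @param seed integer seed making the cohort bit-for-bit reproducible.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          pcr_rate = 0.49,
                          grid_shape = c(64, 64, 64),
                          spacing_mm = c(1.5, 1.5, 1.5),
                          phase_times_s = c(-10, 60, 150, 420),
                          radius_mm_mean = 14,
                          radius_mm_sd = 3,
                          shrinkage = list(pCR = c(C2 = 0.35, C4 = 0.02),
                                           non_pCR = c(C2 = 0.75, C4 = 0.45)),
                          washin = list(pCR = c(0.5, 2.0),
                                        non_pCR = c(0.5, 2.0)),
                          washout = list(pCR = c(0.2, 1.0),
                                         non_pCR = c(0.2, 1.0)),
                          s0 = 100,
                          noise_sd = 2,
                          seed = 1L) {
  stopifnot(n_patients >= 1, pcr_rate > 0, pcr_rate < 1,
            length(grid_shape) == 3L, all(grid_shape >= 4),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            any(phase_times_s <= 0), all(diff(phase_times_s) > 0),
            radius_mm_mean > 0, radius_mm_sd >= 0, s0 > 0, noise_sd >= 0)
  for (arm in c("pCR", "non_pCR")) {
    sh <- shrinkage[[arm]]
    if (is.null(sh) || any(sh < 0) || any(sh > 1))
      stop("shrinkage factors for arm ", arm, " must lie in [0, 1]")
  }
  if (shrinkage$pCR[["C4"]] >= shrinkage$non_pCR[["C4"]])
    stop("the pCR C4 shrinkage factor must be below the non-pCR C4 factor")
  structure(
    list(n_patients = as.integer(n_patients), pcr_rate = pcr_rate,
         grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         phase_times_s = phase_times_s, radius_mm_mean = radius_mm_mean,
         radius_mm_sd = radius_mm_sd, shrinkage = shrinkage,
         washin = washin, washout = washout, s0 = s0, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Time-course shape factor w(t): 0 pre-injection, linear rise to 1 at the
# early anchor t_e (phase nearest 1 min), then linear decay to (1 - W) at
# the late anchor t_l (last phase). W may be a vector (per voxel).
washin_shape <- function(t, W, t_e, t_l) {
  if (t <= 0) return(rep(0, length(W)))
  if (t <= t_e) return(rep(t / t_e, length(W)))
  1 - W * (t - t_e) / (t_l - t_e)
}

#' Generate one synthetic patient (BL, C2, C4)
#'
#' Draws baseline semi-axes, applies the arm's volume shrinkage at C2/C4,
#' builds the ellipsoid mask, assigns per-voxel wash-in amplitude A and
#' washout fraction W uniformly from the arm's ranges, and synthesizes all
#' phases with additive Gaussian noise. Consumes the current RNG stream
#' (callers seed it; [generate_cohort()] does).
#'
#' @param config a [cohort_config()].
#' @param arm `"pCR"` or `"non_pCR"`.
#' @param patient_id identifier string.
#' @return list with `studies`, `masks` (named BL/C2/C4) and `truth`
#'   (per-timepoint `n_enhancing`, `diameters_cm`, per-voxel `A`, `W`, and
#'   the closed-form `pe`/`ser` at the 1-min early phase).
#' @export
generate_patient <- function(config, arm = c("pCR", "non_pCR"),
                             patient_id = "P000") {
  arm <- match.arg(arm)
  shp <- config$grid_shape
  sp <- config$spacing_mm
  times <- config$phase_times_s
  post <- times[times > 0]
  t_e <- post[which.min(abs(post - 60))]
  t_l <- max(post)
  axes_bl <- pmax(stats::rnorm(3, config$radius_mm_mean, config$radius_mm_sd),
                  1.5)
  center <- shp / 2 + stats::runif(3, -2, 2)
  if (any(center - max(axes_bl) / sp < 1) ||
      any(center + max(axes_bl) / sp > shp))
    stop("tumor exceeds the voxel grid; enlarge grid_shape or shrink radius")
  factors <- c(BL = 1, config$shrinkage[[arm]])
  coords <- lapply(1:3, function(d) (seq_len(shp[d]) - center[d]) * sp[d])
  out <- list(studies = list(), masks = list(), truth = list())
  for (tp in c("BL", "C2", "C4")) {
    axes <- axes_bl * factors[[tp]]^(1 / 3)
    d2 <- outer(outer((coords[[1]] / axes[1])^2, (coords[[2]] / axes[2])^2,
                      "+"),
                (coords[[3]] / axes[3])^2, "+")
    mask <- d2 <= 1
    n_vox <- sum(mask)
    A <- stats::runif(n_vox, config$washin[[arm]][1], config$washin[[arm]][2])
    W <- stats::runif(n_vox, config$washout[[arm]][1], config$washout[[arm]][2])
    vols <- array(config$s0, dim = c(shp, length(times)))
    if (n_vox > 0) {
      for (ph in seq_along(times)) {
        w <- washin_shape(times[ph], W, t_e, t_l)
        v <- vols[, , , ph]
        v[mask] <- config$s0 * (1 + A * w)
        vols[, , , ph] <- v
      }
    }
    if (config$noise_sd > 0)
      vols <- vols + stats::rnorm(length(vols), 0, config$noise_sd)
    # closed-form kinetics at the 1-min anchor: w(t_e) = 1, w(t_l) = 1 - W
    ser_true <- ifelse(W >= 1, SER_CAP, 1 / (1 - W))
    out$studies[[tp]] <- dce_study(vols, times, sp, patient_id, tp)
    out$masks[[tp]] <- tumor_mask(mask, source = "synthetic")
    out$truth[[tp]] <- list(
      n_enhancing = n_vox,
      diameters_cm = 2 * axes / 10,
      A = A, W = W,
      pe_1min = 100 * A,
      ser_1min = ser_true)
  }
  out
}

#' Generate a synthetic DCE cohort
#'
#' Seeds the RNG from `config$seed`, draws each patient's arm from a
#' binomial with the configured pCR rate, and generates every patient's
#' three-timepoint study set with ground truth. The same configuration and
#' seed always produce a byte-identical cohort. Holds all volumes in
#' memory, which is intended for desk-scale cohorts; large cohorts are
#' analyzed streamed via [analyze_cohort()] on a `cohort_config`.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `patients` (per-patient
#'   studies/masks/truth), `labels` (1 = pCR), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  labels <- stats::rbinom(config$n_patients, 1, config$pcr_rate)
  if (min(sum(labels), sum(1 - labels)) < 2L)
    stop("cohort draw produced fewer than 2 patients in one response class; ",
         "increase n_patients or change the seed")
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  patients <- vector("list", config$n_patients)
  names(patients) <- ids
  for (i in seq_len(config$n_patients)) {
    arm <- if (labels[i] == 1L) "pCR" else "non_pCR"
    patients[[i]] <- generate_patient(config, arm, ids[i])
  }
  structure(
    list(patients = patients,
         labels = stats::setNames(labels, ids),
         config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%d pCR / %d non-pCR), grid %s\n",
              length(x$patients), sum(x$labels), sum(1 - x$labels),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}
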