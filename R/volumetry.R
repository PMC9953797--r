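# Tumor volumetrics: LD, ellipsoidal TV, ETV, FTV (single pair and full
# threshold grid), relative changes, and histogram-threshold mask
# refinement. Spacing is supplied in mm; conversion to cm^3 happens once at
# the etv/ftv boundary.

#' Orthogonal tumor diameters
#'
#' Anteroposterior, craniocaudal, and transverse tumor dimensions measured
#' on a subtraction image, in cm.
#'
#' @param anteroposterior,craniocaudal,transverse diameters in cm, all
#'   `>= 0`.
#' @param phase_label nominal minutes of the subtraction image the
#'   measurement was made on (1 or 7).
#' @return object of class `diameter_triplet`.
#' @export
diameter_triplet <- function(anteroposterior, craniocaudal, transverse,
                             phase_label = 1) {
  d <- c(anteroposterior = anteroposterior, craniocaudal = craniocaudal,
         transverse = transverse)
  if (any(!is.finite(d)) || any(d < 0))
    stop("all three diameters must be finite and >= 0 (cm)")
  structure(list(diameters = d, phase_label = phase_label),
            class = "diameter_triplet")
}

as_diameters <- function(d) {
  if (inherits(d, "diameter_triplet")) return(unname(d$diameters))
  d <- as.numeric(d)
  if (length(d) != 3L || any(d < 0)) stop("expected 3 nonnegative diameters")
  d
}

#' Ellipsoidal tumor volume (TV)
#'
#' TV = (4/3) pi (AP/2)(CC/2)(TR/2), the volume of the ellipsoid with the
#' three orthogonal diameters as axes. Symmetric under permutation of the
#' diameters.
#'
#' @param d a [diameter_triplet()] or numeric length-3 (cm).
#' @return volume in cm^3.
#' @export
ellipsoid_tv <- function(d) {
  d <- as_diameters(d)
  4 / 3 * pi * prod(d / 2)
}

#' Longest tumor dimension (LD)
#'
#' @param d a [diameter_triplet()] or numeric length-3 (cm).
#' @return the largest of the three diameters, cm.
#' @export
longest_dimension <- function(d) {
  max(as_diameters(d))
}

#' Voxel volume in cm^3 from mm spacing
#' @param spacing_mm numeric length-3 (row, col, slice-increment) in mm.
#' @return single voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  prod(spacing_mm) / 1000
}

#' Enhanced tumor volume (ETV)
#'
#' Voxel volume times the number of voxels in the segmented region.
#'
#' @param mask a [tumor_mask()] (or logical 3D array).
#' @param spacing_mm voxel spacing in mm (row, col, slice-increment).
#' @return volume in cm^3 (0 for an empty mask).
#' @export
etv <- function(mask, spacing_mm) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  voxel_volume_cm3(spacing_mm) * sum(m)
}

#' Functional tumor volume (FTV) at one PE/SER threshold pair
#'
#' Voxel volume times the number of segmented voxels whose PE and SER both
#' lie strictly above the thresholds. Only voxels with a defined (valid)
#' PE/SER pair can count; the strict inequality means non-enhancing voxels
#' (PE <= 0) are excluded even at threshold 0.
#'
#' @param mask a [tumor_mask()].
#' @param maps an [enhancement_maps()] on the same grid.
#' @param pe_thr PE threshold in percent, `>= 0`.
#' @param ser_thr SER threshold, dimensionless, `>= 0`.
#' @param spacing_mm voxel spacing in mm.
#' @return volume in cm^3.
#' @export
ftv <- function(mask, maps, pe_thr, ser_thr, spacing_mm) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  check_same_grid(dim(m), dim(maps$pe), "ftv")
  stopifnot(pe_thr >= 0, ser_thr >= 0)
  sel <- m & maps$valid
  n <- sum(maps$pe[sel] > pe_thr & maps$ser[sel] > ser_thr)
  voxel_volume_cm3(spacing_mm) * n
}

#' FTV over a full PE x SER threshold grid
#'
#' Computes [ftv()] for every threshold pair of `grid` via a 2D cumulative
#' histogram (each voxel is binned once by how many PE and SER thresholds
#' lie strictly below its values, then counts are accumulated), which is
#' exactly equivalent to evaluating `ftv()` pairwise.
#'
#' @inheritParams ftv
#' @param grid a [build_grid()] threshold grid.
#' @return numeric matrix `[pe index, ser index]` of volumes in cm^3, with
#'   the threshold values as dimnames.
#' @export
ftv_grid <- function(mask, maps, grid, spacing_mm) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  check_same_grid(dim(m), dim(maps$pe), "ftv_grid")
  stopifnot(inherits(grid, "threshold_grid"))
  npe <- length(grid$pe)
  nser <- length(grid$ser)
  sel <- m & maps$valid
  pe <- maps$pe[sel]
  ser <- maps$ser[sel]
  counts <- matrix(0, npe, nser)
  if (length(pe)) {
    # a = number of PE thresholds strictly below the voxel's PE (0..npe);
    # the voxel passes threshold i (1-based) iff a >= i, and likewise for SER.
    a <- findInterval(pe, grid$pe, left.open = TRUE)
    b <- findInterval(ser, grid$ser, left.open = TRUE)
    keep <- a > 0 & b > 0
    if (any(keep)) {
      h <- matrix(0, npe, nser)
      tab <- table(factor(a[keep], levels = seq_len(npe)),
                   factor(b[keep], levels = seq_len(nser)))
      h[] <- as.numeric(tab)
      # reverse 2D cumulative sum: counts[i, j] = sum_{a>=i, b>=j} h[a, b]
      h <- apply(h, 2, function(col) rev(cumsum(rev(col))))
      counts <- t(apply(h, 1, function(row) rev(cumsum(rev(row)))))
    }
  }
  vol <- voxel_volume_cm3(spacing_mm) * counts
  dimnames(vol) <- list(pe = grid$pe, ser = grid$ser)
  vol
}

#' Relative change between baseline and a later measurement
#'
#' (later - baseline) / baseline x 100, in percent. Undefined (returned as
#' `NA`) when baseline is not strictly positive: a zero later value is an
#' expected complete response (-100%), but a zero baseline leaves no
#' denominator and propagates as missing rather than an error.
#'
#' @param baseline,later measurement values (same units); vectorized.
#' @return percent change, `NA` where `baseline <= 0`.
#' @export
relative_change <- function(baseline, later) {
  out <- rep(NA_real_, length(baseline))
  ok <- is.finite(baseline) & baseline > 0
  out[ok] <- (later[ok] - baseline[ok]) / baseline[ok] * 100
  out
}

# Exact Otsu threshold over a sample: candidate cuts are the observed
# values; returns the cut t maximizing the between-class variance of the
# split {x <= t} vs {x > t} (smallest t on ties), or NA if < 2 distinct
# values.
otsu_threshold <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(NA_real_)
  cnt <- tabulate(match(x, u))
  n <- length(x)
  csum <- cumsum(cnt)
  cmean <- cumsum(cnt * u)
  total <- cmean[length(u)]
  k <- seq_len(length(u) - 1L)
  w0 <- csum[k] / n
  w1 <- 1 - w0
  m0 <- cmean[k] / csum[k]
  m1 <- (total - cmean[k]) / (n - csum[k])
  bcv <- w0 * w1 * (m0 - m1)^2
  u[k[which.max(bcv)]]
}

#' Histogram-threshold refinement of a tumor mask
#'
#' Semiautomatic refinement step: within the manual mask, an Otsu threshold
#' is computed over the subtraction-image intensities and only voxels
#' strictly above it are retained (the enhancing mode of the masked
#' histogram). The result is always a subset of the input mask. Masks whose
#' intensities are constant (degenerate histogram) are returned unchanged,
#' as are empty masks.
#'
#' @param mask a [tumor_mask()].
#' @param sub_image 3D subtraction image on the mask grid.
#' @return a [tumor_mask()] with `source = "refined"`.
#' @export
refine_mask_histogram <- function(mask, sub_image) {
  stopifnot(inherits(mask, "tumor_mask"))
  check_same_grid(dim(mask$mask), dim(sub_image), "refine_mask_histogram")
  vals <- sub_image[mask$mask]
  if (length(vals) == 0L) return(tumor_mask(mask$mask, source = "refined"))
  thr <- otsu_threshold(vals)
  if (is.na(thr)) return(tumor_mask(mask$mask, source = "refined"))
  refined <- mask$mask & sub_image > thr
  tumor_mask(refined, source = "refined")
}

#' Bounding-box diameters of a mask (synthetic-data helper)
#'
#' Converts a mask to a [diameter_triplet()] from its axis-aligned extents
#' times the voxel spacing. Intended for synthetic axis-aligned ellipsoid
#' tumors, where the extents recover the ground-truth diameters to within a
#' voxel; it does not replace caliper measurement on real images.
#'
#' @param mask a [tumor_mask()] (or logical 3D array).
#' @param spacing_mm voxel spacing in mm (row, col, slice-increment).
#' @param phase_label nominal minutes label carried on the triplet.
#' @return a [diameter_triplet()] in cm; all-zero for an empty mask.
#' @export
mask_to_diameters <- function(mask, spacing_mm, phase_label = 1) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  spacing_mm <- as.numeric(spacing_mm)
  if (!any(m)) return(diameter_triplet(0, 0, 0, phase_label))
  idx <- which(m, arr.ind = TRUE)
  extent_vox <- apply(idx, 2, function(v) diff(range(v)) + 1L)
  d_cm <- extent_vox * spacing_mm / 10
  diameter_triplet(d_cm[1], d_cm[2], d_cm[3], phase_label)
}
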