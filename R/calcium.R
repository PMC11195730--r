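#' False-positive-rate curve over an HU threshold sweep
#'
#' On contrast CT the lumen is bright, so a fixed HU cutoff misclassifies
#' lumen voxels as calcium. For each candidate threshold `t` the false
#' positive rate is the fraction of above-threshold voxels in the region of
#' interest that belong to the contrast lumen:
#' `fpr(t) = #\{lumen voxels with HU >= t\} / #\{ROI voxels with HU >= t\}`.
#' Thresholds where no ROI voxel reaches `t` get `fpr = 0` but are flagged
#' infeasible so [select_threshold()] skips them.
#'
#' @param volume a [voxel_volume()] in HU.
#' @param lumen_mask logical array, the contrast-lumen voxels; must be a
#'   subset of `roi_mask`.
#' @param roi_mask logical array covering the aortic-root region of interest.
#' @param thresholds increasing numeric HU grid; default integer steps from
#'   the 50th to the 99.9th percentile of ROI HU.
#' @return Tibble of class `fpr_curve` with columns `threshold`, `lumen_count`,
#'   `roi_count`, `fpr`, `feasible`.
#' @examples
#' v <- voxel_volume(array(c(100, 200, 300, 500, 600, 0, 0, 0), c(2, 2, 2)))
#' roi <- array(c(rep(TRUE, 5), rep(FALSE, 3)), c(2, 2, 2))
#' lum <- array(c(rep(TRUE, 3), rep(FALSE, 5)), c(2, 2, 2))
#' fpr_curve(v, lum, roi, thresholds = c(50, 250, 400))
#' @export
fpr_curve <- function(volume, lumen_mask, roi_mask, thresholds = NULL) {
  check_aligned(volume, lumen_mask, "lumen_mask")
  check_aligned(volume, roi_mask, "roi_mask")
  if (!any(roi_mask)) stop("`roi_mask` is empty", call. = FALSE)
  if (any(lumen_mask & !roi_mask)) {
    stop("`lumen_mask` must be a subset of `roi_mask`", call. = FALSE)
  }
  roi_hu <- as.numeric(volume)[as.logical(roi_mask)]
  lumen_hu <- as.numeric(volume)[as.logical(lumen_mask)]
  if (is.null(thresholds)) {
    q <- quantile(roi_hu, c(0.5, 0.999), names = FALSE)
    thresholds <- seq(floor(q[1]), ceiling(q[2]), by = 1)
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L) stop("empty threshold grid", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  # count of x >= t: length(x) minus #\{x < t\} from the sorted vector
  sl <- sort(lumen_hu)
  sr <- sort(roi_hu)
  lumen_count <- length(sl) - findInterval(thresholds, sl, left.open = TRUE)
  roi_count <- length(sr) - findInterval(thresholds, sr, left.open = TRUE)
  fpr <- ifelse(roi_count > 0, lumen_count / roi_count, 0)
  out <- tibble::tibble(
    threshold = thresholds,
    lumen_count = as.integer(lumen_count),
    roi_count = as.integer(roi_count),
    fpr = fpr,
    feasible = roi_count > 0L
  )
  class(out) <- c("fpr_curve", class(out))
  out
}

#' Select the calcific threshold from an FPR curve
#'
#' Returns the smallest threshold whose false positive rate does not exceed
#' `epsilon` (among thresholds with at least one above-threshold ROI voxel).
#' This is the minimum calcific threshold `t_min`: everything at or above it
#' is treated as calcium with at most an `epsilon` fraction of lumen
#' contamination.
#'
#' @param curve an [fpr_curve()].
#' @param epsilon tolerated lumen fraction among detected voxels, in `[0, 1)`.
#' @return The selected threshold (HU). Errors if no feasible threshold
#'   attains `fpr <= epsilon`; the message suggests the lumen mean + 3 SD
#'   fallback (see [fallback_threshold()]).
#' @export
select_threshold <- function(curve, epsilon = 0.01) {
  stopifnot(nrow(curve) > 0, epsilon >= 0, epsilon < 1)
  ok <- curve$feasible & curve$fpr <= epsilon
  if (!any(ok)) {
    stop(sprintf(paste0(
      "no threshold reaches fpr <= %g; consider the fallback ",
      "fallback_threshold(lumen_hu) = lumen mean + 3*SD"), epsilon), call. = FALSE)
  }
  min(curve$threshold[ok])
}

#' Fallback calcific threshold from lumen statistics
#'
#' Used when the FPR sweep has no feasible point (e.g. heavy lumen/calcium
#' overlap): threshold = lumen mean + `k` standard deviations.
#'
#' @param lumen_hu numeric vector of lumen HU values.
#' @param k number of SDs above the lumen mean (default 3).
#' @return Threshold in HU.
#' @export
fallback_threshold <- function(lumen_hu, k = 3) {
  mean(lumen_hu) + k * sd(lumen_hu)
}

#' Segment calcium at a fixed threshold
#'
#' Thresholds the ROI at `t_min`, removes connected components smaller than
#' `min_component_mm3` (26-connectivity), and records the HU standard
#' deviation `sigma` over the surviving calcific voxels — the scale parameter
#' of the intensity weighting in [intensity_weight()].
#'
#' @param volume a [voxel_volume()].
#' @param roi_mask logical array restricting the search.
#' @param t_min calcific threshold in HU (from [select_threshold()]).
#' @param min_component_mm3 minimum component volume retained, mm^3;
#'   default 1 suppresses single-voxel contrast noise at typical spacings.
#' @return Object of class `calcific_segmentation`: list with `mask` (logical
#'   array), `t_min`, `hu_sd` (0 when empty), `voxel_mm3`, `components`
#'   (tibble: `component`, `n_voxels`, `volume_mm3`, `peak_hu`), and
#'   `n_voxels`.
#' @export
segment_calcium <- function(volume, roi_mask, t_min, min_component_mm3 = 1) {
  check_aligned(volume, roi_mask, "roi_mask")
  if (!any(roi_mask)) stop("`roi_mask` is empty", call. = FALSE)
  stopifnot(is.finite(t_min), min_component_mm3 >= 0)
  vox <- voxel_size_mm3(volume)
  raw <- roi_mask & (volume >= t_min)
  lab <- cc_label3d(as.logical(raw), dim(volume), connectivity = 26L)
  keep_mask <- array(FALSE, dim(volume))
  comp_tbl <- tibble::tibble(component = integer(), n_voxels = integer(),
                             volume_mm3 = numeric(), peak_hu = numeric())
  k <- attr(lab, "n_components")
  if (k > 0) {
    counts <- tabulate(lab[lab > 0L], nbins = k)
    keep <- which(counts * vox >= min_component_mm3)
    if (length(keep)) {
      keep_mask <- array(lab %in% keep, dim(volume))
      peak <- vapply(keep, function(ci) max(volume[lab == ci]), numeric(1))
      comp_tbl <- tibble::tibble(
        component = seq_along(keep),
        n_voxels = counts[keep],
        volume_mm3 = counts[keep] * vox,
        peak_hu = peak
      )
    }
  }
  hu <- as.numeric(volume)[as.logical(keep_mask)]
  structure(
    list(
      mask = keep_mask,
      t_min = t_min,
      hu_sd = if (length(hu) >= 2) sd(hu) else 0,
      voxel_mm3 = vox,
      components = comp_tbl,
      n_voxels = length(hu),
      volume = volume
    ),
    class = "calcific_segmentation"
  )
}

#' @export
print.calcific_segmentation <- function(x, ...) {
  cat(sprintf(
    "<calcific_segmentation> t_min = %.1f HU, %d voxels (%.2f mm^3), sigma = %.1f HU, %d component(s)\n",
    x$t_min, x$n_voxels, x$n_voxels * x$voxel_mm3, x$hu_sd, nrow(x$components)
  ))
  invisible(x)
}

#' Total calcific volume of a segmentation
#' @param seg a `calcific_segmentation`.
#' @return Volume in mm^3.
#' @export
calcific_volume <- function(seg) {
  seg$n_voxels * seg$voxel_mm3
}

#' Craniocaudal zone volumes along the root axis
#'
#' Splits the calcific volume along the normalized axial coordinate `zeta`
#' into the leaflet zone (above the annular plane, `0 < zeta <= leaflet_upper`)
#' and the annular/LVOT zone (`-alvot_lower <= zeta <= 0`; the annular plane
#' itself counts as annular/LVOT). The device landing zone is their union.
#'
#' @param seg a `calcific_segmentation`.
#' @param frame an [aortic_frame()].
#' @param leaflet_upper upper leaflet bound as a fraction of the STJ height
#'   `h` (default 0.5).
#' @param alvot_lower depth of the annular/LVOT zone below the annular plane,
#'   as a fraction of `h` (default 0.15).
#' @return Tibble with one row: `leaflet_mm3`, `alvot_mm3`, `dlz_mm3`.
#' @export
zone_volumes <- function(seg, frame, leaflet_upper = 0.5, alvot_lower = 0.15) {
  stopifnot(inherits(seg, "calcific_segmentation"), inherits(frame, "aortic_frame"),
            leaflet_upper > 0, alvot_lower > 0)
  if (seg$n_voxels == 0) {
    return(tibble::tibble(leaflet_mm3 = 0, alvot_mm3 = 0, dlz_mm3 = 0))
  }
  idx <- mask_indices(seg$mask)
  zeta <- to_cylindrical(voxel_coords(seg$volume, idx), frame)$zeta
  leaflet <- sum(zeta > 0 & zeta <= leaflet_upper) * seg$voxel_mm3
  alvot <- sum(zeta >= -alvot_lower & zeta <= 0) * seg$voxel_mm3
  tibble::tibble(leaflet_mm3 = leaflet, alvot_mm3 = alvot,
                 dlz_mm3 = leaflet + alvot)
}

#' Agatston score on non-contrast CT
#'
#' Standard per-slice scoring: within each axial slice, lesions are connected
#' regions of HU >= 130 with area >= `min_area_mm2`; each contributes
#' `weight * area` where the weight is 1/2/3/4 for a peak HU of
#' 130-199 / 200-299 / 300-399 / >= 400. Assumes the standard ~3 mm slice
#' protocol, so no slice-thickness renormalization is applied.
#'
#' @param volume a [voxel_volume()] from non-contrast CT.
#' @param slice_axis axis index (1-3) perpendicular to the slices; default 3.
#' @param pixel_area in-plane pixel area in mm^2; derived from the affine
#'   when NULL.
#' @param min_area_mm2 minimum lesion area (default 1 mm^2).
#' @return Non-negative Agatston score (dimensionless).
#' @export
agatston <- function(volume, slice_axis = 3, pixel_area = NULL, min_area_mm2 = 1) {
  stopifnot(slice_axis %in% 1:3)
  a <- vol_affine(volume)[1:3, 1:3]
  in_plane <- setdiff(1:3, slice_axis)
  if (is.null(pixel_area)) {
    pixel_area <- prod(vapply(in_plane, function(j) sqrt(sum(a[, j]^2)), numeric(1)))
  }
  d <- dim(volume)
  total <- 0
  for (s in seq_len(d[slice_axis])) {
    sl <- switch(slice_axis,
                 volume[s, , , drop = TRUE],
                 volume[, s, , drop = TRUE],
                 volume[, , s, drop = TRUE])
    m <- sl >= 130
    if (!any(m)) next
    # 2-D labelling via the 3-D labeller on a 1-deep slab (8-connectivity)
    lab <- cc_label3d(as.logical(m), c(dim(sl), 1L), connectivity = 26L)
    k <- attr(lab, "n_components")
    if (k == 0) next
    counts <- tabulate(lab[lab > 0L], nbins = k)
    for (ci in seq_len(k)) {
      area <- counts[ci] * pixel_area
      if (area < min_area_mm2) next
      peak <- max(sl[lab == ci])
      w <- if (peak >= 400) 4 else if (peak >= 300) 3 else if (peak >= 200) 2 else 1
      total <- total + w * area
    }
  }
  total
}
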