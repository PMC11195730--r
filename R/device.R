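#' Area cover index
#'
#' Percentage oversizing of the transcatheter heart valve (THV) relative to
#' the measured annulus:
#' `(nominal THV area - measured annular area) / nominal THV area * 100`.
#' Positive values mean the device is larger than the annulus; negative values
#' indicate an undersized device.
#'
#' @param nominal_thv_area nominal device area, mm^2 (> 0). Vectorized.
#' @param measured_annular_area measured annular area, mm^2.
#' @return Signed percentage.
#' @examples
#' area_cover_index(450, 400) # 11.11
#' @export
area_cover_index <- function(nominal_thv_area, measured_annular_area) {
  if (any(!is.finite(nominal_thv_area)) || any(nominal_thv_area <= 0)) {
    stop("`nominal_thv_area` must be positive", call. = FALSE)
  }
  (nominal_thv_area - measured_annular_area) / nominal_thv_area * 100
}

#' Deviation from nominal device expansion
#'
#' The expanded valve diameter is measured in three longitudinal views at the
#' cusp plane; the mean diameter gives the expanded area under a circular
#' assumption, and the deviation is the signed percentage difference from the
#' device's nominal area (negative = under-expansion).
#'
#' @param d1,d2,d3 measured diameters, mm (> 0).
#' @param nominal_area nominal expanded device area, mm^2 (> 0).
#' @return Tibble with one row: `mean_diameter_mm`, `expanded_area_mm2`,
#'   `nominal_area_mm2`, `deviation_pct`.
#' @examples
#' expansion_deviation(20, 20, 20, nominal_area = 400)
#' @export
expansion_deviation <- function(d1, d2, d3, nominal_area) {
  d <- c(d1, d2, d3)
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameters must be positive", call. = FALSE)
  if (!is.finite(nominal_area) || nominal_area <= 0) {
    stop("`nominal_area` must be positive", call. = FALSE)
  }
  mean_d <- mean(d)
  area <- pi * (mean_d / 2)^2
  tibble::tibble(
    mean_diameter_mm = mean_d,
    expanded_area_mm2 = area,
    nominal_area_mm2 = nominal_area,
    deviation_pct = (area - nominal_area) / nominal_area * 100
  )
}
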