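#' Configuration of the 18-region cylindrical map
#'
#' The device landing zone is divided into 3 cusps x 2 angular sectors per
#' cusp x 3 radial rings = 18 regions. Radial ring edges are fractions of the
#' annular radius `r`; the angular split within each cusp is at the sector
#' midline; the longitudinal window is the DLZ extent in normalized `zeta`
#' over which the bullseye aggregates (longitudinal collapse).
#'
#' Region ids R1-R18 are assigned deterministically: cusps in the order
#' NCC, RCC, LCC; within a cusp, sector 1 then sector 2 (increasing angle from
#' the cusp's starting commissure); within a sector, rings inner to outer.
#' So R1 = NCC/sector 1/ring 1, R2 = NCC/sector 1/ring 2, ...,
#' R18 = LCC/sector 2/ring 3.
#'
#' @param radial_edges strictly increasing fractions of `r`, the outer edge of
#'   each ring; voxels beyond the last edge clamp into the outer ring.
#' @param sectors_per_cusp angular subdivisions per cusp (default 2).
#' @param zeta_lower,zeta_upper longitudinal window in units of `h`
#'   (defaults match the DLZ zone bounds: `-0.15` to `0.5`).
#' @param cusp_order the cusp ordering that fixes region numbering.
#' @param weight_steps `"continuous"` (default) for the linear intensity
#'   weight, or `"quartile"` to step the weight at 0.25/0.5/0.75/1.
#' @return A `region_config` list.
#' @export
region_config <- function(radial_edges = c(1 / 3, 2 / 3, 1),
                          sectors_per_cusp = 2L,
                          zeta_lower = -0.15, zeta_upper = 0.5,
                          cusp_order = c("NCC", "RCC", "LCC"),
                          weight_steps = c("continuous", "quartile")) {
  stopifnot(length(radial_edges) >= 1, all(diff(radial_edges) > 0),
            all(radial_edges > 0), sectors_per_cusp >= 1,
            zeta_lower < zeta_upper, length(cusp_order) == 3L)
  weight_steps <- match.arg(weight_steps)
  structure(
    list(
      radial_edges = radial_edges,
      n_radial = length(radial_edges),
      sectors_per_cusp = as.integer(sectors_per_cusp),
      zeta_lower = zeta_lower, zeta_upper = zeta_upper,
      cusp_order = cusp_order,
      weight_steps = weight_steps,
      n_regions = 3L * as.integer(sectors_per_cusp) * length(radial_edges)
    ),
    class = "region_config"
  )
}

# Region id from cusp index (1..3 in config$cusp_order), sector (1..S),
# ring (1..K): consecutive numbering cusp-major, then sector, then ring.
region_id <- function(cusp_idx, sector, ring, config) {
  K <- config$n_radial
  S <- config$sectors_per_cusp
  (cusp_idx - 1L) * S * K + (sector - 1L) * K + ring
}

# The full 18-row skeleton in deterministic R1..Rn order.
region_skeleton <- function(config) {
  K <- config$n_radial
  S <- config$sectors_per_cusp
  tibble::tibble(
    region = paste0("R", seq_len(config$n_regions)),
    cusp = rep(config$cusp_order, each = S * K),
    sector = rep(rep(seq_len(S), each = K), times = 3L),
    ring = rep(seq_len(K), times = 3L * S)
  )
}

#' Assign calcific voxels to the 18-region map
#'
#' Each calcific voxel inside the longitudinal window gets exactly one region
#' id from its normalized cylindrical coordinates: the cusp sector containing
#' its bearing `phi` (half-open sectors, boundary belongs counterclockwise),
#' the angular sub-sector within the cusp (split at equal angular fractions of
#' the cusp sector), and the radial ring containing `rho` (clamped into the
#' outer ring when `rho` exceeds the last edge). Voxels outside the window
#' are reported with region `NA` and excluded from the bullseye.
#'
#' @param seg a `calcific_segmentation` from [segment_calcium()].
#' @param frame an [aortic_frame()].
#' @param config a [region_config()].
#' @return Tibble with one row per calcific voxel: `i`, `j`, `k` (0-based
#'   indices), `hu`, `rho`, `phi`, `zeta`, `cusp`, `sector`, `ring`, `region`
#'   (`"R1"`..`"R18"` or `NA` outside the window).
#' @export
assign_regions <- function(seg, frame, config = region_config()) {
  stopifnot(inherits(seg, "calcific_segmentation"), inherits(frame, "aortic_frame"),
            inherits(config, "region_config"))
  if (seg$n_voxels == 0) {
    return(tibble::tibble(
      i = integer(), j = integer(), k = integer(), hu = numeric(),
      rho = numeric(), phi = numeric(), zeta = numeric(),
      cusp = character(), sector = integer(), ring = integer(), region = character()
    ))
  }
  idx <- mask_indices(seg$mask)
  cyl <- to_cylindrical(voxel_coords(seg$volume, idx), frame)
  hu <- seg$volume[seg$mask]

  in_window <- cyl$zeta >= config$zeta_lower & cyl$zeta <= config$zeta_upper

  cusp <- cusp_of(cyl$phi, frame)
  cusp_idx <- match(cusp, config$cusp_order)

  # angular position within the (half-open) cusp sector, as a fraction
  starts <- frame$sector_start
  sec_i <- findInterval(cyl$phi, starts)
  sec_i[sec_i == 0L] <- 3L
  a0 <- starts[sec_i]
  width <- (starts[ifelse(sec_i == 3L, 1L, sec_i + 1L)] - a0) %% 360
  width[width == 0] <- 360
  frac <- ((cyl$phi - a0) %% 360) / width
  sector <- pmin(floor(frac * config$sectors_per_cusp) + 1L, config$sectors_per_cusp)

  ring <- findInterval(cyl$rho, config$radial_edges, left.open = TRUE) + 1L
  ring <- pmin(ring, config$n_radial) # clamp beyond the outer edge

  region <- ifelse(
    in_window,
    paste0("R", region_id(cusp_idx, sector, ring, config)),
    NA_character_
  )
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3], hu = hu,
    rho = cyl$rho, phi = cyl$phi, zeta = cyl$zeta,
    cusp = cusp, sector = as.integer(sector), ring = as.integer(ring),
    region = region
  )
}

#' Per-region volumes, mean HU, and intensity weights
#'
#' Aggregates a voxel labelling into the bullseye table: per region, volume =
#' voxel count x voxel volume, mean HU over the region's voxels, the
#' intensity weight from [intensity_weight()], and the weighted volume.
#' Empty regions have volume 0, `mean_hu` reported as `t_min` and weight 0.25
#' (they contribute nothing to any score).
#'
#' @param seg the `calcific_segmentation` the labelling came from (supplies
#'   `t_min`, `hu_sd` and the voxel volume).
#' @param labelling output of [assign_regions()].
#' @param config the [region_config()] used for the labelling.
#' @return Tibble of class `regional_table`, rows R1..R18 in order: `region`,
#'   `cusp`, `sector`, `ring`, `n_voxels`, `volume_mm3`, `mean_hu`, `weight`,
#'   `weighted_volume_mm3`. Attributes `t_min`, `hu_sd`,
#'   `excluded_volume_mm3` (calcific volume outside the zeta window).
#' @export
regional_table <- function(seg, labelling, config = region_config()) {
  stopifnot(inherits(seg, "calcific_segmentation"))
  skel <- region_skeleton(config)
  inside <- labelling[!is.na(labelling$region), , drop = FALSE]
  agg <- inside |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_voxels = dplyr::n(), mean_hu = mean(.data$hu),
                     .groups = "drop")
  out <- skel |>
    dplyr::left_join(agg, by = "region") |>
    dplyr::mutate(
      n_voxels = dplyr::coalesce(.data$n_voxels, 0L),
      volume_mm3 = .data$n_voxels * seg$voxel_mm3,
      mean_hu = dplyr::coalesce(.data$mean_hu, seg$t_min),
      # empty regions pin to the floor weight (they contribute nothing anyway)
      weight = ifelse(.data$n_voxels == 0L, 0.25,
                      intensity_weight(.data$mean_hu, seg$t_min, seg$hu_sd,
                                       steps = config$weight_steps)),
      weighted_volume_mm3 = .data$volume_mm3 * .data$weight
    )
  attr(out, "t_min") <- seg$t_min
  attr(out, "hu_sd") <- seg$hu_sd
  attr(out, "excluded_volume_mm3") <- sum(is.na(labelling$region)) * seg$voxel_mm3
  class(out) <- c("regional_table", class(out))
  out
}

#' Intensity weighting factor
#'
#' Maps a region's mean HU onto `[0.25, 1]` linearly over the scale from the
#' minimum calcific threshold `t_min` to `t_min + 4 * sigma`, where `sigma` is
#' the HU standard deviation of the entire calcific volume:
#' `w = 0.25 + 0.75 * clip((mean_hu - t_min) / (4 * sigma), 0, 1)`.
#' Regions at the threshold get the floor weight 0.25; regions four standard
#' deviations above it (or more) get full weight 1. With `sigma = 0`
#' (degenerate scale) any region at or above `t_min` gets weight 1.
#'
#' @param mean_hu region mean HU (vectorized).
#' @param t_min minimum calcific threshold, HU.
#' @param hu_sd HU standard deviation of the whole calcific volume (>= 0).
#' @param steps `"continuous"` (default) or `"quartile"` to round the weight
#'   up to the next of 0.25, 0.5, 0.75, 1.
#' @return Weights in `[0.25, 1]`.
#' @export
intensity_weight <- function(mean_hu, t_min, hu_sd, steps = c("continuous", "quartile")) {
  steps <- match.arg(steps)
  stopifnot(hu_sd >= 0, is.finite(t_min))
  if (hu_sd == 0) {
    w <- ifelse(mean_hu >= t_min, 1, 0.25)
  } else {
    frac <- pmin(pmax((mean_hu - t_min) / (4 * hu_sd), 0), 1)
    w <- 0.25 + 0.75 * frac
  }
  if (steps == "quartile") {
    w <- pmax(0.25, ceiling(w / 0.25) * 0.25)
  }
  w
}

#' Per-cusp intensity-weighted calcification scores
#'
#' Sums the weighted volumes of the six regions belonging to each cusp,
#' yielding the DLZ intensity-weighted calcification volume for NCC, RCC and
#' LCC.
#'
#' @param table a [regional_table()].
#' @return Tibble with one row: `NCC`, `RCC`, `LCC` (mm^3, weighted).
#' @export
cusp_scores <- function(table) {
  expected <- 3L * max(table$sector) * max(table$ring)
  if (nrow(table) != expected || anyNA(table$weighted_volume_mm3)) {
    stop("regional table is incomplete", call. = FALSE)
  }
  table |>
    dplyr::group_by(.data$cusp) |>
    dplyr::summarise(score = sum(.data$weighted_volume_mm3), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cusp", values_from = "score") |>
    dplyr::select(dplyr::any_of(c("NCC", "RCC", "LCC")))
}

#' Write the bullseye table to CSV
#'
#' One row per region in deterministic R1..R18 order; columns `region`,
#' `cusp`, `sector`, `ring`, `n_voxels`, `volume_mm3`, `mean_hu`, `weight`,
#' `weighted_volume_mm3`. Re-reading reproduces the volumes bit-exactly
#' (full-precision decimal output).
#'
#' @param table a [regional_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
bullseye_export <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Bullseye (polar) plot of a regional table
#'
#' Renders the 18-region map as a polar heat map, either of the weighted
#' regional volume (default), raw volume, mean HU, or weight.
#'
#' @param object a [regional_table()].
#' @param fill which column to map to fill colour.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.regional_table <- function(object, fill = c("weighted_volume_mm3", "volume_mm3",
                                                     "mean_hu", "weight"), ...) {
  fill <- match.arg(fill)
  S <- max(object$sector)
  K <- max(object$ring)
  edges <- c(0, seq_len(K) / K)
  cusp_levels <- unique(object$cusp)
  df <- object |>
    dplyr::mutate(
      cusp_idx = match(.data$cusp, cusp_levels),
      a0 = (.data$cusp_idx - 1) * 120 + (.data$sector - 1) * 120 / S,
      a1 = .data$a0 + 120 / S,
      r0 = edges[.data$ring],
      r1 = edges[.data$ring + 1]
    )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$a0, xmax = .data$a1, ymin = .data$r0, ymax = .data$r1,
      fill = .data[[fill]]
    ), colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$a0 + .data$a1) / 2, y = (.data$r0 + .data$r1) / 2,
      label = .data$region
    ), size = 2.6) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = (seq_along(cusp_levels) - 1) * 120 + 60,
                                labels = cusp_levels) +
    ggplot2::scale_fill_viridis_c(name = fill) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank())
}

#' @rdname autoplot.regional_table
#' @param table a [regional_table()].
#' @export
plot_bullseye <- function(table, fill = "weighted_volume_mm3") {
  autoplot.regional_table(table, fill = fill)
}
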