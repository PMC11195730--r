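#' Patient-specific aortic-root coordinate frame
#'
#' Builds the normalization frame used by every regional computation: the
#' annular plane (through the annular centre, orthogonal to the annulus-to-STJ
#' axis), the area-derived annular radius `r = sqrt(A / pi)`, the
#' sinotubular-junction height `h`, and the en-face bearings of the three
#' commissures. All downstream coordinates are expressed relative to this
#' frame, which is what makes the 18-region map patient-invariant.
#'
#' The en-face angular reference direction is the in-plane projection of the
#' first commissure point; angles increase counterclockwise when viewed from
#' the aortic (STJ) side. Each inter-commissure sector is labelled with the
#' cusp shared by its two bounding commissures (e.g. the sector between the
#' RCC_NCC and NCC_LCC commissures is the NCC), unless an explicit
#' `cusp_order` overrides this.
#'
#' @param annular_centre length-3 numeric, annular centre in physical mm.
#' @param stj_point length-3 numeric, a point on the axis at the sinotubular
#'   junction, physical mm.
#' @param commissures named list of three length-3 points (physical mm). The
#'   default names `NCC_LCC`, `LCC_RCC`, `RCC_NCC` identify which two cusps
#'   each commissure separates and drive automatic sector labelling.
#' @param annular_area annular area in mm^2 (`> 0`).
#' @param cusp_order optional character vector of three labels assigning cusps
#'   to the angular sectors in increasing-angle order; overrides name-based
#'   labelling.
#' @return An object of class `aortic_frame`: list with `centre`, `axis`
#'   (unit), `r` (mm), `h` (mm), `annular_area` (mm^2), `e1`/`e2` (in-plane
#'   orthonormal basis), `commissure_angles` (degrees, named), `sector_start`
#'   (sorted sector boundaries, degrees) and `sector_cusp` (labels).
#' @examples
#' fr <- aortic_frame(
#'   annular_centre = c(0, 0, 0), stj_point = c(0, 0, 18),
#'   commissures = list(
#'     NCC_LCC = c(12, 0, 0),
#'     LCC_RCC = c(-6, 10.4, 0),
#'     RCC_NCC = c(-6, -10.4, 0)
#'   ),
#'   annular_area = pi * 144
#' )
#' fr$r # 12 mm
#' @export
aortic_frame <- function(annular_centre, stj_point, commissures, annular_area,
                         cusp_order = NULL) {
  annular_centre <- as.numeric(annular_centre)
  stj_point <- as.numeric(stj_point)
  stopifnot(length(annular_centre) == 3L, length(stj_point) == 3L)
  if (!is.finite(annular_area) || annular_area <= 0) {
    stop("`annular_area` must be a positive area in mm^2", call. = FALSE)
  }
  if (length(commissures) != 3L) stop("exactly three commissure points required", call. = FALSE)
  commissures <- lapply(commissures, as.numeric)

  ax <- stj_point - annular_centre
  h <- sqrt(sum(ax^2))
  if (h < 1e-9) stop("degenerate axis: STJ point coincides with annular centre", call. = FALSE)
  axis <- ax / h
  r <- sqrt(annular_area / pi)

  # In-plane orthonormal basis: e1 from the first commissure's projection,
  # e2 = axis x e1 so that phi increases counterclockwise seen from the STJ side.
  proj <- function(p) {
    v <- p - annular_centre
    v - sum(v * axis) * axis
  }
  p1 <- proj(commissures[[1]])
  n1 <- sqrt(sum(p1^2))
  if (n1 < 1e-9) stop("first commissure point projects onto the annular centre", call. = FALSE)
  e1 <- p1 / n1
  e2 <- cross3(axis, e1)

  ang <- vapply(commissures, function(p) {
    v <- proj(p)
    if (sqrt(sum(v^2)) < 1e-9) {
      stop("a commissure point projects onto the annular centre", call. = FALSE)
    }
    (atan2(sum(v * e2), sum(v * e1)) * 180 / pi) %% 360
  }, numeric(1))
  if (length(unique(round(ang %% 360, 6))) < 3L) {
    stop("commissure points are not distinct in the en-face view", call. = FALSE)
  }

  ord <- order(ang)
  sector_start <- ang[ord]
  nms <- names(commissures)
  if (!is.null(cusp_order)) {
    stopifnot(length(cusp_order) == 3L)
    sector_cusp <- as.character(cusp_order)
  } else if (!is.null(nms) && all(grepl("^[A-Z]+_[A-Z]+$", nms))) {
    # The sector [a_i, a_{i+1}) is the cusp shared by its bounding commissures.
    parts <- strsplit(nms[ord], "_")
    sector_cusp <- vapply(seq_len(3), function(i) {
      nxt <- if (i == 3L) 1L else i + 1L
      shared <- intersect(parts[[i]], parts[[nxt]])
      if (length(shared) != 1L) {
        stop("commissure names do not determine the cusp sectors; supply `cusp_order`",
             call. = FALSE)
      }
      shared
    }, character(1))
  } else {
    stop("commissures must be named (e.g. NCC_LCC) or `cusp_order` supplied", call. = FALSE)
  }

  structure(
    list(
      centre = annular_centre, axis = axis, r = r, h = h,
      annular_area = annular_area, e1 = e1, e2 = e2,
      commissure_angles = setNames(ang, nms),
      sector_start = sector_start, sector_cusp = sector_cusp
    ),
    class = "aortic_frame"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.aortic_frame <- function(x, ...) {
  cat(sprintf(
    "<aortic_frame> r = %.2f mm, h = %.2f mm; sectors [%s) -> %s\n",
    x$r, x$h,
    paste(sprintf("%.1f", x$sector_start), collapse = ", "),
    paste(x$sector_cusp, collapse = "/")
  ))
  invisible(x)
}

#' Normalized cylindrical coordinates of physical points
#'
#' Maps physical points into the frame's dimensionless cylindrical
#' coordinates: `rho` = in-plane distance to the axis divided by the annular
#' radius `r`, `phi` = en-face bearing in degrees in `[0, 360)`, `zeta` =
#' signed axial distance to the annular plane divided by the STJ height `h`
#' (positive toward the STJ).
#'
#' @param points n x 3 numeric matrix (or length-3 vector) of physical mm.
#' @param frame an [aortic_frame()].
#' @return Tibble with columns `rho`, `phi`, `zeta`.
#' @export
to_cylindrical <- function(points, frame) {
  stopifnot(inherits(frame, "aortic_frame"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  v <- sweep(points, 2, frame$centre)
  zmm <- as.vector(v %*% frame$axis)
  x <- as.vector(v %*% frame$e1)
  y <- as.vector(v %*% frame$e2)
  rho <- sqrt(x^2 + y^2) / frame$r
  phi <- (atan2(y, x) * 180 / pi) %% 360
  phi[rho == 0] <- 0
  tibble::tibble(rho = rho, phi = phi, zeta = zmm / frame$h)
}

#' Inverse of [to_cylindrical()]: physical point from (rho, phi, zeta)
#'
#' @param rho,phi,zeta normalized cylindrical coordinates (phi in degrees).
#' @param frame an [aortic_frame()].
#' @return n x 3 matrix of physical mm.
#' @export
from_cylindrical <- function(rho, phi, zeta, frame) {
  stopifnot(inherits(frame, "aortic_frame"))
  a <- phi * pi / 180
  ip <- outer(rho * frame$r * cos(a), frame$e1) +
    outer(rho * frame$r * sin(a), frame$e2)
  ip + outer(zeta * frame$h, frame$axis) +
    matrix(frame$centre, nrow = length(rho), ncol = 3, byrow = TRUE)
}

#' Cusp sector containing an en-face bearing
#'
#' Sectors are half-open `[a, b)` in increasing angle, so a bearing exactly on
#' a commissure belongs to the sector counterclockwise of it; `phi` is reduced
#' modulo 360 first.
#'
#' @param phi numeric vector of bearings in degrees.
#' @param frame an [aortic_frame()].
#' @return Character vector of cusp labels.
#' @export
cusp_of <- function(phi, frame) {
  stopifnot(inherits(frame, "aortic_frame"))
  phi <- phi %% 360
  starts <- frame$sector_start
  # sector i covers [starts[i], starts[i+1]) with wrap-around below starts[1]
  idx <- findInterval(phi, starts)
  idx[idx == 0L] <- 3L # below the first boundary -> wrap-around sector
  frame$sector_cusp[idx]
}

#' Read / write the landmark JSON sidecar
#'
#' The sidecar carries the manually measured landmarks in physical mm:
#' `annular_centre`, `stj_point`, `commissures` (named `NCC_LCC`, `LCC_RCC`,
#' `RCC_NCC`), and `annular_area_mm2`.
#'
#' @param path JSON file path.
#' @return `read_landmarks()` returns an [aortic_frame()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("annular_centre", "stj_point", "commissures", "annular_area_mm2")
  missing <- setdiff(req, names(lm))
  if (length(missing)) {
    stop("landmark JSON missing field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  aortic_frame(lm$annular_centre, lm$stj_point, as.list(lm$commissures),
               lm$annular_area_mm2)
}

#' @rdname read_landmarks
#' @param landmarks list with the sidecar fields (see above).
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
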