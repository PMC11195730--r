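#' Specification of a synthetic aortic-root phantom
#'
#' Describes a contrast-filled cylindrical lumen (bright, Gaussian HU) inside
#' a darker background, containing hyperdense spherical calcific deposits at
#' known normalized cylindrical positions. Deposit positions are specified in
#' (rho, phi, zeta) so their ground-truth region membership is analytic.
#' Defaults emulate typical contrast-CT conditions: lumen ~ N(400, 30) HU,
#' deposits ~ N(900, 50) HU, 0.5 mm isotropic voxels, annular radius 12 mm,
#' STJ height 18 mm.
#'
#' @param dim grid dimensions (voxels), default `c(128, 128, 128)`.
#' @param spacing isotropic voxel size, mm.
#' @param r annular radius, mm (annular area is `pi * r^2`).
#' @param h STJ height, mm.
#' @param lumen_hu,lumen_sd lumen HU mean / SD.
#' @param background_hu,background_sd background HU mean / SD.
#' @param deposits tibble/data frame with columns `rho`, `phi`, `zeta`,
#'   `radius_mm`, and optionally `hu` (mean, default 900) and `hu_sd`
#'   (default 50). Default: three deposits in distinct cusps and rings.
#' @param seed integer RNG seed; the phantom is bit-reproducible given the
#'   seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(128L, 128L, 128L), spacing = 0.5,
                         r = 12, h = 18,
                         lumen_hu = 400, lumen_sd = 30,
                         background_hu = 50, background_sd = 20,
                         deposits = default_deposits(), seed = 1L) {
  deposits <- tibble::as_tibble(deposits)
  if (nrow(deposits)) {
    if (!all(c("rho", "phi", "zeta", "radius_mm") %in% names(deposits))) {
      stop("deposits need columns rho, phi, zeta, radius_mm", call. = FALSE)
    }
    if (!"hu" %in% names(deposits)) deposits$hu <- 900
    if (!"hu_sd" %in% names(deposits)) deposits$hu_sd <- 50
    if (any(deposits$hu <= lumen_hu + 4 * lumen_sd)) {
      warning("deposit HU within 4 SD of the lumen mean; detection not guaranteed",
              call. = FALSE)
    }
  }
  structure(
    list(dim = as.integer(dim), spacing = spacing, r = r, h = h,
         lumen_hu = lumen_hu, lumen_sd = lumen_sd,
         background_hu = background_hu, background_sd = background_sd,
         deposits = deposits, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @rdname phantom_spec
#' @export
default_deposits <- function() {
  tibble::tibble(
    rho = c(0.45, 0.85, 0.6),
    phi = c(300, 60, 170),
    zeta = c(0.25, 0.1, -0.05),
    radius_mm = c(3, 2.5, 2),
    hu = c(900, 900, 900),
    hu_sd = c(50, 50, 50)
  )
}

#' Generate a phantom CT volume with ground truth
#'
#' Builds the HU volume, the contrast-lumen mask (blood pool, excluding the
#' planted deposits), a wider cylindrical region-of-interest mask, the
#' matching [aortic_frame()] with landmark sidecar data, and a truth table
#' giving each deposit's analytic and voxelized volume plus its region id
#' under `config`.
#'
#' The root axis is the grid's z axis; the annular plane passes through the
#' grid centre; the three commissures sit at en-face bearings 0, 120 and 240
#' degrees (sectors: LCC `[0,120)`, RCC `[120,240)`, NCC `[240,360)`).
#'
#' @param spec a [phantom_spec()].
#' @param config the [region_config()] used for ground-truth region labels.
#' @return List with elements `volume`, `lumen_mask`, `roi_mask`, `frame`,
#'   `landmarks`, `truth`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), config = region_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  vox <- spec$spacing
  affine <- diag(c(vox, vox, vox, 1))
  centre <- (d - 1) / 2 * vox # physical grid centre

  # voxel-centre physical coordinates
  xs <- (seq_len(d[1]) - 1) * vox
  ys <- (seq_len(d[2]) - 1) * vox
  zs <- (seq_len(d[3]) - 1) * vox
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  rad2 <- (X - centre[1])^2 + (Y - centre[2])^2
  tube <- rad2 <= spec$r^2
  roi <- rad2 <= (spec$r * 1.3)^2

  frame <- aortic_frame(
    annular_centre = centre,
    stj_point = centre + c(0, 0, spec$h),
    commissures = list(
      NCC_LCC = centre + spec$r * c(1, 0, 0),
      LCC_RCC = centre + spec$r * c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
      RCC_NCC = centre + spec$r * c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
    ),
    annular_area = pi * spec$r^2
  )

  vol <- array(rnorm(prod(d), spec$background_hu, spec$background_sd), d)
  n_tube <- sum(tube)
  vol[tube] <- rnorm(n_tube, spec$lumen_hu, spec$lumen_sd)

  dep_mask <- array(FALSE, d)
  truth <- spec$deposits
  if (nrow(truth)) {
    ctr_phys <- from_cylindrical(truth$rho, truth$phi, truth$zeta, frame)
    truth$n_voxels <- NA_integer_
    for (i in seq_len(nrow(truth))) {
      c_i <- ctr_phys[i, ]
      if (any(c_i < truth$radius_mm[i]) ||
          any(c_i > (d - 1) * vox - truth$radius_mm[i])) {
        stop("deposit ", i, " extends outside the grid", call. = FALSE)
      }
      inside <- (X - c_i[1])^2 + (Y - c_i[2])^2 + (Z - c_i[3])^2 <= truth$radius_mm[i]^2
      vol[inside] <- rnorm(sum(inside), truth$hu[i], truth$hu_sd[i])
      truth$n_voxels[i] <- sum(inside)
      dep_mask <- dep_mask | inside
    }
    truth$volume_analytic_mm3 <- 4 / 3 * pi * truth$radius_mm^3
    truth$volume_voxel_mm3 <- truth$n_voxels * vox^3
    # analytic region id of the deposit centre
    cusp <- cusp_of(truth$phi, frame)
    cusp_idx <- match(cusp, config$cusp_order)
    starts <- frame$sector_start
    sec_i <- findInterval(truth$phi %% 360, starts)
    sec_i[sec_i == 0L] <- 3L
    width <- (starts[ifelse(sec_i == 3L, 1L, sec_i + 1L)] - starts[sec_i]) %% 360
    width[width == 0] <- 360
    frac <- ((truth$phi %% 360 - starts[sec_i]) %% 360) / width
    sector <- pmin(floor(frac * config$sectors_per_cusp) + 1L, config$sectors_per_cusp)
    ring <- pmin(findInterval(truth$rho, config$radial_edges, left.open = TRUE) + 1L,
                 config$n_radial)
    in_window <- truth$zeta >= config$zeta_lower & truth$zeta <= config$zeta_upper
    truth$cusp <- cusp
    truth$region <- ifelse(in_window,
                           paste0("R", region_id(cusp_idx, sector, ring, config)),
                           NA_character_)
  }

  volume <- voxel_volume(vol, affine = affine)
  landmarks <- list(
    annular_centre = unname(centre),
    stj_point = unname(centre + c(0, 0, spec$h)),
    commissures = list(
      NCC_LCC = unname(centre + spec$r * c(1, 0, 0)),
      LCC_RCC = unname(centre + spec$r * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)),
      RCC_NCC = unname(centre + spec$r * c(cos(4 * pi / 3), sin(4 * pi / 3), 0))
    ),
    annular_area_mm2 = pi * spec$r^2
  )
  list(volume = volume, lumen_mask = tube & !dep_mask, roi_mask = roi,
       frame = frame, landmarks = landmarks, truth = truth, spec = spec)
}

#' Specification of a simulated cohort
#'
#' Class-structured patient cohorts for exercising the nested multinomial
#' evaluation harness. Covariates (per-cusp weighted scores, zone volumes,
#' calcification grade, Agatston score, valve size, area cover index) are
#' drawn from fixed baseline distributions; the exclusive outcome class is
#' then drawn from a multinomial logit whose linear predictor applies the
#' generative `coefficients` to standardized covariates, with intercepts
#' calibrated so expected class proportions match `n_per_class`.
#'
#' Default class sizes follow a TAVR complication mix dominated by controls
#' (control 67, PVL 26, postD 19, LBBB 11, preD 10 per 133 patients).
#'
#' @param n_total cohort size.
#' @param n_per_class named numeric of expected class weights (normalized
#'   internally).
#' @param coefficients matrix (non-control classes x covariates) of
#'   generative log-odds effects per SD of covariate; default gives each
#'   event class a moderate dependence on a few covariates.
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_total = 133,
                        n_per_class = c(control = 67, PVL = 26, LBBB = 11,
                                        preD = 10, postD = 19),
                        coefficients = NULL, seed = 1L) {
  stopifnot("control" %in% names(n_per_class), all(n_per_class > 0))
  covs <- cohort_covariate_names()
  classes <- names(n_per_class)
  events <- setdiff(classes, "control")
  if (is.null(coefficients)) {
    coefficients <- matrix(0, length(events), length(covs),
                           dimnames = list(events, covs))
    set_if <- function(cls, cov, val) {
      if (cls %in% events) coefficients[cls, cov] <<- val
    }
    set_if("PVL", "NCC", 0.5); set_if("PVL", "RCC", 0.8)
    set_if("PVL", "area_cover_index", -0.5)
    set_if("LBBB", "RCC", -0.6); set_if("LBBB", "alvot_mm3", 0.5)
    set_if("preD", "NCC", 0.7); set_if("preD", "RCC", 0.7)
    set_if("preD", "LCC", 0.7); set_if("preD", "agatston", 0.8)
    set_if("postD", "NCC", 0.5); set_if("postD", "leaflet_mm3", 0.4)
  }
  stopifnot(nrow(coefficients) == length(events),
            ncol(coefficients) == length(covs))
  structure(
    list(n_total = as.integer(n_total),
         class_weights = n_per_class / sum(n_per_class),
         classes = classes, events = events,
         coefficients = coefficients, covariates = covs,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Covariate column names of a cohort table
#'
#' The per-patient covariates consumed by [run_stats()]: the three cusp
#' weighted scores, the two zone volumes, the visual calcification grade,
#' Agatston score, valve size and area cover index.
#' @return Character vector of column names.
#' @export
cohort_covariate_names <- function() {
  c("NCC", "RCC", "LCC", "leaflet_mm3", "alvot_mm3",
    "calc_grade", "agatston", "valve_size", "area_cover_index")
}

# Baseline covariate draws (class-independent); n rows.
draw_covariates <- function(n) {
  tibble::tibble(
    NCC = stats::rlnorm(n, log(60), 0.8),
    RCC = stats::rlnorm(n, log(55), 0.8),
    LCC = stats::rlnorm(n, log(50), 0.8),
    leaflet_mm3 = stats::rlnorm(n, log(250), 0.7),
    alvot_mm3 = stats::rlnorm(n, log(60), 0.9),
    calc_grade = sample(0:3, n, replace = TRUE, prob = c(0.15, 0.35, 0.3, 0.2)),
    agatston = stats::rlnorm(n, log(2200), 0.7),
    valve_size = sample(c(23, 26, 29), n, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
    area_cover_index = rnorm(n, 12, 6)
  )
}

# standardization constants of the baseline covariate distributions,
# estimated once from a large fixed reference draw so the generative model
# is well defined independently of any particular cohort.
cohort_standardization <- function() {
  set.seed(987654L)
  ref <- draw_covariates(200000L)
  list(centre = vapply(ref, mean, numeric(1)),
       scale = vapply(ref, sd, numeric(1)))
}

# class-probability matrix under the generative model for covariate table X
cohort_class_probs <- function(spec, X, std) {
  Xs <- sweep(sweep(as.matrix(X), 2, std$centre), 2, std$scale, "/")
  icpt <- log(spec$class_weights[spec$events] / spec$class_weights[["control"]])
  eta <- sweep(Xs %*% t(spec$coefficients), 2, icpt, "+")
  P <- cbind(1, exp(eta))
  P <- P / rowSums(P)
  colnames(P) <- c("control", spec$events)
  P
}

#' Simulate a cohort with generative truth
#'
#' Draws the covariate table and exclusive outcome classes from the
#' generative multinomial logit in `spec`, and computes the theoretical
#' one-vs-control AUC of each event class by brute force: a large independent
#' Monte-Carlo population is drawn from the same generative model, scored
#' with the true conditional event probability, and the AUC obtained by
#' pairwise rank comparison between its event and control members.
#'
#' @param spec a [cohort_spec()].
#' @param n_mc Monte-Carlo population size for the theoretical AUC.
#' @return List with `cohort` (tibble: `patient_id`, `outcome`, covariates)
#'   and `truth` (list: `coefficients`, `theoretical_auc` tibble with
#'   columns `event`, `auc`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), n_mc = 50000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  std <- cohort_standardization()
  set.seed(spec$seed)
  X <- draw_covariates(spec$n_total)
  P <- cohort_class_probs(spec, X, std)
  outcome <- apply(P, 1, function(p) sample(colnames(P), 1, prob = p))
  cohort <- dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("P%04d", seq_len(spec$n_total)),
                   outcome = outcome),
    X
  )

  # brute-force theoretical AUC on an independent large population
  Xm <- draw_covariates(n_mc)
  Pm <- cohort_class_probs(spec, Xm, std)
  ym <- apply(Pm, 1, function(p) sample(colnames(Pm), 1, prob = p))
  theo <- purrr::map_dfr(spec$events, function(ev) {
    sel <- ym %in% c(ev, "control")
    tibble::tibble(event = ev,
                   auc = roc_points(Pm[sel, ev], ym[sel] == ev)$auc)
  })
  list(cohort = cohort,
       truth = list(coefficients = spec$coefficients, theoretical_auc = theo))
}
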