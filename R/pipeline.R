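#' Pipeline run configuration
#'
#' Bundles every tunable of the scoring pipeline; round-trips losslessly
#' through JSON ([write_run_config()] / [read_run_config()]). All output
#' records carry a hash of this configuration plus the seed, so identical
#' config + seed reproduces identical outputs.
#'
#' @param volume,lumen_mask,roi_mask,landmarks input paths (NIfTI volumes /
#'   masks and the landmark JSON sidecar); may be NULL when objects are
#'   passed to [run_score()] directly.
#' @param epsilon FPR tolerance for [select_threshold()].
#' @param min_component_mm3 component filter for [segment_calcium()].
#' @param leaflet_upper,alvot_lower craniocaudal zone bounds, fractions of h.
#' @param config a [region_config()].
#' @param seed integer seed recorded with outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(volume = NULL, lumen_mask = NULL, roi_mask = NULL,
                       landmarks = NULL, epsilon = 0.01, min_component_mm3 = 1,
                       leaflet_upper = 0.5, alvot_lower = 0.15,
                       config = region_config(), seed = 1L) {
  stopifnot(epsilon >= 0, epsilon < 1, min_component_mm3 >= 0,
            leaflet_upper > 0, alvot_lower > 0, inherits(config, "region_config"))
  structure(
    list(volume = volume, lumen_mask = lumen_mask, roi_mask = roi_mask,
         landmarks = landmarks, epsilon = epsilon,
         min_component_mm3 = min_component_mm3,
         leaflet_upper = leaflet_upper, alvot_lower = alvot_lower,
         config = config, seed = as.integer(seed)),
    class = "run_config"
  )
}

run_config_hash <- function(cfg) {
  flat <- unlist(list(
    epsilon = cfg$epsilon, min_component_mm3 = cfg$min_component_mm3,
    leaflet_upper = cfg$leaflet_upper, alvot_lower = cfg$alvot_lower,
    radial_edges = cfg$config$radial_edges,
    sectors_per_cusp = cfg$config$sectors_per_cusp,
    zeta = c(cfg$config$zeta_lower, cfg$config$zeta_upper),
    weight_steps = cfg$config$weight_steps, seed = cfg$seed
  ))
  s <- paste(names(flat), format(flat, digits = 15), sep = "=", collapse = ";")
  # small stable polynomial hash; no external digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize / load a run configuration
#' @param cfg a [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  out <- cfg
  out$config <- unclass(out$config)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rc <- raw$config
  run_config(
    volume = raw$volume, lumen_mask = raw$lumen_mask, roi_mask = raw$roi_mask,
    landmarks = raw$landmarks, epsilon = raw$epsilon,
    min_component_mm3 = raw$min_component_mm3,
    leaflet_upper = raw$leaflet_upper, alvot_lower = raw$alvot_lower,
    config = region_config(
      radial_edges = rc$radial_edges,
      sectors_per_cusp = rc$sectors_per_cusp,
      zeta_lower = rc$zeta_lower, zeta_upper = rc$zeta_upper,
      cusp_order = rc$cusp_order, weight_steps = rc$weight_steps
    ),
    seed = raw$seed
  )
}

#' Score one patient end to end
#'
#' Runs the full quantification chain: FPR threshold selection, calcium
#' segmentation, craniocaudal zone volumes, 18-region assignment, intensity
#' weighting, and per-cusp weighted scores. Inputs are taken from the config
#' paths unless passed directly.
#'
#' @param cfg a [run_config()].
#' @param volume,lumen_mask,roi_mask,frame in-memory inputs overriding the
#'   config paths: a [voxel_volume()], two logical arrays, an
#'   [aortic_frame()].
#' @param patient_id identifier copied into the record.
#' @return List of class `dlz_record`: `record` (one-row tibble with
#'   `patient_id`, `t_min`, `hu_sd`, zone volumes, cusp scores, `config_hash`,
#'   `seed`), `regional` (the [regional_table()]), `segmentation`, `frame`.
#' @export
run_score <- function(cfg = run_config(), volume = NULL, lumen_mask = NULL,
                      roi_mask = NULL, frame = NULL, patient_id = "patient") {
  stopifnot(inherits(cfg, "run_config"))
  load_arr <- function(obj, path, what) {
    if (!is.null(obj)) return(obj)
    if (is.null(path)) stop("no ", what, " supplied (object or config path)", call. = FALSE)
    if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
    read_volume(path)
  }
  volume <- load_arr(volume, cfg$volume, "volume")
  lumen_mask <- load_arr(lumen_mask, cfg$lumen_mask, "lumen_mask")
  roi_mask <- load_arr(roi_mask, cfg$roi_mask, "roi_mask")
  if (!is.logical(lumen_mask)) lumen_mask <- array(lumen_mask > 0.5, dim(lumen_mask))
  if (!is.logical(roi_mask)) roi_mask <- array(roi_mask > 0.5, dim(roi_mask))
  if (is.null(frame)) {
    if (is.null(cfg$landmarks)) stop("no landmarks supplied", call. = FALSE)
    frame <- read_landmarks(cfg$landmarks)
  }

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  curve <- stage("fpr_curve", fpr_curve(volume, lumen_mask, roi_mask))
  t_min <- stage("select_threshold", {
    tryCatch(select_threshold(curve, cfg$epsilon), error = function(e) {
      warning("FPR selection failed (", conditionMessage(e),
              "); using lumen mean + 3 SD fallback", call. = FALSE)
      fallback_threshold(as.numeric(volume)[as.logical(lumen_mask)])
    })
  })
  seg <- stage("segment_calcium",
               segment_calcium(volume, roi_mask, t_min, cfg$min_component_mm3))
  zones <- stage("zone_volumes",
                 zone_volumes(seg, frame, cfg$leaflet_upper, cfg$alvot_lower))
  labelling <- stage("assign_regions", assign_regions(seg, frame, cfg$config))
  regional <- stage("regional_table", regional_table(seg, labelling, cfg$config))
  scores <- stage("cusp_scores", cusp_scores(regional))

  record <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id, t_min = t_min, hu_sd = seg$hu_sd,
                   n_calcific_voxels = seg$n_voxels,
                   calcific_volume_mm3 = calcific_volume(seg)),
    zones, scores,
    tibble::tibble(config_hash = run_config_hash(cfg), seed = cfg$seed)
  )
  structure(list(record = record, regional = regional, segmentation = seg,
                 frame = frame, cfg = cfg),
            class = "dlz_record")
}

#' @export
print.dlz_record <- function(x, ...) {
  print(x$record)
  invisible(x)
}

#' Nested prognostic-model comparison on a cohort table
#'
#' Fits the three nested multinomial models on a per-patient covariate table
#' and reports, per event class and model, the one-vs-control ROC (AUC,
#' band, Youden cutoff, sensitivity/specificity), the pairwise whole-model
#' delta chi-squared LRTs, and single-parameter drop LRTs within each model.
#' The nesting is: Model 3 (baseline: calcification grade, Agatston score,
#' valve size, area cover index), Model 2 (+ leaflet and annular/LVOT
#' calcific volume), Model 1 (+ the NCC/RCC/LCC intensity-weighted scores).
#'
#' @param cohort data frame with `outcome` plus the covariate columns of
#'   [cohort_covariate_names()].
#' @param reference_class the control class level.
#' @return List of class `dlz_stats_report`: `fits` (named list of
#'   `dlz_multinom`), `roc` (tibble: model x event), `model_comparison`
#'   (pairwise delta chi2), `parameter_tests` (drop-one chi2 per model).
#' @export
run_stats <- function(cohort, reference_class = "control") {
  req <- c("outcome", cohort_covariate_names())
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  model_covs <- list(
    model3 = c("calc_grade", "agatston", "valve_size", "area_cover_index"),
    model2 = c("leaflet_mm3", "alvot_mm3",
               "calc_grade", "agatston", "valve_size", "area_cover_index"),
    model1 = c("NCC", "RCC", "LCC", "leaflet_mm3", "alvot_mm3",
               "calc_grade", "agatston", "valve_size", "area_cover_index")
  )
  fits <- purrr::map(model_covs, function(cv) {
    fit_multinomial(cohort, cv, reference_class = reference_class)
  })
  events <- setdiff(fits$model1$classes, reference_class)

  roc <- purrr::map_dfr(names(fits), function(m) {
    purrr::map_dfr(events, function(ev) {
      dplyr::bind_cols(tibble::tibble(model = m), roc_one_vs_control(fits[[m]], ev))
    })
  })

  pairs <- list(c("model1", "model2"), c("model1", "model3"), c("model2", "model3"))
  model_comparison <- purrr::map_dfr(pairs, function(pr) {
    dplyr::bind_cols(tibble::tibble(full = pr[1], reduced = pr[2]),
                     lrt(fits[[pr[1]]], fits[[pr[2]]]))
  })

  parameter_tests <- purrr::map_dfr(names(fits), function(m) {
    cv <- model_covs[[m]]
    purrr::map_dfr(cv, function(one) {
      red <- fit_multinomial(cohort, setdiff(cv, one),
                             reference_class = reference_class)
      dplyr::bind_cols(tibble::tibble(model = m, parameter = one),
                       lrt(fits[[m]], red))
    })
  })

  structure(list(fits = fits, roc = roc, model_comparison = model_comparison,
                 parameter_tests = parameter_tests),
            class = "dlz_stats_report")
}

#' @export
print.dlz_stats_report <- function(x, ...) {
  cat("Nested multinomial model comparison\n\n")
  cat("One-vs-control ROC per model and event:\n")
  print(as.data.frame(x$roc[, c("model", "event", "auc", "band", "cutoff",
                                "sensitivity_pct", "specificity_pct")]),
        digits = 3, row.names = FALSE)
  cat("\nWhole-model LRTs (delta chi2):\n")
  print(as.data.frame(x$model_comparison), digits = 4, row.names = FALSE)
  invisible(x)
}
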