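# Independent oracles used across tests. These deliberately re-derive every
# quantity from first principles (scalar loops, explicit trigonometry,
# pairwise counting) rather than calling package internals.

# Brute-force per-voxel region classifier: recomputes the cylindrical
# coordinates and the region decision rules from the raw landmarks, one voxel
# at a time.
oracle_classify_voxel <- function(world, landmarks, config) {
  centre <- landmarks$annular_centre
  ax <- landmarks$stj_point - centre
  h <- sqrt(sum(ax^2))
  ax <- ax / h
  r <- sqrt(landmarks$annular_area_mm2 / pi)
  cm <- landmarks$commissures
  p1 <- cm[[1]] - centre
  p1 <- p1 - sum(p1 * ax) * ax
  e1 <- p1 / sqrt(sum(p1^2))
  e2 <- c(
    ax[2] * e1[3] - ax[3] * e1[2],
    ax[3] * e1[1] - ax[1] * e1[3],
    ax[1] * e1[2] - ax[2] * e1[1]
  )
  ang <- sort(vapply(cm, function(p) {
    v <- p - centre
    v <- v - sum(v * ax) * ax
    (atan2(sum(v * e2), sum(v * e1)) * 180 / pi) %% 360
  }, numeric(1)))
  # cusp label per sorted sector: shared cusp of bounding commissure names
  nm <- names(cm)[order(vapply(cm, function(p) {
    v <- p - centre
    v <- v - sum(v * ax) * ax
    (atan2(sum(v * e2), sum(v * e1)) * 180 / pi) %% 360
  }, numeric(1)))]
  labels <- character(3)
  for (i in 1:3) {
    a <- strsplit(nm[i], "_")[[1]]
    b <- strsplit(nm[if (i == 3) 1 else i + 1], "_")[[1]]
    labels[i] <- intersect(a, b)
  }

  v <- world - centre
  z <- sum(v * ax)
  ip <- v - z * ax
  rho <- sqrt(sum(ip^2)) / r
  phi <- (atan2(sum(ip * e2), sum(ip * e1)) * 180 / pi) %% 360
  zeta <- z / h
  if (zeta < config$zeta_lower || zeta > config$zeta_upper) {
    return(NA_character_)
  }
  sec <- 0L
  for (i in 1:3) {
    a0 <- ang[i]
    a1 <- if (i == 3) ang[1] + 360 else ang[i + 1]
    ph <- phi
    if (i == 3 && ph < a0) ph <- ph + 360
    if (ph >= a0 && ph < a1) {
      sec <- i
      break
    }
  }
  cusp <- labels[sec]
  a0 <- ang[sec]
  wid <- if (sec == 3) (ang[1] + 360 - a0) else (ang[sec + 1] - a0)
  frac <- ((phi - a0) %% 360) / wid
  subsec <- min(floor(frac * config$sectors_per_cusp) + 1, config$sectors_per_cusp)
  ring <- config$n_radial
  for (k in seq_along(config$radial_edges)) {
    if (rho <= config$radial_edges[k]) {
      ring <- k
      break
    }
  }
  cusp_idx <- match(cusp, config$cusp_order)
  K <- config$n_radial
  S <- config$sectors_per_cusp
  paste0("R", (cusp_idx - 1) * S * K + (subsec - 1) * K + ring)
}

# Pairwise-counting AUC: every event/control pair contributes 1 (event scored
# higher), 0.5 (tie) or 0.
oracle_auc <- function(score, is_event) {
  ev <- score[is_event]
  ct <- score[!is_event]
  tot <- 0
  for (a in ev) {
    for (b in ct) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(ev) * length(ct))
}

# Direct two-way ANOVA variance-components ICC(2,1).
oracle_icc21 <- function(M) {
  n <- nrow(M)
  k <- ncol(M)
  grand <- mean(M)
  MSR <- k * sum((rowMeans(M) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(M) - grand)^2) / (k - 1)
  SSE <- sum((M - grand)^2) -
    k * sum((rowMeans(M) - grand)^2) - n * sum((colMeans(M) - grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Small-phantom builder for unit tests (cheap 64^3 grid).
small_phantom <- function(seed = 1, deposits = NULL, ...) {
  if (is.null(deposits)) deposits <- default_deposits()
  make_phantom(phantom_spec(dim = c(64L, 64L, 64L), spacing = 1,
                            deposits = deposits, seed = seed, ...))
}

# Random well-separated deposits for property tests.
random_deposits <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    rho = runif(n, 0.15, 1.1),
    phi = runif(n, 0, 360),
    zeta = runif(n, -0.12, 0.45),
    radius_mm = runif(n, 1.5, 3),
    hu = 900, hu_sd = 50
  )
}

# Shared full-size phantom set for the property-based validation suite:
# 20 seeded 128^3 phantoms with randomized deposits, each run through
# detection and region assignment once and cached across test blocks.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_phantom_set <- function() {
  if (!is.null(.acceptance_cache$set)) {
    return(.acceptance_cache$set)
  }
  set <- lapply(1:20, function(seed) {
    ph <- make_phantom(phantom_spec(deposits = random_deposits(3, 1000 + seed),
                                    seed = seed))
    curve <- fpr_curve(ph$volume, ph$lumen_mask, ph$roi_mask)
    t_min <- select_threshold(curve, 0.01)
    seg <- segment_calcium(ph$volume, ph$roi_mask, t_min)
    lab <- assign_regions(seg, ph$frame)
    tbl <- regional_table(seg, lab)
    list(ph = ph, curve = curve, seg = seg, lab = lab, tbl = tbl)
  })
  .acceptance_cache$set <- set
  set
}

run_phantom_pipeline <- function(ph, cfg = run_config()) {
  run_score(cfg, volume = ph$volume, lumen_mask = ph$lumen_mask,
            roi_mask = ph$roi_mask, frame = ph$frame)
}
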