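#' One-vs-control ROC analysis of a fitted multinomial model
#'
#' Restricts the cohort to one event class plus the control (reference)
#' class, scores each patient with the model's fitted probability of the
#' event class, and evaluates the ROC: AUC by the rank (Mann-Whitney)
#' formula with mid-rank tie correction, and the operating cutoff that
#' maximizes Youden's J = sensitivity + specificity - 1 (patients with score
#' >= cutoff are called events; ties on J resolve to the smallest cutoff).
#'
#' @param fit a `dlz_multinom` from [fit_multinomial()].
#' @param event_class the event outcome level (must differ from the
#'   reference).
#' @return Tibble of class `dlz_roc` with one row: `event`, `auc`, `band`,
#'   `cutoff` (probability scale), `sensitivity_pct`, `specificity_pct`,
#'   `n_event`, `n_control`. The full sweep is in attribute `curve`.
#' @export
roc_one_vs_control <- function(fit, event_class) {
  stopifnot(inherits(fit, "dlz_multinom"))
  if (!event_class %in% fit$classes || event_class == fit$reference) {
    stop("`event_class` must be a non-reference class of the fit", call. = FALSE)
  }
  sel <- fit$outcome %in% c(event_class, fit$reference)
  y <- as.character(fit$outcome[sel]) == event_class
  score <- fit$fitted[sel, event_class]
  if (!any(y) || all(y)) stop("need both event and control rows", call. = FALSE)
  res <- roc_points(score, y)
  out <- tibble::tibble(
    event = event_class,
    auc = res$auc,
    band = auc_band(res$auc),
    cutoff = res$cutoff,
    sensitivity_pct = res$sensitivity * 100,
    specificity_pct = res$specificity * 100,
    n_event = sum(y), n_control = sum(!y)
  )
  attr(out, "curve") <- res$curve
  class(out) <- c("dlz_roc", class(out))
  out
}

#' ROC summary of raw scores
#'
#' Rank-formula (Mann-Whitney) AUC with mid-rank tie correction, plus the
#' Youden sweep over the observed scores. [roc_one_vs_control()] wraps this
#' for fitted models; it is exposed for scoring arbitrary markers.
#'
#' @param score numeric marker values (higher = more event-like).
#' @param is_event logical event indicator.
#' @return List with `auc`, `cutoff`, `sensitivity`, `specificity`, `curve`.
#' @export
roc_points <- function(score, is_event) {
  n1 <- sum(is_event); n0 <- sum(!is_event)
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[is_event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(score))
  curve <- tibble::tibble(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(ct) mean(score[is_event] >= ct), numeric(1)),
    specificity = vapply(cuts, function(ct) mean(score[!is_event] < ct), numeric(1))
  )
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))[1] # smallest cutoff on ties (cuts ascending)
  list(auc = auc, cutoff = cuts[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       curve = curve)
}

#' Qualitative AUC band
#'
#' The conventional discriminative-ability bands: 0.5-0.6 fail, 0.6-0.7 poor,
#' 0.7-0.8 acceptable, 0.8-0.9 excellent; AUC >= 0.9 is also labelled
#' excellent, and below-chance AUC (< 0.5) falls in the fail band.
#'
#' @param auc numeric vector in `[0, 1]`.
#' @return Character vector of band labels.
#' @examples
#' auc_band(c(0.55, 0.65, 0.75, 0.85))
#' @export
auc_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  dplyr::case_when(
    auc < 0.6 ~ "fail",
    auc < 0.7 ~ "poor",
    auc < 0.8 ~ "acceptable",
    TRUE ~ "excellent"
  )
}

#' ROC curve plot
#'
#' @param object a `dlz_roc` from [roc_one_vs_control()].
#' @param ... unused.
#' @return A ggplot object showing the ROC curve with the Youden operating
#'   point marked.
#' @export
autoplot.dlz_roc <- function(object, ...) {
  curve <- attr(object, "curve")
  df <- tibble::tibble(
    fpr = c(1, 1 - curve$specificity, 0),
    tpr = c(1, curve$sensitivity, 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point",
                      x = 1 - object$specificity_pct / 100,
                      y = object$sensitivity_pct / 100, colour = "red") +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s vs control: AUC = %.3f (%s)",
                      object$event, object$auc, object$band)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measure absolute-agreement ICC from the two-way random-effects
#' ANOVA decomposition (subjects and raters both random), the agreement
#' statistic used for interobserver reproducibility of the detected calcific
#' volume. With subject mean square `MSR`, rater mean square `MSC` and
#' residual `MSE` over `n` subjects and `k` raters:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The confidence interval is the standard F-based interval (McGraw & Wong).
#'
#' @param ratings numeric matrix or data frame, subjects in rows, raters in
#'   columns, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return Tibble with one row: `icc`, `lower`, `upper`, `n_subjects`,
#'   `n_raters`.
#' @export
icc_two_way_random <- function(ratings, conf_level = 0.95) {
  M <- as.matrix(ratings)
  if (anyNA(M)) stop("ratings must have no missing cells", call. = FALSE)
  n <- nrow(M); k <- ncol(M)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters", call. = FALSE)

  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((M - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (MSR <= MSE || denom <= 0) {
    warning("no between-subject variance beyond error; ICC reported as 0", call. = FALSE)
    return(tibble::tibble(icc = 0, lower = NA_real_, upper = NA_real_,
                          n_subjects = n, n_raters = k))
  }
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf_level
  if (MSE <= 0) {
    # perfect agreement: interval degenerates at 1
    return(tibble::tibble(icc = icc, lower = icc, upper = icc,
                          n_subjects = n, n_raters = k))
  }
  Fj <- MSC / MSE
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * Fj + b)^2 /
    (a^2 * Fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  tibble::tibble(icc = icc, lower = lower, upper = upper,
                 n_subjects = n, n_raters = k)
}
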