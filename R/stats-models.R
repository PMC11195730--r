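#' Fit a multinomial logistic regression with a reference class
#'
#' Maximum-likelihood multinomial logit with reference-class
#' parameterization, the workhorse of the nested prognostic-model comparison
#' (Models 1-3). Covariates are standardized internally for numerical
#' stability; the initial fit from [nnet::multinom()] is polished with exact
#' Newton steps on the multinomial log-likelihood so the attained maximum is
#' reliable to high precision, and coefficients are reported back on the
#' original covariate scale. The fit is deterministic given the data (zero
#' initialization, no randomness).
#'
#' Perfect separation (diverging coefficients) triggers a warning and a
#' refit with a small ridge penalty on the slopes so estimates stay bounded.
#' A rank-deficient design is an error naming the collinear columns.
#'
#' @param data data frame with one row per patient.
#' @param covariates character vector of covariate column names (numeric).
#' @param outcome name of the outcome column (factor or character;
#'   exclusive classes).
#' @param reference_class the reference (control) outcome level.
#' @param ridge ridge penalty used only for the separation fallback.
#' @return Object of class `dlz_multinom`: list with `coefficients`
#'   ((classes-1) x (covariates+1) matrix, original scale), `classes`,
#'   `reference`, `covariates`, `log_likelihood`, `df`, `n`, `fitted`
#'   (n x classes probability matrix), `converged`, `ridged`.
#' @export
fit_multinomial <- function(data, covariates, outcome = "outcome",
                            reference_class = "control", ridge = 1e-4) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  y <- as.character(data[[outcome]])
  if (anyNA(y)) stop("missing outcome values", call. = FALSE)
  lev <- c(reference_class, sort(setdiff(unique(y), reference_class)))
  if (!reference_class %in% y) {
    stop("reference class '", reference_class, "' not present in the data", call. = FALSE)
  }
  if (length(lev) < 2L) stop("need at least two outcome classes", call. = FALSE)
  yf <- factor(y, levels = lev)
  K <- length(lev)
  n <- length(y)
  p <- length(covariates)

  n_min <- min(table(yf))
  if (n_min < p + 1) {
    warning(sprintf("smallest class has %d rows for %d parameters per class; estimates may be unstable",
                    n_min, p + 1), call. = FALSE)
  }

  X <- as.matrix(data[, covariates, drop = FALSE])
  if (!is.numeric(X) && p > 0) stop("covariates must be numeric", call. = FALSE)
  storage.mode(X) <- "double"
  # standardize (constant columns pass through unscaled)
  ctr <- if (p) colMeans(X) else numeric(0)
  scl <- if (p) apply(X, 2, sd) else numeric(0)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- if (p) sweep(sweep(X, 2, ctr), 2, scl, "/") else X
  Xd <- cbind(`(Intercept)` = 1, Xs)

  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  Y <- vapply(lev[-1], function(l) as.numeric(yf == l), numeric(n)) # n x (K-1)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = n)

  fit0 <- if (p) {
    nnet::multinom(yf ~ Xs, trace = FALSE, maxit = 500,
                   abstol = 1e-12, reltol = 1e-14)
  } else {
    nnet::multinom(yf ~ 1, trace = FALSE, maxit = 500,
                   abstol = 1e-12, reltol = 1e-14)
  }
  B0 <- matrix(stats::coef(fit0), nrow = K - 1)

  polished <- multinom_newton(Xd, Y, B0, lambda = 0)
  ridged <- FALSE
  if (!polished$converged || max(abs(polished$B)) > 15) {
    warning("possible separation: coefficients bounded with a ridge penalty",
            call. = FALSE)
    polished <- multinom_newton(Xd, Y, B0 * 0, lambda = ridge)
    ridged <- TRUE
  }
  Bs <- polished$B # (K-1) x (p+1), standardized scale

  # back-transform to the original covariate scale
  B <- Bs
  if (p) {
    B[, -1] <- sweep(Bs[, -1, drop = FALSE], 2, scl, "/")
    B[, 1] <- Bs[, 1] - as.vector(Bs[, -1, drop = FALSE] %*% (ctr / scl))
  }
  dimnames(B) <- list(lev[-1], c("(Intercept)", covariates))

  eta <- Xd %*% t(Bs)
  P <- cbind(1, exp(eta))
  P <- P / rowSums(P)
  colnames(P) <- lev

  structure(
    list(
      coefficients = B, classes = lev, reference = reference_class,
      covariates = covariates, log_likelihood = polished$ll,
      df = (K - 1L) * (p + 1L), n = n, fitted = P,
      outcome = yf, converged = polished$converged, ridged = ridged
    ),
    class = "dlz_multinom"
  )
}

# Newton-Raphson on the multinomial log-likelihood (reference-class logit).
# Xd: n x q design incl. intercept; Y: n x (K-1) indicators; B: (K-1) x q.
# lambda penalizes the non-intercept slopes (ridge), 0 for plain ML.
multinom_newton <- function(Xd, Y, B, lambda = 0, max_iter = 50, tol = 1e-12) {
  n <- nrow(Xd); q <- ncol(Xd); Km1 <- ncol(Y)
  pen_mask <- rep(c(0, rep(1, q - 1)), times = Km1) # no penalty on intercepts
  ll_fun <- function(B) {
    eta <- Xd %*% t(B)
    m <- pmax(apply(eta, 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    ll <- sum(Y * eta) - sum(m + log(denom))
    ll - lambda / 2 * sum((as.vector(t(B)) * pen_mask)^2)
  }
  ll <- ll_fun(B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- Xd %*% t(B)
    m <- pmax(apply(eta, 1, max), 0)
    E <- exp(eta - m)
    P <- E / (exp(-m) + rowSums(E)) # n x (K-1) class probabilities
    G <- t(Y - P) %*% Xd # (K-1) x q gradient blocks
    g <- as.vector(t(G)) - lambda * as.vector(t(B)) * pen_mask
    H <- matrix(0, Km1 * q, Km1 * q)
    for (k in seq_len(Km1)) {
      for (l in k:Km1) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        blk <- crossprod(Xd * w, Xd)
        rk <- (k - 1) * q + seq_len(q); rl <- (l - 1) * q + seq_len(q)
        H[rk, rl] <- blk
        if (l != k) H[rl, rk] <- blk
      }
    }
    H <- H + diag(lambda * pen_mask, Km1 * q)
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), g), error = function(e) NULL)
    if (is.null(step)) break
    # step halving
    improved <- FALSE
    for (half in 0:30) {
      Bn <- B + matrix(step / 2^half, nrow = Km1, byrow = TRUE)
      lln <- ll_fun(Bn)
      if (is.finite(lln) && lln >= ll - 1e-12) {
        improved <- TRUE
        break
      }
    }
    if (!improved) break
    delta <- lln - ll
    B <- Bn; ll <- lln
    if (abs(delta) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  # report the unpenalized log-likelihood at the estimate
  eta <- Xd %*% t(B)
  m <- pmax(apply(eta, 1, max), 0)
  ll_plain <- sum(Y * eta) - sum(m + log(exp(-m) + rowSums(exp(eta - m))))
  list(B = B, ll = ll_plain, converged = converged)
}

#' Predicted class probabilities for new data
#'
#' @param object a `dlz_multinom`.
#' @param newdata data frame containing the model's covariate columns.
#' @param ... unused.
#' @return n x classes matrix of probabilities (columns in class order,
#'   reference first).
#' @export
predict.dlz_multinom <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$covariates, drop = FALSE]))
  eta <- X %*% t(object$coefficients)
  m <- pmax(apply(eta, 1, max), 0)
  P <- cbind(exp(-m), exp(eta - m))
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  P
}

#' @export
print.dlz_multinom <- function(x, ...) {
  cat(sprintf(
    "<dlz_multinom> %d classes (ref %s), %d covariates, n = %d, logLik = %.3f, df = %d%s\n",
    length(x$classes), x$reference, length(x$covariates), x$n,
    x$log_likelihood, x$df, if (x$ridged) " [ridged]" else ""
  ))
  invisible(x)
}

#' Tidy a fitted multinomial model
#'
#' @param x a `dlz_multinom`.
#' @param ... unused.
#' @return Tibble with columns `class`, `term`, `estimate` (original scale).
#' @export
tidy.dlz_multinom <- function(x, ...) {
  B <- x$coefficients
  tibble::tibble(
    class = rep(rownames(B), times = ncol(B)),
    term = rep(colnames(B), each = nrow(B)),
    estimate = as.vector(B)
  ) |>
    dplyr::arrange(match(.data$class, rownames(B)), match(.data$term, colnames(B)))
}

#' @rdname tidy.dlz_multinom
#' @return `glance()` returns a one-row tibble: `log_likelihood`, `df`, `n`,
#'   `n_classes`, `aic`, `converged`.
#' @export
glance.dlz_multinom <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood, df = x$df, n = x$n,
    n_classes = length(x$classes), aic = -2 * x$log_likelihood + 2 * x$df,
    converged = x$converged
  )
}

#' Likelihood-ratio test between nested multinomial fits
#'
#' The delta chi-squared statistic `2 * (LL_full - LL_reduced)` with degrees
#' of freedom equal to the difference in free parameters, referred to the
#' chi-square upper tail. Used both for whole-model comparisons (Model 1 vs
#' Model 2 vs Model 3) and single-parameter drops.
#'
#' @param full,reduced `dlz_multinom` fits on the same rows; the reduced
#'   model's covariates must be a subset of the full model's.
#' @return Tibble with one row: `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "dlz_multinom"), inherits(reduced, "dlz_multinom"))
  if (full$n != reduced$n || !identical(full$classes, reduced$classes)) {
    stop("models were not fitted on the same data", call. = FALSE)
  }
  if (!all(reduced$covariates %in% full$covariates)) {
    stop("models are not nested: reduced covariates must be a subset of the full model's",
         call. = FALSE)
  }
  chi2 <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (chi2 < -1e-6) {
    warning("full-model likelihood below reduced-model likelihood; check convergence",
            call. = FALSE)
  }
  chi2 <- max(chi2, 0)
  df <- full$df - reduced$df
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1)
}
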