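# small deterministic cohorts for model tests
toy_cohort <- function(n = 120, seed = 1, classes = c("control", "A", "B"),
                       effect = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  eta_a <- -0.5 + effect * x1
  eta_b <- -0.8 + effect * 0.5 * x2
  p <- cbind(1, exp(eta_a), exp(eta_b))
  p <- p / rowSums(p)
  cls <- apply(p, 1, function(pr) sample(classes, 1, prob = pr))
  tibble::tibble(outcome = cls, x1 = x1, x2 = x2)
}

test_that("intercept-only log-likelihood matches the multinomial closed form", {
  co <- toy_cohort(n = 150, seed = 2)
  fit <- fit_multinomial(co, covariates = character(0))
  nk <- table(co$outcome)
  expect_equal(fit$log_likelihood, sum(nk * log(nk / sum(nk))), tolerance = 1e-9)
  expect_equal(fit$df, (length(nk) - 1) * 1)
})

test_that("a constant covariate adds nothing to the likelihood", {
  co <- toy_cohort(n = 100, seed = 3)
  co$flat <- 5
  expect_error(fit_multinomial(co, c("x1", "flat")), "collinear.*flat")
  # a near-constant but non-collinear covariate: compare to intercept-only
  fit0 <- fit_multinomial(co, character(0))
  set.seed(4)
  co$noise <- rnorm(100)
  fit1 <- suppressWarnings(fit_multinomial(co, "noise"))
  expect_gte(fit1$log_likelihood, fit0$log_likelihood - 1e-8)
})

test_that("two-class fit reproduces the binomial IRLS (glm) deviance", {
  set.seed(5)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * x))
  co <- tibble::tibble(outcome = ifelse(y == 1, "event", "control"), x = x)
  fit <- fit_multinomial(co, "x")
  oracle <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(-2 * fit$log_likelihood, oracle$deviance, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["event", ]), unname(stats::coef(oracle)),
               tolerance = 1e-6)
})

test_that("likelihood never decreases along the nesting chain", {
  co <- toy_cohort(n = 200, seed = 6)
  f0 <- fit_multinomial(co, character(0))
  f1 <- fit_multinomial(co, "x1")
  f2 <- fit_multinomial(co, c("x1", "x2"))
  expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-6)
  expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-6)
  expect_error(lrt(f1, f2), "not nested")
})

test_that("LRT follows the chi-square reference", {
  co <- toy_cohort(n = 200, seed = 7)
  f2 <- fit_multinomial(co, c("x1", "x2"))
  res_same <- lrt(f2, f2)
  expect_equal(res_same$chi2, 0, tolerance = 1e-9)
  expect_equal(res_same$p_value, 1)
  # closed form: LL -95 vs -100 with 3 df -> chi2 = 10
  f_full <- f2; f_red <- fit_multinomial(co, "x1")
  f_full$log_likelihood <- -95; f_red$log_likelihood <- -100
  f_full$df <- f_red$df + 3
  out <- lrt(f_full, f_red)
  expect_equal(out$chi2, 10)
  expect_equal(out$df, 3)
  expect_equal(out$p_value, pchisq(10, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(out$p_value, 5), 0.01857)
})

test_that("fits are invariant to linear covariate rescaling", {
  co <- toy_cohort(n = 150, seed = 8)
  f <- fit_multinomial(co, c("x1", "x2"))
  co2 <- co
  co2$x1 <- co$x1 * 1000 - 7
  f2 <- fit_multinomial(co2, c("x1", "x2"))
  expect_equal(f2$log_likelihood, f$log_likelihood, tolerance = 1e-8)
  expect_equal(f2$fitted, f$fitted, tolerance = 1e-8)
  expect_equal(f2$coefficients[, "x1"] * 1000, f$coefficients[, "x1"] ,
               tolerance = 1e-6)
  r1 <- roc_one_vs_control(f, "A")
  r2 <- roc_one_vs_control(f2, "A")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-8)
})

test_that("separation triggers the bounded ridge fallback with a warning", {
  co <- tibble::tibble(
    outcome = rep(c("control", "event"), each = 10),
    x = c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1))
  )
  expect_warning(fit <- fit_multinomial(co, "x"), "separation")
  expect_true(fit$ridged)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("ROC AUC matches brute-force pairwise counting and pROC", {
  mk_fit <- function(scores, labels) {
    structure(list(
      classes = c("control", "event"), reference = "control",
      outcome = factor(labels, levels = c("control", "event")),
      fitted = cbind(control = 1 - scores, event = scores)
    ), class = "dlz_multinom")
  }
  # worked 4-point examples
  expect_equal(roc_one_vs_control(mk_fit(c(.5, .5, .5, .5) / 1,
                                         c("control", "control", "event", "event")),
                                  "event")$auc, 0.5)
  expect_equal(roc_one_vs_control(mk_fit(c(.1, .2, .3, .4),
                                         c("control", "control", "event", "event")),
                                  "event")$auc, 1.0)
  expect_equal(roc_one_vs_control(mk_fit(c(.1, .2, .3, .4),
                                         c("control", "event", "control", "event")),
                                  "event")$auc, 0.75)
  # random scores vs both oracles
  set.seed(9)
  for (rep in 1:5) {
    sc <- round(runif(60), 2) # rounded -> ties exercised
    lb <- sample(c("control", "event"), 60, TRUE)
    if (length(unique(lb)) < 2) next
    r <- roc_one_vs_control(mk_fit(sc, lb), "event")
    expect_equal(r$auc, oracle_auc(sc, lb == "event"), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("control", "event"),
                                               direction = "<", quiet = TRUE)))
    expect_equal(r$auc, proc_auc, tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximizes sensitivity + specificity - 1", {
  mk_fit <- function(scores, labels) {
    structure(list(
      classes = c("control", "event"), reference = "control",
      outcome = factor(labels, levels = c("control", "event")),
      fitted = cbind(control = 1 - scores, event = scores)
    ), class = "dlz_multinom")
  }
  sc <- c(0.1, 0.2, 0.35, 0.4, 0.6, 0.7, 0.8, 0.9)
  lb <- c("control", "control", "control", "event", "control", "event", "event", "event")
  r <- roc_one_vs_control(mk_fit(sc, lb), "event")
  # brute force over all cutoffs
  best <- -Inf
  for (ct in sc) {
    sens <- mean(sc[lb == "event"] >= ct)
    spec <- mean(sc[lb == "control"] < ct)
    best <- max(best, sens + spec - 1)
  }
  expect_equal(r$sensitivity_pct / 100 + r$specificity_pct / 100 - 1, best,
               tolerance = 1e-12)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("AUC bands match the printed interpretation scale", {
  expect_equal(auc_band(c(0.55, 0.65, 0.75, 0.85)),
               c("fail", "poor", "acceptable", "excellent"))
  expect_equal(auc_band(0.95), "excellent")
  expect_equal(auc_band(0.45), "fail")
  expect_equal(auc_band(c(0.6, 0.7, 0.8)), c("poor", "acceptable", "excellent"))
})

test_that("ICC(2,1): perfect agreement, rater offset, and ANOVA oracle", {
  set.seed(10)
  x <- rnorm(12, 50, 10)
  M <- cbind(x, x)
  expect_equal(icc_two_way_random(M)$icc, 1)
  # constant offset between raters lowers absolute agreement below 1
  M2 <- cbind(x, x + 5)
  expect_lt(icc_two_way_random(M2)$icc, 1)
  # 5 x 2 table against the direct variance-components oracle
  M3 <- matrix(c(9, 2, 5, 8, 6, 10, 4, 6, 9, 7), ncol = 2)
  res <- icc_two_way_random(M3)
  expect_equal(res$icc, oracle_icc21(M3), tolerance = 1e-9)
  expect_true(res$lower <= res$icc && res$icc <= res$upper)
  # degenerate: no between-subject variance beyond error -> 0 with warning
  flat <- matrix(rep(c(5, 5.1), each = 4), ncol = 2)
  expect_warning(z <- icc_two_way_random(flat), "between-subject")
  expect_equal(z$icc, 0)
  expect_error(icc_two_way_random(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  co <- toy_cohort(n = 100, seed = 11)
  f <- fit_multinomial(co, c("x1", "x2"))
  td <- tidy(f)
  expect_equal(nrow(td), 2 * 3) # 2 non-reference classes x 3 terms
  expect_named(td, c("class", "term", "estimate"))
  gl <- glance(f)
  expect_equal(gl$df, 6)
  expect_equal(gl$n, 100)
  expect_lte(gl$log_likelihood, 0)
})
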