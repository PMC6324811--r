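new_test_result <- function(statistic, df, p_value, test_name, null_hyp,
                            extra = list()) {
  stopifnot(is.finite(statistic))
  if (is.numeric(p_value)) stopifnot(p_value >= 0, p_value <= 1)
  structure(
    c(list(statistic = statistic, df = df, p_value = p_value,
           test_name = test_name, null_hypothesis = null_hyp), extra),
    class = "overdispersion_test")
}

#' @export
print.overdispersion_test <- function(x, ...) {
  cat(sprintf("%s\n  H0: %s\n  statistic = %.4f (df %s), p = %.4g\n",
              x$test_name, x$null_hypothesis, x$statistic,
              as.character(x$df), x$p_value))
  invisible(x)
}

#' Boundary likelihood-ratio test of Poisson vs negative binomial
#'
#' Fits the same mean model (intercept, unpenalized covariates, log-exposure
#' offset) under Poisson and under full-ML negative binomial, and tests
#' H0: alpha = 0 with the statistic 2 (loglik_NB - loglik_Poisson).  Because
#' alpha = 0 sits on the boundary of the parameter space, the null
#' distribution is the mixture 0.5 chi2_0 + 0.5 chi2_1; both the mixture
#' p-value (the primary \code{p_value}) and the plain chi2_1 p-value
#' (\code{p_value_chisq1}) are reported.
#'
#' @param data A [count_dataset()]; only the unpenalized mean model is used.
#' @return An \code{overdispersion_test} with fields \code{statistic},
#'   \code{df = "boundary-mixture"}, \code{p_value} (mixture),
#'   \code{p_value_chisq1}, \code{alpha_hat}, and a \code{recommendation}
#'   (\code{"negbin"} or \code{"poisson"} at the 0.05 level).
#' @export
boundary_lr_test <- function(data) {
  pois <- fit_unpenalized_mle(data, family = "poisson")
  nb <- fit_negbin_ml(data)
  if (!nb$converged) stop("full-ML negative binomial fit did not converge")
  stat <- 2 * (nb$loglik - pois$loglik)
  stat <- max(stat, 0)  # nesting guarantees non-negativity up to round-off
  p1 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pmix <- if (stat <= 0) 1 else 0.5 * p1
  new_test_result(
    stat, df = "boundary-mixture", p_value = pmix,
    test_name = "Boundary likelihood-ratio test (Poisson vs NB)",
    null_hyp = "alpha = 0 (no over-dispersion)",
    extra = list(p_value_chisq1 = p1, alpha_hat = nb$alpha,
                 loglik_poisson = pois$loglik, loglik_negbin = nb$loglik,
                 recommendation = if (pmix < 0.05) "negbin" else "poisson"))
}

#' Score test for over-dispersion (auxiliary regression form)
#'
#' Cameron-Trivedi regression-based score test against the alternative
#' Var(Y) = mu + alpha mu^2: the auxiliary variable
#' z_i = ((y_i - mu_i)^2 - y_i) / mu_i is regressed on mu_i without an
#' intercept, and the one-sided t-statistic on the slope tests
#' H0: alpha = 0 against alpha > 0.
#'
#' @param data A [count_dataset()]; the Poisson mean model uses the
#'   unpenalized covariates and offset.
#' @return An \code{overdispersion_test} (one-sided p, df = N - 1).
#' @export
score_test_overdispersion <- function(data) {
  pois <- fit_unpenalized_mle(data, family = "poisson")
  mu <- pois$mu
  if (any(mu <= 0) || any(!is.finite(mu))) stop("non-positive fitted means")
  z <- ((data$y - mu)^2 - data$y) / mu
  fit <- stats::lm(z ~ mu - 1)
  tval <- summary(fit)$coefficients[1, "t value"]
  n <- length(data$y)
  p <- stats::pt(tval, df = n - 1, lower.tail = FALSE)
  new_test_result(
    tval, df = n - 1L, p_value = p,
    test_name = "Score test for over-dispersion (auxiliary regression)",
    null_hyp = "alpha = 0 against alpha > 0",
    extra = list(alpha_hat = unname(stats::coef(fit)[1])))
}

#' Lagrange multiplier test for over-dispersion
#'
#' LM statistic (Hilbe form) from the fitted Poisson model:
#' \deqn{LM = \left(\sum_i [(y_i - \hat\mu_i)^2 - y_i]\right)^2 / (2 \sum_i \hat\mu_i^2)}
#' referred to chi2_1.
#'
#' @inheritParams score_test_overdispersion
#' @return An \code{overdispersion_test} (df = 1).
#' @export
lagrange_multiplier_test <- function(data) {
  pois <- fit_unpenalized_mle(data, family = "poisson")
  mu <- pois$mu
  if (any(mu <= 0) || any(!is.finite(mu))) stop("non-positive fitted means")
  num <- sum((data$y - mu)^2 - data$y)
  stat <- num^2 / (2 * sum(mu^2))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result(
    stat, df = 1L, p_value = p,
    test_name = "Lagrange multiplier test for over-dispersion",
    null_hyp = "alpha = 0 (equi-dispersion)")
}

#' Pearson dispersion statistic of a Poisson fit
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom, N - (J + 1).  Values well above 1 signal possible
#' over-dispersion.
#'
#' @inheritParams score_test_overdispersion
#' @param poisson_fit Optional result of
#'   \code{fit_unpenalized_mle(data, family = "poisson")}; refit if missing.
#' @return Scalar dispersion statistic.
#' @export
pearson_dispersion <- function(data, poisson_fit = NULL) {
  if (is.null(poisson_fit)) {
    poisson_fit <- fit_unpenalized_mle(data, family = "poisson")
  }
  mu <- poisson_fit$mu
  df <- length(data$y) - (ncol(data$Xu) + 1L)
  if (df <= 0) stop("non-positive residual degrees of freedom")
  sum((data$y - mu)^2 / mu) / df
}
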