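#' Negative binomial log probability mass function
#'
#' Log density of the NB2 parameterization with mean \code{mu} and
#' heterogeneity \code{alpha}, so that Var(Y) = mu + alpha * mu^2.  All
#' gamma-function ratios are evaluated in log space; for very small
#' \code{alpha} (1/alpha beyond 1e7) the ratio
#' log Gamma(y + 1/alpha) - log Gamma(1/alpha) is accumulated as
#' sum_{j < y} log(1/alpha + j), which avoids the catastrophic cancellation
#' that makes the naive difference useless near the Poisson limit.
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param alpha Positive heterogeneity parameter.
#' @return Log pmf value(s), recycled to the common length.
#' @export
#' @examples
#' nb_log_pmf(0, mu = 1, alpha = 1)  # log(1/2)
nb_log_pmf <- function(y, mu, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive")
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    stop("`y` must be non-negative integers")
  }
  n <- max(length(y), length(mu))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  r <- 1 / alpha
  l1p <- log1p(mu / r)   # log(1 + alpha * mu)
  lgamma_ratio(y, r) - lgamma(y + 1) - r * l1p + y * (log(mu) - log(r) - l1p)
}

# log Gamma(y + r) - log Gamma(r), stable for huge r
lgamma_ratio <- function(y, r) {
  if (r <= 1e7) return(lgamma(y + r) - lgamma(r))
  vapply(y, function(yy) {
    if (yy == 0) 0 else sum(log(r + seq_len(yy) - 1))
  }, numeric(1))
}

#' Negative binomial log-likelihood
#'
#' Sum of [nb_log_pmf()] terms at the mean vector implied by \code{params}
#' and \code{data} (log link, log-exposure offset).
#'
#' @inheritParams mean_response
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(params, data) {
  if (params$family != "negbin") stop("`params$family` must be \"negbin\"")
  mu <- mean_response(params, data)
  sum(nb_log_pmf(data$y, mu, params$alpha))
}

#' Poisson log-likelihood
#'
#' Log-likelihood of the Poisson rate model with log link and log-exposure
#' offset; log(y!) is computed through the log-gamma function.
#'
#' @inheritParams mean_response
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(params, data) {
  if (params$family != "poisson") stop("`params$family` must be \"poisson\"")
  mu <- mean_response(params, data)
  sum(data$y * log(mu) - mu - lgamma(data$y + 1))
}

# log-likelihood at a mean vector, dispatching on alpha
loglik_at_mu <- function(y, mu, alpha) {
  if (alpha > 1e-12) {
    sum(nb_log_pmf(y, mu, alpha))
  } else {
    sum(y * log(mu) - mu - lgamma(y + 1))
  }
}

#' Score of the NB log-likelihood over an expanded penalized design
#'
#' Gradient of the NB log-likelihood with respect to the penalized
#' coefficients over an expanded design (typically the standardized
#' \code{[Xp : -Xp]} block used by the GMIFS solver):
#' \code{t(X) \%*\% ((y - mu) / (1 + alpha * mu))}.  The mean is computed at
#' \code{params} with \code{params$beta} applied to the expanded design
#' itself, so when the design is \code{[X : -X]} the two halves of the
#' returned vector are exact negations of each other.
#'
#' @param params [model_params()] whose \code{beta} has one entry per column
#'   of \code{expanded_design}.
#' @param data A [count_dataset()]; its \code{Xp} is ignored in favour of
#'   \code{expanded_design}.
#' @param expanded_design Numeric matrix (N x M) or an
#'   [expand_covariates()] result, whose penalized block is then used.
#' @return Numeric score vector of length M.
#' @export
nb_score_expanded <- function(params, data, expanded_design) {
  if (params$alpha <= 0) stop("`alpha` must be positive for the NB score")
  score_expanded(params, data, expanded_design, alpha = params$alpha)
}

#' Score of the Poisson log-likelihood over an expanded penalized design
#'
#' The NB score with alpha = 0: \code{t(X) \%*\% (y - mu)}.
#'
#' @inheritParams nb_score_expanded
#' @return Numeric score vector.
#' @export
poisson_score_expanded <- function(params, data, expanded_design) {
  score_expanded(params, data, expanded_design, alpha = 0)
}

score_expanded <- function(params, data, expanded_design, alpha) {
  X <- if (inherits(expanded_design, "expanded_design")) {
    expanded_design$penalized
  } else {
    as.matrix(expanded_design)
  }
  if (nrow(X) != length(data$y)) stop("design rows must match observations")
  if (length(params$beta) != ncol(X)) {
    stop("`params$beta` must have one entry per expanded design column")
  }
  eta <- params$gamma0 + log(data$exposure)
  if (ncol(data$Xu) > 0) eta <- eta + drop(data$Xu %*% params$gamma)
  if (ncol(X) > 0) eta <- eta + drop(X %*% params$beta)
  mu <- exp(pmin(eta, 700))
  w <- (data$y - mu) / (1 + alpha * mu)
  drop(crossprod(X, w))
}

#' Method-of-moments estimator of the NB heterogeneity parameter
#'
#' Moment estimator implied by Var(Y) = mu + alpha * mu^2:
#' \deqn{\hat\alpha = \sum_i [(y_i - \hat\mu_i)^2 - \hat\mu_i] / \sum_i \hat\mu_i^2}
#' clipped below at \code{floor} so that downstream NB formulas remain
#' defined under equi- or under-dispersion.
#'
#' The exact moment recipe is configurable, since more than one estimator
#' is in circulation under this name: \code{"ratio_of_sums"} (the default
#' above) and \code{"pearson_df"}, which solves the Pearson-chi-square
#' moment equation \eqn{\sum_i (y_i - \mu_i)^2 / [\mu_i (1 + \alpha \mu_i)]
#' = n - p} for \eqn{\alpha} (the classic equate-chi-square-to-residual-df
#' estimator).
#'
#' @param y Count vector.
#' @param mu Fitted positive mean vector of the same length.
#' @param floor Lower clip for the estimate (default 1e-8, numerically
#'   indistinguishable from Poisson).
#' @param method \code{"ratio_of_sums"} or \code{"pearson_df"}.
#' @param df_resid Residual degrees of freedom n - p used by
#'   \code{"pearson_df"} (default n - 1).
#' @return Non-negative dispersion estimate.
#' @export
estimate_alpha_mom <- function(y, mu, floor = 1e-8,
                               method = c("ratio_of_sums", "pearson_df"),
                               df_resid = length(y) - 1) {
  method <- match.arg(method)
  if (length(y) != length(mu)) stop("`y` and `mu` must have equal length")
  if (length(y) < 2L) stop("at least two observations are required")
  if (any(mu <= 0)) stop("`mu` must be positive")
  if (method == "ratio_of_sums") {
    num <- sum((y - mu)^2 - mu)
    return(max(num / sum(mu^2), floor))
  }
  # pearson_df: chi2(alpha) = sum (y-mu)^2 / (mu (1+alpha mu)) is strictly
  # decreasing in alpha; solve chi2(alpha) = df_resid by bisection
  if (df_resid <= 0) stop("`df_resid` must be positive")
  chi2 <- function(a) sum((y - mu)^2 / (mu * (1 + a * mu)))
  if (chi2(floor) <= df_resid) return(floor)
  hi <- 1
  while (chi2(hi) > df_resid && hi < 1e6) hi <- hi * 10
  stats::uniroot(function(a) chi2(a) - df_resid, c(floor, hi),
                 tol = 1e-10)$root
}

#' Sample negative binomial counts via the gamma-Poisson mixture
#'
#' Draws Y_i ~ NB(mu_i, alpha) as a Poisson draw with a gamma-distributed
#' rate: lambda_i = mu_i * G_i with G_i ~ Gamma(shape = 1/alpha,
#' scale = alpha), so E(Y) = mu and Var(Y) = mu + alpha * mu^2.  Uses R's
#' global RNG stream; seed with [set.seed()] for reproducibility.  At or
#' below the dispersion floor the draw degenerates to Poisson.
#'
#' @param mu Positive mean vector.
#' @param alpha Non-negative heterogeneity parameter.
#' @param floor Dispersion values at or below this are treated as Poisson.
#' @return Integer-valued count vector of length \code{length(mu)}.
#' @export
nb_sample <- function(mu, alpha, floor = 1e-8) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative number")
  }
  if (any(mu <= 0)) stop("`mu` must be positive")
  n <- length(mu)
  if (alpha <= floor) {
    return(stats::rpois(n, mu))
  }
  g <- stats::rgamma(n, shape = 1 / alpha, scale = alpha)
  stats::rpois(n, mu * g)
}
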