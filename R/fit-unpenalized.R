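# Newton maximization of the (gamma0, gamma) block of a count-model
# log-likelihood with everything else held fixed.  Z is the intercept-plus-
# unpenalized design; `offset` already contains log(exposure) plus any fixed
# penalized contribution.  Observed-information Newton with step halving;
# alpha at or below 1e-12 is treated as Poisson.
newton_theta <- function(y, Z, offset, alpha, start = NULL,
                         tol = 1e-8, maxit = 100L) {
  p <- ncol(Z)
  if (sum(y) == 0) {
    # degenerate all-zero response: mean driven to zero, likelihood sup at
    # the boundary; return a practically-zero mean without iterating
    th <- c(-30 - mean(offset), rep(0, p - 1))
    mu <- exp(pmin(drop(Z %*% th) + offset, 700))
    return(list(theta = th, mu = mu, loglik = loglik_at_mu(y, mu, alpha),
                converged = TRUE, iterations = 0L, gradient_norm = NA_real_,
                boundary = TRUE))
  }
  th <- if (!is.null(start)) start else {
    c(log(sum(y) / sum(exp(pmin(offset, 700)))), rep(0, p - 1))
  }
  eta <- pmin(drop(Z %*% th) + offset, 700)
  mu <- exp(eta)
  ll <- loglik_at_mu(y, mu, alpha)
  gnorm <- Inf
  for (it in seq_len(maxit)) {
    w <- (y - mu) / (1 + alpha * mu)
    grad <- drop(crossprod(Z, w))
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol) {
      return(list(theta = th, mu = mu, loglik = ll, converged = TRUE,
                  iterations = it - 1L, gradient_norm = gnorm,
                  boundary = FALSE))
    }
    wi <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
    H <- crossprod(Z, Z * wi)
    delta <- tryCatch(solve(H, grad), error = function(e) grad / max(wi, 1))
    # step halving: the Newton direction is ascent for this concave block
    step <- 1
    repeat {
      th_new <- th + step * delta
      eta <- pmin(drop(Z %*% th_new) + offset, 700)
      mu_new <- exp(eta)
      ll_new <- loglik_at_mu(y, mu_new, alpha)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    th <- th + step * delta
    mu <- exp(pmin(drop(Z %*% th) + offset, 700))
    ll <- loglik_at_mu(y, mu, alpha)
  }
  cond <- structure(
    class = c("nbgmifs_convergence_error", "error", "condition"),
    list(message = sprintf(
      "Newton refit of (gamma0, gamma) did not reach gradient norm < %g in %d iterations (last norm %.3g)",
      tol, maxit, gnorm),
      call = sys.call(-1),
      iterate = list(theta = th, loglik = ll, gradient_norm = gnorm)))
  stop(cond)
}

#' Maximum likelihood for the intercept and unpenalized coefficients
#'
#' Maximizes the Poisson or NB log-likelihood over (gamma0, gamma) only,
#' treating the penalized coefficients and (for NB) the heterogeneity
#' parameter as fixed constants.  This is the inner fit the GMIFS solver
#' repeats at every step, so it uses observed-information Newton with an
#' analytic gradient, convergence at gradient norm < 1e-8, and at most 100
#' iterations.
#'
#' @param data A [count_dataset()].
#' @param beta_fixed Penalized coefficients held fixed (on the scale of
#'   \code{data$Xp}); default all zero.
#' @param alpha_fixed Fixed heterogeneity parameter (ignored for Poisson).
#' @param family \code{"negbin"} or \code{"poisson"}.
#' @param start Optional starting value \code{c(gamma0, gamma)}.
#' @return List with \code{gamma0}, \code{gamma}, \code{mu}, \code{loglik},
#'   \code{converged}, \code{iterations}, \code{gradient_norm}.  On
#'   non-convergence a condition of class
#'   \code{"nbgmifs_convergence_error"} is signalled carrying the last
#'   iterate in its \code{iterate} field.
#' @export
fit_unpenalized_mle <- function(data, beta_fixed = NULL, alpha_fixed = 0,
                                family = c("negbin", "poisson"),
                                start = NULL) {
  family <- match.arg(family)
  alpha <- if (family == "poisson") 0 else alpha_fixed
  if (family == "negbin" && (!is.finite(alpha) || alpha < 0)) {
    stop("`alpha_fixed` must be non-negative")
  }
  offset <- log(data$exposure)
  if (!is.null(beta_fixed) && length(beta_fixed)) {
    if (length(beta_fixed) != ncol(data$Xp)) {
      stop("`beta_fixed` must match the columns of `Xp`")
    }
    offset <- offset + drop(data$Xp %*% beta_fixed)
  }
  Z <- cbind(`(Intercept)` = 1, data$Xu)
  fit <- newton_theta(data$y, Z, offset, alpha, start = start)
  list(gamma0 = unname(fit$theta[1]), gamma = fit$theta[-1], mu = fit$mu,
       loglik = fit$loglik, converged = fit$converged,
       iterations = fit$iterations, gradient_norm = fit$gradient_norm)
}

#' Full maximum likelihood negative binomial fit (low-dimensional)
#'
#' Joint ML over (gamma0, gamma, alpha) for the unpenalized mean model, by
#' alternating a Newton fit of the mean block at fixed alpha with a 1-D
#' profile maximization of alpha on the log scale.  Used by the boundary
#' likelihood-ratio test, where the NB and Poisson log-likelihoods must be
#' directly comparable.
#'
#' @param data A [count_dataset()] (its \code{Xp} is ignored).
#' @param alpha_max Upper bound of the profile search for alpha.
#' @param tol Convergence tolerance on the log-likelihood between
#'   alternations (1e-8; the 1-D profile search cannot locate the optimum
#'   more precisely than about the square root of machine epsilon, so a
#'   tighter tolerance would chase numerical jitter).
#' @param maxit Maximum number of alternations.
#' @return List with \code{gamma0}, \code{gamma}, \code{alpha}, \code{mu},
#'   \code{loglik}, \code{converged}.
#' @export
fit_negbin_ml <- function(data, alpha_max = 1e3, tol = 1e-8, maxit = 100L) {
  Z <- cbind(`(Intercept)` = 1, data$Xu)
  offset <- log(data$exposure)
  pois <- newton_theta(data$y, Z, offset, alpha = 0)
  alpha <- max(estimate_alpha_mom(data$y, pois$mu), 1e-8)
  th <- pois$theta
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    fit <- newton_theta(data$y, Z, offset, alpha, start = th)
    th <- fit$theta
    mu <- fit$mu
    prof <- stats::optimize(
      function(la) sum(nb_log_pmf(data$y, mu, exp(la))),
      interval = c(log(1e-8), log(alpha_max)), maximum = TRUE, tol = 1e-8)
    alpha <- exp(prof$maximum)
    ll <- prof$objective
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # near the alpha = 0 boundary the profile is flat; accept a stalled
  # alternation whose likelihood has stabilised well beyond test precision
  if (!converged && abs(ll - ll_old) < 1e-5) converged <- TRUE
  list(gamma0 = unname(th[1]), gamma = th[-1], alpha = alpha, mu = mu,
       loglik = ll, converged = converged)
}
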