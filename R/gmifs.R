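#' Expand and standardize the penalized design
#'
#' Builds the expanded covariate space \code{[Xp_std : -Xp_std]} in which
#' the forward stagewise solver works: each penalized column is centred and
#' scaled to unit standard deviation, then paired with its negation so that
#' every coefficient update is a non-negative increment and the sign of the
#' effect is carried by which member of the pair is incremented.  Scaling
#' constants are retained for back-transformation to the original predictor
#' scale.
#'
#' @param Xp Penalized design matrix (N x K).
#' @return An object of class \code{expanded_design} with elements
#'   \code{penalized} (N x 2K matrix), \code{center}, \code{scale}
#'   (length-K vectors), and \code{K}.
#' @export
expand_covariates <- function(Xp) {
  Xp <- as.matrix(Xp)
  K <- ncol(Xp)
  if (K == 0) {
    return(structure(
      list(penalized = matrix(numeric(0), nrow(Xp), 0),
           center = numeric(0), scale = numeric(0), K = 0L),
      class = "expanded_design"))
  }
  ctr <- colMeans(Xp)
  sds <- apply(Xp, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(Xp)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant penalized column(s): ", paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(Xp, 2, ctr, "-"), 2, sds, "/")
  structure(
    list(penalized = cbind(Xs, -Xs), center = ctr, scale = sds, K = K),
    class = "expanded_design")
}

#' Fit a GMIFS regularization path for a count model
#'
#' Generalized monotone incremental forward stagewise solver for Poisson and
#' negative binomial regression with a log link, log-exposure offset, and an
#' unpenalized covariate subset.  Starting from all penalized coefficients
#' at zero, each step (i) finds, over the expanded standardized design
#' \code{[Xp_std : -Xp_std]}, the coefficient with the largest positive
#' log-likelihood gradient, (ii) increments it by \code{epsilon}, (iii)
#' refits the intercept and unpenalized coefficients by maximum likelihood
#' with the penalized contribution held fixed, and (iv) for the NB family
#' re-estimates the heterogeneity parameter by the method of moments and
#' refits the unpenalized block at the new value.  Iteration stops when the
#' absolute change in log-likelihood between successive steps falls below
#' \code{tau}, when the number of nonzero differenced coefficients exceeds
#' \code{max_nonzero}, or at \code{max_steps}.
#'
#' For the NB family the heterogeneity parameter is initialized from the
#' method of moments at the intercept/unpenalized-only fit (itself started
#' from the Poisson fit).
#'
#' @param data A [count_dataset()].
#' @param family \code{"negbin"} or \code{"poisson"}.
#' @param epsilon Coefficient increment per step (default 0.001).
#' @param tau Stopping tolerance on successive log-likelihood differences
#'   (default 1e-5).
#' @param max_nonzero Stop once the count of nonzero differenced penalized
#'   coefficients exceeds this (default N - 1).
#' @param max_steps Hard cap on the number of steps (default 50000).
#' @param alpha_method Moment recipe for the per-step dispersion
#'   re-estimate; see [estimate_alpha_mom()].  For \code{"pearson_df"} the
#'   residual df is n minus the current model size.
#' @param verbose Log a one-line milestone every 100 steps.
#' @return An object of class \code{gmifs_fit}; see [coef.gmifs_fit()],
#'   [select_model()], [predict.gmifs_model()].  Its \code{steps} element
#'   is a per-step data frame with columns \code{step}, \code{updated}
#'   (expanded-column index incremented, \code{NA} at step 0),
#'   \code{loglik}, \code{alpha}, \code{gamma0}, \code{nonzero}, \code{df},
#'   \code{aic}, \code{bic}.
#' @export
gmifs_fit <- function(data, family = c("negbin", "poisson"),
                      epsilon = 0.001, tau = 1e-5,
                      max_nonzero = NULL, max_steps = 50000L,
                      alpha_method = c("ratio_of_sums", "pearson_df"),
                      verbose = FALSE) {
  family <- match.arg(family)
  alpha_method <- match.arg(alpha_method)
  stopifnot(epsilon > 0, tau > 0)
  y <- data$y
  n <- length(y)
  if (n < 2L) stop("at least two observations are required")
  J <- ncol(data$Xu)
  if (is.null(max_nonzero)) max_nonzero <- n - 1L
  ed <- expand_covariates(data$Xp)
  K <- ed$K
  Xs <- if (K > 0) ed$penalized[, seq_len(K), drop = FALSE] else
    matrix(numeric(0), n, 0)
  Z <- cbind(`(Intercept)` = 1, data$Xu)
  logc <- log(data$exposure)

  # step 0: intercept/unpenalized fit; NB dispersion initialized by the
  # method of moments at the Poisson means, then the mean block is refit
  alpha_hat <- function(mu, nz) {
    estimate_alpha_mom(y, mu, method = alpha_method,
                       df_resid = max(n - (nz + J + 1L), 1L))
  }
  pois0 <- newton_theta(y, Z, logc, alpha = 0)
  if (family == "negbin") {
    alpha <- alpha_hat(pois0$mu, 0L)
    fit0 <- newton_theta(y, Z, logc, alpha, start = pois0$theta)
  } else {
    alpha <- 0
    fit0 <- pois0
  }
  theta <- fit0$theta
  mu <- fit0$mu
  ll <- fit0$loglik

  cap <- 1024L
  upd <- integer(cap)
  rec_ll <- rec_alpha <- rec_g0 <- numeric(cap)
  rec_nz <- integer(cap)
  gmat <- matrix(NA_real_, cap, J)
  grow <- function(len) {
    upd <<- c(upd, integer(len)); rec_ll <<- c(rec_ll, numeric(len))
    rec_alpha <<- c(rec_alpha, numeric(len)); rec_g0 <<- c(rec_g0, numeric(len))
    rec_nz <<- c(rec_nz, integer(len))
    gmat <<- rbind(gmat, matrix(NA_real_, len, J))
    cap <<- cap + len
  }
  record <- function(s, m, ll, alpha, theta, nz) {
    if (s + 1L > cap) grow(cap)
    upd[s + 1L] <<- m
    rec_ll[s + 1L] <<- ll
    rec_alpha[s + 1L] <<- alpha
    rec_g0[s + 1L] <<- theta[1]
    rec_nz[s + 1L] <<- nz
    if (J > 0) gmat[s + 1L, ] <<- theta[-1]
  }
  record(0L, NA_integer_, ll, alpha, theta, 0L)

  beta_pos <- numeric(K)
  beta_neg <- numeric(K)
  eta_p <- numeric(n)
  s <- 0L
  stop_reason <- "max_steps"
  while (K > 0 && s < max_steps) {
    w <- (y - mu) / (1 + alpha * mu)
    g <- drop(crossprod(Xs, w))
    # argmax of the expanded gradient c(g, -g); which.max takes the lowest
    # index on exact ties, matching the deterministic tie-break contract
    gexp <- c(g, -g)
    m <- which.max(gexp)
    if (m <= K) {
      beta_pos[m] <- beta_pos[m] + epsilon
      eta_p <- eta_p + epsilon * Xs[, m]
    } else {
      beta_neg[m - K] <- beta_neg[m - K] + epsilon
      eta_p <- eta_p - epsilon * Xs[, m - K]
    }
    fit <- newton_theta(y, Z, logc + eta_p, alpha, start = theta)
    theta <- fit$theta
    mu <- fit$mu
    if (family == "negbin") {
      alpha <- alpha_hat(mu, sum(beta_pos != beta_neg))
      fit <- newton_theta(y, Z, logc + eta_p, alpha, start = theta)
      theta <- fit$theta
      mu <- fit$mu
    }
    ll_new <- fit$loglik
    if (!is.finite(ll_new)) {
      stop(sprintf("non-finite log-likelihood at step %d", s + 1L))
    }
    s <- s + 1L
    nz <- sum(beta_pos != beta_neg)
    record(s, m, ll_new, alpha, theta, nz)
    if (verbose && s %% 100L == 0L) {
      message(sprintf("gmifs step %d: loglik %.6f, alpha %.4f, nonzero %d",
                      s, ll_new, alpha, nz))
    }
    if (abs(ll_new - ll) < tau) {
      stop_reason <- "loglik_tolerance"
      break
    }
    if (nz > max_nonzero) {
      stop_reason <- "max_nonzero"
      break
    }
    ll <- ll_new
  }
  if (K == 0) stop_reason <- "no_penalized_predictors"

  idx <- seq_len(s + 1L)
  df <- rec_nz[idx] + J + 1L + as.integer(family == "negbin")
  ic <- information_criteria(rec_ll[idx], df, n)
  steps <- data.frame(
    step = 0:s, updated = upd[idx], loglik = rec_ll[idx],
    alpha = rec_alpha[idx], gamma0 = rec_g0[idx], nonzero = rec_nz[idx],
    df = df, aic = ic$aic, bic = ic$bic)
  structure(
    list(family = family, epsilon = epsilon, tau = tau,
         max_nonzero = max_nonzero, max_steps = max_steps,
         steps = steps, gamma = gmat[idx, , drop = FALSE],
         center = ed$center, scale = ed$scale, K = K, J = J, n = n,
         feature_names = colnames(data$Xp),
         unpenalized_names = colnames(data$Xu),
         stop_reason = stop_reason, data = data),
    class = "gmifs_fit")
}

#' @export
print.gmifs_fit <- function(x, ...) {
  S <- nrow(x$steps) - 1L
  cat(sprintf("gmifs_fit (%s): %d steps, N = %d, J = %d, K = %d\n",
              x$family, S, x$n, x$J, x$K))
  cat(sprintf("  epsilon = %g, tau = %g, stopped by %s\n",
              x$epsilon, x$tau, x$stop_reason))
  cat(sprintf("  final loglik %.4f, alpha %.4f, nonzero %d\n",
              x$steps$loglik[S + 1L], x$steps$alpha[S + 1L],
              x$steps$nonzero[S + 1L]))
  cat(sprintf("  min AIC at step %d, min BIC at step %d\n",
              x$steps$step[which.min(x$steps$aic)],
              x$steps$step[which.min(x$steps$bic)]))
  invisible(x)
}

# expanded coefficient vector (length 2K) at path step s, replayed from the
# per-step update indices
expanded_beta_at <- function(object, step) {
  S <- nrow(object$steps) - 1L
  if (step < 0 || step > S) stop("`step` out of range 0..", S)
  K <- object$K
  if (step == 0 || K == 0) return(numeric(2 * K))
  tabulate(object$steps$updated[2:(step + 1L)], nbins = 2L * K) *
    object$epsilon
}

#' Coefficients along a GMIFS path
#'
#' Differenced penalized coefficients (positive minus negated half of the
#' expanded space) at a given path step, on the standardized scale the
#' solver works in or back-transformed to the original predictor scale
#' (\code{beta_k / sd_k}, with the intercept absorbing
#' \code{-sum(beta_k * mean_k / sd_k)}).
#'
#' @param object A \code{gmifs_fit}.
#' @param step Path step (0-based); defaults to the final step.
#' @param scale \code{"standardized"} or \code{"original"}.
#' @param ... Unused.
#' @return Named list with \code{gamma0}, \code{gamma}, \code{beta},
#'   \code{alpha}.
#' @export
coef.gmifs_fit <- function(object, step = NULL,
                           scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  S <- nrow(object$steps) - 1L
  if (is.null(step)) step <- S
  be <- expanded_beta_at(object, step)
  K <- object$K
  beta <- be[seq_len(K)] - be[K + seq_len(K)]
  names(beta) <- object$feature_names
  gamma0 <- object$steps$gamma0[step + 1L]
  gamma <- if (object$J > 0) object$gamma[step + 1L, ] else numeric(0)
  names(gamma) <- object$unpenalized_names
  if (scale == "original" && K > 0) {
    gamma0 <- gamma0 - sum(beta * object$center / object$scale)
    beta <- beta / object$scale
  }
  list(gamma0 = gamma0, gamma = gamma, beta = beta,
       alpha = object$steps$alpha[step + 1L])
}

#' AIC and BIC from log-likelihood and model size
#'
#' AIC = -2 loglik + 2 df and BIC = -2 loglik + log(N) df.  Along a GMIFS
#' path df counts every estimated quantity: nonzero differenced penalized
#' coefficients + J unpenalized coefficients + 1 intercept + 1 for the NB
#' heterogeneity parameter.
#'
#' @param loglik Log-likelihood value(s).
#' @param df Degrees of freedom (same length or scalar).
#' @param n Number of observations.
#' @return List with vectors \code{aic} and \code{bic}.
#' @export
information_criteria <- function(loglik, df, n) {
  list(aic = -2 * loglik + 2 * df, bic = -2 * loglik + log(n) * df)
}
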