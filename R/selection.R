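#' Select a model along a GMIFS path
#'
#' Picks the path step minimising AIC, BIC, or fold-averaged cross-validated
#' prediction error.  Ties are broken toward the earlier (sparser) step.
#' For \code{criterion = "cv"} the path is refit on each training fold and
#' the held-out error is evaluated at every step (the per-step intercept,
#' unpenalized coefficients, and penalized increments of the fold path are
#' replayed on the held-out observations); fold curves are truncated to the
#' shortest fold path before averaging.
#'
#' @param path A [gmifs_fit()] object.
#' @param criterion \code{"aic"}, \code{"bic"}, or \code{"cv"}.
#' @param folds Number of CV folds (default N, i.e. leave-one-out); only
#'   used for \code{criterion = "cv"}.
#' @param metric Held-out error metric for CV: \code{"mae"} (default) or
#'   \code{"mse"}.
#' @param seed Seed for the fold assignment when \code{folds < N}.
#' @return An object of class \code{gmifs_model} holding the selected step,
#'   coefficients (standardized scale, with scaling constants for
#'   back-transformation), dispersion, criterion name and value.
#' @export
select_model <- function(path, criterion = c("aic", "bic", "cv"),
                         folds = NULL, metric = c("mae", "mse"), seed = 1L) {
  criterion <- match.arg(criterion)
  metric <- match.arg(metric)
  if (!inherits(path, "gmifs_fit")) stop("`path` must be a gmifs_fit")
  if (nrow(path$steps) < 1L) stop("empty path")
  if (criterion == "cv") {
    err <- cv_error_curve(path$data, path$family, folds = folds,
                          metric = metric, seed = seed,
                          epsilon = path$epsilon, tau = path$tau,
                          max_steps = nrow(path$steps) - 1L)
    usable <- seq_len(min(length(err), nrow(path$steps)))
    step <- which.min(err[usable]) - 1L
    value <- min(err[usable])
  } else {
    vals <- path$steps[[criterion]]
    step <- which.min(vals) - 1L   # which.min returns the first minimum
    value <- vals[step + 1L]
  }
  cf <- coef(path, step = step)
  structure(
    list(step = step, criterion = criterion, value = value,
         gamma0 = cf$gamma0, gamma = cf$gamma, beta = cf$beta,
         alpha = cf$alpha, family = path$family,
         center = path$center, scale = path$scale,
         feature_names = path$feature_names,
         unpenalized_names = path$unpenalized_names,
         loglik = path$steps$loglik[step + 1L],
         df = path$steps$df[step + 1L]),
    class = "gmifs_model")
}

#' @export
print.gmifs_model <- function(x, ...) {
  cat(sprintf("gmifs_model (%s): step %d selected by %s = %.4f\n",
              x$family, x$step, toupper(x$criterion), x$value))
  cat(sprintf("  nonzero penalized coefficients: %d; alpha = %.4f\n",
              sum(x$beta != 0), x$alpha))
  invisible(x)
}

#' Coefficients of a selected GMIFS model
#'
#' @param object A \code{gmifs_model}.
#' @param scale \code{"standardized"} (solver scale) or \code{"original"}
#'   (per-unit of the raw predictors, intercept adjusted accordingly).
#' @param ... Unused.
#' @return List with \code{gamma0}, \code{gamma}, \code{beta}, \code{alpha}.
#' @export
coef.gmifs_model <- function(object, scale = c("standardized", "original"),
                             ...) {
  scale <- match.arg(scale)
  gamma0 <- object$gamma0
  beta <- object$beta
  if (scale == "original" && length(beta)) {
    gamma0 <- gamma0 - sum(beta * object$center / object$scale)
    beta <- beta / object$scale
  }
  list(gamma0 = gamma0, gamma = object$gamma, beta = beta,
       alpha = object$alpha)
}

#' Predict expected counts from a selected GMIFS model
#'
#' mu_hat = exposure * exp(gamma0 + Xu gamma + Xp_std beta), where new
#' penalized covariates are standardized with the training-set centering
#' and scaling constants stored in the model.
#'
#' @param object A \code{gmifs_model}.
#' @param Xu_new New unpenalized design (N' x J), or \code{NULL} when J = 0.
#' @param Xp_new New penalized design (N' x K) on the original scale.
#' @param exposure New exposures (default 1).
#' @param ... Unused.
#' @return Positive vector of expected counts.
#' @export
predict.gmifs_model <- function(object, Xp_new = NULL, Xu_new = NULL,
                                exposure = 1, ...) {
  J <- length(object$gamma)
  K <- length(object$beta)
  n <- if (K > 0) nrow(as.matrix(Xp_new)) else if (J > 0)
    nrow(as.matrix(Xu_new)) else length(exposure)
  eta <- rep(object$gamma0, n) + log(rep_len(exposure, n))
  if (J > 0) {
    Xu_new <- as.matrix(Xu_new)
    if (ncol(Xu_new) != J) stop("`Xu_new` must have ", J, " columns")
    eta <- eta + drop(Xu_new %*% object$gamma)
  }
  if (K > 0) {
    Xp_new <- as.matrix(Xp_new)
    if (ncol(Xp_new) != K) stop("`Xp_new` must have ", K, " columns")
    Xs <- sweep(sweep(Xp_new, 2, object$center, "-"), 2, object$scale, "/")
    eta <- eta + drop(Xs %*% object$beta)
  }
  exp(pmin(eta, 700))
}

# Fold-averaged held-out error along the path.  For each fold the GMIFS
# path is refit on the training observations and the held-out linear
# predictor is replayed incrementally across steps.
cv_error_curve <- function(data, family, folds = NULL, metric = "mae",
                           seed = 1L, epsilon = 0.001, tau = 1e-5,
                           max_steps = 50000L) {
  n <- length(data$y)
  assign_f <- cv_fold_assignment(n, folds, seed)
  nf <- max(assign_f)
  curves <- vector("list", nf)
  for (f in seq_len(nf)) {
    test <- which(assign_f == f)
    train <- setdiff(seq_len(n), test)
    if (stats::var(data$y[train]) == 0) {
      warning(sprintf("fold %d has zero response variance; fold retained", f))
    }
    dtr <- count_dataset(data$y[train], data$exposure[train],
                         data$Xu[train, , drop = FALSE],
                         data$Xp[train, , drop = FALSE])
    fit <- gmifs_fit(dtr, family, epsilon = epsilon, tau = tau,
                     max_steps = max_steps)
    S <- nrow(fit$steps) - 1L
    K <- fit$K
    Xs_te <- if (K > 0) {
      sweep(sweep(data$Xp[test, , drop = FALSE], 2, fit$center, "-"),
            2, fit$scale, "/")
    } else matrix(numeric(0), length(test), 0)
    eta_p <- numeric(length(test))
    errs <- numeric(S + 1L)
    for (s in 0:S) {
      if (s > 0) {
        m <- fit$steps$updated[s + 1L]
        if (m <= K) eta_p <- eta_p + epsilon * Xs_te[, m]
        else eta_p <- eta_p - epsilon * Xs_te[, m - K]
      }
      eta <- fit$steps$gamma0[s + 1L] + log(data$exposure[test]) + eta_p
      if (fit$J > 0) {
        eta <- eta + drop(data$Xu[test, , drop = FALSE] %*% fit$gamma[s + 1L, ])
      }
      mu <- exp(pmin(eta, 700))
      errs[s + 1L] <- if (metric == "mae") mean(abs(data$y[test] - mu))
        else mean((data$y[test] - mu)^2)
    }
    curves[[f]] <- errs
  }
  smin <- min(vapply(curves, length, integer(1)))
  rowMeans(vapply(curves, function(e) e[seq_len(smin)], numeric(smin)))
}

cv_fold_assignment <- function(n, folds, seed) {
  if (is.null(folds)) folds <- n
  if (folds > n) stop("`folds` cannot exceed N")
  if (folds == n) return(seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Cross-validated prediction error of criterion-selected GMIFS models
#'
#' For each fold, fits the GMIFS path on the training observations, selects
#' a model within the fold by the given criterion (AIC or BIC), and
#' measures the prediction error on the held-out observations; returns the
#' mean across folds.  With \code{folds = N} this is the leave-one-out
#' (N-fold) cross-validation estimate of mean prediction error.
#'
#' @param data A [count_dataset()].
#' @param family \code{"negbin"} or \code{"poisson"}.
#' @param folds Number of folds; default N (leave-one-out).
#' @param criterion Within-fold selection criterion, \code{"aic"} or
#'   \code{"bic"}.
#' @param metric \code{"mae"} (mean absolute error, default) or
#'   \code{"mse"}.
#' @param seed Fold-assignment seed when \code{folds < N}.
#' @param epsilon,tau,max_steps Passed to [gmifs_fit()] per fold.
#' @return Scalar mean held-out prediction error.
#' @export
cross_validate <- function(data, family = c("negbin", "poisson"),
                           folds = NULL, criterion = c("aic", "bic"),
                           metric = c("mae", "mse"), seed = 1L,
                           epsilon = 0.001, tau = 1e-5,
                           max_steps = 50000L) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  metric <- match.arg(metric)
  n <- length(data$y)
  assign_f <- cv_fold_assignment(n, folds, seed)
  errs <- numeric(max(assign_f))
  for (f in seq_along(errs)) {
    test <- which(assign_f == f)
    train <- setdiff(seq_len(n), test)
    if (stats::var(data$y[train]) == 0) {
      warning(sprintf("fold %d has zero response variance; fold retained", f))
    }
    dtr <- count_dataset(data$y[train], data$exposure[train],
                         data$Xu[train, , drop = FALSE],
                         data$Xp[train, , drop = FALSE])
    fit <- gmifs_fit(dtr, family, epsilon = epsilon, tau = tau,
                     max_steps = max_steps)
    mod <- select_model(fit, criterion)
    mu <- predict(mod, Xp_new = data$Xp[test, , drop = FALSE],
                  Xu_new = if (ncol(data$Xu) > 0)
                    data$Xu[test, , drop = FALSE] else NULL,
                  exposure = data$exposure[test])
    errs[f] <- if (metric == "mae") mean(abs(data$y[test] - mu))
      else mean((data$y[test] - mu)^2)
  }
  mean(errs)
}
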