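#' Assemble a count-regression dataset
#'
#' Bundles a non-negative integer response, an optional positive exposure
#' (entering the model as a \code{log} offset so the mean is a rate per unit
#' of exposure, e.g. micronuclei per binucleated cell scored), a small
#' unpenalized design matrix that is forced into the model, and a
#' high-dimensional penalized design matrix subject to selection.
#'
#' @param y Non-negative integer counts, length N.
#' @param exposure Positive exposures, length N or a scalar (recycled).
#'   Defaults to 1 for every observation (a plain count model).
#' @param Xu Unpenalized design matrix (N x J), or \code{NULL} for J = 0.
#'   Columns are forced into the model and never standardized.
#' @param Xp Penalized design matrix (N x K), or \code{NULL} for K = 0.
#' @param row_ids Optional observation labels, length N.
#'
#' @return An object of class \code{count_dataset} with elements \code{y},
#'   \code{exposure}, \code{Xu}, \code{Xp}, \code{row_ids}.
#' @export
#' @examples
#' d <- count_dataset(y = c(0, 2, 1, 4), exposure = c(500, 1000, 1000, 2000))
#' d
count_dataset <- function(y, exposure = NULL, Xu = NULL, Xp = NULL,
                          row_ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("`y` must contain at least one observation")
  if (anyNA(y)) stop("`y` contains missing values")
  if (any(y < 0) || any(y != floor(y))) {
    stop("`y` must be non-negative integers")
  }
  if (is.null(exposure)) exposure <- 1
  exposure <- as.numeric(exposure)
  if (length(exposure) == 1L) exposure <- rep(exposure, n)
  if (length(exposure) != n) stop("`exposure` length must match `y`")
  if (anyNA(exposure) || any(exposure <= 0)) {
    stop("`exposure` must be positive with no missing values")
  }
  Xu <- check_design(Xu, n, "Xu")
  Xp <- check_design(Xp, n, "Xp")
  if (is.null(row_ids)) row_ids <- as.character(seq_len(n))
  if (length(row_ids) != n) stop("`row_ids` length must match `y`")
  structure(
    list(y = y, exposure = exposure, Xu = Xu, Xp = Xp,
         row_ids = as.character(row_ids)),
    class = "count_dataset"
  )
}

check_design <- function(X, n, what) {
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  X <- as.matrix(X)
  if (!is.numeric(X)) stop(sprintf("`%s` must be numeric", what))
  if (nrow(X) != n) stop(sprintf("`%s` must have %d rows", what, n))
  if (anyNA(X)) stop(sprintf("`%s` contains missing values", what))
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0(sub("X", "", what), seq_len(ncol(X)))
  }
  X
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf(
    "count_dataset: N = %d, J = %d unpenalized, K = %d penalized\n",
    length(x$y), ncol(x$Xu), ncol(x$Xp)))
  cat(sprintf("  response: mean %.3f, var %.3f; exposure range [%g, %g]\n",
              mean(x$y), stats::var(x$y), min(x$exposure), max(x$exposure)))
  invisible(x)
}

#' Model parameters for a count regression
#'
#' @param gamma0 Intercept.
#' @param gamma Unpenalized coefficients, length J.
#' @param beta Penalized coefficients (length must match the design they are
#'   applied to).
#' @param alpha Non-negative NB heterogeneity parameter with
#'   Var(Y) = mu + alpha * mu^2 (alpha = 1/phi); ignored for
#'   \code{family = "poisson"}.
#' @param family \code{"poisson"} or \code{"negbin"}.
#' @return An object of class \code{model_params}.
#' @export
model_params <- function(gamma0 = 0, gamma = numeric(0), beta = numeric(0),
                         alpha = 0, family = c("negbin", "poisson")) {
  family <- match.arg(family)
  stopifnot(is.numeric(gamma0), length(gamma0) == 1L, is.finite(gamma0))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative finite number")
  }
  structure(
    list(gamma0 = gamma0, gamma = as.numeric(gamma),
         beta = as.numeric(beta), alpha = alpha, family = family),
    class = "model_params"
  )
}

#' Fitted mean vector of a count model
#'
#' Computes mu_i = c_i * exp(gamma0 + Xu gamma + Xp beta), i.e. the linear
#' predictor on the log scale plus the log-exposure offset, exponentiated.
#' \code{params$beta} is applied to \code{data$Xp} as given (no
#' standardization happens here).
#'
#' @param params A [model_params()] object.
#' @param data A [count_dataset()].
#' @return Positive mean vector of length N.
#' @export
mean_response <- function(params, data) {
  eta <- linear_predictor(params, data)
  exp(pmin(eta, 700))
}

linear_predictor <- function(params, data) {
  n <- length(data$y)
  eta <- rep(params$gamma0, n) + log(data$exposure)
  if (length(params$gamma)) {
    if (length(params$gamma) != ncol(data$Xu)) {
      stop("length of `gamma` must match the columns of `Xu`")
    }
    eta <- eta + drop(data$Xu %*% params$gamma)
  } else if (ncol(data$Xu) > 0) {
    stop("`params$gamma` is empty but `Xu` has columns")
  }
  if (length(params$beta)) {
    if (length(params$beta) != ncol(data$Xp)) {
      stop("length of `beta` must match the columns of `Xp`")
    }
    eta <- eta + drop(data$Xp %*% params$beta)
  }
  eta
}
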