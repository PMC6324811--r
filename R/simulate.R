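#' Independent standard-normal design
#'
#' N x P matrix of i.i.d. N(0, 1) draws (uses the global RNG; seed with
#' [set.seed()]).
#'
#' @param N,P Dimensions.
#' @return N x P numeric matrix with columns \code{V1..VP}.
#' @export
gen_independent_design <- function(N, P) {
  X <- matrix(stats::rnorm(N * P), N, P)
  colnames(X) <- paste0("V", seq_len(P))
  X
}

#' Block-diagonal random correlation matrix
#'
#' Builds a P x P correlation matrix from \code{n_blocks} blocks of
#' \code{block_size} features: within-block off-diagonals are drawn
#' N(0, corr_sd) (clipped to (-0.99, 0.99)), the matrix is symmetrized with
#' unit diagonal, and each block is repaired to the nearest
#' positive-definite correlation matrix by flooring its eigenvalues at
#' \code{eig_floor} and renormalizing to unit diagonal.  Between-block
#' entries are exactly zero.
#'
#' @param P Total dimension (must equal \code{block_size * n_blocks}).
#' @param block_size Features per block (default 40).
#' @param n_blocks Number of blocks (default 125).
#' @param corr_sd Standard deviation of the raw off-diagonal draws
#'   (default 0.28).
#' @param eig_floor Eigenvalue floor used in the positive-definite repair.
#' @return A sparse symmetric block-diagonal matrix (from
#'   \code{Matrix::bdiag}) with attributes \code{blocks} (list of dense
#'   per-block correlation matrices) and \code{raw_offdiag} (the pre-repair
#'   off-diagonal draws, for distributional checks).
#' @export
gen_block_correlation_matrix <- function(P = 5000, block_size = 40,
                                         n_blocks = 125, corr_sd = 0.28,
                                         eig_floor = 1e-4) {
  if (block_size * n_blocks != P) {
    stop("`block_size * n_blocks` must equal `P`")
  }
  blocks <- vector("list", n_blocks)
  raw <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    lower <- stats::rnorm(block_size * (block_size - 1) / 2, 0, corr_sd)
    raw[[b]] <- lower
    R <- diag(block_size)
    R[lower.tri(R)] <- pmin(pmax(lower, -0.99), 0.99)
    R <- R + t(R) - diag(block_size)
    R <- nearest_pd_correlation(R, eig_floor)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("positive-definite repair failed for block ", b)
    }
    blocks[[b]] <- R
  }
  out <- Matrix::bdiag(blocks)
  attr(out, "blocks") <- blocks
  attr(out, "raw_offdiag") <- unlist(raw)
  out
}

# eigenvalue flooring followed by renormalization to unit diagonal; the
# congruence D^{-1/2} S D^{-1/2} preserves positive definiteness
nearest_pd_correlation <- function(R, eig_floor = 1e-4) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Multivariate normal design with a given correlation
#'
#' Rows are N(0, R) draws.  When \code{R} carries a \code{blocks} attribute
#' (see [gen_block_correlation_matrix()]) the factorization and
#' multiplication are done per block, so the cost is linear in the number
#' of blocks rather than cubic in P.
#'
#' @param N Number of rows.
#' @param R Correlation matrix (dense, or block-diagonal with a
#'   \code{blocks} attribute).
#' @return N x P numeric matrix.
#' @export
gen_correlated_design <- function(N, R) {
  blocks <- attr(R, "blocks")
  if (is.null(blocks)) {
    L <- tryCatch(chol(as.matrix(R)),
                  error = function(e) stop("correlation matrix is not positive definite"))
    X <- matrix(stats::rnorm(N * ncol(R)), N) %*% L
  } else {
    X <- matrix(NA_real_, N, sum(vapply(blocks, ncol, integer(1))))
    at <- 0L
    for (B in blocks) {
      k <- ncol(B)
      L <- tryCatch(chol(B),
                    error = function(e) stop("a correlation block is not positive definite"))
      X[, at + seq_len(k)] <- matrix(stats::rnorm(N * k), N) %*% L
      at <- at + k
    }
  }
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Generate a negative binomial response from a sparse linear signal
#'
#' mu_i = exp(gamma0 + sum_k beta_k x_{i, true_k}) and
#' Y_i ~ NB(mu_i, alpha) via the gamma-Poisson mixture ([nb_sample()]).
#'
#' @param X Design matrix.
#' @param true_indices Column indices of the true predictors.
#' @param beta_values Their coefficients (e.g. \code{c(1, -1, 1, -1, 1) *
#'   log(delta)}).
#' @param gamma0 Intercept (default 0.5).
#' @param alpha Heterogeneity parameter (0 gives Poisson draws).
#' @return List with \code{y} (counts) and \code{mu} (true means).
#' @export
gen_response <- function(X, true_indices, beta_values, gamma0 = 0.5,
                         alpha = 0.3) {
  if (length(true_indices) != length(beta_values)) {
    stop("`true_indices` and `beta_values` must have equal length")
  }
  if (any(true_indices < 1) || any(true_indices > ncol(X))) {
    stop("`true_indices` out of range")
  }
  eta <- gamma0 + drop(X[, true_indices, drop = FALSE] %*% beta_values)
  mu <- exp(pmin(eta, 700))
  list(y = nb_sample(mu, alpha), mu = mu)
}

#' First path step whose L1 norm reaches a reference level
#'
#' Comparator harness utility: given the L1 norm of a reference
#' (GMIFS-selected) coefficient vector and a comparator path ordered by
#' relaxing regularization, returns the first step whose coefficient L1
#' norm reaches the reference; if never reached, the last step with a
#' warning.
#'
#' @param reference_l1 Non-negative reference L1 norm.
#' @param comparator_path List of coefficient vectors, or a matrix with one
#'   column (variable) per coefficient and one row per step, or a numeric
#'   vector of precomputed L1 norms.
#' @return 1-based step index.
#' @export
match_l1_step <- function(reference_l1, comparator_path) {
  l1 <- if (is.list(comparator_path)) {
    vapply(comparator_path, function(b) sum(abs(b)), numeric(1))
  } else if (is.matrix(comparator_path)) {
    rowSums(abs(comparator_path))
  } else {
    as.numeric(comparator_path)
  }
  if (length(l1) == 0) stop("empty comparator path")
  hit <- which(l1 >= reference_l1)
  if (length(hit) == 0) {
    warning("comparator path never attains the reference L1 norm; returning the last step")
    return(length(l1))
  }
  hit[1]
}

#' True- and false-positive counts of a selection
#'
#' @param selected Indices of predictors with nonzero coefficient
#'   estimates.
#' @param true_indices Indices of the truly associated predictors.
#' @return Named integer vector \code{c(tp, fp)}.
#' @export
evaluate_selection <- function(selected, true_indices) {
  c(tp = length(intersect(selected, true_indices)),
    fp = length(setdiff(selected, true_indices)))
}

#' Simulation configuration
#'
#' Bundles the generating conditions of the two simulation designs: the
#' small design (N = 100 independent standard-normal predictors, P = 500)
#' and the large design (N = 50, P = 5000 block-correlated features,
#' 40-feature blocks).  Five true predictors carry coefficients
#' \code{+/- log(delta)} in the alternating sign pattern (+,-,+,-,+), the
#' intercept is 0.5, and responses are NB(mu, alpha).
#'
#' @param N,P Observations and predictors.
#' @param n_true Number of true predictors (5).
#' @param delta Effect multiplier; coefficients are \code{+/- log(delta)}.
#' @param gamma0 Intercept (0.5).
#' @param alpha True heterogeneity parameter.
#' @param design \code{"independent"} or \code{"block_correlated"}.
#' @param block_size,n_blocks,corr_sd Block-correlation parameters (40,
#'   P / 40, 0.28).
#' @param replicates Number of replicates.
#' @param base_seed Base seed; replicate r uses \code{base_seed + r}.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(N = 100, P = 500, n_true = 5, delta = 1.75,
                              gamma0 = 0.5, alpha = 0.3,
                              design = c("independent", "block_correlated"),
                              block_size = 40, n_blocks = P / block_size,
                              corr_sd = 0.28, replicates = 200,
                              base_seed = 1L) {
  design <- match.arg(design)
  if (n_true > P) stop("`n_true` cannot exceed `P`")
  if (design == "block_correlated" && block_size * n_blocks != P) {
    stop("`block_size * n_blocks` must equal `P` for the block design")
  }
  if (base_seed + replicates >= 2^31) stop("`base_seed` too large")
  structure(
    list(N = N, P = P, n_true = n_true, delta = delta, gamma0 = gamma0,
         alpha = alpha, design = design, block_size = block_size,
         n_blocks = n_blocks, corr_sd = corr_sd, replicates = replicates,
         base_seed = as.integer(base_seed)),
    class = "simulation_config")
}

# alternating-sign truth (+,-,+,-,+) scaled by log(delta)
true_beta_pattern <- function(n_true, delta) {
  rep_len(c(1, -1), n_true) * log(delta)
}

#' Run a replicate simulation study
#'
#' For each replicate: draws a training and an independent test design of
#' the configured size and correlation structure, generates NB responses,
#' fits the GMIFS path (NB family by default), selects models by AIC and
#' BIC, and records true positives, false positives, and test-set
#' prediction error.  Optional comparator methods supply a coefficient path
#' (e.g. a penalized Poisson path from another solver); they are evaluated
#' at the first step matching the GMIFS model's coefficient L1 norm
#' ([match_l1_step()]), separately for the AIC- and BIC-selected reference
#' norms.
#'
#' Replicate r is seeded with \code{base_seed + r}, so any subset of
#' replicates is individually reproducible.  In the block-correlated design
#' the correlation matrix and the true-feature positions (one per chosen
#' block) are drawn once from \code{base_seed}; in the independent design
#' the true features are columns 1..n_true.  A failed replicate is recorded
#' with \code{failed = TRUE}, never dropped.
#'
#' @param config A [simulation_config()].
#' @param comparators Named list of comparator functions, each called as
#'   \code{f(data)} and returning a list with elements \code{beta} (steps x
#'   P coefficient matrix on the original predictor scale, ordered by
#'   relaxing regularization) and \code{gamma0} (per-step intercepts).
#'   See [comparator_glmnet_poisson()].
#' @param metric Prediction-error metric, \code{"mae"} or \code{"mse"}.
#' @param epsilon,tau,max_steps Passed to [gmifs_fit()].
#' @param family Model family fitted by the GMIFS method.
#' @param verbose Print a line per replicate.
#' @return Data frame with one row per replicate x method x criterion:
#'   \code{replicate}, \code{method}, \code{criterion}, \code{tp},
#'   \code{fp}, \code{pred_error}, \code{seed}, \code{failed}.
#' @export
run_simulation_study <- function(config, comparators = list(),
                                 metric = c("mae", "mse"),
                                 epsilon = 0.001, tau = 1e-5,
                                 max_steps = 50000L,
                                 family = "negbin", verbose = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(config, "simulation_config"))
  err_fun <- if (metric == "mae") function(y, mu) mean(abs(y - mu))
    else function(y, mu) mean((y - mu)^2)
  set.seed(config$base_seed)
  if (config$design == "block_correlated") {
    R <- gen_block_correlation_matrix(config$P, config$block_size,
                                      config$n_blocks, config$corr_sd)
    chosen_blocks <- sample(config$n_blocks, config$n_true)
    true_idx <- sort((chosen_blocks - 1L) * config$block_size +
                       sample(config$block_size, config$n_true,
                              replace = TRUE))
  } else {
    R <- NULL
    true_idx <- seq_len(config$n_true)
  }
  beta_true <- true_beta_pattern(config$n_true, config$delta)
  rows <- list()
  if (config$replicates == 0) {
    return(data.frame(replicate = integer(0), method = character(0),
                      criterion = character(0), tp = integer(0),
                      fp = integer(0), pred_error = numeric(0),
                      seed = integer(0), failed = logical(0)))
  }
  for (r in seq_len(config$replicates)) {
    seed_r <- config$base_seed + r
    res <- tryCatch(
      run_one_replicate(config, R, true_idx, beta_true, seed_r,
                        comparators, err_fun, epsilon, tau, max_steps,
                        family),
      error = function(e) {
        data.frame(method = "nbgmifs", criterion = c("aic", "bic"),
                   tp = NA_integer_, fp = NA_integer_,
                   pred_error = NA_real_, failed = TRUE,
                   message = conditionMessage(e))
      })
    res$replicate <- r
    res$seed <- seed_r
    if (is.null(res$failed)) res$failed <- FALSE
    rows[[r]] <- res
    if (verbose) {
      message(sprintf("replicate %d/%d done", r, config$replicates))
    }
  }
  out <- do.call(rbind, lapply(rows, function(d) {
    d[c("replicate", "method", "criterion", "tp", "fp", "pred_error",
        "seed", "failed")]
  }))
  rownames(out) <- NULL
  out
}

run_one_replicate <- function(config, R, true_idx, beta_true, seed_r,
                              comparators, err_fun, epsilon, tau,
                              max_steps, family) {
  set.seed(seed_r)
  gen_X <- function() {
    if (config$design == "block_correlated") gen_correlated_design(config$N, R)
    else gen_independent_design(config$N, config$P)
  }
  Xtr <- gen_X()
  rtr <- gen_response(Xtr, true_idx, beta_true, config$gamma0, config$alpha)
  Xte <- gen_X()
  rte <- gen_response(Xte, true_idx, beta_true, config$gamma0, config$alpha)
  dtr <- count_dataset(rtr$y, Xp = Xtr)
  fit <- gmifs_fit(dtr, family = family, epsilon = epsilon, tau = tau,
                   max_steps = max_steps)
  out <- list()
  ref_l1 <- c(aic = NA_real_, bic = NA_real_)
  for (crit in c("aic", "bic")) {
    mod <- select_model(fit, crit)
    sel <- which(mod$beta != 0)
    tf <- evaluate_selection(sel, true_idx)
    mu_te <- predict(mod, Xp_new = Xte)
    ref_l1[crit] <- sum(abs(mod$beta))
    out[[length(out) + 1L]] <- data.frame(
      method = "nbgmifs", criterion = crit, tp = unname(tf["tp"]),
      fp = unname(tf["fp"]), pred_error = err_fun(rte$y, mu_te),
      failed = FALSE, message = "")
  }
  for (nm in names(comparators)) {
    cmp <- tryCatch(comparators[[nm]](dtr), error = function(e) NULL)
    if (is.null(cmp)) {
      out[[length(out) + 1L]] <- data.frame(
        method = nm, criterion = c("aic", "bic"), tp = NA_integer_,
        fp = NA_integer_, pred_error = NA_real_, failed = TRUE,
        message = "comparator failed")
      next
    }
    for (crit in c("aic", "bic")) {
      # comparator coefficients are on the original scale; the GMIFS L1
      # reference norm is taken on the standardized scale, so rescale the
      # comparator path before matching
      sds <- apply(Xtr, 2, stats::sd)
      std_path <- sweep(cmp$beta, 2, sds, "*")
      step <- suppressWarnings(match_l1_step(ref_l1[crit], std_path))
      b <- cmp$beta[step, ]
      sel <- which(b != 0)
      tf <- evaluate_selection(sel, true_idx)
      mu_te <- exp(pmin(cmp$gamma0[step] + drop(Xte %*% b), 700))
      out[[length(out) + 1L]] <- data.frame(
        method = nm, criterion = crit, tp = unname(tf["tp"]),
        fp = unname(tf["fp"]), pred_error = err_fun(rte$y, mu_te),
        failed = FALSE, message = "")
    }
  }
  do.call(rbind, out)
}

#' glmnet Poisson comparator path
#'
#' Returns a comparator function for [run_simulation_study()] that fits an
#' L1-penalized Poisson regression path with \pkg{glmnet} (if installed)
#' over its default lambda sequence, ordered from strongest to weakest
#' penalty, and exposes the per-step coefficients and intercepts on the
#' original predictor scale.
#'
#' @param nlambda Number of lambda values (default 100).
#' @return A function \code{f(data)} suitable for the \code{comparators}
#'   argument of [run_simulation_study()].
#' @export
comparator_glmnet_poisson <- function(nlambda = 100) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("the glmnet package is required for this comparator")
  }
  function(data) {
    fit <- glmnet::glmnet(data$Xp, data$y, family = "poisson",
                          offset = log(data$exposure), nlambda = nlambda)
    list(beta = t(as.matrix(fit$beta)), gamma0 = as.numeric(fit$a0))
  }
}
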