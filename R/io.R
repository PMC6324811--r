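read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a count dataset from delimited text files
#'
#' Reads a response table (one row per sample: response counts plus
#' optional exposure and unpenalized covariate columns) and a penalized
#' feature matrix from CSV/TSV files with header rows.  The feature matrix
#' may be stored samples x features or features x samples (expression
#' matrices usually ship features x samples); the orientation must be
#' declared explicitly, never guessed.  Features containing any missing
#' value are dropped with a message reporting the count; missing values are
#' not permitted anywhere else.
#'
#' @param response_path Path to the response table (CSV or TSV).
#' @param matrix_path Path to the penalized feature matrix, or \code{NULL}
#'   for a model with no penalized predictors.
#' @param response_col Name of the count column (default \code{"y"}).
#' @param offset_col Name of the positive exposure column, or \code{NULL}.
#' @param unpenalized_cols Character vector of unpenalized covariate
#'   columns in the response table.
#' @param orientation \code{"samples_by_features"} (rows of the matrix file
#'   align with rows of the response table) or \code{"features_by_samples"}
#'   (first column holds feature names; remaining columns are samples in
#'   response-table order).
#' @param round_counts Permit non-integer response values by rounding, with
#'   a warning (counts are integer by definition; this is an escape hatch
#'   for files that went through floating-point tools).
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(response_path, matrix_path = NULL,
                               response_col = "y", offset_col = NULL,
                               unpenalized_cols = character(0),
                               orientation = c("samples_by_features",
                                               "features_by_samples"),
                               round_counts = FALSE) {
  orientation <- match.arg(orientation)
  resp <- read_table_auto(response_path)
  if (!response_col %in% names(resp)) {
    stop(sprintf("response column \"%s\" not found in %s",
                 response_col, response_path))
  }
  y <- resp[[response_col]]
  if (anyNA(y)) stop("missing values in the response column")
  if (any(y != floor(y))) {
    if (round_counts) {
      warning("non-integer response values rounded to the nearest integer")
      y <- round(y)
    } else {
      stop("response contains non-integer values (use round_counts = TRUE to override)")
    }
  }
  exposure <- NULL
  if (!is.null(offset_col)) {
    if (!offset_col %in% names(resp)) {
      stop(sprintf("offset column \"%s\" not found", offset_col))
    }
    exposure <- resp[[offset_col]]
    if (anyNA(exposure) || any(exposure <= 0)) {
      stop("exposure column must be positive with no missing values")
    }
  }
  Xu <- NULL
  if (length(unpenalized_cols)) {
    missing_cols <- setdiff(unpenalized_cols, names(resp))
    if (length(missing_cols)) {
      stop("unpenalized column(s) not found: ",
           paste(missing_cols, collapse = ", "))
    }
    Xu <- as.matrix(resp[unpenalized_cols])
  }
  Xp <- NULL
  if (!is.null(matrix_path)) {
    feat <- read_table_auto(matrix_path)
    if (orientation == "features_by_samples") {
      fn <- as.character(feat[[1]])
      M <- t(as.matrix(feat[, -1, drop = FALSE]))
      colnames(M) <- fn
    } else {
      M <- as.matrix(feat)
    }
    if (nrow(M) != length(y)) {
      stop(sprintf("feature matrix has %d samples but the response has %d",
                   nrow(M), length(y)))
    }
    dup <- colnames(M)[duplicated(colnames(M))]
    if (length(dup)) {
      stop("duplicate feature names: ", paste(unique(dup), collapse = ", "))
    }
    has_na <- colSums(is.na(M)) > 0
    if (any(has_na)) {
      message(sprintf("dropped %d feature(s) containing missing values",
                      sum(has_na)))
      M <- M[, !has_na, drop = FALSE]
    }
    Xp <- M
  }
  count_dataset(y, exposure = exposure, Xu = Xu, Xp = Xp,
                row_ids = rownames(resp))
}

#' Write a fitted GMIFS path as a tidy CSV table
#'
#' One row per step with the step index, updated feature label (signed by
#' which half of the expanded space was incremented), log-likelihood,
#' dispersion, intercept, nonzero count, df, AIC and BIC.
#'
#' @param fit A [gmifs_fit()].
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_path_table <- function(fit, path) {
  st <- fit$steps
  lab <- rep(NA_character_, nrow(st))
  upd <- st$updated
  K <- fit$K
  fn <- fit$feature_names
  if (is.null(fn)) fn <- paste0("V", seq_len(K))
  pos <- !is.na(upd) & upd <= K
  neg <- !is.na(upd) & upd > K
  lab[pos] <- paste0("+", fn[upd[pos]])
  lab[neg] <- paste0("-", fn[upd[neg] - K])
  out <- cbind(st[, "step", drop = FALSE], updated_feature = lab,
               st[, c("loglik", "alpha", "gamma0", "nonzero", "df",
                      "aic", "bic")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a path table written by [write_path_table()]
#'
#' @param path CSV path.
#' @return Data frame of per-step records.
#' @export
read_path_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Generate a small packaged-style test fixture
#'
#' Writes a small synthetic dataset (response table, feature matrix, and a
#' sidecar JSON recording the generating truth) of one of four kinds:
#' \describe{
#'   \item{poisson_small}{N = 50, K = 20, Poisson response, unit exposure.}
#'   \item{negbin_small}{N = 50, K = 20, NB response with alpha = 0.5.}
#'   \item{negbin_offset}{N = 60, K = 30, NB response with varying
#'     exposures in \{500, 1000, 2000\} cells scored, emulating rate-type
#'     micronucleus data, plus a binary unpenalized covariate.}
#'   \item{missingness}{5 samples x 3 features with one feature containing
#'     a missing value, for ingestion-filter tests.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
generate_fixture <- function(kind = c("poisson_small", "negbin_small",
                                      "negbin_offset", "missingness"),
                             seed = 1L, out_dir) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  truth <- list(kind = kind, seed = seed)
  if (kind == "missingness") {
    feat <- data.frame(f1 = stats::rnorm(5), f2 = stats::rnorm(5),
                       f3 = stats::rnorm(5))
    feat$f2[3] <- NA
    resp <- data.frame(y = stats::rpois(5, 2))
  } else {
    n <- if (kind == "negbin_offset") 60L else 50L
    k <- if (kind == "negbin_offset") 30L else 20L
    X <- gen_independent_design(n, k)
    colnames(X) <- paste0("gene", seq_len(k))
    beta <- numeric(k)
    # the Poisson fixture is pure noise so that its intercept-only mean
    # model is correctly specified (signal left unmodelled would read as
    # over-dispersion); the NB fixtures carry a sparse signal
    if (kind != "poisson_small") beta[1:3] <- c(0.4, -0.4, 0.3)
    gamma0 <- if (kind == "negbin_offset") -6 else 0.5
    alpha <- switch(kind, poisson_small = 0, negbin_small = 0.5,
                    negbin_offset = 0.5)
    resp <- data.frame(y = integer(n))
    exposure <- rep(1, n)
    gamma <- numeric(0)
    eta <- gamma0 + drop(X %*% beta)
    if (kind == "negbin_offset") {
      exposure <- sample(c(500, 1000, 2000), n, replace = TRUE)
      gender <- stats::rbinom(n, 1, 0.5)
      gamma <- 0.2
      eta <- eta + gamma * gender + log(exposure)
      resp$cells_scored <- exposure
      resp$gender <- gender
    }
    mu <- exp(eta)
    resp$y <- nb_sample(mu, alpha)
    feat <- as.data.frame(X)
    truth <- c(truth, list(gamma0 = gamma0, gamma = gamma,
                           beta = beta, alpha = alpha,
                           true_features = colnames(X)[beta != 0]))
  }
  response_path <- file.path(out_dir, paste0(kind, "_response.csv"))
  matrix_path <- file.path(out_dir, paste0(kind, "_features.csv"))
  truth_path <- file.path(out_dir, paste0(kind, "_truth.json"))
  utils::write.csv(resp, response_path, row.names = FALSE)
  utils::write.csv(feat, matrix_path, row.names = FALSE)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(response = response_path, features = matrix_path,
              truth = truth_path))
}
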