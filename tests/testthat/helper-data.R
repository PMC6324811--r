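# Small simulated datasets reused across test files.  All generation is
# seeded in code; nothing is read from disk.

make_nb_data <- function(n = 50, k = 8, j = 0, alpha = 0.4, gamma0 = 0.5,
                         seed = 1, exposure = NULL,
                         beta = NULL, gamma = NULL) {
  set.seed(seed)
  Xp <- if (k > 0) gen_independent_design(n, k) else NULL
  Xu <- if (j > 0) {
    m <- matrix(stats::rnorm(n * j), n, j)
    colnames(m) <- paste0("u", seq_len(j))
    m
  } else NULL
  if (is.null(beta)) {
    beta <- numeric(k)
    if (k > 0) beta[seq_len(min(3, k))] <- c(0.4, -0.3, 0.2)[seq_len(min(3, k))]
  }
  if (is.null(gamma) && j > 0) gamma <- rep(0.25, j)
  eta <- rep(gamma0, n)
  if (k > 0) eta <- eta + drop(Xp %*% beta)
  if (j > 0) eta <- eta + drop(Xu %*% gamma)
  if (!is.null(exposure)) eta <- eta + log(exposure)
  mu <- exp(eta)
  y <- nb_sample(mu, alpha)
  list(data = count_dataset(y, exposure = exposure, Xu = Xu, Xp = Xp),
       mu = mu, beta = beta, gamma = gamma, gamma0 = gamma0, alpha = alpha)
}

# numerical gradient of f at x by central differences
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
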