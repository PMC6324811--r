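test_that("NB log pmf matches hand-computed values and the reference density", {
  # at y = 0, mu = 1, alpha = 1 the pmf collapses to (1 + alpha*mu)^(-1/alpha)
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # Gamma(2)/(Gamma(2) Gamma(1)) * (1/2)^1 * (1/2)^1
  expect_equal(nb_log_pmf(1, 1, 1), log(0.25), tolerance = 1e-12)
  # independent oracle: R's NB density in the size/mu parameterization
  grid <- expand.grid(y = c(0, 1, 2, 7, 40, 200), mu = c(0.3, 1, 5, 60))
  for (alpha in c(0.05, 0.4, 1, 3)) {
    got <- nb_log_pmf(grid$y, grid$mu, alpha)
    ref <- stats::dnbinom(grid$y, size = 1 / alpha, mu = grid$mu, log = TRUE)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # domain errors
  expect_error(nb_log_pmf(1, -1, 1), "mu")
  expect_error(nb_log_pmf(1, 1, 0), "alpha")
  expect_error(nb_log_pmf(1.5, 1, 1), "integers")
})

test_that("NB pmf normalizes to one over the support", {
  for (mu in c(1, 3, 10)) {
    for (alpha in c(0.2, 0.4, 1)) {
      total <- sum(exp(nb_log_pmf(0:3000, mu, alpha)))
      expect_equal(total, 1, tolerance = 1e-8)
    }
  }
})

test_that("NB log-likelihood is consistent with the pmf and offset identity", {
  set.seed(7)
  y <- rpois(12, 3)
  d <- count_dataset(y)
  p <- model_params(gamma0 = 0.8, alpha = 0.6, family = "negbin")
  expect_equal(nb_loglik(p, d), sum(nb_log_pmf(y, exp(0.8), 0.6)))
  # single observation y = 2, mu = 1, alpha = 1 -> log(1/8)
  d1 <- count_dataset(2)
  p1 <- model_params(gamma0 = 0, alpha = 1, family = "negbin")
  expect_equal(nb_loglik(p1, d1), log(0.125), tolerance = 1e-12)
  # doubling every exposure and shifting the intercept by -log 2 is a no-op
  d2 <- count_dataset(y, exposure = 2)
  p2 <- model_params(gamma0 = 0.8 - log(2), alpha = 0.6, family = "negbin")
  expect_equal(nb_loglik(p2, d2), nb_loglik(p, d), tolerance = 1e-10)
})

test_that("Poisson log-likelihood matches direct evaluation and dpois", {
  d1 <- count_dataset(1)
  p1 <- model_params(gamma0 = 0, family = "poisson")
  expect_equal(poisson_loglik(p1, d1), -1, tolerance = 1e-12)
  set.seed(8)
  y <- rpois(15, 4)
  c_ <- runif(15, 0.5, 3)
  d <- count_dataset(y, exposure = c_)
  p <- model_params(gamma0 = 0.3, family = "poisson")
  expect_equal(poisson_loglik(p, d),
               sum(dpois(y, c_ * exp(0.3), log = TRUE)), tolerance = 1e-10)
  # offset identity
  d2 <- count_dataset(y, exposure = 3 * c_)
  p2 <- model_params(gamma0 = 0.3 - log(3), family = "poisson")
  expect_equal(poisson_loglik(p2, d2), poisson_loglik(p, d),
               tolerance = 1e-10)
})

test_that("NB log-likelihood reaches the Poisson limit as alpha -> 0", {
  set.seed(9)
  for (seed in 1:3) {
    sim <- make_nb_data(n = 25, k = 4, j = 1, alpha = 0.3, seed = seed)
    d <- sim$data
    pn <- model_params(gamma0 = 0.4, gamma = 0.2, beta = rep(0.1, 4),
                       alpha = 1e-10, family = "negbin")
    pp <- model_params(gamma0 = 0.4, gamma = 0.2, beta = rep(0.1, 4),
                       family = "poisson")
    expect_lt(abs(nb_loglik(pn, d) - poisson_loglik(pp, d)), 1e-4)
  }
})

test_that("analytic expanded scores match central finite differences", {
  for (seed in 1:5) {
    sim <- make_nb_data(n = 30, k = 5, j = 1, alpha = 0.5, seed = seed)
    d <- sim$data
    ed <- expand_covariates(d$Xp)
    be <- abs(rnorm(10)) / 10
    p <- model_params(gamma0 = 0.3, gamma = 0.1, beta = be, alpha = 0.5,
                      family = "negbin")
    got <- unname(nb_score_expanded(p, d, ed))
    # the two halves negate each other
    expect_equal(got[1:5], -got[6:10], tolerance = 1e-12)
    # likelihood over the expanded design, evaluated via the generic
    # NB likelihood with the expanded matrix as the penalized design
    dx <- count_dataset(d$y, d$exposure, d$Xu, ed$penalized)
    f <- function(b) nb_loglik(model_params(0.3, 0.1, b, 0.5, "negbin"), dx)
    expect_equal(got, num_grad(f, be), tolerance = 1e-6)

    pp <- model_params(gamma0 = 0.3, gamma = 0.1, beta = be,
                       family = "poisson")
    gotp <- unname(poisson_score_expanded(pp, d, ed))
    fp <- function(b) poisson_loglik(model_params(0.3, 0.1, b,
                                                  family = "poisson"), dx)
    expect_equal(gotp, num_grad(fp, be), tolerance = 1e-6)
    # Poisson score equals the NB score at vanishing dispersion
    p0 <- model_params(0.3, 0.1, be, 1e-12, "negbin")
    expect_equal(gotp, unname(nb_score_expanded(p0, d, ed)),
                 tolerance = 1e-6)
  }
})

test_that("score at a single raw observation reduces to (y-mu)/(1+alpha*mu)", {
  d <- count_dataset(2)
  p <- model_params(gamma0 = 0, beta = 0, alpha = 1, family = "negbin")
  expect_equal(nb_score_expanded(p, d, matrix(1)), 0.5)
  # residual term vanishes when y = mu
  d2 <- count_dataset(c(1, 3, 2))
  p2 <- model_params(gamma0 = 0, beta = c(0, 0), alpha = 0.5,
                     family = "negbin")
  X <- cbind(log(c(1, 3, 2)), -log(c(1, 3, 2)))
  # choose gamma0 = 0 and put log(y) in the offset so mu = y exactly
  d3 <- count_dataset(c(1, 3, 2), exposure = c(1, 3, 2))
  expect_equal(nb_score_expanded(p2, d3, X), c(0, 0))
})

test_that("dispersion moment estimator is consistent and floors correctly", {
  # equi-dispersion: numerator non-positive, clipped at the floor
  mu <- c(1, 2, 3, 4)
  expect_equal(estimate_alpha_mom(mu, mu), 1e-8)
  expect_error(estimate_alpha_mom(1, 1), "two observations")
  # Monte-Carlo consistency against R's own NB sampler
  set.seed(42)
  y <- rnbinom(1e5, size = 1 / 0.5, mu = 5)
  expect_lt(abs(estimate_alpha_mom(y, rep(5, 1e5)) - 0.5), 0.03)
  y0 <- rpois(1e5, 5)
  expect_lt(estimate_alpha_mom(y0, rep(5, 1e5)), 0.02)
  # the Pearson-df variant agrees at scale
  expect_lt(abs(estimate_alpha_mom(y, rep(5, 1e5),
                                   method = "pearson_df") - 0.5), 0.03)
})

test_that("gamma-Poisson sampler has NB moments and is deterministic", {
  set.seed(11)
  y <- nb_sample(rep(4, 2e5), alpha = 0)
  expect_lt(abs(mean(y) - 4), 0.05)
  expect_lt(abs(var(y) - 4), 0.05 * 4)
  y2 <- nb_sample(rep(4, 2e5), alpha = 0.5)
  expect_lt(abs(mean(y2) - 4), 0.05)
  expect_lt(abs(var(y2) - 12), 0.3)
  set.seed(99)
  a <- nb_sample(rep(2, 50), 0.3)
  set.seed(99)
  b <- nb_sample(rep(2, 50), 0.3)
  expect_identical(a, b)
  expect_error(nb_sample(rep(2, 5), -0.1), "non-negative")
})

test_that("unpenalized ML fit solves the score equations and matches GLM fits", {
  set.seed(21)
  y <- rnbinom(80, size = 2, mu = 3)
  d <- count_dataset(y)
  f <- fit_unpenalized_mle(d, family = "negbin", alpha_fixed = 0.5)
  expect_equal(f$gamma0, log(mean(y)), tolerance = 1e-8)
  # constant exposure shifts the intercept by -log k
  d2 <- count_dataset(y, exposure = 4)
  f2 <- fit_unpenalized_mle(d2, family = "negbin", alpha_fixed = 0.5)
  expect_equal(f2$gamma0, log(mean(y) / 4), tolerance = 1e-8)

  # independent-solver oracle with covariates and offset
  sim <- make_nb_data(n = 200, k = 0, j = 2, alpha = 0.4, seed = 3,
                      exposure = runif(200, 0.5, 2))
  d3 <- sim$data
  fp <- fit_unpenalized_mle(d3, family = "poisson")
  g <- stats::glm(d3$y ~ d3$Xu + offset(log(d3$exposure)),
                  family = stats::poisson())
  expect_equal(unname(c(fp$gamma0, fp$gamma)), unname(coef(g)),
               tolerance = 1e-4)
  skip_if_not_installed("MASS")
  fn <- fit_negbin_ml(d3)
  gnb <- MASS::glm.nb(d3$y ~ d3$Xu + offset(log(d3$exposure)))
  expect_equal(unname(c(fn$gamma0, fn$gamma)), unname(coef(gnb)),
               tolerance = 1e-4)
  expect_equal(fn$alpha, 1 / gnb$theta, tolerance = 1e-3)
  expect_equal(fn$loglik, as.numeric(stats::logLik(gnb)), tolerance = 1e-6)
})

test_that("count_dataset validates its invariants", {
  expect_error(count_dataset(c(-1, 2)), "non-negative")
  expect_error(count_dataset(c(1.5, 2)), "non-negative")
  expect_error(count_dataset(c(1, 2), exposure = c(1, 0)), "positive")
  expect_error(count_dataset(c(1, 2), Xp = matrix(1, 3, 1)), "rows")
  expect_error(count_dataset(c(1, 2), Xp = matrix(c(1, NA), 2, 1)),
               "missing")
})
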