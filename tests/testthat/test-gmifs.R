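test_that("covariate expansion standardizes and negates exactly", {
  set.seed(5)
  Xp <- matrix(rnorm(40 * 6, mean = 3, sd = 2), 40, 6)
  ed <- expand_covariates(Xp)
  K <- ed$K
  expect_identical(K, 6L)
  expect_identical(ed$penalized[, 1:K] + ed$penalized[, K + 1:K],
                   matrix(0, 40, K, dimnames = dimnames(ed$penalized[, 1:K])))
  expect_equal(colMeans(ed$penalized[, 1:K]), rep(0, K), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(ed$penalized[, 1:K], 2, sd), rep(1, K),
               tolerance = 1e-10, ignore_attr = TRUE)
  Xp[, 3] <- 7
  expect_error(expand_covariates(Xp), "constant")
})

test_that("a dataset without penalized predictors degenerates to the MLE", {
  sim <- make_nb_data(n = 40, k = 0, j = 1, alpha = 0.4, seed = 2)
  fit <- gmifs_fit(sim$data, "negbin")
  expect_identical(nrow(fit$steps), 1L)
  expect_identical(fit$stop_reason, "no_penalized_predictors")
  ref <- fit_unpenalized_mle(sim$data, family = "negbin",
                             alpha_fixed = fit$steps$alpha[1])
  expect_equal(fit$steps$gamma0[1], ref$gamma0, tolerance = 1e-8)
})

test_that("fitted paths obey the monotone one-increment-per-step invariants", {
  sim <- make_nb_data(n = 50, k = 12, j = 1, alpha = 0.4, seed = 4)
  fit <- gmifs_fit(sim$data, "negbin")
  S <- nrow(fit$steps) - 1L
  expect_gt(S, 10)
  # exactly one expanded coefficient is updated per step
  expect_true(all(!is.na(fit$steps$updated[-1])))
  expect_true(all(fit$steps$updated[-1] >= 1 &
                    fit$steps$updated[-1] <= 2 * fit$K))
  # replay: expanded coefficients are non-negative and non-decreasing, and
  # their L1 norm equals s * epsilon to 1e-12
  prev <- rep(0, 2 * fit$K)
  probe <- unique(c(0:min(5, S), floor(seq(1, S, length.out = 12))))
  for (s in sort(probe)) {
    be <- nbgmifs:::expanded_beta_at(fit, s)
    expect_true(all(be >= 0))
    expect_true(all(be >= prev - 1e-15))
    expect_lt(abs(sum(be) - s * fit$epsilon), 1e-12)
    prev <- be
  }
  # consecutive steps differ in exactly one expanded entry
  for (s in c(1L, floor(S / 2), S)) {
    diffs <- nbgmifs:::expanded_beta_at(fit, s) -
      nbgmifs:::expanded_beta_at(fit, s - 1L)
    expect_identical(sum(diffs != 0), 1L)
    expect_equal(sum(diffs), fit$epsilon, tolerance = 1e-12)
  }
  # likelihood at the end of the path beats the intercept-only model
  expect_gte(fit$steps$loglik[S + 1L], fit$steps$loglik[1L])
})

test_that("path records reproduce their own fitted likelihoods", {
  sim <- make_nb_data(n = 40, k = 8, j = 1, alpha = 0.5, seed = 6)
  fit <- gmifs_fit(sim$data, "negbin", max_steps = 600)
  d <- sim$data
  ed_pen <- nbgmifs:::expand_covariates(d$Xp)
  S <- nrow(fit$steps) - 1L
  for (s in c(0L, floor(S / 3), S)) {
    cf <- coef(fit, step = s)
    eta <- cf$gamma0 + log(d$exposure) + drop(d$Xu %*% cf$gamma) +
      drop(ed_pen$penalized[, 1:fit$K] %*% cf$beta)
    ll <- sum(nb_log_pmf(d$y, exp(eta), cf$alpha))
    expect_equal(ll, fit$steps$loglik[s + 1L], tolerance = 1e-8)
  }
  # original-scale coefficients give the same linear predictor
  cf0 <- coef(fit, step = S, scale = "original")
  eta_orig <- cf0$gamma0 + log(d$exposure) + drop(d$Xu %*% cf0$gamma) +
    drop(d$Xp %*% cf0$beta)
  cf1 <- coef(fit, step = S)
  eta_std <- cf1$gamma0 + log(d$exposure) + drop(d$Xu %*% cf1$gamma) +
    drop(ed_pen$penalized[, 1:fit$K] %*% cf1$beta)
  expect_equal(eta_orig, eta_std, tolerance = 1e-10)
})

test_that("run to convergence agrees with the unpenalized ML fit", {
  skip_if_not_installed("MASS")
  sim <- make_nb_data(n = 150, k = 2, j = 0, alpha = 0.4, seed = 10,
                      beta = c(0.5, -0.4))
  fit <- gmifs_fit(sim$data, "negbin", tau = 1e-12, max_steps = 20000)
  cf <- coef(fit, scale = "original")
  ref <- MASS::glm.nb(sim$data$y ~ sim$data$Xp)
  expect_equal(unname(cf$beta), unname(coef(ref)[-1]), tolerance = 0.05)
  expect_equal(cf$gamma0, unname(coef(ref)[1]), tolerance = 0.05)
})

test_that("information criteria follow their defining arithmetic", {
  ic <- information_criteria(-100, 3, 29)
  expect_equal(ic$aic, 206)
  expect_equal(ic$bic, 200 + 3 * log(29))
  # along a path, df never decreases and the stored AIC/BIC match a direct
  # recomputation from loglik and df
  sim <- make_nb_data(n = 40, k = 6, seed = 12)
  fit <- gmifs_fit(sim$data, "negbin", max_steps = 400)
  st <- fit$steps
  expect_equal(st$aic, -2 * st$loglik + 2 * st$df)
  expect_equal(st$bic, -2 * st$loglik + log(40) * st$df)
})

test_that("model selection returns the brute-force argmin with early tie-break", {
  sim <- make_nb_data(n = 40, k = 6, seed = 13)
  fit <- gmifs_fit(sim$data, "negbin", max_steps = 500)
  for (crit in c("aic", "bic")) {
    mod <- select_model(fit, crit)
    vals <- fit$steps[[crit]]
    brute <- min(which(vals == min(vals))) - 1L
    expect_identical(mod$step, brute)
    expect_equal(mod$value, min(vals))
  }
  # strictly increasing criterion -> step 0; exact ties -> earlier step
  fake <- fit
  fake$steps$aic <- seq_len(nrow(fit$steps))
  expect_identical(select_model(fake, "aic")$step, 0L)
  fake$steps$aic[c(3, 7)] <- -1
  expect_identical(select_model(fake, "aic")$step, 2L)
})

test_that("prediction behaves as a rate model", {
  sim <- make_nb_data(n = 40, k = 5, j = 1, seed = 14)
  fit <- gmifs_fit(sim$data, "negbin", max_steps = 300)
  mod <- select_model(fit, "bic")
  # all-zero model predicts exactly the exposure
  zero <- mod
  zero$gamma0 <- 0
  zero$gamma <- 0 * zero$gamma
  zero$beta <- 0 * zero$beta
  expect_equal(predict(zero, Xp_new = matrix(rnorm(20), 4, 5),
                       Xu_new = matrix(0, 4, 1), exposure = 1),
               rep(1, 4), tolerance = 1e-12)
  # doubling the exposure doubles the expected count
  p1 <- predict(mod, Xp_new = sim$data$Xp, Xu_new = sim$data$Xu,
                exposure = 1)
  p2 <- predict(mod, Xp_new = sim$data$Xp, Xu_new = sim$data$Xu,
                exposure = 2)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  expect_error(predict(mod, Xp_new = sim$data$Xp[, 1:3],
                       Xu_new = sim$data$Xu), "columns")
})

test_that("cross-validation is deterministic and leave-one-out by default", {
  expect_identical(nbgmifs:::cv_fold_assignment(8, NULL, 1), 1:8)
  expect_error(nbgmifs:::cv_fold_assignment(8, 9, 1), "exceed")
  sim <- make_nb_data(n = 18, k = 4, seed = 15)
  e1 <- cross_validate(sim$data, "negbin", folds = 3, seed = 7,
                       epsilon = 0.01, max_steps = 150)
  e2 <- cross_validate(sim$data, "negbin", folds = 3, seed = 7,
                       epsilon = 0.01, max_steps = 150)
  expect_identical(e1, e2)
  expect_true(is.finite(e1) && e1 >= 0)
})

test_that("cross-validated error exceeds resubstitution error on average", {
  n_data <- 20
  gap <- numeric(n_data)
  for (i in seq_len(n_data)) {
    sim <- make_nb_data(n = 30, k = 10, alpha = 0.4, seed = 100 + i,
                        beta = c(0.5, -0.5, 0.4, rep(0, 7)))
    d <- sim$data
    cv <- suppressWarnings(
      cross_validate(d, "negbin", folds = 5, criterion = "aic", seed = i,
                     epsilon = 0.01, max_steps = 250))
    fit <- gmifs_fit(d, "negbin", epsilon = 0.01, max_steps = 250)
    mod <- select_model(fit, "aic")
    resub <- mean(abs(d$y - predict(mod, Xp_new = d$Xp,
                                    exposure = d$exposure)))
    gap[i] <- cv - resub
  }
  expect_gt(mean(gap), 0)
})

test_that("cv model selection minimizes the fold-averaged error curve", {
  sim <- make_nb_data(n = 20, k = 4, seed = 16)
  mod <- select_model(gmifs_fit(sim$data, "negbin", epsilon = 0.01,
                                max_steps = 120),
                      "cv", folds = 4, seed = 3)
  curve <- nbgmifs:::cv_error_curve(sim$data, "negbin", folds = 4, seed = 3,
                                    epsilon = 0.01, max_steps = 120)
  expect_identical(mod$step, which.min(curve) - 1L)
  expect_equal(mod$value, min(curve))
})
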