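test_that("least-squares start recovers an exact linear relationship", {
  d <- data.frame(study = paste0("s", 1:8), eta = 2 * (1:8) / 4 - 1,
                  s_eta2 = 0.1, xi = (1:8) / 4 - 0.5, s_xi2 = 0.1)
  class(d) <- c("crr_data", "data.frame")
  st <- ols_start(d, "none")
  expect_equal(st[["beta1"]], 2, tolerance = 1e-10)
  expect_true(st[["tau2"]] > 0 && st[["sigma_xi2"]] > 0)
})

test_that("starts satisfy the parameter invariants on all scenarios", {
  for (sc in 1:3) {
    set.seed(sc)
    d <- generate_scenario(sim_config(sc, n_studies = 15, tau2 = 0.5,
                                      seed = sc))
    kind <- if (sc == 1) "error_free" else "latent"
    st <- ols_start(d, kind)
    expect_true(all(st[grep("tau2|sigma", names(st))] > 0))
    expect_true(all(is.finite(st)))
  }
})

test_that("Wald intervals use the exact normal quantile", {
  ci <- wald_ci(0, 1, 0.95)
  expect_equal(unname(ci[1, "lower"]), -qnorm(0.975), tolerance = 1e-12)
  expect_equal(as.numeric(ci), c(-1.959964, 1.959964), tolerance = 1e-6)
  ci2 <- wald_ci(c(1, 2), c(0.5, 0), 0.9)
  expect_true(all(ci2[, "lower"] <= c(1, 2) & ci2[, "upper"] >= c(1, 2)))
  expect_error(wald_ci(0, -1), "se")
})

test_that("Hessian standard errors match the closed form on a Gaussian toy likelihood", {
  # iid normal mean/variance model: known information matrix
  set.seed(4)
  n <- 200
  x <- rnorm(n, 2, 1.5)
  d <- data.frame(study = paste0("s", seq_len(n)), eta = x, s_eta2 = 0,
                  xi = rep(c(-1, 1), n / 2), s_xi2 = 0)
  class(d) <- c("crr_data", "data.frame")
  fit <- crr_fit(d, method = "naive", naive_ml = TRUE)
  mu_hat <- fit$params[["beta0"]]
  s2_hat <- fit$params[["tau2"]]
  # SE(mu) = sqrt(s2/n); SE(s2) = s2 * sqrt(2/n)
  expect_equal(fit$se_hessian[["beta0"]], sqrt(s2_hat / n),
               tolerance = 1e-3)
  expect_equal(fit$se_hessian[["tau2"]], s2_hat * sqrt(2 / n),
               tolerance = 1e-3)
})

test_that("standard errors scale as 1/sqrt(n) on replicated data", {
  d <- application_data()
  f1 <- crr_fit(d, method = "likelihood")
  d4 <- d[rep(seq_len(nrow(d)), 4), ]
  class(d4) <- c("crr_data", "data.frame")
  f4 <- crr_fit(d4, method = "likelihood", start = f1$params)
  expect_equal(f4$se_hessian[["beta1"]], f1$se_hessian[["beta1"]] / 2,
               tolerance = 0.02)
})

test_that("fits are deterministic and the two parametrizations agree", {
  d <- synthetic_trivariate()
  f1 <- crr_fit(d, method = "pseudo")
  f2 <- crr_fit(d, method = "pseudo")
  expect_identical(f1$params, f2$params)
  fn <- crr_fit(d, method = "pseudo", parametrization = "natural")
  expect_equal(fn$loglik, f1$loglik, tolerance = 1e-4)
})

test_that("optimizer failure yields converged = FALSE rather than an error", {
  # two studies cannot identify the trivariate model
  d <- synthetic_trivariate(n = 4, seed = 30)
  fit <- crr_fit(d, method = "pseudo")
  expect_s3_class(fit, "crr_fit")
  expect_true(is.logical(fit$converged))
})

test_that("sandwich and Hessian standard errors converge on correctly specified data", {
  set.seed(33)
  d <- generate_scenario(sim_config(1, n_studies = 400, tau2 = 0.5,
                                    seed = 33))
  fit <- crr_fit(d, method = "likelihood", sandwich = TRUE)
  expect_true(fit$converged)
  ratio <- fit$se_sandwich[c("beta0", "beta1", "beta2")] /
    fit$se_hessian[c("beta0", "beta1", "beta2")]
  expect_true(all(abs(ratio - 1) < 0.25))
})

test_that("sandwich matches the classic heteroscedasticity-robust formula for plain regression", {
  # with zero within-study variances the uncorrected ML fit is OLS with an
  # ML error variance, whose coefficient sandwich is exactly HC0
  set.seed(5)
  n <- 150
  xi <- rnorm(n)
  eta <- 0.5 + 0.8 * xi + rnorm(n, 0, 0.7 + 0.5 * abs(xi))
  d <- data.frame(study = paste0("s", seq_len(n)), eta = eta, s_eta2 = 0,
                  xi = xi, s_xi2 = 0)
  class(d) <- c("crr_data", "data.frame")
  fit <- crr_fit(d, method = "naive", naive_ml = TRUE, sandwich = TRUE)
  ols <- lm(eta ~ xi)
  X <- cbind(1, xi)
  r <- resid(ols)
  hc0 <- solve(crossprod(X)) %*% t(X) %*% diag(r^2) %*% X %*%
    solve(crossprod(X))
  expect_equal(unname(fit$se_sandwich[c("beta0", "beta1")]),
               unname(sqrt(diag(hc0))), tolerance = 1e-3)
})

test_that("the application fits reproduce the reference estimates on the packaged dataset", {
  d <- application_data()
  lik <- crr_fit(d, method = "likelihood")
  expect_true(lik$converged)
  expect_equal(lik$params[["beta1"]], 0.761, tolerance = 0.002)
  expect_equal(lik$se_hessian[["beta1"]], 0.091, tolerance = 0.002)
  nav <- crr_fit(d, method = "naive")
  expect_equal(nav$params[["beta1"]], 0.709, tolerance = 0.001)
  expect_equal(nav$params[["tau2"]], 0.527, tolerance = 0.001)
  expect_equal(nav$se_hessian[["tau2"]], 0.211, tolerance = 0.001)

  # covariate fit: scaled mean age via pseudo-likelihood
  da <- assemble_observed(covid_schizophrenia("age"), apply = "never",
                          standardize = TRUE)
  ps <- crr_fit(da, method = "pseudo")
  expect_equal(ps$params[["beta1"]], 1.071, tolerance = 0.01)
  expect_equal(ps$params[["beta2"]], -0.557, tolerance = 0.01)
})
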