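test_that("marginal moments match the model-implied covariance", {
  th <- model_params(beta0 = 0, beta1 = 0, beta2 = 0, mu_xi = 0.3,
                     mu_zeta = -0.2, tau2 = 0.5, sigma_xi2 = 1.2,
                     sigma_zeta2 = 0.7, sigma_xizeta = 0)
  mm <- marginal_moments(th)
  expect_equal(mm$cov, diag(c(0.5, 1.2, 0.7)))
  expect_equal(mm$mean, c(0, 0.3, -0.2))

  th2 <- model_params(beta0 = 0, beta1 = 1, beta2 = 0.8, mu_xi = 0,
                      mu_zeta = 0, tau2 = 0.1, sigma_xi2 = 1,
                      sigma_zeta2 = 1, sigma_xizeta = 0)
  mm2 <- marginal_moments(th2)
  expect_equal(mm2$cov[1, 1], 1.74)
  expect_equal(mm2$cov[1, 2], 1)
  expect_equal(mm2$cov[1, 3], 0.8)
  expect_equal(mm2$cov[2, 3], 0)

  # sigma_xizeta = 0 reproduces the diagonal-latent matrix entry by entry
  b1 <- 0.7; b2 <- -0.4; t2 <- 0.2; sx <- 0.9; sz <- 1.1
  th3 <- model_params(0.1, b1, b2, 0, 0, t2, sx, sz, 0)
  S <- marginal_moments(th3)$cov
  expect_equal(S, matrix(c(b1^2 * sx + b2^2 * sz + t2, b1 * sx, b2 * sz,
                           b1 * sx, sx, 0,
                           b2 * sz, 0, sz), 3, 3))

  # bivariate case drops the covariate block
  th4 <- model_params(0.1, b1, mu_xi = 0.2, tau2 = t2, sigma_xi2 = sx)
  mm4 <- marginal_moments(th4, has_covariate = FALSE)
  expect_equal(dim(mm4$cov), c(2L, 2L))
  expect_equal(mm4$cov[1, 1], b1^2 * sx + t2)

  # a supplied within-study matrix is added
  g <- diag(c(0.05, 0.02))
  expect_equal(marginal_moments(th4, gamma = g, has_covariate = FALSE)$cov,
               mm4$cov + g)
})

test_that("likelihood factorises into univariate densities when slopes vanish", {
  d <- synthetic_trivariate(n = 1)
  th <- c(beta0 = 0.2, beta1 = 0, beta2 = 0, mu_xi = -0.1, mu_zeta = 0.3,
          tau2 = 0.4, sigma_xi2 = 0.8, sigma_zeta2 = 0.6)
  nll <- neg_loglik_approx(th, d, mode = "pseudo")
  expected <- -dnorm(d$eta, 0.2, sqrt(0.4 + d$s_eta2), log = TRUE) -
    dnorm(d$xi, -0.1, sqrt(0.8 + d$s_xi2), log = TRUE) -
    dnorm(d$zeta, 0.3, sqrt(0.6 + d$s_zeta2), log = TRUE)
  expect_equal(nll, sum(expected), tolerance = 1e-12)
})

test_that("pseudo and full modes coincide exactly when covariances are zero", {
  d <- synthetic_trivariate()
  d$s_eta_zeta <- 0
  d$s_xi_zeta <- 0
  th <- c(beta0 = 0.1, beta1 = 0.9, beta2 = 0.5, mu_xi = 0, mu_zeta = 0,
          tau2 = 0.3, sigma_xi2 = 1, sigma_zeta2 = 1)
  expect_identical(neg_loglik_approx(th, d, "full"),
                   neg_loglik_approx(th, d, "pseudo"))
  # and differ when the Taylor covariances are present
  d2 <- synthetic_trivariate()
  expect_false(isTRUE(all.equal(neg_loglik_approx(th, d2, "full"),
                                neg_loglik_approx(th, d2, "pseudo"))))
})

test_that("per-study scores agree with a numerical-gradient oracle and sum to zero at the optimum", {
  d <- synthetic_trivariate()
  th <- c(beta0 = 0.1, beta1 = 0.9, beta2 = 0.5, mu_xi = 0, mu_zeta = 0,
          tau2 = 0.3, sigma_xi2 = 1, sigma_zeta2 = 1)
  sc <- score_per_study(th, d, "pseudo")
  oracle <- -pracma::grad(function(x) {
    names(x) <- names(th)
    neg_loglik_approx(x, d, "pseudo")
  }, unname(th))
  expect_equal(colSums(sc), oracle, tolerance = 1e-6,
               ignore_attr = TRUE)

  fit <- crr_fit(d, method = "pseudo")
  expect_true(fit$converged)
  sc_hat <- score_per_study(fit$params, d, "pseudo")
  expect_lt(max(abs(colSums(sc_hat))), 1e-3)
})

test_that("classical likelihood is location-equivariant in the control risk", {
  d <- application_data()
  f0 <- crr_fit(d, method = "likelihood")
  d2 <- d
  d2$xi <- d$xi + 1.5
  f1 <- crr_fit(d2, method = "likelihood")
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-6)
  expect_equal(f1$params[["beta1"]], f0$params[["beta1"]], tolerance = 1e-4)
  expect_equal(f1$params[["mu_xi"]], f0$params[["mu_xi"]] + 1.5,
               tolerance = 1e-4)
  expect_equal(f1$params[["beta0"]],
               f0$params[["beta0"]] - 1.5 * f0$params[["beta1"]],
               tolerance = 1e-4)
})

test_that("uncorrected ML fit matches the metafor oracle", {
  skip_if_not_installed("metafor")
  set.seed(21)
  d <- generate_scenario(sim_config(1, n_studies = 30, tau2 = 1.5,
                                    seed = 21))
  fit <- crr_fit(d, method = "naive", naive_ml = TRUE)
  or <- metafor::rma(yi = d$eta, vi = d$s_eta2, mods = ~ d$xi + d$zeta,
                     method = "ML")
  expect_equal(fit$params[["beta1"]], as.numeric(coef(or)[2]),
               tolerance = 1e-4)
  expect_equal(fit$params[["tau2"]], or$tau2, tolerance = 1e-3)
})

test_that("classical MLE of the slope approaches weighted least squares as the error variances vanish", {
  set.seed(13)
  n <- 40
  xi_true <- rnorm(n, 0, 1.3)
  eta <- 0.2 + 0.9 * xi_true + rnorm(n, 0, sqrt(0.2))
  d <- data.frame(study = paste0("s", 1:n), eta = eta, s_eta2 = 1e-6,
                  xi = xi_true, s_xi2 = 1e-6)
  class(d) <- c("crr_data", "data.frame")
  fit <- crr_fit(d, method = "likelihood")
  ols <- coef(lm(eta ~ xi_true))
  expect_equal(fit$params[["beta1"]], ols[[2]], tolerance = 1e-3)
})
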