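test_that("Gauss-Hermite rule integrates Gaussian moments exactly", {
  r2 <- gauss_hermite_rule(2)
  expect_equal(sum(r2$weights), 1, tolerance = 1e-12)
  expect_equal(sum(r2$weights * r2$nodes^2), 1, tolerance = 1e-12)
  r10 <- gauss_hermite_rule(10)
  expect_true(all(r10$weights > 0))
  expect_equal(sum(r10$weights * r10$nodes^2), 1, tolerance = 1e-10)
  expect_equal(sum(r10$weights * r10$nodes^8), 105, tolerance = 1e-8)
  expect_error(gauss_hermite_rule(1), "at least 2")

  r2d <- gauss_hermite_rule(5, dims = 2)
  expect_equal(sum(r2d$weights), 1, tolerance = 1e-12)
  expect_equal(sum(r2d$weights * r2d$nodes[, 1]^2 * r2d$nodes[, 2]^2), 1,
               tolerance = 1e-10)
})

test_that("exact binomial likelihood approaches the plug-in binomial in the degenerate-latent limit", {
  d <- data.frame(y = 210, n_treat = 1000, x = 350, n_control = 1000)
  th <- c(beta0 = -0.4, beta1 = 0.6, mu_xi = -0.6, tau2 = 1e-8,
          sigma_xi2 = 1e-8)
  v <- neg_loglik_exact_binomial(th, d, n_nodes = 10)
  direct <- -dbinom(210, 1000, plogis(-0.4 + 0.6 * -0.6), log = TRUE) -
    dbinom(350, 1000, plogis(-0.6), log = TRUE)
  expect_equal(v, direct, tolerance = 1e-4)
})

test_that("exact binomial likelihood matches the adaptive-quadrature oracle", {
  set.seed(3)
  d <- generate_scenario(sim_config(1, n_studies = 5, tau2 = 0.3, seed = 3))
  th <- c(beta0 = 0.1, beta1 = 0.9, mu_xi = -0.2, tau2 = 0.3,
          sigma_xi2 = 0.8)
  p <- as.list(th)
  oracle <- 0
  for (i in 1:5) {
    inner <- function(xi) vapply(xi, function(x0)
      integrate(function(eta)
        dbinom(d$y[i], d$n_treat[i], plogis(eta)) *
          dnorm(eta, p$beta0 + p$beta1 * x0, sqrt(p$tau2)),
        -Inf, Inf, rel.tol = 1e-11)$value, numeric(1))
    oracle <- oracle - log(integrate(function(xi)
      dbinom(d$x[i], d$n_control[i], plogis(xi)) *
        dnorm(xi, p$mu_xi, sqrt(p$sigma_xi2)) * inner(xi),
      -Inf, Inf, rel.tol = 1e-11)$value)
  }
  errs <- vapply(c(10, 40, 160), function(nn)
    abs(neg_loglik_exact_binomial(th, d, nn) - oracle) / abs(oracle),
    numeric(1))
  # refinement toward the oracle, reaching 1e-4 relative accuracy
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("multinomial pseudo-likelihood nests the binomial model at beta2 = 0", {
  d <- synthetic_trivariate(n = 4, seed = 7)
  th <- c(beta0 = 0.1, beta1 = 0.9, beta2 = 0, mu_xi = 0, mu_zeta = 0,
          tau2 = 0.2, sigma_xi2 = 1, sigma_zeta2 = 1)
  vm <- neg_loglik_exact_multinomial(th, d, n_nodes = 12, mode = "pseudo")
  vb <- neg_loglik_exact_binomial(
    th[c("beta0", "beta1", "mu_xi", "tau2", "sigma_xi2")], d, n_nodes = 12)
  # at beta2 = 0 the trait factor separates: difference is the marginal
  # log-likelihood of the trait counts alone
  gh <- gauss_hermite_rule(12)
  recs <- attr(d, "records")
  lz <- 0
  for (rec in recs) {
    cl <- rec$subgroup$cells
    z <- cl[["t1m"]] + cl[["t0m"]] + cl[["c1m"]] + cl[["c0m"]]
    ni <- rec$n_treat + rec$n_control
    lz <- lz - log(sum(gh$weights * dbinom(z, ni, plogis(gh$nodes))))
  }
  expect_equal(vm - vb, lz, tolerance = 1e-8)
})

test_that("multinomial pseudo-likelihood matches a brute-force oracle on one study", {
  d <- synthetic_trivariate(n = 1, seed = 9)
  rec <- attr(d, "records")[[1]]
  cl <- rec$subgroup$cells
  th <- c(beta0 = 0, beta1 = 1, beta2 = 0.8, mu_xi = 0, mu_zeta = 0,
          tau2 = 0.3, sigma_xi2 = 1, sigma_zeta2 = 1)
  p <- as.list(th)
  nT <- rec$n_treat; nC <- rec$n_control; ni <- nT + nC
  z <- cl[["t1m"]] + cl[["t0m"]] + cl[["c1m"]] + cl[["c0m"]]
  f_eta <- function(xi, zeta) vapply(seq_along(xi), function(j)
    integrate(function(eta)
      dbinom(rec$y_events, nT, plogis(eta)) *
        dnorm(eta, p$beta0 + p$beta1 * xi[j] + p$beta2 * zeta, sqrt(p$tau2)),
      -Inf, Inf, rel.tol = 1e-10)$value, numeric(1))
  f_xi <- function(zeta) vapply(zeta, function(zz)
    integrate(function(xi)
      dbinom(rec$x_events, nC, plogis(xi)) * dnorm(xi, p$mu_xi,
        sqrt(p$sigma_xi2)) * f_eta(xi, zz),
      -Inf, Inf, rel.tol = 1e-9)$value, numeric(1))
  oracle <- -log(integrate(function(zeta)
    dbinom(z, ni, plogis(zeta)) * dnorm(zeta, p$mu_zeta,
      sqrt(p$sigma_zeta2)) * f_xi(zeta),
    -Inf, Inf, rel.tol = 1e-8)$value)
  v <- neg_loglik_exact_multinomial(th, d, n_nodes = 60, mode = "pseudo")
  expect_equal(v, oracle, tolerance = 1e-3 * abs(oracle))
})

test_that("full multinomial mode is finite and sensitive to the covariate slope", {
  d <- synthetic_trivariate(n = 3, seed = 11)
  th <- c(beta0 = 0, beta1 = 1, beta2 = 0.8, mu_xi = 0, mu_zeta = 0,
          tau2 = 0.3, sigma_xi2 = 1, sigma_zeta2 = 1)
  v1 <- neg_loglik_exact_multinomial(th, d, n_nodes = 8, mode = "full")
  expect_true(is.finite(v1))
  th2 <- th; th2[["beta2"]] <- 0
  v2 <- neg_loglik_exact_multinomial(th2, d, n_nodes = 8, mode = "full")
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("mean-covariate pseudo-likelihood factorises at zero correlations", {
  set.seed(15)
  d3 <- generate_scenario(sim_config(3, n_studies = 2, tau2 = 0.3,
                                     seed = 15))
  recs <- attr(d3, "records")
  th <- c(beta0 = 0, beta1 = 1, beta2 = 0.8, mu_xi = 0, mu_zeta = 0,
          tau2 = 0.3, sigma_xi2 = 1, sigma_zeta2 = 1)
  v0 <- neg_loglik_exact_meancov(th, recs, rho_t = 0, rho_c = 0,
                                 n_nodes = 10)
  # recompute with the bivariate factors replaced by products of univariate
  # normal densities: identical at rho = 0 by construction of the density
  p <- as.list(th)
  gh <- gauss_hermite_rule(10)
  ll <- 0
  for (rec in recs) {
    m <- rec$subgroup$means; sdw <- rec$subgroup$sd
    y <- rec$y_events; x <- rec$x_events
    nT <- rec$n_treat; nC <- rec$n_control
    ze <- p$mu_zeta + sqrt(p$sigma_zeta2) * gh$nodes
    xi <- p$mu_xi + sqrt(p$sigma_xi2) * gh$nodes
    li <- 0
    for (mm in seq_along(ze)) {
      lsub <- dnorm(m[["t1"]], ze[mm], sdw / sqrt(y), log = TRUE) +
        dnorm(m[["t0"]], ze[mm], sdw / sqrt(nT - y), log = TRUE) +
        dnorm(m[["c1"]], ze[mm], sdw / sqrt(x), log = TRUE) +
        dnorm(m[["c0"]], ze[mm], sdw / sqrt(nC - x), log = TRUE)
      inner <- vapply(xi, function(x0)
        sum(gh$weights * dbinom(y, nT,
          plogis(p$beta0 + p$beta1 * x0 + p$beta2 * ze[mm] +
                   sqrt(p$tau2) * gh$nodes))), numeric(1))
      li <- li + gh$weights[mm] * exp(lsub) *
        sum(gh$weights * dbinom(x, nC, plogis(xi)) * inner)
    }
    ll <- ll - log(li)
  }
  expect_equal(v0, ll, tolerance = 1e-8)
  expect_error(neg_loglik_exact_meancov(th, recs, rho_t = 1.2), "inside")
})

test_that("exact and approximate classical fits agree on large counts", {
  # at group sizes in the hundreds the normal approximation to the log odds
  # is accurate; the node count must grow with the counts because the
  # binomial factors sharpen (non-adaptive quadrature)
  set.seed(19)
  cfg <- sim_config(1, n_studies = 10, tau2 = 0.5, seed = 19,
                    size_range = c(120, 220))
  d <- generate_scenario(cfg)
  fa <- crr_fit(d, method = "likelihood")
  fe <- crr_fit(d, method = "likelihood", error_model = "exact",
                n_nodes = 80, start = fa$params,
                control = list(maxit = 1500, restarts = 1))
  expect_true(fe$optim_convergence == 0)
  expect_equal(fe$params[["beta1"]], fa$params[["beta1"]], tolerance = 0.05)
  expect_equal(fe$params[["sigma_xi2"]], fa$params[["sigma_xi2"]],
               tolerance = 0.15)
})
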