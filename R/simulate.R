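#' Skew-normal random draws
#'
#' Draws from the skew-normal distribution SN(location, scale, shape) using
#' the half-normal representation
#' `X = location + scale * (delta * |Z0| + sqrt(1 - delta^2) * Z1)` with
#' `delta = shape / sqrt(1 + shape^2)`; `shape = 0` recovers the normal
#' distribution.
#'
#' @param n number of draws.
#' @param location,scale,shape distribution parameters (`scale > 0`).
#' @return Numeric vector of draws.
#' @export
draw_skew_normal <- function(n, location = 0, scale = 1, shape = 0) {
  if (scale <= 0) stop("'scale' must be positive")
  delta <- shape / sqrt(1 + shape^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  location + scale * (delta * z0 + sqrt(1 - delta^2) * z1)
}

#' Simulation scenario configuration
#'
#' Scenario 1 pairs the risk measures with an error-free covariate; scenario
#' 2 generates an error-prone binary-trait covariate through two 4-cell
#' multinomial subgroup tables; scenario 3 generates an error-prone
#' mean-value covariate through bivariate-normal subgroup means with
#' uniformly drawn within-study correlations.  Group sizes are drawn
#' integer-uniformly on `size_range`; regression coefficients default to
#' `(0, 1, 0.8)` and the latent baseline risk is standard normal or
#' skew-normal with shape -5.
#'
#' @param scenario 1, 2 or 3.
#' @param n_studies number of studies per replicate.
#' @param tau2 residual between-study variance.
#' @param betas regression coefficients `(beta0, beta1, beta2)`.
#' @param xi_dist `"normal"` or `"skew_normal"` (shape `skew_shape`).
#' @param zeta_dist scenario 1 only: `"normal"` or `"bernoulli"` (prob 0.5).
#' @param n_reps number of replicates for [run_sim_study()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param size_range inclusive integer range of the group sizes.
#' @param sd_within within-study standard deviation of the individual
#'   covariate measurements (scenario 3).
#' @param skew_shape skew-normal shape for `xi_dist = "skew_normal"`.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(scenario, n_studies = 20, tau2 = 0.1,
                       betas = c(0, 1, 0.8),
                       xi_dist = c("normal", "skew_normal"),
                       zeta_dist = c("normal", "bernoulli"),
                       n_reps = 1000, seed = 1, size_range = c(15, 200),
                       sd_within = 1, skew_shape = -5) {
  stopifnot(scenario %in% 1:3, n_studies >= 1, tau2 > 0,
            length(betas) == 3, n_reps >= 1,
            length(size_range) == 2, size_range[1] >= 1,
            size_range[2] >= size_range[1], sd_within > 0)
  structure(list(scenario = scenario, n_studies = n_studies, tau2 = tau2,
                 betas = betas, xi_dist = match.arg(xi_dist),
                 zeta_dist = match.arg(zeta_dist), n_reps = n_reps,
                 seed = seed, size_range = size_range,
                 sd_within = sd_within, skew_shape = skew_shape),
            class = "sim_config")
}

draw_xi <- function(cfg, n) {
  if (cfg$xi_dist == "normal") stats::rnorm(n)
  else draw_skew_normal(n, 0, 1, cfg$skew_shape)
}

# observed log odds in the generator: the Haldane-Anscombe +0.5 correction is
# applied to every cell (the generator's convention; see the vignette)
gen_lo <- function(k, n) {
  list(est = log((k + 0.5) / (n - k + 0.5)),
       var = 1 / (k + 0.5) + 1 / (n - k + 0.5))
}

#' Generate one simulated meta-analysis
#'
#' Draws one replicate of the configured scenario: group sizes, latent risks
#' and covariate, counts (and subgroup data for scenarios 2-3), and the
#' assembled observed measures with their within-study variances and Taylor
#' covariances.  The generating parameter values are stored in the
#' `"truth"` attribute and the latent draws in `"latents"`.
#'
#' @param config a [sim_config()].
#' @return A `"crr_data"` data frame (with study records for scenarios 2-3
#'   in the `"records"` attribute).
#' @export
generate_scenario <- function(config) {
  cfg <- config
  n <- cfg$n_studies
  b <- cfg$betas
  nT <- sample(cfg$size_range[1]:cfg$size_range[2], n, replace = TRUE)
  nC <- sample(cfg$size_range[1]:cfg$size_range[2], n, replace = TRUE)
  xi <- draw_xi(cfg, n)
  zeta <- if (cfg$scenario == 1 && cfg$zeta_dist == "bernoulli")
    stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
  eta <- b[1] + b[2] * xi + b[3] * zeta + stats::rnorm(n, 0, sqrt(cfg$tau2))

  d <- switch(as.character(cfg$scenario),
    "1" = gen_s1(cfg, n, nT, nC, xi, zeta, eta),
    "2" = gen_s2(cfg, n, nT, nC, xi, zeta, eta),
    "3" = gen_s3(cfg, n, nT, nC, xi, zeta, eta))
  attr(d, "truth") <- c(beta0 = b[1], beta1 = b[2], beta2 = b[3],
                        mu_xi = 0, mu_zeta = 0, tau2 = cfg$tau2,
                        sigma_xi2 = 1, sigma_zeta2 = 1)
  attr(d, "latents") <- data.frame(eta = eta, xi = xi, zeta = zeta)
  d
}

gen_s1 <- function(cfg, n, nT, nC, xi, zeta, eta) {
  y <- stats::rbinom(n, nT, stats::plogis(eta))
  x <- stats::rbinom(n, nC, stats::plogis(xi))
  e <- gen_lo(y, nT); c <- gen_lo(x, nC)
  d <- data.frame(study = paste0("s", seq_len(n)), y = y, n_treat = nT,
                  x = x, n_control = nC, eta = e$est, s_eta2 = e$var,
                  xi = c$est, s_xi2 = c$var, zeta = zeta, s_zeta2 = 0,
                  s_eta_zeta = 0, s_xi_zeta = 0, stringsAsFactors = FALSE)
  class(d) <- c("crr_data", "data.frame")
  d
}

gen_s2 <- function(cfg, n, nT, nC, xi, zeta, eta) {
  eh <- stats::plogis(eta); ex <- stats::plogis(xi)
  ec <- stats::plogis(zeta)
  # free treatment cell probability, uniform on its feasible range (the
  # nominal U(0, min) draw is rejected until the implied simplex is valid)
  pT <- stats::runif(n, pmax(0, eh + ec - 1), pmin(eh, ec))
  pC <- stats::runif(n, pmax(0, ex + ec - 1), pmin(ex, ec))
  TT <- matrix(0L, n, 4); CC <- matrix(0L, n, 4)
  for (i in seq_len(n)) {
    TT[i, ] <- stats::rmultinom(1, nT[i],
      c(pT[i], eh[i] - pT[i], ec[i] - pT[i], 1 - eh[i] - ec[i] + pT[i]))
    CC[i, ] <- stats::rmultinom(1, nC[i],
      c(pC[i], ex[i] - pC[i], ec[i] - pC[i], 1 - ex[i] - ec[i] + pC[i]))
  }
  y <- TT[, 1] + TT[, 2]; x <- CC[, 1] + CC[, 2]
  ni <- nT + nC
  z <- TT[, 1] + TT[, 3] + CC[, 1] + CC[, 3]
  e <- gen_lo(y, nT); cl <- gen_lo(x, nC); zl <- gen_lo(z, ni)
  # Taylor covariances on the continuity-corrected margins
  yc <- y + 0.5; nyc <- nT - y + 0.5
  xc <- x + 0.5; nxc <- nC - x + 0.5
  zc <- z + 0.5; nzc <- ni - z + 0.5
  sez <- (TT[, 1] / yc - TT[, 3] / nyc) / zc -
         (TT[, 2] / yc - TT[, 4] / nyc) / nzc
  sxz <- (CC[, 1] / xc - CC[, 3] / nxc) / zc -
         (CC[, 2] / xc - CC[, 4] / nxc) / nzc
  d <- data.frame(study = paste0("s", seq_len(n)), y = y, n_treat = nT,
                  x = x, n_control = nC, eta = e$est, s_eta2 = e$var,
                  xi = cl$est, s_xi2 = cl$var, zeta = zl$est,
                  s_zeta2 = zl$var, s_eta_zeta = sez, s_xi_zeta = sxz,
                  stringsAsFactors = FALSE)
  shr <- psd_shrink_factors(d)
  d$s_eta_zeta <- d$s_eta_zeta * shr
  d$s_xi_zeta <- d$s_xi_zeta * shr
  class(d) <- c("crr_data", "data.frame")
  attr(d, "records") <- lapply(seq_len(n), function(i)
    study_record(paste0("s", i), y[i], nT[i], x[i], nC[i],
                 subgroup = subgroup_binary(TT[i, 1], TT[i, 2], TT[i, 3],
                                            TT[i, 4], CC[i, 1], CC[i, 2],
                                            CC[i, 3], CC[i, 4])))
  d
}

gen_s3 <- function(cfg, n, nT, nC, xi, zeta, eta) {
  y <- stats::rbinom(n, nT, stats::plogis(eta))
  x <- stats::rbinom(n, nC, stats::plogis(xi))
  rT <- stats::runif(n, -1, 1); rC <- stats::runif(n, -1, 1)
  sdw <- cfg$sd_within
  # subgroup-mean draws; empty subgroups get zero pooling weight, so their
  # nominal scale uses a half count to stay finite
  a1 <- pmax(y, 0.5); a0 <- pmax(nT - y, 0.5)
  c1 <- pmax(x, 0.5); c0 <- pmax(nC - x, 0.5)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  z3 <- stats::rnorm(n); z4 <- stats::rnorm(n)
  zt1 <- zeta + sdw / sqrt(a1) * z1
  zt0 <- zeta + sdw / sqrt(a0) * (rT * z1 + sqrt(1 - rT^2) * z2)
  zc1 <- zeta + sdw / sqrt(c1) * z3
  zc0 <- zeta + sdw / sqrt(c0) * (rC * z3 + sqrt(1 - rC^2) * z4)
  ni <- nT + nC
  zh <- (y * zt1 + (nT - y) * zt0 + x * zc1 + (nC - x) * zc0) / ni
  e <- gen_lo(y, nT); cl <- gen_lo(x, nC)
  d <- data.frame(study = paste0("s", seq_len(n)), y = y, n_treat = nT,
                  x = x, n_control = nC, eta = e$est, s_eta2 = e$var,
                  xi = cl$est, s_xi2 = cl$var, zeta = zh,
                  s_zeta2 = sdw^2 / ni, s_eta_zeta = (zt1 - zt0) / ni,
                  s_xi_zeta = (zc1 - zc0) / ni, stringsAsFactors = FALSE)
  shr <- psd_shrink_factors(d)
  d$s_eta_zeta <- d$s_eta_zeta * shr
  d$s_xi_zeta <- d$s_xi_zeta * shr
  class(d) <- c("crr_data", "data.frame")
  attr(d, "records") <- lapply(seq_len(n), function(i)
    study_record(paste0("s", i), y[i], nT[i], x[i], nC[i],
                 subgroup = subgroup_means(zt1[i], zt0[i], zc1[i], zc0[i],
                                           sdw)))
  attr(d, "rho") <- data.frame(rho_t = rT, rho_c = rC)
  d
}

#' Run a simulation study
#'
#' Generates `n_reps` replicates of the configured scenario, fits each
#' requested method to every replicate, and summarises the estimators by
#' bias, mean estimated standard error (se), empirical standard deviation
#' (sd) and the number of convergent replicates, plus the empirical coverage
#' of 95% Wald confidence intervals for the regression coefficients (using
#' Hessian and, for likelihood-based methods when `sandwich = TRUE`,
#' sandwich standard errors).  Bias, se, sd and coverage are computed over
#' the convergent replicates; the closed-form naive analysis always
#' converges.
#'
#' @param config a [sim_config()].
#' @param methods subset of `"likelihood"`, `"pseudo"`, `"naive"`
#'   (`"pseudo"` applies to scenarios 2-3 only).  Defaults to all methods
#'   meaningful for the scenario.
#' @param sandwich also compute sandwich standard errors and their coverage.
#' @param naive_weights weighting of the naive fit; the simulation harness
#'   defaults to the unweighted variant.
#' @param level confidence level for the coverage computation.
#' @return An object of class `"sim_summary"`: list with `summary` (tidy
#'   data frame: parameter, method, bias, se, sd, conv), `coverage`,
#'   `estimates` (per-replicate estimate matrices) and the config.
#' @export
run_sim_study <- function(config, methods = NULL, sandwich = FALSE,
                          naive_weights = "unweighted", level = 0.95) {
  cfg <- config
  if (is.null(methods))
    methods <- if (cfg$scenario == 1) c("likelihood", "naive")
               else c("likelihood", "pseudo", "naive")
  truth_names <- c("beta0", "beta1", "beta2", "mu_xi", "mu_zeta", "tau2",
                   "sigma_xi2", "sigma_zeta2")
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_reps)

  res <- lapply(methods, function(m)
    list(est = NULL, se = NULL, se_sw = NULL, conv = logical(cfg$n_reps)))
  names(res) <- methods

  for (r in seq_len(cfg$n_reps)) {
    set.seed(rep_seeds[r])
    d <- generate_scenario(cfg)
    for (m in methods) {
      fit <- switch(m,
        naive = fit_naive(d, weights = naive_weights),
        likelihood = crr_fit(d, method = "likelihood", sandwich = sandwich),
        pseudo = crr_fit(d, method = "pseudo", sandwich = sandwich))
      if (is.null(res[[m]]$est)) {
        p <- length(fit$params)
        res[[m]]$est <- matrix(NA_real_, cfg$n_reps, p,
                               dimnames = list(NULL, names(fit$params)))
        res[[m]]$se <- res[[m]]$est
        if (sandwich) res[[m]]$se_sw <- res[[m]]$est
      }
      res[[m]]$est[r, ] <- fit$params
      res[[m]]$se[r, ] <- fit$se_hessian
      if (sandwich && !is.null(fit$se_sandwich))
        res[[m]]$se_sw[r, ] <- fit$se_sandwich
      res[[m]]$conv[r] <- fit$converged
    }
  }

  truth <- c(beta0 = cfg$betas[1], beta1 = cfg$betas[2],
             beta2 = cfg$betas[3], mu_xi = 0, mu_zeta = 0, tau2 = cfg$tau2,
             sigma_xi2 = 1, sigma_zeta2 = 1)
  summ <- list(); covg <- list()
  z <- stats::qnorm((1 + level) / 2)
  for (m in methods) {
    est <- res[[m]]$est; se <- res[[m]]$se; ok <- res[[m]]$conv
    for (pn in colnames(est)) {
      tv <- if (pn %in% names(truth)) truth[[pn]] else NA_real_
      summ[[length(summ) + 1]] <- data.frame(
        parameter = pn, method = m,
        bias = mean(est[ok, pn]) - tv,
        se = mean(se[ok, pn], na.rm = TRUE),
        sd = stats::sd(est[ok, pn]),
        conv = sum(ok), stringsAsFactors = FALSE)
      if (grepl("^beta", pn) && !is.na(tv)) {
        inside <- abs(est[ok, pn] - tv) <= z * se[ok, pn]
        row <- data.frame(parameter = pn, method = m,
                          coverage_hessian = mean(inside, na.rm = TRUE),
                          coverage_sandwich = NA_real_,
                          stringsAsFactors = FALSE)
        if (sandwich && !is.null(res[[m]]$se_sw)) {
          sw <- res[[m]]$se_sw
          row$coverage_sandwich <-
            mean(abs(est[ok, pn] - tv) <= z * sw[ok, pn], na.rm = TRUE)
        }
        covg[[length(covg) + 1]] <- row
      }
    }
  }
  structure(list(summary = do.call(rbind, summ),
                 coverage = do.call(rbind, covg),
                 estimates = lapply(res, `[[`, "est"),
                 converged = lapply(res, `[[`, "conv"),
                 config = cfg), class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf("scenario %d: n = %d, tau2 = %g, %d replicates\n",
              cfg$scenario, cfg$n_studies, cfg$tau2, cfg$n_reps))
  print(transform(x$summary,
                  bias = round(bias, digits), se = round(se, digits),
                  sd = round(sd, digits)), row.names = FALSE)
  invisible(x)
}

#' Write simulation summaries as tidy CSV
#'
#' @param x a `"sim_summary"`.
#' @param file output path for the bias/se/sd/conv table.
#' @param coverage_file optional output path for the coverage table.
#' @return Invisibly, the summary data frame.
#' @export
write_sim_csv <- function(x, file, coverage_file = NULL) {
  stopifnot(inherits(x, "sim_summary"))
  cfg <- x$config
  out <- cbind(scenario = cfg$scenario, n = cfg$n_studies, tau2 = cfg$tau2,
               x$summary)
  utils::write.csv(out, file, row.names = FALSE)
  if (!is.null(coverage_file) && !is.null(x$coverage))
    utils::write.csv(cbind(scenario = cfg$scenario, n = cfg$n_studies,
                           tau2 = cfg$tau2, x$coverage),
                     coverage_file, row.names = FALSE)
  invisible(out)
}
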