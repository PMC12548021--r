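# Parameter bookkeeping -------------------------------------------------------
#
# The optimizer works on an unconstrained scale by default: variances are
# log-transformed and the latent covariance sigma_xizeta is expressed as
# atanh of the latent correlation.  A raw-scale parametrization is kept as an
# option; it mirrors the convergence failures that plain Nelder-Mead on the
# natural scale is known to produce (variance components on the boundary).

param_names <- function(covariate = c("none", "error_free", "latent"),
                        estimate_sigma_xizeta = FALSE) {
  covariate <- match.arg(covariate)
  switch(covariate,
    none = c("beta0", "beta1", "mu_xi", "tau2", "sigma_xi2"),
    error_free = c("beta0", "beta1", "beta2", "mu_xi", "tau2", "sigma_xi2"),
    latent = c("beta0", "beta1", "beta2", "mu_xi", "mu_zeta", "tau2",
               "sigma_xi2", "sigma_zeta2",
               if (estimate_sigma_xizeta) "sigma_xizeta"))
}

make_maps <- function(nms, parametrization = "transformed") {
  vpar <- intersect(c("tau2", "sigma_xi2", "sigma_zeta2"), nms)
  has_sxz <- "sigma_xizeta" %in% nms
  if (parametrization == "natural") {
    to <- identity
    from <- function(tp) stats::setNames(tp, nms)
  } else {
    to <- function(th) {
      tp <- th
      tp[vpar] <- log(th[vpar])
      if (has_sxz) {
        r <- th[["sigma_xizeta"]] /
          sqrt(th[["sigma_xi2"]] * th[["sigma_zeta2"]])
        tp[["sigma_xizeta"]] <- atanh(max(-0.99, min(0.99, r)))
      }
      tp
    }
    from <- function(tp) {
      th <- stats::setNames(as.numeric(tp), nms)
      th[vpar] <- exp(th[vpar])
      if (has_sxz)
        th[["sigma_xizeta"]] <- tanh(tp[[which(nms == "sigma_xizeta")]]) *
          sqrt(th[["sigma_xi2"]] * th[["sigma_zeta2"]])
      th
    }
  }
  list(to = to, from = from, names = nms)
}

#' Least-squares starting values
#'
#' Ordinary least squares of the treatment log odds on the observed
#' regressors provides the regression starts; latent means start at the
#' sample means and the variance components at positive moment-based values
#' (observed variance minus mean within-study variance, floored).
#'
#' @param data a `"crr_data"` data frame.
#' @param covariate `"none"`, `"error_free"` or `"latent"`.
#' @param estimate_sigma_xizeta include a zero start for the latent
#'   covariance.
#' @return Named parameter vector on the natural scale.
#' @export
ols_start <- function(data, covariate = c("none", "error_free", "latent"),
                      estimate_sigma_xizeta = FALSE) {
  covariate <- match.arg(covariate)
  nms <- param_names(covariate, estimate_sigma_xizeta)
  if (nrow(data) < length(intersect(c("beta0", "beta1", "beta2"), nms)) + 1)
    stop("too few studies for a least-squares start")
  fml <- if (covariate == "none") eta ~ xi else eta ~ xi + zeta
  f <- stats::lm(fml, data = data)
  cf <- stats::coef(f)
  if (any(is.na(cf))) stop("collinear design in least-squares start")
  th <- c(beta0 = cf[[1]], beta1 = cf[[2]])
  if (covariate != "none") th <- c(th, beta2 = cf[[3]])
  th <- c(th, mu_xi = mean(data$xi))
  if (covariate == "latent") th <- c(th, mu_zeta = mean(data$zeta))
  th <- c(th,
          tau2 = max(mean(stats::resid(f)^2) - mean(data$s_eta2), 0.01),
          sigma_xi2 = max(stats::var(data$xi) - mean(data$s_xi2), 0.05))
  if (covariate == "latent")
    th <- c(th, sigma_zeta2 = max(stats::var(data$zeta) -
                                    mean(data$s_zeta2), 0.05))
  if (estimate_sigma_xizeta) th <- c(th, sigma_xizeta = 0)
  th[nms]
}

#' Wald confidence interval
#'
#' @param estimate point estimate(s).
#' @param se standard error(s), nonnegative.
#' @param level confidence level.
#' @return Matrix with columns `lower`, `upper`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  stopifnot(all(se >= 0 | is.na(se)), level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}

# objective on the optimizer scale; large finite value outside the domain
make_objective <- function(data, mode, maps, include_s_eta2 = TRUE,
                           exact = NULL) {
  force(data); force(mode); force(maps)
  function(tp) {
    th <- maps$from(tp)
    val <- tryCatch({
      if (is.null(exact)) sum(nll_contrib(th, data, mode, include_s_eta2))
      else exact(th)
    }, error = function(e) NaN)
    if (!is.finite(val)) 1e10 else val
  }
}

run_nelder_mead <- function(obj, start, control) {
  ctl <- utils::modifyList(list(maxit = 5000 * length(start),
                                reltol = 1e-10, restarts = 2), control)
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  for (k in seq_len(ctl$restarts - 1))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  o
}

variance_floor <- 1e-10

#' Fit the meta-regression model with baseline risk information
#'
#' Maximises the selected (pseudo-)likelihood by Nelder-Mead from the
#' least-squares start, with variance components optimized on the log scale
#' (and the latent covariance through a bounded correlation transform) unless
#' `parametrization = "natural"`.  Standard errors come from the inverse
#' observed information mapped back to the natural scale by the delta method;
#' sandwich standard errors (recommended for pseudo-likelihood fits) are
#' added by [sandwich_se()].
#'
#' The model is chosen from the data and `method`: without a covariate the
#' classical bivariate model is fitted; with an error-free covariate the
#' covariate enters the mean; with an error-prone covariate
#' `method = "likelihood"` uses the Taylor within-study covariances and
#' `method = "pseudo"` sets them to zero (working independence).
#' `method = "naive"` is the uncorrected analysis: by default the closed-form
#' two-stage estimator (weighted least squares for the coefficients, mean
#' squared residual for `tau2`; see [fit_naive()]), or the uncorrected ML
#' fit when `naive_ml = TRUE`.
#'
#' @param data a `"crr_data"` data frame from [assemble_observed()] or
#'   [generate_scenario()].
#' @param method `"likelihood"`, `"pseudo"` or `"naive"`.
#' @param error_model `"approximate"` (closed form) or `"exact"`
#'   (binomial/multinomial, Gauss-Hermite integration; requires counts and,
#'   with a covariate, subgroup tables in the `"records"` attribute).
#' @param estimate_sigma_xizeta estimate the latent covariance between
#'   baseline risk and covariate instead of fixing it at zero.
#' @param include_s_eta2 naive-ML option, see [neg_loglik_approx()].
#' @param naive_weights weighting of the two-stage naive fit.
#' @param naive_ml use the uncorrected ML fit as the naive analysis.
#' @param n_nodes Gauss-Hermite nodes per dimension for exact fits.
#' @param exact_mode `"pseudo"` or `"full"` observation model for the exact
#'   multinomial fit.
#' @param rho_t,rho_c known within-study correlations for the exact
#'   mean-covariate fit.
#' @param parametrization `"transformed"` (default) or `"natural"`.
#' @param sandwich also compute sandwich standard errors.
#' @param start optional named start values (natural scale).
#' @param control optimizer options: `maxit`, `reltol`, `restarts`.
#' @return An object of class `"crr_fit"`: estimates, standard errors,
#'   log-likelihood, convergence flag.  Optimizer failure is reported through
#'   `converged = FALSE`, never as an error.
#' @examples
#' d <- assemble_observed(covid_schizophrenia(), apply = "never")
#' crr_fit(d, method = "likelihood")
#' @export
crr_fit <- function(data, method = c("likelihood", "pseudo", "naive"),
                    error_model = c("approximate", "exact"),
                    estimate_sigma_xizeta = FALSE, include_s_eta2 = TRUE,
                    naive_weights = c("inverse_variance", "unweighted"),
                    naive_ml = FALSE, n_nodes = 10,
                    exact_mode = c("pseudo", "full"), rho_t = 0, rho_c = 0,
                    parametrization = c("transformed", "natural"),
                    sandwich = FALSE, start = NULL, control = list()) {
  method <- match.arg(method)
  error_model <- match.arg(error_model)
  parametrization <- match.arg(parametrization)
  exact_mode <- match.arg(exact_mode)
  stopifnot(inherits(data, "crr_data") || is.data.frame(data))

  has_cov <- !is.null(data$zeta)
  cov_kind <- if (!has_cov) "none"
              else if (all(data$s_zeta2 == 0)) "error_free" else "latent"
  if (method == "pseudo" && cov_kind != "latent") {
    warning("pseudo-likelihood coincides with the likelihood without an error-prone covariate; fitting the likelihood")
    method <- "likelihood"
  }

  if (method == "naive" && !naive_ml)
    return(fit_naive(data, weights = match.arg(naive_weights)))

  mode <- if (method == "naive") "naive"
          else if (cov_kind == "latent") {
            if (method == "pseudo") "pseudo" else "full"
          } else "classical"
  nms <- param_names(cov_kind,
                     estimate_sigma_xizeta && mode %in% c("full", "pseudo"))
  if (mode == "naive") {
    nms <- setdiff(nms, c("mu_xi", "mu_zeta", "sigma_xi2", "sigma_zeta2",
                          "sigma_xizeta"))
  }
  maps <- make_maps(nms, parametrization)

  exact_fn <- NULL; exact_args <- NULL
  if (error_model == "exact") {
    if (mode == "naive") stop("no exact version of the naive analysis")
    if (mode == "classical") {
      counts <- counts_from(data)
      ef_off <- if (cov_kind == "error_free") data$zeta else NULL
      exact_fn <- function(th) neg_loglik_exact_binomial(th, counts, n_nodes,
                                                         offset = ef_off)
      exact_args <- list(layout = "none", offset = ef_off)
    } else {
      recs <- attr(data, "records")
      if (is.null(recs)) stop("exact fit requires study records with subgroup tables")
      layout <- recs[[1]]$subgroup$layout
      exact_fn <- if (layout == "binary") {
        function(th) neg_loglik_exact_multinomial(th, recs, n_nodes,
                                                  exact_mode)
      } else {
        function(th) neg_loglik_exact_meancov(th, recs, rho_t, rho_c,
                                              n_nodes)
      }
      exact_args <- list(layout = layout, exact_mode = exact_mode,
                         rho_t = rep_len(rho_t, nrow(data)),
                         rho_c = rep_len(rho_c, nrow(data)))
    }
  }

  th0 <- if (!is.null(start)) start[nms]
         else if (mode == "naive") {
           s <- ols_start(data, cov_kind)
           s[nms]
         } else ols_start(data, cov_kind,
                          estimate_sigma_xizeta && mode %in% c("full", "pseudo"))
  obj <- make_objective(data, mode, maps, include_s_eta2, exact_fn)
  opt <- run_nelder_mead(obj, maps$to(th0), control)
  th_hat <- maps$from(opt$par)

  H <- tryCatch(pracma::hessian(obj, opt$par), error = function(e) NULL)
  hess_pd <- !is.null(H) && all(is.finite(H)) &&
    all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
  at_floor <- any(th_hat[intersect(c("tau2", "sigma_xi2", "sigma_zeta2"),
                                   nms)] < variance_floor)
  converged <- opt$convergence == 0 && hess_pd && !at_floor

  se <- rep(NA_real_, length(nms)); names(se) <- nms
  vc <- NULL
  if (hess_pd) {
    Vt <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Vt)) {
      hess_pd <- FALSE
      converged <- FALSE
    } else {
      J <- pracma::jacobian(function(tp) as.numeric(maps$from(tp)), opt$par)
      vc <- J %*% Vt %*% t(J)
      dimnames(vc) <- list(nms, nms)
      dg <- diag(vc)
      se <- sqrt(ifelse(dg > 0, dg, NA_real_))
    }
  }

  fit <- structure(list(
    params = th_hat, loglik = -opt$value, se_hessian = se,
    vcov_hessian = vc, se_sandwich = NULL, vcov_sandwich = NULL,
    converged = converged, hessian_pd = hess_pd, at_floor = at_floor,
    optim_convergence = opt$convergence, n_studies = nrow(data),
    method = method, error_model = error_model, mode = mode,
    covariate = cov_kind, include_s_eta2 = include_s_eta2,
    parametrization = parametrization, maps = maps, opt_par = opt$par,
    data = data, n_nodes = n_nodes, exact_fn = exact_fn,
    exact_args = exact_args, hessian_trans = H), class = "crr_fit")
  if (sandwich) fit <- sandwich_se(fit)
  fit
}

#' Two-stage uncorrected (naive) analysis
#'
#' The uncorrected meta-regression that treats the observed control log odds
#' (and covariate, when present) as error-free regressors: a weighted
#' least-squares fit of the treatment log odds, with residual heterogeneity
#' estimated as the mean squared residual, `tau2 = RSS / n`.  Coefficient
#' standard errors are the dispersion-scaled weighted least-squares ones;
#' the standard error of `tau2` is `tau2 * sqrt(2 (n - p)) / n`, the
#' chi-square variance of the residual sum of squares with the plug-in
#' scale.  The estimator is closed-form, so `converged` is always `TRUE`.
#'
#' @param data a `"crr_data"` data frame.
#' @param weights `"inverse_variance"` (weights `1 / s_eta2`) or
#'   `"unweighted"`.
#' @return A `"crr_fit"` object with `method = "naive"`.
#' @export
fit_naive <- function(data, weights = c("inverse_variance", "unweighted")) {
  weights <- match.arg(weights)
  has_cov <- !is.null(data$zeta)
  fml <- if (has_cov) eta ~ xi + zeta else eta ~ xi
  w <- if (weights == "inverse_variance") 1 / data$s_eta2
       else rep(1, nrow(data))
  f <- stats::lm(fml, data = data, weights = w)
  n <- nrow(data); p <- length(stats::coef(f))
  r <- stats::resid(f)
  tau2 <- mean(r^2)
  cf <- stats::coef(f)
  se_cf <- summary(f)$coefficients[, "Std. Error"]
  th <- c(beta0 = cf[[1]], beta1 = cf[[2]])
  se <- c(beta0 = se_cf[[1]], beta1 = se_cf[[2]])
  if (has_cov) {
    th <- c(th, beta2 = cf[[3]]); se <- c(se, beta2 = se_cf[[3]])
  }
  th <- c(th, tau2 = tau2)
  se <- c(se, tau2 = tau2 * sqrt(2 * (n - p)) / n)
  structure(list(params = th, loglik = NA_real_, se_hessian = se,
                 vcov_hessian = NULL, se_sandwich = NULL,
                 vcov_sandwich = NULL, converged = TRUE, hessian_pd = NA,
                 at_floor = FALSE, optim_convergence = 0L, n_studies = n,
                 method = "naive", error_model = "approximate",
                 mode = "naive_two_stage",
                 covariate = if (has_cov) "observed" else "none",
                 naive_weights = weights, data = data),
            class = "crr_fit")
}

#' Hessian standard errors of a fit
#'
#' Standard errors from the inverse observed information of the objective at
#' the optimum, mapped to the natural scale by the delta method (exact at a
#' stationary point).  These are stored on the fit at creation; this helper
#' recomputes and returns them.
#'
#' @param fit a `"crr_fit"` from [crr_fit()].
#' @return Named vector of standard errors.
#' @export
hessian_se <- function(fit) {
  stopifnot(inherits(fit, "crr_fit"))
  fit$se_hessian
}

#' Sandwich standard errors
#'
#' Robust covariance `A^{-1} B A^{-1}` with `A` the observed information and
#' `B` the sum of outer products of the per-study scores, both evaluated at
#' the fitted optimum on the optimizer scale, then mapped to the natural
#' scale.  This is the variance estimator that remains valid when the
#' pseudo-likelihood's working independence assumption fails.
#'
#' @param fit a converged `"crr_fit"` from a likelihood or pseudo-likelihood
#'   fit.
#' @return The fit with `se_sandwich` and `vcov_sandwich` filled in.
#' @export
sandwich_se <- function(fit) {
  stopifnot(inherits(fit, "crr_fit"))
  if (is.null(fit$hessian_trans) || !isTRUE(fit$hessian_pd)) {
    fit$se_sandwich <- rep(NA_real_, length(fit$params))
    return(fit)
  }
  maps <- fit$maps
  tp <- fit$opt_par
  n <- fit$n_studies
  if (is.null(fit$exact_fn)) {
    contrib <- function(tpar) {
      th <- maps$from(tpar)
      nll_contrib(th, fit$data, fit$mode, fit$include_s_eta2)
    }
  } else {
    recs <- attr(fit$data, "records")
    ea <- fit$exact_args
    contrib <- function(tpar) {
      th <- maps$from(tpar)
      vapply(seq_len(n), function(i) {
        if (fit$mode == "classical")
          neg_loglik_exact_binomial(th, fit$data[i, , drop = FALSE],
                                    fit$n_nodes, offset = ea$offset[i])
        else if (ea$layout == "binary")
          neg_loglik_exact_multinomial(th, recs[i], fit$n_nodes,
                                       ea$exact_mode)
        else neg_loglik_exact_meancov(th, recs[i], ea$rho_t[i], ea$rho_c[i],
                                      fit$n_nodes)
      }, numeric(1))
    }
  }
  p <- length(tp)
  sc <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(1, abs(tp[j]))
    up <- tp; up[j] <- up[j] + h
    dn <- tp; dn[j] <- dn[j] - h
    sc[, j] <- -(contrib(up) - contrib(dn)) / (2 * h)
  }
  A <- fit$hessian_trans
  B <- crossprod(sc)
  Vt <- tryCatch(solve(A, B) %*% solve(A), error = function(e) NULL)
  if (is.null(Vt)) {
    fit$se_sandwich <- rep(NA_real_, length(fit$params))
    return(fit)
  }
  J <- pracma::jacobian(function(x) as.numeric(maps$from(x)), tp)
  vc <- J %*% Vt %*% t(J)
  dimnames(vc) <- list(names(fit$params), names(fit$params))
  fit$vcov_sandwich <- vc
  dg <- diag(vc)
  fit$se_sandwich <- stats::setNames(sqrt(ifelse(dg > 0, dg, NA_real_)),
                                     names(fit$params))
  fit
}

#' @export
coef.crr_fit <- function(object, ...) object$params

#' @export
vcov.crr_fit <- function(object, ...) object$vcov_hessian

#' @export
confint.crr_fit <- function(object, parm, level = 0.95, ...) {
  se <- object$se_hessian
  ci <- wald_ci(object$params, se, level)
  rownames(ci) <- names(object$params)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.crr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$params), class = "logLik")
}

#' @export
print.crr_fit <- function(x, digits = 3, ...) {
  lab <- switch(x$method,
    naive = "naive analysis",
    pseudo = "pseudo-likelihood",
    likelihood = "likelihood")
  cat(sprintf("%s fit (%s error model), %d studies%s\n", lab, x$error_model,
              x$n_studies,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$params
  se <- x$se_hessian
  z <- abs(est / se)
  stars <- ifelse(!is.na(z) & z > stats::qnorm(0.975), " *", "")
  for (i in seq_along(est))
    cat(sprintf("  %-13s %s (%s)%s\n", names(est)[i],
                format(round(est[i], digits), nsmall = digits),
                ifelse(is.na(se[i]), "NA",
                       format(round(se[i], digits), nsmall = digits)),
                stars[i]))
  if (!is.null(x$se_sandwich) && any(is.finite(x$se_sandwich)))
    cat("  (sandwich SEs available via $se_sandwich)\n")
  invisible(x)
}
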