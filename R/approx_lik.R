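#' Marginal moments of the observed measures under the approximate model
#'
#' Under the structural model with Gaussian latent baseline risk and (when
#' present) Gaussian latent covariate, the observed vector of measures is
#' multivariate normal with mean
#' `(beta0 + beta1*mu_xi + beta2*mu_zeta, mu_xi, mu_zeta)` and covariance
#' `Sigma + Gamma_i`, where `Sigma` is the latent-scale covariance implied by
#' the regression and `Gamma_i` the within-study error covariance.  The
#' general form with latent covariance `sigma_xizeta` is
#' \deqn{\Sigma_{11} = \beta_1^2\sigma_\xi^2 + \beta_2^2\sigma_\zeta^2 +
#'   2\beta_1\beta_2\sigma_{\xi\zeta} + \tau^2}
#' with `Sigma_12 = beta1*sigma_xi2 + beta2*sigma_xizeta`,
#' `Sigma_13 = beta2*sigma_zeta2 + beta1*sigma_xizeta`,
#' `Sigma_23 = sigma_xizeta`; it reduces to the familiar diagonal-latent form
#' at `sigma_xizeta = 0`.  Without a covariate the third row and column and
#' the `beta2` terms are dropped.
#'
#' @param params a [model_params()] vector (or named numeric vector).
#' @param gamma optional within-study covariance matrix to add to `Sigma`.
#' @param has_covariate whether the trivariate form is requested; defaults to
#'   `TRUE` when `params` carries `beta2`.
#' @return List with `mean` and `cov`.
#' @export
marginal_moments <- function(params, gamma = NULL,
                             has_covariate = "beta2" %in% names(params)) {
  p <- as.list(params)
  sxz <- if (!is.null(p$sigma_xizeta)) p$sigma_xizeta else 0
  if (has_covariate) {
    mu <- c(p$beta0 + p$beta1 * p$mu_xi + p$beta2 * p$mu_zeta,
            p$mu_xi, p$mu_zeta)
    S <- matrix(0, 3, 3)
    S[1, 1] <- p$beta1^2 * p$sigma_xi2 + p$beta2^2 * p$sigma_zeta2 +
               2 * p$beta1 * p$beta2 * sxz + p$tau2
    S[1, 2] <- S[2, 1] <- p$beta1 * p$sigma_xi2 + p$beta2 * sxz
    S[1, 3] <- S[3, 1] <- p$beta2 * p$sigma_zeta2 + p$beta1 * sxz
    S[2, 2] <- p$sigma_xi2
    S[2, 3] <- S[3, 2] <- sxz
    S[3, 3] <- p$sigma_zeta2
  } else {
    mu <- c(p$beta0 + p$beta1 * p$mu_xi, p$mu_xi)
    S <- matrix(c(p$beta1^2 * p$sigma_xi2 + p$tau2, p$beta1 * p$sigma_xi2,
                  p$beta1 * p$sigma_xi2, p$sigma_xi2), 2, 2)
  }
  if (!is.null(gamma)) {
    stopifnot(all(dim(gamma) == dim(S)))
    S <- S + gamma
  }
  list(mean = mu, cov = S)
}

# Per-study negative log-density contributions, vectorised over studies.
# modes: classical  - bivariate (eta, xi); an error-free covariate (s_zeta2
#                     all zero) enters the mean as a per-study offset
#        full       - trivariate with the Taylor within-study covariances
#        pseudo     - trivariate with Gamma_i forced diagonal
#        naive      - univariate ML regression of eta on observed (xi, zeta)
#                     with variance s_eta2 + tau2 (s_eta2 dropped when
#                     include_s_eta2 = FALSE)
nll_contrib <- function(params, data, mode, include_s_eta2 = TRUE) {
  p <- as.list(params)
  d <- data
  if (mode == "naive") {
    pred <- p$beta0 + p$beta1 * d$xi
    if (!is.null(p$beta2)) pred <- pred + p$beta2 * d$zeta
    v <- p$tau2 + if (include_s_eta2) d$s_eta2 else 0
    if (any(v <= 0)) return(rep(NaN, nrow(d)))
    return(0.5 * (log(2 * pi * v) + (d$eta - pred)^2 / v))
  }
  if (mode == "classical") {
    off <- if (!is.null(p$beta2)) p$beta2 * d$zeta else 0
    a <- d$s_eta2 + p$beta1^2 * p$sigma_xi2 + p$tau2
    b <- p$beta1 * p$sigma_xi2
    e <- d$s_xi2 + p$sigma_xi2
    det <- a * e - b^2
    if (any(det <= 0) || any(a <= 0)) return(rep(NaN, nrow(d)))
    r1 <- d$eta - (p$beta0 + p$beta1 * p$mu_xi + off)
    r2 <- d$xi - p$mu_xi
    return(0.5 * (log(det) + (e * r1^2 - 2 * b * r1 * r2 + a * r2^2) / det +
                  2 * log(2 * pi)))
  }
  # trivariate: full keeps the Taylor covariances, pseudo zeroes them
  sxz <- if (!is.null(p$sigma_xizeta)) p$sigma_xizeta else 0
  use_cov <- mode == "full"
  gez <- if (use_cov && !is.null(d$s_eta_zeta)) d$s_eta_zeta else 0
  gxz <- if (use_cov && !is.null(d$s_xi_zeta)) d$s_xi_zeta else 0
  a11 <- p$beta1^2 * p$sigma_xi2 + p$beta2^2 * p$sigma_zeta2 +
         2 * p$beta1 * p$beta2 * sxz + p$tau2 + d$s_eta2
  a12 <- p$beta1 * p$sigma_xi2 + p$beta2 * sxz
  a13 <- p$beta2 * p$sigma_zeta2 + p$beta1 * sxz + gez
  a22 <- p$sigma_xi2 + d$s_xi2
  a23 <- sxz + gxz
  a33 <- p$sigma_zeta2 + d$s_zeta2
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
         a13 * (a12 * a23 - a22 * a13)
  if (any(!is.finite(det)) || any(det <= 0)) return(rep(NaN, nrow(d)))
  r1 <- d$eta - (p$beta0 + p$beta1 * p$mu_xi + p$beta2 * p$mu_zeta)
  r2 <- d$xi - p$mu_xi
  r3 <- d$zeta - p$mu_zeta
  i11 <- (a22 * a33 - a23^2) / det
  i12 <- -(a12 * a33 - a13 * a23) / det
  i13 <- (a12 * a23 - a13 * a22) / det
  i22 <- (a11 * a33 - a13^2) / det
  i23 <- -(a11 * a23 - a12 * a13) / det
  i33 <- (a11 * a22 - a12^2) / det
  q <- i11 * r1^2 + i22 * r2^2 + i33 * r3^2 +
       2 * (i12 * r1 * r2 + i13 * r1 * r3 + i23 * r2 * r3)
  0.5 * (log(det) + q + 3 * log(2 * pi))
}

#' Negative log-likelihood under the approximate error model
#'
#' Closed-form negative log (pseudo-)likelihood of the observed measures.
#' Mode `"classical"` is the bivariate model in the treatment and control
#' log odds (an error-free covariate, if present in `data`, enters the mean);
#' `"full"` and `"pseudo"` are the trivariate model with an error-prone
#' covariate, with and without the Taylor within-study covariances;
#' `"naive"` is the uncorrected univariate regression likelihood of the
#' treatment log odds on the observed regressors with variance
#' `s_eta2 + tau2`.
#'
#' @param params named parameter vector (see [model_params()]).
#' @param data a `"crr_data"` data frame from [assemble_observed()].
#' @param mode one of `"classical"`, `"full"`, `"pseudo"`, `"naive"`.
#' @param include_s_eta2 naive mode only: whether the within-study variance
#'   of the response enters the residual variance.
#' @return The negative log-likelihood (a scalar; `NaN` when the implied
#'   covariance of some study is not positive definite).
#' @export
neg_loglik_approx <- function(params, data,
                              mode = c("classical", "full", "pseudo", "naive"),
                              include_s_eta2 = TRUE) {
  mode <- match.arg(mode)
  if (nrow(data) == 0L) stop("empty data")
  if (mode %in% c("full", "pseudo") && is.null(data$zeta))
    stop("trivariate mode requires a covariate in 'data'")
  contrib <- nll_contrib(params, data, mode, include_s_eta2)
  if (any(is.nan(contrib))) {
    bad <- which(is.nan(contrib))[1]
    stop(sprintf("singular or non-PD covariance for study '%s'",
                 data$study[bad]))
  }
  sum(contrib)
}

#' Per-study score vectors
#'
#' Central-difference gradient of each study's log-density contribution with
#' respect to the natural parameters; the rows sum to (numerically) zero at a
#' maximum of the corresponding likelihood.  Used by the sandwich variance.
#'
#' @inheritParams neg_loglik_approx
#' @param h relative step size for the central differences.
#' @return An `n_studies` by `length(params)` matrix of scores of the
#'   log-density (not its negative).
#' @export
score_per_study <- function(params, data,
                            mode = c("classical", "full", "pseudo", "naive"),
                            include_s_eta2 = TRUE, h = 1e-6) {
  mode <- match.arg(mode)
  th <- unlist(params)
  n <- nrow(data)
  sc <- matrix(0, n, length(th), dimnames = list(data$study, names(th)))
  for (j in seq_along(th)) {
    step <- h * max(1, abs(th[j]))
    up <- th; up[j] <- up[j] + step
    dn <- th; dn[j] <- dn[j] - step
    sc[, j] <- -(nll_contrib(up, data, mode, include_s_eta2) -
                 nll_contrib(dn, data, mode, include_s_eta2)) / (2 * step)
  }
  sc
}
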