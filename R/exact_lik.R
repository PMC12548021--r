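#' Gauss-Hermite quadrature rule against the Gaussian weight
#'
#' Probabilists' Gauss-Hermite rule: nodes and weights such that
#' `sum(w * f(x))` approximates `E[f(Z)]` for standard normal `Z`, exactly
#' for polynomials up to degree `2 * n_nodes - 1`.  For `dims > 1` the tensor
#' product grid is returned: `nodes` is then a matrix with one column per
#' dimension and `weights` the product weights.
#'
#' @param n_nodes number of nodes per dimension (>= 2).
#' @param dims number of dimensions (1 to 3).
#' @return An object of class `"gh_rule"`: list with `nodes`, `weights`,
#'   `n_nodes`, `dims`.  Weights are normalised to sum to one.
#' @examples
#' r <- gauss_hermite_rule(10)
#' sum(r$weights * r$nodes^8)  # E[Z^8] = 105
#' @export
gauss_hermite_rule <- function(n_nodes, dims = 1) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  stopifnot(dims >= 1, dims <= 3)
  gh <- pracma::gaussHermite(n_nodes)
  x <- gh$x * sqrt(2)           # physicists' -> probabilists'
  w <- gh$w / sqrt(pi)
  w <- w / sum(w)
  if (dims == 1L) {
    nodes <- x; weights <- w
  } else {
    grid <- do.call(expand.grid, rep(list(seq_len(n_nodes)), dims))
    nodes <- matrix(x[as.matrix(grid)], ncol = dims)
    weights <- apply(matrix(w[as.matrix(grid)], ncol = dims), 1, prod)
  }
  structure(list(nodes = nodes, weights = weights,
                 n_nodes = n_nodes, dims = dims), class = "gh_rule")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

counts_from <- function(data) {
  if (inherits(data, "crr_data"))
    return(data[, c("y", "n_treat", "x", "n_control")])
  if (is.data.frame(data)) {
    stopifnot(all(c("y", "n_treat", "x", "n_control") %in% names(data)))
    return(data)
  }
  # a list of study records
  data.frame(
    y = vapply(data, `[[`, numeric(1), "y_events"),
    n_treat = vapply(data, `[[`, numeric(1), "n_treat"),
    x = vapply(data, `[[`, numeric(1), "x_events"),
    n_control = vapply(data, `[[`, numeric(1), "n_control"))
}

#' Exact binomial negative log-likelihood of the classical model
#'
#' Evaluates the marginal likelihood of the observed event counts under the
#' exact measurement error model: conditionally on the latent risks the
#' counts are binomial with probabilities `expit(eta)` and `expit(xi)`, and
#' the double latent integral is computed on a standardized two-dimensional
#' Gauss-Hermite grid (`xi = mu_xi + sigma_xi * u`,
#' `eta = beta0 + beta1 * xi + tau * v`).
#'
#' @param params classical parameters: `beta0`, `beta1`, `mu_xi`, `tau2`,
#'   `sigma_xi2` (with `tau2, sigma_xi2 > 0`); when `offset` is used, a
#'   `beta2` entry multiplies it.
#' @param data counts: a `"crr_data"` frame, a data frame with columns
#'   `y, n_treat, x, n_control`, or a list of study records.
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @param offset optional per-study error-free covariate values entering the
#'   mean of the treatment risk as `beta2 * offset`.
#' @return Negative log-likelihood.
#' @export
neg_loglik_exact_binomial <- function(params, data, n_nodes = 10,
                                      offset = NULL) {
  p <- as.list(params)
  if (p$tau2 <= 0 || p$sigma_xi2 <= 0)
    stop("exact likelihood requires tau2 > 0 and sigma_xi2 > 0")
  d <- counts_from(data)
  off <- if (is.null(offset)) rep(0, nrow(d))
         else p$beta2 * rep_len(offset, nrow(d))
  gh <- gauss_hermite_rule(n_nodes)
  xi_nodes <- p$mu_xi + sqrt(p$sigma_xi2) * gh$nodes           # K
  eta_base <- outer(p$beta0 + p$beta1 * xi_nodes,
                    sqrt(p$tau2) * gh$nodes, `+`)              # K x L
  lw <- log(gh$weights)
  lx_all <- outer(stats::plogis(xi_nodes), seq_len(nrow(d)),
                  function(q, i) stats::dbinom(d$x[i], d$n_control[i], q,
                                               log = TRUE))
  ll <- 0
  for (i in seq_len(nrow(d))) {
    ly <- matrix(stats::dbinom(d$y[i], d$n_treat[i],
                               stats::plogis(eta_base + off[i]),
                               log = TRUE), n_nodes, n_nodes)
    m <- apply(ly, 1, max)
    inner <- m + log(as.vector(exp(ly - m) %*% gh$weights))  # over L
    ll <- ll + logsumexp(lw + lx_all[, i] + inner)
  }
  -ll
}

subgroups_from <- function(data, layout) {
  recs <- if (inherits(data, "crr_data")) attr(data, "records") else data
  if (is.null(recs)) stop("subgroup tables unavailable: supply study records")
  tabs <- lapply(recs, `[[`, "subgroup")
  ok <- vapply(tabs, function(t) !is.null(t) && t$layout == layout,
               logical(1))
  if (!all(ok))
    stop(sprintf("all studies need a '%s'-layout subgroup table", layout))
  list(records = recs, tables = tabs)
}

#' Exact (pseudo-)likelihood with a binary-trait covariate
#'
#' Negative log (pseudo-)likelihood under the exact multinomial measurement
#' error model for a binary-trait covariate.  In `"pseudo"` mode the
#' observation factors are, conditionally on the latents, independent
#' binomials for the treatment events, the control events and the pooled
#' trait count (working independence).  In `"full"` mode the two 4-cell
#' multinomial subgroup tables are used, with the cell probabilities
#' completed by independence of event status and trait given the latents
#' (`pT1M = expit(eta) * expit(zeta)`), which is the only completion
#' satisfying the stated margins for every latent value.  The triple latent
#' integral is evaluated on a standardized 3-D Gauss-Hermite grid.
#'
#' @param params full parameter vector (see [model_params()]); all three
#'   variance components must be positive.
#' @param data list of study records with binary subgroup tables, or a
#'   `"crr_data"` frame carrying them in its `"records"` attribute.
#' @param n_nodes nodes per dimension.
#' @param mode `"pseudo"` (default) or `"full"`.
#' @return Negative log (pseudo-)likelihood.
#' @export
neg_loglik_exact_multinomial <- function(params, data, n_nodes = 10,
                                         mode = c("pseudo", "full")) {
  mode <- match.arg(mode)
  p <- as.list(params)
  if (p$tau2 <= 0 || p$sigma_xi2 <= 0 || p$sigma_zeta2 <= 0)
    stop("exact likelihood requires positive variance components")
  sg <- subgroups_from(data, "binary")
  gh <- gauss_hermite_rule(n_nodes)
  zk <- gh$nodes; lw <- log(gh$weights)
  xi_n <- p$mu_xi + sqrt(p$sigma_xi2) * zk
  ze_n <- p$mu_zeta + sqrt(p$sigma_zeta2) * zk
  ll <- 0
  for (rec in sg$records) {
    cl <- rec$subgroup$cells
    nT <- rec$n_treat; nC <- rec$n_control; ni <- nT + nC
    y <- rec$y_events; x <- rec$x_events
    z <- cl[["t1m"]] + cl[["t0m"]] + cl[["c1m"]] + cl[["c0m"]]
    li_m <- numeric(n_nodes)
    for (m in seq_len(n_nodes)) {
      ez <- stats::plogis(ze_n[m])
      # eta nodes depend on both xi and zeta through the regression
      eta_kl <- outer(p$beta0 + p$beta1 * xi_n + p$beta2 * ze_n[m],
                      sqrt(p$tau2) * zk, `+`)
      eh <- stats::plogis(eta_kl)
      if (mode == "pseudo") {
        lobs_T <- stats::dbinom(y, nT, eh, log = TRUE)
        lz <- stats::dbinom(z, ni, ez, log = TRUE)
        lx <- stats::dbinom(x, nC, stats::plogis(xi_n), log = TRUE)
      } else {
        lobs_T <- lmultinom4(cl[c("t1m", "t1f", "t0m", "t0f")], eh, ez)
        lx <- vapply(stats::plogis(xi_n), function(ex)
          sum(lmultinom4(cl[c("c1m", "c1f", "c0m", "c0f")], ex, ez)),
          numeric(1))
        lz <- 0
      }
      inner <- apply(matrix(lobs_T, n_nodes, n_nodes) +
                     rep(lw, each = n_nodes), 1, logsumexp)
      li_m[m] <- lw[m] + lz + logsumexp(lw + lx + inner)
    }
    ll <- ll + logsumexp(li_m)
  }
  -ll
}

# log multinomial pmf of the 4 cells (event x trait) under independence
# completion: p11 = pe*pt, p10 = pe*(1-pt), p01 = (1-pe)*pt, p00 = rest.
# cells ordered (event&trait, event&no, nonevent&trait, nonevent&no);
# pe may be a vector/matrix, pt scalar.
lmultinom4 <- function(cells, pe, pt) {
  n <- sum(cells)
  lcoef <- lgamma(n + 1) - sum(lgamma(cells + 1))
  lcoef + cells[1] * (log(pe) + log(pt)) +
    cells[2] * (log(pe) + log1p(-pt)) +
    cells[3] * (log1p(-pe) + log(pt)) +
    cells[4] * (log1p(-pe) + log1p(-pt))
}

#' Exact pseudo-likelihood with a mean-value covariate
#'
#' Negative log pseudo-likelihood when the covariate is the mean of an
#' individual-level measurement summarised by event-by-arm subgroup means.
#' Conditionally on the latents, the event counts are binomial and each
#' arm's pair of subgroup means is bivariate normal around the latent
#' covariate with variances `sd^2 / count` and the supplied within-study
#' correlations; the factors are treated as independent (working
#' independence) and the triple latent integral is computed on a 3-D
#' Gauss-Hermite grid.
#'
#' @inheritParams neg_loglik_exact_multinomial
#' @param data study records with mean-layout subgroup tables.
#' @param rho_t,rho_c within-study correlations between the event and
#'   non-event subgroup means, per study (recycled); must lie in (-1, 1).
#'   They are treated as known inputs, 0 by default.
#' @return Negative log pseudo-likelihood.
#' @export
neg_loglik_exact_meancov <- function(params, data, rho_t = 0, rho_c = 0,
                                     n_nodes = 10) {
  p <- as.list(params)
  if (p$tau2 <= 0 || p$sigma_xi2 <= 0 || p$sigma_zeta2 <= 0)
    stop("exact likelihood requires positive variance components")
  if (any(abs(rho_t) >= 1) || any(abs(rho_c) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  sg <- subgroups_from(data, "mean")
  nstud <- length(sg$records)
  rho_t <- rep_len(rho_t, nstud); rho_c <- rep_len(rho_c, nstud)
  gh <- gauss_hermite_rule(n_nodes)
  zk <- gh$nodes; lw <- log(gh$weights)
  xi_n <- p$mu_xi + sqrt(p$sigma_xi2) * zk
  ze_n <- p$mu_zeta + sqrt(p$sigma_zeta2) * zk
  ll <- 0
  for (i in seq_len(nstud)) {
    rec <- sg$records[[i]]; tab <- rec$subgroup
    y <- rec$y_events; x <- rec$x_events
    nT <- rec$n_treat; nC <- rec$n_control
    if (y <= 0 || y >= nT || x <= 0 || x >= nC)
      stop(sprintf("study '%s': subgroup-mean likelihood needs 0 < events < size",
                   rec$study))
    m <- tab$means; sd <- tab$sd
    lt <- dbvn_log(m[["t1"]], m[["t0"]], ze_n, sd / sqrt(y),
                   sd / sqrt(nT - y), rho_t[i])
    lc <- dbvn_log(m[["c1"]], m[["c0"]], ze_n, sd / sqrt(x),
                   sd / sqrt(nC - x), rho_c[i])
    li_m <- numeric(n_nodes)
    for (mm in seq_len(n_nodes)) {
      eta_kl <- outer(p$beta0 + p$beta1 * xi_n + p$beta2 * ze_n[mm],
                      sqrt(p$tau2) * zk, `+`)
      ly <- matrix(stats::dbinom(y, nT, stats::plogis(eta_kl), log = TRUE),
                   n_nodes, n_nodes)
      inner <- apply(ly + rep(lw, each = n_nodes), 1, logsumexp)
      lx <- stats::dbinom(x, nC, stats::plogis(xi_n), log = TRUE)
      li_m[mm] <- lw[mm] + lt[mm] + lc[mm] + logsumexp(lw + lx + inner)
    }
    ll <- ll + logsumexp(li_m)
  }
  -ll
}

# log bivariate normal density of (a, b) with common mean mu (vectorised over
# mu), sds s1, s2 and correlation rho
dbvn_log <- function(a, b, mu, s1, s2, rho) {
  z1 <- (a - mu) / s1; z2 <- (b - mu) / s2
  -log(2 * pi) - log(s1 * s2) - 0.5 * log1p(-rho^2) -
    (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2))
}
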