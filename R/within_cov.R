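#' Taylor within-study covariances for a binary-trait subgroup table
#'
#' First-order Taylor approximation of the sampling covariance between each
#' observed risk log odds and the observed trait log odds, induced by the
#' shared subjects.  Writing `Z` for the total trait count over both arms and
#' `n` for the total study size,
#' \deqn{s_{\eta\zeta} \approx \frac{1}{Z}\Big(\frac{Z_{T1M}}{Y} -
#'   \frac{Z_{T0M}}{n_T - Y}\Big) - \frac{1}{n - Z}\Big(\frac{Z_{T1F}}{Y} -
#'   \frac{Z_{T0F}}{n_T - Y}\Big)}
#' and analogously for the control arm.
#'
#' @param table a binary-layout [subgroup_binary()] table.
#' @return List with `s_eta_zeta` and `s_xi_zeta`.
#' @examples
#' tab <- subgroup_binary(30, 20, 25, 25, 10, 10, 40, 40)
#' taylor_cov_binary(tab)
#' @export
taylor_cov_binary <- function(table) {
  stopifnot(inherits(table, "subgroup_table"), table$layout == "binary")
  cl <- table$cells
  y  <- cl[["t1m"]] + cl[["t1f"]]
  ny <- cl[["t0m"]] + cl[["t0f"]]
  x  <- cl[["c1m"]] + cl[["c1f"]]
  nx <- cl[["c0m"]] + cl[["c0f"]]
  z  <- cl[["t1m"]] + cl[["t0m"]] + cl[["c1m"]] + cl[["c0m"]]
  n  <- sum(cl)
  margins <- c(events_treat = y, nonevents_treat = ny,
               events_control = x, nonevents_control = nx,
               trait = z, no_trait = n - z)
  if (any(margins == 0))
    stop(sprintf("zero margin '%s' in subgroup table",
                 names(margins)[margins == 0][1]))
  list(
    s_eta_zeta = (cl[["t1m"]] / y - cl[["t0m"]] / ny) / z -
                 (cl[["t1f"]] / y - cl[["t0f"]] / ny) / (n - z),
    s_xi_zeta  = (cl[["c1m"]] / x - cl[["c0m"]] / nx) / z -
                 (cl[["c1f"]] / x - cl[["c0f"]] / nx) / (n - z))
}

#' Taylor within-study covariances for a mean-value subgroup table
#'
#' For a covariate reported as subgroup means, the first-order approximation
#' is simply the contrast of the event and non-event means in the
#' corresponding arm divided by the total study size:
#' `s_eta_zeta = (Z_T1 - Z_T0)/n`, `s_xi_zeta = (Z_C1 - Z_C0)/n`.
#'
#' @param table a mean-layout [subgroup_means()] table.
#' @param y_events,n_treat,x_events,n_control the study's counts.
#' @return List with `s_eta_zeta` and `s_xi_zeta`.
#' @export
taylor_cov_mean <- function(table, y_events, n_treat, x_events, n_control) {
  stopifnot(inherits(table, "subgroup_table"), table$layout == "mean")
  n <- n_treat + n_control
  if (n <= 0) stop("total study size must be positive")
  m <- table$means
  list(s_eta_zeta = (m[["t1"]] - m[["t0"]]) / n,
       s_xi_zeta  = (m[["c1"]] - m[["c0"]]) / n)
}

#' Monte-Carlo oracle for the Taylor within-study covariances
#'
#' Validates the first-order Taylor covariances by resampling the subgroup
#' data with the latent quantities held at their plug-in estimates.  For the
#' binary layout, the eight cells are redrawn from the two multinomial
#' distributions with probabilities equal to the observed cell proportions.
#' For the mean layout, the event counts are redrawn binomially at the
#' observed event rates and the subgroup means normally around the observed
#' means (independent subgroups), and the observed measures are recomputed
#' for every draw.
#'
#' @param table a [subgroup_binary()] or [subgroup_means()] table.
#' @param y_events,n_treat,x_events,n_control counts (mean layout only;
#'   ignored for the binary layout, whose counts are implied by the cells).
#' @param reps number of Monte-Carlo replicates (>= 1e4).
#' @param seed RNG seed.
#' @return List with `s_eta_zeta`, `s_xi_zeta` and the Monte-Carlo standard
#'   errors `mc_se_eta`, `mc_se_xi` of the two covariance estimates.
#' @export
monte_carlo_cov_oracle <- function(table, y_events = NULL, n_treat = NULL,
                                   x_events = NULL, n_control = NULL,
                                   reps = 1e4, seed = 1) {
  stopifnot(inherits(table, "subgroup_table"), reps >= 1e4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (table$layout == "binary") {
    cl <- table$cells
    nT <- sum(cl[1:4]); nC <- sum(cl[5:8]); n <- nT + nC
    tt <- stats::rmultinom(reps, nT, cl[1:4] / nT)
    cc <- stats::rmultinom(reps, nC, cl[5:8] / nC)
    y <- tt[1, ] + tt[2, ]; x <- cc[1, ] + cc[2, ]
    z <- tt[1, ] + tt[3, ] + cc[1, ] + cc[3, ]
    eta <- log_odds_with_var(y, nT)$estimate
    xi <- log_odds_with_var(x, nC)$estimate
    zeta <- log_odds_with_var(z, n)$estimate
  } else {
    stopifnot(!is.null(y_events))
    n <- n_treat + n_control
    y <- stats::rbinom(reps, n_treat, y_events / n_treat)
    x <- stats::rbinom(reps, n_control, x_events / n_control)
    m <- table$means; sd <- table$sd
    t1 <- stats::rnorm(reps, m[["t1"]], sd / sqrt(pmax(y, 0.5)))
    t0 <- stats::rnorm(reps, m[["t0"]], sd / sqrt(pmax(n_treat - y, 0.5)))
    c1 <- stats::rnorm(reps, m[["c1"]], sd / sqrt(pmax(x, 0.5)))
    c0 <- stats::rnorm(reps, m[["c0"]], sd / sqrt(pmax(n_control - x, 0.5)))
    eta <- log_odds_with_var(y, n_treat)$estimate
    xi <- log_odds_with_var(x, n_control)$estimate
    zeta <- (y * t1 + (n_treat - y) * t0 + x * c1 + (n_control - x) * c0) / n
  }
  cov_se <- function(a, b) {
    prod <- (a - mean(a)) * (b - mean(b))
    c(cov = mean(prod), se = stats::sd(prod) / sqrt(reps))
  }
  ez <- cov_se(eta, zeta); xz <- cov_se(xi, zeta)
  list(s_eta_zeta = ez[["cov"]], s_xi_zeta = xz[["cov"]],
       mc_se_eta = ez[["se"]], mc_se_xi = xz[["se"]])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
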