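#' Log odds and its sampling variance from a count
#'
#' Converts events out of a total into the observed log odds
#' `log(k / (n - k))` with large-sample variance `1/k + 1/(n - k)`.  A
#' continuity correction `c` is added to both cells, either never
#' (`continuity = 0`), only when a cell is empty, or always, depending on
#' `apply`.
#'
#' @param events,total event count and denominator (vectorised).
#' @param continuity correction added to each cell (default 0.5).
#' @param apply when to add the correction: `"only_zero"` (default) adds it
#'   only to studies with an empty cell, `"always"` adds it everywhere,
#'   `"never"` disables it.
#' @return A list with components `estimate` and `variance`.
#' @examples
#' log_odds_with_var(20, 984, apply = "never")   # -3.8754, 0.05104
#' @export
log_odds_with_var <- function(events, total, continuity = 0.5,
                              apply = c("only_zero", "always", "never")) {
  apply <- match.arg(apply)
  if (any(events < 0) || any(total <= 0) || any(events > total))
    stop("need 0 <= events <= total with total > 0")
  cc <- switch(apply,
    never = rep(0, length(events)),
    always = rep(continuity, length(events)),
    only_zero = ifelse(events == 0 | events == total, continuity, 0))
  bad <- (events == 0 | events == total) & cc == 0
  if (any(bad))
    stop(sprintf("empty cell at position %d and no continuity correction",
                 which(bad)[1]))
  k <- events + cc
  m <- total - events + cc
  list(estimate = log(k / m), variance = 1 / k + 1 / m)
}

#' Observed log-odds covariate from a trait count
#'
#' For a binary trait counted over the whole study (both arms pooled), the
#' observed covariate is `log(z / (n - z))` with variance `1/z + 1/(n - z)`.
#'
#' @inheritParams log_odds_with_var
#' @param count trait count; `total` the study size the count refers to.
#' @return A list with `zeta_hat` and `s_zeta2`.
#' @export
covariate_log_odds <- function(count, total, continuity = 0.5,
                               apply = c("only_zero", "always", "never")) {
  lo <- log_odds_with_var(count, total, continuity, match.arg(apply))
  list(zeta_hat = lo$estimate, s_zeta2 = lo$variance)
}

#' Observed mean-value covariate from subgroup means
#'
#' Pools the four subgroup means into the study-level mean, weighting by the
#' subgroup sizes implied by the event counts, and returns the sampling
#' variance `sd^2 / n` of that mean.
#'
#' @param t1,t0,c1,c0 subgroup means (treatment/control by event status).
#' @param y_events,n_treat,x_events,n_control the study's counts.
#' @param sd within-study standard deviation of the individual measurements.
#' @return A list with `zeta_hat` and `s_zeta2`.
#' @export
covariate_mean <- function(t1, t0, c1, c0, y_events, n_treat,
                           x_events, n_control, sd) {
  if (any(sd <= 0)) stop("'sd' must be positive")
  n <- n_treat + n_control
  zeta <- (y_events * t1 + (n_treat - y_events) * t0 +
           x_events * c1 + (n_control - x_events) * c0) / n
  list(zeta_hat = zeta, s_zeta2 = sd^2 / n)
}

#' Centre and scale an observed covariate
#'
#' Standardises the observed covariate values by their unweighted sample mean
#' and sample standard deviation; the within-study variances are divided by
#' the sample variance so the affine transformation propagates exactly.
#'
#' @param zeta_hat observed covariate values.
#' @param s_zeta2 their within-study variances.
#' @return List with `zeta_hat`, `s_zeta2`, and the `center` and `scale` used.
#' @export
standardize_covariate <- function(zeta_hat, s_zeta2) {
  ctr <- mean(zeta_hat)
  scl <- stats::sd(zeta_hat)
  if (scl == 0) stop("covariate is constant; cannot standardize")
  list(zeta_hat = (zeta_hat - ctr) / scl, s_zeta2 = s_zeta2 / scl^2,
       center = ctr, scale = scl)
}

#' Assemble observed risk measures and covariates from study records
#'
#' Computes, for every study, the observed treatment and control log odds
#' with their variances, the observed covariate (according to its kind) with
#' its variance, and -- when a subgroup table is present -- the first-order
#' Taylor within-study covariances between the risk measures and the
#' covariate.  Assembled per-study covariance matrices that fail positive
#' semidefiniteness have their off-diagonal entries shrunk toward zero (with
#' a warning).
#'
#' @param records list of [study_record()] objects.
#' @param continuity,apply continuity-correction policy passed to
#'   [log_odds_with_var()].
#' @param standardize if `TRUE`, the observed covariate is centred and scaled
#'   by its sample moments (see [standardize_covariate()]).
#' @return A data frame of class `"crr_data"` with one row per study and
#'   columns `study`, `y`, `n_treat`, `x`, `n_control`, `eta`, `s_eta2`,
#'   `xi`, `s_xi2` and, when a covariate is present, `zeta`, `s_zeta2`,
#'   `s_eta_zeta`, `s_xi_zeta`.  The original records are kept in the
#'   `"records"` attribute for the exact-likelihood fits.
#' @examples
#' recs <- covid_schizophrenia()
#' head(assemble_observed(recs, apply = "never"))
#' @export
assemble_observed <- function(records, continuity = 0.5,
                              apply = c("only_zero", "always", "never"),
                              standardize = FALSE) {
  apply <- match.arg(apply)
  if (inherits(records, "study_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  lapply(records, validate_study)

  n <- length(records)
  get <- function(f) vapply(records, function(r) r[[f]], numeric(1))
  y <- get("y_events"); nT <- get("n_treat")
  x <- get("x_events"); nC <- get("n_control")
  lo_t <- log_odds_with_var(y, nT, continuity, apply)
  lo_c <- log_odds_with_var(x, nC, continuity, apply)

  d <- data.frame(study = vapply(records, `[[`, character(1), "study"),
                  y = y, n_treat = nT, x = x, n_control = nC,
                  eta = lo_t$estimate, s_eta2 = lo_t$variance,
                  xi = lo_c$estimate, s_xi2 = lo_c$variance,
                  stringsAsFactors = FALSE)

  has_cov <- vapply(records, function(r) !is.null(r$covariate), logical(1))
  if (any(has_cov)) {
    if (!all(has_cov))
      stop("covariate must be present for all studies or none")
    kinds <- vapply(records, function(r) r$covariate$kind, character(1))
    if (length(unique(kinds)) != 1L)
      stop("all studies must share the same covariate kind")
    kind <- kinds[1]
    zeta <- numeric(n); sz2 <- numeric(n)
    for (i in seq_len(n)) {
      cv <- records[[i]]$covariate
      obs <- switch(kind,
        error_free = list(zeta_hat = cv$value, s_zeta2 = 0),
        log_odds = covariate_log_odds(cv$count, cv$total, continuity, apply),
        mean_value = list(zeta_hat = cv$mean,
                          s_zeta2 = cv$sd^2 / (nT[i] + nC[i])))
      zeta[i] <- obs$zeta_hat; sz2[i] <- obs$s_zeta2
    }
    if (standardize) {
      st <- standardize_covariate(zeta, sz2)
      zeta <- st$zeta_hat; sz2 <- st$s_zeta2
      attr(d, "standardization") <- st[c("center", "scale")]
    }
    d$zeta <- zeta; d$s_zeta2 <- sz2
    d$s_eta_zeta <- 0; d$s_xi_zeta <- 0
    for (i in seq_len(n)) {
      tab <- records[[i]]$subgroup
      if (is.null(tab)) next
      cv <- if (tab$layout == "binary") taylor_cov_binary(tab)
            else taylor_cov_mean(tab, y[i], nT[i], x[i], nC[i])
      if (standardize) {
        cv$s_eta_zeta <- cv$s_eta_zeta / attr(d, "standardization")$scale
        cv$s_xi_zeta <- cv$s_xi_zeta / attr(d, "standardization")$scale
      }
      d$s_eta_zeta[i] <- cv$s_eta_zeta
      d$s_xi_zeta[i] <- cv$s_xi_zeta
    }
    shr <- psd_shrink_factors(d)
    if (any(shr < 1)) {
      warning(sprintf(
        "within-study covariance matrix not PSD for %d study(ies); off-diagonals shrunk",
        sum(shr < 1)))
      d$s_eta_zeta <- d$s_eta_zeta * shr
      d$s_xi_zeta <- d$s_xi_zeta * shr
    }
  }
  class(d) <- c("crr_data", "data.frame")
  attr(d, "records") <- records
  d
}

#' Per-study observed triple with its covariance matrix
#'
#' The per-study view of [assemble_observed()]: the observed measures
#' (treatment log odds, control log odds and, if present, covariate) and the
#' within-study covariance matrix.  The (1,2) entry is zero because the two
#' arms involve distinct subjects.
#'
#' @param data a `"crr_data"` data frame.
#' @param i study index.
#' @return List with `obs` (length 2 or 3 named vector) and `gamma`
#'   (symmetric covariance matrix of matching dimension).
#' @export
observed_triple <- function(data, i) {
  stopifnot(inherits(data, "crr_data"), i >= 1, i <= nrow(data))
  r <- data[i, ]
  if (is.null(data$zeta) || is.na(r$zeta)) {
    list(obs = c(eta = r$eta, xi = r$xi),
         gamma = diag(c(r$s_eta2, r$s_xi2)))
  } else {
    g <- matrix(c(r$s_eta2, 0, r$s_eta_zeta,
                  0, r$s_xi2, r$s_xi_zeta,
                  r$s_eta_zeta, r$s_xi_zeta, r$s_zeta2), 3, 3)
    list(obs = c(eta = r$eta, xi = r$xi, zeta = r$zeta), gamma = g)
  }
}

# Largest factor c in [0,1] per study such that scaling both risk-covariate
# covariances by c makes Gamma_i PSD.  With the fixed zero (1,2) entry, PSD
# reduces to rho1^2 + rho2^2 <= 1 for the two standardized covariances.
psd_shrink_factors <- function(d) {
  if (is.null(d$s_zeta2)) return(rep(1, nrow(d)))
  r2 <- ifelse(d$s_zeta2 > 0,
               d$s_eta_zeta^2 / (d$s_eta2 * d$s_zeta2) +
               d$s_xi_zeta^2 / (d$s_xi2 * d$s_zeta2), 0)
  ifelse(r2 > 1, sqrt((1 - 1e-9) / r2), 1)
}
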