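#' Study-level covariate summary
#'
#' Describes the one additional study-level covariate attached to a study:
#' either an error-free scalar (e.g. a study-level design feature), the count
#' of a binary trait out of a total (so that the covariate enters the model as
#' a log odds), or a reported mean with its within-study standard deviation
#' (mean-value covariate).
#'
#' @param kind one of `"error_free"`, `"log_odds"`, `"mean_value"`.
#' @param value the scalar covariate value (required for `"error_free"`).
#' @param count,total trait count and denominator (required for `"log_odds"`).
#' @param mean,sd reported mean and within-study standard deviation of the
#'   individual-level measurements (required for `"mean_value"`).
#'
#' @return An object of class `"covariate_summary"`.
#' @examples
#' covariate_summary("log_odds", count = 25, total = 100)
#' covariate_summary("mean_value", mean = 51.5, sd = 15.4)
#' @export
covariate_summary <- function(kind = c("error_free", "log_odds", "mean_value"),
                              value = NULL, count = NULL, total = NULL,
                              mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    error_free = {
      if (is.null(value) || !is.finite(value))
        stop("error_free covariate requires a finite 'value'")
      list(kind = kind, value = as.numeric(value))
    },
    log_odds = {
      if (is.null(count) || is.null(total))
        stop("log_odds covariate requires 'count' and 'total'")
      if (count < 0 || total <= 0 || count > total)
        stop("log_odds covariate needs 0 <= count <= total, total > 0")
      list(kind = kind, count = as.numeric(count), total = as.numeric(total))
    },
    mean_value = {
      if (is.null(mean) || is.null(sd))
        stop("mean_value covariate requires 'mean' and 'sd'")
      if (!is.finite(sd) || sd <= 0) stop("'sd' must be positive")
      list(kind = kind, mean = as.numeric(mean), sd = as.numeric(sd))
    })
  structure(out, class = "covariate_summary")
}

#' Subgroup summary table for a binary trait
#'
#' Eight cell counts cross-classifying each arm (treatment/control) by event
#' status (event/non-event) and the binary trait (say male/female).  Cell
#' `t1m` is the number of treated subjects with the event who carry the trait,
#' and so on.  Row margins must reproduce the study's event counts: the
#' treatment events equal `t1m + t1f` and the control events `c1m + c1f`.
#'
#' @param t1m,t1f,t0m,t0f treatment-arm cells (event/non-event by trait).
#' @param c1m,c1f,c0m,c0f control-arm cells.
#' @return An object of class `"subgroup_table"`, layout `"binary"`.
#' @export
subgroup_binary <- function(t1m, t1f, t0m, t0f, c1m, c1f, c0m, c0f) {
  cells <- c(t1m = t1m, t1f = t1f, t0m = t0m, t0f = t0f,
             c1m = c1m, c1f = c1f, c0m = c0m, c0f = c0f)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("subgroup cells must be nonnegative integers")
  structure(list(layout = "binary", cells = cells), class = "subgroup_table")
}

#' Subgroup summary table of means
#'
#' Mean of an individual-level covariate (e.g. age) within each of the four
#' event-by-arm subgroups, together with the common within-study standard
#' deviation of the individual measurements.
#'
#' @param t1,t0 mean in treated subjects with/without the event.
#' @param c1,c0 mean in controls with/without the event.
#' @param sd within-study standard deviation (> 0).
#' @return An object of class `"subgroup_table"`, layout `"mean"`.
#' @export
subgroup_means <- function(t1, t0, c1, c0, sd) {
  means <- c(t1 = t1, t0 = t0, c1 = c1, c0 = c0)
  if (any(!is.finite(means))) stop("subgroup means must be finite")
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be positive")
  structure(list(layout = "mean", means = means, sd = sd),
            class = "subgroup_table")
}

#' One study's aggregated data
#'
#' Event counts and group sizes for the treatment and control arms, plus an
#' optional covariate summary and optional subgroup table.
#'
#' @param study study label.
#' @param y_events,n_treat events and size of the treatment arm.
#' @param x_events,n_control events and size of the control arm.
#' @param covariate optional [covariate_summary()].
#' @param subgroup optional [subgroup_binary()] or [subgroup_means()] table.
#' @return A validated object of class `"study_record"`.
#' @examples
#' study_record("Barcella", y_events = 20, n_treat = 984,
#'              x_events = 632, n_control = 127281)
#' @export
study_record <- function(study, y_events, n_treat, x_events, n_control,
                         covariate = NULL, subgroup = NULL) {
  rec <- structure(list(study = as.character(study),
                        y_events = as.numeric(y_events),
                        n_treat = as.numeric(n_treat),
                        x_events = as.numeric(x_events),
                        n_control = as.numeric(n_control),
                        covariate = covariate, subgroup = subgroup),
                   class = "study_record")
  validate_study(rec)
}

#' Validate a study record
#'
#' Checks count invariants (nonnegative events not exceeding their group
#' sizes) and, when a binary subgroup table is present, that its margins
#' reproduce the arm-level event counts.
#'
#' @param record a `"study_record"`.
#' @return The record, unchanged, if valid; otherwise an error naming the
#'   study and the violated constraint.
#' @export
validate_study <- function(record) {
  stopifnot(inherits(record, "study_record"))
  who <- record$study
  with(record, {
    if (n_treat <= 0 || n_control <= 0)
      stop(sprintf("study '%s': group sizes must be positive", who))
    if (y_events < 0 || x_events < 0)
      stop(sprintf("study '%s': negative event count", who))
    if (y_events > n_treat)
      stop(sprintf("study '%s': treatment events exceed group size", who))
    if (x_events > n_control)
      stop(sprintf("study '%s': control events exceed group size", who))
  })
  if (!is.null(record$covariate) &&
      !inherits(record$covariate, "covariate_summary"))
    stop(sprintf("study '%s': 'covariate' is not a covariate_summary", who))
  if (!is.null(record$subgroup)) {
    tab <- record$subgroup
    if (!inherits(tab, "subgroup_table"))
      stop(sprintf("study '%s': 'subgroup' is not a subgroup_table", who))
    if (tab$layout == "binary") {
      cl <- tab$cells
      if (cl[["t1m"]] + cl[["t1f"]] != record$y_events)
        stop(sprintf(
          "study '%s': treatment subgroup cells sum to %d, not y_events = %d",
          who, cl[["t1m"]] + cl[["t1f"]], record$y_events))
      if (cl[["c1m"]] + cl[["c1f"]] != record$x_events)
        stop(sprintf(
          "study '%s': control subgroup cells sum to %d, not x_events = %d",
          who, cl[["c1m"]] + cl[["c1f"]], record$x_events))
      if (cl[["t0m"]] + cl[["t0f"]] != record$n_treat - record$y_events)
        stop(sprintf("study '%s': treatment non-event cells inconsistent", who))
      if (cl[["c0m"]] + cl[["c0f"]] != record$n_control - record$x_events)
        stop(sprintf("study '%s': control non-event cells inconsistent", who))
    }
  }
  record
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("study '%s': %g/%g events (treatment), %g/%g (control)\n",
              x$study, x$y_events, x$n_treat, x$x_events, x$n_control))
  if (!is.null(x$covariate))
    cat(sprintf("  covariate: %s\n", x$covariate$kind))
  if (!is.null(x$subgroup))
    cat(sprintf("  subgroup table: %s layout\n", x$subgroup$layout))
  invisible(x)
}

#' Model parameters for the (pseudo-)likelihood fits
#'
#' A named numeric vector holding the regression coefficients, latent means
#' and variance components.  `beta2`, `mu_zeta`, `sigma_zeta2` and
#' `sigma_xizeta` are only present when the model carries an error-prone
#' covariate; `sigma_xizeta` is the covariance between the latent baseline
#' risk and the latent covariate.
#'
#' @param beta0,beta1 intercept and slope on the latent baseline risk.
#' @param beta2 slope on the additional covariate (or `NULL`).
#' @param mu_xi,mu_zeta latent means.
#' @param tau2 residual between-study variance (>= 0).
#' @param sigma_xi2,sigma_zeta2 latent variances (>= 0).
#' @param sigma_xizeta latent covariance; the implied 2x2 latent covariance
#'   matrix must be positive semidefinite.
#' @return Named numeric vector of class `"model_params"`.
#' @export
model_params <- function(beta0, beta1, beta2 = NULL, mu_xi,
                         mu_zeta = NULL, tau2, sigma_xi2,
                         sigma_zeta2 = NULL, sigma_xizeta = NULL) {
  th <- c(beta0 = beta0, beta1 = beta1)
  if (!is.null(beta2)) th <- c(th, beta2 = beta2)
  th <- c(th, mu_xi = mu_xi)
  if (!is.null(mu_zeta)) th <- c(th, mu_zeta = mu_zeta)
  th <- c(th, tau2 = tau2, sigma_xi2 = sigma_xi2)
  if (!is.null(sigma_zeta2)) th <- c(th, sigma_zeta2 = sigma_zeta2)
  if (!is.null(sigma_xizeta)) th <- c(th, sigma_xizeta = sigma_xizeta)
  if (th[["tau2"]] < 0 || th[["sigma_xi2"]] < 0)
    stop("variance components must be nonnegative")
  if (!is.null(sigma_zeta2)) {
    if (sigma_zeta2 < 0) stop("sigma_zeta2 must be nonnegative")
    sxz <- if (is.null(sigma_xizeta)) 0 else sigma_xizeta
    if (sxz^2 > th[["sigma_xi2"]] * sigma_zeta2 + 1e-12)
      stop("latent covariance matrix not positive semidefinite")
  }
  structure(th, class = "model_params")
}
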