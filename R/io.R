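#' Read study-level meta-analysis data from CSV
#'
#' One row per study with required columns `study`, `y_events`, `n_treat`,
#' `x_events`, `n_control`.  An optional covariate is declared through
#' `z_kind` (`error_free`, `log_odds` or `mean_value`) with its companion
#' columns: `z_value` (error-free), `z_count` and `z_total` (log odds), or
#' `z_value` and `z_sd` (mean value).  Optional subgroup columns are either
#' the eight binary-layout cells `zt1m, zt1f, zt0m, zt0f, zc1m, zc1f, zc0m,
#' zc0f` or the four mean-layout columns `zt1, zt0, zc1, zc0` together with
#' `z_sd`.
#'
#' @param path CSV file path.
#' @return List of validated [study_record()] objects.
#' @export
read_meta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "y_events", "n_treat", "x_events", "n_control")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no studies in ", path)
  bin_cols <- c("zt1m", "zt1f", "zt0m", "zt0f", "zc1m", "zc1f", "zc0m", "zc0f")
  mean_cols <- c("zt1", "zt0", "zc1", "zc0")
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    wrap <- function(expr) tryCatch(expr, error = function(e)
      stop(sprintf("row %d (%s): %s", i, row$study, conditionMessage(e)),
           call. = FALSE))
    cv <- NULL
    if ("z_kind" %in% names(df) && nzchar(row$z_kind) && !is.na(row$z_kind)) {
      cv <- wrap(switch(row$z_kind,
        error_free = covariate_summary("error_free", value = row$z_value),
        log_odds = covariate_summary("log_odds", count = row$z_count,
                                     total = row$z_total),
        mean_value = covariate_summary("mean_value", mean = row$z_value,
                                       sd = row$z_sd),
        stop("unknown z_kind '", row$z_kind, "'")))
    }
    sg <- NULL
    if (all(bin_cols %in% names(df)) && !anyNA(row[bin_cols])) {
      sg <- wrap(do.call(subgroup_binary, as.list(as.numeric(row[bin_cols]))))
    } else if (all(mean_cols %in% names(df)) && !anyNA(row[mean_cols])) {
      if (!"z_sd" %in% names(df))
        stop(sprintf("row %d: mean-layout subgroup columns need 'z_sd'", i))
      sg <- wrap(subgroup_means(row$zt1, row$zt0, row$zc1, row$zc0, row$z_sd))
    }
    wrap(study_record(row$study, row$y_events, row$n_treat, row$x_events,
                      row$n_control, covariate = cv, subgroup = sg))
  })
}

#' The schizophrenia / COVID-19 mortality meta-analysis
#'
#' Ten studies comparing COVID-19 mortality between patients with and
#' without schizophrenia: deaths and totals per arm, plus the mean age (with
#' SD), the percentage of male patients and the percentage of diabetic
#' patients, as reported by the original meta-analysis.  Percentages are
#' converted to trait counts by rounding `pct * n / 100` over the total
#' study size before the log-odds transformation; the mean age covariate
#' carries the reported mean and SD.
#'
#' @param covariate which covariate to attach: `"none"`, `"age"`
#'   (mean value), `"male"` or `"diabetes"` (log odds of the trait).
#' @return List of [study_record()] objects.
#' @examples
#' length(covid_schizophrenia())        # 10 studies
#' covid_schizophrenia("age")[[2]]$covariate$mean   # 51.5
#' @export
covid_schizophrenia <- function(covariate = c("none", "age", "male",
                                              "diabetes")) {
  covariate <- match.arg(covariate)
  path <- system.file("extdata", "schizophrenia_covid.csv",
                      package = "crrme", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ni <- row$n_treat + row$n_control
    cv <- switch(covariate,
      none = NULL,
      age = covariate_summary("mean_value", mean = row$mean_age,
                              sd = row$sd_age),
      male = covariate_summary("log_odds",
                               count = round(row$pct_male * ni / 100),
                               total = ni),
      diabetes = covariate_summary("log_odds",
                                   count = round(row$pct_diabetes * ni / 100),
                                   total = ni))
    study_record(row$study, row$y_events, row$n_treat, row$x_events,
                 row$n_control, covariate = cv)
  })
}

#' Serialize a fit to JSON-ready structures
#'
#' @param fit a `"crr_fit"`.
#' @return A plain list (parameters, standard errors, convergence metadata)
#'   suitable for `jsonlite::toJSON()`.
#' @export
fit_as_list <- function(fit) {
  stopifnot(inherits(fit, "crr_fit"))
  list(method = fit$method, error_model = fit$error_model,
       n_studies = fit$n_studies, converged = fit$converged,
       loglik = fit$loglik, estimates = as.list(fit$params),
       se_hessian = as.list(fit$se_hessian),
       se_sandwich = if (!is.null(fit$se_sandwich))
         as.list(fit$se_sandwich))
}
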