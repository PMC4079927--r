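# Univariate paired host-parameter testing with log-transform heuristic and
# residual-based outlier removal.

fit_blocked <- function(d) {
  # two-time-point subject-blocked ANOVA, equivalent to a paired comparison
  stats::lm(value ~ subject + time, data = d)
}

test_one_parameter <- function(d, alpha, hetero_threshold, allow_log) {
  # d: tibble(subject, time ("t0"/"t29"), value), complete pairs only
  transform_used <- "none"
  outliers <- character()

  if (all(d$value[d$time == "t29"] == d$value[d$time == "t0"])) {
    return(list(p_value = 1, direction = "none", transform_used = transform_used,
                outliers_removed = outliers, note = "no_change"))
  }

  fit <- fit_blocked(d)
  res <- stats::residuals(fit)
  fv <- stats::fitted(fit)

  # residual spread growing with the fitted value signals a multiplicative
  # error structure; refit on the natural log of the original data
  if (allow_log && stats::sd(res) > 0 && stats::sd(fv) > 0) {
    sp <- suppressWarnings(stats::cor(abs(res), fv, method = "spearman"))
    if (!is.na(sp) && sp > hetero_threshold && all(d$value > 0)) {
      d$value <- log(d$value)
      transform_used <- "log"
      fit <- fit_blocked(d)
      res <- stats::residuals(fit)
    }
  }

  # 3*sqrt(MSE) rule, applied once: subjects with a gross residual are
  # removed from this parameter's data set and the model refit
  mse <- sum(res^2) / stats::df.residual(fit)
  if (mse > 0) {
    flagged <- unique(as.character(d$subject[abs(res) > 3 * sqrt(mse)]))
    if (length(flagged)) {
      outliers <- flagged
      d <- d[!d$subject %in% flagged, ]
      if (length(unique(d$subject)) < 3) {
        return(list(p_value = NA_real_, direction = NA_character_,
                    transform_used = transform_used, outliers_removed = outliers,
                    note = "too_few_pairs_after_outlier_removal"))
      }
      d$subject <- droplevels(d$subject)
      fit <- fit_blocked(d)
    }
  }

  an <- stats::anova(fit)
  p <- an["time", "Pr(>F)"]
  if (is.nan(p)) p <- 1
  dbar <- mean(d$value[d$time == "t29"]) - mean(d$value[d$time == "t0"])
  list(p_value = p,
       direction = if (dbar > 0) "increase" else if (dbar < 0) "decrease" else "none",
       transform_used = transform_used, outliers_removed = outliers, note = NA_character_)
}

#' Paired test of each host parameter across the intervention
#'
#' Per parameter, fits the two-time-point subject-blocked analysis-of-variance
#' model (equivalent to a paired comparison) on complete pairs. If the
#' residual-vs-fitted plot shows spread increasing with the fitted value
#' (Spearman correlation of |residual| against fitted above
#' `hetero_threshold`, default 0.5) and all values are positive, the original
#' data are natural-log transformed and the model refit. Any subject whose
#' residual exceeds `3 * sqrt(MSE)` is removed as a statistical outlier and
#' the model refit once. The null hypothesis of no intervention effect is
#' assessed two-sided.
#'
#' @param host_t0,host_t29 Host tibbles (first column subject id), matched
#'   subjects.
#' @param alpha Nominal level used for the `significant` flag (default 0.05).
#' @param hetero_threshold Spearman threshold triggering the log transform;
#'   set above 1 to disable the heuristic.
#' @param allow_log Set `FALSE` to disable the log-transform step entirely.
#' @return Tibble with one row per parameter: `parameter`, `n_pairs`,
#'   `transform_used`, `outliers_removed` (comma-separated ids),
#'   `p_value`, `significant`, `direction`, `note`.
#' @export
paired_host_test <- function(host_t0, host_t29, alpha = 0.05,
                             hetero_threshold = 0.5, allow_log = TRUE) {
  pair <- host_parameter_pair(host_t0, host_t29)
  p0 <- tbl_to_matrix(pair$values_t0)
  p29 <- tbl_to_matrix(pair$values_t29)
  subjects <- rownames(p0)

  purrr::map_dfr(colnames(p0), function(pm) {
    ok <- stats::complete.cases(p0[, pm], p29[, pm])
    n_ok <- sum(ok)
    if (n_ok <= 2) {
      return(tibble::tibble(parameter = pm, n_pairs = n_ok, transform_used = NA_character_,
                            outliers_removed = "", p_value = NA_real_,
                            significant = NA, direction = NA_character_,
                            note = "too_few_complete_pairs"))
    }
    d <- tibble::tibble(
      subject = factor(rep(subjects[ok], 2)),
      time = factor(rep(c("t0", "t29"), each = n_ok), levels = c("t0", "t29")),
      value = c(p0[ok, pm], p29[ok, pm])
    )
    r <- test_one_parameter(d, alpha, hetero_threshold, allow_log)
    tibble::tibble(parameter = pm, n_pairs = n_ok, transform_used = r$transform_used,
                   outliers_removed = paste(r$outliers_removed, collapse = ","),
                   p_value = r$p_value,
                   significant = !is.na(r$p_value) & r$p_value < alpha,
                   direction = r$direction, note = r$note)
  })
}
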