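#' Flux control coefficient by log-log regression
#'
#' The flux control coefficient (FCC) of an enzyme is the fractional change
#' in pathway flux per fractional change in that enzyme's activity,
#' C = dlog(J) / dlog(v). Given paired flux and DXS activity measurements
#' across lines with different DXS expression (empty-vector controls
#' combined with silenced and overexpressing lines), the FCC is estimated
#' as the ordinary least-squares slope of log(J) on log(v), optionally per
#' environmental condition. A 95% t-based confidence interval that covers
#' zero sets the `zero_flag`: the control exerted by the enzyme is
#' statistically indistinguishable from none.
#'
#' @param records Data.frame with columns `J` (flux) and `v` (DXS
#'   activity), and, if grouping, `condition`. Optional `sample_id`,
#'   `genotype` are carried for diagnostics.
#' @param group_by_condition Estimate one FCC per `condition` level
#'   (default TRUE when the column is present).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Data.frame `condition, fcc, se, ci_low, ci_high, n, r2,
#'   zero_flag`, one row per group with >= 3 usable records; attribute
#'   `excluded` lists dropped records with reasons.
#' @export
#' @examples
#' d <- data.frame(v = c(1, 2, 4, 8), J = 3 * c(1, 2, 4, 8))
#' fcc_regression(d)  # slope 1: proportional control
fcc_regression <- function(records, group_by_condition = "condition" %in% names(records),
                           conf_level = 0.95) {
  if (!all(c("J", "v") %in% names(records))) {
    stop("records need columns 'J' and 'v'", call. = FALSE)
  }
  bad <- !is.finite(records$J) | !is.finite(records$v) |
    records$J <= 0 | records$v <= 0
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- "non-positive or non-finite J or v (not log-transformable)"
    message(nrow(excluded), " record(s) excluded from FCC regression")
  }
  records <- records[!bad, , drop = FALSE]
  groups <- if (group_by_condition) {
    split(records, records$condition)
  } else {
    list(all = records)
  }
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 3L) {
      message("group '", g, "' has fewer than 3 records; no FCC estimate")
      return(NULL)
    }
    fit <- stats::lm(log(J) ~ log(v), data = d)
    co <- summary(fit)$coefficients
    slope <- co["log(v)", "Estimate"]
    se <- co["log(v)", "Std. Error"]
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
    ci <- slope + c(-1, 1) * tcrit * se
    data.frame(condition = g, fcc = slope, se = se,
               ci_low = ci[1], ci_high = ci[2], n = nrow(d),
               r2 = summary(fit)$r.squared,
               zero_flag = ci[1] <= 0 && ci[2] >= 0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(condition = character(), fcc = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(), n = integer(),
                      r2 = numeric(), zero_flag = logical())
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Pointwise flux control coefficient
#'
#' The defining ratio of fractional changes, C = (dJ/J) / (dv/v), for a
#' single perturbation. The regression estimator [fcc_regression()] is the
#' many-point generalization of this formula in log space.
#'
#' @param dJ Change in flux.
#' @param J Reference flux (nonzero).
#' @param dv Change in enzyme activity (nonzero).
#' @param v Reference activity (nonzero).
#' @return Dimensionless control coefficient.
#' @export
#' @examples
#' pointwise_fcc(dJ = 0.09 * 30, J = 30, dv = 0.5 * 2, v = 2)  # 0.18
pointwise_fcc <- function(dJ, J, dv, v) {
  if (any(c(J, v) == 0)) stop("'J' and 'v' must be nonzero", call. = FALSE)
  if (any(dv == 0)) stop("'dv' must be nonzero (perturbation required)",
                         call. = FALSE)
  (dJ / J) / (dv / v)
}
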