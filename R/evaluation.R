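#' Agreement metrics between estimated and reference respiratory rate
#'
#' Computes, over paired per-window rates, the mean error (ME), the sample
#' standard deviation of the errors (STD, n-1 denominator), the mean
#' absolute error (MAE), the root mean square error (RMSE, n denominator),
#' and the Bland-Altman bias with 1.96 SD limits of agreement. Pairs with
#' a missing value on either side are excluded and counted in
#' `n_excluded`, making window loss visible.
#'
#' @param rr_est,rr_ref Numeric vectors of equal length, breaths/min.
#' @return An `error_summary`: list with `me`, `std`, `mae`, `rmse`, `n`,
#'   `n_excluded`, `ba_bias`, `ba_loa` (lower, upper).
#' @examples
#' error_metrics(c(16, 14, 17), c(15, 15, 15))
#' @export
error_metrics <- function(rr_est, rr_ref) {
  if (length(rr_est) != length(rr_ref))
    rf_data_error("rr_est and rr_ref must have equal length")
  ok <- is.finite(rr_est) & is.finite(rr_ref)
  n_excluded <- sum(!ok)
  d <- rr_est[ok] - rr_ref[ok]
  n <- length(d)
  if (n < 2) rf_data_error("need at least 2 complete pairs, have %d", n)
  me <- mean(d)
  std <- stats::sd(d)
  structure(list(me = me, std = std,
                 mae = mean(abs(d)),
                 rmse = sqrt(mean(d^2)),
                 n = n, n_excluded = n_excluded,
                 ba_bias = me,
                 ba_loa = c(lower = me - 1.96 * std, upper = me + 1.96 * std)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d (%d excluded)\n", x$n, x$n_excluded))
  cat(sprintf("  ME %6.3f  STD %6.3f  MAE %6.3f  RMSE %6.3f breaths/min\n",
              x$me, x$std, x$mae, x$rmse))
  cat(sprintf("  Bland-Altman bias %.3f, LoA [%.3f, %.3f]\n",
              x$ba_bias, x$ba_loa[1], x$ba_loa[2]))
  invisible(x)
}

#' Cohort aggregation of per-record agreement
#'
#' Given per-record pairs of estimated and reference rates, returns the
#' per-record summaries together with a pooled summary over the
#' concatenation of all window pairs. Both conventions are reported
#' because dataset-level figures in the literature rarely state which
#' pooling they use.
#'
#' @param records Named list; each element a list (or data frame) with
#'   fields/columns `rr_est` and `rr_ref`.
#' @return List with `per_record` (named list of `error_summary`) and
#'   `pooled` (one `error_summary` over all pairs).
#' @export
pooled_error_metrics <- function(records) {
  if (length(records) < 1) rf_data_error("need at least one record")
  per <- lapply(records, function(r) error_metrics(r$rr_est, r$rr_ref))
  all_est <- unlist(lapply(records, function(r) r$rr_est), use.names = FALSE)
  all_ref <- unlist(lapply(records, function(r) r$rr_ref), use.names = FALSE)
  list(per_record = per, pooled = error_metrics(all_est, all_ref))
}

#' Bland-Altman plot of estimated versus reference rate
#'
#' @param rr_est,rr_ref Numeric vectors, breaths/min.
#' @param ... Passed to [graphics::plot()].
#' @return The `error_summary`, invisibly.
#' @export
plot_bland_altman <- function(rr_est, rr_ref, ...) {
  es <- error_metrics(rr_est, rr_ref)
  ok <- is.finite(rr_est) & is.finite(rr_ref)
  m <- (rr_est[ok] + rr_ref[ok]) / 2
  d <- rr_est[ok] - rr_ref[ok]
  graphics::plot(m, d, xlab = "Mean of estimate and reference (breaths/min)",
                 ylab = "Estimate - reference (breaths/min)", ...)
  graphics::abline(h = es$ba_bias, lty = 1)
  graphics::abline(h = es$ba_loa, lty = 2)
  invisible(es)
}
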