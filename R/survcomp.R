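#' Kaplan-Meier comparison of two groups with log-rank test and hazard ratio
#'
#' Product-limit survival estimates per group (via the survival package), the
#' log-rank test, the hazard ratio from a single-covariate Cox
#' proportional-hazards fit, and the cumulative mortality at a fixed horizon
#' (default 730 days, the study's 2-year follow-up) read from the curves.
#'
#' @param times Follow-up times (days).
#' @param statuses Event indicators (1/TRUE = dead, 0/FALSE = censored alive).
#' @param groups Two-level grouping vector (e.g. objective improvement).
#' @param horizon Horizon in days at which cumulative mortality is reported.
#' @return Object of class `vp_survcomp`: `curves` (per-group data frames of
#'   `time`/`surv`), `logrank_chisq`, `logrank_p`, `hazard_ratio` with
#'   `hr_ci`, `mortality_at_horizon` (named per group), `horizon`.
#' @export
km_logrank <- function(times, statuses, groups, horizon = 730) {
  statuses <- as.integer(as.logical(statuses))
  g <- as.factor(as.vector(groups))
  if (nlevels(droplevels(g)) != 2L) stop_vp("km_logrank needs exactly two groups")
  if (sum(statuses) == 0L) stop_vp("no events observed in either group")
  df <- data.frame(time = as.numeric(times), status = statuses, group = droplevels(g))
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  cph <- survival::coxph(survival::Surv(time, status) ~ group, data = df)
  hr <- exp(stats::coef(cph))[[1]]
  hr_ci <- exp(stats::confint(cph))[1, ]
  lv <- levels(df$group)
  strata_id <- rep(seq_along(fit$strata), fit$strata)
  curves <- lapply(seq_along(lv), function(k) {
    data.frame(time = fit$time[strata_id == k], surv = fit$surv[strata_id == k])
  })
  names(curves) <- lv
  mort <- vapply(curves, function(cv) {
    s <- c(1, cv$surv)[findInterval(horizon, c(0, cv$time)) ]
    1 - s
  }, numeric(1))
  structure(list(curves = curves, logrank_chisq = chisq, logrank_p = p,
                 hazard_ratio = hr, hr_ci = hr_ci,
                 mortality_at_horizon = mort, horizon = horizon,
                 survfit = fit),
            class = "vp_survcomp")
}

#' @export
print.vp_survcomp <- function(x, ...) {
  lv <- names(x$curves)
  cat(sprintf("<vp_survcomp> log-rank chi2 = %.2f, p = %.4g\n",
              x$logrank_chisq, x$logrank_p))
  cat(sprintf("  HR (%s vs %s) = %.2f (95%% CI %.2f-%.2f)\n",
              lv[2], lv[1], x$hazard_ratio, x$hr_ci[1], x$hr_ci[2]))
  cat(sprintf("  mortality at %d days: %s\n", x$horizon,
              paste(sprintf("%s %.1f%%", lv, 100 * x$mortality_at_horizon),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.vp_survcomp <- function(x, col = c("forestgreen", "firebrick"), ...) {
  graphics::plot(x$survfit, col = col, xlab = "Days since TAVI",
                 ylab = "Survival probability", ...)
  graphics::legend("bottomleft", legend = names(x$curves), col = col,
                   lty = 1, bty = "n")
  invisible(x)
}
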