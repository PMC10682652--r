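#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `g` risk groups by deciles of fitted probability
#' and compares observed with expected event counts;
#' the statistic is referred to a chi-squared distribution with `g - 2`
#' degrees of freedom.
#'
#' @param y Observed 0/1 outcomes.
#' @param phat Fitted probabilities.
#' @param g Number of risk groups (default 10).
#' @return List with `statistic`, `df`, `p_value`, `g`.
#' @export
hosmer_lemeshow <- function(y, phat, g = 10) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(phat), all(y %in% c(0, 1)))
  br <- unique(stats::quantile(phat, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) < 3L) stop_vp("fitted probabilities too degenerate for %d risk groups", g)
  grp <- cut(phat, breaks = br, include.lowest = TRUE)
  o1 <- tapply(y, grp, sum); e1 <- tapply(phat, grp, sum)
  ng <- tapply(y, grp, length)
  stat <- sum((o1 - e1)^2 / (e1 * (1 - e1 / ng)))
  df <- length(levels(grp)) - 2L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), g = length(levels(grp)))
}

#' Nagelkerke pseudo-R-squared
#'
#' @param fit A binomial [stats::glm()] fit.
#' @return Nagelkerke R^2 in `[0, 1]` (0 for an intercept-only model).
#' @export
nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  cox_snell <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  max_r2 <- 1 - exp(-fit$null.deviance / n)
  if (max_r2 <= 0) return(0)
  min(max(cox_snell / max_r2, 0), 1)
}

# Detect (quasi-)complete separation; returns the offending predictor or NULL.
find_separation <- function(data, outcome, predictors, fit) {
  ph <- stats::fitted(fit)
  degenerate <- all(ph[data[[outcome]] == 1] > 1 - 1e-7) &&
    all(ph[data[[outcome]] == 0] < 1e-7)
  if (!degenerate) return(NULL)
  y <- data[[outcome]]
  for (v in predictors) {
    x <- data[[v]]
    if (!is.numeric(x)) next
    if (max(x[y == 0]) <= min(x[y == 1]) || max(x[y == 1]) <= min(x[y == 0]))
      return(v)
  }
  predictors[1]
}

#' Backward-stepwise logistic regression
#'
#' Fits a multivariable binomial logistic model on the screened candidates
#' and performs backward elimination: the predictor with the largest Wald
#' p-value is removed until every remaining predictor has p below `alpha`
#' (default), or by AIC (`criterion = "AIC"`, via [stats::step()]).  Reports
#' odds ratios with Wald 95% confidence intervals, the Hosmer-Lemeshow
#' statistic on 10 risk deciles, and Nagelkerke R^2.  Events-per-variable is
#' checked and a warning logged below 10.
#'
#' @param data Data frame with the outcome and candidate columns.
#' @param outcome Name of the 0/1 (or two-level) outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha Retention threshold on Wald p-values (default 0.05).
#' @param criterion `"p"` (default) or `"AIC"`.
#' @return Object of class `vp_logit`: the final `glm` fit, `retained`
#'   predictors, an `or_table` (OR, 95% CI, p), `hosmer_lemeshow`,
#'   `nagelkerke_r2`.
#' @export
fit_logistic_stepwise <- function(data, outcome, candidates, alpha = 0.05,
                                  criterion = c("p", "AIC")) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(data), length(candidates) >= 1L)
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y) || is.logical(y))
    data[[outcome]] <- as.integer(as.factor(y)) - 1L
  if (!all(data[[outcome]] %in% c(0, 1))) stop_vp("outcome must be binary")
  n_events <- min(sum(data[[outcome]] == 1), sum(data[[outcome]] == 0))
  if (n_events / length(candidates) < 10)
    warning(sprintf("events-per-variable %.1f is below 10; estimates may be unstable",
                    n_events / length(candidates)), call. = FALSE)
  fit_on <- function(vars) {
    fm <- stats::reformulate(if (length(vars)) vars else "1", response = outcome)
    suppressWarnings(stats::glm(fm, data = data, family = stats::binomial()))
  }
  vars <- candidates
  fit <- fit_on(vars)
  sep <- find_separation(data, outcome, vars, fit)
  if (!is.null(sep)) stop_vp("complete separation detected (predictor '%s')", sep)
  if (criterion == "AIC") {
    fit <- stats::step(fit, direction = "backward", trace = 0)
    vars <- attr(stats::terms(fit), "term.labels")
  } else {
    repeat {
      if (length(vars) == 0L) break
      cf <- summary(fit)$coefficients
      rows <- setdiff(rownames(cf), "(Intercept)")
      pv <- stats::setNames(cf[rows, 4], rows)
      if (all(pv < alpha)) break
      worst <- names(pv)[which.max(pv)]
      # map coefficient name back to its term
      drop_var <- vars[vapply(vars, function(v) startsWith(worst, v), logical(1))][1]
      vars <- setdiff(vars, drop_var)
      fit <- fit_on(vars)
    }
  }
  cf <- summary(fit)$coefficients
  rows <- setdiff(rownames(cf), "(Intercept)")
  or_table <- if (length(rows)) data.frame(
    term = rows,
    or = exp(cf[rows, 1]),
    ci_lower = exp(cf[rows, 1] - 1.959964 * cf[rows, 2]),
    ci_upper = exp(cf[rows, 1] + 1.959964 * cf[rows, 2]),
    p_value = cf[rows, 4], row.names = NULL
  ) else data.frame(term = character(0), or = numeric(0), ci_lower = numeric(0),
                    ci_upper = numeric(0), p_value = numeric(0))
  hl <- tryCatch(hosmer_lemeshow(fit$y, stats::fitted(fit)),
                 error = function(e) NULL)
  structure(list(fit = fit, retained = vars, or_table = or_table,
                 hosmer_lemeshow = hl, nagelkerke_r2 = nagelkerke_r2(fit),
                 outcome = outcome),
            class = "vp_logit")
}

#' @export
print.vp_logit <- function(x, ...) {
  cat(sprintf("<vp_logit> outcome '%s'; retained: %s\n", x$outcome,
              if (length(x$retained)) paste(x$retained, collapse = ", ") else "(intercept only)"))
  if (nrow(x$or_table)) {
    ot <- x$or_table
    for (i in seq_len(nrow(ot)))
      cat(sprintf("  %s: OR %.3f (95%% CI %.4f-%.4f), p = %.3g\n",
                  ot$term[i], ot$or[i], ot$ci_lower[i], ot$ci_upper[i], ot$p_value[i]))
  }
  if (!is.null(x$hosmer_lemeshow))
    cat(sprintf("  Hosmer-Lemeshow chi2(%d) = %.2f, p = %.3f; Nagelkerke R2 = %.3f\n",
                x$hosmer_lemeshow$df, x$hosmer_lemeshow$statistic,
                x$hosmer_lemeshow$p_value, x$nagelkerke_r2))
  invisible(x)
}

#' @export
coef.vp_logit <- function(object, ...) stats::coef(object$fit)

#' @export
predict.vp_logit <- function(object, newdata = NULL, ...) {
  stats::predict(object$fit, newdata = newdata, type = "response")
}

#' @export
summary.vp_logit <- function(object, ...) summary(object$fit, ...)

#' Bagged ensemble of balanced logistic models
#'
#' Fits `n_models` logistic regressions with a fixed predictor set, each on a
#' bootstrap resample of the training data that is ROSE-balanced before
#' fitting; the ensemble predicts the mean predicted probability across
#' members (majority vote at 0.5 behind `aggregate = "vote"`).  Members whose
#' fit fails are logged and skipped.
#'
#' @param data Training data frame.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor columns.
#' @param n_models Ensemble size (default 100).
#' @param balance ROSE-balance each resample (default TRUE).
#' @param aggregate `"mean"` (default) or `"vote"`.
#' @param seed Integer seed (optional).
#' @return Object of class `vp_ensemble`.
#' @export
bagged_ensemble <- function(data, outcome, predictors, n_models = 100,
                            balance = TRUE, aggregate = c("mean", "vote"),
                            seed = NULL) {
  aggregate <- match.arg(aggregate)
  if (n_models < 1L) stop_vp("n_models must be at least 1")
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y) || is.logical(y))
    data[[outcome]] <- as.integer(as.factor(y)) - 1L
  fm <- stats::reformulate(predictors, response = outcome)
  members <- with_seed(seed, {
    lapply(seq_len(n_models), function(b) {
      tryCatch({
        boot <- data[sample(nrow(data), replace = TRUE), , drop = FALSE]
        if (length(unique(boot[[outcome]])) < 2L) stop("single-class resample")
        if (balance) boot <- rose_balance(boot, outcome)
        suppressWarnings(stats::glm(fm, data = boot, family = stats::binomial()))
      }, error = function(e) {
        message(sprintf("ensemble member %d skipped: %s", b, conditionMessage(e)))
        NULL
      })
    })
  })
  members <- Filter(Negate(is.null), members)
  if (length(members) == 0L) stop_vp("all ensemble members failed to fit")
  structure(list(members = members, predictors = predictors, outcome = outcome,
                 aggregate = aggregate, n_requested = n_models),
            class = "vp_ensemble")
}

#' @export
predict.vp_ensemble <- function(object, newdata, ...) {
  probs <- vapply(object$members,
                  function(m) stats::predict(m, newdata = newdata, type = "response"),
                  numeric(nrow(newdata)))
  probs <- matrix(probs, nrow = nrow(newdata))
  if (object$aggregate == "vote") rowMeans(probs >= 0.5) else rowMeans(probs)
}

#' @export
print.vp_ensemble <- function(x, ...) {
  cat(sprintf("<vp_ensemble> %d/%d logistic members on: %s (aggregate: %s)\n",
              length(x$members), x$n_requested,
              paste(x$predictors, collapse = ", "), x$aggregate))
  invisible(x)
}
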