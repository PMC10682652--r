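#' Fit the improvement-prediction model end to end
#'
#' The study's modelling pipeline as one fitting function: univariate
#' screening of the candidate predictors (p < `screen_p`; test chosen per
#' variable as in [compare_groups()]), a stratified train/test partition,
#' ROSE-style balancing of the training set ([rose_balance()]),
#' backward-stepwise multivariable logistic regression
#' ([fit_logistic_stepwise()]), a bagged ensemble of balanced logistic
#' members ([bagged_ensemble()]), and validation of the ensemble score on
#' the held-out test set by ROC analysis ([roc_analysis()]).
#'
#' @param data Data frame with the outcome and candidate columns.
#' @param outcome Name of the binary outcome column (e.g. objective
#'   improvement; the positive class is the second factor level).
#' @param candidates Character vector of candidate predictor columns.
#' @param screen_p Univariate screening threshold (default 0.2).
#' @param train_fraction Stratified training fraction (default 0.7).
#' @param n_models Ensemble size (default 100).
#' @param alpha Stepwise retention threshold (default 0.05).
#' @param seed Integer seed driving partition, balancing and ensemble
#'   (default 20231114).
#' @return Object of class `vp_fit`: `screen` (data frame of per-candidate
#'   tests), `candidates_kept`, `model` (the [fit_logistic_stepwise()]
#'   result), `ensemble`, `roc` (test-set [roc_analysis()]), `partition`,
#'   and `seed`.
#' @examples
#' \donttest{
#' coh <- gen_cohort(cohort_params(n = 300, seed = 7))
#' fit <- vp_fit(coh, "improved_true",
#'               c("slope_index", "sbp", "mean_gradient", "zva"), seed = 7)
#' print(fit)
#' }
#' @export
vp_fit <- function(data, outcome, candidates, screen_p = 0.2,
                   train_fraction = 0.7, n_models = 100, alpha = 0.05,
                   seed = 20231114) {
  stopifnot(is.data.frame(data), all(c(outcome, candidates) %in% names(data)))
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y) || is.logical(y))
    data[[outcome]] <- as.integer(as.factor(y)) - 1L
  screen <- do.call(rbind, lapply(candidates, function(v) {
    s <- compare_groups(data[[v]], data[[outcome]], screen_p = screen_p)
    data.frame(variable = v, test = s$test, p_value = s$p_value,
               passes_screen = s$passes_screen)
  }))
  kept <- screen$variable[screen$passes_screen]
  if (length(kept) == 0L)
    stop_vp("no candidate passed the univariate screen at p < %.2g", screen_p)
  part <- stratified_partition(data[[outcome]], train_fraction,
                               seed = child_seed(seed, 1))
  train <- data[part$train, c(outcome, kept), drop = FALSE]
  test <- data[part$test, , drop = FALSE]
  balanced <- rose_balance(train, outcome, seed = child_seed(seed, 2))
  model <- fit_logistic_stepwise(balanced, outcome, kept, alpha = alpha)
  predictors <- if (length(model$retained)) model$retained else kept
  ens <- bagged_ensemble(train, outcome, predictors, n_models = n_models,
                         seed = child_seed(seed, 3))
  score <- predict(ens, test)
  roc <- roc_analysis(score, test[[outcome]])
  structure(list(screen = screen, candidates_kept = kept, model = model,
                 ensemble = ens, roc = roc, partition = part, seed = seed,
                 outcome = outcome),
            class = "vp_fit")
}

#' @export
print.vp_fit <- function(x, ...) {
  cat(sprintf("<vp_fit> outcome '%s': %d screened, %d kept (p < 0.2)\n",
              x$outcome, nrow(x$screen), length(x$candidates_kept)))
  print(x$model)
  cat(sprintf("  test-set AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g\n",
              x$roc$auc, x$roc$ci[1], x$roc$ci[2], x$roc$cutoff))
  invisible(x)
}

#' @export
summary.vp_fit <- function(object, ...) {
  list(screen = object$screen, or_table = object$model$or_table,
       hosmer_lemeshow = object$model$hosmer_lemeshow,
       nagelkerke_r2 = object$model$nagelkerke_r2,
       auc = object$roc$auc, auc_ci = object$roc$ci,
       cutoff = object$roc$cutoff, ensemble_size = length(object$ensemble$members))
}

#' @export
coef.vp_fit <- function(object, ...) stats::coef(object$model$fit)

#' @export
predict.vp_fit <- function(object, newdata, ...) predict(object$ensemble, newdata)

#' Serialize a fitted model report to JSON
#'
#' Writes the retained predictors, odds ratios with confidence intervals,
#' calibration statistics, ensemble size and test-set ROC summary as JSON.
#' Output is deterministic for a given fit (fixed field order, full
#' precision), so identical seeds yield byte-identical reports.
#'
#' @param fit A [vp_fit()] result.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "vp_fit"))
  hl <- fit$model$hosmer_lemeshow
  rep <- list(
    outcome = fit$outcome,
    seed = fit$seed,
    screened = fit$screen,
    retained = as.list(fit$model$retained),
    odds_ratios = fit$model$or_table,
    hosmer_lemeshow = if (is.null(hl)) NULL else
      list(statistic = hl$statistic, df = hl$df, p_value = hl$p_value),
    nagelkerke_r2 = fit$model$nagelkerke_r2,
    ensemble_size = length(fit$ensemble$members),
    test_auc = fit$roc$auc,
    test_auc_ci = fit$roc$ci,
    cutoff = fit$roc$cutoff,
    sensitivity = fit$roc$sensitivity,
    specificity = fit$roc$specificity
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
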