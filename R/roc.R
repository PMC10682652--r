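#' ROC analysis with DeLong confidence interval and Youden cutoff
#'
#' Empirical receiver-operating-characteristic analysis of a continuous score
#' against a binary outcome.  The area under the curve is computed by the
#' trapezoid rule, which equals the Mann-Whitney concordance probability
#' (ties counted 1/2); its variance follows DeLong's structural-components
#' estimator, with a 2000-replicate stratified bootstrap fallback when that
#' variance degenerates (e.g. AUC exactly 1).  The operating cutoff maximizes
#' Youden's J = sensitivity + specificity - 1 over the observed score values
#' (prediction rule: score >= cutoff is called positive); ties in J resolve
#' to the lower cutoff.
#'
#' @param scores Numeric score vector (higher = more likely positive).
#' @param labels Binary outcome vector (0/1, logical, or two-level factor;
#'   the second level is the positive class).
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @param boot_seed Seed for the bootstrap fallback (default 20231114).
#' @return Object of class `vp_roc` with `auc`, `ci` (length 2), `se`,
#'   `cutoff`, `sensitivity` and `specificity` at the cutoff, `youden`, the
#'   full `curve` (data frame of cutoff/sensitivity/specificity) and `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95, boot_seed = 20231114) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  y <- labels[keep]
  if (is.factor(y) || is.character(y)) y <- as.integer(as.factor(y)) - 1L
  y <- as.integer(as.logical(y))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop_vp("both outcome classes must be present")
  x1 <- scores[y == 1L]; x0 <- scores[y == 0L]

  # Mann-Whitney AUC via midranks (equivalent to the trapezoid rule)
  r <- rank(c(x1, x0))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong structural components
  all_r <- r
  r1 <- rank(x1); r0 <- rank(x0)
  v10 <- (all_r[seq_len(n1)] - r1) / n0          # P(x1 > X0) per positive
  v01 <- 1 - (all_r[n1 + seq_len(n0)] - r0) / n1 # P(X1 > x0) per negative
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  if (!is.finite(var_auc) || var_auc <= 0) {
    # stratified bootstrap fallback for degenerate variance
    boots <- with_seed(boot_seed, {
      vapply(seq_len(2000), function(b) {
        b1 <- sample(x1, n1, replace = TRUE)
        b0 <- sample(x0, n0, replace = TRUE)
        rb <- rank(c(b1, b0))
        (sum(rb[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      }, numeric(1))
    })
    var_auc <- stats::var(boots)
  }
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  # empirical operating points at each observed score value
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(cc) mean(x1 >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(x0 < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]           # ties -> lower cutoff
  structure(list(auc = auc, ci = ci, se = se,
                 cutoff = cuts[best], sensitivity = sens[best],
                 specificity = spec[best], youden = j[best],
                 curve = data.frame(cutoff = cuts, sensitivity = sens,
                                    specificity = spec),
                 n_pos = n1, n_neg = n0, conf_level = conf_level),
            class = "vp_roc")
}

#' @export
print.vp_roc <- function(x, ...) {
  cat(sprintf("<vp_roc> AUC %.3f (%.0f%% CI %.3f-%.3f), n = %d/%d (pos/neg)\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.3f, specificity %.3f\n",
              x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
plot.vp_roc <- function(x, add = FALSE, col = "black", ...) {
  fpr <- c(1, 1 - x$curve$specificity, 0)
  tpr <- c(1, x$curve$sensitivity, 0)
  o <- order(fpr, tpr)
  if (add) {
    graphics::lines(fpr[o], tpr[o], col = col, ...)
  } else {
    graphics::plot(fpr[o], tpr[o], type = "l", col = col,
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   main = sprintf("ROC (AUC %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}
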