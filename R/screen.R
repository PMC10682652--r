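#' Univariate group comparison with automatic test selection
#'
#' Mirrors the study's screening procedure.  Continuous variables: the
#' Shapiro-Wilk test is applied to each group and a Welch t-test is used when
#' both look normal (p >= 0.05), a Mann-Whitney test otherwise.  Categorical
#' variables: chi-squared, switching to Fisher's exact test when any expected
#' cell count is below 5.  A variable passes the screen when p < `screen_p`
#' and is then a candidate for the multivariable model.
#'
#' @param values Vector of the variable (numeric, or factor/character/logical
#'   for categorical).
#' @param groups Two-level grouping vector, same length.
#' @param kind `"auto"` (default: numeric means continuous), `"continuous"`
#'   or `"categorical"`.
#' @param screen_p Screening threshold (default 0.2).
#' @return List (class `vp_screen`) with `variable`, `test` (one of
#'   `welch_t`, `mann_whitney`, `chi2`, `fisher`), `p_value`, `passes_screen`.
#' @export
compare_groups <- function(values, groups, kind = c("auto", "continuous", "categorical"),
                           screen_p = 0.2) {
  kind <- match.arg(kind)
  variable <- deparse(substitute(values))[1]
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(as.vector(groups[keep]))
  lv <- levels(droplevels(groups))
  if (length(lv) != 2L) stop_vp("compare_groups needs exactly two non-empty groups, got %d", length(lv))
  if (kind == "auto")
    kind <- if (is.numeric(values) && length(unique(values)) > 5L) "continuous" else "categorical"
  if (kind == "continuous") {
    g1 <- values[groups == lv[1]]; g2 <- values[groups == lv[2]]
    if (length(g1) < 3L || length(g2) < 3L)
      stop_vp("each group needs at least 3 observations for a continuous comparison")
    normal <- function(x) {
      if (stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)$p.value >= 0.05
    }
    if (normal(g1) && normal(g2)) {
      test <- "welch_t"
      p <- stats::t.test(g1, g2)$p.value
    } else {
      test <- "mann_whitney"
      p <- stats::wilcox.test(g1, g2, exact = FALSE)$p.value
    }
  } else {
    tab <- table(factor(values), groups)
    if (any(dim(tab) < 2L)) {
      test <- "chi2"; p <- 1       # constant variable carries no information
    } else {
      expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
      if (any(expected < 5)) {
        test <- "fisher"
        p <- stats::fisher.test(tab)$p.value
      } else {
        test <- "chi2"
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
  }
  structure(list(variable = variable, test = test, p_value = p,
                 passes_screen = p < screen_p),
            class = "vp_screen")
}

#' @export
print.vp_screen <- function(x, ...) {
  cat(sprintf("%s: %s p=%.4g %s\n", x$variable, x$test, x$p_value,
              if (x$passes_screen) "(passes screen)" else ""))
  invisible(x)
}

#' Stratified train/test partition
#'
#' Splits patients into disjoint, exhaustive train and test sets with the
#' outcome proportion in the train set within one patient of the overall
#' proportion (per-class `round(n_k * fraction)` sampling), reproducibly for
#' a given seed.
#'
#' @param outcome Two-level outcome vector (one element per patient).
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed (optional).
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_partition <- function(outcome, train_fraction = 0.7, seed = NULL) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop_vp("train_fraction must be in (0, 1)")
  f <- as.factor(as.vector(outcome))
  tab <- table(f)
  if (any(tab < 2L))
    stop_vp("class '%s' has fewer than 2 members", names(tab)[which(tab < 2L)[1]])
  train <- with_seed(seed, {
    unlist(lapply(levels(f), function(lv) {
      idx <- which(f == lv)
      k <- max(1L, min(length(idx) - 1L, round(length(idx) * train_fraction)))
      sample(idx, k)
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(f), train))
}
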