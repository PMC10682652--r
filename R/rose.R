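#' Random over-sampling with a smoothed bootstrap (ROSE-style)
#'
#' Generates a balanced synthetic sample for imbalanced binary outcomes.
#' Each synthetic patient is drawn by resampling a seed patient of the target
#' class and perturbing each continuous predictor with zero-mean Gaussian
#' noise whose per-dimension bandwidth follows the multivariate
#' Silverman-type rule
#' \deqn{h_j = \left(\frac{4}{(q+2)\,n_k}\right)^{1/(q+4)} s_j,}
#' where `q` is the number of continuous predictors, `n_k` the size of the
#' seed class and `s_j` the within-class standard deviation of predictor `j`.
#' Non-numeric columns are carried over from the seed patient unchanged.
#' With `shrink = 0` the noise vanishes and the procedure reduces to a plain
#' balanced bootstrap.
#'
#' @param data Data frame of predictors plus the outcome column.
#' @param outcome Name of the two-level outcome column.
#' @param n Size of the synthetic sample (default `nrow(data)`); classes are
#'   split `n %/% 2` / `n - n %/% 2`.
#' @param shrink Multiplier on the bandwidths (default 1; 0 = plain bootstrap).
#' @param seed Integer seed (optional).
#' @return Data frame of `n` synthetic patients with ~50/50 outcome classes.
#' @export
rose_balance <- function(data, outcome, n = nrow(data), shrink = 1, seed = NULL) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) stop_vp("outcome column '%s' not found", outcome)
  y <- as.factor(as.vector(data[[outcome]]))
  lv <- levels(droplevels(y))
  if (length(lv) != 2L) stop_vp("rose_balance needs both outcome classes present")
  pred <- setdiff(names(data), outcome)
  numcols <- pred[vapply(data[pred], is.numeric, logical(1))]
  q <- length(numcols)
  sizes <- c(n %/% 2L, n - n %/% 2L)
  with_seed(seed, {
    parts <- lapply(1:2, function(k) {
      idx <- which(y == lv[k])
      n_k <- length(idx)
      take <- sample(idx, sizes[k], replace = TRUE)
      out <- data[take, , drop = FALSE]
      if (q > 0 && shrink > 0 && n_k > 1) {
        band <- (4 / ((q + 2) * n_k))^(1 / (q + 4))
        for (j in numcols) {
          h <- shrink * band * stats::sd(data[[j]][idx])
          if (is.finite(h) && h > 0)
            out[[j]] <- out[[j]] + stats::rnorm(sizes[k], 0, h)
        }
      }
      out
    })
    out <- rbind(parts[[1]], parts[[2]])
    rownames(out) <- NULL
    out
  })
}
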