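sim_logit_data <- function(n, beta, alpha = -2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n, 0.2, 0.15)              # slope-index scale
  data.frame(y = rbinom(n, 1, plogis(alpha + beta * x)), x = x)
}

test_that("a strong predictor is retained with its coefficient near truth", {
  d <- sim_logit_data(5000, beta = 8, seed = 1)
  fit <- fit_logistic_stepwise(d, "y", "x")
  expect_identical(fit$retained, "x")
  expect_equal(unname(coef(fit)["x"]), 8, tolerance = 0.25)
  expect_equal(nrow(fit$or_table), 1L)
  expect_true(fit$or_table$ci_lower < fit$or_table$or &
                fit$or_table$or < fit$or_table$ci_upper)
})

test_that("a null predictor is usually eliminated", {
  dropped <- sapply(1:20, function(s) {
    d <- sim_logit_data(2000, beta = 0, seed = 100 + s)
    length(fit_logistic_stepwise(d, "y", "x")$retained) == 0
  })
  expect_gte(mean(dropped), 0.7)        # nominal rate 95%
})

test_that("backward elimination strips noise variables but keeps signal", {
  set.seed(5)
  d <- sim_logit_data(3000, beta = 8)
  d$noise1 <- rnorm(3000); d$noise2 <- rnorm(3000)
  fit <- fit_logistic_stepwise(d, "y", c("x", "noise1", "noise2"))
  expect_true("x" %in% fit$retained)
  aic <- fit_logistic_stepwise(d, "y", c("x", "noise1", "noise2"),
                               criterion = "AIC")
  expect_true("x" %in% aic$retained)
})

test_that("perfect separation raises an error naming the predictor", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(fit_logistic_stepwise(d, "y", "x"), "separation.*x")
})

test_that("Hosmer-Lemeshow and Nagelkerke behave on reference cases", {
  set.seed(6)
  d <- sim_logit_data(2000, beta = 8)
  fit <- glm(y ~ x, data = d, family = binomial())
  hl <- hosmer_lemeshow(fit$y, fitted(fit))
  expect_equal(hl$df, 8)
  expect_gt(hl$p_value, 0.001)          # correctly specified model

  r2 <- nagelkerke_r2(fit)
  expect_true(r2 > 0 && r2 < 1)
  null_fit <- glm(y ~ 1, data = d, family = binomial())
  expect_equal(nagelkerke_r2(null_fit), 0)
  # stronger effect, higher R2
  d2 <- sim_logit_data(2000, beta = 16, seed = 6)
  fit2 <- glm(y ~ x, data = d2, family = binomial())
  expect_gt(nagelkerke_r2(fit2), r2)
})

test_that("a one-member ensemble equals its single balanced model", {
  set.seed(9)
  d <- sim_logit_data(400, beta = 8)
  ens <- bagged_ensemble(d, "y", "x", n_models = 1, balance = FALSE, seed = 11)
  m <- ens$members[[1]]
  newd <- data.frame(x = seq(-0.2, 0.6, 0.1))
  expect_equal(predict(ens, newd),
               unname(predict(m, newdata = newd, type = "response")))
})

test_that("ensemble predictions are probabilities and averaging reduces variance", {
  d <- sim_logit_data(300, beta = 8, seed = 21)
  newd <- data.frame(x = seq(-0.2, 0.6, length.out = 25))
  preds_ens <- preds_one <- matrix(NA, 25, 20)
  for (s in 1:20) {
    train <- sim_logit_data(150, beta = 8, seed = 300 + s)
    ens <- bagged_ensemble(train, "y", "x", n_models = 25, seed = s)
    one <- bagged_ensemble(train, "y", "x", n_models = 1, seed = s)
    preds_ens[, s] <- predict(ens, newd)
    preds_one[, s] <- predict(one, newd)
  }
  expect_true(all(preds_ens >= 0 & preds_ens <= 1))
  # across-replicate variance of the ensemble score is below the single model's
  expect_lt(mean(apply(preds_ens, 1, var)), mean(apply(preds_one, 1, var)))
})
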