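test_that("AICc handles the penalty-free limit and the small-sample guard", {
  expect_equal(aicc(-50, 0, 20), 100)
  expect_error(aicc(-50, 5, 6), "exceed")
  expect_error(aicc(-50, 5, 5), "exceed")
})

test_that("gaussian GLM recovers known coefficients and equals least squares", {
  set.seed(61)
  n <- 500
  x <- runif(n, 0, 10)
  y <- 2.5 + 1.7 * x + rnorm(n, 0, 0.5)
  d <- data.frame(y = y, x = x)
  f <- fit_glm(d, "y", "x", "gaussian")
  co <- f$coefficients
  expect_lt(abs(co$estimate[2] - 1.7), 3 * co$se[2])
  expect_lt(abs(co$estimate[1] - 2.5), 3 * co$se[1])
  ols <- coef(lm(y ~ x, d))
  expect_equal(co$estimate, unname(ols), tolerance = 1e-10)
  expect_equal(f$k, 3)  # intercept + slope + residual variance
})

test_that("gamma GLM guards and degenerate fits raise errors", {
  d <- data.frame(y = c(-1, 2, 3, 4, 5, 6), x = 1:6)
  expect_error(fit_glm(d, "y", "x", "gamma_log"), "positive")
  coll <- data.frame(y = rnorm(20, 10), a = 1:20, b = 2 * (1:20))
  expect_error(fit_glm(coll, "y", c("a", "b"), "gaussian"), "degenerate")
})

test_that("spearman correlation hits the monotone extremes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_test(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
})

test_that("family selection picks the generating distribution", {
  set.seed(67)
  g <- rgamma(2000, shape = 2, rate = 0.5)
  expect_equal(select_family(g)$family, "gamma_log")
  nm <- rnorm(2000, 10, 3)
  expect_equal(select_family(nm)$family, "gaussian")
  expect_error(select_family(c(1, 2, 3)), "at least 5")
})

test_that("Akaike weights sum to one and rank a strong true model first", {
  set.seed(71)
  hits <- 0L
  for (r in 1:30) {
    n <- 25  # the small-sample AICc penalty separates the nested competitor
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 5 + 2 * d$x1 + rnorm(n)
    res <- all_subsets_average(d, "y", c("x1", "x2"))
    expect_equal(sum(res$models$weight), 1, tolerance = 1e-12)
    if (res$models$terms[1] == "x1") hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.8)
})

test_that("averaging a single model returns that model's coefficients", {
  set.seed(73)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d$y <- 1 + 3 * d$x1 + rnorm(50, 0, 0.2)
  res <- all_subsets_average(d, "y", c("x1", "x2"), delta_max = 1e-9)
  best <- res$fits[[1]]$coefficients
  avg <- res$average
  for (tm in best$term)
    expect_equal(avg$estimate[avg$term == tm],
                 best$estimate[best$term == tm])
})

test_that("full and conditional averages differ as documented", {
  set.seed(79)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 + 0.4 * d$x1 + 0.1 * d$x2 + rnorm(n)
  full <- all_subsets_average(d, "y", c("x1", "x2"), delta_max = 10)
  cond <- all_subsets_average(d, "y", c("x1", "x2"), delta_max = 10,
                              method = "conditional")
  for (tm in c("x1", "x2")) {
    bf <- full$average$estimate[full$average$term == tm]
    bc <- cond$average$estimate[cond$average$term == tm]
    expect_lte(abs(bf), abs(bc) + 1e-12)  # shrinkage toward zero
  }
})

test_that("the model suite validates its input table", {
  tbl <- simulate_metrics_table(truth_config(seed = 83))
  bad <- tbl[, setdiff(names(tbl), c("visit_freq", "route"))]
  expect_error(run_paper_models(bad), "visit_freq")
  expect_error(run_paper_models(bad), "route")
  expect_error(run_paper_models(tbl[1, ]), "at least 5 days")
})

test_that("the model suite reproduces the printed structure of the analysis tables", {
  tbl <- simulate_metrics_table(truth_config(seed = 89))
  rep <- run_paper_models(tbl)
  expect_true(all(c("prediction", "predictor", "estimate", "t", "p", "n",
                    "method") %in% names(rep$table1)))
  expect_equal(nrow(rep$table2$models), 4)  # subsets of two predictors
  expect_equal(sum(rep$table2$models$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(rep$table2$models$AICc) >= 0))
  # lagged predictors reduce the sample by the missing first day
  expect_lte(rep$fits$p8$n, nrow(tbl) - 1)
})
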