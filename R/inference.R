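#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`, where `k` counts every
#' estimated parameter including the intercept and the dispersion/scale
#' parameter of the family.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc (finite; errors when `n <= k + 1`).
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 0, n > 0)
  if (n <= k + 1)
    stop("AICc undefined: n (", n, ") must exceed k + 1 (", k + 1, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.glm_family <- function(family) {
  switch(family,
         gaussian = stats::gaussian(),
         gamma_log = stats::Gamma(link = "log"),
         gamma_inverse = stats::Gamma(link = "inverse"),
         stop("unknown family: ", family))
}

#' Fit a single GLM and report coefficients, AICc and tests
#'
#' Maximum-likelihood GLM fit via [stats::glm()]. Wald statistics are
#' `t = estimate / SE` with the dispersion estimated from the data, and
#' two-tailed p-values from the t distribution with `n - p` residual
#' degrees of freedom (the convention of reporting "t" for both Gaussian
#' and Gamma models); the normal-approximation p is reported alongside.
#'
#' @param data data.frame holding the variables.
#' @param response Response column name (must be strictly positive for the
#'   gamma families).
#' @param predictors Character vector of predictor column names.
#' @param family One of `"gaussian"`, `"gamma_log"`, `"gamma_inverse"`.
#' @return list of class `fit_result`: `coefficients` (data.frame `term`,
#'   `estimate`, `se`, `t`, `p`, `p_norm`), `logLik`, `k` (parameters
#'   including dispersion), `n`, `aicc`, `family`, `formula`, `model` (the
#'   `glm` object).
#' @export
fit_glm <- function(data, response, predictors,
                    family = c("gaussian", "gamma_log", "gamma_inverse")) {
  family <- match.arg(family)
  stopifnot(length(predictors) >= 0, response %in% names(data),
            all(predictors %in% names(data)))
  vars <- c(response, predictors)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
               drop = FALSE]
  n <- nrow(data)
  if (n < length(predictors) + 3)
    stop("too few complete observations (", n, ") to fit ", response,
         " ~ ", paste(predictors, collapse = " + "))
  if (startsWith(family, "gamma") && any(data[[response]] <= 0))
    stop("gamma family requires a strictly positive response: ", response)
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressWarnings(stats::glm(fml, data = data,
                                     family = .glm_family(family)))
  if (any(is.na(stats::coef(fit))))
    stop("degenerate fit (collinear or constant predictors) for ", response)
  sm <- summary(fit)
  co <- sm$coefficients
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], t = co[, 3], p = co[, 4],
                              p_norm = 2 * stats::pnorm(-abs(co[, 3])),
                              row.names = NULL),
    logLik = as.numeric(ll), k = k, n = n,
    aicc = aicc(as.numeric(ll), k, n),
    family = family, formula = fml, model = fit),
    class = "fit_result")
}

#' Spearman rank correlation, two-tailed
#'
#' Rank correlation with average ranks for ties (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Choose between gamma and normal response distributions
#'
#' Fits both candidate distributions to the response by maximum likelihood
#' (fitdistrplus) and picks the lower-AIC family.
#'
#' @param y Strictly positive numeric response values (n >= 5).
#' @return list: `family` (`"gamma_log"` or `"gaussian"`), `aic` (named
#'   vector with both AICs).
#' @export
select_family <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 5)
    stop("need at least 5 observations to select a response distribution")
  if (any(y <= 0))
    stop("distribution selection requires a strictly positive response")
  fg <- fitdistrplus::fitdist(y, "gamma")
  fn <- fitdistrplus::fitdist(y, "norm")
  aic <- c(gamma = fg$aic, normal = fn$aic)
  list(family = if (aic["gamma"] < aic["normal"]) "gamma_log" else "gaussian",
       aic = aic)
}

#' All-subsets AICc ranking, Akaike weights and model averaging
#'
#' Fits every subset of the predictors (including the intercept-only
#' model), ranks by AICc, and computes Akaike weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` over the full
#' candidate set. Coefficients are averaged over models with
#' `delta < delta_max` using renormalized weights; in the `"full"` average
#' a coefficient absent from a model contributes 0, in the `"conditional"`
#' average weights are renormalized per term over the models containing it.
#'
#' @param data data.frame.
#' @param response Response column name.
#' @param predictors Character vector of candidate predictors.
#' @param family GLM family as in [fit_glm()].
#' @param delta_max AICc difference defining the averaging set (default 2).
#' @param method `"full"` (default) or `"conditional"` averaging.
#' @return list: `models` (ranked data.frame `terms`, `df`, `logLik`,
#'   `AICc`, `delta`, `weight`), `average` (data.frame `term`,
#'   `estimate`), `fits` (list of `fit_result` in ranked order).
#' @export
all_subsets_average <- function(data, response, predictors,
                                family = "gaussian", delta_max = 2,
                                method = c("full", "conditional")) {
  method <- match.arg(method)
  stopifnot(length(predictors) >= 1)
  subsets <- unlist(lapply(0:length(predictors), function(m)
    utils::combn(predictors, m, simplify = FALSE)), recursive = FALSE)
  fits <- lapply(subsets, function(s) fit_glm(data, response, s, family))
  tab <- data.frame(
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept only)",
      character(1)),
    df = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"))
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  rownames(tab) <- NULL
  top <- which(tab$delta < delta_max)
  w <- tab$weight[top] / sum(tab$weight[top])
  terms <- unique(unlist(lapply(fits[top], function(f) f$coefficients$term)))
  est <- vapply(terms, function(tm) {
    b <- vapply(fits[top], function(f) {
      i <- match(tm, f$coefficients$term)
      if (is.na(i)) NA_real_ else f$coefficients$estimate[i]
    }, numeric(1))
    if (method == "full") sum(ifelse(is.na(b), 0, b) * w)
    else {
      has <- !is.na(b)
      sum(b[has] * w[has] / sum(w[has]))
    }
  }, numeric(1))
  list(models = tab,
       average = data.frame(term = terms, estimate = unname(est),
                            row.names = NULL),
       fits = fits)
}

.paper_model_specs <- function() {
  list(
    list(id = "p1", label = "Prediction 1: average distance from colony",
         response = "mean_dist", predictors = "motr", family = "gamma_log"),
    list(id = "p2", label = "Prediction 2: maximum distance from colony",
         response = "max_dist", predictors = "motr", family = "gaussian"),
    list(id = "p3", label = "Prediction 3: daily route",
         response = "route", predictors = "motr", family = "gamma_log"),
    list(id = "p4", label = "Prediction 4: daily duration of foraging",
         response = "foraging_dur", predictors = "motr", family = "gaussian"),
    list(id = "p5", label = "Prediction 5: frequency of colony visits",
         response = "visit_freq", predictors = c("motr", "mean_dist"),
         family = "gamma_log"),
    list(id = "p6", label = "Prediction 6: average flight speed",
         response = "flight_speed", predictors = "motr", family = "gaussian"),
    list(id = "p7", label = "Prediction 7: evening arrival time",
         response = "arrival_offset", predictors = "motr",
         family = "gaussian"),
    list(id = "p8", label = "Prediction 8: morning departure vs previous-day MoTR",
         response = "departure_offset", predictors = "motr_prev",
         family = "gaussian"),
    list(id = "p9a", label = "Prediction 9a: morning departure vs previous arrival",
         response = "departure_offset", predictors = "arrival_prev",
         family = "gaussian"),
    list(id = "p9b", label = "Prediction 9b: morning departure vs same-day MoTR",
         response = "departure_offset", predictors = "motr",
         family = "gaussian"),
    list(id = "p10", label = "Prediction 10: inter-individual distance",
         response = "interindiv_dist", predictors = c("motr", "mean_dist"),
         family = "gamma_log"))
}

#' Fit the full suite of foraging-response models
#'
#' Runs, on a joined metrics + MoTR day table, the standard model set:
#' a seasonal Spearman trend test of MoTR on date, Gamma GLMs for the
#' positive skewed responses (mean colony distance, daily route, visit
#' frequency, inter-individual distance) and Gaussian GLMs for the rest,
#' including the lagged models (morning departure against previous-day
#' MoTR and against the previous evening's arrival). The visit-frequency
#' two-predictor model set is additionally ranked and averaged by AICc.
#'
#' @param tbl data.frame with one row per day; required columns: `date`,
#'   `motr`, `mean_dist`, `max_dist`, `route`, `foraging_dur`,
#'   `visit_freq`, `flight_speed`, `arrival_offset`, `departure_offset`,
#'   `interindiv_dist`.
#' @param average_method Passed to [all_subsets_average()].
#' @return list: `table1` (data.frame `prediction`, `predictor`,
#'   `estimate`, `t`, `p`, `n`, `method`), `seasonal` (Spearman result),
#'   `table2` (AICc ranking for the visit-frequency model set), `fits`
#'   (named list of `fit_result`).
#' @export
run_paper_models <- function(tbl, average_method = "full") {
  req <- c("date", "motr", "mean_dist", "max_dist", "route",
           "foraging_dur", "visit_freq", "flight_speed", "arrival_offset",
           "departure_offset", "interindiv_dist")
  miss <- setdiff(req, names(tbl))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(tbl) < 5)
    stop("need at least 5 days of joined metrics/MoTR data, got ", nrow(tbl))
  tbl <- tbl[order(tbl$date), , drop = FALSE]
  prev <- match(tbl$date - 1, tbl$date)
  tbl$motr_prev <- tbl$motr[prev]
  tbl$arrival_prev <- tbl$arrival_offset[prev]

  seasonal <- spearman_test(as.numeric(tbl$date), tbl$motr)
  rows <- list(data.frame(prediction = "Seasonal trend: daily MoTR",
                          predictor = "ordinal date",
                          estimate = seasonal$rho, t = NA_real_,
                          p = seasonal$p, n = seasonal$n,
                          method = "Spearman rank correlation"))
  fits <- list()
  for (spec in .paper_model_specs()) {
    f <- fit_glm(tbl, spec$response, spec$predictors, spec$family)
    fits[[spec$id]] <- f
    co <- f$coefficients[f$coefficients$term != "(Intercept)", , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      prediction = spec$label, predictor = co$term, estimate = co$estimate,
      t = co$t, p = co$p, n = f$n,
      method = if (spec$family == "gaussian") "Gaussian GLM"
               else "Gamma GLM")
  }
  table2 <- all_subsets_average(tbl, "visit_freq", c("mean_dist", "motr"),
                                family = "gamma_log",
                                method = average_method)
  table1 <- do.call(rbind, rows)
  rownames(table1) <- NULL
  list(table1 = table1, seasonal = seasonal, table2 = table2, fits = fits)
}
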