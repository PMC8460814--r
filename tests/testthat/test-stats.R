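test_that("threshold fit solves to group means in closed form", {
  fits <- fit_visibility_response_models(c(0, 0, 1, 2), c(4, 6, 1, 3))
  th <- fits[fits$form == "threshold", ]
  expect_equal(th$a, 5)
  expect_equal(th$b, 2)
  ## degenerate inputs are flagged, not silently fitted
  expect_warning(fit_visibility_response_models(c(1, 2, 3), c(1, 2, 3)),
                 "degenerate")
})

test_that("closed-form threshold equals a refining grid-search minimizer", {
  set.seed(10)
  x <- c(rep(0, 50), runif(50, 0.01, 0.1))
  y <- ifelse(x == 0, 30, 25) + rnorm(100)
  th <- fit_visibility_response_models(x, y)
  th <- th[th$form == "threshold", ]
  ## iteratively refined grid search over (a, b) step functions
  sse <- function(a, b) sum((y - ifelse(x == 0, a, b))^2)
  ra <- range(y); rb <- range(y)
  for (it in 1:12) {
    ga <- seq(ra[1], ra[2], length.out = 41)
    gb <- seq(rb[1], rb[2], length.out = 41)
    s <- outer(ga, gb, Vectorize(sse))
    k <- which(s == min(s), arr.ind = TRUE)[1, ]
    sa <- diff(ra) / 40; sb <- diff(rb) / 40
    ra <- c(ga[k[1]] - sa, ga[k[1]] + sa)
    rb <- c(gb[k[2]] - sb, gb[k[2]] + sb)
  }
  expect_equal(th$a, mean(ra), tolerance = 1e-8)
  expect_equal(th$b, mean(rb), tolerance = 1e-8)
})

test_that("noise-free linear data makes the linear form win with zero SSE", {
  x <- c(0, 0, 0.02, 0.05, 0.08, 0.1)
  y <- 3 * x + 1
  fits <- fit_visibility_response_models(x, y)
  lin <- fits[fits$form == "linear", ]
  expect_equal(lin$sse, 0, tolerance = 1e-20)
  expect_equal(fits$form[1], "linear")     # ranked best by AIC
  expect_equal(lin$a, 3); expect_equal(lin$b, 1)
})

test_that("threshold-generated data is identified by AIC most of the time", {
  wins <- vapply(1:20, function(r) {
    set.seed(r)
    x <- c(rep(0, 200), runif(200, 0.008, 0.08))
    y <- ifelse(x == 0, 30, 25) + rnorm(400, 0, 1)
    fits <- fit_visibility_response_models(x, y)
    fits$form[1] == "threshold"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("AIC of the threshold form ignores affine rescaling of x", {
  set.seed(2)
  x <- c(rep(0, 30), runif(30, 0.01, 0.1))
  y <- ifelse(x == 0, 10, 8) + rnorm(60, 0, 0.5)
  f1 <- fit_visibility_response_models(x, y)
  f2 <- fit_visibility_response_models(x * 100, y)
  expect_equal(f1$aic[f1$form == "threshold"],
               f2$aic[f2$form == "threshold"], tolerance = 1e-12)
})

test_that("linear and exponential fits extrapolate beyond cosine = 1", {
  set.seed(5)
  x <- c(rep(0, 100), runif(100, 0.008, 0.08))
  y <- pmin(1, 0.72 + 3.5 * x + rnorm(200, 0, 0.05))
  fits <- fit_visibility_response_models(x, y)
  expect_gt(predict_form(fits, "linear", 0.2), 1)
  expect_gt(predict_form(fits, "exponential", 0.2), 1)
  ## the threshold form cannot leave the observed range
  expect_lte(predict_form(fits, "threshold", 0.2), max(y))
})

test_that("Bonferroni correction and declared thresholds compose", {
  expect_equal(corrected_alpha(0.05, 1), 0.05)
  expect_equal(corrected_alpha(0.05, 21), 0.05 / 21)
  ## a declared stricter threshold (0.001 < 0.05 / 21) wins
  fl <- significance_flags(c(0.0005, 0.002), 0.05, 21, declared = 0.001)
  expect_equal(attr(fl, "threshold"), 0.001)
  expect_equal(as.logical(fl), c(TRUE, FALSE))
  expect_error(corrected_alpha(1.2, 3))
})

test_that("the mixed model recovers an injected visibility effect", {
  hits <- vapply(1:10, function(r) {
    m <- generate_synthetic_measures(
      synthetic_design(effects = list(time_v = -5), seed = 100 + r))
    d <- prepare_trial_table(m)
    fit <- fit_lmer(d, "time_to_escalator",
                    c("AtriaType", "Block", "VisibilityCondition", "Session"),
                    "Participant")
    row <- fit$coefficients[fit$coefficients$term == "VisibilityConditionV", ]
    row$ci_lo <= -5 && -5 <= row$ci_hi
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("with no participant variance the mixed model matches OLS", {
  m <- generate_synthetic_measures(
    synthetic_design(effects = list(sd_p_time = 0), seed = 42))
  d <- prepare_trial_table(m)
  fit <- fit_lmer(d, "time_to_escalator",
                  c("AtriaType", "Block", "VisibilityCondition", "Session"),
                  "Participant")
  ols <- lm(time_to_escalator ~ AtriaType + Block + VisibilityCondition +
              Session, data = d)
  expect_true(fit$singular)
  expect_equal(fit$coefficients$coef, unname(coef(ols)), tolerance = 1e-4)
})

test_that("lmer guards reject unusable inputs", {
  m <- generate_synthetic_measures(synthetic_design(n_participants = 6))
  d <- prepare_trial_table(m)
  d2 <- d; d2$time_to_escalator[1] <- NA
  expect_error(fit_lmer(d2, "time_to_escalator", "Block", "Participant"),
               "missing")
  d3 <- d[d$subject_id == d$subject_id[1], ]
  expect_error(fit_lmer(d3, "time_to_escalator", "Block", "Participant"),
               "groups")
})

test_that("coefficient tables export to CSV and Markdown", {
  m <- generate_synthetic_measures(synthetic_design(n_participants = 10))
  d <- prepare_trial_table(m)
  fit <- fit_lmer(d, "time_to_escalator", "VisibilityCondition",
                  "Participant")
  f <- tempfile(fileext = ".csv")
  write_coef_csv(fit, f)
  expect_equal(nrow(read.csv(f)), nrow(fit$coefficients))
  md <- coef_markdown(fit)
  expect_match(md[1], "Coef")
  expect_match(md[length(md)], "Group var")
})
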