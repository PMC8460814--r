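## Visibility-response curve fitting (threshold / linear / exponential with
## Gaussian information criteria) and the mixed-effects coefficient
## pipeline.

gaussian_ic <- function(sse, n, k_param) {
  ## k_param counts the mean-structure parameters; +1 for the error variance
  k <- k_param + 1
  ll <- -n / 2 * (log(2 * pi * sse / n) + 1)
  list(loglik = ll, aic = 2 * k - 2 * ll, bic = log(n) * k - 2 * ll)
}

#' Fit the three visibility-response model forms
#'
#' Fits, to pairs of average destination visibility \code{x} and a response
#' \code{y}:
#' \itemize{
#'   \item threshold: \code{f(x) = a} if \code{x = 0}, \code{f(x) = b} if
#'     \code{x > 0} (closed form: group means);
#'   \item linear: \code{f(x) = a x + b} (least squares);
#'   \item exponential: \code{f(x) = a exp(b x)} (nonlinear least squares,
#'     log-linear initialization).
#' }
#' Information criteria use a Gaussian likelihood with parameters
#' \{a, b, sigma\} for every form, so AIC/BIC are comparable across forms.
#'
#' @param x non-negative visibility values.
#' @param y responses, same length, at least 3.
#' @return object of class \code{wv_modelfits}: a data frame (one row per
#'   form, ordered by AIC) with columns form, a, b, sse, loglik, aic, bic,
#'   n, converged.
#' @export
fit_visibility_response_models <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(x >= 0))
  n <- length(x)
  rows <- list()

  ## threshold (closed form)
  if (all(x == 0) || all(x > 0)) {
    warning("threshold fit degenerate: only one visibility group present")
    rows$threshold <- data.frame(form = "threshold", a = NA, b = NA,
                                 sse = NA, loglik = NA, aic = NA, bic = NA,
                                 n = n, converged = FALSE)
  } else {
    a <- mean(y[x == 0]); b <- mean(y[x > 0])
    pred <- ifelse(x == 0, a, b)
    sse <- sum((y - pred)^2)
    ic <- gaussian_ic(sse, n, 2)
    rows$threshold <- data.frame(form = "threshold", a = a, b = b, sse = sse,
                                 loglik = ic$loglik, aic = ic$aic,
                                 bic = ic$bic, n = n, converged = TRUE)
  }

  ## linear
  lf <- stats::lm(y ~ x)
  sse <- sum(stats::resid(lf)^2)
  ic <- gaussian_ic(sse, n, 2)
  rows$linear <- data.frame(form = "linear", a = unname(stats::coef(lf)[2]),
                            b = unname(stats::coef(lf)[1]), sse = sse,
                            loglik = ic$loglik, aic = ic$aic, bic = ic$bic,
                            n = n, converged = TRUE)

  ## exponential
  if (all(y > 0)) {
    ll <- stats::lm(log(y) ~ x)
    start <- list(a = exp(unname(stats::coef(ll)[1])),
                  b = unname(stats::coef(ll)[2]))
  } else {
    start <- list(a = mean(y), b = 0)
  }
  ef <- tryCatch(minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                                   control = minpack.lm::nls.lm.control(
                                     maxiter = 200)),
                 error = function(e) NULL)
  if (is.null(ef)) {
    rows$exponential <- data.frame(form = "exponential", a = NA, b = NA,
                                   sse = NA, loglik = NA, aic = NA, bic = NA,
                                   n = n, converged = FALSE)
  } else {
    sse <- sum(stats::resid(ef)^2)
    ic <- gaussian_ic(sse, n, 2)
    cf <- stats::coef(ef)
    rows$exponential <- data.frame(form = "exponential", a = unname(cf["a"]),
                                   b = unname(cf["b"]), sse = sse,
                                   loglik = ic$loglik, aic = ic$aic,
                                   bic = ic$bic, n = n, converged = TRUE)
  }

  out <- do.call(rbind, rows)
  out <- out[order(!out$converged, out$aic), ]
  rownames(out) <- NULL
  class(out) <- c("wv_modelfits", "data.frame")
  out
}

#' Predict from a fitted visibility-response form
#'
#' Useful for extrapolation sanity reports: the linear and exponential forms
#' extended beyond the observed visibility range can predict physically
#' impossible responses (e.g., a cosine similarity above 1), while the
#' threshold form cannot.
#'
#' @param fits a \code{wv_modelfits} data frame.
#' @param form one of "threshold", "linear", "exponential".
#' @param x visibility values to predict at.
#' @return numeric predictions.
#' @export
predict_form <- function(fits, form, x) {
  r <- fits[fits$form == form, ]
  if (nrow(r) != 1 || !r$converged) stop("no converged fit for form ", form)
  switch(form,
         threshold = ifelse(x == 0, r$a, r$b),
         linear = r$a * x + r$b,
         exponential = r$a * exp(r$b * x))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha uncorrected alpha in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return \code{alpha / n_tests}.
#' @export
corrected_alpha <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Significance flags under a (possibly stricter) declared threshold
#'
#' @param p p-values.
#' @param alpha uncorrected alpha.
#' @param n_tests number of tests for the Bonferroni correction.
#' @param declared an optional stricter declared threshold; the effective
#'   threshold is the minimum of the correction and the declared value.
#' @return logical vector of significance flags; the threshold used is
#'   attached as attribute \code{threshold}.
#' @export
significance_flags <- function(p, alpha = 0.05, n_tests = 1,
                               declared = NULL) {
  thr <- corrected_alpha(alpha, n_tests)
  if (!is.null(declared)) thr <- min(thr, declared)
  structure(p < thr, threshold = thr)
}

#' Prepare a trial table for mixed-model fitting
#'
#' Applies the reference encodings used throughout the analyses: visibility
#' condition as a factor with NV as reference (so the reported coefficient is
#' the V-minus-NV effect), block as a 0-based numeric covariate (the
#' intercept then describes non-visible trials in the first block), and
#' atria type / session as 0/1 factors.
#'
#' @param measures a segmented measures data frame.
#' @return data frame with columns ready for \code{\link{fit_lmer}}.
#' @export
prepare_trial_table <- function(measures) {
  d <- measures
  if (!"condition" %in% names(d)) d <- segment_visibility_condition(d)
  d$VisibilityCondition <- factor(d$condition, levels = c("NV", "V"))
  d$Block <- as.numeric(d$block) - 1
  d$AtriaType <- factor(d$atria_type,
                        levels = c("centralized", "distributed"))
  d$Session <- as.numeric(d$session) - 1
  d$Participant <- factor(d$subject_id)
  d
}

#' Fit a random-intercept mixed model and tabulate coefficients
#'
#' Thin wrapper around \code{lme4::lmer} producing the coefficient table
#' reported throughout: estimate, standard error, Wald z, two-sided normal
#' p-value, and 95\% confidence bounds (estimate +/- 1.96 SE), plus the
#' random-intercept ("group") and residual variances.
#'
#' @param data model data frame.
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names.
#' @param group grouping column name for the random intercept.
#' @param method "REML" (default) or "ML" (use ML when comparing models by
#'   information criteria).
#' @return object of class \code{wv_lmer}: list with \code{coefficients}
#'   (data frame), \code{group_var}, \code{resid_var}, \code{formula},
#'   \code{singular}, and the underlying \code{fit}.
#' @export
fit_lmer <- function(data, response, fixed, group, method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(response %in% names(data), all(fixed %in% names(data)),
            group %in% names(data))
  if (anyNA(data[[response]])) stop("missing values in the response")
  if (length(unique(data[[group]])) < 2)
    stop("need at least 2 groups for a random intercept")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(fixed, collapse = " + "),
                                 "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = data, REML = method == "REML")
  sm <- summary(fit)$coefficients
  z <- sm[, "Estimate"] / sm[, "Std. Error"]
  tab <- data.frame(term = rownames(sm),
                    coef = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    ci_lo = sm[, "Estimate"] - 1.96 * sm[, "Std. Error"],
                    ci_hi = sm[, "Estimate"] + 1.96 * sm[, "Std. Error"],
                    row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = tab,
                 group_var = vc$vcov[vc$grp == group][1],
                 resid_var = vc$vcov[vc$grp == "Residual"][1],
                 formula = deparse(fml),
                 method = method,
                 singular = lme4::isSingular(fit),
                 fit = fit),
            class = "wv_lmer")
}

#' @export
print.wv_lmer <- function(x, ...) {
  cat("<wv_lmer> ", x$formula, "  [", x$method, "]\n", sep = "")
  print(format_coef_table(x), row.names = FALSE)
  cat(sprintf("Group var %.3f   Residual var %.3f%s\n", x$group_var,
              x$resid_var,
              if (x$singular) "   (singular fit: a variance is ~0)" else ""))
  invisible(x)
}

format_coef_table <- function(x) {
  tab <- x$coefficients
  data.frame(term = tab$term,
             `Coef.` = round(tab$coef, 3),
             `Std.Err.` = round(tab$se, 3),
             z = round(tab$z, 3),
             p = signif(tab$p, 3),
             ci025 = round(tab$ci_lo, 3),
             ci975 = round(tab$ci_hi, 3),
             check.names = FALSE)
}

#' Write a coefficient table as CSV
#'
#' @param x a \code{wv_lmer}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_coef_csv <- function(x, path) {
  utils::write.csv(x$coefficients, path, row.names = FALSE)
  invisible(path)
}

#' Render a coefficient table as Markdown
#'
#' @param x a \code{wv_lmer}.
#' @return character vector of Markdown lines.
#' @export
coef_markdown <- function(x) {
  tab <- format_coef_table(x)
  hdr <- paste("|", paste(names(tab), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|")
  body <- apply(tab, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, unname(body),
    sprintf("| Group var | %.3f | | | | | |", x$group_var))
}
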