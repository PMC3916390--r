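#' Fit the standard linear mixed-effects model
#'
#' Fits `dependent ~ fixed + (1 + fixed | subject) + (1 | word-pair)` by
#' REML: one fixed effect (a covariate, or a ±1 group coding), by-subject
#' random intercepts and slopes, and by-item (word-pair) random
#' intercepts. The fixed-effect t and p values use the Satterthwaite
#' degrees-of-freedom approximation. A singular random-effects fit
#' triggers a warning and a refit with the by-subject slope dropped,
#' recorded in the result.
#'
#' @param data A `data.frame`.
#' @param dependent,fixed Column names of the dependent variable and the
#'   single fixed effect. When `fixed` is a coding it must be ±1.
#' @param subject,item Grouping column names (defaults `subject_id`,
#'   `pair_id`).
#' @param reml Fit by REML (default TRUE).
#' @return An `lme_result` list: `w` (regression weight of the fixed
#'   effect), `t`, `p`, `loglik`, `n`, `method`, `singular_fallback`,
#'   `formula`.
#' @export
fit_lme <- function(data, dependent, fixed, subject = "subject_id",
                    item = "pair_id", reml = TRUE) {
  for (col in c(dependent, fixed, subject, item))
    if (is.null(data[[col]])) stopf("fit_lme: column '%s' not found", col)
  if (length(unique(data[[subject]])) < 2 || length(unique(data[[item]])) < 2)
    stopf("fit_lme: need at least 2 subjects and 2 word-pairs")
  d <- data.frame(.y = data[[dependent]], .x = data[[fixed]],
                  .subj = factor(data[[subject]]),
                  .item = factor(data[[item]]))
  d <- d[stats::complete.cases(d), ]
  # Satterthwaite t/p via lmerTest; degenerate fits (e.g. zero residual
  # variance) fall back to the plain REML fit with a normal-approximation p
  fit_one <- function(form) {
    method <- "satterthwaite"
    fit <- tryCatch({
      f <- suppressMessages(lmerTest::lmer(form, data = d, REML = reml))
      stats::coef(summary(f))  # Satterthwaite df can fail on degenerate fits
      f
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- suppressMessages(lme4::lmer(form, data = d, REML = reml))
      method <- "normal-approximation"
    }
    list(fit = fit, method = method)
  }
  # progressive simplification: full structure -> no subject slope ->
  # no item intercept -> plain OLS (degenerate inputs, e.g. tiny groups)
  forms <- list(.y ~ .x + (1 + .x | .subj) + (1 | .item),
                .y ~ .x + (1 | .subj) + (1 | .item),
                .y ~ .x + (1 | .subj))
  f1 <- NULL; form <- NULL; fallback <- FALSE
  for (k in seq_along(forms)) {
    f1 <- tryCatch(fit_one(forms[[k]]), error = function(e) NULL)
    if (!is.null(f1) && k == 1 && lme4::isSingular(f1$fit, tol = 1e-4)) {
      warnf("fit_lme: singular random-effects fit; dropping the by-subject slope")
      f1 <- NULL
    }
    if (!is.null(f1)) { form <- forms[[k]]; fallback <- k > 1; break }
  }
  if (is.null(f1)) {
    warnf("fit_lme: mixed model inestimable on these data; plain OLS fallback")
    fit <- stats::lm(.y ~ .x, data = d)
    co <- stats::coef(summary(fit))
    return(structure(list(
      w = unname(co[".x", "Estimate"]), t = unname(co[".x", "t value"]),
      p = unname(co[".x", "Pr(>|t|)"]),
      loglik = as.numeric(stats::logLik(fit)), n = nrow(d), method = "ols",
      singular_fallback = TRUE, formula = ".y ~ .x", fit = fit),
      class = "lme_result"))
  }
  co <- tryCatch(stats::coef(summary(f1$fit)), error = function(e) NULL)
  if (is.null(co)) {
    # perfectly degenerate fit (e.g. zero residual variance): the weight
    # is still defined, the sampling-based t/p are not
    co <- matrix(c(unname(lme4::fixef(f1$fit)[".x"]), NA_real_, NA_real_),
                 1, 3, dimnames = list(".x", c("Estimate", "Std. Error",
                                               "t value")))
    f1$method <- "degenerate"
  }
  tv <- unname(co[".x", "t value"])
  pv <- if ("Pr(>|t|)" %in% colnames(co)) unname(co[".x", "Pr(>|t|)"]) else
    2 * stats::pnorm(-abs(tv))
  structure(list(
    w = unname(co[".x", "Estimate"]),
    t = tv,
    p = pv,
    loglik = as.numeric(stats::logLik(f1$fit)),
    n = nrow(d),
    method = f1$method,
    singular_fallback = fallback,
    formula = deparse(form),
    fit = f1$fit
  ), class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> w = %.4g, t = %.3g, p = %.3g, logLik = %.2f, n = %d%s\n",
              x$w, x$t, x$p, x$loglik, x$n,
              if (x$singular_fallback) " (slope dropped: singular)" else ""))
  invisible(x)
}

#' Compare two mixed models by log-likelihood
#'
#' @param result_a,result_b Two `lme_result`s fitted to the same
#'   dependent data (equal row counts enforced).
#' @return List: `preferred` ("a" or "b"), `loglik_a`, `loglik_b`,
#'   `difference` (a minus b).
#' @export
compare_models <- function(result_a, result_b) {
  if (result_a$n != result_b$n)
    stopf("compare_models: models were fitted to different row counts (%d vs %d)",
          result_a$n, result_b$n)
  diff <- result_a$loglik - result_b$loglik
  list(preferred = if (diff >= 0) "a" else "b",
       loglik_a = result_a$loglik, loglik_b = result_b$loglik,
       difference = diff)
}

#' Fit the raw-AS and log-AS RT models and compare them
#'
#' The log-AS model drops AS = 0 trials (log of zero is undefined; the
#' generator's latent floor is a generative device, not an analysis
#' choice). Both models are then fitted on that same trial subset so
#' their log-likelihoods are comparable.
#'
#' @param trials Behavioural trial table (missed trials are excluded).
#' @param dependent Dependent column (default `rt_s`).
#' @return List: `raw` and `log` (`lme_result`s), `comparison`
#'   (see [compare_models()]).
#' @export
rt_as_models <- function(trials, dependent = "rt_s") {
  d <- trials[!trials$missed & trials$as_score > 0, ]
  d$log_as <- log(d$as_score)
  d$raw_as <- d$as_score
  m_log <- fit_lme(d, dependent, "log_as")
  m_raw <- fit_lme(d, dependent, "raw_as")
  list(raw = m_raw, log = m_log, comparison = compare_models(m_log, m_raw))
}

#' Response ratio per group
#'
#' Fraction of "related" judgements among the non-missing responses of
#' each group. Empty groups yield `NA` with a warning.
#'
#' @param trials Trial table with a `response` column
#'   ("related"/"unrelated", `NA` when missed).
#' @param grouping Factor/vector of group labels (same length as rows of
#'   `trials`).
#' @return Named numeric vector of ratios in `[0, 1]`.
#' @export
response_ratio <- function(trials, grouping) {
  stopifnot(length(grouping) == nrow(trials))
  g <- factor(grouping)
  out <- tapply(trials$response, g, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_real_ else mean(r == "related")
  })
  out <- stats::setNames(as.vector(out), names(out))
  if (anyNA(out)) warnf("response_ratio: group(s) without responses: %s",
                        paste(names(out)[is.na(out)], collapse = ", "))
  out
}
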