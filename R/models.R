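#' Random-intercept mixed model of discounting or workload outcomes
#'
#' Linear mixed model with the given fixed effects and a participant random
#' intercept, fitted by REML through lme4 — the deterministic maximum-
#' likelihood counterpart of the flat-prior Bayesian multilevel models these
#' studies report (which they themselves describe as ML-equivalent).
#' Intervals are Gaussian (estimate +/- 1.96 SE). Load enters numerically,
#' coded 0/1/2 from the lowest high-effort level, so a single coefficient
#' captures the graded load effect.
#'
#' With a single observation per participant the random intercept is not
#' identified and the model degenerates gracefully to ordinary least squares
#' (random-intercept variance 0).
#'
#' @param data data frame; must contain `outcome_col`, `participant_id` and
#'   the fixed-effect columns.
#' @param outcome_col name of the outcome column.
#' @param fixed_effects character vector of predictor columns; `"load"` is
#'   recoded to 0/1/2; `"domain"` and interactions like `"load:domain"` are
#'   allowed.
#' @return `"coged_model_fit"`: list with `coefficients` (term, estimate,
#'   sd, ci_lower, ci_upper), `ranef_var`, `sigma2`, `r2` (explained-variance
#'   ratio of fixed + random predictions, Nakagawa-style conditional R^2),
#'   `residuals_fixed` (observed minus fixed-effect prediction),
#'   `fitted_fixed`, `data` (the model frame used) and `fit` (the underlying
#'   lme4 or lm object).
#' @export
fit_effort_model <- function(data, outcome_col = "sv",
                             fixed_effects = c("load")) {
  if (!outcome_col %in% names(data)) stop("missing outcome column '", outcome_col, "'")
  if (!"participant_id" %in% names(data)) stop("missing 'participant_id'")
  y <- data[[outcome_col]]
  if (any(!is.finite(y))) stop("non-finite outcome values")
  if (stats::sd(y) == 0) stop("zero variance in outcome '", outcome_col, "'")
  df <- data
  if ("load" %in% names(df)) df$load <- df$load - min(df$load) # 0/1/2 coding
  base_terms <- unique(unlist(strsplit(fixed_effects, ":", fixed = TRUE)))
  miss <- setdiff(base_terms, names(df))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  for (v in base_terms) {
    if (is.numeric(df[[v]]) && stats::sd(df[[v]]) == 0)
      stop("singular design: column '", v, "' is constant")
  }
  rhs <- paste(fixed_effects, collapse = " + ")
  Xchk <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
  qx <- qr(Xchk)
  if (qx$rank < ncol(Xchk))
    stop("singular design: collinear columns ",
         paste(colnames(Xchk)[qx$pivot[-seq_len(qx$rank)]], collapse = ", "))
  single_obs <- max(table(df$participant_id)) == 1L

  if (single_obs) {
    fit <- stats::lm(stats::as.formula(paste(outcome_col, "~", rhs)), data = df)
    if (any(is.na(stats::coef(fit))))
      stop("singular design: collinear columns ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ranef_var <- 0
    sigma2 <- stats::sigma(fit)^2
    fitted_fixed <- fitted_all <- stats::fitted(fit)
  } else {
    fml <- stats::as.formula(paste(outcome_col, "~", rhs, "+ (1 | participant_id)"))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    X <- lme4::getME(fit, "X")
    if (qr(X)$rank < ncol(X)) stop("singular design: collinear fixed-effect columns")
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- vc$vcov[vc$grp == "participant_id"][1]
    sigma2 <- stats::sigma(fit)^2
    fitted_fixed <- as.vector(X %*% est)
    fitted_all <- stats::fitted(fit)
  }
  var_f <- stats::var(fitted_fixed)
  var_r <- ranef_var
  r2 <- (var_f + var_r) / (var_f + var_r + sigma2)
  out <- list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              sd = unname(se),
                              ci_lower = unname(est - 1.96 * se),
                              ci_upper = unname(est + 1.96 * se)),
    ranef_var = ranef_var, sigma2 = sigma2,
    r2 = min(max(r2, 0), 1),
    fitted_fixed = fitted_fixed,
    residuals_fixed = y - fitted_fixed,
    residuals = y - fitted_all,
    data = df, fit = fit
  )
  class(out) <- "coged_model_fit"
  out
}

#' @export
print.coged_model_fit <- function(x, ...) {
  cat("Random-intercept model fit\n")
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-18s B = %6.3f [%6.3f, %6.3f], SD = %.3f\n",
                co$term[i], co$estimate[i], co$ci_lower[i], co$ci_upper[i], co$sd[i]))
  cat(sprintf("  random-intercept var = %.4f, R2 = %.3f\n", x$ranef_var, x$r2))
  invisible(x)
}

# domain-appropriate performance covariates
domain_covariates <- function(domain) {
  if (domain == "working_memory") c("hit_rate", "cr_rate", "mean_rt") else "intelligibility"
}

# join cell-level sv scores with the matching familiarization performance.
# high-effort load l corresponds to familiarization level l + 1.
join_performance <- function(sv_scores, performance) {
  sv <- sv_scores
  sv$level <- sv$load + 1L
  merge(sv, performance, by = c("participant_id", "domain", "level"), sort = FALSE)
}

#' Residualise subjective value on load and performance within one domain
#'
#' Fits [fit_effort_model()] with load plus the domain-appropriate
#' performance covariates (working memory: hit rate, correct-rejection rate,
#' mean RT; speech: intelligibility), then averages, per participant, the
#' residuals from the *fixed-effect* prediction only. The participant's
#' random intercept is deliberately not subtracted: it is exactly the
#' trait-like between-participant variance that downstream cross-domain
#' correlations are meant to measure.
#'
#' @param sv_scores cell-level scores of one domain ([score_choices()] rows).
#' @param performance familiarization performance table.
#' @param include_performance include the performance covariates (TRUE) or
#'   control for load only.
#' @param subtract_random_intercept alternative residual definition for
#'   sensitivity checks: also remove the estimated random intercept.
#' @return data frame `participant_id`, `domain`, `mean_residual`; the model
#'   fit is attached as attribute `"fit"`.
#' @export
residualize_domain <- function(sv_scores, performance, include_performance = TRUE,
                               subtract_random_intercept = FALSE) {
  domain <- unique(sv_scores$domain)
  if (length(domain) != 1L) stop("sv_scores must contain exactly one domain")
  dat <- join_performance(sv_scores, performance)
  fx <- c("load", if (include_performance) domain_covariates(domain))
  fit <- fit_effort_model(dat, "sv", fx)
  res <- fit$residuals_fixed
  if (subtract_random_intercept) res <- fit$residuals
  agg <- stats::aggregate(res, by = list(participant_id = dat$participant_id), FUN = mean)
  out <- data.frame(participant_id = agg$participant_id, domain = domain,
                    mean_residual = agg$x)
  attr(out, "fit") <- fit
  out
}

#' Mixed models of workload ratings
#'
#' One random-intercept model per rating scale (mental demand, effort,
#' frustration), with numeric load and domain as fixed effects. Ratings must
#' lie on the 1-21 visual-analog scale.
#'
#' @param ratings data frame `participant_id`, `domain`, `load`, `scale`,
#'   `rating`.
#' @return named list of `"coged_model_fit"` objects, one per scale.
#' @export
fit_ratings_models <- function(ratings) {
  if (any(ratings$rating < 1 | ratings$rating > 21))
    stop("validation error: ratings outside the 1-21 scale")
  scales <- unique(ratings$scale)
  fits <- lapply(scales, function(s) {
    dat <- ratings[ratings$scale == s, ]
    dat$domain <- factor(dat$domain)
    fit_effort_model(dat, "rating", c("load", "domain"))
  })
  names(fits) <- scales
  fits
}
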