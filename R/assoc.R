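#' Logistic regression for obstructive CAD (Wald inference)
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of a binary
#' outcome on an exposure plus optional covariates, with per-term odds
#' ratios, Wald 95% CIs and p-values. Quasi-complete separation is detected
#' (diverging coefficients / exploding standard errors) and reported as an
#' explicit failure rather than returned silently.
#'
#' @param outcome logical/0-1 vector (e.g. obstructive CAD vs the combined
#'   nonobstructive + no-CAD reference); both classes must be present.
#' @param exposure numeric or logical exposure vector.
#' @param covariates optional data.frame of covariate columns.
#' @param model_label label stored with the fit ("unadjusted", "model1",
#'   "model2", ...).
#' @return object of class `logistic_fit`: data.frame `terms` (term,
#'   estimate, se, odds_ratio, ci95_low, ci95_high, p), plus `model_label`,
#'   `converged`, `n`.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         model_label = "unadjusted") {
  y <- as.integer(outcome)
  if (length(unique(y)) < 2L)
    stop("outcome must contain both classes", call. = FALSE)
  df <- data.frame(.y = y, exposure = as.numeric(exposure))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, as.data.frame(lapply(covariates, as.numeric)))
  }
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  separated <- !fit$converged || any(abs(est[-1]) > 15) || any(se > 10)
  if (separated)
    stop("quasi-complete separation detected (diverging coefficients); ",
         "the model cannot be estimated reliably", call. = FALSE)
  z <- stats::qnorm(0.975)
  terms <- data.frame(
    term = rownames(cf),
    estimate = unname(est), se = unname(se),
    odds_ratio = unname(exp(est)),
    ci95_low = unname(exp(est - z * se)),
    ci95_high = unname(exp(est + z * se)),
    p = unname(cf[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(list(terms = terms, model_label = model_label,
                 converged = fit$converged, n = length(y)),
            class = "logistic_fit")
}

#' Covariate sets for the a priori adjusted models
#'
#' Model 1 adjusts for traditional cardiovascular risk (Framingham score,
#' standardised per SD), HIV-related factors (HIV duration per 5 years,
#' MSM, CD4 nadir < 200), microbiota/CAD-relevant medication (statins,
#' abacavir, antibiotics) and inflammation (IL-6, standardised per SD).
#' Model 2 is model 1 plus age (per 10 years) and sex.
#'
#' @param metadata cohort metadata data.frame (see [generate_cohort()]).
#' @param model one of "unadjusted", "model1", "model2".
#' @return a data.frame of covariates (zero columns for "unadjusted").
#' @export
model_covariates <- function(metadata, model = c("unadjusted", "model1",
                                                 "model2")) {
  model <- match.arg(model)
  if (model == "unadjusted")
    return(as.data.frame(matrix(nrow = nrow(metadata), ncol = 0)))
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  out <- data.frame(
    framingham_sd = zscore(metadata$framingham),
    hiv_duration_5y = metadata$hiv_duration_y / 5,
    msm = metadata$msm,
    cd4_nadir_lt200 = metadata$cd4_nadir_lt200,
    statins = metadata$statins,
    abacavir = metadata$abacavir,
    antibiotics = metadata$antibiotics,
    il6_sd = zscore(metadata$il6_pg_ml))
  if (model == "model2") {
    out$age_10y <- metadata$age_y / 10
    out$sex_male <- metadata$sex_male
  }
  out
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique score values; the AUC is the trapezoidal
#' integral of the ROC curve, which gives ties half credit and equals the
#' Mann-Whitney concordance probability.
#'
#' @param score numeric classifier score (higher = more case-like).
#' @param outcome logical/0-1 case indicator; both classes required.
#' @return list of class `roc_result`: `auc`, `thresholds`, `sens`, `spec`.
#' @export
roc_auc <- function(score, outcome) {
  y <- as.logical(outcome)
  if (!any(y) || all(y)) stop("both classes required", call. = FALSE)
  stopifnot(length(score) == length(y))
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  n_pos <- sum(y); n_neg <- sum(!y)
  sens <- vapply(thr, function(t) sum(score >= t & y) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(score < t & !y) / n_neg, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(auc = auc, thresholds = thr, sens = sens, spec = spec),
            class = "roc_result")
}

# fast OLS slope extraction used inside the bootstrap loop
.ols_coefs <- function(X, y) stats::lm.fit(X, y)$coefficients

#' Bootstrap mediation analysis (product of coefficients)
#'
#' Linear product-of-coefficients estimator for the chain exposure ->
#' mediator -> binary outcome, with the outcome entered in linear-probability
#' form: a from `m ~ x + covariates`, (c', b) from `y ~ x + m + covariates`,
#' c from `y ~ x + covariates`. Indirect effect (ACME) = a*b, direct = c',
#' total = c; on every draw total = direct + indirect exactly (OLS identity).
#' Percentile bootstrap (resampling rows) gives 95% CIs and a two-sided p
#' for each effect.
#'
#' @param x exposure (e.g. dysbiosis index), numeric.
#' @param m mediator (e.g. plasma ImP), numeric, non-constant.
#' @param y binary outcome (obstructive CAD), logical/0-1.
#' @param covariates optional data.frame.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return object of class `mediation_result`: `estimates` (data.frame
#'   effect/estimate/ci_low/ci_high/p for total, direct, indirect),
#'   `proportion_mediated`, `n_boot`, `boot` (draws matrix).
#' @export
mediate_bootstrap <- function(x, m, y, covariates = NULL, n_boot = 1000L,
                              seed = 1L) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, n >= 50L)
  if (stats::sd(m) == 0) stop("mediator is constant", call. = FALSE)
  y <- as.numeric(y)
  C <- if (is.null(covariates)) NULL else
    as.matrix(as.data.frame(lapply(covariates, as.numeric)))
  Xa <- cbind(1, x, C)          # m ~ x (+cov); y ~ x (+cov)
  Xb <- cbind(1, x, m, C)       # y ~ x + m (+cov)
  one_fit <- function(idx) {
    a <- .ols_coefs(Xa[idx, , drop = FALSE], m[idx])[2]
    bc <- .ols_coefs(Xb[idx, , drop = FALSE], y[idx])
    ctot <- .ols_coefs(Xa[idx, , drop = FALSE], y[idx])[2]
    c(total = unname(ctot), direct = unname(bc[2]),
      indirect = unname(a * bc[3]))
  }
  point <- one_fit(seq_len(n))
  boot <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_boot),
             function(b) one_fit(sample.int(n, n, replace = TRUE)),
             numeric(3)))
  })
  summarise <- function(col) {
    v <- boot[, col]
    ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    p <- min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
    data.frame(effect = col, estimate = unname(point[col]),
               ci_low = ci[1], ci_high = ci[2], p = p,
               stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, lapply(c("total", "direct", "indirect"), summarise))
  prop <- if (abs(point["total"]) > 1e-12)
    unname(point["indirect"] / point["total"]) else NA_real_
  structure(list(estimates = est, proportion_mediated = prop,
                 n_boot = as.integer(n_boot), boot = boot),
            class = "mediation_result")
}
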