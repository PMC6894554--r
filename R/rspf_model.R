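# Hierarchical resource selection probability function (RSPF):
# used/unused logistic GLMM with density-by-habitat interactions, a random
# iid year intercept and random pack-level coefficients, fit by a
# Laplace-approximated marginal likelihood. Plus penalized-ML variable
# pre-reduction, prediction through the inverse-logit RSPF, diagnostics
# (Pearson r, AUC, WAIC-style criterion, conditional predictive ordinate),
# density-response curves and a pack-heterogeneity post-hoc comparison.

#' Specify an RSPF model
#'
#' @param fixed Character vector of fixed covariate names (columns of the
#'   sample table, standardized).
#' @param density Name of the (standardized) regional density column; NULL
#'   to omit density from the model.
#' @param interactions Covariates interacting with density (subset of
#'   `fixed`); defaults to all fixed covariates.
#' @param year,pack Factor column names for the random year intercept and
#'   random pack coefficients; NULL drops that random term.
#' @param pack_slopes Covariates receiving pack-level random coefficients
#'   (independent variances, no cross-covariate correlation); defaults to
#'   all fixed covariates. A pack random intercept is always included with
#'   the slopes.
#' @return An `rspf_spec`.
#' @export
rspf_spec <- function(fixed, density = "wolf_density", interactions = fixed,
                      year = "year", pack = "pack_id", pack_slopes = fixed) {
  if (!all(interactions %in% fixed))
    stop("interaction covariates must be a subset of fixed covariates")
  structure(list(fixed = fixed, density = density,
                 interactions = if (is.null(density)) character(0) else interactions,
                 year = year, pack = pack, pack_slopes = pack_slopes),
            class = "rspf_spec")
}

rspf_formula <- function(spec) {
  rhs <- spec$fixed
  if (!is.null(spec$density)) rhs <- c(rhs, spec$density)
  if (length(spec$interactions))
    rhs <- c(rhs, paste0(spec$interactions, ":", spec$density))
  re <- character(0)
  if (!is.null(spec$year)) re <- c(re, sprintf("(1 | %s)", spec$year))
  if (!is.null(spec$pack)) {
    terms <- paste(c("1", spec$pack_slopes), collapse = " + ")
    re <- c(re, sprintf("(%s || %s)", terms, spec$pack))
  }
  stats::as.formula(paste("y ~", paste(c(rhs, re), collapse = " + ")))
}

#' Penalized-ML variable pre-reduction
#'
#' Fits a sparsity-inducing (lasso) penalized logistic regression of
#' used/unused on the candidate covariates over a penalty grid, picks the
#' penalty by cross-validated predictive deviance, and drops candidates
#' whose coefficient is zero at the chosen penalty.
#'
#' @param table A SampleTable data.frame with `y` and the candidates.
#' @param candidates Character vector (>= 2) of candidate covariate names.
#' @param lambda Optional penalty grid; a single near-zero value retains
#'   all candidates (the unpenalized limit).
#' @param nfolds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return Character vector of retained names; attributes `path` (the
#'   glmnet fit), `lambda` (chosen penalty) and `cv` (the cv.glmnet object,
#'   when a grid was searched).
#' @export
reduce_variables <- function(table, candidates, lambda = NULL, nfolds = 10,
                             seed = 1L) {
  stopifnot(length(candidates) >= 2)
  if (length(unique(table$y)) < 2) stop("separation error: table has one class")
  X <- as.matrix(table[, candidates, drop = FALSE])
  y <- table$y
  if (!is.null(lambda) && length(lambda) == 1L) {
    fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lambda)
    co <- as.matrix(stats::coef(fit))[-1, 1]
    out <- candidates[abs(co) > 0]
    attr(out, "path") <- fit; attr(out, "lambda") <- lambda
    return(out)
  }
  # perfectly collinear duplicates are resolved before the lasso (the
  # penalized solution is not unique over an exactly duplicated pair)
  dup <- rep(FALSE, length(candidates))
  for (i in seq_along(candidates)[-1]) for (j in seq_len(i - 1)) {
    if (!dup[j] && abs(stats::cor(X[, i], X[, j])) > 1 - 1e-12) dup[i] <- TRUE
  }
  cand <- candidates[!dup]
  X <- X[, cand, drop = FALSE]
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = nfolds,
                          type.measure = "deviance",
                          lambda = lambda)
  # one-standard-error rule: the sparsest model within one CV standard
  # error of the minimum predictive deviance
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  out <- cand[abs(co) > 0]
  attr(out, "path") <- cv$glmnet.fit
  attr(out, "lambda") <- cv$lambda.1se
  attr(out, "cv") <- cv
  out
}

#' Fit the hierarchical RSPF
#'
#' Estimates the used/unused logistic model y ~ X beta + f(year) + f(x, pack)
#' with fixed effects (including covariate-by-density products), an
#' independent Gaussian year intercept and independent Gaussian pack-level
#' coefficient deviations, by maximizing the Laplace-approximated marginal
#' likelihood. When the spec carries no random terms the model reduces
#' exactly to single-level logistic regression. Coefficient summaries
#' follow the mean / s.e. / 2.5th / 97.5th / mode schema from the
#' approximate Gaussian posterior (mode = mean under this approximation).
#'
#' @param table A SampleTable data.frame (`y` plus standardized covariates
#'   and factors).
#' @param spec An `rspf_spec`.
#' @param ridge On (near-)separation, refit with a small ridge penalty and
#'   warn rather than fail (single-level path only).
#' @param ranef `"estimate"` (default) estimates the random-effect
#'   variances; `"zero"` constrains them to zero, under which the Laplace
#'   marginal likelihood degenerates to the ordinary likelihood and the fit
#'   equals single-level logistic regression (solved by the package's own
#'   Newton iteration).
#' @return An `rspf_fit`: `coefficients` (summary data.frame), `vcov`,
#'   `ranef_variance`, `pack_deviations` (matrix packs x coefficients),
#'   `fitted`, `model`, `spec`, `converged`, `scalers` (copied from the
#'   table, if present).
#' @export
fit_rspf <- function(table, spec, ridge = TRUE, ranef = c("estimate", "zero")) {
  ranef <- match.arg(ranef)
  if (length(unique(table$y)) < 2) stop("table must contain both classes")
  has_re <- (!is.null(spec$year) || !is.null(spec$pack)) && ranef == "estimate"
  form <- rspf_formula(spec)
  if (!is.null(spec$year) || !is.null(spec$pack)) form_fixed <- lme4::nobars(form)
  else form_fixed <- form
  if (!has_re && ranef == "zero") {
    # variances fixed at zero: maximize the degenerate marginal likelihood
    # (= ordinary likelihood) with the package's Newton solver
    fit <- ridge_logistic(form_fixed, table, lambda = 0)
    beta <- stats::coef(fit)
    V <- fit$vcov
    nm_var <- c(if (!is.null(spec$year)) paste0(spec$year, ".(Intercept)"),
                if (!is.null(spec$pack)) paste0(spec$pack, ".", c("(Intercept)", spec$pack_slopes)))
    ranef_variance <- stats::setNames(rep(0, length(nm_var)), nm_var)
    pack_dev <- if (!is.null(spec$pack))
      matrix(0, nlevels(factor(table[[spec$pack]])), 1 + length(spec$pack_slopes),
             dimnames = list(levels(factor(table[[spec$pack]])),
                             c("(Intercept)", spec$pack_slopes))) else NULL
    fitted <- stats::fitted(fit)
    conv <- TRUE
    loglik <- as.numeric(stats::logLik(fit))
  } else if (has_re) {
    fit <- lme4::glmer(form, data = table, family = stats::binomial(),
                       control = lme4::glmerControl(optimizer = "bobyqa",
                                                    calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    ranef_variance <- unlist(lapply(vc, function(m) diag(m)))
    pack_dev <- if (!is.null(spec$pack)) as.matrix(lme4::ranef(fit)[[spec$pack]]) else NULL
    fitted <- stats::fitted(fit)
    conv <- length(fit@optinfo$conv$lme4) == 0
    loglik <- as.numeric(stats::logLik(fit))
  } else {
    fit <- stats::glm(form, data = table, family = stats::binomial())
    if (ridge && (!fit$converged || any(abs(stats::coef(fit)) > 20))) {
      warning("possible complete separation; refitting with a small ridge penalty")
      fit <- ridge_logistic(form, table)
    }
    beta <- stats::coef(fit)
    V <- as.matrix(stats::vcov(fit))
    ranef_variance <- numeric(0)
    pack_dev <- NULL
    fitted <- stats::fitted(fit)
    conv <- isTRUE(fit$converged) || is.null(fit$converged)
    loglik <- as.numeric(stats::logLik(fit))
  }
  se <- sqrt(diag(V))
  coefs <- data.frame(parameter = names(beta), mean = unname(beta),
                      se = unname(se),
                      q2.5 = unname(beta - 1.96 * se),
                      q97.5 = unname(beta + 1.96 * se),
                      mode = unname(beta),
                      mean_se = unname(beta / se))
  coefs <- coefs[order(-abs(coefs$mean_se)), ]
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, beta = beta, vcov = V,
                 ranef_variance = ranef_variance,
                 pack_deviations = pack_dev, fitted = as.numeric(fitted),
                 model = fit, spec = spec, converged = conv,
                 loglik = loglik, n = nrow(table),
                 scalers = attr(table, "scalers")),
            class = "rspf_fit")
}

ridge_logistic <- function(form, table, lambda = 1e-4) {
  mf <- stats::model.frame(stats::update(form, . ~ . ), table)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- drop(X %*% beta); p <- stats::plogis(eta)
  out <- list(coefficients = stats::setNames(drop(beta), colnames(X)),
              fitted.values = p, converged = TRUE,
              vcov = solve(crossprod(X, X * (p * (1 - p))) + diag(lambda, ncol(X))),
              loglik = sum(stats::dbinom(y, 1, p, log = TRUE)))
  class(out) <- "ridge_logistic"
  out
}

#' @export
coef.ridge_logistic <- function(object, ...) object$coefficients
#' @export
vcov.ridge_logistic <- function(object, ...) object$vcov
#' @export
fitted.ridge_logistic <- function(object, ...) object$fitted.values
#' @export
logLik.ridge_logistic <- function(object, ...) object$loglik

#' @export
print.rspf_fit <- function(x, ...) {
  cat(sprintf("<rspf_fit> n=%d, %d fixed effects, %d random-effect variances%s\n",
              x$n, length(x$beta), length(x$ranef_variance),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Predict from the RSPF
#'
#' Inverse-logit of the linear predictor (the RSPF of the fitted model).
#' Population level uses the fixed effects conditioned on the supplied
#' density (default 0 = the mean density on the standardized scale); pack
#' level adds that pack's coefficient deviations.
#'
#' @param fit An `rspf_fit`.
#' @param x Named numeric vector (or data.frame row) of standardized
#'   covariate values for the spec's fixed covariates.
#' @param density Standardized regional density at which to condition.
#' @param level `"population"` or `"pack"`.
#' @param pack Pack id (required at pack level).
#' @return Probability of use in (0, 1).
#' @export
predict_rspf <- function(fit, x = NULL, density = 0,
                         level = c("population", "pack"), pack = NULL) {
  level <- match.arg(level)
  spec <- fit$spec
  beta <- fit$beta
  eta <- unname(beta["(Intercept)"])
  xv <- if (is.null(x)) stats::setNames(rep(0, length(spec$fixed)), spec$fixed)
        else unlist(x)[spec$fixed]
  for (nm in spec$fixed) {
    b <- if (nm %in% names(beta)) beta[[nm]] else 0
    eta <- eta + b * xv[[nm]]
  }
  if (!is.null(spec$density)) {
    eta <- eta + beta[[spec$density]] * density
    for (nm in spec$interactions) {
      key <- intersect(c(paste0(nm, ":", spec$density), paste0(spec$density, ":", nm)),
                       names(beta))
      if (length(key)) eta <- eta + beta[[key[1]]] * xv[[nm]] * density
    }
  }
  if (level == "pack") {
    if (is.null(pack) || is.null(fit$pack_deviations) ||
        !(pack %in% rownames(fit$pack_deviations)))
      stop("unknown pack id for pack-level prediction")
    dev <- fit$pack_deviations[pack, ]
    if ("(Intercept)" %in% names(dev)) eta <- eta + dev[["(Intercept)"]]
    for (nm in intersect(names(dev), spec$fixed)) eta <- eta + dev[[nm]] * xv[[nm]]
  }
  stats::plogis(unname(eta))
}

# rank-statistic AUC (Mann-Whitney with midranks for ties)
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class data")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' RSPF fit diagnostics
#'
#' Pearson's correlation between fitted probabilities and the 0/1 response,
#' AUC via the rank statistic, a WAIC-style information criterion and the
#' leave-one-out log-conditional-predictive-ordinate score, the latter two
#' from draws of the approximate Gaussian posterior of the fixed effects
#' (conditional on the random-effect modes).
#'
#' @param fit An `rspf_fit`.
#' @param table The SampleTable the model was fit to.
#' @param n_draws Posterior draws for WAIC / CPO.
#' @param seed Seed for the draws.
#' @return A `diagnostics_report`: `pearson_r`, `auc`, `waic`, `lcpo`,
#'   `p_waic`, plus a `flags` character vector.
#' @export
rspf_diagnostics <- function(fit, table, n_draws = 1000, seed = 1L) {
  y <- table$y
  p <- fit$fitted
  flags <- character(0)
  if (stats::sd(p) < 1e-12) {
    pearson_r <- 0
    auc <- 0.5
    flags <- c(flags, "constant fitted values; pearson_r set to 0")
  } else {
    pearson_r <- stats::cor(p, y)
    auc <- auc_rank(p, y)
  }
  set.seed(seed)
  eta_hat <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  X <- rspf_fixed_design(fit, table)
  offset <- eta_hat - drop(X %*% fit$beta)   # random-effect contribution
  draws <- MASS::mvrnorm(n_draws, fit$beta, fit$vcov)
  ll <- matrix(NA_real_, nrow(table), n_draws)
  for (s in seq_len(n_draws)) {
    ps <- stats::plogis(drop(X %*% draws[s, ]) + offset)
    ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
    ll[, s] <- stats::dbinom(y, 1, ps, log = TRUE)
  }
  lppd <- sum(apply(ll, 1, log_mean_exp))
  p_waic <- sum(apply(ll, 1, stats::var))
  waic <- -2 * (lppd - p_waic)
  # CPO_i = harmonic mean of the per-draw likelihoods
  lcpo <- sum(-apply(-ll, 1, log_mean_exp))
  structure(list(pearson_r = pearson_r, auc = auc, waic = waic,
                 p_waic = p_waic, lcpo = lcpo, n_draws = n_draws,
                 flags = flags),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics> r = %.3f, AUC = %.3f, WAIC = %.1f (p_eff %.1f), LCPO = %.1f\n",
              x$pearson_r, x$auc, x$waic, x$p_waic, x$lcpo))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

log_mean_exp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}

rspf_fixed_design <- function(fit, table) {
  form <- rspf_formula(fit$spec)
  fixed_form <- lme4::nobars(form)
  stats::model.matrix(fixed_form[-2], table)[, names(fit$beta), drop = FALSE]
}

#' Density-response curves for a covariate with a density interaction
#'
#' At each regional density d the covariate's effective slope is
#' beta_x + beta_(x by d) * d; the curve is the inverse logit of
#' logit(baseline probability) + effective slope * z over a standardized
#' covariate range. The density at which the slope changes sign (when the
#' interaction is non-zero) is -beta_x / beta_(x by d).
#'
#' @param fit An `rspf_fit`.
#' @param covariate Fixed covariate name.
#' @param density_grid Standardized densities at which to evaluate.
#' @param baseline_prob Occurrence probability the curves are conditioned
#'   on at z = 0 (default 0.5).
#' @param z_range Standardized covariate range.
#' @param n_z Evaluation points along z.
#' @return A `density_response` list: `z`, `curves` (matrix z x densities),
#'   `effective_slopes`, `sign_switch_density` (NA when no switch).
#' @export
density_response_curves <- function(fit, covariate, density_grid = seq(-2, 2, by = 1),
                                    baseline_prob = 0.5, z_range = c(-3, 3),
                                    n_z = 121) {
  beta <- fit$beta
  if (!(covariate %in% names(beta))) stop("unknown covariate '", covariate, "'")
  b_main <- beta[[covariate]]
  key <- intersect(c(paste0(covariate, ":", fit$spec$density),
                     paste0(fit$spec$density, ":", covariate)), names(beta))
  b_int <- if (length(key)) beta[[key[1]]] else 0
  if (b_int == 0)
    warning("covariate has no density interaction; curves are identical at all densities")
  z <- seq(z_range[1], z_range[2], length.out = n_z)
  slopes <- b_main + b_int * density_grid
  curves <- sapply(slopes, function(s) stats::plogis(stats::qlogis(baseline_prob) + s * z))
  colnames(curves) <- as.character(density_grid)
  switch_d <- if (b_int != 0) -b_main / b_int else NA_real_
  structure(list(z = z, curves = curves, density_grid = density_grid,
                 effective_slopes = stats::setNames(slopes, density_grid),
                 sign_switch_density = switch_d, covariate = covariate,
                 baseline_prob = baseline_prob),
            class = "density_response")
}

#' Post-hoc pack-heterogeneity comparison
#'
#' Splits packs at the 25th and 75th percentiles of their pack-level
#' coefficient for a covariate (fixed effect plus the pack's random
#' deviation) and compares mean annual pack sizes between the weak- and
#' strong-response groups with a two-sample t test and a Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param fit An `rspf_fit` with pack deviations.
#' @param pack_sizes Named numeric: mean annual size per pack id.
#' @param covariate Covariate whose pack-level coefficient defines the split.
#' @return A `pack_heterogeneity` list: group ids and means, `t_stat`,
#'   `t_p`, `w_stat`, `w_p`, `mean_difference`.
#' @export
pack_heterogeneity_test <- function(fit, pack_sizes, covariate) {
  if (is.null(fit$pack_deviations) || !(covariate %in% colnames(fit$pack_deviations)))
    stop("fit has no pack-level deviations for '", covariate, "'")
  coefs <- fit$beta[[covariate]] + fit$pack_deviations[, covariate]
  packs <- rownames(fit$pack_deviations)
  if (length(packs) < 8) stop("insufficient groups: need >= 8 packs")
  sizes <- pack_sizes[packs]
  qs <- stats::quantile(coefs, c(0.25, 0.75))
  weak <- packs[coefs <= qs[1]]
  strong <- packs[coefs >= qs[2]]
  strong <- setdiff(strong, weak)   # degenerate spreads: keep groups disjoint
  if (length(weak) < 2 || length(strong) < 2)
    stop("insufficient groups after quartile split")
  a <- sizes[weak]; b <- sizes[strong]
  if (stats::sd(c(a, b)) < 1e-12) {
    tt <- list(statistic = 0, p.value = 1)
    wt <- list(statistic = length(a) * length(b) / 2, p.value = 1)
  } else {
    tt <- stats::t.test(b, a)
    wt <- stats::wilcox.test(b, a, exact = FALSE, correct = FALSE)
  }
  structure(list(weak_packs = weak, strong_packs = strong,
                 weak_mean = mean(a), strong_mean = mean(b),
                 mean_difference = mean(b) - mean(a),
                 t_stat = unname(tt$statistic), t_p = tt$p.value,
                 w_stat = unname(wt$statistic), w_p = wt$p.value,
                 covariate = covariate),
            class = "pack_heterogeneity")
}

#' @export
print.pack_heterogeneity <- function(x, ...) {
  cat(sprintf("<pack_heterogeneity> %s: weak mean %.2f (n=%d) vs strong %.2f (n=%d); t=%.2f (p=%.3g), W=%.0f (p=%.3g)\n",
              x$covariate, x$weak_mean, length(x$weak_packs), x$strong_mean,
              length(x$strong_packs), x$t_stat, x$t_p, x$w_stat, x$w_p))
  invisible(x)
}
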