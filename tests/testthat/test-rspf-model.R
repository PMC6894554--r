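test_that("penalized reduction keeps signal, drops noise and resolves collinearity", {
  keep_rate <- 0; drop_rate <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 5000
    signal <- rnorm(n); noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 1 * signal))
    tab <- data.frame(y = y, signal = signal, noise = noise)
    kept <- reduce_variables(tab, c("signal", "noise"), seed = s)
    keep_rate <- keep_rate + ("signal" %in% kept)
    drop_rate <- drop_rate + !("noise" %in% kept)
  }
  expect_gte(keep_rate / 10, 0.9)
  expect_gte(drop_rate / 10, 0.9)
  # unpenalized limit retains everything
  set.seed(1)
  tab <- data.frame(y = rbinom(500, 1, 0.5), a = rnorm(500), b = rnorm(500))
  expect_setequal(reduce_variables(tab, c("a", "b"), lambda = 1e-8), c("a", "b"))
  # perfect collinearity: at most one of the duplicated pair survives
  set.seed(2)
  x <- rnorm(4000); y <- rbinom(4000, 1, plogis(x))
  tab2 <- data.frame(y = y, x1 = x, x2 = x, z = rnorm(4000))
  kept2 <- reduce_variables(tab2, c("x1", "x2", "z"), seed = 2)
  expect_lte(sum(c("x1", "x2") %in% kept2), 1 + 0)  # lasso picks one of the pair
})

test_that("fit_rspf recovers plain logistic truth and reduces to glm", {
  # parameter recovery across seeds, single-level path
  cover <- 0
  for (s in 1:10) {
    d <- logistic_data(20000, beta = c(-2, 1, -0.5), seed = s)
    spec <- rspf_spec("x1", interactions = character(0), year = NULL, pack = NULL)
    fit <- fit_rspf(d, spec)
    co <- fit$coefficients
    ok <- all(abs(co$mean[match(c("(Intercept)", "x1", "wolf_density"), co$parameter)] -
                  c(-2, 1, -0.5)) <=
              1.96 * co$se[match(c("(Intercept)", "x1", "wolf_density"), co$parameter)])
    cover <- cover + ok
  }
  expect_gte(cover / 10, 0.8)

  # variances constrained to zero: the hierarchical fit collapses to
  # single-level logistic regression (independent glm oracle) to 1e-4
  d <- logistic_data(5000, seed = 99)
  spec_re <- rspf_spec("x1", interactions = "x1")
  f0 <- fit_rspf(d, spec_re, ranef = "zero")
  g <- glm(y ~ x1 + wolf_density + x1:wolf_density, data = d, family = binomial())
  expect_lt(max(abs(f0$beta - coef(g)[names(f0$beta)]) /
                pmax(abs(coef(g)[names(f0$beta)]), 1e-8)), 1e-4)
  expect_true(all(f0$ranef_variance == 0))
  expect_true(all(f0$pack_deviations == 0))
  # the estimated path lands at (or near) the same boundary solution
  f_re <- fit_rspf(d, spec_re)
  expect_lt(max(abs(f_re$beta - coef(g)[names(f_re$beta)]) /
                pmax(abs(coef(g)[names(f_re$beta)]), 1e-8)), 0.05)
})

test_that("density interactions are recovered with the right sign", {
  hits <- 0
  for (s in 1:10) {
    d <- logistic_data(20000, beta = c(-1, 0.8, 0.3), seed = 200 + s,
                       interaction = -0.3)
    spec <- rspf_spec("x1", interactions = "x1", year = NULL, pack = NULL)
    fit <- fit_rspf(d, spec)
    co <- fit$coefficients
    i <- grep("x1:wolf_density|wolf_density:x1", co$parameter)
    hits <- hits + (co$q97.5[i] < 0)   # CI excludes 0 with the true sign
  }
  expect_gte(hits / 10, 0.9)
})

test_that("predictions follow the inverse-logit linear predictor exactly", {
  d <- logistic_data(2000, seed = 5)
  spec <- rspf_spec("x1", interactions = "x1", year = NULL, pack = NULL)
  fit <- fit_rspf(d, spec)
  # all-zero coefficients give probability one half
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(predict_rspf(fit0, c(x1 = 1), density = 1), 0.5)
  # the published-scale intercept evaluates through the inverse logit
  fit1 <- fit
  fit1$beta[] <- 0
  fit1$beta["(Intercept)"] <- -8.089
  expect_equal(predict_rspf(fit1, c(x1 = 0), density = 0),
               plogis(-8.089), tolerance = 1e-12)
  expect_lt(abs(predict_rspf(fit1, c(x1 = 0), density = 0) - 3.07e-4), 5e-6)
  # a density main effect of 0.724 moves the log-odds by exactly 0.724
  fit2 <- fit
  fit2$beta[] <- 0
  fit2$beta["wolf_density"] <- 0.724
  lo <- function(p) log(p / (1 - p))
  expect_equal(lo(predict_rspf(fit2, c(x1 = 0), density = 1)) -
               lo(predict_rspf(fit2, c(x1 = 0), density = 0)), 0.724,
               tolerance = 1e-10)
  # monotone in each covariate with the sign of its effective slope
  expect_equal(predict_rspf(fit, c(x1 = 1), density = 0) >
                 predict_rspf(fit, c(x1 = -1), density = 0),
               fit$beta[["x1"]] > 0)
})

test_that("diagnostics match brute-force concordance and guard degenerate fits", {
  d <- logistic_data(500, seed = 6)
  spec <- rspf_spec("x1", interactions = character(0), year = NULL, pack = NULL)
  fit <- fit_rspf(d, spec)
  rep <- rspf_diagnostics(fit, d, n_draws = 200, seed = 1)
  # O(n^2) all-pairs concordance oracle
  p <- fit$fitted; y <- d$y
  conc <- 0; tot <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    tot <- tot + 1
    conc <- conc + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  }
  expect_equal(rep$auc, conc / tot, tolerance = 1e-12)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(abs(rep$pearson_r) <= 1)
  expect_true(is.finite(rep$waic) && is.finite(rep$lcpo))
  # perfectly separating fitted values
  fit_perf <- fit; fit_perf$fitted <- ifelse(y == 1, 0.9, 0.1)
  expect_equal(rspf_diagnostics(fit_perf, d, n_draws = 50)$auc, 1)
  # constant fitted values: AUC 0.5 and flagged zero correlation
  fit_c <- fit; fit_c$fitted <- rep(0.4, nrow(d))
  rep_c <- rspf_diagnostics(fit_c, d, n_draws = 50)
  expect_equal(rep_c$auc, 0.5)
  expect_equal(rep_c$pearson_r, 0)
  expect_gt(length(rep_c$flags), 0)
})

test_that("density-response curves implement the effective-slope arithmetic", {
  d <- logistic_data(2000, seed = 7)
  spec <- rspf_spec("x1", interactions = "x1", year = NULL, pack = NULL)
  fit <- fit_rspf(d, spec)
  # published-scale inputs: main 0.287, interaction -0.110
  fit$beta[] <- 0
  fit$beta["x1"] <- 0.287
  fit$beta[grep("x1:wolf_density|wolf_density:x1", names(fit$beta))] <- -0.110
  cur <- density_response_curves(fit, "x1", density_grid = c(0, 2))
  expect_equal(unname(cur$effective_slopes["2"]), 0.287 - 0.220, tolerance = 1e-12)
  expect_gt(cur$effective_slopes["2"], 0)   # positive but shallower
  expect_lt(cur$effective_slopes["2"], cur$effective_slopes["0"])
  # sign switch at -beta_x / beta_xd
  expect_equal(cur$sign_switch_density, 0.287 / 0.110, tolerance = 1e-9)
  # curves pass through the baseline probability at z = 0
  expect_equal(unname(cur$curves[which.min(abs(cur$z)), ]), c(0.5, 0.5),
               tolerance = 1e-6)
  # zero interaction gives identical curves at all densities
  fit$beta[grep("x1:wolf_density|wolf_density:x1", names(fit$beta))] <- 0
  cur0 <- suppressWarnings(density_response_curves(fit, "x1", density_grid = c(-2, 2)))
  expect_equal(cur0$curves[, 1], cur0$curves[, 2])
})

test_that("pack heterogeneity test matches a brute-force rank-sum statistic", {
  mk_fit <- function(coefs) {
    structure(list(beta = c("(Intercept)" = 0, prey = 0.3),
                   pack_deviations = matrix(coefs, ncol = 1,
                     dimnames = list(paste0("P", seq_along(coefs)), "prey"))),
              class = "rspf_fit")
  }
  set.seed(8)
  coefs <- rnorm(20)
  sizes <- setNames(4 + 2 * coefs + rnorm(20, sd = 0.5), paste0("P", 1:20))
  fit <- mk_fit(coefs)
  out <- pack_heterogeneity_test(fit, sizes, "prey")
  # brute-force Mann-Whitney U by pair counting
  a <- sizes[out$weak_packs]; b <- sizes[out$strong_packs]
  U <- 0
  for (x in b) for (z in a) U <- U + (x > z) + 0.5 * (x == z)
  expect_equal(out$w_stat, U, tolerance = 1e-9)
  # identical sizes in both groups: no difference, p about 1
  sizes_c <- setNames(rep(4, 20), paste0("P", 1:20))
  out_c <- pack_heterogeneity_test(fit, sizes_c, "prey")
  expect_equal(out_c$mean_difference, 0)
  expect_gte(out_c$w_p, 0.99)
  expect_error(pack_heterogeneity_test(mk_fit(rnorm(5)),
                                       setNames(rnorm(5), paste0("P", 1:5)), "prey"),
               "insufficient")
})

test_that("a simulated coefficient-size link is detected with good power", {
  detect <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    n_packs <- 60
    coefs <- rnorm(n_packs, sd = 0.6)
    sizes <- setNames(pmax(2, 4 + 1.0 * scale(coefs)[, 1] + rnorm(n_packs, sd = 0.8)),
                      paste0("P", 1:n_packs))
    fit <- structure(list(beta = c("(Intercept)" = 0, prey = 0.3),
                          pack_deviations = matrix(coefs, ncol = 1,
                            dimnames = list(paste0("P", 1:n_packs), "prey"))),
                     class = "rspf_fit")
    out <- pack_heterogeneity_test(fit, sizes, "prey")
    detect <- detect + (out$w_p < 0.05)
  }
  expect_gte(detect / 10, 0.8)
})
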