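# Binomial random-intercept GLMM: quadrature, likelihood, fitting, AICc,
# model selection and Wald tests.

test_that("Gauss-Hermite rule integrates polynomials against exp(-x^2)", {
  gh <- gauss_hermite(15)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  # moments of the standard normal via change of variables
  expect_equal(sum(gh$weights * (sqrt(2) * gh$nodes)^4) / sqrt(pi), 3,
               tolerance = 1e-10)
  expect_equal(gauss_hermite(1)$nodes, 0)
})

test_that("sigma = 0 reduces the marginal likelihood to the binomial GLM", {
  d <- glmm_sim_data(1, S = 6, per = 3)
  X <- model.matrix(~ zone, d)
  beta <- c(0.8, -1)
  ll0 <- glmm_marginal_loglik(beta, 0, d$found, d$found + d$missed, X, d$site)
  direct <- sum(dbinom(d$found, d$found + d$missed,
                       plogis(drop(X %*% beta)), log = TRUE))
  expect_equal(ll0, direct, tolerance = 1e-12)
  # continuity of the profile at the boundary
  ll_eps <- glmm_marginal_loglik(beta, 1e-6, d$found, d$found + d$missed,
                                 X, d$site)
  expect_lt(abs(ll_eps - ll0), 1e-6)
})

test_that("one-node quadrature equals an independent Laplace approximation", {
  d <- glmm_sim_data(2, S = 4, per = 3)
  X <- model.matrix(~ zone, d)
  beta <- c(0.5, -0.8); sigma <- 0.6
  ll1 <- glmm_marginal_loglik(beta, sigma, d$found, d$found + d$missed,
                              X, d$site, n_quad = 1)
  # independent Laplace: per-site scalar optimization + numeric curvature
  eta <- drop(X %*% beta)
  size <- d$found + d$missed
  grp <- as.integer(factor(d$site))
  lap <- 0
  for (s in unique(grp)) {
    ix <- which(grp == s)
    lg <- function(u) sum(dbinom(d$found[ix], size[ix],
                                 plogis(eta[ix] + u), log = TRUE)) +
      dnorm(u, 0, sigma, log = TRUE)
    o <- optimize(lg, c(-10, 10), maximum = TRUE, tol = 1e-12)
    h <- 1e-4
    curv <- (lg(o$maximum + h) - 2 * o$objective + lg(o$maximum - h)) / h^2
    lap <- lap + o$objective + 0.5 * log(2 * pi / (-curv))
  }
  expect_equal(ll1, lap, tolerance = 1e-6)
})

test_that("quadrature matches dense-grid integration and is stable in order", {
  # 3 sites, 2 observations each, denominators <= 4
  d <- data.frame(found = c(1, 3, 0, 2, 4, 1),
                  missed = c(2, 1, 3, 1, 0, 2),
                  x = c(0, 1, 0, 1, 0, 1),
                  site = rep(c("a", "b", "c"), each = 2))
  X <- model.matrix(~ x, d)
  beta <- c(0.3, 0.7); sigma <- 0.8
  size <- d$found + d$missed
  ll15 <- glmm_marginal_loglik(beta, sigma, d$found, size, X, d$site, 15)
  grid <- grid_marginal_loglik(beta, sigma, d$found, size, X, d$site)
  expect_lt(abs(ll15 - grid), 1e-6)
  ll31 <- glmm_marginal_loglik(beta, sigma, d$found, size, X, d$site, 31)
  expect_lt(abs(ll15 - ll31), 1e-6)
})

test_that("likelihood is invariant to row order and site relabeling", {
  d <- glmm_sim_data(3, S = 8, per = 4)
  X <- model.matrix(~ zone, d)
  beta <- c(1, -1.2); sigma <- 0.5
  size <- d$found + d$missed
  base <- glmm_marginal_loglik(beta, sigma, d$found, size, X, d$site)
  set.seed(4)
  ord <- sample(nrow(d))
  expect_equal(glmm_marginal_loglik(beta, sigma, d$found[ord], size[ord],
                                    X[ord, ], d$site[ord]),
               base, tolerance = 1e-10)
  relab <- setNames(sample(unique(d$site)), unique(d$site))
  expect_equal(glmm_marginal_loglik(beta, sigma, d$found, size, X,
                                    relab[d$site]),
               base, tolerance = 1e-10)
})

test_that("sigma fixed at 0 reproduces the IRLS logistic fit to 1e-6", {
  d <- glmm_sim_data(5, S = 10, per = 4)
  fit <- glmm_binom(cbind(found, missed) ~ zone + (1 | site), d,
                    fix_sigma = 0)
  irls <- glm(cbind(found, missed) ~ zone, binomial, d)
  expect_lt(max(abs(coef(fit) - coef(irls))), 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(irls)), tolerance = 1e-8)
})

test_that("data generated without site variance drive sigma to the boundary", {
  d <- glmm_sim_data(6, S = 15, per = 4, sigma = 0)
  fit <- glmm_binom(cbind(found, missed) ~ zone + (1 | site), d)
  expect_lt(fit$sigma_u, 0.05)
  irls <- glm(cbind(found, missed) ~ zone, binomial, d)
  expect_lt(max(abs(coef(fit) - coef(irls))), 1e-3)
  expect_false(any(is.nan(fit$se)))
})

test_that("intercept-only fit on balanced sites recovers the pooled logit", {
  d <- data.frame(found = rep(6, 4), missed = rep(2, 4),
                  site = c("a", "a", "b", "b"))
  fit <- glmm_binom(cbind(found, missed) ~ 1 + (1 | site), d)
  expect_true(fit$boundary)
  expect_equal(unname(coef(fit)[1]), qlogis(0.75), tolerance = 1e-5)
})

test_that("fit agrees with an independent adaptive-quadrature implementation", {
  skip_if_not_installed("lme4")
  d <- glmm_sim_data(7, S = 14, per = 4, mu_n = 12)
  fit <- glmm_binom(cbind(found, missed) ~ zone + (1 | site), d)
  g <- lme4::glmer(cbind(found, missed) ~ zone + (1 | site), d,
                   family = binomial, nAGQ = 15)
  expect_lt(max(abs(coef(fit) - lme4::fixef(g))), 1e-4)
  expect_lt(abs(fit$sigma_u - sqrt(unlist(lme4::VarCorr(g)))), 1e-3)
  expect_lt(max(abs(fit$se - sqrt(diag(as.matrix(vcov(g)))))), 1e-3)
  # lme4 reports the nAGQ binomial log-likelihood relative to the
  # saturated model; add the saturated term back before comparing
  sat <- sum(dbinom(d$found, d$found + d$missed,
                    d$found / (d$found + d$missed), log = TRUE))
  expect_equal(fit$loglik, as.numeric(logLik(g)) + sat, tolerance = 1e-5)
})

test_that("AICc formula, guard and penalty ordering", {
  expect_equal(aicc(-10, k = 2, n = 40), 20 + 4 + 12 / 37)
  expect_error(aicc(-10, k = 2, n = 3), "AICc undefined")
  for (n in c(10, 50, 500)) {
    k <- 3
    expect_gt(aicc(-20, k = k, n = n), -2 * (-20) + 2 * k)
  }
})

test_that("model selection ranks by AICc with normalized weights", {
  d <- glmm_sim_data(8, S = 12, per = 4)
  f1 <- cbind(found, missed) ~ 1 + (1 | site)
  f2 <- cbind(found, missed) ~ zone + (1 | site)
  tab <- model_selection(list(f1, f2, f2), d)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(tab$aicc))
  dup <- tab[tab$model == paste(deparse(f2), collapse = " "), ]
  expect_equal(nrow(dup), 2)
  expect_equal(dup$aicc[1], dup$aicc[2], tolerance = 1e-8)
  expect_equal(dup$weight[1], dup$weight[2], tolerance = 1e-8)
})

test_that("a strong zone effect is detected by AICc nearly always", {
  wins <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    d <- glmm_sim_data(3000 + i, S = 10, per = 4, beta0 = 0.5,
                       beta_zone = -1.5, sigma = 0.4, mu_n = 15)
    tab <- model_selection(list(cbind(found, missed) ~ 1 + (1 | site),
                                cbind(found, missed) ~ zone + (1 | site)), d)
    if (grepl("zone", tab$model[1])) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.95)
})

test_that("Wald tests: closed form, multi-level blocks and marginality", {
  d <- glmm_sim_data(9, S = 12, per = 4, mu_n = 12)
  fit <- glmm_binom(cbind(found, missed) ~ zone + (1 | site), d)
  w <- wald_test(fit, "zone")
  z <- coef(fit)["zoneslope"] / fit$se["zoneslope"]
  expect_equal(w$statistic, unname(z^2), tolerance = 1e-10)
  expect_equal(w$df, 1)
  expect_equal(w$p_value, pchisq(unname(z^2), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # beta-hat = 2, SE = 1 gives chi-square 4, p ~ 0.0455
  expect_equal(pchisq(4, 1, lower.tail = FALSE), 0.04550026,
               tolerance = 1e-7)
  expect_error(wald_test(fit, "aspect"), "not in the model")

  # multi-level term: a 3-level factor gets a 2-df block test
  d$tri <- rep(c("a", "b", "c"), length.out = nrow(d))
  fit3 <- glmm_binom(cbind(found, missed) ~ tri + (1 | site), d)
  expect_equal(wald_test(fit3, "tri")$df, 2)

  # Type-II marginality: a main effect inside an interaction model is
  # tested after removing the interaction, matching the additive fit
  d$tod <- rep(c("day", "day", "night", "night"), length.out = nrow(d))
  fit_int <- glmm_binom(cbind(found, missed) ~ zone * tod + (1 | site), d)
  fit_add <- glmm_binom(cbind(found, missed) ~ zone + tod + (1 | site), d)
  expect_equal(wald_test(fit_int, "zone")$statistic,
               wald_test(fit_add, "zone")$statistic, tolerance = 1e-5)
  # the interaction itself is tested in the full model
  wi <- wald_test(fit_int, "zone:tod")
  expect_equal(wi$df, 1)
})

test_that("rank-deficient designs raise a specification error naming columns", {
  d <- glmm_sim_data(10, S = 6, per = 4)
  d$zone2 <- d$zone
  expect_error(glmm_binom(cbind(found, missed) ~ zone + zone2 + (1 | site), d),
               "aliased")
})

test_that("dispersion check reports a Pearson statistic near 1 for binomial data", {
  d <- glmm_sim_data(11, S = 20, per = 5, mu_n = 12)
  fit <- glmm_binom(cbind(found, missed) ~ zone + (1 | site), d)
  disp <- dispersion_check(fit)
  expect_gt(disp$dispersion, 0.5)
  expect_lt(disp$dispersion, 2)
})
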