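# Independent oracles used to check the estimators and the GLMM likelihood.
# These deliberately share no code with the implementation paths they check.

# Exact expectations of the two-survey mark-recapture estimators for a
# closed population of N individuals, each detected independently with
# probability p in each survey. Enumerates the multinomial distribution of
# (both, first-only, second-only, neither) detection outcomes.
enum_two_survey <- function(N, p) {
  e_lp_num <- 0; p_rpos <- 0; e_chap <- 0
  for (n11 in 0:N) for (n10 in 0:(N - n11)) for (n01 in 0:(N - n11 - n10)) {
    n00 <- N - n11 - n10 - n01
    lpr <- lgamma(N + 1) - lgamma(n11 + 1) - lgamma(n10 + 1) -
      lgamma(n01 + 1) - lgamma(n00 + 1) +
      (n11) * log(p * p) + (n10 + n01) * log(p * (1 - p)) +
      n00 * log((1 - p) * (1 - p))
    pr <- exp(lpr)
    M <- n11 + n10; C <- n11 + n01; R <- n11
    if (R > 0) {
      e_lp_num <- e_lp_num + pr * M * C / R
      p_rpos <- p_rpos + pr
    }
    e_chap <- e_chap + pr * ((M + 1) * (C + 1) / (R + 1) - 1)
  }
  list(e_lp_given_rpos = e_lp_num / p_rpos, p_rpos = p_rpos,
       e_chapman = e_chap)
}

# Dense-grid (trapezoid) evaluation of the marginal log-likelihood of the
# binomial random-intercept model, integrating each site's likelihood over
# u on an equally spaced grid spanning +/- width * sigma.
grid_marginal_loglik <- function(beta, sigma_u, y, size, X, group,
                                 width = 10, n_grid = 40001) {
  group <- as.integer(as.factor(group))
  eta <- drop(X %*% beta)
  u <- seq(-width * sigma_u, width * sigma_u, length.out = n_grid)
  du <- u[2] - u[1]
  total <- 0
  for (s in sort(unique(group))) {
    ix <- which(group == s)
    lg <- vapply(u, function(uu) {
      sum(dbinom(y[ix], size[ix], plogis(eta[ix] + uu), log = TRUE)) +
        dnorm(uu, 0, sigma_u, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    vals <- exp(lg - m)
    integral <- du * (sum(vals) - (vals[1] + vals[n_grid]) / 2)
    total <- total + m + log(integral)
  }
  total
}

# Direct binomial simulation of one two-survey mark-recapture experiment
# (no package code): returns M, C, R counts.
draw_mcr <- function(N, p1, p2 = p1) {
  d1 <- stats::rbinom(N, 1, p1)
  d2 <- stats::rbinom(N, 1, p2)
  c(M = sum(d1), C = sum(d2), R = sum(d1 & d2))
}
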