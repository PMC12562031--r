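# Binomial-logit GLMM with a single random intercept, fitted by maximum
# likelihood with adaptive Gauss-Hermite quadrature over the random effect.

.gh_cache <- new.env(parent = emptyenv())

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-x^2} f(x) dx \approx \sum_k w_k f(x_k)}
#' (physicists' convention), computed by the Golub-Welsch eigenvalue method
#' on the Jacobi matrix of the Hermite recurrence.
#'
#' @param n number of nodes (>= 1).
#' @return list with `nodes` and `weights`, each length `n`.
#' @examples
#' gh <- gauss_hermite(5)
#' sum(gh$weights)            # sqrt(pi)
#' sum(gh$weights * gh$nodes^2)  # sqrt(pi)/2
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  if (n == 1L) {
    rule <- list(nodes = 0, weights = sqrt(pi))
  } else {
    i <- seq_len(n - 1L)
    b <- sqrt(i / 2)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    rule <- list(nodes = e$values[ord],
                 weights = sqrt(pi) * e$vectors[1L, ord]^2)
  }
  .gh_cache[[key]] <- rule
  rule
}

# Per-site penalized log-density pieces and their derivatives. Locates the
# conditional mode of the random intercept for every site by (vectorized)
# Newton iteration; the binomial-logit log-likelihood is concave in u so the
# iteration is globally stable once steps are clipped.
site_modes <- function(eta, sigma_u, y, size, group, n_groups,
                       tol = 1e-11, max_iter = 100L) {
  u <- numeric(n_groups)
  inv_var <- 1 / sigma_u^2
  curv <- NULL
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(eta + u[group])
    score <- group_sum(y - size * p, group, n_groups) - u * inv_var
    curv <- group_sum(size * p * (1 - p), group, n_groups) + inv_var
    step <- score / curv
    step <- pmax(pmin(step, 10), -10)
    u <- u + step
    if (max(abs(step)) < tol) break
  }
  p <- stats::plogis(eta + u[group])
  curv <- group_sum(size * p * (1 - p), group, n_groups) + inv_var
  list(mode = u, scale = 1 / sqrt(curv))
}

#' Marginal log-likelihood of a binomial random-intercept GLMM
#'
#' Integrates the random intercept out of the joint likelihood
#' \deqn{L_s = \int \prod_{i \in s} \mathrm{Bin}(y_i \mid n_i,
#'   \mathrm{logit}^{-1}(x_i'\beta + u))\, \phi(u; 0, \sigma_u^2)\, du}
#' site by site with adaptive Gauss-Hermite quadrature centered and scaled
#' at each site's conditional mode, and returns the summed log over sites.
#' With `sigma_u = 0` the random effect is degenerate and the value equals
#' the fixed-effects binomial GLM log-likelihood exactly; `n_quad = 1`
#' gives the Laplace approximation.
#'
#' @param beta fixed-effect coefficient vector (logit scale).
#' @param sigma_u random-intercept standard deviation, >= 0.
#' @param y integer successes ("found") per observation.
#' @param size integer binomial denominators (found + missed).
#' @param X design matrix, rows matching `y`.
#' @param group integer or factor site index per observation.
#' @param n_quad number of quadrature nodes (default 15).
#' @return the marginal log-likelihood (scalar), including binomial
#'   normalizing constants so values are comparable with [stats::glm()] and
#'   `lme4::glmer()`.
#' @export
glmm_marginal_loglik <- function(beta, sigma_u, y, size, X, group,
                                 n_quad = 15) {
  if (any(y != round(y)) || any(size != round(size)))
    stop("binomial responses (found, missed) must be integers")
  if (sigma_u < 0) stop("sigma_u must be >= 0")
  group <- as.integer(as.factor(group))
  eta <- drop(X %*% beta)
  if (sigma_u == 0) {
    return(sum(stats::dbinom(y, size, stats::plogis(eta), log = TRUE)))
  }
  S <- max(group)
  m <- site_modes(eta, sigma_u, y, size, group, S)
  gh <- gauss_hermite(n_quad)
  K <- length(gh$nodes)
  # quadrature abscissae per site: mode + sqrt(2) * scale * node
  z <- m$mode + sqrt(2) * outer(m$scale, gh$nodes)   # S x K
  logh <- matrix(0, S, K)
  for (k in seq_len(K)) {
    lp <- stats::dbinom(y, size, stats::plogis(eta + z[group, k]), log = TRUE)
    logh[, k] <- group_sum(lp, group, S) +
      stats::dnorm(z[, k], 0, sigma_u, log = TRUE)
  }
  lw <- matrix(log(gh$weights) + gh$nodes^2, S, K, byrow = TRUE)
  ll_site <- log(sqrt(2) * m$scale) + row_log_sum_exp(logh + lw)
  if (any(!is.finite(ll_site)))
    stop("non-finite marginal likelihood; check data and parameters")
  sum(ll_site)
}

# Central-difference Hessian of scalar function f at x.
num_hessian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < n) for (j in seq((i + 1L), n)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# Split a mixed-model formula `cbind(found, missed) ~ fixed + (1 | group)`
# into the fixed-effects formula and the grouping variable name.
parse_glmm_formula <- function(formula) {
  find_bars <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (op == "(") return(find_bars(e[[2L]]))
      if (op == "|") return(list(e))
      if (op == "+") return(c(find_bars(e[[2L]]), find_bars(e[[3L]])))
    }
    list()
  }
  strip_bars <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (op == "(" && length(find_bars(e)) > 0) return(NULL)
      if (op == "+") {
        l <- strip_bars(e[[2L]]); r <- strip_bars(e[[3L]])
        if (is.null(l)) return(r)
        if (is.null(r)) return(l)
        return(call("+", l, r))
      }
    }
    e
  }
  if (length(formula) != 3L) stop("formula must have a response")
  bars <- find_bars(formula[[3L]])
  if (length(bars) != 1L)
    stop("exactly one random-intercept term (1 | group) is required")
  bar <- bars[[1L]]
  if (!identical(bar[[2L]], 1) && !identical(bar[[2L]], 1L))
    stop("only random intercepts (1 | group) are supported")
  gvar <- deparse(bar[[3L]])
  fixed_rhs <- strip_bars(formula[[3L]])
  if (is.null(fixed_rhs)) fixed_rhs <- 1
  fixed <- stats::as.formula(call("~", formula[[2L]], fixed_rhs),
                             env = environment(formula))
  list(fixed = fixed, group = gvar)
}

#' Fit a binomial random-intercept GLMM by adaptive Gauss-Hermite quadrature
#'
#' Maximizes the marginal likelihood of a binomial-logit mixed model with a
#' single random intercept (typically site) over the fixed effects and
#' \eqn{\log \sigma_u}, using a quasi-Newton optimizer started from the
#' corresponding fixed-effects GLM. Standard errors come from the inverse
#' observed information (central-difference Hessian at the optimum).
#'
#' The response is given as `cbind(found, missed)`; covariates use treatment
#' contrasts with the first level (alphabetical for unordered factors) as
#' reference, so coefficient signs depend on the reference level.
#'
#' @param formula model formula of the form
#'   `cbind(found, missed) ~ covariates + (1 | site)`.
#' @param data data frame containing the response counts, covariates and the
#'   grouping variable.
#' @param n_quad quadrature nodes for the marginal likelihood (default 15;
#'   1 gives the Laplace approximation).
#' @param fix_sigma optional non-negative value at which to fix
#'   \eqn{\sigma_u} instead of estimating it; `fix_sigma = 0` reduces the
#'   fit to a plain binomial GLM (useful as a cross-check).
#' @param start optional list with elements `beta` and `sigma` overriding
#'   the default starting values.
#' @return an object of class `cots_glmm`: fixed-effect estimates with
#'   standard errors, `sigma_u`, `loglik`, `n_obs`, `k_params`, `aicc`,
#'   a `converged` flag and the ingredients needed for Wald tests and
#'   refitting.
#' @seealso [aicc()], [model_selection()], [wald_test()]
#' @examples
#' d <- data.frame(found = c(3, 5, 2, 6), missed = c(2, 1, 3, 0),
#'                 zone = c("crest", "slope", "crest", "slope"),
#'                 site = c("a", "a", "b", "b"))
#' fit <- glmm_binom(cbind(found, missed) ~ zone + (1 | site), d)
#' coef(fit)
#' @export
glmm_binom <- function(formula, data, n_quad = 15, fix_sigma = NULL,
                       start = NULL) {
  pf <- parse_glmm_formula(formula)
  if (!pf$group %in% names(data))
    stop("grouping variable '", pf$group, "' not found in data")
  mf <- stats::model.frame(pf$fixed, data = data, na.action = stats::na.fail)
  Y <- stats::model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2L)
    stop("response must be cbind(found, missed)")
  y <- Y[, 1L]
  size <- rowSums(Y)
  if (any(y < 0) || any(Y[, 2L] < 0)) stop("counts must be non-negative")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  grp <- droplevels(as.factor(data[[pf$group]]))
  if (nlevels(grp) < 2L)
    warning("grouping variable has < 2 levels; sigma_u is not identifiable")
  group <- as.integer(grp)
  keep <- size > 0
  if (!all(keep)) {
    y <- y[keep]; size <- size[keep]
    X <- X[keep, , drop = FALSE]
    grp <- droplevels(grp[keep]); group <- as.integer(grp)
  }
  p <- ncol(X)
  n_obs <- length(y)

  g0 <- stats::glm.fit(X, cbind(y, size - y), family = stats::binomial())
  beta_start <- g0$coefficients
  log_floor <- -10

  nll <- function(par) {
    sig <- exp(par[p + 1L])
    -glmm_marginal_loglik(par[seq_len(p)], sig, y, size, X, group, n_quad)
  }
  nll_fixed <- function(par, sig) {
    -glmm_marginal_loglik(par, sig, y, size, X, group, n_quad)
  }
  # optimizers occasionally report "false convergence" at a genuine
  # optimum of a quadrature-based objective; judge convergence by the
  # numeric gradient at the solution instead
  grad_norm <- function(f, x) {
    g <- vapply(seq_along(x), function(i) {
      h <- 1e-5 * max(1, abs(x[i]))
      e <- replace(numeric(length(x)), i, h)
      (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1))
    max(abs(g))
  }

  if (!is.null(fix_sigma)) {
    stopifnot(fix_sigma >= 0)
    opt <- stats::nlminb(beta_start, nll_fixed, sig = fix_sigma,
                         control = list(iter.max = 500, eval.max = 1000,
                                        rel.tol = 1e-14))
    beta_hat <- opt$par
    sigma_hat <- fix_sigma
    loglik <- -opt$objective
    conv <- opt$convergence == 0 ||
      grad_norm(function(b) nll_fixed(b, fix_sigma), beta_hat) < 1e-3
    Hf <- num_hessian(function(b) nll_fixed(b, fix_sigma), beta_hat)
    V <- tryCatch(solve(Hf), error = function(e) matrix(NA_real_, p, p))
    vcov_full <- V
    se_sigma <- NA_real_
    boundary <- TRUE
    k <- p
  } else {
    starts <- list(c(beta_start, log(0.1)), c(beta_start, log(1)))
    if (!is.null(start))
      starts <- c(list(c(start$beta, log(max(start$sigma, exp(log_floor))))),
                  starts)
    best <- NULL
    for (s0 in starts) {
      opt <- tryCatch(
        stats::nlminb(s0, nll,
                      lower = c(rep(-Inf, p), log_floor),
                      control = list(iter.max = 500, eval.max = 1000,
                                     rel.tol = 1e-12)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$objective)) next
      if (is.null(best) || opt$objective < best$objective - 1e-9 ||
          (opt$objective < best$objective + 1e-9 && opt$convergence == 0 &&
           best$convergence != 0))
        best <- opt
      if (best$convergence == 0) break
    }
    if (is.null(best)) stop("GLMM optimization failed from all starts")
    opt <- best
    par_hat <- opt$par
    beta_hat <- par_hat[seq_len(p)]
    sigma_hat <- exp(par_hat[p + 1L])
    loglik <- -opt$objective
    boundary <- par_hat[p + 1L] <= log_floor + 1e-6
    conv <- opt$convergence == 0 ||
      (if (boundary)
        grad_norm(function(b) nll_fixed(b, sigma_hat), beta_hat)
       else grad_norm(nll, par_hat)) < 1e-3
    k <- p + 1L
    if (boundary) {
      # sigma at the soft floor: information in log-sigma is degenerate, so
      # report fixed-effect uncertainty conditional on sigma ~ 0
      Hf <- num_hessian(function(b) nll_fixed(b, sigma_hat), beta_hat)
      V <- tryCatch(solve(Hf), error = function(e) matrix(NA_real_, p, p))
      vcov_full <- V
      se_sigma <- NA_real_
    } else {
      H <- num_hessian(nll, par_hat)
      Vfull <- tryCatch(solve(H), error = function(e)
        matrix(NA_real_, p + 1L, p + 1L))
      V <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
      vcov_full <- Vfull
      # delta method: SE(sigma) = sigma * SE(log sigma)
      se_sigma <- sigma_hat * sqrt(Vfull[p + 1L, p + 1L])
    }
  }

  se <- sqrt(pmax(diag(V), 0))
  names(beta_hat) <- names(se) <- colnames(X)
  if (any(!is.finite(se))) conv <- FALSE
  fit <- structure(list(
    beta = beta_hat, se = se, vcov = V, vcov_full = vcov_full,
    sigma_u = sigma_hat, se_sigma = se_sigma,
    loglik = loglik, n_obs = n_obs, k_params = as.integer(k),
    converged = conv, boundary = boundary,
    formula = formula, fixed_formula = pf$fixed, group_var = pf$group,
    terms = attr(mf, "terms"), assign = attr(X, "assign"),
    data = data, n_quad = n_quad, fix_sigma = fix_sigma,
    y = y, size = size, X = X, group = group
  ), class = "cots_glmm")
  fit$aicc <- aicc(fit)
  fit
}

#' Small-sample corrected Akaike Information Criterion
#'
#' \eqn{\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)}, where `k` counts the
#' fixed effects plus the random-intercept variance.
#'
#' @param fit a `cots_glmm` fit, or a log-likelihood value when `k` and `n`
#'   are supplied.
#' @param k,n number of parameters and observations (only when `fit` is a
#'   bare log-likelihood).
#' @return the AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "cots_glmm")) {
    ll <- fit$loglik; k <- fit$k_params; n <- fit$n_obs
  } else {
    ll <- fit
    if (is.null(k) || is.null(n)) stop("supply k and n with a bare loglik")
  }
  if (n - k - 1 <= 0)
    stop("AICc undefined: n_obs must exceed k_params + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate fixed-effect structures by AICc
#'
#' Fits every candidate model (all sharing the random intercept and data)
#' and returns them sorted by AICc with differences and Akaike weights
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum \exp(-\Delta/2)}.
#'
#' @param formulas list of model formulas (each with the `(1 | group)` term).
#' @param data data frame passed to every fit.
#' @param n_quad quadrature nodes.
#' @return data frame with one row per candidate (`model`, `k`, `loglik`,
#'   `aicc`, `delta`, `weight`), fits attached as attribute `"fits"`.
#' @export
model_selection <- function(formulas, data, n_quad = 15) {
  if (length(formulas) < 2L) stop("supply at least two candidate models")
  fits <- lapply(formulas, glmm_binom, data = data, n_quad = n_quad)
  tab <- data.frame(
    model = vapply(formulas, function(f) paste(deparse(f), collapse = " "),
                   character(1)),
    k = vapply(fits, function(f) f$k_params, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  tab$delta <- tab$aicc - tab$aicc[1L]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Type-II Wald test for a model term
#'
#' Tests a term's coefficient block with \eqn{\chi^2 = \hat\beta' V^{-1}
#' \hat\beta} on the block's degrees of freedom. Following the Type-II
#' marginality convention, a main effect is tested in the model with all
#' other terms but excluding any interaction that contains it (the model is
#' refitted without those interactions when necessary); an interaction is
#' tested in the full model.
#'
#' @param fit a `cots_glmm` fit.
#' @param term character, a term label as in `attr(terms(fit), "term.labels")`.
#' @return data frame with `term`, `statistic` (Wald chi-square), `df` and
#'   `p_value`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "cots_glmm"))
  labels <- attr(fit$terms, "term.labels")
  if (!term %in% labels)
    stop("term '", term, "' is not in the model (terms: ",
         paste(labels, collapse = ", "), ")")
  fac <- attr(fit$terms, "factors")
  vars_of <- function(lab) rownames(fac)[fac[, lab] > 0]
  tv <- vars_of(term)
  contains <- vapply(labels, function(l) {
    l != term && all(tv %in% vars_of(l))
  }, logical(1))
  if (any(contains)) {
    keep <- labels[!contains]
    rhs <- paste(c(keep, paste0("(1 | ", fit$group_var, ")")), collapse = " + ")
    resp <- deparse(fit$formula[[2L]])
    f2 <- stats::as.formula(paste(resp, "~", rhs))
    fit <- glmm_binom(f2, fit$data, n_quad = fit$n_quad,
                      fix_sigma = fit$fix_sigma)
    labels <- attr(fit$terms, "term.labels")
  }
  idx <- which(fit$assign == match(term, labels))
  b <- fit$beta[idx]
  Vb <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(Vb) %*% b)
  df <- length(idx)
  data.frame(term = term, statistic = stat, df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Pearson dispersion statistic for a fitted GLMM
#'
#' Sum of squared Pearson residuals (computed at the marginal fitted
#' probabilities with the random effect at its conditional mode) divided by
#' residual degrees of freedom; values far above 1 indicate overdispersion
#' relative to the binomial.
#'
#' @param fit a `cots_glmm` fit.
#' @return list with `pearson_chisq`, `df` and `dispersion`.
#' @export
dispersion_check <- function(fit) {
  stopifnot(inherits(fit, "cots_glmm"))
  eta <- drop(fit$X %*% fit$beta)
  S <- max(fit$group)
  u <- if (fit$sigma_u > 0)
    site_modes(eta, fit$sigma_u, fit$y, fit$size, fit$group, S)$mode
  else numeric(S)
  p <- stats::plogis(eta + u[fit$group])
  r <- (fit$y - fit$size * p) / sqrt(fit$size * p * (1 - p))
  df <- fit$n_obs - fit$k_params
  chisq <- sum(r^2)
  list(pearson_chisq = chisq, df = df, dispersion = chisq / max(df, 1))
}

#' @export
coef.cots_glmm <- function(object, ...) object$beta

#' @export
vcov.cots_glmm <- function(object, ...) object$vcov

#' @export
logLik.cots_glmm <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
print.cots_glmm <- function(x, digits = 4, ...) {
  cat("Binomial random-intercept GLMM (adaptive Gauss-Hermite, ",
      x$n_quad, " nodes)\n", sep = "")
  cat("  formula: ", paste(deparse(x$formula), collapse = " "), "\n", sep = "")
  z <- x$beta / x$se
  tab <- data.frame(estimate = x$beta, se = x$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, digits))
  cat("  sigma_u (", x$group_var, "): ", format(x$sigma_u, digits = digits),
      if (x$boundary) "  [boundary]" else "", "\n", sep = "")
  cat("  logLik: ", format(x$loglik, digits = 8),
      "   AICc: ", format(x$aicc, digits = 8),
      "   n: ", x$n_obs,
      if (!x$converged) "   (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.cots_glmm <- function(object, ...) {
  z <- object$beta / object$se
  list(coefficients = data.frame(estimate = object$beta, se = object$se,
                                 z = z, p_value = 2 * stats::pnorm(-abs(z))),
       sigma_u = object$sigma_u, se_sigma = object$se_sigma,
       loglik = object$loglik, aicc = object$aicc, n_obs = object$n_obs,
       converged = object$converged, boundary = object$boundary)
}
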