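# Shared generators for test data.

# A configuration where every individual has the same detection probability
# p (single size class, no covariate or site effects), so simulator output
# can be checked against binomial arithmetic.
constant_p_config <- function(p, n_sites = 1, transects_per_site = 1,
                              night_p = NULL, mean_abundance = 10,
                              dispersion = 5, tag_retention = 1,
                              seed = 1) {
  sim_config(
    n_sites = n_sites, transects_per_site = transects_per_site,
    mean_abundance_per_transect = mean_abundance,
    abundance_dispersion = dispersion,
    size_class_probs = c(VS = 1, S = 0, M = 0, L = 0),
    beta0 = qlogis(p),
    beta_size = c(S = 0, M = 0, L = 0),
    beta_night = if (is.null(night_p)) 0 else qlogis(night_p) - qlogis(p),
    beta_zone = 0, beta_aspect = 0, sigma_site = 0,
    tag_retention = tag_retention, rng_seed = seed)
}

# Hand-built closed population with exactly n_true individuals on one
# transect (bypasses the negative-binomial draw when a fixed N is needed).
fixed_population <- function(n_true, zone = "crest", aspect = "windward") {
  transects <- data.frame(
    transect_id = "T01", site = "S01", zone = zone, aspect = aspect,
    area_m2 = 200, n_true = n_true, u_site = 0, stringsAsFactors = FALSE)
  individuals <- data.frame(
    id = sprintf("T01_I%04d", seq_len(n_true)), transect_id = "T01",
    size_cm = 15, size_class = "VS", marked = FALSE, removed = FALSE,
    tag_lost = FALSE, stringsAsFactors = FALSE)
  structure(list(transects = transects, individuals = individuals),
            class = "cots_population")
}

# Binomial found/missed data from the random-intercept logit model, for
# GLMM fitting tests: S sites x per observations, one binary covariate.
glmm_sim_data <- function(seed, S = 40, per = 5, beta0 = 1, beta_zone = -1.2,
                          sigma = 0.5, mu_n = 7) {
  set.seed(seed)
  site <- factor(rep(sprintf("s%02d", seq_len(S)), each = per))
  zone <- rep(c("crest", "slope"), length.out = S * per)
  u <- rnorm(S, 0, sigma)
  n <- pmax(rnbinom(S * per, mu = mu_n, size = 2), 1)
  p <- plogis(beta0 + beta_zone * (zone == "slope") + u[as.integer(site)])
  found <- rbinom(S * per, n, p)
  data.frame(found = found, missed = n - found, zone = zone, site = site,
             stringsAsFactors = FALSE)
}
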