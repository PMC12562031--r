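# Survey simulator: population generation, detection model, and the two
# survey schedules.

test_that("population generation is deterministic and respects degenerate means", {
  cfg <- sim_config(n_sites = 3, transects_per_site = 2, rng_seed = 42)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$transects, p2$transects)
  expect_identical(p1$individuals, p2$individuals)

  empty <- simulate_population(sim_config(mean_abundance_per_transect = 0,
                                          rng_seed = 1))
  expect_true(all(empty$transects$n_true == 0))
  expect_equal(nrow(empty$individuals), 0)

  # per-transect substreams: enlarging the layout must not perturb the
  # populations of transects that already existed
  big <- simulate_population(sim_config(n_sites = 5, transects_per_site = 2,
                                        rng_seed = 42))
  shared <- p1$transects$transect_id
  expect_identical(
    p1$transects[c("transect_id", "n_true")],
    big$transects[match(shared, big$transects$transect_id),
                  c("transect_id", "n_true")])
})

test_that("simulated abundance matches the configured negative-binomial mean", {
  pop <- simulate_population(sim_config(
    n_sites = 5000, transects_per_site = 2,
    mean_abundance_per_transect = 7.2, abundance_dispersion = 50,
    rng_seed = 7))
  expect_equal(nrow(pop$transects), 1e4)
  expect_lt(abs(mean(pop$transects$n_true) - 7.2) / 7.2, 0.02)
})

test_that("detection probability follows the logit-linear structure", {
  cfg0 <- sim_config(beta0 = 0, beta_size = c(S = 0, M = 0, L = 0),
                     beta_night = 0, beta_zone = 0, beta_aspect = 0,
                     sigma_site = 0)
  ind <- data.frame(size_class = "VS")
  day_crest <- list(night = FALSE, zone = "crest", aspect = "windward")
  expect_equal(detection_prob(ind, day_crest, cfg0), 0.5)

  cfg_n <- sim_config(beta0 = 0, beta_size = c(S = 0, M = 0, L = 0),
                      beta_night = 1, beta_zone = 0, beta_aspect = 0,
                      sigma_site = 0)
  night <- list(night = TRUE, zone = "crest", aspect = "windward")
  expect_equal(detection_prob(ind, night, cfg_n), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  # covariates and the site intercept all enter additively on the logit
  cfg <- sim_config()
  eta <- cfg$beta0 + cfg$beta_size[["M"]] + cfg$beta_night +
    cfg$beta_zone + cfg$beta_aspect + 0.3
  expect_equal(
    detection_prob(data.frame(size_class = "M"),
                   list(night = TRUE, zone = "slope", aspect = "leeward"),
                   cfg, site_intercept = 0.3),
    plogis(eta), tolerance = 1e-12)

  expect_error(detection_prob(data.frame(size_class = "VS", removed = TRUE),
                              day_crest, cfg0), "removed")
})

test_that("simulator detection frequency matches the stated probability", {
  # Monte-Carlo check: 1e5 individuals surveyed once; the removal rate
  # must sit within 3 binomial SE of detection_prob's value
  p <- 0.37
  cfg <- constant_p_config(p, seed = 9)
  pop <- fixed_population(1e5)
  out <- simulate_depletion(pop, cfg, k_surveys = 1)
  phat <- out$surveys$n_sighted / 1e5
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(phat - p), 3 * se)
})

test_that("depletion removes detected animals from a closed population", {
  cfg1 <- constant_p_config(0.999999, seed = 2)
  cfg1$beta0 <- 50   # numerically certain detection
  pop <- fixed_population(25)
  out <- simulate_depletion(pop, cfg1, k_surveys = 3)
  expect_equal(out$surveys$n_removed, c(25, 0, 0))

  cfg0 <- constant_p_config(0.5, seed = 2)
  cfg0$beta0 <- -50  # numerically impossible detection
  out0 <- simulate_depletion(fixed_population(25), cfg0, k_surveys = 3)
  expect_true(all(out0$surveys$n_sighted == 0))
  expect_true(all(out0$surveys$n_removed == 0))

  # first-survey removal expectation: E = N p
  reps <- 1000
  removed1 <- vapply(seq_len(reps), function(i) {
    cfg <- constant_p_config(0.7, seed = 1000 + i)
    simulate_depletion(fixed_population(100), cfg, k_surveys = 1)$
      surveys$n_removed
  }, numeric(1))
  se <- sd(removed1) / sqrt(reps)
  expect_lt(abs(mean(removed1) - 70), 3 * se)
})

test_that("mark-recapture marking, recapture and tag-loss contracts hold", {
  cfg <- constant_p_config(0.5, tag_retention = 1, seed = 3)
  cfg$beta0 <- 50
  out <- simulate_mark_recapture(fixed_population(40), cfg,
                                 schedule = c("day", "night"))
  s2 <- out$surveys[out$surveys$survey_index == 2, ]
  expect_equal(s2$n_sighted, 40)
  expect_equal(s2$n_recaptured, 40)

  cfg_loss <- constant_p_config(0.9, tag_retention = 1, seed = 3)
  cfg_loss$tag_retention <- 1e-12   # effectively zero retention
  out0 <- simulate_mark_recapture(fixed_population(40), cfg_loss)
  later <- out0$surveys[out0$surveys$survey_index > 1, ]
  expect_true(all(later$n_recaptured == 0))
})

test_that("closed-population and marking invariants hold across random runs", {
  for (seed in c(11, 37, 101, 223)) {
    cfg <- sim_config(n_sites = 3, transects_per_site = 2, rng_seed = seed)
    pop <- simulate_population(cfg)
    dep <- simulate_depletion(pop, cfg, k_surveys = 3)
    agg <- tapply(dep$surveys$n_removed, dep$surveys$transect_id, sum)
    truth <- pop$transects$n_true[match(names(agg),
                                        pop$transects$transect_id)]
    expect_true(all(agg <= truth))

    mr <- simulate_mark_recapture(pop, cfg)
    for (tid in unique(mr$surveys$transect_id)) {
      ev <- mr$surveys[mr$surveys$transect_id == tid, ]
      ev <- ev[order(ev$survey_index), ]
      cum_marked <- cumsum(ev$n_newly_marked)
      # recaptures can only come from animals marked on earlier surveys
      expect_true(all(ev$n_recaptured[-1] <=
                        pmin(ev$n_sighted[-1], head(cum_marked, -1))))
      expect_true(all(ev$n_recaptured <= ev$n_sighted))
    }
    # byte-identical reproducibility of the whole survey table
    mr2 <- simulate_mark_recapture(simulate_population(cfg), cfg)
    expect_identical(mr$surveys, mr2$surveys)
  }
})

test_that("mark-recapture feeding Lincoln-Petersen recovers true abundance", {
  # two-survey schedule at day p = 0.65, night p = 0.78, N = 200:
  # the mean L-P estimate over replicates must land within 2% of truth
  reps <- 1000
  nhat <- vapply(seq_len(reps), function(i) {
    cfg <- constant_p_config(0.65, night_p = 0.78, tag_retention = 1,
                             seed = 5000 + i)
    mr <- simulate_mark_recapture(fixed_population(200), cfg,
                                  schedule = c("day", "night"))
    ab <- estimate_abundance(mr$surveys, "markrecap")
    ab$n_hat
  }, numeric(1))
  expect_lt(abs(mean(nhat, na.rm = TRUE) - 200) / 200, 0.02)
})

test_that("survey tables round-trip through CSV with validation", {
  cfg <- sim_config(n_sites = 2, transects_per_site = 2, rng_seed = 8)
  pop <- simulate_population(cfg)
  mr <- simulate_mark_recapture(pop, cfg)
  dir <- tempfile()
  write_survey_csv(mr, dir)
  back <- read_surveys(file.path(dir, "surveys.csv"), design = "markrecap")
  expect_equal(back, mr$surveys)
  ind <- read.csv(file.path(dir, "individuals.csv"), comment.char = "#")
  expect_equal(nrow(ind), nrow(mr$individuals))
  expect_true(all(c("id", "transect_id", "size_cm", "size_class")
                  %in% names(ind)))
})

test_that("size classes bin diameters on right-closed boundaries", {
  expect_equal(as.character(size_class_of(c(10, 20, 21, 30, 31, 40, 41, 56))),
               c("VS", "VS", "S", "S", "M", "M", "L", "L"))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(size_class_probs = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(sim_config(tag_retention = 0), "tag_retention")
  expect_error(sim_config(area_m2_by_zone = c(crest = -1, slope = 500)),
               "areas")
  expect_error(sim_config(sigma_site = -0.2), "sigma_site")
})
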