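#' Simulation configuration for synthetic starfish surveys
#'
#' Bundles the study layout, population model and detection model used by
#' [simulate_population()], [simulate_depletion()] and
#' [simulate_mark_recapture()]. Defaults emulate an intensive belt-transect
#' study on an outbreaking reef: a handful of sites split between windward
#' and leeward aspects, crest (shallow) and slope (deep) transects,
#' negative-binomial among-transect abundance, and logit-linear detection
#' with body-size, time-of-day, zone and aspect effects plus a site-level
#' random intercept. Size classes are the conventional diameter bins
#' very small (<= 20 cm), small (21-30), medium (31-40) and large (> 40).
#'
#' @param n_sites number of sites; aspects alternate across sites.
#' @param transects_per_site transects per site; zones alternate across
#'   transects within a site.
#' @param zone_labels two zone labels, first is the detection-model
#'   reference level.
#' @param aspect_labels two aspect labels, first is the reference level.
#' @param area_m2_by_zone named positive areas (m^2), one per zone.
#' @param mean_abundance_per_transect negative-binomial mean of the true
#'   per-transect abundance.
#' @param abundance_dispersion negative-binomial size parameter; smaller
#'   values give stronger among-transect clumping.
#' @param size_class_probs probabilities of the four size classes
#'   (VS, S, M, L); must sum to 1.
#' @param beta0 baseline logit detection probability (very small individual,
#'   daytime, reference zone and aspect, average site).
#' @param beta_size logit offsets for size classes S, M, L relative to VS.
#' @param beta_night logit offset for night surveys.
#' @param beta_zone logit offset for the second zone label.
#' @param beta_aspect logit offset for the second aspect label.
#' @param sigma_site standard deviation of the site random intercept.
#' @param tag_retention probability in (0, 1] that a tag applied at marking
#'   is still attached at any later survey.
#' @param rng_seed integer seed; all draws are reproducible given the
#'   configuration, and per-transect substreams mean added transects do not
#'   perturb existing ones.
#' @return an object of class `sim_config` (validated list).
#' @examples
#' cfg <- sim_config(n_sites = 2, transects_per_site = 2, rng_seed = 7)
#' pop <- simulate_population(cfg)
#' head(pop$transects)
#' @export
sim_config <- function(n_sites = 5,
                       transects_per_site = 2,
                       zone_labels = c("crest", "slope"),
                       aspect_labels = c("windward", "leeward"),
                       area_m2_by_zone = c(crest = 250, slope = 500),
                       mean_abundance_per_transect = 30,
                       abundance_dispersion = 2,
                       size_class_probs = c(VS = 0.10, S = 0.54,
                                            M = 0.27, L = 0.09),
                       beta0 = 0,
                       beta_size = c(S = 1.0, M = 1.1, L = 1.3),
                       beta_night = 0.6,
                       beta_zone = -1.2,
                       beta_aspect = -0.7,
                       sigma_site = 0.5,
                       tag_retention = 0.941,
                       rng_seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              transects_per_site = as.integer(transects_per_site),
              zone_labels = as.character(zone_labels),
              aspect_labels = as.character(aspect_labels),
              area_m2_by_zone = area_m2_by_zone,
              mean_abundance_per_transect = mean_abundance_per_transect,
              abundance_dispersion = abundance_dispersion,
              size_class_probs = size_class_probs,
              beta0 = beta0, beta_size = beta_size,
              beta_night = beta_night, beta_zone = beta_zone,
              beta_aspect = beta_aspect, sigma_site = sigma_site,
              tag_retention = tag_retention,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  err <- character(0)
  add <- function(msg) err <<- c(err, msg)
  if (cfg$n_sites < 1) add("n_sites must be >= 1")
  if (cfg$transects_per_site < 1) add("transects_per_site must be >= 1")
  if (length(cfg$zone_labels) != 2) add("zone_labels must have length 2")
  if (length(cfg$aspect_labels) != 2) add("aspect_labels must have length 2")
  if (length(cfg$size_class_probs) != 4)
    add("size_class_probs must have length 4 (VS, S, M, L)")
  if (any(cfg$size_class_probs < 0) || any(cfg$size_class_probs > 1))
    add("size_class_probs must lie in [0, 1]")
  if (abs(sum(cfg$size_class_probs) - 1) > 1e-12)
    add("size_class_probs must sum to 1 (within 1e-12)")
  if (!all(cfg$zone_labels %in% names(cfg$area_m2_by_zone)))
    add("area_m2_by_zone must name every zone label")
  if (any(cfg$area_m2_by_zone <= 0)) add("areas must be > 0")
  if (cfg$mean_abundance_per_transect < 0)
    add("mean_abundance_per_transect must be >= 0")
  if (cfg$abundance_dispersion <= 0) add("abundance_dispersion must be > 0")
  if (length(cfg$beta_size) != 3) add("beta_size must have length 3 (S, M, L)")
  if (cfg$sigma_site < 0) add("sigma_site must be >= 0")
  if (cfg$tag_retention <= 0 || cfg$tag_retention > 1)
    add("tag_retention must be in (0, 1]")
  if (length(err) > 0)
    stop("invalid simulation configuration:\n  ",
         paste(err, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Survey simulation configuration\n")
  cat("  layout: ", x$n_sites, " sites x ", x$transects_per_site,
      " transects (zones ", paste(x$zone_labels, collapse = "/"),
      "; aspects ", paste(x$aspect_labels, collapse = "/"), ")\n", sep = "")
  cat("  abundance: NB(mean = ", x$mean_abundance_per_transect,
      ", size = ", x$abundance_dispersion, ") per transect\n", sep = "")
  cat("  detection logit: b0 = ", x$beta0,
      "; size S/M/L = ", paste(x$beta_size, collapse = "/"),
      "; night = ", x$beta_night, "; zone = ", x$beta_zone,
      "; aspect = ", x$beta_aspect, "; sigma_site = ", x$sigma_site,
      "\n", sep = "")
  cat("  tag retention: ", x$tag_retention,
      "; seed: ", x$rng_seed, "\n", sep = "")
  invisible(x)
}
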