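# Synthetic survey generator: per-transect populations plus depletion and
# mark-recapture survey schedules with logit-linear detection, so that the
# abundance estimators and the GLMM can be checked by parameter recovery.

SIZE_CLASSES <- c("VS", "S", "M", "L")
# diameter bins (cm): (0,20], (20,30], (30,40], (40,Inf)
SIZE_BREAKS <- c(0, 20, 30, 40, Inf)
# uniform draw ranges for individual diameters within each class
SIZE_RANGES <- list(VS = c(10, 20), S = c(21, 30), M = c(31, 40), L = c(41, 55))

#' Assign size classes from diameters
#'
#' Bins diameters (cm) into the conventional classes: very small (<= 20),
#' small (21-30), medium (31-40), large (> 40); bins are right-closed so
#' integer-cm measurements fall where field protocols place them.
#'
#' @param size_cm numeric diameters in cm.
#' @return factor with levels `VS`, `S`, `M`, `L`.
#' @export
size_class_of <- function(size_cm) {
  cut(size_cm, breaks = SIZE_BREAKS, labels = SIZE_CLASSES, right = TRUE)
}

#' Simulate per-transect starfish populations
#'
#' Lays out sites and transects per the configuration, draws each transect's
#' true abundance from a negative binomial, assigns individual size classes
#' multinomially, and draws one Gaussian random intercept per site. All
#' draws use per-transect (and per-site) RNG substreams derived by stable
#' hashing, so the population on a given transect depends only on the seed
#' and that transect's identity.
#'
#' @param config a [sim_config()].
#' @return an object of class `cots_population`: list with `transects`
#'   (transect_id, site, zone, aspect, area_m2, n_true, u_site) and
#'   `individuals` (id, transect_id, size_cm, size_class, marked, removed,
#'   tag_lost).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  aspects <- config$aspect_labels[(seq_len(config$n_sites) - 1L) %% 2L + 1L]
  u_site <- vapply(sites, function(s) {
    with_seed(substream_seed(config$rng_seed, paste0("site:", s)),
              stats::rnorm(1, 0, config$sigma_site))
  }, numeric(1))
  rows <- list(); ind_rows <- list()
  for (s in seq_along(sites)) {
    for (t in seq_len(config$transects_per_site)) {
      zone <- config$zone_labels[(t - 1L) %% 2L + 1L]
      tid <- sprintf("%s_T%02d", sites[s], t)
      drawn <- with_seed(substream_seed(config$rng_seed, paste0("pop:", tid)), {
        n_true <- if (config$mean_abundance_per_transect == 0) 0L
        else stats::rnbinom(1, size = config$abundance_dispersion,
                            mu = config$mean_abundance_per_transect)
        cls <- if (n_true > 0)
          sample(SIZE_CLASSES, n_true, replace = TRUE,
                 prob = config$size_class_probs)
        else character(0)
        cm <- vapply(cls, function(k) {
          r <- SIZE_RANGES[[k]]
          stats::runif(1, r[1] - 0.499, r[2] + 0.499)
        }, numeric(1))
        list(n_true = n_true, cls = cls, cm = round(unname(cm)))
      })
      rows[[tid]] <- data.frame(
        transect_id = tid, site = sites[s], zone = zone,
        aspect = aspects[s],
        area_m2 = unname(config$area_m2_by_zone[zone]),
        n_true = drawn$n_true, u_site = unname(u_site[s]),
        stringsAsFactors = FALSE)
      if (drawn$n_true > 0) {
        ind_rows[[tid]] <- data.frame(
          id = sprintf("%s_I%04d", tid, seq_len(drawn$n_true)),
          transect_id = tid, size_cm = drawn$cm,
          size_class = drawn$cls,
          marked = FALSE, removed = FALSE, tag_lost = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  transects <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  individuals <- if (length(ind_rows) > 0)
    do.call(rbind, c(ind_rows, list(make.row.names = FALSE)))
  else data.frame(id = character(0), transect_id = character(0),
                  size_cm = numeric(0), size_class = character(0),
                  marked = logical(0), removed = logical(0),
                  tag_lost = logical(0), stringsAsFactors = FALSE)
  structure(list(transects = transects, individuals = individuals,
                 config = config),
            class = "cots_population")
}

#' Per-individual detection probability
#'
#' Inverse-logit of the linear predictor
#' `beta0 + beta_size[class] + beta_night * night + beta_zone * zone +
#' beta_aspect * aspect + u_site`, with the very-small class, daytime and
#' the first zone/aspect labels as the baseline. This is the same
#' logit-linear structure the detectability GLMM assumes, so the model is
#' correctly specified for simulated data.
#'
#' @param individuals data frame with a `size_class` column (and optionally
#'   `removed`, which must be all `FALSE`).
#' @param context list with `night` (logical), `zone`, `aspect`.
#' @param config a [sim_config()].
#' @param site_intercept site random-effect value (default 0).
#' @return vector of detection probabilities in (0, 1).
#' @export
detection_prob <- function(individuals, context, config, site_intercept = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(individuals$removed) && any(individuals$removed))
    stop("detection_prob is undefined for removed individuals")
  off <- c(VS = 0, S = unname(config$beta_size[1]),
           M = unname(config$beta_size[2]), L = unname(config$beta_size[3]))
  eta <- config$beta0 +
    off[as.character(individuals$size_class)] +
    config$beta_night * as.numeric(isTRUE(context$night)) +
    config$beta_zone * as.numeric(context$zone == config$zone_labels[2]) +
    config$beta_aspect * as.numeric(context$aspect == config$aspect_labels[2]) +
    site_intercept
  unname(stats::plogis(eta))
}

empty_event <- function(tr, k, tod) {
  data.frame(transect_id = tr$transect_id, site = tr$site, zone = tr$zone,
             aspect = tr$aspect, area_m2 = tr$area_m2,
             survey_index = k, time_of_day = tod,
             n_sighted = 0L, n_newly_marked = 0L, n_recaptured = 0L,
             n_removed = 0L, stringsAsFactors = FALSE)
}

#' Simulate a depletion (removal) survey schedule
#'
#' Runs `k_surveys` successive daytime passes over every transect. On each
#' pass every not-yet-removed individual is detected independently with its
#' [detection_prob()]; detected individuals are removed before the next
#' pass. The population is closed: nothing enters or leaves a transect.
#'
#' @param population a [simulate_population()] result.
#' @param config the [sim_config()] used to build the population.
#' @param k_surveys number of removal passes (>= 1; the field design this
#'   emulates used 3).
#' @return object of class `cots_surveys`: list with `surveys` (one row per
#'   transect x survey, schema as written by [write_survey_csv()]),
#'   `individuals` (removal flags updated) and `design = "depletion"`.
#' @export
simulate_depletion <- function(population, config, k_surveys = 3) {
  stopifnot(inherits(population, "cots_population"), k_surveys >= 1)
  inds <- population$individuals
  events <- list()
  for (i in seq_len(nrow(population$transects))) {
    tr <- population$transects[i, ]
    ctx <- list(night = FALSE, zone = tr$zone, aspect = tr$aspect)
    for (k in seq_len(k_surveys)) {
      ev <- empty_event(tr, k, "day")
      alive <- which(inds$transect_id == tr$transect_id & !inds$removed)
      if (length(alive) > 0) {
        p <- detection_prob(inds[alive, ], ctx, config, tr$u_site)
        det <- with_seed(
          substream_seed(config$rng_seed,
                         paste0("dep:", tr$transect_id, ":", k)),
          stats::runif(length(alive)) < p)
        ev$n_sighted <- ev$n_removed <- sum(det)
        inds$removed[alive[det]] <- TRUE
      }
      events[[paste(tr$transect_id, k)]] <- ev
    }
  }
  structure(list(surveys = do.call(rbind, c(events, list(make.row.names = FALSE))),
                 individuals = inds, sightings = NULL,
                 design = "depletion", config = config),
            class = "cots_surveys")
}

#' Simulate a mark-recapture survey schedule
#'
#' Runs the survey schedule (default day, night, follow-up day) over every
#' transect without removing animals. Detections on the first survey are
#' marked; on later surveys the event records all animals sighted (C), the
#' sighted animals carrying a retained mark (recaptures R), and previously
#' unmarked detections, which are newly marked. Tag loss is drawn once per
#' individual at marking time with probability `1 - tag_retention`.
#'
#' @param population a [simulate_population()] result.
#' @param config the [sim_config()] used to build the population.
#' @param schedule character vector of `"day"`/`"night"` survey contexts,
#'   length >= 2.
#' @return object of class `cots_surveys` with `surveys`, updated
#'   `individuals`, a per-detection `sightings` table (used for size-class
#'   detectability) and `design = "markrecap"`.
#' @export
simulate_mark_recapture <- function(population, config,
                                    schedule = c("day", "night", "day")) {
  stopifnot(inherits(population, "cots_population"), length(schedule) >= 2,
            all(schedule %in% c("day", "night")))
  inds <- population$individuals
  events <- list(); sight <- list()
  for (i in seq_len(nrow(population$transects))) {
    tr <- population$transects[i, ]
    here <- which(inds$transect_id == tr$transect_id)
    for (k in seq_along(schedule)) {
      tod <- schedule[k]
      ev <- empty_event(tr, k, tod)
      if (length(here) > 0) {
        ctx <- list(night = tod == "night", zone = tr$zone,
                    aspect = tr$aspect)
        p <- detection_prob(inds[here, ], ctx, config, tr$u_site)
        drawn <- with_seed(
          substream_seed(config$rng_seed,
                         paste0("mr:", tr$transect_id, ":", k)), {
            det <- stats::runif(length(here)) < p
            loss <- stats::runif(length(here)) >= config$tag_retention
            list(det = det, loss = loss)
          })
        det <- drawn$det
        recap <- det & inds$marked[here] & !inds$tag_lost[here]
        newly <- det & !inds$marked[here]
        ev$n_sighted <- sum(det)
        ev$n_recaptured <- sum(recap)
        ev$n_newly_marked <- sum(newly)
        if (any(det)) {
          sight[[paste(tr$transect_id, k)]] <- data.frame(
            transect_id = tr$transect_id, survey_index = k,
            time_of_day = tod, id = inds$id[here][det],
            size_cm = inds$size_cm[here][det],
            size_class = inds$size_class[here][det],
            previously_marked = inds$marked[here][det],
            recaptured = recap[det], stringsAsFactors = FALSE)
        }
        # newly marked individuals get their single tag-loss draw now
        inds$tag_lost[here[newly]] <- drawn$loss[newly]
        inds$marked[here[newly]] <- TRUE
      }
      events[[paste(tr$transect_id, k)]] <- ev
    }
  }
  sightings <- if (length(sight) > 0)
    do.call(rbind, c(sight, list(make.row.names = FALSE)))
  else NULL
  structure(list(surveys = do.call(rbind, c(events, list(make.row.names = FALSE))),
                 individuals = inds, sightings = sightings,
                 design = "markrecap", config = config),
            class = "cots_surveys")
}

#' Write simulated survey tables as CSV
#'
#' Writes `surveys.csv` (one row per transect x survey) and
#' `individuals.csv` to a directory. Each file starts with a `#` comment
#' recording the package version and seed, so outputs are self-describing
#' yet byte-reproducible (no timestamps).
#'
#' @param x a `cots_surveys` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_survey_csv <- function(x, dir) {
  stopifnot(inherits(x, "cots_surveys"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# cotsdetect %s; design=%s; seed=%d",
                 as.character(utils::packageVersion("cotsdetect")),
                 x$design, x$config$rng_seed)
  paths <- c(surveys = file.path(dir, "surveys.csv"),
             individuals = file.path(dir, "individuals.csv"))
  write_commented_csv(x$surveys, paths["surveys"], hdr)
  ind <- x$individuals[, c("id", "transect_id", "size_cm", "size_class")]
  write_commented_csv(ind, paths["individuals"], hdr)
  invisible(paths)
}

write_commented_csv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read a survey-record CSV
#'
#' Reads a delimited survey table as written by [write_survey_csv()]
#' (comment lines starting with `#` are skipped) and validates it for the
#' given design.
#'
#' @param path CSV path.
#' @param design `"depletion"` or `"markrecap"`; `NULL` skips validation.
#' @return data frame of survey events.
#' @export
read_surveys <- function(path, design = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(design)) validate_inputs(df, design)
  df
}
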