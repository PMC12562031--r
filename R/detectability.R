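# Detection proportions, pooled and per-transect detectability summaries,
# size-class detectability tables and density conversions.

#' Detection proportion for one transect x survey
#'
#' Detectability is the proportion of the (estimated) total sample
#' population that was sighted: `found / n_hat`, clamped to [0, 1] with a
#' warning if the count exceeds the estimate. The record also carries the
#' integer `missed` count (`round(n_hat) - found`, half-up rounding,
#' floored at 0) used as the binomial complement by the GLMM, and an
#' `included` flag: transects with `n_hat < 1` (no animal presumed
#' present) are excluded from averaging.
#'
#' @param found number sighted (C).
#' @param n_hat estimated sample population (real-valued).
#' @return one-row data frame: `found`, `missed`, `proportion`, `included`.
#' @examples
#' detection_proportion(9, 18)$proportion  # 0.5
#' @export
detection_proportion <- function(found, n_hat) {
  stopifnot(found >= 0, n_hat >= 0)
  if (n_hat == 0 && found > 0)
    stop("inconsistent record: found = ", found,
         " but estimated population is 0")
  prop <- if (n_hat == 0) NA_real_ else found / n_hat
  if (!is.na(prop) && prop > 1) {
    warning("found (", found, ") exceeds estimated population (", n_hat,
            "); proportion clamped to 1")
    prop <- 1
  }
  missed <- max(round_half_up(n_hat) - found, 0)
  data.frame(found = found, missed = missed, n_hat = n_hat,
             proportion = prop, included = n_hat >= 1)
}

#' Build detectability records from surveys and abundance estimates
#'
#' Joins per-transect abundance onto the survey table and computes one
#' detection record per transect x survey. For a depletion design the
#' denominator for survey k is the population still present, i.e. the
#' removal total minus everything removed on earlier surveys; for a
#' mark-recapture design it is the transect's max-N estimate for every
#' survey.
#'
#' @param surveys survey-event data frame.
#' @param abundance per-transect abundance table from
#'   [estimate_abundance()].
#' @param design `"depletion"` or `"markrecap"`.
#' @return data frame with transect metadata, `found`, `missed`,
#'   `proportion`, `included`.
#' @export
detectability_records <- function(surveys,
                                  abundance,
                                  design = c("depletion", "markrecap")) {
  design <- match.arg(design)
  missing_tr <- setdiff(surveys$transect_id, abundance$transect_id)
  if (length(missing_tr) > 0)
    stop("no abundance estimate for transect(s): ",
         paste(missing_tr, collapse = ", "))
  rows <- list()
  for (tid in unique(surveys$transect_id)) {
    ev <- surveys[surveys$transect_id == tid, , drop = FALSE]
    ev <- ev[order(ev$survey_index), , drop = FALSE]
    n_tot <- abundance$n_hat[match(tid, abundance$transect_id)]
    if (is.na(n_tot)) n_tot <- 0
    for (k in seq_len(nrow(ev))) {
      n_eff <- if (design == "depletion")
        n_tot - sum(ev$n_removed[seq_len(k - 1L)])
      else n_tot
      rec <- detection_proportion(ev$n_sighted[k], max(n_eff, 0))
      rows[[paste(tid, k)]] <- cbind(
        ev[k, c("transect_id", "site", "zone", "aspect", "area_m2",
                "survey_index", "time_of_day")],
        rec, row.names = NULL)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pooled detectability
#'
#' Ratio of total found to total estimated population over groups of
#' records: `sum(found) / sum(n_hat)`. The pooled proportion equals the
#' n_hat-weighted mean of the per-record proportions. Groups whose summed
#' denominator is zero are returned as `NA` with a warning.
#'
#' @param records detectability records ([detectability_records()] output,
#'   or any data frame with `found` and `n_hat` columns).
#' @param by character vector of grouping columns (e.g.
#'   `c("survey_index", "time_of_day")`), or `NULL` for a single pool.
#' @return data frame with the grouping columns, `found`, `n_hat`,
#'   `proportion` (2 dp in `proportion_2dp`) and `percent` (1 dp).
#' @export
pooled_detectability <- function(records, by = NULL) {
  n_hat <- if ("n_hat" %in% names(records)) records$n_hat
  else records$found + records$missed
  key <- if (is.null(by)) rep("all", nrow(records))
  else interaction(records[by], drop = TRUE, sep = ":")
  out <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    f <- sum(records$found[ix]); n <- sum(n_hat[ix])
    if (n == 0) {
      warning("pooled group with zero estimated population; proportion NA")
      prop <- NA_real_
    } else prop <- f / n
    g <- if (is.null(by)) data.frame(group = "all")
    else records[ix[1], by, drop = FALSE]
    cbind(g, data.frame(found = f, n_hat = n, proportion = prop,
                        proportion_2dp = round_half_up(prop, 2),
                        percent = round_half_up(100 * prop, 1)),
          row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Mean per-transect detectability
#'
#' Arithmetic mean, standard error (sd/sqrt(n), on the proportion scale),
#' minimum and maximum of the per-record detection proportions, using only
#' records where at least one animal was presumed present
#' (`included = TRUE`). With a single record the SE is `NA` by convention.
#'
#' @param records detectability records.
#' @return one-row data frame: `n`, `mean`, `se`, `min`, `max`.
#' @export
mean_detectability <- function(records) {
  p <- records$proportion[records$included & !is.na(records$proportion)]
  if (length(p) == 0) stop("no included detectability records")
  data.frame(n = length(p), mean = mean(p),
             se = if (length(p) > 1) stats::sd(p) / sqrt(length(p))
             else NA_real_,
             min = min(p), max = max(p))
}

#' Size-class detectability table
#'
#' Pools individual sightings across all transects and, for each size
#' class, estimates the class's sample population by Lincoln-Petersen on
#' pooled counts, then reports detectability as the number sighted (M)
#' over that estimate. The day estimate uses the pair (initial day survey
#' -> night survey): M = class members marked on survey 1, C/R from survey
#' 2. The night estimate uses (night -> follow-up day): M = class members
#' marked on surveys 1-2, C/R from survey 3. The M column for each time of
#' day is the number of class members sighted during that survey.
#'
#' @param sightings per-detection table from [simulate_mark_recapture()]
#'   (columns `survey_index`, `size_class`, `recaptured`,
#'   `previously_marked`), or equivalent field records.
#' @return data frame with one row per size class x time of day: `m`,
#'   `n_hat`, `detectability` (M/N, 2 dp).
#' @export
size_class_table <- function(sightings) {
  need <- c("survey_index", "size_class", "recaptured", "previously_marked")
  stopifnot(all(need %in% names(sightings)))
  ks <- sort(unique(sightings$survey_index))
  if (length(ks) < 3)
    stop("size-class pooling needs a three-survey schedule (day, night, day)")
  out <- list()
  for (cls in SIZE_CLASSES) {
    sc <- sightings[sightings$size_class == cls, , drop = FALSE]
    s1 <- sc[sc$survey_index == ks[1], , drop = FALSE]
    s2 <- sc[sc$survey_index == ks[2], , drop = FALSE]
    s3 <- sc[sc$survey_index == ks[3], , drop = FALSE]
    # day: marks from the initial day survey, recaptured at night
    day_est <- lincoln_petersen(nrow(s1), nrow(s2), sum(s2$recaptured))
    # night: everything marked by the end of the night survey,
    # recaptured on the follow-up day survey
    m_night <- nrow(s1) + sum(!s2$previously_marked)
    night_est <- lincoln_petersen(m_night, nrow(s3), sum(s3$recaptured))
    for (tod in c("day", "night")) {
      m <- if (tod == "day") nrow(s1) else nrow(s2)
      nh <- if (tod == "day") day_est$n_hat else night_est$n_hat
      out[[paste(cls, tod)]] <- data.frame(
        size_class = cls, time_of_day = tod, m = m, n_hat = nh,
        detectability = if (is.na(nh) || nh == 0) NA_real_
        else round_half_up(m / nh, 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Density conversions
#'
#' Converts a count over a surveyed area to the two reporting scales used
#' for starfish surveys: animals per 200 m^2 transect-equivalent and
#' animals per hectare.
#'
#' @param count number of animals (may be an abundance estimate).
#' @param area_m2 surveyed area in m^2 (> 0).
#' @return one-row data frame: `count`, `area_m2`, `per_200m2`, `per_ha`.
#' @examples
#' density_report(7.2, 200)$per_ha  # 360
#' @export
density_report <- function(count, area_m2) {
  stopifnot(area_m2 > 0, count >= 0)
  data.frame(count = count, area_m2 = area_m2,
             per_200m2 = count / area_m2 * 200,
             per_ha = count / area_m2 * 1e4)
}

#' Mean density across transects
#'
#' Mean and standard error (across transects) of per-transect densities on
#' the per-200 m^2 scale, plus the equivalent per-hectare mean.
#'
#' @param counts per-transect counts.
#' @param areas_m2 per-transect areas (m^2), recycled if scalar.
#' @return one-row data frame: `n_transects`, `mean_per_200m2`,
#'   `se_per_200m2`, `mean_per_ha`.
#' @export
mean_density <- function(counts, areas_m2) {
  stopifnot(all(areas_m2 > 0))
  d <- counts / areas_m2 * 200
  data.frame(n_transects = length(d), mean_per_200m2 = mean(d),
             se_per_200m2 = if (length(d) > 1) stats::sd(d) / sqrt(length(d))
             else NA_real_,
             mean_per_ha = mean(counts / areas_m2 * 1e4))
}
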