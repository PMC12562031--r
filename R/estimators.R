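# Closed-population abundance estimators: depletion totals and
# Lincoln-Petersen / Chapman mark-recapture, with the max-N rule for the
# per-transect total sample population.

abundance_row <- function(transect_id = NA_character_, n_hat = NA_real_,
                          method, estimable, survey_pair = NA_character_) {
  data.frame(transect_id = transect_id, method = method, n_hat = n_hat,
             estimable = estimable, survey_pair = survey_pair,
             stringsAsFactors = FALSE)
}

#' Depletion (removal) abundance
#'
#' For a removal design the total sample population on a transect is the
#' cumulative number of animals removed across all successive surveys,
#' assuming every individual initially present is eventually detected and
#' the population is closed.
#'
#' @param events survey events for one transect, ordered by `survey_index`,
#'   with an `n_removed` column.
#' @return one-row abundance estimate (`method = "depletion"`, always
#'   estimable, integer `n_hat`).
#' @examples
#' ev <- data.frame(survey_index = 1:3, n_removed = c(96, 25, 11))
#' depletion_abundance(ev)$n_hat  # 132
#' @export
depletion_abundance <- function(events) {
  stopifnot(is.data.frame(events), "n_removed" %in% names(events))
  if (!is.null(events$survey_index) && is.unsorted(events$survey_index))
    stop("events must be ordered by survey_index")
  if (any(events$n_removed < 0)) stop("removal counts must be non-negative")
  tid <- if ("transect_id" %in% names(events)) events$transect_id[1]
  else NA_character_
  abundance_row(tid, sum(events$n_removed), "depletion", TRUE)
}

#' Lincoln-Petersen mark-recapture abundance
#'
#' The classical closed-population estimator \eqn{\hat N = MC/R}: M animals
#' marked, C animals sighted on a later survey, of which R carry a mark.
#' With no recaptures (R = 0) the estimator is undefined and the estimate
#' is flagged inestimable rather than infinite; downstream summaries skip
#' such transects with a warning.
#'
#' @param M number marked before the recapture survey.
#' @param C number sighted in the recapture survey.
#' @param R number of marked animals among the C sighted.
#' @return one-row abundance estimate; `n_hat` is real-valued (rounding, if
#'   any, happens at report time).
#' @examples
#' lincoln_petersen(10, 8, 4)$n_hat  # 20
#' @export
lincoln_petersen <- function(M, C, R) {
  check_mcr(M, C, R)
  if (R == 0) return(abundance_row(n_hat = NA_real_,
                                   method = "lincoln_petersen",
                                   estimable = FALSE))
  abundance_row(n_hat = M * C / R, method = "lincoln_petersen",
                estimable = TRUE)
}

#' Chapman bias-corrected mark-recapture abundance
#'
#' \eqn{\hat N = (M+1)(C+1)/(R+1) - 1}; defined for R = 0 and less biased
#' than Lincoln-Petersen in small samples. Off by default in the pipeline,
#' which mirrors analyses that use the plain MC/R form.
#'
#' @inheritParams lincoln_petersen
#' @return one-row abundance estimate, always estimable.
#' @examples
#' chapman(10, 8, 4)$n_hat  # 18.8
#' @export
chapman <- function(M, C, R) {
  check_mcr(M, C, R)
  abundance_row(n_hat = (M + 1) * (C + 1) / (R + 1) - 1,
                method = "chapman", estimable = TRUE)
}

check_mcr <- function(M, C, R) {
  stopifnot(length(M) == 1, length(C) == 1, length(R) == 1)
  if (any(c(M, C, R) < 0)) stop("counts must be non-negative")
  if (R > M || R > C)
    stop("impossible recapture count: R = ", R,
         " exceeds min(M, C) = ", min(M, C))
  invisible(TRUE)
}

#' Per-transect total sample population (max-N rule)
#'
#' Successive survey pairs give independent estimates of the same closed
#' population; the maximum estimable value is taken as the transect's total
#' sample population. If no pair is estimable (all R = 0), the maximum
#' observed count is used instead and flagged as a fallback.
#'
#' @param estimates data frame of abundance estimates for one transect
#'   (rows as returned by the estimator functions).
#' @param max_sighted largest single-survey count on the transect, used
#'   only for the fallback.
#' @return one-row abundance estimate; `method = "fallback_max_count"` and
#'   `estimable = FALSE` when the fallback was used.
#' @export
transect_sample_population <- function(estimates, max_sighted = NA_real_) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1)
  ok <- estimates[estimates$estimable & !is.na(estimates$n_hat), ,
                  drop = FALSE]
  if (nrow(ok) == 0) {
    warning("no estimable abundance for transect ",
            estimates$transect_id[1], "; falling back to max observed count")
    return(abundance_row(estimates$transect_id[1], max_sighted,
                         "fallback_max_count", FALSE))
  }
  ok[which.max(ok$n_hat), , drop = FALSE]
}

#' Estimate per-transect abundance from a survey table
#'
#' Applies the design's estimator to every transect in a survey-event
#' table. For a depletion design the estimate is the removal total. For a
#' mark-recapture design every consecutive survey pair (i, i+1) yields a
#' Lincoln-Petersen (or Chapman) estimate with M the cumulative number of
#' animals marked before the recapture survey, C the recapture-survey
#' sighting count and R its recapture count; the max-N rule then picks the
#' transect's total sample population.
#'
#' @param surveys survey-event data frame (schema of [write_survey_csv()]).
#' @param design `"depletion"` or `"markrecap"`.
#' @param use_chapman logical; use the Chapman form instead of plain MC/R.
#' @return data frame with one row per transect (columns `transect_id`,
#'   `method`, `n_hat`, `estimable`, `survey_pair`); all pairwise estimates
#'   are attached as attribute `"pairs"`.
#' @export
estimate_abundance <- function(surveys, design = c("depletion", "markrecap"),
                               use_chapman = FALSE) {
  design <- match.arg(design)
  validate_inputs(surveys, design)
  out <- list(); pairs <- list()
  for (tid in unique(surveys$transect_id)) {
    ev <- surveys[surveys$transect_id == tid, , drop = FALSE]
    ev <- ev[order(ev$survey_index), , drop = FALSE]
    if (design == "depletion") {
      out[[tid]] <- depletion_abundance(ev)
      next
    }
    est <- list()
    cum_marked <- cumsum(ev$n_newly_marked)
    for (i in seq_len(nrow(ev) - 1L)) {
      M <- cum_marked[i]
      C <- ev$n_sighted[i + 1L]
      R <- ev$n_recaptured[i + 1L]
      e <- if (use_chapman) chapman(M, C, R) else lincoln_petersen(M, C, R)
      e$transect_id <- tid
      e$survey_pair <- paste0(ev$survey_index[i], "-", ev$survey_index[i + 1L])
      est[[i]] <- e
    }
    est <- do.call(rbind, est)
    pairs[[tid]] <- est
    out[[tid]] <- transect_sample_population(est, max(ev$n_sighted))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "pairs") <- if (length(pairs) > 0)
    do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  res
}
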