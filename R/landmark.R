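# Landmark analysis: period-specific hazard ratios. At each landmark point
# the risk set is rebuilt (members with a prior event, death, loss or
# censoring before the point are excluded), observation is administratively
# terminated at the window end, and the matched-stratified Cox model of the
# overall screen is refit within the window.

#' Period-specific hazard ratios over landmark windows
#'
#' Windows are closed-open in years from the index date (default
#' `[0,2), [2,5), [5,10), [10,Inf)`); an event at exactly a boundary falls
#' in the later window. With a single window `[0, Inf)` the estimate equals
#' the overall screen estimate exactly.
#'
#' @inheritParams build_survival_dataset
#' @param breaks window breakpoints in years (first 0, last Inf).
#' @return data.frame with one row per window: `phenotype`, `window`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `n_at_risk`, `n_events`, `estimable`.
#' @export
landmark_hrs <- function(sets, events, deaths, persons, phenotype,
                         breaks = LANDMARK_BREAKS,
                         censor_dates = DEFAULT_CENSOR_DATES) {
  if (breaks[1] != 0 || !is.infinite(breaks[length(breaks)]) ||
      is.unsorted(breaks, strictly = TRUE))
    stop("landmark breaks must partition [0, Inf)")
  rec <- build_survival_dataset(sets, events, deaths, persons, phenotype,
                                censor_dates)
  half_day <- 0.5 / DAYS_PER_YEAR
  out <- vector("list", length(breaks) - 1L)
  for (w in seq_len(length(breaks) - 1L)) {
    ws <- breaks[w]; we <- breaks[w + 1L]
    # risk set at the landmark point: follow-up must extend past ws, or the
    # member has their (first) event exactly at the boundary, which the
    # closed-open rule assigns to this window
    in_risk <- rec$time > ws | (rec$event == 1 & rec$time == ws)
    sub <- rec[in_risk, , drop = FALSE]
    sub$w_event <- as.numeric(sub$event == 1 & sub$time < we)
    sub$w_time <- pmax(pmin(sub$time, we) - ws, half_day)
    fitrec <- data.frame(person_id = sub$person_id, set_id = sub$set_id,
                         exposed = sub$exposed, time = sub$w_time,
                         event = sub$w_event, stringsAsFactors = FALSE)
    row <- stratified_cox(fitrec, phenotype)
    out[[w]] <- data.frame(phenotype = phenotype,
                           window = sprintf("[%g,%g)", ws, we),
                           hr = row$hr, ci_low = row$ci_low,
                           ci_high = row$ci_high, p = row$p,
                           n_at_risk = nrow(sub),
                           n_events = sum(sub$w_event),
                           estimable = row$estimable,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Landmark screen over several phenotypes
#'
#' @inheritParams landmark_hrs
#' @param phenotypes PheCodes to analyse.
#' @return row-bound landmark results keyed by (phenotype, window).
#' @export
run_landmark_screen <- function(sets, events, deaths, persons, phenotypes,
                                breaks = LANDMARK_BREAKS,
                                censor_dates = DEFAULT_CENSOR_DATES) {
  res <- do.call(rbind, lapply(phenotypes, function(ph)
    landmark_hrs(sets, events, deaths, persons, ph, breaks, censor_dates)))
  rownames(res) <- NULL
  res
}
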