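# Phenome-wide screening over the matched cohort: candidate selection,
# per-phenotype survival datasets with the censoring/exclusion rules,
# matched-stratified Cox fits, Fine-Gray competing-risk screening of causes
# of death, Bonferroni control and sensitivity filters.

#' Select candidate phenotypes
#'
#' Phenotypes diagnosed in at least `min_cases` exposed persons (at any
#' time by default, or post-index only), excluding the exposure PheCodes
#' themselves.
#'
#' @param events mapped, deduplicated diagnosis events.
#' @param exposure exposure table (`person_id`, `index_date`).
#' @param min_cases co-occurrence threshold.
#' @param exclude_codes PheCodes never eligible (the exposure definition).
#' @param post_index_only count only diagnoses after the person's index date.
#' @return character vector of candidate PheCodes (sorted).
#' @export
select_candidates <- function(events, exposure, min_cases = 20L,
                              exclude_codes = EXPOSURE_PHECODES,
                              post_index_only = FALSE) {
  ev <- events[events$person_id %in% exposure$person_id &
                 !(events$code %in% exclude_codes), , drop = FALSE]
  if (post_index_only) {
    idx <- exposure$index_date[match(ev$person_id, exposure$person_id)]
    ev <- ev[ev$date > idx, , drop = FALSE]
  }
  if (nrow(ev) == 0L) return(character(0))
  counts <- table(unique(ev[, c("person_id", "code")])$code)
  sort(names(counts)[counts >= min_cases])
}

#' Build the survival dataset for one phenotype
#'
#' One record per remaining matched-set member. Follow-up runs from the
#' set's index date to the earliest of phenotype onset, death, loss to
#' follow-up, or the region's administrative censoring date; the event
#' indicator marks onset occurring first (onset wins a same-day tie with
#' death). Members already diagnosed with the phenotype on or before the
#' index date are excluded as prevalent; members whose follow-up would be
#' non-positive are excluded and logged.
#'
#' @param sets matched sets (post-exclusion).
#' @param events mapped first-occurrence events.
#' @param deaths deaths table.
#' @param persons persons table.
#' @param phenotype PheCode under analysis.
#' @param censor_dates named (by region) censoring dates.
#' @return data.frame (`person_id`, `set_id`, `exposed`, `time` in years,
#'   `event`) with attribute `exclusions` = c(prevalent, nonpositive).
#' @export
build_survival_dataset <- function(sets, events, deaths, persons, phenotype,
                                   censor_dates = DEFAULT_CENSOR_DATES) {
  ev <- events[events$code == phenotype, , drop = FALSE]
  onset <- ev$date[match(sets$person_id, ev$person_id)]
  dd <- deaths$death_date[match(sets$person_id, deaths$person_id)]
  pidx <- match(sets$person_id, persons$person_id)
  ld <- persons$lost_to_followup_date[pidx]
  cds <- as.Date(unlist(censor_dates))
  cd <- cds[match(persons$region[pidx], names(censor_dates))]

  prevalent <- !is.na(onset) & onset <= sets$index_date
  end <- pmin(onset, dd, ld, cd, na.rm = TRUE)
  event <- !is.na(onset) & onset == end
  time <- years_between(end, sets$index_date)
  nonpos <- !prevalent & time <= 0
  keep <- !prevalent & !nonpos
  out <- data.frame(person_id = sets$person_id[keep],
                    set_id = sets$set_id[keep],
                    exposed = as.numeric(sets$role[keep] == "case"),
                    time = time[keep],
                    event = as.numeric(event[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(prevalent = sum(prevalent),
                               nonpositive = sum(nonpos))
  out
}

#' Build the competing-risks mortality dataset
#'
#' One record per matched-set member with time from index date to death or
#' censoring, the cause category of death (`event_type = "censored"` when
#' follow-up ends without death), the exposure flag and the eight baseline
#' covariates (adjusters for the unstratified Fine-Gray fit).
#'
#' @inheritParams build_survival_dataset
#' @return data.frame with columns `person_id`, `set_id`, `exposed`,
#'   `time`, `event_type` and the matching covariates.
#' @export
build_mortality_dataset <- function(sets, deaths, persons,
                                    censor_dates = DEFAULT_CENSOR_DATES) {
  didx <- match(sets$person_id, deaths$person_id)
  dd <- deaths$death_date[didx]
  cause <- deaths$cause_category[didx]
  pidx <- match(sets$person_id, persons$person_id)
  ld <- persons$lost_to_followup_date[pidx]
  cds <- as.Date(unlist(censor_dates))
  cd <- cds[match(persons$region[pidx], names(censor_dates))]
  end <- pmin(dd, ld, cd, na.rm = TRUE)
  died <- !is.na(dd) & dd == end
  time <- years_between(end, sets$index_date)
  keep <- time > 0
  out <- data.frame(person_id = sets$person_id[keep],
                    set_id = sets$set_id[keep],
                    exposed = as.numeric(sets$role[keep] == "case"),
                    time = time[keep],
                    event_type = ifelse(died[keep], cause[keep], "censored"),
                    stringsAsFactors = FALSE)
  cov <- persons[pidx[keep], MATCHING_COVARIATES]
  out <- cbind(out, cov)
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(nonpositive = sum(!keep))
  out
}

association_row <- function(phenotype, hr = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p = NA_real_,
                            n_events_exposed = NA_integer_,
                            n_events_control = NA_integer_,
                            n_at_risk = NA_integer_, estimable = FALSE) {
  data.frame(phenotype = phenotype, hr = hr, ci_low = ci_low,
             ci_high = ci_high, p = p, p_adjusted = NA_real_,
             n_events_exposed = n_events_exposed,
             n_events_control = n_events_control,
             n_at_risk = n_at_risk, estimable = estimable,
             stringsAsFactors = FALSE)
}

#' Matched-stratified Cox fit for one phenotype
#'
#' Fits the exposure log hazard ratio by stratified partial likelihood with
#' one baseline hazard per matched set (Efron approximation for ties), and
#' returns the Wald 95% CI and p-value. If no stratum is informative (at
#' least one event and both exposure levels), the result is flagged
#' non-estimable rather than raising an error, so a screen can continue.
#'
#' @param records survival records from [build_survival_dataset()].
#' @param phenotype label carried into the result row.
#' @return one-row data.frame (an association result).
#' @export
stratified_cox <- function(records, phenotype = NA_character_) {
  base <- association_row(
    phenotype,
    n_events_exposed = sum(records$event[records$exposed == 1]),
    n_events_control = sum(records$event[records$exposed == 0]),
    n_at_risk = nrow(records))
  if (nrow(records) == 0L || sum(records$event) == 0L) return(base)
  agg <- rowsum(cbind(records$event, records$exposed, 1 - records$exposed),
                records$set_id)
  if (!any(agg[, 1] > 0 & agg[, 2] > 0 & agg[, 3] > 0)) return(base)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ exposed + survival::strata(set_id),
      data = records, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(base)
  beta <- unname(stats::coef(fit)["exposed"])
  se <- sqrt(diag(stats::vcov(fit)))[["exposed"]]
  if (!is.finite(beta) || !is.finite(se) || se <= 0 || abs(beta) > 15)
    return(base)
  z <- stats::qnorm(0.975)
  base$hr <- exp(beta); base$ci_low <- exp(beta - z * se)
  base$ci_high <- exp(beta + z * se)
  base$p <- 2 * stats::pnorm(-abs(beta / se))
  base$estimable <- TRUE
  attr(base, "beta") <- beta
  attr(base, "se") <- se
  base
}

#' Fine-Gray subdistribution-hazard fit for one cause of death
#'
#' Estimates the exposure effect on the subdistribution hazard of the given
#' cause using censoring-distribution weighting (competing-event subjects
#' remain in the risk set with declining weights), adjusted for the
#' supplied covariates, with a robust Wald CI and p-value. With a single
#' event type the fit reduces to the cause-specific Cox model.
#'
#' @param records mortality records from [build_mortality_dataset()].
#' @param cause cause category to analyse.
#' @param covariates adjuster column names present in `records`.
#' @return one-row data.frame (`hr` is the subdistribution hazard ratio).
#' @export
fine_gray <- function(records, cause, covariates = MATCHING_COVARIATES) {
  lab <- paste0("death:", cause)
  n_exp <- sum(records$event_type == cause & records$exposed == 1)
  n_ctl <- sum(records$event_type == cause & records$exposed == 0)
  base <- association_row(lab, n_events_exposed = n_exp,
                          n_events_control = n_ctl,
                          n_at_risk = nrow(records))
  if (n_exp == 0L) return(base)
  dat <- records
  causes <- setdiff(unique(dat$event_type), "censored")
  dat$status <- factor(dat$event_type, levels = c("censored", causes))
  for (cv in covariates)
    if (is.character(dat[[cv]])) dat[[cv]] <- factor(dat[[cv]])
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(dat[[cv]])) > 1L, logical(1))]
  fg <- tryCatch(
    survival::finegray(survival::Surv(time, status) ~ ., data = dat,
                       etype = cause),
    error = function(e) NULL)
  if (is.null(fg)) return(base)
  form <- stats::reformulate(c("exposed", covariates),
                             response = "survival::Surv(fgstart, fgstop, fgstatus)")
  fg$.pid <- fg$person_id
  fit <- tryCatch(
    suppressWarnings(survival::coxph(form, data = fg, weights = fg$fgwt,
                                     cluster = .pid, robust = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(base)
  beta <- unname(stats::coef(fit)["exposed"])
  se <- sqrt(diag(stats::vcov(fit)))[["exposed"]]
  if (!is.finite(beta) || !is.finite(se) || se <= 0) return(base)
  z <- stats::qnorm(0.975)
  base$hr <- exp(beta); base$ci_low <- exp(beta - z * se)
  base$ci_high <- exp(beta + z * se)
  base$p <- 2 * stats::pnorm(-abs(beta / se))
  base$estimable <- TRUE
  attr(base, "beta") <- beta
  base
}

#' Bonferroni adjustment over a test family
#'
#' @param results association results (rows with `p`).
#' @param m family size; defaults to the number of rows with a computed p.
#' @param alpha significance level applied to the adjusted p.
#' @return `results` with `p_adjusted = min(1, m * p)` and `significant`.
#' @export
bonferroni <- function(results, m = NULL, alpha = 0.05) {
  if (is.null(m)) m <- sum(!is.na(results$p))
  if (m <= 0) stop("Bonferroni family size m must be positive")
  results$p_adjusted <- pmin(1, m * results$p)
  results$significant <- !is.na(results$p_adjusted) &
    results$p_adjusted < alpha
  results
}

#' Run the PheWAS screen over a set of phenotypes
#'
#' Builds the survival dataset and fits the matched-stratified Cox model
#' for each phenotype, then applies Bonferroni control over the family of
#' phenotypes actually tested.
#'
#' @inheritParams build_survival_dataset
#' @param phenotypes candidate PheCodes (see [select_candidates()]).
#' @param alpha significance level.
#' @return data.frame of association results, one row per phenotype, with
#'   attribute `exclusions` (per-phenotype prevalent/nonpositive counts).
#' @export
run_phewas_screen <- function(sets, events, deaths, persons, phenotypes,
                              censor_dates = DEFAULT_CENSOR_DATES,
                              alpha = 0.05) {
  rows <- vector("list", length(phenotypes))
  excl <- matrix(0L, length(phenotypes), 2,
                 dimnames = list(phenotypes, c("prevalent", "nonpositive")))
  ev_split <- split(events, factor(events$code, levels = phenotypes))
  for (i in seq_along(phenotypes)) {
    rec <- build_survival_dataset(sets, ev_split[[i]], deaths, persons,
                                  phenotypes[i], censor_dates)
    excl[i, ] <- attr(rec, "exclusions")
    rows[[i]] <- stratified_cox(rec, phenotypes[i])
  }
  res <- do.call(rbind, rows)
  res <- bonferroni(res, m = length(phenotypes), alpha = alpha)
  attr(res, "exclusions") <- excl
  res
}

#' Screen causes of death with Fine-Gray models
#'
#' Causes with at least `min_cases` exposed deaths are analysed; the others
#' are skipped and listed in the `skipped` attribute. Bonferroni control is
#' applied over the causes tested.
#'
#' @param records mortality records from [build_mortality_dataset()].
#' @param min_cases minimum exposed deaths per cause.
#' @param covariates adjuster columns.
#' @param alpha significance level.
#' @return data.frame of association results (one per analysed cause).
#' @export
screen_death_causes <- function(records, min_cases = 20L,
                                covariates = MATCHING_COVARIATES,
                                alpha = 0.05) {
  tab <- table(records$event_type[records$exposed == 1 &
                                    records$event_type != "censored"])
  causes <- sort(names(tab)[tab >= min_cases])
  skipped <- sort(setdiff(names(tab), causes))
  rows <- lapply(causes, function(cc) fine_gray(records, cc, covariates))
  res <- if (length(rows)) do.call(rbind, rows) else
    association_row("placeholder")[0, ]
  if (nrow(res)) res <- bonferroni(res, m = length(causes), alpha = alpha)
  attr(res, "skipped") <- skipped
  res
}

SENSITIVITY_MODES <- c("lag6m", "persistent", "no_prior_thyroid",
                       "no_prior_malignancy", "gender:F", "gender:M")

phecode_in_range <- function(codes, lo, hi) {
  v <- suppressWarnings(as.numeric(codes))
  !is.na(v) & v >= lo & v <= hi
}

#' Sensitivity-analysis input filters
#'
#' Returns filtered copies of the inputs for one of the supported modes:
#' \describe{
#'   \item{lag6m}{drop non-exposure diagnosis records dated within 6
#'     months (182.625 days) after the member's index date.}
#'   \item{persistent}{keep only cases with at least two exposure-code
#'     records spaced more than 3 months (91.3125 days) apart (requires
#'     `raw_events`, the mapped events before deduplication).}
#'   \item{no_prior_thyroid}{drop cases with another thyroid disorder
#'     diagnosed before the index date.}
#'   \item{no_prior_malignancy}{drop cases with any malignant neoplasm
#'     diagnosed before the index date.}
#'   \item{gender:F / gender:M}{restrict to one gender (requires
#'     `persons`).}
#' }
#'
#' @param events mapped first-occurrence events.
#' @param exposure exposure table.
#' @param mode one of `lag6m`, `persistent`, `no_prior_thyroid`,
#'   `no_prior_malignancy`, `gender:F`, `gender:M`.
#' @param raw_events mapped events before deduplication (persistent mode).
#' @param persons persons table (gender modes).
#' @param sets optional matched sets; when given, `lag6m` also filters
#'   controls' records by their set's index date, and case removals
#'   propagate to their sets.
#' @param thyroid_codes,malignancy_codes PheCode sets for the history
#'   exclusions (defaults: thyroid block 240-246.99 minus the exposure
#'   codes; malignancy block 145-199.99).
#' @return list(`events`, `exposure`, `sets`, `n_removed`).
#' @export
sensitivity_filters <- function(events, exposure, mode, raw_events = NULL,
                                persons = NULL, sets = NULL,
                                thyroid_codes = NULL,
                                malignancy_codes = NULL) {
  if (!mode %in% SENSITIVITY_MODES)
    stop(sprintf("unknown sensitivity mode '%s'", mode))
  n_removed <- 0L
  if (mode == "lag6m") {
    lag_days <- 6 * DAYS_PER_YEAR / 12
    idx <- exposure$index_date[match(events$person_id, exposure$person_id)]
    if (!is.null(sets)) {
      sidx <- sets$index_date[match(events$person_id, sets$person_id)]
      idx <- as.Date(ifelse(is.na(idx), sidx, idx), origin = "1970-01-01")
    }
    gap <- as.numeric(events$date - idx)
    drop <- !is.na(gap) & gap >= 0 & gap <= lag_days &
      !(events$code %in% EXPOSURE_PHECODES)
    n_removed <- sum(drop)
    events <- events[!drop, , drop = FALSE]
  } else if (mode == "persistent") {
    if (is.null(raw_events))
      stop("persistent mode requires `raw_events` (pre-deduplication)")
    exp_ev <- raw_events[raw_events$code %in% EXPOSURE_PHECODES, , drop = FALSE]
    span <- tapply(as.numeric(exp_ev$date), exp_ev$person_id,
                   function(d) diff(range(d)))
    keep_ids <- names(span)[span > 3 * DAYS_PER_YEAR / 12]
    drop <- !(exposure$person_id %in% keep_ids)
    n_removed <- sum(drop)
    exposure <- exposure[!drop, , drop = FALSE]
  } else if (mode %in% c("no_prior_thyroid", "no_prior_malignancy")) {
    codes <- if (mode == "no_prior_thyroid") {
      thyroid_codes %||% setdiff(
        unique(events$code)[phecode_in_range(unique(events$code), 240, 246.99)],
        EXPOSURE_PHECODES)
    } else {
      malignancy_codes %||%
        unique(events$code)[phecode_in_range(unique(events$code), 145, 199.99)]
    }
    ev <- events[events$code %in% codes, , drop = FALSE]
    idx <- exposure$index_date[match(ev$person_id, exposure$person_id)]
    offenders <- unique(ev$person_id[!is.na(idx) & ev$date < idx])
    drop <- exposure$person_id %in% offenders
    n_removed <- sum(drop)
    exposure <- exposure[!drop, , drop = FALSE]
  } else {                                   # gender strata
    if (is.null(persons)) stop("gender modes require `persons`")
    g <- if (mode == "gender:F") "female" else "male"
    keep_ids <- persons$person_id[persons$gender == g]
    drop <- !(exposure$person_id %in% keep_ids)
    n_removed <- sum(drop)
    exposure <- exposure[!drop, , drop = FALSE]
    events <- events[events$person_id %in% keep_ids, , drop = FALSE]
    if (!is.null(sets)) {
      sets <- sets[sets$person_id %in% keep_ids, , drop = FALSE]
      ok <- intersect(sets$set_id[sets$role == "case"],
                      sets$set_id[sets$role == "control"])
      sets <- sets[sets$set_id %in% ok, , drop = FALSE]
    }
  }
  if (!is.null(sets) && mode %in% c("persistent", "no_prior_thyroid",
                                    "no_prior_malignancy")) {
    case_ids <- sets$person_id[sets$role == "case"]
    keep_sets <- sets$set_id[sets$role == "case" &
                               sets$person_id %in% exposure$person_id]
    sets <- sets[sets$set_id %in% keep_sets, , drop = FALSE]
  }
  list(events = events, exposure = exposure, sets = sets,
       n_removed = n_removed)
}
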