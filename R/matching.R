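# Propensity-score estimation, 1:4 greedy nearest-neighbour matching on the
# logit of the score, post-match exclusions, and balance diagnostics.

#' Estimate exposure propensity scores
#'
#' Main-effects logistic regression of exposure on the eight baseline
#' covariates (year of birth, gender, BMI, deprivation index, education,
#' smoking, alcohol, physical activity). Persons with missing covariates
#' are excluded and counted.
#'
#' @param persons persons table.
#' @param exposure exposure table (`person_id`, `index_date`) marking who is
#'   a case; everyone else in `persons` is treated as unexposed.
#' @param covariates covariate column names entering the model.
#' @return data.frame (`person_id`, `score`) with attributes `model`
#'   (the glm fit) and `n_missing_covariates`.
#' @export
estimate_propensity <- function(persons, exposure,
                                covariates = MATCHING_COVARIATES) {
  dat <- persons[, c("person_id", covariates)]
  complete <- stats::complete.cases(dat[, covariates, drop = FALSE])
  n_miss <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  dat$exposed <- as.numeric(dat$person_id %in% exposure$person_id)
  for (cv in covariates)
    if (is.character(dat[[cv]])) dat[[cv]] <- factor(dat[[cv]])
  # degenerate design: every covariate constant -> constant score
  varying <- vapply(covariates, function(cv) length(unique(dat[[cv]])) > 1L,
                    logical(1))
  form <- if (any(varying))
    stats::reformulate(covariates[varying], response = "exposed")
  else stats::as.formula("exposed ~ 1")
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <- find_separating_covariate(dat, covariates[varying])
        stop(sprintf("complete separation in propensity model (covariate: %s)",
                     sep), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  out <- data.frame(person_id = dat$person_id,
                    score = as.numeric(stats::fitted(fit)),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  attr(out, "n_missing_covariates") <- n_miss
  out
}

# name a covariate that perfectly separates exposure, if one exists
find_separating_covariate <- function(dat, covariates) {
  for (cv in covariates) {
    x <- dat[[cv]]
    if (is.factor(x) || is.character(x)) {
      tab <- table(x, dat$exposed)
      if (all(apply(tab, 1, function(r) any(r == 0)))) return(cv)
    } else {
      if (max(x[dat$exposed == 1]) < min(x[dat$exposed == 0]) ||
          min(x[dat$exposed == 1]) > max(x[dat$exposed == 0])) return(cv)
    }
  }
  "unidentified"
}

#' Greedy 1:k nearest-neighbour matching without replacement
#'
#' Matches each case to up to `ratio` controls by nearest logit propensity
#' score, processing cases in a seeded random order, without replacement,
#' within a caliper of `caliper_sd` standard deviations of the logit score.
#' Cases with no in-caliper control are dropped and counted; sets with
#' fewer than `ratio` controls are retained.
#'
#' @param scores data.frame (`person_id`, `score`) from
#'   [estimate_propensity()].
#' @param exposure exposure table (`person_id`, `index_date`); defines the
#'   cases and each set's index date.
#' @param pool person_ids eligible as controls (must exclude ever-exposed
#'   persons).
#' @param ratio maximum controls per case.
#' @param caliper_sd caliper width in SDs of the logit score; `Inf`
#'   disables the caliper.
#' @param seed seed for the random case processing order.
#' @return data.frame (`set_id`, `person_id`, `role`, `index_date`) with
#'   attribute `n_unmatched_cases`.
#' @export
match_1to4 <- function(scores, exposure, pool, ratio = 4L,
                       caliper_sd = 0.2, seed = 1L) {
  if (length(pool) == 0L) stop("empty control pool")
  logit <- stats::qlogis(scores$score)
  names(logit) <- scores$person_id
  case_ids <- intersect(exposure$person_id, scores$person_id)
  pool_ids <- intersect(setdiff(pool, case_ids), scores$person_id)
  if (length(pool_ids) == 0L) stop("empty control pool")
  cal <- caliper_sd * stats::sd(logit[c(case_ids, pool_ids)])
  if (!is.finite(cal)) cal <- Inf

  set.seed(seed)
  case_ids <- sample(case_ids)

  pl <- logit[pool_ids]
  ord <- order(pl, pool_ids)          # person_id breaks exact score ties
  pl <- pl[ord]; pool_ids <- pool_ids[ord]
  avail <- rep(TRUE, length(pool_ids))
  idx_dates <- exposure$index_date[match(case_ids, exposure$person_id)]

  out <- vector("list", length(case_ids))
  n_unmatched <- 0L
  for (i in seq_along(case_ids)) {
    target <- logit[case_ids[i]]
    pos <- findInterval(target, pl)
    lo <- pos; hi <- pos + 1L
    picked <- integer(0)
    while (length(picked) < ratio) {
      while (lo >= 1L && !avail[lo]) lo <- lo - 1L
      while (hi <= length(pl) && !avail[hi]) hi <- hi + 1L
      dlo <- if (lo >= 1L) abs(pl[lo] - target) else Inf
      dhi <- if (hi <= length(pl)) abs(pl[hi] - target) else Inf
      if (dlo > cal) dlo <- Inf
      if (dhi > cal) dhi <- Inf
      if (!is.finite(dlo) && !is.finite(dhi)) break
      if (dlo <= dhi) { picked <- c(picked, lo); avail[lo] <- FALSE }
      else { picked <- c(picked, hi); avail[hi] <- FALSE }
    }
    if (length(picked) == 0L) { n_unmatched <- n_unmatched + 1L; next }
    out[[i]] <- data.frame(
      set_id = i,
      person_id = c(case_ids[i], pool_ids[picked]),
      role = c("case", rep("control", length(picked))),
      index_date = idx_dates[i],
      stringsAsFactors = FALSE)
  }
  sets <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sets))
    sets <- data.frame(set_id = integer(0), person_id = character(0),
                       role = character(0), index_date = as.Date(character(0)))
  # renumber sets consecutively for tidiness
  sets$set_id <- match(sets$set_id, unique(sets$set_id))
  rownames(sets) <- NULL
  attr(sets, "n_unmatched_cases") <- n_unmatched
  attr(sets, "caliper") <- cal
  sets
}

#' Apply post-match control exclusions
#'
#' Removes controls who died or were lost to follow-up before their set's
#' index date, and controls carrying a treatment/surgery flag (proxy for
#' under-reported exposure). Sets left with no controls are dropped
#' entirely. Per-rule counts are attached.
#'
#' @param sets matched sets from [match_1to4()].
#' @param persons persons table (for loss-to-follow-up dates).
#' @param deaths deaths table.
#' @param treatment_flags optional character vector of person_ids flagged
#'   as treated (e.g. antithyroid drugs, thyroid surgery).
#' @return filtered sets with attribute `exclusions` = c(dead_before_index,
#'   lost_before_index, treated, sets_dropped).
#' @export
apply_post_match_exclusions <- function(sets, persons, deaths,
                                        treatment_flags = character(0)) {
  is_ctrl <- sets$role == "control"
  dd <- deaths$death_date[match(sets$person_id, deaths$person_id)]
  ld <- persons$lost_to_followup_date[match(sets$person_id, persons$person_id)]
  dead_before <- is_ctrl & !is.na(dd) & dd < sets$index_date
  lost_before <- is_ctrl & !is.na(ld) & ld < sets$index_date & !dead_before
  treated <- is_ctrl & sets$person_id %in% treatment_flags &
    !dead_before & !lost_before
  drop <- dead_before | lost_before | treated
  out <- sets[!drop, , drop = FALSE]
  # drop sets with no remaining controls (their case leaves the analysis)
  keep_sets <- unique(out$set_id[out$role == "control"])
  n_sets_dropped <- length(setdiff(unique(out$set_id), keep_sets))
  out <- out[out$set_id %in% keep_sets, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(dead_before_index = sum(dead_before),
                               lost_before_index = sum(lost_before),
                               treated = sum(treated),
                               sets_dropped = n_sets_dropped)
  out
}

#' Standardized mean differences between cases and matched controls
#'
#' Continuous covariates: difference in means over the pooled standard
#' deviation; categorical covariates: per-level difference in proportions
#' over the pooled proportion SD. A zero pooled SD yields SMD 0 with
#' `degenerate = TRUE`.
#'
#' @param sets matched sets.
#' @param persons persons table.
#' @param covariates covariate names to tabulate.
#' @return data.frame (`covariate`, `level`, `smd`, `degenerate`).
#' @export
balance_table <- function(sets, persons, covariates = MATCHING_COVARIATES) {
  if (nrow(sets) == 0L) stop("balance_table requires at least one matched set")
  dat <- persons[match(sets$person_id, persons$person_id), covariates,
                 drop = FALSE]
  grp <- sets$role == "case"
  rows <- list()
  for (cv in covariates) {
    x <- dat[[cv]]
    if (is.numeric(x)) {
      s <- sqrt((stats::var(x[grp]) + stats::var(x[!grp])) / 2)
      smd <- if (is.na(s) || s == 0) 0 else
        (mean(x[grp]) - mean(x[!grp])) / s
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = NA_character_, smd = smd,
        degenerate = is.na(s) || s == 0, stringsAsFactors = FALSE)
    } else {
      for (lev in sort(unique(x))) {
        p1 <- mean(x[grp] == lev); p0 <- mean(x[!grp] == lev)
        s <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
        smd <- if (s == 0) 0 else (p1 - p0) / s
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, level = lev, smd = smd, degenerate = s == 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
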