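# Replicated simulation studies that validate the pipeline by recovering
# planted ground truth: CI coverage of a constant hazard ratio, landmark
# recovery of a short-term-only effect, family-wise error under a global
# null, and structural recovery of a planted disease chain. These are the
# package's calibration experiments; the test suite and the acceptance
# script both run them.

# matched analysis of one generated cohort, for a single phenotype
match_and_screen_one <- function(coh, phenotype, seed) {
  ev <- first_occurrences(coh$events)
  expo <- identify_exposure(ev, coh$deaths)
  scores <- estimate_propensity(coh$persons, expo)
  pool <- setdiff(coh$persons$person_id, expo$person_id)
  sets <- match_1to4(scores, expo, pool, seed = seed)
  sets <- apply_post_match_exclusions(sets, coh$persons, coh$deaths)
  list(events = ev, exposure = expo, sets = sets)
}

#' Coverage study for a planted constant hazard ratio
#'
#' For each replicate, generates a cohort with a single phenotype carrying
#' a constant exposure hazard ratio, runs the full matched analysis
#' (propensity model, 1:4 matching, post-match exclusions, survival
#' dataset, stratified Cox) and records whether the Wald 95% CI covers the
#' planted value.
#'
#' @param n_reps replicates.
#' @param n_persons cohort size per replicate.
#' @param hr planted hazard ratio.
#' @param seed base seed; replicate r uses seed + r.
#' @return list(`coverage`, `covered` logical vector, `estimates`).
#' @export
coverage_study <- function(n_reps = 200L, n_persons = 20000L, hr = 2,
                           seed = 1L) {
  covered <- logical(n_reps); est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- scenario_config(
      n_persons = n_persons, exposure_prevalence = 0.015,
      phenotypes = data.frame(phecode = "427.21", base_rate = 0.006,
                              log_hr = log(hr)),
      chains = data.frame(d1 = character(0), d2 = character(0),
                          log_hr = numeric(0)),
      death_causes = data.frame(cause = "other_causes", base_rate = 0.003,
                                log_hr = log(1.2)),
      death_links = data.frame(phecode = character(0),
                               cause = character(0), log_hr = numeric(0)),
      seed = seed + r)
    coh <- generate_cohort(cfg)
    ms <- match_and_screen_one(coh, "427.21", seed + r)
    res <- stratified_cox(
      build_survival_dataset(ms$sets, ms$events, coh$deaths, coh$persons,
                             "427.21"),
      "427.21")
    est[r] <- res$hr
    covered[r] <- isTRUE(res$ci_low <= hr && hr <= res$ci_high)
  }
  list(coverage = mean(covered), covered = covered, estimates = est)
}

#' Landmark recovery of a short-term-only effect
#'
#' Plants a hazard ratio of `hr1` in the first landmark window and 1
#' afterwards, and checks per replicate that the window-1 CI excludes 1
#' while the last-window CI covers 1.
#'
#' @param n_reps replicates.
#' @param n_persons cohort size per replicate.
#' @param hr1 planted first-window hazard ratio.
#' @param seed base seed.
#' @return list(`success_rate`, `w1_excludes_1`, `w4_covers_1`, `results`).
#' @export
landmark_recovery_study <- function(n_reps = 100L, n_persons = 20000L,
                                    hr1 = 3, seed = 1L) {
  w1 <- logical(n_reps); w4 <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- scenario_config(
      n_persons = n_persons, exposure_prevalence = 0.015,
      phenotypes = data.frame(phecode = "427.21", base_rate = 0.03,
                              log_hr = 0),
      window_effects = list(`427.21` = c(log(hr1), 0, 0, 0)),
      chains = data.frame(d1 = character(0), d2 = character(0),
                          log_hr = numeric(0)),
      death_causes = data.frame(cause = "other_causes", base_rate = 0.003,
                                log_hr = log(1.2)),
      death_links = data.frame(phecode = character(0),
                               cause = character(0), log_hr = numeric(0)),
      origin_date = as.Date("1995-01-01"),
      enrol_window = as.Date(c("1997-01-01", "2008-12-31")),
      seed = seed + 20000L + r)
    coh <- generate_cohort(cfg)
    ms <- match_and_screen_one(coh, "427.21", seed + r)
    lm <- landmark_hrs(ms$sets, ms$events, coh$deaths, coh$persons,
                       "427.21")
    w1[r] <- isTRUE(lm$estimable[1] && lm$ci_low[1] > 1)
    w4[r] <- isTRUE(lm$estimable[4] && lm$ci_low[4] <= 1 &&
                      lm$ci_high[4] >= 1)
  }
  list(success_rate = mean(w1 & w4), w1_excludes_1 = w1, w4_covers_1 = w4)
}

#' Family-wise error under a global null
#'
#' Generates cohorts in which no phenotype carries any exposure effect,
#' screens `m` candidate phenotypes with the matched-stratified Cox model
#' and Bonferroni control, and reports the fraction of replicates with at
#' least one (false) discovery.
#'
#' @param n_reps replicates.
#' @param m number of null candidate phenotypes.
#' @param n_persons cohort size per replicate.
#' @param seed base seed.
#' @return list(`fwer`, `any_discovery` logical vector).
#' @export
fwer_study <- function(n_reps = 500L, m = 100L, n_persons = 1200L,
                       seed = 1L) {
  codes <- sprintf("N%03d", seq_len(m))
  phe <- data.frame(phecode = codes, base_rate = 0.02, log_hr = 0)
  any_disc <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- scenario_config(
      n_persons = n_persons, exposure_prevalence = 0.10,
      phenotypes = phe,
      chains = data.frame(d1 = character(0), d2 = character(0),
                          log_hr = numeric(0)),
      death_causes = data.frame(cause = "other_causes", base_rate = 0.003,
                                log_hr = 0),
      death_links = data.frame(phecode = character(0),
                               cause = character(0), log_hr = numeric(0)),
      seed = seed + 40000L + r)
    coh <- generate_cohort(cfg)
    ms <- match_and_screen_one(coh, NULL, seed + r)
    cand <- select_candidates(ms$events, ms$exposure, min_cases = 20L)
    res <- run_phewas_screen(ms$sets, ms$events, coh$deaths, coh$persons,
                             cand)
    any_disc[r] <- any(res$significant, na.rm = TRUE)
  }
  list(fwer = mean(any_disc), any_discovery = any_disc)
}

#' Structural recovery of a planted disease chain
#'
#' Plants the chain D1 -> D2 -> D3 (hazard multipliers about 3, plus a
#' weaker direct D1 -> D3 path) in an all-exposed cohort, runs the
#' four-step trajectory construction, and scores a replicate as a success
#' when the emitted edge set is exactly the three planted ordered pairs,
#' the mediation-validated triple is (D1, D2, D3), and no reverse edge
#' appears.
#'
#' @param n_reps replicates.
#' @param n_persons exposed persons per replicate.
#' @param n_boot mediation bootstrap resamples.
#' @param seed base seed.
#' @return list(`success_rate`, `success` logical vector, `details`).
#' @export
chain_recovery_study <- function(n_reps = 20L, n_persons = 20000L,
                                 n_boot = 199L, seed = 1L) {
  d1 <- "250.2"; d2 <- "585.3"; d3 <- "280.1"
  planted <- c(paste(d1, d2), paste(d2, d3), paste(d1, d3))
  success <- logical(n_reps)
  details <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- scenario_config(
      n_persons = n_persons, exposure_prevalence = 1,
      phenotypes = data.frame(
        phecode = c(d1, d2, d3),
        base_rate = c(0.010, 0.006, 0.004),
        log_hr = 0),
      chains = data.frame(d1 = c(d1, d2, d1), d2 = c(d2, d3, d3),
                          log_hr = log(c(3, 3, 1.5))),
      death_causes = data.frame(cause = "other_causes", base_rate = 0.003,
                                log_hr = 0),
      death_links = data.frame(phecode = character(0),
                               cause = character(0), log_hr = numeric(0)),
      enrol_window = as.Date(c("1997-01-01", "2005-12-31")),
      seed = seed + 60000L + r)
    coh <- generate_cohort(cfg)
    ev <- first_occurrences(coh$events)
    expo <- identify_exposure(ev, coh$deaths)
    traj <- trajectory_dataset(ev, expo, coh$persons, c(d1, d2, d3))
    pairs <- pair_odds_ratio(
      binomial_direction_test(enumerate_pairs(traj$dates)),
      traj$dates, traj$covars)
    triples <- run_mediation(pairs, traj$dates, traj$covars,
                             n_boot = n_boot, seed = seed + r)
    g <- assemble_graph(pairs, triples)
    got <- paste(g$edges$d1, g$edges$d2)
    ok_edges <- setequal(got, planted)
    ok_triple <- nrow(g$triples) == 1L &&
      all(g$triples[1, c("d1", "d2", "d3")] == c(d1, d2, d3))
    # a cycle would mean some emitted edge also appears reversed
    ok_no_reverse <- !any(paste(g$edges$d2, g$edges$d1) %in% got)
    success[r] <- ok_edges && ok_triple && ok_no_reverse
    details[[r]] <- list(edges = got, n_triples = nrow(g$triples))
  }
  list(success_rate = mean(success), success = success, details = details)
}
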