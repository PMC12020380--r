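# Candidate selection, survival-dataset construction, stratified Cox,
# Fine-Gray, Bonferroni, and the sensitivity filters.

test_that("candidate selection enforces the 20-case threshold exactly", {
  mk <- function(n_with) {
    ids <- sprintf("C%03d", 1:25)
    ev <- make_events(ids[seq_len(n_with)], "427.21",
                      rep("2005-05-05", n_with))
    expo <- data.frame(person_id = ids,
                       index_date = as.Date("2003-01-01"))
    select_candidates(ev, expo)
  }
  expect_equal(mk(19), character(0))
  expect_equal(mk(20), "427.21")
  # no exposed persons at all
  expect_equal(select_candidates(
    make_events("X", "427.21", "2005-05-05"),
    data.frame(person_id = character(0),
               index_date = as.Date(character(0)))), character(0))
})

test_that("candidate selection matches brute-force counting on a random fixture", {
  set.seed(6)
  ids <- sprintf("P%03d", 1:500)
  codes <- c("244", "250.2", "427.21", "530.11", "585.3", "242")
  ev <- make_events(sample(ids, 3000, TRUE), sample(codes, 3000, TRUE),
                    as.Date("2000-01-01") + sample.int(6000, 3000, TRUE))
  ev <- first_occurrences(ev)
  expo <- data.frame(person_id = sample(ids, 120),
                     index_date = as.Date("2003-01-01"))
  got <- select_candidates(ev, expo, min_cases = 30L)
  counts <- vapply(setdiff(codes, "242"), function(cc)
    length(unique(ev$person_id[ev$code == cc &
                                 ev$person_id %in% expo$person_id])),
    numeric(1))
  expect_setequal(got, names(counts)[counts >= 30])
})

test_that("survival records apply prevalence, censoring and the tie rule", {
  sets <- make_sets(c("A", "B"), list(c("K1", "K2"), "K3"),
                    c("2012-10-31", "2010-01-01"))
  pers <- make_persons(c("A", "B", "K1", "K2", "K3"), region = "england")
  # K1 prevalent (onset before index); A has onset on death day
  ev <- make_events(c("K1", "A"), c("428.2", "428.2"),
                    c("2010-06-01", "2015-01-01"))
  deaths <- make_deaths("A", "2015-01-01")
  rec <- build_survival_dataset(sets, ev, deaths, pers, "428.2")
  expect_equal(attr(rec, "exclusions")[["prevalent"]], 1L)
  expect_false("K1" %in% rec$person_id)
  # onset wins the same-day tie with death
  expect_equal(rec$event[rec$person_id == "A"], 1)
  # English member with no events: 10 calendar years to 2022-10-31,
  # i.e. 3652 days under the days/365.25 convention
  expect_equal(rec$time[rec$person_id == "K2"], 3652 / 365.25)
  expect_equal(rec$time[rec$person_id == "K2"], 10, tolerance = 1e-3)
  expect_equal(rec$event[rec$person_id == "K2"], 0)
})

test_that("symmetric event patterns give a hazard ratio of one", {
  rec <- data.frame(person_id = sprintf("P%d", 1:8),
                    set_id = rep(1:2, each = 4),
                    exposed = rep(c(1, 1, 0, 0), 2),
                    time = rep(c(1, 3, 1, 3), 2),
                    event = rep(c(1, 0, 1, 0), 2))
  res <- stratified_cox(rec, "x")
  expect_equal(res$hr, 1, tolerance = 1e-8)
})

test_that("stratified Cox matches the grid-search partial-likelihood oracle", {
  rec <- cox_fixture()
  res <- stratified_cox(rec, "fixture")
  expect_true(res$estimable)
  beta_oracle <- oracle_strat_cox_beta(rec)
  expect_equal(attr(res, "beta"), beta_oracle, tolerance = 1e-6)
})

test_that("stratified Cox is invariant to stratum relabeling and row order", {
  rec <- cox_fixture()
  base <- stratified_cox(rec, "x")
  rl <- rec
  rl$set_id <- ifelse(rec$set_id == 1, 99L, 42L)
  perm <- rl[c(4, 2, 6, 1, 3, 5), ]
  out <- stratified_cox(perm, "x")
  expect_equal(out$hr, base$hr, tolerance = 1e-10)
  expect_equal(out$p, base$p, tolerance = 1e-10)
})

test_that("uninformative strata yield a flagged, non-estimable result", {
  rec <- data.frame(person_id = c("A", "B"), set_id = c(1, 1),
                    exposed = c(1, 0), time = c(5, 5), event = c(0, 0))
  res <- stratified_cox(rec, "x")
  expect_false(res$estimable)
  expect_true(is.na(res$hr))
})

test_that("Fine-Gray with a single event type reduces to the cause-specific Cox", {
  set.seed(12)
  n <- 400
  pers <- make_persons(sprintf("P%03d", 1:n),
                       gender = sample(c("female", "male"), n, TRUE),
                       bmi = rnorm(n, 28, 4))
  exposed <- rep(c(1, 0), n / 2)
  time <- rexp(n, 0.1 * exp(0.5 * exposed))
  cens <- runif(n, 0, 15)
  rec <- data.frame(person_id = pers$person_id, set_id = seq_len(n),
                    exposed = exposed,
                    time = pmin(time, cens),
                    event_type = ifelse(time <= cens, "cardiovascular",
                                        "censored"),
                    birth_year = pers$birth_year, gender = pers$gender,
                    bmi = pers$bmi, townsend = pers$townsend,
                    education = pers$education, smoking = pers$smoking,
                    alcohol = pers$alcohol, activity = pers$activity,
                    stringsAsFactors = FALSE)
  fg <- fine_gray(rec, "cardiovascular", covariates = c("gender", "bmi"))
  cs <- survival::coxph(survival::Surv(time, event_type == "cardiovascular") ~
                          exposed + factor(gender) + bmi, data = rec,
                        ties = "efron")
  expect_equal(attr(fg, "beta"), unname(coef(cs)["exposed"]),
               tolerance = 1e-6)
})

test_that("Fine-Gray agrees with an independent subdistribution implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(13)
  n <- 500
  exposed <- rep(c(1, 0), n / 2)
  t1 <- rexp(n, 0.08 * exp(0.6 * exposed))   # cause of interest
  t2 <- rexp(n, 0.05)                        # competing cause
  cens <- runif(n, 2, 18)
  time <- pmin(t1, t2, cens)
  type <- ifelse(t1 <= pmin(t2, cens), "cardiovascular",
                 ifelse(t2 <= cens, "other_causes", "censored"))
  rec <- make_persons(sprintf("P%03d", 1:n))
  rec <- data.frame(person_id = rec$person_id, set_id = seq_len(n),
                    exposed = exposed, time = time, event_type = type,
                    bmi = rnorm(n, 28, 4), stringsAsFactors = FALSE)
  fg <- fine_gray(rec, "cardiovascular", covariates = "bmi")
  fstatus <- ifelse(type == "cardiovascular", 1,
                    ifelse(type == "censored", 0, 2))
  crr_fit <- cmprsk::crr(time, fstatus, cbind(exposed, rec$bmi))
  expect_equal(attr(fg, "beta"), unname(crr_fit$coef[1]), tolerance = 0.02)
})

test_that("zero exposed deaths from a cause is flagged non-estimable", {
  rec <- data.frame(person_id = c("A", "B"), set_id = c(1, 1),
                    exposed = c(1, 0), time = c(2, 3),
                    event_type = c("censored", "cardiovascular"),
                    bmi = c(28, 27), stringsAsFactors = FALSE)
  res <- fine_gray(rec, "cardiovascular", covariates = "bmi")
  expect_false(res$estimable)
})

test_that("a death screen with no qualifying cause returns an empty table", {
  rec <- data.frame(person_id = c("A", "B"), set_id = c(1, 1),
                    exposed = c(1, 0), time = c(2, 3),
                    event_type = c("censored", "cardiovascular"),
                    bmi = c(28, 27), stringsAsFactors = FALSE)
  res <- screen_death_causes(rec, min_cases = 20L, covariates = "bmi")
  expect_equal(nrow(res), 0L)
  expect_true(all(c("phenotype", "hr", "p") %in% names(res)))
})

test_that("Bonferroni adjustment multiplies, caps and gates at 0.05", {
  res <- data.frame(phenotype = c("a", "b"), p = c(0.0001, 0.5))
  out <- bonferroni(res, m = 412)
  expect_equal(out$p_adjusted, c(0.0412, 1))
  expect_equal(out$significant, c(TRUE, FALSE))
  expect_error(bonferroni(res, m = 0), "positive")
})

test_that("the six-month lag filter drops only the early post-index records", {
  expo <- data.frame(person_id = "A", index_date = as.Date("2010-01-01"))
  ev <- make_events(c("A", "A", "A"), c("428.2", "530.11", "244"),
                    as.Date("2010-01-01") + c(120, 200, -30))
  out <- sensitivity_filters(ev, expo, "lag6m")
  expect_false("428.2" %in% out$events$code)   # 120 days: removed
  expect_true("530.11" %in% out$events$code)   # 200 days: kept
  expect_true("244" %in% out$events$code)      # pre-index: kept
  expect_equal(out$n_removed, 1L)
})

test_that("the persistence filter needs two exposure records over 3 months apart", {
  expo <- data.frame(person_id = c("A", "B"),
                     index_date = as.Date(c("2001-01-01", "2001-01-01")))
  raw <- make_events(c("A", "A", "B", "B"), rep("242", 4),
                     c("2001-01-01", "2001-03-15",   # 73 days: excluded
                       "2001-01-01", "2001-06-01"))  # 151 days: kept
  out <- sensitivity_filters(first_occurrences(raw), expo, "persistent",
                             raw_events = raw)
  expect_equal(out$exposure$person_id, "B")
  expect_error(sensitivity_filters(first_occurrences(raw), expo,
                                   "persistent"), "raw_events")
})

test_that("history filters drop cases with prior thyroid or malignant disease", {
  expo <- data.frame(person_id = c("A", "B"),
                     index_date = as.Date(c("2005-01-01", "2005-01-01")))
  ev <- make_events(c("A", "B"), c("245", "174.1"),
                    c("2004-06-01", "2004-06-01"))
  thy <- sensitivity_filters(ev, expo, "no_prior_thyroid")
  expect_equal(thy$exposure$person_id, "B")
  mal <- sensitivity_filters(ev, expo, "no_prior_malignancy")
  expect_equal(mal$exposure$person_id, "A")
})

test_that("gender restriction to an all-female cohort is the identity", {
  pers <- make_persons(c("A", "B"), gender = "female")
  expo <- data.frame(person_id = c("A", "B"),
                     index_date = as.Date("2005-01-01"))
  ev <- make_events(c("A", "B"), c("244", "428.2"),
                    c("2006-01-01", "2007-01-01"))
  out <- sensitivity_filters(ev, expo, "gender:F", persons = pers)
  expect_equal(out$exposure, expo)
  expect_equal(out$events, ev)
  expect_error(sensitivity_filters(ev, expo, "bogus"), "unknown sensitivity")
})
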