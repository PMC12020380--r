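# Shared fixture builders: all test data is constructed in code.

make_persons <- function(ids, gender = "female", region = "england",
                         birth_year = 1950, bmi = 28, townsend = -1,
                         education = "degree", smoking = "never",
                         alcohol = "occasional", activity = "moderate",
                         lost = as.Date(NA)) {
  n <- length(ids)
  data.frame(person_id = ids,
             birth_year = rep_len(birth_year, n),
             gender = rep_len(gender, n),
             bmi = rep_len(bmi, n), townsend = rep_len(townsend, n),
             education = rep_len(education, n),
             smoking = rep_len(smoking, n),
             alcohol = rep_len(alcohol, n),
             activity = rep_len(activity, n),
             region = rep_len(region, n),
             lost_to_followup_date = rep(lost, length.out = n),
             stringsAsFactors = FALSE)
}

make_events <- function(person_id, code, date, code_system = "phecode",
                        source = "inpatient") {
  n <- length(person_id)
  data.frame(person_id = person_id, code = code,
             code_system = rep_len(code_system, n),
             date = as.Date(date), source = rep_len(source, n),
             stringsAsFactors = FALSE)
}

make_deaths <- function(person_id, death_date,
                        cause = "cardiovascular") {
  data.frame(person_id = person_id, death_date = as.Date(death_date),
             cause_category = rep_len(cause, length(person_id)),
             stringsAsFactors = FALSE)
}

# two-stratum six-person survival fixture with one tied event time,
# exercising the Efron correction
cox_fixture <- function() {
  data.frame(
    person_id = paste0("P", 1:6),
    set_id = c(1, 1, 1, 2, 2, 2),
    exposed = c(1, 0, 0, 1, 0, 0),
    time = c(1, 2, 3, 2, 2, 4),
    event = c(1, 1, 0, 1, 1, 0))
}

# matched sets built directly (one case + controls sharing an index date)
make_sets <- function(cases, controls_per_case, index_dates) {
  rows <- list()
  for (i in seq_along(cases)) {
    ctr <- controls_per_case[[i]]
    rows[[i]] <- data.frame(
      set_id = i,
      person_id = c(cases[i], ctr),
      role = c("case", rep("control", length(ctr))),
      index_date = as.Date(index_dates[i]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# small end-to-end synthetic cohort reused by pipeline tests
demo_tables <- function(seed = 11, n = 6000, prevalence = 0.05) {
  cfg <- scenario_config(n_persons = n, exposure_prevalence = prevalence,
                         seed = seed)
  coh <- generate_cohort(cfg)
  list(cfg = cfg, cohort = coh,
       tables = list(persons = coh$persons, events = coh$events,
                     deaths = coh$deaths, map = load_demo_map(),
                     selfreport_map = load_demo_selfreport_map()))
}
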