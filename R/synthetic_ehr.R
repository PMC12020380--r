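# Synthetic EHR generator: matched-cohort-shaped longitudinal diagnosis
# records with known ground truth (planted exposure hazard ratios, optional
# landmark-window effects, sequential disease chains, cause-specific death
# effects), so every downstream stage can be validated by recovery.
#
# Simulation clock: years from `origin_date`. Each phenotype and each death
# cause has an exponential (or piecewise-exponential) latent time whose
# hazard is multiplied by planted effects from the exposure onset and from
# upstream-disease onsets; observed records are the latent events truncated
# at death / loss to follow-up / region-specific administrative censoring.

default_phenotypes <- function() {
  data.frame(
    phecode   = c("244", "427.21", "411.4", "428.2", "250.2", "530.11",
                  "743.1", "585.3", "280.1"),
    base_rate = c(0.003, 0.004, 0.005, 0.003, 0.004, 0.005,
                  0.003, 0.002, 0.002),
    log_hr    = log(c(6, 1.9, 1.5, 1.8, 1.6, 1.4, 1.5, 1.4, 1.3)),
    stringsAsFactors = FALSE)
}

default_chains <- function() {
  data.frame(d1     = c("250.2", "585.3", "250.2"),
             d2     = c("585.3", "280.1", "280.1"),
             log_hr = log(c(3, 3, 1.5)),
             stringsAsFactors = FALSE)
}

default_death_causes <- function() {
  data.frame(
    cause     = c("cardiovascular", "malignant_neoplasms", "respiratory",
                  "other_causes"),
    base_rate = c(0.003, 0.004, 0.0015, 0.004),
    log_hr    = log(c(1.8, 1.5, 1.76, 1.2)),
    stringsAsFactors = FALSE)
}

#' Build a synthetic-cohort scenario configuration
#'
#' Defaults describe a registry-linked cohort dominated by women (77%
#' female) with a rare exposure (1.5% prevalence) assigned by a logistic
#' propensity model, exposure onsets spread uniformly over 1997--2015, and
#' region-specific administrative censoring in late 2022. Phenotype and
#' death-cause hazards are events/person-year; planted exposure effects are
#' log hazard ratios, optionally piecewise over the landmark windows.
#'
#' @param n_persons cohort size.
#' @param exposure_prevalence target marginal probability of exposure
#'   (1 means an all-exposed cohort, used for trajectory-only scenarios).
#' @param female_frac proportion female.
#' @param birth_year_range inclusive integer range to sample birth years.
#' @param bmi_mean,bmi_sd,townsend_mean,townsend_sd covariate moments.
#' @param education_probs,smoking_probs,alcohol_probs,activity_probs,region_probs
#'   category probabilities (must each sum to 1), in the fixed level orders.
#' @param propensity named log-odds coefficients of exposure on covariates;
#'   allowed names: `male`, `birth_year`, `bmi`, `townsend` and
#'   `<covariate>_<level>` for categorical levels (e.g. `smoking_current`).
#'   The intercept is calibrated internally to `exposure_prevalence`.
#' @param phenotypes data.frame(`phecode`, `base_rate`, `log_hr`).
#' @param window_effects named list: phecode -> numeric vector of per-window
#'   log hazard ratios (one per landmark window), overriding `log_hr`.
#' @param chains data.frame(`d1`, `d2`, `log_hr`): onset of `d1` multiplies
#'   the hazard of `d2` by `exp(log_hr)` from that time on.
#' @param death_causes data.frame(`cause`, `base_rate`, `log_hr`).
#' @param death_links data.frame(`phecode`, `cause`, `log_hr`): phenotype
#'   onset effects on cause-specific death hazards.
#' @param windows landmark window breakpoints in years (first 0, last Inf).
#' @param origin_date simulation time zero (calendar).
#' @param enrol_window calendar window over which exposure onsets fall.
#' @param censor_dates named (by region) administrative censoring dates.
#' @param loss_rate exponential loss-to-follow-up rate (per person-year).
#' @param emit_icd10 if TRUE, diagnosis events are written with ICD-10 codes
#'   taken from the bundled demo map (exercising the mapping stage);
#'   otherwise events carry PheCodes directly.
#' @param seed integer seed governing all sampling.
#' @return object of class `phetraj_scenario`.
#' @export
scenario_config <- function(n_persons = 20000,
                            exposure_prevalence = 0.015,
                            female_frac = 0.77,
                            birth_year_range = c(1937, 1970),
                            bmi_mean = 28.1, bmi_sd = 5.4,
                            townsend_mean = -1.0, townsend_sd = 3.2,
                            education_probs = c(0.280, 0.104, 0.214, 0.180, 0.222),
                            smoking_probs = c(0.125, 0.349, 0.526),
                            alcohol_probs = c(0.319, 0.565, 0.116),
                            activity_probs = c(0.364, 0.333, 0.303),
                            region_probs = c(0.89, 0.07, 0.04),
                            propensity = c(male = -1.0, birth_year = 0.005,
                                           bmi = 0.02, townsend = 0.03,
                                           smoking_current = 0.2),
                            phenotypes = default_phenotypes(),
                            window_effects = list(),
                            chains = default_chains(),
                            death_causes = default_death_causes(),
                            death_links = data.frame(phecode = "428.2",
                                                     cause = "cardiovascular",
                                                     log_hr = log(2.5)),
                            windows = LANDMARK_BREAKS,
                            origin_date = as.Date("1990-01-01"),
                            enrol_window = as.Date(c("1997-01-01", "2015-12-31")),
                            censor_dates = DEFAULT_CENSOR_DATES,
                            loss_rate = 0.005,
                            emit_icd10 = FALSE,
                            seed = 1L) {
  cfg <- list(n_persons = as.integer(n_persons),
              exposure_prevalence = exposure_prevalence,
              female_frac = female_frac,
              birth_year_range = birth_year_range,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              townsend_mean = townsend_mean, townsend_sd = townsend_sd,
              education_probs = education_probs,
              smoking_probs = smoking_probs,
              alcohol_probs = alcohol_probs,
              activity_probs = activity_probs,
              region_probs = region_probs,
              propensity = propensity,
              phenotypes = phenotypes,
              window_effects = window_effects,
              chains = chains,
              death_causes = death_causes,
              death_links = death_links,
              windows = windows,
              origin_date = as.Date(origin_date),
              enrol_window = as.Date(enrol_window),
              censor_dates = censor_dates,
              loss_rate = loss_rate,
              emit_icd10 = isTRUE(emit_icd10),
              seed = as.integer(seed))
  class(cfg) <- "phetraj_scenario"
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks probability vectors, hazard positivity, window structure and
#' acyclicity of the planted chain graph; errors before any sampling.
#'
#' @param cfg a `phetraj_scenario`.
#' @return `cfg`, invisibly.
#' @export
validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "phetraj_scenario"))
  if (cfg$n_persons < 1L) stop("invalid scenario: n_persons must be >= 1")
  if (cfg$exposure_prevalence < 0 || cfg$exposure_prevalence > 1)
    stop("invalid scenario: exposure_prevalence must lie in [0, 1]")
  probs <- list(education_probs = cfg$education_probs,
                smoking_probs = cfg$smoking_probs,
                alcohol_probs = cfg$alcohol_probs,
                activity_probs = cfg$activity_probs,
                region_probs = cfg$region_probs)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("invalid scenario: %s must be non-negative and sum to 1", nm))
  }
  if (any(cfg$phenotypes$base_rate <= 0))
    stop("invalid scenario: phenotype base rates must be > 0")
  if (nrow(cfg$death_causes) && any(cfg$death_causes$base_rate <= 0))
    stop("invalid scenario: death-cause base rates must be > 0")
  w <- cfg$windows
  if (w[1] != 0 || !is.infinite(w[length(w)]) || is.unsorted(w, strictly = TRUE))
    stop("invalid scenario: windows must partition [0, Inf)")
  for (nm in names(cfg$window_effects)) {
    if (!(nm %in% cfg$phenotypes$phecode))
      stop(sprintf("invalid scenario: window_effects for unknown phenotype %s", nm))
    if (length(cfg$window_effects[[nm]]) != length(w) - 1L)
      stop("invalid scenario: window_effects must give one value per window")
  }
  if (nrow(cfg$chains)) {
    unknown <- setdiff(c(cfg$chains$d1, cfg$chains$d2), cfg$phenotypes$phecode)
    if (length(unknown))
      stop(sprintf("invalid scenario: chain phenotype(s) not defined: %s",
                   paste(unknown, collapse = ", ")))
    topo_order_phenotypes(cfg$phenotypes$phecode, cfg$chains)  # errors on cycle
  }
  if (cfg$loss_rate < 0) stop("invalid scenario: loss_rate must be >= 0")
  invisible(cfg)
}

# Kahn topological sort of phenotypes under the chain DAG (upstream first)
topo_order_phenotypes <- function(phecodes, chains) {
  indeg <- stats::setNames(integer(length(phecodes)), phecodes)
  for (d2 in chains$d2) indeg[d2] <- indeg[d2] + 1L
  out <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    kids <- chains$d2[chains$d1 == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(out) != length(phecodes))
    stop("invalid scenario: planted chains contain a cycle")
  out
}

# sample the eight baseline covariates from rows 1..9 of the uniform block
sample_covariates <- function(cfg, U) {
  n <- ncol(U)
  cut_cat <- function(u, probs, levels)
    levels[findInterval(u, cumsum(probs), rightmost.closed = TRUE) + 1L]
  data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    birth_year = cfg$birth_year_range[1] +
      as.integer(floor(U[2, ] * (diff(cfg$birth_year_range) + 1L))),
    gender = ifelse(U[1, ] < cfg$female_frac, "female", "male"),
    bmi = cfg$bmi_mean + cfg$bmi_sd * stats::qnorm(U[3, ]),
    townsend = cfg$townsend_mean + cfg$townsend_sd * stats::qnorm(U[4, ]),
    education = cut_cat(U[5, ], cfg$education_probs, EDUCATION_LEVELS),
    smoking = cut_cat(U[6, ], cfg$smoking_probs, SMOKING_LEVELS),
    alcohol = cut_cat(U[7, ], cfg$alcohol_probs, ALCOHOL_LEVELS),
    activity = cut_cat(U[8, ], cfg$activity_probs, ACTIVITY_LEVELS),
    region = cut_cat(U[9, ], cfg$region_probs, REGION_LEVELS),
    stringsAsFactors = FALSE)
}

# linear predictor of the exposure propensity model (no intercept); numeric
# covariates are centred for stability only (slopes are unaffected)
propensity_linpred <- function(pers, coefs) {
  lp <- numeric(nrow(pers))
  for (nm in names(coefs)) {
    b <- coefs[[nm]]
    term <- switch(nm,
      male = as.numeric(pers$gender == "male"),
      birth_year = pers$birth_year - 1950,
      bmi = pers$bmi - 28,
      townsend = pers$townsend + 1,
      {
        parts <- strsplit(nm, "_")[[1]]
        covar <- parts[1]; level <- paste(parts[-1], collapse = "_")
        if (!covar %in% c("education", "smoking", "alcohol", "activity"))
          stop(sprintf("unknown propensity coefficient '%s'", nm))
        as.numeric(pers[[covar]] == level)
      })
    lp <- lp + b * term
  }
  lp
}

# Calibrate the propensity intercept so the implied marginal exposure
# probability equals the target prevalence. Uses a fixed-seed Monte-Carlo
# draw over the covariate distribution (independent of n_persons and of the
# scenario seed) so per-person reproducibility is unaffected.
calibrate_propensity_intercept <- function(cfg, n_mc = 40000L) {
  if (cfg$exposure_prevalence <= 0) return(-Inf)
  if (cfg$exposure_prevalence >= 1) return(Inf)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(360360L)
  U <- matrix(stats::runif(9L * n_mc), nrow = 9L)
  lp <- propensity_linpred(sample_covariates(cfg, U), cfg$propensity)
  f <- function(a) mean(stats::plogis(a + lp)) - cfg$exposure_prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# latent event time for one phenotype/cause across all persons
latent_times <- function(u, base, exp_onset, exp_mults, upstream_times,
                         upstream_mults, windows = NULL) {
  n <- length(u)
  cps <- NULL; mults <- NULL
  if (!is.null(exp_onset)) {
    if (!is.null(windows)) {
      # one changepoint per window start, multiplier = increment over the
      # previous window so the cumulative product gives exp(beta_w)
      k <- length(exp_mults)
      starts <- windows[seq_len(k)]
      inc <- exp_mults / c(1, exp_mults[-k])
      cps <- outer(exp_onset, starts, `+`)
      mults <- matrix(inc, n, k, byrow = TRUE)
    } else {
      cps <- matrix(exp_onset, ncol = 1)
      mults <- matrix(exp_mults, n, 1)
    }
  }
  if (length(upstream_times)) {
    up <- do.call(cbind, upstream_times)
    um <- matrix(rep(upstream_mults, each = n), nrow = n)
    cps <- if (is.null(cps)) up else cbind(cps, up)
    mults <- if (is.null(mults)) um else cbind(mults, um)
  }
  rpexp_changepoints(u, rep(base, n), cps, mults)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates, assigns exposure by the scenario's logistic propensity
#' model, samples first-occurrence phenotype events from (piecewise)
#' exponential hazards carrying the planted exposure/chain effects, samples
#' cause-coded deaths from competing cause-specific hazards, and truncates
#' all records at death, loss to follow-up or the region's administrative
#' censoring date. Fully reproducible from `cfg$seed`; a person's draws
#' depend only on the seed and their position, so enlarging the cohort
#' never perturbs existing persons.
#'
#' @param cfg a `phetraj_scenario`.
#' @return list with `persons`, `events`, `deaths` (pipeline-ready
#'   data.frames), `exposure_assigned` (person_id, exposed flag, latent
#'   onset date) and `ground_truth` (planted parameters; regenerable from
#'   `cfg` alone).
#' @export
generate_cohort <- function(cfg) {
  validate_scenario(cfg)
  alpha <- calibrate_propensity_intercept(cfg)
  phe <- cfg$phenotypes
  P <- nrow(phe); C <- nrow(cfg$death_causes)
  K <- 12L + P + C
  n <- cfg$n_persons

  set.seed(cfg$seed)
  U <- matrix(stats::runif(as.double(K) * n), nrow = K)

  pers <- sample_covariates(cfg, U)
  lp <- propensity_linpred(pers, cfg$propensity)
  p_exp <- if (is.infinite(alpha)) rep(as.numeric(alpha > 0), n)
           else stats::plogis(alpha + lp)
  exposed <- U[10, ] < p_exp

  origin <- cfg$origin_date
  enrol_t <- years_between(cfg$enrol_window, origin)
  onset_t <- ifelse(exposed,
                    enrol_t[1] + U[11, ] * diff(enrol_t), Inf)
  censor_t <- years_between(
    as.Date(cfg$censor_dates[pers$region]), origin)
  loss_t <- if (cfg$loss_rate > 0) -log(U[12, ]) / cfg$loss_rate else
    rep(Inf, n)

  # phenotype latent onset times, upstream diseases first
  topo <- topo_order_phenotypes(phe$phecode, cfg$chains)
  T_phe <- matrix(NA_real_, n, P, dimnames = list(NULL, phe$phecode))
  exp_onset_vec <- ifelse(exposed, onset_t, Inf)
  for (code in topo) {
    j <- match(code, phe$phecode)
    weff <- cfg$window_effects[[code]]
    if (!is.null(weff)) {
      exp_mults <- exp(weff); windows <- cfg$windows
    } else {
      exp_mults <- exp(phe$log_hr[j]); windows <- NULL
    }
    up <- cfg$chains[cfg$chains$d2 == code, , drop = FALSE]
    up_times <- lapply(up$d1, function(d) T_phe[, d])
    T_phe[, j] <- latent_times(U[12L + j, ], phe$base_rate[j],
                               exp_onset_vec, exp_mults,
                               up_times, exp(up$log_hr), windows)
  }

  # competing cause-specific death times
  if (C > 0L) {
    T_cause <- matrix(Inf, n, C, dimnames = list(NULL, cfg$death_causes$cause))
    for (k in seq_len(C)) {
      cause <- cfg$death_causes$cause[k]
      links <- cfg$death_links[cfg$death_links$cause == cause, , drop = FALSE]
      up_times <- lapply(links$phecode, function(d) T_phe[, d])
      T_cause[, k] <- latent_times(U[12L + P + k, ],
                                   cfg$death_causes$base_rate[k],
                                   exp_onset_vec,
                                   exp(cfg$death_causes$log_hr[k]),
                                   up_times, exp(links$log_hr), NULL)
    }
    death_t <- do.call(pmin, as.data.frame(T_cause))
    death_cause <- cfg$death_causes$cause[max.col(-T_cause, "first")]
  } else {
    death_t <- rep(Inf, n); death_cause <- character(n)
  }

  end_t <- pmin(censor_t, loss_t, death_t)
  to_date <- function(t) origin + round(t * DAYS_PER_YEAR)
  end_date <- to_date(end_t)

  lost <- loss_t < pmin(censor_t, death_t)
  ltf <- rep(NA_real_, n)
  ltf[lost] <- as.numeric(to_date(loss_t[lost]))
  pers$lost_to_followup_date <- as.Date(ltf, origin = "1970-01-01")

  died <- death_t <= pmin(censor_t, loss_t)
  deaths <- data.frame(person_id = pers$person_id[died],
                       death_date = to_date(death_t[died]),
                       cause_category = death_cause[died],
                       stringsAsFactors = FALSE)

  # assemble observed events (exposure diagnoses + phenotype onsets)
  demo_map <- if (cfg$emit_icd10) load_demo_map() else NULL
  icd_for <- function(code) {
    if (is.null(demo_map)) return(code)
    demo_map$icd10[match(code, demo_map$phecode)]
  }
  ev_list <- list()
  dx <- exposed & onset_t <= end_t
  idx_date <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  idx_date[dx] <- to_date(onset_t[dx])
  okd <- dx & !is.na(idx_date) & idx_date <= end_date
  if (any(okd))
    ev_list[[1]] <- data.frame(
      person_id = pers$person_id[okd],
      code = if (cfg$emit_icd10) "E05.3" else "242",
      code_system = if (cfg$emit_icd10) "icd10" else "phecode",
      date = idx_date[okd], source = "inpatient",
      stringsAsFactors = FALSE)
  for (j in seq_len(P)) {
    tt <- T_phe[, j]
    ok <- is.finite(tt) & tt <= end_t
    dts <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
    dts[ok] <- to_date(tt[ok])
    ok <- ok & dts <= end_date
    if (!any(ok)) next
    ev_list[[length(ev_list) + 1L]] <- data.frame(
      person_id = pers$person_id[ok],
      code = icd_for(phe$phecode[j]) %||% phe$phecode[j],
      code_system = if (cfg$emit_icd10) "icd10" else "phecode",
      date = dts[ok], source = "inpatient",
      stringsAsFactors = FALSE)
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(person_id = character(0), code = character(0),
               code_system = character(0), date = as.Date(character(0)),
               source = character(0))
  events <- canonical_order(events, c("person_id", "date", "code"))
  rownames(events) <- NULL

  ground_truth <- list(
    phenotypes = phe,
    window_effects = cfg$window_effects,
    windows = cfg$windows,
    chains = cfg$chains,
    death_causes = cfg$death_causes,
    death_links = cfg$death_links,
    propensity = as.list(cfg$propensity),
    propensity_intercept = alpha,
    seed = cfg$seed)

  list(persons = pers, events = events, deaths = deaths,
       exposure_assigned = data.frame(
         person_id = pers$person_id, exposed = exposed,
         onset_date = idx_date,
         stringsAsFactors = FALSE),
       ground_truth = ground_truth)
}

#' Load the bundled demonstration PheCode map
#'
#' A miniature ICD-10 to PheCode map (~50 rows across the major disease
#' categories) sufficient for examples and tests; real analyses supply a
#' full map file.
#'
#' @return data.frame mapping table.
#' @export
load_demo_map <- function() {
  read_phecode_map(system.file("extdata", "phecode_map_demo.tsv",
                               package = "phetraj", mustWork = TRUE))
}

#' Load the bundled demonstration self-report map
#' @return data.frame with columns `code`, `phecode`.
#' @export
load_demo_selfreport_map <- function() {
  read_selfreport_map(system.file("extdata", "selfreport_map_demo.tsv",
                                  package = "phetraj", mustWork = TRUE))
}

#' Serialise ground truth to JSON
#' @param ground_truth as returned by [generate_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
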