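# Orchestration: run configuration, the end-to-end pipeline
# (map -> dedup -> exposure -> match -> screen -> landmark -> trajectory),
# structured provenance logging, and run summaries.

#' Build (or read) a run configuration
#'
#' All analysis constants live here with their standard defaults: the
#' 20-case candidate threshold, the 10-person pair threshold, the 0.05
#' family-wise alpha, the four landmark windows and the region-specific
#' censoring dates. A YAML file with any subset of the fields can be
#' supplied; explicit arguments override it.
#'
#' @param path optional YAML config file.
#' @param ... overrides for any config field.
#' @return object of class `phetraj_config` (a named list).
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    paths = list(persons = NULL, events = NULL, deaths = NULL, map = NULL,
                 selfreport_map = NULL),
    ratio = 4L,
    caliper_sd = 0.2,
    min_cases = 20L,
    min_pairs = 10L,
    alpha = 0.05,
    windows = LANDMARK_BREAKS,
    censor_dates = as.list(DEFAULT_CENSOR_DATES),
    exposure_codes = EXPOSURE_PHECODES,
    min_index_date = "1997-01-01",
    sensitivity = NULL,
    post_index_pairs = TRUE,
    n_boot = 1000L,
    seed = 1L,
    landmark_max_phenotypes = 25L,
    mortality_trajectories = TRUE)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$windows <- as.numeric(unlist(cfg$windows))
  if (is.na(cfg$windows[length(cfg$windows)]))
    cfg$windows[length(cfg$windows)] <- Inf
  stopifnot(cfg$min_cases > 0, cfg$min_pairs > 0, cfg$alpha > 0,
            cfg$ratio >= 1, !is.unsorted(cfg$windows, strictly = TRUE))
  class(cfg) <- "phetraj_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' `Inf` window bounds are serialised as `.inf`-safe nulls and restored on
#' read, so a config round-trips losslessly through its file format.
#'
#' @param cfg a `phetraj_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$windows <- ifelse(is.infinite(out$windows), NA, out$windows)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a generated cohort to a directory
#'
#' Writes `persons.tsv`, `events.tsv`, `deaths.tsv`, copies of the demo
#' maps, and `ground_truth.json`.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(cohort$persons, file.path(dir, "persons.tsv"))
  write_table(cohort$events, file.path(dir, "events.tsv"))
  write_table(cohort$deaths, file.path(dir, "deaths.tsv"))
  write_table(load_demo_map(), file.path(dir, "phecode_map.tsv"))
  write_table(load_demo_selfreport_map(),
              file.path(dir, "selfreport_map.tsv"))
  write_ground_truth(cohort$ground_truth,
                     file.path(dir, "ground_truth.json"))
  invisible(dir)
}

log_stage <- function(prov, stage, ...) {
  prov[[stage]] <- list(...)
  prov
}

#' Run the full pipeline
#'
#' Executes mapping, first-occurrence deduplication, exposure
#' identification, propensity matching with post-match exclusions, the
#' PheWAS and death-cause screens, the landmark analysis of significant
#' phenotypes, and trajectory construction, writing each stage's table and
#' a structured provenance log (`provenance.yaml`) into `out_dir`. A rerun
#' with the same config and inputs reproduces the outputs exactly.
#'
#' @param cfg run configuration from [run_config()].
#' @param out_dir output directory.
#' @param tables optional list(`persons`, `events`, `deaths`, `map`,
#'   `selfreport_map`) of in-memory inputs; when NULL they are read from
#'   `cfg$paths`.
#' @return invisibly, a list with the main in-memory results
#'   (`exposure`, `sets`, `phewas`, `deaths_screen`, `landmark`, `pairs`,
#'   `triples`, `graph`, `provenance`).
#' @export
run_pipeline <- function(cfg, out_dir, tables = NULL) {
  stopifnot(inherits(cfg, "phetraj_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list()
  stage <- "load"
  result <- tryCatch({
    if (is.null(tables)) tables <- load_tables(cfg$paths)
    persons <- tables$persons; deaths <- tables$deaths
    map <- tables$map
    prov <- log_stage(prov, "load",
                      persons = nrow(persons), events = nrow(tables$events),
                      deaths = nrow(deaths), map_rows = nrow(map))

    stage <- "map"
    mapped <- map_to_phecodes(tables$events, map, tables$selfreport_map)
    prov <- log_stage(prov, "map", input = nrow(tables$events),
                      mapped = nrow(mapped),
                      unmapped = attr(mapped, "n_unmapped"),
                      excluded_category = attr(mapped, "n_excluded_category"))

    stage <- "dedup"
    events <- first_occurrences(mapped)
    prov <- log_stage(prov, "dedup", input = nrow(mapped),
                      first_occurrences = nrow(events),
                      duplicates_removed = nrow(mapped) - nrow(events))

    stage <- "exposure"
    exposure <- identify_exposure(events, deaths, cfg$exposure_codes,
                                  as.Date(cfg$min_index_date))
    exc <- attr(exposure, "exclusions")
    prov <- log_stage(prov, "exposure",
                      candidates = nrow(exposure) + sum(exc),
                      cases = nrow(exposure),
                      pre_cutoff = unname(exc["pre_cutoff"]),
                      same_day_death = unname(exc["same_day_death"]))

    stage <- "sensitivity"
    if (!is.null(cfg$sensitivity)) {
      filt <- sensitivity_filters(events, exposure, cfg$sensitivity,
                                  raw_events = mapped, persons = persons)
      events <- filt$events; exposure <- filt$exposure
      prov <- log_stage(prov, "sensitivity", mode = cfg$sensitivity,
                        removed = filt$n_removed)
    }

    stage <- "match"
    scores <- estimate_propensity(persons, exposure)
    pool <- setdiff(persons$person_id, exposure$person_id)
    sets <- match_1to4(scores, exposure, pool, ratio = cfg$ratio,
                       caliper_sd = cfg$caliper_sd, seed = cfg$seed)
    prov <- log_stage(prov, "match",
                      cases_in = nrow(exposure),
                      cases_matched = length(unique(sets$set_id)),
                      cases_unmatched = attr(sets, "n_unmatched_cases"),
                      missing_covariates = attr(scores,
                                                "n_missing_covariates"))

    stage <- "post_match_exclusions"
    n_before <- nrow(sets)
    sets <- apply_post_match_exclusions(sets, persons, deaths,
                                        tables$treatment_flags %||%
                                          character(0))
    pexc <- attr(sets, "exclusions")
    prov <- log_stage(prov, "post_match_exclusions",
                      members_in = n_before, members_out = nrow(sets),
                      dead_before_index = unname(pexc["dead_before_index"]),
                      lost_before_index = unname(pexc["lost_before_index"]),
                      treated = unname(pexc["treated"]),
                      dropped_set_cases = unname(pexc["sets_dropped"]))
    write_table(sets, file.path(out_dir, "matched_sets.tsv"))
    bal <- balance_table(sets, persons)
    write_table(bal, file.path(out_dir, "balance.tsv"))

    stage <- "phewas"
    censor <- unlist(cfg$censor_dates)
    candidates <- select_candidates(events, exposure, cfg$min_cases,
                                    cfg$exposure_codes)
    phewas <- run_phewas_screen(sets, events, deaths, persons, candidates,
                                censor, cfg$alpha)
    phewas$phenotype_label <- map$phenotype[match(phewas$phenotype,
                                                  map$phecode)]
    phewas$category <- map$category[match(phewas$phenotype, map$phecode)]
    write_table(phewas, file.path(out_dir, "phewas_results.tsv"))
    pex <- attr(phewas, "exclusions")
    prov <- log_stage(prov, "phewas",
                      candidates = length(candidates),
                      tested = nrow(phewas),
                      significant = sum(phewas$significant, na.rm = TRUE),
                      members = nrow(sets),
                      exclusions_per_phenotype = apply(pex, 1, function(r)
                        as.list(r), simplify = FALSE))

    stage <- "death_screen"
    mort <- build_mortality_dataset(sets, deaths, persons, censor)
    deaths_screen <- screen_death_causes(mort, cfg$min_cases,
                                         alpha = cfg$alpha)
    write_table(deaths_screen, file.path(out_dir, "deaths_results.tsv"))
    prov <- log_stage(prov, "death_screen",
                      members = nrow(sets), analyzed = nrow(mort),
                      nonpositive = unname(attr(mort,
                                                "exclusions")["nonpositive"]),
                      causes_tested = nrow(deaths_screen),
                      causes_skipped = attr(deaths_screen, "skipped"))

    stage <- "landmark"
    sig <- phewas$phenotype[phewas$significant %in% TRUE]
    lm_phe <- utils::head(sig, cfg$landmark_max_phenotypes)
    landmark <- if (length(lm_phe))
      run_landmark_screen(sets, events, deaths, persons, lm_phe,
                          cfg$windows, censor)
    else data.frame()
    write_table(landmark, file.path(out_dir, "landmark_results.tsv"))
    prov <- log_stage(prov, "landmark", phenotypes = length(lm_phe))

    stage <- "trajectory"
    traj <- trajectory_dataset(events, exposure, persons, sig,
                               post_index_only = cfg$post_index_pairs)
    pairs <- pair_odds_ratio(
      binomial_direction_test(enumerate_pairs(traj$dates, cfg$min_pairs),
                              cfg$alpha),
      traj$dates, traj$covars, cfg$alpha)
    triples <- run_mediation(pairs, traj$dates, traj$covars,
                             n_boot = cfg$n_boot, alpha = cfg$alpha,
                             seed = cfg$seed)
    graph <- assemble_graph(pairs, triples, exposure_links = sig)
    write_table(pairs, file.path(out_dir, "pairs.tsv"))
    write_table(triples, file.path(out_dir, "triples.tsv"))
    write_table(graph$edges, file.path(out_dir, "trajectory_edges.tsv"))
    graph_to_json(graph, file.path(out_dir, "graph.json"))
    graph_to_dot(graph, file.path(out_dir, "graph.dot"))
    prov <- log_stage(prov, "trajectory",
                      phenotypes = length(sig),
                      pairs_enumerated = nrow(pairs),
                      pairs_directional = sum(pairs$passed_direction),
                      pairs_validated = sum(pairs$passed_or),
                      triples_tested = nrow(triples),
                      triples_validated = sum(triples$significant))

    stage <- "mortality_trajectories"
    mt <- list()
    if (isTRUE(cfg$mortality_trajectories) && nrow(deaths_screen)) {
      sig_causes <- sub("^death:", "",
                        deaths_screen$phenotype[deaths_screen$significant
                                                %in% TRUE])
      for (cc in sig_causes) {
        g <- tryCatch(
          mortality_trajectories(traj$dates, traj$covars, deaths, exposure,
                                 cc, cfg$min_cases, cfg$min_pairs,
                                 cfg$alpha, cfg$n_boot, cfg$seed),
          error = function(e) NULL)
        if (!is.null(g)) {
          mt[[cc]] <- g
          graph_to_json(g, file.path(out_dir,
                                     sprintf("mortality_graph_%s.json", cc)))
        }
      }
    }
    prov <- log_stage(prov, "mortality_trajectories", causes = names(mt))

    yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
    list(exposure = exposure, sets = sets, balance = bal, phewas = phewas,
         deaths_screen = deaths_screen, landmark = landmark, pairs = pairs,
         triples = triples, graph = graph, mortality_graphs = mt,
         provenance = prov)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s' (outputs in %s): %s",
                 stage, out_dir, conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Summarise a completed run
#'
#' Recounts the written result tables into a short human-readable report:
#' significant phenotypes per category, the top hazard ratios, death-cause
#' results and trajectory edge counts. Written as both `report.txt` and
#' `report.json` (which agree on every number); missing stage outputs
#' produce a partial report with warnings.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return the report list, invisibly.
#' @export
summarize_run <- function(run_dir) {
  rep <- list()
  warnings <- character(0)
  pw_path <- file.path(run_dir, "phewas_results.tsv")
  if (file.exists(pw_path)) {
    pw <- utils::read.delim(pw_path, stringsAsFactors = FALSE)
    sig <- pw[pw$significant %in% TRUE, , drop = FALSE]
    rep$phenotypes_tested <- nrow(pw)
    rep$phenotypes_significant <- nrow(sig)
    rep$significant_by_category <- if (nrow(sig))
      as.list(table(sig$category)) else list()
    cols <- intersect(c("phenotype", "phenotype_label", "hr", "ci_low",
                        "ci_high", "p_adjusted"), names(sig))
    rep$top_hr <- utils::head(sig[order(-sig$hr), cols, drop = FALSE], 5)
  } else warnings <- c(warnings, "phewas_results.tsv missing")
  dr_path <- file.path(run_dir, "deaths_results.tsv")
  if (file.exists(dr_path)) {
    dr <- utils::read.delim(dr_path, stringsAsFactors = FALSE)
    rep$death_causes_tested <- nrow(dr)
    rep$death_causes_significant <- sum(dr$significant %in% TRUE)
  } else warnings <- c(warnings, "deaths_results.tsv missing")
  ed_path <- file.path(run_dir, "trajectory_edges.tsv")
  if (file.exists(ed_path)) {
    ed <- utils::read.delim(ed_path, stringsAsFactors = FALSE)
    rep$trajectory_edges <- nrow(ed)
  } else warnings <- c(warnings, "trajectory_edges.tsv missing")
  rep$warnings <- warnings

  txt <- c("phetraj run summary",
           "===================",
           sprintf("phenotypes tested: %s", rep$phenotypes_tested %||% "NA"),
           sprintf("phenotypes significant: %s",
                   rep$phenotypes_significant %||% "NA"),
           if (length(rep$significant_by_category))
             paste0("  ", names(rep$significant_by_category), ": ",
                    unlist(rep$significant_by_category)),
           sprintf("death causes tested: %s",
                   rep$death_causes_tested %||% "NA"),
           sprintf("death causes significant: %s",
                   rep$death_causes_significant %||% "NA"),
           sprintf("trajectory edges: %s", rep$trajectory_edges %||% "NA"),
           if (length(warnings)) paste("WARNING:", warnings))
  writeLines(txt, file.path(run_dir, "report.txt"))
  jsonlite::write_json(rep, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (length(warnings))
    warning(paste(warnings, collapse = "; "), call. = FALSE)
  invisible(rep)
}

#' Check the provenance bookkeeping identities of a run
#'
#' Verifies that at every stage the input count equals the analyzed count
#' plus the logged exclusions.
#'
#' @param prov provenance list from [run_pipeline()].
#' @return TRUE if all identities hold, otherwise a character vector of
#'   violated identities.
#' @export
check_bookkeeping <- function(prov) {
  bad <- character(0)
  chk <- function(label, lhs, rhs) {
    if (!isTRUE(all.equal(lhs, rhs)))
      bad <<- c(bad, sprintf("%s: %s != %s", label, lhs, rhs))
  }
  with(prov$map, chk("map", input, mapped + unmapped + excluded_category))
  with(prov$dedup, chk("dedup", input,
                       first_occurrences + duplicates_removed))
  with(prov$exposure, chk("exposure", candidates,
                          cases + pre_cutoff + same_day_death))
  with(prov$match, chk("match", cases_in, cases_matched + cases_unmatched))
  with(prov$post_match_exclusions,
       chk("post_match", members_in,
           members_out + dead_before_index + lost_before_index + treated +
             dropped_set_cases))
  if (!is.null(prov$phewas$exclusions_per_phenotype)) {
    members <- prov$phewas$members
    for (ph in names(prov$phewas$exclusions_per_phenotype)) {
      e <- prov$phewas$exclusions_per_phenotype[[ph]]
      # analyzed member count is members - prevalent - nonpositive by
      # construction; the identity is that exclusions never exceed members
      if (e$prevalent + e$nonpositive > members)
        bad <- c(bad, sprintf("phewas[%s]: exclusions exceed members", ph))
    }
  }
  if (length(bad)) bad else TRUE
}
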