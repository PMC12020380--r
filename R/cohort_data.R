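# Cohort data layer: typed TSV readers/writers, ICD-10 -> PheCode mapping
# with longest-prefix matching, first-occurrence deduplication, and
# identification of the exposed cohort with its index dates.

EXCLUDED_MAP_CATEGORIES <- c("pregnancy complications",
                             "congenital anomalies",
                             "injuries & poisonings")

PERSONS_COLS <- c("person_id", "birth_year", "gender", "bmi", "townsend",
                  "education", "smoking", "alcohol", "activity", "region",
                  "lost_to_followup_date")
EVENTS_COLS  <- c("person_id", "code", "code_system", "date", "source")
DEATHS_COLS  <- c("person_id", "death_date", "cause_category")
MAP_COLS     <- c("icd10", "phecode", "phenotype", "category")

read_tsv_checked <- function(path, required, skip_bad_rows = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in '%s': missing required column(s) %s",
                 path, paste(missing, collapse = ", ")))
  df
}

parse_date_col <- function(df, col, path, skip_bad_rows = FALSE,
                           allow_na = FALSE) {
  raw <- df[[col]]
  parsed <- as.Date(raw, format = "%Y-%m-%d")
  bad <- which(!is.na(raw) & is.na(parsed))
  if (!allow_na) bad <- union(bad, which(is.na(raw)))
  bad <- sort(bad)
  if (length(bad)) {
    msg <- sprintf("malformed date in '%s' column '%s' at row %s",
                   path, col, paste(bad, collapse = ", "))
    if (!skip_bad_rows) stop(msg)
    warning(paste0(msg, " (rows skipped)"), call. = FALSE)
  }
  df[[col]] <- parsed
  list(df = df, bad_rows = bad)
}

check_levels <- function(x, levels, what, path) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad))
    stop(sprintf("invalid %s value(s) in '%s' at row %s (allowed: %s)",
                 what, path, paste(utils::head(bad, 5), collapse = ", "),
                 paste(levels, collapse = ", ")))
  invisible(TRUE)
}

#' Read a persons table
#'
#' Expects a tab-delimited file with columns `person_id`, `birth_year`,
#' `gender`, `bmi`, `townsend`, `education`, `smoking`, `alcohol`,
#' `activity`, `region`, `lost_to_followup_date` (ISO-8601 or empty).
#'
#' @param path file path.
#' @param skip_bad_rows drop rows with malformed dates instead of failing.
#' @return data.frame of persons with typed columns.
#' @export
read_persons <- function(path, skip_bad_rows = FALSE) {
  df <- read_tsv_checked(path, PERSONS_COLS, skip_bad_rows)
  res <- parse_date_col(df, "lost_to_followup_date", path, skip_bad_rows,
                        allow_na = TRUE)
  df <- res$df
  if (length(res$bad_rows)) df <- df[-res$bad_rows, , drop = FALSE]
  df$birth_year <- as.integer(df$birth_year)
  df$bmi <- as.numeric(df$bmi)
  df$townsend <- as.numeric(df$townsend)
  check_levels(df$gender, GENDER_LEVELS, "gender", path)
  check_levels(df$region, REGION_LEVELS, "region", path)
  check_levels(df$education, EDUCATION_LEVELS, "education", path)
  check_levels(df$smoking, SMOKING_LEVELS, "smoking", path)
  check_levels(df$alcohol, ALCOHOL_LEVELS, "alcohol", path)
  check_levels(df$activity, ACTIVITY_LEVELS, "activity", path)
  bad_by <- which(!is.na(df$birth_year) &
                  (df$birth_year < 1900 | df$birth_year > 2010))
  if (length(bad_by))
    stop(sprintf("implausible birth_year in '%s' at row %s", path,
                 paste(utils::head(bad_by, 5), collapse = ", ")))
  rownames(df) <- NULL
  df
}

#' Read a diagnosis-events table
#'
#' Columns: `person_id`, `code`, `code_system` (icd10/phecode/self_report),
#' `date` (ISO-8601), `source` (inpatient/self_report).
#'
#' @inheritParams read_persons
#' @return data.frame of diagnosis events.
#' @export
read_events <- function(path, skip_bad_rows = FALSE) {
  df <- read_tsv_checked(path, EVENTS_COLS, skip_bad_rows)
  if (any(is.na(df$code) | df$code == ""))
    stop(sprintf("empty diagnosis code in '%s'", path))
  check_levels(df$code_system, CODE_SYSTEMS, "code_system", path)
  check_levels(df$source, SOURCE_LEVELS, "source", path)
  res <- parse_date_col(df, "date", path, skip_bad_rows)
  df <- res$df
  if (length(res$bad_rows)) df <- df[-res$bad_rows, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a deaths table
#'
#' Columns: `person_id`, `death_date` (ISO-8601), `cause_category` (one of
#' the 16 system-level cause categories).
#'
#' @inheritParams read_persons
#' @return data.frame of death records, at most one per person.
#' @export
read_deaths <- function(path, skip_bad_rows = FALSE) {
  df <- read_tsv_checked(path, DEATHS_COLS, skip_bad_rows)
  res <- parse_date_col(df, "death_date", path, skip_bad_rows)
  df <- res$df
  if (length(res$bad_rows)) df <- df[-res$bad_rows, , drop = FALSE]
  check_levels(df$cause_category, DEATH_CAUSE_LEVELS, "cause_category", path)
  if (anyDuplicated(df$person_id))
    stop(sprintf("duplicate death record(s) in '%s'", path))
  rownames(df) <- NULL
  df
}

#' Read an ICD-10 to PheCode mapping table
#'
#' Columns: `icd10` (a full code like `E05.0` or a prefix like `E05`),
#' `phecode`, `phenotype`, `category`. Matching at lookup time is
#' longest-prefix: an event coded `E05.9` matches an `E05` row when no
#' finer row exists. Each ICD code/prefix maps to exactly one PheCode.
#'
#' @inheritParams read_persons
#' @return data.frame mapping table.
#' @export
read_phecode_map <- function(path, skip_bad_rows = FALSE) {
  df <- read_tsv_checked(path, MAP_COLS, skip_bad_rows)
  if (nrow(df) == 0L) stop("configuration error: empty PheCode map")
  if (anyDuplicated(df$icd10))
    stop(sprintf("duplicate icd10 entries in map '%s'", path))
  rownames(df) <- NULL
  df
}

#' Read a self-report code to PheCode mapping table
#'
#' Two columns: `code` (the self-report questionnaire code, e.g. `1225`)
#' and `phecode`.
#'
#' @inheritParams read_persons
#' @return data.frame with columns `code`, `phecode`.
#' @export
read_selfreport_map <- function(path, skip_bad_rows = FALSE) {
  df <- read_tsv_checked(path, c("code", "phecode"), skip_bad_rows)
  if (nrow(df) == 0L) stop("configuration error: empty self-report map")
  df
}

#' Load all input tables for a run
#'
#' @param paths named list/vector with elements `persons`, `events`,
#'   `deaths`, `map` and optionally `selfreport_map`.
#' @param skip_bad_rows drop rows with malformed dates instead of failing.
#' @return list with elements `persons`, `events`, `deaths`, `map`,
#'   `selfreport_map` (NULL if not supplied) and `row_counts`.
#' @export
load_tables <- function(paths, skip_bad_rows = FALSE) {
  persons <- read_persons(paths[["persons"]], skip_bad_rows)
  events  <- read_events(paths[["events"]], skip_bad_rows)
  deaths  <- read_deaths(paths[["deaths"]], skip_bad_rows)
  map     <- read_phecode_map(paths[["map"]], skip_bad_rows)
  srm <- NULL
  if (!is.null(paths[["selfreport_map"]]) && !is.na(paths[["selfreport_map"]]))
    srm <- read_selfreport_map(paths[["selfreport_map"]], skip_bad_rows)
  list(persons = persons, events = events, deaths = deaths, map = map,
       selfreport_map = srm,
       row_counts = c(persons = nrow(persons), events = nrow(events),
                      deaths = nrow(deaths), map = nrow(map)))
}

format_date_col <- function(x) {
  ifelse(is.na(x), NA, format(x, "%Y-%m-%d"))
}

#' Write a table as TSV with a YAML sidecar logging row counts
#'
#' @param df data.frame (Date columns serialised as ISO-8601).
#' @param path output path; a `<path>.yaml` sidecar is written alongside.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, meta = list()) {
  out <- df
  for (col in names(out))
    if (inherits(out[[col]], "Date")) out[[col]] <- format_date_col(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  sidecar <- c(list(file = basename(path), rows = nrow(df),
                    columns = names(df)), meta)
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

# longest-prefix lookup of one set of codes against the map's icd10 keys
match_icd10_prefix <- function(codes, map_keys) {
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(map_keys)) assign(map_keys[i], i, envir = lookup)
  vapply(codes, function(code) {
    cand <- code
    while (nchar(cand) > 0L) {
      hit <- get0(cand, envir = lookup)
      if (!is.null(hit)) return(hit)
      cand <- substr(cand, 1L, nchar(cand) - 1L)
      cand <- sub("\\.$", "", cand)
    }
    NA_integer_
  }, integer(1))
}

#' Map diagnosis events to PheCodes
#'
#' Re-codes ICD-10 events via longest-prefix lookup in the mapping table and
#' self-report events via the self-report table. Events whose code has no
#' mapping are dropped and counted, as are events mapping to excluded
#' categories (pregnancy/childbirth, congenital anomalies, external-cause
#' injuries and poisonings).
#'
#' @param events data.frame of diagnosis events (icd10 or self_report).
#' @param map ICD-10 to PheCode mapping table.
#' @param selfreport_map optional two-column self-report mapping table.
#' @return data.frame of events with `code_system = "phecode"`; attributes
#'   `n_unmapped` and `n_excluded_category` carry the drop counts, and
#'   `phenotype`/`category` columns are added from the map.
#' @export
map_to_phecodes <- function(events, map, selfreport_map = NULL) {
  if (is.null(map) || nrow(map) == 0L)
    stop("configuration error: empty PheCode map")
  is_icd <- events$code_system == "icd10"
  is_sr  <- events$code_system == "self_report"
  phe <- rep(NA_character_, nrow(events))
  lab <- rep(NA_character_, nrow(events))
  cat <- rep(NA_character_, nrow(events))
  if (any(is_icd)) {
    idx <- match_icd10_prefix(events$code[is_icd], map$icd10)
    phe[is_icd] <- map$phecode[idx]
    lab[is_icd] <- map$phenotype[idx]
    cat[is_icd] <- map$category[idx]
  }
  if (any(is_sr)) {
    if (is.null(selfreport_map))
      stop("self-report events present but no self-report map supplied")
    idx <- match(events$code[is_sr], selfreport_map$code)
    phe[is_sr] <- selfreport_map$phecode[idx]
    # pick up phenotype/category from the main map where available
    midx <- match(phe[is_sr], map$phecode)
    lab[is_sr] <- map$phenotype[midx]
    cat[is_sr] <- map$category[midx]
  }
  already <- events$code_system == "phecode"
  phe[already] <- events$code[already]
  midx <- match(phe[already], map$phecode)
  lab[already] <- map$phenotype[midx]
  cat[already] <- map$category[midx]

  unmapped <- is.na(phe)
  excluded <- !unmapped & !is.na(cat) & cat %in% EXCLUDED_MAP_CATEGORIES
  keep <- !unmapped & !excluded
  out <- events[keep, , drop = FALSE]
  out$code <- phe[keep]
  out$code_system <- rep("phecode", nrow(out))
  out$phenotype <- lab[keep]
  out$category <- cat[keep]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(unmapped)
  attr(out, "n_excluded_category") <- sum(excluded)
  out
}

#' Keep only the first occurrence of each (person, PheCode)
#'
#' Retains, for every person and phenotype code, the earliest dated record.
#' The result is invariant under permutation of the input rows.
#'
#' @param events data.frame of (mapped) diagnosis events.
#' @return deduplicated events, in (person_id, code, date) order.
#' @export
first_occurrences <- function(events) {
  if (nrow(events) == 0L) return(events)
  ord <- order(events$person_id, events$code, events$date, events$source,
               method = "radix")
  ev <- events[ord, , drop = FALSE]
  keep <- !duplicated(paste(ev$person_id, ev$code, sep = "\r"))
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify the exposed cohort and its index dates
#'
#' A person is exposed if they carry at least one exposure PheCode; the
#' earliest such diagnosis date is the index date. Cases whose index date is
#' not after the records-completeness cutoff (default 1997-01-01) and cases
#' who died on the day of diagnosis are removed, with per-rule counts.
#'
#' @param events mapped, deduplicated diagnosis events.
#' @param deaths deaths table.
#' @param exposure_codes PheCodes defining exposure.
#' @param min_index_date exclusive lower bound for index dates.
#' @return data.frame (`person_id`, `index_date`) with attribute
#'   `exclusions` = c(pre_cutoff, same_day_death).
#' @export
identify_exposure <- function(events, deaths,
                              exposure_codes = EXPOSURE_PHECODES,
                              min_index_date = as.Date("1997-01-01")) {
  ev <- events[events$code %in% exposure_codes, , drop = FALSE]
  if (nrow(ev) == 0L) {
    out <- data.frame(person_id = character(0),
                      index_date = as.Date(character(0)))
    attr(out, "exclusions") <- c(pre_cutoff = 0L, same_day_death = 0L)
    return(out)
  }
  ord <- order(ev$person_id, ev$date, method = "radix")
  ev <- ev[ord, , drop = FALSE]
  first <- ev[!duplicated(ev$person_id), c("person_id", "date")]
  names(first) <- c("person_id", "index_date")
  pre <- first$index_date <= min_index_date
  n_pre <- sum(pre)
  first <- first[!pre, , drop = FALSE]
  dd <- deaths$death_date[match(first$person_id, deaths$person_id)]
  same_day <- !is.na(dd) & dd == first$index_date
  n_same <- sum(same_day)
  out <- first[!same_day, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(pre_cutoff = n_pre, same_day_death = n_same)
  out
}
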