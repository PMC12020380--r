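# Disease-trajectory construction among exposed patients, in four steps:
# (1) enumerate ordered disease pairs D1 -> D2 with enough co-diagnosed
# persons; (2) exact binomial test that D1 precedes D2 in more than half of
# them; (3) adjusted logistic odds ratio of D2 on D1 with OR > 1; (4) for
# coexisting pairs D1->D2, D2->D3, D1->D3, a bootstrap mediation test of
# the indirect effect through D2. Validated triples are linked into
# trajectories; a parallel path builds trajectories into causes of death.

#' Per-person first-diagnosis dates for a phenotype list
#'
#' Restricts events to the exposed cohort (optionally to diagnoses after
#' each person's index date) and returns an n x P matrix of first-diagnosis
#' dates (numeric days, NA = never diagnosed), plus the covariates used by
#' the trajectory gates (gender, age at index).
#'
#' @param events mapped first-occurrence events.
#' @param exposure exposure table (`person_id`, `index_date`).
#' @param persons persons table.
#' @param phenotypes PheCodes (matrix columns).
#' @param post_index_only count only diagnoses strictly after the index date.
#' @return list(`dates` matrix, `covars` data.frame with `male`,
#'   `age_at_index`).
#' @export
trajectory_dataset <- function(events, exposure, persons, phenotypes,
                               post_index_only = TRUE) {
  ids <- exposure$person_id
  ev <- events[events$person_id %in% ids & events$code %in% phenotypes, ,
               drop = FALSE]
  if (post_index_only) {
    idx <- exposure$index_date[match(ev$person_id, exposure$person_id)]
    ev <- ev[ev$date > idx, , drop = FALSE]
  }
  D <- matrix(NA_real_, length(ids), length(phenotypes),
              dimnames = list(ids, phenotypes))
  if (nrow(ev))
    D[cbind(match(ev$person_id, ids), match(ev$code, phenotypes))] <-
      as.numeric(ev$date)
  pidx <- match(ids, persons$person_id)
  covars <- data.frame(
    male = as.numeric(persons$gender[pidx] == "male"),
    age_at_index = as.numeric(format(exposure$index_date, "%Y")) -
      persons$birth_year[pidx])
  list(dates = D, covars = covars)
}

#' Enumerate ordered disease pairs with ordering counts
#'
#' For every ordered pair (D1, D2) of distinct phenotypes co-diagnosed in
#' at least `min_pairs` persons, counts how many persons received D1 first,
#' D2 first, or both on the same day (same-day co-diagnoses carry no
#' ordering information and are tallied separately).
#'
#' @param dates first-diagnosis date matrix from [trajectory_dataset()].
#' @param min_pairs minimum number of co-diagnosed persons.
#' @return data.frame (`d1`, `d2`, `n_both`, `n_d1_first`, `n_d2_first`,
#'   `n_same_day`).
#' @export
enumerate_pairs <- function(dates, min_pairs = 10L) {
  P <- ncol(dates)
  codes <- colnames(dates)
  rows <- list()
  if (P >= 2L) for (j in seq_len(P - 1L)) for (k in (j + 1L):P) {
    both <- !is.na(dates[, j]) & !is.na(dates[, k])
    nb <- sum(both)
    if (nb < min_pairs) next
    dj <- dates[both, j]; dk <- dates[both, k]
    n_j_first <- sum(dj < dk); n_k_first <- sum(dk < dj)
    n_same <- nb - n_j_first - n_k_first
    rows[[length(rows) + 1L]] <- data.frame(
      d1 = c(codes[j], codes[k]), d2 = c(codes[k], codes[j]),
      n_both = nb, n_d1_first = c(n_j_first, n_k_first),
      n_d2_first = c(n_k_first, n_j_first), n_same_day = n_same,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(d1 = character(0), d2 = character(0), n_both = integer(0),
               n_d1_first = integer(0), n_d2_first = integer(0),
               n_same_day = integer(0))
  rownames(out) <- NULL
  out
}

#' Exact binomial directionality test for disease pairs
#'
#' One-sided exact binomial tail probability that D1 precedes D2 in at
#' least the observed number of the informatively ordered co-diagnoses
#' (same-day pairs excluded from the trial count), under the null of a
#' fair ordering: `p = P(X >= n_d1_first | n, 1/2)`. Bonferroni control is
#' applied within the family of unordered pairs tested; a pair passes when
#' the adjusted p is below `alpha` (which requires the D1-first proportion
#' to exceed 50%).
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param alpha significance level for the adjusted p.
#' @return `pairs` with `binom_p`, `binom_p_adjusted`, `passed_direction`.
#' @export
binomial_direction_test <- function(pairs, alpha = 0.05) {
  n <- pairs$n_d1_first + pairs$n_d2_first
  p <- rep(NA_real_, nrow(pairs))
  usable <- n >= 1L
  p[usable] <- stats::pbinom(pairs$n_d1_first[usable] - 1L, n[usable], 0.5,
                             lower.tail = FALSE)
  m <- length(unique(paste(pmin(pairs$d1, pairs$d2),
                           pmax(pairs$d1, pairs$d2))[usable]))
  pairs$binom_p <- p
  pairs$binom_p_adjusted <- pmin(1, m * p)
  pairs$passed_direction <- usable & !is.na(p) &
    pairs$binom_p_adjusted < alpha
  attr(pairs, "binom_family_size") <- m
  pairs
}

#' Adjusted odds-ratio gate for directionally validated pairs
#'
#' For each pair that passed the directionality test, fits a logistic model
#' of ever-D2 on ever-D1 adjusted for gender and age at the index date
#' among exposed persons. The pair passes when the Bonferroni-adjusted p
#' (over the pairs entering this gate) is below `alpha` and OR > 1.
#' Quasi-separated fits are flagged non-estimable and fail the gate.
#'
#' @param pairs output of [binomial_direction_test()].
#' @param dates first-diagnosis date matrix.
#' @param covars covariate data.frame from [trajectory_dataset()].
#' @param alpha significance level.
#' @return `pairs` with `or_estimate`, `or_ci_low`, `or_ci_high`, `or_p`,
#'   `or_p_adjusted`, `or_estimable`, `passed_or`.
#' @export
pair_odds_ratio <- function(pairs, dates, covars, alpha = 0.05) {
  nr <- nrow(pairs)
  pairs$or_estimate <- rep(NA_real_, nr); pairs$or_ci_low <- rep(NA_real_, nr)
  pairs$or_ci_high <- rep(NA_real_, nr); pairs$or_p <- rep(NA_real_, nr)
  pairs$or_estimable <- rep(FALSE, nr)
  todo <- which(pairs$passed_direction)
  X0 <- cbind(1, d1 = 0, male = covars$male, age = covars$age_at_index)
  for (i in todo) {
    y <- as.numeric(!is.na(dates[, pairs$d2[i]]))
    X <- X0; X[, "d1"] <- as.numeric(!is.na(dates[, pairs$d1[i]]))
    fit <- fast_logit(X, y, se = TRUE)
    b <- fit$coef["d1"]; s <- fit$se[2]
    if (!fit$converged || !is.finite(b) || !is.finite(s) || abs(b) > 10)
      next
    pairs$or_estimate[i] <- exp(b)
    z <- stats::qnorm(0.975)
    pairs$or_ci_low[i] <- exp(b - z * s)
    pairs$or_ci_high[i] <- exp(b + z * s)
    pairs$or_p[i] <- 2 * stats::pnorm(-abs(b / s))
    pairs$or_estimable[i] <- TRUE
  }
  m <- length(todo)
  pairs$or_p_adjusted <- pmin(1, m * pairs$or_p)
  pairs$passed_or <- pairs$passed_direction & pairs$or_estimable &
    !is.na(pairs$or_p_adjusted) & pairs$or_p_adjusted < alpha &
    pairs$or_estimate > 1
  attr(pairs, "or_family_size") <- m
  pairs
}

#' Bootstrap mediation test for one disease triple
#'
#' Product-of-coefficients indirect effect of D1 on D3 through D2 on the
#' logistic scale: `a` is the D1 coefficient in D2 ~ D1 + covariates and
#' `b` the D2 coefficient in D3 ~ D2 + D1 + covariates; the indirect
#' effect is `a * b` with a seeded percentile bootstrap CI over persons.
#'
#' @param dates first-diagnosis date matrix.
#' @param covars covariate data.frame.
#' @param d1,d2,d3 phenotype codes.
#' @param n_boot bootstrap resamples (a warning is raised below 100).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return one-row data.frame (`d1`, `d2`, `d3`, `indirect`, `ci_low`,
#'   `ci_high`, `significant`, `estimable`).
#' @export
mediation_test <- function(dates, covars, d1, d2, d3, n_boot = 1000L,
                           conf = 0.95, seed = 1L) {
  if (n_boot < 100L)
    warning("fewer than 100 bootstrap resamples; CI will be unstable")
  x1 <- as.numeric(!is.na(dates[, d1]))
  x2 <- as.numeric(!is.na(dates[, d2]))
  x3 <- as.numeric(!is.na(dates[, d3]))
  Z <- cbind(male = covars$male, age = covars$age_at_index)
  point <- mediation_ab(x1, x2, x3, Z)
  out <- data.frame(d1 = d1, d2 = d2, d3 = d3,
                    indirect = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, significant = FALSE,
                    estimable = FALSE, stringsAsFactors = FALSE)
  if (!is.finite(point)) return(out)
  n <- length(x1)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    mediation_ab(x1[idx], x2[idx], x3[idx], Z[idx, , drop = FALSE])
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  if (length(boot) < 0.5 * n_boot) return(out)
  alpha2 <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha2, 1 - alpha2), names = FALSE)
  out$indirect <- point; out$ci_low <- ci[1]; out$ci_high <- ci[2]
  out$significant <- ci[1] > 0 | ci[2] < 0
  out$estimable <- TRUE
  out
}

mediation_ab <- function(x1, x2, x3, Z) {
  Xa <- cbind(1, d1 = x1, Z)
  fa <- fast_logit(Xa, x2)
  Xb <- cbind(1, d2 = x2, d1 = x1, Z)
  fb <- fast_logit(Xb, x3)
  if (!fa$converged || !fb$converged) return(NA_real_)
  a <- fa$coef["d1"]; b <- fb$coef["d2"]
  if (!is.finite(a) || !is.finite(b) || abs(a) > 10 || abs(b) > 10)
    return(NA_real_)
  unname(a * b)
}

#' Run mediation over all coexisting validated triples
#'
#' Tests every (D1, D2, D3) whose three pairs D1->D2, D2->D3 and D1->D3
#' all passed the direction and OR gates, with Bonferroni control over the
#' triples tested (a triple is validated when its CI excludes 0 at the
#' per-family-adjusted level via CI on the adjusted confidence level).
#'
#' @param pairs output of [pair_odds_ratio()].
#' @param dates,covars trajectory dataset components.
#' @param n_boot bootstrap resamples per triple.
#' @param alpha family-wise significance level.
#' @param seed base seed; triple i uses seed + i.
#' @return data.frame of mediation results, one row per coexisting triple.
#' @export
run_mediation <- function(pairs, dates, covars, n_boot = 1000L,
                          alpha = 0.05, seed = 1L) {
  ok <- pairs[pairs$passed_or, c("d1", "d2"), drop = FALSE]
  key <- paste(ok$d1, ok$d2, sep = ">")
  triples <- list()
  for (i in seq_len(nrow(ok))) {
    a <- ok$d1[i]; b <- ok$d2[i]
    nxt <- ok$d2[ok$d1 == b]
    for (cc in nxt)
      if (cc != a && paste(a, cc, sep = ">") %in% key)
        triples[[length(triples) + 1L]] <- c(a, b, cc)
  }
  if (!length(triples))
    return(data.frame(d1 = character(0), d2 = character(0),
                      d3 = character(0), indirect = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      significant = logical(0), estimable = logical(0)))
  m <- length(triples)
  conf <- 1 - alpha / m                     # Bonferroni-adjusted CI level
  res <- do.call(rbind, lapply(seq_len(m), function(i)
    mediation_test(dates, covars, triples[[i]][1], triples[[i]][2],
                   triples[[i]][3], n_boot = n_boot, conf = conf,
                   seed = seed + i)))
  rownames(res) <- NULL
  res
}

#' Assemble the trajectory graph
#'
#' Edges are the pairs that passed both the directionality and OR gates;
#' trajectories of length 3 are the mediation-validated triples, and longer
#' chains are grown by concatenating overlapping validated triples
#' (D1->D2->D3 with D2->D3->D4 yields D1->D2->D3->D4). Connected components
#' of the edge graph are reported as clusters, each seeded by its members
#' directly linked to the exposure (if `exposure_links` is supplied).
#'
#' @param pairs output of [pair_odds_ratio()].
#' @param triples output of [run_mediation()].
#' @param exposure_links phenotypes directly associated with the exposure
#'   (e.g. the PheWAS-significant list).
#' @return object of class `trajectory_graph`: list(`nodes`, `edges`,
#'   `triples`, `trajectories`, `clusters`).
#' @export
assemble_graph <- function(pairs, triples, exposure_links = character(0)) {
  edges <- pairs[pairs$passed_or,
                 c("d1", "d2", "n_both", "or_estimate"), drop = FALSE]
  rownames(edges) <- NULL
  val <- triples[triples$significant & triples$estimable, , drop = FALSE]
  trajectories <- grow_trajectories(val)
  nodes <- sort(unique(c(edges$d1, edges$d2)))
  clusters <- if (length(nodes)) {
    g <- igraph::graph_from_data_frame(edges[, c("d1", "d2")],
                                       vertices = nodes, directed = TRUE)
    comp <- igraph::components(g, mode = "weak")
    split(names(comp$membership), comp$membership)
  } else list()
  clusters <- lapply(unname(clusters), function(members)
    list(members = sort(members),
         seeds = sort(intersect(members, exposure_links))))
  structure(list(nodes = nodes, edges = edges, triples = val,
                 trajectories = trajectories, clusters = clusters),
            class = "trajectory_graph")
}

# grow maximal chains by overlapping validated triples
grow_trajectories <- function(triples, max_len = 10L) {
  if (nrow(triples) == 0L) return(list())
  paths <- lapply(seq_len(nrow(triples)),
                  function(i) c(triples$d1[i], triples$d2[i], triples$d3[i]))
  repeat {
    grew <- FALSE
    nxt <- list()
    for (p in paths) {
      k <- length(p)
      ext <- triples$d3[triples$d1 == p[k - 1L] & triples$d2 == p[k]]
      ext <- setdiff(ext, p)
      if (length(ext) && k < max_len) {
        for (e in ext) nxt[[length(nxt) + 1L]] <- c(p, e)
        grew <- TRUE
      } else nxt[[length(nxt) + 1L]] <- p
    }
    paths <- unique(nxt)
    if (!grew) break
  }
  # drop paths that are sub-sequences (prefixes) of longer retained paths
  keys <- vapply(paths, paste, character(1), collapse = ">")
  keep <- !vapply(seq_along(paths), function(i)
    any(vapply(seq_along(paths), function(j)
      i != j && grepl(keys[i], keys[j], fixed = TRUE), logical(1))),
    logical(1))
  paths[keep]
}

#' @export
print.trajectory_graph <- function(x, ...) {
  cat(sprintf("trajectory graph: %d nodes, %d edges, %d validated triples, %d clusters\n",
              length(x$nodes), nrow(x$edges), nrow(x$triples),
              length(x$clusters)))
  invisible(x)
}

#' Trajectories leading to one cause of death
#'
#' Among exposed persons, selects phenotypes whose adjusted logistic
#' association with death from the given cause is Bonferroni-significant
#' with OR > 1, draws phenotype-to-death edges for them, and builds the
#' upstream pair/mediation structure restricted to the selected
#' phenotypes. The death cause appears as a sink node `death:<cause>`.
#'
#' @param dates,covars trajectory dataset over the candidate phenotypes.
#' @param deaths deaths table.
#' @param exposure exposure table (defines the population and row order of
#'   `dates`).
#' @param cause death-cause category.
#' @param min_cases minimum exposed deaths from the cause.
#' @param min_pairs pair-count threshold for the upstream structure.
#' @param alpha significance level per gate family.
#' @param n_boot mediation bootstrap resamples.
#' @param seed seed for the mediation bootstrap.
#' @return `trajectory_graph` whose edges include `<phenotype> -> death:<cause>`;
#'   empty graph (with attribute `skipped_reason`) when nothing passes.
#' @export
mortality_trajectories <- function(dates, covars, deaths, exposure, cause,
                                   min_cases = 20L, min_pairs = 10L,
                                   alpha = 0.05, n_boot = 1000L, seed = 1L) {
  didx <- match(exposure$person_id, deaths$person_id)
  y <- as.numeric(!is.na(didx) & deaths$cause_category[didx] == cause)
  if (sum(y) < min_cases)
    stop(sprintf("cause '%s' has fewer than %d exposed deaths", cause,
                 min_cases))
  phe <- colnames(dates)
  assoc <- data.frame(phenotype = phe, or = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  X0 <- cbind(1, d = 0, male = covars$male, age = covars$age_at_index)
  for (i in seq_along(phe)) {
    X <- X0; X[, "d"] <- as.numeric(!is.na(dates[, phe[i]]))
    if (all(X[, "d"] == 0) || all(X[, "d"] == 1)) next
    fit <- fast_logit(X, y, se = TRUE)
    b <- fit$coef["d"]; s <- fit$se[2]
    if (!fit$converged || !is.finite(b) || !is.finite(s) || abs(b) > 10)
      next
    assoc$or[i] <- exp(b)
    assoc$p[i] <- 2 * stats::pnorm(-abs(b / s))
  }
  m <- sum(!is.na(assoc$p))
  assoc$p_adjusted <- pmin(1, m * assoc$p)
  sel <- assoc$phenotype[!is.na(assoc$p_adjusted) &
                           assoc$p_adjusted < alpha & assoc$or > 1]
  sink <- paste0("death:", cause)
  if (!length(sel)) {
    g <- assemble_graph(
      pair_odds_ratio(binomial_direction_test(
        enumerate_pairs(dates[, character(0), drop = FALSE], min_pairs)),
        dates, covars),
      run_mediation(data.frame(d1 = character(0), d2 = character(0),
                               passed_or = logical(0)), dates, covars,
                    n_boot = 100L, seed = seed))
    attr(g, "skipped_reason") <- "no phenotype significantly associated"
    attr(g, "associations") <- assoc
    return(g)
  }
  sub <- dates[, sel, drop = FALSE]
  pairs <- pair_odds_ratio(
    binomial_direction_test(enumerate_pairs(sub, min_pairs), alpha),
    sub, covars, alpha)
  triples <- run_mediation(pairs, sub, covars, n_boot = n_boot,
                           alpha = alpha, seed = seed)
  g <- assemble_graph(pairs, triples)
  sink_edges <- data.frame(d1 = sel, d2 = sink,
                           n_both = vapply(sel, function(ph)
                             sum(!is.na(dates[, ph]) & y == 1), numeric(1)),
                           or_estimate = assoc$or[match(sel, assoc$phenotype)],
                           stringsAsFactors = FALSE)
  g$edges <- rbind(g$edges, sink_edges)
  g$nodes <- sort(unique(c(g$nodes, sel, sink)))
  attr(g, "associations") <- assoc
  g
}

#' Export a trajectory graph as Sankey-ready JSON
#'
#' Writes `{"nodes":[{"id":...}], "links":[{"source","target","n_both","or"}]}`.
#'
#' @param graph a `trajectory_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
graph_to_json <- function(graph, path) {
  obj <- list(
    nodes = lapply(graph$nodes, function(nd) list(id = nd)),
    links = lapply(seq_len(nrow(graph$edges)), function(i)
      list(source = graph$edges$d1[i], target = graph$edges$d2[i],
           n_both = graph$edges$n_both[i],
           or = graph$edges$or_estimate[i])),
    trajectories = graph$trajectories)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a trajectory graph in Graphviz DOT format
#' @inheritParams graph_to_json
#' @return `path`, invisibly.
#' @export
graph_to_dot <- function(graph, path) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph trajectories {",
             paste0("  ", q(graph$nodes), ";"),
             vapply(seq_len(nrow(graph$edges)), function(i)
               sprintf('  %s -> %s [label="n=%d"];',
                       q(graph$edges$d1[i]), q(graph$edges$d2[i]),
                       as.integer(graph$edges$n_both[i])), character(1)),
             "}")
  writeLines(lines, path)
  invisible(path)
}
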