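# Four-step trajectory construction: pair enumeration, binomial
# directionality, adjusted OR gate, mediation, graph assembly, and
# mortality trajectories.

# small deterministic date matrix helper
date_matrix <- function(spec, phenotypes) {
  # spec: list(person = c(code = days-since-2000, ...))
  D <- matrix(NA_real_, length(spec), length(phenotypes),
              dimnames = list(names(spec), phenotypes))
  for (p in names(spec))
    D[p, names(spec[[p]])] <- as.numeric(as.Date("2000-01-01")) + spec[[p]]
  D
}

test_that("pairs below ten co-diagnosed persons are not emitted", {
  spec <- stats::setNames(
    lapply(1:9, function(i) c(A = i, B = i + 10)),
    sprintf("P%d", 1:9))
  D <- date_matrix(spec, c("A", "B"))
  expect_equal(nrow(enumerate_pairs(D)), 0L)
  expect_equal(nrow(enumerate_pairs(D, min_pairs = 9L)), 2L)
})

test_that("pair ordering counts are symmetric between the two directions", {
  spec <- list(P1 = c(A = 1, B = 700), P2 = c(A = 5, B = 2),
               P3 = c(A = 3, B = 3), P4 = c(A = 1, B = 9))
  D <- date_matrix(spec, c("A", "B"))
  pr <- enumerate_pairs(D, min_pairs = 1L)
  ab <- pr[pr$d1 == "A", ]; ba <- pr[pr$d1 == "B", ]
  expect_equal(ab$n_d1_first, 2); expect_equal(ab$n_d2_first, 1)
  expect_equal(ab$n_same_day, 1)
  expect_equal(ab$n_d1_first, ba$n_d2_first)
  expect_equal(ab$n_both, 4)
  expect_equal(ab$n_d1_first + ab$n_d2_first + ab$n_same_day, ab$n_both)
})

test_that("pair counts equal the brute-force double loop on a 500-person fixture", {
  set.seed(14)
  phen <- c("244", "250.2", "427.21", "585.3")
  ids <- sprintf("P%03d", 1:500)
  D <- matrix(NA_real_, 500, 4, dimnames = list(ids, phen))
  for (j in 1:4) {
    has <- runif(500) < 0.4
    D[has, j] <- sample(1000:8000, sum(has), replace = TRUE)
  }
  pr <- enumerate_pairs(D, min_pairs = 1L)
  for (i in seq_len(nrow(pr))) {
    o <- oracle_pair_counts(D, pr$d1[i], pr$d2[i])
    expect_equal(unlist(pr[i, c("n_both", "n_d1_first", "n_d2_first",
                                "n_same_day")]),
                 o, ignore_attr = TRUE)
  }
})

test_that("binomial direction p-values follow the closed forms", {
  pr <- data.frame(d1 = c("A", "C", "E"), d2 = c("B", "D", "F"),
                   n_both = c(10, 20, 10),
                   n_d1_first = c(10, 18, 5), n_d2_first = c(0, 2, 5),
                   n_same_day = 0)
  out <- binomial_direction_test(pr)
  expect_equal(out$binom_p[1], 2^-10)
  expect_equal(out$binom_p[2], sum(choose(20, 18:20)) / 2^20)
  expect_gt(out$binom_p[3], 0.5)
  expect_false(out$passed_direction[3])
})

test_that("an unadjusted pair odds ratio equals the cross-product", {
  # 2x2 table: D1+/D2+ 30, D1+/D2- 20, D1-/D2+ 10, D1-/D2- 40 -> OR 6
  x1 <- rep(c(1, 1, 0, 0), c(30, 20, 10, 40))
  x2 <- rep(c(1, 0, 1, 0), c(30, 20, 10, 40))
  fit <- phetraj:::fast_logit(cbind(1, d1 = x1), x2, se = TRUE)
  expect_equal(exp(unname(fit$coef["d1"])), 6.0, tolerance = 1e-6)
})

test_that("the adjusted OR gate matches a hand-rolled logistic MLE", {
  set.seed(15)
  n <- 200
  covars <- data.frame(male = rbinom(n, 1, 0.25),
                       age_at_index = sample(45:75, n, TRUE))
  d1 <- rbinom(n, 1, 0.4)
  p2 <- plogis(-1 + 1.2 * d1 + 0.3 * covars$male)
  d2 <- rbinom(n, 1, p2)
  D <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("X", "Y")))
  D[d1 == 1, "X"] <- 1; D[d2 == 1, "Y"] <- 2
  pr <- data.frame(d1 = "X", d2 = "Y", n_both = sum(d1 & d2),
                   n_d1_first = sum(d1 & d2), n_d2_first = 0, n_same_day = 0)
  pr <- binomial_direction_test(pr)
  out <- pair_odds_ratio(pr, D, covars)
  X <- cbind(1, d1, covars$male, covars$age_at_index)
  oracle <- oracle_logit_mle(X, d2)
  expect_equal(log(out$or_estimate), oracle[2], tolerance = 1e-4)
})

test_that("independent diseases fail the OR gate", {
  set.seed(16)
  n <- 4000
  covars <- data.frame(male = rbinom(n, 1, 0.25),
                       age_at_index = sample(45:75, n, TRUE))
  D <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("X", "Y")))
  hx <- runif(n) < 0.3; hy <- runif(n) < 0.3
  D[hx, "X"] <- sample(1:2000, sum(hx), TRUE)
  D[hy, "Y"] <- sample(2001:4000, sum(hy), TRUE)
  pr <- enumerate_pairs(D, min_pairs = 10L)
  pr <- pair_odds_ratio(binomial_direction_test(pr), D, covars)
  done <- pr[pr$passed_direction, ]
  if (nrow(done))
    expect_true(all(done$or_ci_low <= 1 | !done$passed_or |
                      done$or_ci_high >= 1))
  expect_false(any(pr$passed_or & pr$or_ci_low > 1.5))
})

test_that("mediation is deterministic given a seed and finds a planted chain", {
  set.seed(18)
  n <- 10000
  covars <- data.frame(male = rbinom(n, 1, 0.25),
                       age_at_index = sample(45:75, n, TRUE))
  a <- 1.1; b <- 0.9
  x1 <- rbinom(n, 1, 0.35)
  x2 <- rbinom(n, 1, plogis(-1.5 + a * x1))
  x3 <- rbinom(n, 1, plogis(-1.8 + b * x2 + 0.3 * x1))
  D <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  D[x1 == 1, "A"] <- 1; D[x2 == 1, "B"] <- 2; D[x3 == 1, "C"] <- 3
  m1 <- mediation_test(D, covars, "A", "B", "C", n_boot = 200, seed = 5)
  m2 <- mediation_test(D, covars, "A", "B", "C", n_boot = 200, seed = 5)
  expect_identical(m1, m2)
  expect_true(m1$significant)
  # product-of-coefficients point estimate near the planted a*b
  se_guess <- abs(a * b) * 0.2
  expect_lt(abs(m1$indirect - a * b), 3 * se_guess)
  expect_warning(mediation_test(D, covars, "A", "B", "C", n_boot = 50,
                                seed = 1), "bootstrap")
})

test_that("a null mediator yields an indirect-effect CI covering zero", {
  set.seed(20)
  n <- 6000
  covars <- data.frame(male = rbinom(n, 1, 0.25),
                       age_at_index = sample(45:75, n, TRUE))
  x1 <- rbinom(n, 1, 0.35)
  x2 <- rbinom(n, 1, 0.25)                     # independent of x1
  x3 <- rbinom(n, 1, plogis(-1.5 + 0.8 * x2))
  D <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  D[x1 == 1, "A"] <- 1; D[x2 == 1, "B"] <- 2; D[x3 == 1, "C"] <- 3
  m <- mediation_test(D, covars, "A", "B", "C", n_boot = 300, seed = 2)
  expect_true(m$ci_low <= 0 && m$ci_high >= 0)
})

test_that("emitted edges are antisymmetric under reversal", {
  spec <- stats::setNames(lapply(1:30, function(i) {
    c(A = i, B = i + 50 + (i %% 3))
  }), sprintf("P%02d", 1:30))
  D <- date_matrix(spec, c("A", "B"))
  pr <- binomial_direction_test(enumerate_pairs(D, min_pairs = 10L))
  fwd <- pr[pr$d1 == "A", ]; rev <- pr[pr$d1 == "B", ]
  expect_true(fwd$passed_direction)
  expect_false(rev$passed_direction)
})

test_that("graph assembly links overlapping triples into longer chains", {
  pairs <- data.frame(
    d1 = c("A", "B", "C", "A", "B"), d2 = c("B", "C", "D", "C", "D"),
    n_both = 20, or_estimate = 3, passed_direction = TRUE,
    passed_or = TRUE, stringsAsFactors = FALSE)
  triples <- data.frame(
    d1 = c("A", "B"), d2 = c("B", "C"), d3 = c("C", "D"),
    indirect = 0.5, ci_low = 0.2, ci_high = 0.9,
    significant = TRUE, estimable = TRUE, stringsAsFactors = FALSE)
  g <- assemble_graph(pairs, triples, exposure_links = "A")
  expect_s3_class(g, "trajectory_graph")
  expect_true(list(c("A", "B", "C", "D")) %in% g$trajectories ||
                any(vapply(g$trajectories, identical,
                           logical(1), c("A", "B", "C", "D"))))
  expect_equal(length(g$clusters), 1L)
  expect_equal(g$clusters[[1]]$seeds, "A")
  # order invariance and idempotence
  g2 <- assemble_graph(pairs[sample(1:5), ], triples[2:1, ],
                       exposure_links = "A")
  expect_equal(g2$trajectories, g$trajectories)
  expect_equal(g2$edges[order(g2$edges$d1, g2$edges$d2), "d1"],
               g$edges[order(g$edges$d1, g$edges$d2), "d1"])
  # empty input gives an empty graph
  e <- assemble_graph(pairs[pairs$passed_or == FALSE, ], triples[0, ])
  expect_equal(length(e$nodes), 0L)
  expect_equal(nrow(e$edges), 0L)
})

test_that("graph exports parse as JSON and DOT", {
  td <- withr::local_tempdir()
  pairs <- data.frame(d1 = "A", d2 = "B", n_both = 15, or_estimate = 2.5,
                      passed_direction = TRUE, passed_or = TRUE,
                      stringsAsFactors = FALSE)
  triples <- data.frame(d1 = character(0), d2 = character(0),
                        d3 = character(0), indirect = numeric(0),
                        ci_low = numeric(0), ci_high = numeric(0),
                        significant = logical(0), estimable = logical(0))
  g <- assemble_graph(pairs, triples)
  graph_to_json(g, file.path(td, "g.json"))
  obj <- jsonlite::read_json(file.path(td, "g.json"))
  expect_equal(obj$links[[1]]$source, "A")
  graph_to_dot(g, file.path(td, "g.dot"))
  dot <- readLines(file.path(td, "g.dot"))
  expect_true(any(grepl("\"A\" -> \"B\"", dot)))
})

test_that("with no planted chains the edge count is alpha-consistent", {
  # equal base rates make the within-person ordering exchangeable, so the
  # directionality null holds exactly; the Bonferroni-gated expected
  # number of emitted edges per replicate is then at most about alpha
  n_reps <- 200
  edges <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- scenario_config(
      n_persons = 2000, exposure_prevalence = 1,
      phenotypes = data.frame(phecode = c("244", "250.2", "427.21"),
                              base_rate = 0.008, log_hr = 0),
      chains = data.frame(d1 = character(0), d2 = character(0),
                          log_hr = numeric(0)),
      death_causes = data.frame(cause = "other_causes", base_rate = 0.003,
                                log_hr = 0),
      death_links = data.frame(phecode = character(0),
                               cause = character(0), log_hr = numeric(0)),
      enrol_window = as.Date(c("1997-01-01", "2005-12-31")),
      seed = 80000 + r)
    coh <- generate_cohort(cfg)
    ev <- first_occurrences(coh$events)
    expo <- identify_exposure(ev, coh$deaths)
    traj <- trajectory_dataset(ev, expo, coh$persons,
                               c("244", "250.2", "427.21"))
    pr <- pair_odds_ratio(
      binomial_direction_test(enumerate_pairs(traj$dates)),
      traj$dates, traj$covars)
    edges[r] <- sum(pr$passed_or)
  }
  # direction gate alone bounds E[edges] by ~alpha; allow 3 SE of slack
  expect_lte(mean(edges), 0.05 + 3 * sqrt(0.05 / n_reps))
})

test_that("mortality trajectories attach only associated phenotypes to the sink", {
  set.seed(24)
  n <- 8000
  ids <- sprintf("P%05d", 1:n)
  covars <- data.frame(male = rbinom(n, 1, 0.25),
                       age_at_index = sample(45:75, n, TRUE))
  exposure <- data.frame(person_id = ids,
                         index_date = as.Date("2005-01-01"))
  has_a <- rbinom(n, 1, 0.3)                  # linked to death
  has_b <- rbinom(n, 1, 0.3)                  # independent of death
  died <- rbinom(n, 1, plogis(-3 + 1.2 * has_a))
  D <- matrix(NA_real_, n, 2, dimnames = list(ids, c("428.2", "530.11")))
  D[has_a == 1, 1] <- as.numeric(as.Date("2006-01-01"))
  D[has_b == 1, 2] <- as.numeric(as.Date("2007-01-01"))
  deaths <- data.frame(person_id = ids[died == 1],
                       death_date = as.Date("2015-01-01"),
                       cause_category = "cardiovascular",
                       stringsAsFactors = FALSE)
  g <- mortality_trajectories(D, covars, deaths, exposure,
                              "cardiovascular", min_cases = 20,
                              n_boot = 100, seed = 3)
  sink_edges <- g$edges[g$edges$d2 == "death:cardiovascular", ]
  expect_true("428.2" %in% sink_edges$d1)
  expect_false("530.11" %in% sink_edges$d1)
  expect_error(
    mortality_trajectories(D, covars, deaths[0, ], exposure,
                           "cardiovascular", min_cases = 20),
    "fewer than")
})
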