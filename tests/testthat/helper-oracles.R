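# Independent oracles used by the tests. These deliberately avoid the code
# paths (and, where possible, the libraries) they are checking.

# Stratified Cox partial log-likelihood with the Efron tie correction,
# written directly from the formula; maximised by coarse grid search plus
# golden-section refinement, never via survival::coxph.
oracle_strat_pl <- function(beta, records) {
  ll <- 0
  for (s in split(records, records$set_id)) {
    for (t in sort(unique(s$time[s$event == 1]))) {
      D <- which(s$event == 1 & s$time == t)
      R <- which(s$time >= t)
      d <- length(D)
      sr <- sum(exp(beta * s$exposed[R]))
      sd_ <- sum(exp(beta * s$exposed[D]))
      ll <- ll + beta * sum(s$exposed[D])
      for (l in seq_len(d) - 1)
        ll <- ll - log(sr - (l / d) * sd_)
    }
  }
  ll
}

oracle_strat_cox_beta <- function(records, lower = -8, upper = 8) {
  grid <- seq(lower, upper, by = 0.01)
  vals <- vapply(grid, oracle_strat_pl, numeric(1), records = records)
  b0 <- grid[which.max(vals)]
  stats::optimize(oracle_strat_pl, c(b0 - 0.02, b0 + 0.02),
                  records = records, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Exact one-sided binomial tail by direct pmf summation
oracle_binom_tail <- function(k, n) {
  if (n == 0) return(NA_real_)
  sum(choose(n, k:n)) / 2^n
}

# Hand-written logistic MLE by explicit Newton-Raphson on the score and
# Hessian written from the log-likelihood; independent of glm/glm.fit.
oracle_logit_mle <- function(X, y, tol = 1e-12, maxit = 100L) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    score <- crossprod(X, y - mu)
    H <- crossprod(X * (mu * (1 - mu)), X)
    step <- solve(H, score)
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# Naive greedy 1:k nearest-neighbour matching (O(cases x pool) scan),
# replicating the documented deterministic rules: seeded random case order,
# nearest available |logit difference|, ties toward the lower score then
# the lexicographically smaller person id, caliper on the logit scale.
oracle_greedy_match <- function(scores, exposure, pool, ratio, caliper_sd,
                                seed) {
  logit <- stats::qlogis(scores$score)
  names(logit) <- scores$person_id
  case_ids <- intersect(exposure$person_id, scores$person_id)
  pool_ids <- intersect(setdiff(pool, case_ids), scores$person_id)
  cal <- caliper_sd * stats::sd(logit[c(case_ids, pool_ids)])
  if (!is.finite(cal)) cal <- Inf
  set.seed(seed)
  case_ids <- sample(case_ids)
  avail <- stats::setNames(rep(TRUE, length(pool_ids)), pool_ids)
  out <- list()
  for (cid in case_ids) {
    picked <- character(0)
    for (r in seq_len(ratio)) {
      cand <- names(avail)[avail]
      if (!length(cand)) break
      d <- abs(logit[cand] - logit[cid])
      d <- d[d <= cal]
      if (!length(d)) break
      best <- names(d)[d == min(d)]
      if (length(best) > 1L) {
        sc <- logit[best]
        best <- best[sc == min(sc)]
        best <- sort(best)[1]
      } else best <- best[1]
      picked <- c(picked, best)
      avail[best] <- FALSE
    }
    if (length(picked))
      out[[cid]] <- data.frame(case = cid, control = picked,
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(out))
}

# brute-force first-occurrence reduction by explicit group minima
oracle_group_min <- function(events) {
  keys <- unique(events[, c("person_id", "code")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- events[events$person_id == keys$person_id[i] &
                    events$code == keys$code[i], , drop = FALSE]
    sub[which.min(sub$date)[1], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out[order(out$person_id, out$code), , drop = FALSE]
}

# brute-force ordered-pair counting by a double loop over persons
oracle_pair_counts <- function(dates, d1, d2) {
  n_both <- 0L; n_d1 <- 0L; n_d2 <- 0L; n_same <- 0L
  for (i in seq_len(nrow(dates))) {
    a <- dates[i, d1]; b <- dates[i, d2]
    if (is.na(a) || is.na(b)) next
    n_both <- n_both + 1L
    if (a < b) n_d1 <- n_d1 + 1L
    else if (b < a) n_d2 <- n_d2 + 1L
    else n_same <- n_same + 1L
  }
  c(n_both = n_both, n_d1_first = n_d1, n_d2_first = n_d2,
    n_same_day = n_same)
}
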