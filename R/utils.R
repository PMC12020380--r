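# Internal helpers: fixed category level sets, date arithmetic, piecewise
# exponential inversion, and a lean logistic fitter used in bootstrap loops.

DAYS_PER_YEAR <- 365.25

GENDER_LEVELS    <- c("female", "male")
REGION_LEVELS    <- c("england", "scotland", "wales")
EDUCATION_LEVELS <- c("degree", "a_level", "o_level", "other", "none")
SMOKING_LEVELS   <- c("current", "previous", "never")
ALCOHOL_LEVELS   <- c("frequent", "occasional", "never")
ACTIVITY_LEVELS  <- c("low", "moderate", "high")
SOURCE_LEVELS    <- c("inpatient", "self_report")
CODE_SYSTEMS     <- c("icd10", "phecode", "self_report")

# 16 system-level underlying-cause-of-death categories
DEATH_CAUSE_LEVELS <- c(
  "infectious_diseases", "malignant_neoplasms", "other_neoplasms",
  "blood_diseases", "endocrine_metabolic", "mental_behavioural",
  "nervous_system", "cardiovascular", "respiratory", "digestive",
  "skin_subcutaneous", "musculoskeletal", "genitourinary",
  "ill_defined", "external_causes", "other_causes")

MATCHING_COVARIATES <- c("birth_year", "gender", "bmi", "townsend",
                         "education", "smoking", "alcohol", "activity")

EXPOSURE_PHECODES <- c("242", "242.1", "242.2")

DEFAULT_CENSOR_DATES <- c(england  = "2022-10-31",
                          scotland = "2022-08-31",
                          wales    = "2022-05-31")

LANDMARK_BREAKS <- c(0, 2, 5, 10, Inf)

years_between <- function(later, earlier) {
  as.numeric(later - earlier) / DAYS_PER_YEAR
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample from a piecewise-exponential distribution by inverse CDF
#'
#' Given hazard-rate segments covering `[0, Inf)` and a uniform draw `u`,
#' returns the time `t` with survival `S(t) = u`, i.e. the inverse of the
#' cumulative hazard evaluated at `-log(u)`. With a single segment this
#' reduces to `-log(u) / rate`.
#'
#' @param breaks numeric vector of segment start times; must begin at 0 and
#'   be strictly increasing (segment `i` runs from `breaks[i]` to
#'   `breaks[i+1]`, the last to `Inf`).
#' @param rates positive hazard rates, one per segment.
#' @param u uniform draw(s) in (0, 1); vectorised.
#' @return sampled event time(s), same length as `u`.
#' @export
sample_piecewise_exponential <- function(breaks, rates, u) {
  if (length(breaks) != length(rates))
    stop("`breaks` and `rates` must have equal length")
  if (breaks[1] != 0)
    stop("segments must cover [0, Inf): first break must be 0")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("`breaks` must be strictly increasing")
  if (any(rates <= 0)) stop("all rates must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must lie in (0, 1)")
  k <- length(rates)
  target <- -log(u)
  # cumulative hazard at the END of each segment (last is Inf)
  widths <- diff(breaks)
  cumh <- c(0, cumsum(widths * rates[-k]))
  seg <- findInterval(target, cumh, rightmost.closed = FALSE)
  breaks[seg] + (target - cumh[seg]) / rates[seg]
}

# Vectorised piecewise-exponential inversion across persons.
# base: length-n baseline rates. cps: n x m matrix of changepoint times
# (Inf = never), mults: n x m multipliers applied to the hazard from the
# corresponding changepoint onward. u: length-n uniforms.
# Rows are sorted internally by repeated row-minimum extraction (m is small).
rpexp_changepoints <- function(u, base, cps, mults) {
  n <- length(u)
  target <- -log(u)
  if (is.null(cps) || ncol(cps) == 0L) return(target / base)
  m <- ncol(cps)
  # selection-sort the (cps, mults) pairs rowwise
  scp <- matrix(Inf, n, m)
  smu <- matrix(1, n, m)
  work <- cps
  for (j in seq_len(m)) {
    idx <- max.col(-work, ties.method = "first")
    pick <- cbind(seq_len(n), idx)
    scp[, j] <- work[pick]
    smu[, j] <- mults[pick]
    work[pick] <- Inf
  }
  # segment rates: base, then cumulative product of multipliers
  rates <- matrix(base, n, m + 1)
  acc <- rep(1, n)
  for (j in seq_len(m)) {
    acc <- acc * ifelse(is.finite(scp[, j]), smu[, j], 1)
    rates[, j + 1] <- base * acc
  }
  bks <- cbind(0, scp)                      # n x (m+1) segment starts
  widths <- scp - bks[, seq_len(m), drop = FALSE]
  widths[!is.finite(widths)] <- Inf
  cumh <- matrix(0, n, m + 1)               # cum hazard at segment starts
  for (j in seq_len(m)) {
    inc <- widths[, j] * rates[, j]
    inc[!is.finite(inc)] <- Inf
    cumh[, j + 1] <- cumh[, j] + inc
  }
  seg <- rowSums(target >= cumh) # in {1..m+1}; cumh[,1]=0 always counted
  pick <- cbind(seq_len(n), seg)
  bks[pick] + (target - cumh[pick]) / rates[pick]
}

# Minimal logistic regression on a model matrix; returns coefficients and,
# optionally, standard errors. Used in bootstrap loops where glm() overhead
# dominates.
fast_logit <- function(X, y, se = FALSE) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 50)))
  out <- list(coef = fit$coefficients, converged = fit$converged)
  if (se) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    out$se <- if (is.null(cov)) rep(NA_real_, ncol(X)) else sqrt(diag(cov))
  }
  out
}

# sort a data.frame into a canonical row order (used before writing/compare)
canonical_order <- function(df, cols) {
  df[do.call(order, c(unname(df[cols]), list(method = "radix"))), ,
     drop = FALSE]
}
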