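#' Two-stage clonal-expansion model parameters
#'
#' Container for the rate parameters of the two-stage clonal-expansion
#' (TSCE) carcinogenesis model: normal stem cells acquire a first hit at
#' Poisson rate `nu` per cell-year, the resulting initiated cells undergo a
#' birth-death process with division rate `alpha` and death rate `beta`, and
#' each initiated cell converts to a malignant cell at rate `mu` per
#' cell-year.  A deterministic lag `tau` (the tumour sojourn time) separates
#' the first malignant cell from clinical detection.  Birth-cohort trends in
#' incidence are modelled as a log-linear multiplier on the hazard with slope
#' `cohort_slope` per birth year relative to `ref_birth_year`.
#'
#' @param X normal stem-cell count (cells), non-negative.
#' @param nu initiation rate per cell-year.
#' @param alpha initiated-cell division rate per year.
#' @param beta initiated-cell death rate per year.
#' @param mu malignant transformation rate per initiated cell-year.
#' @param tau lag (sojourn) time in years between the first malignant cell
#'   and detection.
#' @param cohort_slope log-linear birth-trend coefficient per birth year.
#' @param ref_birth_year reference birth year at which the trend multiplier
#'   is exactly 1.
#' @return An object of class `tsce_params`.
#' @examples
#' p <- tsce_params(X = 1e7, nu = 1e-7, alpha = 9, beta = 8.7, mu = 1e-6,
#'                  tau = 9)
#' tsce_hazard(p, age = 60)
#' @export
tsce_params <- function(X, nu, alpha, beta, mu, tau = 0,
                        cohort_slope = 0, ref_birth_year = 1925) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    x
  }
  X <- num1(X, "X"); nu <- num1(nu, "nu"); alpha <- num1(alpha, "alpha")
  beta <- num1(beta, "beta"); mu <- num1(mu, "mu"); tau <- num1(tau, "tau")
  cohort_slope <- num1(cohort_slope, "cohort_slope")
  ref_birth_year <- num1(ref_birth_year, "ref_birth_year")
  if (X < 0 || nu < 0 || alpha < 0 || beta < 0 || mu < 0)
    stop("rates and cell counts must be non-negative", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  structure(list(X = X, nu = nu, alpha = alpha, beta = beta, mu = mu,
                 tau = tau, cohort_slope = cohort_slope,
                 ref_birth_year = ref_birth_year),
            class = "tsce_params")
}

#' @export
print.tsce_params <- function(x, ...) {
  cat("Two-stage clonal-expansion parameters:\n")
  cat(sprintf("  X = %.4g cells, nu = %.4g /cell-yr, alpha = %.4g /yr,\n",
              x$X, x$nu, x$alpha))
  cat(sprintf("  beta = %.4g /yr, mu = %.4g /cell-yr, tau = %.4g yr\n",
              x$beta, x$mu, x$tau))
  if (x$cohort_slope != 0)
    cat(sprintf("  birth trend: %.4g per year from %d\n",
                x$cohort_slope, round(x$ref_birth_year)))
  invisible(x)
}

# Probability phi(t) that a single initiated cell founded at time 0 has
# produced no malignant descendant by time t.  phi solves the Riccati
# equation phi' = alpha*phi^2 - (alpha+beta+mu)*phi + beta, phi(0) = 1, whose
# constant-coefficient solution is expressed through the roots r1 < 1 < r2 of
# alpha*z^2 - (alpha+beta+mu)*z + beta = 0.  Written with the decaying
# exponential only, so it is overflow-safe at any age.
.tsce_phi <- function(params, t) {
  a <- params$alpha; b <- params$beta; m <- params$mu
  if (m == 0) return(rep(1, length(t)))
  if (a == 0) {
    # no clonal expansion: each initiated cell dies (beta) or converts (mu)
    return(b / (b + m) + m / (b + m) * exp(-(b + m) * t))
  }
  s <- a + b + m
  disc <- s * s - 4 * a * b          # > 0 whenever mu > 0
  sq <- sqrt(disc)
  r1 <- (s - sq) / (2 * a)
  r2 <- (s + sq) / (2 * a)
  u0 <- (1 - r1) / (1 - r2)          # <= 0 since r1 < 1 < r2
  u <- u0 * exp(-a * (r2 - r1) * t)
  (r1 - r2 * u) / (1 - u)
}

#' Hazard of the two-stage clonal-expansion model
#'
#' Closed-form age-specific hazard of first detected malignancy,
#' \eqn{h(t) = \nu X (1 - \phi(t - \tau))} for \eqn{t \ge \tau} and 0 before,
#' where \eqn{\phi} is the probability that an initiated clone has produced
#' no malignant cell.  Equals \eqn{-d/dt \log S(t)} of the branching process
#' and agrees with numerical integration of the backward Riccati equation
#' (see [tsce_hazard_ode()]) and with the event-driven simulator
#' ([simulate_branching()]).
#'
#' @param params a [tsce_params()] object.
#' @param age vector of ages in years, all non-negative.
#' @return Hazard per person-year at each age; finite and non-negative.
#' @export
tsce_hazard <- function(params, age) {
  stopifnot(inherits(params, "tsce_params"))
  if (any(!is.finite(age)) || any(age < 0))
    stop("'age' must be finite and non-negative", call. = FALSE)
  t <- pmax(age - params$tau, 0)
  h <- params$nu * params$X * (1 - .tsce_phi(params, t))
  h[age < params$tau] <- 0
  if (any(!is.finite(h)))
    stop("non-finite hazard at age ", age[which(!is.finite(h))[1]],
         "; check parameter magnitudes", call. = FALSE)
  h
}

#' Hazard via numerical integration of the backward equation
#'
#' Cross-check for [tsce_hazard()]: integrates the Riccati equation for the
#' no-malignancy probability of an initiated clone with `deSolve::lsoda` at
#' tight tolerances and forms the same hazard.  Slower than the closed form;
#' intended for verification, not for MCMC.
#'
#' @inheritParams tsce_hazard
#' @param rtol,atol solver tolerances.
#' @return Hazard per person-year at each age.
#' @export
tsce_hazard_ode <- function(params, age, rtol = 1e-12, atol = 1e-14) {
  stopifnot(inherits(params, "tsce_params"))
  if (any(age < 0)) stop("'age' must be non-negative", call. = FALSE)
  t <- pmax(age - params$tau, 0)
  ord <- order(t)
  times <- unique(c(0, t[ord]))
  a <- params$alpha; b <- params$beta; m <- params$mu
  deriv <- function(tt, y, parms) {
    list(a * y[1]^2 - (a + b + m) * y[1] + b)
  }
  sol <- deSolve::lsoda(c(phi = 1), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  phi <- stats::approx(sol[, "time"], sol[, "phi"], xout = t)$y
  h <- params$nu * params$X * (1 - phi)
  h[age < params$tau] <- 0
  pmax(h, 0)
}

#' Birth-cohort adjusted hazard
#'
#' Multiplies the two-stage hazard by the log-linear birth-trend factor
#' `exp(cohort_slope * (birth_year - ref_birth_year))`.  With
#' `cohort_slope = 0` this reduces exactly to [tsce_hazard()].
#'
#' @inheritParams tsce_hazard
#' @param birth_year birth year(s), recycled against `age`.
#' @return Hazard per person-year.
#' @export
cohort_adjusted_hazard <- function(params, age, birth_year) {
  h <- tsce_hazard(params, age)
  h * exp(params$cohort_slope * (birth_year - params$ref_birth_year))
}

#' Poisson log-likelihood of an incidence table
#'
#' Sum over strata of the Poisson log-probability of the observed case count
#' with mean `person_years` times the cohort-adjusted hazard evaluated at the
#' age-bin midpoint (and birth-band midpoint for the trend factor).
#'
#' @param params a [tsce_params()] object.
#' @param table an incidence data frame with columns `age_lo`, `age_hi`,
#'   `cases`, `person_years` and optionally `birth_lo`, `birth_hi` (see
#'   [read_incidence()]).  An empty table gives log-likelihood 0.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(params, table) {
  table <- validate_incidence(table)
  if (nrow(table) == 0L) return(0)
  mid_age <- (table$age_lo + table$age_hi) / 2
  mid_by <- if (all(c("birth_lo", "birth_hi") %in% names(table)))
    (table$birth_lo + table$birth_hi) / 2 else params$ref_birth_year
  h <- cohort_adjusted_hazard(params, mid_age, mid_by)
  if (any(!is.finite(h)))
    stop("non-finite hazard in incidence bin ", which(!is.finite(h))[1],
         call. = FALSE)
  sum(stats::dpois(table$cases, lambda = table$person_years * h, log = TRUE))
}

validate_incidence <- function(table) {
  req <- c("age_lo", "age_hi", "cases", "person_years")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("incidence table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(table) == 0L) return(table)
  if (any(table$cases < 0) || any(table$cases != round(table$cases)))
    stop("'cases' must be non-negative integers", call. = FALSE)
  if (any(table$person_years <= 0))
    stop("'person_years' must be positive", call. = FALSE)
  if (any(table$age_hi <= table$age_lo))
    stop("age bins must satisfy age_lo < age_hi", call. = FALSE)
  table
}

#' Sojourn time implied by an exponential doubling time
#'
#' Converts a tumour volume doubling time into a sojourn time under
#' deterministic exponential growth from one cell to a clinically detectable
#' size: the growth rate is `r = ln(2) / (doubling_time_days / 365.25)` per
#' year and the sojourn is `ln(detection_size_cells) / r` years.
#'
#' @param doubling_time_days doubling time in days, positive.
#' @param detection_size_cells tumour size at detection in cells, at least 1.
#' @return Sojourn time in years.
#' @examples
#' sojourn_from_doubling(144, 1e8)  # about 10.5 years
#' sojourn_from_doubling(144, 1e9)  # about 11.8 years
#' @export
sojourn_from_doubling <- function(doubling_time_days, detection_size_cells) {
  if (any(doubling_time_days <= 0))
    stop("'doubling_time_days' must be positive", call. = FALSE)
  if (any(detection_size_cells < 1))
    stop("'detection_size_cells' must be >= 1", call. = FALSE)
  r <- log(2) / (doubling_time_days / 365.25)
  log(detection_size_cells) / r
}

#' Event-driven simulation of the two-stage branching process
#'
#' Exact Gillespie simulation of the carcinogenesis process for independent
#' subjects: initiations arrive as a Poisson process at rate `nu * X`; each
#' initiated clone evolves as a linear birth-death process (rates `alpha`,
#' `beta` per cell) in which every cell can convert to a malignant cell at
#' rate `mu`.  The returned age per subject is the time of the first
#' malignant conversion plus the lag `tau`, or `NA` if no malignancy occurred
#' before `horizon_years` (censoring).  Randomness flows through R's RNG, so
#' `set.seed()`-style seeding makes runs reproducible.
#'
#' Event counts scale with the clone size at which conversion typically
#' fires (about `1/mu` cells), so keep `mu` moderate for large simulations.
#'
#' @param params a [tsce_params()] object.
#' @param n_subjects number of independent subjects.
#' @param horizon_years follow-up horizon in years (applies to the
#'   conversion time before the lag is added).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_subjects`: detection ages, `NA` for
#'   censored subjects.
#' @export
simulate_branching <- function(params, n_subjects, horizon_years,
                               seed = NULL) {
  stopifnot(inherits(params, "tsce_params"))
  if (horizon_years <= 0) stop("'horizon_years' must be positive",
                               call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ages <- simulate_tsce_cpp(as.integer(n_subjects), params$nu * params$X,
                            params$alpha, params$beta, params$mu,
                            as.numeric(horizon_years))
  ifelse(is.na(ages), NA_real_, ages + params$tau)
}
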