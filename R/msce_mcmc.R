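#' MCMC calibration of the two-stage model to incidence data
#'
#' Random-walk Metropolis sampling of selected two-stage model parameters
#' against a registry-style incidence table under the Poisson likelihood of
#' [poisson_loglik()].  Rate parameters (`X`, `nu`, `alpha`, `beta`, `mu`)
#' are proposed on the log scale with log-uniform priors; `tau` and
#' `cohort_slope` are proposed on the natural scale with uniform priors.
#' Proposal scales are adapted towards a target acceptance rate during
#' burn-in only and frozen afterwards, so the post-burn-in chain satisfies
#' detailed balance.
#'
#' Only the combinations (`nu*X*mu`, `alpha - beta - mu`, `alpha*mu`) plus
#' `tau` are identifiable from incidence alone, so free parameters should be
#' chosen accordingly (e.g. free `nu` and `tau` with the clonal rates fixed
#' by convention).
#'
#' @param table incidence data frame (see [poisson_loglik()]).
#' @param init a [tsce_params()] object supplying starting values and the
#'   fixed values of non-free parameters.
#' @param free character vector naming the parameters to sample; subset of
#'   `c("X", "nu", "alpha", "beta", "mu", "tau", "cohort_slope")`.
#' @param priors named list of length-2 numeric vectors `c(lower, upper)`
#'   bounding each free parameter.  Defaults: six decades around the
#'   starting value (log-uniform) for rates, `c(0, 30)` years for `tau`,
#'   `c(-0.1, 0.1)` for `cohort_slope`.  A degenerate prior with
#'   `lower == upper` pins the parameter at that point.
#' @param n_cycles total Metropolis cycles (default 100000).
#' @param burn_in cycles discarded and used for proposal adaptation
#'   (default 4000).
#' @param seed optional integer seed; identical seeds give identical chains.
#' @param target_accept acceptance rate targeted during adaptation.
#' @return Object of class `tsce_fit`: a list with `summary` (one row per
#'   free parameter: posterior mean, 2.5/97.5 percentiles, effective sample
#'   size, split-chain R-hat), `chain` (post-burn-in draws), `accept_rate`,
#'   and the call configuration.
#' @export
fit_mcmc <- function(table, init, free = c("nu", "tau"), priors = list(),
                     n_cycles = 100000L, burn_in = 4000L, seed = NULL,
                     target_accept = 0.3) {
  stopifnot(inherits(init, "tsce_params"))
  table <- validate_incidence(table)
  all_names <- c("X", "nu", "alpha", "beta", "mu", "tau", "cohort_slope")
  if (!all(free %in% all_names))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, all_names), collapse = ", "), call. = FALSE)
  if (nrow(table) < length(free))
    stop("fewer incidence strata than free parameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  log_scale <- free %in% c("X", "nu", "alpha", "beta", "mu")
  cur_par <- unlist(init[free])

  # prior bounds on the sampling scale (log for rates)
  bounds <- lapply(seq_along(free), function(i) {
    nm <- free[i]
    b <- priors[[nm]]
    if (is.null(b)) {
      b <- if (nm == "tau") c(0, 30)
      else if (nm == "cohort_slope") c(-0.1, 0.1)
      else cur_par[i] * c(1e-3, 1e3)
    }
    if (length(b) != 2L || b[1] > b[2])
      stop("prior for '", nm, "' must be c(lower, upper)", call. = FALSE)
    b
  })
  theta <- ifelse(log_scale, log(pmax(cur_par, 1e-300)), cur_par)
  lo <- vapply(seq_along(free), function(i)
    if (log_scale[i]) log(max(bounds[[i]][1], 1e-300)) else bounds[[i]][1],
    numeric(1))
  hi <- vapply(seq_along(free), function(i)
    if (log_scale[i]) log(max(bounds[[i]][2], 1e-300)) else bounds[[i]][2],
    numeric(1))
  fixed_pt <- lo == hi
  theta <- pmin(pmax(theta, lo), hi)

  par_from_theta <- function(th) {
    p <- init
    vals <- ifelse(log_scale, exp(th), th)
    for (i in seq_along(free)) p[[free[i]]] <- vals[i]
    class(p) <- "tsce_params"
    p
  }
  loglik <- function(th) poisson_loglik(par_from_theta(th), table)

  cur_ll <- loglik(theta)
  if (!is.finite(cur_ll))
    stop("log-likelihood not finite at starting values", call. = FALSE)

  sd_prop <- ifelse(fixed_pt, 0, pmax((hi - lo) / 50, 1e-6))
  k <- length(free)
  draws <- matrix(NA_real_, nrow = n_cycles - burn_in, ncol = k,
                  dimnames = list(NULL, free))
  n_acc <- 0L
  window_acc <- 0L
  window_n <- 0L
  adapt_acc <- 0L
  adapt_block <- 50L
  burn_draws <- matrix(NA_real_, nrow = burn_in, ncol = k)
  prop_chol <- NULL  # covariance-informed proposal, learned in burn-in

  for (it in seq_len(n_cycles)) {
    prop <- if (is.null(prop_chol))
      theta + stats::rnorm(k, 0, sd_prop)
    else
      theta + drop(crossprod(prop_chol, stats::rnorm(k)))
    acc <- FALSE
    if (all(prop >= lo & prop <= hi)) {
      prop_ll <- loglik(prop)
      if (is.finite(prop_ll) &&
          log(stats::runif(1)) < prop_ll - cur_ll) {
        theta <- prop
        cur_ll <- prop_ll
        acc <- TRUE
      }
    } else {
      stats::runif(1)  # keep RNG stream length fixed per cycle
    }
    if (acc) { n_acc <- n_acc + 1L; window_acc <- window_acc + 1L
               adapt_acc <- adapt_acc + 1L }
    if (it > burn_in) {
      window_n <- window_n + 1L
      if (window_n == 1000L) {
        if (window_acc == 0L && !all(fixed_pt))
          stop("zero Metropolis acceptance over 1000 cycles; ",
               "rescale the proposal (target_accept) or revise priors",
               call. = FALSE)
        window_acc <- 0L; window_n <- 0L
      }
    }
    if (it <= burn_in) {
      burn_draws[it, ] <- theta
      if (it %% adapt_block == 0L) {
        rate <- adapt_acc / adapt_block
        fac <- exp(pmin(pmax(2 * (rate - target_accept), -0.7), 0.7))
        sd_prop <- ifelse(fixed_pt, 0, sd_prop * fac)
        adapt_acc <- 0L
      }
      if (it == burn_in && !any(fixed_pt) && burn_in >= 20L * k) {
        # freeze a covariance-informed proposal from the late burn-in
        late <- burn_draws[seq(ceiling(burn_in / 2), burn_in), ,
                           drop = FALSE]
        S <- stats::cov(late) * 2.38^2 / k
        diag(S) <- diag(S) + 1e-12
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(ch) && all(is.finite(ch))) prop_chol <- ch
      }
    }
    if (it > burn_in)
      draws[it - burn_in, ] <- ifelse(log_scale, exp(theta), theta)
  }

  summ <- do.call(rbind, lapply(seq_len(k), function(i) {
    x <- draws[, i]
    data.frame(parameter = free[i],
               mean = mean(x),
               q2.5 = stats::quantile(x, 0.025, names = FALSE),
               q97.5 = stats::quantile(x, 0.975, names = FALSE),
               ess = .ess(x),
               rhat_split = .split_rhat(x),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, chain = draws,
                 accept_rate = n_acc / n_cycles,
                 free = free, n_cycles = n_cycles, burn_in = burn_in),
            class = "tsce_fit")
}

#' @export
print.tsce_fit <- function(x, ...) {
  cat(sprintf("Two-stage model MCMC fit: %d cycles (%d burn-in), %.1f%% accepted\n",
              x$n_cycles, x$burn_in, 100 * x$accept_rate))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# effective sample size via initial positive autocorrelation sums
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  # truncate at first non-positive autocorrelation
  cut <- which(rho <= 0)[1]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

# split-chain potential scale reduction (Gelman-Rubin on chain halves)
.split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- list(x[seq_len(n)], x[(length(x) - n + 1L):length(x)])
  w <- mean(vapply(halves, stats::var, numeric(1)))
  if (w == 0) return(1)
  b <- n * stats::var(vapply(halves, mean, numeric(1)))
  sqrt(((n - 1) / n * w + b / n) / w)
}
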