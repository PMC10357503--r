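#' Expression matrix prefilter
#'
#' Removes genes that fail the expression thresholds — at most 0.5
#' expression units or raw counts below 6 in more than 93% of samples — and
#' genes in excluded classes (e.g. ribosomal RNA, Y-chromosomal and histone
#' genes, whose library representation is artefactual for poly-A data).
#'
#' @param mat numeric matrix, genes x samples, non-negative expression.
#' @param excluded_genes character vector of gene ids to drop regardless of
#'   expression.
#' @param min_expr expression floor (default 0.5): genes whose maximum
#'   value is at or below this are removed.
#' @param low_count count threshold (default 6) and
#' @param low_frac sample fraction (default 0.93): genes with values below
#'   `low_count` in more than `low_frac` of samples are removed.
#' @return Filtered matrix.
#' @export
expression_prefilter <- function(mat, excluded_genes = character(),
                                 min_expr = 0.5, low_count = 6,
                                 low_frac = 0.93) {
  if (nrow(mat) == 0L) return(mat)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (any(mat < 0)) stop("expression values must be non-negative",
                         call. = FALSE)
  low_expr <- apply(mat, 1, max) <= min_expr
  mostly_low <- rowMeans(mat < low_count) > low_frac
  excluded <- rownames(mat) %in% excluded_genes
  mat[!(low_expr | mostly_low | excluded), , drop = FALSE]
}

#' Fit a gamma-Gaussian mixture to a gene's nonzero expression
#'
#' Expectation-maximization fit of
#' \eqn{f(x) = \lambda \, \mathrm{Gamma}(\alpha, \beta) +
#' (1-\lambda) \, N(\mu, \sigma)} to the nonzero expression values of one
#' gene, where the gamma component captures samples with low expression and
#' the Gaussian component samples with high expression (enforced by seeding
#' the gamma component on the lowest 30% of values).  The proportion of
#' zeros `omega` is computed separately and is not part of the mixture.
#' The observed-data log-likelihood is non-decreasing over iterations.
#'
#' Because a high-shape gamma can mimic a Gaussian, the two-component fit
#' is weakly identifiable on unimodal data; after EM the fit is compared
#' against a single Gaussian by BIC and collapsed to `lambda = 0` (with
#' the single-Gaussian moments) when the mixture is not supported.  This
#' keeps stable genes from being assigned spurious mixing mass.
#'
#' @param values numeric vector of expression values for one gene (zeros
#'   allowed; the mixture is fitted on the nonzero part, which must have at
#'   least 10 elements).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param sigma_floor lower bound on the Gaussian standard deviation.
#' @return Object of class `gamma_gaussian_fit`: list with `alpha`, `beta`
#'   (gamma shape/rate), `mu`, `sigma`, `lambda` (gamma mixing proportion),
#'   `omega` (zero fraction of the full vector), `cv` (`sigma/mu`),
#'   `loglik`, `loglik_trace`, `converged`, `n_nonzero`.
#' @export
fit_gamma_gaussian <- function(values, max_iter = 200, tol = 1e-8,
                               sigma_floor = 1e-6) {
  if (any(values < 0)) stop("expression values must be non-negative",
                            call. = FALSE)
  omega <- mean(values == 0)
  x <- values[values > 0]
  n <- length(x)
  if (n < 10L)
    stop("need at least 10 nonzero values to fit the mixture",
         call. = FALSE)

  # degenerate: (near-)constant positive values
  if (stats::sd(x) < sigma_floor) {
    out <- list(alpha = NA_real_, beta = NA_real_, mu = mean(x),
                sigma = sigma_floor, lambda = 0, omega = omega,
                cv = sigma_floor / mean(x), loglik = NA_real_,
                loglik_trace = numeric(), converged = TRUE,
                n_nonzero = n)
    class(out) <- "gamma_gaussian_fit"
    return(out)
  }

  # initialization: gamma from the lowest 30%, Gaussian from the rest
  q <- stats::quantile(x, 0.3, names = FALSE)
  lowx <- x[x <= q]; highx <- x[x > q]
  if (length(lowx) < 2L) lowx <- sort(x)[1:2]
  lambda <- length(lowx) / n
  gam <- .gamma_mle(lowx, rep(1, length(lowx)))
  alpha <- gam$shape; beta <- gam$rate
  mu <- mean(highx); sigma <- max(stats::sd(highx), sigma_floor)
  if (!is.finite(sigma)) sigma <- sigma_floor

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- log(lambda) + stats::dgamma(x, shape = alpha, rate = beta,
                                      log = TRUE)
    ln <- log1p(-lambda) + stats::dnorm(x, mu, sigma, log = TRUE)
    m <- pmax(lg, ln)
    ll <- sum(m + log(exp(lg - m) + exp(ln - m)))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- 1 / (1 + exp(ln - lg))          # responsibility of gamma comp.
    w[lg == -Inf] <- 0
    sw <- sum(w)
    lambda <- min(max(sw / n, 1e-6), 1 - 1e-6)
    if (sw > 1e-8) {
      gam <- .gamma_mle(x, w)
      alpha <- gam$shape; beta <- gam$rate
    }
    sw2 <- n - sw
    if (sw2 > 1e-8) {
      mu <- sum((1 - w) * x) / sw2
      sigma <- max(sqrt(sum((1 - w) * (x - mu)^2) / sw2), sigma_floor)
    }
  }
  ll <- ll_trace[length(ll_trace)]
  # BIC guard against the unidentifiable high-shape-gamma solution: keep
  # the mixture only if it beats a single Gaussian by the 3-parameter
  # penalty
  mu0 <- mean(x)
  sd0 <- max(sqrt(mean((x - mu0)^2)), sigma_floor)
  ll0 <- sum(stats::dnorm(x, mu0, sd0, log = TRUE))
  collapsed <- (ll - ll0) < 1.5 * log(n)
  if (collapsed) {
    lambda <- 0; mu <- mu0; sigma <- sd0
    alpha <- NA_real_; beta <- NA_real_
  }
  out <- list(alpha = alpha, beta = beta, mu = mu, sigma = sigma,
              lambda = lambda, omega = omega, cv = sigma / mu,
              loglik = if (collapsed) ll0 else ll,
              loglik_trace = ll_trace, converged = converged || collapsed,
              collapsed = collapsed, n_nonzero = n)
  class(out) <- "gamma_gaussian_fit"
  out
}

# weighted gamma MLE: solve log(shape) - digamma(shape) = log(wm) - wlm
# by Newton iteration (exact M-step, keeping EM monotone)
.gamma_mle <- function(x, w) {
  sw <- sum(w)
  wm <- sum(w * x) / sw
  wlm <- sum(w * log(x)) / sw
  s <- log(wm) - wlm
  if (s <= 0) s <- 1e-8
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / fp
    new <- shape - step
    if (new <= 0) new <- shape / 2
    if (abs(new - shape) < 1e-12 * shape) { shape <- new; break }
    shape <- new
  }
  list(shape = shape, rate = shape / wm)
}

#' @export
print.gamma_gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "gamma-Gaussian fit (n=%d nonzero): lambda=%.3f, Gamma(%.3g, %.3g), N(%.3g, %.3g), omega=%.3f%s\n",
    x$n_nonzero, x$lambda, x$alpha, x$beta, x$mu, x$sigma, x$omega,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Stable-expression scores across genes
#'
#' Fits the gamma-Gaussian mixture per gene and scores each gene by the
#' percentile ranks of its mixing proportion `lambda`, coefficient of
#' variation `sigma/mu`, and zero fraction `omega` across genes:
#' `score = 1 - mean(rank_lambda, rank_cv, rank_omega)` with average-tie
#' percentile ranks `(rank - 0.5)/n`, so the highest-scoring genes have the
#' lowest mixing proportions, CVs and zero fractions.  Genes whose mixture
#' cannot be fitted (fewer than 10 nonzero samples) receive the worst rank
#' on all three metrics.
#'
#' @param mat numeric matrix, genes x samples (prefiltered; see
#'   [expression_prefilter()]).
#' @param ... passed to [fit_gamma_gaussian()].
#' @return Data frame per gene: `gene`, `score` in \[0, 1\], the three
#'   metrics and their percentile ranks; fits attached as attribute
#'   `"fits"`.
#' @export
seg_scores <- function(mat, ...) {
  genes <- rownames(mat)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  fits <- lapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    if (sum(v > 0) < 10L) return(NULL)
    fit_gamma_gaussian(v, ...)
  })
  get <- function(f, field, worst) if (is.null(f)) worst else f[[field]]
  lam <- vapply(fits, get, numeric(1), "lambda", Inf)
  cv <- vapply(fits, get, numeric(1), "cv", Inf)
  om <- vapply(seq_along(fits), function(i)
    if (is.null(fits[[i]])) Inf else fits[[i]]$omega, numeric(1))
  n <- length(lam)
  pr <- function(v) (rank(v, ties.method = "average") - 0.5) / n
  r_lam <- pr(lam); r_cv <- pr(cv); r_om <- pr(om)
  out <- data.frame(gene = genes,
                    score = 1 - (r_lam + r_cv + r_om) / 3,
                    lambda = lam, cv = cv, omega = om,
                    rank_lambda = r_lam, rank_cv = r_cv, rank_omega = r_om,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Tissue-specific stably expressed genes
#'
#' Genes stable in the target tissue but not in any background tissue:
#' `{g : target score > threshold}` minus the union over background tissues
#' of `{g : background score > threshold}`.
#'
#' @param target_scores data frame from [seg_scores()] for the target
#'   tissue (e.g. melanocytes).
#' @param background_scores list of [seg_scores()] data frames, one per
#'   background tissue.
#' @param threshold stability score threshold (default 0.69).
#' @return Character vector of gene ids.
#' @export
derive_tissue_specific_segs <- function(target_scores, background_scores,
                                        threshold = 0.69) {
  if (!length(background_scores))
    return(target_scores$gene[target_scores$score > threshold])
  for (b in background_scores) {
    if (!any(b$gene %in% target_scores$gene))
      stop("background score table shares no genes with the target ",
           "(disjoint gene universes)", call. = FALSE)
  }
  stable_t <- target_scores$gene[target_scores$score > threshold]
  stable_b <- unique(unlist(lapply(background_scores, function(b)
    b$gene[b$score > threshold])))
  setdiff(stable_t, stable_b)
}
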