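#' Log2 distances between adjacent covered CpGs
#'
#' Computes `log2(pos[i+1] - pos[i])` for every pair of adjacent records on
#' the same chromosome. Enrichment protocols cover CpGs in clusters, so this
#' sample is bimodal on the log2 scale: a small-gap mode of within-cluster
#' ("regional") distances and a large-gap mode of between-cluster
#' ("boundary") distances. When CpGs are reported per strand, the reverse
#' complement of each CpG sits 1 bp away on the opposite strand and produces
#' a spike at log2 distance 0; these 1-bp gaps carry no information about
#' region boundaries and are removed before fitting (gaps of 0 bp, possible
#' only for same-position records on opposite strands, are discarded with
#' them).
#'
#' @param cpgs a [cpg_table].
#' @param min_gaps minimum number of retained gap values required (default
#'   500); below this the mixture fit is unreliable and an error is raised.
#' @return An object of class `gap_sample`: list with `values` (retained
#'   log2 distances) and `n_removed_spike`.
#' @export
compute_gap_sample <- function(cpgs, min_gaps = 500L) {
  n <- nrow(cpgs)
  if (n < 2L) stop("insufficient gap sample: need >= 2 CpGs")
  d <- diff(cpgs$pos)
  same <- cpgs$chrom[-1L] == cpgs$chrom[-n]
  gaps <- d[same]
  if (!length(gaps)) stop("insufficient gap sample: no same-chromosome pairs")
  spike <- gaps <= 1L
  values <- log2(gaps[!spike])
  if (length(values) < min_gaps) {
    stop("insufficient gap sample: ", length(values),
         " retained values (< ", min_gaps, ")")
  }
  structure(list(values = values, n_removed_spike = sum(spike)),
            class = "gap_sample")
}

as_gap_values <- function(sample) {
  if (inherits(sample, "gap_sample")) sample$values else as.numeric(sample)
}

#' Fit a two-component normal mixture by EM
#'
#' Standard univariate Gaussian-mixture expectation maximisation on the
#' log2 adjacent-CpG distances. Initialisation is deterministic: the sample
#' is split at its median and component moments are taken from each half,
#' which avoids seed-dependent label flips. Components are relabelled after
#' convergence so that `mu1 < mu2`; component 1 then describes regional
#' (within-cluster) distances, component 2 boundary distances.
#'
#' @param sample a `gap_sample` or numeric vector of log2 distances.
#' @param tol convergence tolerance on the relative change in observed-data
#'   log-likelihood between iterations (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @return An object of class `mixture_fit`: list with `lambda`, `mu`,
#'   `sigma` (length-2 each, component 1 first), `loglik`, `n_iter`,
#'   `converged`.
#' @export
fit_bimodal_em <- function(sample, tol = 1e-8, max_iter = 1000L) {
  x <- as_gap_values(sample)
  n <- length(x)
  if (n < 10L) stop("insufficient gap sample for mixture fit")
  if (stats::sd(x) < 1e-8) stop("constant-valued sample")
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  mu <- c(mean(lo), mean(hi))
  sigma <- pmax(c(stats::sd(lo), stats::sd(hi)), 0.05, na.rm = TRUE)
  lambda <- c(0.5, 0.5)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step in log space for numerical stability
    l1 <- log(lambda[1]) + stats::dnorm(x, mu[1], sigma[1], log = TRUE)
    l2 <- log(lambda[2]) + stats::dnorm(x, mu[2], sigma[2], log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(lse)
    g1 <- exp(l1 - lse)
    # M step
    w1 <- sum(g1); w2 <- n - w1
    if (w1 < 1e-8 || w2 < 1e-8) stop("degenerate mixture: empty component")
    mu_new <- c(sum(g1 * x) / w1, sum((1 - g1) * x) / w2)
    sigma_new <- sqrt(c(sum(g1 * (x - mu_new[1])^2) / w1,
                        sum((1 - g1) * (x - mu_new[2])^2) / w2))
    lambda_new <- c(w1, w2) / n
    if (any(sigma_new < 1e-6) || any(lambda_new < 1e-4)) {
      stop("degenerate mixture: collapsed component (sigma < 1e-6 or lambda < 1e-4)")
    }
    mu <- mu_new; sigma <- sigma_new; lambda <- lambda_new
    if (is.finite(loglik) && abs(ll - loglik) < tol * (abs(ll) + 1)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sigma <- rev(sigma); lambda <- rev(lambda)
  }
  structure(
    list(lambda = lambda, mu = mu, sigma = sigma, loglik = loglik,
         n_iter = iter, converged = converged),
    class = "mixture_fit"
  )
}

#' Construct a mixture fit from known parameters
#'
#' Useful for testing and for re-using a previously fitted model.
#'
#' @param lambda1 mixing proportion of the first (regional) component.
#' @param mu1,sigma1 first-component mean and standard deviation (log2 bp).
#' @param mu2,sigma2 second-component parameters; requires `mu1 < mu2`.
#' @return A `mixture_fit`.
#' @export
mixture_fit <- function(lambda1, mu1, sigma1, mu2, sigma2) {
  stopifnot(lambda1 > 0, lambda1 < 1, sigma1 > 0, sigma2 > 0, mu1 < mu2)
  structure(
    list(lambda = c(lambda1, 1 - lambda1), mu = c(mu1, mu2),
         sigma = c(sigma1, sigma2), loglik = NA_real_, n_iter = 0L,
         converged = TRUE),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component normal mixture fit\n")
  cat(sprintf("  component 1 (regional): lambda = %.4f, mu = %.4f, sigma = %.4f\n",
              x$lambda[1], x$mu[1], x$sigma[1]))
  cat(sprintf("  component 2 (boundary): lambda = %.4f, mu = %.4f, sigma = %.4f\n",
              x$lambda[2], x$mu[2], x$sigma[2]))
  if (is.finite(x$loglik)) {
    cat(sprintf("  loglik = %.3f after %d iterations (converged: %s)\n",
                x$loglik, x$n_iter, x$converged))
  }
  invisible(x)
}

#' Weighted misclassification cost of a separation point
#'
#' For a candidate log2-distance cutoff `x`, the cost is the
#' mixing-proportion-weighted probability of misclassifying a distance:
#' regional distances falling at or above the cutoff plus boundary distances
#' falling at or below it,
#' `C(x) = lambda1 * P1(X >= x) + lambda2 * P2(X <= x)`.
#' Weighting by the mixing proportions penalises the two populations by
#' their actual abundance: in enrichment data the regional component
#' dominates, so an unweighted rule would place the cutoff too low.
#'
#' @param x log2 distance(s); vectorised.
#' @param fit a `mixture_fit`.
#' @return Cost value(s) in \[0, 1\].
#' @export
mixture_cost <- function(x, fit) {
  fit$lambda[1] * stats::pnorm(x, fit$mu[1], fit$sigma[1], lower.tail = FALSE) +
    fit$lambda[2] * stats::pnorm(x, fit$mu[2], fit$sigma[2])
}

# derivative of the cost: C'(x) = -lambda1 f1(x) + lambda2 f2(x)
mixture_cost_deriv <- function(x, fit) {
  -fit$lambda[1] * stats::dnorm(x, fit$mu[1], fit$sigma[1]) +
    fit$lambda[2] * stats::dnorm(x, fit$mu[2], fit$sigma[2])
}

#' Optimise the region-boundary distance cutoff
#'
#' Minimises the weighted misclassification cost over the observed range of
#' log2 distances using successive parabolic interpolation
#' ([stats::optimize()]), then polishes the minimiser with a few Newton
#' steps on the stationarity condition
#' `lambda1 * f1(x) = lambda2 * f2(x)` (the weighted component densities
#' cross at the optimum). The base-pair cutoff is `D = round(2^x_hat)`,
#' floored at 2 bp.
#'
#' @param fit a `mixture_fit`.
#' @param sample `gap_sample` or numeric vector defining the search
#'   interval (its observed range after spike removal).
#' @param tol optimiser tolerance on `x` (default 1e-6).
#' @return An object of class `cutoff_result`: list with `x_hat`, `D`,
#'   `cost_at_min`, `interior` (logical: whether the minimum is interior to
#'   the search interval) and `fit`.
#' @export
optimize_cutoff <- function(fit, sample, tol = 1e-6) {
  values <- as_gap_values(sample)
  if (!length(values)) stop("empty gap sample")
  interval <- range(values)
  opt <- stats::optimize(mixture_cost, interval, fit = fit, tol = tol)
  x_hat <- opt$minimum
  # Newton polish on C'(x) = 0; C''(x) from the component density derivatives
  for (i in 1:12) {
    d1 <- mixture_cost_deriv(x_hat, fit)
    d2 <- fit$lambda[1] * stats::dnorm(x_hat, fit$mu[1], fit$sigma[1]) *
            (x_hat - fit$mu[1]) / fit$sigma[1]^2 -
          fit$lambda[2] * stats::dnorm(x_hat, fit$mu[2], fit$sigma[2]) *
            (x_hat - fit$mu[2]) / fit$sigma[2]^2
    if (!is.finite(d1) || !is.finite(d2) || d2 <= 0) break
    step <- d1 / d2
    cand <- x_hat - step
    if (cand < interval[1] || cand > interval[2]) break
    x_hat <- cand
    if (abs(step) < 1e-12) break
  }
  if (mixture_cost(x_hat, fit) > opt$objective) x_hat <- opt$minimum
  width <- diff(interval)
  interior <- x_hat > interval[1] + 1e-6 * width &&
              x_hat < interval[2] - 1e-6 * width
  if (!interior) {
    warning("no interior minimum; mixture components may not separate")
  }
  structure(
    list(x_hat = x_hat, D = max(2L, as.integer(round(2^x_hat))),
         cost_at_min = mixture_cost(x_hat, fit), interior = interior,
         fit = fit),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Empirical region-boundary cutoff: %d bp (log2 = %.4f, cost = %.5f)\n",
              x$D, x$x_hat, x$cost_at_min))
  if (!x$interior) cat("  [warning] minimum at search-interval endpoint\n")
  invisible(x)
}

#' Diagnostic plot of the gap mixture fit and cost curve
#'
#' Draws the histogram of retained log2 adjacent-CpG distances, the two
#' fitted weighted component densities, the combined mixture density, the
#' misclassification cost curve (rescaled), and the optimised cutoff.
#'
#' @param sample a `gap_sample`.
#' @param cutoff a `cutoff_result`.
#' @param ... passed to [graphics::hist()].
#' @return `NULL`, invisibly.
#' @export
plot_gap_fit <- function(sample, cutoff, ...) {
  x <- as_gap_values(sample)
  fit <- cutoff$fit
  h <- graphics::hist(x, breaks = 80, freq = FALSE,
                      main = "Adjacent-CpG log2 distance mixture",
                      xlab = "log2 distance (bp)", border = "grey70", ...)
  xs <- seq(min(x), max(x), length.out = 400)
  graphics::lines(xs, fit$lambda[1] * stats::dnorm(xs, fit$mu[1], fit$sigma[1]),
                  col = "firebrick", lwd = 2)
  graphics::lines(xs, fit$lambda[2] * stats::dnorm(xs, fit$mu[2], fit$sigma[2]),
                  col = "forestgreen", lwd = 2)
  cost <- mixture_cost(xs, fit)
  graphics::lines(xs, cost / max(cost) * max(h$density), col = "steelblue",
                  lwd = 2, lty = 2)
  graphics::abline(v = cutoff$x_hat, col = "red", lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("firebrick", "forestgreen", "steelblue", "red"),
                   lty = c(1, 1, 2, 1),
                   legend = c("regional component", "boundary component",
                              "cost (rescaled)", "optimised cutoff"))
  invisible(NULL)
}
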