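#' Estimate binned spatial autocorrelation of per-CpG signal
#'
#' Per-site differential-methylation signals are spatially autocorrelated:
#' neighbouring CpGs tend to change together, so naively combining their
#' p-values overstates significance. To quantify this, each chromosome is
#' partitioned into consecutive `bin_size`-bp bins, the bin value is the
#' mean of the chosen source quantity over the CpGs in the bin (p-values
#' are probit-transformed to `z = qnorm(1 - p)` before averaging), and
#' `rho[lag]` is the Pearson correlation between values of bin pairs
#' exactly `lag` bins apart on the same chromosome. Lags with fewer than 3
#' pairs, or with a constant series, get `rho = 0` with a warning.
#'
#' @param cpgs a [cpg_table].
#' @param bin_size spatial bin width in bp (default 100).
#' @param max_lag largest lag, in bins, to estimate (default 10);
#'   correlations beyond it are taken as 0.
#' @param source `"pvalue"` (probit scale; the default used in the
#'   dependence adjustment) or `"meth_diff"` (diagnostic).
#' @return An object of class `acf_estimate`: list with `bin_size`,
#'   `max_lag`, `rho` (length `max_lag + 1`, `rho[1]` is lag 0 and equals
#'   1), `n_pairs`, `source`.
#' @export
estimate_acf <- function(cpgs, bin_size = 100L, max_lag = 10L,
                         source = c("pvalue", "meth_diff")) {
  source <- match.arg(source)
  if (nrow(cpgs) == 0L) stop("no CpGs")
  stopifnot(bin_size >= 1, max_lag >= 1)
  v <- if (source == "pvalue") {
    stats::qnorm(pmin(pmax(cpgs$pvalue, 1e-15), 1 - 1e-15), lower.tail = FALSE)
  } else {
    cpgs$meth_diff
  }
  bi <- (cpgs$pos - 1L) %/% as.integer(bin_size)
  n <- nrow(cpgs)
  # cpgs are sorted, so occupied (chrom, bin) runs are consecutive rows
  new_bin <- c(TRUE, cpgs$chrom[-1L] != cpgs$chrom[-n] | bi[-1L] != bi[-n])
  grp <- cumsum(new_bin)
  first <- which(new_bin)
  bin_chrom <- cpgs$chrom[first]
  bin_index <- bi[first]
  bin_value <- as.vector(rowsum(v, grp)) / tabulate(grp)
  if (length(bin_value) < 2L) stop("need >= 2 non-empty bins")
  key <- paste(bin_chrom, bin_index, sep = "\r")
  rho <- c(1, numeric(max_lag))
  n_pairs <- c(length(bin_value), integer(max_lag))
  warned <- FALSE
  for (lag in seq_len(max_lag)) {
    j <- match(paste(bin_chrom, bin_index + lag, sep = "\r"), key)
    ok <- !is.na(j)
    a <- bin_value[ok]; b <- bin_value[j[ok]]
    n_pairs[lag + 1L] <- length(a)
    if (length(a) >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0) {
      rho[lag + 1L] <- stats::cor(a, b)
    } else {
      warned <- TRUE
    }
  }
  if (warned) {
    warning("undefined autocorrelation at one or more lags; set to 0")
  }
  structure(
    list(bin_size = as.integer(bin_size), max_lag = as.integer(max_lag),
         rho = rho, n_pairs = n_pairs, source = source),
    class = "acf_estimate"
  )
}

# rho at integer lag(s); 1 at lag 0, 0 beyond max_lag
acf_rho <- function(acf, lag) {
  out <- numeric(length(lag))
  inside <- lag >= 0 & lag <= acf$max_lag
  out[inside] <- acf$rho[lag[inside] + 1L]
  out
}

#' Map a binned ACF onto member-CpG pairs of a region
#'
#' Builds the k-by-k correlation matrix used by the dependence-adjusted
#' combination: unit diagonal, and for two member CpGs at distance `d` bp,
#' `sigma_ij = rho[ceiling(d / bin_size)]` (0 beyond the estimated maximum
#' lag). An ACF-derived matrix is not guaranteed positive semidefinite; if
#' its smallest eigenvalue is negative the spectrum is floored at 0 and the
#' matrix reconstructed.
#'
#' @param positions member-CpG positions (bp) of one region.
#' @param acf an `acf_estimate`.
#' @return A k-by-k symmetric matrix.
#' @export
region_correlation_matrix <- function(positions, acf) {
  k <- length(positions)
  if (k == 1L) return(matrix(1, 1, 1))
  d <- abs(outer(positions, positions, "-"))
  lag <- ceiling(d / acf$bin_size)
  sigma <- matrix(acf_rho(acf, as.vector(lag)), k, k)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    sigma <- (sigma + t(sigma)) / 2
  }
  sigma
}

#' Dependence-adjusted Stouffer-Liptak combination of p-values
#'
#' Transforms each p-value to a probit z-score, `z_i = qnorm(1 - p_i)`
#' (p clamped to \[1e-15, 1 - 1e-15\] to keep z finite), and combines them
#' as `T = sum(z) / sqrt(sum(sigma))`, where `sigma` is the correlation
#' matrix of the tests; the combined p-value is `1 - pnorm(T)`. With the
#' identity matrix this is the classical Stouffer combination; positive
#' correlations inflate the denominator and make the combination
#' appropriately conservative.
#'
#' @param pvalues p-values in \[0, 1\], length k >= 1.
#' @param corr k-by-k symmetric correlation matrix with unit diagonal;
#'   identity if omitted.
#' @return Combined p-value in (0, 1).
#' @export
stouffer_liptak <- function(pvalues, corr = NULL) {
  k <- length(pvalues)
  if (k < 1L) stop("need at least one p-value")
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(corr)) corr <- diag(k)
  if (!is.matrix(corr) || nrow(corr) != k || ncol(corr) != k) {
    stop("corr must be a ", k, "x", k, " matrix")
  }
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric")
  denom <- sum(corr)
  if (denom <= 0) stop("degenerate correlation: sum(corr) <= 0")
  p <- pmin(pmax(pvalues, 1e-15), 1 - 1e-15)
  z <- stats::qnorm(p, lower.tail = FALSE)
  stats::pnorm(sum(z) / sqrt(denom), lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR q-values, `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1,
#' returned in the original order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Combine member-CpG p-values into region-level significance
#'
#' For each region the member p-values (all members by default, or only the
#' DMCs) are combined by the dependence-adjusted Stouffer-Liptak statistic
#' using the binned ACF, and the combined p-values are FDR-corrected across
#' the region set.
#'
#' @param regions a filtered `region_table` (see [filter_regions()]).
#' @param cpgs the [cpg_table] the regions were segmented from.
#' @param acf an `acf_estimate` (source `"pvalue"`).
#' @param combine `"all"` (default) combines every member CpG's p-value;
#'   `"dmc-only"` restricts to members passing the DMC thresholds.
#' @param dmc_qvalue,dmc_diff DMC thresholds, used only for `"dmc-only"`.
#' @return `regions` with `p_combined` and `q_value` columns added; rows
#'   with no eligible member p-values (possible only under `"dmc-only"`
#'   with inconsistent thresholds) get `p_combined = NA`.
#' @export
combine_region_pvalues <- function(regions, cpgs, acf,
                                   combine = c("all", "dmc-only"),
                                   dmc_qvalue = 0.01, dmc_diff = 25) {
  combine <- match.arg(combine)
  n <- nrow(regions)
  p_combined <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rows <- regions$first_row[i]:regions$last_row[i]
    if (combine == "dmc-only") {
      keep <- cpgs$qvalue[rows] < dmc_qvalue &
              abs(cpgs$meth_diff[rows]) >= dmc_diff
      rows <- rows[keep]
      if (!length(rows)) next
    }
    sigma <- region_correlation_matrix(cpgs$pos[rows], acf)
    p_combined[i] <- stouffer_liptak(cpgs$pvalue[rows], sigma)
  }
  regions$p_combined <- p_combined
  regions$q_value <- bh_fdr(p_combined)
  regions
}
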