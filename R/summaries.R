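#' Descriptive statistics for a set of called DMRs
#'
#' @param dmrs DMR data frame (e.g. from [call_dmrs()]).
#' @return An object of class `dmr_summary`: list with `n_dmrs`, `n_hyper`,
#'   `n_hypo`, and quantiles (min/quartiles/max) of region length in bp
#'   (`end - start + 1`), mean methylation difference, and DMCs per DMR.
#'   An empty input gives `n_dmrs = 0` with `NA` quantiles.
#' @export
summarize_dmrs <- function(dmrs) {
  q5 <- function(x) {
    if (!length(x)) {
      return(stats::setNames(rep(NA_real_, 5L),
                             c("0%", "25%", "50%", "75%", "100%")))
    }
    stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1))
  }
  n <- nrow(dmrs)
  lengths <- if (n) dmrs$end - dmrs$start + 1L else integer(0)
  out <- list(
    n_dmrs = n,
    n_hyper = if (n) sum(dmrs$mean_diff > 0) else 0L,
    n_hypo = if (n) sum(dmrs$mean_diff <= 0) else 0L,
    length_quantiles = q5(lengths),
    mean_diff_quantiles = q5(if (n) dmrs$mean_diff else numeric(0)),
    dmcs_per_dmr_quantiles = q5(if (n && !is.null(dmrs$dmc_count))
      dmrs$dmc_count else numeric(0))
  )
  class(out) <- "dmr_summary"
  out
}

#' @export
print.dmr_summary <- function(x, ...) {
  cat(sprintf("DMRs: %d (%d hypermethylated, %d hypomethylated)\n",
              x$n_dmrs, x$n_hyper, x$n_hypo))
  if (x$n_dmrs > 0L) {
    cat("length (bp):      ", paste(format(x$length_quantiles), collapse = "  "), "\n")
    cat("mean diff (pp):   ", paste(format(round(x$mean_diff_quantiles, 2)), collapse = "  "), "\n")
    cat("DMCs per DMR:     ", paste(format(x$dmcs_per_dmr_quantiles), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Compare DMR length distributions between two call sets
#'
#' Two-sample Kolmogorov-Smirnov test on the region length vectors, e.g.
#' for contrasting DMR geometry between disease subtypes.
#'
#' @param a,b DMR data frames, both non-empty.
#' @return List with `statistic` (KS D) and `p_value`.
#' @export
compare_length_distributions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both DMR sets must be non-empty")
  la <- a$end - a$start + 1L
  lb <- b$end - b$start + 1L
  ks <- suppressWarnings(stats::ks.test(la, lb))
  list(statistic = unname(ks$statistic), p_value = unname(ks$p.value))
}
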