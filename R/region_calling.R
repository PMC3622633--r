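#' Segment CpGs into candidate regions at a distance cutoff
#'
#' Scans the sorted CpG table and starts a new region whenever the distance
#' to the previous CpG on the same chromosome is strictly greater than `D`
#' bp (a gap exactly equal to `D` keeps the run together), or at a
#' chromosome change. Every CpG belongs to exactly one region; singleton
#' regions are legal here and are removed later by [filter_regions()].
#'
#' @param cpgs a [cpg_table] (sorted by chrom, pos).
#' @param D base-pair distance cutoff (>= 1), typically from
#'   [optimize_cutoff()].
#' @return A data frame of class `region_table`, ordered by `(chrom,
#'   start)`, with columns `region_id`, `chrom`, `start`, `end` (positions
#'   of the first and last member CpG), `cpg_count`, `mean_diff`
#'   (unweighted arithmetic mean of member `meth_diff`), `direction`
#'   (`"hyper"` iff `mean_diff > 0`), and bookkeeping columns `first_row`,
#'   `last_row` indexing member rows of `cpgs`.
#' @export
segment_regions <- function(cpgs, D) {
  stopifnot(D >= 1)
  n <- nrow(cpgs)
  new_region <- c(TRUE, cpgs$chrom[-1L] != cpgs$chrom[-n] |
                        diff(cpgs$pos) > D)
  id <- cumsum(new_region)
  first <- which(new_region)
  last <- c(first[-1L] - 1L, n)
  counts <- (last - first) + 1L
  mean_diff <- as.vector(rowsum(cpgs$meth_diff, id)) / counts
  out <- data.frame(
    region_id = seq_along(first),
    chrom = cpgs$chrom[first],
    start = cpgs$pos[first],
    end = cpgs$pos[last],
    cpg_count = counts,
    mean_diff = mean_diff,
    direction = ifelse(mean_diff > 0, "hyper", "hypo"),
    first_row = first,
    last_row = last,
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_table", "data.frame")
  out
}

#' Count differentially methylated cytosines per region
#'
#' A member CpG is a DMC when `qvalue < dmc_qvalue` and `|meth_diff| >=
#' dmc_diff`. The defaults (q < 0.01, |difference| >= 25 percentage points)
#' follow common practice for per-site differential calls from upstream
#' tools; both are adjustable.
#'
#' @param regions a `region_table` from [segment_regions()].
#' @param cpgs the [cpg_table] the regions were segmented from.
#' @param dmc_qvalue,dmc_diff DMC thresholds.
#' @return `regions` with a `dmc_count` column added.
#' @export
count_dmcs <- function(regions, cpgs, dmc_qvalue = 0.01, dmc_diff = 25) {
  rows <- sequence(regions$cpg_count, from = regions$first_row)
  is_dmc <- cpgs$qvalue[rows] < dmc_qvalue &
            abs(cpgs$meth_diff[rows]) >= dmc_diff
  id <- rep.int(seq_len(nrow(regions)), regions$cpg_count)
  counts <- as.vector(rowsum(as.numeric(is_dmc), id))
  regions$dmc_count <- as.integer(counts)
  regions
}

#' Filter candidate regions
#'
#' Applies the three independent region filters: at least `min_dmcs` DMCs,
#' at least `min_cpgs` CpGs, and absolute mean methylation difference
#' strictly greater than `min_abs_mean_diff` percentage points. Order is
#' preserved.
#'
#' @param regions a `region_table` with `dmc_count` (see [count_dmcs()]).
#' @param min_dmcs minimum DMCs per region (default 1).
#' @param min_cpgs minimum CpGs per region (default 3).
#' @param min_abs_mean_diff mean-difference threshold in percentage points
#'   (default 20; strict inequality).
#' @return The surviving subset of `regions`.
#' @export
filter_regions <- function(regions, min_dmcs = 1L, min_cpgs = 3L,
                           min_abs_mean_diff = 20) {
  if (is.null(regions$dmc_count)) {
    stop("regions lack dmc_count; run count_dmcs() first")
  }
  keep <- regions$dmc_count >= min_dmcs &
          regions$cpg_count >= min_cpgs &
          abs(regions$mean_diff) > min_abs_mean_diff
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
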