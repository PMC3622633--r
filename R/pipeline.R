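#' Call differentially methylated regions from a per-CpG table
#'
#' Runs the full empirical DMR workflow: (1) unless a fixed cutoff is
#' supplied, fit the two-component normal mixture to the log2 adjacent-CpG
#' distances and minimise the weighted misclassification cost to obtain the
#' region-boundary distance `D`; (2) segment the CpGs into candidate
#' regions at `D`; (3) apply the three region filters (DMC count, CpG
#' count, absolute mean difference); (4) estimate the binned spatial
#' autocorrelation and assign each surviving region a dependence-adjusted
#' Stouffer-Liptak combined p-value, FDR-corrected across regions.
#'
#' @param cpgs a [cpg_table] (see [read_dmc_table()]).
#' @param dist_cutoff `"auto"` (fit the mixture) or a fixed base-pair
#'   cutoff.
#' @param num_dmcs,num_cpgs,mean_diff region filters: minimum DMCs,
#'   minimum CpGs, and the strict lower bound on \|mean difference\| in
#'   percentage points.
#' @param dmc_qvalue,dmc_diff per-site DMC definition (q-value below,
#'   absolute difference at or above).
#' @param bin_size,max_lag,acf_source autocorrelation estimation settings
#'   (see [estimate_acf()]).
#' @param combine `"all"` or `"dmc-only"` member p-values per region (see
#'   [combine_region_pvalues()]).
#' @param min_gaps minimum retained adjacent-gap count required for the
#'   mixture fit.
#' @return An object of class `dmr_result`: list with `dmrs` (filtered
#'   regions with `p_combined`, `q_value`), `cutoff` (`cutoff_result` or
#'   the fixed override), `fit` (`mixture_fit` or `NULL`), `acf`,
#'   `n_regions_segmented`, and the call parameters.
#' @export
call_dmrs <- function(cpgs,
                      dist_cutoff = "auto",
                      num_dmcs = 1L, num_cpgs = 3L, mean_diff = 20,
                      dmc_qvalue = 0.01, dmc_diff = 25,
                      bin_size = 100L, max_lag = 10L,
                      acf_source = "pvalue",
                      combine = "all",
                      min_gaps = 500L) {
  cpgs <- validate_cpg_table(as.data.frame(cpgs))
  if (identical(dist_cutoff, "auto")) {
    gaps <- compute_gap_sample(cpgs, min_gaps = min_gaps)
    fit <- fit_bimodal_em(gaps)
    cutoff <- optimize_cutoff(fit, gaps)
    D <- cutoff$D
  } else {
    D <- as.integer(dist_cutoff)
    if (is.na(D) || D < 1L) stop("dist_cutoff must be 'auto' or a positive integer")
    fit <- NULL
    cutoff <- list(x_hat = log2(D), D = D, cost_at_min = NA_real_,
                   interior = NA, fit = NULL, fixed = TRUE)
  }
  regions <- segment_regions(cpgs, D)
  regions <- count_dmcs(regions, cpgs, dmc_qvalue = dmc_qvalue,
                        dmc_diff = dmc_diff)
  kept <- filter_regions(regions, min_dmcs = num_dmcs, min_cpgs = num_cpgs,
                         min_abs_mean_diff = mean_diff)
  acf <- estimate_acf(cpgs, bin_size = bin_size, max_lag = max_lag,
                      source = acf_source)
  if (nrow(kept)) {
    kept <- combine_region_pvalues(kept, cpgs, acf, combine = combine,
                                   dmc_qvalue = dmc_qvalue,
                                   dmc_diff = dmc_diff)
  } else {
    kept$p_combined <- numeric(0)
    kept$q_value <- numeric(0)
  }
  structure(
    list(dmrs = kept, cutoff = cutoff, fit = fit, acf = acf,
         n_regions_segmented = nrow(regions),
         params = list(dist_cutoff = dist_cutoff, num_dmcs = num_dmcs,
                       num_cpgs = num_cpgs, mean_diff = mean_diff,
                       dmc_qvalue = dmc_qvalue, dmc_diff = dmc_diff,
                       bin_size = bin_size, max_lag = max_lag,
                       acf_source = acf_source, combine = combine)),
    class = "dmr_result"
  )
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("Empirical DMR call\n")
  cat(sprintf("  distance cutoff: %d bp%s\n", x$cutoff$D,
              if (is.null(x$fit)) " (user-fixed)" else " (fitted)"))
  cat(sprintf("  regions segmented: %d; DMRs after filters: %d\n",
              x$n_regions_segmented, nrow(x$dmrs)))
  if (nrow(x$dmrs)) {
    cat(sprintf("  hyper: %d, hypo: %d; %d at q < 0.05\n",
                sum(x$dmrs$mean_diff > 0), sum(x$dmrs$mean_diff <= 0),
                sum(x$dmrs$q_value < 0.05)))
  }
  invisible(x)
}

#' Run the full pipeline on a file and write all outputs
#'
#' Reads a per-CpG differential table, calls DMRs, optionally annotates
#' them against supplied tracks, and writes `dmr.tsv`, `dmr.bed`,
#' `fit.json` (mixture parameters and cutoff), `acf.tsv`, `summary.txt`
#' and, when tracks are given, `annotation.tsv` and
#' `annotation_counts.tsv` into `out_dir`. Reruns with identical inputs
#' and parameters produce identical files.
#'
#' @param dmc_path path to the per-CpG table.
#' @param out_dir output directory (created if absent).
#' @param format input dialect, passed to [read_dmc_table()].
#' @param strip_chr passed to [read_dmc_table()].
#' @param tracks optional named list of `feature_track`s for annotation.
#' @param ... passed to [call_dmrs()].
#' @return The `dmr_result`, invisibly.
#' @export
run_pipeline <- function(dmc_path, out_dir, format = "methyldiff",
                         strip_chr = FALSE, tracks = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  cpgs <- read_dmc_table(dmc_path, format = format, strip_chr = strip_chr)
  say("read %d CpG records from %s", nrow(cpgs), dmc_path)
  res <- call_dmrs(cpgs, ...)
  say("distance cutoff: %d bp", res$cutoff$D)
  say("segmented %d regions; %d pass filters", res$n_regions_segmented,
      nrow(res$dmrs))
  if (nrow(res$dmrs) == 0L) {
    warning("no regions survive the filters; writing empty outputs")
  }
  write_dmr_output(res$dmrs, file.path(out_dir, "dmr.tsv"), "tsv")
  write_dmr_output(res$dmrs, file.path(out_dir, "dmr.bed"), "bed")
  fit_json <- list(
    dist_cutoff_bp = res$cutoff$D,
    x_hat = res$cutoff$x_hat,
    fixed = is.null(res$fit)
  )
  if (!is.null(res$fit)) {
    fit_json <- c(fit_json, list(
      lambda = res$fit$lambda, mu = res$fit$mu, sigma = res$fit$sigma,
      loglik = res$fit$loglik, n_iter = res$fit$n_iter,
      converged = res$fit$converged, cost_at_min = res$cutoff$cost_at_min
    ))
  }
  jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(lag = seq_along(res$acf$rho) - 1L, rho = res$acf$rho,
               n_pairs = res$acf$n_pairs),
    file.path(out_dir, "acf.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  smry <- summarize_dmrs(res$dmrs)
  writeLines(utils::capture.output(print(smry)),
             file.path(out_dir, "summary.txt"))
  if (!is.null(tracks) && nrow(res$dmrs)) {
    ann <- annotate_dmrs(res$dmrs, tracks)
    utils::write.table(ann$rows, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(feature = names(ann$counts), n_dmrs = as.integer(ann$counts)),
      file.path(out_dir, "annotation_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    say("annotated %d DMRs against %d tracks", nrow(res$dmrs), length(tracks))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}
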