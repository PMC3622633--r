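#' Configuration for the synthetic methylome generator
#'
#' The generator emulates the structure of enrichment-based bisulfite data
#' that the DMR caller assumes: CpG positions clustered so that adjacent
#' log2 gaps follow a two-component normal mixture plus a 1-bp
#' opposite-strand spike; planted DMR intervals whose CpGs carry an
#' elevated methylation difference and shifted p-values; and spatially
#' autocorrelated null p-values driven by an AR(1) latent z-process over
#' fixed-width genomic bins.
#'
#' @param seed RNG seed.
#' @param n_cpgs number of base (plus-strand) CpGs before strand spikes.
#' @param chroms chromosome names; CpGs are split evenly across them.
#' @param lambda1,mu1,sigma1,mu2,sigma2 gap-mixture parameters on the log2
#'   scale. The defaults place the weighted-density crossing near
#'   log2 distance 7.5 (about 180 bp), typical of enrichment protocols.
#' @param spike_fraction fraction of base CpGs duplicated 1 bp downstream
#'   on the minus strand (the un-destranded reverse-complement CpG).
#' @param n_dmrs number of planted DMRs.
#' @param dmr_min_cpgs minimum CpGs a position cluster must hold to be
#'   eligible for planting; the whole cluster is planted.
#' @param effect planted methylation difference in percentage points.
#' @param noise_sd per-CpG methylation-difference noise (percentage
#'   points).
#' @param ar1 AR(1) coefficient of the latent z-process across consecutive
#'   `bin_size`-bp bins, in \[0, 1).
#' @param bin_size latent-process bin width in bp.
#' @param bin_weight share of each CpG's z-variance contributed by its
#'   bin's latent value (the rest is independent site noise); controls how
#'   strongly p-values are spatially autocorrelated.
#' @param z_shift probit-scale shift added to planted CpGs' latent z, so
#'   planted sites have coherently small p-values.
#' @param coverage_mu,coverage_size negative-binomial coverage parameters;
#'   10 reads are added so every site clears a 10X floor.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_cpgs = 200000L,
                         chroms = paste0("chr", 1:4),
                         lambda1 = 0.85, mu1 = 4.65, sigma1 = 1.2,
                         mu2 = 9.5, sigma2 = 1.5,
                         spike_fraction = 0.10,
                         n_dmrs = 50L, dmr_min_cpgs = 10L,
                         effect = 40, noise_sd = 5,
                         ar1 = 0.3, bin_size = 100L, bin_weight = 0.5,
                         z_shift = 5,
                         coverage_mu = 60, coverage_size = 4) {
  cfg <- list(seed = as.integer(seed), n_cpgs = as.integer(n_cpgs),
              chroms = sort(as.character(chroms)),
              lambda1 = lambda1, mu1 = mu1, sigma1 = sigma1,
              mu2 = mu2, sigma2 = sigma2,
              spike_fraction = spike_fraction,
              n_dmrs = as.integer(n_dmrs),
              dmr_min_cpgs = as.integer(dmr_min_cpgs),
              effect = effect, noise_sd = noise_sd,
              ar1 = ar1, bin_size = as.integer(bin_size),
              bin_weight = bin_weight, z_shift = z_shift,
              coverage_mu = coverage_mu, coverage_size = coverage_size)
  stopifnot(cfg$n_cpgs >= 10L, lambda1 > 0, lambda1 < 1,
            sigma1 > 0, sigma2 > 0, mu1 < mu2,
            spike_fraction >= 0, spike_fraction < 1,
            effect > 0, effect <= 100, noise_sd >= 0,
            ar1 >= 0, ar1 < 1, bin_weight >= 0, bin_weight <= 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Crossing point of the weighted mixture densities
#'
#' Solves `lambda1 * f1(x) = lambda2 * f2(x)` for x between the two
#' component means: the point where the misclassification cost of the
#' mixture is stationary, i.e. the generative ground truth for the
#' optimised cutoff.
#'
#' @param fit a `mixture_fit` or `synth_config`.
#' @return The crossing point x* (log2 bp).
#' @export
mixture_crossing <- function(fit) {
  if (inherits(fit, "synth_config")) {
    fit <- mixture_fit(fit$lambda1, fit$mu1, fit$sigma1, fit$mu2, fit$sigma2)
  }
  f <- function(x) {
    log(fit$lambda[1]) + stats::dnorm(x, fit$mu[1], fit$sigma[1], log = TRUE) -
      log(fit$lambda[2]) - stats::dnorm(x, fit$mu[2], fit$sigma[2], log = TRUE)
  }
  stats::uniroot(f, c(fit$mu[1], fit$mu[2]), tol = 1e-12)$root
}

# positions for one chromosome: base CpGs at mixture-drawn gaps, plus the
# opposite-strand spike 1 bp downstream of a random subset
gen_chrom_positions <- function(cfg, n_c) {
  comp2 <- stats::runif(n_c - 1L) > cfg$lambda1
  x <- stats::rnorm(n_c - 1L,
                    mean = ifelse(comp2, cfg$mu2, cfg$mu1),
                    sd = ifelse(comp2, cfg$sigma2, cfg$sigma1))
  gaps <- pmax(2, round(2^x))
  pos <- 10000 + cumsum(c(0, gaps))
  strand <- rep("+", n_c)
  n_spike <- floor(cfg$spike_fraction * n_c)
  if (n_spike > 0L) {
    at <- sort(sample.int(n_c, n_spike))
    pos <- c(pos, pos[at] + 1)
    strand <- c(strand, rep("-", n_spike))
    o <- order(pos)
    pos <- pos[o]; strand <- strand[o]
  }
  data.frame(pos = pos, strand = strand, stringsAsFactors = FALSE)
}

gen_positions <- function(cfg) {
  n_per <- diff(round(seq(0, cfg$n_cpgs, length.out = length(cfg$chroms) + 1L)))
  dfs <- lapply(seq_along(cfg$chroms), function(i) {
    d <- gen_chrom_positions(cfg, n_per[i])
    d$chrom <- cfg$chroms[i]
    d
  })
  df <- do.call(rbind, dfs)
  df[, c("chrom", "pos", "strand")]
}

#' Generate synthetic CpG positions
#'
#' @param config a [synth_config()].
#' @return List with `positions` (data frame `chrom`, `pos`, `strand`,
#'   sorted) and `x_star`, the true weighted-density crossing point of the
#'   generating mixture.
#' @export
simulate_positions <- function(config) {
  set.seed(config$seed)
  list(positions = gen_positions(config),
       x_star = mixture_crossing(config))
}

#' Generate a full synthetic differential-methylation dataset
#'
#' Draws CpG positions from the gap mixture, segments them into clusters at
#' the true crossing distance, plants `n_dmrs` whole clusters (of at least
#' `dmr_min_cpgs` CpGs) as DMRs with random direction, and assigns per-CpG
#' methylation differences and p-values. Null CpGs get differences
#' `N(0, noise_sd)` and uniform p-values made spatially autocorrelated
#' through the AR(1) bin-latent z; planted CpGs get differences
#' `N(±effect, noise_sd)` and the same latent z shifted by `z_shift`, so
#' effect size and significance are coherent. q-values are BH-corrected
#' over all CpGs.
#'
#' @param config a [synth_config()].
#' @return An object of class `synthetic_methylome`: list with `cpgs` (a
#'   [cpg_table]) and `truth` (list: `dmrs` data frame with planted
#'   intervals and directions, `x_star`, `D_star`, per-CpG logical
#'   `is_dmr`, and the `config`).
#' @export
simulate_methylome <- function(config) {
  set.seed(config$seed)
  df <- gen_positions(config)
  n <- nrow(df)
  x_star <- mixture_crossing(config)
  D_star <- round(2^x_star)

  # cluster positions at the true cutoff and plant whole clusters
  new_cl <- c(TRUE, df$chrom[-1L] != df$chrom[-n] | diff(df$pos) > D_star)
  cl <- cumsum(new_cl)
  cl_size <- tabulate(cl)
  eligible <- which(cl_size >= config$dmr_min_cpgs)
  if (length(eligible) < config$n_dmrs) {
    stop("only ", length(eligible), " clusters with >= ",
         config$dmr_min_cpgs, " CpGs; cannot plant ", config$n_dmrs, " DMRs")
  }
  planted <- sort(sample(eligible, config$n_dmrs))
  direction <- sample(c(1, -1), config$n_dmrs, replace = TRUE)
  is_dmr <- cl %in% planted
  dir_per_cpg <- numeric(n)
  dir_per_cpg[is_dmr] <- direction[match(cl[is_dmr], planted)]

  first <- which(new_cl); last <- c(first[-1L] - 1L, n)
  truth_dmrs <- data.frame(
    chrom = df$chrom[first[planted]],
    start = df$pos[first[planted]],
    end = df$pos[last[planted]],
    n_cpgs = cl_size[planted],
    direction = ifelse(direction > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )

  meth_diff <- stats::rnorm(n, mean = config$effect * dir_per_cpg,
                            sd = config$noise_sd)
  meth_diff <- pmin(pmax(meth_diff, -100), 100)

  # AR(1) latent z over consecutive bins, stationary N(0,1) marginals
  bi <- (df$pos - 1L) %/% config$bin_size
  z_bin_value <- numeric(n)
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    nb <- max(bi[sel]) + 1L
    innov_sd <- sqrt(1 - config$ar1^2)
    b <- as.numeric(stats::filter(stats::rnorm(nb, sd = innov_sd),
                                  config$ar1, method = "recursive",
                                  init = stats::rnorm(1)))
    z_bin_value[sel] <- b[bi[sel] + 1L]
  }
  w <- config$bin_weight
  z <- sqrt(w) * z_bin_value + sqrt(1 - w) * stats::rnorm(n) +
       config$z_shift * is_dmr
  pvalue <- pmax(stats::pnorm(z, lower.tail = FALSE), 1e-300)
  qvalue <- bh_fdr(pvalue)
  coverage <- stats::rnbinom(n, mu = config$coverage_mu,
                             size = config$coverage_size) + 10L

  cpgs <- cpg_table(chrom = df$chrom, pos = df$pos, strand = df$strand,
                    coverage = coverage, meth_diff = meth_diff,
                    pvalue = pvalue, qvalue = qvalue)
  structure(
    list(cpgs = cpgs,
         truth = list(dmrs = truth_dmrs, x_star = x_star, D_star = D_star,
                      is_dmr = is_dmr, config = config)),
    class = "synthetic_methylome"
  )
}

#' Analytic bin-level autocorrelation of the synthetic p-value field
#'
#' Closed form for the lag-`lag` Pearson correlation between bin means of
#' the latent z when each bin holds `m` CpGs:
#' `w * ar1^lag / (w + (1 - w) / m)` — the site-noise term attenuates the
#' latent AR(1) correlation by the bin-mean noise variance.
#'
#' @param config a [synth_config()].
#' @param lag lag in bins.
#' @param m CpGs per bin (use a representative mean of occupied bins).
#' @return Expected bin-mean autocorrelation.
#' @export
analytic_bin_acf <- function(config, lag, m) {
  w <- config$bin_weight
  w * config$ar1^lag / (w + (1 - w) / m)
}

#' Compare called DMRs with planted truth
#'
#' @param called DMR data frame (`chrom`, `start`, `end`).
#' @param truth planted-DMR data frame (`chrom`, `start`, `end`).
#' @return List with `sensitivity` (fraction of truth intervals overlapped
#'   by at least one call), `false_call_rate` (fraction of calls
#'   overlapping no truth interval), and `jaccard` (base-level intersection
#'   over union of the two interval sets).
#' @export
evaluate_recovery <- function(called, truth) {
  to_gr <- function(d) GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = d$chrom, ranges = IRanges::IRanges(d$start, d$end)))
  if (nrow(called) == 0L) {
    return(list(sensitivity = 0, false_call_rate = NA_real_, jaccard = 0))
  }
  cg <- to_gr(called); tg <- to_gr(truth)
  ov_t <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end)), cg)
  ov_c <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(called$chrom, IRanges::IRanges(called$start, called$end)), tg)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(cg, tg)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(cg, tg)))
  list(sensitivity = mean(ov_t > 0),
       false_call_rate = mean(ov_c == 0),
       jaccard = inter / uni)
}

#' Write a CpG table in the tab-delimited differential format
#'
#' Writes the methyldiff dialect read by [read_dmc_table()]: header `chr`,
#' `start`, `end`, `strand`, `pvalue`, `qvalue`, `meth.diff`, one row per
#' site with `start == end == pos`. Numeric fields are serialised at full
#' double precision so the table round-trips exactly.
#'
#' @param cpgs a [cpg_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmc_table <- function(cpgs, path) {
  out <- data.frame(
    chr = cpgs$chrom, start = cpgs$pos, end = cpgs$pos,
    strand = cpgs$strand,
    pvalue = sprintf("%.17g", cpgs$pvalue),
    qvalue = sprintf("%.17g", cpgs$qvalue),
    meth.diff = sprintf("%.17g", cpgs$meth_diff),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write planted truth intervals as BED
#'
#' @param truth the `truth` element of a [simulate_methylome()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(truth$dmrs$chrom, truth$dmrs$start - 1L,
                    truth$dmrs$end, truth$dmrs$direction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
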