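# quick CpG table builder for hand-constructed cases
make_cpgs <- function(pos, chrom = "chr1", strand = "+", meth_diff = 0,
                      pvalue = 0.5, qvalue = 0.5, coverage = 10L) {
  cpg_table(
    chrom = rep_len(chrom, length(pos)), pos = pos,
    strand = rep_len(strand, length(pos)),
    coverage = rep_len(coverage, length(pos)),
    meth_diff = rep_len(meth_diff, length(pos)),
    pvalue = rep_len(pvalue, length(pos)),
    qvalue = rep_len(qvalue, length(pos))
  )
}

# reference segmentation: test every adjacent pair independently
brute_segment <- function(cpgs, D) {
  n <- nrow(cpgs)
  id <- integer(n)
  id[1] <- 1L
  for (i in 2:n) {
    boundary <- cpgs$chrom[i] != cpgs$chrom[i - 1L] ||
      (cpgs$pos[i] - cpgs$pos[i - 1L]) > D
    id[i] <- id[i - 1L] + as.integer(boundary)
  }
  id
}

# literal BH step-up definition: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) q_sorted[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# random refFlat-style gene model written to a temp file and read back
random_gene_model_file <- function(n, seed) {
  set.seed(seed)
  lines <- character(n)
  for (i in seq_len(n)) {
    n_ex <- sample(1:6, 1)
    ex_len <- sample(50:400, n_ex, replace = TRUE)
    gap_len <- if (n_ex > 1) sample(30:500, n_ex - 1, replace = TRUE) else integer(0)
    tx_start0 <- sample(1000:50000, 1)
    starts0 <- tx_start0 + c(0, cumsum(ex_len[-n_ex] + gap_len))
    ends0 <- starts0 + ex_len
    tx_end0 <- ends0[n_ex]
    coding <- stats::runif(1) < 0.8
    if (coding) {
      cds0 <- sort(sample(tx_start0:(tx_end0 - 1), 2))
      cds_start0 <- cds0[1]; cds_end0 <- cds0[2]
    } else {
      cds_start0 <- tx_start0; cds_end0 <- tx_start0
    }
    lines[i] <- paste(
      paste0("GENE", i), paste0("TX", i), "chr1",
      sample(c("+", "-"), 1), tx_start0, tx_end0, cds_start0, cds_end0,
      n_ex, paste0(paste(starts0, collapse = ","), ","),
      paste0(paste(ends0, collapse = ","), ","),
      sep = "\t"
    )
  }
  path <- tempfile(fileext = ".refflat")
  writeLines(lines, path)
  path
}

# set of covered bases of a feature track restricted to one transcript
track_bases <- function(track, tx = NULL) {
  if (!is.null(tx)) track <- track[track$name == tx, , drop = FALSE]
  if (nrow(track) == 0L) return(integer(0))
  unlist(Map(seq.int, track$start, track$end))
}
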