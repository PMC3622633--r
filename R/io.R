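#' Construct and validate a per-CpG differential-methylation table
#'
#' A `cpg_table` is an ordinary data frame with one row per covered cytosine
#' and columns `chrom`, `pos` (1-based), `strand` (`+`, `-` or `.`),
#' `coverage`, `meth_diff` (treatment minus control, percentage points in
#' \[-100, 100\]), `pvalue` and `qvalue`. Rows are sorted by `(chrom, pos)`
#' and duplicate `(chrom, pos, strand)` entries are rejected: destranding, if
#' wanted, is the caller's responsibility.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions.
#' @param strand strand characters; defaults to `"."`.
#' @param coverage read depth per site; `NA` allowed (some upstream
#'   differential tables do not carry coverage).
#' @param meth_diff methylation difference in percentage points.
#' @param pvalue,qvalue per-site differential-methylation p- and q-values.
#' @return A data frame of class `cpg_table`, sorted by `(chrom, pos)`.
#' @export
cpg_table <- function(chrom, pos, strand = ".", coverage = NA_integer_,
                      meth_diff, pvalue, qvalue) {
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    strand = as.character(strand),
    coverage = as.integer(coverage),
    meth_diff = as.numeric(meth_diff),
    pvalue = as.numeric(pvalue),
    qvalue = as.numeric(qvalue),
    stringsAsFactors = FALSE
  )
  validate_cpg_table(df)
}

validate_cpg_table <- function(df) {
  if (nrow(df) == 0L) stop("empty CpG table")
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  bad_p <- !is.finite(df$pvalue) | df$pvalue < 0 | df$pvalue > 1
  bad_q <- !is.finite(df$qvalue) | df$qvalue < 0 | df$qvalue > 1
  if (any(bad_p)) {
    stop("pvalue outside [0, 1] at row(s) ", paste(head(which(bad_p), 5L), collapse = ", "))
  }
  if (any(bad_q)) {
    stop("qvalue outside [0, 1] at row(s) ", paste(head(which(bad_q), 5L), collapse = ", "))
  }
  if (any(abs(df$meth_diff) > 100, na.rm = TRUE)) {
    stop("meth_diff outside [-100, 100]")
  }
  if (anyNA(df$coverage) == FALSE && any(df$coverage < 0L)) {
    stop("coverage must be non-negative")
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$chrom, df$pos, df$strand, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (chrom, pos, strand) record: ", gsub("\r", ":", dup, fixed = TRUE))
  }
  class(df) <- c("cpg_table", "data.frame")
  df
}

#' Read a per-CpG differential-methylation table
#'
#' Two dialects are supported. `"methyldiff"` is the tab-delimited format
#' written by per-site differential callers such as methylKit: a header line
#' followed by columns `chr`, `start`, `end`, `strand`, `pvalue`, `qvalue`,
#' `meth.diff`, with `start == end == pos` in 1-based coordinates. `"bed"`
#' is a headerless BED-like file with columns chrom, start, end, strand,
#' pvalue, qvalue, meth.diff in 0-based half-open coordinates; positions are
#' converted to 1-based on ingestion.
#'
#' @param path file path.
#' @param format one of `"methyldiff"` or `"bed"`.
#' @param strip_chr drop a leading `"chr"` from chromosome names. Off by
#'   default: chromosome names are otherwise compared verbatim, since silent
#'   renaming causes annotation mismatches.
#' @return A [cpg_table] sorted by `(chrom, pos)`.
#' @export
read_dmc_table <- function(path, format = c("methyldiff", "bed"),
                           strip_chr = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- format == "methyldiff"
  raw <- tryCatch(
    utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(raw) == 0L) stop("empty file: ", path)
  if (ncol(raw) < 7L) stop("expected >= 7 columns, got ", ncol(raw))
  raw <- raw[, 1:7]
  names(raw) <- c("chrom", "start", "end", "strand", "pvalue", "qvalue", "meth_diff")
  num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad)) {
      stop("malformed ", nm, " at line ", bad[1L] + as.integer(header))
    }
    v
  }
  start <- num("start", "start")
  end <- num("end", "end")
  pos <- if (format == "bed") end else start
  if (format == "methyldiff" && any(start != end)) {
    stop("methyldiff rows must have start == end (per-base records)")
  }
  chrom <- raw$chrom
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  cpg_table(
    chrom = chrom, pos = pos, strand = raw$strand,
    meth_diff = num("meth_diff", "meth.diff"),
    pvalue = num("pvalue", "pvalue"), qvalue = num("qvalue", "qvalue")
  )
}

#' Read a BED interval file as a feature track
#'
#' Intervals are converted from BED's 0-based half-open convention to the
#' package-internal 1-based inclusive convention. Strand is taken from BED
#' column 6 when present, `"."` otherwise.
#'
#' @param path BED file with at least 3 columns.
#' @param name track label (e.g. `"cpg_island"`).
#' @return A `feature_track` data frame with columns `chrom`, `start`,
#'   `end`, `strand`, `name`.
#' @export
read_interval_track <- function(path, name) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty track file: ", path)
    return(feature_track(character(), integer(), integer(), name = name))
  }
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file needs >= 3 columns")
  start <- as.integer(raw[[2]]) + 1L
  end <- as.integer(raw[[3]])
  if (any(end < start)) stop("interval with end < start after BED conversion")
  iv_name <- if (ncol(raw) >= 4L) as.character(raw[[4]]) else rep("", nrow(raw))
  strand <- if (ncol(raw) >= 6L) as.character(raw[[6]]) else rep(".", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "."
  feature_track(as.character(raw[[1]]), start, end,
                strand = strand, interval_name = iv_name, name = name)
}

#' Construct a feature track
#'
#' @param chrom,start,end interval coordinates, 1-based inclusive.
#' @param strand strand per interval, default `"."`.
#' @param interval_name free label per interval.
#' @param name track label.
#' @return A data frame of class `feature_track`.
#' @export
feature_track <- function(chrom, start, end, strand = ".",
                          interval_name = "", name = "track") {
  df <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom)),
    name = rep_len(as.character(interval_name), length(chrom)),
    stringsAsFactors = FALSE
  )
  if (nrow(df) && any(df$start < 1L | df$end < df$start)) {
    stop("invalid interval coordinates in track '", name, "'")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "track_name") <- name
  class(df) <- c("feature_track", "data.frame")
  df
}

#' Read a refFlat-style gene model table
#'
#' Expects the standard 11 refFlat columns (gene name, transcript id, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds) with 0-based half-open coordinates and comma-separated exon
#' block lists. Coordinates are converted to 1-based inclusive. Transcripts
#' with `cdsStart == cdsEnd` are non-coding.
#'
#' @param path refFlat file, no header.
#' @return A data frame of class `gene_model`, one row per transcript, with
#'   list columns `exon_start` and `exon_end` (1-based inclusive).
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 11L) stop("refFlat table needs 11 columns, got ", ncol(raw))
  names(raw)[1:11] <- c("gene", "tx", "chrom", "strand", "tx_start0",
                        "tx_end", "cds_start0", "cds_end", "exon_count",
                        "exon_starts", "exon_ends")
  parse_blocks <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  out <- data.frame(
    gene = raw$gene, tx = raw$tx, chrom = raw$chrom, strand = raw$strand,
    tx_start = as.integer(raw$tx_start0) + 1L, tx_end = as.integer(raw$tx_end),
    cds_start = as.integer(raw$cds_start0) + 1L, cds_end = as.integer(raw$cds_end),
    stringsAsFactors = FALSE
  )
  # cds_start > cds_end after conversion marks a non-coding transcript
  out$coding <- out$cds_start <= out$cds_end
  es <- lapply(raw$exon_starts, parse_blocks)
  ee <- lapply(raw$exon_ends, parse_blocks)
  for (i in seq_len(nrow(out))) {
    if (length(es[[i]]) != raw$exon_count[i] || length(ee[[i]]) != raw$exon_count[i]) {
      stop("exonCount mismatch for transcript ", out$tx[i])
    }
    es[[i]] <- es[[i]] + 1L
    o <- order(es[[i]])
    es[[i]] <- es[[i]][o]; ee[[i]] <- ee[[i]][o]
    if (any(ee[[i]] < es[[i]]) || is.unsorted(es[[i]]) ||
        any(es[[i]][-1] <= ee[[i]][-length(ee[[i]])])) {
      stop("overlapping or malformed exon blocks for transcript ", out$tx[i])
    }
    if (es[[i]][1] < out$tx_start[i] || ee[[i]][length(ee[[i]])] > out$tx_end[i]) {
      stop("exons outside transcript bounds for ", out$tx[i])
    }
    if (out$coding[i] &&
        (out$cds_start[i] < out$tx_start[i] || out$cds_end[i] > out$tx_end[i])) {
      stop("CDS bounds outside transcript bounds for ", out$tx[i])
    }
  }
  out$exon_start <- es
  out$exon_end <- ee
  class(out) <- c("gene_model", "data.frame")
  out
}

#' Write called DMRs to disk
#'
#' `"tsv"` writes every DMR field tab-delimited with a header, with numeric
#' fields serialised at full double precision so the table round-trips
#' losslessly through [read_dmr_table()]. `"bed"` writes 0-based half-open
#' intervals with the direction (`hyper`/`hypo`) in the name field and
#' `min(1000, round(-10 * log10(q)))` as the score.
#'
#' @param dmrs DMR data frame as returned by [call_dmrs()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_dmr_output <- function(dmrs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  cols <- c("chrom", "start", "end", "cpg_count", "dmc_count", "mean_diff",
            "direction", "p_combined", "q_value")
  dmrs <- as.data.frame(dmrs)[, intersect(cols, colnames(dmrs)), drop = FALSE]
  if (nrow(dmrs)) dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  if (format == "tsv") {
    out <- dmrs
    for (nm in colnames(out)) {
      if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    score <- integer(0)
    if (nrow(dmrs)) {
      score <- pmin(1000, round(-10 * log10(pmax(dmrs$q_value, 1e-100))))
    }
    bed <- data.frame(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                      dmrs$direction, score)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a DMR table written by [write_dmr_output()]
#'
#' @param path TSV path.
#' @return DMR data frame.
#' @export
read_dmr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (nm in c("start", "end", "cpg_count", "dmc_count")) {
    if (nm %in% colnames(df)) df[[nm]] <- as.integer(df[[nm]])
  }
  df
}
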