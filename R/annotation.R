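track_to_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start, end = track$end),
    name = track$name
  )
}

granges_to_track <- function(gr, name, interval_name = "") {
  feature_track(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    interval_name = interval_name,
    name = name
  )
}

#' Derive gene-part feature tracks from gene models
#'
#' Splits every transcript into promoter, 5' UTR, coding sequence, introns
#' and 3' UTR. The promoter is the window from `promoter_up` bp upstream to
#' `promoter_down` bp downstream of the transcription start site,
#' strand-aware (TSS is the transcript start on `+`, the transcript end on
#' `-`) and clipped at position 1. UTRs are the exonic sequence outside the
#' CDS bounds at either transcript end, assigned 5'/3' by strand; the CDS
#' is the exonic sequence within the CDS bounds; introns are the gaps
#' between consecutive exons. Non-coding transcripts contribute a promoter
#' (and introns when multi-exon) but no CDS/UTR parts. For every coding
#' transcript the UTRs, CDS and introns partition the transcript span
#' exactly.
#'
#' @param models a `gene_model` (see [read_gene_model()]).
#' @param promoter_up,promoter_down promoter window around the TSS in bp
#'   (defaults 1000/1000).
#' @return Named list of `feature_track`s: `promoter`, `utr5`, `cds`,
#'   `intron`, `utr3`. Interval names carry the transcript id.
#' @export
derive_gene_parts <- function(models, promoter_up = 1000L,
                              promoter_down = 1000L) {
  parts <- list(promoter = list(), utr5 = list(), cds = list(),
                intron = list(), utr3 = list())
  add <- function(what, chrom, start, end, tx) {
    if (!length(start)) return()
    keep <- end >= start & end >= 1L
    start <- pmax(start[keep], 1L); end <- end[keep]
    if (!length(start)) return()
    parts[[what]][[length(parts[[what]]) + 1L]] <<-
      data.frame(chrom = chrom, start = start, end = end, tx = tx,
                 stringsAsFactors = FALSE)
  }
  intersect_blocks <- function(bs, be, lo, hi) {
    s <- pmax(bs, lo); e <- pmin(be, hi)
    keep <- s <= e
    list(start = s[keep], end = e[keep])
  }
  for (i in seq_len(nrow(models))) {
    chrom <- models$chrom[i]; strand <- models$strand[i]
    tx <- models$tx[i]
    es <- models$exon_start[[i]]; ee <- models$exon_end[[i]]
    tss <- if (strand == "-") models$tx_end[i] else models$tx_start[i]
    if (strand == "-") {
      add("promoter", chrom, tss - promoter_down, tss + promoter_up, tx)
    } else {
      add("promoter", chrom, tss - promoter_up, tss + promoter_down, tx)
    }
    if (length(es) > 1L) {
      add("intron", chrom, ee[-length(ee)] + 1L, es[-1L] - 1L, tx)
    }
    if (models$coding[i]) {
      cs <- models$cds_start[i]; ce <- models$cds_end[i]
      cds <- intersect_blocks(es, ee, cs, ce)
      add("cds", chrom, cds$start, cds$end, tx)
      left <- intersect_blocks(es, ee, models$tx_start[i], cs - 1L)
      right <- intersect_blocks(es, ee, ce + 1L, models$tx_end[i])
      if (strand == "-") {
        add("utr3", chrom, left$start, left$end, tx)
        add("utr5", chrom, right$start, right$end, tx)
      } else {
        add("utr5", chrom, left$start, left$end, tx)
        add("utr3", chrom, right$start, right$end, tx)
      }
    }
  }
  out <- lapply(names(parts), function(nm) {
    dfs <- parts[[nm]]
    if (!length(dfs)) {
      return(feature_track(character(), integer(), integer(), name = nm))
    }
    df <- do.call(rbind, dfs)
    feature_track(df$chrom, df$start, df$end, interval_name = df$tx,
                  name = nm)
  })
  names(out) <- names(parts)
  out
}

#' Derive CpG island shores
#'
#' The shores of an island `[s, e]` are the flanks `[s - shore_width,
#' s - 1]` and `[e + 1, e + shore_width]`, clipped at position 1, with any
#' sequence belonging to an island (this one or a neighbour) subtracted, so
#' that no shore base lies in an island.
#'
#' @param islands a `feature_track` of CpG islands.
#' @param shore_width flank width in bp (default 2000, the conventional
#'   definition).
#' @return A `feature_track` named `"shore"`.
#' @export
derive_shores <- function(islands, shore_width = 2000L) {
  if (nrow(islands) == 0L) {
    return(feature_track(character(), integer(), integer(), name = "shore"))
  }
  left_s <- pmax(islands$start - shore_width, 1L)
  left_e <- islands$start - 1L
  right_s <- islands$end + 1L
  right_e <- islands$end + shore_width
  keep_l <- left_e >= left_s
  cand <- feature_track(
    chrom = c(islands$chrom[keep_l], islands$chrom),
    start = c(left_s[keep_l], right_s),
    end = c(left_e[keep_l], right_e),
    name = "shore"
  )
  gr <- GenomicRanges::setdiff(track_to_granges(cand),
                               track_to_granges(islands),
                               ignore.strand = TRUE)
  granges_to_track(gr, name = "shore", interval_name = "shore")
}

#' Annotate DMRs against feature tracks
#'
#' Reports every (DMR, feature interval) pair with at least 1 bp of
#' overlap, ignoring strand. By default a DMR overlapping several feature
#' classes is counted once in each of them (no precedence); passing
#' `precedence` assigns each DMR only to its highest-listed overlapped
#' feature for the per-feature counts, yielding disjoint tallies. DMRs
#' overlapping no track at all are reported in the `intergenic` count.
#'
#' @param dmrs DMR data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param tracks named list of `feature_track`s.
#' @param precedence optional character vector of track names, highest
#'   priority first, e.g. `c("promoter", "utr5", "utr3", "cds", "intron")`.
#' @return List with `rows` (data frame: `dmr_id`, `feature`,
#'   `interval_name`, `overlap_bp`) and `counts` (named integer vector of
#'   distinct DMRs per feature, plus `intergenic`).
#' @export
annotate_dmrs <- function(dmrs, tracks, precedence = NULL) {
  n_dmr <- nrow(dmrs)
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  dmr_gr <- GenomicRanges::GRanges(
    seqnames = dmrs$chrom,
    ranges = IRanges::IRanges(start = dmrs$start, end = dmrs$end)
  )
  rows <- list()
  hit_any <- rep(FALSE, n_dmr)
  hits_by_feature <- list()
  for (nm in names(tracks)) {
    track <- tracks[[nm]]
    if (nrow(track) == 0L) {
      hits_by_feature[[nm]] <- integer(0)
      next
    }
    tr_gr <- track_to_granges(track)
    ov <- GenomicRanges::findOverlaps(dmr_gr, tr_gr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    if (length(qi)) {
      width <- pmin(dmrs$end[qi], track$end[si]) -
               pmax(dmrs$start[qi], track$start[si]) + 1L
      rows[[nm]] <- data.frame(
        dmr_id = qi, feature = nm, interval_name = track$name[si],
        overlap_bp = width, stringsAsFactors = FALSE
      )
      hit_any[qi] <- TRUE
    }
    hits_by_feature[[nm]] <- unique(qi)
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dmr_id = integer(0), feature = character(0),
               interval_name = character(0), overlap_bp = integer(0),
               stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  if (is.null(precedence)) {
    counts <- vapply(hits_by_feature, length, integer(1))
  } else {
    missing <- setdiff(precedence, names(tracks))
    if (length(missing)) stop("precedence names not in tracks: ",
                              paste(missing, collapse = ", "))
    assigned <- rep(NA_character_, n_dmr)
    for (nm in c(precedence, setdiff(names(tracks), precedence))) {
      idx <- hits_by_feature[[nm]]
      idx <- idx[is.na(assigned[idx])]
      assigned[idx] <- nm
    }
    counts <- vapply(names(tracks),
                     function(nm) sum(assigned == nm, na.rm = TRUE),
                     integer(1))
  }
  counts <- c(counts, intergenic = sum(!hit_any))
  list(rows = rows, counts = counts)
}
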