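hand_model_line <- function(strand = "+") {
  # tx 1001-2000 (1-based), cds 1201-1800, exons 1001-1400 and 1601-2000
  paste("G", "T1", "chr1", strand, 1000, 2000, 1200, 1800, 2,
        "1000,1600,", "1400,2000,", sep = "\t")
}

read_model <- function(line) {
  p <- tempfile()
  writeLines(line, p)
  read_gene_model(p)
}

test_that("gene parts of a hand-constructed transcript are exact", {
  parts <- derive_gene_parts(read_model(hand_model_line("+")))
  expect_equal(parts$utr5[, c("start", "end")],
               data.frame(start = 1001L, end = 1200L), ignore_attr = TRUE)
  expect_equal(parts$cds[, c("start", "end")],
               data.frame(start = c(1201L, 1601L), end = c(1400L, 1800L)),
               ignore_attr = TRUE)
  expect_equal(parts$intron[, c("start", "end")],
               data.frame(start = 1401L, end = 1600L), ignore_attr = TRUE)
  expect_equal(parts$utr3[, c("start", "end")],
               data.frame(start = 1801L, end = 2000L), ignore_attr = TRUE)
  # promoter: TSS 1001, window [1, 2001] after clipping at position 1
  expect_equal(parts$promoter[, c("start", "end")],
               data.frame(start = 1L, end = 2001L), ignore_attr = TRUE)

  # minus strand: 5' and 3' UTRs swap ends, promoter flips around TSS 2000
  minus <- derive_gene_parts(read_model(hand_model_line("-")))
  expect_equal(minus$utr5[, c("start", "end")],
               data.frame(start = 1801L, end = 2000L), ignore_attr = TRUE)
  expect_equal(minus$utr3[, c("start", "end")],
               data.frame(start = 1001L, end = 1200L), ignore_attr = TRUE)
  expect_equal(minus$promoter[, c("start", "end")],
               data.frame(start = 1000L, end = 3000L), ignore_attr = TRUE)
})

test_that("non-coding transcripts contribute only promoter and introns", {
  nc <- read_model("G\tT2\tchr1\t+\t5000\t6000\t5000\t5000\t1\t5000,\t6000,")
  parts <- derive_gene_parts(nc)
  expect_equal(nrow(parts$promoter), 1L)
  expect_equal(nrow(parts$utr5), 0L)
  expect_equal(nrow(parts$cds), 0L)
  expect_equal(nrow(parts$utr3), 0L)
  expect_equal(nrow(parts$intron), 0L)
})

test_that("UTRs, CDS and introns partition every coding transcript exactly", {
  models <- read_gene_model(random_gene_model_file(100, seed = 88))
  parts <- derive_gene_parts(models)
  for (i in which(models$coding)) {
    tx <- models$tx[i]
    covered <- c(track_bases(parts$utr5, tx), track_bases(parts$cds, tx),
                 track_bases(parts$utr3, tx), track_bases(parts$intron, tx))
    expect_false(anyDuplicated(covered) > 0)       # pairwise disjoint
    expect_setequal(covered, models$tx_start[i]:models$tx_end[i])
  }
})

test_that("shores flank islands by the shore width and never overlap them", {
  isl <- feature_track("chr1", 10001, 11000, name = "cpg_island")
  sh <- derive_shores(isl)
  expect_equal(sh$start, c(8001L, 11001L))
  expect_equal(sh$end, c(10000L, 13000L))

  # two islands 1000 bp apart: inter-island shore sequence is trimmed
  isl2 <- feature_track(c("chr1", "chr1"), c(10001, 12001), c(11000, 13000),
                        name = "cpg_island")
  sh2 <- derive_shores(isl2)
  island_bases <- track_bases(isl2)
  expect_length(intersect(track_bases(sh2), island_bases), 0L)
  expect_true(any(sh2$start == 11001 & sh2$end == 12000))

  # island at chromosome start: no left shore
  sh3 <- derive_shores(feature_track("chr1", 1, 500, name = "cpg_island"))
  expect_equal(nrow(sh3), 1L)
  expect_equal(c(sh3$start, sh3$end), c(501L, 2500L))

  # property: randomized islands, shores disjoint from islands and bounded
  set.seed(52)
  starts <- sort(sample.int(200000, 20))
  isl_r <- feature_track("chr1", starts, starts + sample(200:2000, 20, TRUE),
                         name = "cpg_island")
  sh_r <- derive_shores(isl_r, shore_width = 2000)
  expect_length(intersect(track_bases(sh_r), track_bases(isl_r)), 0L)
  expect_lte(sum(sh_r$end - sh_r$start + 1), 2 * 2000 * nrow(isl_r))
})

test_that("DMR annotation reports overlaps, counts and the intergenic tally", {
  dmrs <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                     start = c(150, 1380, 9000), end = c(250, 1650, 9100))
  parts <- derive_gene_parts(read_model(hand_model_line("+")))
  tracks <- c(parts["cds"], parts["intron"],
              list(promoter = feature_track("chr1", 100, 200,
                                            interval_name = "p1",
                                            name = "promoter")))
  ann <- annotate_dmrs(dmrs, tracks)
  prom_row <- ann$rows[ann$rows$feature == "promoter", ]
  expect_equal(prom_row$dmr_id, 1L)
  expect_equal(prom_row$overlap_bp, 51L)  # 200 - 150 + 1
  # DMR 2 spans the exon/intron boundary: counted once in each feature
  expect_setequal(ann$rows$feature[ann$rows$dmr_id == 2], c("cds", "intron"))
  expect_equal(unname(ann$counts["cds"]), 1L)
  expect_equal(unname(ann$counts["intron"]), 1L)
  expect_equal(unname(ann$counts["intergenic"]), 1L)

  # precedence yields disjoint counts
  annp <- annotate_dmrs(dmrs, tracks,
                        precedence = c("promoter", "cds", "intron"))
  expect_equal(unname(annp$counts["cds"]), 1L)
  expect_equal(unname(annp$counts["intron"]), 0L)
  expect_equal(sum(annp$counts), nrow(dmrs))
})

test_that("overlap reporting matches an all-pairs scan on random instances", {
  set.seed(61)
  for (rep in 1:10) {
    nd <- sample(5:40, 1); nt <- sample(5:40, 1)
    ds <- sample.int(5000, nd)
    dmrs <- data.frame(chrom = sample(c("chr1", "chr2"), nd, TRUE),
                       start = ds, end = ds + sample(1:300, nd, TRUE))
    ts <- sample.int(5000, nt)
    track <- feature_track(sample(c("chr1", "chr2"), nt, TRUE), ts,
                           ts + sample(1:300, nt, TRUE), name = "t")
    ann <- annotate_dmrs(dmrs, list(t = track))
    expected <- 0L
    for (i in seq_len(nd)) {
      for (j in seq_len(nt)) {
        if (dmrs$chrom[i] == track$chrom[j] &&
            min(dmrs$end[i], track$end[j]) >=
              max(dmrs$start[i], track$start[j])) {
          expected <- expected + 1L
          ov <- min(dmrs$end[i], track$end[j]) -
                max(dmrs$start[i], track$start[j]) + 1L
          expect_true(ov %in% ann$rows$overlap_bp[ann$rows$dmr_id == i])
        }
      }
    }
    expect_equal(nrow(ann$rows), expected)
  }
})
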