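## quality strings: "?" = Q30, ")" = Q8, "+" = Q10
q30 <- strrep("?", 31)

make_read <- function(cid, mid = "ACGTAC") paste0(cid, mid)

test_that("demultiplexing applies CID correction and the MID quality filter", {
  lay <- emit_chip_layout(3, 3, pitch_um = 0.5, seed = 2)
  bc <- lay$barcode[5]

  ## exact barcode, clean MID -> accepted
  r <- demultiplex_read1(make_read(bc), q30, lay)
  expect_equal(r$status, "ok")
  expect_equal(c(r$x_index, r$y_index), c(lay$x_index[5], lay$y_index[5]))
  expect_equal(r$mid, "ACGTAC")

  ## one substitution -> corrected to the same spot
  mut <- bc
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(bc, 3, 3))[1]
  r2 <- demultiplex_read1(make_read(mut), q30, lay)
  expect_equal(r2$status, "ok")
  expect_true(r2$corrected)
  expect_equal(c(r2$x_index, r2$y_index), c(lay$x_index[5], lay$y_index[5]))

  ## MID with N -> rejected("mid")
  r3 <- demultiplex_read1(make_read(bc, "ACGNTA"), q30, lay)
  expect_equal(r3$status, "mid")

  ## exactly 2 bases below Q10 -> accepted; 3 -> rejected
  q2 <- paste0(strrep("?", 25), "))????")
  q3 <- paste0(strrep("?", 25), ")))???")
  expect_equal(demultiplex_read1(make_read(bc), q2, lay)$status, "ok")
  expect_equal(demultiplex_read1(make_read(bc), q3, lay)$status, "mid")
  ## Q10 itself is not low quality (strictly 'lower than 10')
  q10x3 <- paste0(strrep("?", 25), "+++???")
  expect_equal(demultiplex_read1(make_read(bc), q10x3, lay)$status, "ok")

  ## short read
  expect_equal(demultiplex_read1(substr(make_read(bc), 1, 30), q30, lay)$status,
               "short")
})

test_that("a CID one mismatch from two layout barcodes is rejected as ambiguous", {
  ## two barcodes at Hamming distance 2; a read between them is distance 1
  ## from both (brute-force scan confirms)
  b1 <- strrep("A", 25)
  b2 <- paste0("CC", strrep("A", 23))
  lay <- data.frame(barcode = c(b1, b2), x_index = c(0L, 1L),
                    y_index = c(0L, 0L), stringsAsFactors = FALSE)
  attr(lay, "pitch_um") <- 0.5
  query <- paste0("CA", strrep("A", 23))
  d <- vapply(lay$barcode, function(b)
    sum(strsplit(b, "")[[1]] != strsplit(query, "")[[1]]), integer(1))
  expect_true(all(d == 1))
  r <- demultiplex_read1(make_read(query), q30, lay)
  expect_equal(r$status, "cid")
})

test_that("read partition is complete: accepted + rejections = total", {
  cfg <- phantom_config(seed = 17, field_size_um = c(200, 200))
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(40, 40, pitch_um = 5, seed = 17)
  rd <- emit_stereo_reads(p, 1, lay, depth = 2)
  dm <- demultiplex_read1(rd$read1, rd$qual1, lay)
  tab <- table(dm$status)
  expect_equal(sum(tab), length(rd$read1))
  expect_setequal(setdiff(names(tab), c("ok", "cid", "mid", "short")),
                  character(0))
})

test_that("gene assignment respects the MAPQ > 10 filter and taxon partition", {
  ref <- toy_reference(c("G1", "G2"), seed = 1)
  tags <- setNames(ref$tag, ref$id)
  r <- assign_gene(c(tags[["G1"]], tags[["MULTIMAP"]],
                     tags[["Escherichia_coli"]], tags[["MT-CO1"]],
                     strrep("A", 40)), ref)
  expect_equal(r$kind,
               c("gene", "lowmapq", "taxon", "mito", "unassigned"))
  expect_equal(r$mapq[1], 255L)
  expect_equal(r$mapq[2], 0L)
  expect_equal(r$taxon_class[3], "Gammaproteobacteria")
  expect_error(assign_gene("A", ref[0, ]), "empty reference")
})

test_that("UMI collapse counts Hamming<=1 components", {
  expect_equal(collapse_umis(character(0)), 0L)
  expect_equal(collapse_umis(c("AAAAAA", "AAAAAT", "CCCCCC")), 2L)
  ## chain: A-B at d1, B-C at d1, A-C at d2 -> one component
  expect_equal(collapse_umis(c("AAAAAA", "AAAAAT", "AAAATT")), 1L)
  ## duplicates of one MID -> 1
  expect_equal(collapse_umis(rep("ACGTAC", 5)), 1L)
})

test_that("UMI collapse equals the O(n^2) component oracle on random sets", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(5:100, 1)
    mids <- replicate(n, paste(sample(c("A", "C", "G", "T"), 6,
                                      replace = TRUE), collapse = ""))
    expect_equal(collapse_umis(mids), oracle_umi_components(mids))
  }
})

test_that("UMI collapse is permutation-invariant and monotone", {
  set.seed(7)
  mids <- replicate(40, paste(sample(c("A", "C", "G", "T"), 6,
                                     replace = TRUE), collapse = ""))
  expect_equal(collapse_umis(mids), collapse_umis(rev(mids)))
  expect_equal(collapse_umis(mids), collapse_umis(sample(mids)))
  ## adding distinct MIDs never decreases the count
  base <- collapse_umis(mids[1:20])
  expect_gte(collapse_umis(mids[1:30]), base - 0)
  ## subset count <= superset count + removed
  expect_lte(base, collapse_umis(mids[1:30]))
})

test_that("matrix construction collapses MIDs per (spot, gene) locus", {
  lay <- emit_chip_layout(2, 2, pitch_um = 0.5, seed = 3)
  ref <- toy_reference("G1", seed = 3)
  tag <- ref$tag[ref$id == "G1"]
  ## same MID twice at the same spot -> 1; at two spots -> 2
  r1 <- c(make_read(lay$barcode[1], "AAAAAA"),
          make_read(lay$barcode[1], "AAAAAA"),
          make_read(lay$barcode[2], "AAAAAA"))
  m <- build_matrix(r1, rep(q30, 3), rep(tag, 3), lay, ref)
  expect_equal(sum(m$counts), 2)
  expect_equal(unname(m$read_stats["accepted"]), 3)

  ## single read -> total 1
  m1 <- build_matrix(r1[1], q30, tag, lay, ref)
  expect_equal(sum(m1$counts), 1)
})

test_that("error-free phantom demultiplexing reproduces the truth aggregation", {
  cfg <- phantom_config(seed = 23, field_size_um = c(150, 150),
                        barcode_error_rate = 0, mid_lowq_rate = 0,
                        mid_borderq_rate = 0, mid_n_rate = 0,
                        mito_fraction = 0, microbe_fraction = 0,
                        multimap_fraction = 0)
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(30, 30, pitch_um = 5, seed = 23)
  rd <- emit_stereo_reads(p, 1, lay, depth = 2)
  m <- build_matrix(rd$read1, rd$qual1, rd$read2, lay, rd$reference)
  ## oracle: aggregate the truth table directly with the same collapse rule
  tt <- rd$truth
  key <- paste(tt$x_index, tt$y_index, tt$id, sep = "|")
  oracle <- vapply(split(tt$mid, key), oracle_umi_components, integer(1))
  expect_equal(sum(m$counts), sum(oracle))
  ## spot-level totals agree
  spot_tot <- tapply(oracle, sub("\\|[^|]+$", "", names(oracle)), sum)
  got <- Matrix::rowSums(m$counts)
  names(got) <- sub("_", "|", names(got))
  expect_equal(sort(names(got)), sort(names(spot_tot)))
  expect_true(all(got[names(spot_tot)] == spot_tot))
})

test_that("QC summary computes tissue coverage, bin medians and mito share", {
  lay <- emit_chip_layout(40, 40, pitch_um = 0.5, seed = 5)
  ref <- toy_reference("G1", seed = 5)
  tag <- ref$tag[ref$id == "G1"]
  ## 4 distinct-MID reads on every spot -> uniform 4 counts/spot
  mids <- c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT")
  reads <- unlist(lapply(lay$barcode, function(b)
    vapply(mids, function(md) make_read(b, md), character(1))))
  m <- build_matrix(reads, rep(q30, length(reads)),
                    rep(tag, length(reads)), lay, ref)
  mask <- matrix(1, 20, 20)
  attr(mask, "pitch_um") <- 1
  ## bin200 at 0.5 um pitch would need a bigger chip; use bin20 (10 um):
  ## 20 x 20 spots/bin x 4 = 1600 MID per bin
  qc <- qc_summary(m, mask, bin_size = 20L)
  expect_equal(qc$mid_under_tissue_pct, 100)
  expect_equal(qc$median_mid_bin, 1600)
  expect_equal(qc$median_genes_bin, 1)
  expect_equal(qc$mito_pct, 0)

  ## mito-only input -> mito share 100%
  mt <- ref$tag[ref$id == "MT-CO1"]
  m2 <- build_matrix(reads[1:4], rep(q30, 4), rep(mt, 4), lay, ref)
  qc2 <- qc_summary(m2, mask, bin_size = 20L)
  expect_equal(qc2$mito_pct, 100)
  expect_error(qc_summary(m, matrix(0, 5, 5)), "empty tissue mask")
})

test_that("FASTQ round trip preserves reads and qualities", {
  cfg <- phantom_config(seed = 27, field_size_um = c(100, 100))
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(20, 20, pitch_um = 5, seed = 27)
  rd <- emit_stereo_reads(p, 1, lay, depth = 1)
  d <- tempfile(); dir.create(d)
  write_stereo_fastq(rd, file.path(d, "r1.fastq"), file.path(d, "r2.fastq"))
  back <- read_stereo_fastq(file.path(d, "r1.fastq"), file.path(d, "r2.fastq"))
  expect_equal(unname(back$read1), rd$read1)
  expect_equal(unname(back$qual1), rd$qual1)
  expect_equal(unname(back$read2), rd$read2)
  unlink(d, recursive = TRUE)
})

test_that("phantom demultiplexing recovers >= 99% of spots at 2% barcode error", {
  ## distance-3 barcodes + single-substitution errors: every error is
  ## uniquely correctable, and no read lands on a wrong spot
  cfg <- phantom_config(seed = 31, field_size_um = c(250, 250),
                        barcode_error_rate = 0.02, mid_lowq_rate = 0,
                        mid_borderq_rate = 0, mid_n_rate = 0)
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(50, 50, pitch_um = 5, seed = 31)
  rd <- emit_stereo_reads(p, 1, lay, depth = 4)
  dm <- demultiplex_read1(rd$read1, rd$qual1, lay)
  ok <- dm$status == "ok"
  correct <- ok & dm$x_index == rd$truth$x_index &
    dm$y_index == rd$truth$y_index
  expect_gte(mean(correct), 0.99)
  ## zero misassignments among accepted reads
  expect_equal(sum(ok & !correct), 0)
})
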