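## Read 1 layout: CID = bases 1-25 (spatial barcode), MID = bases 26-31
## (molecular identifier). Demultiplexing corrects at most one barcode
## substitution; correction must be unique or the read is rejected.

#' Demultiplex read 1 sequences against a chip layout
#'
#' The CID (bases 1-25) is matched exactly against the layout; failing that,
#' a unique Hamming-distance-1 neighbour wins; ambiguous or absent barcodes
#' are rejected. The MID (bases 26-31) is rejected if it contains an N or
#' has more than 2 bases with quality below Q10.
#'
#' @param seqs character vector of read-1 sequences (>= 31 bases).
#' @param quals character vector of Phred+33 quality strings.
#' @param layout a materialised [emit_chip_layout()] (or any data.frame with
#'   `barcode`, `x_index`, `y_index`).
#' @return data.frame per read: `status` (`"ok"` or rejection reason
#'   `"short"`/`"cid"`/`"mid"`), `x_index`, `y_index` (NA when rejected),
#'   `mid`, `corrected` (TRUE when a 1-mismatch correction was applied).
#' @export
demultiplex_read1 <- function(seqs, quals, layout) {
  stopifnot(length(seqs) == length(quals))
  n <- length(seqs)
  status <- rep("ok", n)
  xi <- rep(NA_integer_, n); yi <- rep(NA_integer_, n)
  corrected <- rep(FALSE, n)
  mid <- rep(NA_character_, n)

  short <- nchar(seqs) < 31L
  status[short] <- "short"
  live <- which(!short)

  cid <- substr(seqs[live], 1L, 25L)
  mid[live] <- substr(seqs[live], 26L, 31L)

  ## MID filter: N bases, or > 2 bases below Q10
  qm <- substr(quals[live], 26L, 31L)
  nlow <- vapply(qm, function(q) sum(utf8ToInt(q) - 33L < 10L), integer(1),
                 USE.NAMES = FALSE)
  midbad <- grepl("N", mid[live], fixed = TRUE) | nlow > 2L
  status[live[midbad]] <- "mid"
  live <- live[!midbad]
  if (!length(live)) {
    return(data.frame(status = status, x_index = xi, y_index = yi,
                      mid = mid, corrected = corrected,
                      stringsAsFactors = FALSE))
  }

  ## exact lookup via hashed environment
  lut <- new.env(hash = TRUE, size = nrow(layout) * 2L)
  for (r in seq_len(nrow(layout)))
    assign(layout$barcode[r], r, envir = lut)
  cid <- substr(seqs[live], 1L, 25L)
  hit <- vapply(cid, function(b) {
    row <- mget(b, envir = lut, ifnotfound = list(NA_integer_))[[1]]
    if (!is.na(row)) return(row)
    ## 1-mismatch correction: unique neighbour wins
    found <- NA_integer_
    for (nb in hamming1_neighbors(b)) {
      r2 <- mget(nb, envir = lut, ifnotfound = list(NA_integer_))[[1]]
      if (!is.na(r2)) {
        if (!is.na(found)) return(-1L)   # ambiguous
        found <- r2
      }
    }
    if (is.na(found)) -2L else -found - 2L   # encode corrected as -(row+2)
  }, integer(1), USE.NAMES = FALSE)

  nohit <- hit == -2L | hit == -1L
  status[live[nohit]] <- "cid"
  exact <- hit > 0L
  corr <- hit < -2L
  rows <- integer(length(hit))
  rows[exact] <- hit[exact]
  rows[corr] <- -hit[corr] - 2L
  ok <- exact | corr
  xi[live[ok]] <- layout$x_index[rows[ok]]
  yi[live[ok]] <- layout$y_index[rows[ok]]
  corrected[live[corr]] <- TRUE
  data.frame(status = status, x_index = xi, y_index = yi, mid = mid,
             corrected = corrected, stringsAsFactors = FALSE)
}

#' Assign read-2 sequences to genes or taxa
#'
#' Tag-based assignment against a [toy_reference()]: host or mitochondrial
#' hits with MAPQ > 10 are counted; host hits at MAPQ <= 10 (multi-mappers)
#' are discarded; microbial hits go to the taxon partition; unknown tags are
#' unassigned.
#'
#' @param seqs character vector of read-2 sequences.
#' @param reference a [toy_reference()].
#' @return data.frame per read: `kind` (`"gene"`, `"mito"`, `"taxon"`,
#'   `"lowmapq"`, `"unassigned"`), `id`, `mapq`, `taxon_class`.
#' @export
assign_gene <- function(seqs, reference) {
  if (is.null(reference) || nrow(reference) == 0)
    stop_sf("assign_gene: empty reference")
  m <- match(seqs, reference$tag)
  kind <- rep("unassigned", length(seqs))
  id <- rep(NA_character_, length(seqs))
  mapq <- rep(NA_integer_, length(seqs))
  cls <- rep(NA_character_, length(seqs))
  hit <- !is.na(m)
  id[hit] <- reference$id[m[hit]]
  mapq[hit] <- reference$mapq[m[hit]]
  type <- reference$type[m[hit]]
  kh <- kind[hit]
  kh[type == "host"] <- "gene"
  kh[type == "mito"] <- "mito"
  kh[type == "microbe"] <- "taxon"
  kh[(type %in% c("host", "multi")) & reference$mapq[m[hit]] <= 10L] <- "lowmapq"
  kind[hit] <- kh
  cls[hit] <- reference$class[m[hit]]
  data.frame(kind = kind, id = id, mapq = mapq, taxon_class = cls,
             stringsAsFactors = FALSE)
}

#' Collapse molecular identifiers allowing one mismatch
#'
#' Counts unique molecules at one (spot, gene) locus: the number of
#' connected components of the graph whose vertices are the distinct MIDs
#' and whose edges join MIDs at Hamming distance <= 1.
#'
#' @param mids character vector (multiset) of 6-mers over A/C/G/T.
#' @return integer molecule count.
#' @export
collapse_umis <- function(mids) {
  if (length(mids) == 0) return(0L)
  u <- unique(mids)
  n <- length(u)
  if (n == 1) return(1L)
  ## union-find over neighbour lookups (18 mutants per 6-mer)
  idx <- setNames(seq_len(n), u)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (nb in hamming1_neighbors(u[i])) {
      j <- idx[nb]
      if (!is.na(j) && j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Build the spot-level expression matrix from paired reads
#'
#' Runs demultiplexing and tag assignment, collapses MIDs per (spot, gene)
#' locus, and partitions counts into host genes, mitochondrial counts per
#' spot, and microbial counts per taxon.
#'
#' @param read1,qual1,read2 read vectors (e.g. from a `stereo_reads`
#'   emission or [read_stereo_fastq()]).
#' @param layout chip layout.
#' @param reference [toy_reference()].
#' @param section section id stored in the result.
#' @return `spot_expression`: list with `counts` (sparse spot x gene
#'   dgCMatrix; rownames `"x_y"` spot keys), `spots` (data.frame x_index,
#'   y_index, x_um, y_um), `mito_counts` (per spot, MID-collapsed),
#'   `microbe_counts` (named per-taxon MID counts), `taxon_class_counts`,
#'   `pitch_um`, `section`, `read_stats` (partition tallies).
#' @export
build_matrix <- function(read1, qual1, read2, layout, reference,
                         section = 1L) {
  dm <- demultiplex_read1(read1, qual1, layout)
  asg <- assign_gene(read2, reference)
  pitch <- attr(layout, "pitch_um") %||% 0.5

  ok <- dm$status == "ok"
  stats <- c(total = nrow(dm),
             accepted = sum(ok),
             rejected_cid = sum(dm$status == "cid"),
             rejected_mid = sum(dm$status == "mid"),
             rejected_short = sum(dm$status == "short"))

  spot_key <- paste(dm$x_index, dm$y_index, sep = "_")

  ## host gene counts: MID-collapse per (spot, gene)
  sel <- ok & asg$kind == "gene"
  counts <- collapse_by_locus(spot_key[sel], asg$id[sel], dm$mid[sel])
  ## mitochondrial counts per spot (collapsed per spot x mito gene)
  selm <- ok & asg$kind == "mito"
  mito <- collapse_by_locus(spot_key[selm], asg$id[selm], dm$mid[selm])
  mito_per_spot <- if (nrow(mito)) Matrix::rowSums(mito) else
    setNames(numeric(0), character(0))
  ## microbial MID counts per taxon (per-spot loci, summed over spots)
  selt <- ok & asg$kind == "taxon"
  microbe <- collapse_by_locus(spot_key[selt], asg$id[selt], dm$mid[selt])
  microbe_counts <- if (ncol(microbe)) Matrix::colSums(microbe) else
    setNames(numeric(0), character(0))
  cls_of <- setNames(reference$class, reference$id)
  taxon_class <- if (length(microbe_counts))
    tapply(microbe_counts, cls_of[names(microbe_counts)], sum) else
      setNames(numeric(0), character(0))

  keys <- rownames(counts) %||% character(0)
  xy <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  spots <- if (length(keys))
    data.frame(x_index = as.integer(xy[, 1]), y_index = as.integer(xy[, 2]))
  else data.frame(x_index = integer(), y_index = integer())
  spots$x_um <- spots$x_index * pitch
  spots$y_um <- spots$y_index * pitch

  structure(list(counts = counts, spots = spots,
                 mito_counts = mito_per_spot,
                 microbe_counts = microbe_counts,
                 taxon_class_counts = taxon_class,
                 pitch_um = pitch, section = section,
                 read_stats = stats),
            class = "spot_expression")
}

## sparse locus matrix with MID collapse: rows = spot keys, cols = ids
collapse_by_locus <- function(spot_key, id, mid) {
  if (!length(spot_key)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0, 0),
                                dimnames = list(character(), character())))
  }
  locus <- paste(spot_key, id, sep = "\r")
  counts <- vapply(split(mid, locus), collapse_umis, integer(1))
  parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  spots <- sort(unique(parts[, 1]))
  ids <- sort(unique(parts[, 2]))
  Matrix::sparseMatrix(i = match(parts[, 1], spots),
                       j = match(parts[, 2], ids),
                       x = as.numeric(counts),
                       dims = c(length(spots), length(ids)),
                       dimnames = list(spots, ids))
}

#' @export
print.spot_expression <- function(x, ...) {
  cat(sprintf("spot_expression: %d spots x %d genes, %d MID total (section %s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$section))
  invisible(x)
}

#' QC summary of a spot expression matrix
#'
#' Tissue-coverage and per-bin library statistics in the style of a chip QC
#' report: percentage of MIDs under the tissue mask, median reads / MIDs /
#' gene types per bin200 (100 um x 100 um at 0.5 um pitch), mitochondrial
#' MID percentage, and the total microbial MID count.
#'
#' @param matrix a `spot_expression`.
#' @param tissue_mask logical or 0/1 matrix over micron space with a
#'   `pitch_um` attribute; spots are tested at their micron position.
#' @param reads_per_spot optional numeric vector of raw read counts aligned
#'   with `matrix$spots` rows (defaults to MID counts, i.e. assumes one read
#'   per molecule).
#' @param bin_size bin side in spots for the per-bin medians (200 = 100 um).
#' @return `qc_summary` list: `mid_under_tissue_pct`, `median_reads_bin`,
#'   `median_mid_bin`, `median_genes_bin`, `mito_pct`,
#'   `microbiome_transcripts`, `bin_size`.
#' @export
qc_summary <- function(matrix, tissue_mask, reads_per_spot = NULL,
                       bin_size = 200L) {
  stopifnot(inherits(matrix, "spot_expression"))
  if (is.null(tissue_mask) || !any(tissue_mask > 0))
    stop_sf("qc_summary: empty tissue mask")
  mid_per_spot <- Matrix::rowSums(matrix$counts)
  under <- sample_raster(structure(tissue_mask * 1,
                                   pitch_um = attr(tissue_mask, "pitch_um") %||% 1),
                         matrix$spots$x_um, matrix$spots$y_um) > 0
  total_mid <- sum(mid_per_spot)
  pct <- if (total_mid > 0) 100 * sum(mid_per_spot[under]) / total_mid else NA_real_

  bx <- matrix$spots$x_index %/% bin_size
  by <- matrix$spots$y_index %/% bin_size
  key <- paste(bx, by)
  med_mid <- median(tapply(mid_per_spot, key, sum))
  reads <- reads_per_spot %||% mid_per_spot
  med_reads <- median(tapply(reads, key, sum))
  genes_bin <- tapply(seq_len(nrow(matrix$counts)), key, function(rows)
    sum(Matrix::colSums(matrix$counts[rows, , drop = FALSE]) > 0))
  med_genes <- median(genes_bin)

  mito_total <- sum(matrix$mito_counts)
  host_total <- sum(matrix$counts)
  mito_pct <- if (mito_total + host_total > 0)
    100 * mito_total / (mito_total + host_total) else NA_real_

  structure(list(mid_under_tissue_pct = pct,
                 median_reads_bin = unname(med_reads),
                 median_mid_bin = unname(med_mid),
                 median_genes_bin = unname(med_genes),
                 mito_pct = mito_pct,
                 microbiome_transcripts = sum(matrix$microbe_counts),
                 bin_size = bin_size),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(paste0("qc_summary: %.1f%% MID under tissue | median/bin%d: ",
                     "%.0f reads, %.0f MID, %.0f genes | mito %.2f%% | ",
                     "%d microbial MID\n"),
              x$mid_under_tissue_pct, x$bin_size, x$median_reads_bin,
              x$median_mid_bin, x$median_genes_bin, x$mito_pct,
              x$microbiome_transcripts))
  invisible(x)
}

#' Write a spot expression matrix as MTX + TSV
#'
#' @param matrix a `spot_expression`.
#' @param dir output directory (created if needed). Writes `matrix.mtx`,
#'   `spots.tsv` (key, x_index, y_index, x_um, y_um, mito_count),
#'   `genes.tsv`, `microbes.csv`.
#' @export
write_spot_matrix <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  sp <- matrix$spots
  sp$key <- rownames(matrix$counts)
  sp$mito_count <- as.numeric(matrix$mito_counts[sp$key])
  sp$mito_count[is.na(sp$mito_count)] <- 0
  write.table(sp, file.path(dir, "spots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = colnames(matrix$counts)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mb <- data.frame(taxon = names(matrix$microbe_counts),
                   mid_count = as.numeric(matrix$microbe_counts))
  write.table(mb, file.path(dir, "microbes.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
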