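## Phantom emitters: chip layout, paired reads, MSI datasets, seqIF images.

#' Generate a spatial chip layout
#'
#' Emits the barcode-to-coordinate table of a patterned capture chip: one
#' distinct 25-mer coordinate identity (CID) per spot on a full grid at
#' fixed pitch. Barcodes are built from an error-tolerant code (8 base-4
#' index digits, each written three times, plus a checksum base, then
#' position-permuted and symbol-remapped from the seed), which guarantees a
#' minimum pairwise Hamming distance of 3 so that single-mismatch barcode
#' correction is always unambiguous.
#'
#' @param n_spots_x,n_spots_y grid dimensions in spots.
#' @param pitch_um spot pitch in microns (0.5 for the submicron chip).
#' @param seed integer seed.
#' @param materialize if FALSE, return only the grid geometry (no barcode
#'   table); useful to reason about full-chip extents (a 1 cm chip is
#'   20000 x 20000 spots at 0.5 um) without generating 4e8 barcodes.
#' @return `chip_layout`: data.frame (barcode, x_index, y_index) with
#'   attributes `pitch_um`, `n_x`, `n_y`. Physical spot position is
#'   `index * pitch_um` (0-based indices, origin top-left).
#' @export
emit_chip_layout <- function(n_spots_x, n_spots_y, pitch_um = 0.5, seed = 1,
                             materialize = TRUE) {
  stopifnot(pitch_um > 0, n_spots_x >= 1, n_spots_y >= 1)
  n <- as.numeric(n_spots_x) * as.numeric(n_spots_y)
  if (!materialize) {
    df <- data.frame(barcode = character(), x_index = integer(),
                     y_index = integer(), stringsAsFactors = FALSE)
    return(structure(df, pitch_um = pitch_um, n_x = n_spots_x,
                     n_y = n_spots_y, class = c("chip_layout", "data.frame")))
  }
  if (n > 65536)
    stop_sf(paste0("emit_chip_layout: %g spots exceed the 65536 codewords of ",
                   "the distance-3 barcode code; use materialize = FALSE for ",
                   "geometry-only layouts"), n)
  set.seed(derive_seed(seed, "chip_layout"))
  perm <- sample.int(25)
  ## per-position random bijection digit -> base
  maps <- replicate(25, sample(DNA_BASES), simplify = FALSE)
  idx <- seq_len(n) - 1L
  ## 8 base-4 digits per index
  digs <- sapply(0:7, function(p) (idx %/% 4L^p) %% 4L)   # n x 8
  if (n == 1) digs <- matrix(digs, nrow = 1)
  code <- cbind(digs[, rep(1:8, each = 3), drop = FALSE],
                rowSums(digs) %% 4L)                      # n x 25 digits
  code <- code[, perm, drop = FALSE]
  chars <- vapply(seq_len(25), function(j) maps[[j]][code[, j] + 1L],
                  character(n))
  if (n == 1) chars <- matrix(chars, nrow = 1)
  barcodes <- apply(chars, 1, paste, collapse = "")
  df <- data.frame(barcode = barcodes,
                   x_index = as.integer(idx %% n_spots_x),
                   y_index = as.integer(idx %/% n_spots_x),
                   stringsAsFactors = FALSE)
  structure(df, pitch_um = pitch_um, n_x = n_spots_x, n_y = n_spots_y,
            class = c("chip_layout", "data.frame"))
}

#' Physical extent of a chip layout in microns
#' @param layout a `chip_layout`.
#' @return numeric length-2 (width, height) in microns.
#' @export
chip_extent_um <- function(layout) {
  c(attr(layout, "n_x"), attr(layout, "n_y")) * attr(layout, "pitch_um")
}

#' Toy tag reference for read assignment
#'
#' Maps exact transcript tag sequences carried by read 2 to host genes,
#' mitochondrial genes, a multi-mapping decoy (MAPQ 0), or microbial taxa
#' from a small fixed taxonomy (classes Actinomycetia and
#' Gammaproteobacteria). Stands in for genome alignment: unique host tags
#' get MAPQ 255, the decoy MAPQ 0, so the MAPQ > 10 filter is exercised.
#'
#' @param genes character vector of host gene names.
#' @param seed integer seed for tag sequences.
#' @param tag_length tag length in bases.
#' @return data.frame (tag, id, type, mapq, class) of class `toy_reference`.
#' @export
toy_reference <- function(genes, seed = 1, tag_length = 40) {
  set.seed(derive_seed(seed, "reference"))
  mito <- c("MT-CO1", "MT-ND1")
  taxa <- data.frame(
    id = c("Cutibacterium_acnes", "Streptomyces_sp",
           "Escherichia_coli", "Pseudomonas_aeruginosa"),
    class = c("Actinomycetia", "Actinomycetia",
              "Gammaproteobacteria", "Gammaproteobacteria"),
    stringsAsFactors = FALSE)
  ids <- c(genes, mito, "MULTIMAP", taxa$id)
  type <- c(rep("host", length(genes)), rep("mito", length(mito)), "multi",
            rep("microbe", nrow(taxa)))
  repeat {
    tags <- random_dna(length(ids), tag_length)
    if (!anyDuplicated(tags)) break
  }
  ref <- data.frame(tag = tags, id = ids, type = type,
                    mapq = ifelse(type == "multi", 0L, 255L),
                    class = c(rep(NA_character_,
                                  length(genes) + length(mito) + 1L),
                              taxa$class),
                    stringsAsFactors = FALSE)
  class(ref) <- c("toy_reference", "data.frame")
  ref
}

#' Emit paired spatial transcriptomics reads for one section
#'
#' Read 1 is the 25-base CID followed by the 6-base MID (positions 26-31)
#' with Phred qualities; read 2 carries the transcript tag of the sampled
#' gene (or a mitochondrial / microbial / multi-mapping tag). Per-spot gene
#' choice follows the compartment's gene program; barcode substitutions and
#' low-quality MIDs are injected at the configured rates. The full truth
#' table is retained so demultiplexing can be scored exactly.
#'
#' @param phantom a [make_phantom()] result.
#' @param section section number.
#' @param layout a materialised [emit_chip_layout()].
#' @param depth expected reads per on-tissue spot (Poisson).
#' @param reference optional [toy_reference()]; built from the phantom's
#'   genes if NULL.
#' @param seed optional override seed (defaults to the phantom seed).
#' @return `stereo_reads`: list with `read1`, `qual1`, `read2` (character
#'   vectors), `truth` (data.frame), `reference`, `layout_pitch_um`.
#' @export
emit_stereo_reads <- function(phantom, section, layout, depth = 2,
                              reference = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(layout, "chip_layout"))
  cfg <- phantom$config
  if (section < 1 || section > cfg$n_sections)
    stop_sf("emit_stereo_reads: section %d does not exist", section)
  if (is.null(reference))
    reference <- toy_reference(rownames(cfg$gene_programs), seed = cfg$seed)
  set.seed(derive_seed(seed %||% cfg$seed, paste0("reads", section)))

  field <- phantom$compartments[[section]]
  labs <- attr(field, "labels")
  pitch <- attr(layout, "pitch_um")
  sx <- layout$x_index * pitch
  sy <- layout$y_index * pitch
  lab <- field_label_at(field, sx, sy)
  lam <- ifelse(lab > 0, depth, depth * cfg$ambient_depth_frac)
  nreads <- rpois(length(lam), lam)
  spot <- rep.int(seq_len(nrow(layout)), nreads)
  n <- length(spot)
  if (n == 0)
    stop_sf("emit_stereo_reads: zero reads emitted; increase depth")

  ## class per read
  u <- runif(n)
  cls <- rep("host", n)
  p1 <- cfg$mito_fraction
  p2 <- p1 + cfg$microbe_fraction
  p3 <- p2 + cfg$multimap_fraction
  cls[u < p1] <- "mito"
  cls[u >= p1 & u < p2] <- "microbe"
  cls[u >= p2 & u < p3] <- "multi"

  ## gene per host read from the spot's compartment program (ambient reads
  ## draw from the mean program)
  gp <- cfg$gene_programs
  progs <- cbind(rowMeans(gp), gp[, labs[labs %in% colnames(gp)], drop = FALSE])
  prog_of_lab <- c(1L, vapply(labs, function(l)
    if (l %in% colnames(gp)) match(l, colnames(progs)) else 1L, integer(1)))
  read_lab <- lab[spot]
  read_prog <- prog_of_lab[read_lab + 1L]
  id <- character(n)
  for (pi in unique(read_prog)) {
    sel <- which(read_prog == pi & cls == "host")
    if (!length(sel)) next
    id[sel] <- sample(rownames(gp), length(sel), replace = TRUE,
                      prob = progs[, pi])
  }
  mito_ids <- reference$id[reference$type == "mito"]
  taxa_ids <- reference$id[reference$type == "microbe"]
  id[cls == "mito"] <- sample(mito_ids, sum(cls == "mito"), replace = TRUE)
  id[cls == "microbe"] <- sample(taxa_ids, sum(cls == "microbe"),
                                 replace = TRUE)
  id[cls == "multi"] <- "MULTIMAP"

  ## read 2 = tag of the id
  tag_of <- setNames(reference$tag, reference$id)
  read2 <- unname(tag_of[id])

  ## read 1 = CID + MID with injected errors
  cid <- layout$barcode[spot]
  cid_err <- runif(n) < cfg$barcode_error_rate
  if (any(cid_err)) {
    ce <- which(cid_err)
    pos <- sample.int(25, length(ce), replace = TRUE)
    for (k in seq_along(ce)) {
      s <- cid[ce[k]]
      old <- substr(s, pos[k], pos[k])
      new <- sample(DNA_BASES[DNA_BASES != old], 1)
      substr(s, pos[k], pos[k]) <- new
      cid[ce[k]] <- s
    }
  }
  mid <- random_dna_fast(n, 6)
  qmid <- matrix(30L, n, 6)
  um <- runif(n)
  lowq <- um < cfg$mid_lowq_rate
  bordq <- um >= cfg$mid_lowq_rate &
    um < cfg$mid_lowq_rate + cfg$mid_borderq_rate
  for (k in which(lowq)) qmid[k, sample.int(6, 3)] <- 8L
  for (k in which(bordq)) qmid[k, sample.int(6, 2)] <- 8L
  hasN <- runif(n) < cfg$mid_n_rate
  for (k in which(hasN)) {
    p <- sample.int(6, 1)
    substr(mid[k], p, p) <- "N"
  }
  qual1 <- vapply(seq_len(n), function(k)
    paste0(strrep(rawToChar(as.raw(30L + 33L)), 25),
           intToUtf8(qmid[k, ] + 33L)), character(1))
  read1 <- paste0(cid, mid)

  truth <- data.frame(read = seq_len(n),
                      x_index = layout$x_index[spot],
                      y_index = layout$y_index[spot],
                      class = cls, id = id, mid = mid,
                      cid_err = cid_err,
                      mid_bad = lowq | hasN,
                      stringsAsFactors = FALSE)
  structure(list(read1 = read1, qual1 = qual1, read2 = read2, truth = truth,
                 reference = reference, layout_pitch_um = pitch,
                 section = section),
            class = "stereo_reads")
}

## column-sampled fast random k-mers
random_dna_fast <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Write paired reads as FASTQ
#' @param reads a `stereo_reads` object.
#' @param r1_path,r2_path output FASTQ paths.
#' @export
write_stereo_fastq <- function(reads, r1_path, r2_path) {
  ids <- sprintf("read%07d", reads$truth$read)
  r1 <- Biostrings::DNAStringSet(reads$read1)
  names(r1) <- ids
  Biostrings::writeXStringSet(r1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual1))
  r2 <- Biostrings::DNAStringSet(reads$read2)
  names(r2) <- ids
  q2 <- Biostrings::BStringSet(strrep("?", nchar(reads$read2)))
  Biostrings::writeXStringSet(r2, r2_path, format = "fastq", qualities = q2)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files
#' @param r1_path,r2_path FASTQ paths (read 1 carries CID+MID).
#' @return list with `read1`, `qual1`, `read2` character vectors.
#' @export
read_stereo_fastq <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  list(read1 = as.character(r1),
       qual1 = as.character(S4Vectors::mcols(r1)$qualities),
       read2 = as.character(r2))
}

#' Emit an MSI dataset for one section
#'
#' Renders per-pixel centroided spectra on a 20 um grid: one peak per
#' configured m/z whose intensity follows the compartment analyte truth
#' raster sampled through the modality's ground-truth affine, plus Gaussian
#' intensity noise and a small ppm jitter on the m/z axis.
#'
#' @param phantom a [make_phantom()] result.
#' @param section section number.
#' @param peak_mzs numeric m/z centres (must be rows of the phantom's
#'   `analyte_maps`).
#' @param pixel_pitch_um MSI pixel pitch (20 um on the instrument).
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param mz_jitter_ppm per-peak m/z jitter, ppm standard deviation.
#' @param polarity `"negative"` or `"positive"`.
#' @param seed optional override seed.
#' @return an [msi_dataset()].
#' @export
emit_msi <- function(phantom, section, peak_mzs, pixel_pitch_um = 20,
                     noise_sd = 0, mz_jitter_ppm = 0, polarity = "negative",
                     seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), length(peak_mzs) >= 1)
  cfg <- phantom$config
  set.seed(derive_seed(seed %||% cfg$seed, paste0("msi", section)))
  nx <- max(1L, floor(cfg$field_size_um[1] / pixel_pitch_um))
  ny <- max(1L, floor(cfg$field_size_um[2] / pixel_pitch_um))
  lx <- (rep(seq_len(nx), times = ny) - 0.5) * pixel_pitch_um
  ly <- (rep(seq_len(ny), each = nx) - 0.5) * pixel_pitch_um
  tr <- phantom$truth_transforms$msi
  R <- apply_affine(tr, cbind(lx, ly))
  field <- phantom$compartments[[section]]
  truth <- lapply(peak_mzs, function(mz) {
    ras <- analyte_truth_raster(phantom, section, mz)
    v <- sample_raster(ras, R[, 1], R[, 2])
    v
  })
  npx <- nx * ny
  spectra <- vector("list", npx)
  for (p in seq_len(npx)) {
    ints <- vapply(truth, function(tv) tv[p], numeric(1))
    if (noise_sd > 0) ints <- pmax(0, ints + rnorm(length(ints), 0, noise_sd))
    mzs <- peak_mzs
    if (mz_jitter_ppm > 0)
      mzs <- mzs * (1 + rnorm(length(mzs), 0, mz_jitter_ppm) * 1e-6)
    o <- order(mzs)
    spectra[[p]] <- list(mz = mzs[o], intensity = ints[o])
  }
  coords <- data.frame(x_index = rep(seq_len(nx), times = ny) - 1L,
                       y_index = rep(seq_len(ny), each = nx) - 1L,
                       x_um = lx, y_um = ly)
  msi_dataset(coords, spectra, pixel_pitch_um, polarity)
}

## nearest-pixel raster sampling at micron coordinates; 0 outside
sample_raster <- function(raster, x_um, y_um) {
  pitch <- attr(raster, "pitch_um")
  i <- floor(x_um / pitch) + 1L
  j <- floor(y_um / pitch) + 1L
  ok <- i >= 1L & i <= nrow(raster) & j >= 1L & j <= ncol(raster)
  out <- numeric(length(x_um))
  out[ok] <- raster[cbind(i[ok], j[ok])]
  out
}

#' Emit a multiplex immunofluorescence image for one section
#'
#' Renders a DAPI channel of nuclear disks plus one channel per marker.
#' Cells contribute their phenotype's marker profile over the whole cell
#' disk; tissue-level stains (keratin over tumor, collagen over stroma) add
#' a diffuse compartment signal so tissue segmentation rules have support.
#' Cell positions are placed through the inverse of the modality's
#' ground-truth affine, i.e. the image is misaligned by exactly that
#' transform.
#'
#' @param phantom a [make_phantom()] result.
#' @param section section number.
#' @param markers channels to render; must include `"DAPI"`.
#' @param pixel_pitch_um pixel pitch (0.23 um on the instrument; coarser
#'   values render faster).
#' @param compartment_levels named numeric: diffuse channel intensity per
#'   compartment-level stain.
#' @param noise_sd additive Gaussian background noise.
#' @param nucleus_frac nucleus diameter as a fraction of cell diameter.
#' @param seed optional override seed.
#' @return `seqif_image`: list(`data` array x-by-y-by-channel, `channels`,
#'   `pitch_um`, `section`).
#' @export
emit_seqif <- function(phantom, section,
                       markers = c("DAPI", "Keratin8_18", "COL1A1",
                                   "ACTA2", "CD45"),
                       pixel_pitch_um = 2,
                       compartment_levels = c(tumor = 0.3, stroma = 0.3),
                       noise_sd = 0, nucleus_frac = 0.4, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (!"DAPI" %in% markers)
    stop_sf("emit_seqif: markers must include DAPI")
  cfg <- phantom$config
  set.seed(derive_seed(seed %||% cfg$seed, paste0("seqif", section)))
  nx <- max(1L, floor(cfg$field_size_um[1] / pixel_pitch_um))
  ny <- max(1L, floor(cfg$field_size_um[2] / pixel_pitch_um))
  arr <- array(0, dim = c(nx, ny, length(markers)),
               dimnames = list(NULL, NULL, markers))
  tr <- phantom$truth_transforms$seqif
  inv <- invert_affine(tr)

  ## diffuse compartment-level stains (sampled through the truth affine)
  comp_marker <- c(tumor = "Keratin8_18", stroma = "COL1A1")
  base_field <- attr(phantom$compartments[[section]], "base") %||%
    phantom$compartments[[section]]
  labs <- attr(base_field, "labels")
  lx <- (rep(seq_len(nx), times = ny) - 0.5) * pixel_pitch_um
  ly <- (rep(seq_len(ny), each = nx) - 0.5) * pixel_pitch_um
  R <- apply_affine(tr, cbind(lx, ly))
  lab <- field_label_at(base_field, R[, 1], R[, 2])
  for (comp in names(compartment_levels)) {
    mk <- comp_marker[[comp]]
    if (is.null(mk) || !mk %in% markers || !comp %in% labs) next
    sel <- lab == match(comp, labs)
    arr[, , mk] <- arr[, , mk] +
      matrix(ifelse(sel, compartment_levels[[comp]], 0), nx, ny)
  }

  ## cells: nuclei into DAPI, cell disks into marker channels
  cells <- phantom$cells[phantom$cells$section == section, , drop = FALSE]
  prof <- cfg$marker_profiles
  if (nrow(cells) > 0) {
    loc <- apply_affine(inv, cbind(cells$x_um, cells$y_um))
    for (k in seq_len(nrow(cells))) {
      ph <- cells$phenotype[k]
      rcell <- cells$diameter_um[k] / 2
      rnuc <- rcell * nucleus_frac
      arr[, , "DAPI"] <- draw_disk(arr[, , "DAPI"], loc[k, 1], loc[k, 2],
                                   rnuc, 1, pixel_pitch_um)
      for (mk in intersect(markers, colnames(prof))) {
        v <- if (ph %in% rownames(prof)) prof[ph, mk] else 0
        if (v > 0.05)
          arr[, , mk] <- draw_disk(arr[, , mk], loc[k, 1], loc[k, 2],
                                   rcell, v, pixel_pitch_um)
      }
    }
  }
  if (noise_sd > 0) {
    arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim = dim(arr),
                       dimnames = dimnames(arr))
    arr[arr < 0] <- 0
  }
  structure(list(data = arr, channels = markers, pitch_um = pixel_pitch_um,
                 section = section),
            class = "seqif_image")
}

## additive disk rendering (max blend so overlapping cells stay bounded)
draw_disk <- function(img, cx_um, cy_um, r_um, value, pitch) {
  i0 <- max(1L, floor((cx_um - r_um) / pitch))
  i1 <- min(nrow(img), ceiling((cx_um + r_um) / pitch))
  j0 <- max(1L, floor((cy_um - r_um) / pitch))
  j1 <- min(ncol(img), ceiling((cy_um + r_um) / pitch))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  px <- (ii - 0.5) * pitch; py <- (jj - 0.5) * pitch
  D2 <- outer((px - cx_um)^2, (py - cy_um)^2, "+")
  sub <- img[ii, jj, drop = FALSE]
  sub[D2 <= r_um^2] <- pmax(sub[D2 <= r_um^2], value)
  img[ii, jj] <- sub
  img
}

#' Write a seqIF image as a multi-channel TIFF
#' @param img a `seqif_image`.
#' @param path output TIFF path (one page per channel; channel names are
#'   stored in the page descriptions).
#' @export
write_seqif_tiff <- function(img, path) {
  pages <- lapply(seq_along(img$channels), function(c) {
    m <- t(img$data[, , c])          # TIFF rows = y
    m / max(1, max(m))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write the phantom truth manifest as JSON
#'
#' Records the generator configuration (scalars), ground-truth transforms
#' and the cell table, so downstream scoring does not need the in-memory
#' phantom.
#'
#' @param phantom a [make_phantom()] result.
#' @param path output JSON path.
#' @export
write_truth_manifest <- function(phantom, path) {
  cfg <- phantom$config
  jsonlite::write_json(list(
    seed = cfg$seed,
    field_size_um = cfg$field_size_um,
    n_sections = cfg$n_sections,
    section_thickness_um = cfg$section_thickness_um,
    section_spacing_um = cfg$section_spacing_um,
    section_z_um = phantom$section_z_um,
    transforms = lapply(phantom$truth_transforms, function(t)
      cbind(t$A, t$b)),
    cells = phantom$cells), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
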