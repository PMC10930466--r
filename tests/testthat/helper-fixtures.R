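## shared test fixtures and independent oracles

## adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

## O(n^2) Hamming connected-components oracle for UMI collapse
oracle_umi_components <- function(mids) {
  u <- unique(mids)
  n <- length(u)
  if (n == 0) return(0L)
  ch <- strsplit(u, "", fixed = TRUE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- sum(ch[[i]] != ch[[j]]) <= 1
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] & !seen))
    }
  }
  comp
}

## seqIF image built directly from channel matrices
seqif_from_channels <- function(channels, pitch_um = 1) {
  nms <- names(channels)
  arr <- array(0, dim = c(nrow(channels[[1]]), ncol(channels[[1]]),
                          length(channels)),
               dimnames = list(NULL, NULL, nms))
  for (k in seq_along(channels)) arr[, , k] <- channels[[k]]
  structure(list(data = arr, channels = nms, pitch_um = pitch_um,
                 section = 1L), class = "seqif_image")
}

## small deterministic MSI dataset (nx x ny grid, given peaks per pixel)
msi_fixture <- function(nx, ny, mz, intensity_fun, pitch_um = 20,
                        polarity = "negative") {
  coords <- expand.grid(x_index = seq_len(nx) - 1L,
                        y_index = seq_len(ny) - 1L)
  spectra <- lapply(seq_len(nrow(coords)), function(i) {
    it <- intensity_fun(coords$x_index[i], coords$y_index[i])
    o <- order(mz)
    list(mz = mz[o], intensity = it[o])
  })
  msi_dataset(coords, spectra, pitch_um, polarity)
}

## phantom + demultiplexed matrices under tissue mask, shared by the
## clustering / marker / integration tests (moderate size, seeded)
build_phantom_run <- function(seed = 11, depth = 3, n_chip = 120,
                              chip_pitch = 5, bin_size = 5) {
  cfg <- phantom_config(seed = seed)
  ph <- make_phantom(cfg)
  lay <- emit_chip_layout(n_chip, n_chip, pitch_um = chip_pitch, seed = seed)
  mask <- ph$compartments[[1]] > 0
  attr(mask, "pitch_um") <- attr(ph$compartments[[1]], "pitch_um")
  reference <- toy_reference(rownames(cfg$gene_programs), seed = seed)
  binned <- lapply(seq_len(cfg$n_sections), function(s) {
    rd <- emit_stereo_reads(ph, s, lay, depth = depth, reference = reference)
    m <- build_matrix(rd$read1, rd$qual1, rd$read2, lay, reference,
                      section = s)
    qc_filter(bin_spots(m, bin_size), tissue_mask = mask)
  })
  tx <- preprocess(binned)
  list(phantom = ph, layout = lay, binned = binned, tx = tx,
       mask = mask, side_um = bin_size * chip_pitch)
}

## truth compartment code at bin centres
truth_compartments <- function(phantom, labels_df, side_um) {
  field <- phantom$compartments[[1]]
  spatialfuse:::field_label_at(field,
                               (labels_df$bin_x + 0.5) * side_um,
                               (labels_df$bin_y + 0.5) * side_um)
}
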