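#' Aggregate spots into square bins
#'
#' Sums spot counts over bins of `bin_size` x `bin_size` spots:
#' `bin = floor(index / bin_size)`. At the default 0.5 um spot pitch, bin50
#' squares are 25 um x 25 um and bin200 squares 100 um x 100 um. Counts are
#' conserved exactly.
#'
#' @param matrix a `spot_expression` from [build_matrix()].
#' @param bin_size bin side in spots (>= 1).
#' @return `binned_expression`: list with `counts` (sparse bin x gene),
#'   `bins` (data.frame bin_x, bin_y, section), `mito` (per-bin
#'   mitochondrial counts), `bin_size`, `pitch_um`, `side_um`, `section`.
#' @export
bin_spots <- function(matrix, bin_size) {
  stopifnot(inherits(matrix, "spot_expression"), bin_size >= 1)
  bin_size <- as.integer(bin_size)
  bx <- matrix$spots$x_index %/% bin_size
  by <- matrix$spots$y_index %/% bin_size
  key <- paste(bx, by, sep = "_")
  f <- factor(key, levels = unique(key))
  agg <- Matrix::t(Matrix::fac2sparse(f)) # spots x bins indicator
  counts <- Matrix::t(Matrix::t(matrix$counts) %*% agg)
  rownames(counts) <- levels(f)

  mito <- setNames(rep(0, nlevels(f)), levels(f))
  if (length(matrix$mito_counts)) {
    msp <- do.call(rbind, strsplit(names(matrix$mito_counts), "_",
                                   fixed = TRUE))
    mkey <- paste(as.integer(msp[, 1]) %/% bin_size,
                  as.integer(msp[, 2]) %/% bin_size, sep = "_")
    ms <- tapply(as.numeric(matrix$mito_counts), mkey, sum)
    common <- intersect(names(ms), names(mito))
    mito[common] <- ms[common]
    extra <- setdiff(names(ms), names(mito))
    if (length(extra)) mito <- c(mito, ms[extra])
  }
  keys <- rownames(counts)
  xy <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  bins <- data.frame(bin_x = as.integer(xy[, 1]),
                     bin_y = as.integer(xy[, 2]),
                     section = matrix$section)
  structure(list(counts = methods::as(counts, "CsparseMatrix"), bins = bins,
                 mito = mito[keys], bin_size = bin_size,
                 pitch_um = matrix$pitch_um,
                 side_um = bin_size * matrix$pitch_um,
                 section = matrix$section),
            class = "binned_expression")
}

#' @export
print.binned_expression <- function(x, ...) {
  cat(sprintf("binned_expression: %d bins (bin%d, %.1f um side) x %d genes\n",
              nrow(x$counts), x$bin_size, x$side_um, ncol(x$counts)))
  invisible(x)
}

#' Quality-filter binned expression
#'
#' Removes bins with fewer than `min_genes` detected genes or with a
#' mitochondrial percentage strictly above `max_mito_pct`, and genes
#' detected in fewer than `min_bins` bins. Filters are iterated to a fixed
#' point so the operation is idempotent.
#'
#' @param binned a `binned_expression`.
#' @param min_genes minimum detected genes per bin.
#' @param min_bins minimum bins a gene must appear in to be retained.
#' @param max_mito_pct mitochondrial percentage cutoff (strict `>` removal).
#' @param tissue_mask optional raster (with `pitch_um` attribute) over
#'   micron space; bins whose centre falls outside the mask are dropped
#'   first, mirroring the under-tissue restriction of chip analyses.
#' @return filtered `binned_expression`.
#' @export
qc_filter <- function(binned, min_genes = 3, min_bins = 3,
                      max_mito_pct = 20, tissue_mask = NULL) {
  stopifnot(inherits(binned, "binned_expression"))
  counts <- binned$counts
  mito <- binned$mito
  bins <- binned$bins
  if (!is.null(tissue_mask)) {
    cx <- (bins$bin_x + 0.5) * binned$side_um
    cy <- (bins$bin_y + 0.5) * binned$side_um
    under <- sample_raster(structure(tissue_mask * 1,
                                     pitch_um = attr(tissue_mask, "pitch_um") %||% 1),
                           cx, cy) > 0
    counts <- counts[under, , drop = FALSE]
    mito <- mito[under]
    bins <- bins[under, , drop = FALSE]
    if (nrow(counts) == 0)
      stop_sf("qc_filter: no bins under the tissue mask")
  }
  repeat {
    host <- Matrix::rowSums(counts)
    mpct <- ifelse(host + mito > 0, 100 * mito / (host + mito), 0)
    keep_bin <- Matrix::rowSums(counts > 0) >= min_genes & mpct <= max_mito_pct
    keep_gene <- Matrix::colSums(counts[keep_bin, , drop = FALSE] > 0) >= min_bins
    if (all(keep_bin) && all(keep_gene)) break
    counts <- counts[keep_bin, keep_gene, drop = FALSE]
    mito <- mito[keep_bin]
    bins <- bins[keep_bin, , drop = FALSE]
    if (nrow(counts) == 0)
      stop_sf("qc_filter: all bins removed by QC thresholds")
  }
  out <- binned
  out$counts <- counts
  out$mito <- mito
  out$bins <- bins
  out
}

#' Merge sections, normalise, and log-transform
#'
#' Concatenates the binned sections of one batch (so downstream clustering
#' is shared across sections), scales each bin's counts to the median
#' per-bin total of the merged data, and applies `log1p`.
#'
#' @param binned_list list of `binned_expression` objects (>= 1).
#' @param target_sum normalisation target; default = median per-bin total.
#' @return list of class `tx_matrix`: `data` (sparse bins x genes,
#'   normalised log counts), `meta` (bin_x, bin_y, section per row),
#'   `target_sum`, `bin_size`, `side_um`.
#' @export
preprocess <- function(binned_list, target_sum = NULL) {
  if (inherits(binned_list, "binned_expression"))
    binned_list <- list(binned_list)
  stopifnot(length(binned_list) >= 1)
  genes <- Reduce(union, lapply(binned_list, function(b) colnames(b$counts)))
  mats <- lapply(binned_list, function(b) {
    m <- b$counts
    miss <- setdiff(genes, colnames(m))
    if (length(miss)) {
      pad <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(nrow(m), length(miss)),
                                  dimnames = list(rownames(m), miss))
      m <- cbind(m, pad)
    }
    m[, genes, drop = FALSE]
  })
  counts <- do.call(rbind, mats)
  meta <- do.call(rbind, lapply(binned_list, function(b) b$bins))
  rownames(counts) <- paste(meta$section, meta$bin_x, meta$bin_y, sep = "_")
  tot <- Matrix::rowSums(counts)
  if (is.null(target_sum)) target_sum <- median(tot[tot > 0])
  sf <- ifelse(tot > 0, target_sum / tot, 0)
  norm <- Matrix::Diagonal(x = sf) %*% counts
  data <- norm
  data@x <- log1p(data@x)
  dimnames(data) <- dimnames(counts)
  structure(list(data = data, meta = meta, target_sum = target_sum,
                 bin_size = binned_list[[1]]$bin_size,
                 side_um = binned_list[[1]]$side_um),
            class = "tx_matrix")
}

#' PCA + kNN graph + Leiden clustering of bins
#'
#' Standard community-detection clustering of the normalised matrix:
#' principal components, a shared-nearest-neighbour graph (Jaccard-weighted
#' kNN), and Leiden with the modularity objective. Deterministic given
#' `seed`.
#'
#' @param x a `tx_matrix` from [preprocess()].
#' @param n_pcs number of principal components.
#' @param n_neighbors kNN neighbourhood size.
#' @param resolution Leiden resolution.
#' @param seed integer seed (mandatory).
#' @return data.frame: bin_x, bin_y, section, cluster (integer, 1-based),
#'   pc1, pc2.
#' @export
cluster_bins <- function(x, n_pcs = 30, n_neighbors = 25, resolution = 1.0,
                         seed) {
  stopifnot(inherits(x, "tx_matrix"))
  if (missing(seed)) stop_sf("cluster_bins: 'seed' is mandatory")
  n <- nrow(x$data)
  if (n == 0) stop_sf("cluster_bins: empty matrix")
  if (n <= n_neighbors)
    stop_sf("cluster_bins: %d bins <= %d neighbours", n, n_neighbors)
  set.seed(derive_seed(seed, "leiden"))
  npc <- min(n_pcs, ncol(x$data) - 1L, n - 1L)
  pcs <- prcomp(as.matrix(x$data), center = TRUE, scale. = FALSE,
                rank. = npc)$x
  g <- snn_graph(pcs, k = n_neighbors)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  lab <- as.integer(igraph::membership(cl))
  data.frame(bin_x = x$meta$bin_x, bin_y = x$meta$bin_y,
             section = x$meta$section, cluster = lab,
             pc1 = pcs[, 1], pc2 = if (npc >= 2) pcs[, 2] else 0)
}

## Jaccard-weighted shared-nearest-neighbour graph from a score matrix
snn_graph <- function(scores, k, prune = 1 / 15) {
  n <- nrow(scores)
  d <- as.matrix(dist(scores))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k + 1)]))  # incl self
  ## adjacency of kNN sets
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- as.matrix(shared) / (2 * (k + 1) - as.matrix(shared))
  jac[jac < prune] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Wilcoxon rank-sum test, one group against the rest
#'
#' Two-sided normal approximation with tie correction (no continuity
#' correction), vectorised over the columns of `data`.
#'
#' @param data numeric matrix (observations x genes).
#' @param in_group logical vector over rows.
#' @return data.frame per gene: `statistic` (rank-sum U of the in-group),
#'   `z`, `p_value`.
#' @export
wilcoxon_rank_sum <- function(data, in_group) {
  data <- as.matrix(data)
  n1 <- sum(in_group); n2 <- sum(!in_group)
  if (n1 < 2 || n2 < 2)
    stop_sf("wilcoxon_rank_sum: both groups need >= 2 observations")
  N <- n1 + n2
  res <- apply(data, 2, function(v) {
    r <- rank(v)
    R1 <- sum(r[in_group])
    U <- R1 - n1 * (n1 + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    mu <- n1 * n2 / 2
    if (sig2 <= 0) return(c(U, 0, 1))
    z <- (U - mu) / sqrt(sig2)
    c(U, z, 2 * pnorm(-abs(z)))
  })
  data.frame(gene = colnames(data), statistic = res[1, ], z = res[2, ],
             p_value = res[3, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank genes per cluster and select shared markers
#'
#' Per section and per cluster, tests each gene cluster-vs-rest with the
#' Wilcoxon rank-sum test on the normalised data and computes the log2 fold
#' change of mean de-logged expression (pseudo-count 1e-9). A gene is a
#' selected marker of a cluster iff `p < p_cut` and `log2fc > lfc_cut` in
#' every section. Raw p-values drive selection; BH-adjusted values are
#' reported alongside.
#'
#' @param x a `tx_matrix`.
#' @param labels integer cluster labels aligned with rows of `x$data` (e.g.
#'   `cluster_bins()$cluster`).
#' @param p_cut,lfc_cut selection thresholds.
#' @return `marker_table` data.frame per (cluster, gene): `p_value` (max
#'   over sections), `p_adj`, `log2fc` (min over sections),
#'   `n_sections_selected`, `selected`; attribute `per_section` holds the
#'   full per-section table.
#' @export
rank_and_select <- function(x, labels, p_cut = 0.01, lfc_cut = 1) {
  stopifnot(inherits(x, "tx_matrix"), length(labels) == nrow(x$data))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2)
    stop_sf("rank_and_select: need >= 2 clusters")
  sections <- sort(unique(x$meta$section))
  per <- list()
  for (s in sections) {
    rows <- x$meta$section == s
    dat <- as.matrix(x$data[rows, , drop = FALSE])
    labs <- labels[rows]
    for (cl in clusters) {
      ing <- labs == cl
      if (sum(ing) < 2 || sum(!ing) < 2) {
        warning(sprintf("cluster %s has < 2 bins in section %s; skipped",
                        cl, s))
        next
      }
      w <- wilcoxon_rank_sum(dat, ing)
      mu1 <- colMeans(expm1(dat[ing, , drop = FALSE]))
      mu0 <- colMeans(expm1(dat[!ing, , drop = FALSE]))
      w$log2fc <- log2((mu1 + 1e-9) / (mu0 + 1e-9))
      w$cluster <- cl
      w$section <- s
      per[[length(per) + 1L]] <- w
    }
  }
  ps <- do.call(rbind, per)
  ps$p_adj <- p.adjust(ps$p_value, method = "BH")
  key <- paste(ps$cluster, ps$gene, sep = "\r")
  agg <- do.call(rbind, lapply(split(ps, key), function(d) {
    data.frame(cluster = d$cluster[1], gene = d$gene[1],
               p_value = max(d$p_value), p_adj = max(d$p_adj),
               log2fc = min(d$log2fc),
               n_sections_selected = sum(d$p_value < p_cut &
                                           d$log2fc > lfc_cut),
               stringsAsFactors = FALSE)
  }))
  agg$selected <- agg$n_sections_selected == length(sections)
  agg <- agg[order(agg$cluster, agg$p_value), ]
  rownames(agg) <- NULL
  attr(agg, "per_section") <- ps
  class(agg) <- c("marker_table", "data.frame")
  agg
}
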