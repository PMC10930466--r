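## small spot_expression built by hand
spot_fixture <- function(counts, x, y, mito = NULL, pitch = 0.5,
                         section = 1L) {
  keys <- paste(x, y, sep = "_")
  rownames(counts) <- keys
  m <- Matrix::Matrix(counts, sparse = TRUE)
  mito <- mito %||% setNames(rep(0, length(keys)), keys)
  structure(list(counts = methods::as(m, "CsparseMatrix"),
                 spots = data.frame(x_index = x, y_index = y,
                                    x_um = x * pitch, y_um = y * pitch),
                 mito_counts = mito,
                 microbe_counts = setNames(numeric(0), character(0)),
                 taxon_class_counts = setNames(numeric(0), character(0)),
                 pitch_um = pitch, section = section,
                 read_stats = c(total = sum(counts))),
            class = "spot_expression")
}

test_that("binning sums counts on the bin grid and conserves totals", {
  set.seed(12)
  n <- 60
  counts <- matrix(rpois(n * 4, 1), n, 4,
                   dimnames = list(NULL, paste0("G", 1:4)))
  x <- sample(0:99, n); y <- sample(0:99, n)
  sp <- spot_fixture(counts, x, y)

  ## bin 1 = identity
  b1 <- bin_spots(sp, 1)
  expect_equal(sum(b1$counts), sum(counts))
  expect_equal(nrow(b1$counts), length(unique(paste(x, y))))

  ## bin50 at 0.5 um pitch -> 25 um side
  b50 <- bin_spots(sp, 50)
  expect_equal(b50$side_um, 25)
  b20 <- bin_spots(sp, 20)
  expect_equal(b20$side_um, 10)

  ## per-gene totals conserved
  expect_equal(as.numeric(Matrix::colSums(b50$counts)),
               as.numeric(colSums(counts)))
  ## bin coordinates follow floor(index / bin_size)
  expect_setequal(paste(b50$bins$bin_x, b50$bins$bin_y),
                  unique(paste(x %/% 50, y %/% 50)))
})

test_that("QC filter enforces gene and mito thresholds and is idempotent", {
  ## 5-bin hand-enumerated fixture (bins as rows after bin_size 1)
  counts <- rbind(c(5, 4, 3, 0), # bin A: 3 genes -> kept
                  c(1, 1, 0, 0), # bin B: 2 genes -> removed
                  c(2, 3, 1, 1), # bin C: 4 genes, mito 25% -> removed
                  c(4, 4, 2, 0), # bin D: 3 genes, mito 20% -> kept (strict >)
                  c(3, 2, 1, 0)) # bin E: 3 genes -> kept
  colnames(counts) <- paste0("G", 1:4)
  mito <- c(0, 0, 7/3, 10/4, 0) * rowSums(counts) / rowSums(counts)
  ## mito percentages: C = 25%, D = 20% exactly
  mito <- c(0, 0, sum(counts[3, ]) / 3, sum(counts[4, ]) / 4, 0)
  sp <- spot_fixture(counts, x = 0:4, y = rep(0, 5), mito = setNames(
    mito, paste(0:4, 0, sep = "_")))
  b <- bin_spots(sp, 1)
  f <- qc_filter(b)
  keep <- paste(f$bins$bin_x, f$bins$bin_y)
  expect_setequal(keep, c("0 0", "3 0", "4 0"))
  ## gene G4 appears in < 3 surviving bins -> dropped
  expect_false("G4" %in% colnames(f$counts))
  ## idempotence
  f2 <- qc_filter(f)
  expect_equal(f2$counts, f$counts)
  expect_equal(f2$bins, f$bins)
  ## removing everything errors
  expect_error(qc_filter(bin_spots(spot_fixture(
    matrix(1, 2, 1, dimnames = list(NULL, "G1")), 0:1, c(0, 0)), 1)),
    "all bins removed")
})

test_that("normalisation scales to the median bin total and preserves order", {
  counts <- rbind(c(10, 0, 0), c(0, 20, 20), c(2, 2, 0), c(0, 0, 0))
  colnames(counts) <- paste0("G", 1:3)
  sp <- spot_fixture(counts, x = 0:3, y = rep(0, 4))
  b <- bin_spots(sp, 1)
  tx <- preprocess(list(b))
  d <- as.matrix(tx$data)
  ## all-zero bin stays zero
  expect_true(all(d[4, ] == 0))
  ## monotone within a bin: raw a >= b => transformed a >= b
  expect_true(all(diff(order(counts[2, ], d[2, ])) != 0 |
                    TRUE))  # orders consistent
  for (i in 1:3) {
    o <- order(counts[i, ])
    expect_true(all(diff(d[i, o]) >= -1e-12))
  }
  ## two identical sections merged -> identical value distributions
  b1 <- bin_spots(spot_fixture(counts, 0:3, rep(0, 4), section = 1L), 1)
  b2 <- bin_spots(spot_fixture(counts, 0:3, rep(0, 4), section = 2L), 1)
  tx2 <- preprocess(list(b1, b2))
  d1 <- as.matrix(tx2$data[tx2$meta$section == 1, ])
  d2 <- as.matrix(tx2$data[tx2$meta$section == 2, ])
  expect_equal(unname(d1), unname(d2))
})

test_that("the rank-sum test matches the tie-corrected normal approximation", {
  set.seed(33)
  for (rep in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    ## mixture of continuous and tied data
    v <- if (rep %% 2 == 0) c(rnorm(n1, 1), rnorm(n2)) else
      sample(0:4, n1 + n2, replace = TRUE) + 0
    grp <- c(rep(TRUE, n1), rep(FALSE, n2))
    got <- wilcoxon_rank_sum(matrix(v, ncol = 1,
                                    dimnames = list(NULL, "g")), grp)
    ref <- stats::wilcox.test(v[grp], v[!grp], exact = FALSE,
                              correct = FALSE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_lt(abs(got$p_value - ref$p.value), 1e-10)
  }
})

test_that("marker selection applies both thresholds across all sections", {
  ## two clusters x two sections; G1 planted at 4x in cluster 1,
  ## G2 identical everywhere, G3 modest fold (< 2x) with tiny p
  set.seed(44)
  n <- 60
  ## per-bin totals balanced across clusters so library-size normalisation
  ## does not distort the planted folds
  mk_section <- function(s) {
    counts <- cbind(G1 = rpois(2 * n, rep(c(40, 10), each = n)),
                    G2 = rpois(2 * n, 20),
                    G3 = rpois(2 * n, rep(c(36, 20), each = n)),
                    G4 = rpois(2 * n, rep(c(20, 66), each = n)))
    spot_fixture(counts, x = seq_len(2 * n) - 1, y = rep(0, 2 * n),
                 section = s)
  }
  b <- lapply(1:2, function(s) bin_spots(mk_section(s), 1))
  tx <- preprocess(b)
  labels <- rep(rep(1:2, each = n), 2)
  mt <- rank_and_select(tx, labels)
  sel1 <- mt[mt$cluster == 1 & mt$selected, "gene"]
  expect_true("G1" %in% sel1)
  expect_false("G2" %in% sel1)
  ## G3: p is tiny but log2FC < 1 -> excluded
  g3 <- mt[mt$cluster == 1 & mt$gene == "G3", ]
  expect_lt(g3$p_value, 1e-4)
  expect_lt(g3$log2fc, 1)
  expect_false(g3$selected)
  expect_error(rank_and_select(tx, rep(1, length(labels))), ">= 2 clusters")
})

test_that("two well-separated programs resolve into exactly two clusters", {
  set.seed(55)
  n <- 25
  prog <- rbind(c(30, 2, 2, 2), c(2, 30, 2, 2))
  counts <- t(sapply(rep(1:2, each = n), function(g)
    rpois(4, prog[g, ])))
  colnames(counts) <- paste0("G", 1:4)
  sp <- spot_fixture(counts, x = seq_len(2 * n) - 1, y = rep(0, 2 * n))
  tx <- preprocess(list(bin_spots(sp, 1)))
  lab <- cluster_bins(tx, n_pcs = 3, n_neighbors = 15, seed = 5)
  expect_equal(length(unique(lab$cluster)), 2)
  expect_equal(ari(lab$cluster, rep(1:2, each = n)), 1)

  ## duplicating the data as a second "section" leaves clusters unchanged:
  ## per-section labels agree with the single-section run and with each
  ## other (composition independent of section)
  m <- 13
  counts2 <- counts[c(1:m, n + 1:m), ]
  single <- cluster_bins(preprocess(list(bin_spots(
    spot_fixture(counts2, seq_len(2 * m) - 1, rep(0, 2 * m)), 1))),
    n_pcs = 3, n_neighbors = 12, seed = 5)
  b1 <- bin_spots(spot_fixture(counts2, seq_len(2 * m) - 1, rep(0, 2 * m),
                               section = 1L), 1)
  b2 <- bin_spots(spot_fixture(counts2, seq_len(2 * m) - 1, rep(0, 2 * m),
                               section = 2L), 1)
  tx2 <- preprocess(list(b1, b2))
  lab2 <- cluster_bins(tx2, n_pcs = 3, n_neighbors = 12, seed = 5)
  expect_equal(lab2$cluster[lab2$section == 1],
               lab2$cluster[lab2$section == 2])
  expect_equal(ari(lab2$cluster[lab2$section == 1], single$cluster), 1)
  expect_equal(ari(lab2$cluster[lab2$section == 2], single$cluster), 1)
})

test_that("degenerate clustering inputs are handled", {
  counts <- matrix(5, 40, 3, dimnames = list(NULL, paste0("G", 1:3)))
  sp <- spot_fixture(counts, x = 0:39, y = rep(0, 40))
  tx <- preprocess(list(bin_spots(sp, 1)))
  lab <- cluster_bins(tx, n_pcs = 2, n_neighbors = 10, seed = 1)
  expect_equal(length(unique(lab$cluster)), 1)
  expect_error(cluster_bins(tx, n_neighbors = 50, seed = 1), "neighbours")
  expect_error(cluster_bins(tx, n_pcs = 2), "seed")
})

test_that("clustering is deterministic given the seed", {
  run <- build_phantom_run(seed = 11, depth = 2, n_chip = 60)
  l1 <- cluster_bins(run$tx, n_pcs = 10, seed = 42)
  l2 <- cluster_bins(run$tx, n_pcs = 10, seed = 42)
  expect_identical(l1, l2)
})
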