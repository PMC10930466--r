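test_that("phantom generation is deterministic and geometry-complete", {
  cfg <- phantom_config(seed = 3, field_size_um = c(300, 300))
  p1 <- make_phantom(cfg)
  p2 <- make_phantom(cfg)
  expect_identical(p1, p2)
  ## full coverage: every pixel has a defined (possibly background) label
  expect_true(all(p1$compartments[[1]] %in%
                    0:length(attr(p1$compartments[[1]], "labels"))))
  expect_equal(length(p1$compartments), cfg$n_sections)
})

test_that("single-compartment geometry yields a constant tissue label", {
  cfg <- phantom_config(seed = 5, field_size_um = c(200, 200),
                        compartment_spec = list(type = "uniform",
                                                compartment = "stroma",
                                                tissue_radius_um = 80))
  p <- make_phantom(cfg)
  f <- p$compartments[[1]]
  expect_identical(attr(f, "labels"), "stroma")
  expect_setequal(unique(as.vector(f)), c(0L, 1L))
})

test_that("interface annulus around a tumor disk matches the analytic area", {
  ## tumor disk r = 200 um in stroma; interface = annulus 150-250 um
  cfg <- phantom_config(seed = 2, field_size_um = c(600, 600),
                        field_pitch_um = 1,
                        compartment_spec = list(type = "disk",
                                                tumor_radius_um = 200,
                                                tissue_radius_um = 295),
                        interface_halfwidth_um = 50)
  p <- make_phantom(cfg)
  f <- p$compartments[[1]]
  code <- match("interface", attr(f, "labels"))
  n_px <- sum(f == code)
  analytic <- pi * (250^2 - 150^2)   # um^2, at 1 um/px = pixels
  expect_lt(abs(n_px - analytic) / analytic, 0.03)
})

test_that("cells of diameter d span about ceiling(d/thickness) consecutive sections", {
  ## contiguous 5 um sectioning: a 20 um cell must appear in 4 +/- 1 runs
  cfg <- phantom_config(seed = 9, field_size_um = c(300, 300),
                        n_sections = 9, section_spacing_um = 5,
                        section_thickness_um = 5, cell_diameter_um = 20)
  p <- make_phantom(cfg)
  runs <- tapply(p$cells$section, p$cells$id, function(s) {
    expect_true(all(diff(sort(s)) == 1))   # consecutive sections
    length(s)
  })
  ## interior cells (not clipped by the top/bottom of the block)
  interior <- tapply(p$cells$z_um, p$cells$id, mean)
  sel <- interior > 15 & interior < 30
  expect_true(all(runs[sel] %in% 3:5))
  expect_true(mean(runs[sel] >= 4) > 0.5)
  ## every centroid lies inside the field
  expect_true(all(p$cells$x_um >= 0 & p$cells$x_um <= 300))
  expect_true(all(p$cells$y_um >= 0 & p$cells$y_um <= 300))
})

test_that("chip layout emits distinct distance-separated barcodes on a full grid", {
  lay <- emit_chip_layout(2, 2, pitch_um = 0.5, seed = 1)
  expect_equal(nrow(lay), 4)
  expect_true(all(nchar(lay$barcode) == 25))
  expect_false(anyDuplicated(lay$barcode) > 0)
  expect_setequal(paste(lay$x_index, lay$y_index),
                  c("0 0", "0 1", "1 0", "1 1"))

  ## pairwise Hamming >= 3 (full scan over a 20 x 20 layout)
  lay2 <- emit_chip_layout(20, 20, pitch_um = 0.5, seed = 4)
  chars <- do.call(rbind, strsplit(lay2$barcode, "", fixed = TRUE))
  n <- nrow(chars)
  mind <- 25L
  for (i in seq_len(n - 1)) {
    d <- rowSums(chars[(i + 1):n, , drop = FALSE] !=
                   matrix(chars[i, ], n - i, 25, byrow = TRUE))
    mind <- min(mind, d)
  }
  expect_gte(mind, 3)
})

test_that("a full 1 cm chip is 20000 x 20000 spots at 0.5 um pitch", {
  lay <- emit_chip_layout(20000, 20000, pitch_um = 0.5, seed = 1,
                          materialize = FALSE)
  expect_equal(chip_extent_um(lay), c(10000, 10000))  # 1 cm x 1 cm
})

test_that("noise-free single-spot emission yields one exact read pair", {
  cfg <- phantom_config(seed = 6, field_size_um = c(4, 4), field_pitch_um = 1,
                        compartment_spec = list(type = "uniform",
                                                compartment = "stroma",
                                                tissue_radius_um = 10),
                        gene_programs = matrix(1, 1, 1,
                                               dimnames = list("G1", "stroma")),
                        mito_fraction = 0, microbe_fraction = 0,
                        multimap_fraction = 0, barcode_error_rate = 0,
                        mid_lowq_rate = 0, mid_borderq_rate = 0,
                        mid_n_rate = 0,
                        cell_density_per_mm2 = c(immune = 0),
                        phenotype_compartment = c(immune = "any"))
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(1, 1, pitch_um = 1, seed = 6)
  ## deterministic depth: Poisson draw repeated until a single read appears
  rd <- NULL
  for (trial in 1:20) {
    rd <- tryCatch(emit_stereo_reads(p, 1, lay, depth = 1, seed = trial),
                   error = function(e) NULL)
    if (!is.null(rd) && length(rd$read1) == 1) break
  }
  expect_equal(length(rd$read1), 1)
  expect_identical(substr(rd$read1, 1, 25), lay$barcode[1])
  expect_identical(substr(rd$read1, 26, 31), rd$truth$mid[1])
  expect_identical(rd$read2, rd$reference$tag[rd$reference$id == "G1"])
})

test_that("mitochondrial read fraction is binomial around its target", {
  cfg <- phantom_config(seed = 8, field_size_um = c(500, 500),
                        mito_fraction = 0.01, microbe_fraction = 0,
                        barcode_error_rate = 0, mid_lowq_rate = 0,
                        mid_borderq_rate = 0, mid_n_rate = 0)
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(100, 100, pitch_um = 5, seed = 8)
  rd <- emit_stereo_reads(p, 1, lay, depth = 10)
  n <- nrow(rd$truth)
  expect_gt(n, 50000)
  n_mito <- sum(rd$truth$class == "mito")
  expect_lt(abs(n_mito - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("barcode errors appear at the configured rate at Hamming distance 1", {
  cfg <- phantom_config(seed = 13, field_size_um = c(300, 300),
                        barcode_error_rate = 0.05, mid_lowq_rate = 0,
                        mid_borderq_rate = 0, mid_n_rate = 0)
  p <- make_phantom(cfg)
  lay <- emit_chip_layout(60, 60, pitch_um = 5, seed = 13)
  rd <- emit_stereo_reads(p, 1, lay, depth = 3)
  truth_bc <- lay$barcode[match(paste(rd$truth$x_index, rd$truth$y_index),
                                paste(lay$x_index, lay$y_index))]
  obs <- substr(rd$read1, 1, 25)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              obs, truth_bc)
  expect_true(all(d[rd$truth$cid_err] == 1))
  expect_true(all(d[!rd$truth$cid_err] == 0))
  frac <- mean(d == 1)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(d)))
})

test_that("noise-free MSI emission reproduces the analyte truth", {
  cfg <- phantom_config(seed = 21, field_size_um = c(1000, 1000),
                        misalignment = list(
                          stereo = list(theta_deg = 0, dx_um = 0, dy_um = 0),
                          msi = list(theta_deg = 0, dx_um = 0, dy_um = 0),
                          seqif = list(theta_deg = 0, dx_um = 0, dy_um = 0)))
  p <- make_phantom(cfg)
  msi <- emit_msi(p, 1, c(1077.361), pixel_pitch_um = 20, noise_sd = 0)
  ## pitch 20 um over a 1 mm field -> 50 x 50 pixels
  expect_equal(max(msi$coords$x_index) + 1, 50)
  expect_equal(max(msi$coords$y_index) + 1, 50)
  img <- extract_ion_image(msi, 1077.361, 15)
  ## identity misalignment: ion image correlates with the truth raster
  truth <- spatialfuse:::analyte_truth_raster(p, 1, 1077.361)
  truth_ds <- spatialfuse:::sample_raster(truth, msi$coords$x_um,
                                          msi$coords$y_um)
  expect_gt(cor(as.vector(img), truth_ds), 0.9)

  ## uniform single-compartment phantom: every pixel identical
  cfgu <- phantom_config(seed = 22, field_size_um = c(200, 200),
                         compartment_spec = list(type = "vertical"),
                         interface_halfwidth_um = 0,
                         analyte_maps = matrix(7, 1, 2,
                                               dimnames = list("500", c("tumor", "stroma"))),
                         misalignment = cfg$misalignment)
  pu <- make_phantom(cfgu)
  mu <- emit_msi(pu, 1, 500, pixel_pitch_um = 20, noise_sd = 0)
  iu <- extract_ion_image(mu, 500, 15)
  expect_true(all(iu == 7))
})

test_that("seqIF rendering places nuclei and restricts keratin to tumor", {
  ## no cells -> blank DAPI
  cfg0 <- phantom_config(seed = 31, field_size_um = c(100, 100),
                         cell_density_per_mm2 = c(immune = 0),
                         phenotype_compartment = c(immune = "any"))
  p0 <- make_phantom(cfg0)
  sq0 <- emit_seqif(p0, 1, pixel_pitch_um = 2,
                    compartment_levels = c(tumor = 0, stroma = 0))
  expect_true(all(sq0$data[, , "DAPI"] == 0))

  ## 100 well-separated nuclei -> 100 connected components (labeling oracle)
  set.seed(41)
  grid <- expand.grid(x = seq(25, 475, by = 50), y = seq(25, 475, by = 50))
  cells <- data.frame(id = 1:100, section = 1, x_um = grid$x, y_um = grid$y,
                      z_um = 2.5, diameter_um = 20,
                      phenotype = "tumor_epithelial", compartment = "tumor")
  cfg1 <- phantom_config(seed = 42, field_size_um = c(500, 500),
                         misalignment = list(
                           stereo = list(theta_deg = 0, dx_um = 0, dy_um = 0),
                           msi = list(theta_deg = 0, dx_um = 0, dy_um = 0),
                           seqif = list(theta_deg = 0, dx_um = 0, dy_um = 0)))
  p1 <- make_phantom(cfg1)
  p1$cells <- cells
  sq1 <- emit_seqif(p1, 1, pixel_pitch_um = 2,
                    compartment_levels = c(tumor = 0, stroma = 0))
  lab <- EBImage::bwlabel(EBImage::Image((sq1$data[, , "DAPI"] > 0.5) * 1))
  expect_equal(max(lab), 100)

  ## keratin positive only over the tumor compartment (no tumor cells placed)
  cfg2 <- phantom_config(seed = 43, field_size_um = c(300, 300),
                         cell_density_per_mm2 = c(immune = 0),
                         phenotype_compartment = c(immune = "any"),
                         misalignment = cfg1$misalignment)
  p2 <- make_phantom(cfg2)
  sq2 <- emit_seqif(p2, 1, pixel_pitch_um = 2)
  ker <- sq2$data[, , "Keratin8_18"]
  base <- attr(p2$compartments[[1]], "base")
  px <- (row(ker) - 0.5) * 2
  py <- (col(ker) - 0.5) * 2
  lab2 <- matrix(spatialfuse:::field_label_at(base, as.vector(px),
                                              as.vector(py)),
                 nrow(ker), ncol(ker))
  tumor_code <- match("tumor", attr(base, "labels"))
  expect_true(all(ker[lab2 != tumor_code] == 0))
  expect_true(any(ker[lab2 == tumor_code] > 0))
})
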