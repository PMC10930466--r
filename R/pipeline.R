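#' Validate a pipeline configuration
#'
#' Schema check for the end-to-end run: a mandatory seed, known keys only,
#' and module parameters with the documented defaults filled in.
#'
#' @param config named list; must contain `seed`. Recognised keys:
#'   `seed`, `phantom` (passed to [phantom_config()]), `chip`
#'   (n_spots_x, n_spots_y, pitch_um), `depth`, `bin_size`, `resolution`,
#'   `n_neighbors`, `n_pcs`, `peak_mzs`, `msi_noise_sd`, `seqif_pitch_um`,
#'   `erosion_um`, `voxel_um`.
#' @return validated config (class `pipeline_config`) with defaults filled.
#' @export
validate_config <- function(config) {
  known <- c("seed", "phantom", "chip", "depth", "bin_size", "resolution",
             "n_neighbors", "n_pcs", "peak_mzs", "msi_noise_sd",
             "seqif_pitch_um", "erosion_um", "voxel_um")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_sf("validate_config: unknown key(s): %s",
            paste(unknown, collapse = ", "))
  if (is.null(config$seed) || !is_count(config$seed))
    stop_sf("validate_config: 'seed' is mandatory and must be an integer")
  defaults <- list(chip = list(n_spots_x = 120, n_spots_y = 120,
                               pitch_um = 5),
                   depth = 2, bin_size = 5, resolution = 1.0,
                   n_neighbors = 25, n_pcs = 20,
                   peak_mzs = c(1077.361, 958.578, 140.010),
                   msi_noise_sd = 0.5, seqif_pitch_um = 2,
                   erosion_um = 50, voxel_um = 5)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  class(config) <- "pipeline_config"
  config
}

#' Run the full phantom-to-voxel-table pipeline
#'
#' Generates the phantom, emits and demultiplexes reads, bins / filters /
#' normalises / clusters, builds the indexed Leiden-voxel image, extracts
#' MSI ion images, segments and phenotypes the immunofluorescence image,
#' aggregates everything per voxel for each section, and assembles the 3D
#' stack. Writes artifacts plus a `manifest.json` with file hashes;
#' idempotent given the seed.
#'
#' @param config a list accepted by [validate_config()].
#' @param out_dir output directory.
#' @param verbose log applied thresholds to the console.
#' @return invisibly, a list with `voxel_tables` (per section),
#'   `cluster_labels`, `markers`, `qc`, `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("spatialfuse_run_"),
                         verbose = TRUE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  set.seed(derive_seed(config$seed, "pipeline"))

  ph_args <- config$phantom %||% list()
  ph_args$seed <- ph_args$seed %||% config$seed
  cfg <- do.call(phantom_config, ph_args)
  phantom <- make_phantom(cfg)
  log_("phantom: %d sections, %d cell slices", cfg$n_sections,
       nrow(phantom$cells))

  layout <- emit_chip_layout(config$chip$n_spots_x, config$chip$n_spots_y,
                             config$chip$pitch_um, seed = config$seed)
  reference <- toy_reference(rownames(cfg$gene_programs), seed = config$seed)

  binned <- list()
  qc <- list()
  for (s in seq_len(cfg$n_sections)) {
    reads <- emit_stereo_reads(phantom, s, layout, depth = config$depth,
                               reference = reference)
    mat <- build_matrix(reads$read1, reads$qual1, reads$read2, layout,
                        reference, section = s)
    mask <- phantom$compartments[[s]] > 0
    attr(mask, "pitch_um") <- attr(phantom$compartments[[s]], "pitch_um")
    qc[[s]] <- qc_summary(mat, mask, bin_size = 40L)
    b <- bin_spots(mat, config$bin_size)
    binned[[s]] <- qc_filter(b)
    log_("section %d: %d reads -> %d bins after QC (min_genes=3, mito<=20%%)",
         s, mat$read_stats["total"], nrow(binned[[s]]$counts))
  }
  tx <- preprocess(binned)
  labels <- cluster_bins(tx, n_pcs = config$n_pcs,
                         n_neighbors = config$n_neighbors,
                         resolution = config$resolution, seed = config$seed)
  markers <- rank_and_select(tx, labels$cluster)
  log_("clustering: %d clusters; %d selected markers (p<0.01, log2FC>1)",
       length(unique(labels$cluster)), sum(markers$selected))

  side_um <- config$bin_size * config$chip$pitch_um
  voxel_tables <- list()
  stack_imgs <- list()
  for (s in seq_len(cfg$n_sections)) {
    lab_s <- labels[labels$section == s, ]
    vimg <- build_voxel_index(lab_s, config$bin_size,
                              pitch_um = config$chip$pitch_um)
    msi <- emit_msi(phantom, s, config$peak_mzs,
                    noise_sd = config$msi_noise_sd)
    ion <- lapply(config$peak_mzs, function(mz)
      extract_ion_image(msi, mz, 15))
    names(ion) <- format_mz(config$peak_mzs)
    sq <- emit_seqif(phantom, s, pixel_pitch_um = config$seqif_pitch_um)
    tmask <- segment_tissue(sq, erosion_um = config$erosion_um)
    seg <- segment_cells(sq)
    cells <- phenotype_cells(seg, sq, seed = config$seed,
                             compartment_mask = tmask)
    ## register modalities via phantom truth landmarks
    msi_tr <- phantom$truth_transforms$msi
    seqif_tr <- phantom$truth_transforms$seqif
    bins_s <- list(counts = tx$data[tx$meta$section == s, , drop = FALSE],
                   bins = tx$meta[tx$meta$section == s, ])
    class(bins_s) <- "binned_expression"
    voxel_tables[[s]] <- aggregate_per_voxel(
      vimg, gene_matrix = bins_s, ion_images = ion,
      msi_transform = msi_tr, cell_table = cells,
      cell_transform = seqif_tr)
    stack_imgs[[s]] <- voxel_index_raster(vimg)
    utils::write.csv(voxel_tables[[s]],
                     file.path(out_dir, sprintf("voxel_table_s%d.csv", s)),
                     row.names = FALSE)
  }

  if (cfg$n_sections >= 2) {
    dims <- sapply(stack_imgs, dim)
    nx <- min(dims[1, ]); ny <- min(dims[2, ])
    stk <- section_stack(lapply(stack_imgs, function(m)
      m[seq_len(nx), seq_len(ny), drop = FALSE]),
      z_um = phantom$section_z_um,
      thickness_um = cfg$section_thickness_um,
      pitch_um = side_um)
    vol <- assemble_resample(stk, voxel_um = config$voxel_um)
    log_("stack3d: %d x %d x %d volume at %g um voxels",
         dim(vol)[1], dim(vol)[2], dim(vol)[3], config$voxel_um)
  }

  utils::write.csv(labels, file.path(out_dir, "cluster_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(markers),
                   file.path(out_dir, "markers.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(qc, unclass),
                       file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(voxel_tables = voxel_tables, cluster_labels = labels,
                 markers = markers, qc = qc, manifest_path = mpath))
}
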