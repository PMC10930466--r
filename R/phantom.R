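#' Configuration for the synthetic tissue phantom
#'
#' Builds the ground-truth model specification from which all three modalities
#' (spatial transcriptomics reads, MSI datasets, immunofluorescence images)
#' are emitted. Defaults emulate a tumor/stroma block sectioned serially:
#' a tissue disk containing a central tumor nodule surrounded by stroma, with
#' the interface defined as all points within `interface_halfwidth_um` of the
#' tumor--stroma boundary.
#'
#' @param seed integer seed; all emissions are deterministic given it.
#' @param field_size_um numeric length-2, field width and height in microns.
#' @param field_pitch_um pitch of the ground-truth compartment raster.
#' @param n_sections number of analysed sections.
#' @param section_thickness_um physical section thickness (5 um sectioning).
#' @param section_spacing_um center-to-center spacing of the analysed
#'   sections. Contiguous sectioning corresponds to spacing equal to the
#'   thickness; an every-third-section layout to three times the thickness.
#' @param compartment_spec list describing geometry. `type` is one of
#'   `"disk"` (tumor disk in stroma inside a tissue disk), `"uniform"`
#'   (single compartment filling a tissue disk), `"vertical"` (left tumor /
#'   right stroma, no background). Fields: `tumor_radius_um`,
#'   `tissue_radius_um`, `compartment` (for uniform).
#' @param interface_halfwidth_um half-width of the interface band around the
#'   tumor--stroma boundary.
#' @param gene_programs numeric matrix, genes x compartments, of relative
#'   expression rates. Default plants 6 marker genes per compartment at a
#'   4-fold (log2FC = 2) rate over a shared baseline of housekeeping genes.
#' @param mito_fraction fraction of reads that are mitochondrial.
#' @param microbe_fraction fraction of reads that are microbial.
#' @param multimap_fraction fraction of host reads emitted as multi-mapping
#'   (MAPQ 0) tags.
#' @param analyte_maps numeric matrix, m/z peaks x compartments, of mean ion
#'   intensities; rownames are m/z values as strings.
#' @param cell_density_per_mm2 named numeric, cells per mm^2 per phenotype.
#' @param cell_diameter_um nominal cell diameter (drives how many consecutive
#'   sections one cell spans).
#' @param marker_profiles numeric matrix, phenotypes x markers, of mean
#'   marker intensities per cell.
#' @param phenotype_compartment named character, home compartment of each
#'   phenotype (`"any"` allows the whole tissue).
#' @param misalignment list of per-modality ground-truth affines, each a list
#'   with `theta_deg`, `dx_um`, `dy_um` mapping modality-local micron
#'   coordinates to reference (chip) micron coordinates.
#' @param barcode_error_rate per-read probability of one substitution in the
#'   spatial barcode.
#' @param mid_lowq_rate per-read probability that the molecular identifier
#'   carries 3 bases below Q10 (and is therefore filtered).
#' @param mid_borderq_rate per-read probability of exactly 2 bases below Q10
#'   (retained; exercises the filter boundary).
#' @param mid_n_rate per-read probability of an N base in the MID.
#' @param ambient_depth_frac read depth of off-tissue spots relative to
#'   on-tissue depth.
#'
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(seed,
                           field_size_um = c(600, 600),
                           field_pitch_um = 2,
                           n_sections = 3,
                           section_thickness_um = 5,
                           section_spacing_um = 10,
                           compartment_spec = list(type = "disk",
                                                   tumor_radius_um = 120,
                                                   tissue_radius_um = 270),
                           interface_halfwidth_um = 50,
                           gene_programs = NULL,
                           mito_fraction = 0.01,
                           microbe_fraction = 0.005,
                           multimap_fraction = 0.01,
                           analyte_maps = NULL,
                           cell_density_per_mm2 = c(tumor_epithelial = 800,
                                                    fibroblast = 600,
                                                    immune = 200),
                           cell_diameter_um = 20,
                           marker_profiles = NULL,
                           phenotype_compartment = c(tumor_epithelial = "tumor",
                                                     fibroblast = "stroma",
                                                     immune = "any"),
                           misalignment = list(
                             stereo = list(theta_deg = 0, dx_um = 0, dy_um = 0),
                             msi    = list(theta_deg = 2, dx_um = 15, dy_um = -10),
                             seqif  = list(theta_deg = -1.5, dx_um = -8, dy_um = 12)),
                           barcode_error_rate = 0.01,
                           mid_lowq_rate = 0.02,
                           mid_borderq_rate = 0.05,
                           mid_n_rate = 0.002) {
  if (missing(seed) || !is_count(seed))
    stop_sf("phantom_config: 'seed' must be a single non-negative integer")
  stopifnot(length(field_size_um) == 2, all(field_size_um > 0),
            field_pitch_um > 0, n_sections >= 1,
            section_thickness_um > 0, section_spacing_um > 0)
  fracs <- c(mito_fraction, microbe_fraction, multimap_fraction,
             barcode_error_rate, mid_lowq_rate, mid_borderq_rate, mid_n_rate)
  if (any(fracs < 0) || any(fracs >= 1))
    stop_sf("phantom_config: all rates/fractions must lie in [0, 1)")

  if (is.null(gene_programs)) gene_programs <- default_gene_programs()
  if (is.null(analyte_maps)) analyte_maps <- default_analyte_maps()
  if (is.null(marker_profiles)) marker_profiles <- default_marker_profiles()

  cfg <- list(seed = as.integer(seed),
              field_size_um = as.numeric(field_size_um),
              field_pitch_um = field_pitch_um,
              n_sections = as.integer(n_sections),
              section_thickness_um = section_thickness_um,
              section_spacing_um = section_spacing_um,
              compartment_spec = compartment_spec,
              interface_halfwidth_um = interface_halfwidth_um,
              gene_programs = gene_programs,
              mito_fraction = mito_fraction,
              microbe_fraction = microbe_fraction,
              multimap_fraction = multimap_fraction,
              analyte_maps = analyte_maps,
              cell_density_per_mm2 = cell_density_per_mm2,
              cell_diameter_um = cell_diameter_um,
              marker_profiles = marker_profiles,
              phenotype_compartment = phenotype_compartment,
              misalignment = misalignment,
              barcode_error_rate = barcode_error_rate,
              mid_lowq_rate = mid_lowq_rate,
              mid_borderq_rate = mid_borderq_rate,
              mid_n_rate = mid_n_rate,
              ambient_depth_frac = 0.05)
  class(cfg) <- "phantom_config"
  cfg
}

## 6 markers per compartment at 4x baseline (log2FC = 2), 18 housekeeping
default_gene_programs <- function(base = 1, fold = 4) {
  comps <- c("tumor", "stroma", "interface")
  genes <- c(paste0("TUM", 1:6), paste0("STR", 1:6), paste0("INT", 1:6),
             paste0("HK", 1:18))
  m <- matrix(base, nrow = length(genes), ncol = length(comps),
              dimnames = list(genes, comps))
  m[1:6, "tumor"] <- base * fold
  m[7:12, "stroma"] <- base * fold
  m[13:18, "interface"] <- base * fold
  m
}

## one stroma-enriched glycan-like peak, one tumor peak, one uniform peak
default_analyte_maps <- function() {
  m <- matrix(c(
    ## tumor stroma interface
    2,  10,  8,    # stroma/interface-enriched (glycan-like)
    9,   2,  5,    # tumor-enriched
    5,   5,  5),   # uniform
    ncol = 3, byrow = TRUE,
    dimnames = list(c("1077.361", "958.578", "140.010"),
                    c("tumor", "stroma", "interface")))
  m
}

default_marker_profiles <- function() {
  markers <- c("Keratin8_18", "COL1A1", "ACTA2", "CD45")
  m <- matrix(0.02, nrow = 3, ncol = length(markers),
              dimnames = list(c("tumor_epithelial", "fibroblast", "immune"),
                              markers))
  m["tumor_epithelial", "Keratin8_18"] <- 1
  m["fibroblast", c("COL1A1", "ACTA2")] <- c(0.9, 0.8)
  m["immune", "CD45"] <- 1
  m
}

#' Build the ground-truth tissue phantom
#'
#' Realises the compartment geometry, places cells in 3D (so that a cell of
#' diameter d intersects roughly `ceiling(d / thickness)` consecutive
#' sections), and records the per-modality ground-truth affine transforms.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom` with elements `config`,
#'   `compartments` (list of per-section label rasters with a `labels`
#'   attribute), `cells` (data.frame: id, section, x_um, y_um, z_um,
#'   diameter_um, phenotype, compartment), `truth_transforms` (per-modality
#'   [affine_transform()]), `section_z_um` (section centre positions).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(derive_seed(config$seed, "phantom"))

  field <- compartment_field(config)
  labs <- attr(field, "labels")
  if (!any(field > 0)) stop_sf("make_phantom: compartment geometry has zero area")
  compartments <- rep(list(field), config$n_sections)

  zc <- section_z_centers(config)
  cells <- place_cells(config, field, zc)

  tt <- lapply(config$misalignment, function(m)
    affine_transform(rotation_deg = m$theta_deg %||% 0,
                     translation = c(m$dx_um %||% 0, m$dy_um %||% 0),
                     center = config$field_size_um / 2))

  ph <- list(config = config,
             compartments = compartments,
             cells = cells,
             truth_transforms = tt,
             section_z_um = zc)
  class(ph) <- "phantom"
  ph
}

section_z_centers <- function(config) {
  config$section_thickness_um / 2 +
    (seq_len(config$n_sections) - 1) * config$section_spacing_um
}

## label raster: 0 background, then compartment codes per attr(,"labels")
compartment_field <- function(config) {
  pitch <- config$field_pitch_um
  nx <- max(1L, floor(config$field_size_um[1] / pitch))
  ny <- max(1L, floor(config$field_size_um[2] / pitch))
  ## pixel centers in microns (half-open pixel convention, origin top-left)
  cx <- (seq_len(nx) - 0.5) * pitch
  cy <- (seq_len(ny) - 0.5) * pitch
  X <- matrix(cx, nx, ny)
  Y <- matrix(cy, nx, ny, byrow = TRUE)
  ctr <- config$field_size_um / 2
  spec <- config$compartment_spec
  type <- spec$type %||% "disk"

  if (type == "uniform") {
    comp <- spec$compartment %||% "stroma"
    r <- spec$tissue_radius_um %||% (0.45 * min(config$field_size_um))
    fld <- matrix(0L, nx, ny)
    fld[(X - ctr[1])^2 + (Y - ctr[2])^2 <= r^2] <- 1L
    attr(fld, "labels") <- c(comp)
  } else if (type == "vertical") {
    split_x <- spec$split_x_um %||% ctr[1]
    fld <- matrix(2L, nx, ny)
    fld[X <= split_x] <- 1L
    attr(fld, "labels") <- c("tumor", "stroma")
  } else if (type == "disk") {
    rt <- spec$tumor_radius_um %||% 120
    rs <- spec$tissue_radius_um %||% (0.45 * min(config$field_size_um))
    if (rt >= rs) stop_sf("compartment_spec: tumor radius must be < tissue radius")
    d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
    fld <- matrix(0L, nx, ny)
    fld[d2 <= rs^2] <- 2L          # stroma
    fld[d2 <= rt^2] <- 1L          # tumor
    attr(fld, "labels") <- c("tumor", "stroma")
  } else stop_sf("unknown compartment_spec type '%s'", type)

  ## interface = within halfwidth of the tumor-stroma boundary; the
  ## pre-interface raster is kept (attr "base") for rendering raw stains
  labs <- attr(fld, "labels")
  base_fld <- fld
  attr(base_fld, "labels") <- labs
  attr(base_fld, "pitch_um") <- pitch
  if (all(c("tumor", "stroma") %in% labs) && config$interface_halfwidth_um > 0) {
    hw_px <- config$interface_halfwidth_um / pitch
    ti <- which(labs == "tumor"); si <- which(labs == "stroma")
    dt <- dist_to_mask(fld == ti)   # distance of every pixel to tumor
    ds <- dist_to_mask(fld == si)
    iface <- (fld == ti & ds <= hw_px) | (fld == si & dt <= hw_px)
    code <- length(labs) + 1L
    fld[iface] <- code
    attr(fld, "labels") <- c(labs, "interface")
  }
  attr(fld, "pitch_um") <- pitch
  attr(fld, "base") <- base_fld
  fld
}

## Euclidean distance (in pixels) from each pixel to the nearest TRUE pixel
dist_to_mask <- function(mask) {
  ## distmap measures distance of foreground to nearest background; invert
  m <- EBImage::Image(1 - mask * 1)
  d <- EBImage::distmap(m, metric = "euclidean")
  as.matrix(EBImage::imageData(d))
}

## sample compartment label at micron coordinates (0 outside field)
field_label_at <- function(field, x_um, y_um) {
  pitch <- attr(field, "pitch_um")
  i <- floor(x_um / pitch) + 1L
  j <- floor(y_um / pitch) + 1L
  ok <- i >= 1L & i <= nrow(field) & j >= 1L & j <= ncol(field)
  out <- integer(length(x_um))
  out[ok] <- field[cbind(i[ok], j[ok])]
  out
}

place_cells <- function(config, field, zc) {
  labs <- attr(field, "labels")
  W <- config$field_size_um[1]; H <- config$field_size_um[2]
  area_mm2 <- W * H / 1e6
  th <- config$section_thickness_um
  z_lo <- 0
  z_hi <- (config$n_sections - 1) * config$section_spacing_um + th
  rows <- list()
  id0 <- 0L
  for (ph in names(config$cell_density_per_mm2)) {
    n <- rpois(1, config$cell_density_per_mm2[[ph]] * area_mm2)
    if (n == 0) next
    x <- runif(n, 0, W); y <- runif(n, 0, H)
    z <- runif(n, z_lo - config$cell_diameter_um / 2,
               z_hi + config$cell_diameter_um / 2)
    lab <- field_label_at(field, x, y)
    home <- config$phenotype_compartment[[ph]] %||% "any"
    keep <- if (home == "any") lab > 0 else {
      ## interface pixels belong to both flanking compartments
      want <- which(labs %in% c(home, "interface"))
      lab %in% want
    }
    if (!any(keep)) next
    rows[[ph]] <- data.frame(x_um = x[keep], y_um = y[keep], z_um = z[keep],
                             phenotype = ph,
                             compartment = labs[pmax(lab[keep], 1L)],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(id = integer(), section = integer(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      diameter_um = numeric(), phenotype = character(),
                      compartment = character(), stringsAsFactors = FALSE))
  }
  all3d <- do.call(rbind, rows)
  all3d$id <- seq_len(nrow(all3d))
  all3d$diameter_um <- config$cell_diameter_um
  ## intersect 3D cells with each section slab
  r <- config$cell_diameter_um / 2
  out <- list()
  for (s in seq_len(config$n_sections)) {
    z0 <- zc[s] - th / 2; z1 <- zc[s] + th / 2
    hit <- all3d$z_um + r > z0 & all3d$z_um - r < z1
    if (!any(hit)) next
    d <- all3d[hit, ]
    d$section <- s
    out[[s]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("id", "section", "x_um", "y_um", "z_um", "diameter_um",
          "phenotype", "compartment")]
}

#' @export
print.phantom <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("phantom: %g x %g um field, %d section(s), %d cell slice(s)\n",
              cfg$field_size_um[1], cfg$field_size_um[2], cfg$n_sections,
              nrow(x$cells)))
  cat(sprintf("  compartments: %s\n",
              paste(attr(x$compartments[[1]], "labels"), collapse = ", ")))
  invisible(x)
}

## per-section analyte truth raster for one m/z peak (field grid)
analyte_truth_raster <- function(phantom, section, mz) {
  field <- phantom$compartments[[section]]
  labs <- attr(field, "labels")
  am <- phantom$config$analyte_maps
  ## match by numeric value (rownames are printed m/z strings)
  row <- which(abs(as.numeric(rownames(am)) - as.numeric(mz)) < 1e-6)
  if (!length(row))
    stop_sf("analyte_truth_raster: m/z %s not in analyte_maps",
            format_mz(mz))
  lut <- c(0, vapply(labs, function(l)
    if (l %in% colnames(am)) am[row[1], l] else 0, numeric(1)))
  r <- matrix(lut[field + 1L], nrow(field), ncol(field))
  attr(r, "pitch_um") <- attr(field, "pitch_um")
  r
}

format_mz <- function(mz) {
  if (is.character(mz)) mz else format(mz, trim = TRUE)
}
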