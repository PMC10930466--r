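#' Construct an MSI dataset
#'
#' Container for a mass spectrometry imaging acquisition: a pixel grid at
#' fixed pitch and one centroided spectrum per pixel.
#'
#' @param coords data.frame with `x_index`, `y_index` (0-based) and
#'   optionally `x_um`, `y_um`.
#' @param spectra list (one per coords row) of `list(mz, intensity)` with
#'   `mz` sorted ascending and intensities >= 0.
#' @param pixel_pitch_um pixel pitch in microns (20 on the instrument).
#' @param polarity `"negative"` or `"positive"`.
#' @return object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, spectra, pixel_pitch_um = 20,
                        polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(is.data.frame(coords), nrow(coords) == length(spectra),
            pixel_pitch_um > 0)
  if (nrow(coords) == 0) stop_sf("msi_dataset: empty pixel list")
  for (s in spectra) {
    if (is.unsorted(s$mz)) stop_sf("msi_dataset: m/z must be sorted ascending")
    if (any(s$intensity < 0)) stop_sf("msi_dataset: negative intensity")
  }
  if (!"x_um" %in% names(coords))
    coords$x_um <- (coords$x_index + 0.5) * pixel_pitch_um
  if (!"y_um" %in% names(coords))
    coords$y_um <- (coords$y_index + 0.5) * pixel_pitch_um
  structure(list(coords = coords, spectra = spectra,
                 pixel_pitch_um = pixel_pitch_um, polarity = polarity),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset: %d pixels at %g um pitch, %s mode\n",
              nrow(x$coords), x$pixel_pitch_um, x$polarity))
  invisible(x)
}

#' Write an MSI dataset as imzML + ibd
#'
#' Emits the open imzML dialect: an XML index file plus the binary `.ibd`
#' companion holding the m/z and intensity arrays (64-bit floats). Both the
#' `"processed"` dialect (per-pixel m/z axis) and the `"continuous"` dialect
#' (shared m/z axis, written once) are supported.
#'
#' @param dataset an [msi_dataset()].
#' @param path output path ending in `.imzML`; the `.ibd` is written next
#'   to it.
#' @param mode `"processed"` or `"continuous"` (requires identical m/z
#'   arrays across pixels).
#' @export
write_imzml <- function(dataset, path, mode = c("processed", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "msi_dataset"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  ns <- length(dataset$spectra)
  if (mode == "continuous") {
    mz0 <- dataset$spectra[[1]]$mz
    same <- all(vapply(dataset$spectra, function(s)
      length(s$mz) == length(mz0) && all(s$mz == mz0), logical(1)))
    if (!same)
      stop_sf("write_imzml: continuous mode requires a shared m/z axis")
  }

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  writeBin(uuid, con)
  offset <- 16
  offs <- vector("list", ns)
  if (mode == "continuous") {
    mz0 <- dataset$spectra[[1]]$mz
    writeBin(as.double(mz0), con, size = 8, endian = "little")
    mz_off <- offset; mz_len <- length(mz0)
    offset <- offset + 8 * mz_len
    for (i in seq_len(ns)) {
      s <- dataset$spectra[[i]]
      writeBin(as.double(s$intensity), con, size = 8, endian = "little")
      offs[[i]] <- list(mz_off = mz_off, mz_len = mz_len,
                        int_off = offset, int_len = length(s$intensity))
      offset <- offset + 8 * length(s$intensity)
    }
  } else {
    for (i in seq_len(ns)) {
      s <- dataset$spectra[[i]]
      writeBin(as.double(s$mz), con, size = 8, endian = "little")
      mz_off <- offset; offset <- offset + 8 * length(s$mz)
      writeBin(as.double(s$intensity), con, size = 8, endian = "little")
      offs[[i]] <- list(mz_off = mz_off, mz_len = length(s$mz),
                        int_off = offset, int_len = length(s$intensity))
      offset <- offset + 8 * length(s$intensity)
    }
  }

  uuid_str <- paste(sprintf("%02X", as.integer(uuid)), collapse = "")
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  spec_xml <- vapply(seq_len(ns), function(i) {
    o <- offs[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, o$mz_len,
      dataset$coords$x_index[i] + 1L, dataset$coords$y_index[i] + 1L,
      o$mz_len, o$mz_off, o$int_len, o$int_off)
  }, character(1))

  pol_acc <- if (dataset$polarity == "negative")
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>' else
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<fileDescription><fileContent>',
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s"/>',
            mode_acc, mode),
    sprintf(paste0('<cvParam cvRef="IMS" accession="IMS:1000080" ',
                   'name="universally unique identifier" value="{%s}"/>'),
            uuid_str),
    pol_acc,
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>\n',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    sprintf(paste0('<cvParam cvRef="IMS" accession="IMS:1000046" ',
                   'name="pixel size" value="%g"/>'),
            dataset$pixel_pitch_um),
    '</scanSettings></scanSettingsList>\n',
    sprintf('<run id="run1"><spectrumList count="%d">', ns),
    paste(spec_xml, collapse = "\n"),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Read an imzML + ibd pair
#'
#' Parses both the continuous and the processed dialect into the same
#' in-memory [msi_dataset()] form.
#'
#' @param path path to the `.imzML` file; the `.ibd` must sit next to it.
#' @param pixel_pitch_um fallback pitch if the file carries no pixel size.
#' @return an [msi_dataset()].
#' @export
read_imzml <- function(path, pixel_pitch_um = 20) {
  if (!file.exists(path)) stop_sf("read_imzml: no such file '%s'", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path))
    stop_sf("read_imzml: missing binary companion '%s'", ibd_path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_sf("read_imzml: malformed XML: %s",
                                              conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  pol_node <- xml2::xml_find_first(doc, "//cvParam[@accession='MS:1000129']")
  polarity <- if (!inherits(pol_node, "xml_missing")) "negative" else "positive"
  px_node <- xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000046']")
  pitch <- if (!inherits(px_node, "xml_missing"))
    as.numeric(xml2::xml_attr(px_node, "value")) else pixel_pitch_um

  specs <- xml2::xml_find_all(doc, "//spectrum")
  if (length(specs) == 0) stop_sf("read_imzml: no spectra in '%s'", path)
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  coords <- data.frame(x_index = integer(length(specs)),
                       y_index = integer(length(specs)))
  spectra <- vector("list", length(specs))
  read_arr <- function(off, len) {
    seek(con, where = off, origin = "start")
    readBin(con, what = "double", n = len, size = 8, endian = "little")
  }
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    px <- xml2::xml_find_first(sp, ".//cvParam[@accession='IMS:1000050']")
    py <- xml2::xml_find_first(sp, ".//cvParam[@accession='IMS:1000051']")
    coords$x_index[i] <- as.integer(xml2::xml_attr(px, "value")) - 1L
    coords$y_index[i] <- as.integer(xml2::xml_attr(py, "value")) - 1L
    arrs <- xml2::xml_find_all(sp, ".//binaryDataArray")
    if (length(arrs) != 2)
      stop_sf("read_imzml: spectrum %d lacks the two binary arrays", i)
    get_arr <- function(node) {
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        node, ".//cvParam[@accession='IMS:1000102']"), "value"))
      len <- as.integer(xml2::xml_attr(xml2::xml_find_first(
        node, ".//cvParam[@accession='IMS:1000103']"), "value"))
      read_arr(off, len)
    }
    which_mz <- vapply(arrs, function(a)
      !inherits(xml2::xml_find_first(
        a, ".//referenceableParamGroupRef[@ref='mzArray']"), "xml_missing"),
      logical(1))
    mz <- get_arr(arrs[[which(which_mz)[1]]])
    it <- get_arr(arrs[[which(!which_mz)[1]]])
    spectra[[i]] <- list(mz = mz, intensity = it)
  }
  msi_dataset(coords, spectra, pitch, polarity)
}

#' Extract an ion image in a ppm window
#'
#' Per pixel, sums the intensities of all centroids within the ppm window:
#' `|m/z - mz| / mz * 1e6 <= width_ppm / 2` (the stated width is the full
#' window, so half on each side).
#'
#' @param dataset an [msi_dataset()].
#' @param mz window centre.
#' @param width_ppm full window width, ppm (15 for metabolites, 10 for
#'   glycans and peptides).
#' @return matrix (x by y) of summed intensity with a `pitch_um` attribute;
#'   pixels with no centroid in window are 0.
#' @export
extract_ion_image <- function(dataset, mz, width_ppm) {
  stopifnot(inherits(dataset, "msi_dataset"), mz > 0, width_ppm > 0)
  tol <- mz * width_ppm / 2 * 1e-6
  nx <- max(dataset$coords$x_index) + 1L
  ny <- max(dataset$coords$y_index) + 1L
  img <- matrix(0, nx, ny)
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    sel <- abs(s$mz - mz) <= tol
    img[dataset$coords$x_index[i] + 1L, dataset$coords$y_index[i] + 1L] <-
      sum(s$intensity[sel])
  }
  attr(img, "pitch_um") <- dataset$pixel_pitch_um
  img
}

## exact particle/atom masses (u), CODATA / IUPAC monoisotopic
PROTON_MASS <- 1.007276466879
ELECTRON_MASS <- 0.000548579909
MASS_NA <- 22.98976928
MASS_K <- 38.96370649
MASS_CL <- 34.968852682

adduct_table <- function(polarity) {
  if (polarity == "negative") {
    data.frame(adduct = c("[M-H]-", "[M]-", "[M+Cl]-"),
               shift = c(-PROTON_MASS, ELECTRON_MASS,
                         MASS_CL + ELECTRON_MASS),
               stringsAsFactors = FALSE)
  } else if (polarity == "positive") {
    data.frame(adduct = c("[M+H]+", "[M+Na]+", "[M+K]+"),
               shift = c(PROTON_MASS, MASS_NA - ELECTRON_MASS,
                         MASS_K - ELECTRON_MASS),
               stringsAsFactors = FALSE)
  } else stop_sf("annotate_adducts: unknown polarity '%s'", polarity)
}

#' Annotate observed m/z values with adduct-mass compound candidates
#'
#' For each adduct of the polarity ([M-H]-, [M]-, [M+Cl]- in negative mode;
#' [M+H]+, [M+Na]+, [M+K]+ in positive mode), derives the neutral mass from
#' the observed m/z using exact particle masses and reports compounds whose
#' neutral monoisotopic mass matches within `tol_ppm`, sorted by |ppm error|
#' within each observed m/z.
#'
#' @param mz_list numeric observed m/z values.
#' @param compound_masses data.frame with `name` and `neutral_mass`.
#' @param polarity `"negative"` or `"positive"`.
#' @param tol_ppm match tolerance, ppm.
#' @return data.frame: mz, adduct, compound, neutral_mass, ppm_error.
#' @export
annotate_adducts <- function(mz_list, compound_masses, polarity, tol_ppm = 10) {
  ad <- adduct_table(polarity)
  out <- list()
  for (mz in mz_list) {
    hits <- list()
    for (a in seq_len(nrow(ad))) {
      M <- mz - ad$shift[a]
      if (nrow(compound_masses) == 0) next
      ppm <- (M - compound_masses$neutral_mass) /
        compound_masses$neutral_mass * 1e6
      sel <- which(abs(ppm) <= tol_ppm)
      if (length(sel))
        hits[[length(hits) + 1L]] <- data.frame(
          mz = mz, adduct = ad$adduct[a],
          compound = compound_masses$name[sel],
          neutral_mass = compound_masses$neutral_mass[sel],
          ppm_error = ppm[sel], stringsAsFactors = FALSE)
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      out[[length(out) + 1L]] <- h[order(abs(h$ppm_error)), ]
    }
  }
  if (!length(out)) {
    return(data.frame(mz = numeric(), adduct = character(),
                      compound = character(), neutral_mass = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Propose peaks from the pooled spectrum (convenience)
#'
#' Groups all centroids across pixels into ppm-tolerance clusters and
#' returns clusters whose mean intensity exceeds `snr` times the noise
#' floor, estimated as the weakest cluster's mean. A convenience stand-in
#' for manual peak picking; the curated peak list remains the primary input.
#'
#' @param dataset an [msi_dataset()].
#' @param tol_ppm clustering tolerance.
#' @param snr signal-to-noise multiple over the noise floor.
#' @return data.frame: mz (cluster mean), mean_intensity, n_pixels.
#' @export
propose_peaks <- function(dataset, tol_ppm = 10, snr = 3) {
  mzs <- unlist(lapply(dataset$spectra, `[[`, "mz"))
  its <- unlist(lapply(dataset$spectra, `[[`, "intensity"))
  o <- order(mzs)
  mzs <- mzs[o]; its <- its[o]
  if (!length(mzs)) {
    return(data.frame(mz = numeric(), mean_intensity = numeric(),
                      n_pixels = integer()))
  }
  grp <- cumsum(c(1, diff(mzs) / head(mzs, -1) * 1e6 > tol_ppm))
  mz_c <- tapply(mzs, grp, mean)
  it_c <- tapply(its, grp, mean)
  n_c <- tapply(its, grp, length)
  thr <- snr * min(it_c)
  sel <- it_c >= thr & it_c > 0
  data.frame(mz = as.numeric(mz_c[sel]),
             mean_intensity = as.numeric(it_c[sel]),
             n_pixels = as.integer(n_c[sel]), row.names = NULL)
}

#' Standard peak-list widths by analyte class
#'
#' @param mz numeric m/z values.
#' @param class analyte class per peak: `"metabolite"` (15 ppm) or
#'   `"glycan"`/`"peptide"` (10 ppm).
#' @return data.frame peak list: mz, width_ppm, class.
#' @export
peak_list <- function(mz, class) {
  class <- match.arg(class, c("metabolite", "glycan", "peptide"),
                     several.ok = TRUE)
  class <- rep_len(class, length(mz))
  data.frame(mz = mz, width_ppm = ifelse(class == "metabolite", 15, 10),
             class = class, stringsAsFactors = FALSE)
}
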