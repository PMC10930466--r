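## Classical (deterministic) replacements for the proprietary interactive
## segmentation steps: rule-based tissue segmentation with erosion-defined
## interface, DAPI watershed cell segmentation, and top-quintile marker
## phenotyping.

get_channel <- function(img, name) {
  if (inherits(img, "seqif_image")) {
    if (!name %in% img$channels)
      stop_sf("channel '%s' not present", name)
    m <- img$data[, , name]
    attr(m, "pitch_um") <- img$pitch_um
    m
  } else stop_sf("expected a seqif_image")
}

## erosion via Euclidean distance transform: pixels closer than r_px to the
## mask complement are removed (exact for straight boundaries)
erode_mask <- function(mask, r_px) {
  if (!any(mask)) return(mask)
  d <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1),
                                  metric = "euclidean"))
  mask & d > r_px
}

#' Rule-based tissue segmentation with an erosion-defined interface
#'
#' Each rule channel (e.g. keratin 8/18 for tumor, COL1A1 for stroma) is
#' thresholded (Otsu by default), pixels are assigned to the compartment
#' with the maximal rule response, and small holes are closed. Both
#' compartments are then eroded by `erosion_um`; the union of the
#' eroded-away tissue pixels is labelled interface, which for a straight
#' boundary gives a band of exactly `2 * erosion_um`.
#'
#' @param img a `seqif_image` (or pass channels via [emit_seqif()]).
#' @param rules named character: compartment -> channel name; needs at
#'   least `tumor` and `stroma` entries (or analogous pair).
#' @param erosion_um erosion radius, microns (50 for a ~100 um interface).
#' @param thresholds optional named numeric per compartment; Otsu if NULL.
#' @param smooth_um Gaussian smoothing (replicate boundary) applied to the
#'   rule channels before thresholding, so punctate cell staining and
#'   diffuse compartment staining merge into one tissue-scale response.
#'   Symmetric about compartment boundaries, hence boundary-preserving.
#' @param closing_um radius of the morphological closing applied to each
#'   compartment mask (0 disables).
#' @return `compartment_mask`: integer matrix (0 = background) with
#'   attributes `labels` (compartment names + `"interface"`) and `pitch_um`.
#' @export
segment_tissue <- function(img, rules = c(tumor = "Keratin8_18",
                                          stroma = "COL1A1"),
                           erosion_um = 50, thresholds = NULL,
                           smooth_um = 10, closing_um = 0) {
  stopifnot(inherits(img, "seqif_image"))
  pitch <- img$pitch_um
  if (is.null(pitch)) stop_sf("segment_tissue: unknown pixel pitch")
  missing_ch <- setdiff(unname(rules), img$channels)
  if (length(missing_ch))
    stop_sf("segment_tissue: missing rule channel(s): %s",
            paste(missing_ch, collapse = ", "))
  comps <- names(rules)
  chans <- lapply(rules, function(ch) {
    m <- get_channel(img, ch)
    if (smooth_um > 0) {
      sig <- smooth_um / pitch
      m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sig,
                                    boundary = "replicate"))
    }
    m
  })
  thr <- vapply(comps, function(cp) {
    if (!is.null(thresholds) && cp %in% names(thresholds))
      return(thresholds[[cp]])
    v <- chans[[cp]]
    rng <- range(v)
    if (diff(rng) == 0) return(Inf)   # flat channel: nothing positive
    sc <- (v - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
  }, numeric(1))

  nx <- nrow(chans[[1]]); ny <- ncol(chans[[1]])
  resp <- array(-Inf, dim = c(nx, ny, length(comps)))
  for (k in seq_along(comps)) {
    ch <- chans[[k]]
    resp[, , k] <- ifelse(ch > thr[k], ch, -Inf)
  }
  lab <- apply(resp, c(1, 2), function(v)
    if (all(!is.finite(v))) 0L else which.max(v))
  if (closing_um > 0) {
    br <- EBImage::makeBrush(2 * max(1, round(closing_um / pitch)) + 1,
                             shape = "disc")
    for (k in seq_along(comps)) {
      m <- EBImage::closing(EBImage::Image((lab == k) * 1), br)
      lab[as.matrix(m) > 0 & lab == 0L] <- k
    }
  }

  r_px <- erosion_um / pitch
  tissue <- lab > 0L
  eroded <- lab
  for (k in seq_along(comps)) {
    keep <- erode_mask(lab == k, r_px)
    eroded[lab == k & !keep] <- 0L
  }
  iface <- tissue & eroded == 0L
  out <- eroded
  out[iface] <- length(comps) + 1L
  attr(out, "labels") <- c(comps, "interface")
  attr(out, "pitch_um") <- pitch
  class(out) <- c("compartment_mask", class(out))
  out
}

#' Width of the interface band along the boundary normal
#'
#' Helper for straight-boundary constructions: measures the interface run
#' length per row (x direction) and returns the median width in microns.
#'
#' @param mask a `compartment_mask`.
#' @return median interface width, microns.
#' @export
interface_width_um <- function(mask) {
  labs <- attr(mask, "labels")
  code <- match("interface", labs)
  pitch <- attr(mask, "pitch_um")
  runs <- apply(unclass(mask) == code, 2, sum)
  median(runs[runs > 0]) * pitch
}

#' Segment nuclei and cells from the DAPI channel
#'
#' Classical pipeline: Gaussian smoothing, Otsu threshold,
#' distance-transform watershed to split touching nuclei, size filter, then
#' cell bodies grown from each nucleus by constrained propagation (nearest
#' nucleus within a dilated mask), so neighbouring cells clip each other.
#'
#' @param img a `seqif_image` with a DAPI channel.
#' @param min_area_um2,max_area_um2 nucleus area filter.
#' @param sigma_um Gaussian smoothing sigma.
#' @param expand_um radius by which cells extend beyond their nucleus.
#' @param threshold absolute DAPI threshold; Otsu if NULL.
#' @return `cell_segmentation`: list with `nuclei` and `cells` label
#'   matrices, `table` (data.frame id, x_um, y_um, area_um2), `pitch_um`.
#'   A blank image yields zero cells, not an error.
#' @export
segment_cells <- function(img, min_area_um2 = 8, max_area_um2 = 600,
                          sigma_um = 1, expand_um = 3, threshold = NULL) {
  dapi <- get_channel(img, "DAPI")
  pitch <- img$pitch_um
  empty <- function() {
    z <- matrix(0L, nrow(dapi), ncol(dapi))
    structure(list(nuclei = z, cells = z,
                   table = data.frame(id = integer(), x_um = numeric(),
                                      y_um = numeric(), area_um2 = numeric()),
                   pitch_um = pitch),
              class = "cell_segmentation")
  }
  if (max(dapi) == 0) return(empty())
  im <- EBImage::Image(dapi / max(dapi))
  sig <- max(0.3, sigma_um / pitch)
  sm <- EBImage::gblur(im, sigma = sig)
  thr <- if (is.null(threshold)) EBImage::otsu(sm) else threshold / max(dapi)
  bw <- sm > thr
  if (!any(bw)) return(empty())
  dm <- EBImage::distmap(bw)
  nuclei <- EBImage::watershed(dm, tolerance = 1)
  nl <- as.matrix(EBImage::imageData(nuclei))

  areas <- tabulate(nl[nl > 0])
  amin <- min_area_um2 / pitch^2
  amax <- max_area_um2 / pitch^2
  bad <- which(areas < amin | areas > amax)
  if (length(bad)) nl[nl %in% bad] <- 0L
  ## relabel 1..n
  ids <- sort(unique(nl[nl > 0]))
  if (!length(ids)) return(empty())
  nl <- matrix(match(nl, ids, nomatch = 0L) , nrow(nl), ncol(nl))

  ## grow cells: nearest nucleus within the dilated footprint
  rad <- max(1L, round(expand_um / pitch))
  br <- EBImage::makeBrush(2 * rad + 1, shape = "disc")
  mask <- EBImage::dilate(EBImage::Image((nl > 0) * 1), br) > 0
  cells <- EBImage::propagate(EBImage::Image(matrix(0, nrow(nl), ncol(nl))),
                              seeds = EBImage::Image(nl), mask = mask,
                              lambda = 1e4)
  cl <- as.matrix(EBImage::imageData(cells))

  n <- max(nl)
  rows <- row(nl)[nl > 0]; cols <- col(nl)[nl > 0]; labs <- nl[nl > 0]
  cx <- tapply(rows, labs, mean); cy <- tapply(cols, labs, mean)
  area <- tabulate(labs, nbins = n) * pitch^2
  tab <- data.frame(id = seq_len(n),
                    x_um = (as.numeric(cx) - 0.5) * pitch,
                    y_um = (as.numeric(cy) - 0.5) * pitch,
                    area_um2 = area)
  structure(list(nuclei = nl, cells = cl, table = tab, pitch_um = pitch),
            class = "cell_segmentation")
}

#' Top-quintile marker features and phenotype clustering
#'
#' Per cell and marker channel the feature is the mean of the pixels at or
#' above the cell's 80th intensity percentile in that channel (cells
#' smaller than `min_pixels` fall back to the plain mean and are flagged).
#' Features are k-means clustered and clusters are named after their
#' dominant marker (largest mean feature relative to the global mean).
#'
#' @param seg a [segment_cells()] result.
#' @param img the `seqif_image` with marker channels.
#' @param markers channels to featurise (default: all but DAPI).
#' @param k number of phenotype clusters (default: number of markers).
#' @param seed integer seed for k-means.
#' @param compartment_mask optional [segment_tissue()] mask; cells get the
#'   compartment of their centroid.
#' @param marker_names optional named character mapping marker -> phenotype
#'   name for cluster naming.
#' @param min_pixels minimum cell size for the percentile feature.
#' @return `cell_table` data.frame: id, x_um, y_um, area_um2,
#'   `feature_<marker>` columns, `phenotype`, `small_cell` flag, and
#'   `compartment` when a mask is given.
#' @export
phenotype_cells <- function(seg, img, markers = NULL, k = NULL, seed = 1,
                            compartment_mask = NULL, marker_names = NULL,
                            min_pixels = 5) {
  stopifnot(inherits(seg, "cell_segmentation"))
  markers <- markers %||% setdiff(img$channels, "DAPI")
  n <- nrow(seg$table)
  if (n == 0) {
    out <- seg$table
    out$phenotype <- character(0)
    return(out)
  }
  cl <- seg$cells
  idx <- which(cl > 0)
  labs <- cl[idx]
  feats <- matrix(0, n, length(markers),
                  dimnames = list(NULL, markers))
  small <- tabulate(labs, nbins = n) < min_pixels
  for (m in markers) {
    ch <- get_channel(img, m)
    vals <- split(ch[idx], labs)
    feats[as.integer(names(vals)), m] <- vapply(seq_along(vals), function(i) {
      v <- vals[[i]]
      if (length(v) < min_pixels) return(mean(v))
      q <- quantile(v, 0.8, names = FALSE)
      mean(v[v >= q])
    }, numeric(1))
  }
  k <- k %||% length(markers)
  k <- min(k, n)
  set.seed(derive_seed(seed, "phenotype"))
  sc <- scale(feats)
  sc[!is.finite(sc)] <- 0
  km <- if (k <= 1) rep(1L, n) else if (k >= n) seq_len(n) else
    kmeans(sc, centers = k, nstart = 10)$cluster
  k <- max(km)
  ## name clusters by dominant marker (largest mean feature / global mean)
  gmean <- colMeans(feats)
  gmean[gmean == 0] <- 1
  cl_name <- vapply(seq_len(k), function(g) {
    mu <- colMeans(feats[km == g, , drop = FALSE])
    dom <- markers[which.max(mu / gmean)]
    if (!is.null(marker_names) && dom %in% names(marker_names))
      marker_names[[dom]] else paste0(dom, "+")
  }, character(1))

  out <- seg$table
  for (m in markers) out[[paste0("feature_", m)]] <- feats[, m]
  out$phenotype <- cl_name[km]
  out$small_cell <- small
  if (!is.null(compartment_mask)) {
    labs2 <- attr(compartment_mask, "labels")
    code <- sample_raster(
      structure(unclass(compartment_mask) * 1,
                pitch_um = attr(compartment_mask, "pitch_um")),
      out$x_um, out$y_um)
    out$compartment <- ifelse(code > 0, labs2[pmax(code, 1)], "background")
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Subtract a per-channel background image (autofluorescence correction)
#'
#' @param img a `seqif_image`.
#' @param background a `seqif_image` (or array) with matching channels;
#'   subtracted channel-wise and clipped at 0.
#' @return corrected `seqif_image`.
#' @export
subtract_background <- function(img, background) {
  bg <- if (inherits(background, "seqif_image")) background$data else background
  stopifnot(all(dim(img$data) == dim(bg)))
  out <- img
  out$data <- img$data - bg
  out$data[out$data < 0] <- 0
  out
}
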