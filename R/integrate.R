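#' Affine transform between modality frames
#'
#' A 2D affine map `y = A x + b` from source coordinates (microns in a
#' modality-local frame) to reference coordinates (microns in the chip
#' frame). Constructed either from `matrix23` directly, or from a rotation
#' about `center` plus a translation.
#'
#' @param matrix23 a 2 x 3 matrix `[A | b]`.
#' @param rotation_deg rotation angle, degrees counter-clockwise.
#' @param translation numeric length-2 shift in microns.
#' @param center rotation center, microns (default origin).
#' @return object of class `affine_transform` with elements `A` (2 x 2) and
#'   `b` (length 2).
#' @export
affine_transform <- function(matrix23 = NULL, rotation_deg = 0,
                             translation = c(0, 0), center = c(0, 0)) {
  if (!is.null(matrix23)) {
    stopifnot(is.matrix(matrix23), all(dim(matrix23) == c(2, 3)))
    A <- matrix23[, 1:2, drop = FALSE]
    b <- matrix23[, 3]
  } else {
    th <- rotation_deg * pi / 180
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    b <- as.numeric(center) - A %*% as.numeric(center) + as.numeric(translation)
  }
  if (abs(det(A)) < 1e-12)
    stop_sf("affine_transform: linear part is singular")
  structure(list(A = A, b = as.numeric(b)), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform [A | b]:\n")
  print(cbind(x$A, x$b))
  invisible(x)
}

#' Apply an affine transform to point coordinates
#'
#' @param transform an [affine_transform()].
#' @param xy n x 2 matrix (or length-2 vector) of coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_affine <- function(transform, xy) {
  stopifnot(inherits(transform, "affine_transform"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  t(transform$A %*% t(xy) + transform$b)
}

#' Invert an affine transform
#' @param transform an [affine_transform()].
#' @return the inverse `affine_transform`.
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  structure(list(A = Ai, b = as.numeric(-Ai %*% transform$b)),
            class = "affine_transform")
}

#' Compose two affine transforms
#' @param t2,t1 transforms; result applies `t1` first, then `t2`.
#' @return composed `affine_transform`.
#' @export
compose_affine <- function(t2, t1) {
  structure(list(A = t2$A %*% t1$A,
                 b = as.numeric(t2$A %*% t1$b + t2$b)),
            class = "affine_transform")
}

#' Least-squares affine fit from landmark pairs
#'
#' Estimates the affine map minimising the sum of squared residuals
#' `|| dst - (A src + b) ||^2` over at least three non-collinear landmark
#' pairs. With exactly three non-collinear pairs the fit is exact.
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 3).
#' @return an [affine_transform()] with attribute `rms_um`, the residual
#'   root-mean-square distance.
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 3)
    stop_sf("fit_affine: need at least 3 landmark pairs, got %d", nrow(src))
  X <- cbind(src, 1)
  if (qr(X)$rank < 3)
    stop_sf("fit_affine: landmarks are collinear; affine fit is degenerate")
  coef <- qr.solve(X, dst)            # 3 x 2: rows = (a_x, a_y, b)
  A <- t(coef[1:2, , drop = FALSE])
  b <- coef[3, ]
  res <- dst - X %*% coef
  tr <- structure(list(A = A, b = as.numeric(b)), class = "affine_transform")
  attr(tr, "rms_um") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Warp a raster into the reference frame
#'
#' Inverse-mapping resampler: each output pixel centre is pulled back through
#' the inverse transform and sampled from the source raster. Label and index
#' rasters must use `mode = "nearest"` (never creates label values absent
#' from the source); `mode = "linear"` (bilinear) is for intensity rasters
#' only.
#'
#' @param image numeric matrix; optionally with a `pitch_um` attribute.
#' @param transform [affine_transform()] mapping source microns to reference
#'   microns.
#' @param mode `"nearest"` or `"linear"`.
#' @param out_dim output dimensions (default: same as input).
#' @param pitch_um pixel pitch of source, microns (default: `pitch_um`
#'   attribute, else 1).
#' @param out_pitch_um pixel pitch of output (default: same as source).
#' @param background fill value for pixels mapping outside the source.
#' @return warped matrix with `pitch_um` attribute.
#' @export
warp_image <- function(image, transform, mode = c("nearest", "linear"),
                       out_dim = dim(image), pitch_um = NULL,
                       out_pitch_um = NULL, background = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(transform, "affine_transform"))
  pitch_um <- pitch_um %||% attr(image, "pitch_um") %||% 1
  out_pitch_um <- out_pitch_um %||% pitch_um
  inv <- invert_affine(transform)
  nx <- out_dim[1]; ny <- out_dim[2]
  ## output pixel centres (reference frame, microns)
  ux <- (seq_len(nx) - 0.5) * out_pitch_um
  uy <- (seq_len(ny) - 0.5) * out_pitch_um
  U <- cbind(rep(ux, times = ny), rep(uy, each = nx))
  S <- apply_affine(inv, U)           # source microns
  sx <- S[, 1] / pitch_um + 0.5       # fractional source pixel index
  sy <- S[, 2] / pitch_um + 0.5
  out <- rep(background, nx * ny)
  if (mode == "nearest") {
    i <- round(sx); j <- round(sy)
    ok <- i >= 1 & i <= nrow(image) & j >= 1 & j <= ncol(image)
    out[ok] <- image[cbind(i[ok], j[ok])]
  } else {
    i0 <- floor(sx); j0 <- floor(sy)
    fx <- sx - i0; fy <- sy - j0
    ok <- i0 >= 1 & i0 + 1 <= nrow(image) & j0 >= 1 & j0 + 1 <= ncol(image)
    idx <- function(di, dj) image[cbind(i0[ok] + di, j0[ok] + dj)]
    out[ok] <- idx(0, 0) * (1 - fx[ok]) * (1 - fy[ok]) +
      idx(1, 0) * fx[ok] * (1 - fy[ok]) +
      idx(0, 1) * (1 - fx[ok]) * fy[ok] +
      idx(1, 1) * fx[ok] * fy[ok]
  }
  m <- matrix(out, nx, ny)
  attr(m, "pitch_um") <- out_pitch_um
  m
}

#' @rdname warp_image
#' @export
warp_labels <- function(image, transform, out_dim = dim(image),
                        pitch_um = NULL, out_pitch_um = NULL,
                        background = 0) {
  warp_image(image, transform, mode = "nearest", out_dim = out_dim,
             pitch_um = pitch_um, out_pitch_um = out_pitch_um,
             background = background)
}

#' Build the indexed Leiden-voxel image
#'
#' Each cluster-labelled bin50-style square ("Leiden voxel") receives a
#' globally unique 16-bit index; the image has one channel per cluster and
#' channel c carries only voxels of cluster c. This indexed raster is the
#' common coordinate frame the other modalities are registered to.
#'
#' @param labels data.frame with integer columns `bin_x`, `bin_y` (0-based)
#'   and `cluster`; optionally `section`.
#' @param bin_size bin side in spots.
#' @param pitch_um spot pitch, microns (default 0.5).
#' @return object of class `leiden_voxel_image`: `channels` (3D integer
#'   array, x by y by cluster, 0 = no voxel), `index_map` (data.frame index,
#'   bin_x, bin_y, cluster, section), `voxel_side_um`, `bin_size`,
#'   `pitch_um`, `clusters`.
#' @export
build_voxel_index <- function(labels, bin_size, pitch_um = 0.5) {
  stopifnot(is.data.frame(labels),
            all(c("bin_x", "bin_y", "cluster") %in% names(labels)))
  if (nrow(labels) == 0)
    stop_sf("build_voxel_index: no labelled bins")
  if (anyDuplicated(labels[, c("bin_x", "bin_y")]))
    stop_sf("build_voxel_index: duplicated bin coordinates")
  n <- nrow(labels)
  if (n > 65535L)
    stop_sf(paste0("build_voxel_index: %d voxels exceed the 16-bit index ",
                   "capacity (65535)"), n)
  ## row-major scan order: top row left-to-right, then next row
  ord <- order(labels$bin_y, labels$bin_x)
  labels <- labels[ord, , drop = FALSE]
  labels$index <- seq_len(n)
  clusters <- sort(unique(labels$cluster))
  nx <- max(labels$bin_x) + 1L
  ny <- max(labels$bin_y) + 1L
  ch <- array(0L, dim = c(nx, ny, length(clusters)),
              dimnames = list(NULL, NULL, as.character(clusters)))
  ci <- match(labels$cluster, clusters)
  ch[cbind(labels$bin_x + 1L, labels$bin_y + 1L, ci)] <- labels$index
  im <- data.frame(index = labels$index, bin_x = labels$bin_x,
                   bin_y = labels$bin_y, cluster = labels$cluster,
                   section = if ("section" %in% names(labels))
                     labels$section else 1L)
  structure(list(channels = ch, index_map = im,
                 voxel_side_um = bin_size * pitch_um,
                 bin_size = bin_size, pitch_um = pitch_um,
                 clusters = clusters),
            class = "leiden_voxel_image")
}

#' @export
print.leiden_voxel_image <- function(x, ...) {
  cat(sprintf("leiden_voxel_image: %d voxels, %d clusters, side %.1f um\n",
              nrow(x$index_map), length(x$clusters), x$voxel_side_um))
  invisible(x)
}

## flat single-channel voxel-index raster (for warping / export)
voxel_index_raster <- function(vimg) {
  r <- apply(vimg$channels, c(1, 2), max)
  attr(r, "pitch_um") <- vimg$voxel_side_um
  r
}

#' Aggregate all modalities per Leiden voxel
#'
#' Joins bin-level gene expression (inherently aligned by bin coordinate),
#' averages registered MSI ion-image pixels, and counts registered
#' phenotyped cells inside each voxel. Voxel membership uses half-open
#' micron intervals `[x, x + side)` in the reference frame, so each MSI
#' pixel and each cell is assigned to at most one voxel. Voxels covered by
#' no MSI pixel get `NA` (not 0).
#'
#' @param voxel_img a [build_voxel_index()] result.
#' @param gene_matrix optional bin-level expression: a `binned_expression`
#'   (see [bin_spots()]) or a matrix with rownames `"x_y"` bin keys.
#' @param ion_images optional named list of ion-image matrices (each with a
#'   `pitch_um` attribute), one per m/z.
#' @param msi_transform [affine_transform()] mapping MSI-local microns to the
#'   reference frame (identity if NULL).
#' @param cell_table optional data.frame with `x_um`, `y_um`, `phenotype`.
#' @param cell_transform transform for cell centroids (identity if NULL).
#' @return data.frame (one row per voxel): index, cluster, bin_x, bin_y,
#'   section, then `gene_*` columns, `mz_*` mean intensities, `n_*`
#'   phenotype counts.
#' @export
aggregate_per_voxel <- function(voxel_img, gene_matrix = NULL,
                                ion_images = NULL, msi_transform = NULL,
                                cell_table = NULL, cell_transform = NULL) {
  stopifnot(inherits(voxel_img, "leiden_voxel_image"))
  vt <- voxel_img$index_map
  side <- voxel_img$voxel_side_um

  if (!is.null(gene_matrix)) {
    if (inherits(gene_matrix, "binned_expression")) {
      gm <- as.matrix(gene_matrix$counts)
      bx <- gene_matrix$bins$bin_x; by <- gene_matrix$bins$bin_y
    } else {
      gm <- as.matrix(gene_matrix)
      key <- do.call(rbind, strsplit(rownames(gm), "_", fixed = TRUE))
      bx <- as.integer(key[, 1]); by <- as.integer(key[, 2])
    }
    m <- match(paste(vt$bin_x, vt$bin_y), paste(bx, by))
    ge <- gm[m, , drop = FALSE]
    colnames(ge) <- paste0("gene_", colnames(gm))
    vt <- cbind(vt, as.data.frame(ge, row.names = NULL))
  }

  voxel_of <- function(x_um, y_um) {
    bx <- floor(x_um / side); by <- floor(y_um / side)
    m <- match(paste(bx, by), paste(vt$bin_x, vt$bin_y))
    m
  }

  if (!is.null(ion_images)) {
    for (nm in names(ion_images)) {
      img <- ion_images[[nm]]
      pitch <- attr(img, "pitch_um") %||%
        stop_sf("aggregate_per_voxel: ion image '%s' lacks pitch_um", nm)
      nx <- nrow(img); ny <- ncol(img)
      px <- (rep(seq_len(nx), times = ny) - 0.5) * pitch
      py <- (rep(seq_len(ny), each = nx) - 0.5) * pitch
      P <- cbind(px, py)
      if (!is.null(msi_transform)) P <- apply_affine(msi_transform, P)
      hit <- voxel_of(P[, 1], P[, 2])
      val <- as.vector(img)
      agg <- tapply(val[!is.na(hit)], hit[!is.na(hit)], mean)
      col <- rep(NA_real_, nrow(vt))
      col[as.integer(names(agg))] <- as.numeric(agg)
      vt[[paste0("mz_", nm)]] <- col
    }
  }

  if (!is.null(cell_table) && nrow(cell_table) > 0) {
    P <- cbind(cell_table$x_um, cell_table$y_um)
    if (!is.null(cell_transform)) P <- apply_affine(cell_transform, P)
    hit <- voxel_of(P[, 1], P[, 2])
    phe <- as.character(cell_table$phenotype)
    for (ph in sort(unique(phe))) {
      cnt <- tabulate(hit[phe == ph & !is.na(hit)], nbins = nrow(vt))
      vt[[paste0("n_", ph)]] <- cnt
    }
  } else if (!is.null(cell_table)) {
    ## empty table: still emit nothing (no phenotypes known)
  }
  vt
}

#' Per-cluster summaries of a voxel-table quantity
#'
#' @param voxel_table result of [aggregate_per_voxel()].
#' @param quantity column name to summarise.
#' @return data.frame per cluster: n (non-missing voxels), mean, var, q25,
#'   median, q75.
#' @export
cluster_stats <- function(voxel_table, quantity) {
  if (!quantity %in% names(voxel_table))
    stop_sf("cluster_stats: unknown quantity '%s'", quantity)
  sp <- split(voxel_table[[quantity]], voxel_table$cluster)
  out <- do.call(rbind, lapply(names(sp), function(cl) {
    v <- sp[[cl]]; v <- v[!is.na(v)]
    data.frame(cluster = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               var = if (length(v) > 1) var(v) else
                 if (length(v) == 1) 0 else NA_real_,
               q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               median = if (length(v)) median(v) else NA_real_,
               q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read an affine transform as JSON
#' @param transform an [affine_transform()].
#' @param path file path.
#' @param source,target frame names recorded in the file.
#' @export
write_affine_json <- function(transform, path, source = "modality",
                              target = "reference") {
  jsonlite::write_json(list(matrix = cbind(transform$A, transform$b),
                            source = source, target = target),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix23 = matrix(as.numeric(j$matrix), 2, 3))
}
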