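#' Ordered stack of registered sections
#'
#' @param images list of per-section 2D matrices (registered to the
#'   reference frame, common pitch).
#' @param z_um numeric section centre positions, strictly increasing.
#' @param thickness_um physical section thickness.
#' @param pitch_um in-plane pixel pitch.
#' @return object of class `section_stack`.
#' @export
section_stack <- function(images, z_um, thickness_um = 5, pitch_um = 1) {
  stopifnot(is.list(images), length(images) == length(z_um))
  if (is.unsorted(z_um, strictly = TRUE))
    stop_sf("section_stack: z positions must be strictly increasing")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_sf("section_stack: all sections must share dimensions")
  structure(list(images = images, z_um = as.numeric(z_um),
                 thickness_um = thickness_um, pitch_um = pitch_um),
            class = "section_stack")
}

#' Depth spanned by a section stack
#'
#' Thickness-inclusive: from the top of the first section to the bottom of
#' the last (`z` positions are section centres).
#'
#' @param stack a [section_stack()]; or give `z_um`/`thickness_um` directly.
#' @param z_um,thickness_um used when `stack` is missing.
#' @return depth in microns.
#' @export
stack_depth_um <- function(stack = NULL, z_um = NULL, thickness_um = NULL) {
  if (!is.null(stack)) {
    z_um <- stack$z_um
    thickness_um <- stack$thickness_um
  }
  diff(range(z_um)) + thickness_um
}

#' Resample a section stack to an isotropic 3D volume
#'
#' XY is resampled to `voxel_um` (nearest neighbour, aspect ratio
#' preserved) and the Z axis is sliced at the same pitch so voxels are
#' isotropic; each output slice is filled from the section whose centre is
#' nearest in Z. The slice count is `floor(depth / voxel_um)` exactly.
#'
#' @param stack a [section_stack()] with >= 2 sections.
#' @param voxel_um isotropic voxel side (0.23 um to match the imaging
#'   pixel size).
#' @param depth_um depth to slice; default [stack_depth_um()] of the stack.
#' @return 3D array (x, y, z) with attributes `voxel_um` and `z_centers_um`.
#' @export
assemble_resample <- function(stack, voxel_um = 0.23, depth_um = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  if (voxel_um <= 0) stop_sf("assemble_resample: voxel size must be positive")
  if (length(stack$images) < 2)
    stop_sf("assemble_resample: need >= 2 sections")
  depth_um <- depth_um %||% stack_depth_um(stack)
  nz <- floor(depth_um / voxel_um + 1e-9)
  ## in-plane resample (nearest neighbour, same scale both axes)
  scale <- stack$pitch_um / voxel_um
  nx <- max(1L, floor(nrow(stack$images[[1]]) * scale + 1e-9))
  ny <- max(1L, floor(ncol(stack$images[[1]]) * scale + 1e-9))
  xs <- pmin(nrow(stack$images[[1]]),
             pmax(1L, round((seq_len(nx) - 0.5) / scale + 0.5)))
  ys <- pmin(ncol(stack$images[[1]]),
             pmax(1L, round((seq_len(ny) - 0.5) / scale + 0.5)))
  planes <- lapply(stack$images, function(m) m[xs, ys, drop = FALSE])
  z0 <- min(stack$z_um) - stack$thickness_um / 2
  zc <- z0 + (seq_len(nz) - 0.5) * voxel_um
  nearest <- vapply(zc, function(z) which.min(abs(stack$z_um - z)),
                    integer(1))
  vol <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vol[, , k] <- planes[[nearest[k]]]
  attr(vol, "voxel_um") <- voxel_um
  attr(vol, "z_centers_um") <- zc
  vol
}

#' 3D proximity of phenotyped cells across sections
#'
#' Euclidean distances between cells where the Z component is the
#' difference of section centre positions. Returns all pairs below the
#' threshold (cells of the same or different sections).
#'
#' @param cell_tables named/indexed list of cell tables (data.frames with
#'   `x_um`, `y_um` and optionally `phenotype`), one per section.
#' @param z_um section centre positions aligned with `cell_tables`.
#' @param max_dist_um distance threshold.
#' @param phenotype optional phenotype filter.
#' @return data.frame: section_a, id_a, section_b, id_b, dist_um.
#' @export
z_proximity <- function(cell_tables, z_um, max_dist_um = 20,
                        phenotype = NULL) {
  stopifnot(length(cell_tables) == length(z_um))
  pts <- do.call(rbind, lapply(seq_along(cell_tables), function(s) {
    d <- cell_tables[[s]]
    if (!is.null(phenotype) && "phenotype" %in% names(d))
      d <- d[d$phenotype == phenotype, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(section = s, id = d$id %||% seq_len(nrow(d)),
               x = d$x_um, y = d$y_um, z = z_um[s])
  }))
  if (is.null(pts) || nrow(pts) < 2) {
    return(data.frame(section_a = integer(), id_a = integer(),
                      section_b = integer(), id_b = integer(),
                      dist_um = numeric()))
  }
  D <- as.matrix(dist(pts[, c("x", "y", "z")]))
  sel <- which(upper.tri(D) & D <= max_dist_um, arr.ind = TRUE)
  out <- data.frame(section_a = pts$section[sel[, 1]],
                    id_a = pts$id[sel[, 1]],
                    section_b = pts$section[sel[, 2]],
                    id_b = pts$id[sel[, 2]],
                    dist_um = D[sel])
  out[order(out$dist_um), , drop = FALSE]
}

#' Write a 3D volume as a multi-page TIFF (one page per Z slice)
#' @param volume array from [assemble_resample()].
#' @param path output path.
#' @export
write_volume_tiff <- function(volume, path) {
  mx <- max(volume, 1)
  pages <- lapply(seq_len(dim(volume)[3]), function(k) t(volume[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
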