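#' Single-cell mask with physical pixel size
#'
#' One frame of a traced single cell. The mask is reduced to its largest
#' connected foreground component (smaller fragments are dropped and
#' counted), and holes are filled, so downstream shape measures see exactly
#' one solid object.
#'
#' @param mask logical matrix.
#' @param pixel_size µm per pixel.
#' @param frame_time min.
#' @param cell_id,sample_id identifiers.
#' @return object of class `cell_mask`.
#' @export
cell_mask <- function(mask, pixel_size, frame_time = NA_real_,
                      cell_id = NA_character_, sample_id = NA_character_) {
  mask <- as.matrix(mask) > 0
  stopifnot(pixel_size > 0)
  n_dropped <- 0L
  if (any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    tab <- tabulate(as.integer(lab)[as.integer(lab) > 0L])
    keep <- which.max(tab)
    n_dropped <- length(tab) - 1L
    mask <- matrix(as.integer(lab) == keep, nrow(mask), ncol(mask))
    mask <- matrix(as.logical(EBImage::fillHull(EBImage::Image(mask * 1))),
                   nrow(mask), ncol(mask))
  }
  structure(list(mask = mask, pixel_size = pixel_size,
                 frame_time = frame_time, cell_id = cell_id,
                 sample_id = sample_id, n_dropped_fragments = n_dropped),
            class = "cell_mask")
}

#' Segment a single cell from a 2D frame
#'
#' Smooths the frame, thresholds it (Otsu), and keeps the connected
#' component containing the seed point; holes are filled. Errors if the
#' seed lands on background or the frame carries no signal.
#'
#' @param frame numeric matrix (intensity image).
#' @param seed integer length-2 (row, col) inside the cell of interest.
#' @param pixel_size µm per pixel.
#' @param smoothing_sigma µm, Gaussian sd (default 0.3).
#' @param ... passed to [cell_mask()] (frame_time, cell_id, sample_id).
#' @return a `cell_mask`.
#' @export
segment_cell <- function(frame, seed, pixel_size, smoothing_sigma = 0.3, ...) {
  frame <- as.matrix(frame)
  stopifnot(length(seed) == 2L, pixel_size > 0)
  if (max(frame) <= min(frame)) stop("frame carries no signal")
  s_px <- smoothing_sigma / pixel_size
  img <- EBImage::Image(frame / max(frame))
  if (s_px > 0) img <- EBImage::gblur(img, sigma = s_px)
  th <- otsu_threshold(as.numeric(img))
  fg <- img > th
  lab <- EBImage::bwlabel(fg)
  seed_lab <- as.integer(lab[seed[1], seed[2]])
  if (seed_lab == 0L) stop("seed point lies on background")
  cell_mask(matrix(as.integer(lab) == seed_lab, nrow(frame), ncol(frame)),
            pixel_size, ...)
}

# outline polygon of a mask: marching-squares contour at level 0.5, which
# runs along the physical object boundary (half-way between foreground and
# background pixel centers); rows are (row, col) pixel coordinates. The
# mask is zero-padded so border-touching objects still close.
.boundary_polygon <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)) - 1,
                                y = seq_len(ncol(pad)) - 1,
                                z = pad, levels = 0.5)
  cl <- cl[[which.max(vapply(cl, function(s) length(s$x), 1L))]]
  p <- cbind(cl$x, cl$y)
  if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

# perimeter estimator: circular moving-average smoothing of the boundary
# polygon followed by polyline length; the smoothing removes the staircase
# bias of pixel contours (window in vertices)
.smoothed_perimeter <- function(poly, window = 5L) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  w <- min(window, n)
  half <- (w - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  sm <- poly
  for (j in seq_len(n)) {
    rows <- idx(j + (-half:half))
    sm[j, ] <- colMeans(poly[rows, , drop = FALSE])
  }
  i2 <- c(2:n, 1L)
  sum(sqrt(rowSums((sm[i2, , drop = FALSE] - sm)^2)))
}

#' Shape measurements of a single-cell mask
#'
#' Computes the morphometric descriptors used to quantify protrusion
#' formation, all in physical units:
#' \itemize{
#'   \item area: pixel count times pixel area (µm²);
#'   \item perimeter: length of the smoothed boundary polygon (µm);
#'   \item circularity: \eqn{4\pi A / P^2}, capped at 1 (the ImageJ
#'     convention) — 1 for a perfect circle;
#'   \item solidity: area over convex-hull area — 1 for a convex (round)
#'     cell, decreasing toward 0 as protrusions form. The hull area is
#'     measured on the same pixel grid (pixels whose centers fall inside
#'     the hull of the mask's pixel centers), so solidity is consistently
#'     bounded by 1.
#' }
#'
#' @param m a [cell_mask()] (or a logical matrix plus `pixel_size`).
#' @param pixel_size µm per pixel; only needed when `m` is a bare matrix.
#' @return tibble with `area_um2`, `perimeter_um`, `circularity`,
#'   `solidity`, `hull_area_um2`, plus the mask's identifiers.
#' @export
morphology <- function(m, pixel_size = NULL) {
  if (!inherits(m, "cell_mask")) {
    stopifnot(!is.null(pixel_size))
    m <- cell_mask(m, pixel_size)
  }
  mask <- m$mask
  if (!any(mask)) stop("empty mask")
  px <- m$pixel_size
  area <- sum(mask) * px^2
  poly <- .boundary_polygon(mask)
  per <- .smoothed_perimeter(poly) * px
  circ <- min(4 * pi * area / per^2, 1)
  hull_area <- .convex_pixel_area(mask) * px^2
  tibble::tibble(cell_id = m$cell_id, sample_id = m$sample_id,
                 frame_time = m$frame_time,
                 area_um2 = area, perimeter_um = per, circularity = circ,
                 solidity = min(area / hull_area, 1),
                 hull_area_um2 = hull_area)
}

# number of pixels whose centers lie inside (or on) the convex hull of the
# mask's foreground pixel centers
.convex_pixel_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(nrow(idx))
  h <- grDevices::chull(idx)
  poly <- idx[h, , drop = FALSE]
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  cand <- as.matrix(expand.grid(row = rr[1]:rr[2], col = cc[1]:cc[2]))
  # on-boundary centers count as inside: test with a tiny inward expansion
  ctr <- colMeans(poly)
  grown <- sweep(sweep(poly, 2L, ctr), 2L, c(1, 1) * 1.000001, `*`)
  grown <- sweep(grown, 2L, ctr, `+`)
  sum(point_in_polygon(cand, grown))
}

#' Pooled morphology table across cells and groups
#'
#' Pools all frames of all cells per treatment group into one long-form
#' table (one row per cell x frame) for group statistics; per-cell means
#' are attached as an attribute because pooled frames of one cell are not
#' independent observations.
#'
#' @param groups named list: `group_label -> list of cell_mask objects` (or
#'   of lists of masks, one per frame).
#' @return tibble with `group`, `cell_id`, `frame_time` and all
#'   [morphology()] columns; attribute `per_cell` holds per-cell means.
#' @export
morphology_table <- function(groups) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  rows <- list()
  for (g in names(groups)) {
    masks <- groups[[g]]
    for (m in masks) {
      rec <- morphology(m)
      rec$group <- g
      rows[[length(rows) + 1L]] <- rec
    }
  }
  tab <- dplyr::relocate(dplyr::bind_rows(rows), "group")
  per_cell <- dplyr::summarise(
    dplyr::group_by(tab, .data$group, .data$cell_id),
    dplyr::across(c("area_um2", "circularity", "solidity"), mean),
    n_frames = dplyr::n(), .groups = "drop")
  attr(tab, "per_cell") <- per_cell
  tab
}

#' Cell body after removal of fine protrusions
#'
#' Morphological opening with a disk structuring element of the given
#' diameter deletes protrusions thinner than the element while preserving
#' the cell body, separating global membrane movement from filopodial
#' activity. The default diameter of 2 µm matches the upper bound of
#' filopodium thickness.
#'
#' @param m a [cell_mask()].
#' @param protrusion_diameter µm, structuring-element diameter (> 0).
#' @return a `cell_mask` of the body (always a subset of the input mask);
#'   attribute `empty_body` flags an annihilated mask.
#' @export
cell_body <- function(m, protrusion_diameter = 2) {
  stopifnot(inherits(m, "cell_mask"), protrusion_diameter > 0)
  d_px <- protrusion_diameter / m$pixel_size
  if (d_px <= 1) return(m)  # element below one pixel: opening is identity
  size <- max(3L, 2L * floor(d_px / 2) + 1L)
  brush <- EBImage::makeBrush(size, shape = "disc")
  opened <- EBImage::opening(EBImage::Image(m$mask * 1), brush)
  body <- matrix(as.logical(opened > 0), nrow(m$mask), ncol(m$mask)) & m$mask
  out <- cell_mask(body, m$pixel_size, m$frame_time, m$cell_id, m$sample_id)
  attr(out, "empty_body") <- !any(body)
  out
}

#' Membrane motility between consecutive frames
#'
#' Compares the cell body (protrusions removed, see [cell_body()]) across a
#' frame pair: expansion is the area gained, retraction the area lost, and
#' the motility index their sum normalized by the mean body area. Raw areas
#' are reported alongside the index.
#'
#' @param body_a,body_b `cell_mask` bodies of the same cell in consecutive
#'   frames, on identical grids.
#' @return tibble with `expansion_um2`, `retraction_um2`, `body_area_um2`
#'   (mean of the two frames), `motility_index`, and `flagged` (TRUE when
#'   either body is empty).
#' @export
membrane_motility <- function(body_a, body_b) {
  stopifnot(inherits(body_a, "cell_mask"), inherits(body_b, "cell_mask"),
            identical(dim(body_a$mask), dim(body_b$mask)),
            isTRUE(all.equal(body_a$pixel_size, body_b$pixel_size)))
  px2 <- body_a$pixel_size^2
  exp_a <- sum(body_b$mask & !body_a$mask) * px2
  ret_a <- sum(body_a$mask & !body_b$mask) * px2
  mean_area <- (sum(body_a$mask) + sum(body_b$mask)) / 2 * px2
  flagged <- !any(body_a$mask) || !any(body_b$mask)
  tibble::tibble(cell_id = body_a$cell_id,
                 expansion_um2 = exp_a, retraction_um2 = ret_a,
                 body_area_um2 = mean_area,
                 motility_index = if (mean_area > 0)
                   (exp_a + ret_a) / mean_area else NA_real_,
                 flagged = flagged)
}
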