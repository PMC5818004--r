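#' Head/tail region of interest
#'
#' The automated islet pipeline requires one manual input: a polyline drawn
#' on the xy projection that separates the pancreatic head from the tail,
#' plus a flag saying on which side of the line the posterior pancreas
#' (tail) lies. All downstream segmentation is restricted to the tail side.
#'
#' @param polyline matrix of at least 2 points, columns (y, x) in µm.
#' @param tail_side `+1` or `-1`: the sign of the cross product
#'   (segment direction x offset) that identifies the tail half-plane.
#' @return object of class `head_tail_roi`.
#' @export
head_tail_roi <- function(polyline, tail_side = 1L) {
  polyline <- matrix(as.numeric(polyline), ncol = 2)
  stopifnot(nrow(polyline) >= 2L, tail_side %in% c(-1L, 1L))
  structure(list(polyline = polyline, tail_side = as.integer(tail_side)),
            class = "head_tail_roi")
}

#' Read / write an ROI as JSON
#' @param path JSON file path.
#' @rdname head_tail_roi
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  head_tail_roi(as.matrix(j$polyline_um), j$tail_side)
}

#' @param roi a `head_tail_roi`.
#' @rdname head_tail_roi
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(list(polyline_um = roi$polyline,
                            tail_side = roi$tail_side),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# signed side of each (y, x) point relative to the ROI polyline: sign of the
# 2D cross product of the nearest segment's direction with the point offset
.roi_side <- function(pts_yx, roi) {
  pl <- roi$polyline
  nseg <- nrow(pl) - 1L
  best_d2 <- rep(Inf, nrow(pts_yx))
  side <- numeric(nrow(pts_yx))
  for (s in seq_len(nseg)) {
    a <- pl[s, ]; b <- pl[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel_y <- pts_yx[, 1] - a[1]; rel_x <- pts_yx[, 2] - a[2]
    t <- if (len2 > 0) pmin(pmax((rel_y * ab[1] + rel_x * ab[2]) / len2, 0), 1) else 0
    dy <- rel_y - t * ab[1]; dx <- rel_x - t * ab[2]
    d2 <- dy^2 + dx^2
    cr <- ab[1] * rel_x - ab[2] * rel_y   # cross(ab, rel), z-component
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    side[upd] <- sign(cr[upd])
  }
  side
}

# logical (z,y,x) array marking the tail half of the field
.tail_mask <- function(dims, voxel_size, roi) {
  yy <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  xx <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  pts <- cbind(rep(yy, times = dims[3]), rep(xx, each = dims[2]))
  side2d <- matrix(.roi_side(pts, roi) == roi$tail_side, dims[2], dims[3])
  aperm(array(side2d, c(dims[2], dims[3], dims[1])), c(3, 1, 2))
}

#' Delineate the exocrine pancreas from the red channel
#'
#' Segments the whole pancreas from the exocrine (mCherry) channel on the
#' tail side of the head/tail ROI: Gaussian smoothing, local background
#' subtraction, automatic (Otsu) or fixed thresholding, then the largest 3D
#' connected component. Returns an empty mask with a flag (not an error)
#' when no foreground survives the threshold.
#'
#' @param red `volumetric_image`, exocrine channel.
#' @param roi a [head_tail_roi()].
#' @param smoothing_sigma µm, Gaussian sd (default 0.5, the standard
#'   smoothing used for islet surface extraction).
#' @param background_radius µm, top-hat element radius (default 10).
#' @param threshold `"otsu"` or a fixed numeric intensity.
#' @return list: `mask` (logical (z,y,x) array), `empty` flag, `threshold`
#'   used, `volume_um3` of the mask.
#' @export
delineate_pancreas <- function(red, roi, smoothing_sigma = 0.5,
                               background_radius = 10, threshold = "otsu") {
  stopifnot(inherits(red, "volumetric_image"), inherits(roi, "head_tail_roi"))
  if (any(red$voxel_size > 2 * smoothing_sigma + background_radius))
    warning("z-step exceeds the object scale; segmentation may be unreliable ",
            "for strongly anisotropic stacks")
  img <- smooth_gaussian(red, smoothing_sigma)
  img <- subtract_background(img, background_radius)
  tail <- .tail_mask(dim(img$voxels), img$voxel_size, roi)
  vals <- img$voxels[tail]
  th <- if (identical(threshold, "otsu")) otsu_threshold(vals)
        else as.numeric(threshold)
  fg <- img$voxels > th & tail
  if (!any(fg))
    return(list(mask = fg, empty = TRUE, threshold = th, volume_um3 = 0))
  lab <- label_components_3d(fg)
  mask <- lab == 1L   # components are ordered by size; keep the largest
  list(mask = mask, empty = FALSE, threshold = th,
       volume_um3 = sum(mask) * voxel_volume(red))
}

#' Segment secondary islets inside the pancreas
#'
#' Applies the same smoothing / background-subtraction / threshold chain to
#' the endocrine (GFP) channel, restricted to the pancreas mask, labels 3D
#' connected components (26-connectivity) and discards objects smaller than
#' `min_volume` (default 100 µm³, the standard minimum object size for
#' secondary-islet quantitation).
#'
#' @param green `volumetric_image`, endocrine channel; voxel metadata is
#'   required — volumes are physical.
#' @param pancreas_mask logical (z,y,x) array from [delineate_pancreas()].
#' @param min_volume µm³, smallest object reported.
#' @param smoothing_sigma,background_radius,threshold as in
#'   [delineate_pancreas()].
#' @return tibble with one row per islet: `label`, `volume_um3`,
#'   `voxel_count`, `centroid_z/y/x_um`, `mean_intensity`, sorted by
#'   decreasing volume. Attribute `label_array` carries the filtered label
#'   volume for QC rendering.
#' @export
segment_islets <- function(green, pancreas_mask, min_volume = 100,
                           smoothing_sigma = 0.5, background_radius = 10,
                           threshold = "otsu") {
  stopifnot(inherits(green, "volumetric_image"))
  if (is.null(green$voxel_size) || any(!is.finite(green$voxel_size)))
    stop("voxel size metadata is required: volumes would be meaningless")
  pancreas_mask <- as.array(pancreas_mask)
  stopifnot(identical(dim(pancreas_mask), dim(green$voxels)))
  empty <- tibble::tibble(label = integer(0), volume_um3 = numeric(0),
                          voxel_count = integer(0), centroid_z_um = numeric(0),
                          centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                          mean_intensity = numeric(0))
  if (!any(pancreas_mask)) return(empty)
  img <- smooth_gaussian(green, smoothing_sigma)
  img <- subtract_background(img, background_radius)
  vals <- img$voxels[pancreas_mask]
  th <- if (identical(threshold, "otsu")) otsu_threshold(vals)
        else as.numeric(threshold)
  fg <- img$voxels > th & pancreas_mask
  if (!any(fg)) return(empty)
  lab <- label_components_3d(fg)
  vvol <- voxel_volume(green)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * vvol >= min_volume)
  if (length(keep) == 0L) return(empty)
  out <- lapply(seq_along(keep), function(i) {
    lin <- which(lab == keep[i])
    ctr <- colMeans(voxel_centers_um(lin, dim(lab), green$voxel_size))
    tibble::tibble(label = i, volume_um3 = length(lin) * vvol,
                   voxel_count = length(lin),
                   centroid_z_um = ctr[1], centroid_y_um = ctr[2],
                   centroid_x_um = ctr[3],
                   mean_intensity = mean(green$voxels[lin]))
  })
  res <- dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$volume_um3))
  res$label <- seq_len(nrow(res))
  filt <- array(0L, dim(lab))
  for (i in seq_along(keep)) filt[lab == keep[i]] <- i
  attr(res, "label_array") <- filt
  res
}

#' Count labeled nuclei by scale-matched blob detection
#'
#' Laplacian-of-Gaussian detection of bright spots of a configured physical
#' diameter (default 5 µm, the standard spot size for endocrine nuclei),
#' restricted to a mask. The Gaussian scale is sigma = diameter / (2 sqrt 2),
#' at which the LoG response of a ball of that diameter peaks; candidate
#' maxima closer than `diameter / 2` are merged (strongest wins) and spots
#' dimmer than `intensity_threshold` at their center are discarded.
#'
#' @param image `volumetric_image` containing the nuclei.
#' @param mask logical array restricting the search; NULL = whole image.
#' @param diameter µm, expected spot diameter.
#' @param intensity_threshold minimum (smoothed) center intensity; spots
#'   below it are filtered out.
#' @return tibble: `z_um`, `y_um`, `x_um`, `center_intensity`, `response`;
#'   attribute `diameter`.
#' @export
count_spots <- function(image, mask = NULL, diameter = 5,
                        intensity_threshold = 0) {
  stopifnot(inherits(image, "volumetric_image"), diameter > 0)
  dims <- dim(image$voxels)
  if (is.null(mask)) mask <- array(TRUE, dims)
  empty <- tibble::tibble(z_um = numeric(0), y_um = numeric(0),
                          x_um = numeric(0), center_intensity = numeric(0),
                          response = numeric(0))
  attr(empty, "diameter") <- diameter
  if (!any(mask)) return(empty)
  sigma <- diameter / (2 * sqrt(2))
  sm <- smooth_gaussian(image, sigma)
  # scale-normalized negative Laplacian: bright blobs become positive peaks
  lap <- array(0, dims)
  for (axis in 1:3) {
    h <- image$voxel_size[axis]
    lap <- lap + (.shift3(sm$voxels, axis, 1L) + .shift3(sm$voxels, axis, -1L) -
                    2 * sm$voxels) / h^2
  }
  resp <- -sigma^2 * lap
  r_vox <- pmax(1L, as.integer(round(diameter / 2 / image$voxel_size)))
  mx <- .box_extremum(resp, r_vox, pmax)
  is_peak <- resp >= mx & resp > 0 & mask
  lin <- which(is_peak)
  if (length(lin) == 0L) return(empty)
  centers <- voxel_centers_um(lin, dims, image$voxel_size)
  inten <- sm$voxels[lin]
  keep <- inten >= intensity_threshold
  out <- tibble::tibble(z_um = centers[keep, 1], y_um = centers[keep, 2],
                        x_um = centers[keep, 3],
                        center_intensity = inten[keep],
                        response = resp[lin][keep])
  # enforce non-duplication: greedy suppression of peaks within d/2
  if (nrow(out) > 1L) {
    out <- dplyr::arrange(out, dplyr::desc(.data$response))
    pos <- as.matrix(out[, c("z_um", "y_um", "x_um")])
    keep2 <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1L]) {
      prev <- pos[seq_len(i - 1L)[keep2[seq_len(i - 1L)]], , drop = FALSE]
      if (nrow(prev) > 0 &&
          min(sqrt(rowSums(sweep(prev, 2L, pos[i, ])^2))) < diameter / 2)
        keep2[i] <- FALSE
    }
    out <- out[keep2, ]
  }
  attr(out, "diameter") <- diameter
  out
}

#' Islet results table and QC montages for a batch of samples
#'
#' Collates per-sample islet tables into one results CSV (one row per
#' islet; samples without islets appear in the run log with zero rows) and
#' writes a pre-/post-processing montage PNG per sample: maximum-intensity
#' projection of the raw green channel next to the projection of the
#' segmented labels. A JSON run log records parameters and per-sample
#' object counts. Output is deterministic: rerunning on the same inputs
#' reproduces the CSV byte for byte.
#'
#' @param samples named list; each element a list with `islets` (tibble from
#'   [segment_islets()]), `group` (label), and optionally `green`
#'   (`volumetric_image`) for montage rendering.
#' @param out_dir output directory (created if needed).
#' @param params list of pipeline parameters to record in the run log.
#' @return invisibly, the combined tibble (also written to
#'   `islet_volumes.csv`).
#' @export
islet_report <- function(samples, out_dir, params = list()) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); log_entries <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    isl <- s$islets
    if (nrow(isl) > 0L)
      rows[[nm]] <- dplyr::mutate(isl, sample = nm,
                                  group = s$group %||% NA_character_,
                                  .before = 1L)
    log_entries[[nm]] <- list(sample = nm, group = s$group %||% NA_character_,
                              n_islets = nrow(isl),
                              total_volume_um3 = sum(isl$volume_um3))
    if (!is.null(s$green)) {
      lab_arr <- attr(isl, "label_array")
      .write_montage_png(s$green, lab_arr,
                         file.path(out_dir, paste0(nm, "_montage.png")))
    }
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(sample = character(0), group = character(0),
                   label = integer(0), volume_um3 = numeric(0))
  utils::write.csv(tab, file.path(out_dir, "islet_volumes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(parameters = params, samples = log_entries),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

# side-by-side max projection montage: raw (left) vs segmentation (right)
.write_montage_png <- function(green, label_array, path) {
  proj <- apply(green$voxels, c(2, 3), max)
  proj <- proj / max(proj, 1e-12)
  seg <- if (!is.null(label_array)) {
    sp <- apply(label_array, c(2, 3), max)
    sp / max(sp, 1L)
  } else matrix(0, nrow(proj), ncol(proj))
  sep <- matrix(1, nrow(proj), 2L)
  png::writePNG(pmin(pmax(cbind(proj, sep, seg), 0), 1), path)
  invisible(path)
}

#' Run the full automated islet pipeline on one two-channel sample
#'
#' Convenience wrapper chaining [delineate_pancreas()] and
#' [segment_islets()]; this is what the batch CLI calls per image pair.
#'
#' @param red,green `volumetric_image`s (exocrine / endocrine channels).
#' @param roi a [head_tail_roi()].
#' @param min_volume µm³ object filter (default 100).
#' @param smoothing_sigma,background_radius,threshold pipeline parameters.
#' @return list with `pancreas` (from [delineate_pancreas()]) and `islets`
#'   (tibble).
#' @export
quantify_islets <- function(red, green, roi, min_volume = 100,
                            smoothing_sigma = 0.5, background_radius = 10,
                            threshold = "otsu") {
  pan <- delineate_pancreas(red, roi, smoothing_sigma, background_radius,
                            threshold)
  islets <- if (pan$empty) segment_islets(green, array(FALSE, dim(green$voxels)),
                                          min_volume)
  else segment_islets(green, pan$mask, min_volume, smoothing_sigma,
                      background_radius, threshold)
  list(pancreas = pan, islets = islets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read pipeline parameters from a YAML config file
#'
#' Supported keys (all optional, defaults shown): `smoothing_sigma` (0.5
#' µm), `background_radius` (10 µm), `threshold` ("otsu" or a number),
#' `min_volume` (100 µm³), `spot_diameter` (5 µm), `max_displacement`
#' (10 µm), `protrusion_diameter` (2 µm). Unknown keys raise an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return named list of parameters.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(smoothing_sigma = 0.5, background_radius = 10,
                   threshold = "otsu", min_volume = 100, spot_diameter = 5,
                   max_displacement = 10, protrusion_diameter = 2)
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}
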