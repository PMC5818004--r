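#' Volumetric image with physical voxel sizes
#'
#' A light container for one channel of a confocal stack: a numeric voxel
#' grid plus the physical voxel size in µm per axis. Axis order is (z, y, x)
#' throughout the package, voxel centers sit at `(index - 0.5) * voxel_size`,
#' and every physical computation (smoothing widths, volumes, distances) is
#' carried out in µm so that anisotropic stacks (confocal z-step larger than
#' the xy pixel) are handled correctly.
#'
#' @param voxels 3D numeric array, dimensions (z, y, x).
#' @param voxel_size numeric length-3, µm per voxel along (z, y, x).
#' @param channel_label optional channel name, e.g. "red" or "green".
#' @return object of class `volumetric_image`.
#' @export
volumetric_image <- function(voxels, voxel_size, channel_label = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array ordered (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (µm), order (z, y, x)")
  structure(
    list(voxels = voxels, voxel_size = voxel_size,
         channel_label = as.character(channel_label)),
    class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volumetric_image> %s  %d x %d x %d voxels (z,y,x), voxel %s um\n",
              if (nzchar(x$channel_label)) x$channel_label else "(unlabeled)",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Volume of one voxel in µm³
#' @param img a `volumetric_image`.
#' @export
voxel_volume <- function(img) prod(img$voxel_size)

# shift a 3D array by `by` voxels along `axis` with edge replication
.shift3 <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable 1D convolution along one axis, replicated edges
.conv_axis <- function(a, axis, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * .shift3(a, axis, j - r - 1L)
  out
}

#' Gaussian smoothing of a volumetric image in physical units
#'
#' Separable Gaussian filter whose standard deviation is specified in µm and
#' converted to voxels per axis, so anisotropic stacks are smoothed
#' isotropically in physical space.
#'
#' @param img a `volumetric_image`.
#' @param sigma_um smoothing sd in µm (scalar, or length 3 per (z, y, x)).
#' @return smoothed `volumetric_image`.
#' @export
smooth_gaussian <- function(img, sigma_um) {
  stopifnot(inherits(img, "volumetric_image"))
  sigma_um <- rep(as.numeric(sigma_um), length.out = 3L)
  a <- img$voxels
  for (axis in 1:3) {
    s_vox <- sigma_um[axis] / img$voxel_size[axis]
    if (s_vox <= 0) next
    r <- max(1L, ceiling(3 * s_vox))
    k <- stats::dnorm(-r:r, sd = s_vox)
    k <- k / sum(k)
    a <- .conv_axis(a, axis, k)
  }
  volumetric_image(a, img$voxel_size, img$channel_label)
}

# running min/max over a box of half-width r voxels along each axis
.box_extremum <- function(a, r_vox, fun) {
  for (axis in 1:3) {
    r <- r_vox[axis]
    if (r < 1L) next
    out <- a
    for (by in c(-(r:1), 1:r)) out <- fun(out, .shift3(a, axis, by))
    a <- out
  }
  a
}

#' Local background subtraction by grayscale top-hat
#'
#' Removes slowly varying background (tissue autofluorescence, uneven
#' illumination) by subtracting the grayscale opening of the image with a
#' box structuring element of the given physical radius. Objects smaller
#' than the element are retained; broad background is removed.
#'
#' @param img a `volumetric_image`.
#' @param radius_um structuring-element half-width in µm; should exceed the
#'   size of objects to keep (default 10 µm for ~5 µm islet cells).
#' @return background-subtracted `volumetric_image` (non-negative).
#' @export
subtract_background <- function(img, radius_um = 10) {
  stopifnot(inherits(img, "volumetric_image"), radius_um > 0)
  r_vox <- pmax(0L, as.integer(round(radius_um / img$voxel_size)))
  er <- .box_extremum(img$voxels, r_vox, pmin)
  op <- .box_extremum(er, r_vox, pmax)
  volumetric_image(pmax(img$voxels - op, 0), img$voxel_size, img$channel_label)
}

#' Otsu threshold of voxel intensities
#'
#' Histogram-based two-class threshold (Otsu) computed on the supplied
#' intensities, the default automatic threshold of the segmentation pipeline.
#'
#' @param values numeric vector of intensities.
#' @param levels number of histogram bins.
#' @return scalar threshold on the intensity scale of `values`.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= 0) return(rng[1])
  scaled <- (values - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled, dim = c(length(scaled), 1L)),
                      range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

#' Label 3D connected components
#'
#' Labels foreground voxels of a boolean grid into connected components
#' under 26-connectivity (voxels sharing a face, edge or corner belong to
#' the same object), the convention used for islet objects.
#'
#' @param mask 3D logical array.
#' @return integer array of the same dimension; 0 = background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components_3d <- function(mask) {
  mask <- as.array(mask)
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  co <- arrayInd(fg, d)
  id <- integer(prod(d)); id[fg] <- seq_along(fg)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[offs[, 1] * 9 + offs[, 2] * 3 + offs[, 3] > 0, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, -offs[k, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    tgt <- id[lin]
    src <- which(ok)[tgt > 0L]
    edges[[k]] <- cbind(src, tgt[tgt > 0L])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  rank <- match(comp, names(sort(sizes, decreasing = TRUE)))
  lab[fg] <- as.integer(rank)
  lab
}

#' Physical coordinates of voxel centers
#'
#' @param lin linear indices into the voxel array.
#' @param dims array dimensions (z, y, x).
#' @param voxel_size µm per axis (z, y, x).
#' @return matrix of µm coordinates, columns (z, y, x).
#' @export
voxel_centers_um <- function(lin, dims, voxel_size) {
  co <- arrayInd(lin, dims)
  sweep(co - 0.5, 2L, voxel_size, `*`)
}

#' Write a volumetric image as a multi-page TIFF
#'
#' One grayscale page per z-slice; the voxel size, channel label and
#' intensity scale are stored in a `.json` sidecar next to the file.
#'
#' @param img a `volumetric_image`.
#' @param path output file path (`.tif`).
#' @export
write_volumetric_tiff <- function(img, path) {
  stopifnot(inherits(img, "volumetric_image"))
  a <- img$voxels
  mx <- max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / mx)
  meta <- list(voxel_size_um = img$voxel_size, channel_label = img$channel_label,
               intensity_scale = mx, axis_order = "zyx")
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volumetric image written by [write_volumetric_tiff()]
#'
#' @param path TIFF path; voxel size is taken from the JSON sidecar or the
#'   TIFF description tag, and can be overridden.
#' @param voxel_size optional µm per axis (z, y, x) overriding metadata.
#' @return a `volumetric_image`.
#' @export
read_volumetric_tiff <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  meta <- NULL
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc))
      meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  }
  if (is.null(voxel_size)) {
    if (is.null(meta$voxel_size_um))
      stop("voxel size metadata missing; supply `voxel_size` explicitly ",
           "(volumes would be meaningless without it)")
    voxel_size <- meta$voxel_size_um
  }
  scl <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  a <- array(0, c(length(pages), dim(pages[[1]])[1:2]))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # collapse any samples-per-pixel
    a[z, , ] <- pg
  }
  volumetric_image(a * scl, voxel_size,
                   if (!is.null(meta$channel_label)) meta$channel_label else "")
}
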