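#' Specification of a synthetic two-channel pancreas scene
#'
#' Describes a ground-truthed synthetic confocal stack emulating the
#' anatomy used for secondary-islet quantitation: an ellipsoidal exocrine
#' "pancreas" in the red channel containing spherical endocrine cells in the
#' green channel. Rendering applies a Gaussian point-spread approximation
#' and Poisson-plus-Gaussian noise; the unblurred, noise-free masks are
#' returned as ground truth.
#'
#' @param grid_shape integer length-3, voxels per axis (z, y, x).
#' @param voxel_size µm per axis (z, y, x); z may exceed xy (anisotropy).
#' @param pancreas_center ellipsoid center, µm (z, y, x).
#' @param pancreas_semiaxes ellipsoid semi-axes, µm (z, y, x).
#' @param n_cells number of endocrine cells to place inside the ellipsoid.
#' @param cell_radius_range µm, min and max cell radius.
#' @param psf_sigma µm per axis, Gaussian blur approximating the PSF
#'   (0 disables blurring).
#' @param noise_gaussian_sd additive read-noise sd (intensity units).
#' @param noise_poisson_scale photon count at unit intensity for shot noise
#'   (0 disables Poisson noise).
#' @param red_intensity,green_intensity signal amplitudes (arbitrary units;
#'   free parameters of the simulation).
#' @param seed integer; identical spec + seed gives bit-identical scenes.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(grid_shape = c(40L, 96L, 96L),
                       voxel_size = c(1, 0.5, 0.5),
                       pancreas_center = NULL,
                       pancreas_semiaxes = c(12, 18, 20),
                       n_cells = 5L,
                       cell_radius_range = c(2.5, 4),
                       psf_sigma = c(1, 0.4, 0.4),
                       noise_gaussian_sd = 0.02,
                       noise_poisson_scale = 200,
                       red_intensity = 0.6,
                       green_intensity = 1,
                       seed = 1L) {
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  extent <- grid_shape * voxel_size
  if (is.null(pancreas_center)) pancreas_center <- extent / 2
  stopifnot(all(grid_shape >= 1), all(voxel_size > 0),
            all(pancreas_semiaxes > 0), all(cell_radius_range > 0),
            n_cells >= 0, noise_gaussian_sd >= 0, noise_poisson_scale >= 0)
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    pancreas_center = pancreas_center, pancreas_semiaxes = pancreas_semiaxes,
    n_cells = as.integer(n_cells), cell_radius_range = cell_radius_range,
    psf_sigma = rep(as.numeric(psf_sigma), length.out = 3L),
    noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson_scale = noise_poisson_scale,
    red_intensity = red_intensity, green_intensity = green_intensity,
    seed = as.integer(seed)), class = "scene_spec")
}

# µm coordinate grids of voxel centers for a spec-sized array
.center_grids <- function(grid_shape, voxel_size) {
  list(z = (seq_len(grid_shape[1]) - 0.5) * voxel_size[1],
       y = (seq_len(grid_shape[2]) - 0.5) * voxel_size[2],
       x = (seq_len(grid_shape[3]) - 0.5) * voxel_size[3])
}

# boolean voxelization of an axis-aligned ellipsoid (center/semiaxes in µm)
.voxelize_ellipsoid <- function(grid_shape, voxel_size, center, semiaxes) {
  g <- .center_grids(grid_shape, voxel_size)
  dz2 <- ((g$z - center[1]) / semiaxes[1])^2
  dy2 <- ((g$y - center[2]) / semiaxes[2])^2
  dx2 <- ((g$x - center[3]) / semiaxes[3])^2
  outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
}

#' Sample admissible cell centers inside the pancreas ellipsoid
#'
#' Rejection-samples `n_cells` centers uniformly in the ellipsoid, shrunk by
#' each cell's radius so whole cells stay inside, with pairwise separation
#' of at least the sum of radii (no overlap). Deterministic given the seed.
#'
#' @param spec a [scene_spec()].
#' @return list with `centers` (matrix µm, (z, y, x)) and `radii` (µm).
#' @export
sample_cells <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_cells
  if (n == 0L)
    return(list(centers = matrix(numeric(0), 0, 3), radii = numeric(0)))
  set.seed(spec$seed)
  radii <- stats::runif(n, spec$cell_radius_range[1], spec$cell_radius_range[2])
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (try in 1:5000) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- stats::runif(1)^(1 / 3)
      cand <- spec$pancreas_center +
        u * r * (spec$pancreas_semiaxes - radii[i]) *
        (spec$pancreas_semiaxes >= radii[i])
      ok <- TRUE
      if (i > 1L) {
        dd <- sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                 2L, cand)^2))
        ok <- all(dd >= radii[i] + radii[seq_len(i - 1L)])
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (anyNA(centers[i, ]))
      stop("could not place ", n, " non-overlapping cells in the ellipsoid")
  }
  list(centers = centers, radii = radii)
}

#' Render a two-channel synthetic pancreas scene
#'
#' Voxelizes the pancreas ellipsoid (red channel) and the endocrine cells
#' (green channel), applies the Gaussian PSF approximation and the
#' Poisson-shot plus Gaussian-read noise model, and returns both channels
#' together with the pre-blur, pre-noise ground truth.
#'
#' @param spec a [scene_spec()].
#' @param centers optional cell-center matrix (µm, (z, y, x)); default:
#'   sampled by [sample_cells()].
#' @param radii optional cell radii (µm), paired with `centers`.
#' @return list with `red` and `green` (`volumetric_image`s) and
#'   `ground_truth`: `pancreas_mask`, `cell_mask` (label array), `centers`,
#'   `radii`, `islet_volumes_um3` (voxelized per-cell volumes) and
#'   `islet_volumes_analytic_um3` (= 4/3 pi r^3).
#' @export
render_scene <- function(spec, centers = NULL, radii = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(centers)) {
    cl <- sample_cells(spec)
    centers <- cl$centers; radii <- cl$radii
  }
  centers <- matrix(as.numeric(centers), ncol = 3)
  radii <- as.numeric(radii)
  stopifnot(nrow(centers) == length(radii), all(radii > 0) || length(radii) == 0)
  extent <- spec$grid_shape * spec$voxel_size
  if (nrow(centers) > 0 &&
      (any(centers < 0) || any(sweep(centers, 2L, extent) > 0)))
    stop("cell centers must lie inside the image grid (0..",
         paste(signif(extent, 4), collapse = " x "), " um)")

  pancreas <- .voxelize_ellipsoid(spec$grid_shape, spec$voxel_size,
                                  spec$pancreas_center, spec$pancreas_semiaxes)
  cell_lab <- array(0L, spec$grid_shape)
  for (i in seq_len(nrow(centers))) {
    m <- .voxelize_ellipsoid(spec$grid_shape, spec$voxel_size,
                             centers[i, ], rep(radii[i], 3))
    cell_lab[m] <- i
  }
  vvol <- prod(spec$voxel_size)
  islet_volumes <- as.numeric(tabulate(cell_lab[cell_lab > 0L],
                                       nbins = nrow(centers))) * vvol

  red <- volumetric_image(pancreas * spec$red_intensity, spec$voxel_size, "red")
  green <- volumetric_image((cell_lab > 0L) * spec$green_intensity,
                            spec$voxel_size, "green")
  if (any(spec$psf_sigma > 0)) {
    red <- smooth_gaussian(red, spec$psf_sigma)
    green <- smooth_gaussian(green, spec$psf_sigma)
  }
  set.seed(spec$seed + 1L)  # noise stream independent of placement stream
  red$voxels <- .apply_noise(red$voxels, spec)
  green$voxels <- .apply_noise(green$voxels, spec)

  list(red = red, green = green,
       ground_truth = list(
         pancreas_mask = pancreas, cell_mask = cell_lab,
         centers = centers, radii = radii,
         islet_volumes_um3 = islet_volumes,
         islet_volumes_analytic_um3 = 4 / 3 * pi * radii^3,
         seed = spec$seed))
}

# Poisson shot noise on the signal plus additive Gaussian read noise
.apply_noise <- function(a, spec) {
  out <- a
  if (spec$noise_poisson_scale > 0)
    out <- array(stats::rpois(length(a), pmax(a, 0) * spec$noise_poisson_scale),
                 dim(a)) / spec$noise_poisson_scale
  if (spec$noise_gaussian_sd > 0)
    out <- out + array(stats::rnorm(length(a), 0, spec$noise_gaussian_sd), dim(a))
  out
}

#' Specification of an attraction-plus-noise motion model
#'
#' Euler scheme for coalescing cells: every center moves a fraction
#' `attraction_rate * dt` of the way toward the current group centroid per
#' frame, plus isotropic Gaussian diffusion. With zero noise each step
#' contracts all centroid distances by exactly `(1 - attraction_rate * dt)`,
#' so the convex-hull volume of the group shrinks by that factor cubed —
#' the closed form the clustering statistic is validated against.
#'
#' @param attraction_rate 1/min, pull toward the group centroid (>= 0).
#' @param diffusion_sd µm per sqrt(min), isotropic diffusion scale.
#' @param dt min, frame interval (> 0).
#' @param n_frames number of frames to simulate (>= 1).
#' @param seed integer seed.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(attraction_rate = 0.004, diffusion_sd = 0.3,
                        dt = 18, n_frames = 20L, seed = 1L) {
  stopifnot(attraction_rate >= 0, dt > 0, diffusion_sd >= 0, n_frames >= 1)
  structure(list(attraction_rate = attraction_rate, diffusion_sd = diffusion_sd,
                 dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)), class = "motion_spec")
}

#' Simulate coalescing cell trajectories
#'
#' @param motion a [motion_spec()].
#' @param initial_centers matrix (n_cells x 3), µm.
#' @return 3D array (n_frames, n_cells, 3) of centers in µm; frame 1 is the
#'   initial configuration. Attribute `time_min` holds frame times.
#' @export
simulate_motion <- function(motion, initial_centers) {
  stopifnot(inherits(motion, "motion_spec"))
  x <- matrix(as.numeric(initial_centers), ncol = 3)
  n <- nrow(x)
  if (n < 1L) stop("at least one cell is required")
  set.seed(motion$seed)
  out <- array(NA_real_, c(motion$n_frames, n, 3))
  out[1, , ] <- x
  k <- motion$attraction_rate * motion$dt
  s <- motion$diffusion_sd * sqrt(motion$dt)
  for (f in seq_len(motion$n_frames - 1L)) {
    ctr <- colMeans(x)
    x <- x + k * sweep(-x, 2L, -ctr) +
      matrix(stats::rnorm(n * 3, 0, s), n, 3)
    out[f + 1L, , ] <- x
  }
  attr(out, "time_min") <- (seq_len(motion$n_frames) - 1) * motion$dt
  out
}

#' Render a 2D cell mask with radial protrusions
#'
#' Rasterizes a disk-bodied cell carrying `n_protrusions` thin radial arms,
#' the fixture used to validate morphometry: a bare disk has solidity and
#' circularity near 1, and each added protrusion lowers solidity because the
#' convex hull grows faster than the mask area.
#'
#' @param body_radius µm, radius of the cell body disk.
#' @param n_protrusions number of evenly spaced radial arms.
#' @param protrusion_length µm, arm length beyond the body edge.
#' @param protrusion_width µm, arm width (filopodia-scale, typically < 2).
#' @param pixel_size µm per pixel (> 0).
#' @param grid integer length-2, image size (rows, cols); default sized to
#'   fit the cell with margin.
#' @param center µm (y, x); default image center.
#' @return list with `mask` (logical matrix), `pixel_size`, and
#'   `ground_truth` (body radius/center and per-arm angle/length/width).
#' @export
render_cell_mask <- function(body_radius = 5, n_protrusions = 0L,
                             protrusion_length = 4, protrusion_width = 1,
                             pixel_size = 0.2, grid = NULL, center = NULL) {
  stopifnot(pixel_size > 0, body_radius > 0, n_protrusions >= 0)
  reach <- body_radius + if (n_protrusions > 0) protrusion_length else 0
  if (is.null(grid)) grid <- rep(ceiling(2 * (reach + 2) / pixel_size), 2L)
  if (is.null(center)) center <- grid / 2 * pixel_size
  if (reach > min(center, grid * pixel_size - center))
    stop("protrusions extend beyond the image grid; enlarge `grid`")
  yy <- (seq_len(grid[1]) - 0.5) * pixel_size
  xx <- (seq_len(grid[2]) - 0.5) * pixel_size
  dy <- outer(yy - center[1], rep(1, grid[2]))
  dx <- outer(rep(1, grid[1]), xx - center[2])
  mask <- dy^2 + dx^2 <= body_radius^2
  angles <- if (n_protrusions > 0) 2 * pi * (seq_len(n_protrusions) - 1) /
    n_protrusions else numeric(0)
  for (a in angles) {
    u <- c(sin(a), cos(a))            # along-arm direction (y, x)
    along <- dy * u[1] + dx * u[2]
    across <- -dy * u[2] + dx * u[1]
    mask <- mask | (along >= 0 & along <= body_radius + protrusion_length &
                      abs(across) <= protrusion_width / 2)
  }
  list(mask = mask, pixel_size = pixel_size,
       ground_truth = list(body_radius = body_radius, center = center,
                           angles = angles,
                           protrusion_length = protrusion_length,
                           protrusion_width = protrusion_width))
}

#' Render a time-lapse series of single-cell masks
#'
#' Generates `n_frames` masks of one protrusion-bearing cell with small
#' seeded frame-to-frame jitter of the protrusion lengths and body radius,
#' emulating a traced cell in a time-lapse series. Cohorts rendered with
#' fewer/shorter protrusions emulate PI3K-inhibited cells (more compact,
#' higher solidity); cohorts with many long protrusions emulate controls.
#'
#' @param n_frames number of frames.
#' @param frame_interval min between frames.
#' @param body_radius,n_protrusions,protrusion_length,protrusion_width,pixel_size
#'   cell geometry as in [render_cell_mask()].
#' @param jitter_sd µm, sd of per-frame protrusion-length jitter.
#' @param seed integer seed.
#' @param cell_id,sample_id identifiers stamped on each mask.
#' @return list of [cell_mask()] objects (one per frame).
#' @export
render_cell_frames <- function(n_frames = 5L, frame_interval = 4,
                               body_radius = 5, n_protrusions = 4L,
                               protrusion_length = 4, protrusion_width = 1,
                               pixel_size = 0.2, jitter_sd = 0.3, seed = 1L,
                               cell_id = "c1", sample_id = "s1") {
  stopifnot(n_frames >= 1L, pixel_size > 0)
  set.seed(seed)
  reach <- body_radius + protrusion_length + 4 * jitter_sd + 2
  grid <- rep(ceiling(2 * reach / pixel_size), 2L)
  lapply(seq_len(n_frames), function(f) {
    len <- max(0.2, protrusion_length +
                 if (n_protrusions > 0) stats::rnorm(1, 0, jitter_sd) else 0)
    rc <- render_cell_mask(body_radius, n_protrusions, len, protrusion_width,
                           pixel_size, grid = grid)
    cell_mask(rc$mask, pixel_size, frame_time = (f - 1) * frame_interval,
              cell_id = cell_id, sample_id = sample_id)
  })
}

#' Star polygon vertices
#'
#' Alternating outer/inner radius polygon used as a morphometry fixture with
#' an exactly known solidity (shoelace area over shoelace hull area).
#'
#' @param n_arms number of points of the star.
#' @param r_outer,r_inner µm, tip and notch radii.
#' @param center µm (y, x).
#' @return matrix of vertices (2 * n_arms rows, columns y, x), in order.
#' @export
star_polygon <- function(n_arms = 5L, r_outer = 8, r_inner = 3,
                         center = c(0, 0)) {
  stopifnot(n_arms >= 3L, r_outer > r_inner, r_inner > 0)
  ang <- seq(0, 2 * pi, length.out = 2L * n_arms + 1L)[-(2L * n_arms + 1L)]
  r <- rep(c(r_outer, r_inner), n_arms)
  cbind(y = center[1] + r * sin(ang), x = center[2] + r * cos(ang))
}

#' Rasterize a polygon onto a pixel grid
#'
#' Even-odd (ray casting) point-in-polygon test applied to pixel centers.
#'
#' @param poly matrix of vertices (columns y, x in µm), in order.
#' @param pixel_size µm per pixel.
#' @param grid integer length-2 (rows, cols); default fits the polygon.
#' @param origin µm (y, x) of the grid corner; default places the polygon
#'   with a 2-pixel margin.
#' @return logical matrix mask.
#' @export
rasterize_polygon <- function(poly, pixel_size = 0.1, grid = NULL,
                              origin = NULL) {
  stopifnot(pixel_size > 0, nrow(poly) >= 3L)
  if (is.null(origin)) origin <- apply(poly, 2L, min) - 2 * pixel_size
  if (is.null(grid))
    grid <- ceiling((apply(poly, 2L, max) - origin) / pixel_size + 2)
  yy <- origin[1] + (seq_len(grid[1]) - 0.5) * pixel_size
  xx <- origin[2] + (seq_len(grid[2]) - 0.5) * pixel_size
  pts <- cbind(rep(yy, times = grid[2]), rep(xx, each = grid[1]))
  inside <- point_in_polygon(pts, poly)
  matrix(inside, grid[1], grid[2])
}

#' Even-odd point-in-polygon test
#'
#' @param pts matrix of query points (columns y, x).
#' @param poly matrix of polygon vertices (columns y, x), in order.
#' @return logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > pts[, 1]) != (yj > pts[, 1])) &
      (pts[, 2] < (xj - xi) * (pts[, 1] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Shoelace (polygon) area
#'
#' @param poly matrix of vertices (columns y, x), in order.
#' @return area in the square of the coordinate unit.
#' @export
shoelace_area <- function(poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  abs(sum(poly[, 2] * poly[i2, 1] - poly[i2, 2] * poly[, 1])) / 2
}

#' Specification of a filopodium length program
#'
#' A filopodium is modeled as a thin (< 2 µm diameter) protrusion whose
#' length follows a piecewise-linear program: each segment extends
#' (positive rate) or retracts (negative rate) for a set duration, matching
#' the extension/retraction dynamics seen in time-lapse series.
#'
#' @param base µm, anchor point on the cell body (length 2 or 3).
#' @param direction unit vector of growth (same length as `base`).
#' @param segments data.frame with columns `duration_min` and `rate_um_min`
#'   (positive = extension, negative = retraction).
#' @param diameter µm, protrusion thickness (must be < 2).
#' @param initial_length µm at time 0.
#' @return object of class `filopodium_spec`.
#' @export
filopodium_spec <- function(base = c(0, 0), direction = c(0, 1),
                            segments = data.frame(duration_min = c(1, 1),
                                                  rate_um_min = c(3, -2)),
                            diameter = 0.8, initial_length = 0) {
  direction <- direction / sqrt(sum(direction^2))
  stopifnot(length(base) == length(direction), diameter > 0,
            all(segments$duration_min > 0), initial_length >= 0)
  if (diameter >= 2)
    stop("filopodia are thin protrusions; `diameter` must be below 2 um")
  lens_at_breaks <- initial_length +
    cumsum(segments$rate_um_min * segments$duration_min)
  if (any(lens_at_breaks < -1e-9))
    stop("length program goes negative; adjust segment rates/durations")
  structure(list(base = base, direction = direction, segments = segments,
                 diameter = diameter, initial_length = initial_length),
            class = "filopodium_spec")
}

#' Evaluate a piecewise-linear filopodium length program
#'
#' @param segments data.frame (`duration_min`, `rate_um_min`).
#' @param initial_length µm at t = 0.
#' @param t times (min) at which to evaluate; lengths are clamped at 0
#'   (a fully retracted filopodium cannot have negative length).
#' @return µm lengths at `t`.
#' @export
filopodium_length_profile <- function(segments, initial_length = 0, t) {
  breaks <- c(0, cumsum(segments$duration_min))
  lens_at_breaks <- initial_length +
    c(0, cumsum(segments$rate_um_min * segments$duration_min))
  pmax(stats::approx(breaks, lens_at_breaks, xout = pmin(t, max(breaks)),
                     rule = 2)$y, 0)
}

#' Write trajectories as a tidy CSV
#'
#' @param trajectories array from [simulate_motion()].
#' @param path output CSV (`frame, time_min, cell_id, x, y, z` in µm).
#' @export
write_trajectories_csv <- function(trajectories, path) {
  tm <- attr(trajectories, "time_min")
  d <- dim(trajectories)
  df <- do.call(rbind, lapply(seq_len(d[1]), function(f) {
    data.frame(frame = f, time_min = tm[f], cell_id = seq_len(d[2]),
               x = trajectories[f, , 3], y = trajectories[f, , 2],
               z = trajectories[f, , 1])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
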