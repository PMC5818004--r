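# Shared fixture builders; everything is generated in code, seeded.

# logical disk mask of radius r_px pixels in an n x n grid
fx_disk <- function(r_px, n = 2 * r_px + 20) {
  ctr <- n / 2
  yy <- seq_len(n) - 0.5; xx <- seq_len(n) - 0.5
  outer((yy - ctr)^2, rep(1, n)) + outer(rep(1, n), (xx - ctr)^2) <= r_px^2
}

# thin horizontal protrusion mask: length len_um from x = x0, half-width hw
fx_filopodium_mask <- function(len_um, pixel_size = 0.1, half_w = 0.3,
                               x0 = 2, y0 = 3, nrow = 60, ncol = 140) {
  yy <- (seq_len(nrow) - 0.5) * pixel_size
  xx <- (seq_len(ncol) - 0.5) * pixel_size
  dy <- outer(yy - y0, rep(1, ncol))
  dx <- outer(rep(1, nrow), xx - x0)
  dx >= 0 & dx <= len_um & abs(dy) <= half_w
}

# head/tail ROI: vertical split line near x = x_um, tail on the +x side
fx_roi <- function(x_um = 0.1, y_max = 48) {
  head_tail_roi(rbind(c(0, x_um), c(y_max, x_um)), tail_side = 1L)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
fx_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# cached noise-free two-sphere scene used by several segmentation tests
fx_two_sphere_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- scene_spec(grid_shape = c(40L, 96L, 96L),
                       voxel_size = c(1, 0.5, 0.5), n_cells = 2L,
                       psf_sigma = c(0, 0, 0), noise_gaussian_sd = 0,
                       noise_poisson_scale = 0, seed = 11L)
      cache <<- render_scene(sp, centers = rbind(c(20, 18, 24), c(20, 30, 30)),
                             radii = c(4, 2.5))
    }
    cache
  }
})
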