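#' Volume of the 3D convex hull of a point cloud
#'
#' Computes the volume of the convex polytope enclosing a set of 3D points,
#' the scalar statistic used to quantify endocrine cell clustering: as cells
#' coalesce into an islet, the hull volume spanned by their centers shrinks.
#'
#' The hull is built by incremental insertion (quickhull-style): an initial
#' non-degenerate tetrahedron is grown by attaching, for every outside point,
#' a cone of new facets over the horizon of its visible region. Facets are
#' kept consistently outward-oriented, so the enclosed volume follows from
#' the divergence theorem as the sum of signed origin-tetrahedra.
#'
#' Configurations with fewer than 4 points, or points that are collinear or
#' coplanar, have no 3D volume; these return 0 with `degenerate = TRUE`
#' together with informative fallbacks (2D hull area of the best-fit plane
#' projection and the maximum pairwise distance) so that low-n time series
#' remain interpretable.
#'
#' @param points numeric matrix with one row per point and 3 columns
#'   (coordinates in µm; any consistent unit works, volume is unit³).
#' @return list with elements `volume` (µm³), `degenerate` (logical),
#'   `n_points`, `area_2d` (µm², 2D hull area fallback, NA when the cloud is
#'   full-rank), and `max_extent` (µm, maximum pairwise distance).
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' hull_volume(cube)$volume  # 1
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("`points` must be a numeric matrix with 3 columns")
  if (anyNA(points) || any(!is.finite(points)))
    stop("non-finite coordinates in `points`")
  n <- nrow(points)
  if (n < 1L) stop("at least one point is required")

  max_extent <- if (n >= 2L) max(stats::dist(points)) else 0
  degenerate_result <- function() {
    list(volume = 0, degenerate = TRUE, n_points = n,
         area_2d = as.numeric(.hull_area_planar(points)),
         max_extent = as.numeric(max_extent))
  }
  if (n < 4L) return(degenerate_result())

  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x)$d
  scale <- max(sv[1], 1e-30)
  # affinely dependent (collinear/coplanar) clouds carry no 3D volume
  if (sv[3] <= 1e-10 * scale) return(degenerate_result())

  facets <- .convhull3d_facets(x, tol = 1e-12 * scale^3)
  if (is.null(facets)) return(degenerate_result())
  v <- 0
  for (i in seq_len(nrow(facets))) {
    a <- x[facets[i, 1L], ]; b <- x[facets[i, 2L], ]; c <- x[facets[i, 3L], ]
    v <- v + .det3(a, b, c)
  }
  list(volume = as.numeric(v) / 6, degenerate = FALSE, n_points = n,
       area_2d = NA_real_, max_extent = as.numeric(max_extent))
}

# signed volume determinant |a b c|
.det3 <- function(a, b, c) {
  a[1] * (b[2] * c[3] - b[3] * c[2]) -
  a[2] * (b[1] * c[3] - b[3] * c[1]) +
  a[3] * (b[1] * c[2] - b[2] * c[1])
}

# 2D hull area of the projection onto the best-fit plane (fallback statistic
# for degenerate clouds); 0 for collinear input
.hull_area_planar <- function(points) {
  if (nrow(points) < 3L) return(0)
  x <- sweep(points, 2L, colMeans(points))
  dec <- svd(x)
  if (dec$d[2] <= 1e-10 * max(dec$d[1], 1e-30)) return(0)
  xy <- x %*% dec$v[, 1:2, drop = FALSE]
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(0)
  p <- xy[h, , drop = FALSE]
  i2 <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Incremental 3D convex hull. `x` centered full-rank cloud; returns a matrix
# of vertex-index triples, outward-oriented, or NULL if no valid start
# simplex is found. `tol` is an absolute signed-volume tolerance.
.convhull3d_facets <- function(x, tol) {
  n <- nrow(x)
  # initial simplex: extremal pair, then farthest from line, then from plane
  i1 <- which.min(x[, 1]); i2 <- which.max(x[, 1])
  if (i1 == i2) { i1 <- which.min(x[, 2]); i2 <- which.max(x[, 2]) }
  d12 <- x[i2, ] - x[i1, ]
  rel <- sweep(x, 2L, x[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  i3 <- which.max(rowSums(cr^2))
  nrm <- cr[i3, ]
  h <- abs(rel %*% nrm)
  i4 <- which.max(h)
  if (length(unique(c(i1, i2, i3, i4))) < 4L) return(NULL)
  s <- .det3(x[i2, ] - x[i1, ], x[i3, ] - x[i1, ], x[i4, ] - x[i1, ])
  if (abs(s) <= tol) return(NULL)
  # orient the four facets so normals point away from the simplex interior
  f <- if (s > 0)
    rbind(c(i1, i3, i2), c(i1, i2, i4), c(i2, i3, i4), c(i1, i4, i3))
  else
    rbind(c(i1, i2, i3), c(i1, i4, i2), c(i2, i4, i3), c(i1, i3, i4))

  seen <- c(i1, i2, i3, i4)
  for (p in setdiff(seq_len(n), seen)) {
    pt <- x[p, ]
    vis <- logical(nrow(f))
    for (k in seq_len(nrow(f))) {
      a <- x[f[k, 1L], ]
      vis[k] <- .det3(x[f[k, 2L], ] - a, x[f[k, 3L], ] - a, pt - a) > tol
    }
    if (!any(vis)) next
    # horizon: directed edges of visible facets whose reverse is not visible
    vf <- f[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(edges[, 1], edges[, 2])
    rkey <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(key %in% rkey), , drop = FALSE]
    newf <- cbind(horizon[, 1], horizon[, 2], p)
    f <- rbind(f[!vis, , drop = FALSE], newf)
  }
  f
}

#' Brute-force convex hull volume by facet enumeration
#'
#' Independent reference computation intended for small point clouds: every
#' triple of points is tested as a supporting plane (all other points on one
#' side); supporting triangles are oriented outward and summed as signed
#' origin-tetrahedra. Runs in O(n^4); practical for n up to a few dozen.
#'
#' @param points numeric matrix, rows are 3D points.
#' @return hull volume (unit³); 0 for degenerate input.
#' @export
hull_volume_bruteforce <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4L) return(0)
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  scale <- max(abs(x), 1e-30)
  tol <- 1e-10 * scale^3
  v <- 0
  counted <- character(0)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- x[i, ]; b <- x[j, ]; c <- x[k, ]
    others <- setdiff(seq_len(n), c(i, j, k))
    s <- vapply(others, function(m) .det3(b - a, c - a, x[m, ] - a), 0)
    if (all(s <= tol)) {        # outward as (a, b, c)
      key <- paste(i, j, k, "+")
      if (!(key %in% counted)) { counted <- c(counted, key); v <- v + .det3(a, b, c) }
    } else if (all(s >= -tol)) { # outward as (a, c, b)
      key <- paste(i, j, k, "-")
      if (!(key %in% counted)) { counted <- c(counted, key); v <- v + .det3(a, c, b) }
    }
  }
  v / 6
}

#' Test points for membership in the convex hull of a cloud
#'
#' Uses the supporting-plane facets from brute-force enumeration, so it is
#' independent of the incremental hull construction. A point belongs to the
#' hull iff it lies on the inner side of every supporting plane.
#'
#' @param query numeric matrix of points to test (rows).
#' @param points numeric matrix defining the hull.
#' @return logical vector, one entry per query row.
#' @export
in_hull <- function(query, points) {
  points <- as.matrix(points); query <- as.matrix(query)
  n <- nrow(points)
  stopifnot(n >= 4L, ncol(points) == 3L, ncol(query) == 3L)
  scale <- max(abs(sweep(points, 2L, colMeans(points))), 1e-30)
  tol <- 1e-9 * scale
  # enumerate supporting planes once, then test all queries in one product
  normals <- list(); offsets <- numeric(0)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- points[i, ]; b <- points[j, ]; c <- points[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn <= tol) next
    nrm <- nrm / nn
    s <- sweep(points, 2L, a) %*% nrm
    side <- if (all(s <= tol)) 1 else if (all(s >= -tol)) -1 else 0
    if (side == 0) next
    normals[[length(normals) + 1L]] <- nrm * side
    offsets <- c(offsets, sum(a * nrm * side))
  }
  if (length(normals) == 0L) return(rep(FALSE, nrow(query)))
  nm <- do.call(cbind, normals)
  d <- query %*% nm
  inside <- rep(TRUE, nrow(query))
  for (f in seq_along(offsets))
    inside <- inside & (d[, f] <= offsets[f] + tol * 10)
  inside
}
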