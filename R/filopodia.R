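#' Skeletonize a binary 2D mask (Zhang-Suen thinning)
#'
#' Iterative thinning to a 1-pixel-wide, 8-connected skeleton; used to
#' extract the backbone of thin protrusions from projected masks.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- as.matrix(mask) > 0
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  m <- pad
  nb <- function(a, dr, dc) {
    r <- nrow(a); c <- ncol(a)
    out <- matrix(FALSE, r, c)
    out[max(1, 1 + dr):min(r, r + dr), max(1, 1 + dc):min(c, c + dc)] <-
      a[max(1, 1 - dr):min(r, r - dr), max(1, 1 - dc):min(c, c - dc)]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors P2..P9 clockwise from north
      p <- list(nb(m, -1, 0), nb(m, -1, 1), nb(m, 0, 1), nb(m, 1, 1),
                nb(m, 1, 0), nb(m, 1, -1), nb(m, 0, -1), nb(m, -1, -1))
      B <- Reduce(`+`, p)
      A <- Reduce(`+`, lapply(1:8, function(i)
        (!p[[i]]) & p[[if (i == 8) 1 else i + 1]]))
      if (phase == 1) {
        c1 <- !(p[[1]] & p[[3]] & p[[5]]); c2 <- !(p[[3]] & p[[5]] & p[[7]])
      } else {
        c1 <- !(p[[1]] & p[[3]] & p[[7]]); c2 <- !(p[[1]] & p[[5]] & p[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) { m <- m & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(pad) - 1L), 2:(ncol(pad) - 1L)]
}

# polyline length of an ordered pixel path, measured over k-step chords to
# suppress the metrication bias of per-pixel 8-connected steps
.chord_length <- function(coords, k = 4L) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  idx <- unique(c(seq(1L, n, by = k), n))
  p <- coords[idx, , drop = FALSE]
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# distance (pixels) the mask continues beyond the skeleton tip along the
# terminal path direction, searched in a local window
.tip_extension <- function(mask, path, window = 15L) {
  m <- nrow(path)
  if (m < 2L) return(0)
  tip <- path[m, ]
  d <- tip - path[max(1L, m - 4L), ]
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(0)
  d <- d / nd
  idx <- which(mask, arr.ind = TRUE)
  near <- abs(idx[, 1] - tip[1]) <= window & abs(idx[, 2] - tip[2]) <= window
  if (!any(near)) return(0)
  rel <- sweep(idx[near, , drop = FALSE], 2L, tip)
  proj <- rel[, 1] * d[1] + rel[, 2] * d[2]
  min(max(0, max(proj)), window)
}

# graph over skeleton pixels: 8-adjacency, edge weight = physical distance
.skeleton_graph <- function(skel, pixel_size) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  key <- idx[, 1] + 1i * idx[, 2]
  lookup <- seq_len(n); names(lookup) <- as.character(key)
  edges <- list(); weights <- numeric(0)
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (k in seq_len(nrow(offs))) {
    nbkey <- (idx[, 1] + offs[k, 1]) + 1i * (idx[, 2] + offs[k, 2])
    hit <- lookup[as.character(nbkey)]
    ok <- !is.na(hit)
    if (any(ok)) {
      edges[[k]] <- cbind(lookup[ok], hit[ok])
      weights <- c(weights, rep(sqrt(sum(offs[k, ]^2)) * pixel_size, sum(ok)))
    }
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0)
    g <- igraph::add_edges(g, t(el), weight = weights)
  list(graph = g, coords = idx)
}

#' Trace a filopodium through a time series
#'
#' Builds a time-indexed length record for one filopodium. Two entry paths
#' are supported and labeled in the output:
#' \itemize{
#'   \item `masks`: automatic tracing — each frame's protrusion mask is
#'     skeletonized and the backbone is the shortest skeleton path from the
#'     base to the farthest connected skeleton pixel; length is the
#'     geodesic polyline length in µm (never less than the base-to-tip
#'     chord). An absent protrusion gives length 0.
#'   \item `tips`: manual annotation — per-frame tip points override
#'     tracing; length is the base-to-tip chord (or the annotated polyline
#'     length if more than one point per frame is given).
#' }
#'
#' @param masks list of logical matrices (one per frame), or NULL.
#' @param base numeric length-2, (row, col) pixel position of the anchor on
#'   the cell body boundary (mask path) or µm (y, x) for the tip path.
#' @param pixel_size µm per pixel (mask path).
#' @param frame_times min, one per frame (sampling is typically seconds).
#' @param tips optional data.frame `frame, y_um, x_um` of manual tip
#'   annotations; rows may be missing for frames where the filopodium is
#'   fully retracted (length 0).
#' @param filopodium_id identifier.
#' @return a `filopodium_trace`: tibble `frame`, `time_min`, `length_um`,
#'   `tip_y`, `tip_x` (µm, NA when retracted), `method`; attribute
#'   `n_branch_points` logs branching seen during tracing.
#' @export
trace_filopodium <- function(masks = NULL, base, pixel_size = NULL,
                             frame_times, tips = NULL,
                             filopodium_id = "f1") {
  if (!is.null(tips)) {
    frames <- seq_along(frame_times)
    rows <- lapply(frames, function(f) {
      tp <- tips[tips$frame == f, , drop = FALSE]
      if (nrow(tp) == 0L)
        return(tibble::tibble(frame = f, time_min = frame_times[f],
                              length_um = 0, tip_y = NA_real_,
                              tip_x = NA_real_, method = "annotated"))
      pts <- rbind(base, as.matrix(tp[, c("y_um", "x_um")]))
      seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                                pts[-nrow(pts), , drop = FALSE])^2))
      tibble::tibble(frame = f, time_min = frame_times[f],
                     length_um = sum(seglen),
                     tip_y = tp$y_um[nrow(tp)], tip_x = tp$x_um[nrow(tp)],
                     method = "annotated")
    })
    out <- dplyr::bind_rows(rows)
  } else {
    stopifnot(!is.null(masks), length(masks) == length(frame_times),
              !is.null(pixel_size), pixel_size > 0)
    n_branch <- 0L
    rows <- lapply(seq_along(masks), function(f) {
      mk <- as.matrix(masks[[f]]) > 0
      if (!any(mk))
        return(tibble::tibble(frame = f, time_min = frame_times[f],
                              length_um = 0, tip_y = NA_real_,
                              tip_x = NA_real_, method = "traced"))
      skel <- skeletonize(mk)
      if (!any(skel)) skel <- mk
      sg <- .skeleton_graph(skel, pixel_size)
      # anchor: skeleton pixel nearest the base
      d2 <- (sg$coords[, 1] - base[1])^2 + (sg$coords[, 2] - base[2])^2
      root <- which.min(d2)
      dist <- igraph::distances(sg$graph, v = root)[1, ]
      reach <- is.finite(dist)
      deg <- igraph::degree(sg$graph)
      n_branch <<- n_branch + sum(deg > 2 & reach)
      tip <- which.max(ifelse(reach, dist, -Inf))
      vp <- igraph::shortest_paths(sg$graph, from = root, to = tip)$vpath[[1]]
      path <- sg$coords[as.integer(vp), , drop = FALSE]
      len <- .chord_length(path) * pixel_size
      # thinning erodes roughly half the protrusion width at either end;
      # reconnect the base anchor and extend to the mask margin at the tip
      len <- len + sqrt(sum((path[1, ] - base)^2)) * pixel_size
      len <- len + .tip_extension(mk, path) * pixel_size
      tibble::tibble(frame = f, time_min = frame_times[f],
                     length_um = len,
                     tip_y = (sg$coords[tip, 1] - 0.5) * pixel_size,
                     tip_x = (sg$coords[tip, 2] - 0.5) * pixel_size,
                     method = "traced")
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "n_branch_points") <- n_branch
  }
  out$filopodium_id <- filopodium_id
  class(out) <- c("filopodium_trace", class(out))
  out
}

#' Trace built directly from a known length profile
#'
#' Convenience constructor for simulated filopodia: evaluates a
#' [filopodium_spec()] length program at the frame times.
#'
#' @param fspec a [filopodium_spec()].
#' @param frame_times min.
#' @param filopodium_id identifier.
#' @return a `filopodium_trace`.
#' @export
trace_from_spec <- function(fspec, frame_times, filopodium_id = "f1") {
  lens <- filopodium_length_profile(fspec$segments, fspec$initial_length,
                                    frame_times)
  nd <- length(fspec$base)
  tips <- outer(lens, fspec$direction) + matrix(fspec$base, length(lens),
                                                nd, byrow = TRUE)
  out <- tibble::tibble(frame = seq_along(frame_times),
                        time_min = frame_times, length_um = lens,
                        tip_y = tips[, 1], tip_x = tips[, 2],
                        method = "simulated", filopodium_id = filopodium_id)
  class(out) <- c("filopodium_trace", class(out))
  out
}

#' Instantaneous extension/retraction rates of a filopodium
#'
#' Rates are consecutive-frame length differences over true timestamp
#' differences (no smoothing): positive = extension, negative = retraction.
#' Frame pairs whose length change is within the dead-band are classed as
#' pauses and excluded from the extension/retraction means (the dead-band
#' suppresses segmentation jitter; set it to 0 for noiseless data).
#'
#' @param trace a `filopodium_trace` (needs `time_min`, `length_um`).
#' @param dead_band µm, minimum |length change| per frame pair to count as
#'   a movement (default 0.1).
#' @return list: `rates` tibble (`time_min` midpoint, `rate_um_min`,
#'   `phase` in extension/retraction/pause), `max_length_um`,
#'   `mean_extension_rate`, `mean_retraction_rate` (both µm/min, positive),
#'   `max_extension_rate`, `max_retraction_rate`, `filopodium_id`.
#' @export
filopodium_rates <- function(trace, dead_band = 0.1) {
  d <- as.data.frame(trace)
  stopifnot(all(c("time_min", "length_um") %in% names(d)))
  d <- d[order(d$time_min), ]
  if (nrow(d) < 2L) stop("at least two frames are required to compute rates")
  if (any(diff(d$time_min) <= 0)) stop("frame times must be strictly increasing")
  dL <- diff(d$length_um)
  dt <- diff(d$time_min)
  rate <- dL / dt
  phase <- ifelse(dL > dead_band, "extension",
                  ifelse(dL < -dead_band, "retraction", "pause"))
  rates <- tibble::tibble(
    time_min = (d$time_min[-1] + d$time_min[-nrow(d)]) / 2,
    rate_um_min = rate, phase = phase)
  ext <- rate[phase == "extension"]; ret <- -rate[phase == "retraction"]
  list(rates = rates,
       max_length_um = max(d$length_um),
       mean_extension_rate = if (length(ext)) mean(ext) else NA_real_,
       mean_retraction_rate = if (length(ret)) mean(ret) else NA_real_,
       max_extension_rate = if (length(ext)) max(ext) else NA_real_,
       max_retraction_rate = if (length(ret)) max(ret) else NA_real_,
       filopodium_id = d$filopodium_id[1] %||% NA_character_)
}

#' Maximal-length distribution of a filopodium cohort
#'
#' Summarizes per-filopodium maximal lengths: the empirical CDF, the
#' fraction of filopodia whose maximal extension stays below a short-length
#' threshold (default 9 µm), and the count exceeding a long-length
#' threshold (default 15 µm) — the two headline descriptors of filopodium
#' length in this system.
#'
#' @param traces list of `filopodium_trace` objects (or of
#'   [filopodium_rates()] results).
#' @param below_um,above_um µm thresholds.
#' @return list: `max_lengths_um`, `fraction_below`, `n_above`, `n`,
#'   `ecdf` (function), and the thresholds used.
#' @export
length_distribution <- function(traces, below_um = 9, above_um = 15) {
  stopifnot(length(traces) >= 1L)
  mx <- vapply(traces, function(tr) {
    if (is.list(tr) && "max_length_um" %in% names(tr)) tr[["max_length_um"]]
    else max(as.data.frame(tr)$length_um)
  }, 0)
  list(max_lengths_um = mx,
       fraction_below = mean(mx < below_um),
       n_above = sum(mx > above_um),
       n = length(mx),
       ecdf = stats::ecdf(mx),
       below_um = below_um, above_um = above_um)
}
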