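#' Link per-frame detections into cell tracks
#'
#' Frame-to-frame data association for tracked endocrine cells: each
#' consecutive frame pair is solved as a global minimum-cost assignment
#' (Hungarian algorithm) on Euclidean distance, with links longer than
#' `max_displacement` forbidden. Unmatched detections open new tracks;
#' tracks that find no match simply end (no interpolation through gaps, so
#' positions are never invented).
#'
#' @param detections tibble/data.frame with columns `frame`, `x`, `y`, `z`
#'   (µm) and optionally `time_min` (default: frame index in minutes).
#' @param max_displacement µm, largest allowed frame-to-frame step
#'   (default 10).
#' @return a `cell_track_set`: tibble with `cell_id`, `frame`, `time_min`,
#'   `x`, `y`, `z`, plus attribute `has_gaps` flagging tracks that end
#'   before the final frame.
#' @export
link_detections <- function(detections, max_displacement = 10) {
  d <- as.data.frame(detections)
  stopifnot(all(c("frame", "x", "y", "z") %in% names(d)), nrow(d) >= 1L)
  if (!"time_min" %in% names(d)) d$time_min <- as.numeric(d$frame)
  frames <- sort(unique(d$frame))
  per <- lapply(frames, function(f) d[d$frame == f, , drop = FALSE])
  ids <- vector("list", length(frames))
  ids[[1]] <- seq_len(nrow(per[[1]]))
  next_id <- nrow(per[[1]]) + 1L
  for (f in seq_along(frames)[-1L]) {
    prev <- per[[f - 1L]]; cur <- per[[f]]
    assigned <- rep(NA_integer_, nrow(cur))
    if (nrow(prev) > 0L && nrow(cur) > 0L) {
      cost <- sqrt(outer(prev$x, cur$x, `-`)^2 +
                     outer(prev$y, cur$y, `-`)^2 +
                     outer(prev$z, cur$z, `-`)^2)
      big <- max_displacement * 1e6 + 1
      gated <- ifelse(cost <= max_displacement, cost, big)
      # solve_LSAP needs nrow <= ncol; pad conceptually by transposing
      if (nrow(gated) <= ncol(gated)) {
        sol <- clue::solve_LSAP(gated)
        for (i in seq_along(sol))
          if (gated[i, sol[i]] < big) assigned[sol[i]] <- ids[[f - 1L]][i]
      } else {
        sol <- clue::solve_LSAP(t(gated))
        for (j in seq_along(sol))
          if (gated[sol[j], j] < big) assigned[j] <- ids[[f - 1L]][sol[j]]
      }
    }
    new <- which(is.na(assigned))
    if (length(new)) {
      assigned[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    ids[[f]] <- assigned
  }
  out <- dplyr::bind_rows(lapply(seq_along(frames), function(f)
    tibble::tibble(cell_id = ids[[f]], frame = per[[f]]$frame,
                   time_min = per[[f]]$time_min, x = per[[f]]$x,
                   y = per[[f]]$y, z = per[[f]]$z)))
  out <- dplyr::arrange(out, .data$cell_id, .data$frame)
  n_frames <- length(frames)
  span <- dplyr::summarise(dplyr::group_by(out, .data$cell_id),
                           n = dplyr::n(), .groups = "drop")
  attr(out, "has_gaps") <- any(span$n < n_frames)
  class(out) <- c("cell_track_set", class(out))
  out
}

#' Convert a trajectory array to a track table
#'
#' @param trajectories array (n_frames, n_cells, 3) from [simulate_motion()]
#'   with coordinates (z, y, x).
#' @return `cell_track_set` tibble with ground-truth cell ids.
#' @export
tracks_from_trajectories <- function(trajectories) {
  tm <- attr(trajectories, "time_min")
  d <- dim(trajectories)
  out <- dplyr::bind_rows(lapply(seq_len(d[1]), function(f)
    tibble::tibble(cell_id = seq_len(d[2]), frame = f, time_min = tm[f],
                   x = trajectories[f, , 3], y = trajectories[f, , 2],
                   z = trajectories[f, , 1])))
  attr(out, "has_gaps") <- FALSE
  class(out) <- c("cell_track_set", class(out))
  out
}

#' Convex-hull clustering series of tracked cells
#'
#' The clustering statistic over time: per frame, the volume of the convex
#' polytope enclosing the centers of the tracked cells present in that
#' frame. Coalescence of an islet appears as a decreasing series. Frames
#' where fewer than 4 cells are present, or where the present cells are
#' coplanar, are degenerate: volume 0 is reported with a flag together with
#' the 2D hull area and maximum pairwise distance fallbacks, so low-n
#' series remain informative.
#'
#' @param tracks a `cell_track_set` (or any table with `cell_id`, `frame`,
#'   `time_min`, `x`, `y`, `z`).
#' @param subset optional cell ids to restrict the statistic to (e.g. the
#'   colored tracked subset of a panel); default: all cells.
#' @return tibble: `frame`, `time_min`, `n_points`, `hull_volume_um3`,
#'   `degenerate`, `incomplete` (TRUE when not all requested cells are
#'   present in the frame), `hull_area_2d_um2`, `max_extent_um`.
#' @export
clustering_series <- function(tracks, subset = NULL) {
  d <- as.data.frame(tracks)
  stopifnot(all(c("cell_id", "frame", "time_min", "x", "y", "z") %in% names(d)))
  if (!is.null(subset)) d <- d[d$cell_id %in% subset, , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for the requested cells")
  n_requested <- length(unique(d$cell_id))
  frames <- sort(unique(d$frame))
  if (!is.null(subset)) {
    common <- sum(vapply(frames, function(f)
      length(unique(d$cell_id[d$frame == f])) == n_requested, TRUE))
    if (common < 2L)
      stop("requested cells share fewer than 2 common frames")
  }
  rows <- lapply(frames, function(f) {
    sub <- d[d$frame == f, , drop = FALSE]
    hv <- hull_volume(as.matrix(sub[, c("z", "y", "x")]))
    tibble::tibble(frame = f, time_min = sub$time_min[1],
                   n_points = nrow(sub), hull_volume_um3 = hv$volume,
                   degenerate = hv$degenerate,
                   incomplete = length(unique(sub$cell_id)) < n_requested,
                   hull_area_2d_um2 = hv$area_2d,
                   max_extent_um = hv$max_extent)
  })
  dplyr::bind_rows(rows)
}

#' Plot a clustering series
#'
#' Hull volume against time, one line per sample, the standard display of
#' islet coalescence.
#'
#' @param series tibble from [clustering_series()], optionally with a
#'   `sample` column.
#' @return a ggplot object.
#' @export
plot_clustering_series <- function(series) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time_min,
                                    y = .data$hull_volume_um3))
  if ("sample" %in% names(series))
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$sample))
  else p <- p + ggplot2::geom_line()
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (min)", y = expression(Hull~volume~(mu*m^3))) +
    ggplot2::theme_classic()
}
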