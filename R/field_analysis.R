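#' Construct a bead trajectory
#'
#' @param id Bead identifier.
#' @param positions Matrix (frames x 2) of positions, micrometers (or pixels
#'   with a stated scale).
#' @param frame_interval Minutes between frames (15 in the time-lapse
#'   protocol).
#' @param region Spatial region label 1-4 (see [region_map_default()]).
#' @return A `trajectory`.
#' @export
trajectory <- function(id, positions, frame_interval = 15, region = 1L) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, nrow(positions) >= 1,
            all(is.finite(positions)), frame_interval > 0,
            region %in% 1:4)
  structure(list(id = id, positions = positions,
                 frame_interval = frame_interval,
                 region = as.integer(region)),
            class = "trajectory")
}

#' Displacement statistics of one bead trajectory
#'
#' Cumulative displacement at frame `t` is the net displacement
#' `|p_t - p_0|` (not the path length); the instantaneous rate is the
#' inter-frame displacement norm divided by the frame interval; the
#' period-average rate over each `window`-minute window is the change in
#' cumulative displacement across the window divided by the window length
#' (so back-and-forth motion that returns to the start averages to zero).
#'
#' @param traj A [trajectory()] (needs >= 2 frames).
#' @param window Period-average window in minutes (default 360 = 6 h); must
#'   be a multiple of the frame interval.
#' @return List: `cumulative` (µm, per frame), `instantaneous_rate`
#'   (µm/min, per frame step), `period_rate` (µm/min, per window) with the
#'   window end times (min) as names.
#' @export
displacement_stats <- function(traj, window = 360) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  if (nrow(p) < 2) stop("at least 2 frames are required")
  dt <- traj$frame_interval
  if (abs(window / dt - round(window / dt)) > 1e-9)
    stop(sprintf("window (%g min) is not a multiple of the frame interval (%g min)",
                 window, dt))
  disp0 <- sweep(p, 2, p[1, ])
  cumulative <- sqrt(rowSums(disp0^2))
  steps <- sqrt(rowSums(diff(p)^2))
  instantaneous_rate <- steps / dt
  k <- as.integer(round(window / dt))
  ends <- if (nrow(p) >= k + 1) seq(k + 1, nrow(p), by = k) else integer(0)
  period_rate <- if (length(ends)) {
    starts <- ends - k
    r <- (cumulative[ends] - cumulative[starts]) / window
    names(r) <- (ends - 1) * dt
    r
  } else numeric(0)
  list(cumulative = cumulative,
       instantaneous_rate = instantaneous_rate,
       period_rate = period_rate)
}

#' Default 6x6 tile-to-region map
#'
#' The tiled imaging field is a 6 x 6 grid; tiles are grouped into four
#' regions: Region 1 = the non-axial band above the explants (top row),
#' Region 2 = the lateral non-axial columns, Region 3 = the axial/central
#' tiles between the explants, Region 4 = the non-axial band below the
#' explants (bottom row). Row 1 is the top of the field.
#'
#' @param nrow,ncol Tile grid dimensions.
#' @return A `region_map`: integer matrix (tiles) with values 1-4.
#' @export
region_map_default <- function(nrow = 6, ncol = 6) {
  m <- matrix(2L, nrow, ncol)
  m[1, ] <- 1L
  m[nrow, ] <- 4L
  m[2:(nrow - 1), 2:(ncol - 1)] <- 3L
  structure(m, class = c("region_map", "matrix"))
}

#' Assign trajectories to regions by tile position
#'
#' @param positions Matrix (n x 2) of initial bead positions, same units as
#'   `field_dim`.
#' @param region_map A [region_map_default()]-style matrix.
#' @param field_dim `(width, height)` of the full tiled field.
#' @return Integer region labels (1-4).
#' @export
assign_regions <- function(positions, region_map = region_map_default(),
                           field_dim) {
  positions <- as.matrix(positions)
  nr <- nrow(region_map); nc <- ncol(region_map)
  col <- pmin(pmax(ceiling(positions[, 1] / field_dim[1] * nc), 1), nc)
  # row 1 = top of the field (largest y in image convention: y grows down)
  row <- pmin(pmax(ceiling(positions[, 2] / field_dim[2] * nr), 1), nr)
  region_map[cbind(row, col)]
}

#' Per-region displacement summaries across beads
#'
#' @param trajectories List of [trajectory()] objects (all with the same
#'   frame count and interval).
#' @return List with `by_region` (data frame: region, time_min, n, mean and
#'   SD of cumulative displacement) and `overall` (data frame per time
#'   point across all beads). Empty regions are dropped with a warning.
#' @export
regional_summary <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  nf <- nrow(trajectories[[1]]$positions)
  dt <- trajectories[[1]]$frame_interval
  cum <- vapply(trajectories,
                function(tr) displacement_stats(tr)$cumulative, numeric(nf))
  reg <- vapply(trajectories, function(tr) tr$region, integer(1))
  times <- (seq_len(nf) - 1) * dt
  present <- sort(unique(reg))
  missing_regions <- setdiff(1:4, present)
  if (length(missing_regions))
    warning("empty region(s) excluded: ",
            paste(missing_regions, collapse = ", "))
  by_region <- do.call(rbind, lapply(present, function(r) {
    m <- cum[, reg == r, drop = FALSE]
    data.frame(region = r, time_min = times,
               n = ncol(m),
               mean = rowMeans(m),
               sd = apply(m, 1, sd))
  }))
  overall <- data.frame(time_min = times,
                        n = length(trajectories),
                        mean = rowMeans(cum),
                        sd = apply(cum, 1, sd))
  list(by_region = by_region, overall = overall)
}

#' Write trajectories to long-format CSV
#'
#' Columns: bead, frame, time_min, x, y, region.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param path Output CSV.
#' @export
write_trajectory_csv <- function(trajectories, path) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    nf <- nrow(tr$positions)
    data.frame(bead = tr$id, frame = seq_len(nf),
               time_min = (seq_len(nf) - 1) * tr$frame_interval,
               x = tr$positions[, 1], y = tr$positions[, 2],
               region = tr$region)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$bead), function(d) {
    d <- d[order(d$frame), ]
    dt <- if (nrow(d) > 1) diff(d$time_min)[1] else 15
    trajectory(d$bead[1], cbind(d$x, d$y), dt, d$region[1])
  })
}

#' Explant morphology over time
#'
#' Computes area, centroid, the area ratio relative to the first time point,
#' and (when several explants are given) centroid-to-centroid distances and
#' their ratios — the normalization used to compare explant shrinkage
#' across gels.
#'
#' @param shapes For a single explant: a list (over time) of either logical
#'   masks (matrix; `pixel_size` converts to mm) or polygon matrices
#'   (vertices x 2, mm). For several explants: a list (over time) of lists
#'   (one shape per explant).
#' @param pixel_size Edge length of one mask pixel in mm (ignored for
#'   polygons).
#' @return A data frame with one row per time point and explant: `time`,
#'   `explant`, `area_mm2`, `cx`, `cy`, `area_ratio`, and, for multi-explant
#'   input, `dist_12`, `dist_13`, `dist_23` and `dist_ratio_*` columns.
#' @export
explant_morphology <- function(shapes, pixel_size = 1) {
  stopifnot(length(shapes) >= 1)
  multi <- is.list(shapes[[1]]) && !is.matrix(shapes[[1]])
  if (!multi) shapes <- lapply(shapes, list)
  nexp <- length(shapes[[1]])
  rows <- list()
  dist_block <- list()
  for (t_ in seq_along(shapes)) {
    geo <- lapply(shapes[[t_]], shape_area_centroid, pixel_size = pixel_size)
    for (p in seq_len(nexp))
      rows[[length(rows) + 1L]] <-
        data.frame(time = t_, explant = p,
                   area_mm2 = geo[[p]]$area,
                   cx = geo[[p]]$centroid[1], cy = geo[[p]]$centroid[2])
    if (nexp >= 2) {
      cen <- t(vapply(geo, function(g) g$centroid, numeric(2)))
      pr <- utils::combn(nexp, 2)
      d <- apply(pr, 2, function(ij) sqrt(sum((cen[ij[1], ] - cen[ij[2], ])^2)))
      dist_block[[t_]] <- d
    }
  }
  df <- do.call(rbind, rows)
  a0 <- df$area_mm2[df$time == 1]
  df$area_ratio <- df$area_mm2 / a0[df$explant]
  out <- df
  if (nexp >= 2) {
    dm <- do.call(rbind, dist_block)
    pr <- utils::combn(nexp, 2)
    colnames(dm) <- paste0("dist_", pr[1, ], pr[2, ])
    dr <- sweep(dm, 2, dm[1, ], "/")
    colnames(dr) <- paste0("dist_ratio_", pr[1, ], pr[2, ])
    attr(out, "distances") <- data.frame(time = seq_along(shapes), dm, dr)
  }
  out
}

shape_area_centroid <- function(shape, pixel_size = 1) {
  if (is.logical(shape) || (is.matrix(shape) && all(shape %in% c(0, 1)) &&
                            nrow(shape) > 2 && ncol(shape) > 2 &&
                            is.integer(shape[1]))) {
    shape <- shape != 0
  }
  if (is.matrix(shape) && is.logical(shape)) {
    if (!any(shape)) stop("empty explant mask")
    idx <- which(shape, arr.ind = TRUE)
    area <- nrow(idx) * pixel_size^2
    cen <- colMeans(idx)[c(2, 1)] * pixel_size # (x, y) = (col, row)
    return(list(area = area, centroid = unname(cen)))
  }
  poly <- as.matrix(shape)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) stop("degenerate polygon")
  cx <- sum((x + xs) * cr) / (6 * a)
  cy <- sum((y + ys) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}
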