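#' Image sequence container
#'
#' @param frames List of 2D numeric matrices on the 8-bit scale (0-255),
#'   all the same size. Matrix rows are image rows (y, growing downward),
#'   columns are x.
#' @param pixel_size Micrometers per pixel.
#' @param frame_interval Minutes between frames.
#' @return An `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size = 1, frame_interval = 15) {
  stopifnot(is.list(frames), length(frames) >= 1, pixel_size > 0,
            frame_interval > 0)
  dm <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dm),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical size")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_sequence")
}

#' Read a (multi-page) TIFF as an image sequence
#'
#' Grayscale pages are rescaled from [0, 1] to the 8-bit 0-255 range.
#'
#' @param path TIFF file (single- or multi-page), or a character vector of
#'   single-page files.
#' @param pixel_size,frame_interval See [image_sequence()].
#' @export
read_image_sequence <- function(path, pixel_size = 1, frame_interval = 15) {
  pages <- if (length(path) > 1) {
    lapply(path, function(p) tiff::readTIFF(p))
  } else {
    x <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(x)) list(x) else x
  }
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # first channel of RGB
    p * 255
  })
  image_sequence(frames, pixel_size, frame_interval)
}

#' Write an image sequence as an 8-bit multi-page TIFF
#'
#' @param seq An [image_sequence()].
#' @param path Output file.
#' @export
write_image_sequence_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  imgs <- lapply(seq$frames, function(f) pmin(pmax(f, 0), 255) / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

# sub-pixel refinement of a correlation peak by 1D quadratic fits
subpixel_offset <- function(cm1, c0, cp1) {
  den <- cm1 - 2 * c0 + cp1
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  off <- 0.5 * (cm1 - cp1) / den
  max(min(off, 0.5), -0.5)
}

#' Track microspheres by normalized cross-correlation template matching
#'
#' Sequential matching between successive frames: for each bead, a square
#' template centered on its current position in frame `t-1` is correlated
#' (normalized cross-correlation, so the tracker is invariant to intensity
#' gain and offset) against a search window in frame `t`; the correlation
#' peak, refined to sub-pixel precision by quadratic interpolation, gives
#' the new position and the template is re-sampled there. A bead whose peak
#' correlation drops below `min_correlation` (e.g. because it drifts out of
#' focus) is marked lost from that frame on.
#'
#' @param seq An [image_sequence()].
#' @param initial_positions Matrix (n x 2) of starting `(x, y)` pixel
#'   coordinates (1-based, x = column).
#' @param template_halfwidth,search_halfwidth Template and search-window
#'   half-sizes in pixels.
#' @param min_correlation Lost-bead threshold on the peak NCC score.
#' @return List of [trajectory()] objects (positions in pixels; lost frames
#'   are `NA`), each with attributes `scores` (per-step peak correlation)
#'   and `lost_at` (first lost frame or `NA`).
#' @export
track_beads <- function(seq, initial_positions, template_halfwidth = 10,
                        search_halfwidth = 20, min_correlation = 0.5) {
  stopifnot(inherits(seq, "image_sequence"))
  P0 <- as.matrix(initial_positions)
  stopifnot(ncol(P0) == 2)
  nf <- length(seq$frames)
  dm <- dim(seq$frames[[1]])
  tw <- as.integer(template_halfwidth)
  sw <- as.integer(search_halfwidth)
  if (sw <= tw) stop("search halfwidth must exceed template halfwidth")
  margin <- tw + 1L
  if (any(P0[, 1] < margin | P0[, 1] > dm[2] - margin |
          P0[, 2] < margin | P0[, 2] > dm[1] - margin))
    stop("initial positions must lie at least template_halfwidth + 1 px inside the frame")
  out <- vector("list", nrow(P0))
  for (b in seq_len(nrow(P0))) {
    pos <- matrix(NA_real_, nf, 2)
    pos[1, ] <- P0[b, ]
    scores <- rep(NA_real_, nf)
    lost_at <- NA_integer_
    for (t_ in seq_len(nf - 1L)) {
      cur <- pos[t_, ]
      ci <- round(cur)
      # template in frame t_, search window in frame t_+1
      tr <- (ci[2] - tw):(ci[2] + tw); tc <- (ci[1] - tw):(ci[1] + tw)
      sr <- (ci[2] - sw):(ci[2] + sw); sc <- (ci[1] - sw):(ci[1] + sw)
      if (min(tr) < 1 || max(tr) > dm[1] || min(tc) < 1 || max(tc) > dm[2] ||
          min(sr) < 1 || max(sr) > dm[1] || min(sc) < 1 || max(sc) > dm[2]) {
        lost_at <- t_ + 1L
        break
      }
      templ <- seq$frames[[t_]][tr, tc, drop = FALSE]
      win <- seq$frames[[t_ + 1L]][sr, sc, drop = FALSE]
      cc <- cpp_ncc(win, templ)
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      score <- cc[pk[1], pk[2]]
      scores[t_ + 1L] <- score
      if (!is.finite(score) || score < min_correlation) {
        lost_at <- t_ + 1L
        break
      }
      dy <- dx <- 0
      if (pk[1] > 1 && pk[1] < nrow(cc))
        dy <- subpixel_offset(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]],
                              cc[pk[1] + 1, pk[2]])
      if (pk[2] > 1 && pk[2] < ncol(cc))
        dx <- subpixel_offset(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]],
                              cc[pk[1], pk[2] + 1])
      # peak at (1,1) means template centered at (ci - (sw - tw))
      new_xy <- c(ci[1] - (sw - tw) + (pk[2] - 1) + dx,
                  ci[2] - (sw - tw) + (pk[1] - 1) + dy)
      # carry sub-pixel phase of the current estimate
      new_xy <- new_xy + (cur - ci)
      pos[t_ + 1L, ] <- new_xy
    }
    keep <- if (is.na(lost_at)) nf else lost_at - 1L
    tr_obj <- trajectory(b, pos[seq_len(keep), , drop = FALSE],
                         seq$frame_interval)
    tr_obj$positions_full <- pos
    attr(tr_obj, "scores") <- scores
    attr(tr_obj, "lost_at") <- lost_at
    out[[b]] <- tr_obj
  }
  out
}

#' FFT-based fiber orientation tensor of an image tile
#'
#' The tile is mean-subtracted, Hann-windowed and Fourier transformed; the
#' power spectrum (DC removed, annular band-pass in cycles/px) is binned by
#' angle into an orientation distribution over `[0, pi)` using the mean
#' power per bin (which removes the square-grid density bias). Because
#' spectral energy of an oriented texture lies perpendicular to the fibers,
#' bin angles are rotated by 90 degrees before forming the second-moment
#' orientation tensor, from which `alpha = 1 - w1/w2` and the principal
#' angle follow.
#'
#' @param tile Numeric matrix (>= 64 px on each side).
#' @param band Annular band-pass `(low, high)` in cycles/px; the default
#'   keeps mid frequencies, where finite fiber length and width bias the
#'   angular distribution least.
#' @param nbins Number of angular bins over `[0, pi)`.
#' @return An `orientation_result` (see [orientation_tensor_2d()]); a
#'   constant tile returns `alpha = 0` with attribute `degenerate = TRUE`.
#' @export
fft_alignment <- function(tile, band = c(0.1, 0.3), nbins = 180) {
  tile <- as.matrix(tile)
  if (min(dim(tile)) < 64) stop("tile must be at least 64 px on each side")
  nr <- nrow(tile); nc <- ncol(tile)
  tile <- tile - mean(tile)
  if (max(abs(tile)) < 1e-12) {
    res <- orientation_result(diag(2) / 2)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  w <- outer(hann_window(nr), hann_window(nc))
  P <- Mod(stats::fft(tile * w))^2
  # frequency coordinates in cycles/px (unshifted FFT layout)
  fy <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr - floor(nr / 2)) / nr
  fx <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc - floor(nc / 2)) / nc
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  R <- sqrt(FX^2 + FY^2)
  sel <- R >= band[1] & R <= band[2]
  if (!any(sel)) stop("empty band-pass annulus")
  ang <- atan2(FY[sel], FX[sel]) %% pi
  bin <- pmin(floor(ang / pi * nbins) + 1, nbins)
  e_sum <- tapply(P[sel], bin, sum)
  e_cnt <- tapply(P[sel], bin, length)
  centers <- (as.numeric(names(e_sum)) - 0.5) * pi / nbins
  energy <- as.numeric(e_sum / e_cnt)
  th <- centers + pi / 2 # image-space fiber direction
  W <- sum(energy)
  Omega <- matrix(c(sum(energy * cos(th)^2), sum(energy * cos(th) * sin(th)),
                    sum(energy * cos(th) * sin(th)), sum(energy * sin(th)^2)) / W,
                  2, 2)
  orientation_result(Omega)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Tile-wise alignment map of a fiber image
#'
#' Applies [fft_alignment()] to non-overlapping square tiles.
#'
#' @param image Numeric matrix.
#' @param tile_size Tile edge, px (>= 64).
#' @param band,nbins Passed to [fft_alignment()].
#' @return Data frame: tile row/col, tile center (px), `alpha`, `angle`
#'   (radians), eigenvalues `w1`, `w2`.
#' @export
alignment_map <- function(image, tile_size = 128, band = c(0.1, 0.3),
                          nbins = 180) {
  image <- as.matrix(image)
  ntr <- nrow(image) %/% tile_size
  ntc <- ncol(image) %/% tile_size
  if (ntr < 1 || ntc < 1) stop("image smaller than one tile")
  rows <- list()
  for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
    ri <- ((i - 1) * tile_size + 1):(i * tile_size)
    cj <- ((j - 1) * tile_size + 1):(j * tile_size)
    o <- fft_alignment(image[ri, cj], band, nbins)
    rows[[length(rows) + 1L]] <-
      data.frame(tile_row = i, tile_col = j,
                 cx = mean(cj), cy = mean(ri),
                 alpha = o$alpha, angle = o$angle,
                 w1 = o$eigenvalues[1], w2 = o$eigenvalues[2])
  }
  do.call(rbind, rows)
}

#' Ellipse-glyph overlay of an alignment map
#'
#' Draws the image with one ellipse per tile whose axes are the principal
#' directions/magnitudes of fiber orientation — round tiles are isotropic,
#' elongated tiles aligned.
#'
#' @param image Numeric matrix (0-255).
#' @param map An [alignment_map()] result.
#' @param scale Glyph radius in px at `w = 0.5`.
#' @export
plot_alignment_glyphs <- function(image, map, scale = 40) {
  image <- as.matrix(image)
  graphics::image(t(image[nrow(image):1, ]) , col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  nr <- nrow(image); nc <- ncol(image)
  tt <- seq(0, 2 * pi, length.out = 90)
  for (k in seq_len(nrow(map))) {
    a2 <- 2 * scale * map$w2[k]; a1 <- 2 * scale * map$w1[k]
    th <- map$angle[k]
    ex <- a2 * cos(tt) * cos(th) - a1 * sin(tt) * sin(th)
    ey <- a2 * cos(tt) * sin(th) + a1 * sin(tt) * cos(th)
    graphics::lines((map$cx[k] + ex) / nc, 1 - (map$cy[k] + ey) / nr,
                    col = "yellow")
  }
  invisible(map)
}
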