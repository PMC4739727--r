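#' Specification of a synthetic bead-tracking scene
#'
#' Describes a microsphere-seeded time-lapse sequence advected by a
#' prescribed displacement field, used to validate the tracker against
#' known ground truth. Beads are rendered as 2D Gaussian spots
#' (`sigma = radius / 2`) on a dark background — the tracker contract only
#' needs localizable blobs, so DIC image formation is not simulated.
#'
#' @param frame_dim `(rows, cols)` in pixels.
#' @param n_beads Number of beads.
#' @param bead_radius Bead radius, px (4 µm beads at typical magnification
#'   are a few px across).
#' @param field Displacement field, one of:
#'   `list(type = "uniform", v = c(vx, vy))` (px/frame),
#'   `list(type = "radial", center = c(x, y), factor = f)` (per-frame
#'   contraction of the vector to `center` by factor `f < 1`), or
#'   `list(type = "function", fun = function(p0, t) ...)` returning absolute
#'   positions at frame `t` (e.g. a field exported from a simulation).
#' @param n_frames Number of frames.
#' @param noise_sd Gaussian noise SD on the 8-bit scale.
#' @param peak Bead peak intensity above background.
#' @param background Background intensity.
#' @param pixel_size µm/px; `frame_interval` min between frames.
#' @param frame_interval Minutes between frames.
#' @param seed Seed; fixes bead placement and noise.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(frame_dim = c(256, 256), n_beads = 25,
                       bead_radius = 3,
                       field = list(type = "uniform", v = c(0, 0)),
                       n_frames = 10, noise_sd = 2, peak = 180,
                       background = 20, pixel_size = 1,
                       frame_interval = 15, seed = 1) {
  stopifnot(length(frame_dim) == 2, n_beads >= 1, bead_radius > 0,
            n_frames >= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

# absolute bead positions (n x 2, (x, y)) at frame t for a scene field
advect_positions <- function(p0, field, t) {
  switch(field$type,
         uniform = sweep(p0, 2, (t - 1) * field$v, "+"),
         radial = {
           cen <- matrix(field$center, nrow(p0), 2, byrow = TRUE)
           cen + (p0 - cen) * field$factor^(t - 1)
         },
         "function" = field$fun(p0, t),
         stop("unknown field type: ", field$type))
}

#' Render a synthetic bead sequence with ground truth
#'
#' @param spec A [scene_spec()].
#' @return List: `seq` (an [image_sequence()]), `truth` (list of
#'   [trajectory()] objects with the exact sub-pixel positions),
#'   `truth_table` (long data frame incl. an `in_frame` flag; beads advected
#'   outside the frame are clipped and flagged, with a warning), `spec`.
#' @export
render_bead_sequence <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$frame_dim[1]; nc <- spec$frame_dim[2]
    margin <- 4 * spec$bead_radius + 24
    p0 <- cbind(runif(spec$n_beads, margin, nc - margin),
                runif(spec$n_beads, margin, nr - margin))
    sigma <- spec$bead_radius / 2
    frames <- vector("list", spec$n_frames)
    pos_t <- vector("list", spec$n_frames)
    for (t_ in seq_len(spec$n_frames)) {
      p <- advect_positions(p0, spec$field, t_)
      pos_t[[t_]] <- p
      img <- matrix(spec$background, nr, nc)
      for (b in seq_len(nrow(p))) {
        cx <- p[b, 1]; cy <- p[b, 2]
        r0 <- max(1, floor(cy - 4 * sigma)); r1 <- min(nr, ceiling(cy + 4 * sigma))
        c0 <- max(1, floor(cx - 4 * sigma)); c1 <- min(nc, ceiling(cx + 4 * sigma))
        if (r0 > r1 || c0 > c1) next
        g <- spec$peak * outer(exp(-((r0:r1) - cy)^2 / (2 * sigma^2)),
                               exp(-((c0:c1) - cx)^2 / (2 * sigma^2)))
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      frames[[t_]] <- round(pmin(pmax(img, 0), 255))
    }
    in_frame <- vapply(seq_len(spec$n_frames), function(t_) {
      p <- pos_t[[t_]]
      p[, 1] >= 1 & p[, 1] <= nc & p[, 2] >= 1 & p[, 2] <= nr
    }, logical(spec$n_beads))
    if (!all(in_frame))
      warning("some beads were advected out of frame; see truth_table$in_frame")
    truth <- lapply(seq_len(spec$n_beads), function(b) {
      tr <- trajectory(b, t(vapply(pos_t, function(p) p[b, ], numeric(2))),
                       spec$frame_interval)
      tr
    })
    truth_table <- do.call(rbind, lapply(seq_len(spec$n_beads), function(b) {
      data.frame(bead = b, frame = seq_len(spec$n_frames),
                 x = vapply(pos_t, function(p) p[b, 1], numeric(1)),
                 y = vapply(pos_t, function(p) p[b, 2], numeric(1)),
                 in_frame = in_frame[b, ])
    }))
    list(seq = image_sequence(frames, spec$pixel_size, spec$frame_interval),
         truth = truth, truth_table = truth_table, spec = spec)
  })
}

#' Specification of a synthetic fiber texture
#'
#' @param dim `(rows, cols)` px.
#' @param n_fibers Number of line segments.
#' @param length_range `(min, max)` segment length, px.
#' @param orientation `list(type = "uniform")` or
#'   `list(type = "vonmises", mu = <radians>, kappa = <concentration>)`;
#'   fiber angles are axial (defined mod pi), sampled by drawing `2*theta`
#'   from a von Mises distribution with mean `2*mu`.
#' @param line_width Gaussian half-width of the rendered line profile, px.
#' @param peak,background,noise_sd Intensities on the 8-bit scale.
#' @param seed Seed.
#' @return A `texture_spec`.
#' @export
texture_spec <- function(dim = c(256, 256), n_fibers = 400,
                         length_range = c(40, 120),
                         orientation = list(type = "uniform"),
                         line_width = 1.2, peak = 110, background = 15,
                         noise_sd = 2, seed = 1) {
  stopifnot(length(dim) == 2, n_fibers >= 1, line_width > 0)
  if (identical(orientation$type, "vonmises"))
    stopifnot(orientation$kappa >= 0)
  structure(as.list(environment()), class = "texture_spec")
}

# Best-Fisher (1979) von Mises sampler (mean mu, concentration kappa)
rvonmises_local <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# analytic alignment strength of the axial von Mises distribution:
# with 2*theta ~ VM(2mu, kappa), E[cos 2(theta-mu)] = I1(kappa)/I0(kappa)
vonmises_alpha <- function(kappa) {
  if (kappa < 1e-12) return(0)
  A <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  2 * A / (1 + A)
}

#' Render a synthetic fiber texture with its exact orientation tensor
#'
#' Line segments with the prescribed orientation distribution are
#' composited with an anti-aliased Gaussian cross-profile. The ground-truth
#' tensor is the equal-weight second moment of the sampled angles, and, for
#' von Mises orientations, the analytic `alpha` of the distribution is also
#' returned.
#'
#' @param spec A [texture_spec()].
#' @return List: `image` (matrix), `angles` (sampled, radians mod pi),
#'   `truth` (an `orientation_result` from the sampled angles),
#'   `alpha_analytic` (`NA` for non-von-Mises), `spec`.
#' @export
render_fiber_texture <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$dim[1]; nc <- spec$dim[2]
    n <- spec$n_fibers
    th <- switch(spec$orientation$type,
                 uniform = runif(n, 0, pi),
                 vonmises = (rvonmises_local(n, 2 * spec$orientation$mu,
                                             spec$orientation$kappa) / 2) %% pi,
                 stop("unknown orientation type"))
    len <- runif(n, spec$length_range[1], spec$length_range[2])
    cen <- cbind(runif(n, 1, nc), runif(n, 1, nr))
    img <- matrix(spec$background, nr, nc)
    w <- spec$line_width
    for (f in seq_len(n)) {
      d <- c(cos(th[f]), sin(th[f]))
      p1 <- cen[f, ] - len[f] / 2 * d
      p2 <- cen[f, ] + len[f] / 2 * d
      r0 <- max(1, floor(min(p1[2], p2[2]) - 3 * w))
      r1 <- min(nr, ceiling(max(p1[2], p2[2]) + 3 * w))
      c0 <- max(1, floor(min(p1[1], p2[1]) - 3 * w))
      c1 <- min(nc, ceiling(max(p1[1], p2[1]) + 3 * w))
      if (r0 > r1 || c0 > c1) next
      xs <- c0:c1; ys <- r0:r1
      PX <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      PY <- matrix(ys, length(ys), length(xs))
      vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
      L2 <- vx^2 + vy^2
      t_ <- pmin(pmax(((PX - p1[1]) * vx + (PY - p1[2]) * vy) / L2, 0), 1)
      dx <- PX - (p1[1] + t_ * vx); dy <- PY - (p1[2] + t_ * vy)
      img[ys, xs] <- img[ys, xs] + spec$peak * exp(-(dx^2 + dy^2) / (2 * w^2))
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img <- round(pmin(pmax(img, 0), 255))
    Omega <- matrix(c(mean(cos(th)^2), mean(cos(th) * sin(th)),
                      mean(cos(th) * sin(th)), mean(sin(th)^2)), 2, 2)
    list(image = img, angles = th,
         truth = orientation_result(Omega),
         alpha_analytic = if (identical(spec$orientation$type, "vonmises"))
           vonmises_alpha(spec$orientation$kappa) else NA_real_,
         spec = spec)
  })
}
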