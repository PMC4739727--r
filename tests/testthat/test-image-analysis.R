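test_that("tracker reports zero displacement on a static scene", {
  sc <- render_bead_sequence(scene_spec(n_frames = 6, seed = 2))
  trs <- track_beads(sc$seq, sc$truth_table[sc$truth_table$frame == 1,
                                            c("x", "y")])
  disp <- unlist(lapply(trs, function(tr)
    displacement_stats(tr)$cumulative))
  expect_lt(max(disp), 0.1)
})

test_that("tracker recovers uniform translation within a quarter pixel per frame", {
  sc <- render_bead_sequence(
    scene_spec(frame_dim = c(320, 320),
               field = list(type = "uniform", v = c(3, 0)),
               n_frames = 8, seed = 4))
  trs <- track_beads(sc$seq, sc$truth_table[sc$truth_table$frame == 1,
                                            c("x", "y")])
  ok <- vapply(trs, function(tr) is.na(attr(tr, "lost_at")), logical(1))
  expect_gt(mean(ok), 0.6)
  for (b in which(ok)) {
    steps <- diff(trs[[b]]$positions)
    expect_lt(max(abs(steps[, 1] - 3)), 0.25)
    expect_lt(max(abs(steps[, 2])), 0.25)
  }
})

test_that("tracker recovers a radially contracting field below half-pixel RMS", {
  sc <- render_bead_sequence(
    scene_spec(field = list(type = "radial", center = c(128, 128),
                            factor = 0.985),
               n_frames = 12, seed = 9))
  trs <- track_beads(sc$seq, sc$truth_table[sc$truth_table$frame == 1,
                                            c("x", "y")])
  sq_err <- unlist(lapply(seq_along(trs), function(b) {
    p <- trs[[b]]$positions
    q <- sc$truth[[b]]$positions[seq_len(nrow(p)), , drop = FALSE]
    rowSums((p - q)^2)
  }))
  expect_lt(sqrt(mean(sq_err)), 0.5)
})

test_that("tracker is invariant to global intensity gain and offset", {
  sc <- render_bead_sequence(
    scene_spec(field = list(type = "uniform", v = c(2, 1)),
               n_frames = 6, noise_sd = 0, seed = 12))
  trs_a <- track_beads(sc$seq, sc$truth_table[sc$truth_table$frame == 1,
                                              c("x", "y")])
  seq_b <- sc$seq
  seq_b$frames <- lapply(seq_b$frames, function(f) 0.5 * f + 30)
  trs_b <- track_beads(seq_b, sc$truth_table[sc$truth_table$frame == 1,
                                             c("x", "y")])
  for (b in seq_along(trs_a))
    expect_equal(trs_b[[b]]$positions, trs_a[[b]]$positions,
                 tolerance = 1e-10)
})

test_that("beads below the correlation threshold are marked lost", {
  sc <- render_bead_sequence(
    scene_spec(n_frames = 6, noise_sd = 0, seed = 5))
  seq_cut <- sc$seq
  # blank the second half of the sequence: tracker must flag loss
  for (t_ in 4:6) seq_cut$frames[[t_]] <- matrix(runif(256 * 256, 0, 255),
                                                 256, 256)
  trs <- track_beads(seq_cut, sc$truth_table[sc$truth_table$frame == 1,
                                             c("x", "y")])
  expect_true(all(vapply(trs, function(tr) identical(attr(tr, "lost_at"), 4L),
                         logical(1))))
  expect_true(all(vapply(trs, function(tr) nrow(tr$positions) == 3L,
                         logical(1))))
})

test_that("FFT alignment is near-isotropic on white noise", {
  set.seed(2)
  wn <- matrix(runif(256 * 256, 0, 255), 256, 256)
  expect_lt(fft_alignment(wn)$alpha, 0.05)
})

test_that("FFT alignment recovers stripes and flags constant tiles", {
  # bands running along 30 degrees (intensity varies along 120 degrees)
  th <- pi / 6
  x <- outer(1:256, 1:256, function(r, c)
    128 + 100 * cos(2 * pi * (c * cos(th + pi / 2) + r * sin(th + pi / 2)) / 8))
  o <- fft_alignment(x)
  expect_gt(o$alpha, 0.8)
  dang <- abs((o$angle - th) %% pi)
  expect_lt(min(dang, pi - dang) * 180 / pi, 3)
  flat <- fft_alignment(matrix(128, 128, 128))
  expect_equal(flat$alpha, 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_error(fft_alignment(matrix(0, 32, 32)), "64 px")
})

test_that("FFT alignment matches the closed-form von Mises tensor", {
  for (kap in c(0.5, 2, 4)) {
    tx <- render_fiber_texture(
      texture_spec(orientation = list(type = "vonmises", mu = pi / 6,
                                      kappa = kap),
                   n_fibers = 500, seed = 3))
    o <- fft_alignment(tx$image)
    expect_lt(abs(o$alpha - tx$alpha_analytic), 0.05)
    if (kap >= 2) {
      dang <- abs((o$angle - pi / 6) %% pi)
      expect_lt(min(dang, pi - dang) * 180 / pi, 5)
    }
  }
})

test_that("alpha and angle transform correctly under rotation and gain", {
  tx <- render_fiber_texture(
    texture_spec(orientation = list(type = "vonmises", mu = pi / 3,
                                    kappa = 3), n_fibers = 400, seed = 8))
  o <- fft_alignment(tx$image)
  # intensity scaling leaves both alpha and angle unchanged
  o_gain <- fft_alignment(0.4 * tx$image + 11)
  expect_equal(o_gain$alpha, o$alpha, tolerance = 1e-8)
  expect_equal(o_gain$angle, o$angle, tolerance = 1e-8)
  # 90-degree image rotation rotates the principal angle by 90 degrees
  rot <- t(tx$image)[ncol(tx$image):1, ] # transpose + flip = rotation
  o_rot <- fft_alignment(rot)
  expect_equal(o_rot$alpha, o$alpha, tolerance = 0.05)
  dang <- (o$angle - o_rot$angle) %% pi
  expect_lt(abs(dang - pi / 2) * 180 / pi, 6)
})

test_that("alignment maps tile an image and TIFF IO round-trips", {
  tx <- render_fiber_texture(
    texture_spec(dim = c(256, 256),
                 orientation = list(type = "vonmises", mu = 0.5, kappa = 3),
                 n_fibers = 500, seed = 6))
  map <- alignment_map(tx$image, tile_size = 128)
  expect_identical(nrow(map), 4L)
  expect_true(all(map$alpha > 0.2))
  f <- tempfile(fileext = ".tif")
  sc <- render_bead_sequence(scene_spec(n_frames = 3, seed = 3))
  write_image_sequence_tiff(sc$seq, f)
  back <- read_image_sequence(f)
  expect_identical(length(back$frames), 3L)
  expect_equal(back$frames[[2]], sc$seq$frames[[2]], tolerance = 0.5)
  # glyph overlay draws without error
  pdf(NULL)
  expect_silent(plot_alignment_glyphs(tx$image, map))
  dev.off()
})
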