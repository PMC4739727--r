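test_that("fiber force law matches hand-evaluated values and limits", {
  mat <- network_material() # EfAf = 3e-10 N, B = 4
  expect_identical(fiber_force(1, mat), 0)
  # direct arithmetic: eps = 0.5*(1.1^2-1) = 0.105,
  # F = 3e-10/4 * (exp(0.42) - 1)
  expect_equal(fiber_force(1.1, mat), 3.914712e-11, tolerance = 1e-6)
  # strictly increasing
  lam <- seq(0.6, 1.8, by = 0.01)
  expect_true(all(diff(fiber_force(lam, mat)) > 0))
  # small-B branch equals the linear law
  lin <- network_material(EfAf = 3e-10, B = 0)
  eps <- 0.5 * (1.2^2 - 1)
  expect_equal(fiber_force(1.2, lin), 3e-10 * eps)
  # B -> 0 continuity across the branch switch
  expect_equal(fiber_force(1.2, network_material(B = 1e-9)),
               fiber_force(1.2, lin), tolerance = 1e-6)
  # linear-law agreement to < 1% at |eps| < 1e-3 with B = 4
  lam_small <- sqrt(1 + 2 * c(-1e-3, -1e-4, 1e-4, 1e-3))
  rel <- abs(fiber_force(lam_small, mat) /
               (3e-10 * 0.5 * (lam_small^2 - 1)) - 1)
  expect_true(all(rel < 0.01))
  expect_error(fiber_force(NaN, mat), "non-finite")
  expect_error(fiber_force(-1, mat), "lambda")
})

test_that("generated networks are deterministic, cross-linked and near-isotropic", {
  a <- generate_network(42)
  b <- generate_network(42)
  expect_identical(a, b)
  expect_false(identical(a, generate_network(43)))
  expect_true(all(a$reference_lengths > 0))
  # two distinct nodes per fiber
  expect_true(all(a$fibers[, 1] != a$fibers[, 2]))
  # boundary nodes on a cube face, interior nodes strictly inside
  bpos <- a$node_positions[a$boundary, , drop = FALSE]
  on_face <- apply(bpos, 1, function(p) any(abs(p) < 1e-9 | abs(p - 1) < 1e-9))
  expect_true(all(on_face))
  # every interior node is mechanically connected (cross-link degree 4)
  deg <- tabulate(c(a$fibers), nbins = nrow(a$node_positions))
  expect_true(all(deg[!a$boundary] >= 2))
  # near-isotropy of the 2D projection
  expect_lt(orientation_tensor_2d(a)$alpha, 0.15)
})

test_that("mean fiber count over seeds is calibrated to the target", {
  counts <- vapply(1:40, function(s) nrow(generate_network(s)$fibers),
                   numeric(1))
  expect_lt(abs(mean(counts) - 337), 15)
  expect_lt(sd(counts), 60)
})

test_that("network JSON and CSV round-trips preserve the network", {
  net <- generate_network(7, target_fibers = 60)
  f <- tempfile(fileext = ".json")
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_equal(back$node_positions, net$node_positions)
  expect_equal(back$fibers, net$fibers)
  expect_equal(back$reference_lengths, net$reference_lengths)
  expect_identical(back$boundary, net$boundary)
  csv <- tempfile(fileext = ".csv")
  write_fiber_csv(net, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), nrow(net$fibers))
  expect_equal(df$reference_length, net$reference_lengths)
})

test_that("equilibrium solver reproduces reference, symmetry and oracle states", {
  mat <- network_material()
  # stress-free reference: zero boundary displacement, zero motion
  net <- generate_network(5, target_fibers = 60)
  sol0 <- solve_equilibrium(net, matrix(0, sum(net$boundary), 3), mat)
  expect_true(sol0$converged)
  expect_equal(sol0$deformed_positions, net$node_positions)
  expect_lt(max(abs(sol0$boundary_forces)), 1e-20)
  # split fiber under uniaxial stretch: interior node at the 0.4 fraction
  ts <- toy_split_fiber()
  sol <- solve_equilibrium(ts, rbind(c(0, 0, 0), c(0.1, 0, 0)), mat)
  expect_equal(sol$deformed_positions[2, ], c(0.44, 0.5, 0.5),
               tolerance = 1e-9)
  # independent energy-minimization oracle on the 5-node toy
  tf <- toy_five_node()
  set.seed(7)
  bd <- matrix(rnorm(12, 0, 0.02), 4, 3)
  sol5 <- solve_equilibrium(tf, bd, mat, tol = 1e-10 * mat$EfAf,
                            max_iter = 200)
  oracle <- oracle_equilibrium(tf, bd, mat)
  expect_equal(sol5$deformed_positions[5, ], oracle[5, ],
               tolerance = 1e-8)
})

test_that("solver reports non-convergence with its residual history", {
  mat <- network_material()
  net <- generate_network(9, target_fibers = 60)
  bd <- matrix(0.3, sum(net$boundary), 3) # rigid translation is fine...
  expect_error(
    solve_equilibrium(net, matrix(rnorm(3 * sum(net$boundary), 0, 0.3),
                                  ncol = 3),
                      mat, max_iter = 1),
    "did not converge")
  out <- solve_equilibrium(net, matrix(rnorm(3 * sum(net$boundary), 0, 0.3),
                                       ncol = 3),
                           mat, max_iter = 1, on_fail = "return")
  expect_false(out$converged)
  expect_gte(length(out$residual_history), 1)
})

test_that("volume-averaged stress matches hand evaluation and brute force", {
  mat <- network_material()
  # undeformed network: zero tensor
  net <- generate_network(3, target_fibers = 60)
  sol0 <- solve_equilibrium(net, matrix(0, sum(net$boundary), 3), mat)
  expect_lt(max(abs(volume_avg_stress(sol0, net))), 1e-20)
  # single fiber along x stretched to lambda: sxx = lambda*F/V, rest 0
  sf <- toy_single_fiber()
  lam <- 1.15
  sol <- solve_equilibrium(sf, rbind(c(0, 0, 0), c(lam - 1, 0, 0)), mat)
  S <- volume_avg_stress(sol, sf)
  expect_equal(S[1, 1], lam * fiber_force(lam, mat), tolerance = 1e-12)
  expect_lt(max(abs(S[-1])), 1e-25)
  # physical scaling: dividing by the squared RVE edge gives Pa
  Sp <- volume_avg_stress(sol, sf, rve_edge = 2e-5)
  expect_equal(Sp[1, 1], S[1, 1] / 4e-10)
})

test_that("averaging equals the brute-force Eq-2 oracle on many small networks", {
  mat <- network_material()
  for (s in 1:50) {
    net <- generate_network(s, n_segments = 5, capture_radius = 0.15)
    expect_lte(nrow(net$node_positions), 20)
    set.seed(1000 + s)
    bd <- matrix(rnorm(3 * sum(net$boundary), 0, 0.02), ncol = 3)
    sol <- solve_equilibrium(net, bd, mat, on_fail = "return")
    if (!sol$converged) next
    S <- volume_avg_stress(sol, net)
    raw <- oracle_volume_avg_stress(sol$deformed_positions, net$boundary,
                                    sol$boundary_forces, net$volume)
    expect_equal(unclass(S), 0.5 * (raw + t(raw)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(attr(S, "asymmetry"), norm(0.5 * (raw - t(raw)), "F"),
                 tolerance = 1e-12)
  }
})

test_that("reference-length shortening composes multiplicatively", {
  net <- generate_network(2, target_fibers = 60)
  expect_equal(shorten_reference_lengths(net, 0)$reference_lengths,
               net$reference_lengths)
  s24 <- shorten_reference_lengths(net, 0.24)
  expect_equal(s24$reference_lengths, 0.76 * net$reference_lengths)
  expect_identical(s24$fibers, net$fibers)
  twice <- shorten_reference_lengths(
    shorten_reference_lengths(net, 0.12), 0.12)
  once <- shorten_reference_lengths(net, 1 - 0.88^2)
  expect_equal(twice$reference_lengths, once$reference_lengths)
  expect_error(shorten_reference_lengths(net, 1), "fraction")
  expect_error(shorten_reference_lengths(net, -0.1), "fraction")
})

test_that("2D orientation tensor handles the canonical fiber arrangements", {
  # single fiber along x
  o <- orientation_tensor_2d(rbind(c(0, 0, 1, 0)))
  expect_equal(o$Omega, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(o$alpha, 1)
  # two equal orthogonal fibers: isotropic
  o2 <- orientation_tensor_2d(rbind(c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(o2$Omega, diag(2) / 2)
  expect_equal(o2$alpha, 0)
  # one fiber at 45 degrees: rank-1
  o3 <- orientation_tensor_2d(rbind(c(0, 0, 1, 1)))
  expect_equal(o3$Omega, matrix(0.5, 2, 2))
  expect_equal(o3$alpha, 1)
  expect_equal(o3$angle, pi / 4, tolerance = 1e-12)
  expect_error(orientation_tensor_2d(rbind(c(0, 0, 0, 0))), "degenerate")
})

test_that("orientation tensor is trace-one and rotation-equivariant", {
  for (s in 1:10) {
    set.seed(s)
    seg <- matrix(runif(4 * 30), ncol = 4)
    o <- orientation_tensor_2d(seg)
    expect_equal(sum(diag(o$Omega)), 1, tolerance = 1e-12)
    expect_gte(o$alpha, 0)
    expect_lte(o$alpha, 1)
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- cbind(t(R %*% t(seg[, 1:2])), t(R %*% t(seg[, 3:4])))
    o_rot <- orientation_tensor_2d(rot)
    dang <- (o_rot$angle - o$angle - th) %% pi
    expect_lt(min(dang, pi - dang), 1e-8)
    expect_equal(o_rot$alpha, o$alpha, tolerance = 1e-10)
  }
})
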