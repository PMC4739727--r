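test_that("mesh counts and spacings follow the grid formulae", {
  m <- build_mesh(46, 46, 4, 8, 8, 0.8)
  expect_identical(nrow(m$elems), 8464L)
  expect_identical(nrow(m$nodes), 11045L)
  expect_equal(m$hx, 8 / 46)
  m1 <- build_mesh(1, 1, 1, 1, 1, 1)
  expect_identical(nrow(m1$elems), 1L)
  expect_identical(nrow(m1$nodes), 8L)
  for (s in 1:5) {
    set.seed(s)
    n <- sample(1:6, 3, replace = TRUE)
    mm <- build_mesh(n[1], n[2], n[3], 2, 3, 1)
    expect_identical(nrow(mm$elems), as.integer(prod(n)))
    expect_identical(nrow(mm$nodes), as.integer(prod(n + 1L)))
  }
  expect_error(build_mesh(0, 1, 1), "nx")
})

test_that("default explant layout reproduces the target geometry", {
  m <- build_mesh(46, 46, 4, 8, 8, 0.8)
  lab <- assign_domains(m)
  expect_identical(sum(lab$label == "cellular"), 48L)
  expect_equal(lab$patch_area, 0.484, tolerance = 1e-3)
  d <- centroid_distances(lab)
  expect_equal(unname(d[1]), 2.09, tolerance = 3e-3)
  expect_equal(unname(d[2]), 2.03, tolerance = 2e-3)
  expect_equal(unname(d[3]), 2.03, tolerance = 2e-3)
  # patches all in the top element layer and disjoint
  ktop <- m$nz - 1L
  expect_true(all(m$elem_grid[unlist(lab$patches), "k"] == ktop))
  expect_identical(length(unique(unlist(lab$patches))), 48L)
  expect_error(assign_domains(m, size = 4, dx_top = 2),
               "overlap")
})

test_that("RVE bookkeeping counts 8 networks per element on the full mesh", {
  m <- build_mesh(46, 46, 4, 8, 8, 0.8)
  expect_identical(count_rves(m, 8), 67712L)
  expect_identical(count_rves(m, 1), 8464L)
})

test_that("boundary conditions pick the prescribed node sets", {
  m <- build_mesh(8, 8, 2, 8, 8, 0.8)
  fx <- boundary_condition(m, "fixed")
  nd <- m$nodes[fx$fixed_nodes, ]
  # every fixed node on bottom or a lateral face; the top interior is free
  expect_true(all(nd[, 3] < 1e-9 | nd[, 1] < 1e-9 | nd[, 1] > 8 - 1e-9 |
                    nd[, 2] < 1e-9 | nd[, 2] > 8 - 1e-9))
  top_center <- which(m$nodes[, 3] > 0.8 - 1e-9 &
                        abs(m$nodes[, 1] - 4) < 1 & abs(m$nodes[, 2] - 4) < 1)
  expect_false(any(top_center %in% fx$fixed_nodes))
  fr <- boundary_condition(m, "free", anchor = 1.74)
  nd2 <- m$nodes[fr$fixed_nodes, , drop = FALSE]
  expect_true(all(nd2[, 3] < 1e-9))
  expect_true(all(abs(nd2[, 1] - 4) <= 0.87 + 1e-6))
  expect_true(all(abs(nd2[, 2] - 4) <= 0.87 + 1e-6))
})

test_that("neo-Hookean stress matches closed-form shear and dilation", {
  cm <- continuum_material(G = 1, nu = 0.3)
  expect_equal(neo_hookean_stress(diag(3), cm), matrix(0, 3, 3))
  # simple shear gamma = 0.1: J = 1, B - I has s12 = gamma, s11 = gamma^2
  Fs <- diag(3); Fs[1, 2] <- 0.1
  s <- neo_hookean_stress(Fs, cm)
  expect_equal(s[1, 2], 0.1)
  expect_equal(s[1, 1], 0.01)
  expect_equal(s[2, 2], 0)
  # pure dilation lambda = 1.01: closed-form evaluation gives 0.0630 Pa
  sdil <- neo_hookean_stress(diag(3) * 1.01, cm)
  expect_equal(sdil[1, 1], 0.0630, tolerance = 1e-3)
  expect_equal(sdil[1, 1], sdil[2, 2])
  expect_lt(max(abs(sdil[upper.tri(sdil)])), 1e-15)
  expect_error(neo_hookean_stress(-diag(3), cm), "inverted")
})

test_that("zero compaction leaves the gel exactly at rest", {
  cfg <- compaction_config(nx = 3, ny = 3, nz = 1, explant_size = 1,
                           explant_dx_top = 2,
                           explant_bottom_offset = c(1, 1),
                           target_fibers = 30, n_increments = 0, seed = 5)
  r <- run_compaction(cfg)
  expect_equal(max(abs(r$fields$u)), 0)
  expect_equal(r$history$area_ratio, 1)
  expect_equal(r$history$dist_ratio, 1)
  expect_equal(max(abs(r$fields$delta_alpha)), 0)
})

test_that("single-element macro stress equals standalone RVE average plus continuum term", {
  # linear-limit fibers; prescribe an affine stretch on all 8 nodes and
  # compare the element residual path against the two independent pieces
  mesh <- build_mesh(1, 1, 1, 1, 1, 1)
  net <- generate_network(4, target_fibers = 40)
  net_mat <- network_material(B = 0)
  cont_mat <- continuum_material()
  Fm <- diag(3) + matrix(c(0.02, 0.005, 0, 0.005, -0.01, 0, 0, 0, 0.004),
                         3, 3)
  rve_edge <- 2e-5
  # path 1: element machinery
  rv <- list(net = net, pos = net$node_positions,
             L0 = net$reference_lengths)
  pr <- fibrogel:::rve_stress_provider(rv, Fm, net_mat, rve_edge,
                                       want_tangent = FALSE)
  # path 2: standalone solve + volume average at deformed volume J*V
  ctr <- matrix(rep(c(0.5, 0.5, 0.5), nrow(net$node_positions)),
                ncol = 3, byrow = TRUE)
  bd_all <- t(Fm %*% t(net$node_positions - ctr)) + ctr - net$node_positions
  sol <- solve_equilibrium(net, bd_all[net$boundary, ], net_mat,
                           tol = 1e-8 * net_mat$EfAf, max_iter = 100)
  S2 <- volume_avg_stress(sol, net, volume = det(Fm) * net$volume,
                          rve_edge = rve_edge)
  expect_equal(unclass(pr$stress), unclass(S2), tolerance = 1e-6,
               ignore_attr = TRUE)
  # the continuum term is additive on top of the network stress
  total <- pr$stress + neo_hookean_stress(Fm, cont_mat)
  expect_equal(total - pr$stress, neo_hookean_stress(Fm, cont_mat))
})

test_that("global reactions balance under Fixed boundary conditions", {
  cfg <- compaction_config(nx = 4, ny = 4, nz = 1, explant_size = 1,
                           explant_dx_top = 2,
                           explant_bottom_offset = c(1, 1),
                           target_fibers = 40, n_increments = 2,
                           total_shortening = 0.12, bc_case = "fixed",
                           seed = 3)
  r <- run_compaction(cfg)
  # internal forces over all nodes sum to zero, so the reaction sum equals
  # minus the (converged) free-node residual sum: small on the scale of
  # the O(0.1 Pa mm^2) internal forces
  reac <- r$logs[[length(r$logs)]]$reactions
  expect_lt(max(abs(colSums(reac))), 1e-3)
  # explant area decreases monotonically with compaction
  expect_true(all(diff(r$history$area_ratio) < 0))
  # displacement and fields are finite and deterministic for a fixed seed
  r2 <- run_compaction(cfg)
  expect_equal(r2$history, r$history, tolerance = 1e-12)
  expect_equal(r2$fields$u, r$fields$u, tolerance = 1e-12)
})

test_that("element region classification separates axial and far field", {
  m <- build_mesh(12, 12, 1, 8, 8, 0.8)
  lab <- assign_domains(m, 1, 4, c(2, 3))
  reg <- classify_elements(m, lab)
  expect_identical(levels(reg), c("cellular", "adjacent", "axial", "far"))
  expect_identical(sum(reg == "cellular"), 3L)
  expect_gt(sum(reg == "axial"), 0)
  expect_gt(sum(reg == "far"), 0)
  # corners are far field
  eg <- m$elem_grid
  corner <- which(eg[, "i"] == 0 & eg[, "j"] == 0)
  expect_identical(as.character(reg[corner]), "far")
})

test_that("compaction exports write valid VTK, CSV and config files", {
  cfg <- compaction_config(nx = 3, ny = 3, nz = 1, explant_size = 1,
                           explant_dx_top = 2,
                           explant_bottom_offset = c(1, 1),
                           target_fibers = 30, n_increments = 1,
                           total_shortening = 0.05, seed = 5)
  r <- run_compaction(cfg)
  out <- file.path(tempdir(), "export-test")
  export_compaction(r, out)
  vtk <- readLines(file.path(out, "fields.vtk"))
  expect_identical(vtk[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 32 double$", vtk)))
  expect_true(any(grepl("^CELLS 9 81$", vtk)))
  expect_true(any(grepl("VECTORS displacement", vtk)))
  expect_true(any(grepl("SCALARS delta_alpha", vtk)))
  hist <- read.csv(file.path(out, "history.csv"))
  expect_identical(nrow(hist), 2L)
  cfg_back <- jsonlite::read_json(file.path(out, "config.json"))
  expect_identical(cfg_back$seed, 5L)
  unlink(out, recursive = TRUE)
})
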