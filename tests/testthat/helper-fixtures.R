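# hand-built miniature networks used across test files

# one fiber along x split by an interior node at 0.4
toy_split_fiber <- function() {
  structure(list(
    node_positions = matrix(c(0, 0.5, 0.5,
                              0.4, 0.5, 0.5,
                              1, 0.5, 0.5), 3, 3, byrow = TRUE),
    fibers = cbind(c(1L, 2L), c(2L, 3L)),
    reference_lengths = c(0.4, 0.6),
    boundary = c(TRUE, FALSE, TRUE),
    volume = 1), class = "fiber_network")
}

# single fiber spanning the cube along x (two boundary nodes)
toy_single_fiber <- function() {
  structure(list(
    node_positions = matrix(c(0, 0.5, 0.5,
                              1, 0.5, 0.5), 2, 3, byrow = TRUE),
    fibers = cbind(1L, 2L),
    reference_lengths = 1,
    boundary = c(TRUE, TRUE),
    volume = 1), class = "fiber_network")
}

# 5 nodes, 6 fibers, one interior node — small enough for an independent
# energy-minimization oracle
toy_five_node <- function() {
  pos <- matrix(c(0, 0, 0,
                  1, 0, 0,
                  0, 1, 0,
                  0, 0, 1,
                  0.4, 0.3, 0.3), 5, 3, byrow = TRUE)
  fib <- rbind(c(1L, 5L), c(2L, 5L), c(3L, 5L), c(4L, 5L),
               c(1L, 2L), c(3L, 4L))
  L0 <- sqrt(rowSums((pos[fib[, 2], ] - pos[fib[, 1], ])^2))
  structure(list(node_positions = pos, fibers = fib,
                 reference_lengths = L0,
                 boundary = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                 volume = 1), class = "fiber_network")
}

# plain-R re-statement of the volume-average stress sum, written before the
# solver path and kept independent of it
oracle_volume_avg_stress <- function(positions, boundary, forces, volume) {
  S <- matrix(0, 3, 3)
  bidx <- which(boundary)
  for (k in seq_along(bidx)) {
    x <- positions[bidx[k], ]
    f <- forces[k, ]
    for (i in 1:3) for (j in 1:3) S[i, j] <- S[i, j] + x[i] * f[j]
  }
  S / volume
}

# independent total-elastic-energy of a network state: R quadrature of the
# fiber law, no reuse of the solver's energy code
oracle_network_energy <- function(net, positions, material) {
  tot <- 0
  for (k in seq_len(nrow(net$fibers))) {
    d <- positions[net$fibers[k, 2], ] - positions[net$fibers[k, 1], ]
    lam <- sqrt(sum(d^2)) / net$reference_lengths[k]
    W <- stats::integrate(function(s) fiber_force(s, material), 1, lam,
                          rel.tol = 1e-13)$value
    tot <- tot + W * net$reference_lengths[k]
  }
  tot
}

# energy minimization over interior nodes: BFGS start + damped Newton
# polish on central-difference derivatives of the oracle energy
oracle_equilibrium <- function(net, boundary_displacements, material) {
  bidx <- which(net$boundary)
  iidx <- which(!net$boundary)
  fixed <- net$node_positions
  fixed[bidx, ] <- fixed[bidx, ] + boundary_displacements
  en <- function(x) {
    p <- fixed
    p[iidx, ] <- matrix(x, ncol = 3)
    oracle_network_energy(net, p, material)
  }
  x <- as.vector(net$node_positions[iidx, , drop = FALSE])
  x <- stats::optim(x, en, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 500,
                                   ndeps = rep(1e-7, length(x))))$par
  h <- 1e-6
  gr <- function(x) vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (en(x + e) - en(x - e)) / (2 * h)
  }, numeric(1))
  for (it in 1:12) {
    g <- gr(x)
    if (max(abs(g)) < 1e-22) break
    H <- vapply(seq_along(x), function(i) {
      e <- numeric(length(x)); e[i] <- h
      (gr(x + e) - gr(x - e)) / (2 * h)
    }, numeric(length(x)))
    H <- 0.5 * (H + t(H))
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(H)))
    x <- x - step
  }
  p <- fixed
  p[iidx, ] <- matrix(x, ncol = 3)
  p
}

# desk-scale compaction runs shared by ordering tests (computed once)
desk_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- list(
        fixed = run_compaction(preset_config("paper-fixed", "desk", seed = 11)),
        free = run_compaction(preset_config("paper-free", "desk", seed = 11)))
    cache
  }
})
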