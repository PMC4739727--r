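#' Fiber constitutive parameters
#'
#' Parameters of the exponential fiber force law
#' \deqn{F(\lambda) = \frac{E_f A_f}{B}\left[\exp(B\,\varepsilon_f) - 1\right],
#'   \qquad \varepsilon_f = \tfrac{1}{2}(\lambda^2 - 1)}
#' where \eqn{E_f} reduces to a Young's modulus at small strain, \eqn{A_f} is
#' the fiber cross-section and \eqn{B} controls the strain-stiffening
#' nonlinearity. The defaults are the values fitted to a uniaxial test of a
#' 6.8 mg/mL fibrin gel.
#'
#' @param EfAf Product of fiber modulus and cross-sectional area, in N.
#' @param B Dimensionless nonlinearity parameter; `B -> 0` recovers the
#'   linear law `EfAf * eps`.
#' @return An object of class `network_material`.
#' @export
network_material <- function(EfAf = 3e-10, B = 4) {
  stopifnot(is.numeric(EfAf), length(EfAf) == 1, EfAf > 0,
            is.numeric(B), length(B) == 1, B >= 0)
  structure(list(EfAf = EfAf, B = B), class = "network_material")
}

#' Axial force carried by a fiber at a given stretch
#'
#' Evaluates the exponential fiber law (see [network_material()]) at stretch
#' ratio `lambda`. Values below 1 give compressive (negative) force; the law
#' is used as-is with no buckling cutoff. A series branch at `B < 1e-8`
#' avoids the 0/0 limit.
#'
#' @param lambda Stretch ratio(s), current length / reference length; > 0.
#' @param material A [network_material()].
#' @return Force in N, same length as `lambda`. Strictly increasing in
#'   `lambda`, zero at `lambda = 1`.
#' @export
fiber_force <- function(lambda, material = network_material()) {
  if (!all(is.finite(lambda))) stop("non-finite stretch ratio 'lambda'")
  if (any(lambda <= 0)) stop("'lambda' must be > 0")
  eps <- 0.5 * (lambda^2 - 1)
  if (material$B < 1e-8) material$EfAf * eps
  else material$EfAf / material$B * (exp(material$B * eps) - 1)
}

# quasi-uniform directions: randomly rotated Fibonacci sphere point set.
# Near-perfect angular coverage keeps the generated networks close to
# isotropic even at ~100 segments, where iid sampling fluctuates visibly.
fibonacci_directions <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- 2 * pi * k * (1 - 1 / ((1 + sqrt(5)) / 2))
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  d %*% t(Q)
}

# clip the line p + t*d to the unit cube; p must be inside. Returns t range.
clip_to_cube <- function(p, d) {
  tmin <- -Inf; tmax <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-14) next
    t1 <- (0 - p[a]) / d[a]; t2 <- (1 - p[a]) / d[a]
    tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
  }
  c(tmin, tmax)
}

# closest-approach parameters (arc length along each segment) and distance
# between two segments given start points and unit directions; unclamped
# line-line solution (caller checks parameter interiority).
segment_closest <- function(p1, d1, p2, d2) {
  w <- p1 - p2
  b <- sum(d1 * d2)
  den <- 1 - b * b
  if (den < 1e-12) return(NULL) # near-parallel: no well-defined cross-link
  e <- sum(d1 * w); f <- sum(d2 * w)
  s <- (b * f - e) / den
  t <- (f - b * e) / den
  list(s = s, t = t,
       dist = sqrt(sum((p1 + s * d1 - p2 - t * d2)^2)))
}

#' Generate a cross-linked fiber network RVE
#'
#' Builds a nearly isotropic 3D fiber network in the unit cube. Straight
#' segments with quasi-uniform orientations are grown through uniformly
#' random interior points and clipped at the cube faces (creating boundary
#' nodes). Wherever two segments pass within `capture_radius` of one
#' another, a cross-link node is created at the midpoint of their mutual
#' perpendicular and both segments are split there. The resulting network
#' therefore has `n_segments + 2 * n_crosslinks` fibers and
#' `2 * n_segments + n_crosslinks` nodes; the defaults are calibrated so the
#' mean fiber count over seeds is approximately 337 (about 1,000 nodal
#' degrees of freedom).
#'
#' @param seed Integer seed; the network is a deterministic function of it.
#' @param target_fibers Desired mean fiber count; used to choose the segment
#'   count via the calibrated cross-link rate when `n_segments` is `NULL`.
#' @param capture_radius Cross-link capture distance, RVE-local units.
#' @param n_segments Number of seed segments; overrides `target_fibers`.
#' @param max_retries Retries (fresh substreams) if the network fails the
#'   percolation check (largest connected component touching all six faces).
#' @return An object of class `fiber_network` with fields `node_positions`
#'   (n x 3), `fibers` (m x 2, node indices), `reference_lengths` (m),
#'   `boundary` (logical n, TRUE for nodes on a cube face), `volume` (= 1),
#'   `seed`, and the generation parameters.
#' @export
generate_network <- function(seed, target_fibers = 337,
                             capture_radius = NULL, n_segments = NULL,
                             max_retries = 20) {
  # calibrated pair cross-link rate at the default capture radius (see the
  # methods vignette); E[fibers] = N + kappa * N * (N - 1)
  kappa_default <- list(radius = 0.02, kappa = 0.0259)
  if (is.null(capture_radius)) capture_radius <- kappa_default$radius
  if (is.null(n_segments)) {
    kap <- kappa_default$kappa * (capture_radius / kappa_default$radius)
    n_segments <- round((kap - 1 + sqrt((1 - kap)^2 + 4 * kap * target_fibers)) /
                          (2 * kap))
  }
  stopifnot(n_segments >= 2, capture_radius > 0)
  with_local_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      net <- build_network_once(n_segments, capture_radius)
      if (!is.null(net)) {
        net$seed <- as.integer(seed)
        net$params <- list(n_segments = n_segments,
                           capture_radius = capture_radius,
                           target_fibers = target_fibers)
        return(net)
      }
    }
    stop(sprintf(
      "network generation failed to percolate after %d attempts (seed %s)",
      max_retries, format(seed)))
  })
}

# one generation attempt; NULL if the percolation check fails
build_network_once <- function(n_segments, capture_radius) {
  N <- n_segments
  dirs <- fibonacci_directions(N)
  pts <- matrix(runif(3 * N), N, 3)
  e0 <- matrix(0, N, 3); e1 <- matrix(0, N, 3)
  len <- numeric(N)
  for (i in seq_len(N)) {
    tr <- clip_to_cube(pts[i, ], dirs[i, ])
    e0[i, ] <- pts[i, ] + tr[1] * dirs[i, ]
    e1[i, ] <- pts[i, ] + tr[2] * dirs[i, ]
    len[i] <- tr[2] - tr[1]
  }
  # pairwise closest approach; cross-link where distance < capture radius
  # and the contact is interior to both segments
  xnode <- list()  # crosslink node positions
  seg_hits <- vector("list", N) # per-segment list of (arclen, node id)
  nid <- 0L
  for (i in seq_len(N - 1L)) {
    for (j in seq.int(i + 1L, N)) {
      cl <- segment_closest(e0[i, ], dirs[i, ], e0[j, ], dirs[j, ])
      if (is.null(cl) || cl$dist >= capture_radius) next
      marg <- 1e-6
      if (cl$s <= marg || cl$s >= len[i] - marg) next
      if (cl$t <= marg || cl$t >= len[j] - marg) next
      m <- 0.5 * (e0[i, ] + cl$s * dirs[i, ] + e0[j, ] + cl$t * dirs[j, ])
      nid <- nid + 1L
      xnode[[nid]] <- m
      seg_hits[[i]] <- c(seg_hits[[i]], list(c(cl$s, nid)))
      seg_hits[[j]] <- c(seg_hits[[j]], list(c(cl$t, nid)))
    }
  }
  n_cross <- nid
  pos <- rbind(e0, e1,
               if (n_cross > 0) do.call(rbind, xnode) else NULL)
  boundary <- c(rep(TRUE, 2L * N), rep(FALSE, n_cross))
  fib_i <- integer(0); fib_j <- integer(0)
  for (i in seq_len(N)) {
    hits <- seg_hits[[i]]
    if (length(hits)) {
      hm <- do.call(rbind, hits)
      hm <- hm[order(hm[, 1]), , drop = FALSE]
      # drop cross-links landing at (numerically) the same arc position
      keep <- c(TRUE, diff(hm[, 1]) > 1e-9)
      hm <- hm[keep, , drop = FALSE]
      chain <- c(i, 2L * N + as.integer(hm[, 2]), N + i)
    } else {
      chain <- c(i, N + i)
    }
    fib_i <- c(fib_i, chain[-length(chain)])
    fib_j <- c(fib_j, chain[-1])
  }
  fibers <- cbind(fib_i, fib_j, deparse.level = 0)
  L0 <- sqrt(rowSums((pos[fibers[, 2], , drop = FALSE] -
                        pos[fibers[, 1], , drop = FALSE])^2))
  ok <- L0 > 1e-12
  fibers <- fibers[ok, , drop = FALSE]
  L0 <- L0[ok]
  # percolation check: some connected component must link two opposite
  # faces of the cube (load path across the RVE along at least one axis)
  comp <- graph_components(nrow(pos), fibers)
  tol <- 1e-9
  percolates <- FALSE
  for (cid in unique(comp)) {
    on_c <- comp == cid & boundary
    if (!any(on_c)) next
    for (a in 1:3) {
      if (any(on_c & pos[, a] < tol) && any(on_c & pos[, a] > 1 - tol)) {
        percolates <- TRUE
        break
      }
    }
    if (percolates) break
  }
  if (!percolates) return(NULL)
  net <- structure(list(node_positions = pos, fibers = fibers,
                        reference_lengths = L0, boundary = boundary,
                        volume = 1), class = "fiber_network")
  # near-isotropy quality gate on the 2D projection; only meaningful at
  # production network sizes (tiny test networks are anisotropic by
  # sampling alone)
  if (N >= 50 && orientation_tensor_2d(net)$alpha >= 0.15) return(NULL)
  net
}

# connected components by breadth-first search over an adjacency list
graph_components <- function(n_nodes, edges) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n_nodes)
  cur <- 0L
  for (start in seq_len(n_nodes)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf(
    "<fiber_network> %d fibers, %d nodes (%d boundary), seed %s\n",
    nrow(x$fibers), nrow(x$node_positions), sum(x$boundary),
    format(x$seed)))
  invisible(x)
}

#' Uniformly shorten fiber reference lengths
#'
#' Models incremental cell traction: every fiber's reference length is
#' multiplied by `1 - fraction`, leaving the topology and node positions
#' untouched. Successive calls compose multiplicatively.
#'
#' @param network A [generate_network()] result.
#' @param fraction Shortening fraction in `[0, 1)`; e.g. 0.24 for the full
#'   24% traction used for the explant simulations.
#' @return The network with scaled `reference_lengths`.
#' @export
shorten_reference_lengths <- function(network, fraction) {
  stopifnot(inherits(network, "fiber_network"))
  if (!is.numeric(fraction) || length(fraction) != 1 || !is.finite(fraction) ||
      fraction < 0 || fraction >= 1)
    stop("'fraction' must be a single value in [0, 1)")
  network$reference_lengths <- network$reference_lengths * (1 - fraction)
  network
}

#' Solve interior force balance of an RVE under prescribed boundary motion
#'
#' Newton iteration (with backtracking line search on the total fiber strain
#' energy) drives the net fiber force on every interior node to zero while
#' boundary nodes are held at their prescribed displaced positions.
#'
#' @param network A [generate_network()] result.
#' @param boundary_displacements Matrix (n_boundary x 3) of displacements, in
#'   RVE-local units, ordered as the boundary nodes appear in node order.
#' @param material A [network_material()].
#' @param tol Convergence tolerance on the max interior nodal force norm, in
#'   N. Defaults to `1e-6 * EfAf` so it scales with the force level of the
#'   material (absolute pN-scale forces make a fixed tolerance meaningless).
#' @param max_iter Maximum Newton iterations.
#' @param initial_positions Optional warm-start node positions (n x 3).
#' @param on_fail `"error"` (default) aborts with the residual history;
#'   `"return"` returns the unconverged solution with `converged = FALSE`.
#' @return An `rve_solution`: `deformed_positions` (n x 3),
#'   `boundary_forces` (n_boundary x 3, reaction forces in N),
#'   `residual_norm`, `converged`, `iterations`, `residual_history`.
#' @export
solve_equilibrium <- function(network, boundary_displacements,
                              material = network_material(),
                              tol = 1e-6 * material$EfAf, max_iter = 50,
                              initial_positions = NULL,
                              on_fail = c("error", "return")) {
  stopifnot(inherits(network, "fiber_network"))
  on_fail <- match.arg(on_fail)
  nb <- sum(network$boundary)
  bd <- as.matrix(boundary_displacements)
  if (nrow(bd) != nb || ncol(bd) != 3)
    stop(sprintf("'boundary_displacements' must be %d x 3", nb))
  bnd_pos <- network$node_positions[network$boundary, , drop = FALSE] + bd
  res <- cpp_rve_solve(network$node_positions, network$fibers,
                       network$reference_lengths, network$boundary,
                       bnd_pos, material$EfAf, material$B, tol, max_iter,
                       initial_positions)
  if (!res$converged && on_fail == "error")
    stop(sprintf(
      "RVE equilibrium did not converge (residual %.3e N after %d iterations; history: %s)",
      res$residual, res$iterations,
      paste(signif(res$residual_history, 3), collapse = " ")))
  structure(list(deformed_positions = res$pos,
                 boundary_forces = res$boundary_forces,
                 residual_norm = res$residual,
                 converged = res$converged,
                 iterations = res$iterations,
                 residual_history = res$residual_history,
                 energy = res$energy),
            class = "rve_solution")
}

#' Volume-averaged Cauchy stress of a solved RVE
#'
#' Computes the boundary-node sum
#' \deqn{\langle\sigma_{ij}\rangle = \frac{1}{V}\sum_{\mathrm{bnd}} x_i F_j}
#' over deformed boundary-node positions \eqn{x} and reaction forces
#' \eqn{F}. The raw sum is not exactly symmetric for a finite network; the
#' symmetric part is returned (Cauchy stress symmetry) with the asymmetry
#' norm attached as attribute `"asymmetry"`.
#'
#' @param solution An [solve_equilibrium()] result (must have converged).
#' @param network The network the solution belongs to.
#' @param volume Averaging volume in RVE-local units; defaults to the
#'   network's reference volume. Pass the deformed volume `J * V` when the
#'   boundary was displaced by a deformation gradient with `det != 1`.
#' @param rve_edge Physical edge length of the unit-cube RVE in meters; when
#'   given, the local-unit stress is converted to Pa by dividing by
#'   `rve_edge^2` (positions are in units of `rve_edge`, forces in N).
#' @return 3 x 3 symmetric stress tensor (RVE-local units, or Pa when
#'   `rve_edge` is supplied).
#' @export
volume_avg_stress <- function(solution, network, volume = network$volume,
                              rve_edge = NULL) {
  stopifnot(inherits(solution, "rve_solution"),
            inherits(network, "fiber_network"))
  if (!isTRUE(solution$converged))
    stop("volume averaging requires a converged solution")
  x <- solution$deformed_positions[network$boundary, , drop = FALSE]
  f <- solution$boundary_forces
  S <- crossprod(x, f) / volume
  if (!is.null(rve_edge)) S <- S / rve_edge^2
  sym <- 0.5 * (S + t(S))
  structure(sym, asymmetry = norm(0.5 * (S - t(S)), "F"))
}

#' Length-weighted 2D orientation tensor and alignment strength
#'
#' Projects fiber segments onto the gel (x-y) plane and forms
#' \deqn{\Omega = \frac{\sum_i l_i
#'   \begin{bmatrix}\cos^2\theta_i & \cos\theta_i\sin\theta_i\\
#'   \cos\theta_i\sin\theta_i & \sin^2\theta_i\end{bmatrix}}{\sum_i l_i}}
#' with \eqn{l_i} the projected length and \eqn{\theta_i} the in-plane
#' angle. The strength of alignment is \eqn{\alpha = 1 - \omega_1/\omega_2}
#' for eigenvalues \eqn{\omega_1 \le \omega_2}: 0 = isotropic, 1 = fully
#' aligned.
#'
#' @param fibers A `fiber_network` (reference geometry), or a matrix of
#'   segments with columns `x0, y0, x1, y1` (extra columns such as z are
#'   projected away), or a deformed-network pair via `positions`.
#' @param positions Optional n x 3 node positions overriding the network's
#'   reference positions (e.g. a deformed state).
#' @return An `orientation_result`: `Omega` (2 x 2, trace 1), `eigenvalues`
#'   `(w1, w2)`, `alpha`, `angle` (principal direction, radians mod pi).
#' @export
orientation_tensor_2d <- function(fibers, positions = NULL) {
  if (inherits(fibers, "fiber_network")) {
    pos <- if (is.null(positions)) fibers$node_positions else positions
    seg <- cbind(pos[fibers$fibers[, 1], 1:2, drop = FALSE],
                 pos[fibers$fibers[, 2], 1:2, drop = FALSE])
  } else {
    seg <- as.matrix(fibers)
    if (ncol(seg) == 6) seg <- seg[, c(1, 2, 4, 5), drop = FALSE]
    if (ncol(seg) != 4) stop("'fibers' must have columns x0, y0, x1, y1")
  }
  dx <- seg[, 3] - seg[, 1]
  dy <- seg[, 4] - seg[, 2]
  l <- sqrt(dx^2 + dy^2)
  keep <- l > 1e-14
  if (!any(keep)) stop("degenerate input: all fibers have zero projected length")
  dx <- dx[keep]; dy <- dy[keep]; l <- l[keep]
  c2 <- dx^2 / l; cs <- dx * dy / l; s2 <- dy^2 / l # l * cos^2 etc.
  W <- sum(l)
  Omega <- matrix(c(sum(c2), sum(cs), sum(cs), sum(s2)) / W, 2, 2)
  orientation_result(Omega)
}

# shared constructor: eigen-decompose a 2x2 orientation tensor
orientation_result <- function(Omega) {
  e <- eigen(Omega, symmetric = TRUE)
  w2 <- e$values[1]; w1 <- e$values[2]
  alpha <- if (w2 > 1e-300) 1 - max(w1, 0) / w2 else 0
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1]) %% pi
  structure(list(Omega = Omega, eigenvalues = c(w1 = w1, w2 = w2),
                 alpha = alpha, angle = ang),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("<orientation_result> alpha = %.3f, angle = %.1f deg\n",
              x$alpha, x$angle * 180 / pi))
  invisible(x)
}

#' Serialize a fiber network to hierarchical JSON
#'
#' The schema stores nodes, fibers, reference lengths, boundary flags, seed
#' and generation parameters under a `format` version tag, so networks can
#' be archived and re-read exactly.
#'
#' @param network A `fiber_network`.
#' @param path Output file path.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "fiber_network"))
  obj <- list(format = "fibrogel-network-1",
              seed = network$seed,
              params = network$params,
              volume = network$volume,
              node_positions = network$node_positions,
              boundary = network$boundary,
              fibers = network$fibers,
              reference_lengths = network$reference_lengths)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fibrogel-network-1"))
    stop("not a fibrogel network file")
  structure(list(node_positions = matrix(obj$node_positions,
                                         ncol = 3),
                 fibers = matrix(as.integer(obj$fibers), ncol = 2),
                 reference_lengths = as.numeric(obj$reference_lengths),
                 boundary = as.logical(obj$boundary),
                 volume = obj$volume,
                 seed = obj$seed,
                 params = obj$params),
            class = "fiber_network")
}

#' Export the fiber table as CSV for inspection
#'
#' One row per fiber: node indices, endpoint coordinates, reference length
#' and current (reference-geometry) length.
#'
#' @param network A `fiber_network`.
#' @param path Output CSV path.
#' @export
write_fiber_csv <- function(network, path) {
  p1 <- network$node_positions[network$fibers[, 1], , drop = FALSE]
  p2 <- network$node_positions[network$fibers[, 2], , drop = FALSE]
  df <- data.frame(node_i = network$fibers[, 1], node_j = network$fibers[, 2],
                   x0 = p1[, 1], y0 = p1[, 2], z0 = p1[, 3],
                   x1 = p2[, 1], y1 = p2[, 2], z1 = p2[, 3],
                   reference_length = network$reference_lengths,
                   length = sqrt(rowSums((p2 - p1)^2)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
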