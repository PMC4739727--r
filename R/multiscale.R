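# --- shape functions -------------------------------------------------------

# local node coordinates of the 8-node hexahedron (matches build_mesh order)
HEX_XI <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                   -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
                 8, 3, byrow = TRUE)

# reference-coordinate shape gradients at the 2x2x2 Gauss points and the
# centroid, for a regular element of spacings hx, hy, hz
hex_shape_grads <- function(hx, hy, hz) {
  gp1 <- 1 / sqrt(3)
  gps <- as.matrix(expand.grid(x = c(-gp1, gp1), y = c(-gp1, gp1),
                               z = c(-gp1, gp1)))
  grad_at <- function(xi) {
    g <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- HEX_XI[a, ]
      g[a, 1] <- 0.125 * s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3])
      g[a, 2] <- 0.125 * (1 + s[1] * xi[1]) * s[2] * (1 + s[3] * xi[3])
      g[a, 3] <- 0.125 * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) * s[3]
    }
    # chain rule to physical reference coords
    sweep(g, 2, c(2 / hx, 2 / hy, 2 / hz), "*")
  }
  list(gps = lapply(seq_len(8), function(q) grad_at(gps[q, ])),
       centroid = grad_at(c(0, 0, 0)),
       dV = hx * hy * hz / 8)
}

# --- RVE attachment --------------------------------------------------------

#' Number of RVE networks a simulation will carry
#'
#' Pure counting (no networks are built): `elements x rve_per_element`.
#' The full-scale mesh with 8 RVEs per element (one per Gauss point) carries
#' 67,712 networks.
#'
#' @param mesh A [build_mesh()] result.
#' @param rve_per_element 8 (one per Gauss point) or 1 (element centroid).
#' @return Integer count.
#' @export
count_rves <- function(mesh, rve_per_element = 8) {
  stopifnot(inherits(mesh, "hex_mesh"), rve_per_element %in% c(1L, 8L))
  nrow(mesh$elems) * as.integer(rve_per_element)
}

#' Attach fiber-network RVEs to every element of a mesh
#'
#' Each element receives `rve_per_element` independently seeded networks
#' (seed = `seed + rve index`). With 1 RVE per element the network supplies
#' the stress at the element centroid (full 2x2x2 quadrature is still used
#' for the continuum term); with 8, one network sits at each Gauss point.
#'
#' @param mesh,labels Mesh and [assign_domains()] partition.
#' @param rve_per_element 1 or 8.
#' @param target_fibers Mean fiber count per network (337 full scale).
#' @param seed Base seed.
#' @return A `multiscale_state` with zero displacement and zero compaction.
#' @export
attach_rves <- function(mesh, labels, rve_per_element = 8,
                        target_fibers = 337, seed = 1) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(labels, "domain_labels"),
            rve_per_element %in% c(1L, 8L))
  ne <- nrow(mesh$elems)
  k <- as.integer(rve_per_element)
  rves <- vector("list", ne)
  idx <- 0L
  for (e in seq_len(ne)) {
    rves[[e]] <- lapply(seq_len(k), function(q) {
      net <- generate_network(seed + idx + q - 1L,
                              target_fibers = target_fibers)
      list(net = net, pos = net$node_positions,
           L0 = net$reference_lengths)
    })
    idx <- idx + k
  }
  structure(list(mesh = mesh, labels = labels,
                 u = matrix(0, nrow(mesh$nodes), 3),
                 rves = rves, rve_per_element = k,
                 compaction = 0, seed = seed,
                 logs = list()),
            class = "multiscale_state")
}

#' @export
print.multiscale_state <- function(x, ...) {
  cat(sprintf(
    "<multiscale_state> %d elements, %d RVEs, compaction %.3f, max |u| %.4g mm\n",
    nrow(x$mesh$elems), length(x$rves) * x$rve_per_element, x$compaction,
    max(abs(x$u))))
  invisible(x)
}

# --- element-level mechanics ----------------------------------------------

RVE_CENTER <- c(0.5, 0.5, 0.5)

# solve one RVE under the affine map F and return exact network Cauchy
# stress (Pa), a linearized stress closure for stiffness FD, fiber forces
# and the updated warm-start positions
rve_stress_provider <- function(rve, Fm, net_mat, rve_edge, tol_rel = 1e-8,
                                fd_step = 1e-4, want_tangent = TRUE) {
  tol <- tol_rel * net_mat$EfAf
  res <- cpp_rve_affine(rve$net$node_positions, rve$net$fibers, rve$L0,
                        rve$net$boundary, Fm, RVE_CENTER,
                        net_mat$EfAf, net_mat$B, tol, 100L, rve$pos,
                        want_tangent, fd_step)
  if (!res$converged) # retry once from the reference configuration
    res <- cpp_rve_affine(rve$net$node_positions, rve$net$fibers, rve$L0,
                          rve$net$boundary, Fm, RVE_CENTER,
                          net_mat$EfAf, net_mat$B, tol, 100L, NULL,
                          want_tangent, fd_step)
  # mechanism (floppy) modes can stall Newton short of the absolute target;
  # a residual far below the fiber-force scale is still equilibrium for
  # upscaling purposes (stress error ~1e-4 Pa at the default RVE scale)
  accept <- max(1e-3 * max(abs(res$fiber_forces), 1e-30),
                3e-4 * net_mat$EfAf)
  if (!res$converged && res$residual > accept)
    stop(sprintf("RVE solve failed (residual %.3e N)", res$residual))
  s2 <- rve_edge^2
  sig <- function(S, J) {
    Ssym <- 0.5 * (S + t(S))
    Ssym / (J * s2)
  }
  J0 <- det(Fm)
  out <- list(stress = sig(res$S, J0), pos = res$pos,
              fiber_forces = res$fiber_forces,
              boundary_forces = res$boundary_forces,
              S_raw = res$S, F0 = Fm)
  if (want_tangent) {
    A <- res$tangent
    S0 <- res$S
    out$stress_lin <- function(F) {
      S <- S0 + matrix(A %*% as.vector(F - Fm), 3, 3)
      sig(S, det(F))
    }
  }
  out
}

# internal force vector (8 x 3) of one element.
# sigma_net: list(centroid = f(Fc) | NULL, gp = list of f(Fg))
element_internal_force <- function(ue, grads, sigma_net, cmat, elem_id = NA) {
  Fc0 <- diag(3) + crossprod(ue, grads$centroid)
  sigc <- if (!is.null(sigma_net$centroid)) sigma_net$centroid(Fc0) else NULL
  f <- matrix(0, 8, 3)
  for (q in 1:8) {
    Fg <- diag(3) + crossprod(ue, grads$gps[[q]])
    Jg <- det(Fg)
    if (!is.finite(Jg) || Jg <= 0)
      stop(sprintf("inverted element %s at Gauss point %d (J = %g)",
                   format(elem_id), q, Jg))
    sn <- if (is.null(sigc)) sigma_net$gp[[q]](Fg) else sigc
    sig <- sn + neo_hookean_stress(Fg, cmat)
    P <- Jg * sig %*% t(solve(Fg))
    f <- f + grads$gps[[q]] %*% t(P) * grads$dV
  }
  f
}

# Discrete estimator of the scale-coupling surface term
# (1/V) sum_b [F_j^b - <sig>_mj n_m A_b] (n^T H n): returns the 3-vector
# (local force units) and its size relative to the Eq-2 sum.
rve_coupling_term <- function(net, pos, bnd_forces, S_raw, H) {
  bidx <- which(net$boundary)
  X <- net$node_positions[bidx, , drop = FALSE]
  tolf <- 1e-9
  n_mat <- matrix(0, length(bidx), 3)
  area <- numeric(length(bidx))
  # outward unit normal (face average for edge/corner nodes); per-node area
  # = face area / nodes on that face
  for (a in 1:3) for (sgn in c(0, 1)) {
    on_face <- abs(X[, a] - sgn) < tolf
    if (!any(on_face)) next
    nrm <- c(0, 0, 0); nrm[a] <- if (sgn == 1) 1 else -1
    n_mat[on_face, ] <- n_mat[on_face, ] + rep(nrm, each = sum(on_face))
    area[on_face] <- area[on_face] + 1 / sum(on_face)
  }
  nn <- sqrt(rowSums(n_mat^2))
  n_mat <- n_mat / pmax(nn, 1e-12)
  sig_avg <- 0.5 * (S_raw + t(S_raw)) / net$volume
  proj <- rowSums((n_mat %*% H) * n_mat)  # n^T H n per node
  corr <- bnd_forces - (n_mat %*% sig_avg) * area
  q <- colSums(corr * proj) / net$volume
  list(q = q, rel = sqrt(sum(q^2)) / max(norm(S_raw, "F"), 1e-300))
}

# --- macro Newton solve ----------------------------------------------------

#' Solve macroscopic equilibrium of the coupled multi-scale model
#'
#' Newton iteration on the macro nodal displacements. At every iteration
#' each RVE is re-solved (warm-started) under the affine boundary map given
#' by the local deformation gradient; its symmetrized volume-averaged stress
#' plus the neo-Hookean term forms the element stress. The consistent
#' tangent uses finite differences of the element internal-force vector with
#' the network stress linearized around the converged RVE state.
#'
#' @param state A [attach_rves()] state (displacements are taken from and
#'   written back to it).
#' @param bc A [boundary_condition()].
#' @param net_mat,cont_mat Materials ([network_material()],
#'   [continuum_material()]).
#' @param rve_edge Physical RVE edge length in meters (stress scale).
#' @param tol_rel Relative drop of the max free-node residual required.
#' @param tol_abs Absolute residual floor (Pa mm^2).
#' @param max_iter Newton iteration cap.
#' @param coupling Include the discrete scale-coupling surface term as a
#'   body force (default `FALSE`; its relative magnitude is always logged).
#' @return The updated `multiscale_state` (converged displacements, logs).
#' @export
macro_solve <- function(state, bc, net_mat = network_material(),
                        cont_mat = continuum_material(), rve_edge = 2e-5,
                        tol_rel = 1e-4, tol_abs = 1e-6, max_iter = 40,
                        coupling = FALSE) {
  mesh <- state$mesh
  ne <- nrow(mesh$elems)
  nn <- nrow(mesh$nodes)
  grads <- hex_shape_grads(mesh$hx, mesh$hy, mesh$hz)
  free <- setdiff(seq_len(nn), bc$fixed_nodes)
  free_dof <- as.vector(t(outer(free, 1:3, function(n, c) 3 * (n - 1) + c)))
  fd_h <- 1e-7 * max(mesh$hx, mesh$hy, mesh$hz)
  per <- state$rve_per_element

  # warm: list (per element) of lists (per RVE) of node-position matrices;
  # returned updated so trial evaluations never corrupt accepted state
  assemble <- function(u, warm, build_K) {
    R <- matrix(0, nn, 3)
    trip_i <- trip_j <- trip_x <- vector("list", if (build_K) ne else 0)
    coup_rel <- numeric(0)
    for (e in seq_len(ne)) {
      conn <- mesh$elems[e, ]
      ue <- u[conn, , drop = FALSE]
      # exact network stress + linearization at current element state
      if (per == 1L) {
        Fc <- diag(3) + crossprod(ue, grads$centroid)
        rv <- state$rves[[e]][[1]]
        rv$pos <- warm[[e]][[1]]
        pr <- tryCatch(
          rve_stress_provider(rv, Fc, net_mat, rve_edge,
                              want_tangent = build_K),
          error = function(err) stop(sprintf("element %d, RVE 1: %s", e,
                                             conditionMessage(err))))
        warm[[e]][[1]] <- pr$pos
        sig0 <- pr$stress
        if (coupling) {
          ct <- rve_coupling_term(rv$net, pr$pos,
                                  pr$boundary_forces, pr$S_raw, Fc - diag(3))
          coup_rel <- c(coup_rel, ct$rel)
          # body-force contribution, converted to Pa/mm over the element
          qf <- ct$q / (det(Fc) * rve_edge^2) / max(mesh$hx, mesh$hy)
          R[conn, ] <- R[conn, ] -
            matrix(qf, 8, 3, byrow = TRUE) * grads$dV
        }
        sigma_exact <- list(centroid = function(F) sig0, gp = NULL)
        sigma_lin <- if (build_K) list(centroid = pr$stress_lin, gp = NULL)
      } else {
        prs <- lapply(seq_len(8L), function(q) {
          Fg <- diag(3) + crossprod(ue, grads$gps[[q]])
          rv <- state$rves[[e]][[q]]
          rv$pos <- warm[[e]][[q]]
          pr <- tryCatch(
            rve_stress_provider(rv, Fg, net_mat, rve_edge,
                                want_tangent = build_K),
            error = function(err) stop(sprintf("element %d, RVE %d: %s", e,
                                               q, conditionMessage(err))))
          warm[[e]][[q]] <<- pr$pos
          pr
        })
        sigma_exact <- list(centroid = NULL,
                            gp = lapply(prs, function(p) {
                              force(p); function(F) p$stress
                            }))
        sigma_lin <- if (build_K)
          list(centroid = NULL, gp = lapply(prs, function(p) p$stress_lin))
      }
      fe <- element_internal_force(ue, grads, sigma_exact, cont_mat, e)
      R[conn, ] <- R[conn, ] + fe
      if (build_K) {
        Ke <- matrix(0, 24, 24)
        for (col in seq_len(24)) {
          up <- ue
          up[(col - 1) %% 8 + 1, (col - 1) %/% 8 + 1] <-
            up[(col - 1) %% 8 + 1, (col - 1) %/% 8 + 1] + fd_h
          fp <- element_internal_force(up, grads, sigma_lin, cont_mat, e)
          Ke[, col] <- as.vector(fp - fe) / fd_h
        }
        # element DOF ordering: node-major rows (u1x..u8x, u1y.., u1z..)
        gdof <- c(3 * (conn - 1) + 1, 3 * (conn - 1) + 2, 3 * (conn - 1) + 3)
        # convert Ke (8x3 vec layout) to that ordering: as.vector stacks
        # column-wise, i.e. x components of 8 nodes, then y, then z -> same
        trip_i[[e]] <- rep(gdof, times = 24)
        trip_j[[e]] <- rep(gdof, each = 24)
        trip_x[[e]] <- as.vector(Ke)
      }
    }
    out <- list(R = R, coup_rel = coup_rel, warm = warm)
    if (build_K)
      out$K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                    x = unlist(trip_x),
                                    dims = c(3 * nn, 3 * nn))
    out
  }

  u <- state$u
  warm0 <- lapply(state$rves, function(el) lapply(el, function(rv) rv$pos))
  hist <- numeric(0)
  asm <- assemble(u, warm0, build_K = TRUE)
  r_free <- as.vector(t(asm$R))[free_dof]
  res0 <- max(abs(r_free))
  hist <- c(hist, res0)
  target <- max(tol_abs, tol_rel * res0)
  it <- 0
  while (max(abs(r_free)) > target && it < max_iter) {
    it <- it + 1
    Kff <- asm$K[free_dof, free_dof, drop = FALSE]
    du <- tryCatch(as.vector(Matrix::solve(Kff, -r_free)),
                   error = function(err)
                     stop(sprintf(
                       "macro tangent solve failed at iteration %d: %s",
                       it, conditionMessage(err))))
    # cap the step along soft (nearly rigid) modes: max nodal move per
    # iteration limited to a fraction of the element size
    mxmove <- max(sqrt(rowSums(matrix(du, ncol = 3, byrow = TRUE)^2)))
    lim <- 0.25 * min(mesh$hx, mesh$hy, mesh$hz)
    if (mxmove > lim) du <- du * lim / mxmove
    step <- 1
    repeat {
      u_try <- u
      uu <- as.vector(t(u_try))
      uu[free_dof] <- uu[free_dof] + step * du
      u_try <- matrix(uu, nn, 3, byrow = TRUE)
      asm_try <- tryCatch(assemble(u_try, asm$warm, build_K = TRUE),
                          error = function(err) NULL)
      if (!is.null(asm_try) && all(is.finite(asm_try$R))) {
        r_try <- as.vector(t(asm_try$R))[free_dof]
        if (max(abs(r_try)) < max(abs(r_free)) || step < 0.2) break
      }
      step <- step / 2
      if (step < 0.01)
        stop(sprintf(
          "macro Newton diverged (residual trace: %s); cut the compaction increment",
          paste(signif(hist, 3), collapse = " ")))
    }
    u <- u_try
    asm <- asm_try
    r_free <- as.vector(t(asm$R))[free_dof]
    hist <- c(hist, max(abs(r_free)))
  }
  if (max(abs(r_free)) > target)
    stop(sprintf(
      "macro Newton did not converge in %d iterations (residual trace: %s); cut the compaction increment",
      max_iter, paste(signif(hist, 3), collapse = " ")))
  state$u <- u
  for (e in seq_len(ne))
    for (q in seq_len(per))
      state$rves[[e]][[q]]$pos <- asm$warm[[e]][[q]]
  state$logs <- c(state$logs, list(list(
    residual_history = hist, iterations = it,
    reactions = asm$R[bc$fixed_nodes, , drop = FALSE],
    coupling_rel = if (length(asm$coup_rel)) stats::median(asm$coup_rel) else NA_real_)))
  state
}
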