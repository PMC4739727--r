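#' Configuration for a compaction simulation
#'
#' Collects the geometry, explant layout, materials, boundary case and
#' traction schedule of one run. See [preset_config()] for ready-made
#' configurations.
#'
#' @param nx,ny,nz,Lx,Ly,Lz Mesh resolution and gel dimensions (mm).
#' @param explant_size,explant_dx_top,explant_bottom_offset Explant layout
#'   in element units (see [assign_domains()]).
#' @param bc_case `"fixed"` or `"free"`.
#' @param anchor Free-case bottom anchor square side, mm.
#' @param EfAf,B Fiber law parameters (N, dimensionless).
#' @param G,nu Neo-Hookean parameters (Pa, dimensionless).
#' @param total_shortening Total cellular fiber reference-length reduction
#'   (0.24 = 24%).
#' @param n_increments Number of equal multiplicative shortening steps.
#' @param rve_per_element 1 or 8 RVEs per element.
#' @param target_fibers Mean fiber count per network.
#' @param rve_edge Physical RVE edge length, meters (stress scale).
#' @param seed Base seed for all network generation.
#' @param coupling Include the discrete scale-coupling surface term.
#' @return A `compaction_config` list.
#' @export
compaction_config <- function(nx = 12, ny = 12, nz = 1,
                              Lx = 8, Ly = 8, Lz = 0.8,
                              explant_size = 1, explant_dx_top = 4,
                              explant_bottom_offset = c(2, 3),
                              bc_case = c("fixed", "free"), anchor = 1.74,
                              EfAf = 3e-10, B = 4, G = 1, nu = 0.3,
                              total_shortening = 0.24, n_increments = 6,
                              rve_per_element = 1, target_fibers = 60,
                              rve_edge = 2e-5, seed = 1,
                              coupling = FALSE) {
  bc_case <- match.arg(bc_case)
  stopifnot(total_shortening >= 0, total_shortening < 1, n_increments >= 0)
  structure(as.list(environment()), class = "compaction_config")
}

#' Ready-made simulation configurations
#'
#' `paper-fixed` / `paper-free` encode the full-scale configuration
#' (46 x 46 x 4 mesh, three 4 x 4-element explants, 8 RVEs of ~337 fibers
#' per element = 67,712 networks, 24 x 1% shortening). `scale = "desk"`
#' swaps in a coarse configuration (12 x 12 x 1 mesh, single-element
#' explants, one ~60-fiber RVE per element, 6 shortening steps) that runs on
#' a laptop while preserving the qualitative mechanics.
#'
#' @param case `"paper-fixed"` or `"paper-free"`.
#' @param scale `"desk"`, `"full"`, or `"mini"` (a 4 x 4 x 1 smoke-test
#'   geometry for quick checks).
#' @param seed Base seed.
#' @return A [compaction_config()].
#' @export
preset_config <- function(case = c("paper-fixed", "paper-free"),
                          scale = c("desk", "full", "mini"), seed = 1) {
  case <- match.arg(case)
  scale <- match.arg(scale)
  bc <- if (case == "paper-fixed") "fixed" else "free"
  switch(scale,
         full = compaction_config(nx = 46, ny = 46, nz = 4,
                                  explant_size = 4, explant_dx_top = 12,
                                  explant_bottom_offset = c(6, 10),
                                  bc_case = bc, n_increments = 24,
                                  rve_per_element = 8, target_fibers = 337,
                                  seed = seed),
         desk = compaction_config(bc_case = bc, seed = seed),
         mini = compaction_config(nx = 4, ny = 4, nz = 1,
                                  explant_size = 1, explant_dx_top = 2,
                                  explant_bottom_offset = c(1, 1),
                                  bc_case = bc, n_increments = 3,
                                  target_fibers = 40, seed = seed))
}

#' Classify elements into explant-relative regions
#'
#' `cellular` = explant patches; `adjacent` = ECM elements whose in-plane
#' footprint touches a patch (Chebyshev distance <= 1 element);
#' `axial` = remaining ECM elements whose in-plane centroid lies within
#' `tube_halfwidth` of one of the three centroid-to-centroid segments
#' between explants; `far` = everything else.
#'
#' @param mesh,labels Mesh and domain partition.
#' @param tube_halfwidth Half-width of the axial corridor, mm; defaults to
#'   half the patch width plus half an element.
#' @return Factor of length `n_elements` with those four levels.
#' @export
classify_elements <- function(mesh, labels, tube_halfwidth = NULL) {
  if (is.null(tube_halfwidth))
    tube_halfwidth <- (labels$size * mesh$hx + mesh$hx) / 2
  eg <- mesh$elem_grid
  cen <- cbind((eg[, "i"] + 0.5) * mesh$hx, (eg[, "j"] + 0.5) * mesh$hy)
  out <- rep("far", nrow(eg))
  out[labels$label == "cellular"] <- "cellular"
  # adjacency by in-plane element-grid distance to any patch element
  pe <- unlist(labels$patches)
  pij <- eg[pe, c("i", "j"), drop = FALSE]
  for (e in which(out == "far")) {
    d <- pmax(abs(pij[, 1] - eg[e, "i"]), abs(pij[, 2] - eg[e, "j"]))
    if (min(d) <= 1) out[e] <- "adjacent"
  }
  # axial corridors between patch centroids
  segs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (e in which(out == "far")) {
    p <- cen[e, ]
    for (sg in segs) {
      a <- labels$centroids[sg[1], ]; b <- labels$centroids[sg[2], ]
      ab <- b - a
      t_ <- sum((p - a) * ab) / sum(ab^2)
      if (t_ < 0 || t_ > 1) next
      d <- sqrt(sum((a + t_ * ab - p)^2))
      if (d <= tube_halfwidth) { out[e] <- "axial"; break }
    }
  }
  factor(out, levels = c("cellular", "adjacent", "axial", "far"))
}

# deformed top-surface geometry of the explant patches: areas (mm^2) and
# centroids (mm). Top face of the build_mesh hexahedron = local nodes 5:8.
patch_geometry <- function(mesh, labels, u) {
  nodes <- mesh$nodes + u
  quad_area_centroid <- function(q) {
    # q: 4 x 3 corner coords; split into two triangles
    a1 <- 0.5 * sqrt(sum(pracma_cross(q[2, ] - q[1, ], q[3, ] - q[1, ])^2))
    a2 <- 0.5 * sqrt(sum(pracma_cross(q[3, ] - q[1, ], q[4, ] - q[1, ])^2))
    c1 <- colMeans(q[c(1, 2, 3), ]); c2 <- colMeans(q[c(1, 3, 4), ])
    list(area = a1 + a2,
         centroid = (a1 * c1 + a2 * c2) / max(a1 + a2, 1e-300))
  }
  areas <- numeric(3)
  cents <- matrix(0, 3, 3)
  for (p in 1:3) {
    tot <- 0; ac <- c(0, 0, 0)
    for (e in labels$patches[[p]]) {
      q <- nodes[mesh$elems[e, 5:8], , drop = FALSE]
      g <- quad_area_centroid(q)
      tot <- tot + g$area
      ac <- ac + g$area * g$centroid
    }
    areas[p] <- tot
    cents[p, ] <- ac / tot
  }
  list(areas = areas, centroids = cents)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# per-element alignment strength and mean fiber force from the warm RVE
# states of a multiscale state
element_network_stats <- function(state, net_mat) {
  ne <- nrow(state$mesh$elems)
  alpha <- numeric(ne)
  ffmean <- numeric(ne)
  for (e in seq_len(ne)) {
    al <- ff <- numeric(0)
    for (rv in state$rves[[e]]) {
      al <- c(al, orientation_tensor_2d(rv$net, positions = rv$pos)$alpha)
      lam <- fiber_stretches(rv)
      ff <- c(ff, fiber_force(lam, net_mat))
    }
    alpha[e] <- mean(al)
    ffmean[e] <- mean(ff)
  }
  list(alpha = alpha, fiber_force = ffmean)
}

fiber_stretches <- function(rv) {
  p <- rv$pos
  l <- sqrt(rowSums((p[rv$net$fibers[, 2], , drop = FALSE] -
                       p[rv$net$fibers[, 1], , drop = FALSE])^2))
  l / rv$L0
}

# nodes touching no cellular element
ecm_nodes <- function(mesh, labels) {
  cell_nodes <- unique(as.vector(mesh$elems[labels$label == "cellular", ]))
  setdiff(seq_len(nrow(mesh$nodes)), cell_nodes)
}

#' Run an explant compaction simulation
#'
#' Applies the total cellular fiber shortening over `n_increments` equal
#' multiplicative steps. After each step the coupled macro equilibrium is
#' re-solved and the explant geometry, displacement summaries and network
#' state are recorded.
#'
#' @param config A [compaction_config()] or [preset_config()].
#' @param verbose Print per-increment progress.
#' @return A `compaction_result`: `history` (per-increment data frame:
#'   compaction level, explant areas and area ratio, centroid distances and
#'   ratios, mean ECM nodal displacement, mean ECM fiber force),
#'   `fields` (per-element `alpha`, `alpha0`, `delta_alpha`,
#'   `fiber_force`; nodal displacement `u`), plus the mesh, labels, element
#'   `regions`, boundary condition, solver `logs` and the `config`.
#' @export
run_compaction <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "compaction_config"))
  mesh <- build_mesh(config$nx, config$ny, config$nz,
                     config$Lx, config$Ly, config$Lz)
  labels <- assign_domains(mesh, size = config$explant_size,
                           dx_top = config$explant_dx_top,
                           bottom_offset = config$explant_bottom_offset)
  bc <- boundary_condition(mesh, config$bc_case, config$anchor)
  net_mat <- network_material(config$EfAf, config$B)
  cont_mat <- continuum_material(config$G, config$nu)
  state <- attach_rves(mesh, labels, config$rve_per_element,
                       config$target_fibers, config$seed)
  regions <- classify_elements(mesh, labels)
  stats0 <- element_network_stats(state, net_mat)
  geo0 <- patch_geometry(mesh, labels, state$u)
  d0 <- centroid_distances(geo0$centroids)
  en <- ecm_nodes(mesh, labels)
  cellular <- which(labels$label == "cellular")

  record <- function(state, inc, level) {
    geo <- patch_geometry(mesh, labels, state$u)
    dd <- centroid_distances(geo$centroids)
    st <- element_network_stats(state, net_mat)
    data.frame(increment = inc, compaction = level,
               area1 = geo$areas[1], area2 = geo$areas[2],
               area3 = geo$areas[3],
               mean_area = mean(geo$areas),
               area_ratio = mean(geo$areas) / mean(geo0$areas),
               d12 = dd[1], d13 = dd[2], d23 = dd[3],
               dist_ratio = mean(dd / d0),
               mean_ecm_disp = mean(sqrt(rowSums(state$u[en, ]^2))),
               mean_ecm_fiber_force =
                 mean(st$fiber_force[labels$label == "ecm"]),
               row.names = NULL)
  }

  # apply one shortening fraction and re-solve; on solver failure the
  # increment is bisected (multiplicative halves) up to 4 levels deep
  advance <- function(state, frac, depth = 0) {
    st <- state
    for (e in cellular)
      for (q in seq_along(st$rves[[e]]))
        st$rves[[e]][[q]]$L0 <- st$rves[[e]][[q]]$L0 * (1 - frac)
    res <- tryCatch(macro_solve(st, bc, net_mat, cont_mat, config$rve_edge,
                                coupling = config$coupling),
                    error = function(err) err)
    if (!inherits(res, "error")) return(res)
    if (depth >= 4) stop(res)
    half <- 1 - sqrt(1 - frac)
    advance(advance(state, half, depth + 1), half, depth + 1)
  }

  history <- record(state, 0L, 0)
  if (config$n_increments > 0 && config$total_shortening > 0) {
    step <- 1 - (1 - config$total_shortening)^(1 / config$n_increments)
    for (inc in seq_len(config$n_increments)) {
      state <- advance(state, step)
      state$compaction <- 1 - (1 - config$total_shortening)^(inc / config$n_increments)
      history <- rbind(history, record(state, inc, state$compaction))
      if (verbose)
        message(sprintf(
          "increment %d/%d: compaction %.3f, area ratio %.3f, mean ECM |u| %.4f mm",
          inc, config$n_increments, state$compaction,
          history$area_ratio[nrow(history)],
          history$mean_ecm_disp[nrow(history)]))
    }
  }
  stats1 <- element_network_stats(state, net_mat)
  structure(list(history = history,
                 fields = list(u = state$u,
                               alpha = stats1$alpha,
                               alpha0 = stats0$alpha,
                               delta_alpha = stats1$alpha - stats0$alpha,
                               fiber_force = stats1$fiber_force),
                 mesh = mesh, labels = labels, regions = regions,
                 bc = bc, logs = state$logs, config = config,
                 state = state),
            class = "compaction_result")
}

#' @export
print.compaction_result <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<compaction_result> %s BC, compaction %.3f: area ratio %.3f, dist ratio %.3f, mean ECM |u| %.4f mm\n",
    x$bc$case, h$compaction, h$area_ratio, h$dist_ratio, h$mean_ecm_disp))
  invisible(x)
}
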