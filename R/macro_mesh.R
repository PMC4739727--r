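#' Build a regular trilinear hexahedral mesh
#'
#' Nodes are laid out on a regular `(nx+1) x (ny+1) x (nz+1)` grid over the
#' gel volume; elements use the standard 8-node hexahedron ordering (the
#' bottom face counter-clockwise, then the top face).
#'
#' @param nx,ny,nz Element counts along x, y, z.
#' @param Lx,Ly,Lz Physical dimensions in mm. The defaults are the cast-gel
#'   mold dimensions, 8 x 8 x 0.8 mm.
#' @return A `hex_mesh`: `nodes` (n x 3, mm), `elems` (ne x 8 node indices),
#'   the counts and dimensions, and element spacings `hx, hy, hz`.
#' @examples
#' m <- build_mesh(46, 46, 4)
#' nrow(m$elems)  # 8464
#' nrow(m$nodes)  # 11045
#' @export
build_mesh <- function(nx, ny, nz, Lx = 8, Ly = 8, Lz = 0.8) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, Lx > 0, Ly > 0, Lz > 0)
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  zs <- seq(0, Lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) 1L + i + (nx + 1L) * j + (nx + 1L) * (ny + 1L) * k
  eg <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  elems <- cbind(nid(eg$i,     eg$j,     eg$k),
                 nid(eg$i + 1L, eg$j,     eg$k),
                 nid(eg$i + 1L, eg$j + 1L, eg$k),
                 nid(eg$i,     eg$j + 1L, eg$k),
                 nid(eg$i,     eg$j,     eg$k + 1L),
                 nid(eg$i + 1L, eg$j,     eg$k + 1L),
                 nid(eg$i + 1L, eg$j + 1L, eg$k + 1L),
                 nid(eg$i,     eg$j + 1L, eg$k + 1L))
  structure(list(nodes = nodes, elems = elems,
                 elem_grid = as.matrix(eg),
                 nx = nx, ny = ny, nz = nz, Lx = Lx, Ly = Ly, Lz = Lz,
                 hx = Lx / nx, hy = Ly / ny, hz = Lz / nz),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d x %d x %d elements (%d), %d nodes, %g x %g x %g mm\n",
              x$nx, x$ny, x$nz, nrow(x$elems), nrow(x$nodes),
              x$Lx, x$Ly, x$Lz))
  invisible(x)
}

#' Partition the mesh into cellular (explant) and ECM domains
#'
#' Three square explant patches of `size x size` top-layer elements are
#' arranged as a triangle: two patches side by side (centroids `dx_top`
#' element widths apart) and one below, offset by `bottom_offset` element
#' widths from the left top patch. The triangle is centered in the mesh.
#' The full-scale defaults (`size = 4`, `dx_top = 12`,
#' `bottom_offset = c(6, 10)` on a 46 x 46 grid of an 8 mm gel) give patch
#' area 0.484 mm^2 and centroid-to-centroid distances 2.09 / 2.03 / 2.03 mm.
#'
#' @param mesh A [build_mesh()] result.
#' @param size Patch edge length in elements.
#' @param dx_top Horizontal centroid separation of the top pair, elements.
#' @param bottom_offset `(dx, dy)` of the bottom patch relative to the left
#'   top patch, elements (positive dy means below).
#' @return A `domain_labels`: `label` (per-element factor `cellular`/`ecm`),
#'   `patches` (list of element index vectors), `centroids` (3 x 2, mm),
#'   `patch_area` (mm^2, per patch, reference configuration).
#' @export
assign_domains <- function(mesh, size = 4, dx_top = 12,
                           bottom_offset = c(6, 10)) {
  stopifnot(inherits(mesh, "hex_mesh"))
  bx <- bottom_offset[1]; by <- bottom_offset[2]
  # patch origins (lower-left element column/row), before centering
  origins <- rbind(c(0, 0), c(dx_top, 0), c(bx, -by))
  xr <- range(c(origins[, 1], origins[, 1] + size))
  yr <- range(c(origins[, 2], origins[, 2] + size))
  shift <- c(floor((mesh$nx - diff(xr)) / 2) - xr[1],
             floor((mesh$ny - diff(yr)) / 2) - yr[1])
  origins <- sweep(origins, 2, shift, "+")
  if (any(origins < 0) || any(origins[, 1] + size > mesh$nx) ||
      any(origins[, 2] + size > mesh$ny))
    stop("explant layout does not fit inside the mesh top layer")
  ktop <- mesh$nz - 1L
  eg <- mesh$elem_grid
  patches <- lapply(seq_len(3), function(p) {
    ii <- origins[p, 1] + 0:(size - 1L)
    jj <- origins[p, 2] + 0:(size - 1L)
    which(eg[, "k"] == ktop & eg[, "i"] %in% ii & eg[, "j"] %in% jj)
  })
  if (length(unique(unlist(patches))) != 3L * size^2)
    stop("explant patches overlap")
  label <- rep("ecm", nrow(mesh$elems))
  label[unlist(patches)] <- "cellular"
  centroids <- t(vapply(seq_len(3), function(p)
    c((origins[p, 1] + size / 2) * mesh$hx,
      (origins[p, 2] + size / 2) * mesh$hy), numeric(2)))
  structure(list(label = factor(label, levels = c("cellular", "ecm")),
                 patches = patches, centroids = centroids,
                 patch_area = size^2 * mesh$hx * mesh$hy,
                 size = size, origins = origins),
            class = "domain_labels")
}

#' Pairwise centroid-to-centroid distances of the explant patches
#'
#' @param labels An [assign_domains()] result (or deformed centroids, 3 x 2
#'   or 3 x 3).
#' @return Numeric length 3: distances 1-2 (top pair), 1-3, 2-3, in mm.
#' @export
centroid_distances <- function(labels) {
  cen <- if (inherits(labels, "domain_labels")) labels$centroids else labels
  c(d12 = sqrt(sum((cen[1, ] - cen[2, ])^2)),
    d13 = sqrt(sum((cen[1, ] - cen[3, ])^2)),
    d23 = sqrt(sum((cen[2, ] - cen[3, ])^2)))
}

#' Gel boundary conditions: Fixed or Free
#'
#' *Fixed* models a gel left attached to its mold: all nodes on the bottom
#' and the four lateral faces are fully constrained and only the top surface
#' is free. *Free* models a gel released from the mold walls: only the
#' bottom-face nodes inside a centered anchor square (default 1.74 x 1.74
#' mm, the region that remains stuck to the glass) are constrained.
#'
#' @param mesh A [build_mesh()] result.
#' @param case `"fixed"` or `"free"`.
#' @param anchor Side length of the centered bottom anchor square for the
#'   Free case, mm.
#' @return A `boundary_condition`: `case`, `fixed_nodes` (indices, all three
#'   components constrained), `anchor`.
#' @export
boundary_condition <- function(mesh, case = c("fixed", "free"),
                               anchor = 1.74) {
  stopifnot(inherits(mesh, "hex_mesh"))
  case <- match.arg(case)
  tol <- 1e-9
  nd <- mesh$nodes
  if (case == "fixed") {
    fixed <- which(nd[, 3] < tol |
                     nd[, 1] < tol | nd[, 1] > mesh$Lx - tol |
                     nd[, 2] < tol | nd[, 2] > mesh$Ly - tol)
  } else {
    fixed <- which(nd[, 3] < tol &
                     abs(nd[, 1] - mesh$Lx / 2) <= anchor / 2 + tol &
                     abs(nd[, 2] - mesh$Ly / 2) <= anchor / 2 + tol)
  }
  if (!length(fixed)) stop("boundary condition fixes no nodes")
  structure(list(case = case, fixed_nodes = fixed, anchor = anchor),
            class = "boundary_condition")
}

#' Continuum (neo-Hookean) material parameters
#'
#' The additive compressible neo-Hookean stress limits distortion and
#' compressibility of the fiber networks. Defaults are the values fitted to
#' a uniaxial test of a 6.8 mg/mL fibrin gel.
#'
#' @param G Shear modulus, Pa.
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return A `continuum_material`.
#' @export
continuum_material <- function(G = 1, nu = 0.3) {
  stopifnot(G > 0, nu >= 0, nu < 0.5)
  structure(list(G = G, nu = nu), class = "continuum_material")
}

#' Compressible neo-Hookean Cauchy stress
#'
#' \deqn{\sigma^{nH} = \frac{G}{J}(B - I) +
#'   \frac{2 G \nu}{J(1 - 2\nu)} \ln(J)\, I}
#' with \eqn{B = F F^T} the left Cauchy-Green tensor and \eqn{J = \det F}.
#'
#' @param F 3 x 3 deformation gradient with `det(F) > 0`.
#' @param material A [continuum_material()].
#' @return 3 x 3 Cauchy stress, Pa.
#' @export
neo_hookean_stress <- function(F, material = continuum_material()) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("inverted element: det(F) = ", format(J))
  B <- F %*% t(F)
  G <- material$G; nu <- material$nu
  G / J * (B - diag(3)) + 2 * G * nu / (J * (1 - 2 * nu)) * log(J) * diag(3)
}
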