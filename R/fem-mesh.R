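#' Structured hexahedral cylinder mesh with a slanted top face
#'
#' Builds an 8-node hexahedral mesh of a cylinder by mapping a uniform
#' square grid onto the disk with the smooth elliptical (butterfly-style
#' single-block) map `x = xi * sqrt(1 - eta^2/2)`,
#' `y = eta * sqrt(1 - xi^2/2)`, which places all boundary nodes exactly on
#' the circle and keeps element Jacobians positive. A slight inclination of
#' the top face — specimens settle with slanted tops — is applied by scaling
#' each node's height linearly in z: `z -> z * (1 + tan(slant) * x / L0)`,
#' so the bottom face stays flat and the top-face height varies by
#' `D0 * tan(slant)` across the diameter.
#'
#' @param D0 Diameter (mm).
#' @param L0 Height (mm).
#' @param slant_deg Top-face inclination (degrees, in `[0, 10)`).
#' @param n_radial Elements across the radius (>= 1); the plane grid has
#'   `2 * n_radial` cells across the diameter.
#' @param n_axial Element layers through the height (>= 1).
#' @return An object of class `cylinder_mesh`: `nodes` (N x 3, mm),
#'   `elems` (E x 8 connectivity, bottom face counter-clockwise then top),
#'   `bottom`, `top` (boundary node index sets), plus the build parameters.
#' @examples
#' m <- build_cylinder_mesh(70, 65, slant_deg = 0, n_radial = 1, n_axial = 2)
#' nrow(m$elems)  # 8 elements
#' @export
build_cylinder_mesh <- function(D0, L0, slant_deg = 0, n_radial = 2,
                                n_axial = 2) {
  check_number(D0, "D0", positive = TRUE)
  check_number(L0, "L0", positive = TRUE)
  if (n_radial < 1 || n_axial < 1) abort("Resolutions must be >= 1.")
  if (slant_deg < 0 || slant_deg >= 10) abort("`slant_deg` must be in [0, 10).")
  R <- D0 / 2
  m <- 2L * as.integer(n_radial)          # plane cells across the diameter
  s <- seq(-1, 1, length.out = m + 1L)
  grid <- expand.grid(xi = s, eta = s)
  px <- grid$xi * sqrt(1 - grid$eta^2 / 2) * R
  py <- grid$eta * sqrt(1 - grid$xi^2 / 2) * R
  nz <- as.integer(n_axial)
  zs <- seq(0, L0, length.out = nz + 1L)
  npl <- (m + 1L)^2
  nodes <- cbind(
    x = rep(px, nz + 1L),
    y = rep(py, nz + 1L),
    z = rep(zs, each = npl)
  )
  if (slant_deg > 0) {
    nodes[, "z"] <- nodes[, "z"] * (1 + tan(slant_deg * pi / 180) * nodes[, "x"] / L0)
  }
  nid <- function(i, j, k) (k - 1L) * npl + (j - 1L) * (m + 1L) + i
  elems <- matrix(0L, nrow = m * m * nz, ncol = 8L)
  e <- 0L
  for (k in seq_len(nz)) {
    for (j in seq_len(m)) {
      for (i in seq_len(m)) {
        e <- e + 1L
        elems[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k),
                        nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                        nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                        nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
      }
    }
  }
  mesh <- structure(list(
    nodes = nodes, elems = elems,
    bottom = seq_len(npl),
    top = nz * npl + seq_len(npl),
    D0 = D0, L0 = L0, slant_deg = slant_deg,
    n_radial = as.integer(n_radial), n_axial = nz
  ), class = "cylinder_mesh")
  jmin <- min_jacobian(mesh)
  if (jmin <= 0) abort("Mesh build produced a non-positive element Jacobian.")
  mesh
}

#' @export
print.cylinder_mesh <- function(x, ...) {
  cat(sprintf(paste0("<cylinder_mesh> D0 = %g mm, L0 = %g mm, slant %g deg, ",
                     "%d nodes, %d hex elements\n"),
              x$D0, x$L0, x$slant_deg, nrow(x$nodes), nrow(x$elems)))
  invisible(x)
}

# Trilinear shape-function derivatives wrt (xi, eta, zeta) at a point;
# node order: bottom CCW then top. Returns 8 x 3.
hex_dshape <- function(xi, eta, zeta) {
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  cbind(
    sx * (1 + sy * eta) * (1 + sz * zeta),
    (1 + sx * xi) * sy * (1 + sz * zeta),
    (1 + sx * xi) * (1 + sy * eta) * sz
  ) / 8
}

# 2x2x2 Gauss points (weight 1 each) for the reference hex.
hex_gauss <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
}

# Per-element, per-quadrature-point reference gradients and weights:
# list of elements, each with G[[qp]] (8 x 3, d/dX) and w (detJ, weight 1).
precompute_quadrature <- function(mesh) {
  gp <- hex_gauss()
  dsh <- lapply(seq_len(nrow(gp)), function(q) {
    hex_dshape(gp[q, 1], gp[q, 2], gp[q, 3])
  })
  lapply(seq_len(nrow(mesh$elems)), function(e) {
    Xe <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    G <- vector("list", length(dsh))
    w <- numeric(length(dsh))
    for (q in seq_along(dsh)) {
      Jm <- t(Xe) %*% dsh[[q]]          # 3 x 3 reference Jacobian
      dj <- det(Jm)
      w[q] <- dj
      G[[q]] <- dsh[[q]] %*% solve(Jm)  # gradients wrt X
    }
    list(G = G, w = w)
  })
}

min_jacobian <- function(mesh) {
  quad <- precompute_quadrature(mesh)
  min(vapply(quad, function(el) min(el$w), numeric(1)))
}

#' Reference volume of a mesh by quadrature
#'
#' @param mesh A `cylinder_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  quad <- precompute_quadrature(mesh)
  sum(vapply(quad, function(el) sum(el$w), numeric(1)))
}

#' Reference cross-sectional area of the meshed disk
#'
#' The polygonal footprint of the discretised disk; for a coarse mesh this
#' is a few percent below `pi * D0^2 / 4` and is the exact reference area
#' of the homogeneous finite-element solution (use it when comparing the
#' solver against the closed-form uniaxial stress).
#'
#' @param mesh A `cylinder_mesh`.
#' @return Area in mm^2.
#' @export
mesh_cross_section_area <- function(mesh) {
  mesh_volume(mesh) / mean(mesh$nodes[mesh$top, "z"])
}
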