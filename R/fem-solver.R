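# --- element-level kernels ---------------------------------------------------

# Second Piola-Kirchhoff stress and tangent modulus (both in 3x3 / 9x9
# column-major matrix form) for the compressible Neo-Hookean energy
# w = c (tr C - 3 - ln det C) + d (sqrt(det C) - 1)^2, S = 2 dw/dC:
#   S  = 2c (I - C^-1) + 2d (J - 1) J C^-1,  J = sqrt(det C)
#   CC = 2 dS/dC = (4c - 4d(J-1)J) D + 2d(2J-1)J (C^-1 x C^-1),
# with D_IJKL = (Ci_IK Ci_JL + Ci_IL Ci_JK)/2.
nh_stress_tangent <- function(Cmat, params, want_tangent = TRUE) {
  detC <- det(Cmat)
  if (!is.finite(detC) || detC <= 0) return(NULL)  # inverted state
  J <- sqrt(detC)
  Ci <- solve(Cmat)
  S <- 2 * params$c * (diag(3) - Ci) + 2 * params$d * (J - 1) * J * Ci
  if (!want_tangent) return(list(S = S, J = J))
  tp <- c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L)   # transpose permutation
  M1 <- kronecker(Ci, Ci)
  D9 <- (M1 + M1[, tp]) / 2
  ci9 <- as.vector(Ci)
  CC9 <- (4 * params$c - 4 * params$d * (J - 1) * J) * D9 +
    2 * params$d * (2 * J - 1) * J * tcrossprod(ci9)
  list(S = S, J = J, CC9 = CC9)
}

# Internal force (8 x 3) of one element; Ue is nodal displacement 8 x 3.
# Returns NULL on element inversion (J <= 0 at any quadrature point).
element_internal_force <- function(Ue, elquad, params) {
  fint <- matrix(0, 8, 3)
  for (q in seq_along(elquad$G)) {
    G <- elquad$G[[q]]
    Fdef <- diag(3) + t(Ue) %*% G
    st <- nh_stress_tangent(crossprod(Fdef), params, want_tangent = FALSE)
    if (is.null(st)) return(NULL)
    P <- Fdef %*% st$S
    fint <- fint + (G %*% t(P)) * elquad$w[q]
  }
  fint
}

#' Internal force and consistent tangent of one hexahedral element
#'
#' Total-Lagrangian kernel used by [run_compression()], exposed for
#' verification: at zero displacement the internal force vanishes and the
#' tangent is the symmetric linear-elastic stiffness; at finite strain the
#' analytic tangent matches a finite difference of the residual.
#'
#' @param mesh A `cylinder_mesh`.
#' @param element Element index.
#' @param Ue 8 x 3 matrix of nodal displacements (mm).
#' @param params A [neo_hooke_params()] object.
#' @return A list with `fint` (8 x 3, N) and `K` (24 x 24, N/mm; dof order
#'   node-major x, y, z), or an error on element inversion.
#' @export
element_residual_and_tangent <- function(mesh, element, Ue, params) {
  params <- as_nh_params(params)
  elquad <- precompute_quadrature(mesh)[[element]]
  out <- element_force_stiffness(Ue, elquad, params)
  if (is.null(out)) abort("Element inversion: non-positive deformation Jacobian.")
  out
}

element_force_stiffness <- function(Ue, elquad, params) {
  fint <- matrix(0, 8, 3)
  K <- matrix(0, 24, 24)
  I3 <- diag(3)
  for (q in seq_along(elquad$G)) {
    G <- elquad$G[[q]]
    Fdef <- I3 + t(Ue) %*% G
    st <- nh_stress_tangent(crossprod(Fdef), params)
    if (is.null(st)) return(NULL)
    P <- Fdef %*% st$S
    fint <- fint + (G %*% t(P)) * elquad$w[q]
    # dP_iJ = A[(i,J),(k,L)] dF_kL with A = S (x) I + (I (x) F) CC (I (x) F)^T
    IF <- kronecker(I3, Fdef)
    A9 <- kronecker(st$S, I3) + IF %*% st$CC9 %*% t(IF)
    B <- kronecker(t(G), I3)       # 9 x 24, dof order node-major xyz
    K <- K + crossprod(B, A9 %*% B) * elquad$w[q]
  }
  list(fint = fint, K = K)
}

# --- contact -----------------------------------------------------------------

#' Rigid-stamp penalty contact forces
#'
#' For a horizontal rigid stamp at height `h`, every top-surface node whose
#' current height exceeds `h` penetrates by `g = z - h` and receives a
#' downward restoring force `kappa * g`; non-penetrating nodes are
#' untouched. The stamp reaction equals the sum of the contact forces.
#' Frictionless: only the vertical component is constrained.
#'
#' @param z_top Current heights of the top-surface nodes (mm).
#' @param h Stamp height (mm).
#' @param kappa Penalty stiffness per node (N/mm, > 0).
#' @return A list: `force` (vector of downward force magnitudes per top
#'   node, 0 where inactive), `active` (logical), `reaction` (N).
#' @export
apply_penalty_contact <- function(z_top, h, kappa) {
  check_number(kappa, "kappa", positive = TRUE)
  g <- pmax(0, z_top - h)
  f <- kappa * g
  list(force = f, active = g > 0, reaction = sum(f))
}

# --- solver ------------------------------------------------------------------

#' Simulate the compression test by nonlinear finite elements
#'
#' Total-Lagrangian hexahedral elements with the compressible Neo-Hookean
#' material, loaded by a rigid horizontal stamp descending from the highest
#' point of the (possibly slanted) top face. Contact is enforced by a node
#' penalty; each stamp increment is solved by Newton iteration on the free
#' degrees of freedom with automatic increment halving on failure. The
#' bottom face is fixed vertically; laterally it is frictionless with
#' minimal pinning of the in-plane rigid modes (default), which admits the
#' exact homogeneous uniaxial solution used for verification, or fully
#' clamped for qualitative barreling.
#'
#' @param mesh A [build_cylinder_mesh()] mesh.
#' @param params A [neo_hooke_params()] object.
#' @param u_max Total stamp travel (mm); default 30 % of `L0`.
#' @param n_steps Number of uniform stamp increments; default
#'   `ceiling(u_max / (L0 / 100))`.
#' @param penalty Penalty stiffness per node (N/mm); default
#'   `penalty_factor * E * A_node / L0` with `E` from
#'   [small_strain_moduli()] and `A_node` the tributary top area per node.
#' @param penalty_factor Dimensionless scale of the default penalty
#'   stiffness (default 1000).
#' @param tol Relative residual tolerance of the Newton loop (in
#'   `(0, 1e-2]`, default 1e-9).
#' @param max_iter Maximum Newton iterations per increment (default 30).
#' @param max_halvings Increment halvings before giving up (default 8).
#' @param bottom_bc `"frictionless"` (default) or `"clamped"`.
#' @return An object of class `fem_result`: tibble-friendly
#'   force-displacement history (`displacement` mm = stamp travel, `force`
#'   N = stamp reaction), final nodal displacement field `U`, per-element
#'   equivalent (von Mises) Cauchy stress `von_mises` (MPa) at the final
#'   state, the mesh, the per-increment contact node sets
#'   (`contact_history`), a convergence log, and the settings used.
#' @export
run_compression <- function(mesh, params, u_max = NULL, n_steps = NULL,
                            penalty = NULL, penalty_factor = 1000,
                            tol = 1e-9, max_iter = 30, max_halvings = 8,
                            bottom_bc = c("frictionless", "clamped")) {
  params <- as_nh_params(params)
  bottom_bc <- match.arg(bottom_bc)
  if (tol <= 0 || tol > 1e-2) abort("`tol` must lie in (0, 1e-2].")
  u_max <- u_max %||% (0.3 * mesh$L0)
  n_steps <- n_steps %||% ceiling(u_max / (mesh$L0 / 100))
  if (n_steps < 1) abort("`n_steps` must be >= 1.")

  nn <- nrow(mesh$nodes)
  quad <- precompute_quadrature(mesh)
  top <- mesh$top
  A_node <- mesh_cross_section_area(mesh) / length(top)
  if (is.null(penalty)) {
    E <- small_strain_moduli(params)$E
    penalty <- penalty_factor * E * A_node / mesh$L0
  }
  check_number(penalty, "penalty", positive = TRUE)

  # fixed dofs (dof = 3*(node-1) + comp, comp 1:3 = x,y,z)
  dof <- function(nodes, comp) 3L * (nodes - 1L) + comp
  fixed <- dof(mesh$bottom, 3L)
  if (bottom_bc == "clamped") {
    fixed <- c(dof(mesh$bottom, 1L), dof(mesh$bottom, 2L), fixed)
  } else {
    r <- sqrt(mesh$nodes[mesh$bottom, 1]^2 + mesh$nodes[mesh$bottom, 2]^2)
    centre <- mesh$bottom[which.min(r)]
    onx <- mesh$bottom[which.max(mesh$nodes[mesh$bottom, 1])]
    fixed <- c(fixed, dof(centre, 1L), dof(centre, 2L), dof(onx, 2L))
  }
  fixed <- sort(unique(fixed))
  free <- setdiff(seq_len(3L * nn), fixed)

  assemble <- function(U) {
    # U: nn x 3. Returns list(fint_vec, K) or NULL on element inversion.
    fint <- matrix(0, nn, 3)
    K <- matrix(0, 3L * nn, 3L * nn)
    for (e in seq_len(nrow(mesh$elems))) {
      en <- mesh$elems[e, ]
      out <- element_force_stiffness(U[en, , drop = FALSE], quad[[e]], params)
      if (is.null(out)) return(NULL)
      fint[en, ] <- fint[en, ] + out$fint
      edof <- as.vector(t(cbind(dof(en, 1L), dof(en, 2L), dof(en, 3L))))
      K[edof, edof] <- K[edof, edof] + out$K
    }
    list(fint = as.vector(t(fint)), K = K)
  }

  U <- matrix(0, nn, 3)
  h0 <- max(mesh$nodes[top, 3])
  travel_hist <- 0
  force_hist <- 0
  contact_hist <- list()
  log_rows <- list()
  travel <- 0
  step_size <- u_max / n_steps
  halvings <- 0
  partial <- FALSE

  while (travel < u_max - 1e-12) {
    dt <- min(step_size, u_max - travel)
    target <- travel + dt
    h <- h0 - target
    U_try <- U
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      sys <- assemble(U_try)
      if (is.null(sys)) break  # element inversion -> halve
      z_now <- mesh$nodes[top, 3] + U_try[top, 3]
      con <- apply_penalty_contact(z_now, h, penalty)
      Rvec <- sys$fint
      Rvec[dof(top, 3L)] <- Rvec[dof(top, 3L)] + con$force
      ref <- max(1, con$reaction)
      if (sqrt(sum(Rvec[free]^2)) < tol * ref) {
        converged <- TRUE
        break
      }
      K <- sys$K
      act <- top[con$active]
      if (length(act)) {
        iz <- dof(act, 3L)
        K[cbind(iz, iz)] <- K[cbind(iz, iz)] + penalty
      }
      du <- tryCatch(solve(K[free, free], -Rvec[free]),
                     error = function(e) NULL)
      if (is.null(du)) break
      Ut <- as.vector(t(U_try))
      Ut[free] <- Ut[free] + du
      U_try <- matrix(Ut, nn, 3, byrow = TRUE)
    }
    if (converged) {
      U <- U_try
      travel <- target
      z_now <- mesh$nodes[top, 3] + U[top, 3]
      con_final <- apply_penalty_contact(z_now, h, penalty)
      reaction <- con_final$reaction
      travel_hist <- c(travel_hist, travel)
      force_hist <- c(force_hist, reaction)
      contact_hist[[length(contact_hist) + 1L]] <- top[con_final$active]
      log_rows[[length(log_rows) + 1L]] <-
        tibble(travel = travel, iterations = iters, converged = TRUE,
               step = dt)
      halvings <- 0
    } else {
      halvings <- halvings + 1
      if (halvings > max_halvings) {
        warn(sprintf(paste0("Newton failed at stamp travel %.3f mm after %d ",
                            "halvings; returning the partial result."),
                     travel, max_halvings))
        partial <- TRUE
        break
      }
      step_size <- step_size / 2
    }
  }

  vm <- element_von_mises(mesh, quad, U, params)
  structure(list(
    displacement = travel_hist,
    force = force_hist,
    U = U,
    von_mises = vm,
    mesh = mesh,
    contact_history = contact_hist,
    convergence = list_rbind(log_rows),
    partial = partial,
    settings = list(penalty = penalty, tol = tol, n_steps = n_steps,
                    u_max = u_max, bottom_bc = bottom_bc,
                    params = params)
  ), class = "fem_result")
}

# Equivalent (von Mises) Cauchy stress per element, averaged over
# quadrature points; Cauchy stress from the push-forward (1/J) F S F^T.
element_von_mises <- function(mesh, quad, U, params) {
  vapply(seq_len(nrow(mesh$elems)), function(e) {
    en <- mesh$elems[e, ]
    Ue <- U[en, , drop = FALSE]
    vals <- vapply(seq_along(quad[[e]]$G), function(q) {
      G <- quad[[e]]$G[[q]]
      Fdef <- diag(3) + t(Ue) %*% G
      st <- nh_stress_tangent(crossprod(Fdef), params, want_tangent = FALSE)
      if (is.null(st)) return(NA_real_)
      sig <- Fdef %*% st$S %*% t(Fdef) / st$J
      dev <- sig - diag(3) * sum(diag(sig)) / 3
      sqrt(1.5 * sum(dev^2))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
}

#' @export
print.fem_result <- function(x, ...) {
  cat(sprintf(paste0("<fem_result> %d increments to %.2f mm travel, final ",
                     "reaction %.2f N%s\n"),
              length(x$displacement) - 1L, max(x$displacement),
              tail(x$force, 1), if (x$partial) " (PARTIAL)" else ""))
  invisible(x)
}

#' Tidy a finite-element result into its force-displacement table
#'
#' @param x A `fem_result`.
#' @param ... Unused.
#' @return A tibble with `displacement_mm` (stamp travel) and `force_N`.
#' @export
tidy.fem_result <- function(x, ...) {
  tibble(displacement_mm = x$displacement, force_N = x$force)
}

#' One-row summary of a finite-element run
#'
#' @inheritParams tidy.fem_result
#' @return A one-row tibble with travel, final reaction, increment count,
#'   total Newton iterations and the partial-result flag.
#' @export
glance.fem_result <- function(x, ...) {
  tibble(u_max = max(x$displacement), final_force = tail(x$force, 1),
         n_increments = length(x$displacement) - 1L,
         newton_iterations = sum(x$convergence$iterations),
         partial = x$partial)
}
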