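test_that("cylinder meshes have flat or correctly slanted tops and converging volume", {
  m <- build_cylinder_mesh(70, 65, slant_deg = 0, n_radial = 1, n_axial = 2)
  expect_equal(nrow(m$elems), 8)
  expect_true(all(abs(m$nodes[m$top, "z"] - 65) < 1e-12))
  # volume error (vs pi R^2 L) at least halves per refinement
  v_exact <- pi * 35^2 * 65
  errs <- vapply(c(1, 2, 4), function(nr) {
    abs(mesh_volume(build_cylinder_mesh(70, 65, 0, nr, 2)) - v_exact) / v_exact
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 2)
  expect_lt(errs[3], errs[2] / 2)
  expect_lt(errs[3], 0.01)
  # slanted top: height range across the face equals D0 * tan(slant)
  ms <- build_cylinder_mesh(70, 65, slant_deg = 2, n_radial = 2, n_axial = 2)
  topz <- ms$nodes[ms$top, "z"]
  expect_equal(max(topz) - min(topz), 70 * tan(2 * pi / 180), tolerance = 1e-9)
  expect_error(build_cylinder_mesh(70, 65, n_radial = 0), "Resolutions")
  expect_error(build_cylinder_mesh(70, 65, slant_deg = 15), "slant")
})

test_that("element kernel: zero state, tangent symmetry and finite-difference consistency", {
  m <- build_cylinder_mesh(70, 65, 0, 1, 1)
  p <- neo_hooke_params(0.05, 0.08)
  z <- element_residual_and_tangent(m, 1, matrix(0, 8, 3), p)
  expect_equal(max(abs(z$fint)), 0, tolerance = 1e-12)
  expect_lt(max(abs(z$K - t(z$K))), 1e-8 * max(abs(z$K)))
  # deformed state: analytic tangent vs central difference of the force
  set.seed(3)
  Ue <- matrix(rnorm(24, 0, 0.5), 8, 3)
  out <- element_residual_and_tangent(m, 1, Ue, p)
  expect_lt(max(abs(out$K - t(out$K))), 1e-8 * max(abs(out$K)))
  h <- 1e-5
  Kfd <- matrix(0, 24, 24)   # component-major dof order (matrix layout)
  for (j in 1:24) {
    node <- (j - 1) %% 8 + 1
    comp <- (j - 1) %/% 8 + 1
    Up <- Ue; Um <- Ue
    Up[node, comp] <- Up[node, comp] + h
    Um[node, comp] <- Um[node, comp] - h
    fp <- element_residual_and_tangent(m, 1, Up, p)$fint
    fm <- element_residual_and_tangent(m, 1, Um, p)$fint
    Kfd[, j] <- as.vector((fp - fm) / (2 * h))
  }
  # analytic K uses node-major (x, y, z per node) dof order
  perm <- vapply(1:24, function(i) {
    node <- (i - 1) %/% 3 + 1
    comp <- (i - 1) %% 3 + 1
    as.integer(8 * (comp - 1) + node)
  }, integer(1))
  expect_lt(max(abs(Kfd[perm, perm] - out$K)) / max(abs(out$K)), 1e-5)
})

test_that("rigid rotation of the reference produces no internal force (objectivity)", {
  m <- build_cylinder_mesh(70, 65, 0, 1, 1)
  p <- neo_hooke_params(0.05, 0.08)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  X <- m$nodes[m$elems[1, ], ]
  Ue <- X %*% t(R) - X
  out <- element_residual_and_tangent(m, 1, Ue, p)
  expect_lt(max(abs(out$fint)), 1e-9 * p$c * 70^2)
})

test_that("penalty contact is linear in penetration and inactive above the stamp", {
  con <- apply_penalty_contact(c(64, 65, 65.01), h = 66, kappa = 1e4)
  expect_equal(con$reaction, 0)
  expect_true(all(!con$active))
  con2 <- apply_penalty_contact(65.01, h = 65, kappa = 1e4)
  expect_equal(con2$force, 100, tolerance = 1e-9)
  expect_error(apply_penalty_contact(65, 64, kappa = -1), "kappa")
})

test_that("frictionless flat-stamp compression reproduces the closed-form uniaxial response", {
  p <- neo_hooke_params(0.05, 0.05)
  m <- build_cylinder_mesh(70, 65, 0, n_radial = 1, n_axial = 2)
  res <- run_compression(m, p, u_max = 0.3 * 65, n_steps = 30)
  expect_false(res$partial)
  expect_equal(res$force[1], 0)
  lam <- 1 - res$displacement[-1] / 65
  closed <- mesh_cross_section_area(m) * lam * abs(uniaxial_stress(lam, p))
  expect_lt(max(abs(res$force[-1] - closed) / closed), 0.02)
  # small-strain stiffness F/u vs E A / L0
  E <- small_strain_moduli(p)$E
  res2 <- run_compression(m, p, u_max = 0.01 * 65, n_steps = 2)
  k_fem <- utils::tail(res2$force, 1) / utils::tail(res2$displacement, 1)
  expect_lt(abs(k_fem - E * mesh_cross_section_area(m) / 65) /
              (E * mesh_cross_section_area(m) / 65), 0.03)
  # homogeneous state: equivalent stress spatially uniform
  vm <- res$von_mises
  expect_lt((max(vm) - min(vm)) / mean(vm), 0.01)
})

test_that("slanted tops engage a monotonically growing contact set", {
  p <- neo_hooke_params(0.08, 0.08)
  m <- build_cylinder_mesh(70, 65, slant_deg = 2, n_radial = 1, n_axial = 2)
  res <- run_compression(m, p, u_max = 6, n_steps = 12)
  sets <- res$contact_history
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
  }
  expect_gt(length(sets[[length(sets)]]), length(sets[[1]]))
})

test_that("the discretisation is converged at the nominal-stress level on refinement", {
  p <- neo_hooke_params(0.08, 0.08)
  m1 <- build_cylinder_mesh(70, 65, 2, n_radial = 1, n_axial = 2)
  m2 <- build_cylinder_mesh(70, 65, 2, n_radial = 2, n_axial = 4)
  r1 <- run_compression(m1, p, u_max = 0.2 * 65, n_steps = 20)
  r2 <- run_compression(m2, p, u_max = 0.2 * 65, n_steps = 20)
  s1 <- utils::tail(r1$force, 1) / mesh_cross_section_area(m1)
  s2 <- utils::tail(r2$force, 1) / mesh_cross_section_area(m2)
  expect_lt(abs(s1 - s2) / s2, 0.02)
})

test_that("VTK export round-trips mesh, displacement field and stress names", {
  p <- neo_hooke_params(0.05, 0.05)
  m <- build_cylinder_mesh(70, 65, 0, 1, 1)
  res <- run_compression(m, p, u_max = 2, n_steps = 2)
  base <- file.path(tempdir(), "fem_out")
  files <- export_fields(res, base)
  back <- read_vtk(files[["vtk"]])
  expect_equal(nrow(back$points), nrow(m$nodes))
  expect_equal(nrow(back$cells), nrow(m$elems))
  expect_equal(back$cells, unname(m$elems))
  expect_named(back$point_vectors, "displacement")
  expect_named(back$cell_scalars, "von_mises")
  expect_equal(back$point_vectors$displacement, unname(res$U),
               tolerance = 1e-9)
  fd <- read.csv(files[["csv"]])
  expect_equal(fd$force_N, res$force, tolerance = 1e-9)
  # zero-state export carries zero fields
  res0 <- run_compression(m, p, u_max = 1e-9, n_steps = 1)
  f0 <- export_fields(res0, file.path(tempdir(), "fem_zero"))
  b0 <- read_vtk(f0[["vtk"]])
  expect_lt(max(abs(b0$point_vectors$displacement)), 1e-6)
  unlink(c(files, f0))
})
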