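test_that("strain energy vanishes at identity, matches hand substitution and is symmetric", {
  p <- neo_hooke_params(1, 1)
  expect_equal(strain_energy(1, 1, 1, p), 0)
  # (2,1,1), c = d = 1: 1*(4+1+1-3-2 ln 2) + 1*(2-1)^2 = 4 - 2 ln 2
  expect_equal(strain_energy(2, 1, 1, p), 4 - 2 * log(2), tolerance = 1e-12)
  q <- neo_hooke_params(0.3, 0.7)
  expect_equal(strain_energy(0.8, 1.1, 0.9, q),
               strain_energy(1.1, 0.8, 0.9, q), tolerance = 1e-14)
  expect_error(strain_energy(-1, 1, 1, p), "stretches")
  # non-negativity over a sampled stretch domain
  grid <- expand.grid(l1 = seq(0.5, 1.5, 0.25), l2 = seq(0.5, 1.5, 0.25),
                      l3 = seq(0.5, 1.5, 0.25))
  expect_true(all(strain_energy(grid$l1, grid$l2, grid$l3, q) >= 0))
})

test_that("lateral solution gives the positive quadratic root, psi(1) = 2, incompressible limit", {
  p <- neo_hooke_params(0.07, 0.07)
  ls1 <- lateral_solution(1, p)
  expect_equal(ls1$J, 1, tolerance = 1e-14)
  expect_equal(ls1$psi, 2, tolerance = 1e-14)
  # generic-quadratic cross-check at lambda = 0.8, c = d
  lam <- 0.8
  roots <- polyroot(c(-p$c, p$c / lam - p$d, p$d))
  pos <- Re(roots)[abs(Im(roots)) < 1e-12 & Re(roots) > 0]
  expect_equal(lateral_solution(lam, p)$J, pos, tolerance = 1e-12)
  # d >> c: volume preserved for all lambda
  pin <- neo_hooke_params(1e-6, 1)
  lams <- seq(0.5, 1, 0.05)
  expect_true(all(abs(lateral_solution(lams, pin)$J - 1) < 1e-3))
})

test_that("psi satisfies its quadratic identity and the published form breaks the stress-free state", {
  prs <- random_params(50)
  lams <- seq(0.45, 1, 0.05)
  for (i in seq_len(nrow(prs))) {
    p <- neo_hooke_params(prs$c[i], prs$d[i])
    psi <- lateral_solution(lams, p)$psi
    resid <- psi^2 + (2 * p$c / p$d - 2 * lams) * psi - 4 * lams^2 * p$c / p$d
    # relative to the largest term: the identity cancels large terms when
    # c/d is extreme
    scale <- pmax(psi^2, abs((2 * p$c / p$d - 2 * lams) * psi),
                  4 * lams^2 * p$c / p$d)
    expect_lt(max(abs(resid) / scale), 1e-11)
  }
  # the as-published variant yields a nonzero stress at the identity
  p <- neo_hooke_params(0.05, 0.08)
  expect_equal(uniaxial_stress(1, p), 0)
  expect_gt(abs(uniaxial_stress(1, p, psi_form = "as-published")), 1e-3)
})

test_that("closed-form stress is compressive, smooth-monotone and matches the energy oracle", {
  lams <- seq(0.5, 0.99, by = 0.07)
  for (r in c(0.01, 0.1, 1, 10, 100)) {
    p <- neo_hooke_params(0.1 * r, 0.1)
    s <- uniaxial_stress(lams, p)
    expect_true(all(s < 0))
    expect_true(all(diff(abs(s)) < 0))     # |S33| grows as lambda drops
    o <- uniaxial_stress_oracle(lams, p)
    expect_lt(max(abs(s - o) / abs(s)), 1e-8)
  }
  expect_error(uniaxial_stress(-0.5, neo_hooke_params(1, 1)), "lambda")
})

test_that("oracle minimiser agrees with the lateral solution and sits in a convex well", {
  p <- neo_hooke_params(0.3, 0.9)
  lam <- 0.75
  # q^2 = J / lambda
  obj <- function(q) strain_energy(q, q, lam, p)
  q <- optimize(obj, c(1e-3, 20), tol = 1e-14)$minimum
  for (k in 1:40) {
    g <- p$c * (4 * q - 4 / q) + 4 * p$d * q * lam * (q^2 * lam - 1)
    gp <- p$c * (4 + 4 / q^2) + 4 * p$d * lam * (3 * q^2 * lam - 1)
    q <- q - g / gp
  }
  expect_equal(q^2, lateral_solution(lam, p)$J / lam, tolerance = 1e-10)
  expect_equal(uniaxial_stress_oracle(1, p), 0, tolerance = 1e-9)
})

test_that("small-strain moduli match the stress slope at identity and respect the nu range", {
  p <- neo_hooke_params(1, 1)
  ss <- small_strain_moduli(p)
  expect_equal(ss$E, 5)
  expect_equal(ss$nu, 0.25)
  # limits: volumetric-dominated -> nu 1/2, E = 6c; shear-only -> nu 0, E = 4c
  expect_equal(small_strain_moduli(neo_hooke_params(2, 2e8))$E, 12,
               tolerance = 1e-6)
  expect_equal(small_strain_moduli(neo_hooke_params(2, 2e8))$nu, 0.5,
               tolerance = 1e-6)
  expect_equal(small_strain_moduli(neo_hooke_params(2, 2e-8))$E, 8,
               tolerance = 1e-6)
  expect_equal(small_strain_moduli(neo_hooke_params(2, 2e-8))$nu, 0,
               tolerance = 1e-6)
  prs <- random_params(200, seed = 7)
  ss <- small_strain_moduli(neo_hooke_params(1, 1))
  for (i in seq_len(20)) {
    p <- neo_hooke_params(prs$c[i], prs$d[i])
    h <- 1e-6
    slope <- (uniaxial_stress(1 + h, p) - uniaxial_stress(1 - h, p)) / (2 * h)
    expect_equal(slope, 2 * p$c * (2 * p$c + 3 * p$d) / (p$c + p$d),
                 tolerance = 1e-6)
  }
  nu <- small_strain_moduli(neo_hooke_params(1, 1))$nu
  nus <- vapply(seq_len(nrow(prs)), function(i) {
    small_strain_moduli(neo_hooke_params(prs$c[i], prs$d[i]))$nu
  }, numeric(1))
  expect_true(all(nus > 0 & nus < 0.5))
})

test_that("fitting a noiseless synthetic curve recovers the parameters to high precision", {
  ssc <- synthetic_ssc(0.05, 0.08)
  fit <- fit_neo_hooke(ssc, interpretation = "nominal")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$c - 0.05) / 0.05, 1e-6)
  expect_lt(abs(fit$params$d - 0.08) / 0.08, 1e-6)
  td <- tidy(fit)
  expect_equal(td$term, c("c", "d"))
  expect_equal(td$estimate, c(fit$params$c, fit$params$d))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nu, small_strain_moduli(fit$params)$nu)
})

test_that("the fit residual Jacobian has full rank at the optimum (identifiability)", {
  ssc <- synthetic_ssc(0.06, 0.10, u_max = 26)   # spans eps ~ [0, 0.4]
  fit <- fit_neo_hooke(ssc, interpretation = "nominal")
  lam <- 1 - fit$data$strain
  h <- 1e-6
  jc <- (abs(uniaxial_stress(lam, neo_hooke_params(fit$params$c * (1 + h), fit$params$d),
                             interpretation = "nominal")) -
           abs(uniaxial_stress(lam, neo_hooke_params(fit$params$c * (1 - h), fit$params$d),
                               interpretation = "nominal"))) / (2 * h * fit$params$c)
  jd <- (abs(uniaxial_stress(lam, neo_hooke_params(fit$params$c, fit$params$d * (1 + h)),
                             interpretation = "nominal")) -
           abs(uniaxial_stress(lam, neo_hooke_params(fit$params$c, fit$params$d * (1 - h)),
                               interpretation = "nominal"))) / (2 * h * fit$params$d)
  sv <- svd(cbind(jc, jd))$d
  expect_gt(sv[2] / sv[1], 1e-6)
})

test_that("degenerate fits are rejected with clear errors", {
  flat <- tibble::tibble(strain = seq(0, 0.3, 0.01), stress = 0)
  expect_error(fit_neo_hooke(flat), "zero")
  short <- tibble::tibble(strain = seq(0, 0.02, 0.005), stress = 1:5 / 10)
  expect_error(fit_neo_hooke(short), "0.05")
  nonmono <- tibble::tibble(strain = c(0, 0.1, 0.05, 0.2, 0.3, 0.4),
                            stress = 1:6 / 10)
  expect_error(fit_neo_hooke(nonmono), "increasing")
})
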