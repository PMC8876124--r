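test_that("stress-strain conversion applies F/A0 and u/L0 with unit discipline", {
  cur <- tibble::tibble(displacement_mm = c(0, 16, 32),
                        force_N = c(0, 700, 1800))
  ssc <- to_stress_strain(cur, D0 = 70, L0 = 64, preload_N = 0)
  expect_equal(ssc$strain, c(0, 0.25, 0.5))
  expect_equal(ssc$stress[3], 1800 / (pi * 35^2), tolerance = 1e-12)
  expect_equal(ssc$stress[1], 0)
  expect_error(to_stress_strain(cur, D0 = 0, L0 = 64), "D0")
  over <- tibble::tibble(displacement_mm = c(0, 70), force_N = c(0, 10))
  expect_error(to_stress_strain(over, D0 = 70, L0 = 64, preload_N = 0),
               "Strain")
})

test_that("pre-load trimming drops leading samples below the threshold", {
  cur <- tibble::tibble(displacement_mm = seq(0, 5, 0.5),
                        force_N = c(0, 0.2, 0.4, 0.8, 1.5, 3, 6, 10, 15, 21, 28))
  ssc <- to_stress_strain(cur, D0 = 70, L0 = 65)
  # crossing happens at sample 5 (1.5 N); the bracketing sample is kept
  expect_equal(min(ssc$strain), 1.5 / 65)
  expect_equal(nrow(ssc), 8)
})

test_that("elastic modulus is the OLS slope on the window, with invariances", {
  ssc <- line_ssc(2.37)
  em <- elastic_modulus(ssc, window = c(0, 0.3))
  expect_equal(em$modulus, 2.37, tolerance = 1e-12)
  expect_equal(elastic_modulus(line_ssc(0), window = c(0, 0.3))$modulus, 0,
               tolerance = 1e-12)
  # shift invariance and scale equivariance
  em_shift <- elastic_modulus(line_ssc(2.37, offset = 0.4), window = c(0, 0.3))
  expect_equal(em_shift$modulus, 2.37, tolerance = 1e-12)
  em_scaled <- elastic_modulus(line_ssc(2.37 * 3), window = c(0, 0.3))
  expect_equal(em_scaled$modulus, 3 * 2.37, tolerance = 1e-12)
  expect_error(elastic_modulus(ssc, window = c(0.2, 0.1)), "eps_lo")
  expect_error(elastic_modulus(ssc, window = c(0.1, 0.9)), "outside")
  expect_error(elastic_modulus(line_ssc(1, n = 5), window = c(0, 0.05)),
               "Fewer")
})

test_that("modulus of a synthetic curve matches the analytic secant over the window", {
  ssc <- synthetic_ssc(0.05, 0.05)
  rec <- 0.25
  em <- elastic_modulus(ssc, elastic_recovery = rec)
  p <- neo_hooke_params(0.05, 0.05)
  nominal <- function(e) abs(uniaxial_stress(1 - e, p, interpretation = "nominal"))
  secant <- (nominal(0.10 + rec) - nominal(0.10)) / rec
  expect_equal(em$modulus, secant, tolerance = 0.03)
})

test_that("strength and stress-at-strain interpolate linearly and report absence", {
  ssc <- line_ssc(0.5)
  expect_equal(compressive_strength(ssc), 0.10, tolerance = 1e-12)
  two <- tibble::tibble(strain = c(0.19, 0.21), stress = c(0.09, 0.11))
  class(two) <- c("stress_strain", class(two))
  expect_equal(compressive_strength(two), 0.10, tolerance = 1e-12)
  shorty <- line_ssc(0.5, eps_max = 0.15)
  expect_message(val <- compressive_strength(shorty), "ends")
  expect_true(is.na(val))
  # interpolation exactness at a knot of a piecewise-linear curve
  kn <- tibble::tibble(strain = c(0, 0.1, 0.25, 0.5), stress = c(0, 0.3, 0.31, 1.2))
  class(kn) <- c("stress_strain", class(kn))
  expect_equal(stress_at_strain(kn, 0.25), 0.31)
  expect_equal(stress_at_strain(line_ssc(0.5, eps_max = 0.6), 0.5), 0.25,
               tolerance = 1e-12)
})

test_that("recovery split does the height arithmetic and guards impossible values", {
  expect_equal(recovery_split(0.4, 65, L0 = 65),
               tibble::tibble(plastic_strain = 0, elastic_recovery = 0.4))
  r <- recovery_split(0.5, 52, L0 = 65)
  expect_equal(r$plastic_strain, 0.2)
  expect_equal(r$elastic_recovery, 0.3)
  expect_error(recovery_split(0.5, 70, L0 = 65), "exceeds")
  expect_warning(r2 <- recovery_split(0.1, 52, L0 = 65), "clipping")
  expect_equal(r2$elastic_recovery, 0)
})

test_that("mean curves average onto the shortest replicate with Student-t bands", {
  a <- line_ssc(1, eps_max = 0.5)
  b <- line_ssc(3, eps_max = 0.4)
  mc <- mean_curve(list(a, b), grid_step = 0.01)
  expect_lte(max(mc$strain), 0.4)           # bounded by the shortest
  expect_equal(mc$mean_stress, 2 * mc$strain, tolerance = 1e-12)
  # half-width: t(0.975, df = 1) * sd / sqrt(2), sd = sqrt(2) * eps
  expect_equal(mc$ci_half_width,
               qt(0.975, 1) * sqrt(2) * mc$strain / sqrt(2), tolerance = 1e-10)
  same <- mean_curve(list(a, a, a), grid_step = 0.01)
  expect_true(all(same$ci_half_width == 0))
  expect_error(mean_curve(list(a)), "2 replicates")
})

test_that("the generate-reduce-summarise pipeline recovers the analytic strength exactly", {
  gt <- ground_truth(c = 0.08, d = 0.11)
  cur <- simulate_load_displacement(gt, list(D0 = 70, L0 = 65),
                                    displacement_limit = 30)
  ssc <- to_stress_strain(cur, preload_N = 0)
  p <- neo_hooke_params(0.08, 0.11)
  expected <- 0.8 * abs(uniaxial_stress(0.8, p))
  expect_lt(abs(compressive_strength(ssc) - expected) / expected, 1e-9)
})

test_that("machine exports in other dialects are read correctly", {
  f1 <- tempfile(fileext = ".csv")
  writeLines(c("displacement_mm;force_N", "0,0;0,0", "1,5;12,5", "3,0;40,0"), f1)
  r1 <- read_load_displacement(f1, D0 = 70, L0 = 65)
  expect_equal(r1$displacement_mm, c(0, 1.5, 3))
  expect_equal(r1$force_N, c(0, 12.5, 40))
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("disp\tload", "0\t0", "2\t30"), f2)
  r2 <- read_load_displacement(f2, D0 = 70, L0 = 65)
  expect_equal(r2$force_N, c(0, 30))
  unlink(c(f1, f2))
})
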