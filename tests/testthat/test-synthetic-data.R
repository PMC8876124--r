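test_that("specimen geometries respect their ranges and collapse to points", {
  g <- generate_specimen(1, list(D0 = 70, L0 = 65, slant_deg = 0), seed = 1)
  expect_equal(g$D0, 70)
  expect_equal(g$L0, 65)
  expect_equal(g$slant_deg, 0)
  g <- generate_specimen(200, seed = 2)
  expect_true(all(g$D0 >= 69 & g$D0 <= 71))
  expect_true(all(g$L0 >= 60 & g$L0 <= 70))
  expect_identical(generate_specimen(5, seed = 9), generate_specimen(5, seed = 9))
  expect_error(generate_specimen(3, list(D0 = c(71, 69)), seed = 1), "min")
})

test_that("the noise-free forward model equals the closed-form nominal force", {
  gt <- ground_truth(c = 0.1, d = 0.1)
  cur <- simulate_load_displacement(gt, list(D0 = 70, L0 = 65),
                                    displacement_limit = 20)
  expect_equal(cur$force_N[1], 0)
  A0 <- pi * 70^2 / 4
  u <- 0.2 * 65      # eps = 0.2 lies on the 0.1 mm grid for L0 = 65
  lam <- 0.8
  expected <- A0 * lam * abs(uniaxial_stress(lam, neo_hooke_params(0.1, 0.1)))
  # cross-check the expected value itself against the energy oracle
  expect_equal(expected, A0 * lam * abs(uniaxial_stress_oracle(lam, neo_hooke_params(0.1, 0.1))),
               tolerance = 1e-8)
  got <- cur$force_N[match(u, cur$displacement_mm)]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("records truncate at the machine stop rules and flag the reason", {
  gt <- ground_truth(c = 0.3, d = 0.3, noise_cv = 0.05)
  cur <- simulate_load_displacement(gt, list(D0 = 70, L0 = 65),
                                    force_limit = 1800,
                                    displacement_limit = 40, seed = 3)
  expect_identical(attr(cur, "stop_reason"), "force_limit")
  expect_lt(max(cur$force_N), 1800 * (1 + 5 * gt$noise_cv))
  expect_gte(max(cur$force_N), 1800)        # the triggering sample is kept
  soft <- ground_truth(c = 0.01, d = 0.01)
  cur2 <- simulate_load_displacement(soft, list(D0 = 70, L0 = 65),
                                     displacement_limit = 20)
  expect_identical(attr(cur2, "stop_reason"), "displacement_limit")
  expect_equal(max(cur2$displacement_mm), 20)
})

test_that("toe region consumes early travel smoothly and reduces early force", {
  gt0 <- ground_truth(c = 0.1, d = 0.1)
  gt1 <- ground_truth(c = 0.1, d = 0.1, toe_depth = 2, toe_sharpness = 3)
  g <- list(D0 = 70, L0 = 65)
  c0 <- simulate_load_displacement(gt0, g, displacement_limit = 20)
  c1 <- simulate_load_displacement(gt1, g, displacement_limit = 20)
  expect_true(all(c1$force_N <= c0$force_N + 1e-12))
  # early samples are much softer; late samples approach the toe-free curve
  i <- match(1.0, c0$displacement_mm)
  expect_lt(c1$force_N[i], 0.5 * c0$force_N[i])
})

test_that("studies have the right cardinality, scatter behaviour and determinism", {
  conds <- paste0("C", 1:6)
  des <- study_design(conds, replicates = 6, displacement_limits = 20, seed = 11)
  gts <- setNames(lapply(seq(0.04, 0.14, length.out = 6),
                         function(p) ground_truth(p, p, replicate_cv = 0.05)),
                  conds)
  st <- generate_study(des, gts)
  expect_equal(nrow(st), 36 + 6)            # 6 x 6 replicates + EPS benchmark
  expect_equal(sum(st$is_benchmark), 6)
  st2 <- generate_study(des, gts)
  expect_identical(st$data, st2$data)       # bit-identical under one seed
  # replicate_cv = 0 -> all replicates share the condition parameters
  des1 <- study_design("A", replicates = 4, displacement_limits = 15, seed = 5)
  st3 <- generate_study(des1, list(A = ground_truth(0.07, 0.09)),
                        eps_benchmark = FALSE)
  expect_true(all(st3$true_c == 0.07) && all(st3$true_d == 0.09))
})

test_that("between-specimen scatter is unbiased (law of large numbers)", {
  des <- study_design("A", replicates = 10000, displacement_limits = 2,
                      seed = 21)
  st <- generate_study(des, list(A = ground_truth(0.08, 0.05, replicate_cv = 0.15)),
                       eps_benchmark = FALSE)
  expect_lt(abs(mean(st$true_c) - 0.08) / 0.08, 0.02)
  expect_lt(abs(mean(st$true_d) - 0.05) / 0.05, 0.02)
})

test_that("a study round-trips through the on-disk layout", {
  dir <- file.path(tempdir(), "study_rt")
  des <- study_design(c("A", "B"), replicates = 2, displacement_limits = 10,
                      seed = 31)
  gts <- list(A = ground_truth(0.06, 0.06, noise_cv = 0.01),
              B = ground_truth(0.09, 0.09))
  st <- generate_study(des, gts, eps_benchmark = FALSE)
  write_study(st, dir, seed = 31)
  back <- read_study(dir)
  expect_equal(nrow(back), nrow(st))
  expect_equal(back$condition, st$condition)
  for (i in seq_len(nrow(st))) {
    expect_equal(back$data[[i]]$force_N, st$data[[i]]$force_N,
                 tolerance = 1e-12)
  }
  unlink(dir, recursive = TRUE)
})

test_that("particle generator: squares in the degenerate case, presets ordered, errors on n < 1", {
  sq <- generate_particles(50, preset = NULL,
                           shape_params = list(aspect_meanlog = 0,
                                               aspect_sdlog = 0,
                                               jitter = 0), seed = 41)
  fs <- feret_summary(sq)
  expect_true(all(abs(fs$ratio - 1 / sqrt(2)) < 1e-9))
  expect_error(generate_particles(0), ">= 1")
  hemp <- ratio_histogram(generate_particles(5000, "hemp", seed = 42))
  rape <- ratio_histogram(generate_particles(5000, "rapeseed", seed = 43))
  expect_lt(hemp$modal_ratio, rape$modal_ratio)
})
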