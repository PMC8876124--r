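# Shared fixtures, built in code at test time.

# A straight-line stress-strain curve sigma = slope * eps (+ offset),
# sampled on a uniform strain grid.
line_ssc <- function(slope, eps_max = 0.3, n = 61, offset = 0, L0 = 65) {
  eps <- seq(0, eps_max, length.out = n)
  out <- tibble::tibble(strain = eps, stress = slope * eps + offset)
  attr(out, "A0") <- pi * 35^2
  attr(out, "L0") <- L0
  class(out) <- c("stress_strain", class(out))
  out
}

# Noise-free synthetic stress-strain curve from known parameters;
# forward model generates nominal force, so the reduced stress is the
# nominal-stress magnitude.
synthetic_ssc <- function(c, d, L0 = 65, D0 = 70, u_max = 30, toe = 0) {
  gt <- ground_truth(c = c, d = d, toe_depth = toe)
  cur <- simulate_load_displacement(gt, list(D0 = D0, L0 = L0),
                                    displacement_limit = u_max)
  to_stress_strain(cur, preload_N = 0)
}

# Regular n-gon of circumscribed diameter `diam`, centred at origin.
regular_polygon <- function(n, diam = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = diam / 2 * cos(th), y = diam / 2 * sin(th))
}

rotate_outline <- function(v, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(v %*% t(R), 2, shift, "+")
}

# Random positive parameter pairs spanning several decades, fixed seed.
random_params <- function(n, seed = 101) {
  mycomech:::with_local_seed(seed, {
    tibble::tibble(c = 10^runif(n, -3, 2), d = 10^runif(n, -3, 2))
  })
}
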