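#' Compressible Neo-Hookean material parameters
#'
#' Constructs and validates the parameter pair of the compressible
#' Neo-Hookean model used throughout the package. `c` scales the isochoric
#' (shear-like) response, `d` the volumetric response; both carry units of
#' MPa and must be strictly positive.
#'
#' The strain-energy density in principal stretches is
#' \deqn{w(\lambda_i) = c(\lambda_1^2 + \lambda_2^2 + \lambda_3^2 - 3
#'   - 2\ln(\lambda_1\lambda_2\lambda_3)) + d(\lambda_1\lambda_2\lambda_3 - 1)^2.}
#'
#' @param c Shear-like parameter (MPa, > 0).
#' @param d Volumetric parameter (MPa, > 0).
#' @return An object of class `neo_hooke_params`.
#' @examples
#' p <- neo_hooke_params(0.05, 0.08)
#' small_strain_moduli(p)
#' @export
neo_hooke_params <- function(c, d) {
  check_number(c, "c", positive = TRUE)
  check_number(d, "d", positive = TRUE)
  structure(list(c = c, d = d), class = "neo_hooke_params")
}

#' @export
print.neo_hooke_params <- function(x, ...) {
  cat(sprintf("<neo_hooke_params>  c = %.6g MPa,  d = %.6g MPa\n", x$c, x$d))
  invisible(x)
}

as_nh_params <- function(params) {
  if (inherits(params, "neo_hooke_params")) return(params)
  if (is.list(params) && all(c("c", "d") %in% names(params))) {
    return(neo_hooke_params(params$c, params$d))
  }
  abort("`params` must be a neo_hooke_params object or a list with c and d.")
}

#' Strain-energy density in principal stretches
#'
#' @param l1,l2,l3 Principal stretches (> 0); vectors are recycled to a
#'   common length.
#' @param params A [neo_hooke_params()] object.
#' @return Energy density in MPa (numeric vector).
#' @export
strain_energy <- function(l1, l2, l3, params) {
  params <- as_nh_params(params)
  n <- max(length(l1), length(l2), length(l3))
  l1 <- rep_len(l1, n); l2 <- rep_len(l2, n); l3 <- rep_len(l3, n)
  if (any(l1 <= 0 | l2 <= 0 | l3 <= 0)) {
    abort("All principal stretches must be > 0.")
  }
  J <- l1 * l2 * l3
  params$c * (l1^2 + l2^2 + l3^2 - 3 - 2 * log(J)) + params$d * (J - 1)^2
}

#' Lateral-contraction solution for uniaxial loading
#'
#' For a prescribed axial stretch `lambda` the lateral faces are stress
#' free. Setting the derivative of the energy with respect to the lateral
#' stretch to zero gives a quadratic in the volume ratio J,
#' \deqn{d J^2 + (c/\lambda - d) J - c = 0,}
#' whose unique positive root determines the lateral stretch
#' \eqn{\sqrt{J/\lambda}} and the auxiliary function \eqn{\psi = 2\lambda J}
#' that appears in the closed-form axial stress.
#'
#' @param lambda Axial stretch(es), > 0 (compression: `lambda < 1`).
#' @param params A [neo_hooke_params()] object.
#' @return A tibble with columns `lambda`, `J`, `psi`, `lateral_stretch`.
#' @export
lateral_solution <- function(lambda, params) {
  params <- as_nh_params(params)
  if (any(lambda <= 0)) abort("`lambda` must be > 0.")
  cc <- params$c; dd <- params$d
  b <- cc / lambda - dd
  disc <- b^2 + 4 * dd * cc          # always > 0 for positive c, d, lambda
  J <- (-b + sqrt(disc)) / (2 * dd)
  tibble(
    lambda = lambda, J = J, psi = 2 * lambda * J,
    lateral_stretch = sqrt(J / lambda)
  )
}

# psi(lambda) in its two algebraic forms. The consistent form carries
# (lambda - c/d)^2 inside the root and satisfies psi(1) = 2 (hence a
# stress-free identity); the "as-published" form carries (lambda + c/d)^2
# and is retained only to document that it violates S33(1) = 0.
psi_value <- function(lambda, params, psi_form = c("consistent", "as-published")) {
  psi_form <- match.arg(psi_form)
  r <- params$c / params$d
  if (psi_form == "consistent") {
    lambda - r + sqrt(4 * r * lambda^2 + (lambda - r)^2)
  } else {
    lambda - r + sqrt(4 * r * lambda^2 + (lambda + r)^2)
  }
}

#' Closed-form axial stress under uniaxial loading
#'
#' Evaluates the closed-form axial second Piola-Kirchhoff stress
#' \deqn{S_{33}(\lambda) = 2c(1 - 1/\lambda^2)
#'   + d\,\frac{\psi}{\lambda^3}\Big(\frac{\psi}{2\lambda} - 1\Big),}
#' with \eqn{\psi = 2\lambda J} from [lateral_solution()]. The nominal
#' (first Piola-Kirchhoff) stress, the quantity a testing machine reports as
#' force per reference area, is \eqn{P_{33} = \lambda S_{33}}.
#'
#' @param lambda Axial stretch(es), > 0.
#' @param params A [neo_hooke_params()] object.
#' @param interpretation `"second_piola"` (default) or `"nominal"`.
#' @param psi_form `"consistent"` (default) uses the re-derived
#'   lateral-contraction solution; `"as-published"` reproduces a variant with
#'   a sign flip inside the root that fails the stress-free identity at
#'   `lambda = 1` (kept for documentation; do not fit with it).
#' @return Signed stress in MPa (negative in compression).
#' @export
uniaxial_stress <- function(lambda, params,
                            interpretation = c("second_piola", "nominal"),
                            psi_form = c("consistent", "as-published")) {
  params <- as_nh_params(params)
  interpretation <- match.arg(interpretation)
  psi_form <- match.arg(psi_form)
  if (any(lambda <= 0)) abort("`lambda` must be > 0.")
  psi <- psi_value(lambda, params, psi_form)
  s33 <- 2 * params$c * (1 - 1 / lambda^2) +
    params$d * psi / lambda^3 * (psi / (2 * lambda) - 1)
  if (interpretation == "nominal") lambda * s33 else s33
}

#' Brute-force uniaxial stress oracle
#'
#' Independent verification path for [uniaxial_stress()]: minimises the
#' strain energy `w(q, q, lambda)` over the lateral stretch `q` with a
#' robust 1-D minimiser, then evaluates the axial stress
#' \eqn{S_{33} = (1/\lambda)\,\partial w/\partial\lambda_3} at the minimiser
#' by central differences. Used in tests; never on the analysis path.
#'
#' @inheritParams uniaxial_stress
#' @return Signed second Piola-Kirchhoff stress in MPa.
#' @export
uniaxial_stress_oracle <- function(lambda, params) {
  params <- as_nh_params(params)
  if (any(lambda <= 0)) abort("`lambda` must be > 0.")
  vapply(lambda, function(lam) {
    obj <- function(q) strain_energy(q, q, lam, params)
    opt <- optimize(obj, interval = c(1e-3, 20), tol = 1e-14)
    q <- opt$minimum
    # polish to machine precision: Newton on dw/dq = 0 (optimize alone
    # locates the minimiser only to about sqrt(machine eps))
    cc <- params$c; dd <- params$d
    for (k in 1:50) {
      g <- cc * (4 * q - 4 / q) + 4 * dd * q * lam * (q^2 * lam - 1)
      gp <- cc * (4 + 4 / q^2) + 4 * dd * lam * (3 * q^2 * lam - 1)
      step <- g / gp
      q <- q - step
      if (abs(step) < 1e-15 * max(1, abs(q))) break
    }
    # convexity guard: the minimiser must sit in a locally convex well
    h <- 1e-5 * max(1, q)
    d2 <- (obj(q + h) - 2 * obj(q) + obj(q - h)) / h^2
    if (!is.finite(d2) || d2 <= 0) {
      abort("Energy minimisation failed: non-convex at reported minimiser.")
    }
    hl <- 1e-5 * max(1, lam)
    dw <- (strain_energy(q, q, lam + hl, params) -
             strain_energy(q, q, lam - hl, params)) / (2 * hl)
    dw / lam
  }, numeric(1))
}

#' Small-strain elastic constants of the model
#'
#' Linearising the model about the identity gives shear modulus
#' \eqn{\mu = 2c} and Lame constant \eqn{\Lambda = 2d}, hence
#' \deqn{E = \frac{2c(2c + 3d)}{c + d}, \qquad \nu = \frac{d}{2(c + d)},}
#' with \eqn{0 < \nu < 1/2} for all positive parameters. Used to seed the
#' least-squares fit and to cross-check the finite-element solver in its
#' linear-elastic limit.
#'
#' @param params A [neo_hooke_params()] object.
#' @return A one-row tibble with columns `E` (MPa) and `nu`.
#' @export
small_strain_moduli <- function(params) {
  params <- as_nh_params(params)
  cc <- params$c; dd <- params$d
  tibble(E = 2 * cc * (2 * cc + 3 * dd) / (cc + dd),
         nu = dd / (2 * (cc + dd)))
}

#' Identify Neo-Hookean parameters from a stress-strain curve
#'
#' Fits the closed-form uniaxial stress to a (mean) compressive
#' stress-strain curve by bounded nonlinear least squares. Strains map to
#' stretches through `lambda = 1 - strain`; the curve stores stress
#' magnitudes, the model layer tracks signed stresses, and the conversion
#' happens exactly here. The default interpretation fits the second
#' Piola-Kirchhoff stress directly to `F/A0`; `"nominal"` fits
#' `lambda * S33`, the measure that actually equals force per reference
#' area, and is what the finite-element cross-checks use.
#'
#' Optimisation runs in log-parameter space so positivity needs no
#' constrained-solver edge cases; box bounds (default `1e-6`-`1e3` MPa) are
#' applied on the log scale. The initial guess inverts
#' [small_strain_moduli()] against the secant modulus of the data at an
#' assumed Poisson ratio `nu0`.
#'
#' @param data A data frame with strain and stress columns (e.g. a
#'   [to_stress_strain()] curve or a [mean_curve()] table, where the mean
#'   stress column is picked up automatically).
#' @param strain,stress Column names (strings) holding strain (dimensionless)
#'   and stress magnitude (MPa).
#' @param interpretation Stress measure fitted to the data; see Details.
#' @param nu0 Poisson ratio assumed when seeding the fit (default 0.25).
#' @param bounds Length-2 numeric, lower/upper bounds on both parameters (MPa).
#' @param psi_form Passed to [uniaxial_stress()].
#' @return An object of class `neo_hooke_fit`; see [tidy.neo_hooke_fit()].
#' @export
fit_neo_hooke <- function(data, strain = "strain", stress = "stress",
                          interpretation = c("second_piola", "nominal"),
                          nu0 = 0.25, bounds = c(1e-6, 1e3),
                          psi_form = "consistent") {
  interpretation <- match.arg(interpretation)
  if (!strain %in% names(data)) {
    abort(sprintf("Column `%s` not found in `data`.", strain))
  }
  if (!stress %in% names(data) && stress == "stress" && "mean_stress" %in% names(data)) {
    stress <- "mean_stress"
  }
  if (!stress %in% names(data)) {
    abort(sprintf("Column `%s` not found in `data`.", stress))
  }
  eps <- data[[strain]]
  sig <- data[[stress]]
  keep <- is.finite(eps) & is.finite(sig)
  eps <- eps[keep]; sig <- sig[keep]
  if (length(eps) < 5) abort("Need at least 5 finite data points to fit.")
  if (any(diff(eps) <= 0)) abort("Strain must be strictly increasing.")
  if (diff(range(eps)) < 0.05) {
    abort("Curve must span a strain range of at least 0.05.")
  }
  if (all(sig <= 0)) abort("All-zero (or negative) stress: nothing to fit.")
  if (any(eps >= 1)) abort("Strains must be < 1 (stretch must stay positive).")

  lam <- 1 - eps
  model_mag <- function(p) {
    abs(uniaxial_stress(lam, p, interpretation = interpretation,
                        psi_form = psi_form))
  }

  # seed: secant modulus of the data inverted through the small-strain
  # formulas at Poisson ratio nu0 (nu0 = 1/4 gives d0 = c0 = m/5)
  m0 <- max(diff(range(sig)) / diff(range(eps)), 1e-6)
  r0 <- 2 * nu0 / (1 - 2 * nu0)
  c0 <- m0 * (1 + r0) / (2 * (2 + 3 * r0))
  c0 <- min(max(c0, bounds[1] * 10), bounds[2] / 10)
  d0 <- min(max(r0 * c0, bounds[1] * 10), bounds[2] / 10)

  resid_fn <- function(logp) {
    p <- neo_hooke_params(exp(logp[1]), exp(logp[2]))
    model_mag(p) - sig
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(c0, d0)), fn = resid_fn,
    lower = log(c(bounds[1], bounds[1])), upper = log(c(bounds[2], bounds[2])),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (!fit$info %in% 1:4) {
    warn(sprintf("Fit did not converge cleanly (nls.lm info = %d: %s).",
                 fit$info, fit$message))
  }
  params <- neo_hooke_params(exp(fit$par[1]), exp(fit$par[2]))
  structure(list(
    params = params,
    residual_norm = sqrt(sum(fit$fvec^2)),
    strain_range = range(eps),
    interpretation = interpretation,
    psi_form = psi_form,
    converged = fit$info %in% 1:4,
    info = fit$info,
    message = fit$message,
    n = length(eps),
    data = tibble(strain = eps, stress = sig,
                  fitted = model_mag(params))
  ), class = "neo_hooke_fit")
}

#' @export
print.neo_hooke_fit <- function(x, ...) {
  cat("<neo_hooke_fit>\n")
  cat(sprintf("  c = %.6g MPa, d = %.6g MPa (%s stress, %s psi)\n",
              x$params$c, x$params$d, x$interpretation, x$psi_form))
  cat(sprintf("  residual norm %.3e over %d points, strain %.3f-%.3f, %s\n",
              x$residual_norm, x$n, x$strain_range[1], x$strain_range[2],
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a Neo-Hookean fit
#'
#' @param x A `neo_hooke_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate` (MPa).
#' @export
tidy.neo_hooke_fit <- function(x, ...) {
  tibble(term = c("c", "d"), estimate = c(x$params$c, x$params$d))
}

#' One-row summary of a Neo-Hookean fit
#'
#' @inheritParams tidy.neo_hooke_fit
#' @return A one-row tibble with the parameters, derived small-strain
#'   constants, residual norm and convergence flag.
#' @export
glance.neo_hooke_fit <- function(x, ...) {
  ss <- small_strain_moduli(x$params)
  tibble(c = x$params$c, d = x$params$d, E = ss$E, nu = ss$nu,
         residual_norm = x$residual_norm, n = x$n,
         converged = x$converged, interpretation = x$interpretation)
}
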