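#' Read a load-displacement machine export
#'
#' Reads generic two-column delimited exports (comma, semicolon or tab
#' separated; decimal commas tolerated when the field separator is a
#' semicolon or tab) and attaches the specimen geometry needed for the
#' stress-strain reduction.
#'
#' @param path File path.
#' @param D0,L0 Specimen diameter and height (mm).
#' @param displacement_col,force_col Column names in the file (defaults
#'   `displacement_mm`, `force_N`); column order is used as a fallback when
#'   names do not match.
#' @param sep Field separator; `NULL` (default) sniffs `,`, `;` or tab.
#' @return A `load_displacement` tibble.
#' @export
read_load_displacement <- function(path, D0, L0,
                                   displacement_col = "displacement_mm",
                                   force_col = "force_N", sep = NULL) {
  check_number(D0, "D0", positive = TRUE)
  check_number(L0, "L0", positive = TRUE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl(";", header)) ";" else if (grepl("\t", header)) "\t" else ","
  }
  dec <- if (sep %in% c(";", "\t")) "," else "."
  df <- read.csv(path, sep = sep, dec = dec, check.names = FALSE)
  if (dec == "," && !any(vapply(df, is.numeric, logical(1)))) {
    df <- read.csv(path, sep = sep, dec = ".", check.names = FALSE)
  }
  if (all(c(displacement_col, force_col) %in% names(df))) {
    u <- df[[displacement_col]]; f <- df[[force_col]]
  } else if (ncol(df) >= 2) {
    u <- df[[1]]; f <- df[[2]]
  } else {
    abort("Expected at least two columns (displacement, force).")
  }
  out <- tibble(displacement_mm = as.numeric(u), force_N = as.numeric(f))
  if (nrow(out) < 2) abort("Record must contain at least 2 samples.")
  attr(out, "geometry") <- list(D0 = D0, L0 = L0)
  class(out) <- c("load_displacement", class(out))
  out
}

#' Convert a load-displacement record to engineering stress-strain
#'
#' Applies the standard foam-testing reduction: stress `sigma = F / A0`
#' with `A0 = pi * D0^2 / 4` (N and mm in, MPa out) and strain
#' `eps = u / L0`, the relative height decrease (positive in compression;
#' the stretch convention `lambda = 1 - eps` is used model-side). Samples
#' before the force first crosses the machine pre-load (default 1 N) are
#' trimmed.
#'
#' @param curve A `load_displacement` tibble (or any data frame with
#'   `displacement_mm` and `force_N`).
#' @param D0,L0 Geometry (mm); defaults come from the curve's attributes.
#' @param preload_N Pre-load threshold for leading-sample trimming
#'   (default 1 N); set to 0 to keep everything.
#' @return A tibble (class `stress_strain`) with columns `strain`,
#'   `stress` (MPa); attributes `A0` (mm^2) and `L0` (mm).
#' @examples
#' curve <- tibble::tibble(displacement_mm = c(0, 16, 32),
#'                         force_N = c(0, 700, 1800))
#' to_stress_strain(curve, D0 = 70, L0 = 64, preload_N = 0)
#' @export
to_stress_strain <- function(curve, D0 = NULL, L0 = NULL, preload_N = 1) {
  geom <- attr(curve, "geometry")
  D0 <- D0 %||% geom$D0
  L0 <- L0 %||% geom$L0
  if (is.null(D0) || is.null(L0)) abort("Geometry (D0, L0) is required.")
  check_number(D0, "D0", positive = TRUE)
  check_number(L0, "L0", positive = TRUE)
  u <- curve$displacement_mm
  f <- curve$force_N
  if (any(!is.finite(f))) abort("Forces must be finite.")
  if (any(diff(u) < 0)) abort("Displacement must be non-decreasing.")
  if (preload_N > 0) {
    first <- which(f >= preload_N)[1]
    if (is.na(first)) abort("No sample reaches the pre-load threshold.")
    keep <- seq(max(1L, first - 1L), length(u))  # keep the crossing bracket
    u <- u[keep]; f <- f[keep]
  }
  eps <- u / L0
  if (any(eps >= 1)) abort("Strain reached 1: displacement exceeds specimen height.")
  out <- tibble(strain = eps, stress = f / (pi * D0^2 / 4))
  attr(out, "A0") <- pi * D0^2 / 4
  attr(out, "L0") <- L0
  attr(out, "condition") <- attr(curve, "condition")
  class(out) <- c("stress_strain", class(out))
  out
}

#' Elastic modulus from the quasi-linear strain window
#'
#' Fits an ordinary least-squares line to the stress-strain curve within a
#' strain window and reports the slope as the elastic modulus (MPa). The
#' default window starts at 10 % strain — below it the cross-section is
#' unevenly loaded because of the inclined top faces — and extends over
#' the elastic-recovery span measured from the post-test height
#' (`rule = "span"`: upper bound `0.10 + elastic_recovery`). With
#' `rule = "absolute"` the recovery value is used directly as the upper
#' bound.
#'
#' @param ssc A `stress_strain` tibble.
#' @param window Explicit `c(eps_lo, eps_hi)`; overrides the rule.
#' @param elastic_recovery Recovery strain from [recovery_split()]; needed
#'   when `window` is not given.
#' @param lower Lower window bound (default 0.10).
#' @param rule `"span"` (default) or `"absolute"`; see Details.
#' @return One-row tibble: `modulus` (MPa), `eps_lo`, `eps_hi`, `n_points`.
#' @export
elastic_modulus <- function(ssc, window = NULL, elastic_recovery = NULL,
                            lower = 0.10, rule = c("span", "absolute")) {
  rule <- match.arg(rule)
  if (is.null(window)) {
    if (is.null(elastic_recovery)) {
      abort("Provide either `window` or `elastic_recovery`.")
    }
    upper <- if (rule == "span") lower + elastic_recovery else elastic_recovery
    window <- c(lower, upper)
  }
  if (window[1] >= window[2]) abort("Window must satisfy eps_lo < eps_hi.")
  if (window[1] < min(ssc$strain) || window[2] > max(ssc$strain)) {
    abort("Fit window lies (partly) outside the measured strain range.")
  }
  inside <- ssc$strain >= window[1] & ssc$strain <= window[2]
  if (sum(inside) < 5) abort("Fewer than 5 samples inside the fit window.")
  m <- unname(coef(lm(stress ~ strain, data = ssc[inside, ]))[2])
  tibble(modulus = m, eps_lo = window[1], eps_hi = window[2],
         n_points = sum(inside))
}

#' Stress at an arbitrary strain by linear interpolation
#'
#' @param ssc A `stress_strain` tibble.
#' @param at Target strain.
#' @return Stress in MPa, or `NA` (with a message) when the curve ends
#'   before the target strain — an absent value, never 0.
#' @export
stress_at_strain <- function(ssc, at) {
  check_number(at, "at", non_negative = TRUE)
  val <- interp_at(ssc$strain, ssc$stress, at)
  if (is.na(val)) {
    inform(sprintf("Curve ends at strain %.3f, before the requested %.3f.",
                   max(ssc$strain), at))
  }
  val
}

#' Compressive strength: stress at 20 % strain
#'
#' The foam-testing convention evaluated throughout the package: the
#' compressive strength is the engineering stress interpolated at 20 %
#' strain.
#'
#' @inheritParams stress_at_strain
#' @return Stress in MPa (or `NA` when the curve stops before 20 % strain).
#' @export
compressive_strength <- function(ssc) {
  stress_at_strain(ssc, 0.20)
}

#' Split the final deformation into plastic and elastic parts
#'
#' The specimen height measured immediately after the test gives the
#' remaining (plastic) strain `(L0 - post_test_height)/L0`; the elastic
#' recovery is the maximum applied strain minus that plastic part.
#' Physically the recovery cannot be negative; measurement error can make
#' it so, in which case it is clipped to 0 with a warning.
#'
#' @param curve A `load_displacement` tibble, or a `stress_strain` tibble
#'   (its maximum strain is used), or a plain number giving the maximum
#'   strain.
#' @param post_test_height Height after the test (mm), `<= L0`.
#' @param L0 Original height (mm); taken from attributes when available.
#' @return One-row tibble: `plastic_strain`, `elastic_recovery`.
#' @export
recovery_split <- function(curve, post_test_height, L0 = NULL) {
  if (is.numeric(curve) && length(curve) == 1L) {
    eps_max <- curve
    if (is.null(L0)) abort("`L0` is required when `curve` is a strain value.")
  } else if (inherits(curve, "stress_strain")) {
    eps_max <- max(curve$strain)
    L0 <- L0 %||% attr(curve, "L0")
  } else {
    L0 <- L0 %||% attr(curve, "geometry")$L0
    if (is.null(L0)) abort("`L0` is required.")
    eps_max <- max(curve$displacement_mm) / L0
  }
  check_number(post_test_height, "post_test_height", positive = TRUE)
  if (post_test_height > L0) {
    abort("`post_test_height` exceeds the original height L0.")
  }
  plastic <- (L0 - post_test_height) / L0
  recovery <- eps_max - plastic
  if (recovery < 0) {
    warn(sprintf(paste0("Post-test height implies more plastic strain (%.3f) ",
                        "than was ever applied (%.3f); clipping recovery to 0."),
                 plastic, eps_max))
    recovery <- 0
  }
  tibble(plastic_strain = plastic, elastic_recovery = recovery)
}

#' Mean stress-strain curve with a 95 % confidence band
#'
#' Interpolates each replicate onto a common uniform strain grid (bounded
#' by the shortest replicate so no point is extrapolated) and computes the
#' pointwise mean and a two-sided Student-t 95 % confidence half-width.
#'
#' @param replicates A list of `stress_strain` tibbles, or a long tibble
#'   with columns `specimen`, `strain`, `stress`.
#' @param grid_step Strain grid spacing (default 0.005).
#' @param level Confidence level (default 0.95).
#' @return A tibble (class `mean_curve`) with columns `strain`,
#'   `mean_stress`, `ci_half_width`, `n`.
#' @export
mean_curve <- function(replicates, grid_step = 0.005, level = 0.95) {
  if (is.data.frame(replicates)) {
    if (!all(c("specimen", "strain", "stress") %in% names(replicates))) {
      abort("Long input needs columns `specimen`, `strain`, `stress`.")
    }
    replicates <- split(replicates[c("strain", "stress")], replicates$specimen)
  }
  if (length(replicates) < 2) {
    abort("At least 2 replicates are needed for a confidence band.")
  }
  top <- min(vapply(replicates, function(r) max(r$strain), numeric(1)))
  lo <- max(vapply(replicates, function(r) min(r$strain), numeric(1)))
  grid <- seq(0, top, by = grid_step)
  grid <- grid[grid >= lo]
  mat <- vapply(replicates, function(r) {
    approx(r$strain, r$stress, xout = grid, ties = "ordered")$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n <- ncol(mat)
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  out <- tibble(strain = grid, mean_stress = mu, ci_half_width = half, n = n)
  class(out) <- c("mean_curve", class(out))
  out
}

#' Per-specimen mechanical summary of a study
#'
#' Runs the full reduction on every specimen of a study table: stress-strain
#' conversion, recovery split from the post-test height, elastic modulus in
#' the recovery-derived window, compressive strength at 20 % strain and
#' stress at 50 % strain.
#'
#' @param study A study tibble as produced by [generate_study()] /
#'   [read_study()].
#' @param preload_N Pre-load trim threshold (N).
#' @param modulus_rule Passed to [elastic_modulus()].
#' @return A tibble with one row per specimen: condition, replicate,
#'   `modulus`, `eps_lo`, `eps_hi`, `strength_20`, `stress_50`,
#'   `plastic_strain`, `elastic_recovery`, `max_strain`.
#' @export
summarize_mechanics <- function(study, preload_N = 1,
                                modulus_rule = c("span", "absolute")) {
  modulus_rule <- match.arg(modulus_rule)
  purrr::map(seq_len(nrow(study)), function(i) {
    ssc <- to_stress_strain(study$data[[i]], D0 = study$D0[i],
                            L0 = study$L0[i], preload_N = preload_N)
    rec <- recovery_split(ssc, study$post_test_height[i], L0 = study$L0[i])
    # the recovery-derived upper bound cannot be observed beyond the last
    # recorded sample; clamp it to the measured range
    upper <- if (modulus_rule == "span") 0.10 + rec$elastic_recovery else rec$elastic_recovery
    upper <- min(upper, max(ssc$strain))
    em <- tryCatch(
      elastic_modulus(ssc, window = c(0.10, upper)),
      error = function(e) tibble(modulus = NA_real_, eps_lo = NA_real_,
                                 eps_hi = NA_real_, n_points = NA_integer_))
    s20 <- suppressMessages(compressive_strength(ssc))
    s50 <- suppressMessages(stress_at_strain(ssc, 0.50))
    tibble(condition = study$condition[i], replicate = study$replicate[i],
           specimen_id = study$specimen_id[i],
           modulus = em$modulus, eps_lo = em$eps_lo, eps_hi = em$eps_hi,
           strength_20 = s20, stress_50 = s50,
           plastic_strain = rec$plastic_strain,
           elastic_recovery = rec$elastic_recovery,
           max_strain = max(ssc$strain))
  }) |> list_rbind()
}
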