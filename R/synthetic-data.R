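#' Ground-truth parameters for a synthetic compression condition
#'
#' Bundles the constitutive pair driving a virtual condition with the
#' nuisance parameters of the forward model: a soft toe region standing in
#' for the gradual engagement of the surface mycelium layer, multiplicative
#' measurement noise on force, and between-specimen scatter on `(c, d)`.
#'
#' @param c,d Neo-Hookean parameters (MPa, > 0); see [neo_hooke_params()].
#' @param toe_depth Depth (mm, >= 0) of the soft surface layer that
#'   compacts before the bulk carries load.
#' @param toe_sharpness Dimensionless rate (> 0) of the exponential
#'   engagement of that layer.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   force noise (>= 0), applied pointwise.
#' @param replicate_cv Coefficient of variation of the lognormal
#'   between-specimen scatter applied to `c` and `d` (>= 0).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(c, d, toe_depth = 0, toe_sharpness = 5,
                         noise_cv = 0, replicate_cv = 0) {
  check_number(c, "c", positive = TRUE)
  check_number(d, "d", positive = TRUE)
  check_number(toe_depth, "toe_depth", non_negative = TRUE)
  check_number(toe_sharpness, "toe_sharpness", positive = TRUE)
  check_number(noise_cv, "noise_cv", non_negative = TRUE)
  check_number(replicate_cv, "replicate_cv", non_negative = TRUE)
  structure(list(c = c, d = d, toe_depth = toe_depth,
                 toe_sharpness = toe_sharpness, noise_cv = noise_cv,
                 replicate_cv = replicate_cv),
            class = "ground_truth")
}

#' Sample specimen geometries
#'
#' Draws cylindrical specimen geometries uniformly within ranges:
#' diameter, height and the inclination of the top face (specimens settle
#' slightly slanted during growth). Defaults emulate tube-grown cylinders
#' of about 70 mm diameter and 60-70 mm height.
#'
#' @param n Number of specimens.
#' @param geometry_spec Named list of length-2 ranges (min, max) for
#'   `D0` (mm), `L0` (mm) and `slant_deg` (degrees, in `[0, 10)`); a single
#'   value collapses a range to a point.
#' @param seed Optional integer; when given, sampling is done under a local
#'   RNG state so results are reproducible without touching the caller's
#'   stream.
#' @return A tibble with columns `specimen`, `D0`, `L0`, `slant_deg`.
#' @examples
#' generate_specimen(3, seed = 1)
#' @export
generate_specimen <- function(n = 1,
                              geometry_spec = list(D0 = c(69, 71),
                                                   L0 = c(60, 70),
                                                   slant_deg = c(0, 3)),
                              seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  spec <- modifyList(list(D0 = c(69, 71), L0 = c(60, 70), slant_deg = c(0, 3)),
                     as.list(geometry_spec))
  draw <- function(rng, name, lo_ok = 0) {
    r <- rep_len(as.numeric(rng), 2L)
    if (r[1] > r[2]) {
      abort(sprintf("Invalid range for `%s`: min %g > max %g.", name, r[1], r[2]))
    }
    runif(n, r[1], r[2])
  }
  with_local_seed(seed, {
    out <- tibble(
      specimen = seq_len(n),
      D0 = draw(spec$D0, "D0"),
      L0 = draw(spec$L0, "L0"),
      slant_deg = draw(spec$slant_deg, "slant_deg")
    )
    if (any(out$D0 <= 0) || any(out$L0 <= 0)) {
      abort("Geometry ranges must keep D0 and L0 positive.")
    }
    if (any(out$slant_deg < 0 | out$slant_deg >= 10)) {
      abort("`slant_deg` must lie in [0, 10).")
    }
    out
  })
}

# Smooth toe engagement: the consumed displacement
# u_toe(u) = toe_depth * (1 - exp(-toe_sharpness * u / toe_depth))
# rises from 0 toward toe_depth, so early travel compacts the surface
# layer before straining the bulk.
toe_displacement <- function(u, toe_depth, toe_sharpness) {
  if (toe_depth <= 0) return(rep(0, length(u)))
  toe_depth * (1 - exp(-toe_sharpness * u / toe_depth))
}

#' Simulate a load-displacement record for one specimen
#'
#' Forward model of the compression test: displacement is sampled on a
#' uniform machine-like grid; after the toe correction the effective strain
#' is `max(0, (u - u_toe(u)) / L0)`, the axial stretch `lambda = 1 - eps`,
#' and the recorded force is the nominal-stress magnitude
#' `A0 * lambda * |S33(lambda)|` times the reference area, with optional
#' multiplicative lognormal noise (unit mean, coefficient of variation
#' `noise_cv`). Recording stops at the first sample reaching the force
#' limit or the condition's displacement limit, mirroring a machine that
#' ends the test automatically.
#'
#' @param gt A [ground_truth()] object.
#' @param geometry One row of [generate_specimen()] output (or any list
#'   with `D0` and `L0` in mm).
#' @param force_limit Stop force (N), default 1800.
#' @param displacement_limit Stop displacement (mm).
#' @param step_mm Displacement sampling step (mm), default 0.1.
#' @param seed Optional integer for a local RNG state (noise only).
#' @return A tibble (class `load_displacement`) with columns
#'   `displacement_mm`, `force_N`; attributes `geometry`, `ground_truth`,
#'   `stop_reason` (`"force_limit"` or `"displacement_limit"`).
#' @export
simulate_load_displacement <- function(gt, geometry, force_limit = 1800,
                                       displacement_limit = 35,
                                       step_mm = 0.1, seed = NULL) {
  if (!inherits(gt, "ground_truth")) abort("`gt` must be a ground_truth object.")
  D0 <- geometry$D0; L0 <- geometry$L0
  check_number(D0, "D0", positive = TRUE)
  check_number(L0, "L0", positive = TRUE)
  check_number(force_limit, "force_limit", positive = TRUE)
  check_number(displacement_limit, "displacement_limit", positive = TRUE)
  if (gt$toe_depth >= L0) abort("`toe_depth` must be smaller than the specimen height.")
  A0 <- pi * D0^2 / 4
  u <- seq(0, displacement_limit, by = step_mm)
  if (tail(u, 1) < displacement_limit) u <- c(u, displacement_limit)
  eps_eff <- pmax(0, (u - toe_displacement(u, gt$toe_depth, gt$toe_sharpness)) / L0)
  if (any(eps_eff >= 1)) abort("Effective strain reached 1; displacement limit too large for L0.")
  lam <- 1 - eps_eff
  p <- neo_hooke_params(gt$c, gt$d)
  force <- A0 * abs(uniaxial_stress(lam, p, interpretation = "nominal"))
  force[eps_eff == 0] <- 0
  if (gt$noise_cv > 0) {
    sdlog <- sqrt(log(1 + gt$noise_cv^2))
    force <- with_local_seed(seed,
      force * rlnorm(length(force), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  hit <- which(force >= force_limit)
  if (length(hit) > 0) {
    cut <- hit[1]
    stop_reason <- "force_limit"
  } else {
    cut <- length(u)
    stop_reason <- "displacement_limit"
  }
  out <- tibble(displacement_mm = u[seq_len(cut)], force_N = force[seq_len(cut)])
  attr(out, "geometry") <- as.list(geometry[c("D0", "L0")])
  attr(out, "slant_deg") <- geometry$slant_deg %||% 0
  attr(out, "ground_truth") <- gt
  attr(out, "stop_reason") <- stop_reason
  class(out) <- c("load_displacement", class(out))
  out
}

#' Design of a virtual compression study
#'
#' @param conditions Character vector of condition labels.
#' @param replicates Replicates per condition (>= 1; studies of this kind
#'   use at least six biological replicates).
#' @param force_limit Machine stop force (N), default 1800.
#' @param displacement_limits Named numeric vector (mm), one per condition;
#'   a single value is recycled.
#' @param seed Integer master seed.
#' @return An object of class `study_design`.
#' @export
study_design <- function(conditions, replicates = 6, force_limit = 1800,
                         displacement_limits = 35, seed = 1L) {
  if (length(conditions) < 1) abort("`conditions` must name at least one condition.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  check_number(force_limit, "force_limit", positive = TRUE)
  dl <- rep_len(as.numeric(displacement_limits), length(conditions))
  names(dl) <- conditions
  if (!is.null(names(displacement_limits))) {
    common <- intersect(names(displacement_limits), conditions)
    dl[common] <- displacement_limits[common]
  }
  structure(list(conditions = conditions, replicates = as.integer(replicates),
                 force_limit = force_limit, displacement_limits = dl,
                 seed = as.integer(seed)),
            class = "study_design")
}

# Three-segment EPS-like benchmark: linear rise, gently hardening plateau,
# then densification. Report plumbing only; not a fitted material.
eps_benchmark_stress <- function(strain, E = 2.4, yield_strain = 0.05,
                                 densify_strain = 0.45) {
  sy <- E * yield_strain
  plateau <- sy * (1 + 0.2 * (strain - yield_strain))
  dens <- sy * (1 + 0.2 * (densify_strain - yield_strain)) +
    8 * sy * (strain - densify_strain)^2
  ifelse(strain <= yield_strain, E * strain,
         ifelse(strain <= densify_strain, plateau, dens))
}

eps_benchmark_curve <- function(geometry, displacement_limit = 35,
                                force_limit = 1800, step_mm = 0.1) {
  A0 <- pi * geometry$D0^2 / 4
  u <- seq(0, displacement_limit, by = step_mm)
  eps <- u / geometry$L0
  force <- A0 * eps_benchmark_stress(eps)
  hit <- which(force >= force_limit)
  cut <- if (length(hit)) hit[1] else length(u)
  out <- tibble(displacement_mm = u[seq_len(cut)], force_N = force[seq_len(cut)])
  attr(out, "geometry") <- as.list(geometry[c("D0", "L0")])
  attr(out, "slant_deg") <- 0
  attr(out, "stop_reason") <- if (length(hit)) "force_limit" else "displacement_limit"
  class(out) <- c("load_displacement", class(out))
  out
}

#' Generate a full virtual compression study
#'
#' For each condition, draws per-replicate `(c, d)` from lognormal scatter
#' around the condition means (unit-mean, coefficient of variation
#' `replicate_cv`), samples a specimen geometry, simulates the
#' load-displacement record, and assigns a post-test height from the
#' plastic fraction of the maximum strain. An EPS-like benchmark condition
#' (three-segment curve) is appended for comparative reports.
#'
#' @param design A [study_design()] object.
#' @param ground_truths Named list of [ground_truth()] objects, one per
#'   condition in `design$conditions`.
#' @param plastic_fraction Fraction of the maximum strain that remains as
#'   plastic deformation after unloading (default 0.3); sets the recorded
#'   post-test height.
#' @param eps_benchmark Append the EPS-like benchmark condition? Default TRUE.
#' @return A tibble with one row per specimen: `condition`, `replicate`,
#'   `specimen_id`, geometry columns, `true_c`, `true_d`,
#'   `post_test_height`, `stop_reason`, `is_benchmark`, and a `data`
#'   list-column of load-displacement tibbles.
#' @export
generate_study <- function(design, ground_truths, plastic_fraction = 0.3,
                           eps_benchmark = TRUE) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design.")
  missing <- setdiff(design$conditions, names(ground_truths))
  if (length(missing)) {
    abort(paste0("No ground truth given for condition(s): ",
                 paste(missing, collapse = ", ")))
  }
  n_cond <- length(design$conditions)
  seeds <- derive_seeds(design$seed, n_cond + 1L)
  rows <- purrr::imap(setNames(design$conditions, design$conditions),
                      function(cond, .nm) {
    i <- match(cond, design$conditions)
    gt <- ground_truths[[cond]]
    with_local_seed(seeds[i], {
      geoms <- generate_specimen(design$replicates)
      purrr::map(seq_len(design$replicates), function(r) {
        if (gt$replicate_cv > 0) {
          sdlog <- sqrt(log(1 + gt$replicate_cv^2))
          fac <- rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else {
          fac <- c(1, 1)
        }
        gt_r <- ground_truth(gt$c * fac[1], gt$d * fac[2], gt$toe_depth,
                             gt$toe_sharpness, gt$noise_cv, gt$replicate_cv)
        geom <- geoms[r, ]
        curve <- simulate_load_displacement(
          gt_r, geom, force_limit = design$force_limit,
          displacement_limit = design$displacement_limits[[cond]])
        eps_max <- max(curve$displacement_mm) / geom$L0
        post <- geom$L0 * (1 - plastic_fraction * eps_max)
        tibble(condition = cond, replicate = r,
               specimen_id = sprintf("%s_%02d", cond, r),
               D0 = geom$D0, L0 = geom$L0, slant_deg = geom$slant_deg,
               true_c = gt_r$c, true_d = gt_r$d,
               post_test_height = post,
               stop_reason = attr(curve, "stop_reason"),
               is_benchmark = FALSE,
               data = list(curve))
      }) |> list_rbind()
    })
  }) |> list_rbind()

  if (eps_benchmark) {
    bench <- with_local_seed(seeds[n_cond + 1L], {
      geoms <- generate_specimen(design$replicates)
      purrr::map(seq_len(design$replicates), function(r) {
        geom <- geoms[r, ]
        curve <- eps_benchmark_curve(geom,
                                     displacement_limit = max(design$displacement_limits),
                                     force_limit = design$force_limit)
        tibble(condition = "EPS_benchmark", replicate = r,
               specimen_id = sprintf("EPS_%02d", r),
               D0 = geom$D0, L0 = geom$L0, slant_deg = geom$slant_deg,
               true_c = NA_real_, true_d = NA_real_,
               post_test_height = geom$L0 * (1 - 0.05 * max(curve$displacement_mm) / geom$L0),
               stop_reason = attr(curve, "stop_reason"),
               is_benchmark = TRUE,
               data = list(curve))
      }) |> list_rbind()
    })
    rows <- bind_rows(rows, bench)
  }
  rows
}

#' Write a study to disk in the package's file layout
#'
#' One delimited text file per specimen (columns `displacement_mm`,
#' `force_N`) plus a JSON manifest recording condition, geometry, seed and
#' ground truth, so a study round-trips through [read_study()].
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest (provenance only).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map_chr(seq_len(nrow(study)), function(i) {
    f <- file.path(dir, paste0(study$specimen_id[i], ".csv"))
    write.csv(study$data[[i]], f, row.names = FALSE)
    basename(f)
  })
  manifest <- list(
    seed = seed,
    specimens = purrr::map(seq_len(nrow(study)), function(i) {
      list(specimen_id = study$specimen_id[i],
           condition = study$condition[i],
           replicate = study$replicate[i],
           file = files[i],
           D0 = study$D0[i], L0 = study$L0[i],
           slant_deg = study$slant_deg[i],
           post_test_height = study$post_test_height[i],
           true_c = study$true_c[i], true_d = study$true_d[i],
           stop_reason = study$stop_reason[i],
           is_benchmark = study$is_benchmark[i])
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `manifest.json` and per-specimen files.
#' @return A tibble in the [generate_study()] layout.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  purrr::map(manifest$specimens, function(s) {
    curve <- read_load_displacement(file.path(dir, s$file),
                                    D0 = s$D0, L0 = s$L0)
    attr(curve, "stop_reason") <- s$stop_reason
    tibble(condition = s$condition, replicate = s$replicate,
           specimen_id = s$specimen_id,
           D0 = s$D0, L0 = s$L0, slant_deg = s$slant_deg %||% 0,
           true_c = s$true_c %||% NA_real_, true_d = s$true_d %||% NA_real_,
           post_test_height = s$post_test_height %||% NA_real_,
           stop_reason = s$stop_reason, is_benchmark = isTRUE(s$is_benchmark),
           data = list(curve))
  }) |> list_rbind()
}

#' Generate synthetic substrate particle outlines
#'
#' Particles are rotated rectangles with jittered vertices (kept convex by
#' hull reconstruction): length from a lognormal distribution, width from
#' length times a lognormal aspect ratio. Two presets emulate the
#' qualitative contrast between substrates — the `"hemp"` preset has a
#' lower modal width/length ratio (thinner, more elongated particles) than
#' the `"rapeseed"` preset.
#'
#' @param n Number of particles (>= 1).
#' @param preset `"hemp"`, `"rapeseed"`, or `NULL` to use `shape_params`.
#' @param shape_params Named list overriding the preset:
#'   `length_meanlog`, `length_sdlog` (log mm), `aspect_meanlog`,
#'   `aspect_sdlog` (log width/length), `jitter` (fraction of width).
#' @param seed Optional integer for a local RNG state.
#' @return A tibble with columns `particle` and a list-column `vertices`
#'   (n x 2 matrices of mm coordinates, counter-clockwise convex polygons).
#' @export
generate_particles <- function(n, preset = c("hemp", "rapeseed"),
                               shape_params = list(), seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  defaults <- if (is.null(preset)) {
    list(length_meanlog = log(2.5), length_sdlog = 0.3,
         aspect_meanlog = log(0.4), aspect_sdlog = 0.3, jitter = 0.05)
  } else {
    preset <- match.arg(preset)
    switch(preset,
      hemp = list(length_meanlog = log(2.8), length_sdlog = 0.3,
                  aspect_meanlog = log(0.28), aspect_sdlog = 0.25,
                  jitter = 0.05),
      rapeseed = list(length_meanlog = log(2.4), length_sdlog = 0.3,
                      aspect_meanlog = log(0.48), aspect_sdlog = 0.35,
                      jitter = 0.05))
  }
  sp <- modifyList(defaults, as.list(shape_params))
  with_local_seed(seed, {
    len <- rlnorm(n, sp$length_meanlog, sp$length_sdlog)
    asp <- pmin(rlnorm(n, sp$aspect_meanlog, sp$aspect_sdlog), 1)
    ang <- runif(n, 0, pi)
    verts <- purrr::map(seq_len(n), function(i) {
      L <- len[i]; W <- asp[i] * len[i]
      v <- rbind(c(-L/2, -W/2), c(L/2, -W/2), c(L/2, W/2), c(-L/2, W/2))
      if (sp$jitter > 0) {
        v <- v + matrix(stats::rnorm(8, 0, sp$jitter * W), ncol = 2)
        h <- grDevices::chull(v)
        v <- v[h, , drop = FALSE]
      }
      rot <- matrix(c(cos(ang[i]), sin(ang[i]), -sin(ang[i]), cos(ang[i])), 2)
      out <- v %*% t(rot)
      colnames(out) <- c("x", "y")
      out
    })
    tibble(particle = seq_len(n), vertices = verts)
  })
}
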