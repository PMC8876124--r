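#' Minimum and maximum Feret diameters of a particle outline
#'
#' The Feret diameter along a direction is the distance between the two
#' parallel tangent lines perpendicular to it. The maximum Feret diameter
#' equals the largest pairwise distance between convex-hull vertices; the
#' minimum is the smallest projection width over hull-edge directions
#' (rotating-calipers equivalent: the minimal width is always attained
#' with one caliper flush against a hull edge). Both are invariant under
#' rotation and translation of the outline.
#'
#' @param outline An n x 2 matrix (or data frame with columns x, y) of
#'   vertex coordinates, n >= 3, describing a simple polygon.
#' @return A one-row tibble: `min_feret`, `max_feret`, `ratio`
#'   (`min/max`, in (0, 1]).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' feret_diameters(sq)   # (1, sqrt(2)), ratio 1/sqrt(2)
#' @export
feret_diameters <- function(outline) {
  v <- as.matrix(outline)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (nrow(v) < 3) abort("Outline needs at least 3 vertices.")
  if (any(!is.finite(v))) abort("Outline coordinates must be finite.")
  h <- grDevices::chull(v)
  if (length(h) < 3) abort("Degenerate (collinear) outline: no area.")
  hv <- v[h, , drop = FALSE]
  # max Feret: hull diameter
  dmat <- as.matrix(stats::dist(hv))
  max_f <- max(dmat)
  # min Feret: minimal width over hull edge normals
  nh <- nrow(hv)
  nxt <- c(2:nh, 1)
  widths <- vapply(seq_len(nh), function(i) {
    e <- hv[nxt[i], ] - hv[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- hv %*% nrm
    max(proj) - min(proj)
  }, numeric(1))
  min_f <- min(widths)
  tibble(min_feret = min_f, max_feret = max_f, ratio = min_f / max_f)
}

polygon_area <- function(outline) {
  v <- as.matrix(outline)[, 1:2, drop = FALSE]
  n <- nrow(v)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' Per-particle Feret summary for a particle table
#'
#' @param particles A tibble with a `vertices` list-column (as returned by
#'   [generate_particles()]), or a bare list of outlines.
#' @return A tibble with one row per particle: `particle`, `min_feret`,
#'   `max_feret`, `ratio`, `area` (mm^2).
#' @export
feret_summary <- function(particles) {
  if (!is.data.frame(particles)) {
    particles <- tibble(particle = seq_along(particles),
                        vertices = as.list(particles))
  }
  purrr::map(seq_len(nrow(particles)), function(i) {
    fd <- feret_diameters(particles$vertices[[i]])
    fd$particle <- particles$particle[i]
    fd$area <- polygon_area(particles$vertices[[i]])
    fd[c("particle", "min_feret", "max_feret", "ratio", "area")]
  }) |> list_rbind()
}

#' Histogram of min/max Feret-diameter ratios
#'
#' @param particles Particle table or list accepted by [feret_summary()]
#'   (a precomputed [feret_summary()] tibble also works).
#' @param bins Number of uniform bins on (0, 1] (default 20), or a vector
#'   of bin edges spanning (0, 1].
#' @return A list of class `feret_summary_hist`: `per_particle` (tibble),
#'   `histogram` (tibble with `bin_lo`, `bin_hi`, `bin_mid`, `count`),
#'   `modal_ratio` (midpoint of the fullest bin; ties resolved to the
#'   lower bin), `n`.
#' @export
ratio_histogram <- function(particles, bins = 20) {
  per <- if (is.data.frame(particles) && "ratio" %in% names(particles)) {
    particles
  } else {
    feret_summary(particles)
  }
  if (nrow(per) < 1) abort("At least one particle is required.")
  edges <- if (length(bins) == 1L) seq(0, 1, length.out = bins + 1L) else sort(bins)
  counts <- tabulate(findInterval(per$ratio, edges, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  hist_tbl <- tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                     bin_mid = (head(edges, -1) + tail(edges, -1)) / 2,
                     count = counts)
  modal <- hist_tbl$bin_mid[which.max(hist_tbl$count)]  # which.max -> lowest tie
  structure(list(per_particle = per, histogram = hist_tbl,
                 modal_ratio = modal, n = nrow(per)),
            class = "feret_summary_hist")
}

#' @export
print.feret_summary_hist <- function(x, ...) {
  cat(sprintf("<feret_summary_hist> %d particles, modal ratio %.3f\n",
              x$n, x$modal_ratio))
  invisible(x)
}

#' Sieve specification
#'
#' @param meshes Strictly ascending mesh sizes (mm).
#' @param labels Fraction labels; there are `length(meshes) + 1` fractions
#'   (below the finest mesh, the intervals between meshes, above the
#'   coarsest). Default labels are built from the mesh sizes with an
#'   `undersize` bucket.
#' @return An object of class `sieve_spec`.
#' @export
sieve_spec <- function(meshes = c(0.63, 2, 3.15), labels = NULL) {
  if (any(diff(meshes) <= 0)) abort("Mesh sizes must be strictly ascending.")
  if (is.null(labels)) {
    labels <- c("undersize",
                paste0(head(meshes, -1), "-", tail(meshes, -1), " mm"),
                paste0("> ", tail(meshes, 1), " mm"))
  }
  if (length(labels) != length(meshes) + 1L) {
    abort("Need one label per fraction: length(meshes) + 1.")
  }
  structure(list(meshes = meshes, labels = labels), class = "sieve_spec")
}

#' Classify particles into sieve mass fractions
#'
#' A particle passes a square mesh iff its minimum Feret diameter is
#' smaller than the mesh size (the standard proxy for elongated particles);
#' its fraction is the interval between the largest mesh it does not pass
#' and the smallest it passes. Masses default to the polygon area times a
#' unit thickness; supplied masses take precedence.
#'
#' @param particles Particle table or list accepted by [feret_summary()].
#' @param sieve A [sieve_spec()].
#' @param mass Optional numeric vector of particle masses (g); defaults to
#'   the area x unit-thickness proxy.
#' @return A tibble with one row per fraction: `fraction`, `mesh_lo`,
#'   `mesh_hi`, `n`, `mass`, `mass_fraction` (summing to 1).
#' @export
sieve_classify <- function(particles, sieve = sieve_spec(), mass = NULL) {
  per <- feret_summary(particles)
  m <- mass %||% per$area  # area x 1 mm thickness proxy
  if (length(m) != nrow(per)) abort("`mass` must have one value per particle.")
  if (any(m <= 0)) abort("Masses must be positive.")
  # fraction index: number of meshes the particle does NOT pass, + 1
  idx <- findInterval(per$min_feret, sieve$meshes) + 1L
  edges <- c(0, sieve$meshes, Inf)
  out <- tibble(fraction = sieve$labels,
                mesh_lo = head(edges, -1), mesh_hi = tail(edges, -1),
                n = tabulate(idx, nbins = length(sieve$labels)),
                mass = vapply(seq_along(sieve$labels),
                              function(k) sum(m[idx == k]), numeric(1)))
  out$mass_fraction <- out$mass / sum(out$mass)
  out
}

#' Bulk density from total mass and bulk volume
#'
#' @param mass_g Total mass (g, > 0 unless `volume_cm3` is the only zero).
#' @param volume_cm3 Bulk volume (cm^3, > 0).
#' @return Density in g/cm^3.
#' @export
bulk_density <- function(mass_g, volume_cm3) {
  check_number(mass_g, "mass_g", positive = TRUE)
  check_number(volume_cm3, "volume_cm3", positive = TRUE)
  mass_g / volume_cm3
}
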