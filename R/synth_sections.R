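#' Generate serial sections of a sphere phantom with countable particles
#'
#' Emulates exhaustive serial sectioning of a solid (a sphere of radius
#' `radius_um`) seeded with `n_particles` spherical particles ("nuclei") of
#' lognormally realistic but here normally distributed diameter. Sections
#' are slabs of thickness `thickness_um` spanning the solid. For each
#' section the generator reports:
#'
#' * `area_mm2` - the solid's cross-sectional area at the slab mid-plane
#'   (the profile a tracer would outline);
#' * `raw_count` - transect count: a particle is counted in every section
#'   its extent `[z - d/2, z + d/2)` intersects, which is exactly the
#'   overcounting the Abercrombie factor corrects;
#' * `mean_diameter_um` - mean diameter of the particles counted there.
#'
#' @param radius_um sphere radius, um.
#' @param thickness_um section thickness, um (> 0).
#' @param n_particles number of particles (>= 0).
#' @param diameter_mean_um,diameter_sd_um particle diameter distribution
#'   (normal, truncated at > 0.5 um).
#' @param seed integer seed.
#' @return data.frame of class `slice_table`: `slice_index`, `area_mm2`,
#'   `raw_count`, `mean_diameter_um`; attribute `truth` holds the inputs.
#' @export
gen_sections <- function(radius_um = 300, thickness_um = 30,
                         n_particles = 500, diameter_mean_um = 15,
                         diameter_sd_um = 0, seed) {
  stopifnot(radius_um > 0, thickness_um > 0, n_particles >= 0)
  r <- radius_um; H <- thickness_um
  edges <- seq(-r, r, by = H)
  if (edges[length(edges)] < r) edges <- c(edges, edges[length(edges)] + H)
  n_sec <- length(edges) - 1L
  mid <- (edges[-length(edges)] + edges[-1L]) / 2
  area_um2 <- pmax(r^2 - mid^2, 0) * pi
  dat <- with_rng(seed, {
    if (n_particles == 0L) {
      data.frame(z = numeric(0), d = numeric(0))
    } else {
      # uniform positions inside the sphere via rejection
      pts <- matrix(numeric(0), ncol = 3)
      while (nrow(pts) < n_particles) {
        cand <- matrix(stats::runif(3 * n_particles * 2, -r, r), ncol = 3)
        cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts <- pts[seq_len(n_particles), , drop = FALSE]
      d <- stats::rnorm(n_particles, diameter_mean_um, diameter_sd_um)
      data.frame(z = pts[, 3], d = pmax(d, 0.5))
    }
  })
  raw <- integer(n_sec); mean_d <- rep(NA_real_, n_sec)
  if (nrow(dat)) {
    for (i in seq_len(n_sec)) {
      hit <- dat$z - dat$d / 2 < edges[i + 1L] & dat$z + dat$d / 2 >= edges[i]
      raw[i] <- sum(hit)
      if (raw[i]) mean_d[i] <- mean(dat$d[hit])
    }
  }
  out <- data.frame(slice_index = seq_len(n_sec), area_mm2 = area_um2 / 1e6,
                    raw_count = raw, mean_diameter_um = mean_d)
  attr(out, "truth") <- list(radius_um = r, thickness_um = H,
                             n_particles = n_particles,
                             diameter_mean_um = diameter_mean_um,
                             diameter_sd_um = diameter_sd_um, seed = seed)
  class(out) <- c("slice_table", "data.frame")
  out
}
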