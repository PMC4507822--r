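#' Cavalieri volume estimate
#'
#' Volume = d * (a1 + a2 + a3 + ...): the distance between serial sections
#' times the sum of the per-section cross-sectional areas.
#'
#' @param areas_mm2 per-section areas, mm^2 (>= 0).
#' @param d_um distance between sections, um (> 0).
#' @return volume in mm^3 (0 for an empty list).
#' @export
cavalieri_volume <- function(areas_mm2, d_um) {
  if (!is.numeric(d_um) || d_um <= 0) stop("d must be positive", call. = FALSE)
  if (length(areas_mm2) == 0L) return(0)
  if (any(!is.finite(areas_mm2)) || any(areas_mm2 < 0))
    stop("areas must be finite and >= 0", call. = FALSE)
  (d_um / 1000) * sum(areas_mm2)
}

#' Abercrombie correction factor
#'
#' Profile counts from sections overcount particles because a particle of
#' height `h` is seen in every section its extent crosses: on average
#' `(T + h)/T` sections of thickness `T`. The Abercrombie factor
#' `N = T / (T + h)` multiplies raw counts to undo this. `N` is in (0, 1),
#' tends to 1 for vanishing particle size, and grows with section thickness
#' (thicker sections overcount relatively less).
#'
#' @param thickness_um section thickness `T`, um (> 0).
#' @param diameter_um particle height/diameter `h`, um (> 0).
#' @return correction factor in (0, 1).
#' @export
abercrombie_factor <- function(thickness_um, diameter_um) {
  if (any(thickness_um <= 0)) stop("thickness must be positive", call. = FALSE)
  if (any(diameter_um <= 0)) stop("diameter must be positive", call. = FALSE)
  thickness_um / (thickness_um + diameter_um)
}

#' Corrected particle count and density from a slice table
#'
#' Per slice, the raw profile count is multiplied by the Abercrombie factor
#' computed from that slice's own mean particle diameter (a global-diameter
#' mode is available via `global_diameter`); the corrected counts are
#' summed. Volume comes from [cavalieri_volume()] with section spacing `d_um`
#' (defaulting to the section thickness, as when every section is kept), and
#' density = corrected count / volume.
#'
#' @param slices data.frame with `area_mm2`, `raw_count`,
#'   `mean_diameter_um` (as from [gen_sections()] or [read_stereology_csv()]).
#' @param thickness_um section thickness `T`, um.
#' @param d_um section spacing for the Cavalieri sum, um (default
#'   `thickness_um`).
#' @param global_diameter optional single diameter (um) used for all slices
#'   instead of per-slice means.
#' @return list of class `stereology_result`: `volume_mm3`,
#'   `corrected_count`, `raw_count`, `density_per_mm3`, `per_slice_factors`.
#' @export
corrected_density <- function(slices, thickness_um, d_um = thickness_um,
                              global_diameter = NULL) {
  stopifnot(is.data.frame(slices),
            all(c("area_mm2", "raw_count", "mean_diameter_um") %in%
                  names(slices)))
  if (any(slices$raw_count < 0)) stop("raw counts must be >= 0", call. = FALSE)
  dia <- if (is.null(global_diameter)) slices$mean_diameter_um
         else rep(global_diameter, nrow(slices))
  fac <- rep(NA_real_, nrow(slices))
  use <- slices$raw_count > 0
  if (any(use & (!is.finite(dia) | dia <= 0)))
    stop("slices with nonzero counts need a positive mean diameter",
         call. = FALSE)
  fac[use] <- abercrombie_factor(thickness_um, dia[use])
  corrected <- sum(slices$raw_count[use] * fac[use])
  vol <- cavalieri_volume(slices$area_mm2, d_um)
  if (vol == 0 && corrected > 0)
    stop("zero volume with nonzero counts: check areas", call. = FALSE)
  structure(
    list(volume_mm3 = vol, corrected_count = corrected,
         raw_count = sum(slices$raw_count),
         density_per_mm3 = if (vol > 0) corrected / vol else 0,
         per_slice_factors = fac),
    class = "stereology_result")
}

#' @export
print.stereology_result <- function(x, ...) {
  cat(sprintf(
    "<stereology_result> volume %.4f mm^3, corrected count %.1f (raw %d), density %.1f /mm^3\n",
    x$volume_mm3, x$corrected_count, x$raw_count, x$density_per_mm3))
  invisible(x)
}
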