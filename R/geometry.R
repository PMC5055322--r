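#' Sarcomere filament geometry
#'
#' Bundles the lengths that determine how much of the thin filament lies in
#' the single-overlap region at a given sarcomere length. Defaults follow the
#' Rice et al. (2008) myofilament geometry: a 1.65 um thick filament with a
#' 0.1 um central bare zone, and 1.2 um thin filaments.
#'
#' @param sl Sarcomere length (Z-disk to Z-disk), um. The supported range is
#'   1.85--2.25 um, the range over which skinned-muscle calcium-tension
#'   measurements are available.
#' @param thick_len Thick filament length, um.
#' @param thin_len Thin filament length, um.
#' @param bare_zone_len Length of the cross-bridge-free bare zone at the
#'   centre of the thick filament, um.
#'
#' @return An object of class `"sarcomere_geometry"`: a list with the four
#'   lengths.
#' @examples
#' g <- sarcomere_geometry(2.05)
#' single_overlap_length(g)
#' @export
sarcomere_geometry <- function(sl, thick_len = 1.65, thin_len = 1.2,
                               bare_zone_len = 0.1) {
  stopifnot(is.numeric(sl), length(sl) == 1L,
            is.numeric(thick_len), is.numeric(thin_len),
            is.numeric(bare_zone_len))
  if (!is.finite(sl) || sl <= 0)
    stop("sarcomere length must be a positive finite number, got ", sl)
  if (thick_len <= 0 || thin_len <= 0 || bare_zone_len <= 0)
    stop("all filament lengths must be strictly positive")
  if (bare_zone_len >= thick_len)
    stop("bare zone (", bare_zone_len, " um) must be shorter than the thick filament (",
         thick_len, " um)")
  if (sl < 1.85 - 1e-9 || sl > 2.25 + 1e-9)
    stop("sarcomere length ", sl, " um is outside the supported range [1.85, 2.25] um")
  structure(list(sl = sl, thick_len = thick_len, thin_len = thin_len,
                 bare_zone_len = bare_zone_len),
            class = "sarcomere_geometry")
}

#' @export
print.sarcomere_geometry <- function(x, ...) {
  cat("Sarcomere geometry: SL", x$sl, "um",
      "(thick", x$thick_len, "| thin", x$thin_len,
      "| bare zone", x$bare_zone_len, "um)\n")
  cat("  single-overlap length x_max:",
      format(single_overlap_length(x), digits = 4), "um\n")
  invisible(x)
}

#' Single-overlap length of the thin filament
#'
#' Length of the region where a thin filament overlaps the cross-bridge
#' bearing part of the thick filament without running into the opposing thin
#' filament (double overlap). Cross-bridges, and hence active tension, form
#' only in this region. Measured from the mid-line end of the overlap region
#' (x = 0) toward the Z-disk, the overlap runs from
#' `max(thin_len - sl/2, bare_zone_len/2)` to `min(thick_len/2, sl/2)` in
#' distance from the sarcomere centre; the difference is `x_max`.
#'
#' Over the supported sarcomere-length range the double-overlap edge recedes
#' as the sarcomere lengthens, so `x_max` is non-decreasing in `sl`.
#'
#' @param geom A [sarcomere_geometry()] object.
#' @return Single-overlap length `x_max`, um (scalar, >= 0).
#' @examples
#' single_overlap_length(sarcomere_geometry(1.85)) # 0.55 um
#' single_overlap_length(sarcomere_geometry(2.25)) # 0.75 um
#' @export
single_overlap_length <- function(geom) {
  stopifnot(inherits(geom, "sarcomere_geometry"))
  zline_edge <- min(geom$thick_len / 2, geom$sl / 2)
  centre_edge <- max(geom$thin_len - geom$sl / 2, geom$bare_zone_len / 2)
  max(zline_edge - centre_edge, 0)
}
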