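#' Well geometry for the fluid column above a disk
#'
#' Describes the quiescent fluid column sitting on top of a biomaterial disk:
#' a cylinder whose cross-section equals the disk's top face, so the column
#' height is `volume / area`. The default is 200 uL of medium over a 6 mm
#' diameter disk (height ~ 7.074 mm), the standard well-plate configuration
#' for disk incubation assays.
#'
#' @param fluid_volume_uL Fluid volume in microlitres. Must be positive.
#' @param disk_diameter_mm Disk diameter in millimetres. Must be positive.
#' @return An object of class `well_geometry`: a list with `fluid_volume_uL`,
#'   `disk_diameter_mm`, `area_mm2` (disk top face), `height_mm` (fluid
#'   column height) and `volume_mm3`.
#' @examples
#' geom <- well_geometry()
#' geom$height_mm # ~7.074
#' @export
well_geometry <- function(fluid_volume_uL = 200, disk_diameter_mm = 6) {
  stopifnot(is.numeric(fluid_volume_uL), length(fluid_volume_uL) == 1,
            is.finite(fluid_volume_uL), fluid_volume_uL > 0,
            is.numeric(disk_diameter_mm), length(disk_diameter_mm) == 1,
            is.finite(disk_diameter_mm), disk_diameter_mm > 0)
  area <- pi * (disk_diameter_mm / 2)^2
  volume_mm3 <- fluid_volume_uL # 1 uL == 1 mm^3
  structure(
    list(fluid_volume_uL = fluid_volume_uL,
         disk_diameter_mm = disk_diameter_mm,
         area_mm2 = area,
         height_mm = volume_mm3 / area,
         volume_mm3 = volume_mm3),
    class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf("Well geometry: %.4g uL over a %.4g mm disk\n",
              x$fluid_volume_uL, x$disk_diameter_mm))
  cat(sprintf("  area %.4f mm^2, fluid height %.4f mm\n",
              x$area_mm2, x$height_mm))
  invisible(x)
}

assert_geometry <- function(geometry) {
  if (!inherits(geometry, "well_geometry"))
    stop("`geometry` must be created by well_geometry()", call. = FALSE)
  geometry
}

#' Convert a fluid-phase concentration change to an areal surface density
#'
#' A depletion `delta_c` (ug/mL) of the whole fluid column corresponds to a
#' mass `delta_c * volume` that ends up on the disk face, i.e. an areal
#' density of `delta_c * volume[mL] / area[mm^2]` ug/mm^2. For the default
#' geometry, the 4100 ug/mL depletion seen in disk incubation experiments
#' converts to ~29.0 ug/mm^2.
#'
#' @param delta_c Fluid concentration change in ug/mL (scalar or vector).
#' @param geometry A [well_geometry()].
#' @return Surface density in ug/mm^2.
#' @seealso [surface_to_fluid()] for the inverse.
#' @export
fluid_to_surface <- function(delta_c, geometry = well_geometry()) {
  assert_geometry(geometry)
  delta_c * (geometry$fluid_volume_uL / 1000) / geometry$area_mm2
}

#' Convert an areal surface density to the equivalent fluid concentration
#'
#' Inverse of [fluid_to_surface()]: the fluid concentration change produced
#' by releasing `delta_cs` (ug/mm^2) from the disk face into the column.
#'
#' @param delta_cs Surface density in ug/mm^2 (scalar or vector).
#' @param geometry A [well_geometry()].
#' @return Fluid concentration in ug/mL.
#' @export
surface_to_fluid <- function(delta_cs, geometry = well_geometry()) {
  assert_geometry(geometry)
  delta_cs * geometry$area_mm2 / (geometry$fluid_volume_uL / 1000)
}
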