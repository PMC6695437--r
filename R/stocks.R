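#' Subsoil organic-carbon stock
#'
#' Converts soil-attribute layers into the SOC stock of the layer:
#' `SOC = OC/100 * D * BD * (1 - G/100)` in kg C m-2, where `OC` is organic
#' carbon as percent of soil weight, `D` the layer thickness (m), `BD` the
#' bulk density and `G` gravel as percent of soil volume. The canonical bulk
#' density unit is kg m-3; soil databases often ship g cm-3, declared via
#' `bd_units` and converted (x1000) on entry.
#'
#' @param oc_percent [grid2d()] of organic-carbon content, percent of weight.
#' @param bd [grid2d()] of bulk density.
#' @param gravel_percent [grid2d()] of gravel content, percent of volume.
#' @param thickness Layer thickness in metres (0.7 for the 0.3-1 m layer).
#' @param bd_units Either `"kg m-3"` (default) or `"g cm-3"`.
#' @return A [grid2d()] named `SOC` (kg C m-2), masked wherever any input is
#'   masked.
#' @export
compute_stock <- function(oc_percent, bd, gravel_percent, thickness = 0.7,
                          bd_units = c("kg m-3", "g cm-3")) {
  stopifnot(is_grid2d(oc_percent), is_grid2d(bd), is_grid2d(gravel_percent))
  bd_units <- match.arg(bd_units)
  if (thickness <= 0) stop("thickness must be positive")
  mask <- oc_percent$mask | bd$mask | gravel_percent$mask
  oc <- oc_percent$values
  g <- gravel_percent$values
  bdv <- bd$values * if (bd_units == "g cm-3") 1000 else 1
  ok <- !mask
  bad <- ok & (oc < 0 | oc > 100)
  if (any(bad))
    stop("organic-carbon percent outside [0, 100] at pixel index ",
         which(bad)[1])
  bad <- ok & (g < 0 | g > 100)
  if (any(bad))
    stop("gravel percent outside [0, 100] at pixel index ", which(bad)[1])
  bad <- ok & bdv <= 0
  if (any(bad))
    stop("non-positive bulk density at pixel index ", which(bad)[1])
  soc <- oc / 100 * thickness * bdv * (1 - g / 100)
  soc[mask] <- NA_real_
  grid2d(soc, mask, origin_lat = oc_percent$origin_lat,
         origin_lon = oc_percent$origin_lon,
         resolution = oc_percent$resolution,
         name = "SOC", units = "kg C m-2")
}
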