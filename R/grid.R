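#' Georeferenced 2-D grid
#'
#' The atom all raster layers share: a matrix of values, a nodata mask, and a
#' north-up georeference. Row 1 is the northernmost row; the pixel centre of
#' cell (i, j) sits at `origin_lat - (i - 0.5) * resolution` and
#' `origin_lon + (j - 0.5) * resolution`, where the origin is the upper-left
#' corner of the top-left pixel.
#'
#' @param values Numeric matrix of cell values (variable-specific units).
#' @param mask Logical matrix, `TRUE` where the cell holds no data. Defaults
#'   to `is.na(values)`.
#' @param origin_lat,origin_lon Degrees of the top-left pixel's upper-left
#'   corner.
#' @param resolution Degrees per (square) pixel; must be positive.
#' @param name Variable identifier.
#' @param units Free-text units.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(values, mask = NULL, origin_lat, origin_lon, resolution,
                   name = "value", units = "") {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(values), dim(mask)))
    stop("values and mask must have identical shape")
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (resolution <= 0) stop("resolution must be positive")
  south <- origin_lat - nrow(values) * resolution
  if (origin_lat > 90 + 1e-9 || south < -90 - 1e-9)
    stop("latitude extent must stay within [-90, 90]")
  structure(
    list(values = values, mask = mask, origin_lat = origin_lat,
         origin_lon = origin_lon, resolution = resolution,
         name = name, units = units),
    class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %s [%s]: %d x %d @ %g deg, %d masked\n",
              x$name, x$units, nrow(x$values), ncol(x$values),
              x$resolution, sum(x$mask)))
  invisible(x)
}

is_grid2d <- function(x) inherits(x, "grid2d")

#' Latitudes of pixel-row centres
#' @param grid A [grid2d()].
#' @return Numeric vector, one latitude per row (north to south).
#' @export
grid_lat_centers <- function(grid) {
  grid$origin_lat - (seq_len(nrow(grid$values)) - 0.5) * grid$resolution
}

#' Read a grid from a plain-text raster file
#'
#' Reads the package's plain-text raster dialect: a 6-line ASCII-grid-style
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `nodata_value`) followed by `nrows` rows of whitespace-separated values,
#' the first row being the northernmost.
#'
#' @param path File path.
#' @param variable Optional variable name to attach; defaults to the file
#'   stem.
#' @param units Units string to attach.
#' @return A [grid2d()] with nodata entries masked.
#' @export
read_grid <- function(path, variable = NULL, units = "") {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line in ", path, ": ", ln)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("header of ", path, " is missing: ", paste(miss, collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  dat <- scan(path, what = double(), skip = 6L, quiet = TRUE,
              na.strings = c("NA", "NaN"))
  if (length(dat) != nr * nc)
    stop("expected ", nr * nc, " values in ", path, ", found ", length(dat))
  values <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- is.na(values) | values == hdr$nodata_value
  values[mask] <- NA_real_
  grid2d(values, mask,
         origin_lat = hdr$yllcorner + nr * hdr$cellsize,
         origin_lon = hdr$xllcorner,
         resolution = hdr$cellsize,
         name = if (is.null(variable)) sub("\\.[^.]*$", "", basename(path))
                else variable,
         units = units)
}

#' Write a grid to a plain-text raster file
#'
#' Inverse of [read_grid()]. Finite values survive a write/read round trip
#' bit-exactly (17 significant digits); masked cells are written as the
#' nodata value.
#'
#' @param grid A [grid2d()].
#' @param path Output file path.
#' @param nodata_value Sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata_value = -9999) {
  stopifnot(is_grid2d(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.17g", grid$origin_lon)),
    paste("yllcorner", sprintf("%.17g", grid$origin_lat - nr * grid$resolution)),
    paste("cellsize", sprintf("%.17g", grid$resolution)),
    paste("nodata_value", sprintf("%.17g", nodata_value))), con)
  v <- grid$values
  v[grid$mask] <- nodata_value
  for (i in seq_len(nr))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' Assemble co-registered layers into a world stack
#'
#' @param grids Named list of [grid2d()] objects, or named character vector of
#'   file paths (read with [read_grid()]).
#' @param tol Georeference tolerance in degrees.
#' @return An object of class `world_stack`.
#' @export
assemble_stack <- function(grids, tol = 1e-9) {
  if (is.character(grids)) {
    paths <- grids
    grids <- lapply(seq_along(paths), function(i)
      read_grid(paths[i], variable = names(paths)[i]))
    names(grids) <- names(paths)
  }
  if (length(grids) == 0) stop("no layers supplied")
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("layers must be named")
  ref <- grids[[1]]
  for (nm in names(grids)) {
    g <- grids[[nm]]
    if (!is_grid2d(g)) stop("layer ", nm, " is not a grid2d")
    if (!identical(dim(g$values), dim(ref$values)))
      stop("alignment error: layers ", names(grids)[1], " and ", nm,
           " differ in shape")
    if (abs(g$origin_lat - ref$origin_lat) > tol ||
        abs(g$origin_lon - ref$origin_lon) > tol ||
        abs(g$resolution - ref$resolution) > tol)
      stop("alignment error: layers ", names(grids)[1], " and ", nm,
           " differ in georeference beyond ", tol, " degrees")
  }
  structure(
    list(grids = grids, nrows = nrow(ref$values), ncols = ncol(ref$values),
         origin_lat = ref$origin_lat, origin_lon = ref$origin_lon,
         resolution = ref$resolution),
    class = "world_stack")
}

#' @export
print.world_stack <- function(x, ...) {
  cat(sprintf("<world_stack> %d x %d @ %g deg; layers: %s\n",
              x$nrows, x$ncols, x$resolution,
              paste(names(x$grids), collapse = ", ")))
  invisible(x)
}

#' Combined nodata mask of a stack
#'
#' A pixel is valid iff it is valid in every requested layer, so the combined
#' mask is the union of member masks (adding a layer never unmasks a pixel).
#'
#' @param stack A `world_stack`.
#' @param vars Layer names to combine; defaults to all.
#' @return Logical matrix, `TRUE` = invalid in at least one layer.
#' @export
stack_mask <- function(stack, vars = names(stack$grids)) {
  miss <- setdiff(vars, names(stack$grids))
  if (length(miss))
    stop("stack has no layer(s): ", paste(miss, collapse = ", "),
         "; available: ", paste(names(stack$grids), collapse = ", "))
  m <- matrix(FALSE, stack$nrows, stack$ncols)
  for (v in vars) m <- m | stack$grids[[v]]$mask
  m
}

#' Fixed biome code book
#'
#' @return Named integer vector mapping the nine biome classes to their codes.
#' @export
biome_codes <- function() {
  c("tropical/subtropical forests" = 1L,
    "tropical/subtropical grasslands/savannas" = 2L,
    "temperate forests" = 3L,
    "temperate grasslands" = 4L,
    "Mediterranean/montane shrublands" = 5L,
    "boreal forests" = 6L,
    "tundra" = 7L,
    "deserts" = 8L,
    "croplands" = 9L)
}
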