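#' Shape parameter of the logistic dose-response root-depth curve
#'
#' The cumulative root profile is `F(D) = 1 / (1 + (D/D50)^c)`, where `D50`
#' and `D95` are the depths above which 50% and 95% of total root mass lie.
#' Anchoring the curve at those two depths forces
#' `c = -log10(19) / (log10 D95 - log10 D50)`; the literature prints the
#' numerator rounded to -1.27875. The exact constant is used here so that
#' `F(D95) = 0.95` holds to machine precision.
#'
#' @param d50,d95 Depths in metres, `0 < d50 < d95`.
#' @return The (negative) dimensionless shape parameter.
#' @export
shape_parameter <- function(d50, d95) {
  if (any(!(d50 > 0 & d95 > d50)))
    stop("need 0 < d50 < d95 (equal depths leave the shape undefined)")
  -log10(19) / (log10(d95) - log10(d50))
}

#' Logistic dose-response root-depth curve
#'
#' @inheritParams shape_parameter
#' @return An object of class `root_curve` holding `d50`, `d95` and the shape
#'   parameter `c`.
#' @seealso [cumulative_fraction()], [layer_fraction()]
#' @export
root_curve <- function(d50, d95) {
  structure(list(d50 = d50, d95 = d95, c = shape_parameter(d50, d95)),
            class = "root_curve")
}

#' Cumulative root fraction above a depth
#'
#' Evaluates `F(D) = 1 / (1 + (D/D50)^c)`, the fraction of total root mass
#' above depth `D`. By construction `F(D50) = 0.5` and `F(D95) = 0.95`;
#' `F(0) = 0` in the limit and `F` is strictly increasing.
#'
#' @param curve A [root_curve()].
#' @param depth Depth(s) in metres, `>= 0`.
#' @return Fraction(s) in `[0, 1)`.
#' @export
cumulative_fraction <- function(curve, depth) {
  stopifnot(inherits(curve, "root_curve"))
  if (any(depth < 0)) stop("depth must be non-negative")
  ifelse(depth == 0, 0, 1 / (1 + (depth / curve$d50)^curve$c))
}

#' Root fraction within a depth layer
#'
#' `F(bottom) - F(top)`: with the default bounds this is the fraction of
#' roots in the 0.3-1 m layer.
#'
#' @param curve A [root_curve()].
#' @param top,bottom Layer bounds in metres, `0 <= top < bottom`.
#' @return Fraction in `[0, 1)`.
#' @export
layer_fraction <- function(curve, top = 0.3, bottom = 1.0) {
  if (any(!(top >= 0 & top < bottom))) stop("need 0 <= top < bottom")
  cumulative_fraction(curve, bottom) - cumulative_fraction(curve, top)
}

# Vectorised layer fraction over (d50, d95) pairs; used by the ensemble.
# top/bottom are scalars with 0 <= top < bottom.
layer_fraction_v <- function(d50, d95, top = 0.3, bottom = 1.0) {
  cc <- -log10(19) / (log10(d95) - log10(d50))
  fb <- 1 / (1 + (bottom / d50)^cc)
  ft <- if (top == 0) 0 else 1 / (1 + (top / d50)^cc)
  fb - ft
}

# Validate an allocation-tables object (see generate_allocation_tables()).
validate_allocation_tables <- function(tables) {
  f <- tables$fbnpp_records
  r <- tables$root_records
  if (!all(c("biome", "f_bnpp") %in% names(f)))
    stop("fbnpp_records needs columns biome, f_bnpp")
  if (!all(c("biome", "d50_m", "d95_m") %in% names(r)))
    stop("root_records needs columns biome, d50_m, d95_m")
  if (any(f$f_bnpp <= 0 | f$f_bnpp >= 1))
    stop("all f_bnpp must lie in (0, 1)")
  if (any(!(r$d50_m > 0 & r$d95_m > r$d50_m)))
    stop("all root records must satisfy d95 > d50 > 0")
  for (b in 1:8) {
    if (sum(r$biome == b) < 2)
      stop("biome ", b, " needs at least 2 root records")
    if (sum(f$biome == b) < 2)
      stop("biome ", b, " needs at least 2 f_bnpp records")
  }
  if (!(tables$crop_d50_mean > 0)) stop("crop_d50_mean must be positive")
  if (!(tables$crop_d95_ratio > 1)) stop("crop_d95_ratio must exceed 1")
  invisible(tables)
}

# Per-biome resampling pools: f_bnpp values and precomputed layer fractions
# for every root record. Croplands (code 9) are parametric and flagged.
allocation_pools <- function(tables, top = 0.3, bottom = 1.0) {
  pools <- list()
  for (b in 1:9) {
    f <- tables$fbnpp_records$f_bnpp[tables$fbnpp_records$biome == b]
    if (b == 9L) {
      pools[[b]] <- list(f = f, fr = NULL, crop = TRUE)
    } else {
      rr <- tables$root_records[tables$root_records$biome == b, , drop = FALSE]
      fr <- if (nrow(rr)) layer_fraction_v(rr$d50_m, rr$d95_m, top, bottom)
            else numeric(0)
      pools[[b]] <- list(f = f, fr = fr, crop = FALSE)
    }
  }
  pools
}

#' Draw bootstrap allocation samples for a biome
#'
#' For biomes 1-8, `f_bnpp` and the root record are drawn independently with
#' replacement from that biome's observation tables (the two source
#' compilations are unrelated, so the resamples are not paired). For
#' croplands (biome 9), `d50` is drawn from a positive-truncated normal with
#' the reported mean and a standard error of 10% of the mean, `d95` is a
#' fixed multiple of `d50`, and `f_bnpp` is resampled from the crop records.
#'
#' @param tables An allocation-tables object
#'   (see [generate_allocation_tables()]).
#' @param biome Integer biome code in 1..9.
#' @param n Number of draws.
#' @param top,bottom Soil-layer bounds in metres.
#' @return A data frame with columns `f_bnpp`, `fr` and the sampled `d50_m`
#'   (`n` rows). Draws use the current RNG stream; seed it for
#'   reproducibility.
#' @export
sample_allocation <- function(tables, biome, n = 1L, top = 0.3, bottom = 1.0) {
  if (!(biome %in% 1:9)) stop("biome must be an integer code in 1..9")
  f_pool <- tables$fbnpp_records$f_bnpp[tables$fbnpp_records$biome == biome]
  if (length(f_pool) == 0)
    stop("no f_bnpp records for biome ", biome)
  if (biome == 9L) {
    d50 <- rnorm_trunc_pos(n, tables$crop_d50_mean,
                           tables$crop_d50_se_fraction * tables$crop_d50_mean)
    fr <- layer_fraction_v(d50, d50 * tables$crop_d95_ratio, top, bottom)
  } else {
    rr <- tables$root_records[tables$root_records$biome == biome, , drop = FALSE]
    if (nrow(rr) == 0) stop("no root records for biome ", biome)
    idx <- sample.int(nrow(rr), n, replace = TRUE)
    d50 <- rr$d50_m[idx]
    fr <- layer_fraction_v(d50, rr$d95_m[idx], top, bottom)
  }
  f <- f_pool[sample.int(length(f_pool), n, replace = TRUE)]
  data.frame(f_bnpp = f, fr = fr, d50_m = d50)
}

#' Carbon input flux to the soil layer
#'
#' `BNPP = NPP * f_bnpp * fr`: total net primary production times the
#' belowground allocation fraction times the root fraction in the layer.
#'
#' @param npp Net primary production, kg C m-2 yr-1 (`>= 0`).
#' @param f_bnpp Fraction of NPP allocated belowground.
#' @param fr Fraction of belowground allocation entering the layer.
#' @return Flux in kg C m-2 yr-1.
#' @export
bnpp_layer <- function(npp, f_bnpp, fr) {
  if (any(npp < 0)) stop("npp must be non-negative")
  npp * f_bnpp * fr
}
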