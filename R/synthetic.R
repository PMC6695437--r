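#' Configuration of the synthetic world generator
#'
#' The generator emulates the statistical structure of the gridded soil,
#' climate and productivity sources the pipeline was designed for: spatially
#' autocorrelated fields (Gaussian-filtered white noise), a latitudinal
#' temperature gradient, lognormal precipitation, skewed positive
#' productivity, biome-blocked allocation observations, and a configurable,
#' *known* causal dependence of the decomposition rate on soil versus climate
#' drivers so that attribution can be checked against ground truth.
#'
#' @param nrows,ncols Grid size in pixels.
#' @param resolution Degrees per pixel.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param biome_layout `"latitudinal_bands"` (nine bands symmetric about the
#'   equator) or `"voronoi_patches"` (nearest-seed patches).
#' @param spatial_correlation_length Gaussian-filter scale in pixels.
#' @param driver_mode One of `"soil_dominant"`, `"climate_dominant"`,
#'   `"mixed"`, `"null"`; selects the default effect sizes on the log
#'   decomposition rate.
#' @param effect_sizes Optional named numeric vector of per-driver
#'   coefficients on the (standardised-driver) log decomposition rate;
#'   recognised names are the twelve predictors plus `"soilQ"`, the latent
#'   soil-quality factor. Overrides the `driver_mode` defaults.
#' @param noise_sd Lognormal residual SD of the turnover-time components.
#' @param soil_factor_loading Loading of each chemical soil field on the
#'   shared soil-quality factor; defaults to 0.6 for `mixed`/`null` (real
#'   soil properties covary) and 0 for the single-driver recovery modes.
#' @param records_per_biome Observation-table records per biome.
#' @param crop_d50_mean,crop_d50_se_fraction Parametric crop root-depth rule:
#'   mean `D50` (m) and its standard error as a fraction of the mean.
#' @param crop_d95_ratio Crop `D95`/`D50` ratio (the source compilation does
#'   not report crop `D95`).
#' @param tau_scale Baseline turnover time in years at average driver values.
#' @param origin_lat,origin_lon Upper-left corner; defaults centre the grid
#'   on the equator.
#' @return A list of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(nrows = 120L, ncols = 120L,
                                   resolution = 0.25, seed = 1L,
                                   biome_layout = c("latitudinal_bands",
                                                    "voronoi_patches"),
                                   spatial_correlation_length = 8,
                                   driver_mode = c("mixed", "soil_dominant",
                                                   "climate_dominant", "null"),
                                   effect_sizes = NULL,
                                   noise_sd = 0.3,
                                   soil_factor_loading = NULL,
                                   records_per_biome = 30L,
                                   crop_d50_mean = 0.15,
                                   crop_d50_se_fraction = 0.10,
                                   crop_d95_ratio = 5,
                                   tau_scale = 200,
                                   origin_lat = NULL, origin_lon = 0) {
  biome_layout <- match.arg(biome_layout)
  driver_mode <- match.arg(driver_mode)
  if (nrows * ncols == 0) stop("configuration error: empty grid")
  if (is.null(effect_sizes)) effect_sizes <- default_effect_sizes(driver_mode)
  if (any(!is.finite(effect_sizes))) stop("effect sizes must be finite")
  if (is.null(soil_factor_loading))
    soil_factor_loading <-
      if (driver_mode %in% c("mixed", "null")) 0.6 else 0
  if (is.null(origin_lat)) origin_lat <- nrows * resolution / 2
  structure(
    list(nrows = as.integer(nrows), ncols = as.integer(ncols),
         resolution = resolution, seed = as.integer(seed),
         biome_layout = biome_layout,
         spatial_correlation_length = spatial_correlation_length,
         driver_mode = driver_mode, effect_sizes = effect_sizes,
         noise_sd = noise_sd, soil_factor_loading = soil_factor_loading,
         records_per_biome = as.integer(records_per_biome),
         crop_d50_mean = crop_d50_mean,
         crop_d50_se_fraction = crop_d50_se_fraction,
         crop_d95_ratio = crop_d95_ratio, tau_scale = tau_scale,
         origin_lat = origin_lat, origin_lon = origin_lon),
    class = "synthetic_world_config")
}

# Default per-driver coefficients on the log decomposition rate. A positive
# coefficient speeds decomposition (shortens turnover). "soilQ" is the latent
# soil-quality factor behind the chemical soil fields.
default_effect_sizes <- function(mode) {
  switch(mode,
    soil_dominant = c(pH = 1.0, clay = 0.12, TEB = 0.08,
                      MAT = 0.12, MAP = 0.06),
    climate_dominant = c(MAT = 1.0, MAP = 0.25, pH = 0.10, clay = 0.05),
    mixed = c(MAT = 0.45, MAP = 0.12,
              pH = -0.35, TEB = -0.25, clay = -0.15, CaCO3 = -0.12,
              BS = -0.15, silt = -0.08, sand = 0.10),
    null = c(MAT = 0))
}

# Gaussian-smoothed standard-normal field: white noise convolved with a
# separable Gaussian kernel (circular convolution, so the field is
# stationary with no edge artifacts), re-standardised to mean 0, sd 1.
# Cheap stand-in for geostatistical simulation; the stated correlation
# length is the kernel sigma in pixels.
smooth_field <- function(nrows, ncols, sigma) {
  z <- matrix(rnorm(nrows * ncols), nrows, ncols)
  if (sigma <= 0) return(z)
  conv1 <- function(v) {
    # circular convolution needs the kernel no longer than the series
    half <- min(max(1L, ceiling(3 * sigma)), (length(v) - 1L) %/% 2L)
    if (half < 1L) return(v)
    k <- dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    as.numeric(stats::filter(v, k, sides = 2, circular = TRUE))
  }
  z <- apply(z, 2, conv1)
  z <- t(apply(z, 1, conv1))
  (z - mean(z)) / sd(z)
}

#' Generate biome-blocked allocation observation tables
#'
#' Emulates the two field compilations behind NPP partitioning: belowground
#' allocation fractions `f_bnpp` (beta-distributed, forests low ~0.2-0.35,
#' grasslands and tundra high ~0.5-0.8) and root-profile depths `(D50, D95)`
#' (lognormal depths with biome-specific means and `D95/D50 > 1`). Root
#' records cover biomes 1-8; croplands are governed by the parametric crop
#' rule carried in the returned object.
#'
#' @param cfg A [synthetic_world_config()].
#' @return A list of class `allocation_tables` with `fbnpp_records`
#'   (biome, f_bnpp), `root_records` (biome, d50_m, d95_m), and the crop-rule
#'   parameters.
#' @export
generate_allocation_tables <- function(cfg) {
  set.seed(pixel_seed(cfg$seed, 1L, 0L))
  n <- cfg$records_per_biome
  f_mu <- c(0.25, 0.55, 0.30, 0.60, 0.45, 0.35, 0.65, 0.50, 0.40)
  phi <- 50
  fbnpp <- do.call(rbind, lapply(1:9, function(b)
    data.frame(biome = b,
               f_bnpp = rbeta(n, f_mu[b] * phi, (1 - f_mu[b]) * phi))))
  d50_mu <- c(0.15, 0.25, 0.18, 0.20, 0.30, 0.12, 0.08, 0.35)
  roots <- do.call(rbind, lapply(1:8, function(b) {
    d50 <- rlnorm(n, log(d50_mu[b]), 0.12)
    ratio <- 1 + rlnorm(n, log(3.5), 0.08)
    data.frame(biome = b, d50_m = d50, d95_m = d50 * ratio)
  }))
  tables <- structure(
    list(fbnpp_records = fbnpp, root_records = roots,
         crop_d50_mean = cfg$crop_d50_mean,
         crop_d50_se_fraction = cfg$crop_d50_se_fraction,
         crop_d95_ratio = cfg$crop_d95_ratio),
    class = "allocation_tables")
  validate_allocation_tables(tables)
}

#' Generate a synthetic world with known causal structure
#'
#' Builds a co-registered stack of all pipeline inputs. Temperature follows a
#' latitudinal gradient plus smoothed noise; precipitation is a smoothed
#' lognormal field; chemical soil properties share a latent soil-quality
#' factor (plus idiosyncratic smoothed noise); texture fractions close to
#' 100; productivity increases with temperature and precipitation. The latent
#' log decomposition rate is a linear form in the standardised drivers with
#' the configured effect sizes plus lognormal noise, and the organic-carbon
#' layer is back-computed from the implied turnover time and the expected
#' carbon input flux, so the causal structure is known exactly and stored.
#'
#' @param cfg A [synthetic_world_config()].
#' @return A list of class `synthetic_world`: `stack` (a `world_stack` with
#'   layers OC, BD, G, pH, clay, silt, sand, ECE, ESP, CaSO4, CaCO3, TEB, BS,
#'   MAT, MAP, NPP, biome), `tables` (allocation tables from the same seed),
#'   and `truth` (log turnover time, decomposition rate `k`, coefficients,
#'   per-group linear-predictor components and variance shares).
#' @export
generate_world <- function(cfg) {
  if (cfg$nrows * cfg$ncols == 0) stop("configuration error: empty grid")
  set.seed(cfg$seed)
  nr <- cfg$nrows; nc <- cfg$ncols
  scl <- cfg$spatial_correlation_length
  sm <- function() smooth_field(nr, nc, scl)
  lat <- matrix(rep(cfg$origin_lat - (seq_len(nr) - 0.5) * cfg$resolution, nc),
                nr, nc)

  biome <- switch(cfg$biome_layout,
    latitudinal_bands = {
      # nine |latitude| bands, equator outwards:
      # tropical forest, tropical grassland, desert, shrubland, cropland,
      # temperate forest, temperate grassland, boreal forest, tundra
      ord <- c(1L, 2L, 8L, 5L, 9L, 3L, 4L, 6L, 7L)
      band <- pmin(floor(rank(abs(lat)) / (length(lat) + 1) * 9), 8) + 1
      matrix(ord[band], nr, nc)
    },
    voronoi_patches = {
      ns <- 45L
      sr <- runif(ns, 1, nr); sc <- runif(ns, 1, nc)
      code <- rep(1:9, length.out = ns)
      ri <- matrix(rep(seq_len(nr), nc), nr, nc)
      ci <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      near <- matrix(0L, nr, nc)
      best <- matrix(Inf, nr, nc)
      for (s in seq_len(ns)) {
        d <- (ri - sr[s])^2 + (ci - sc[s])^2
        upd <- d < best
        near[upd] <- code[s]
        best[upd] <- d[upd]
      }
      near
    })

  MAT <- 28 - 0.55 * abs(lat) + 2.5 * sm()
  MAP <- exp(6.4 - 0.012 * abs(lat) + 0.55 * sm())

  q <- sm()                                 # latent soil-quality factor
  w <- cfg$soil_factor_loading
  mixq <- function() w * q + sqrt(max(0, 1 - w^2)) * sm()
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  pH <- clamp(6.5 + 1.1 * mixq(), 3.5, 9.5)
  TEB <- exp(2.3 + 0.5 * mixq())
  ECE <- exp(0.2 + 0.6 * mixq())
  ESP <- 100 * plogis(-2 + 0.8 * mixq())
  CaSO4 <- exp(-0.5 + 0.7 * mixq())
  CaCO3 <- exp(0.8 + 0.8 * mixq())
  BS <- 100 * plogis(0.4 + 0.9 * mixq())
  a_clay <- exp(0.80 + 0.50 * mixq())
  a_silt <- exp(0.90 + 0.50 * sm())
  a_sand <- exp(1.10 - 0.40 * mixq())
  tot <- a_clay + a_silt + a_sand
  clay <- 100 * a_clay / tot
  silt <- 100 * a_silt / tot
  sand <- 100 - clay - silt                 # exact closure
  BD <- clamp(1300 + 180 * sm(), 800, 1800) # kg m-3
  G <- clamp(15 + 12 * sm(), 0, 60)
  NPP <- 1.4 * plogis((MAT - 5) / 9) * (1 - exp(-MAP / 900)) *
    exp(0.15 * sm())

  fields <- list(MAT = MAT, MAP = MAP, pH = pH, clay = clay, silt = silt,
                 sand = sand, ECE = ECE, ESP = ESP, CaSO4 = CaSO4,
                 CaCO3 = CaCO3, TEB = TEB, BS = BS, soilQ = q)
  zs <- function(m) (m - mean(m)) / max(sd(m), .Machine$double.eps)
  es <- cfg$effect_sizes
  unknown <- setdiff(names(es), names(fields))
  if (length(unknown))
    stop("unknown effect-size driver(s): ", paste(unknown, collapse = ", "))
  lp_climate <- matrix(0, nr, nc)
  lp_soil <- matrix(0, nr, nc)
  for (v in names(es)) {
    term <- es[[v]] * zs(fields[[v]])
    if (v %in% c("MAT", "MAP")) lp_climate <- lp_climate + term
    else lp_soil <- lp_soil + term
  }
  eps <- matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  log_tau <- log(cfg$tau_scale) - (lp_climate + lp_soil) + eps
  tau_true <- exp(log_tau)
  k <- 1 / tau_true

  tables <- generate_allocation_tables(cfg)
  pools <- allocation_pools(tables)
  f_bar <- vapply(1:9, function(b) mean(pools[[b]]$f), 0)
  fr_bar <- vapply(1:9, function(b) {
    if (b == 9L) layer_fraction_v(tables$crop_d50_mean,
                                  tables$crop_d50_mean * tables$crop_d95_ratio)
    else mean(pools[[b]]$fr)
  }, 0)
  bnpp_bar <- NPP * f_bar[biome] * fr_bar[biome]
  SOC <- tau_true * bnpp_bar
  OC <- 100 * SOC / (0.7 * BD * (1 - G / 100))
  n_clipped <- sum(OC > 100)
  OC <- pmin(OC, 100)

  g <- function(v, name, units) grid2d(v, matrix(FALSE, nr, nc),
                                       origin_lat = cfg$origin_lat,
                                       origin_lon = cfg$origin_lon,
                                       resolution = cfg$resolution,
                                       name = name, units = units)
  stack <- assemble_stack(list(
    OC = g(OC, "OC", "% weight"), BD = g(BD, "BD", "kg m-3"),
    G = g(G, "G", "% volume"), pH = g(pH, "pH", "-"),
    clay = g(clay, "clay", "%"), silt = g(silt, "silt", "%"),
    sand = g(sand, "sand", "%"), ECE = g(ECE, "ECE", "dS m-1"),
    ESP = g(ESP, "ESP", "%"), CaSO4 = g(CaSO4, "CaSO4", "%"),
    CaCO3 = g(CaCO3, "CaCO3", "%"), TEB = g(TEB, "TEB", "cmol kg-1"),
    BS = g(BS, "BS", "%"), MAT = g(MAT, "MAT", "degC"),
    MAP = g(MAP, "MAP", "mm yr-1"),
    NPP = g(NPP, "NPP", "kg C m-2 yr-1"),
    biome = g(biome, "biome", "code")))

  var_c <- var(as.numeric(lp_climate))
  var_s <- var(as.numeric(lp_soil))
  var_t <- var(as.numeric(lp_climate + lp_soil))
  structure(
    list(stack = stack, tables = tables, cfg = cfg,
         truth = list(log_tau = log_tau, k = k, coefficients = es,
                      lp_climate = lp_climate, lp_soil = lp_soil,
                      bnpp_bar = bnpp_bar,
                      soil_factor = q,
                      var_share_soil = if (var_t > 0) var_s / var_t else NA_real_,
                      var_share_climate = if (var_t > 0) var_c / var_t else NA_real_,
                      n_oc_clipped = n_clipped)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d, mode %s, soil variance share %.2f\n",
    x$cfg$nrows, x$cfg$ncols, x$cfg$driver_mode,
    x$truth$var_share_soil))
  invisible(x)
}
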