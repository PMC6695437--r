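#' Global and biome summaries of the turnover ensemble
#'
#' Reproduces the pipeline's summary surfaces: global and per-biome means of
#' the mean/lower/upper turnover maps and of the percentage uncertainty, plus
#' the 5/25/50/75/95% quantiles of each map across all valid pixels. Means
#' are unweighted pixel means by default; with `config$area_weighting` they
#' are cos(latitude) weighted (quantiles stay unweighted).
#'
#' @param ens A `turnover_ensemble`.
#' @param biomes [grid2d()] of integer biome codes, co-registered with the
#'   ensemble.
#' @param config A [run_config()].
#' @return A list of class `turnover_summary`: `global` (one row per
#'   statistic), `biome` (one row per biome present), `quantiles` (map x
#'   probability), and the count of pixels excluded by the flux floor.
#' @export
summarize_turnover <- function(ens, biomes, config = run_config()) {
  stopifnot(inherits(ens, "turnover_ensemble"), is_grid2d(biomes))
  ok <- !ens$mean$mask
  if (!any(ok)) stop("empty valid set: nothing to summarise")
  maps <- list(mean = ens$mean, lower = ens$lower, upper = ens$upper,
               pct_uncertainty = ens$pct_uncertainty)
  wts <- if (config$area_weighting) {
    matrix(rep(cos(grid_lat_centers(ens$mean) * pi / 180),
               ncol(ens$mean$values)), nrow(ens$mean$values))
  } else matrix(1, nrow(ens$mean$values), ncol(ens$mean$values))
  wmean <- function(v, sel) {
    sel <- sel & !is.na(v)
    if (!any(sel)) return(NA_real_)
    sum(v[sel] * wts[sel]) / sum(wts[sel])
  }

  global <- data.frame(
    stat = paste0("mean_of_", names(maps)),
    value = vapply(maps, function(g) wmean(g$values, ok), 0),
    row.names = NULL)

  bb <- biomes$values
  present <- sort(unique(bb[ok & !biomes$mask]))
  biome_df <- do.call(rbind, lapply(present, function(b) {
    sel <- ok & !biomes$mask & bb == b
    data.frame(biome = b,
               mean_tau = wmean(maps$mean$values, sel),
               lower_tau = wmean(maps$lower$values, sel),
               upper_tau = wmean(maps$upper$values, sel),
               pct_uncertainty = wmean(maps$pct_uncertainty$values, sel),
               n = sum(sel))
  }))

  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  quant <- do.call(rbind, lapply(names(maps), function(nm) {
    v <- maps[[nm]]$values[ok]
    v <- v[!is.na(v)]
    data.frame(map = nm, prob = probs,
               value = quantile(v, probs, names = FALSE, type = 7))
  }))

  structure(list(global = global, biome = biome_df, quantiles = quant,
                 n_excluded_flux = ens$n_flux_masked),
            class = "turnover_summary")
}

#' Zonal (latitudinal) mean profile of a map
#'
#' Means of valid pixels within closed-open latitude bands of the given
#' width, labelled by band centre. Empty bands are absent from the output.
#'
#' @param grid A [grid2d()].
#' @param band_width Band width in degrees (> 0).
#' @return Data frame with `lat_center`, `mean`, `n`, ordered north to south.
#' @export
zonal_profile <- function(grid, band_width = 1) {
  stopifnot(is_grid2d(grid))
  if (band_width <= 0) stop("band_width must be positive")
  lat <- matrix(rep(grid_lat_centers(grid), ncol(grid$values)),
                nrow(grid$values))
  ok <- !grid$mask & !is.na(grid$values)
  if (!any(ok)) return(data.frame(lat_center = numeric(0), mean = numeric(0),
                                  n = integer(0)))
  band <- floor(lat[ok] / band_width)
  agg <- tapply(grid$values[ok], band, mean)
  cnt <- tapply(grid$values[ok], band, length)
  centers <- (as.numeric(names(agg)) + 0.5) * band_width
  o <- order(centers, decreasing = TRUE)
  data.frame(lat_center = centers[o], mean = as.numeric(agg)[o],
             n = as.integer(cnt)[o], row.names = NULL)
}

#' Log-log correlations of turnover with stock and input flux
#'
#' Samples pixels without replacement, natural-log-transforms turnover time,
#' SOC stock and mean input flux, and returns the two Pearson coefficients
#' `r(ln tau, ln SOC)` and `r(ln tau, ln BNPP)`. Pixels with any non-positive
#' value are excluded and counted.
#'
#' @param ens A `turnover_ensemble`.
#' @param n_sample Number of pixels to sample (capped at the usable count).
#' @param seed Integer seed for the sample.
#' @return A list with `r_soc`, `r_bnpp`, `n_used`, `n_excluded_nonpositive`.
#' @export
loglog_correlation <- function(ens, n_sample = 10000L,
                               seed = ens$config$seed) {
  stopifnot(inherits(ens, "turnover_ensemble"))
  tau <- ens$mean$values
  soc <- ens$soc$values
  bnpp <- ens$bnpp_mean$values
  ok <- !ens$mean$mask & !is.na(tau) & !is.na(soc) & !is.na(bnpp)
  pos <- ok & tau > 0 & soc > 0 & bnpp > 0
  n_excl <- sum(ok) - sum(pos)
  idx <- which(pos)
  if (length(idx) < 3) stop("fewer than 3 usable pixels for correlation")
  set.seed(pixel_seed(seed, 2L, 0L))
  take <- if (length(idx) > n_sample) idx[sample.int(length(idx), n_sample)]
          else idx
  lt <- log(tau[take]); ls <- log(soc[take]); lb <- log(bnpp[take])
  if (sd(lt) == 0)
    stop("degenerate variance: turnover is constant, correlation undefined")
  list(r_soc = if (sd(ls) > 0) cor(lt, ls) else NA_real_,
       r_bnpp = if (sd(lb) > 0) cor(lt, lb) else NA_real_,
       n_used = length(take), n_excluded_nonpositive = n_excl)
}
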