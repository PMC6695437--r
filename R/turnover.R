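#' Point estimate of apparent turnover time
#'
#' `tau = SOC / BNPP` in years, under the quasi-steady-state assumption that
#' carbon input to the layer balances output. Pixels whose flux is at or
#' below the floor are undefined and returned as `NA` (masked, never an
#' exception); `SOC = 0` gives `tau = 0`.
#'
#' @param soc SOC stock, kg C m-2 (`>= 0`).
#' @param bnpp Carbon input flux, kg C m-2 yr-1.
#' @param flux_floor Minimum flux treated as defined.
#' @return Turnover time(s) in years, `NA` where undefined.
#' @export
tau_point <- function(soc, bnpp, flux_floor = 1e-6) {
  if (any(soc < 0, na.rm = TRUE)) stop("soc must be non-negative")
  out <- ifelse(bnpp > flux_floor, soc / bnpp, NA_real_)
  out[!is.na(soc) & soc == 0 & !is.na(bnpp)] <- 0
  out
}

#' Per-pixel turnover ensemble with uncertainty propagation
#'
#' For every valid pixel, draws `n_ensemble` joint realisations: NPP from a
#' positive-truncated normal centred on the pixel mean with SD a fixed
#' fraction of the mean (Monte Carlo), and `(f_bnpp, fr)` by bootstrap from
#' the pixel biome's observation tables ([sample_allocation()]). The i-th NPP
#' draw is paired with the i-th allocation bootstrap, giving `n_ensemble`
#' turnover estimates `tau_i = SOC / (NPP_i * f_i * fr_i)` per pixel, then
#' the ensemble mean, the empirical 2.5%/97.5% quantiles (type-7 linear
#' interpolation between order statistics), and the percentage uncertainty
#' `100 * (upper - lower) / mean`.
#'
#' Draws are seeded per pixel from `(seed, row, col)`, so results are
#' invariant to pixel evaluation order. Pixels whose ensemble-median flux is
#' at or below `flux_floor` are masked and counted rather than propagated as
#' near-infinite turnover.
#'
#' @param stack A `world_stack` with layers `OC`, `BD`, `G`, `NPP`, `biome`.
#' @param tables Allocation tables covering every biome present.
#' @param config A [run_config()].
#' @param store_draws Keep the per-pixel draw matrix (needed for
#'   distributional checks; costs `n_valid * n_ensemble` doubles).
#' @param bd_units Bulk-density units of the `BD` layer.
#' @return An object of class `turnover_ensemble`: grids `mean`, `lower`,
#'   `upper`, `pct_uncertainty` (years / %), `soc` and `bnpp_mean` grids, the
#'   count of flux-floor-masked pixels, and (optionally) `draws` with
#'   `draw_index` giving each row's pixel index.
#' @export
run_ensemble <- function(stack, tables, config = run_config(),
                         store_draws = FALSE, bd_units = "kg m-3") {
  need <- c("OC", "BD", "G", "NPP", "biome")
  miss <- setdiff(need, names(stack$grids))
  if (length(miss))
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  validate_allocation_tables(tables)
  soc <- compute_stock(stack$grids$OC, stack$grids$BD, stack$grids$G,
                       thickness = config$layer_bottom - config$layer_top,
                       bd_units = bd_units)
  valid <- !(stack_mask(stack, need) | soc$mask)
  biome <- stack$grids$biome$values
  present <- sort(unique(biome[valid]))
  if (any(!(present %in% 1:9)))
    stop("biome codes outside 1..9 at valid pixels")
  for (b in present) {
    if (sum(tables$fbnpp_records$biome == b) == 0 ||
        (b != 9L && sum(tables$root_records$biome == b) == 0))
      stop("allocation tables do not cover biome ", b)
  }
  pools <- allocation_pools(tables, config$layer_top, config$layer_bottom)

  nr <- stack$nrows; nens <- config$n_ensemble
  idx <- which(valid)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  npp <- stack$grids$NPP$values
  socv <- soc$values

  m_mean <- m_lo <- m_hi <- m_bnpp <- rep(NA_real_, length(idx))
  flux_masked <- logical(length(idx))
  draws <- if (store_draws) matrix(NA_real_, length(idx), nens) else NULL

  for (t in seq_along(idx)) {
    i <- idx[t]
    set.seed(pixel_seed(config$seed, rr[t], cc[t]))
    npp_d <- rnorm_trunc_pos(nens, npp[i], config$npp_sd_fraction * npp[i])
    b <- biome[i]
    pool <- pools[[b]]
    if (b == 9L) {
      d50 <- rnorm_trunc_pos(nens, tables$crop_d50_mean,
                             tables$crop_d50_se_fraction * tables$crop_d50_mean)
      fr_d <- layer_fraction_v(d50, d50 * tables$crop_d95_ratio,
                               config$layer_top, config$layer_bottom)
    } else {
      fr_d <- pool$fr[sample.int(length(pool$fr), nens, replace = TRUE)]
    }
    f_d <- pool$f[sample.int(length(pool$f), nens, replace = TRUE)]
    bnpp_d <- npp_d * f_d * fr_d
    if (median(bnpp_d) <= config$flux_floor) {
      flux_masked[t] <- TRUE
      next
    }
    tau_d <- socv[i] / bnpp_d
    if (store_draws) draws[t, ] <- tau_d
    m_mean[t] <- mean(tau_d)
    qs <- quantile(tau_d, c(0.025, 0.975), names = FALSE, type = 7)
    m_lo[t] <- qs[1]
    m_hi[t] <- qs[2]
    m_bnpp[t] <- mean(bnpp_d)
  }

  shape <- function(vals) {
    m <- matrix(NA_real_, stack$nrows, stack$ncols)
    m[idx] <- vals
    m
  }
  gmask <- matrix(TRUE, stack$nrows, stack$ncols)
  gmask[idx[!flux_masked]] <- FALSE
  mk <- function(v, name, units) grid2d(shape(v), gmask,
                                        origin_lat = stack$origin_lat,
                                        origin_lon = stack$origin_lon,
                                        resolution = stack$resolution,
                                        name = name, units = units)
  ens <- structure(
    list(mean = mk(m_mean, "tau_mean", "yr"),
         lower = mk(m_lo, "tau_lower", "yr"),
         upper = mk(m_hi, "tau_upper", "yr"),
         soc = soc,
         bnpp_mean = mk(m_bnpp, "bnpp_mean", "kg C m-2 yr-1"),
         draws = draws,
         draw_index = if (store_draws) idx else NULL,
         n_flux_masked = sum(flux_masked),
         config = config),
    class = "turnover_ensemble")
  ens$pct_uncertainty <- percentage_uncertainty(ens)
  ens
}

#' Percentage uncertainty of the turnover ensemble
#'
#' `100 * (upper - lower) / mean` per pixel: the width of the 95% confidence
#' interval relative to the ensemble mean. Scale-invariant; 0 for a
#' degenerate ensemble. Pixels with zero mean but nonzero interval width are
#' masked with a warning.
#'
#' @param ens A `turnover_ensemble`.
#' @return A [grid2d()] in percent.
#' @export
percentage_uncertainty <- function(ens) {
  stopifnot(inherits(ens, "turnover_ensemble"))
  m <- ens$mean$values
  width <- ens$upper$values - ens$lower$values
  pu <- 100 * width / m
  pu[!is.na(m) & m == 0 & !is.na(width) & width == 0] <- 0
  bad <- !is.na(m) & m == 0 & !is.na(width) & width > 0
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with zero mean but nonzero interval width ",
            "masked in percentage uncertainty")
    pu[bad] <- NA_real_
  }
  grid2d(pu, ens$mean$mask | is.na(pu),
         origin_lat = ens$mean$origin_lat, origin_lon = ens$mean$origin_lon,
         resolution = ens$mean$resolution,
         name = "tau_pct_uncertainty", units = "%")
}

#' @export
print.turnover_ensemble <- function(x, ...) {
  ok <- !x$mean$mask
  cat(sprintf(
    "<turnover_ensemble> %d valid pixels, n = %d draws, %d flux-masked\n",
    sum(ok), x$config$n_ensemble, x$n_flux_masked))
  if (any(ok))
    cat(sprintf("  mean tau %.1f yr (map average), mean PU %.1f%%\n",
                mean(x$mean$values[ok]),
                mean(x$pct_uncertainty$values[ok], na.rm = TRUE)))
  invisible(x)
}
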