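#' Run configuration for the turnover pipeline
#'
#' Bundles every tunable of the estimation and attribution stages. Defaults
#' follow the study design: 200-member ensembles, 10% NPP standard deviation,
#' 101 x 101-pixel windows with the >50-valid-pixel rule, 10-fold
#' cross-validation, and 200 path-model bootstrap resamples.
#'
#' @param seed Master integer seed; every stochastic stage derives its stream
#'   from it.
#' @param n_ensemble Number of turnover draws per pixel.
#' @param npp_sd_fraction Standard deviation of the per-pixel NPP Monte-Carlo
#'   draw, as a fraction of the pixel mean.
#' @param window_size Moving-window edge length in pixels (odd).
#' @param min_window_pixels Minimum valid pixels for a window to be fitted
#'   (the ">50" rule, i.e. at least 51).
#' @param n_windows Number of window centres sampled for local attribution.
#' @param n_global_pixels Pixel sample size for the global analyses.
#' @param cv_folds Cross-validation folds for boosted-tree fitting.
#' @param n_path_bootstrap Bootstrap resamples for path-model intervals.
#' @param layer_top,layer_bottom Bounds of the soil layer in metres.
#' @param area_weighting If `TRUE`, spatial means are cos(latitude) weighted.
#' @param flux_floor Minimum carbon input flux (kg C m-2 yr-1) below which a
#'   pixel's turnover time is treated as undefined and masked.
#' @param learning_rate,max_depth,subsample,n_trees,min_trees,min_node
#'   Boosted-tree hyperparameters: shrinkage, tree depth, bag fraction,
#'   maximum and minimum number of trees (count selected by cross-validation),
#'   and minimum observations per terminal node.
#' @param log_tau If `TRUE` (default) attribution models are fitted on
#'   ln(turnover time), which spans several orders of magnitude.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_ensemble = 200L,
                       npp_sd_fraction = 0.10,
                       window_size = 101L,
                       min_window_pixels = 51L,
                       n_windows = 10000L,
                       n_global_pixels = 10000L,
                       cv_folds = 10L,
                       n_path_bootstrap = 200L,
                       layer_top = 0.3,
                       layer_bottom = 1.0,
                       area_weighting = FALSE,
                       flux_floor = 1e-6,
                       learning_rate = 0.01,
                       max_depth = 3L,
                       subsample = 0.5,
                       n_trees = 3000L,
                       min_trees = 50L,
                       min_node = 10L,
                       log_tau = TRUE) {
  cfg <- list(seed = as.integer(seed), n_ensemble = as.integer(n_ensemble),
              npp_sd_fraction = npp_sd_fraction,
              window_size = as.integer(window_size),
              min_window_pixels = as.integer(min_window_pixels),
              n_windows = as.integer(n_windows),
              n_global_pixels = as.integer(n_global_pixels),
              cv_folds = as.integer(cv_folds),
              n_path_bootstrap = as.integer(n_path_bootstrap),
              layer_top = layer_top, layer_bottom = layer_bottom,
              area_weighting = isTRUE(area_weighting),
              flux_floor = flux_floor,
              learning_rate = learning_rate, max_depth = as.integer(max_depth),
              subsample = subsample, n_trees = as.integer(n_trees),
              min_trees = as.integer(min_trees), min_node = as.integer(min_node),
              log_tau = isTRUE(log_tau))
  if (cfg$window_size %% 2L == 0L) stop("window_size must be odd")
  if (!(cfg$layer_top > 0 && cfg$layer_top < cfg$layer_bottom))
    stop("need 0 < layer_top < layer_bottom")
  counts <- c(cfg$n_ensemble, cfg$min_window_pixels, cfg$n_windows,
              cfg$n_global_pixels, cfg$cv_folds, cfg$n_path_bootstrap,
              cfg$n_trees, cfg$min_trees)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (cfg$npp_sd_fraction < 0) stop("npp_sd_fraction must be >= 0")
  structure(cfg, class = "run_config")
}

# Deterministic per-pixel / per-task seed derived from the master seed.
# Keeps results invariant to evaluation order; stays below 2^31.
pixel_seed <- function(master, row, col = 0L) {
  s <- (abs(as.double(master)) * 2654435 + as.double(row) * 9973 +
          as.double(col) * 7919111) %% 2147483646
  as.integer(s) + 1L
}

# Positive-truncated normal via resampling; exact mean at sd = 0.
rnorm_trunc_pos <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}
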