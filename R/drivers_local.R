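#' Predictor sets for driver attribution
#'
#' Twelve predictors: the two climate variables (mean annual temperature and
#' precipitation) and ten soil physiochemical properties.
#'
#' @return Character vector of layer names.
#' @export
predictor_names <- function() {
  c("MAT", "MAP", "pH", "clay", "silt", "sand", "ECE", "ESP", "CaSO4",
    "CaCO3", "TEB", "BS")
}

#' @rdname predictor_names
#' @export
climate_vars <- function() c("MAT", "MAP")

#' Localised moving-window attribution of turnover drivers
#'
#' Samples up to `config$n_windows` distinct window centres uniformly among
#' valid pixels whose surrounding `window_size` x `window_size` window
#' (truncated at the domain edge) contains at least `min_window_pixels` valid
#' pixels (the ">50" rule). In each window a boosted-tree model of turnover
#' time (ln-transformed when `config$log_tau`) on the twelve predictors is
#' fitted with [fit_brt()], and the per-variable relative influence is
#' grouped into climate (MAT + MAP) versus soil (all others).
#'
#' @param stack A `world_stack` with the predictor layers.
#' @param tau_mean [grid2d()] of mean turnover times, co-registered.
#' @param config A [run_config()]; window geometry, sample size and
#'   boosted-tree hyperparameters are taken from it.
#' @param predictors Predictor layer names (default [predictor_names()]).
#' @return A data frame of class `window_attributions`: one row per fitted
#'   window with `center_row`, `center_col`, `n_train`, `n_trees`, `cv_r2`,
#'   one `ri_*` column per predictor, and the grouped `ri_climate`,
#'   `ri_soil`. Windows skipped for a degenerate response are counted in
#'   `attr(, "n_skipped")`.
#' @export
run_windows <- function(stack, tau_mean, config = run_config(),
                        predictors = predictor_names()) {
  stopifnot(inherits(stack, "world_stack"), is_grid2d(tau_mean))
  if (config$window_size > min(stack$nrows, stack$ncols))
    stop("window_size exceeds the grid dimensions")
  tau <- tau_mean$values
  valid <- !stack_mask(stack, predictors) & !tau_mean$mask &
    is.finite(tau) & tau > 0
  nr <- stack$nrows; nc <- stack$ncols
  half <- (config$window_size - 1L) %/% 2L

  # integral image for O(1) valid-pixel counts per (truncated) window
  csum <- rbind(0, apply(valid, 2, cumsum))
  csum <- cbind(0, t(apply(csum, 1, cumsum)))
  wcount <- function(r, c) {
    r1 <- pmax(r - half, 1L); r2 <- pmin(r + half, nr)
    c1 <- pmax(c - half, 1L); c2 <- pmin(c + half, nc)
    csum[cbind(r2 + 1L, c2 + 1L)] - csum[cbind(r1, c2 + 1L)] -
      csum[cbind(r2 + 1L, c1)] + csum[cbind(r1, c1)]
  }

  cand <- which(valid)
  cr <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  eligible <- wcount(cr, cc) >= config$min_window_pixels
  if (!any(eligible))
    stop("no eligible window centre: every window has <= ",
         config$min_window_pixels - 1L, " valid pixels (the >50 rule)")
  cand <- cand[eligible]; cr <- cr[eligible]; cc <- cc[eligible]

  set.seed(pixel_seed(config$seed, 6L, 0L))
  take <- if (length(cand) > config$n_windows)
    sample.int(length(cand), config$n_windows) else seq_along(cand)

  pred_mats <- lapply(predictors, function(v) stack$grids[[v]]$values)
  names(pred_mats) <- predictors
  y_all <- if (config$log_tau) log(tau) else tau
  cl <- intersect(climate_vars(), predictors)

  rows <- vector("list", length(take))
  n_skipped <- 0L
  for (t in seq_along(take)) {
    r <- cr[take[t]]; c <- cc[take[t]]
    r1 <- max(r - half, 1L); r2 <- min(r + half, nr)
    c1 <- max(c - half, 1L); c2 <- min(c + half, nc)
    sel <- valid[r1:r2, c1:c2]
    Xw <- vapply(pred_mats, function(m) m[r1:r2, c1:c2][sel],
                 numeric(sum(sel)))
    yw <- y_all[r1:r2, c1:c2][sel]
    fit <- tryCatch(
      fit_brt(Xw, yw, cv_folds = config$cv_folds,
              learning_rate = config$learning_rate,
              max_depth = config$max_depth, subsample = config$subsample,
              n_trees = config$n_trees, min_trees = config$min_trees,
              min_node = config$min_node, seed = pixel_seed(config$seed, r, c)),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ri <- fit$ri
    out <- data.frame(center_row = r, center_col = c, n_train = fit$n_train,
                      n_trees = fit$n_trees, cv_r2 = fit$cv_r2)
    for (v in predictors) out[[paste0("ri_", v)]] <- unname(ri[v])
    out$ri_climate <- sum(ri[cl])
    out$ri_soil <- sum(ri[setdiff(predictors, cl)])
    rows[[t]] <- out
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) stop("every sampled window was skipped")
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("window_attributions", class(res))
  res
}

#' Performance-weighted relative influence
#'
#' `RI_w = sum(RI_i * R2_i) / sum(R2_i)` over windows, computed separately
#' for the climate and soil groups; the two results sum to 100.
#'
#' @param attributions A `window_attributions` data frame (or any data frame
#'   with `ri_climate`, `ri_soil`, `cv_r2`).
#' @return Named numeric vector `c(climate = , soil = )`, in percent.
#' @export
weighted_ri <- function(attributions) {
  if (nrow(attributions) < 1) stop("need at least one window attribution")
  w <- attributions$cv_r2
  if (all(w == 0)) stop("undefined weights: every window has R2 = 0")
  c(climate = sum(attributions$ri_climate * w) / sum(w),
    soil = sum(attributions$ri_soil * w) / sum(w))
}

#' Mean relative influence by model-performance decile
#'
#' Groups windows into ten R2 bins `[0,0.1), ..., [0.9,1]` (last bin closed)
#' and averages the grouped relative influence within each bin. Empty bins
#' are reported with count 0.
#'
#' @inheritParams weighted_ri
#' @return Data frame with `decile`, `r2_lo`, `r2_hi`, `mean_ri_climate`,
#'   `mean_ri_soil`, `n`.
#' @export
ri_by_r2_decile <- function(attributions) {
  if (nrow(attributions) < 1) stop("need at least one window attribution")
  bin <- pmin(floor(attributions$cv_r2 * 10), 9) + 1
  out <- data.frame(decile = 1:10, r2_lo = (0:9) / 10, r2_hi = (1:10) / 10)
  out$mean_ri_climate <- vapply(1:10, function(b) {
    v <- attributions$ri_climate[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  out$mean_ri_soil <- vapply(1:10, function(b) {
    v <- attributions$ri_soil[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  out$n <- vapply(1:10, function(b) sum(bin == b), 0L)
  out
}

#' Fraction of windows where climate dominates
#'
#' Share of windows whose climate-group relative influence exceeds 50%.
#'
#' @inheritParams weighted_ri
#' @return Fraction in `[0, 1]`.
#' @export
climate_dominant_fraction <- function(attributions) {
  if (nrow(attributions) < 1) stop("need at least one window attribution")
  mean(attributions$ri_climate > 50)
}
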