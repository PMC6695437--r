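#' Sample fully valid pixels for the global analyses
#'
#' Uniform sample without replacement of pixels valid in every predictor
#' layer and in the turnover map.
#'
#' @param stack A `world_stack`.
#' @param ens A `turnover_ensemble` (its mean map supplies the response).
#' @param n Sample size; must not exceed the valid-pixel count.
#' @param seed Integer seed.
#' @param predictors Predictor layer names.
#' @return Data frame with `row`, `col`, `tau` and one column per predictor.
#' @export
sample_pixels <- function(stack, ens, n = 10000L, seed = ens$config$seed,
                          predictors = predictor_names()) {
  tau <- ens$mean$values
  valid <- !stack_mask(stack, predictors) & !ens$mean$mask &
    is.finite(tau) & tau > 0
  idx <- which(valid)
  if (length(idx) < n)
    stop("insufficient valid pixels: have ", length(idx), ", need ", n)
  set.seed(pixel_seed(seed, 7L, 0L))
  take <- if (length(idx) > n) idx[sample.int(length(idx), n)] else idx
  nr <- stack$nrows
  out <- data.frame(row = ((take - 1L) %% nr) + 1L,
                    col = ((take - 1L) %/% nr) + 1L,
                    tau = tau[take])
  for (v in predictors) out[[v]] <- stack$grids[[v]]$values[take]
  out
}

#' Global boosted-tree attribution on a pixel sample
#'
#' Fits [fit_brt()] to the sampled pixels: turnover time (ln-transformed when
#' `config$log_tau`) on the twelve predictors.
#'
#' @param pixels Data frame from [sample_pixels()].
#' @param config A [run_config()].
#' @param predictors Predictor column names.
#' @param seed Integer seed.
#' @return A `brt_fit`.
#' @export
global_brt <- function(pixels, config = run_config(),
                       predictors = predictor_names(), seed = config$seed) {
  y <- if (config$log_tau) log(pixels$tau) else pixels$tau
  fit_brt(as.matrix(pixels[, predictors, drop = FALSE]), y,
          cv_folds = config$cv_folds, learning_rate = config$learning_rate,
          max_depth = config$max_depth, subsample = config$subsample,
          n_trees = config$n_trees, min_trees = config$min_trees,
          min_node = config$min_node, seed = seed)
}

#' Path-model specification
#'
#' Latent climate (indicators MAT, MAP) and soil (pH, TEB, ECE, BS, CaCO3,
#' clay, silt, sand) variables with inner paths climate -> soil,
#' climate -> tau and soil -> tau; the turnover time is a single-indicator
#' latent. Outer mode is reflective; the inner weighting scheme defaults to
#' centroid (the classical choice of the PLS path-modelling literature),
#' with factorial available.
#'
#' @param climate,soil Character vectors of indicator column names.
#' @param response Name of the observed outcome column.
#' @param scheme Inner weighting scheme.
#' @param max_iter,tol Iteration cap and convergence tolerance on the outer
#'   weights.
#' @return A list of class `path_model_spec`.
#' @export
path_model_spec <- function(climate = c("MAT", "MAP"),
                            soil = c("pH", "TEB", "ECE", "BS", "CaCO3",
                                     "clay", "silt", "sand"),
                            response = "tau",
                            scheme = c("centroid", "factorial"),
                            max_iter = 100L, tol = 1e-6) {
  scheme <- match.arg(scheme)
  if (length(intersect(climate, soil)))
    stop("an indicator may belong to exactly one latent")
  structure(list(climate = climate, soil = soil, response = response,
                 scheme = scheme, max_iter = as.integer(max_iter), tol = tol),
            class = "path_model_spec")
}

# One PLS-PM estimation pass (Lohmoller algorithm, mode A outer model).
# Z: standardised indicator matrix; blocks: list of column-index vectors;
# path: b x b lower-triangular adjacency, path[j, i] = 1 means i -> j.
pls_core <- function(Z, blocks, path, scheme, max_iter, tol) {
  n <- nrow(Z)
  B <- length(blocks)
  A <- (path + t(path)) > 0
  std1 <- function(v) {
    s <- sd(v) * sqrt((n - 1) / n)
    if (s < .Machine$double.eps) stop("singular indicator combination")
    (v - mean(v)) / s
  }
  W <- lapply(blocks, function(ix) rep(1, length(ix)))
  scores <- vapply(seq_len(B),
                   function(b) std1(Z[, blocks[[b]], drop = FALSE] %*% W[[b]]),
                   numeric(n))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W_old <- W
    C <- suppressWarnings(cor(scores))
    for (b in seq_len(B)) {
      nb <- which(A[b, ])
      e <- if (scheme == "centroid") sign(C[b, nb]) else C[b, nb]
      e[e == 0] <- 1
      inner <- scores[, nb, drop = FALSE] %*% e
      w <- as.numeric(crossprod(Z[, blocks[[b]], drop = FALSE], inner)) / n
      if (w[which.max(abs(w))] < 0) w <- -w   # sign determinacy
      W[[b]] <- w
      scores[, b] <- std1(Z[, blocks[[b]], drop = FALSE] %*% w)
    }
    delta <- max(vapply(seq_len(B), function(b) {
      a <- W[[b]] / sqrt(sum(W[[b]]^2))
      o <- W_old[[b]] / sqrt(sum(W_old[[b]]^2))
      max(abs(a - o))
    }, 0))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("path model did not converge in ", max_iter,
         " iterations (last delta ", format(delta), ")")
  loadings <- lapply(seq_len(B), function(b)
    as.numeric(cor(Z[, blocks[[b]], drop = FALSE], scores[, b])))
  # inner paths by OLS of each endogenous latent on its predecessors
  paths <- matrix(NA_real_, B, B, dimnames = dimnames(path))
  r2 <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pr <- which(path[b, ] > 0)
    if (!length(pr)) next
    fit <- lm.fit(cbind(1, scores[, pr, drop = FALSE]), scores[, b])
    paths[b, pr] <- fit$coefficients[-1]
    r2[b] <- 1 - sum(fit$residuals^2) / sum((scores[, b] - mean(scores[, b]))^2)
  }
  list(weights = W, scores = scores, loadings = loadings, paths = paths,
       r2 = r2, iterations = it)
}

#' Fit the PLS path model of turnover on latent climate and soil
#'
#' Iterative partial-least-squares path modelling (reflective outer model):
#' latent scores are alternately updated from their indicators and from their
#' inner neighbours until the outer weights converge, loadings are the
#' indicator-score correlations, and inner path coefficients are standardised
#' OLS regressions of the final scores (soil on climate; tau on climate and
#' soil). Indicators with a negative loading are sign-flipped and the model
#' re-estimated, so all reported loadings are positive. Non-parametric
#' bootstrap resampling of rows yields percentile 95% intervals per
#' coefficient; a coefficient is significant when its interval excludes 0.
#' The indirect effect is the product of the climate -> soil and soil -> tau
#' coefficients.
#'
#' @param pixels Data frame holding the indicator and response columns
#'   (e.g. from [sample_pixels()]); at least 30 rows.
#' @param spec A [path_model_spec()].
#' @param n_boot Bootstrap resamples (0 skips the bootstrap).
#' @param seed Integer seed.
#' @param log_tau Model ln(tau) instead of tau (default `FALSE`).
#' @return An object of class `path_model_result`: `loadings` (data frame
#'   with indicator, block, loading, flipped), `paths` (estimate, bootstrap
#'   CI, significance per inner path and for the indirect effect), `r2_tau`,
#'   `iterations`.
#' @export
fit_path_model <- function(pixels, spec = path_model_spec(), n_boot = 200L,
                           seed = 1L, log_tau = FALSE) {
  stopifnot(inherits(spec, "path_model_spec"))
  vars <- c(spec$climate, spec$soil, spec$response)
  miss <- setdiff(vars, names(pixels))
  if (length(miss))
    stop("pixels is missing column(s): ", paste(miss, collapse = ", "))
  dat <- pixels[, vars]
  if (log_tau) dat[[spec$response]] <- log(dat[[spec$response]])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 30) stop("need at least 30 complete rows")
  Z0 <- scale(as.matrix(dat))
  if (any(!is.finite(Z0))) stop("singular indicator covariance")
  blocks <- list(climate = seq_along(spec$climate),
                 soil = length(spec$climate) + seq_along(spec$soil),
                 tau = length(spec$climate) + length(spec$soil) + 1L)
  path <- matrix(0, 3, 3, dimnames = list(names(blocks), names(blocks)))
  path["soil", "climate"] <- 1
  path["tau", "climate"] <- 1
  path["tau", "soil"] <- 1

  flip_pass <- function(Z, flips) {
    for (pass in 1:6) {
      core <- pls_core(sweep(Z, 2, flips, `*`), blocks, path, spec$scheme,
                       spec$max_iter, spec$tol)
      neg <- integer(0)
      for (b in 1:2) {   # never flip the observed outcome
        ld <- core$loadings[[b]]
        neg <- c(neg, blocks[[b]][ld < 0])
      }
      if (!length(neg)) break
      flips[neg] <- -flips[neg]
    }
    list(core = core, flips = flips)
  }

  fit_with_flips <- function(Z) {
    res <- flip_pass(Z, rep(1, ncol(Z)))
    # The all-positive-loadings rule has two mirrored fixed points per
    # latent; orient each so that a minority of its indicators is inverted.
    flips <- res$flips
    reorient <- FALSE
    for (b in 1:2) {
      ix <- blocks[[b]]
      nflip <- 2 * sum(flips[ix] < 0)
      # exact ties (half the block inverted) anchor on the first indicator
      if (nflip > length(ix) ||
          (nflip == length(ix) && flips[ix[1]] < 0)) {
        flips[ix] <- -flips[ix]
        reorient <- TRUE
      }
    }
    if (reorient) res <- flip_pass(Z, flips)
    core <- res$core
    flips <- res$flips
    # the outcome's single-indicator latent must carry loading +1
    if (core$loadings[[3]][1] < 0) {
      core$scores[, 3] <- -core$scores[, 3]
      core$loadings[[3]] <- -core$loadings[[3]]
      core$paths[3, ] <- -core$paths[3, ]
    }
    list(core = core, flips = flips)
  }

  main <- fit_with_flips(Z0)
  core <- main$core
  est <- c(climate_to_soil = core$paths["soil", "climate"],
           climate_to_tau = core$paths["tau", "climate"],
           soil_to_tau = core$paths["tau", "soil"])
  est["indirect_climate_via_soil"] <-
    est["climate_to_soil"] * est["soil_to_tau"]

  ci <- matrix(NA_real_, 4, 2,
               dimnames = list(names(est), c("lower", "upper")))
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 4)
    set.seed(pixel_seed(seed, 8L, 0L))
    b <- 0L
    tries <- 0L
    while (b < n_boot && tries < 4L * n_boot) {
      tries <- tries + 1L
      rows <- sample.int(nrow(dat), replace = TRUE)
      res <- tryCatch({
        Zb <- scale(as.matrix(dat[rows, , drop = FALSE]))
        fb <- fit_with_flips(Zb)$core
        p <- c(fb$paths["soil", "climate"], fb$paths["tau", "climate"],
               fb$paths["tau", "soil"])
        c(p, p[1] * p[3])
      }, error = function(e) NULL)
      if (is.null(res)) next
      b <- b + 1L
      boot[b, ] <- res
    }
    boot <- boot[seq_len(b), , drop = FALSE]
    if (b >= 10)
      ci <- t(apply(boot, 2, quantile, c(0.025, 0.975), names = FALSE))
    dimnames(ci) <- list(names(est), c("lower", "upper"))
  }

  ld_df <- data.frame(
    indicator = vars,
    block = c(rep("climate", length(spec$climate)),
              rep("soil", length(spec$soil)), "tau"),
    loading = c(core$loadings[[1]], core$loadings[[2]], core$loadings[[3]]),
    flipped = main$flips < 0)
  paths_df <- data.frame(
    path = names(est), estimate = unname(est),
    ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
    significant = !is.na(ci[, "lower"]) &
      (ci[, "lower"] > 0 | ci[, "upper"] < 0),
    row.names = NULL)
  structure(list(loadings = ld_df, paths = paths_df,
                 r2_tau = core$r2[3], iterations = core$iterations,
                 scheme = spec$scheme, n = nrow(dat)),
            class = "path_model_result")
}

#' @export
print.path_model_result <- function(x, ...) {
  cat(sprintf("<path_model_result> n = %d, R2(tau) = %.3f\n", x$n, x$r2_tau))
  print(x$paths, row.names = FALSE)
  invisible(x)
}
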