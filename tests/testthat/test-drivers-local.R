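mk_attr <- function(ri_climate, cv_r2) {
  data.frame(ri_climate = ri_climate, ri_soil = 100 - ri_climate,
             cv_r2 = cv_r2)
}

test_that("performance-weighted influence matches hand arithmetic", {
  # RI = (50, 100), R2 = (0.5, 1.0)  ->  RI_w = 83.33
  a <- mk_attr(c(50, 100), c(0.5, 1.0))
  w <- weighted_ri(a)
  expect_equal(unname(w["climate"]), 250 / 3, tolerance = 1e-9)
  expect_equal(sum(w), 100)
  # equal weights reduce to the simple mean
  b <- mk_attr(c(10, 30, 50), c(0.4, 0.4, 0.4))
  expect_equal(unname(weighted_ri(b)["climate"]), 30)
  # a single window returns its own RI
  expect_equal(unname(weighted_ri(mk_attr(70, 0.9))["climate"]), 70)
  expect_error(weighted_ri(mk_attr(numeric(0), numeric(0))), "at least one")
  expect_error(weighted_ri(mk_attr(c(10, 20), c(0, 0))), "undefined weights")
})

test_that("decile grouping partitions the windows and matches brute force", {
  set.seed(31)
  a <- mk_attr(runif(200, 0, 100), runif(200))
  d <- ri_by_r2_decile(a)
  expect_equal(sum(d$n), 200L)
  for (b in 1:10) {
    sel <- a$cv_r2 >= (b - 1) / 10 & (if (b == 10) a$cv_r2 <= 1
                                      else a$cv_r2 < b / 10)
    expect_equal(d$n[b], sum(sel))
    if (any(sel))
      expect_equal(d$mean_ri_climate[b], mean(a$ri_climate[sel]))
  }
  # all high performance -> only the top decile populated
  hi <- ri_by_r2_decile(mk_attr(c(40, 60), c(0.95, 0.99)))
  expect_equal(hi$n, c(rep(0L, 9), 2L))
})

test_that("the climate-dominant fraction is an explicit count", {
  expect_equal(climate_dominant_fraction(mk_attr(c(10, 20, 30), 1:3 / 10)), 0)
  expect_equal(climate_dominant_fraction(mk_attr(c(60, 60, 40, 40),
                                                 rep(0.5, 4))), 0.5)
  set.seed(8)
  a <- mk_attr(runif(100, 0, 100), runif(100))
  expect_equal(climate_dominant_fraction(a), mean(a$ri_climate > 50))
})

test_that("windows below the valid-pixel threshold are rejected", {
  w <- generate_world(synthetic_world_config(nrows = 12, ncols = 12,
                                             seed = 13))
  ens <- run_ensemble(w$stack, w$tables, run_config(seed = 13,
                                                    n_ensemble = 20L))
  # mask almost everything: no window can reach 51 valid pixels
  keep <- ens$mean
  keep$mask[] <- TRUE
  keep$mask[1:5, 1:5] <- FALSE
  cfg <- run_config(seed = 13, window_size = 11L)
  expect_error(run_windows(w$stack, keep, cfg), ">50")
  expect_error(run_windows(w$stack, ens$mean,
                           run_config(seed = 1, window_size = 101L)),
               "exceeds")
})

test_that("window sampling and fits are reproducible under a seed", {
  w <- generate_world(synthetic_world_config(nrows = 60, ncols = 60, seed = 17,
                                             driver_mode = "soil_dominant"))
  ens <- run_ensemble(w$stack, w$tables, run_config(seed = 17,
                                                    n_ensemble = 50L))
  cfg <- run_config(seed = 17, window_size = 21L, n_windows = 3L,
                    n_trees = 150L, learning_rate = 0.1, cv_folds = 5L)
  a1 <- run_windows(w$stack, ens$mean, cfg)
  a2 <- run_windows(w$stack, ens$mean, cfg)
  expect_identical(a1, a2)
  expect_equal(a1$ri_climate + a1$ri_soil, rep(100, nrow(a1)))
  expect_true(all(a1$n_train >= cfg$min_window_pixels))
})
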