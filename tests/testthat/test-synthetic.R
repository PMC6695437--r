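test_that("generation is deterministic under a seed and distinct across seeds", {
  cfg <- synthetic_world_config(nrows = 40, ncols = 40, seed = 5)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$stack$grids$OC$values, w2$stack$grids$OC$values)
  expect_identical(w1$truth$log_tau, w2$truth$log_tau)
  expect_identical(w1$tables$root_records, w2$tables$root_records)
  w3 <- generate_world(synthetic_world_config(nrows = 40, ncols = 40,
                                              seed = 6))
  expect_false(identical(w1$stack$grids$OC$values, w3$stack$grids$OC$values))
})

test_that("generated fields respect their physical supports", {
  w <- generate_world(synthetic_world_config(nrows = 50, ncols = 50,
                                             seed = 2))
  g <- w$stack$grids
  expect_true(all(g$pH$values >= 3.5 & g$pH$values <= 9.5))
  expect_true(all(g$BD$values >= 800 & g$BD$values <= 1800))
  expect_true(all(g$G$values >= 0 & g$G$values <= 60))
  expect_true(all(g$NPP$values > 0))
  expect_true(all(g$OC$values >= 0 & g$OC$values <= 100))
  expect_true(all(g$biome$values %in% 1:9))
  # texture closure at every pixel
  closure <- g$clay$values + g$silt$values + g$sand$values
  expect_lt(max(abs(closure - 100)), 1e-9)
})

test_that("allocation tables have valid supports and the configured counts", {
  tabs <- generate_allocation_tables(synthetic_world_config(seed = 9))
  expect_true(all(tabs$fbnpp_records$f_bnpp > 0 &
                    tabs$fbnpp_records$f_bnpp < 1))
  expect_true(all(tabs$root_records$d95_m > tabs$root_records$d50_m))
  expect_true(all(tabs$root_records$d50_m > 0))
  expect_equal(nrow(tabs$root_records), 240L)       # 30 x 8 non-crop biomes
  expect_equal(nrow(tabs$fbnpp_records), 270L)      # 30 x 9 biomes
})

test_that("stored coefficients reproduce the soil-dominant variance share", {
  w <- generate_world(synthetic_world_config(nrows = 60, ncols = 60, seed = 8,
                                             driver_mode = "soil_dominant"))
  # recompute the linear predictor from the stored coefficients and fields
  es <- w$truth$coefficients
  zs <- function(m) (m - mean(m)) / sd(m)
  lp_s <- 0; lp_c <- 0
  for (v in names(es)) {
    term <- es[[v]] * zs(w$stack$grids[[v]]$values)
    if (v %in% c("MAT", "MAP")) lp_c <- lp_c + term else lp_s <- lp_s + term
  }
  share <- var(as.numeric(lp_s)) / var(as.numeric(lp_s + lp_c))
  expect_gte(share, 0.8)
  expect_equal(share, w$truth$var_share_soil, tolerance = 1e-10)
})

test_that("the null world has flat turnover up to flux variation", {
  w <- generate_world(synthetic_world_config(nrows = 30, ncols = 30, seed = 4,
                                             driver_mode = "null",
                                             noise_sd = 0))
  expect_lt(max(abs(w$truth$log_tau - log(200))), 1e-12)
  expect_error(generate_world(synthetic_world_config(nrows = 0, ncols = 10)),
               "configuration error")
})

test_that("both biome layouts cover all nine classes", {
  for (lay in c("latitudinal_bands", "voronoi_patches")) {
    w <- generate_world(synthetic_world_config(nrows = 60, ncols = 60,
                                               seed = 3, biome_layout = lay))
    expect_setequal(unique(as.integer(w$stack$grids$biome$values)), 1:9)
  }
})
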