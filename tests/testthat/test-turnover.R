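test_that("the turnover ratio matches hand arithmetic and scaling laws", {
  expect_equal(tau_point(9.8, 0.0545225), 179.7423, tolerance = 1e-6)
  expect_equal(tau_point(0, 0.5), 0)
  expect_equal(tau_point(10, 0.2), 2 * tau_point(10, 0.4))
  expect_true(is.na(tau_point(10, 1e-9)))   # below the flux floor: undefined
  expect_error(tau_point(-1, 0.5), "non-negative")
})

test_that("zero input uncertainty collapses the ensemble interval", {
  stk <- mk_pixel_stack()
  tabs <- mk_const_tables()
  cfg <- run_config(seed = 1, npp_sd_fraction = 0)
  ens <- run_ensemble(stk, tabs, cfg, store_draws = TRUE)
  expect_equal(ncol(ens$draws), 200L)
  expect_equal(length(unique(ens$draws[1, ])), 1L)
  expect_equal(ens$lower$values[1, 1], ens$mean$values[1, 1])
  expect_equal(ens$upper$values[1, 1], ens$mean$values[1, 1])
  expect_equal(ens$pct_uncertainty$values[1, 1], 0)
})

test_that("ensembles are reproducible and respect the quantile sandwich", {
  w <- generate_world(synthetic_world_config(nrows = 12, ncols = 12,
                                             seed = 21))
  cfg <- run_config(seed = 21, n_ensemble = 100L)
  e1 <- run_ensemble(w$stack, w$tables, cfg, store_draws = TRUE)
  e2 <- run_ensemble(w$stack, w$tables, cfg, store_draws = TRUE)
  expect_identical(e1$draws, e2$draws)
  expect_identical(e1$mean$values, e2$mean$values)
  ok <- !e1$mean$mask
  expect_true(all(e1$lower$values[ok] <= e1$upper$values[ok]))
  lo <- apply(e1$draws, 1, min)
  hi <- apply(e1$draws, 1, max)
  med <- apply(e1$draws, 1, median)
  expect_true(all(lo <= e1$lower$values[ok] + 1e-12))
  expect_true(all(e1$lower$values[ok] <= med & med <= e1$upper$values[ok]))
  expect_true(all(e1$upper$values[ok] <= hi + 1e-12))
  expect_true(all(e1$pct_uncertainty$values[ok] >= 0))
})

test_that("near-zero flux pixels are masked and counted, not infinite", {
  stk <- mk_pixel_stack(npp = 1e-9)
  ens <- run_ensemble(stk, mk_const_tables(), run_config(seed = 2))
  expect_equal(ens$n_flux_masked, 1L)
  expect_true(ens$mean$mask[1, 1])
})

test_that("a missing biome in the tables fails before any computation", {
  stk <- mk_pixel_stack(biome = 5)
  tabs <- mk_const_tables()
  tabs$fbnpp_records <- tabs$fbnpp_records[tabs$fbnpp_records$biome != 5, ]
  expect_error(run_ensemble(stk, tabs, run_config()), "biome 5")
})

test_that("percentage uncertainty is the relative CI width", {
  # mean 100, lower 80, upper 139 -> 59%
  ens <- structure(list(
    mean = mk_grid(100), lower = mk_grid(80), upper = mk_grid(139)),
    class = "turnover_ensemble")
  pu <- percentage_uncertainty(ens)
  expect_equal(pu$values[1, 1], 59)
  # scaling all draws by a constant leaves it unchanged
  ens2 <- structure(list(
    mean = mk_grid(100 * 7), lower = mk_grid(80 * 7),
    upper = mk_grid(139 * 7)), class = "turnover_ensemble")
  expect_equal(percentage_uncertainty(ens2)$values[1, 1], 59)
  # degenerate ensemble -> 0; zero mean with width -> masked with warning
  ens3 <- structure(list(
    mean = mk_grid(c(0, 0)), lower = mk_grid(c(0, 0)),
    upper = mk_grid(c(0, 5))), class = "turnover_ensemble")
  expect_warning(pu3 <- percentage_uncertainty(ens3), "masked")
  expect_equal(pu3$values[1, 1], 0)
  expect_true(pu3$mask[1, 2])
})
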