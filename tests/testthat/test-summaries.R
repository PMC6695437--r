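# Minimal hand-built ensemble wrapper around given maps.
mk_ens <- function(mean_g, soc = NULL, bnpp = NULL, n_flux = 0L,
                   cfg = run_config()) {
  ens <- structure(list(
    mean = mean_g, lower = mean_g, upper = mean_g,
    soc = if (is.null(soc)) mean_g else soc,
    bnpp_mean = if (is.null(bnpp)) mean_g else bnpp,
    n_flux_masked = n_flux, config = cfg), class = "turnover_ensemble")
  ens$pct_uncertainty <- percentage_uncertainty(ens)
  ens
}

test_that("summaries of a constant map are that constant everywhere", {
  g <- mk_grid(rep(100, 16), nrow = 4)
  biome <- mk_grid(rep(c(1, 2), 8), nrow = 4)
  s <- summarize_turnover(mk_ens(g), biome)
  expect_true(all(s$quantiles$value[s$quantiles$map == "mean"] == 100))
  expect_true(all(s$biome$mean_tau == 100))
  expect_equal(s$global$value[s$global$stat == "mean_of_mean"], 100)
})

test_that("a two-pixel world has the unweighted mean 15", {
  g <- mk_grid(c(10, 20))
  s <- summarize_turnover(mk_ens(g), mk_grid(c(1, 1)))
  expect_equal(s$global$value[s$global$stat == "mean_of_mean"], 15)
})

test_that("map quantiles agree with a full-sort oracle", {
  set.seed(77)
  v <- rlnorm(10000, 5, 1)
  g <- mk_grid(v, nrow = 100)
  s <- summarize_turnover(mk_ens(g), mk_grid(rep(1, 10000), nrow = 100))
  got <- s$quantiles$value[s$quantiles$map == "mean"]
  sv <- sort(v)                       # type-7: linear order-statistic interp
  oracle <- vapply(c(0.05, 0.25, 0.5, 0.75, 0.95), function(p) {
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }, 0)
  expect_equal(got, oracle)
})

test_that("zonal means match brute-force per-band averaging", {
  set.seed(12)
  g <- grid2d(matrix(runif(2500), 50, 50), origin_lat = 25, origin_lon = 0,
              resolution = 1, name = "x")
  zp <- zonal_profile(g, band_width = 5)
  lat <- rep(grid_lat_centers(g), 50)
  band <- floor(lat / 5)
  for (b in unique(band)) {
    expect_equal(zp$mean[zp$lat_center == (b + 0.5) * 5],
                 mean(g$values[matrix(rep(grid_lat_centers(g), 50), 50) >=
                                 b * 5 &
                               matrix(rep(grid_lat_centers(g), 50), 50) <
                                 (b + 1) * 5]))
  }
  # identity field: profile equals band centres up to discretisation
  gi <- grid2d(matrix(rep(grid_lat_centers(g), 50), 50), origin_lat = 25,
               origin_lon = 0, resolution = 1, name = "lat")
  zpi <- zonal_profile(gi, band_width = 5)
  expect_true(all(abs(zpi$mean - zpi$lat_center) <= 2.5))
  # constant map: flat profile
  zc <- zonal_profile(mk_grid(rep(3, 100), nrow = 10), band_width = 0.3)
  expect_true(all(zc$mean == 3))
  expect_error(zonal_profile(g, band_width = 0), "positive")
})

test_that("log-log correlations match a two-pass Pearson oracle", {
  set.seed(9)
  n <- 400
  soc <- rlnorm(n, 2, 0.6)
  bnpp <- rlnorm(n, -3, 0.4)
  tau <- soc / bnpp
  ens <- mk_ens(mk_grid(tau, nrow = 20), soc = mk_grid(soc, nrow = 20),
                bnpp = mk_grid(bnpp, nrow = 20))
  cc <- loglog_correlation(ens, n_sample = n)
  two_pass <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  expect_equal(cc$r_soc, two_pass(log(tau), log(soc)))
  expect_equal(cc$r_bnpp, two_pass(log(tau), log(bnpp)))
  # exact proportionality: constant allocation makes r(ln tau, ln SOC) = 1
  ens2 <- mk_ens(mk_grid(soc / 0.05, nrow = 20),
                 soc = mk_grid(soc, nrow = 20),
                 bnpp = mk_grid(rep(0.05, n), nrow = 20))
  expect_equal(loglog_correlation(ens2, n_sample = n)$r_soc, 1)
  # constant turnover: undefined correlation errors
  ens3 <- mk_ens(mk_grid(rep(7, n), nrow = 20),
                 soc = mk_grid(soc, nrow = 20),
                 bnpp = mk_grid(bnpp, nrow = 20))
  expect_error(loglog_correlation(ens3, n_sample = n), "degenerate")
})
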