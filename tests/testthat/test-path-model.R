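test_that("single-indicator latents collapse to standardised OLS", {
  set.seed(2)
  n <- 500
  x1 <- rnorm(n)
  x2 <- 0.4 * x1 + rnorm(n)
  tau <- -0.3 * x1 + 0.5 * x2 + rnorm(n, 0, 0.5)
  d <- data.frame(a = x1, b = x2, tau = tau)
  pm <- fit_path_model(d, path_model_spec(climate = "a", soil = "b"),
                       n_boot = 0, seed = 1)
  ols <- coef(lm(scale(tau) ~ scale(x1) + scale(x2)))
  expect_equal(pm$paths$estimate[pm$paths$path == "climate_to_tau"],
               unname(ols[2]), tolerance = 1e-6)
  expect_equal(pm$paths$estimate[pm$paths$path == "soil_to_tau"],
               unname(ols[3]), tolerance = 1e-6)
  expect_equal(pm$loadings$loading, rep(1, 3))
})

test_that("a perfectly coherent block loads at one", {
  set.seed(3)
  n <- 200
  x <- rnorm(n)
  d <- data.frame(s1 = x, s2 = x, s3 = x, c1 = rnorm(n),
                  tau = x + rnorm(n, 0, 0.3))
  pm <- fit_path_model(d, path_model_spec(climate = "c1",
                                          soil = c("s1", "s2", "s3")),
                       n_boot = 0, seed = 1)
  soil_ld <- pm$loadings$loading[pm$loadings$block == "soil"]
  expect_equal(soil_ld, rep(1, 3), tolerance = 1e-12)
})

test_that("generative latent-variable structure is recovered at n = 5000", {
  set.seed(5)
  n <- 5000
  p_cs <- 0.2; p_ct <- -0.15; p_st <- 0.25
  LC <- rnorm(n)
  LS <- p_cs * LC + sqrt(1 - p_cs^2) * rnorm(n)
  lin <- p_ct * LC + p_st * LS
  tau <- lin + sqrt(1 - var(lin)) * rnorm(n)
  lam <- c(0.9, 0.8, 0.7)
  mk <- function(L) sapply(lam, function(l) l * L + sqrt(1 - l^2) * rnorm(n))
  d <- data.frame(mk(LC), mk(LS), tau = tau)
  names(d) <- c(paste0("c", 1:3), paste0("s", 1:3), "tau")
  pm <- fit_path_model(d, path_model_spec(climate = paste0("c", 1:3),
                                          soil = paste0("s", 1:3)),
                       n_boot = 50, seed = 5)
  est <- setNames(pm$paths$estimate, pm$paths$path)
  expect_lt(abs(est["climate_to_soil"] - p_cs), 0.05)
  expect_lt(abs(est["climate_to_tau"] - p_ct), 0.05)
  expect_lt(abs(est["soil_to_tau"] - p_st), 0.05)
  # composite loadings converge to the indicator-composite correlation:
  # with weights proportional to lambda, loading_j ->
  # (lam_j * sum(lam^2) + lam_j * (1 - lam_j^2)) / sd(composite)
  s2 <- sum(lam^2)
  sdS <- sqrt(s2^2 + sum(lam^2 * (1 - lam^2)))
  plim <- (lam * s2 + lam * (1 - lam^2)) / sdS
  got <- pm$loadings$loading[pm$loadings$block == "climate"]
  expect_true(all(abs(got - plim) < 0.05))
  got_s <- pm$loadings$loading[pm$loadings$block == "soil"]
  expect_true(all(abs(got_s - plim) < 0.05))
  # bootstrap intervals bracket the estimates for this well-behaved fixture
  expect_true(all(pm$paths$ci_lower <= pm$paths$estimate &
                    pm$paths$estimate <= pm$paths$ci_upper))
})

test_that("estimation is invariant to pre-flipping a minority indicator", {
  set.seed(6)
  n <- 800
  LC <- rnorm(n); LS <- 0.3 * LC + rnorm(n)
  tau <- -0.2 * LC + 0.4 * LS + rnorm(n)
  d <- data.frame(c1 = LC + rnorm(n, 0, 0.4), c2 = LC + rnorm(n, 0, 0.5),
                  s1 = LS + rnorm(n, 0, 0.4), s2 = LS + rnorm(n, 0, 0.5),
                  s3 = LS + rnorm(n, 0, 0.6), tau = tau)
  sp <- path_model_spec(climate = c("c1", "c2"), soil = c("s1", "s2", "s3"))
  pm1 <- fit_path_model(d, sp, n_boot = 0, seed = 2)
  d2 <- d; d2$s1 <- -d2$s1
  pm2 <- fit_path_model(d2, sp, n_boot = 0, seed = 2)
  expect_equal(pm1$paths$estimate, pm2$paths$estimate, tolerance = 1e-9)
  expect_equal(abs(pm1$loadings$loading), abs(pm2$loadings$loading),
               tolerance = 1e-9)
  expect_true(pm2$loadings$flipped[pm2$loadings$indicator == "s1"])
})

test_that("the latent structure cannot beat unrestricted OLS on R2", {
  set.seed(7)
  n <- 1000
  LC <- rnorm(n); LS <- rnorm(n)
  tau <- -0.3 * LC + 0.5 * LS + rnorm(n, 0, 0.8)
  d <- data.frame(c1 = LC + rnorm(n, 0, 0.5), c2 = LC + rnorm(n, 0, 0.6),
                  s1 = LS + rnorm(n, 0, 0.5), s2 = LS + rnorm(n, 0, 0.6),
                  tau = tau)
  pm <- fit_path_model(d, path_model_spec(climate = c("c1", "c2"),
                                          soil = c("s1", "s2")),
                       n_boot = 0, seed = 3)
  ols_r2 <- summary(lm(tau ~ c1 + c2 + s1 + s2, data = d))$r.squared
  expect_lte(pm$r2_tau, ols_r2 + 1e-12)
})
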