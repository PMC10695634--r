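test_that("exponential feeding law matches its closed form", {
  expect_equal(exponential_feed(1, 0.3, 0), 1)
  expect_equal(exponential_feed(1, 0.16, 10), exp(1.6), tolerance = 1e-12)
  expect_equal(exponential_feed(2, 0.16, 10), 2 * exp(1.6), tolerance = 1e-12)
  # feed doubling time at SFR 0.16 is ln2 / 0.16
  t2 <- log(2) / 0.16
  expect_equal(exponential_feed(1, 0.16, t2), 2, tolerance = 1e-12)
  expect_equal(t2, 4.332, tolerance = 1e-3)
  expect_error(exponential_feed(1, 0.16, -1), "non-negative")
})

test_that("OD <-> biomass conversion with factor 2.30 is an exact involution", {
  expect_equal(od_to_biomass(2.30), 1.0)
  expect_equal(od_to_biomass(0), 0)
  x <- c(0, 0.3, 1, 12.7, 30)
  expect_equal(od_to_biomass(biomass_to_od(x)), x, tolerance = 1e-14)
  expect_error(od_to_biomass(1, factor = 0), "positive")
  expect_error(od_to_biomass(-1), "non-negative")
})

test_that("growth rate series is the backward difference", {
  g <- tibble::tibble(time_h = c(0, 1, 2), biomass_g_per_L = c(1, 2, 4))
  r <- growth_rate_series(g)
  expect_equal(r$rate, c(1, 2))
  expect_equal(r$time_h, c(1, 2))
  const <- tibble::tibble(time_h = 0:5, biomass_g_per_L = rep(3, 6))
  expect_true(all(growth_rate_series(const)$rate == 0))
  # linear biomass on an irregular grid gives a constant rate
  t <- c(0, 0.7, 1.1, 3, 4.6)
  lin <- tibble::tibble(time_h = t, biomass_g_per_L = 2 + 0.8 * t)
  expect_equal(growth_rate_series(lin)$rate, rep(0.8, 4), tolerance = 1e-12)
  expect_error(growth_rate_series(
    tibble::tibble(time_h = c(0, 0), biomass_g_per_L = c(1, 1))),
    "duplicate")
  expect_error(growth_rate_series(g[1, ]), "at least two")
})

test_that("limited feed profile reduces to the exponential law for constant mu", {
  p <- fedbatch_params(F0 = 1, sfr = 0.16, switch_time = 5)
  t <- seq(0, 20, by = 0.5)
  expo <- tibble::tibble(time_h = t, biomass_g_per_L = exp(0.16 * t))
  prof <- limited_feed_profile(p, expo)
  expect_equal(prof$feed_rate, exponential_feed(1, 0.16, t), tolerance = 1e-9)
  # mu -> 0 plateaus the feed
  flat <- tibble::tibble(time_h = t,
                         biomass_g_per_L = c(exp(0.16 * t[t <= 10]),
                                             rep(exp(1.6), sum(t > 10))))
  prof2 <- limited_feed_profile(p, flat)
  n <- length(t)
  expect_equal(prof2$sfr[n], 0)
  expect_lt(diff(tail(prof2$feed_rate, 2)), 1e-9)
  expect_error(limited_feed_profile(p, expo[c(2, 1, 3), ]), "non-monotone")
})

test_that("limited feed profile tracks a logistic growth-rate decline", {
  p <- fedbatch_params(F0 = 1, sfr = 0.16, switch_time = 8)
  t <- seq(0, 30, by = 0.25)
  K <- 30; x0 <- 1; r <- 0.25
  x <- K / (1 + (K - x0) / x0 * exp(-r * t))
  growth <- tibble::tibble(time_h = t, biomass_g_per_L = x)
  prof <- limited_feed_profile(p, growth)
  # discrete specific growth rate of the logistic curve, as the rule sees it
  mu <- c(NA, diff(log(x)) / diff(t)); mu[1] <- mu[2]
  mu_sw <- mu[t == 8]
  expected_sfr <- ifelse(t < 8, 0.16, pmin(0.16, 0.16 * mu / mu_sw))
  expect_equal(prof$sfr, expected_sfr, tolerance = 1e-12)
  expect_true(all(diff(prof$feed_rate) >= 0))
})

test_that("simulator reproduces exponential growth when inhibition is off", {
  # substrate in huge excess, no inhibitor: mu ~ mu_max throughout
  p <- fedbatch_params(F0 = 0, mu_max = 0.3, Ks = 1e-9, S0 = 1e6,
                       k_inhibitor = 0, inhibitor_capacity = Inf,
                       X0 = 1, feed_duration = 10)
  sim <- simulate_fedbatch(p, "efc", dt = 0.01)
  expect_equal(sim$biomass_g_per_L[nrow(sim)], exp(0.3 * 10),
               tolerance = 1e-6)
})

test_that("simulator conserves mass and respects limiting cases", {
  # no substrate, no feed: biomass stays put
  p0 <- fedbatch_params(F0 = 0, S0 = 0, X0 = 2, feed_duration = 5)
  sim0 <- simulate_fedbatch(p0, "efc")
  expect_equal(sim0$biomass_g_per_L, rep(2, nrow(sim0)), tolerance = 1e-12)
  # no growth (mu_max = 0): substrate fed equals substrate accumulated
  p1 <- fedbatch_params(F0 = 0.001, sfr = 0.16, mu_max = 0, S0 = 0,
                        feed_duration = 10)
  sim1 <- simulate_fedbatch(p1, "efc")
  fed <- 0.001 * 300 / 0.16 * (exp(0.16 * 10) - 1)  # integral of F * s_in
  # feed is held piecewise-constant within a step, so allow first-order slack
  expect_equal(sim1$substrate[nrow(sim1)], fed, tolerance = 0.01)
  expect_error(simulate_fedbatch(p1, dt = 0), "positive")
})

test_that("integrator is converged at the default step", {
  p <- fedbatch_params()
  a <- simulate_fedbatch(p, "efc", dt = 0.01)
  b <- simulate_fedbatch(p, "efc", dt = 0.005)
  rel <- abs(tail(b$biomass_g_per_L, 1) - tail(a$biomass_g_per_L, 1)) /
    tail(a$biomass_g_per_L, 1)
  expect_lt(rel, 0.001)
})

test_that("inhibition lowers final biomass; matched EFC and LFC runs converge", {
  p <- fedbatch_params()
  efc <- simulate_fedbatch(p, "efc")
  lfc <- simulate_fedbatch(p, "lfc")
  x_efc <- tail(efc$biomass_g_per_L, 1)
  x_lfc <- tail(lfc$biomass_g_per_L, 1)
  expect_lt(abs(x_efc - x_lfc) / x_efc, 0.10)
  # biomass never decreases
  expect_true(all(diff(efc$biomass_g_per_L) >= -1e-12))
  expect_true(all(diff(lfc$biomass_g_per_L) >= -1e-12))
  # LFC feeds less in total once its SFR starts tracking the mu decline
  expect_lt(tail(lfc$feed_rate, 1), tail(efc$feed_rate, 1))
  # disabling the inhibitor strictly raises final biomass
  p_free <- fedbatch_params(k_inhibitor = 0)
  free <- simulate_fedbatch(p_free, "efc")
  expect_gt(tail(free$biomass_g_per_L, 1), x_efc)
})
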