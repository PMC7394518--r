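test_that("establishment probability matches its closed form and caps at alpha", {
  a <- data.frame(temperature = 20, salinity = 30)
  expect_identical(prob_establish(a, a), 0.00015)
  b <- data.frame(temperature = 22, salinity = 30)
  expect_equal(prob_establish(a, b), 0.00015 * exp(-0.5), tolerance = 1e-12)
  expect_equal(prob_establish(a, b), prob_establish(b, a))
  # monotone vanishing in temperature difference
  dts <- seq(0, 40, by = 2)
  vals <- vapply(dts, function(dt) {
    prob_establish(a, data.frame(temperature = 20 + dt, salinity = 30))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= 0.00015))
})

test_that("nonindigenous indicator follows the ecoregion neighbourhood", {
  w <- tiny_world()
  p <- function(id) w$ports[w$ports$port_id == id, ]
  expect_equal(prob_nonindigenous(p("AAA"), p("DDD"), w$eco), 0)  # same ecoregion
  expect_equal(prob_nonindigenous(p("AAA"), p("BBB"), w$eco), 0)  # neighbours
  expect_equal(prob_nonindigenous(p("AAA"), p("CCC"), w$eco), 1)  # distinct
  expect_equal(prob_nonindigenous(p("CCC"), p("AAA"), w$eco), 1)  # symmetric
  bad <- p("AAA"); bad$ecoregion_id <- "nope"
  expect_error(prob_nonindigenous(bad, p("BBB"), w$eco), "nope")
})

test_that("biofouling accumulation follows the zone cubics with clamping", {
  expect_equal(biofouling_accumulation(0, "tropical"), 0)
  expect_equal(biofouling_accumulation(60, "tropical"),
               1.29e-7 * 60^3 - 8.316e-5 * 60^2 + 0.0149 * 60, tolerance = 1e-12)
  expect_equal(biofouling_accumulation(60, "tropical"), 0.622488, tolerance = 1e-9)
  # the raw tropical cubic exceeds 1 for very long stays and is clamped
  expect_equal(biofouling_accumulation(500, "tropical"), 1)
  raw <- default_params(clamp_accumulation = FALSE)
  expect_equal(biofouling_accumulation(500, "tropical", raw), 2.785, tolerance = 1e-9)
  expect_equal(biofouling_accumulation(60, "temperate"),
               1.4e-9 * 60^3 - 1.6566e-5 * 60^2 + 5.193e-3 * 60, tolerance = 1e-12)
  expect_error(biofouling_accumulation(-1, "tropical"), "non-negative")
})

test_that("biofouling survival decays exponentially in velocity", {
  expect_equal(biofouling_survival(0), 1)
  expect_equal(biofouling_survival(100), exp(-0.8), tolerance = 1e-12)
  v <- seq(0, 1000, by = 50)
  expect_true(all(diff(biofouling_survival(v)) < 0))
})

test_that("biofouling voyage probability is the product of its three factors", {
  got <- biofouling_voyage_prob(60, 100, "Container", "tropical")
  expect_equal(got, 0.19 * 0.622488 * exp(-0.8), tolerance = 1e-9)
  # antifouling ratio between types on the same voyage
  bulk <- biofouling_voyage_prob(60, 100, "Bulk", "tropical")
  expect_equal(bulk / got, 0.42 / 0.19, tolerance = 1e-12)
  # unknown type falls back to the 'other' value 0.60
  other <- biofouling_voyage_prob(60, 100, "Hovercraft", "tropical")
  expect_equal(other / got, 0.60 / 0.19, tolerance = 1e-12)
  expect_equal(biofouling_voyage_prob(0, 100, "Bulk", "tropical"), 0)
})

test_that("ballast discharge uses observations, else type coefficient times GWT", {
  p <- default_params(discharge_coeff = c(Bulk = 0.3))
  expect_equal(ballast_discharge("Bulk", 10000, observed = 500, p), 500)
  expect_equal(ballast_discharge("Bulk", 10000, NA, p), 3000)
  expect_error(ballast_discharge("Bulk", 0, NA, p), "gwt")
})

test_that("ballast voyage probability follows the discharge-mortality form", {
  expect_equal(ballast_voyage_prob(0, 10), 0)
  expect_equal(ballast_voyage_prob(1e6, 10),
               (1 - exp(-3.22)) * exp(-0.2), tolerance = 1e-12)
  expect_equal(ballast_voyage_prob(1e6, 10, rho = 0), 0)
  # monotone in discharge, decaying in duration (numeric-derivative signs)
  D <- seq(0, 5e6, length.out = 40)
  expect_true(all(diff(ballast_voyage_prob(D, 5)) > 0))
  dt <- seq(0, 60, length.out = 40)
  expect_true(all(diff(ballast_voyage_prob(1e5, dt)) < 0))
  # limit: rho as discharge grows without bound at zero duration
  expect_equal(ballast_voyage_prob(1e12, 0, rho = 0.7), 0.7, tolerance = 1e-9)
})

test_that("voyage-union aggregation matches the direct-product oracle", {
  expect_equal(prob_union(numeric(0)), 0)
  expect_equal(prob_union(0.4), 0.4)
  expect_equal(prob_union(c(0.5, 0.5)), 0.75)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    expect_equal(prob_union(p), oracle_union(p), tolerance = 1e-12)
    expect_equal(prob_union(p), prob_union(sample(p)))  # permutation invariant
    expect_gte(prob_union(p) + 1e-15, max(p))
  }
})

test_that("pair risks multiply the three probabilities over aggregated voyages", {
  w <- tiny_world()
  vr <- voyage_risks(w$voyages, w$ships, w$ports, "biofouling")
  pr <- pair_risks(vr, w$ports, w$eco)
  expect_equal(nrow(pr), 3L)
  # same/neighbour-ecoregion pair has zero spread whatever the traffic
  ab <- pr[pr$source == "AAA" & pr$dest == "BBB", ]
  expect_equal(ab$p_nonindigenous, 0)
  expect_equal(ab$p_spread, 0)
  # single-voyage pair: p_intro equals the voyage probability
  bc <- pr[pr$source == "BBB" & pr$dest == "CCC", ]
  expect_equal(bc$p_intro, vr$prob[vr$source == "BBB"], tolerance = 1e-12)
  expect_true(all(pr$p_spread <= 0.00015))
  expect_equal(pr$p_spread,
               pr$p_nonindigenous * pr$p_establish * pr$p_intro, tolerance = 1e-15)
})

test_that("every probability stays in [0,1] over random admissible inputs", {
  set.seed(21)
  for (i in 1:200) {
    stay <- runif(1, 0, 600); vel <- runif(1, 0, 2000)
    z <- sample(c("tropical", "temperate"), 1)
    ty <- sample(c("Container", "Bulk", "weird"), 1)
    b <- biofouling_voyage_prob(stay, vel, ty, z)
    expect_true(b >= 0 && b <= 1)
    bl <- ballast_voyage_prob(runif(1, 0, 1e7), runif(1, 0, 100), runif(1))
    expect_true(bl >= 0 && bl <= 1)
  }
})

test_that("parameter configs round-trip through YAML", {
  p <- default_params(gamma = 0.0008, antifouling = c(Container = 0.25))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(p2$gamma, 0.0008)
  expect_equal(p2$antifouling[["Container"]], 0.25)
  expect_equal(p2$beta_tropical, p$beta_tropical)
})
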