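test_that("parameter constructor validates names, ranges and geometry", {
  p <- model_params()
  expect_equal(p$ksat, 600)
  expect_equal(p$k0p, 0.0025)
  expect_error(model_params(nosuch = 1), "unknown parameter")
  expect_error(model_params(k2n = -1), "non-negative")
  expect_error(model_params(h = 0.5), "Hill")
  expect_error(model_params(noise_mode = "sometimes"), "noise_mode")
  p2 <- model_params(lambda = Inf, Ectot = 500)
  expect_true(is.infinite(p2$lambda))
  expect_equal(cell_volume(p2$geometry), 80 * pi / 3)
})

test_that("config files round-trip through the symbol names", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("ksat: 450", "k5n: 0.015", "lambda: inf", "L: 10"), f)
  p <- read_config(f)
  expect_equal(p$ksat, 450)
  expect_equal(p$k5n, 0.015)
  expect_true(is.infinite(p$lambda))
  expect_equal(p$L, 10)
  writeLines(c("ksat: 450", "bogus_key: 1"), f)
  expect_error(read_config(f), "unknown parameter")
  unlink(f)
})

test_that("quasi-static GEF field: trivial cases and exact conservation", {
  mesh <- default_mesh()
  p <- model_params()
  n <- nrow(mesh$nodes)
  gf0 <- gef_field(rep(0, n), p, mesh)
  expect_equal(gf0$CGEF, rep(0, n))
  expect_equal(gf0$Ec, p$Ectot)
  set.seed(11)
  for (k in 1:5) {
    CT <- runif(n, 0, 10^k / 10)
    gf <- gef_field(CT, p, mesh)
    expect_lt(abs(gf$Ec + sum(gf$CGEF * mesh$areas) - p$Ectot) / p$Ectot, 1e-12)
  }
})

test_that("uniform GEF field matches the scalar closed form", {
  mesh <- default_mesh()
  p <- model_params()
  n <- nrow(mesh$nodes)
  cc <- 120
  gf <- gef_field(rep(cc, n), p, mesh)
  ## scalar arithmetic with the mesh's own area (exact) ...
  V <- 80 * pi / 3
  g <- (p$k1p * cc + p$k2p * cc^2) / V
  Ec_mesh <- p$Ectot / (1 + g * sum(mesh$areas))
  expect_equal(gf$Ec, Ec_mesh, tolerance = 1e-12)
  expect_equal(gf$CGEF, rep(g * Ec_mesh, n), tolerance = 1e-12)
  ## ... and with the analytic area 32*pi (mesh discretization error only)
  Ec_analytic <- p$Ectot / (1 + g * 32 * pi)
  expect_equal(gf$Ec, Ec_analytic, tolerance = 0.005)
})

test_that("reaction terms reproduce hand-evaluated scalar kinetics", {
  mesh <- default_mesh()
  p <- model_params(lambda = Inf, noise_mode = "off")
  ## no activation machinery: membrane exchange fixed point CD = jDp/rD
  st <- uniform_state(mesh, p, CD = 50, CT = 0)
  d <- reaction_rates(st, p, mesh)
  expect_equal(d$dCD, rep(p$jDp - p$rD * 50, nrow(mesh$nodes)))
  expect_equal(p$jDp / p$rD, 80)  # the unpolarized resting concentration
  st80 <- uniform_state(mesh, p, CD = 80, CT = 0)
  expect_equal(max(abs(reaction_rates(st80, p, mesh)$dCD)), 0)
  ## GAP_I Hill recruitment at half saturation
  st_half <- uniform_state(mesh, p, CT = p$ksat)
  expect_equal(reaction_rates(st_half, p, mesh)$dCGAPI,
               rep(p$k4n / 2, nrow(mesh$nodes)))
  ## independent scalar evaluation of every term at hand-picked values
  CD <- 37; CT <- 412; GI <- 830; GF <- 12.5; GS <- 340
  st_mix <- uniform_state(mesh, p, CD = CD, CT = CT, CGAPI = GI,
                          CGAPIIfast = GF, CGAPIIslow = GS)
  d <- reaction_rates(st_mix, p, mesh)
  V <- cell_volume(mesh$geom)
  A <- sum(mesh$areas)
  Ec <- p$Ectot / (1 + (p$k1p * CT / V + p$k2p * CT^2 / V) * A)
  CGEF <- (p$k1p * CT / V + p$k2p * CT^2 / V) * Ec
  hyd <- (p$k1n + p$k2n * GI + p$k3n * GF + p$k8n * GS) * CT
  act <- p$k0p * CGEF * CD
  expect_equal(d$dCD[1], p$jDp + hyd - act - p$rD * CD, tolerance = 1e-12)
  expect_equal(d$dCT[1], act - hyd - p$rT * CT, tolerance = 1e-12)
  expect_equal(d$dCGAPI[1], p$k4n * CT^2 / (p$ksat^2 + CT^2) - p$rGAPI * GI,
               tolerance = 1e-12)
  expect_equal(d$dCGAPIIfast[1],
               p$k5n * CT - (p$k6n * GF - p$k7n * GS * CT) - p$rGAPIIfast * GF,
               tolerance = 1e-12)
  expect_equal(d$dCGAPIIslow[1],
               (p$k6n * GF - p$k7n * GS * CT) - p$rGAPIIslow * GS,
               tolerance = 1e-12)
  ## negative concentrations beyond tolerance name the offending field
  st_bad <- st_mix
  st_bad$CGAPI[3] <- -1e-6
  expect_error(reaction_rates(st_bad, p, mesh), "CGAPI")
})

test_that("tip bias is exponential in arc length and unity when unbiased", {
  mesh <- default_mesh()
  b <- tip_bias(mesh, 2.5)
  expect_equal(b, exp(-mesh$s / 2.5))
  expect_equal(tip_bias(mesh, Inf), rep(1, nrow(mesh$nodes)))
})

test_that("stochastic noise conserves total Cdc42 and has the Poisson mean", {
  mesh <- default_mesh()
  p <- model_params(noise_mode = "stochastic")
  st <- uniform_state(mesh, p, CD = 80, CT = 5)
  ## rnoise = 0 leaves the state untouched
  p0 <- model_params(rnoise = 0, noise_mode = "stochastic")
  expect_identical(apply_noise(st, p0, 0.01, mesh)$CD, st$CD)
  set.seed(99)
  mass0 <- sum((st$CD + st$CT) * mesh$areas)
  converted <- 0
  s2 <- st
  nrep <- 200L
  dt <- 0.1
  for (k in seq_len(nrep)) {
    s_new <- apply_noise(s2, p, dt, mesh)
    expect_lt(abs(sum((s_new$CD + s_new$CT) * mesh$areas) - mass0), 1e-9 * mass0)
    converted <- converted + sum((s_new$CT - s2$CT) * mesh$areas)
    s2$CD <- st$CD; s2$CT <- st$CT   # reset so the mean stays fixed
  }
  expected <- p$rnoise * 80 * sum(mesh$areas) * dt * nrep
  expect_equal(converted, expected, tolerance = 0.1)
  expect_true(all(s_new$CD >= 0))
})

test_that("initial state is the perturbed unpolarized resting state", {
  mesh <- default_mesh()
  p <- model_params()
  set.seed(5); st1 <- initial_state(p, mesh)
  set.seed(5); st2 <- initial_state(p, mesh)
  expect_identical(st1$CD, st2$CD)
  expect_equal(mean(st1$CD), 80, tolerance = 0.005)
  expect_true(all(abs(st1$CD - 80) <= 0.8 + 1e-12))
  expect_true(all(st1$CT >= 0 & st1$CT <= 0.8 + 1e-12))
  expect_equal(st1$CGAPI, numeric(nrow(mesh$nodes)))
  ## zero-amplitude fluctuations give the exactly uniform state
  p0 <- model_params(init_fluct = 0)
  st0 <- initial_state(p0, mesh)
  expect_equal(st0$CD, rep(80, nrow(mesh$nodes)))
  expect_equal(st0$CT, rep(0, nrow(mesh$nodes)))
})
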