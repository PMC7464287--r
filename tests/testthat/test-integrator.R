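test_that("pure diffusion conserves mass, contracts variance, and flattens", {
  mesh <- default_mesh()
  p <- diffusion_only_params(duration = 10)
  set.seed(8)
  st0 <- uniform_state(mesh, p)
  st0$CD <- runif(nrow(mesh$nodes), 50, 110)
  st0$CT <- runif(nrow(mesh$nodes), 0, 40)
  traj <- suppressWarnings(run(p, mesh = mesh, init = st0))  # 1000 diffusion-only steps
  m <- traj$mass
  for (f in c("CD", "CT"))
    expect_lt(abs(m[nrow(m), f] - m[1, f]) / m[1, f], 1e-10)
  ## heat equation contracts the spatial variance of CD
  set.seed(2)
  st <- uniform_state(mesh, p)
  spike <- which.max(mesh$s)
  st$CT <- numeric(nrow(mesh$nodes)); st$CT[spike] <- 1000
  v_prev <- Inf
  for (k in 1:200) {
    st <- step(st, p, mesh)
    if (k %% 50 == 0) {
      v <- sum((st$CT - area_mean(st$CT, mesh))^2 * mesh$areas)
      expect_lt(v, v_prev)
      v_prev <- v
    }
  }
  expect_true(all(st$CT >= 0))
  ## L2 norm non-increasing without reactions
  expect_lt(sum(st$CT^2 * mesh$areas), 1000^2 * mesh$areas[spike])
})

test_that("the R reference step and the compiled run agree", {
  mesh <- default_mesh()
  p <- model_params(duration = 0.5, noise_mode = "off")
  traj <- suppressWarnings(run(p, mesh = mesh))
  set.seed(p$seed)
  st <- initial_state(p, mesh)
  for (k in seq_len(round(p$duration / p$dt))) st <- step(st, p, mesh)
  for (f in c("CD", "CT", "CGAPI", "CGAPIIfast", "CGAPIIslow", "CGEF")) {
    scale <- max(abs(st[[f]]), 1e-12)
    expect_lt(max(abs(st[[f]] - traj$final[[f]])) / scale, 1e-10,
              label = sprintf("R/compiled mismatch in %s", f))
  }
  expect_equal(traj$final$Ec, st$Ec, tolerance = 1e-12)
})

test_that("uniform unbiased kinetics match an independent scalar oracle", {
  ## With lambda = Inf and uniform fields, every node follows the same
  ## scalar ODE system; an independently coded scalar forward-Euler and a
  ## high-accuracy deSolve solution bracket the compiled integrator.
  mesh <- default_mesh()
  p <- model_params(lambda = Inf, noise_mode = "off", init_fluct = 0,
                    duration = 100)
  traj <- run(p, mesh = mesh)
  A <- sum(mesh$areas); V <- cell_volume(mesh$geom)
  rhs_scalar <- function(CD, CT, GI, GF, GS) {
    Ec <- p$Ectot / (1 + (p$k1p * CT / V + p$k2p * CT^2 / V) * A)
    CGEF <- (p$k1p * CT / V + p$k2p * CT^2 / V) * Ec
    hyd <- (p$k1n + p$k2n * GI + p$k3n * GF + p$k8n * GS) * CT
    act <- p$k0p * CGEF * CD
    conv <- p$k6n * GF - p$k7n * GS * CT
    c(p$jDp + hyd - act - p$rD * CD,
      act - hyd - p$rT * CT,
      p$k4n * CT^p$h / (p$ksat^p$h + CT^p$h) - p$rGAPI * GI,
      p$k5n * CT - conv - p$rGAPIIfast * GF,
      conv - p$rGAPIIslow * GS)
  }
  y <- c(80, 0, 0, 0, 0)
  for (k in seq_len(10000L)) y <- y + 0.01 * do.call(rhs_scalar, as.list(y))
  expect_lt(max(abs(traj$final$CD - y[1])) / y[1], 1e-9)
  expect_lt(max(abs(traj$final$CT - y[2])) / max(y[2], 1e-9), 1e-6)
  expect_lt(max(abs(traj$final$CGAPI - y[3])) / max(y[3], 1e-9), 1e-6)
  skip_if_not_installed("deSolve")
  sol <- deSolve::ode(
    y = c(CD = 80, CT = 0, GI = 0, GF = 0, GS = 0),
    times = c(0, 100),
    func = function(t, y, parms) list(do.call(rhs_scalar, as.list(y))),
    rtol = 1e-10, atol = 1e-12)
  exact <- sol[2, -1]
  ## forward Euler at dt = 0.01 s carries only its O(dt) discretization error
  expect_equal(unname(y), unname(exact), tolerance = 2e-3)
  expect_equal(mean(traj$final$CD), unname(exact["CD"]), tolerance = 2e-3)
})

test_that("isolated membrane exchange relaxes to the closed-form fixed point", {
  mesh <- default_mesh()
  p <- model_params(k0p = 0, k4n = 0, k5n = 0, noise_mode = "off",
                    init_fluct = 0, duration = 100)
  traj <- run(p, mesh = mesh)
  CD0 <- 80
  ## starting exactly at jDp/rD the state is stationary: CD stays at 80
  expect_lt(max(abs(traj$final$CD - CD0)) / CD0, 1e-5)
  expect_lt(max(traj$final$CT), 1e-9)
  ## and from a displaced start it relaxes as jDp/rD + (CD0' - jDp/rD) e^(-rD t)
  p2 <- model_params(k0p = 0, k1n = 0, k4n = 0, k5n = 0, noise_mode = "off",
                     init_fluct = 0, duration = 50)
  set.seed(1)
  st <- uniform_state(mesh, p2, CD = 120, CT = 10)
  for (k in seq_len(round(50 / p2$dt))) st <- step(st, p2, mesh)
  ## tolerance reflects the O(dt) discretization error of the explicit scheme
  expect_equal(mean(st$CD), 80 + 40 * exp(-p2$rD * 50), tolerance = 1e-4)
  expect_equal(mean(st$CT), 10 * exp(-p2$rT * 50), tolerance = 1e-4)
})

test_that("runs are deterministic in the seed and duration-0 returns the start", {
  p <- model_params(duration = 2, seed = 123)
  t1 <- suppressWarnings(run(p)); t2 <- suppressWarnings(run(p))
  expect_identical(t1$tip1, t2$tip1)
  expect_identical(t1$final$CT, t2$final$CT)
  p3 <- model_params(duration = 2, seed = 124)
  expect_false(identical(t1$final$CT, suppressWarnings(run(p3))$final$CT))
  p0 <- model_params(duration = 0)
  t0 <- run(p0)
  expect_length(t0$times, 1L)
  expect_equal(t0$final$t, 0)
  expect_warning(run(model_params(duration = 50)), "unreliable")
})

test_that("GEF conservation holds along a stochastic trajectory", {
  p <- model_params(duration = 20, noise_mode = "stochastic")
  traj <- suppressWarnings(run(p))
  expect_lt(gef_conservation_error(traj$final, p, traj$mesh), 1e-12)
  ## total Cdc42 exchanges only with the cytoplasm: with jDp = rD = rT = 0
  ## every remaining term (activation, hydrolysis, diffusion, noise events)
  ## conserves CD+CT mass exactly
  p2 <- model_params(jDp = 0, rD = 0, rT = 0, k1n = 0, duration = 5,
                     noise_mode = "stochastic")
  mesh <- default_mesh()
  set.seed(4)
  st0 <- uniform_state(mesh, p2, CD = 80, CT = 20)
  traj2 <- suppressWarnings(run(p2, mesh = mesh, init = st0))
  tot <- traj2$mass[, "CD"] + traj2$mass[, "CT"]
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
})

test_that("halving dt changes the early tip trace only at the O(dt) level", {
  ## temporal convergence at the asymmetric stationary parameter set; the
  ## scheme is first order, and at t = 200 s (mid symmetry-breaking, the
  ## most dt-sensitive stretch) the measured convergence constant puts the
  ## dt -> dt/2 difference near 1.4%, halving again from dt/2 -> dt/4
  p1 <- model_params(ksat = 900, Ectot = 700, duration = 200,
                     noise_mode = "off")
  p2 <- model_params(ksat = 900, Ectot = 700, duration = 200, dt = 0.005,
                     noise_mode = "off")
  mesh <- default_mesh()
  tr1 <- run(p1, mesh = mesh)
  tr2 <- run(p2, mesh = mesh)
  i1 <- length(tr1$times); i2 <- length(tr2$times)
  scale <- max(tr1$tip1[i1], tr1$tip2[i1])
  expect_lt(abs(tr1$tip1[i1] - tr2$tip1[i2]) / scale, 0.025)
  expect_lt(abs(tr1$tip2[i1] - tr2$tip2[i2]) / scale, 0.025)
})

test_that("trajectories export traces and snapshots to plain-text formats", {
  p <- model_params(duration = 4, noise_mode = "off")
  traj <- suppressWarnings(run(p, snapshots_every = 2, snapshot_start = 0))
  f <- tempfile(fileext = ".csv")
  write_traces_csv(traj, f)
  d <- read.csv(f)
  expect_named(d, c("time_s", "tip1_CT", "tip2_CT", "Ec", "mass_CD", "mass_CT",
                    "mass_CGAPI", "mass_CGAPIIfast", "mass_CGAPIIslow"))
  expect_equal(nrow(d), length(traj$times))
  g <- tempfile(fileext = ".json")
  write_run_json(traj, classify_state(tip_traces(traj)), g)
  rec <- jsonlite::read_json(g)
  expect_equal(rec$params$ksat, 600)
  expect_equal(rec$label, "INDETERMINATE")
  vd <- tempfile()
  files <- write_vtk_snapshots(traj, vd)
  expect_length(files, 3L)
  expect_true(all(file.exists(files)))
  unlink(c(f, g)); unlink(vd, recursive = TRUE)
})
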