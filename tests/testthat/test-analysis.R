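## Synthetic trace/profile fixtures with known properties.

make_traces <- function(t, tip1, tip2) {
  structure(list(t = t, tip1 = tip1, tip2 = tip2), class = "tip_traces")
}

test_that("peak detection recovers prominence-filtered maxima", {
  t <- seq(0, 2000, by = 1)
  x <- 100 + 50 * sin(2 * pi * t / 300)
  pk <- find_peaks(x, min_prominence = 10)
  expect_equal(nrow(pk), 7L)
  expect_equal(mean(diff(t[pk$i])), 300, tolerance = 0.01)
  ## small ripples below the prominence threshold are ignored
  y <- x + 2 * sin(2 * pi * t / 23)
  pk2 <- find_peaks(smooth_trace(y, 21L), min_prominence = 10)
  expect_equal(nrow(pk2), 7L)
  expect_equal(nrow(find_peaks(rep(1, 100))), 0L)
})

test_that("oscillation period: constructed sinusoid and degenerate traces", {
  t <- seq(0, 2000, by = 1)
  x <- 100 + 40 * sin(2 * pi * t / 300)
  expect_equal(oscillation_period(x, t, transient_cut = 100), 300, tolerance = 2 / 300)
  expect_true(is.na(oscillation_period(rep(5, 2001), t)))
  ## fewer than 3 peaks gives no period
  short <- 100 + 40 * sin(2 * pi * seq(0, 500, 1) / 300)
  expect_true(is.na(oscillation_period(short, seq(0, 500, 1))))
})

test_that("classifier labels constructed archetypes and is tip-swap invariant", {
  t <- seq(0, 1200, by = 1)
  n <- length(t)
  arche <- list(
    BPS = make_traces(t, rep(500, n), rep(490, n)),
    MPS = make_traces(t, rep(500, n), rep(100, n)),
    UNPOLARIZED = make_traces(t, rep(20, n), rep(21, n)),
    BPO = make_traces(t, 300 + 250 * sin(2 * pi * t / 300),
                      300 - 250 * sin(2 * pi * t / 300)),
    MPDO = make_traces(t,
                       300 + 150 * exp(-t / 600) * sin(2 * pi * t / 300),
                       150 - 150 * exp(-t / 600) * sin(2 * pi * t / 300))
  )
  for (lbl in names(arche)) {
    res <- classify_state(arche[[lbl]])
    expect_equal(res$label, lbl, label = sprintf("archetype %s", lbl))
    swapped <- make_traces(t, arche[[lbl]]$tip2, arche[[lbl]]$tip1)
    expect_equal(classify_state(swapped)$label, lbl,
                 label = sprintf("tip-swapped archetype %s", lbl))
  }
  expect_equal(classify_state(arche$BPO)$period_s, 300, tolerance = 0.02)
  expect_lt(classify_state(arche$BPO)$anticorrelation, -0.9)
  ## too-short traces are an explicit indeterminate outcome
  expect_equal(classify_state(make_traces(0:300, rep(1, 301), rep(1, 301)))$label,
               "INDETERMINATE")
})

test_that("profiles are flat for uniform fields and area-weighted by bin", {
  mesh <- default_mesh()
  p <- model_params()
  st <- uniform_state(mesh, p, CD = 80, CT = 33)
  prof <- profile_vs_arclength(st, mesh)
  expect_true(all(abs(prof$CT - 33) < 1e-9))
  expect_true(all(abs(prof$CD - 80) < 1e-9))
  expect_equal(prof$CGAPII, prof$CGAPIIfast + prof$CGAPIIslow)
  smax <- pi * mesh$geom$R / 2 + (mesh$geom$L - 2 * mesh$geom$R) / 2
  expect_equal(max(prof$s) + attr(prof, "bin_width") / 2, smax, tolerance = 0.1)
  full <- profile_vs_arclength(st, mesh, full_length = TRUE)
  expect_equal(max(full$s) + attr(full, "bin_width") / 2, 2 * smax, tolerance = 0.1)
  expect_error(profile_vs_arclength(st, mesh, bin_width = 0.05), "cell diameter")
})

test_that("decay-length fit recovers planted exponentials within 2%", {
  mesh <- default_mesh()
  p <- model_params()
  for (lam in c(0.3, 0.5, 0.64, 0.72, 1.0, 1.5)) {
    st <- uniform_state(mesh, p)
    st$CT <- 800 * exp(-mesh$s / lam)
    prof <- profile_vs_arclength(st, mesh)
    fit <- decay_length_fit(prof, fit_range = 2)
    expect_equal(fit$decay_length, lam, tolerance = 0.02,
                 label = sprintf("planted decay length %.2f um", lam))
  }
})

test_that("tip-to-side ratio: uniform unity, enriched tip, disjointness guard", {
  mesh <- default_mesh()
  p <- model_params()
  st <- uniform_state(mesh, p, CD = 80, CT = 10)
  expect_equal(tip_to_side_ratio(st, mesh), 1, tolerance = 1e-9)
  ## without activation the ratio only reflects the (absent) CD dip
  st0 <- uniform_state(mesh, p, CD = 80, CT = 0)
  expect_equal(tip_to_side_ratio(st0, mesh), 1, tolerance = 1e-9)
  st$CT <- st$CT + 300 * exp(-mesh$s / 0.7) * (mesh$nodes[, 3] < 0)
  expect_gt(tip_to_side_ratio(st, mesh), 2)
  expect_error(tip_to_side_ratio(st, mesh, s_tip = 4.5), "disjoint")
})

test_that("tip traces recompute from snapshots at other radii", {
  p <- model_params(duration = 6, noise_mode = "off")
  traj <- suppressWarnings(run(p, snapshots_every = 2, snapshot_start = 0))
  tr <- tip_traces(traj)
  expect_s3_class(tr, "tip_traces")
  expect_equal(tr$t, traj$times)
  tr2 <- tip_traces(traj, s_tip = 1.0)
  expect_length(tr2$tip1, length(traj$snapshots$t))
  expect_error(tip_traces(suppressWarnings(run(p)), s_tip = 1.0), "snapshots")
})

test_that("patch tracking separates stationary, jumping and traveling patches", {
  mesh <- default_mesh()
  gauss_patch <- function(center) {
    d2 <- rowSums(sweep(mesh$nodes, 2, center)^2)
    20 + 500 * exp(-d2 / (2 * 0.6^2))
  }
  fake_traj <- function(centers) {
    ct <- vapply(centers, gauss_patch, numeric(nrow(mesh$nodes)))
    structure(list(snapshots = list(t = seq_along(centers) * 10, CT = ct),
                   mesh = mesh), class = "cdc42_trajectory")
  }
  ## fixed patch at one tip
  still <- fake_traj(rep(list(c(0, 0, -4)), 8))
  r_still <- patch_tracking(still)
  expect_equal(r_still$label, "STATIONARY_PATCH")
  expect_lt(r_still$net_drift, 0.1)
  ## patch hopping between distant sites without directed motion
  hop <- fake_traj(rep(list(c(0, 0, -4), c(2, 0, 1), c(0, -2, -1)), 4))
  expect_equal(patch_tracking(hop)$label, "PATCH_DYNAMIC")
  ## patch circulating smoothly around the cylinder: a traveling wave
  ang <- seq(0, 1.75 * pi, length.out = 15)
  wave <- fake_traj(lapply(ang, function(a) c(2 * cos(a), 2 * sin(a), 0)))
  r_wave <- patch_tracking(wave)
  expect_equal(r_wave$label, "WAVE")
  expect_gt(r_wave$coherence, 0.9)
  ## no patch at all
  flat <- structure(list(snapshots = list(t = c(10, 20),
                                          CT = matrix(30, nrow(mesh$nodes), 2)),
                         mesh = mesh), class = "cdc42_trajectory")
  expect_equal(patch_tracking(flat)$label, "NONE")
})
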