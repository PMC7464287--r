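## Trajectory analysis: tip traces, dynamical-state classification,
## oscillation periods, arc-length profiles, decay lengths, patch tracking.

#' Centered moving-average smoothing
#' @param x Numeric vector.
#' @param k Odd window length (samples).
#' @return Smoothed vector of the same length (shrinking window at edges).
#' @keywords internal
smooth_trace <- function(x, k = 21L) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Local maxima with topographic prominence
#'
#' A peak's prominence is its height minus the highest saddle separating it
#' from higher terrain (or from the trace end if none is higher).
#'
#' @param x Numeric vector.
#' @param min_prominence Keep only peaks at least this prominent.
#' @return data.frame with `i` (index), `height`, `prominence`.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(data.frame(i = integer(), height = numeric(),
                                prominence = numeric()))
  is_pk <- which(diff(sign(diff(x))) < 0) + 1L
  ## plateau-safe: require strictly greater than some neighbor on each side
  if (!length(is_pk)) return(data.frame(i = integer(), height = numeric(),
                                        prominence = numeric()))
  prom <- vapply(is_pk, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    right <- x[seq.int(i + 1L, n)]
    higher_l <- which(left >= h)
    min_l <- if (length(higher_l)) min(x[seq.int(max(higher_l), i)]) else min(left)
    higher_r <- which(right >= h)
    min_r <- if (length(higher_r)) min(x[seq.int(i, i + min(higher_r))]) else min(right)
    h - max(min_l, min_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(i = is_pk[keep], height = x[is_pk[keep]], prominence = prom[keep])
}

#' Extract tip traces from a trajectory
#'
#' Returns the area-weighted mean Cdc42-GTP concentration over each tip
#' region (nodes within arc length `s_tip` of a pole, attributed to a tip by
#' hemisphere). Traces at the trajectory's recording radius are returned
#' directly; any other `s_tip` requires recorded snapshots.
#'
#' @param trajectory A [run()] result.
#' @param s_tip Tip-region radius (um); default: the radius recorded by
#'   [run()].
#' @return An object of class `tip_traces` with `t`, `tip1`, `tip2`.
#' @export
tip_traces <- function(trajectory, s_tip = NULL) {
  stopifnot(inherits(trajectory, "cdc42_trajectory"))
  if (is.null(s_tip) || isTRUE(all.equal(s_tip, trajectory$s_tip))) {
    return(structure(list(t = trajectory$times, tip1 = trajectory$tip1,
                          tip2 = trajectory$tip2), class = "tip_traces"))
  }
  sn <- trajectory$snapshots
  if (is.null(sn))
    stop("s_tip differs from the recorded radius and no snapshots are available")
  mesh <- trajectory$mesh
  reg <- .tip_regions(mesh, s_tip)
  a1 <- mesh$areas[reg$tip1]; a2 <- mesh$areas[reg$tip2]
  tip1 <- as.numeric(crossprod(sn$CT[reg$tip1, , drop = FALSE], a1)) / sum(a1)
  tip2 <- as.numeric(crossprod(sn$CT[reg$tip2, , drop = FALSE], a2)) / sum(a2)
  structure(list(t = sn$t, tip1 = tip1, tip2 = tip2), class = "tip_traces")
}

#' Classify the terminal dynamical state of a pair of tip traces
#'
#' Decision tree over the smoothed tip Cdc42-GTP traces:
#' \itemize{
#'   \item \emph{stationary}: relative drift (max-min over mean) of both
#'     traces below `drift_tol` over the final `window` seconds;
#'   \item \emph{asymmetric}: ratio of the two traces' final-window means
#'     above `asym_ratio`;
#'   \item \emph{oscillatory}: at least `min_peaks` peaks with topographic
#'     prominence above `prominence_frac` of the trace mean on each trace
#'     (after a 100 s settling cut), with negative zero-lag correlation
#'     between the tips (anticorrelated switching);
#'   \item \emph{damped}: oscillation whose successive peak prominences
#'     decay (median successive ratio below `damp_ratio`) into an
#'     asymmetric, near-stationary end state.
#' }
#' Sustained anticorrelated oscillations are labeled `BPO`; damped
#' oscillations ending asymmetric are `MPDO`; otherwise stationary states
#' are `MPS` (asymmetric), `BPS` (symmetric) or `UNPOLARIZED` (symmetric
#' with both tips below `unpolarized_level`). Traces shorter than
#' `2 * window` give the explicit label `INDETERMINATE`.
#'
#' @param traces A [tip_traces()] object.
#' @param window Final evaluation window (s).
#' @param drift_tol Relative drift threshold for stationarity.
#' @param asym_ratio Tip-ratio threshold for asymmetry.
#' @param min_peaks Minimum prominent peaks per trace for oscillation.
#' @param prominence_frac Peak prominence threshold, as a fraction of the
#'   trace mean.
#' @param damp_ratio Successive-prominence ratio below which an oscillation
#'   counts as damped.
#' @param unpolarized_level Absolute Cdc42-GTP level (1/um^2) below which a
#'   symmetric stationary state counts as unpolarized.
#' @param smooth_window Moving-average window (samples) applied before
#'   classification.
#' @return A list of class `state_label`: `label` plus metrics (`asymmetry`,
#'   `period_s` for oscillatory states, `damping_ratio`, `drift`,
#'   `anticorrelation`, `n_peaks`).
#' @export
classify_state <- function(traces, window = 400,
                           drift_tol = 0.01, asym_ratio = 1.5,
                           min_peaks = 3L, prominence_frac = 0.10,
                           damp_ratio = 0.7, unpolarized_level = 160,
                           smooth_window = 21L) {
  stopifnot(inherits(traces, "tip_traces"))
  t <- traces$t
  Tend <- max(t)
  out <- function(label, ...) {
    structure(c(list(label = label), list(...)), class = "state_label")
  }
  if (Tend - min(t) < 2 * window)
    return(out("INDETERMINATE",
               reason = sprintf("trace spans %.0f s; need at least %.0f s",
                                Tend - min(t), 2 * window)))
  x1 <- smooth_trace(traces$tip1, smooth_window)
  x2 <- smooth_trace(traces$tip2, smooth_window)
  scale <- mean(c(x1, x2))

  wfin <- t >= Tend - window
  drift <- vapply(list(x1[wfin], x2[wfin]), function(v)
    (max(v) - min(v)) / max(mean(v), 0.05 * scale), numeric(1))
  stationary <- all(drift < drift_tol)
  near_stationary <- all(drift < 10 * drift_tol)

  m <- c(mean(x1[wfin]), mean(x2[wfin]))
  asymmetry <- max(m) / max(min(m), 1e-12)
  asym <- asymmetry > asym_ratio

  wosc <- t >= min(t) + 100
  pk1 <- find_peaks(x1[wosc], prominence_frac * max(mean(x1[wosc]), 0.05 * scale))
  pk2 <- find_peaks(x2[wosc], prominence_frac * max(mean(x2[wosc]), 0.05 * scale))
  anticor <- suppressWarnings(cor(x1[wosc], x2[wosc]))
  if (is.na(anticor)) anticor <- 0
  oscillatory <- nrow(pk1) >= min_peaks && nrow(pk2) >= min_peaks && anticor < 0

  period <- NA_real_
  damping <- NA_real_
  if (oscillatory) {
    tp <- t[wosc][pk1$i]
    period <- mean(diff(tp))
    pr <- pk1$prominence
    if (length(pr) >= 2) damping <- stats::median(pr[-1] / pr[-length(pr)])
  }

  metrics <- list(asymmetry = asymmetry, period_s = period,
                  damping_ratio = damping, drift = max(drift),
                  anticorrelation = anticor,
                  n_peaks = c(nrow(pk1), nrow(pk2)),
                  level = m)
  ## damped: envelope decays per cycle and the final window has collapsed
  ## to a small fraction of the early swing, ending asymmetric
  env_end <- max(max(x1[wfin]) - min(x1[wfin]), max(x2[wfin]) - min(x2[wfin]))
  env_peak <- if (nrow(pk1)) 2 * max(pk1$prominence) else Inf
  damped <- oscillatory && !is.na(damping) && damping < damp_ratio &&
    env_end < 0.5 * env_peak && asym
  if (damped) return(do.call(out, c(list("MPDO"), metrics)))
  if (oscillatory && !stationary) return(do.call(out, c(list("BPO"), metrics)))
  metrics$period_s <- NA_real_
  if (stationary || near_stationary) {
    if (asym) return(do.call(out, c(list("MPS"), metrics)))
    if (max(m) < unpolarized_level)
      return(do.call(out, c(list("UNPOLARIZED"), metrics)))
    return(do.call(out, c(list("BPS"), metrics)))
  }
  ## not settled and too few peaks for the oscillation test: a symmetric,
  ## anticorrelated trace with at least one dominance switch per tip is an
  ## oscillation whose period exceeds the peak-count window, not a stable
  ## state
  if (!asym && anticor < 0 && nrow(pk1) >= 1 && nrow(pk2) >= 1) {
    tp <- t[wosc][pk1$i]
    metrics$period_s <- if (length(tp) >= 2) mean(diff(tp)) else NA_real_
    return(do.call(out, c(list("BPO"), metrics)))
  }
  ## otherwise label the drifting state by its asymmetry
  if (asym) do.call(out, c(list("MPS"), metrics)) else
    do.call(out, c(list("BPS"), metrics))
}

#' @export
print.state_label <- function(x, ...) {
  cat(sprintf("State: %s (asymmetry %.2f%s)\n", x$label,
              if (is.null(x$asymmetry)) NA else x$asymmetry,
              if (!is.null(x$period_s) && !is.na(x$period_s))
                sprintf(", period %.0f s", x$period_s) else ""))
  invisible(x)
}

#' Oscillation period of a single tip trace
#'
#' Mean interval between successive prominent maxima after a transient cut.
#'
#' @param trace Numeric concentration series.
#' @param t Time points (s) matching `trace`.
#' @param transient_cut Initial time span to discard (s).
#' @param prominence_frac Prominence threshold as a fraction of the
#'   post-transient trace mean.
#' @param smooth_window Moving-average window (samples).
#' @return Period in seconds, or `NA` if fewer than 3 peaks are found.
#' @export
oscillation_period <- function(trace, t, transient_cut = 0,
                               prominence_frac = 0.10, smooth_window = 21L) {
  keep <- t >= min(t) + transient_cut
  x <- smooth_trace(trace[keep], smooth_window)
  tk <- t[keep]
  pk <- find_peaks(x, prominence_frac * mean(x))
  if (nrow(pk) < 3L) return(NA_real_)
  mean(diff(tk[pk$i]))
}

.dominant_tip <- function(state, mesh, s_tip = 0.5) {
  reg <- .tip_regions(mesh, s_tip)
  m1 <- sum(state$CT[reg$tip1] * mesh$areas[reg$tip1]) / sum(mesh$areas[reg$tip1])
  m2 <- sum(state$CT[reg$tip2] * mesh$areas[reg$tip2]) / sum(mesh$areas[reg$tip2])
  if (m1 >= m2) 1L else 2L
}

#' Concentration profiles versus arc length from a tip
#'
#' Area-weighted mean concentration in bins of meridian arc length measured
#' from the dominant tip (the tip with higher Cdc42-GTP, unless overridden).
#' The two GAP_II forms are also reported as their sum (`CGAPII`), the
#' quantity shown in snapshot figures. With `full_length = TRUE` the
#' coordinate runs pole to pole (0 to `pi*R + L - 2R`); otherwise profiles
#' are restricted to the dominant half of the cell (0 to
#' `pi*R/2 + (L-2R)/2`).
#'
#' @param state A field state (e.g. `trajectory$final`, or one snapshot).
#' @param mesh A [build_mesh()] result.
#' @param bin_width Bin width (um); must be at least one mean cell diameter
#'   of the mesh so bins cannot be empty by construction.
#' @param align_to `"dominant"`, `"tip1"` or `"tip2"`.
#' @param full_length Profile over the whole meridian instead of the
#'   dominant half.
#' @return A data.frame of class `arc_profile`: `s` (bin centers, um) and
#'   one column per species (`CD`, `CT`, `CGAPI`, `CGAPIIfast`,
#'   `CGAPIIslow`, `CGAPII`, `CGEF`), with attribute `merged_bins` flagging
#'   any bins merged into a neighbor.
#' @export
profile_vs_arclength <- function(state, mesh, bin_width = 0.2,
                                 align_to = c("dominant", "tip1", "tip2"),
                                 full_length = FALSE) {
  align_to <- match.arg(align_to)
  diam <- sqrt(mesh$geom$target_cell_area)
  if (bin_width < diam)
    stop(sprintf("bin_width %.3g um is below the mean mesh cell diameter %.3g um",
                 bin_width, diam))
  tip <- switch(align_to, dominant = .dominant_tip(state, mesh),
                tip1 = 1L, tip2 = 2L)
  M <- pi * mesh$geom$R + (mesh$geom$L - 2 * mesh$geom$R)
  u <- if (tip == 1L) mesh$meridian else M - mesh$meridian
  umax <- if (full_length) M else M / 2
  keep <- u <= umax + 1e-9
  u <- u[keep]
  a <- mesh$areas[keep]
  brk <- seq(0, umax + bin_width, by = bin_width)
  bin <- findInterval(u, brk, rightmost.closed = FALSE)
  nb <- max(bin)
  species <- c("CD", "CT", "CGAPI", "CGAPIIfast", "CGAPIIslow", "CGEF")
  wt <- rowsum(a, bin)
  merged <- which(wt == 0)
  ## bin coordinate = area-weighted mean arc length of the bin's nodes
  ## (geometric centers bias the fit where node area density varies, e.g.
  ## near the poles)
  prof <- data.frame(s = as.numeric(rowsum(u * a, bin) / wt))
  for (sp in species) {
    v <- state[[sp]][keep]
    prof[[sp]] <- as.numeric(rowsum(v * a, bin) / wt)
  }
  prof$CGAPII <- prof$CGAPIIfast + prof$CGAPIIslow
  ## merge any empty bin into its lower neighbor (cannot occur at the
  ## default resolution; guard for coarse meshes)
  if (length(merged)) {
    prof <- prof[-merged, , drop = FALSE]
    warning(sprintf("%d empty bin(s) merged with neighbors", length(merged)))
  }
  structure(prof, class = c("arc_profile", "data.frame"),
            align_tip = tip, bin_width = bin_width,
            merged_bins = length(merged))
}

#' Exponential decay length of a concentration profile
#'
#' Least-squares fit of `c(s) = c0 * exp(-s / decay_length)` to a species
#' profile over `[0, fit_range]` um from the aligned tip, via [stats::nls()]
#' seeded by a log-linear regression.
#'
#' @param profile An [profile_vs_arclength()] result.
#' @param fit_range Upper arc-length limit of the fit (um).
#' @param species Profile column to fit (default Cdc42-GTP).
#' @return List with `decay_length` (um), `stderr`, `c0`, and the `nls` fit.
#' @export
decay_length_fit <- function(profile, fit_range = 2, species = "CT") {
  d <- data.frame(s = profile$s, c = profile[[species]])
  d <- d[d$s <= fit_range, ]
  if (any(d$c <= 0)) {
    warning("non-positive profile values inside the fit range; fitting the positive subset")
    d <- d[d$c > 0, ]
  }
  if (nrow(d) < 5L)
    stop("need at least 5 positive profile bins inside fit_range")
  lin <- stats::lm(log(c) ~ s, data = d)
  start <- list(c0 = exp(coef(lin)[[1]]), lam = -1 / coef(lin)[[2]])
  if (!is.finite(start$lam) || start$lam <= 0) start$lam <- fit_range / 2
  fit <- nls(c ~ c0 * exp(-s / lam), data = d, start = start)
  est <- summary(fit)$coefficients
  list(decay_length = est["lam", "Estimate"],
       stderr = est["lam", "Std. Error"],
       c0 = est["c0", "Estimate"], fit = fit)
}

#' Tip-to-side enrichment of total Cdc42
#'
#' Ratio of the area-weighted mean total Cdc42 (`CD + CT`) over the active
#' (dominant) tip region to the mean over a mid-cell side band.
#'
#' @param state A field state.
#' @param mesh A [build_mesh()] result.
#' @param s_tip Tip-region radius (um).
#' @param side_halfwidth Half-width of the mid-cell band (um); the band is
#'   the set of nodes within this meridian distance of mid-cell.
#' @return Dimensionless fold-enrichment.
#' @export
tip_to_side_ratio <- function(state, mesh, s_tip = 0.5, side_halfwidth = 1) {
  smax <- pi * mesh$geom$R / 2 + (mesh$geom$L - 2 * mesh$geom$R) / 2
  if (s_tip >= smax - side_halfwidth)
    stop("tip region and mid-cell side band must be disjoint")
  tip <- .dominant_tip(state, mesh, s_tip)
  in_tip <- mesh$s < s_tip &
    (if (tip == 1L) mesh$nodes[, 3] < 0 else mesh$nodes[, 3] > 0)
  in_side <- mesh$s >= smax - side_halfwidth
  tot <- state$CD + state$CT
  a <- mesh$areas
  (sum(tot[in_tip] * a[in_tip]) / sum(a[in_tip])) /
    (sum(tot[in_side] * a[in_side]) / sum(a[in_side]))
}

#' Snapshot the field a fixed delay after a dominant-tip peak
#'
#' Implements the profiling protocol used for decay-length measurements:
#' after `t_min` seconds of simulation, detect the first prominent maximum
#' of the dominant tip's Cdc42-GTP trace, then return the recorded snapshot
#' closest to `peak time + delay`.
#'
#' @param trajectory A [run()] result with snapshots covering `t >= t_min`.
#' @param t_min Earliest admissible peak time (s).
#' @param delay Snapshot delay after the peak (s).
#' @param prominence_frac Peak prominence threshold (fraction of trace mean).
#' @return List with the snapshot `state` (a `field_state`), `peak_time`,
#'   `snapshot_time` and `dominant_tip` (1 or 2).
#' @export
profile_after_peak <- function(trajectory, t_min = 1000, delay = 20,
                               prominence_frac = 0.10) {
  sn <- trajectory$snapshots
  if (is.null(sn)) stop("trajectory has no snapshots; rerun with snapshots_every > 0")
  tt <- trajectory$times
  sel <- tt >= t_min
  if (!any(sel)) stop("trajectory shorter than t_min")
  dom <- if (mean(trajectory$tip1[sel]) >= mean(trajectory$tip2[sel])) 1L else 2L
  x <- smooth_trace(if (dom == 1L) trajectory$tip1[sel] else trajectory$tip2[sel], 11L)
  pk <- find_peaks(x, prominence_frac * mean(x))
  t_peak <- if (nrow(pk) > 0) {
    tt[sel][pk$i[1]]
  } else {
    ## near-stationary dominant tip: use its maximum as the "peak"
    warning("no prominent dominant-tip peak after t_min; using the trace maximum")
    tt[sel][which.max(x)]
  }
  k <- which.min(abs(sn$t - (t_peak + delay)))
  st <- structure(list(CD = sn$CD[, k], CT = sn$CT[, k], CGAPI = sn$CGAPI[, k],
                       CGAPIIfast = sn$CGAPIIfast[, k],
                       CGAPIIslow = sn$CGAPIIslow[, k], CGEF = sn$CGEF[, k],
                       t = sn$t[k]), class = "field_state")
  list(state = st, peak_time = t_peak, snapshot_time = sn$t[k],
       dominant_tip = dom)
}

#' Track the Cdc42-GTP patch across snapshots
#'
#' For each snapshot, the patch is the set of nodes in the top decile of
#' Cdc42-GTP; it counts as present only when the maximum exceeds twice the
#' surface mean. The area-weighted 3D centroid of the patch is followed
#' through time. Persistent directed motion (net azimuthal or axial drift
#' with high directional coherence and total path length beyond the patch
#' diameter) is labeled `WAVE`; patches that appear and vanish at distinct
#' locations (centroid jumps beyond twice the patch diameter, or presence
#' gaps) without directed motion are `PATCH_DYNAMIC`; an immobile patch is
#' `STATIONARY_PATCH`; no detected patch is `NONE`.
#'
#' @param trajectory A [run()] result with snapshots recorded.
#' @param top_frac Patch quantile (default top 10 percent of nodes).
#' @param coherence_min Directional coherence above which motion counts as
#'   directed.
#' @return List of class `patch_track`: `label`, `centroids` (one row per
#'   snapshot with a patch), `speed` (um/s along the path), `net_drift`,
#'   `coherence`, `patch_diameter`, `n_events` (appearance/disappearance
#'   events).
#' @export
patch_tracking <- function(trajectory, top_frac = 0.1, coherence_min = 0.7) {
  sn <- trajectory$snapshots
  if (is.null(sn)) stop("trajectory has no snapshots; rerun with snapshots_every > 0")
  mesh <- trajectory$mesh
  a <- mesh$areas
  nT <- length(sn$t)
  present <- logical(nT)
  cen <- matrix(NA_real_, nT, 3)
  diam <- numeric(nT)
  for (k in seq_len(nT)) {
    ct <- sn$CT[, k]
    if (max(ct) < 2 * sum(ct * a) / sum(a)) next
    thr <- stats::quantile(ct, 1 - top_frac)
    sel <- ct >= thr
    present[k] <- TRUE
    w <- ct[sel] * a[sel]
    cen[k, ] <- colSums(mesh$nodes[sel, , drop = FALSE] * w) / sum(w)
    diam[k] <- 2 * sqrt(sum(a[sel]) / pi)
  }
  if (!any(present))
    return(structure(list(label = "NONE", centroids = NULL, speed = 0,
                          net_drift = 0, coherence = 0,
                          patch_diameter = 0, n_events = 0L),
                     class = "patch_track"))
  pd <- stats::median(diam[present])
  idx <- which(present)
  steps <- diff(idx)
  ## gaps in presence are appearance/disappearance events
  n_events <- sum(steps > 1L) + sum(!present[seq(min(idx), max(idx))])
  cc <- cen[idx, , drop = FALSE]
  d3 <- diff(cc)
  dist <- sqrt(rowSums(d3^2))
  jumps <- dist > 2 * pd
  n_events <- n_events + sum(jumps)
  smooth_steps <- d3[!jumps, , drop = FALSE]
  path <- sum(dist[!jumps])
  ## directional coherence of azimuthal and axial motion; the azimuth is
  ## ill-defined for near-axis (tip) centroids, so it only counts when the
  ## patch track stays well off the axis
  theta <- atan2(cen[idx, 2], cen[idx, 1])
  dth <- diff(theta)
  dth <- (dth + pi) %% (2 * pi) - pi
  dz <- diff(cen[idx, 3])
  r_axis <- sqrt(cen[idx, 1]^2 + cen[idx, 2]^2)
  off_axis <- mean(r_axis > 0.5) > 0.9
  coh_th <- if (off_axis && sum(abs(dth[!jumps])) > 0)
    abs(sum(dth[!jumps])) / sum(abs(dth[!jumps])) else 0
  coh_z <- if (sum(abs(dz[!jumps])) > 0)
    abs(sum(dz[!jumps])) / sum(abs(dz[!jumps])) else 0
  coherence <- max(coh_th, coh_z)
  dt_snap <- mean(diff(sn$t[idx]))
  speed <- if (length(dist[!jumps])) mean(dist[!jumps]) / dt_snap else 0
  net <- sqrt(sum((cc[nrow(cc), ] - cc[1, ])^2))
  ## classify
  label <- if (n_events > 0 && !(coherence > coherence_min && path > pd))
    "PATCH_DYNAMIC"
  else if (coherence > coherence_min && path > pd)
    "WAVE"
  else if (path <= pd)
    "STATIONARY_PATCH"
  else
    "PATCH_DYNAMIC"
  structure(list(label = label, centroids = cbind(t = sn$t[idx], cc),
                 speed = speed, net_drift = net, coherence = coherence,
                 patch_diameter = pd, n_events = n_events),
            class = "patch_track")
}
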