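## Figure-level drivers: 2-D parameter scans, the cell-length (NETO) series
## with the GEF pool scaled by cell volume, and mutant scenarios.

.derive_seed <- function(seed, idx, rep = 1L) {
  as.integer((as.numeric(seed) + 104729 * idx + 7919 * rep) %% 2147483629 + 1)
}

#' Two-dimensional parameter scan with terminal-state classification
#'
#' Runs one (or more) simulations per grid point of two swept parameters,
#' classifies each terminal state from its tip traces, and returns the grid
#' as a data.frame. With `replicates > 1` the majority label is reported
#' together with a coexistence flag (near regime boundaries different runs
#' may settle into different patterns).
#'
#' @param base A [model_params()] object supplying all non-swept values.
#' @param axis1,axis2 Named lists `list(name = <parameter>, values =
#'   <numeric vector>)`. Names must be valid model parameters.
#' @param replicates Simulations per grid point (seeds derived from the base
#'   seed).
#' @param duration Run length (s) for every grid point.
#' @param classify_args Optional list of overrides for [classify_state()].
#' @return A data.frame of class `scan_result`: one row per grid point with
#'   the two parameter values, `label`, `coexist`, `asymmetry`, `period_s`,
#'   `seed` (first replicate) and `params_hash`; failed cells carry label
#'   `"ERROR"` and continue the scan.
#' @export
run_scan <- function(base, axis1, axis2, replicates = 1L, duration = 1200,
                     classify_args = list()) {
  stopifnot(inherits(base, "model_params"))
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || !all(c("name", "values") %in% names(ax)) ||
        length(ax$values) == 0)
      stop("each axis must be list(name = <parameter>, values = <non-empty numeric>)")
    if (!ax$name %in% names(default_params()))
      stop("unknown scan parameter: ", ax$name)
  }
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    over <- stats::setNames(list(grid$v1[g], grid$v2[g], duration),
                            c(axis1$name, axis2$name, "duration"))
    labels <- character(replicates)
    mets <- vector("list", replicates)
    seed1 <- NA_integer_; phash <- NA_character_
    for (r in seq_len(replicates)) {
      sd <- .derive_seed(base$seed, g, r)
      if (r == 1L) seed1 <- sd
      res <- tryCatch({
        p <- do.call(model_params,
                     modifyList(unclass(base)[names(default_params())],
                                c(over, list(seed = sd))))
        traj <- run(p)
        phash <- traj$provenance$params_hash
        do.call(classify_state, c(list(tip_traces(traj)), classify_args))
      }, error = function(e) structure(list(label = "ERROR",
                                            reason = conditionMessage(e)),
                                       class = "state_label"))
      labels[r] <- res$label
      mets[[r]] <- res
    }
    tab <- sort(table(labels), decreasing = TRUE)
    maj <- names(tab)[1]
    best <- mets[[match(maj, labels)]]
    rows[[g]] <- data.frame(
      v1 = grid$v1[g], v2 = grid$v2[g], label = maj,
      coexist = length(tab) > 1L,
      asymmetry = if (is.null(best$asymmetry)) NA_real_ else best$asymmetry,
      period_s = if (is.null(best$period_s)) NA_real_ else best$period_s,
      seed = seed1, params_hash = phash, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(axis1$name, axis2$name)
  structure(out, class = c("scan_result", "data.frame"),
            axes = c(axis1$name, axis2$name), duration = duration,
            replicates = replicates, base_hash = params_hash(base))
}

#' Cell-length series with volume-scaled GEF pool (NETO transition)
#'
#' For each cell length `L`, the total GEF pool is scaled in proportion to
#' the spherocylinder volume, `Ectot(L) = Ectot_ref * V(L) / V(L_ref)`,
#' emulating accumulation of the limiting activator with cell growth. Each
#' cell is simulated from the unpolarized state and its terminal state
#' classified; the monopolar-damped-oscillatory to bipolar-oscillatory
#' transition along this series is the model's account of new-end take-off.
#'
#' @param lengths Cell lengths to simulate (um), each above `2R`.
#' @param base A [model_params()] object (reference uses `ksat = 650`).
#' @param Ectot_ref GEF pool at the reference length.
#' @param L_ref Reference length (um).
#' @param duration Run length per cell (s).
#' @param classify_args Optional [classify_state()] overrides.
#' @return data.frame with `L`, `Ectot`, `label`, `asymmetry`, `period_s`,
#'   `seed`; errors are recorded per length and do not stop the series.
#' @export
neto_series <- function(lengths, base = model_params(ksat = 650),
                        Ectot_ref = 300, L_ref = 7, duration = 1200,
                        classify_args = list()) {
  stopifnot(inherits(base, "model_params"))
  vol <- function(L) {
    g <- cell_geometry(L = L, R = base$R)
    cell_volume(g)
  }
  Vref <- vol(L_ref)
  rows <- lapply(seq_along(lengths), function(i) {
    L <- lengths[i]
    Ectot_L <- Ectot_ref * vol(L) / Vref
    sd <- .derive_seed(base$seed, i)
    res <- tryCatch({
      p <- do.call(model_params,
                   modifyList(unclass(base)[names(default_params())],
                              list(L = L, Ectot = Ectot_L, duration = duration,
                                   seed = sd)))
      traj <- run(p)
      do.call(classify_state, c(list(tip_traces(traj)), classify_args))
    }, error = function(e) list(label = "ERROR", reason = conditionMessage(e)))
    data.frame(L = L, Ectot = Ectot_L, label = res$label,
               asymmetry = if (is.null(res$asymmetry)) NA_real_ else res$asymmetry,
               period_s = if (is.null(res$period_s)) NA_real_ else res$period_s,
               seed = sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predefined mutant and regime scenarios
#'
#' \describe{
#'   \item{`gapII_half`}{GAP_II tip recruitment halved (`k5n = 0.015`),
#'     emulating loss of one side-localized GAP; widens the Cdc42-GTP zone.}
#'   \item{`gapII_off`}{GAP_II eliminated (`k5n = 0`).}
#'   \item{`unbiased`}{No tip bias (`lambda = Inf`) with strengthened
#'     positive feedback (`k0p = 0.01`); Cdc42-GTP patches appear and
#'     disappear at random membrane locations.}
#'   \item{`unbiased_gapII_off`}{Additionally `k5n = 0`; the patch travels
#'     as a wave chased by the remaining tip-type GAP.}
#' }
#'
#' @param scenario One of the names above.
#' @param overrides Named list of further parameter overrides (merged over
#'   the scenario's settings).
#' @param duration Run length (s).
#' @param snapshots_every Snapshot interval (s); defaults to 10 s for the
#'   unbiased scenarios (needed for patch tracking), otherwise none.
#' @param snapshot_start First snapshot time (s).
#' @return List with `trajectory`, `label` (a [classify_state()] result for
#'   tip-biased scenarios, a [patch_tracking()] result for unbiased ones),
#'   `profile` (final-state arc-length profiles) and `decay` (exponential
#'   decay-length fit of the Cdc42-GTP profile, where positive).
#' @export
mutant_run <- function(scenario = c("gapII_half", "gapII_off", "unbiased",
                                    "unbiased_gapII_off"),
                       overrides = list(), duration = 1200,
                       snapshots_every = NULL, snapshot_start = NULL) {
  scenario <- match.arg(scenario)
  sets <- switch(scenario,
                 gapII_half = list(k5n = 0.015),
                 gapII_off = list(k5n = 0),
                 unbiased = list(lambda = Inf, k0p = 0.01),
                 unbiased_gapII_off = list(lambda = Inf, k0p = 0.01, k5n = 0))
  unbiased <- is.infinite(sets$lambda %||% 1)
  if (is.null(snapshots_every)) snapshots_every <- if (unbiased) 10 else 0
  if (is.null(snapshot_start)) snapshot_start <- if (unbiased) duration / 3 else 0
  p <- do.call(model_params, modifyList(c(sets, list(duration = duration)),
                                        overrides))
  traj <- run(p, snapshots_every = snapshots_every,
              snapshot_start = snapshot_start)
  label <- if (unbiased && snapshots_every > 0) patch_tracking(traj)
           else classify_state(tip_traces(traj))
  prof <- profile_vs_arclength(traj$final, traj$mesh)
  decay <- tryCatch(decay_length_fit(prof), error = function(e) NULL)
  list(trajectory = traj, label = label, profile = prof, decay = decay,
       scenario = scenario, params = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decay-length experiment at the dominant tip
#'
#' Runs the model (reference values except where overridden, with the
#' saturation pushed down to `ksat = 450` where the system oscillates),
#' snapshots the fields `delay` seconds after the first prominent
#' dominant-tip Cdc42-GTP peak past `t_min`, and fits an exponential to the
#' tip-aligned Cdc42-GTP arc-length profile. Halving the GAP_II recruitment
#' rate `k5n` widens the activation zone and increases the fitted decay
#' length.
#'
#' @param k5n GAP_II recruitment rate (1/s).
#' @param ksat GAP_I saturation concentration (1/um^2).
#' @param duration Run length (s); must leave room for a peak after `t_min`.
#' @param t_min Earliest admissible peak time (s).
#' @param delay Snapshot delay after the peak (s).
#' @param fit_range Arc-length fit window (um).
#' @param overrides Further parameter overrides (e.g. `seed`).
#' @return List with `decay_length` (um), `stderr`, `peak_time`,
#'   `snapshot_time`, `profile`, and the `trajectory`.
#' @export
decay_experiment <- function(k5n = 0.03, ksat = 450, duration = 1800,
                             t_min = 1000, delay = 20, fit_range = 2,
                             overrides = list()) {
  p <- do.call(model_params,
               modifyList(list(k5n = k5n, ksat = ksat, duration = duration),
                          overrides))
  traj <- run(p, snapshots_every = 2, snapshot_start = t_min)
  snap <- profile_after_peak(traj, t_min = t_min, delay = delay)
  prof <- profile_vs_arclength(snap$state, traj$mesh)
  fit <- decay_length_fit(prof, fit_range = fit_range)
  list(decay_length = fit$decay_length, stderr = fit$stderr,
       peak_time = snap$peak_time, snapshot_time = snap$snapshot_time,
       profile = prof, trajectory = traj)
}
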