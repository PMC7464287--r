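## Forward-Euler integration: single reference step in R, full runs through
## the compiled core, trajectory container.

#' Advance the system by one forward-Euler step (reference implementation)
#'
#' Updates the five dynamic fields by `dt * (diffusion + reaction)`, applies
#' stochastic activation noise (if enabled), then refreshes the quasi-static
#' GEF field; time advances by `p$dt`. Concentrations in `[-1e-9, 0)` are
#' clamped to zero (roundoff); anything below `-1e-9` aborts with a
#' diagnostic naming the field (instability). [run()] performs the same
#' update in compiled code; this R version is the readable reference used
#' in the equivalence tests.
#'
#' @param state Field state with `CGEF`/`Ec` consistent with its `CT`.
#' @param p A [model_params()] object.
#' @param mesh A [build_mesh()] result.
#' @return The updated field state.
#' @export
step <- function(state, p, mesh) {
  d <- reaction_rates(state, p, mesh)
  dt <- p$dt
  state$CD <- state$CD + dt * (p$DD * laplace_beltrami(mesh, state$CD) + d$dCD)
  state$CT <- state$CT + dt * (p$DT * laplace_beltrami(mesh, state$CT) + d$dCT)
  state$CGAPI <- state$CGAPI +
    dt * (p$DGAPI * laplace_beltrami(mesh, state$CGAPI) + d$dCGAPI)
  state$CGAPIIfast <- state$CGAPIIfast +
    dt * (p$DGAPIIfast * laplace_beltrami(mesh, state$CGAPIIfast) + d$dCGAPIIfast)
  state$CGAPIIslow <- state$CGAPIIslow +
    dt * (p$DGAPIIslow * laplace_beltrami(mesh, state$CGAPIIslow) + d$dCGAPIIslow)
  for (nm in c("CD", "CT", "CGAPI", "CGAPIIfast", "CGAPIIslow")) {
    v <- state[[nm]]
    if (any(v < -1e-9))
      stop(sprintf("numerical instability: field %s reached %.3e at t = %.2f s",
                   nm, min(v), state$t + dt))
    v[v < 0] <- 0
    state[[nm]] <- v
  }
  if (identical(p$noise_mode, "stochastic"))
    state <- apply_noise(state, p, dt, mesh)
  gf <- gef_field(state$CT, p, mesh)
  state$CGEF <- gf$CGEF
  state$Ec <- gf$Ec
  state$t <- state$t + dt
  state
}

.tip_regions <- function(mesh, s_tip) {
  smax <- pi * mesh$geom$R / 2 + (mesh$geom$L - 2 * mesh$geom$R) / 2
  if (s_tip <= 0 || s_tip > smax)
    stop(sprintf("s_tip must lie in (0, %.3f] um", smax))
  in_tip <- mesh$s < s_tip
  list(tip1 = which(in_tip & mesh$nodes[, 3] < 0),
       tip2 = which(in_tip & mesh$nodes[, 3] > 0))
}

#' Run a full simulation
#'
#' Builds the mesh (unless supplied), draws the unpolarized initial state,
#' checks the explicit-diffusion stability bound, and integrates for
#' `p$duration` seconds with the compiled forward-Euler core. Tip traces
#' (area-weighted mean Cdc42-GTP over each tip region), the free cytoplasmic
#' GEF count and per-field total masses are sampled every `trace_every`
#' seconds; optional full-field snapshots are recorded every
#' `snapshots_every` seconds starting at `snapshot_start`.
#'
#' All randomness (initial fluctuations and stochastic noise) derives from
#' `p$seed`: identical parameters and seed give identical trajectories.
#'
#' @param p A [model_params()] object.
#' @param mesh Optional pre-built [build_mesh()] result (must match `p`'s
#'   geometry).
#' @param init Optional starting field state (defaults to the unpolarized
#'   [initial_state()]); useful for continuation runs and controlled
#'   numerical experiments.
#' @param s_tip Tip-region arc-length radius for the traces (um).
#' @param trace_every Trace sampling interval (s).
#' @param snapshots_every Snapshot interval (s); 0 disables snapshots.
#' @param snapshot_start Time of the first snapshot (s).
#' @return An object of class `cdc42_trajectory` with elements `times`,
#'   `tip1`, `tip2`, `Ec`, `mass`, `snapshots` (or `NULL`), `final`
#'   (the final field state), `params`, `mesh`, `provenance`.
#' @examples
#' \donttest{
#' p <- model_params(duration = 200)
#' traj <- run(p)
#' plot(traj$times, traj$tip1, type = "l")
#' }
#' @export
run <- function(p, mesh = NULL, init = NULL, s_tip = 0.5, trace_every = 1,
                snapshots_every = 0, snapshot_start = 0) {
  stopifnot(inherits(p, "model_params"))
  if (is.null(mesh)) mesh <- build_mesh(p$geometry, seed = p$seed)
  sc <- stability_check(p, mesh)
  if (!sc$stable)
    stop(sprintf("dt = %g s exceeds the explicit-diffusion stability bound %.4g s",
                 p$dt, sc$dt_max))
  if (p$duration > 0 && p$duration < 100)
    warning("duration < 100 s: state classification on this trajectory will be unreliable")

  set.seed(p$seed)
  st <- if (is.null(init)) initial_state(p, mesh) else init
  if (length(st$CD) != nrow(mesh$nodes))
    stop("init state does not match the mesh node count")
  regions <- .tip_regions(mesh, s_tip)

  nsteps <- round(p$duration / p$dt)
  trace_stride <- max(1L, round(trace_every / p$dt))
  snap_stride <- if (snapshots_every > 0) max(1L, round(snapshots_every / p$dt)) else 0L
  snap_start <- round(snapshot_start / p$dt)

  par_c <- p[c("DT", "DD", "DGAPI", "DGAPIIfast", "DGAPIIslow",
               "k1n", "k2n", "k3n", "k4n", "k5n", "k6n", "k7n", "k8n",
               "ksat", "h", "k0p", "k1p", "k2p", "Ectot", "jDp",
               "rT", "rD", "rGAPI", "rGAPIIfast", "rGAPIIslow",
               "rnoise", "dt")]
  par_c$V <- cell_volume(mesh$geom)
  par_c$t0 <- 0
  par_c$noise_mode_int <- match(p$noise_mode, c("off", "deterministic", "stochastic")) - 1L

  W <- methods::as(mesh$lap, "CsparseMatrix")
  res <- simulate_core(W@p, W@i, W@x, mesh$areas, tip_bias(mesh, p$lambda),
                       regions$tip1 - 1L, regions$tip2 - 1L,
                       par_c, st, nsteps, trace_stride, snap_stride, snap_start)

  final <- res$final
  class(final) <- "field_state"
  snaps <- res$snapshots
  if (length(snaps) == 0) snaps <- NULL
  structure(list(
    times = res$times, tip1 = res$tip1, tip2 = res$tip2, Ec = res$Ec,
    mass = `colnames<-`(res$mass, c("CD", "CT", "CGAPI", "CGAPIIfast", "CGAPIIslow")),
    snapshots = snaps, final = final, params = p, mesh = mesh,
    s_tip = s_tip,
    provenance = list(seed = p$seed, params_hash = params_hash(p),
                      n_nodes = nrow(mesh$nodes))
  ), class = "cdc42_trajectory")
}

#' @export
print.cdc42_trajectory <- function(x, ...) {
  cat(sprintf("Cdc42 trajectory: %.0f s on %d nodes (seed %d, params %s)\n",
              max(x$times), nrow(x$mesh$nodes), x$provenance$seed,
              x$provenance$params_hash))
  cat(sprintf("  final tip Cdc42-GTP: %.1f / %.1f per um^2\n",
              x$tip1[length(x$tip1)], x$tip2[length(x$tip2)]))
  invisible(x)
}

#' Relative error of the GEF conservation identity
#'
#' `Ec + sum_i CGEF_i a_i` must equal `Ectot` up to roundoff at every step.
#'
#' @param state Field state.
#' @param p A [model_params()] object.
#' @param mesh A [build_mesh()] result.
#' @return Relative deviation from `Ectot`.
#' @export
gef_conservation_error <- function(state, p, mesh) {
  abs(state$Ec + sum(state$CGEF * mesh$areas) - p$Ectot) / p$Ectot
}
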