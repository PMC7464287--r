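## Reaction kinetics: GTPase cycle, quasi-static conserved GEF field,
## tip-biased activation, stochastic activation noise.

#' Quasi-static conserved GEF field
#'
#' The limiting GEF pool (total `Ectot` molecules) is assumed to
#' equilibrate instantaneously with the Cdc42-GTP field: the membrane GEF
#' concentration at node i is
#' `CGEF_i = (k1p*CT_i/V + k2p*CT_i^2/V) * Ec`, with the free cytoplasmic
#' count `Ec = Ectot / (1 + sum_i (k1p*CT_i/V + k2p*CT_i^2/V) * a_i)`.
#' The quadratic term makes the positive feedback strong enough to break
#' symmetry; the shared scalar `Ec` is the only global coupling in the
#' model and mediates competition between the two tips for the limiting
#' activator.
#'
#' By construction `Ec + sum_i CGEF_i * a_i = Ectot` exactly.
#'
#' @param CT Per-node Cdc42-GTP concentration (1/um^2).
#' @param p A [model_params()] object.
#' @param mesh A [build_mesh()] result.
#' @return List with `CGEF` (per-node, 1/um^2) and `Ec` (molecules).
#' @export
gef_field <- function(CT, p, mesh) {
  V <- cell_volume(mesh$geom)
  g <- (p$k1p * CT + p$k2p * CT^2) / V
  Ec <- p$Ectot / (1 + sum(g * mesh$areas))
  list(CGEF = g * Ec, Ec = Ec)
}

#' Tip-biased activation factor
#'
#' GEF-mediated activation is restricted to the cell tips by the factor
#' `exp(-s/lambda)`, with `s` the meridian arc length to the nearest pole.
#' `lambda = Inf` (unbiased activation) gives 1 everywhere.
#'
#' @param mesh A [build_mesh()] result.
#' @param lambda Bias length scale (um) or `Inf`.
#' @return Per-node factor in (0, 1].
#' @export
tip_bias <- function(mesh, lambda) {
  if (is.infinite(lambda)) rep(1, nrow(mesh$nodes)) else exp(-mesh$s / lambda)
}

#' Reaction rates of the five dynamic fields
#'
#' Evaluates the local reaction terms (everything except diffusion and the
#' stochastic realization of the activation noise) for Cdc42-GDP, Cdc42-GTP,
#' GAP_I and the fast/slow GAP_II forms:
#' \itemize{
#'   \item hydrolysis `(k1n + k2n*CGAPI + k3n*CGAPIIfast + k8n*CGAPIIslow)*CT`
#'     returns Cdc42-GTP to the GDP form;
#'   \item activation `k0p * exp(-s/lambda) * CGEF * CD` converts GDP to GTP;
#'   \item Cdc42-GDP exchanges with a constant cytoplasmic pool
#'     (`jDp` on, `rD*CD` off); Cdc42-GTP dissociates at `rT*CT`;
#'   \item GAP_I is recruited at `k4n * CT^h / (ksat^h + CT^h)` (Hill
#'     saturation) and dissociates at `rGAPI`;
#'   \item GAP_II is recruited in the fast form at `k5n*CT`, converts to the
#'     slow form at `k6n`, converts back via Cdc42-GTP at `k7n*CGAPIIslow*CT`,
#'     and each form dissociates at its own rate.
#' }
#' In `noise_mode = "deterministic"` the literal `-rnoise*CD` / `+rnoise*CD`
#' exchange terms are included; in the other modes they are omitted here
#' (the stochastic mode realizes them as discrete events in [apply_noise()]).
#'
#' @param state A field state as returned by [initial_state()]; its `CGEF`
#'   must be refreshed from the current `CT` (quasi-static assumption).
#' @param p A [model_params()] object.
#' @param mesh A [build_mesh()] result.
#' @return List of per-node time derivatives `dCD`, `dCT`, `dCGAPI`,
#'   `dCGAPIIfast`, `dCGAPIIslow` (1/um^2/s).
#' @export
reaction_rates <- function(state, p, mesh) {
  for (nm in c("CD", "CT", "CGAPI", "CGAPIIfast", "CGAPIIslow")) {
    if (any(state[[nm]] < -1e-9))
      stop(sprintf("negative concentration in field %s (min %.3g)",
                   nm, min(state[[nm]])))
  }
  CD <- state$CD; CT <- state$CT
  GI <- state$CGAPI; GF <- state$CGAPIIfast; GS <- state$CGAPIIslow
  bias <- tip_bias(mesh, p$lambda)
  hyd <- (p$k1n + p$k2n * GI + p$k3n * GF + p$k8n * GS) * CT
  act <- p$k0p * bias * state$CGEF * CD
  dCD <- p$jDp + hyd - act - p$rD * CD
  dCT <- act - hyd - p$rT * CT
  if (identical(p$noise_mode, "deterministic")) {
    dCD <- dCD - p$rnoise * CD
    dCT <- dCT + p$rnoise * CD
  }
  CTh <- CT^p$h
  dGI <- p$k4n * CTh / (p$ksat^p$h + CTh) - p$rGAPI * GI
  conv <- p$k6n * GF - p$k7n * GS * CT
  dGF <- p$k5n * CT - conv - p$rGAPIIfast * GF
  dGS <- conv - p$rGAPIIslow * GS
  list(dCD = dCD, dCT = dCT, dCGAPI = dGI, dCGAPIIfast = dGF, dCGAPIIslow = dGS)
}

#' Stochastic activation noise
#'
#' Converts discrete Cdc42-GDP molecules to Cdc42-GTP at each node: the
#' number of converted molecules is Poisson with mean
#' `rnoise * CD_i * a_i * dt`, capped by the Cdc42-GDP mass available at the
#' node. Total Cdc42 mass (GDP + GTP) is unchanged.
#'
#' @param state Field state.
#' @param p A [model_params()] object (`noise_mode` must be `"stochastic"`;
#'   with `rnoise = 0` the state is returned unchanged).
#' @param dt Time step (s).
#' @param mesh A [build_mesh()] result.
#' @return Updated field state.
#' @export
apply_noise <- function(state, p, dt, mesh) {
  if (p$rnoise <= 0) return(state)
  a <- mesh$areas
  n_conv <- rpois(length(a), p$rnoise * state$CD * a * dt)
  if (all(n_conv == 0L)) return(state)
  conv <- pmin(n_conv, state$CD * a) / a    # converted concentration
  state$CD <- state$CD - conv
  state$CT <- state$CT + conv
  state
}

#' Unpolarized initial state
#'
#' Cdc42-GDP starts at the steady-state concentration it would have without
#' activation, `jDp/rD`, modulated by small relative random fluctuations
#' (uniform within `init_fluct`, default 1 percent); Cdc42-GTP starts as a
#' smaller random field (uniform in `[0, init_fluct * jDp/rD]`); both GAP
#' fields start at zero. The GEF field is computed quasi-statically from the
#' initial Cdc42-GTP.
#'
#' @param p A [model_params()] object.
#' @param mesh A [build_mesh()] result.
#' @return A list of class `field_state` with per-node `CD`, `CT`, `CGAPI`,
#'   `CGAPIIfast`, `CGAPIIslow`, `CGEF`, scalar `Ec`, and time `t = 0`.
#' @export
initial_state <- function(p, mesh) {
  n <- nrow(mesh$nodes)
  if (p$rD <= 0)
    stop("the unpolarized resting state jDp/rD is undefined for rD = 0; ",
         "pass an explicit init state to run()")
  CD0 <- p$jDp / p$rD
  CD <- CD0 * (1 + runif(n, -p$init_fluct, p$init_fluct))
  CT <- runif(n, 0, p$init_fluct * CD0)
  st <- list(CD = CD, CT = CT,
             CGAPI = numeric(n), CGAPIIfast = numeric(n), CGAPIIslow = numeric(n),
             t = 0)
  gf <- gef_field(st$CT, p, mesh)
  st$CGEF <- gf$CGEF
  st$Ec <- gf$Ec
  class(st) <- "field_state"
  st
}
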