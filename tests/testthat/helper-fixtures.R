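## Shared fixtures: meshes are expensive enough to build once per suite.

default_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_mesh(cell_geometry(L = 8, R = 2), seed = 1)
    cache
  }
})

## Near-sphere mesh for spectral tests (shortest admissible cylinder).
sphere_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_mesh(cell_geometry(L = 4.02, R = 2, target_cell_area = 0.03),
                           seed = 1)
    cache
  }
})

## Uniform field state on a mesh (helper for kinetics tests).
uniform_state <- function(mesh, p, CD = 80, CT = 0, CGAPI = 0,
                          CGAPIIfast = 0, CGAPIIslow = 0) {
  n <- nrow(mesh$nodes)
  st <- list(CD = rep(CD, n), CT = rep(CT, n), CGAPI = rep(CGAPI, n),
             CGAPIIfast = rep(CGAPIIfast, n), CGAPIIslow = rep(CGAPIIslow, n),
             t = 0)
  gf <- gef_field(st$CT, p, mesh)
  st$CGEF <- gf$CGEF
  st$Ec <- gf$Ec
  class(st) <- "field_state"
  st
}

## Parameters with all reactions and noise off (pure diffusion).
diffusion_only_params <- function(...) {
  model_params(k0p = 0, k1n = 0, k2n = 0, k3n = 0, k4n = 0, k5n = 0, k6n = 0,
               k7n = 0, k8n = 0, jDp = 0, rT = 0, rD = 0, rGAPI = 0,
               rGAPIIfast = 0, rGAPIIslow = 0, rnoise = 0, noise_mode = "off",
               ...)
}

area_mean <- function(x, mesh) sum(x * mesh$areas) / sum(mesh$areas)
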