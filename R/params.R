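## Model parameters: reference values, validation, config I/O.

## Reference parameter set. Concentrations are molecules/um^2, Ectot is a
## molecule count, rates in 1/s, bimolecular rate constants in um^2/s.
.default_params <- list(
  DT = 0.02,            # Cdc42-GTP membrane diffusion (um^2/s, measured)
  DD = 0.2,             # Cdc42-GDP membrane diffusion (um^2/s, measured)
  DGAPI = 0.03,         # GAP_I diffusion (um^2/s)
  DGAPIIfast = 0.0625,  # fast GAP_II diffusion (um^2/s)
  DGAPIIslow = 0.005,   # slow GAP_II diffusion (um^2/s)
  k1n = 0.000625,       # spontaneous Cdc42-GTP hydrolysis (1/s)
  k2n = 0.00325,        # GAP_I-mediated hydrolysis (um^2/s)
  k3n = 0.00125,        # fast-GAP_II-mediated hydrolysis (um^2/s)
  k4n = 250,            # Cdc42-GTP-mediated GAP_I recruitment (1/um^2/s at saturation)
  k5n = 0.03,           # Cdc42-GTP-mediated GAP_II recruitment (1/s)
  k6n = 2,              # fast -> slow GAP_II conversion (1/s)
  k7n = 0.025,          # Cdc42-GTP-mediated slow -> fast conversion (um^2/s)
  k8n = 0.0005,         # slow-GAP_II-mediated hydrolysis (um^2/s)
  ksat = 600,           # GAP_I recruitment saturation concentration (1/um^2)
  h = 2,                # Hill exponent of GAP_I recruitment
  k0p = 0.0025,         # GEF-mediated activation (um^2/s)
  k1p = 0.5,            # linear GEF recruitment coefficient (um^3)
  k2p = 0.1,            # quadratic GEF recruitment coefficient (um^5)
  Ectot = 250,          # total GEF pool (molecules)
  jDp = 2.4,            # cytoplasm -> membrane Cdc42-GDP flux (1/s/um^2)
  rT = 0.005,           # Cdc42-GTP membrane dissociation (1/s, measured)
  rD = 0.03,            # Cdc42-GDP membrane dissociation (1/s, measured)
  rGAPI = 0.01,         # GAP_I dissociation (1/s)
  rGAPIIfast = 0.0125,  # fast GAP_II dissociation (1/s)
  rGAPIIslow = 0.0025,  # slow GAP_II dissociation (1/s)
  rnoise = 0.0021,      # random Cdc42-GDP -> GTP activation rate (1/s)
  lambda = 2.5,         # tip-bias length scale (um); Inf disables the bias
  L = 8,                # cell length (um)
  R = 2,                # cell radius (um)
  target_cell_area = 0.03,  # mesh Voronoi cell area (um^2)
  dt = 0.01,            # integration time step (s)
  duration = 1200,      # simulated time (s)
  seed = 1L,            # RNG seed (mesh jitter, initial state, noise)
  noise_mode = "deterministic",  # "deterministic", "stochastic" or "off"
  init_fluct = 0.01     # relative amplitude of initial random fluctuations
)

.rate_names <- c("DT", "DD", "DGAPI", "DGAPIIfast", "DGAPIIslow",
                 "k1n", "k2n", "k3n", "k4n", "k5n", "k6n", "k7n", "k8n",
                 "ksat", "k0p", "k1p", "k2p", "Ectot", "jDp",
                 "rT", "rD", "rGAPI", "rGAPIIfast", "rGAPIIslow", "rnoise")

#' Model parameters for the Cdc42 polarization system
#'
#' Builds a validated parameter object holding every rate constant of the
#' reaction-diffusion system, the cell geometry, and run controls. Defaults
#' are the reference values used throughout; override any subset by name.
#'
#' The random activation term `rnoise` has three interpretations selected by
#' `noise_mode`: `"stochastic"` (default) converts Cdc42-GDP to Cdc42-GTP in
#' discrete Poisson-distributed molecule events with per-node mean
#' `rnoise * CD_i * a_i * dt`; `"deterministic"` includes the literal
#' `-rnoise*CD` / `+rnoise*CD` terms in the rate equations; `"off"` removes
#' the term.
#'
#' @param ... Named overrides of any default (see [default_params()] for
#'   names and units). Unknown names are an error.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(ksat = 900, Ectot = 700)
#' p$Ectot
#' @export
model_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  p <- .default_params
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(p)
  p$geometry <- cell_geometry(L = p$L, R = p$R,
                              target_cell_area = p$target_cell_area)
  structure(p, class = "model_params")
}

#' Reference parameter values
#'
#' @return Named list of the package's reference parameter set.
#' @export
default_params <- function() .default_params

validate_params <- function(p) {
  for (nm in .rate_names)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop(sprintf("parameter %s must be a single non-negative number", nm))
  if (p$h < 1) stop("Hill exponent h must be >= 1")
  if (!(is.infinite(p$lambda) || p$lambda > 0)) stop("lambda must be positive or Inf")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$duration < 0) stop("duration must be non-negative")
  if (!p$noise_mode %in% c("stochastic", "deterministic", "off"))
    stop("noise_mode must be one of 'stochastic', 'deterministic', 'off'")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Cdc42 model parameters (L = %g um, R = %g um, dt = %g s, %s noise)\n",
              x$L, x$R, x$dt, x$noise_mode))
  dev <- names(.default_params)[vapply(names(.default_params), function(nm)
    !identical(as.numeric(.default_params[[nm]]), suppressWarnings(as.numeric(x[[nm]]))) &&
      !is.character(.default_params[[nm]]), logical(1))]
  dev <- setdiff(dev, c("seed", "duration"))
  if (length(dev))
    cat("  non-reference:",
        paste(sprintf("%s = %g", dev, unlist(x[dev])), collapse = ", "), "\n")
  invisible(x)
}

#' Read a parameter configuration from YAML or JSON
#'
#' The file is a flat mapping using the model's symbol names (`DT`, `k0p`,
#' `lambda`, `L`, ...). Unknown keys are an error. `lambda: inf` (any case,
#' or `.inf`) selects the unbiased-activation regime.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A [model_params()] object.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$lambda) && is.character(cfg$lambda)) {
    if (tolower(cfg$lambda) %in% c("inf", ".inf", "infinity"))
      cfg$lambda <- Inf
    else stop("lambda must be numeric or 'inf'")
  }
  do.call(model_params, cfg)
}

## Short provenance hash of the numeric parameter content.
params_hash <- function(p) {
  v <- unlist(p[c(.rate_names, "h", "lambda", "L", "R", "target_cell_area",
                  "dt", "noise_mode", "init_fluct")], use.names = TRUE)
  s <- paste(names(v), as.character(v), sep = "=", collapse = ";")
  ## 32-bit polynomial rolling hash, hex
  bytes <- utf8ToInt(s)
  hval <- 5381
  for (b in bytes) hval <- (hval * 33 + b) %% 4294967296
  paste0(format(as.hexmode(hval %/% 65536), width = 4),
         format(as.hexmode(hval %% 65536), width = 4))
}
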