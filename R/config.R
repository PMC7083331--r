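#' Read and validate a scenario configuration file
#'
#' Scenario files are YAML key-value documents describing an energy
#' configuration plus a topology. Recognized keys: `delta_E`, `k0`,
#' `calibration` (with `k_fit`, `N_fit`), `variant`, `N_int`, `N_pth`,
#' `N_ly`, `stabilized` (with `S`, `m`, `case`). Unknown keys are rejected
#' with the offending key path, never silently ignored. Either `k0` or
#' `calibration` may be given, not both.
#'
#' @param path Path to the YAML file, or a pre-parsed named list.
#' @return A list with `energy` ([energy_config()]), `topology`
#'   ([topology_spec()]), `stabilized` ([stabilized_spec()] or `NULL`),
#'   and the raw `config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop_domain("scenario config must be a key-value mapping")
  allowed <- c("delta_E", "k0", "calibration", "variant", "N_int",
               "N_pth", "N_ly", "stabilized")
  check_keys(cfg, allowed, "")
  if (!is.null(cfg$calibration))
    check_keys(cfg$calibration, c("k_fit", "N_fit"), "calibration.")
  if (!is.null(cfg$stabilized))
    check_keys(cfg$stabilized, c("S", "m", "case"), "stabilized.")
  if (is.null(cfg$delta_E)) stop_domain("config key `delta_E` is required")
  if (!is.null(cfg$k0) && !is.null(cfg$calibration))
    stop_domain("give either `k0` or `calibration`, not both")
  k0 <- if (!is.null(cfg$calibration)) {
    cal <- calibration_spec(cfg$calibration$k_fit %||% 3.4261,
                            cfg$calibration$N_fit %||% 9)
    calibrate_k0(cfg$delta_E, cal)
  } else cfg$k0 %||% 1
  energy <- energy_config(cfg$delta_E, k0)
  topo <- topology_spec(cfg$variant %||% "chain", N_int = cfg$N_int %||% 0L,
                        N_pth = cfg$N_pth, N_ly = cfg$N_ly)
  stab <- if (!is.null(cfg$stabilized))
    stabilized_spec(cfg$stabilized$S, cfg$stabilized$m,
                    cfg$stabilized$case %||% "constant_total")
  list(energy = energy, topology = topo, stabilized = stab, config = cfg)
}

check_keys <- function(x, allowed, prefix) {
  if (!is.list(x)) stop_domain("config section `", prefix, "` must be a mapping")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop_domain("unknown config key(s): ",
                paste0(prefix, bad, collapse = ", "))
  invisible(x)
}
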