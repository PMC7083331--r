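# Sweep drivers reproducing the package's computational experiments as
# deterministic tabular outputs. Tables are the contract; plotting is left
# to the user (all outputs are plain data frames / TSV files).

write_tsv_precise <- function(df, path) {
  out <- df
  out[] <- lapply(out, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(cfg, out_dir, seed) {
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(yaml::as.yaml(cfg), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package = "emtkinetics",
    package_version = as.character(utils::packageVersion("emtkinetics")))
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

resolve_k0 <- function(cfg) {
  if (!is.null(cfg$k0) && !is.null(cfg$calibration))
    stop_domain("give either `k0` or `calibration`, not both")
  if (!is.null(cfg$calibration)) {
    cal <- calibration_spec(cfg$calibration$k_fit %||% 3.4261,
                            cfg$calibration$N_fit %||% 9)
    function(dE) calibrate_k0(dE, cal)
  } else {
    k0 <- cfg$k0 %||% 1
    function(dE) k0
  }
}

classify_regime <- function(mfat, tol = 1e-12) {
  d <- diff(mfat)
  if (all(d <= tol)) "monotone_down"
  else if (all(d >= -tol)) "monotone_up"
  else "non_monotone"
}

#' Chain MFAT sweep: surface, per-barrier argmin, FAT distributions
#'
#' Evaluates the MFAT of the uniform chain over a (`delta_E`, `N_int`)
#' grid, reports the per-barrier minimizing chain length, and writes FAT
#' densities for requested (`delta_E`, `N_int`) pairs. Outputs (written to
#' `out_dir`): `mfat_surface.tsv`, `mfat_argmin.tsv`,
#' `fat_dE<dE>_N<N>.tsv`, `config.yaml`, `manifest.yaml`.
#'
#' Config keys: `delta_E` (vector), `N_int` (vector), `k0` or
#' `calibration{k_fit,N_fit}`, optional `fat_pairs` (list of
#' `{delta_E, N_int}`).
#'
#' @param config YAML path or named list.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the manifest (the sweep itself is
#'   deterministic).
#' @return Invisibly, a list with the surface and argmin data frames.
#' @export
run_chain_mfat <- function(config, out_dir, seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, c("delta_E", "N_int", "k0", "calibration", "fat_pairs"), "")
  if (is.null(cfg$delta_E) || is.null(cfg$N_int))
    stop_domain("config keys `delta_E` and `N_int` are required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k0_of <- resolve_k0(cfg)
  surf <- mfat_surface(cfg$delta_E, cfg$N_int,
                       cal = if (!is.null(cfg$calibration))
                         calibration_spec(cfg$calibration$k_fit %||% 3.4261,
                                          cfg$calibration$N_fit %||% 9),
                       k0 = if (is.null(cfg$calibration)) (cfg$k0 %||% 1) else 1)
  write_tsv_precise(surf$table, file.path(out_dir, "mfat_surface.tsv"))
  write_tsv_precise(surf$argmin, file.path(out_dir, "mfat_argmin.tsv"))
  for (pair in (cfg$fat_pairs %||% list())) {
    dE <- pair$delta_E; N <- pair$N_int
    k <- k0_of(dE) * exp(-dE / (N + 1))
    fs <- fat_mfat_chain(k, N)
    write_fat(fs, file.path(out_dir,
                            sprintf("fat_dE%g_N%d.tsv", dE, as.integer(N))))
  }
  write_manifest(cfg, out_dir, seed)
  invisible(list(surface = surf$table, argmin = surf$argmin))
}

#' Branched-topology sweeps: phase tables, regimes, minima, comparison
#'
#' For parallel and/or layered topologies at fixed `N_int`, evaluates the
#' MFAT over a (branches, `delta_E`) grid, classifies each barrier row as
#' monotone-down / non-monotone / monotone-up in the branch count, traces
#' the minimum-over-branches MFAT as a function of `N_int` at a fixed
#' barrier, and tabulates the parallel-versus-layered comparison with
#' crossing brackets. Outputs: `mfat_parallel.tsv` / `mfat_layered.tsv`,
#' `regimes_<variant>.tsv`, `min_curve_<variant>.tsv`, `compare.tsv`,
#' `crossings.tsv`, `config.yaml`, `manifest.yaml`.
#'
#' Config keys: `N_int` (default 9), `branches` (vector; default
#' `1:N_int`), `delta_E` (vector), `k0` or `calibration`, `variant`
#' (`"parallel"`, `"layered"` or `"both"`), optional
#' `min_curve{delta_E, N_int}` and `compare{N_int, branches, delta_E}`.
#'
#' @inheritParams run_chain_mfat
#' @return Invisibly, a named list of the data frames written.
#' @export
run_branch_sweeps <- function(config, out_dir, seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, c("N_int", "branches", "delta_E", "k0", "calibration",
                    "variant", "min_curve", "compare"), "")
  if (is.null(cfg$delta_E)) stop_domain("config key `delta_E` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k0_of <- resolve_k0(cfg)
  N_int <- cfg$N_int %||% 9L
  branches <- cfg$branches %||% seq_len(N_int)
  variants <- switch(cfg$variant %||% "both",
                     both = c("parallel", "layered"),
                     parallel = "parallel", layered = "layered",
                     stop_domain("variant must be parallel, layered or both"))
  out <- list()
  for (v in variants) {
    tab <- expand.grid(branches = as.integer(branches),
                       delta_E = as.numeric(cfg$delta_E),
                       KEEP.OUT.ATTRS = FALSE)
    tab$mfat <- vapply(seq_len(nrow(tab)), function(i) {
      dE <- tab$delta_E[i]; nb <- tab$branches[i]
      k0 <- k0_of(dE)
      if (v == "parallel") {
        ki <- k0 * exp(-dE / (split_paths(N_int, nb) + 1))
        (1 + N_int) / sum(ki)
      } else {
        sl <- split_layers(N_int, nb)
        k <- k0 * exp(-dE / (nb + 1))
        (nb + 1 / sl$N_L1) / k
      }
    }, numeric(1L))
    reg <- do.call(rbind, lapply(split(tab, tab$delta_E), function(d) {
      d <- d[order(d$branches), ]
      data.frame(delta_E = d$delta_E[1L],
                 regime = classify_regime(d$mfat),
                 branches_min = d$branches[which.min(d$mfat)],
                 mfat_min = min(d$mfat))
    }))
    rownames(reg) <- NULL
    write_tsv_precise(tab, file.path(out_dir, sprintf("mfat_%s.tsv", v)))
    write_tsv_precise(reg, file.path(out_dir, sprintf("regimes_%s.tsv", v)))
    out[[paste0("mfat_", v)]] <- tab
    out[[paste0("regimes_", v)]] <- reg
    if (!is.null(cfg$min_curve)) {
      mc <- cfg$min_curve
      dE <- mc$delta_E %||% if (v == "parallel") 6 else 5
      Ns <- mc$N_int %||% 2:20
      curve <- do.call(rbind, lapply(as.integer(Ns), function(N) {
        k0 <- k0_of(dE)
        mf <- vapply(seq_len(N), function(nb) {
          if (v == "parallel") {
            ki <- k0 * exp(-dE / (split_paths(N, nb) + 1))
            (1 + N) / sum(ki)
          } else {
            sl <- split_layers(N, nb)
            (nb + 1 / sl$N_L1) / (k0 * exp(-dE / (nb + 1)))
          }
        }, numeric(1L))
        data.frame(N_int = N, delta_E = dE,
                   branches_min = which.min(mf), mfat_min = min(mf))
      }))
      write_tsv_precise(curve, file.path(out_dir,
                                         sprintf("min_curve_%s.tsv", v)))
      out[[paste0("min_curve_", v)]] <- curve
    }
  }
  if (!is.null(cfg$compare)) {
    cmp <- cfg$compare
    res <- compare_topologies(cmp$N_int %||% 15L, cmp$branches %||% 4L,
                              cmp$delta_E %||% cfg$delta_E,
                              k0 = k0_of(0))
    write_tsv_precise(res$table, file.path(out_dir, "compare.tsv"))
    write_tsv_precise(res$crossings, file.path(out_dir, "crossings.tsv"))
    out$compare <- res$table
    out$crossings <- res$crossings
  }
  write_manifest(cfg, out_dir, seed)
  invisible(out)
}

#' Stabilized-state sweeps: dwelling-time and MFAT surfaces, occupancies
#'
#' Evaluates the mean dwelling time in the stabilized state and the MFAT
#' to the mesenchymal state over an (m, `delta_E`) grid for the requested
#' barrier-accounting case(s), and writes macrostate occupancy time
#' courses for example scenarios (barrier ratios and stabilized
#' placements). Outputs: `sweep_<case>.tsv`,
#' `occupancy_m<m>_S<S>_<case>.tsv`, `config.yaml`, `manifest.yaml`.
#'
#' Config keys: `N_int` (default 9), `S` (default 6), `m` (vector),
#' `delta_E` (vector), `case` (`"constant_total"`, `"varying_total"` or
#' `"both"`), `k0` or `calibration`, optional `occupancy` (list with
#' `times`, `m`, `S` vectors for the example time courses).
#'
#' @inheritParams run_chain_mfat
#' @return Invisibly, a named list of the data frames written.
#' @export
run_stabilized <- function(config, out_dir, seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, c("N_int", "S", "m", "delta_E", "case", "k0",
                    "calibration", "occupancy"), "")
  if (is.null(cfg$m) || is.null(cfg$delta_E))
    stop_domain("config keys `m` and `delta_E` are required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k0_of <- resolve_k0(cfg)
  N_int <- cfg$N_int %||% 9L
  S <- cfg$S %||% 6L
  cases <- switch(cfg$case %||% "both",
                  both = c("constant_total", "varying_total"),
                  constant_total = "constant_total",
                  varying_total = "varying_total",
                  stop_domain("case must be constant_total, varying_total or both"))
  out <- list()
  for (cs in cases) {
    sw <- stabilized_sweep(N_int, S, cfg$m, cfg$delta_E, case = cs,
                           k0 = if (is.null(cfg$calibration)) (cfg$k0 %||% 1)
                                else NULL,
                           cal = if (!is.null(cfg$calibration))
                             calibration_spec(cfg$calibration$k_fit %||% 3.4261,
                                              cfg$calibration$N_fit %||% 9))
    write_tsv_precise(sw, file.path(out_dir, sprintf("sweep_%s.tsv", cs)))
    out[[paste0("sweep_", cs)]] <- sw
    occ_cfg <- cfg$occupancy %||% list()
    times <- occ_cfg$times %||% seq(0, 20, by = 0.1)
    for (m in (occ_cfg$m %||% c(1, 6))) {
      for (Socc in (occ_cfg$S %||% c(6, 8))) {
        if (Socc > N_int) next
        dE <- max(cfg$delta_E)
        en <- energy_config(dE, k0_of(dE))
        ch <- stabilized_from_energy(en, N_int, Socc, m, cs)
        g <- stabilized_occupancy(ch, times)
        write_occupancy(g, file.path(out_dir,
          sprintf("occupancy_m%g_S%d_%s.tsv", m, as.integer(Socc), cs)))
      }
    }
  }
  write_manifest(cfg, out_dir, seed)
  invisible(out)
}
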