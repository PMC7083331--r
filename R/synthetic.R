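#' Specification for synthetic time-course generation
#'
#' Defines the ground-truth hidden-microstate model and sampling design
#' used to emulate a TGF-beta induction experiment: cells start 100%
#' epithelial and convert monotonically to mesenchymal over about a week,
#' observed as macrostate percentages at daily time points with
#' finite-cell multinomial sampling noise.
#'
#' The defaults mirror the best-fit regime for MCF10A EMT: truth
#' `N_E = 5`, `N_P = 5`, `k = 3.4261`/day, days 0-8 daily, 1e4 cells per
#' time point.
#'
#' @param N_E,N_P Ground-truth microstate counts.
#' @param k Forward step rate, 1/day.
#' @param k_bwd Backward rate for a reversible truth (default 0,
#'   irreversible).
#' @param times Sampling days (must start at 0).
#' @param n_cells Multinomial sampling depth per time point, or `NULL` for
#'   noiseless fractions.
#' @param seed RNG seed for the sampling noise.
#' @param source `"analytic"` (macrostate probabilities from the
#'   closed-form/uniformized solver) or `"gillespie"` (empirical fractions
#'   from simulated cells).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(N_E = 5, N_P = 5, k = 3.4261, k_bwd = 0,
                           times = 0:8, n_cells = 10000, seed = 1L,
                           source = c("analytic", "gillespie")) {
  N_E <- assert_count(N_E, "N_E", lower = 1L)
  N_P <- assert_count(N_P, "N_P", lower = 0L)
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  assert_scalar_number(k_bwd, "k_bwd", lower = 0)
  times <- assert_times(times)
  if (times[1L] != 0) stop_domain("`times` must start at 0")
  if (!is.null(n_cells)) n_cells <- assert_count(n_cells, "n_cells", lower = 1L)
  source <- match.arg(source)
  structure(list(N_E = N_E, N_P = N_P, k = k, k_bwd = k_bwd,
                 times = times, n_cells = n_cells,
                 seed = assert_count(seed, "seed"), source = source),
            class = "generator_spec")
}

#' Generate a synthetic macrostate time course
#'
#' Computes the ground-truth macrostate probabilities (analytically, or
#' empirically from a Gillespie ensemble) and optionally applies
#' multinomial sampling at `n_cells` cells per time point, so sampled
#' fractions always sum to exactly 100. Deterministic under a fixed seed.
#'
#' @param spec A [generator_spec()].
#' @return A [timecourse_data()] whose `meta` records the generator
#'   settings (including that the data are synthetic).
#' @export
#' @examples
#' tc <- generate_timecourse(generator_spec(n_cells = NULL))
#' head(tc$fractions)
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  map <- microstate_map(spec$N_E, spec$N_P)
  if (spec$source == "analytic") {
    g <- if (spec$k_bwd > 0) {
      reversible_occupancy(spec$k, spec$k_bwd, spec$N_E + spec$N_P + 1L,
                           spec$times, macrostate_map = map)
    } else {
      erlang_occupancy(spec$k, spec$N_E + spec$N_P - 1L, spec$times,
                       macrostate_map = map)
    }
    frac <- macro_fractions(g)                     # probabilities
  } else {
    if (spec$k_bwd > 0)
      stop_domain("gillespie source supports irreversible truth only")
    topo <- topology_spec("chain", N_int = spec$N_E + spec$N_P - 1L)
    ra <- step_rates(energy_config(0, spec$k), topo)
    sys <- build_transition_system(topo, ra)
    n <- spec$n_cells %||% 10000L
    cfg <- sim_config(n, T_max = max(spec$times) + 1e-9, seed = spec$seed)
    ens <- summarize_ensemble(simulate_cells(sys, cfg), spec$times, sys)
    frac <- sapply(c("E", "P", "M"), function(s)
      rowSums(ens$fractions[, map == s, drop = FALSE]))
    frac <- matrix(frac, nrow = length(spec$times),
                   dimnames = list(NULL, c("E", "P", "M")))
  }
  if (!is.null(spec$n_cells) && spec$source == "analytic") {
    set.seed(spec$seed)
    frac <- t(apply(frac, 1L, function(p) {
      p <- pmin(pmax(p, 0), 1)
      as.numeric(stats::rmultinom(1L, spec$n_cells, p / sum(p))) / spec$n_cells
    }))
    colnames(frac) <- c("E", "P", "M")
  }
  timecourse_data(spec$times, frac * 100, n_cells = spec$n_cells,
                  meta = list(synthetic = "yes", source = spec$source,
                              truth_N_E = spec$N_E, truth_N_P = spec$N_P,
                              truth_k = spec$k, truth_k_bwd = spec$k_bwd,
                              n_cells = spec$n_cells %||% "noiseless",
                              seed = spec$seed))
}
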