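#' Energy-barrier configuration for Arrhenius transition rates
#'
#' The transition rate for one step with barrier \eqn{\delta E} is
#' \eqn{k = k_0 e^{-\delta E}}, with the energy measured in units of
#' \eqn{k_B T}. `delta_E` is the *total* barrier from the epithelial to the
#' mesenchymal state; topology constructors divide it across steps.
#'
#' @param delta_E Total energy barrier, units of \eqn{k_B T}; must be >= 0.
#' @param k0 Pre-exponential attempt rate, 1/day; must be > 0. Defaults to
#'   1/day when no calibration is supplied.
#' @return An object of class `energy_config`.
#' @seealso [calibrate_k0()] to obtain `k0` from a fitted step rate.
#' @export
#' @examples
#' energy_config(delta_E = 10, k0 = calibrate_k0(10))
energy_config <- function(delta_E, k0 = 1) {
  assert_scalar_number(delta_E, "delta_E", lower = 0)
  assert_scalar_number(k0, "k0", lower = 0, strict_lower = TRUE)
  structure(list(delta_E = as.numeric(delta_E), k0 = as.numeric(k0)),
            class = "energy_config")
}

#' Calibration of the attempt rate from a fitted chain
#'
#' Holds the step rate and intermediate-state count obtained by fitting the
#' uniform-chain model to population time-course data. The defaults are the
#' best-fit values for TGF-beta-induced EMT in MCF10A cells: a common step
#' rate of 3.4261/day through nine intermediate microstates.
#'
#' @param k_fit Fitted per-step transition rate, 1/day; > 0.
#' @param N_fit Number of intermediate states used in the fit; integer >= 0.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(k_fit = 3.4261, N_fit = 9) {
  assert_scalar_number(k_fit, "k_fit", lower = 0, strict_lower = TRUE)
  N_fit <- assert_count(N_fit, "N_fit", lower = 0L)
  structure(list(k_fit = as.numeric(k_fit), N_fit = N_fit),
            class = "calibration_spec")
}

#' Calibrate the attempt rate k0 from a fitted step rate
#'
#' Inverts the even-split Arrhenius relation
#' \eqn{k_{fit} = k_0 e^{-\Delta E/(N_{fit}+1)}} so that, for any assumed
#' total barrier \eqn{\Delta E}, the uniform chain with `N_fit` intermediates
#' reproduces the fitted step rate exactly:
#' \eqn{k_0 = k_{fit}\, e^{\Delta E/(N_{fit}+1)}}.
#'
#' @param delta_E Total energy barrier, \eqn{k_B T} units; >= 0.
#' @param cal A [calibration_spec()]; defaults to the MCF10A calibration
#'   (k_fit = 3.4261/day, N_fit = 9).
#' @return The attempt rate `k0` in 1/day.
#' @export
#' @examples
#' calibrate_k0(0)    # equals k_fit
#' calibrate_k0(10)   # k_fit * e
calibrate_k0 <- function(delta_E, cal = calibration_spec()) {
  assert_scalar_number(delta_E, "delta_E", lower = 0)
  stopifnot(inherits(cal, "calibration_spec"))
  cal$k_fit * exp(delta_E / (cal$N_fit + 1))
}

#' State-graph topology specification
#'
#' Describes the arrangement of the `N_int` intermediate (partial-EMT)
#' states between the epithelial root and the absorbing mesenchymal state:
#' a single chain, `N_pth` parallel paths, or `N_ly` sequential layers.
#' The chain is the degenerate case `N_pth = 1` (and `N_L1 = 1`).
#'
#' @param variant `"chain"`, `"parallel"`, or `"layered"`.
#' @param N_int Number of intermediate states; integer >= 0 (chain) or >= 1.
#' @param N_pth Number of parallel paths (parallel only), 1 <= N_pth <= N_int.
#' @param N_ly Number of layers (layered only), 1 <= N_ly <= N_int.
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(variant = c("chain", "parallel", "layered"),
                          N_int, N_pth = NULL, N_ly = NULL) {
  variant <- match.arg(variant)
  N_int <- assert_count(N_int, "N_int", lower = 0L)
  if (variant == "chain" && (!is.null(N_pth) || !is.null(N_ly)))
    stop_domain("N_pth/N_ly are not valid for the chain variant")
  if (variant == "parallel") {
    if (is.null(N_pth)) stop_domain("parallel topology requires `N_pth`")
    if (!is.null(N_ly)) stop_domain("`N_ly` is not valid for the parallel variant")
    N_pth <- assert_count(N_pth, "N_pth", lower = 1L)
    if (N_pth > N_int)
      stop_domain("N_pth > N_int: a path would have zero intermediate states")
  }
  if (variant == "layered") {
    if (is.null(N_ly)) stop_domain("layered topology requires `N_ly`")
    if (!is.null(N_pth)) stop_domain("`N_pth` is not valid for the layered variant")
    N_ly <- assert_count(N_ly, "N_ly", lower = 1L)
    if (N_ly > N_int)
      stop_domain("N_ly > N_int: a layer would have zero states")
  }
  structure(list(variant = variant, N_int = N_int,
                 N_pth = N_pth, N_ly = N_ly),
            class = "topology_spec")
}

#' Stabilized-intermediate-state specification
#'
#' One intermediate state along a chain has an exit barrier `m` times the
#' regular per-step barrier (a deeper well that traps cells). Two barrier
#' accounting cases exist: `"constant_total"` redistributes barriers so the
#' total stays \eqn{\Delta E}; `"varying_total"` keeps regular steps at the
#' even split and lets the total barrier grow with `m`.
#'
#' @param S 1-based index of the stabilized state among the intermediates.
#' @param m Barrier ratio \eqn{\delta E_s / \delta E_i}; >= 1 (m = 1 is the
#'   uniform chain).
#' @param case `"constant_total"` or `"varying_total"`.
#' @return An object of class `stabilized_spec`.
#' @export
stabilized_spec <- function(S, m, case = c("constant_total", "varying_total")) {
  S <- assert_count(S, "S", lower = 1L)
  assert_scalar_number(m, "m", lower = 1)
  case <- match.arg(case)
  structure(list(S = S, m = as.numeric(m), case = case),
            class = "stabilized_spec")
}

#' Divide intermediate states over parallel paths
#'
#' Splits `N_int` intermediates into `N_pth` paths of near-equal size
#' (any two sizes differ by at most 1), returned in ascending order.
#'
#' @param N_int Total intermediate states; >= 1.
#' @param N_pth Number of paths, 1 <= N_pth <= N_int.
#' @return Integer vector of path sizes summing to `N_int`.
#' @export
#' @examples
#' split_paths(9, 2)   # c(4, 5)
split_paths <- function(N_int, N_pth) {
  N_int <- assert_count(N_int, "N_int", lower = 1L)
  N_pth <- assert_count(N_pth, "N_pth", lower = 1L)
  if (N_pth > N_int)
    stop_domain("N_pth > N_int: a path would have zero intermediate states")
  base <- N_int %/% N_pth
  extra <- N_int %% N_pth
  sort(c(rep(base, N_pth - extra), rep(base + 1L, extra)))
}

#' Divide intermediate states over transition layers
#'
#' Splits `N_int` intermediates into `N_ly` layers of near-equal size, with
#' remainder states assigned to the earliest layers, so the first layer is
#' the largest: `N_L1 = ceiling(N_int / N_ly)`.
#'
#' @param N_int Total intermediate states; >= 1.
#' @param N_ly Number of layers, 1 <= N_ly <= N_int.
#' @return A list with `sizes` (integer vector, earliest first) and `N_L1`.
#' @export
#' @examples
#' split_layers(15, 4)  # sizes 4,4,4,3; N_L1 = 4
split_layers <- function(N_int, N_ly) {
  N_int <- assert_count(N_int, "N_int", lower = 1L)
  N_ly <- assert_count(N_ly, "N_ly", lower = 1L)
  if (N_ly > N_int)
    stop_domain("N_ly > N_int: a layer would have zero states")
  base <- N_int %/% N_ly
  extra <- N_int %% N_ly
  sizes <- c(rep(base + 1L, extra), rep(base, N_ly - extra))
  list(sizes = sizes, N_L1 = sizes[1L])
}

#' Assign Arrhenius per-step rates to a topology
#'
#' Divides the total barrier across steps and converts each per-step
#' barrier to a rate via \eqn{k = k_0 e^{-\delta E}}:
#' \itemize{
#'   \item chain: every step \eqn{k = k_0 e^{-\Delta E/(N_{int}+1)}};
#'   \item chain + stabilized, constant-total: regular
#'     \eqn{k_1 = k_0 e^{-\Delta E/(N_{int}+m)}}, stabilized
#'     \eqn{k_2 = k_0 e^{-m\Delta E/(N_{int}+m)}};
#'   \item chain + stabilized, varying-total: regular
#'     \eqn{k_1 = k_0 e^{-\Delta E/(N_{int}+1)}}, stabilized
#'     \eqn{k_2 = k_0 e^{-m\Delta E/(N_{int}+1)}};
#'   \item parallel: path i with \eqn{N_i} intermediates has per-step rate
#'     \eqn{k_i = k_0 e^{-\Delta E/(N_i+1)}}; aggregate root exit
#'     \eqn{k_A = \sum_i k_i};
#'   \item layered: all steps \eqn{k = k_0 e^{-\Delta E/(N_{ly}+1)}};
#'     aggregate root exit \eqn{k_A = N_{L1} k}.
#' }
#'
#' The per-path even split in the parallel case (each path's barrier divided
#' over its own \eqn{N_i + 1} steps) is an explicit modelling assumption.
#'
#' @param energy An [energy_config()].
#' @param topo A [topology_spec()].
#' @param stab Optional [stabilized_spec()] (chain variant only).
#' @return A `rate_assignment` list: `variant`, `step_rates` (per-step
#'   rates keyed to topology edges; per-path rates for parallel), `k_A`
#'   (aggregate root-exit rate, parallel/layered), plus variant metadata
#'   (`path_sizes`, `layer_sizes`, `N_L1`, `k1`, `k2`, `S`, `case`).
#' @export
step_rates <- function(energy, topo, stab = NULL) {
  stopifnot(inherits(energy, "energy_config"), inherits(topo, "topology_spec"))
  dE <- energy$delta_E; k0 <- energy$k0
  if (!is.null(stab)) {
    stopifnot(inherits(stab, "stabilized_spec"))
    if (topo$variant != "chain")
      stop_domain("a stabilized state is only defined for the chain variant")
    if (stab$S > topo$N_int)
      stop_domain("stabilized index S exceeds N_int")
    if (stab$m < 1)
      stop_domain("m < 1: state would not be stabilized")
    m <- stab$m; N <- topo$N_int
    if (stab$case == "constant_total") {
      k1 <- k0 * exp(-dE / (N + m))
      k2 <- k0 * exp(-dE * m / (N + m))
    } else {
      k1 <- k0 * exp(-dE / (N + 1))
      k2 <- k0 * exp(-dE * m / (N + 1))
    }
    rates <- rep(k1, N + 1L)
    rates[stab$S + 1L] <- k2   # exit from the S-th intermediate
    return(structure(list(variant = "chain", step_rates = rates,
                          k_A = rates[1L], k1 = k1, k2 = k2,
                          S = stab$S, case = stab$case, N_int = N),
                     class = "rate_assignment"))
  }
  switch(topo$variant,
    chain = {
      k <- k0 * exp(-dE / (topo$N_int + 1))
      structure(list(variant = "chain",
                     step_rates = rep(k, topo$N_int + 1L),
                     k_A = k, N_int = topo$N_int),
                class = "rate_assignment")
    },
    parallel = {
      sizes <- split_paths(topo$N_int, topo$N_pth)
      ki <- k0 * exp(-dE / (sizes + 1))
      structure(list(variant = "parallel", step_rates = ki,
                     k_A = sum(ki), path_sizes = sizes,
                     N_int = topo$N_int),
                class = "rate_assignment")
    },
    layered = {
      sl <- split_layers(topo$N_int, topo$N_ly)
      k <- k0 * exp(-dE / (topo$N_ly + 1))
      structure(list(variant = "layered", step_rates = rep(k, topo$N_ly),
                     k_A = sl$N_L1 * k, k = k,
                     layer_sizes = sl$sizes, N_L1 = sl$N_L1,
                     N_ly = topo$N_ly, N_int = topo$N_int),
                class = "rate_assignment")
    })
}
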