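#' Chain with one stabilized intermediate state
#'
#' Describes an irreversible chain of `N_int` intermediates where the exit
#' from the `S`-th intermediate proceeds at a slower rate `k2 < k1`
#' (a deeper well in the landscape picture). Construct directly from rates
#' or from an energy configuration via [stabilized_from_energy()].
#'
#' @param N_int Number of intermediate states; >= 1.
#' @param S 1-based index of the stabilized intermediate, 1 <= S <= N_int.
#' @param k1 Regular step rate, 1/day; > 0.
#' @param k2 Stabilized exit rate, 1/day; 0 < k2 <= k1.
#' @param m Optional barrier ratio metadata (>= 1).
#' @param case Optional barrier accounting case metadata.
#' @return An object of class `stabilized_chain`.
#' @export
stabilized_chain <- function(N_int, S, k1, k2, m = NULL, case = NULL) {
  N_int <- assert_count(N_int, "N_int", lower = 1L)
  S <- assert_count(S, "S", lower = 1L)
  if (S > N_int) stop_domain("S must satisfy 1 <= S <= N_int")
  assert_scalar_number(k1, "k1", lower = 0, strict_lower = TRUE)
  assert_scalar_number(k2, "k2", lower = 0, strict_lower = TRUE)
  if (k2 > k1 * (1 + 1e-12))
    stop_domain("k2 > k1: the state would not be stabilized")
  structure(list(N_int = N_int, S = S, k1 = as.numeric(k1),
                 k2 = as.numeric(k2), m = m, case = case),
            class = "stabilized_chain")
}

#' Build a stabilized chain from an energy configuration
#'
#' Applies the Arrhenius barrier split of [step_rates()] for the requested
#' case and returns the corresponding [stabilized_chain()].
#'
#' @param energy An [energy_config()].
#' @param N_int Number of intermediates.
#' @param S Stabilized index.
#' @param m Barrier ratio >= 1.
#' @param case `"constant_total"` or `"varying_total"`.
#' @return A [stabilized_chain()].
#' @export
stabilized_from_energy <- function(energy, N_int, S, m,
                                   case = c("constant_total", "varying_total")) {
  case <- match.arg(case)
  ra <- step_rates(energy, topology_spec("chain", N_int = N_int),
                   stab = stabilized_spec(S, m, case))
  stabilized_chain(N_int, S, ra$k1, ra$k2, m = m, case = case)
}

# CDF at t of Erlang(n, k1) + Exp(k2), the arrival time into the state
# reached after n regular steps and the stabilized exit. Evaluated via the
# incomplete-gamma identity
#   H_n(t) = pgamma(k1 t, n) - (k1/(k1-k2))^n e^{-k2 t} pgamma((k1-k2) t, n)
# with the second term assembled in log space (the ratio power overflows
# for k1 close to k2).
stab_arrival_cdf <- function(t, n, k1, k2) {
  if (n == 0L) return(1 - exp(-k2 * t))
  lb <- n * (log(k1) - log(k1 - k2)) - k2 * t +
    stats::pgamma((k1 - k2) * t, shape = n, log.p = TRUE)
  pmin(pmax(stats::pgamma(k1 * t, shape = n) - exp(lb), 0), 1)
}

#' Occupancy of a chain with one stabilized state
#'
#' Closed-form occupancy of every state of the stabilized chain. States
#' before the stabilized one are Erlang (Poisson-mass) terms in `k1`; the
#' stabilized state and those after it mix `e^{-k2 t}` and `e^{-k1 t}`
#' contributions, evaluated through regularized incomplete-gamma
#' identities in log space (the direct alternating sums lose all precision
#' for small `k1 - k2`). When `k1` and `k2` agree to a relative 1e-9 the
#' uniform-chain limit is returned.
#'
#' @param chain A [stabilized_chain()].
#' @param times Time grid, days.
#' @param macrostate_map Optional macrostate assignment of the
#'   `N_int + 2` states.
#' @return An [occupancy_grid()] with states `E`, `P1..P<N_int>`, `M`.
#' @export
stabilized_occupancy <- function(chain, times, macrostate_map = NULL) {
  stopifnot(inherits(chain, "stabilized_chain"))
  t <- assert_times(times)
  N <- chain$N_int; S <- chain$S; k1 <- chain$k1; k2 <- chain$k2
  nm <- c("E", paste0("P", seq_len(N)), "M")
  if (is.null(macrostate_map)) macrostate_map <- c("E", rep("P", N), "M")
  if (abs(k1 - k2) < 1e-9 * k1) {
    g <- erlang_occupancy(k1, N, t, macrostate_map = macrostate_map)
    colnames(g$probs) <- nm
    g$state_names <- nm
    return(g)
  }
  probs <- matrix(0, length(t), N + 2L, dimnames = list(NULL, nm))
  lam <- k1 * t
  for (j in 0:(S - 1L)) probs[, j + 1L] <- stats::dpois(j, lam)
  # stabilized state: P_S = (k1/(k1-k2))^S e^{-k2 t} pgamma((k1-k2)t, S)
  lS <- S * (log(k1) - log(k1 - k2)) - k2 * t +
    stats::pgamma((k1 - k2) * t, shape = S, log.p = TRUE)
  probs[, S + 1L] <- exp(lS)
  if (S < N) {
    H <- sapply(S:N, function(n) stab_arrival_cdf(t, n, k1, k2))
    H <- matrix(H, nrow = length(t))
    for (u in seq_len(N - S))
      probs[, S + 1L + u] <- pmax(H[, u] - H[, u + 1L], 0)
    probs[, N + 2L] <- H[, N - S + 1L]
  } else {
    probs[, N + 2L] <- stab_arrival_cdf(t, N, k1, k2)
  }
  occupancy_grid(t, probs, nm, macrostate_map)
}

#' Mean first arrival time to the stabilized state
#'
#' The arrival process into the `S`-th intermediate consists of `S`
#' exponential steps at rate `k1`, an Erlang(S, k1) time with mean
#' `S / k1` (the default, confirmed by stochastic simulation). An
#' alternative offset convention counting the epithelial state as a step,
#' `(S + 1) / k1`, is exposed as `convention = "offset"`; both are
#' reported because published closed forms differ in this indexing.
#'
#' @param chain A [stabilized_chain()].
#' @param convention `"erlang"` (default, `S/k1`) or `"offset"`
#'   (`(S+1)/k1`).
#' @return Mean arrival time in days.
#' @export
mfat_to_stabilized <- function(chain, convention = c("erlang", "offset")) {
  stopifnot(inherits(chain, "stabilized_chain"))
  convention <- match.arg(convention)
  if (convention == "erlang") chain$S / chain$k1
  else (chain$S + 1) / chain$k1
}

#' Mean dwelling time in the stabilized state
#'
#' The sojourn in the stabilized state is exponential with its exit rate,
#' so the mean dwelling time is exactly \eqn{D_S = 1/k_2}, independent of
#' everything else in the chain.
#'
#' @param chain A [stabilized_chain()], or a single exit rate `k2`.
#' @return Mean dwelling time in days.
#' @export
mean_dwelling_time <- function(chain) {
  k2 <- if (inherits(chain, "stabilized_chain")) chain$k2 else chain
  assert_scalar_number(k2, "k2", lower = 0, strict_lower = TRUE)
  1 / k2
}

#' First-arrival-time summary for the stabilized chain
#'
#' The arrival time into M is Erlang(`N_int`, `k1`) + Exp(`k2`); the
#' density is evaluated through the same incomplete-gamma route as the
#' occupancy, and the mean is \eqn{N_{int}/k_1 + 1/k_2}.
#'
#' @param chain A [stabilized_chain()].
#' @param times Optional time grid.
#' @return A [fat_summary()].
#' @export
stabilized_fat <- function(chain, times = NULL) {
  stopifnot(inherits(chain, "stabilized_chain"))
  N <- chain$N_int; k1 <- chain$k1; k2 <- chain$k2
  mfat <- N / k1 + 1 / k2
  if (abs(k1 - k2) < 1e-9 * k1)
    return(fat_mfat_chain(k1, N, times = times))
  dens <- function(t) {
    lb <- log(k2) + N * (log(k1) - log(k1 - k2)) - k2 * t +
      stats::pgamma((k1 - k2) * t, shape = N, log.p = TRUE)
    exp(lb)
  }
  fat_summary(dens, mfat = mfat, times = times)
}

#' Sweep of dwelling time and MFAT over barrier ratio and total barrier
#'
#' Evaluates the mean dwelling time in the stabilized state and the MFAT
#' to the mesenchymal state on an (m, delta_E) grid for either barrier
#' accounting case.
#'
#' @param N_int Number of intermediates.
#' @param S Stabilized index.
#' @param m Numeric vector of barrier ratios (>= 1).
#' @param delta_E Numeric vector of total barriers.
#' @param case `"constant_total"` or `"varying_total"`.
#' @param k0 Attempt rate (1/day) or `NULL` to recalibrate per barrier
#'   from `cal`.
#' @param cal Optional [calibration_spec()] used when `k0` is `NULL`.
#' @return data.frame with columns `m`, `delta_E`, `dwell_time`, `mfat_m`.
#' @export
stabilized_sweep <- function(N_int, S, m, delta_E,
                             case = c("constant_total", "varying_total"),
                             k0 = 1, cal = NULL) {
  case <- match.arg(case)
  if (!length(m) || !length(delta_E)) stop_domain("grids must be nonempty")
  grid <- expand.grid(m = as.numeric(m), delta_E = as.numeric(delta_E),
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1L, function(row) {
    k0_here <- if (is.null(k0)) calibrate_k0(row[["delta_E"]], cal) else k0
    en <- energy_config(row[["delta_E"]], k0_here)
    ch <- stabilized_from_energy(en, N_int, S, row[["m"]], case)
    c(dwell_time = 1 / ch$k2, mfat_m = N_int / ch$k1 + 1 / ch$k2)
  }))
  cbind(grid, as.data.frame(res))
}
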