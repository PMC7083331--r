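#' Three-state occupancy: E -> P -> M with distinct rates
#'
#' Closed-form solution of the irreversible three-state master equation
#' \deqn{p_E = e^{-k_1 t},\quad
#'       p_P = \frac{k_1}{k_2-k_1}(e^{-k_1 t} - e^{-k_2 t}),\quad
#'       p_M = 1 - \frac{k_2}{k_2-k_1}e^{-k_1 t} + \frac{k_1}{k_2-k_1}e^{-k_2 t}.}
#' When \eqn{k_1 \approx k_2} (relative difference below 1e-9) the removable
#' singularity is handled by the confluent limit
#' \eqn{p_P = k_1 t\, e^{-k_1 t}}.
#'
#' @param k1 Rate E -> P, 1/day; > 0.
#' @param k2 Rate P -> M, 1/day; > 0.
#' @param times Time grid, days.
#' @return An [occupancy_grid()] with states `E`, `P`, `M`.
#' @export
#' @examples
#' three_state_occupancy(0.6657, 0.4908, times = 0:8)
three_state_occupancy <- function(k1, k2, times) {
  assert_scalar_number(k1, "k1", lower = 0, strict_lower = TRUE)
  assert_scalar_number(k2, "k2", lower = 0, strict_lower = TRUE)
  t <- assert_times(times)
  pE <- exp(-k1 * t)
  if (abs(k1 - k2) < 1e-9 * k1) {
    pP <- k1 * t * exp(-k1 * t)
  } else {
    pP <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  }
  pM <- pmin(pmax(1 - pE - pP, 0), 1)
  occupancy_grid(t, cbind(pE, pP, pM), c("E", "P", "M"), c("E", "P", "M"))
}

#' Uniform-chain (Erlang) occupancy
#'
#' Occupancy of the irreversible chain of `N_int + 1` microstates followed
#' by the absorbing mesenchymal state, with the same rate `k` at every
#' step: \eqn{p_n(t) = e^{-kt}(kt)^{n-1}/(n-1)!} for
#' \eqn{1 \le n \le N_{int}+1} and \eqn{p_M = 1 - \sum_n p_n}. Evaluated as
#' Poisson point masses (log-space internally), so it is finite for
#' arbitrarily large `k t`.
#'
#' @param k Per-step rate, 1/day; > 0.
#' @param N_int Number of intermediate states; integer >= 0.
#' @param times Time grid, days.
#' @param macrostate_map Optional macrostate assignment of the
#'   `N_int + 2` states; default: first microstate "E", remaining
#'   intermediates "P", absorbing "M".
#' @return An [occupancy_grid()] with states `S1 ... S<N_int+1>`, `M`.
#' @export
erlang_occupancy <- function(k, N_int, times, macrostate_map = NULL) {
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  N_int <- assert_count(N_int, "N_int", lower = 0L)
  t <- assert_times(times)
  n_states <- N_int + 2L
  lam <- k * t
  probs <- sapply(0:N_int, function(n) stats::dpois(n, lam))
  probs <- matrix(probs, nrow = length(t))
  pM <- stats::ppois(N_int, lam, lower.tail = FALSE)
  probs <- cbind(probs, pM)
  nm <- c(paste0("S", seq_len(N_int + 1L)), "M")
  if (is.null(macrostate_map))
    macrostate_map <- c("E", rep("P", N_int), "M")
  occupancy_grid(t, probs, nm, macrostate_map)
}

#' Reversible-chain occupancy via uniformized matrix exponential
#'
#' Solves \eqn{dp/dt = A p} for the birth-death chain of
#' `N_states - 1` transient microstates with forward rate `k_fwd`
#' (i to i+1), backward rate `k_bwd` (i to i-1, not out of the first
#' state), and an absorbing final state M (no backward flow out of M).
#' The matrix exponential is computed by uniformization: with
#' \eqn{\lambda = \max_i(-A_{ii})} and \eqn{P = I + A/\lambda},
#' \eqn{p(t) = \sum_j \mathrm{Pois}(j; \lambda t) P^j p(0)}, truncated at a
#' tail mass below 1e-12 and propagated sequentially across sorted time
#' points.
#'
#' @param k_fwd Forward rate, 1/day; >= 0.
#' @param k_bwd Backward rate, 1/day; >= 0. `k_bwd = 0` reduces exactly to
#'   the irreversible Erlang chain.
#' @param N_states Total number of states including absorbing M; >= 2.
#' @param times Time grid, days.
#' @param macrostate_map Optional macrostate assignment (length
#'   `N_states`); default first state "E", intermediates "P", last "M".
#' @return An [occupancy_grid()].
#' @export
reversible_occupancy <- function(k_fwd, k_bwd, N_states, times,
                                 macrostate_map = NULL) {
  assert_scalar_number(k_fwd, "k_fwd", lower = 0)
  assert_scalar_number(k_bwd, "k_bwd", lower = 0)
  N_states <- assert_count(N_states, "N_states", lower = 2L)
  t <- assert_times(times)
  A <- reversible_generator(k_fwd, k_bwd, N_states)
  p0 <- c(1, rep(0, N_states - 1L))
  probs <- matexp_uniform(A, p0, t)
  if (any(!is.finite(probs)))
    stop("reversible_occupancy: numerical failure (non-finite probabilities)",
         call. = FALSE)
  nm <- c(paste0("S", seq_len(N_states - 1L)), "M")
  if (is.null(macrostate_map))
    macrostate_map <- c("E", rep("P", N_states - 2L), "M")
  occupancy_grid(t, probs, nm, macrostate_map)
}

# generator acting on column vector p (A[i, j] = rate j -> i for i != j)
reversible_generator <- function(k_fwd, k_bwd, N_states) {
  Tn <- N_states - 1L  # transient states
  A <- matrix(0, N_states, N_states)
  for (i in seq_len(Tn)) {
    out <- k_fwd + if (i > 1L) k_bwd else 0
    A[i, i] <- -out
    tgt <- i + 1L               # forward (last transient feeds M)
    A[tgt, i] <- A[tgt, i] + k_fwd
    if (i > 1L) A[i - 1L, i] <- A[i - 1L, i] + k_bwd
  }
  A
}

# p(t) = e^{A t} p0 by uniformization, propagated over sorted times
matexp_uniform <- function(A, p0, times, tail_tol = 1e-12) {
  lam <- max(-diag(A))
  n <- length(p0)
  ord <- order(times)
  probs <- matrix(0, length(times), n)
  if (lam <= 0) {  # no dynamics
    probs[] <- rep(p0, each = length(times))
    return(probs)
  }
  P <- diag(n) + A / lam
  p <- p0
  t_prev <- 0
  for (idx in ord) {
    dt <- times[idx] - t_prev
    if (dt > 0) {
      x <- lam * dt
      jmax <- max(20L, ceiling(x + 12 * sqrt(x + 1) + 40))
      w <- stats::dpois(0:jmax, x)
      acc <- w[1L] * p
      v <- p
      for (j in seq_len(jmax)) {
        v <- P %*% v
        acc <- acc + w[j + 1L] * v
      }
      # renormalize the truncated Poisson mixture (conserves probability)
      p <- as.numeric(acc) / sum(w)
      t_prev <- times[idx]
    }
    probs[idx, ] <- p
  }
  probs
}

#' First-arrival-time density and mean for the uniform chain
#'
#' The arrival time into the absorbing state of a uniform chain with
#' `N_int` intermediates is Erlang-distributed:
#' \deqn{f_M(t) = \frac{1}{N_{int}!} e^{-kt} k^{N_{int}+1} t^{N_{int}},
#'       \qquad \langle f_M \rangle = \frac{N_{int}+1}{k}.}
#'
#' @param k Per-step rate, 1/day; > 0.
#' @param N_int Number of intermediate states; integer >= 0.
#' @param times Optional explicit time grid for the stored density.
#' @return A [fat_summary()].
#' @export
#' @examples
#' fat_mfat_chain(3.4261, 9)$mfat  # 10 / 3.4261
fat_mfat_chain <- function(k, N_int, times = NULL) {
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  N_int <- assert_count(N_int, "N_int", lower = 0L)
  fat_summary(function(t) stats::dgamma(t, shape = N_int + 1, rate = k),
              mfat = (N_int + 1) / k, times = times)
}

#' MFAT surface over energy barrier and chain length
#'
#' Evaluates \eqn{\mathrm{MFAT}(\Delta E, N_{int}) =
#' (N_{int}+1) / (k_0(\Delta E)\, e^{-\Delta E/(N_{int}+1)})} on a grid and
#' reports, per \eqn{\Delta E}, the integer `N_int` minimizing the MFAT.
#' The continuous relaxation has its optimum at \eqn{N_{int}+1 = \Delta E},
#' so for barriers above ~2 the curve has an interior minimum while for
#' small barriers it is monotone increasing.
#'
#' @param delta_E Numeric vector of total barriers (kBT units).
#' @param N_int Integer vector of chain lengths.
#' @param cal Optional [calibration_spec()]; when supplied, `k0` is
#'   recalibrated per barrier via [calibrate_k0()]. Otherwise `k0` is used
#'   as a fixed attempt rate.
#' @param k0 Fixed attempt rate (1/day) when `cal` is `NULL`; default 1.
#' @return List with `table` (data.frame: delta_E, N_int, mfat) and
#'   `argmin` (data.frame: delta_E, N_int_min, mfat_min).
#' @export
mfat_surface <- function(delta_E, N_int, cal = NULL, k0 = 1) {
  if (!length(delta_E) || !length(N_int))
    stop_domain("grids must be nonempty")
  N_int <- vapply(N_int, assert_count, integer(1L), name = "N_int")
  tab <- expand.grid(delta_E = as.numeric(delta_E), N_int = N_int,
                     KEEP.OUT.ATTRS = FALSE)
  k0_of <- if (is.null(cal)) function(dE) k0 else function(dE) calibrate_k0(dE, cal)
  k0v <- vapply(tab$delta_E, k0_of, numeric(1L))
  tab$mfat <- (tab$N_int + 1) / (k0v * exp(-tab$delta_E / (tab$N_int + 1)))
  argmin <- do.call(rbind, lapply(split(tab, tab$delta_E), function(d) {
    i <- which.min(d$mfat)
    data.frame(delta_E = d$delta_E[1L], N_int_min = d$N_int[i],
               mfat_min = d$mfat[i])
  }))
  rownames(argmin) <- NULL
  list(table = tab, argmin = argmin[order(argmin$delta_E), , drop = FALSE])
}
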