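#' Explicit transition system (source / target / rate representation)
#'
#' Builds the per-transition indicator representation of the absorbing
#' Markov chain used by the stochastic simulator: `sources` and `targets`
#' are 0/1 matrices with one row per transition selecting exactly one
#' state, and `rates` holds the corresponding transition rates.
#'
#' Wiring per topology: a chain with `N_int` intermediates has
#' `N_int + 1` bidiagonal transitions; a parallel topology fans the root
#' out into each path's first state at that path's rate; a layered
#' topology fans the root into every first-layer state at the common step
#' rate `k` (aggregate `N_L1 * k`), and each layer-l state feeds one
#' designated layer-(l+1) state (index folded into the next layer's size),
#' consistent with the layer-aggregate analytic model.
#'
#' @param topo A [topology_spec()].
#' @param rates A `rate_assignment` from [step_rates()].
#' @param stab Optional [stabilized_spec()] metadata (already reflected in
#'   `rates` when it was built with one; used here only for validation).
#' @return A `transition_system` list: `sources`, `targets` (matrices),
#'   `rates` (vector), `n_states`, `state_names`, `absorbing`
#'   (state index), `macrostate_map`.
#' @export
build_transition_system <- function(topo, rates, stab = NULL) {
  stopifnot(inherits(topo, "topology_spec"), inherits(rates, "rate_assignment"))
  if (topo$variant != rates$variant)
    stop_domain("topology variant and rate assignment variant disagree")
  edges <- switch(topo$variant,
    chain = {
      n_states <- topo$N_int + 2L
      nm <- c("E", if (topo$N_int > 0) paste0("P", seq_len(topo$N_int)), "M")
      list(from = seq_len(n_states - 1L), to = 2:n_states,
           rate = rates$step_rates, n_states = n_states, names = nm,
           map = c("E", rep("P", topo$N_int), "M"))
    },
    parallel = {
      sizes <- rates$path_sizes
      n_states <- 1L + sum(sizes) + 1L
      nm <- c("E", unlist(lapply(seq_along(sizes), function(i)
        paste0("P", i, ".", seq_len(sizes[i])))), "M")
      offs <- 1L + c(0L, cumsum(sizes))[seq_along(sizes)]
      from <- integer(0); to <- integer(0); rt <- numeric(0)
      for (i in seq_along(sizes)) {
        idx <- offs[i] + seq_len(sizes[i])      # states of path i
        from <- c(from, 1L, idx)
        to <- c(to, idx[1L], idx[-1L], n_states)
        rt <- c(rt, rep(rates$step_rates[i], sizes[i] + 1L))
      }
      list(from = from, to = to, rate = rt, n_states = n_states, names = nm,
           map = c("E", rep("P", sum(sizes)), "M"))
    },
    layered = {
      sizes <- rates$layer_sizes
      n_states <- 1L + sum(sizes) + 1L
      nm <- c("E", unlist(lapply(seq_along(sizes), function(i)
        paste0("L", i, ".", seq_len(sizes[i])))), "M")
      offs <- 1L + c(0L, cumsum(sizes))[seq_along(sizes)]
      k <- rates$k
      from <- rep(1L, sizes[1L])
      to <- offs[1L] + seq_len(sizes[1L])
      rt <- rep(k, sizes[1L])
      for (l in seq_along(sizes)) {
        for (j in seq_len(sizes[l])) {
          src <- offs[l] + j
          if (l < length(sizes)) {
            tgt <- offs[l + 1L] + min(j, sizes[l + 1L])
          } else {
            tgt <- n_states
          }
          from <- c(from, src); to <- c(to, tgt); rt <- c(rt, k)
        }
      }
      list(from = from, to = to, rate = rt, n_states = n_states, names = nm,
           map = c("E", rep("P", sum(sizes)), "M"))
    })
  if (any(edges$from == edges$n_states))
    stop_domain("absorbing state must have no outgoing transitions")
  reach <- unique(c(1L, edges$to))
  if (!all(seq_len(edges$n_states) %in% reach))
    stop_domain("transition system is disconnected")
  n_tr <- length(edges$rate)
  Smat <- matrix(0L, n_tr, edges$n_states)
  Pmat <- matrix(0L, n_tr, edges$n_states)
  Smat[cbind(seq_len(n_tr), edges$from)] <- 1L
  Pmat[cbind(seq_len(n_tr), edges$to)] <- 1L
  colnames(Smat) <- colnames(Pmat) <- edges$names
  structure(list(sources = Smat, targets = Pmat, rates = edges$rate,
                 n_states = edges$n_states, state_names = edges$names,
                 absorbing = edges$n_states, macrostate_map = edges$map),
            class = "transition_system")
}

#' Simulation configuration
#'
#' @param n_cells Number of independent cells; >= 1.
#' @param T_max Simulation horizon, days; > 0.
#' @param seed Integer RNG seed; per-cell substreams are derived from
#'   `seed + cell index`, so enlarging `n_cells` never reshuffles earlier
#'   cells.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells, T_max, seed = 1L) {
  n_cells <- assert_count(n_cells, "n_cells", lower = 1L)
  assert_scalar_number(T_max, "T_max", lower = 0, strict_lower = TRUE)
  seed <- assert_count(seed, "seed")
  structure(list(n_cells = n_cells, T_max = as.numeric(T_max), seed = seed),
            class = "sim_config")
}

#' Simulate single-cell trajectories with the Gillespie algorithm
#'
#' Each cell starts in state 1 at time 0 and is simulated independently:
#' the waiting time to the next event is exponential with the total
#' propensity of the current state (`dt = log(1/u1)/a0`), and the event is
#' chosen by the cumulative-propensity rule (strict-left / inclusive-right
#' at the measure-zero tie). Simulation stops at absorption or at `T_max`.
#'
#' @param sys A [build_transition_system()] result.
#' @param cfg A [sim_config()].
#' @return List of `cell_trajectory` objects, each with `times` (event
#'   times, starting at 0), `states` (visited state indices, starting at
#'   1) and `absorbed` flag. Identical seeds give identical trajectories.
#' @export
simulate_cells <- function(sys, cfg) {
  stopifnot(inherits(sys, "transition_system"), inherits(cfg, "sim_config"))
  n_tr <- length(sys$rates)
  from <- max.col(sys$sources, ties.method = "first")
  to <- max.col(sys$targets, ties.method = "first")
  # per-state outgoing transitions
  out_by_state <- split(seq_len(n_tr), from)
  trajs <- vector("list", cfg$n_cells)
  for (cell in seq_len(cfg$n_cells)) {
    set.seed((cfg$seed + cell) %% 2147483629L)
    state <- 1L
    t_now <- 0
    times <- 0
    states <- state
    absorbed <- FALSE
    repeat {
      if (state == sys$absorbing) { absorbed <- TRUE; break }
      tr <- out_by_state[[as.character(state)]]
      a <- sys$rates[tr]
      a0 <- sum(a)
      if (a0 <= 0)
        stop("zero total propensity in a non-absorbing state", call. = FALSE)
      u <- stats::runif(2L)
      dt <- log(1 / u[1L]) / a0
      if (t_now + dt > cfg$T_max) break
      ca <- cumsum(a)
      r <- tr[which(u[2L] * a0 <= ca)[1L]]
      t_now <- t_now + dt
      state <- to[r]
      times <- c(times, t_now)
      states <- c(states, state)
    }
    trajs[[cell]] <- structure(list(times = times, states = states,
                                    absorbed = absorbed),
                               class = "cell_trajectory")
  }
  trajs
}

#' Summarize an ensemble of trajectories
#'
#' Piecewise-constant interpolation of each trajectory onto a common time
#' grid gives per-state occupancy fractions; first-arrival times are the
#' first entry times into the absorbing state (censored cells excluded and
#' counted); dwell times are per-state sojourn durations.
#'
#' @param trajectories List of `cell_trajectory` objects from
#'   [simulate_cells()].
#' @param times Time grid, days.
#' @param sys The [build_transition_system()] the trajectories came from.
#' @return An `ensemble_summary` list: `times`, `fractions` (matrix time x
#'   state, rows sum to 1), `fat` (numeric vector of arrival times),
#'   `n_censored`, `dwell` (list of sojourn-duration vectors per state).
#' @export
summarize_ensemble <- function(trajectories, times, sys) {
  if (!length(trajectories)) stop_domain("empty trajectory list")
  times <- assert_times(times)
  n_states <- sys$n_states
  counts <- matrix(0, length(times), n_states,
                   dimnames = list(NULL, sys$state_names))
  fat <- numeric(0)
  n_censored <- 0L
  dwell <- vector("list", n_states)
  for (tr in trajectories) {
    idx <- findInterval(times, tr$times)
    idx[idx < 1L] <- 1L
    st <- tr$states[idx]
    counts[cbind(seq_along(times), st)] <- counts[cbind(seq_along(times), st)] + 1
    if (tr$absorbed) {
      fat <- c(fat, tr$times[length(tr$times)])
    } else {
      n_censored <- n_censored + 1L
    }
    # sojourn durations (exclude the final, possibly censored, sojourn
    # unless the cell was absorbed, in which case the absorbing sojourn
    # is open-ended and also excluded)
    nseg <- length(tr$times) - 1L
    if (nseg > 0L) {
      dur <- diff(tr$times)
      for (i in seq_len(nseg)) {
        s <- tr$states[i]
        dwell[[s]] <- c(dwell[[s]], dur[i])
      }
    }
  }
  structure(list(times = times,
                 fractions = counts / length(trajectories),
                 fat = fat, n_censored = n_censored, dwell = dwell),
            class = "ensemble_summary")
}

#' Export trajectories as a long-format table
#'
#' @param trajectories List of `cell_trajectory` objects.
#' @return data.frame with columns `cell_id`, `time`, `state`.
#' @export
trajectories_long <- function(trajectories) {
  do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(cell_id = i, time = tr$times, state = tr$states)
  }))
}
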