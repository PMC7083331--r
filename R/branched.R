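#' Parallel-path kinetics
#'
#' Occupancy and first-arrival-time solution for `N_pth` parallel paths:
#' the epithelial root exits into the first state of path i at rate
#' \eqn{k_i} (total exit rate \eqn{k_A = \sum_i k_i}); within path i every
#' step proceeds at \eqn{k_i}. The per-state occupancy is hypoexponential
#' (two distinct rates \eqn{k_A, k_i}) and is evaluated by a positive-term
#' log-space series rather than the cancellation-prone alternating form.
#'
#' The aggregate FAT density is \eqn{f_M(t) = \sum_i k_i\, p_{N_i}(t)} and
#' the mean is \eqn{(1 + \sum_i N_i)/k_A}, obtained by first-step analysis
#' (choose path i with probability \eqn{k_i/k_A}, then traverse \eqn{N_i}
#' exponential stages of mean \eqn{1/k_i} each). The quadrature of the
#' density reproduces this value; see the package vignette for the
#' dimensional subtlety in alternative printed forms of this mean.
#'
#' @param sizes Integer vector of per-path intermediate counts (e.g. from
#'   [split_paths()]).
#' @param energy An [energy_config()]; path i receives
#'   \eqn{k_i = k_0 e^{-\Delta E/(N_i+1)}}.
#' @param times Optional time grid for the occupancy; default is the FAT
#'   summary grid.
#' @return A `parallel_solution` list: `occupancy` (an [occupancy_grid()]
#'   with root, per-path states `P<i>.<n>`, and `M`), `fat`
#'   (a [fat_summary()]), `k_i`, `k_A`, `sizes`.
#' @export
parallel_kinetics <- function(sizes, energy, times = NULL) {
  stopifnot(inherits(energy, "energy_config"))
  sizes <- vapply(sizes, assert_count, integer(1L), name = "sizes", lower = 1L)
  ki <- energy$k0 * exp(-energy$delta_E / (sizes + 1))
  kA <- sum(ki)
  mfat <- (1 + sum(sizes)) / kA
  if (length(sizes) == 1L) {
    # single path: the chain solution (k_i = k_A is the removable
    # singularity of the branched formulas)
    fs <- fat_mfat_chain(ki, sizes, times = times)
    occ <- erlang_occupancy(ki, sizes, times %||% fs$times)
    return(structure(list(occupancy = occ, fat = fs, k_i = ki, k_A = kA,
                          sizes = sizes), class = "parallel_solution"))
  }
  dens <- function(t) {
    f <- 0
    for (i in seq_along(sizes))
      f <- f + ki[i] * hypoexp_stage_occ(kA, ki[i], sizes[i], t)
    f
  }
  fs <- fat_summary(dens, mfat = mfat, times = NULL)
  tt <- times %||% fs$times
  cols <- list(root = exp(-kA * tt))
  map <- "E"
  for (i in seq_along(sizes)) {
    for (n in seq_len(sizes[i])) {
      cols[[paste0("P", i, ".", n)]] <- hypoexp_stage_occ(kA, ki[i], n, tt)
      map <- c(map, "P")
    }
  }
  probs <- do.call(cbind, cols)
  pM <- pmin(pmax(1 - rowSums(probs), 0), 1)
  probs <- cbind(probs, M = pM)
  occ <- occupancy_grid(tt, probs, colnames(probs), c(map, "M"))
  structure(list(occupancy = occ, fat = fs, k_i = ki, k_A = kA,
                 sizes = sizes), class = "parallel_solution")
}

#' Layered kinetics
#'
#' Occupancy and first-arrival-time solution for the layered topology: the
#' root fans out into the `N_L1` first-layer states (aggregate exit rate
#' \eqn{N_{L1} k}), after which the cell crosses one layer per step at
#' rate \eqn{k = k_0 e^{-\Delta E/(N_{ly}+1)}}. Only layer-aggregate
#' occupancy is computed; the printed formulas depend on
#' \eqn{(N_{L1}, N_{ly}, k)} only, and per-state detail is available from
#' the stochastic simulator. MFAT \eqn{= (N_{ly} + 1/N_{L1})/k}.
#'
#' @param N_int Total intermediate states.
#' @param N_ly Number of layers, 1 <= N_ly <= N_int.
#' @param energy An [energy_config()].
#' @param times Optional time grid.
#' @return A `layered_solution` list: `occupancy` (root, layers
#'   `L1..L<N_ly>`, `M`), `fat`, `k`, `N_L1`, `N_ly`, `layer_sizes`.
#' @export
layered_kinetics <- function(N_int, N_ly, energy, times = NULL) {
  stopifnot(inherits(energy, "energy_config"))
  sl <- split_layers(N_int, N_ly)
  k <- energy$k0 * exp(-energy$delta_E / (N_ly + 1))
  a <- sl$N_L1 * k
  mfat <- (N_ly + 1 / sl$N_L1) / k
  if (sl$N_L1 == 1L) {
    # one state per layer: plain chain (removable singularity at a = k)
    fs <- fat_mfat_chain(k, N_ly, times = times)
    occ <- erlang_occupancy(k, N_ly, times %||% fs$times)
    return(structure(list(occupancy = occ, fat = fs, k = k, N_L1 = 1L,
                          N_ly = N_ly, layer_sizes = sl$sizes),
                     class = "layered_solution"))
  }
  # layer aggregate carries the full flux: p_L_i = (a/k) * stage occupancy
  dens <- function(t) k * (a / k) * hypoexp_stage_occ(a, k, N_ly, t)
  fs <- fat_summary(dens, mfat = mfat, times = NULL)
  tt <- times %||% fs$times
  probs <- cbind(root = exp(-a * tt))
  for (i in seq_len(N_ly))
    probs <- cbind(probs, (a / k) * hypoexp_stage_occ(a, k, i, tt))
  colnames(probs) <- c("root", paste0("L", seq_len(N_ly)))
  pM <- pmin(pmax(1 - rowSums(probs), 0), 1)
  probs <- cbind(probs, M = pM)
  occ <- occupancy_grid(tt, probs, colnames(probs),
                        c("E", rep("P", N_ly), "M"))
  structure(list(occupancy = occ, fat = fs, k = k, N_L1 = sl$N_L1,
                 N_ly = N_ly, layer_sizes = sl$sizes),
            class = "layered_solution")
}

#' Compare parallel and layered topologies across energy barriers
#'
#' For a fixed intermediate-state count and branch count, evaluates the
#' parallel MFAT (branches = paths) and layered MFAT (branches = layers)
#' over a barrier grid and brackets any sign change of their difference.
#' At low barriers the parallel topology completes the transition faster;
#' at high barriers the order reverses, with a single crossing in between
#' for comparable topologies.
#'
#' @param N_int Total intermediate states.
#' @param N_branch Number of paths / layers.
#' @param delta_E Numeric vector of barriers.
#' @param k0 Attempt rate, 1/day (fixed across the grid).
#' @return List with `table` (delta_E, mfat_parallel, mfat_layered, diff)
#'   and `crossings` (data.frame of bracketing intervals of sign changes;
#'   zero rows if none).
#' @export
compare_topologies <- function(N_int, N_branch, delta_E, k0 = 1) {
  if (!length(delta_E)) stop_domain("delta_E grid must be nonempty")
  sizes <- split_paths(N_int, N_branch)
  sl <- split_layers(N_int, N_branch)
  mfp <- vapply(delta_E, function(dE) {
    ki <- k0 * exp(-dE / (sizes + 1))
    (1 + N_int) / sum(ki)
  }, numeric(1L))
  mfl <- vapply(delta_E, function(dE) {
    k <- k0 * exp(-dE / (N_branch + 1))
    (N_branch + 1 / sl$N_L1) / k
  }, numeric(1L))
  d <- mfp - mfl
  s <- sign(d)
  idx <- which(s[-1L] * s[-length(s)] < 0)
  crossings <- data.frame(lower = delta_E[idx], upper = delta_E[idx + 1L])
  list(table = data.frame(delta_E = as.numeric(delta_E),
                          mfat_parallel = mfp, mfat_layered = mfl,
                          diff = d),
       crossings = crossings)
}
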