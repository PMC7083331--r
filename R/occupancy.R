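#' Occupancy grid: per-state probability versus time
#'
#' Container for the solution of a master equation: a matrix of state
#' probabilities on a time grid, together with a macrostate map assigning
#' each microstate to one of the observable phenotypes E (epithelial),
#' P (partial EMT) or M (mesenchymal).
#'
#' @param times Time grid, days.
#' @param probs Matrix, `length(times)` rows, one column per state.
#' @param state_names Character vector of state names (column names).
#' @param macrostate_map Character vector, one of "E", "P", "M" per state.
#' @return An object of class `occupancy_grid`.
#' @export
occupancy_grid <- function(times, probs, state_names, macrostate_map) {
  times <- assert_times(times)
  probs <- as.matrix(probs)
  if (nrow(probs) != length(times))
    stop_domain("`probs` must have one row per time point")
  if (length(state_names) != ncol(probs) ||
      length(macrostate_map) != ncol(probs))
    stop_domain("state_names/macrostate_map length must match state count")
  if (!all(macrostate_map %in% c("E", "P", "M")))
    stop_domain("macrostate_map entries must be 'E', 'P' or 'M'")
  colnames(probs) <- state_names
  structure(list(times = times, probs = probs,
                 state_names = state_names,
                 macrostate_map = macrostate_map),
            class = "occupancy_grid")
}

#' Validate conservation and range of an occupancy grid
#'
#' Checks that every probability lies in `[0, 1]` (within `tol`) and that
#' each row sums to 1 within `tol`.
#'
#' @param grid An [occupancy_grid()].
#' @param tol Tolerance, default 1e-8.
#' @return `grid`, invisibly; errors on violation.
#' @export
validate_occupancy <- function(grid, tol = 1e-8) {
  stopifnot(inherits(grid, "occupancy_grid"))
  p <- grid$probs
  if (any(p < -tol) || any(p > 1 + tol))
    stop_domain("occupancy probabilities outside [0, 1]")
  if (any(abs(rowSums(p) - 1) > tol))
    stop_domain("occupancy rows do not sum to 1 within tolerance ", tol)
  invisible(grid)
}

#' Macrostate fractions from an occupancy grid
#'
#' Aggregates microstate probabilities into the three observable
#' macrostates using the grid's macrostate map.
#'
#' @param grid An [occupancy_grid()].
#' @param percent If `TRUE`, return percentages (0-100) instead of
#'   fractions.
#' @return Matrix with columns `E`, `P`, `M` and one row per time point.
#' @export
macro_fractions <- function(grid, percent = FALSE) {
  stopifnot(inherits(grid, "occupancy_grid"))
  out <- sapply(c("E", "P", "M"), function(s) {
    idx <- which(grid$macrostate_map == s)
    if (length(idx) == 0L) rep(0, length(grid$times))
    else rowSums(grid$probs[, idx, drop = FALSE])
  })
  out <- matrix(out, nrow = length(grid$times),
                dimnames = list(NULL, c("E", "P", "M")))
  if (percent) out * 100 else out
}

#' @export
as.data.frame.occupancy_grid <- function(x, ...) {
  data.frame(time = x$times, x$probs, check.names = FALSE)
}

#' Write an occupancy grid as a delimited table
#'
#' Tab-separated text, header included, full double precision.
#'
#' @param grid An [occupancy_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(grid, path) {
  df <- as.data.frame(grid)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- first-arrival-time summaries --------------------------------------

#' First-arrival-time summary
#'
#' Holds the first-arrival-time (FAT) density to the absorbing mesenchymal
#' state on a time grid, its mean (MFAT, computed from the closed form),
#' and Simpson-rule quadrature cross-checks of the normalization and mean.
#'
#' @param density_fun Vectorized density function of time (1/day).
#' @param mfat Closed-form mean first arrival time, days.
#' @param times Optional explicit grid; by default a uniform grid on
#'   `[0, max(50 * mfat, 10)]` with 4097 points, which carries all but
#'   ~1e-9 of the density mass for the phase-type densities used here.
#' @return An object of class `fat_summary` with fields `times`, `density`,
#'   `mfat`, `mfat_quad`, `norm_quad` and the density function itself.
#' @export
fat_summary <- function(density_fun, mfat, times = NULL) {
  assert_scalar_number(mfat, "mfat", lower = 0, strict_lower = TRUE)
  if (is.null(times)) {
    upper <- max(50 * mfat, 10)
    times <- seq(0, upper, length.out = 4097L)
  } else {
    times <- assert_times(times)
  }
  dens <- density_fun(times)
  if (any(!is.finite(dens)) || any(dens < -1e-12))
    stop_domain("FAT density must be finite and non-negative")
  dens <- pmax(dens, 0)
  structure(list(times = times, density = dens, mfat = mfat,
                 norm_quad = simpson_quad(times, dens),
                 mfat_quad = simpson_quad(times, times * dens),
                 density_fun = density_fun),
            class = "fat_summary")
}

# composite Simpson on a uniform grid with an odd number of points;
# falls back to trapezoid for non-uniform grids
simpson_quad <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  if (n >= 3L && n %% 2L == 1L && max(abs(h - h[1L])) < 1e-9 * h[1L]) {
    w <- rep(c(4, 2), length.out = n - 2L)
    h[1L] / 3 * (y[1L] + y[n] + sum(w * y[2:(n - 1L)]))
  } else {
    sum((y[-1L] + y[-n]) / 2 * h)
  }
}

#' @export
as.data.frame.fat_summary <- function(x, ...) {
  data.frame(time = x$times, density = x$density)
}

#' Write a FAT summary as a delimited table
#'
#' Tab-separated columns `time`, `density`; the mean is stored in a
#' comment header line.
#'
#' @param fs A [fat_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fat <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mfat_days = %.17g", fs$mfat), con)
  writeLines("time\tdensity", con)
  writeLines(sprintf("%.17g\t%.17g", fs$times, fs$density), con)
  invisible(path)
}

# ---- hypoexponential stage occupancy -----------------------------------

# Occupancy at time t of the n-th stage (n >= 1) of a sequence entered at
# rate `k_in` from a root state whose *total* exit rate is `a`, with all
# subsequent steps at rate `k_in`. This is the building block for both the
# parallel-path occupancy (root exit k_A, per-path entry/step rate k_i) and
# the layered occupancy (root exit N_L1*k, layer steps at k; the layer
# aggregate carries the full flux, handled by the caller's a/k prefactor).
#
# The textbook closed form subtracts truncated exponential sums and is
# numerically catastrophic for large |a - k_in| * t; instead the occupancy
# is written as a convolution and expanded as a positive-term series that
# is summed in log space:
#   a > k:  p_n = k^n t^n e^{-a t} / (n-1)! * sum_m (bt)^m / (m! (m+n)),
#           b = a - k
#   a < k:  p_n = k^n e^{-k t} * sum_m c^m t^{m+n} / (m+n)!,  c = k - a
#   a == k: p_n = dpois(n, k t)   (uniform-chain / Erlang limit)
hypoexp_stage_occ <- function(a, k_in, n, times) {
  stopifnot(a > 0, k_in > 0, n >= 1)
  t <- as.numeric(times)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (!length(tp)) return(out)
  if (abs(a - k_in) <= 1e-12 * max(a, k_in)) {
    out[pos] <- stats::dpois(n, k_in * tp)
    return(out)
  }
  if (a > k_in) {
    b <- a - k_in
    xmax <- max(b * tp)
    M <- ceiling(xmax + 12 * sqrt(xmax + 1) + 60)
    m <- 0:M
    # log term_m(t) = m log(bt) - lgamma(m+1) - log(m+n)
    lt <- outer(m, log(b * tp)) - lgamma(m + 1) - log(m + n)
    colmax <- apply(lt, 2L, max)
    logS <- colmax + log(colSums(exp(sweep(lt, 2L, colmax))))
    lp <- n * log(k_in * tp) - lgamma(n) - a * tp + logS
    out[pos] <- exp(lp)
  } else {
    cc <- k_in - a
    xmax <- max(cc * tp)
    M <- ceiling(xmax + 12 * sqrt(xmax + 1) + 60)
    m <- 0:M
    # log term_m(t) = m log(c) + (m+n) log(t) - lgamma(m+n+1)
    lt <- outer(m + n, log(tp)) + (m * log(cc) - lgamma(m + n + 1))
    colmax <- apply(lt, 2L, max)
    logS <- colmax + log(colSums(exp(sweep(lt, 2L, colmax))))
    lp <- n * log(k_in) - k_in * tp + logS
    out[pos] <- exp(lp)
  }
  out
}
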