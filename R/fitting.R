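#' Population macrostate time-course data
#'
#' Observed (or synthetic) percentages of cells in the three observable
#' macrostates over time. Fractions are on the percent scale (0-100) and
#' each row must sum to 100 within 0.5.
#'
#' @param times Sampling times, days; strictly increasing.
#' @param fractions Matrix (or data.frame) with columns `E`, `P`, `M`,
#'   percent.
#' @param n_cells Optional sampling depth per time point.
#' @param meta Optional named list of metadata.
#' @return An object of class `timecourse_data`.
#' @export
timecourse_data <- function(times, fractions, n_cells = NULL, meta = list()) {
  times <- assert_times(times)
  if (any(diff(times) <= 0))
    stop_domain("`times` must be strictly increasing")
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != 3L || nrow(fractions) != length(times))
    stop_domain("`fractions` must be length(times) x 3 (E, P, M)")
  colnames(fractions) <- c("E", "P", "M")
  if (any(abs(rowSums(fractions) - 100) > 0.5))
    stop_domain("macrostate fractions must sum to 100 (percent) within 0.5")
  structure(list(times = times, fractions = fractions,
                 n_cells = n_cells, meta = meta),
            class = "timecourse_data")
}

#' RMSE between model macrostate fractions and data
#'
#' Root mean squared error pooled with equal weight over all three
#' macrostates and all time points, on the percent scale.
#'
#' @param model An [occupancy_grid()] evaluated at exactly the data's time
#'   points (no interpolation is performed), or a numeric matrix of
#'   percent fractions with columns E, P, M.
#' @param data A [timecourse_data()].
#' @return RMSE in percentage points.
#' @export
rmse_score <- function(model, data) {
  stopifnot(inherits(data, "timecourse_data"))
  if (inherits(model, "occupancy_grid")) {
    if (length(model$times) != length(data$times) ||
        max(abs(model$times - data$times)) > 1e-9)
      stop_domain("model time grid does not match the data time points")
    mf <- macro_fractions(model, percent = TRUE)
  } else {
    mf <- as.matrix(model)
    if (nrow(mf) != length(data$times) || ncol(mf) != 3L)
      stop_domain("model matrix must be length(times) x 3 (percent)")
  }
  sqrt(mean((mf - data$fractions)^2))
}

# macrostate map for a chain with N_E epithelial and N_P partial
# microstates ahead of the absorbing state
microstate_map <- function(N_E, N_P) {
  c(rep("E", N_E), rep("P", N_P), "M")
}

# occupancy of the (N_E, N_P) irreversible chain at the data's times
chain_model_fractions <- function(N_E, N_P, k, times) {
  g <- erlang_occupancy(k, N_E + N_P - 1L, times,
                        macrostate_map = microstate_map(N_E, N_P))
  macro_fractions(g, percent = TRUE)
}

#' Fit the irreversible hidden-microstate chain to a time course
#'
#' Grid search over the number of epithelial (`N_E`) and partial-EMT
#' (`N_P`) microstates; at each grid point the common step rate `k` is
#' fitted by bounded scalar minimization of the pooled RMSE
#' (log-parameterized [stats::optimize()]). `N_P = 0` yields the two-state
#' model (no partial macrostate). Grid ties are broken toward smaller
#' `N_E + N_P`, then smaller `N_E`.
#'
#' @param data A [timecourse_data()].
#' @param N_E_range Integer vector of epithelial microstate counts
#'   (default 1:10).
#' @param N_P_range Integer vector of partial microstate counts
#'   (default 0:10).
#' @param k_bounds Length-2 positive bounds for `k`, 1/day
#'   (default `c(1e-3, 1e3)`).
#' @return A `fit_result` list: `N_E`, `N_P`, `rates` (named `k`), `rmse`,
#'   `score_grid` (data.frame with per-cell `N_E`, `N_P`, `k`, `rmse`,
#'   `boundary` flag), `boundary`.
#' @export
fit_irreversible <- function(data, N_E_range = 1:10, N_P_range = 0:10,
                             k_bounds = c(1e-3, 1e3)) {
  stopifnot(inherits(data, "timecourse_data"))
  if (!length(N_E_range) || !length(N_P_range))
    stop_domain("grid ranges must be nonempty")
  if (length(k_bounds) != 2L || any(k_bounds <= 0) || diff(k_bounds) <= 0)
    stop_domain("k_bounds must be positive and increasing")
  grid <- expand.grid(N_E = as.integer(N_E_range),
                      N_P = as.integer(N_P_range),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$N_E >= 1L & grid$N_P >= 0L, , drop = FALSE]
  # parsimony order: the first strict minimum encountered wins ties
  grid <- grid[order(grid$N_E + grid$N_P, grid$N_E), , drop = FALSE]
  lb <- log(k_bounds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    NE <- grid$N_E[i]; NP <- grid$N_P[i]
    obj <- function(lk)
      rmse_score(chain_model_fractions(NE, NP, exp(lk), data$times), data)
    opt <- tryCatch(stats::optimize(obj, interval = lb, tol = 1e-10),
                    error = function(e) NULL)
    if (is.null(opt))
      return(data.frame(N_E = NE, N_P = NP, k = NA_real_, rmse = Inf,
                        boundary = NA))
    bnd <- min(opt$minimum - lb[1L], lb[2L] - opt$minimum) < 1e-6
    data.frame(N_E = NE, N_P = NP, k = exp(opt$minimum),
               rmse = opt$objective, boundary = bnd)
  })
  score <- do.call(rbind, rows)
  best <- score[which.min(score$rmse), ]
  structure(list(N_E = best$N_E, N_P = best$N_P,
                 rates = c(k = best$k), rmse = best$rmse,
                 boundary = isTRUE(best$boundary), score_grid = score,
                 model = "irreversible"),
            class = "fit_result")
}

#' Fit the reversible hidden-microstate chain to a time course
#'
#' As [fit_irreversible()], but the chain allows backward transitions at
#' rate `k_bwd` (the absorbing mesenchymal state still has no backward
#' flow) and each grid point performs a 2-parameter bounded optimization
#' (log-parameterized L-BFGS-B, 3 starts) of `(k_fwd, k_bwd)`. Setting the
#' upper `k_bwd` bound to 0 fixes `k_bwd = 0` and reduces to the
#' irreversible fit.
#'
#' @param data A [timecourse_data()].
#' @param N_E_range,N_P_range Grid ranges, as in [fit_irreversible()].
#' @param k_bounds Bounds for the forward rate (default `c(1e-3, 1e2)`;
#'   the uniformization solver cost grows with rate x horizon and
#'   day-scale data never needs faster rates — widen explicitly if
#'   required).
#' @param k_bwd_bounds Bounds for the backward rate (default
#'   `c(1e-6, 1e2)`; use `c(0, 0)` to pin it at zero).
#' @return A `fit_result` with `rates = c(k_fwd, k_bwd)`.
#' @export
fit_reversible <- function(data, N_E_range = 1:10, N_P_range = 0:10,
                           k_bounds = c(1e-3, 1e2),
                           k_bwd_bounds = c(1e-6, 1e2)) {
  stopifnot(inherits(data, "timecourse_data"))
  fix_bwd <- all(k_bwd_bounds == 0)
  grid <- expand.grid(N_E = as.integer(N_E_range),
                      N_P = as.integer(N_P_range),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$N_E >= 1L & grid$N_P >= 0L, , drop = FALSE]
  grid <- grid[order(grid$N_E + grid$N_P, grid$N_E), , drop = FALSE]
  model_frac <- function(NE, NP, kf, kb) {
    g <- reversible_occupancy(kf, kb, NE + NP + 1L, data$times,
                              macrostate_map = microstate_map(NE, NP))
    macro_fractions(g, percent = TRUE)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    NE <- grid$N_E[i]; NP <- grid$N_P[i]
    if (fix_bwd) {
      obj1 <- function(lk)
        rmse_score(model_frac(NE, NP, exp(lk), 0), data)
      opt <- stats::optimize(obj1, interval = log(k_bounds), tol = 1e-10)
      return(data.frame(N_E = NE, N_P = NP, k_fwd = exp(opt$minimum),
                        k_bwd = 0, rmse = opt$objective, converged = TRUE))
    }
    obj <- function(lp)
      rmse_score(model_frac(NE, NP, exp(lp[1L]), exp(lp[2L])), data)
    lo <- log(c(k_bounds[1L], k_bwd_bounds[1L]))
    hi <- log(c(k_bounds[2L], k_bwd_bounds[2L]))
    starts <- list(c(log(1), log(0.1)),
                   c(log(5), log(0.5)),
                   c(mean(lo), mean(lo)))
    best <- NULL
    ok <- FALSE
    for (st in starts) {
      st <- pmin(pmax(st, lo), hi)
      o <- tryCatch(stats::optim(st, obj, method = "L-BFGS-B",
                                 lower = lo, upper = hi,
                                 control = list(factr = 1e4)),
                    error = function(e) NULL)
      if (!is.null(o)) {
        ok <- ok || o$convergence == 0L
        if (is.null(best) || o$value < best$value) best <- o
      }
    }
    if (is.null(best))
      return(data.frame(N_E = NE, N_P = NP, k_fwd = NA_real_,
                        k_bwd = NA_real_, rmse = Inf, converged = FALSE))
    data.frame(N_E = NE, N_P = NP, k_fwd = exp(best$par[1L]),
               k_bwd = exp(best$par[2L]), rmse = best$value,
               converged = ok)
  })
  score <- do.call(rbind, rows)
  best <- score[which.min(score$rmse), ]
  structure(list(N_E = best$N_E, N_P = best$N_P,
                 rates = c(k_fwd = best$k_fwd, k_bwd = best$k_bwd),
                 rmse = best$rmse, boundary = FALSE, score_grid = score,
                 model = "reversible"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("hidden-microstate %s fit\n", x$model))
  cat(sprintf("  N_E = %d, N_P = %d\n", x$N_E, x$N_P))
  cat("  rates (1/day):",
      paste(sprintf("%s = %.6g", names(x$rates), x$rates), collapse = ", "),
      "\n")
  cat(sprintf("  RMSE = %.4g percent\n", x$rmse))
  if (isTRUE(x$boundary)) cat("  WARNING: rate at optimization boundary\n")
  invisible(x)
}

#' Read a macrostate time course from delimited text
#'
#' Expects header `time,frac_E,frac_P,frac_M` (comma- or tab-separated),
#' time in days, fractions in percent; lines starting with `#` are
#' metadata comments and are preserved in `meta$header`.
#'
#' @param path File path.
#' @return A [timecourse_data()].
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)],
                          header = TRUE, sep = "", fill = FALSE)
  if (ncol(df) == 1L)  # comma-separated
    df <- utils::read.table(text = lines[!grepl("^#", lines)],
                            header = TRUE, sep = ",")
  need <- c("time", "frac_E", "frac_P", "frac_M")
  if (!all(need %in% names(df)))
    stop_domain("time course file must have columns ",
                paste(need, collapse = ", "))
  timecourse_data(df$time, df[, c("frac_E", "frac_P", "frac_M")],
                  meta = list(header = hdr))
}

#' Write a macrostate time course as delimited text
#'
#' Comma-separated with header `time,frac_E,frac_P,frac_M`; metadata are
#' written as leading `#` comment lines.
#'
#' @param data A [timecourse_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(data, path) {
  stopifnot(inherits(data, "timecourse_data"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(data$meta))
    if (nm != "header")
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(data$meta[[nm]]), collapse = " ")), con)
  writeLines("time,frac_E,frac_P,frac_M", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                     data$times, data$fractions[, "E"],
                     data$fractions[, "P"], data$fractions[, "M"]), con)
  invisible(path)
}
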