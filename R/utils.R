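# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`", name, "` must be a single finite number")
  if (strict_lower && x <= lower)
    stop_domain("`", name, "` must be > ", lower)
  if (!strict_lower && x < lower)
    stop_domain("`", name, "` must be >= ", lower)
  if (x > upper)
    stop_domain("`", name, "` must be <= ", upper)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_domain("`", name, "` must be a single integer")
  if (x < lower)
    stop_domain("`", name, "` must be >= ", lower)
  invisible(as.integer(x))
}

assert_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop_domain("`times` must be a non-empty finite numeric vector")
  if (any(times < 0))
    stop_domain("`times` must be >= 0 (days)")
  invisible(as.numeric(times))
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
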