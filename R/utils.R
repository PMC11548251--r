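stop_input <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             allow_zero_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (allow_zero_lower) x >= lower else x > lower
  if (!lo_ok || x > upper)
    stop_input(sprintf("`%s` out of range", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_input(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_fixed_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

l2norm <- function(x) sqrt(sum(x * x))

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}
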