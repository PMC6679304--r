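# shared internal helpers

sigmoid <- function(z) 1 / (1 + exp(-z))

# rolling sum of `v` over windows of width `w`, one value per start position
rollsum <- function(v, w) {
  cs <- cumsum(c(0, v))
  cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]
}

# Lehmer-style derivation of per-component seeds from one master seed.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + index) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

stop_if_not_count <- function(x, name, min = 1) {
  if (!is_count(x, min)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}
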