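# internal helpers shared across modules

# Derive a per-component seed from one root seed. Keeps every derived value
# a valid 32-bit integer and distinct across small offsets.
derive_seed <- function(seed, offset) {
  seed <- as.double(seed)
  as.integer((seed * 7919 + offset * 104729) %% 2147483629)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
}

default_labels <- function(n) {
  sprintf("elem_%04d", seq_len(n))
}
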