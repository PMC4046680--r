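# Shared validation and seed-derivation helpers.

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

# Deterministic 31-bit seed derived from a base seed plus arbitrary
# tokens (integers or strings); used so each simulated dataset and each
# SNP set gets its own reproducible stream.
.derive_seed <- function(seed, ...) {
  m <- 2147483563
  h <- as.double(seed) %% m
  for (tok in list(...)) {
    if (is.character(tok)) tok <- utf8ToInt(tok)
    for (v in as.double(tok)) {
      h <- (h * 69069 + v + 1) %% m
    }
  }
  as.integer(h)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}
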