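# Internal helpers shared across modules.

# stopifnot-style check with a clean message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "iptlquant_error")
  invisible(TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric", name))
  if (!allow_na && anyNA(x)) abort(sprintf("`%s` must not contain NA", name))
  bad <- x < lower | x > upper
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("`%s` must lie in [%s, %s]", name, lower, upper))
  }
  invisible(TRUE)
}

# Derive a child seed from a base seed and a stream label so that the
# different generator outputs are independent but jointly reproducible.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  check_number(seed, "seed")
  h <- sum(utf8ToInt(as.character(stream)) * (31L^(seq_along(utf8ToInt(as.character(stream))) %% 7L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
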