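#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (`0.125 -> 0.13` at 2 digits),
#' independent of the IEEE round-half-even rule used by [base::round()].
#' All reported percentages in metric tables go through this function;
#' internal computation stays in full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(88.575, 2) # 88.58, where round() would give 88.57 or 88.58
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Clamp values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit string hash (polynomial rolling hash, mod 2^31 - 1).
# Used to derive per-candidate training seeds from a canonical config string;
# must be stable across platforms, so it avoids serialize()/locale effects.
stable_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  codes <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (k in codes) h <- (h * 31 + k) %% m
  as.integer(h)
}

# Derive a child seed below 2^31 from a base seed and a key string.
derive_seed <- function(base_seed, key) {
  as.integer((as.numeric(base_seed) + stable_hash(key)) %% 2147483647)
}

# Format a number the way config files print it (no scientific noise).
format_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 12)

# Abort unless a stage artifact exists, naming the command that produces it.
require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run `%s` first", path, producer),
         call. = FALSE)
  }
  invisible(path)
}
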