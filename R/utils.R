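#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop2(name, " must be finite numeric")
  }
  if (open) {
    if (any(x <= 0 | x >= 1)) stop2(name, " must lie strictly inside (0, 1)")
  } else {
    if (any(x < 0 | x > 1)) stop2(name, " must lie in [0, 1]")
  }
  invisible(x)
}

variant_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Deterministic per-stage seed derivation from a single run seed.
# Stage seeds are base * 131 + counter, folded into [0, 2^31).
stage_seed <- function(seed, stage) {
  s <- (as.numeric(seed) * 131 + stage) %% 2147483647
  as.integer(s)
}

# Balanced bin assignment: n items in `order` into n_bins groups whose sizes
# differ by at most one, smallest values first.
balanced_bins <- function(ord, n_bins) {
  n <- length(ord)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}
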