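# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Reverse complement of a base string (gaps and N pass through).
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  chars <- rev(seq_chars(x))
  paste(comp[chars], collapse = "")
}

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, restoring
# the caller's RNG state afterwards; otherwise evaluate as-is.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive a reproducible child seed (kept well below .Machine$integer.max).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + 12345 * k) %% 2147483587)
}

# Edge-to-edge gap between two half-open intervals [s1, e1) and [s2, e2);
# 0 when they overlap or abut.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer.", name))
  }
}
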