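# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` uses the session RNG as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

log_note <- function(...) message(sprintf(...))

dna_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_strand_ambiguous <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}
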