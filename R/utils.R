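# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# OTHER_BASES[i, ] = the three bases that are not DNA_BASES[i]
OTHER_BASES <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                        character(3)))

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package go
# through this so a single integer seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-stage seed from a base seed with a documented counter scheme;
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Fast columnwise identity between two equal-length strings.
hamming_identity <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  mean(ra == rb)
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Reverse-complement without splitting (vector-safe for long strings).
revcomp_fast <- function(s) {
  x <- rev(charToRaw(s))
  comp <- chartr("ACGTacgt", "TGCAtgca", rawToChar(x))
  comp
}

# All k-mers of a string as a character vector (1-based start positions).
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

stop_if_not_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
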