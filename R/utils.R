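# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1], got %s", name,
          paste(format(x), collapse = ","))
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stopf("'%s' must be non-negative", name)
  invisible(x)
}

# run expr with the RNG seeded at `seed`, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic child seed stream: distinct, reproducible sub-seeds below 2^31
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 1664525 * as.numeric(index)) %% 2147483587
}

# split a string into single characters (fast path for long sequences)
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

collapse0 <- function(x) paste(x, collapse = "")

# numeric k-mer codes at every start position of a nucleotide string.
# Codes fit exactly in a double for k <= 26 (4^26 < 2^53).
kmer_codes <- function(residues, k) {
  n <- nchar(residues)
  if (n < k) return(numeric(0))
  v <- utf8ToInt(residues)
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 0L
  code[v == utf8ToInt("C")] <- 1L
  code[v == utf8ToInt("G")] <- 2L
  code[v == utf8ToInt("T")] <- 3L
  bad <- !(v %in% utf8ToInt("ACGT"))
  w <- 4^((k - 1):0)
  out <- as.numeric(stats::filter(code, w, method = "convolution",
                                  sides = 1))
  out <- out[k:n]
  if (any(bad)) {
    # positions whose window touches a non-ACGT character are invalid
    badpos <- which(bad)
    hit <- unique(unlist(lapply(badpos, function(p) {
      lo <- max(1L, p - k + 1L)
      hi <- min(n - k + 1L, p)
      if (lo <= hi) lo:hi else integer(0)
    })))
    out[hit] <- NA_real_
  }
  out
}
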