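# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Reverse complement for plain character vectors (ACGTN only).
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Enumerate all read windows of length k over one replicon sequence.
# Returns 1-based start positions, forward window strings, canonical forms
# (NA where the window contains non-ACGT), and wrap flags. Circular
# replicons yield one window per position (L windows); linear ones
# L - k + 1. Strings are upper-cased.
.enumWindows <- function(seq, k, circular) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  k <- as.integer(k)
  if (k > L)
    stop("read length (", k, ") exceeds replicon length (", L, ")")
  if (circular && k > 1L) {
    ext <- paste0(s, substr(s, 1L, k - 1L))
    n <- L
  } else {
    ext <- s
    n <- L - k + 1L
  }
  starts <- seq_len(n)
  fwd <- substring(ext, starts, starts + k - 1L)
  nExt <- nchar(ext)
  rcExt <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ext)))
  rc <- substring(rcExt, nExt - starts - k + 2L, nExt - starts + 1L)
  canonical <- pmin(fwd, rc)
  excluded <- grepl("[^ACGT]", fwd)
  canonical[excluded] <- NA_character_
  wraps <- if (circular && k > 1L) starts > L - k + 1L else rep(FALSE, n)
  list(starts = starts, fwd = fwd, canonical = canonical,
       excluded = excluded, wraps = wraps, length = L)
}

# Extended (junction-crossing) sequence string for a replicon.
.extSeq <- function(seq, k, circular) {
  s <- toupper(as.character(seq))
  if (circular && k > 1L) paste0(s, substr(s, 1L, k - 1L)) else s
}

# Positive modulo for 1-based circular coordinates.
.mod1 <- function(x, L) ((x - 1L) %% L) + 1L

.isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
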