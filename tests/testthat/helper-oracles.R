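# Independent brute-force oracles, deliberately implemented with plain R
# string/vector operations (no Biostrings, no shared code with the package
# internals) so they can vouch for the k-mer classification, gene
# attribution and mismatch-search paths on small fixtures.

# reverse complement via chartr + character reversal
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all read windows of length k (1-based starts), wrapping if circular
oracle_windows <- function(s, k, circular) {
  L <- nchar(s)
  if (circular) {
    ext <- paste0(s, substr(s, 1L, k - 1L))
    n <- L
  } else {
    ext <- s
    n <- L - k + 1L
  }
  substring(ext, seq_len(n), seq_len(n) + k - 1L)
}

# per-window classification of one organism's windows against a pool:
# "excluded" (non-ACGT), "intra" (>= 2 loci within own organism, strand-
# collapsed), "inter" (unique within own organism, >= 2 loci in the pool),
# else "unique". O(n^2), all-pairs including reverse complements.
oracle_classify <- function(org_wins, other_wins) {
  all_wins <- c(org_wins, other_wins)
  all_rc <- rc_chr(all_wins)
  org_rc <- rc_chr(org_wins)
  n_org <- length(org_wins)
  cls <- character(n_org)
  for (i in seq_len(n_org)) {
    w <- org_wins[i]
    if (grepl("[^ACGT]", w)) {
      cls[i] <- "excluded"
      next
    }
    wrc <- org_rc[i]
    own <- sum(org_wins == w | org_rc == w)        # wins[j] %in% {w, rc(w)}
    if (own >= 2L) {
      cls[i] <- "intra"
    } else {
      pool <- sum(all_wins == w | all_rc == w)
      cls[i] <- if (pool >= 2L) "inter" else "unique"
    }
  }
  cls
}

# integer matrix of window byte codes for fast Hamming distances
oracle_window_mat <- function(wins) {
  vapply(wins, function(w) utf8ToInt(w), integer(nchar(wins[1L])),
         USE.NAMES = FALSE)
}

# exhaustive scan: all loci of one replicon within Hamming distance
# max_mm of the read, on either strand, strand-collapsed with min mismatch
oracle_hits <- function(read, seq_chr, k, circular, max_mm) {
  wins <- oracle_windows(seq_chr, k, circular)
  m <- oracle_window_mat(wins)
  q1 <- utf8ToInt(read)
  q2 <- utf8ToInt(rc_chr(read))
  d1 <- colSums(m != q1)
  d2 <- colSums(m != q2)
  mm <- pmin(d1, d2)
  keep <- mm <= max_mm
  data.frame(start = seq_along(wins)[keep],
             strand = ifelse(d1 <= d2, "+", "-")[keep],
             mismatches = as.integer(mm[keep]))
}

# unique-best-match resolution over a whole pool, via oracle_hits
oracle_resolve <- function(read, seqs_chr, organisms_chr, circular, max_mm) {
  hits <- list()
  for (i in seq_along(seqs_chr)) {
    h <- oracle_hits(read, seqs_chr[i], nchar(read), circular[i], max_mm)
    if (nrow(h)) {
      h$organism <- organisms_chr[i]
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(list(status = "unmapped"))
  hits <- do.call(rbind, hits)
  m_star <- min(hits$mismatches)
  best <- hits[hits$mismatches == m_star, , drop = FALSE]
  if (nrow(best) >= 2L) list(status = "ambiguous")
  else list(status = "assigned", organism = best$organism,
            start = best$start, mismatches = m_star)
}

# all window starts whose (possibly wrapping) interval intersects the
# 1-based closed gene interval [gs, ge], by direct position enumeration
oracle_gene_starts <- function(gs, ge, L, k, circular) {
  n <- if (circular) L else L - k + 1L
  keep <- logical(n)
  for (s in seq_len(n)) {
    pos <- ((s - 1L) + 0:(k - 1L)) %% L + 1L
    keep[s] <- any(pos >= gs & pos <= ge)
  }
  which(keep)
}

# random ACGT string without the package generator
oracle_random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant an exact duplicate of seq[from..from+len-1] at position `to`
oracle_plant_copy <- function(s, from, len, to) {
  unit <- substr(s, from, from + len - 1L)
  substr(s, to, to + len - 1L) <- unit
  s
}

make_pool_chr <- function(seqs_chr, organisms_chr, ids, readLength,
                          circular) {
  byorg <- split(seq_along(seqs_chr), factor(organisms_chr,
                                             levels = unique(organisms_chr)))
  lst <- lapply(byorg, function(idx)
    Biostrings::DNAStringSet(stats::setNames(seqs_chr[idx], ids[idx])))
  buildPool(lst, readLength = readLength, circular = circular)
}
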