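#' Enumerate every possible read over a replicon
#'
#' Slides a window of `readLength` bp over the forward strand with a shift
#' of one, so every locus is covered exactly once. A circular replicon of
#' length L yields exactly L reads (windows crossing the junction wrap); a
#' linear one yields `L - readLength + 1`.
#'
#' @param seq A single replicon: `DNAString`, length-1 `DNAStringSet`, or
#'   character string.
#' @param readLength Window length in bp.
#' @param circular Whether the replicon is circular (default `TRUE`).
#' @return A `data.frame` with columns `start` (1-based), `sequence`, and
#'   `wraps` (window crosses the circular junction), ordered by start.
#' @examples
#' enumerateReads("ACGTACGTAC", 4, circular = FALSE)
#' @export
enumerateReads <- function(seq, readLength, circular = TRUE) {
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  w <- .enumWindows(seq, readLength, circular)
  data.frame(start = w$starts, sequence = w$fwd, wraps = w$wraps,
             stringsAsFactors = FALSE)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, giving strand-agnostic locus matching:
#' `canonicalKmers(x) == canonicalKmers(revcomp(x))`, and the operation is
#' idempotent. K-mers containing non-ACGT characters are returned as `NA`
#' (the caller counts them as excluded rather than indexing them).
#'
#' @param x Character vector of k-mers (ACGT alphabet).
#' @return Character vector of canonical forms, `NA` where `x` contains
#'   non-ACGT characters.
#' @examples
#' canonicalKmers(c("AAAA", "TTTT", "ACGT"))
#' @export
canonicalKmers <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  out <- rep(NA_character_, length(x))
  if (any(!bad)) {
    fwd <- x[!bad]
    out[!bad] <- pmin(fwd, .revcomp(fwd))
  }
  out
}

#' Build a canonical k-mer multiplicity index
#'
#' Enumerates every window of length `k` over the given replicons (wrapping
#' circular junctions) and counts, for each canonical k-mer, the number of
#' loci at which it occurs. A locus is one start position on one replicon,
#' counted once regardless of strand (a palindromic window still counts one
#' locus). Windows containing non-ACGT characters are excluded from the
#' index and tallied in `excludedLoci`.
#'
#' @param seqs A named `DNAStringSet` (or a [PoolSpec-class], in which case
#'   `k` and `circular` default to the pool's settings).
#' @param k Window length in bp.
#' @param circular Logical, recycled over replicons.
#' @return A [KmerIndex-class] object.
#' @examples
#' buildKmerIndex(Biostrings::DNAStringSet(c(chr = "AAAAA")), k = 4,
#'                circular = FALSE)
#' @export
buildKmerIndex <- function(seqs, k = NULL, circular = TRUE) {
  if (is(seqs, "PoolSpec")) {
    if (is.null(k)) k <- readLength(seqs)
    circular <- seqs@circular
    seqs <- replicons(seqs)
  }
  if (is.null(k)) .stopf("k is required when seqs is not a PoolSpec")
  if (length(seqs) < 1L) .stopf("need at least one replicon")
  circular <- rep_len(circular, length(seqs))
  canon <- character(0)
  excluded <- 0L
  total <- 0L
  for (i in seq_along(seqs)) {
    w <- .enumWindows(seqs[[i]], k, circular[i])
    total <- total + length(w$starts)
    excluded <- excluded + sum(w$excluded)
    canon <- c(canon, w$canonical[!w$excluded])
  }
  counts <- table(canon)
  new("KmerIndex", k = as.integer(k),
      counts = stats::setNames(as.integer(counts), names(counts)),
      excludedLoci = excluded, nLoci = total)
}

#' Look up locus counts in a KmerIndex
#'
#' @param index A [KmerIndex-class].
#' @param kmers Character vector of k-mers (canonicalized internally).
#' @return Integer vector of locus counts (0 for absent k-mers, `NA` for
#'   non-ACGT queries).
#' @export
kmerCount <- function(index, kmers) {
  canon <- canonicalKmers(kmers)
  out <- index@counts[canon]
  out[is.na(out) & !is.na(canon)] <- 0L
  stats::setNames(as.integer(out), kmers)
}

# Classify every enumerated window start of every replicon in the pool.
# Returns a list keyed by replicon id, each element a character vector of
# classes ("unique", "intra", "inter", "excluded") parallel to window
# starts, plus attributes with per-organism windows counts.
.positionClasses <- function(pool) {
  seqs <- replicons(pool)
  k <- readLength(pool)
  org <- pool@organism
  wins <- lapply(seq_along(seqs),
                 function(i) .enumWindows(seqs[[i]], k, pool@circular[i]))
  nWin <- vapply(wins, function(w) length(w$starts), 1L)
  canon <- unlist(lapply(wins, `[[`, "canonical"), use.names = FALSE)
  orgPer <- rep(org, nWin)
  keep <- !is.na(canon)

  u <- unique(canon[keep])
  code <- match(canon, u)                       # NA for excluded windows
  poolCnt <- tabulate(code[keep], nbins = length(u))

  orgFac <- factor(orgPer, levels = unique(org))
  # counts within the window's own organism: offset codes per organism
  code2 <- code + (as.integer(orgFac) - 1L) * length(u)
  orgTab <- tabulate(code2[keep], nbins = length(u) * nlevels(orgFac))
  ownCnt <- orgTab[code2]

  cls <- rep("unique", length(canon))
  cls[!keep] <- "excluded"
  cls[keep & ownCnt >= 2L] <- "intra"
  cls[keep & ownCnt == 1L & poolCnt[code] >= 2L] <- "inter"

  splits <- split(cls, rep(seq_along(wins), nWin))
  out <- stats::setNames(splits, names(seqs))
  attr(out, "organism") <- stats::setNames(org, names(seqs))
  out
}

#' Organism- and pool-level read loss
#'
#' Enumerates every possible read of the pool's read length from every
#' replicon and classifies it. A read is `ambiguous_intra` if its canonical
#' form occurs at two or more loci within its own organism (intra-organism
#' repeats; lost in single-sample mapping already); it is `ambiguous_inter`
#' if it is unique within its own organism but occurs at two or more loci
#' across the whole pool (inter-organism homology; the additional loss
#' caused by pooling). Intra takes precedence over inter. For error-free
#' reads under the unique-best-match criterion, ambiguity is exactly
#' canonical k-mer duplication, so this classification needs no mismatch
#' search.
#'
#' @param pool A [PoolSpec-class].
#' @return A `data.frame` with one row per organism: `organism`,
#'   `total_reads`, `excluded_reads`, `unique_single`, `ambiguous_intra`,
#'   `ambiguous_inter`, `unique_pooled`, `intra_loss_pct`, `inter_loss_pct`.
#'   `unique_single` counts reads uniquely mappable in single-sample mode;
#'   `unique_pooled = unique_single - ambiguous_inter`. Loss percentages are
#'   relative to `total_reads`.
#' @seealso [classifyReads()] for a single organism, [perGeneLoss()] for
#'   gene-level resolution.
#' @export
readLoss <- function(pool) {
  stopifnot(is(pool, "PoolSpec"))
  cls <- .positionClasses(pool)
  org <- attr(cls, "organism")
  out <- lapply(organisms(pool), function(o) {
    v <- unlist(cls[names(org)[org == o]], use.names = FALSE)
    total <- length(v)
    excl <- sum(v == "excluded")
    intra <- sum(v == "intra")
    inter <- sum(v == "inter")
    uniq <- sum(v == "unique") + inter   # unique in single-sample mapping
    data.frame(organism = o, total_reads = total, excluded_reads = excl,
               unique_single = uniq, ambiguous_intra = intra,
               ambiguous_inter = inter, unique_pooled = uniq - inter,
               intra_loss_pct = 100 * intra / total,
               inter_loss_pct = 100 * inter / total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname readLoss
#' @param organism Organism name (must be a member of the pool).
#' @return `classifyReads()` returns the single corresponding row.
#' @export
classifyReads <- function(pool, organism) {
  stopifnot(is(pool, "PoolSpec"))
  if (!organism %in% organisms(pool))
    .stopf("organism '%s' is not a member of the pool", organism)
  rep <- readLoss(pool)
  rep[rep$organism == organism, , drop = FALSE]
}

#' All loci within a mismatch budget of a query read
#'
#' Finds every locus (replicon, 1-based start, strand) at which the query
#' aligns with at most `maxMismatch` substitutions, on either strand,
#' wrapping circular junctions. For `maxMismatch = 1` the search uses exact
#' half-seed lookup (any Hamming-1 match shares at least one exact
#' half-window with the query) followed by mismatch-count verification, so
#' the minimum over returned loci is the true minimum within the budget.
#' Loci are strand-collapsed: if both strands match at one position, one
#' locus is reported with the smaller mismatch count.
#'
#' @param read Query sequence (character), same length as the reads being
#'   modelled.
#' @param pool A [PoolSpec-class] (or named `DNAStringSet` plus `circular`).
#' @param maxMismatch 0 or 1.
#' @param circular Logical, recycled; used when `pool` is a `DNAStringSet`.
#' @return A `data.frame` with columns `replicon`, `start`, `strand`,
#'   `mismatches`; zero rows when no locus is within the budget.
#' @export
minMismatchHits <- function(read, pool, maxMismatch = 1L, circular = TRUE) {
  if (is(pool, "PoolSpec")) {
    seqs <- replicons(pool)
    circular <- pool@circular
  } else {
    seqs <- pool
    circular <- rep_len(circular, length(seqs))
  }
  maxMismatch <- as.integer(maxMismatch)
  if (!maxMismatch %in% c(0L, 1L))
    .stopf("maxMismatch must be 0 or 1")
  read <- toupper(read)
  k <- nchar(read)
  hits <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ext <- Biostrings::DNAString(.extSeq(seqs[[i]], k, circular[i]))
    L <- Biostrings::width(seqs)[i]
    h <- rbind(.strandHits(read, ext, k, L, maxMismatch, "+"),
               .strandHits(.revcomp(read), ext, k, L, maxMismatch, "-"))
    if (nrow(h)) {
      h$replicon <- names(seqs)[i]
      # strand-collapse: one locus per (replicon, start), min mismatches
      h <- h[order(h$start, h$mismatches, h$strand), , drop = FALSE]
      h <- h[!duplicated(h$start), , drop = FALSE]
    }
    hits[[i]] <- h
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(replicon = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[, c("replicon", "start", "strand", "mismatches")]
}

# Candidate generation + verification for one strand orientation.
# `pattern` is the read as it would appear on the forward strand.
.strandHits <- function(pattern, ext, k, L, maxMismatch, strand) {
  pat <- Biostrings::DNAString(pattern)
  if (maxMismatch == 0L) {
    cand <- BiocGenerics::start(Biostrings::matchPattern(pat, ext))
    mm <- rep(0L, length(cand))
  } else {
    h <- k %/% 2L
    s1 <- Biostrings::subseq(pat, 1L, h)
    s2 <- Biostrings::subseq(pat, h + 1L, k)
    c1 <- BiocGenerics::start(Biostrings::matchPattern(s1, ext))
    c2 <- BiocGenerics::start(Biostrings::matchPattern(s2, ext)) - h
    cand <- unique(c(c1, c2))
    cand <- cand[cand >= 1L & cand + k - 1L <= length(ext)]
    if (length(cand)) {
      mm <- Biostrings::neditStartingAt(pat, ext, starting.at = cand,
                                        with.indels = FALSE)
      keep <- mm <= maxMismatch
      cand <- cand[keep]
      mm <- mm[keep]
    } else mm <- integer(0)
  }
  keep <- cand <= L   # starts beyond L duplicate wrapped loci
  data.frame(start = as.integer(cand[keep]),
             strand = rep_len(strand, sum(keep)),
             mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE)
}

#' Resolve a read to its unique best match in a pool
#'
#' Implements the unique-best-match read separation criterion: compute the
#' minimum mismatch count `m*` over all loci within the allowance; if
#' exactly one locus attains `m*` the read is assigned to that locus's
#' organism; if two or more do (a second match with the same number or fewer
#' mismatches), the read is ambiguous; if no locus is within the allowance,
#' it is unmapped. The optional `"any-valid"` mode disqualifies a read as
#' soon as any second locus lies within the allowance, regardless of
#' stratum, for sensitivity analysis of aligner suppression behaviour.
#'
#' @param read Query sequence (character).
#' @param pool A [PoolSpec-class].
#' @param maxMismatch Mismatch allowance; defaults to the pool's.
#' @param mode `"best-stratum"` (default) or `"any-valid"`.
#' @return A list with `status` (`"assigned"`, `"ambiguous"`, or
#'   `"unmapped"`) and, when assigned, `organism`, `replicon`, `start`,
#'   `mismatches`.
#' @export
resolveBestStratum <- function(read, pool, maxMismatch = NULL,
                               mode = c("best-stratum", "any-valid")) {
  stopifnot(is(pool, "PoolSpec"))
  mode <- match.arg(mode)
  if (is.null(maxMismatch)) maxMismatch <- mismatchAllowance(pool)
  hits <- minMismatchHits(read, pool, maxMismatch = maxMismatch)
  if (!nrow(hits)) return(list(status = "unmapped"))
  if (mode == "any-valid" && nrow(hits) >= 2L)
    return(list(status = "ambiguous", n_hits = nrow(hits)))
  mStar <- min(hits$mismatches)
  best <- hits[hits$mismatches == mStar, , drop = FALSE]
  if (nrow(best) >= 2L)
    return(list(status = "ambiguous", n_hits = nrow(best),
                mismatches = mStar))
  orgMap <- repliconOrganism(pool)
  list(status = "assigned", organism = unname(orgMap[best$replicon]),
       replicon = best$replicon, start = best$start,
       strand = best$strand, mismatches = mStar)
}

#' Write organism-level read-loss reports as TSV
#'
#' @param report A `data.frame` from [readLoss()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeReadLoss <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
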