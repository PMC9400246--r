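#' Inject substitution errors into reads
#'
#' Applies a substitution-only error model: either a fixed number of errors
#' per read (positions drawn without replacement) or an independent per-base
#' substitution probability. Every substituted base differs from the
#' original, drawn uniformly from the three alternatives. Results are
#' reproducible given `seed`.
#'
#' @param reads Character vector of reads over `{A,C,G,T}`.
#' @param prob Per-base substitution probability in `[0, 1)`; mutually
#'   exclusive with `fixed`.
#' @param fixed Fixed number of errors per read.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Character vector of mutated reads.
#' @examples
#' injectErrors("ACGTACGT", fixed = 2, seed = 1)
#' @export
injectErrors <- function(reads, prob = NULL, fixed = NULL, seed = NULL) {
  if (is.null(prob) == is.null(fixed))
    .stopf("specify exactly one of prob or fixed")
  if (!is.null(prob) && (prob < 0 || prob >= 1))
    .stopf("prob must be in [0, 1)")
  .withSeed(seed, {
    vapply(reads, function(r) {
      k <- nchar(r)
      if (!is.null(fixed)) {
        if (fixed > k)
          .stopf("fixed error count (%d) exceeds read length (%d)", fixed, k)
        if (fixed == 0L) return(r)
        pos <- sample.int(k, fixed)
      } else {
        pos <- which(stats::runif(k) < prob)
        if (!length(pos)) return(r)
      }
      ch <- strsplit(r, "", fixed = TRUE)[[1L]]
      bases <- c("A", "C", "G", "T")
      for (p in pos) {
        alt <- bases[bases != ch[p]]
        ch[p] <- alt[sample.int(3L, 1L)]
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Sequencing-error-driven misassignment between pooled organisms
#'
#' Samples reads uniformly from the enumerated loci of a source organism
#' (with replacement, or exhaustively over every locus), injects
#' substitution errors, and resolves each read with the unique-best-match
#' criterion against the whole pool. A read is misassigned when its unique
#' best locus lies in a non-source organism — the mechanism by which a
#' sequencing error at the right position with the right base flip can
#' convert a read of one organism into an exact (or better-scoring) copy of
#' another's locus. Under best-stratum semantics an error-free read can
#' never be misassigned: it matches its own locus perfectly, so no
#' foreign locus can beat it.
#'
#' @param pool A [PoolSpec-class].
#' @param source Source organism name (member of the pool).
#' @param prob,fixed Error model passed to [injectErrors()].
#' @param nReads Number of reads to sample (ignored when
#'   `exhaustive = TRUE`).
#' @param seed Integer seed; the result is bit-for-bit reproducible.
#' @param exhaustive Enumerate every locus exactly once instead of sampling
#'   (intended for genomes up to ~100 kb).
#' @param maxMismatch Mismatch allowance; defaults to the pool's.
#' @return A list: `n_reads`, `n_misassigned`, `n_ambiguous`, `n_unmapped`,
#'   `rate` (misassigned per read), `ci` (95% binomial confidence interval
#'   for the rate), and `misassigned` (data.frame of the misassigned reads
#'   with their source and target loci).
#' @export
misassignmentRate <- function(pool, source, prob = NULL, fixed = NULL,
                              nReads = 10000L, seed = 0L,
                              exhaustive = FALSE, maxMismatch = NULL) {
  stopifnot(is(pool, "PoolSpec"))
  if (!source %in% organisms(pool))
    .stopf("organism '%s' is not a member of the pool", source)
  if (is.null(maxMismatch)) maxMismatch <- mismatchAllowance(pool)
  k <- readLength(pool)
  orgMap <- repliconOrganism(pool)
  srcIdx <- which(pool@organism == source)
  seqs <- replicons(pool)

  ext <- lapply(srcIdx, function(i)
    .extSeq(seqs[[i]], k, pool@circular[i]))
  nStart <- vapply(srcIdx, function(i) {
    L <- Biostrings::width(seqs)[i]
    if (pool@circular[i] && k > 1L) L else L - k + 1L
  }, 1L)

  # exact canonical pool counts resolve the (frequent) error-free reads
  idx <- buildKmerIndex(pool)

  .withSeed(seed, {
    if (exhaustive) {
      repSel <- rep(seq_along(srcIdx), nStart)
      startSel <- unlist(lapply(nStart, seq_len))
    } else {
      n <- as.integer(nReads)
      if (n < 1L) .stopf("nReads must be >= 1")
      repSel <- sample.int(length(srcIdx), n, replace = TRUE,
                           prob = nStart / sum(nStart))
      startSel <- vapply(repSel, function(j)
        sample.int(nStart[j], 1L), 1L)
    }
    reads0 <- vapply(seq_along(repSel), function(i)
      substr(ext[[repSel[i]]], startSel[i], startSel[i] + k - 1L),
      character(1))
    reads <- injectErrors(reads0, prob = prob, fixed = fixed, seed = NULL)

    nMis <- 0L; nAmb <- 0L; nUnm <- 0L
    misRows <- list()
    intact <- reads == reads0
    for (i in seq_along(reads)) {
      if (intact[i]) {
        cnt <- kmerCount(idx, reads[i])
        if (is.na(cnt) || cnt >= 2L) nAmb <- nAmb + 1L
        next
      }
      res <- resolveBestStratum(reads[i], pool, maxMismatch = maxMismatch)
      if (res$status == "ambiguous") nAmb <- nAmb + 1L
      else if (res$status == "unmapped") nUnm <- nUnm + 1L
      else if (res$organism != source) {
        nMis <- nMis + 1L
        misRows[[length(misRows) + 1L]] <- data.frame(
          read = reads[i],
          source_replicon = names(seqs)[srcIdx[repSel[i]]],
          source_start = startSel[i], target_organism = res$organism,
          target_replicon = res$replicon, target_start = res$start,
          mismatches = res$mismatches, stringsAsFactors = FALSE)
      }
    }
    n <- length(reads)
    ci <- as.numeric(stats::binom.test(nMis, n)$conf.int)
    list(n_reads = n, n_misassigned = nMis, n_ambiguous = nAmb,
         n_unmapped = nUnm, rate = nMis / n, ci = ci,
         misassigned = if (length(misRows)) do.call(rbind, misRows) else
           data.frame())
  })
}
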