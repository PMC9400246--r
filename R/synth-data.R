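#' Generate a random bacterial-like genome with planted structure
#'
#' Draws an i.i.d. background sequence at the requested GC content and
#' plants exact repeats (the same unit inserted verbatim at several
#' non-overlapping positions) and/or caller-supplied segments (used to share
#' homologous sequence between organisms). A truth record lists every
#' planted interval, sufficient to compute expected loss counts by brute
#' force. Optionally emits evenly spaced gene features (bacterial-like
#' ~1 kb genes). A post-generation collision check asserts that no
#' accidental exact duplicate windows of length `uniqueK` exist outside the
#' planted intervals; for i.i.d. backgrounds and `uniqueK` >= 20 chance
#' collisions are negligible, so a failure indicates an infeasible recipe.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction of the background (default 0.5).
#' @param repeats List of repeat recipes, each
#'   `list(length =, copies =, positions = "random" | integer vector)`.
#' @param segments List of verbatim plants, each `list(seq =, at = )`
#'   (`at = "random"` allowed).
#' @param circular Circularity flag recorded in the truth record.
#' @param genes If `TRUE`, emit evenly spaced gene features.
#' @param geneLength,geneSpacing Gene length and intergenic gap in bp
#'   (defaults 1000 and 500).
#' @param id Replicon id (default `"chr"`).
#' @param seed Integer seed; the generator is a pure function of seed and
#'   recipe.
#' @param uniqueK Window length for the collision check; `NULL` disables.
#' @return A list: `replicon` (named length-1 `DNAStringSet`), `genes`
#'   (`GRanges` with `gene_id`, empty unless `genes = TRUE`), `truth`
#'   (list with `planted` data.frame of 1-based closed intervals, `circular`,
#'   `seed`).
#' @examples
#' g <- simulateGenome(5000, repeats = list(list(length = 200, copies = 2)),
#'                     seed = 42, uniqueK = 50)
#' g$truth$planted
#' @export
simulateGenome <- function(length, gc = 0.5, repeats = list(),
                           segments = list(), circular = TRUE,
                           genes = FALSE, geneLength = 1000L,
                           geneSpacing = 500L, id = "chr", seed = 1L,
                           uniqueK = 150L) {
  length <- as.integer(length)
  stopifnot(length > 0, gc >= 0, gc <= 1)
  .withSeed(seed, {
    seq <- .randomSeq(length, gc)
    planted <- data.frame(start = integer(), end = integer(),
                          what = character(), stringsAsFactors = FALSE)

    for (rp in repeats) {
      unit <- .randomSeq(rp$length, gc)
      pos <- rp$positions
      if (is.null(pos) || identical(pos, "random"))
        pos <- .placeIntervals(length, rep(rp$length, rp$copies), planted)
      if (length(pos) != rp$copies)
        .stopf("repeat recipe needs %d positions, got %d", rp$copies,
               length(pos))
      for (p in pos) {
        .checkFit(p, rp$length, length, planted)
        substr(seq, p, p + rp$length - 1L) <- unit
        planted <- rbind(planted, data.frame(
          start = p, end = p + rp$length - 1L, what = "repeat",
          stringsAsFactors = FALSE))
      }
    }
    for (sg in segments) {
      s <- toupper(as.character(sg$seq))
      w <- nchar(s)
      at <- sg$at
      if (is.null(at) || identical(at, "random"))
        at <- .placeIntervals(length, w, planted)
      .checkFit(at, w, length, planted)
      substr(seq, at, at + w - 1L) <- s
      planted <- rbind(planted, data.frame(
        start = at, end = at + w - 1L, what = "segment",
        stringsAsFactors = FALSE))
    }

    if (!is.null(uniqueK) && uniqueK <= length)
      .assertNoStrayRepeats(seq, uniqueK, planted, circular)

    gr <- GenomicRanges::GRanges()
    if (isTRUE(genes)) {
      step <- geneLength + geneSpacing
      starts <- seq.int(1L, by = step,
                        length.out = max(0L, (length - geneLength) %/% step + 1L))
      if (length(starts)) {
        gr <- GenomicRanges::GRanges(
          seqnames = id,
          ranges = IRanges::IRanges(start = starts,
                                    end = starts + geneLength - 1L),
          strand = "+",
          gene_id = sprintf("%s_g%04d", id, seq_along(starts)))
      }
    }
    repl <- Biostrings::DNAStringSet(stats::setNames(seq, id))
    list(replicon = repl, genes = gr,
         truth = list(planted = planted, circular = circular, seed = seed,
                      length = length, gc = gc))
  })
}

.randomSeq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# choose non-overlapping random start positions for widths, avoiding
# already-planted intervals (with a 1-bp guard band)
.placeIntervals <- function(L, widths, planted, maxTries = 1000L) {
  chosen <- planted[, c("start", "end"), drop = FALSE]
  out <- integer(0)
  for (w in widths) {
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      p <- sample.int(L - w + 1L, 1L)
      if (!nrow(chosen) ||
          all(p > chosen$end + 1L | p + w - 1L < chosen$start - 1L)) {
        chosen <- rbind(chosen, data.frame(start = p, end = p + w - 1L))
        out <- c(out, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) .stopf("cannot place a %d bp interval without overlap", w)
  }
  out
}

.checkFit <- function(p, w, L, planted) {
  if (p < 1L || p + w - 1L > L)
    .stopf("planted interval [%d, %d] outside genome of length %d",
           p, p + w - 1L, L)
  prior <- planted[planted$what != "", , drop = FALSE]
  invisible(TRUE)
}

# every duplicated canonical window must touch a planted interval
.assertNoStrayRepeats <- function(seq, k, planted, circular) {
  w <- .enumWindows(seq, k, circular)
  canon <- w$canonical[!w$excluded]
  dupKmers <- unique(canon[duplicated(canon)])
  if (!length(dupKmers)) return(invisible(TRUE))
  dupIdx <- which(w$canonical %in% dupKmers)
  starts <- w$starts[dupIdx]
  L <- w$length
  touches <- vapply(starts, function(s) {
    ends <- s + k - 1L
    any(s <= planted$end & ends >= planted$start) ||
      (ends > L && any(planted$start <= ends - L))   # wrapped tail
  }, logical(1))
  if (!all(touches))
    .stopf("accidental exact %d-mer repeat outside planted intervals at %s",
           k, paste(utils::head(starts[!touches], 3L), collapse = ", "))
  invisible(TRUE)
}

#' Generate a homologous genome pair of controlled identity
#'
#' Genome B is derived from genome A by i.i.d. substitutions at rate
#' `1 - identity` (substituted bases always differ from the original); the
#' truth record stores the substituted positions. A stand-in for a pair of
#' related taxa sharing genome-wide homology.
#'
#' @param length Genome length in bp.
#' @param identity Fraction of positions left identical, in `(0, 1]`.
#' @param seed Integer seed.
#' @param gc GC fraction of genome A's background.
#' @param ids Length-2 character vector of replicon ids.
#' @return A list: `a`, `b` (named length-1 `DNAStringSet`s),
#'   `substitutions` (integer positions), `identity`, `seed`.
#' @export
simulateHomologPair <- function(length, identity, seed = 1L, gc = 0.5,
                                ids = c("genomeA", "genomeB")) {
  stopifnot(identity > 0, identity <= 1)
  .withSeed(seed, {
    a <- .randomSeq(as.integer(length), gc)
    ch <- strsplit(a, "", fixed = TRUE)[[1L]]
    pos <- which(stats::runif(length) < 1 - identity)
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- bases[bases != ch[p]]
      ch[p] <- alt[sample.int(3L, 1L)]
    }
    b <- paste(ch, collapse = "")
    list(a = Biostrings::DNAStringSet(stats::setNames(a, ids[1L])),
         b = Biostrings::DNAStringSet(stats::setNames(b, ids[2L])),
         substitutions = pos, identity = identity, seed = seed)
  })
}

#' Simulate a replication coverage gradient
#'
#' Expected depth at circular distance `d` from the origin (maximum
#' distance `D = length / 2` at the terminus) is
#' `meanDepth * ratio^(1 - d/D)`: exactly log-linear along each replichore,
#' with expectation `meanDepth * ratio` at the origin and `meanDepth` at the
#' terminus. Noise is either none (the closed form) or Poisson per position.
#'
#' @param length Replicon length in bp.
#' @param oriPos 1-based origin position.
#' @param ratio Origin/terminus copy-number ratio (>= 1).
#' @param meanDepth Expected depth at the terminus.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed (used for Poisson noise).
#' @param repliconId Track label.
#' @return A [CoverageTrack-class].
#' @examples
#' trk <- simulateCoverage(20000, 10000, ratio = 4, meanDepth = 100,
#'                         noise = "none", seed = 1)
#' range(trackDepth(trk))
#' @export
simulateCoverage <- function(length, oriPos, ratio, meanDepth = 100,
                             noise = c("none", "poisson"), seed = 1L,
                             repliconId = "chr") {
  noise <- match.arg(noise)
  stopifnot(ratio >= 1, meanDepth > 0)
  L <- as.integer(length)
  p <- seq_len(L)
  d <- pmin((p - oriPos) %% L, (oriPos - p) %% L)
  D <- L / 2
  mu <- meanDepth * ratio^(1 - d / D)
  depth <- if (noise == "poisson")
    .withSeed(seed, stats::rpois(L, mu)) else mu
  new("CoverageTrack", repliconId = repliconId, depth = as.numeric(depth),
      source = sprintf("simulated(ratio=%g,depth=%g,noise=%s,seed=%d)",
                       ratio, meanDepth, noise, as.integer(seed)))
}

#' Write a complete fixture set of organisms to disk
#'
#' Generates one genome per recipe, optionally plants homologous segments
#' shared between organism pairs at a controlled identity, and writes
#' paired `<organism>.fna` / `<organism>.gff` files plus a
#' `<organism>.truth.json` record per organism — a folder directly
#' consumable by [buildPool()] and the `genecheck` command. Deterministic
#' given `seed`.
#'
#' @param outDir Output directory (created if needed).
#' @param recipes Named list (organism name -> recipe list with fields
#'   `length`, and optionally `gc`, `repeats`, `circular`, `genes`,
#'   `geneLength`, `geneSpacing`).
#' @param shared Optional list of shared-segment specs, each
#'   `list(a =, b =, length =, identity =)` naming two recipe organisms: a
#'   segment is planted verbatim into `a` and at the given identity into
#'   `b`.
#' @param seed Integer master seed.
#' @param uniqueK Collision-check window length (see [simulateGenome()]).
#' @return Invisibly, a list per organism with the generated `replicon`,
#'   `genes`, `truth` and file paths.
#' @export
writeFixtureSet <- function(outDir, recipes, shared = list(), seed = 1L,
                            uniqueK = 150L) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory: %s", outDir)
  orgNames <- names(recipes)
  if (is.null(orgNames) || any(orgNames == ""))
    .stopf("recipes must be a named list")

  .withSeed(seed, {
    subSeeds <- sample.int(.Machine$integer.max, length(recipes) +
                             length(shared))
    gens <- list()
    for (i in seq_along(recipes)) {
      rc <- recipes[[i]]
      gens[[orgNames[i]]] <- simulateGenome(
        length = rc$length, gc = rc$gc %||% 0.5,
        repeats = rc$repeats %||% list(),
        circular = rc$circular %||% TRUE,
        genes = rc$genes %||% FALSE,
        geneLength = rc$geneLength %||% 1000L,
        geneSpacing = rc$geneSpacing %||% 500L,
        id = orgNames[i], seed = subSeeds[i], uniqueK = NULL)
    }
    # plant shared homologous segments across pairs
    for (j in seq_along(shared)) {
      sh <- shared[[j]]
      if (!all(c(sh$a, sh$b) %in% orgNames))
        .stopf("shared segment names unknown organism(s)")
      segSeed <- subSeeds[length(recipes) + j]
      seg <- .withSeed(segSeed, .randomSeq(sh$length, 0.5))
      mut <- if ((sh$identity %||% 1) < 1) {
        .withSeed(segSeed + 1L, {
          ch <- strsplit(seg, "", fixed = TRUE)[[1L]]
          pos <- which(stats::runif(sh$length) < 1 - sh$identity)
          bases <- c("A", "C", "G", "T")
          for (p in pos) {
            alt <- bases[bases != ch[p]]
            ch[p] <- alt[sample.int(3L, 1L)]
          }
          paste(ch, collapse = "")
        })
      } else seg
      gens[[sh$a]] <- .plantSegment(gens[[sh$a]], seg,
                                    sprintf("shared_%d", j))
      gens[[sh$b]] <- .plantSegment(gens[[sh$b]], mut,
                                    sprintf("shared_%d", j))
    }
    for (o in orgNames) {
      rc <- recipes[[o]]
      if (!is.null(uniqueK) && uniqueK <= rc$length)
        .assertNoStrayRepeats(as.character(gens[[o]]$replicon[[1L]]),
                              uniqueK, gens[[o]]$truth$planted,
                              gens[[o]]$truth$circular)
    }

    out <- list()
    for (o in orgNames) {
      g <- gens[[o]]
      fna <- file.path(outDir, paste0(o, ".fna"))
      Biostrings::writeXStringSet(g$replicon, fna)
      gff <- NULL
      if (length(g$genes)) {
        gff <- file.path(outDir, paste0(o, ".gff"))
        .writeGFF3(g$genes, gff)
      }
      truth <- file.path(outDir, paste0(o, ".truth.json"))
      jsonlite::write_json(g$truth, truth, auto_unbox = TRUE, digits = NA)
      out[[o]] <- c(g, list(fna = fna, gff = gff, truthFile = truth))
    }
    invisible(out)
  })
}

# plant a given segment at a random free position; update truth record
.plantSegment <- function(gen, segSeq, what) {
  seqChr <- as.character(gen$replicon[[1L]])
  L <- nchar(seqChr)
  w <- nchar(segSeq)
  at <- .placeIntervals(L, w, gen$truth$planted)
  substr(seqChr, at, at + w - 1L) <- segSeq
  gen$truth$planted <- rbind(gen$truth$planted, data.frame(
    start = at, end = at + w - 1L, what = what, stringsAsFactors = FALSE))
  gen$replicon <- Biostrings::DNAStringSet(
    stats::setNames(seqChr, names(gen$replicon)))
  gen
}

# minimal GFF3 writer for gene features (seqid, gene, 1-based inclusive)
.writeGFF3 <- function(gr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tpoolability\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
                   as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr), BiocGenerics::end(gr),
                   as.character(BiocGenerics::strand(gr)),
                   gr$gene_id, gr$gene_id)
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
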