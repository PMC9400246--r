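#' Per-organism abundance from per-replicon read counts
#'
#' Sums counts over each organism's replicons and returns fractions of the
#' total, the post-separation bookkeeping used to check that a pooled run
#' reflects the intended mix ratio.
#'
#' @param counts Named numeric vector of per-replicon read counts; every
#'   name must be a replicon of `pool`.
#' @param pool A [PoolSpec-class].
#' @return Named numeric vector of per-organism fractions (pool organism
#'   order); sums to 1.
#' @examples
#' pool <- buildPool(list(
#'   A = Biostrings::DNAStringSet(c(a1 = "ACGTACGTACGTACGTACGT")),
#'   B = Biostrings::DNAStringSet(c(b1 = "TGCATGCATGCATGCATGCA"))),
#'   readLength = 5)
#' organismAbundance(c(a1 = 100, b1 = 300), pool)
#' @export
organismAbundance <- function(counts, pool) {
  stopifnot(is(pool, "PoolSpec"))
  orgMap <- repliconOrganism(pool)
  unknown <- setdiff(names(counts), names(orgMap))
  if (length(unknown))
    .stopf("unknown replicon id(s): %s", paste(unknown, collapse = ", "))
  if (any(counts < 0)) .stopf("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) .stopf("total read count is zero")
  per <- vapply(organisms(pool), function(o)
    sum(counts[names(counts) %in% names(orgMap)[orgMap == o]]), numeric(1))
  per / total
}

#' Windowed coverage deviation between two samples
#'
#' Compares two coverage tracks of the same replicon after total-count
#' scaling. The per-window deviation is the symmetric percent difference
#' `100 * (a - b) / ((a + b) / 2)` of window means; windows with `a + b ==
#' 0` are dropped; `r_squared` is the squared Pearson correlation of the
#' window means. Both statistics are invariant to positive rescaling of
#' either track, and swapping the tracks negates every deviation while
#' preserving `r_squared`.
#'
#' @param a,b [CoverageTrack-class] objects or numeric depth vectors of
#'   equal length.
#' @param window Window size in bp (default 5000).
#' @return A `ComparisonStats` list: `values` (per-window deviation, %),
#'   `r_squared`, `n_units`, `normalization`.
#' @export
coverageDeviation <- function(a, b, window = 5000L) {
  da <- if (is(a, "CoverageTrack")) trackDepth(a) else as.numeric(a)
  db <- if (is(b, "CoverageTrack")) trackDepth(b) else as.numeric(b)
  if (length(da) != length(db))
    .stopf("tracks differ in length (%d vs %d)", length(da), length(db))
  db <- db * sum(da) / sum(db)
  wa <- windowMeans(da, window)$mean
  wb <- windowMeans(db, window)$mean
  keep <- (wa + wb) > 0
  dev <- 100 * (wa[keep] - wb[keep]) / ((wa[keep] + wb[keep]) / 2)
  structure(list(values = dev,
                 r_squared = stats::cor(wa[keep], wb[keep])^2,
                 n_units = sum(keep), normalization = "total-count"),
            class = "ComparisonStats")
}

#' Gene expression ratios between two samples
#'
#' Scales the two count vectors to equal totals, drops genes whose scaled
#' count falls below `minCount` in either sample (guards against ratio
#' blow-ups at near-zero counts), and returns per-gene log2 ratios plus the
#' squared Pearson correlation of the log2-scaled counts.
#'
#' @param a,b Named numeric vectors of per-gene read counts.
#' @param minCount Minimum scaled count required in both samples
#'   (default 10).
#' @return A `ComparisonStats` list: `values` (log2 ratios a/b, named by
#'   gene), `r_squared`, `n_units`, `normalization`.
#' @export
expressionRatios <- function(a, b, minCount = 10) {
  shared <- intersect(names(a), names(b))
  if (!length(shared)) .stopf("no shared gene ids between the two samples")
  a <- a[shared]
  b <- b[shared]
  b <- b * sum(a) / sum(b)
  keep <- a >= minCount & b >= minCount
  if (!any(keep))
    .stopf("no gene passes the minimum count filter (%g)", minCount)
  la <- log2(a[keep])
  lb <- log2(b[keep])
  structure(list(values = la - lb,
                 r_squared = stats::cor(la, lb)^2,
                 n_units = sum(keep), normalization = "total-count"),
            class = "ComparisonStats")
}

#' @export
print.ComparisonStats <- function(x, ...) {
  cat(sprintf(
    "ComparisonStats: %d units, R^2 = %.4f, spread (sd) = %.3f (%s-normalized)\n",
    x$n_units, x$r_squared, stats::sd(x$values), x$normalization))
  invisible(x)
}

#' Per-gene read counts from a coverage track
#'
#' Approximates gene-level read counts as the summed depth over the gene
#' interval divided by the read length (fractional counts allowed), the
#' quantification used for expression-ratio comparisons when only coverage
#' tracks are available.
#'
#' @param track A [CoverageTrack-class] or numeric depth vector.
#' @param genes A `GRanges` of gene features (with `gene_id`) on the
#'   track's replicon.
#' @param readLength Read length in bp (default 150).
#' @return Named numeric vector of per-gene counts.
#' @export
geneCountsFromCoverage <- function(track, genes, readLength = 150L) {
  depth <- if (is(track, "CoverageTrack")) trackDepth(track) else
    as.numeric(track)
  gs <- BiocGenerics::start(genes)
  ge <- pmin(BiocGenerics::end(genes), length(depth))
  counts <- vapply(seq_along(genes), function(i)
    sum(depth[gs[i]:ge[i]]) / readLength, numeric(1))
  stats::setNames(counts, genes$gene_id)
}

#' One-line JSON summary of a comparison
#'
#' @param stats A `ComparisonStats` object.
#' @param label Comparison label.
#' @return A JSON string (also usable as a log line).
#' @export
comparisonSummaryJSON <- function(stats, label = "comparison") {
  jsonlite::toJSON(list(label = label, n_units = stats$n_units,
                        r_squared = stats$r_squared,
                        sd = stats::sd(stats$values),
                        normalization = stats$normalization),
                   auto_unbox = TRUE, digits = NA)
}
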