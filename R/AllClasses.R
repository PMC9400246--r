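#' @import methods
NULL

#' PoolSpec: a registry of organisms and their replicons
#'
#' A `PoolSpec` defines the mapping universe for pooled-sample analysis: an
#' ordered set of organisms, each contributing one or more replicons
#' (chromosomes or plasmids), together with the read length and mismatch
#' allowance used for read classification. Single-organism specs are valid
#' and describe the classical single-sample mapping universe.
#'
#' @slot seqs A [Biostrings::DNAStringSet] holding every replicon in the
#'   pool; names are replicon ids, unique across the whole pool.
#' @slot organism Character vector parallel to `seqs`: the organism each
#'   replicon belongs to.
#' @slot circular Logical vector parallel to `seqs`: whether the replicon is
#'   circular (bacterial default `TRUE`).
#' @slot genes Named list of [GenomicRanges::GRanges] with per-organism gene
#'   features (may be empty). Each `GRanges` carries a `gene_id` metadata
#'   column and uses replicon ids as seqnames.
#' @slot readLength Integer, the read length in bp used for enumeration
#'   (default 150).
#' @slot mismatchAllowance Integer in `{0, 1}`: maximum mismatches allowed
#'   when resolving best-stratum assignments (default 1).
#'
#' @seealso [buildPool()], [readLoss()], [perGeneLoss()]
#' @export
setClass("PoolSpec",
  representation(
    seqs = "DNAStringSet",
    organism = "character",
    circular = "logical",
    genes = "list",
    readLength = "integer",
    mismatchAllowance = "integer"
  )
)

setValidity("PoolSpec", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (n < 1L) msg <- c(msg, "a PoolSpec needs at least one replicon")
  ids <- names(object@seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "every replicon must be named")
  if (anyDuplicated(ids)) msg <- c(msg, "replicon ids must be unique")
  if (length(object@organism) != n)
    msg <- c(msg, "organism vector must match the number of replicons")
  if (length(object@circular) != n)
    msg <- c(msg, "circular vector must match the number of replicons")
  if (any(Biostrings::width(object@seqs) < 1L))
    msg <- c(msg, "replicon sequences must be non-empty")
  if (length(object@readLength) != 1L || is.na(object@readLength) ||
      object@readLength < 1L)
    msg <- c(msg, "readLength must be a positive integer")
  if (length(object@mismatchAllowance) != 1L ||
      is.na(object@mismatchAllowance) || object@mismatchAllowance < 0L)
    msg <- c(msg, "mismatchAllowance must be a non-negative integer")
  if (length(object@genes) &&
      !all(names(object@genes) %in% unique(object@organism)))
    msg <- c(msg, "gene lists must be named by pool organisms")
  if (length(msg)) msg else TRUE
})

#' KmerIndex: canonical k-mer multiplicity map
#'
#' Maps every canonical fixed-length window (k-mer) enumerated from a set of
#' replicons to the number of loci (start positions, strand-collapsed) at
#' which it occurs. Windows containing non-ACGT characters are excluded from
#' the index and counted separately.
#'
#' @slot k Integer window length.
#' @slot counts Named integer vector: canonical k-mer -> locus count.
#' @slot excludedLoci Integer, number of enumerated windows containing
#'   non-ACGT characters (not indexed).
#' @slot nLoci Integer, total number of enumerated windows.
#'
#' @seealso [buildKmerIndex()]
#' @export
setClass("KmerIndex",
  representation(
    k = "integer",
    counts = "integer",
    excludedLoci = "integer",
    nLoci = "integer"
  )
)

setValidity("KmerIndex", function(object) {
  msg <- character()
  if (length(object@counts) && any(object@counts < 1L))
    msg <- c(msg, "all k-mer counts must be >= 1")
  if (sum(object@counts) + object@excludedLoci != object@nLoci)
    msg <- c(msg, "counts plus excluded loci must equal total windows")
  if (length(msg)) msg else TRUE
})

#' CoverageTrack: per-position sequencing depth along one replicon
#'
#' @slot repliconId Character, the replicon the track belongs to.
#' @slot depth Numeric vector of non-negative per-position depths; its
#'   length is the replicon length.
#' @slot source Character label recording where the track came from (file
#'   path or simulation tag).
#'
#' @seealso [readCoverageTrack()], [simulateCoverage()], [windowMeans()]
#' @export
setClass("CoverageTrack",
  representation(
    repliconId = "character",
    depth = "numeric",
    source = "character"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@depth) < 1L) msg <- c(msg, "depth must be non-empty")
  if (any(object@depth < 0, na.rm = TRUE))
    msg <- c(msg, "depths must be non-negative")
  if (anyNA(object@depth)) msg <- c(msg, "depths must not contain NA")
  if (length(msg)) msg else TRUE
})

#' CopyNumberFit: marker-frequency regression result for one replicon
#'
#' Holds the per-replichore log-linear regressions of windowed coverage and
#' the derived origin/terminus copy-number ratio. With `terNormalized =
#' TRUE` (the default downstream convention) the terminus copy number is 1
#' and the origin copy number equals `ratio`.
#'
#' @slot repliconId Character.
#' @slot oriPos,terPos Numeric, 1-based positions of the replication origin
#'   and terminus on the (circular) replicon.
#' @slot window Integer window size in bp used for coverage averaging.
#' @slot midpoints Numeric, window midpoints in unrolled coordinates (origin
#'   interior, terminus at the cut).
#' @slot logMeans Numeric, log2 mean coverage per window (NA where unusable).
#' @slot usable Logical, whether each window entered a regression.
#' @slot replichore Character, "left" or "right" per window.
#' @slot slopes,intercepts Numeric length-2 vectors (left, right) of the
#'   log2-space regressions.
#' @slot oriValue,terValue Numeric, linear-scale coverage at the two
#'   regression-line intersections.
#' @slot ratio Numeric, `oriValue / terValue`.
#' @slot terNormalized Logical, whether reported copy numbers are scaled so
#'   the terminus is 1.
#'
#' @seealso [fitReplichores()], [oriTerRatio()]
#' @export
setClass("CopyNumberFit",
  representation(
    repliconId = "character",
    oriPos = "numeric",
    terPos = "numeric",
    window = "integer",
    midpoints = "numeric",
    logMeans = "numeric",
    usable = "logical",
    replichore = "character",
    slopes = "numeric",
    intercepts = "numeric",
    oriValue = "numeric",
    terValue = "numeric",
    ratio = "numeric",
    terNormalized = "logical"
  )
)

setValidity("CopyNumberFit", function(object) {
  msg <- character()
  if (!(object@ratio > 0)) msg <- c(msg, "ratio must be positive")
  if (length(object@slopes) != 2L || length(object@intercepts) != 2L)
    msg <- c(msg, "slopes and intercepts must have length 2 (left, right)")
  if (length(msg)) msg else TRUE
})
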