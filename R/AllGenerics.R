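#' Accessors for PoolSpec and related objects
#'
#' `organisms()` returns the organism names in pool order; `replicons()` the
#' replicon sequences (a `DNAStringSet`); `repliconOrganism()` the
#' replicon -> organism map; `isCircular()` the per-replicon circularity
#' flags; `poolGenes()` the per-organism gene `GRanges`; `readLength()` and
#' `mismatchAllowance()` the classification parameters.
#'
#' @param x A [PoolSpec-class] object.
#' @return See individual descriptions.
#' @name PoolSpec-accessors
#' @aliases organisms replicons repliconOrganism isCircular poolGenes
#'   readLength mismatchAllowance
#' @examples
#' pool <- buildPool(list(
#'   orgA = Biostrings::DNAStringSet(c(chr = "ACGTACGTACGTACGTACGT"))),
#'   readLength = 5)
#' organisms(pool)
#' readLength(pool)
NULL

#' @rdname PoolSpec-accessors
#' @export
setGeneric("organisms", function(x) standardGeneric("organisms"))

#' @rdname PoolSpec-accessors
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))

#' @rdname PoolSpec-accessors
#' @export
setGeneric("repliconOrganism", function(x) standardGeneric("repliconOrganism"))

#' @rdname PoolSpec-accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname PoolSpec-accessors
#' @export
setGeneric("poolGenes", function(x) standardGeneric("poolGenes"))

#' @rdname PoolSpec-accessors
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @rdname PoolSpec-accessors
#' @export
setGeneric("mismatchAllowance", function(x) standardGeneric("mismatchAllowance"))

#' @rdname PoolSpec-accessors
#' @export
setMethod("organisms", "PoolSpec", function(x) unique(x@organism))

#' @rdname PoolSpec-accessors
#' @export
setMethod("replicons", "PoolSpec", function(x) x@seqs)

#' @rdname PoolSpec-accessors
#' @export
setMethod("repliconOrganism", "PoolSpec", function(x) {
  stats::setNames(x@organism, names(x@seqs))
})

#' @rdname PoolSpec-accessors
#' @export
setMethod("isCircular", "PoolSpec", function(x) {
  stats::setNames(x@circular, names(x@seqs))
})

#' @rdname PoolSpec-accessors
#' @export
setMethod("poolGenes", "PoolSpec", function(x) x@genes)

#' @rdname PoolSpec-accessors
#' @export
setMethod("readLength", "PoolSpec", function(x) x@readLength)

#' @rdname PoolSpec-accessors
#' @export
setMethod("mismatchAllowance", "PoolSpec", function(x) x@mismatchAllowance)

#' Extract the origin/terminus copy-number ratio from a fit
#'
#' @param x A [CopyNumberFit-class] object.
#' @return A single positive number: fitted coverage at the origin divided
#'   by fitted coverage at the terminus.
#' @export
setGeneric("oriTerRatio", function(x) standardGeneric("oriTerRatio"))

#' @rdname oriTerRatio
#' @export
setMethod("oriTerRatio", "CopyNumberFit", function(x) x@ratio)

#' Per-position depth of a coverage track
#'
#' @param x A [CoverageTrack-class] object.
#' @return Numeric vector of per-position depths.
#' @export
setGeneric("trackDepth", function(x) standardGeneric("trackDepth"))

#' @rdname trackDepth
#' @export
setMethod("trackDepth", "CoverageTrack", function(x) x@depth)

setMethod("show", "PoolSpec", function(object) {
  orgs <- organisms(object)
  cat(sprintf("PoolSpec: %d organism(s), %d replicon(s), %s bp total\n",
              length(orgs), length(object@seqs),
              format(sum(Biostrings::width(object@seqs)), big.mark = ",")))
  cat(sprintf("  read length %d bp, mismatch allowance %d\n",
              object@readLength, object@mismatchAllowance))
  for (o in orgs) {
    idx <- which(object@organism == o)
    ng <- if (!is.null(object@genes[[o]])) length(object@genes[[o]]) else 0L
    cat(sprintf("  %s: %s (%s bp%s)\n", o,
                paste(names(object@seqs)[idx], collapse = ", "),
                format(sum(Biostrings::width(object@seqs)[idx]),
                       big.mark = ","),
                if (ng) sprintf(", %d genes", ng) else ""))
  }
  invisible(object)
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf(
    "KmerIndex: k = %d, %s loci (%s distinct canonical k-mers, %s excluded)\n",
    object@k, format(object@nLoci, big.mark = ","),
    format(length(object@counts), big.mark = ","),
    format(object@excludedLoci, big.mark = ",")))
  invisible(object)
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack '%s': %s bp, mean depth %.2f (source: %s)\n",
              object@repliconId,
              format(length(object@depth), big.mark = ","),
              mean(object@depth), object@source))
  invisible(object)
})

setMethod("show", "CopyNumberFit", function(object) {
  cat(sprintf("CopyNumberFit '%s': ori %d, ter %d, window %d bp\n",
              object@repliconId, as.integer(object@oriPos),
              as.integer(object@terPos), object@window))
  cat(sprintf("  slopes (log2/bp): left %.3g, right %.3g\n",
              object@slopes[1], object@slopes[2]))
  if (object@terNormalized) {
    cat(sprintf("  copy number: ori %.3f, ter 1 (ratio %.3f)\n",
                object@ratio, object@ratio))
  } else {
    cat(sprintf("  coverage: ori %.2f, ter %.2f (ratio %.3f)\n",
                object@oriValue, object@terValue, object@ratio))
  }
  invisible(object)
})
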