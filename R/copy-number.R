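#' Read a coverage track from wig or bedGraph
#'
#' Imports a coverage file via rtracklayer (format detected from the
#' extension: `.wig`, `.bedGraph`/`.bg`) and expands it to a per-position
#' depth vector. Positions not covered by any record get depth 0.
#'
#' @param path Coverage file path.
#' @param repliconId Replicon to extract; defaults to the single seqname
#'   present (an error if the file covers several).
#' @param length Replicon length; defaults to the largest end coordinate.
#' @return A [CoverageTrack-class].
#' @export
readCoverageTrack <- function(path, repliconId = NULL, length = NULL) {
  if (!file.exists(path)) .stopf("coverage file not found: %s", path)
  gr <- rtracklayer::import(path)
  if (length(gr) == 0L) .stopf("no coverage records in %s", path)
  sn <- as.character(GenomeInfoDb::seqnames(gr))
  if (is.null(repliconId)) {
    repliconId <- unique(sn)
    if (length(repliconId) > 1L)
      .stopf("%s covers several replicons (%s); pass repliconId",
             path, paste(repliconId, collapse = ", "))
  }
  gr <- gr[sn == repliconId]
  if (length(gr) == 0L)
    .stopf("replicon '%s' not present in %s", repliconId, path)
  L <- if (is.null(length)) max(BiocGenerics::end(gr)) else as.integer(length)
  depth <- numeric(L)
  st <- BiocGenerics::start(gr)
  en <- pmin(BiocGenerics::end(gr), L)
  sc <- gr$score
  for (j in seq_along(gr)) depth[st[j]:en[j]] <- sc[j]
  new("CoverageTrack", repliconId = repliconId, depth = depth, source = path)
}

#' Construct a CoverageTrack from a depth vector
#'
#' @param depth Numeric vector of non-negative per-position depths.
#' @param repliconId Replicon id label.
#' @param source Provenance label.
#' @return A [CoverageTrack-class].
#' @export
coverageTrack <- function(depth, repliconId = "replicon",
                          source = "in-memory") {
  new("CoverageTrack", repliconId = repliconId, depth = as.numeric(depth),
      source = source)
}

#' Write a CoverageTrack as fixed-step wig
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path (`.wig`).
#' @return `path`, invisibly.
#' @export
writeCoverageTrack <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=1 step=1 span=1",
                     track@repliconId), con)
  writeLines(format(track@depth, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Windowed mean coverage
#'
#' Averages depth over consecutive non-overlapping windows starting at
#' position 1. A trailing partial window is included iff it is at least half
#' a window long. Windows with zero mean are flagged unusable (they are
#' excluded from regressions).
#'
#' @param track A [CoverageTrack-class] or numeric depth vector.
#' @param window Window size in bp (default 5000).
#' @return A `data.frame` with columns `midpoint` (bp, centre of the
#'   window), `mean`, `n` (window width) and `usable`.
#' @export
windowMeans <- function(track, window = 5000L) {
  depth <- if (is(track, "CoverageTrack")) trackDepth(track) else
    as.numeric(track)
  window <- as.integer(window)
  if (window < 1L) .stopf("window must be >= 1")
  L <- length(depth)
  nFull <- L %/% window
  rem <- L - nFull * window
  bounds <- (seq_len(nFull) - 1L) * window
  widths <- rep(window, nFull)
  if (rem >= window / 2) {
    bounds <- c(bounds, nFull * window)
    widths <- c(widths, rem)
  }
  if (!length(bounds)) .stopf("track shorter than half a window")
  means <- vapply(seq_along(bounds), function(i)
    mean(depth[(bounds[i] + 1L):(bounds[i] + widths[i])]), numeric(1))
  if (all(means == 0)) .stopf("all windows have zero coverage (no signal)")
  data.frame(midpoint = bounds + widths / 2, mean = means, n = widths,
             usable = means > 0)
}

#' Marker-frequency analysis: per-replichore regression fit
#'
#' Estimates the origin/terminus copy-number ratio from a DNA-seq coverage
#' track. Coverage is averaged in consecutive windows; window midpoints are
#' unrolled on the circle so the origin is interior with the terminus at the
#' cut (ter defaults to the position diametrically opposite the origin);
#' log2 window means are regressed on position separately for the left and
#' right replichore; the regression-line values at their intersections near
#' the origin and near the terminus, transformed back from log space, give
#' `oriValue` and `terValue`, whose quotient is the copy-number ratio. With
#' `terNormalized = TRUE` the terminus is reported as copy number 1 and the
#' origin as the ratio. If the two lines are parallel (e.g. perfectly flat
#' coverage) there is no intersection; each line is then evaluated at the
#' origin and terminus positions and the two values averaged in log space,
#' with a warning.
#'
#' @param track A [CoverageTrack-class] or numeric depth vector.
#' @param oriPos 1-based position of the replication origin.
#' @param terPos Optional 1-based terminus position; default is diametrically
#'   opposite `oriPos`.
#' @param window Window size in bp (default 5000).
#' @param terNormalized Report copy numbers scaled so ter = 1 (default).
#' @return A [CopyNumberFit-class].
#' @examples
#' trk <- simulateCoverage(50000, oriPos = 25000, ratio = 4,
#'                         meanDepth = 100, noise = "none", seed = 1)
#' fit <- fitReplichores(trk, oriPos = 25000, window = 2500)
#' oriTerRatio(fit)
#' @export
fitReplichores <- function(track, oriPos, terPos = NULL, window = 5000L,
                           terNormalized = TRUE) {
  depth <- if (is(track, "CoverageTrack")) trackDepth(track) else
    as.numeric(track)
  repliconId <- if (is(track, "CoverageTrack")) track@repliconId else
    "replicon"
  L <- length(depth)
  oriPos <- as.numeric(oriPos)
  if (is.null(terPos)) terPos <- (oriPos - 1 + L / 2) %% L + 1
  terPos <- as.numeric(terPos)

  wm <- windowMeans(depth, window)
  u <- (wm$midpoint - terPos) %% L          # unrolled: ter at the cut
  uOri <- (oriPos - terPos) %% L            # origin interior
  side <- ifelse(u < uOri, "left", "right")
  use <- wm$usable
  if (sum(use & side == "left") < 3L || sum(use & side == "right") < 3L)
    .stopf("need >= 3 usable windows per replichore (got %d left, %d right)",
           sum(use & side == "left"), sum(use & side == "right"))

  fitLine <- function(idx) {
    cf <- stats::coef(stats::lm(log2(wm$mean[idx]) ~ u[idx]))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  fl <- fitLine(use & side == "left")
  fr <- fitLine(use & side == "right")
  a1 <- fl["intercept"]; b1 <- fl["slope"]
  a2 <- fr["intercept"]; b2 <- fr["slope"]

  tol <- 1e-12 * max(1, abs(b1), abs(b2))
  if (abs(b1 - b2) < tol) {
    warning("replichore regression lines are parallel; evaluating both ",
            "lines at ori/ter and averaging", call. = FALSE)
    oriLog <- mean(c(a1 + b1 * uOri, a2 + b2 * uOri))
    terLog <- mean(c(a1, a2 + b2 * L))      # the cut is both u = 0 and u = L
  } else {
    uStarOri <- (a2 - a1) / (b1 - b2)
    oriLog <- unname(a1 + b1 * uStarOri)
    # near ter the left line re-enters from the other side of the cut:
    # intersect right line with the left line shifted by one period
    uStarTer <- (a1 - b1 * L - a2) / (b2 - b1)
    terLog <- unname(a2 + b2 * uStarTer)
  }
  oriValue <- unname(2^oriLog)
  terValue <- unname(2^terLog)

  new("CopyNumberFit", repliconId = repliconId, oriPos = oriPos,
      terPos = terPos, window = as.integer(window), midpoints = u,
      logMeans = ifelse(wm$usable, log2(pmax(wm$mean, .Machine$double.xmin)),
                        NA_real_),
      usable = wm$usable, replichore = side,
      slopes = unname(c(b1, b2)), intercepts = unname(c(a1, a2)),
      oriValue = oriValue, terValue = terValue,
      ratio = oriValue / terValue, terNormalized = terNormalized)
}

#' Summarise copy-number fits across replicons
#'
#' One row per replicon with its origin(/oriV)-to-terminus fold change;
#' secondary chromosomes are treated identically with their own annotated
#' origin.
#'
#' @param fits A list of [CopyNumberFit-class] objects (optionally named).
#' @return A `data.frame` with columns `replicon`, `ori_ter_ratio`,
#'   `ori_copy_number`, `ter_copy_number`.
#' @export
multiRepliconSummary <- function(fits) {
  if (is(fits, "CopyNumberFit")) fits <- list(fits)
  if (!length(fits)) .stopf("need at least one fit")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    nm <- if (!is.null(names(fits)) && names(fits)[i] != "")
      names(fits)[i] else f@repliconId
    data.frame(replicon = nm, ori_ter_ratio = f@ratio,
               ori_copy_number = if (f@terNormalized) f@ratio else f@oriValue,
               ter_copy_number = if (f@terNormalized) 1 else f@terValue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
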