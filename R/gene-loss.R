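#' Resolve read loss at gene level
#'
#' For every gene of one organism, counts the enumerated reads (windows of
#' the pool's read length) whose interval overlaps the gene by at least one
#' bp — a read near a boundary therefore counts toward every gene it
#' touches — and partitions them into intra-organism-ambiguous and
#' inter-organism-ambiguous reads, classified exactly as in [readLoss()].
#' Percent denominators are the per-gene overlapping-read totals. Genes
#' overlapping the circular junction are supported through the wrap
#' convention of [enumerateReads()].
#'
#' @param pool A [PoolSpec-class].
#' @param organism Organism name within the pool.
#' @param genes A `GRanges` of gene features with a `gene_id` metadata
#'   column on the organism's replicons; defaults to the annotation stored
#'   in the pool.
#' @return A `data.frame` with columns `gene_id`, `organism`, `replicon`,
#'   `reads_total`, `reads_ambiguous_intra`, `reads_ambiguous_inter`,
#'   `intra_loss_pct`, `inter_loss_pct`, `total_loss_pct`, sorted by
#'   `total_loss_pct` descending with ties broken by `gene_id`.
#' @export
perGeneLoss <- function(pool, organism, genes = NULL) {
  stopifnot(is(pool, "PoolSpec"))
  if (!organism %in% organisms(pool))
    .stopf("organism '%s' is not a member of the pool", organism)
  if (is.null(genes)) genes <- poolGenes(pool)[[organism]]
  if (is.null(genes) || length(genes) == 0L) {
    return(data.frame(gene_id = character(), organism = character(),
                      replicon = character(), reads_total = integer(),
                      reads_ambiguous_intra = integer(),
                      reads_ambiguous_inter = integer(),
                      intra_loss_pct = numeric(), inter_loss_pct = numeric(),
                      total_loss_pct = numeric(), stringsAsFactors = FALSE))
  }
  orgMap <- repliconOrganism(pool)
  reps <- as.character(GenomeInfoDb::seqnames(genes))
  bad <- !(reps %in% names(orgMap)) | orgMap[reps] != organism
  if (any(bad))
    .stopf("gene '%s' lies on replicon '%s' which does not belong to '%s'",
           genes$gene_id[which(bad)[1L]], reps[which(bad)[1L]], organism)

  cls <- .positionClasses(pool)
  k <- readLength(pool)
  circ <- isCircular(pool)
  lens <- stats::setNames(Biostrings::width(replicons(pool)),
                          names(replicons(pool)))

  n <- length(genes)
  gs <- BiocGenerics::start(genes)
  ge <- BiocGenerics::end(genes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- reps[i]
    L <- lens[[r]]
    starts <- .overlappingStarts(gs[i], ge[i], L, k, circ[[r]])
    v <- cls[[r]][starts]
    total <- length(v)
    intra <- sum(v == "intra")
    inter <- sum(v == "inter")
    rows[[i]] <- data.frame(
      gene_id = genes$gene_id[i], organism = organism, replicon = r,
      reads_total = total, reads_ambiguous_intra = intra,
      reads_ambiguous_inter = inter,
      intra_loss_pct = if (total) 100 * intra / total else 0,
      inter_loss_pct = if (total) 100 * inter / total else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$total_loss_pct <- out$intra_loss_pct + out$inter_loss_pct
  out[order(-out$total_loss_pct, out$gene_id), , drop = FALSE]
}

# 1-based start positions of all enumerated windows of length k that
# overlap the (1-based, closed) gene interval [gs, ge] by >= 1 bp.
.overlappingStarts <- function(gs, ge, L, k, circular) {
  if (circular) {
    # valid starts form the circular interval [gs-k+1, ge] of length
    # (ge-gs) + k; cap at L when the gene plus margin spans the circle
    len <- min((ge - gs + 1L) + k - 1L, L)
    .mod1(gs - k + 1L + seq_len(len) - 1L, L)
  } else {
    lo <- max(1L, gs - k + 1L)
    hi <- min(ge, L - k + 1L)
    if (hi < lo) integer(0) else lo:hi
  }
}

#' Write gene-level and organism-level loss reports
#'
#' Emits one gene-list TSV per organism plus one pool-level summary TSV
#' (`read_loss_summary.tsv`), the file set produced by the `genecheck`
#' command. Row order is deterministic (the order of [perGeneLoss()]), and
#' a header line is always present, so identical inputs give byte-identical
#' outputs.
#'
#' @param geneRecords Named list (by organism) of [perGeneLoss()] frames.
#' @param report Organism-level [readLoss()] frame.
#' @param outDir Output directory (created if needed).
#' @return Character vector of file paths written, invisibly.
#' @export
writeLossReports <- function(geneRecords, report, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory: %s", outDir)
  paths <- character(0)
  for (o in names(geneRecords)) {
    p <- file.path(outDir, paste0(o, "_gene_loss.tsv"))
    utils::write.table(geneRecords[[o]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "read_loss_summary.tsv")
  utils::write.table(report, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
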