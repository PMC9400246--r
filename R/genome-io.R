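#' Load one organism's replicons and gene annotation
#'
#' Reads a (multi-record) FASTA of replicons and, optionally, a GFF3
#' annotation. Sequences are upper-cased on load; replicon ids are the first
#' whitespace-delimited token of each FASTA header. GFF features are
#' filtered to the requested feature types (default `"gene"`, falling back
#' to `"CDS"` when no gene features exist), features on replicons absent
#' from the FASTA are skipped with a warning, and out-of-bounds coordinates
#' are a hard error naming the offending feature. Gene ids are taken from
#' the GFF attributes in priority order `locus_tag` > `ID` > `Name` and
#' de-duplicated with a numeric suffix on collision.
#'
#' @param fasta Path to a FASTA file (conventionally `*.fna`).
#' @param gff Optional path to a GFF3 file paired with the FASTA.
#' @param organism Organism name; defaults to the FASTA basename.
#' @param featureTypes Character vector of GFF types to keep.
#' @return A list with elements `replicons` (a named
#'   [Biostrings::DNAStringSet]) and `genes` (a [GenomicRanges::GRanges]
#'   with a `gene_id` metadata column; empty when no GFF is given).
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' Biostrings::writeXStringSet(
#'   Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGT")), fa)
#' loadOrganism(fa, organism = "demo")$replicons
#' @export
loadOrganism <- function(fasta, gff = NULL, organism = NULL,
                         featureTypes = "gene") {
  if (!file.exists(fasta)) .stopf("FASTA file not found: %s", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) .stopf("empty FASTA: %s", fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    .stopf("duplicate replicon ids within %s", fasta)
  # normalise case without touching the alphabet
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (is.null(organism))
    organism <- tools::file_path_sans_ext(basename(fasta))

  genes <- GenomicRanges::GRanges()
  if (!is.null(gff)) {
    genes <- .loadGenes(gff, seqs, featureTypes)
  }
  list(replicons = seqs, genes = genes, organism = organism)
}

.loadGenes <- function(gff, seqs, featureTypes) {
  if (!file.exists(gff)) .stopf("GFF file not found: %s", gff)
  gr <- rtracklayer::import(gff, format = "gff3")
  if (length(gr) == 0L) return(GenomicRanges::GRanges())
  keep <- as.character(gr$type) %in% featureTypes
  if (!any(keep) && identical(featureTypes, "gene"))
    keep <- as.character(gr$type) %in% "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) return(GenomicRanges::GRanges())

  known <- as.character(GenomeInfoDb::seqnames(gr)) %in% names(seqs)
  if (any(!known)) {
    bad <- unique(as.character(GenomeInfoDb::seqnames(gr))[!known])
    warning("skipping ", sum(!known), " feature(s) on replicon id(s) ",
            "absent from the FASTA: ", paste(bad, collapse = ", "),
            call. = FALSE)
    gr <- gr[known]
  }
  if (length(gr) == 0L) return(GenomicRanges::GRanges())

  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  repl <- as.character(GenomeInfoDb::seqnames(gr))
  oob <- BiocGenerics::start(gr) < 1L |
    BiocGenerics::end(gr) > lens[repl]
  if (any(oob)) {
    i <- which(oob)[1L]
    .stopf("feature '%s' out of bounds on replicon %s (%d-%d, length %d)",
           .geneIds(gr)[i], repl[i], BiocGenerics::start(gr)[i],
           BiocGenerics::end(gr)[i], lens[repl[i]])
  }
  ids <- make.unique(.geneIds(gr), sep = "_")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = ids)
  GenomeInfoDb::seqlevels(gr) <- unique(repl)
  gr
}

# gene id priority: locus_tag > ID > Name > positional fallback
.geneIds <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  ids <- rep(NA_character_, length(gr))
  for (field in c("locus_tag", "ID", "Name")) {
    if (field %in% colnames(mc)) {
      v <- as.character(mc[[field]])
      ids[is.na(ids) & !is.na(v) & v != ""] <-
        v[is.na(ids) & !is.na(v) & v != ""]
    }
  }
  miss <- is.na(ids)
  if (any(miss))
    ids[miss] <- sprintf("feature_%06d", which(miss))
  ids
}

#' Assemble a pool of organisms into a PoolSpec
#'
#' Builds the registry that defines the single and pooled mapping universes.
#' Input is either a directory containing paired `<organism>.fna` /
#' `<organism>.gff` files (the `.gff` is optional per organism), or a named
#' list where each element is a `DNAStringSet` (or the list returned by
#' [loadOrganism()]). Organism order is input order. Replicon ids colliding
#' across organisms are rewritten as `"<organism>|<id>"` with a message.
#'
#' @param x Directory path or named list of organisms (see Details).
#' @param readLength Read length in bp used for enumeration (default 150).
#' @param mismatchAllowance Maximum mismatches for best-stratum resolution
#'   (default 1).
#' @param circular Logical, recycled per replicon: circularity flags
#'   (bacterial default `TRUE`).
#' @param featureTypes GFF feature types to keep when reading annotations.
#' @return A [PoolSpec-class] object.
#' @examples
#' pool <- buildPool(list(
#'   orgA = Biostrings::DNAStringSet(c(chr = "ACGTACGTACGTACGTACGT")),
#'   orgB = Biostrings::DNAStringSet(c(chr = "TTTTACGTACGTACGTCCCC"))),
#'   readLength = 8)
#' pool
#' @export
buildPool <- function(x, readLength = 150L, mismatchAllowance = 1L,
                      circular = TRUE, featureTypes = "gene") {
  if (.isString(x) && dir.exists(x)) {
    x <- .loadPoolDir(x, featureTypes)
  }
  if (!is.list(x) || length(x) < 1L)
    .stopf("need a directory or a non-empty named list of organisms")
  orgNames <- names(x)
  if (is.null(orgNames) || any(orgNames == ""))
    .stopf("every organism must be named")
  if (anyDuplicated(orgNames))
    .stopf("duplicate organism names: %s",
           paste(unique(orgNames[duplicated(orgNames)]), collapse = ", "))

  seqsList <- vector("list", length(x))
  genes <- list()
  for (i in seq_along(x)) {
    el <- x[[i]]
    if (is(el, "DNAStringSet")) {
      seqsList[[i]] <- el
    } else if (is.list(el) && !is.null(el$replicons)) {
      seqsList[[i]] <- el$replicons
      if (!is.null(el$genes) && length(el$genes))
        genes[[orgNames[i]]] <- el$genes
    } else {
      .stopf("organism '%s' must be a DNAStringSet or a loadOrganism() result",
             orgNames[i])
    }
    if (is.null(names(seqsList[[i]])) || any(names(seqsList[[i]]) == ""))
      .stopf("replicons of organism '%s' must be named", orgNames[i])
  }

  allIds <- unlist(lapply(seqsList, names), use.names = FALSE)
  dup <- unique(allIds[duplicated(allIds)])
  if (length(dup)) {
    for (i in seq_along(seqsList)) {
      hit <- names(seqsList[[i]]) %in% dup
      if (any(hit)) {
        old <- names(seqsList[[i]])[hit]
        new <- paste0(orgNames[i], "|", old)
        names(seqsList[[i]])[hit] <- new
        if (!is.null(genes[[orgNames[i]]])) {
          g <- genes[[orgNames[i]]]
          lv <- GenomeInfoDb::seqlevels(g)
          m <- match(lv, old)
          lv[!is.na(m)] <- new[m[!is.na(m)]]
          GenomeInfoDb::seqlevels(g) <- lv
          genes[[orgNames[i]]] <- g
        }
        message("replicon id collision: ",
                paste(sprintf("%s -> %s", old, new), collapse = ", "))
      }
    }
  }

  seqs <- do.call(c, seqsList)
  organism <- rep(orgNames, vapply(seqsList, length, 1L))
  circular <- rep_len(circular, length(seqs))
  new("PoolSpec", seqs = seqs, organism = organism, circular = circular,
      genes = genes, readLength = as.integer(readLength),
      mismatchAllowance = as.integer(mismatchAllowance))
}

# Folder convention: paired files sharing a basename, '.fna' + '.gff'.
.loadPoolDir <- function(dir, featureTypes = "gene") {
  fnas <- sort(list.files(dir, pattern = "\\.fna$", full.names = TRUE))
  if (!length(fnas)) .stopf("no .fna files found in %s", dir)
  out <- list()
  for (fa in fnas) {
    base <- tools::file_path_sans_ext(basename(fa))
    gff <- file.path(dir, paste0(base, ".gff"))
    out[[base]] <- loadOrganism(fa, gff = if (file.exists(gff)) gff,
                                organism = base,
                                featureTypes = featureTypes)
  }
  out
}

#' Write replicons back to FASTA
#'
#' @param seqs A named `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeReplicons <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
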