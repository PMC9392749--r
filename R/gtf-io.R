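# GTF and sample-sheet I/O. GTF parsing/writing delegates to rtracklayer;
# thin validation on top enforces the contracts the pipeline relies on
# (transcript_id present, CDS frames known when gene models are requested).

# Error (naming line numbers) if feature lines lack a transcript_id attribute.
.checkGtfAttributes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  feat <- sub("^[^\t]*\t[^\t]*\t([^\t]*)\t.*$", "\\1", lines)
  bad <- which(body & feat %in% c("transcript", "exon", "CDS") &
                 !grepl("transcript_id", lines, fixed = TRUE))
  if (length(bad))
    stop(sprintf("malformed GTF attribute block (no transcript_id) at line %s of %s",
                 paste(bad, collapse = ", "), path))
  invisible(TRUE)
}

#' Read transcript or gene models from a GTF file
#'
#' With \code{kind = "transcripts"} (StringTie-style per-sample assembly),
#' exon records are grouped by \code{transcript_id} into a
#' \code{\linkS4class{TranscriptSet}}; transcripts that have a
#' \code{transcript} record but no exon records are skipped with a warning.
#' With \code{kind = "genes"}, \code{CDS} records (with their frame column)
#' and gene extents are assembled into a \code{\linkS4class{GeneSet}}; when a
#' gene has several transcripts, the transcript with the longest total CDS
#' defines the canonical CDS.
#'
#' @param path path to a GTF file (1-based inclusive coordinates; converted
#'   to GRanges at import).
#' @param kind \code{"transcripts"} or \code{"genes"}.
#' @param sampleId sample label attached to transcripts; defaults to the file
#'   name without extension.
#' @return A \code{TranscriptSet} or a \code{GeneSet}.
#' @seealso \code{\link{writeGtf}}
#' @export
readGtf <- function(path, kind = c("transcripts", "genes"), sampleId = NULL) {
  kind <- match.arg(kind)
  .checkGtfAttributes(path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (kind == "transcripts") {
    if (is.null(sampleId))
      sampleId <- sub("\\.(gtf|gff2?)$", "", basename(path), ignore.case = TRUE)
    ex <- gr[mcols(gr)$type == "exon"]
    if (length(ex) == 0L) {
      warning(sprintf("%s: no exon records", path))
      return(TranscriptSet(GRangesList(), sampleId = character(0)))
    }
    txIds <- mcols(gr)$transcript_id[mcols(gr)$type == "transcript"]
    skipped <- setdiff(txIds, unique(mcols(ex)$transcript_id))
    if (length(skipped))
      warning(sprintf("%s: skipped %d transcript(s) with no exon records: %s",
                      path, length(skipped), paste(skipped, collapse = ", ")))
    exl <- split(ex, mcols(ex)$transcript_id)
    exl <- GRangesList(lapply(exl, function(g) { mcols(g) <- NULL; g }))
    TranscriptSet(exl, sampleId = sampleId)
  } else {
    if (!("gene_id" %in% colnames(mcols(gr))))
      stop(sprintf("%s: gene_id attribute missing", path))
    cds <- gr[mcols(gr)$type == "CDS"]
    if (length(cds) && any(is.na(mcols(cds)$phase)))
      stop(sprintf("%s: CDS record(s) without frame", path))
    gid <- mcols(gr)$gene_id
    gname <- if ("gene_name" %in% colnames(mcols(gr))) mcols(gr)$gene_name else gid
    gname[is.na(gname)] <- gid[is.na(gname)]
    gidU <- sort(unique(gid))
    first <- match(gidU, gid)
    genes <- GRanges(as.character(seqnames(gr))[first],
                     IRanges(as.integer(tapply(start(gr), gid, min)[gidU]),
                             as.integer(tapply(end(gr), gid, max)[gidU])),
                     strand = as.character(strand(gr))[first])
    mcols(genes)$gene_id <- gidU
    mcols(genes)$gene_name <- gname[first]
    names(genes) <- gidU

    cdsList <- GRangesList()
    if (length(cds)) {
      byTx <- split(cds, mcols(cds)$transcript_id)
      txGene <- vapply(byTx, function(g) mcols(g)$gene_id[1], character(1))
      txLen <- vapply(byTx, function(g) sum(width(g)), numeric(1))
      pick <- vapply(split(seq_along(byTx), txGene), function(ix) {
        ix[order(-txLen[ix], names(byTx)[ix])][1]
      }, integer(1))
      cdsList <- GRangesList(lapply(byTx[pick], function(g) {
        st <- as.character(strand(g))[1]
        g <- g[order(start(g), decreasing = identical(st, "-"))]
        fr <- mcols(g)$phase
        mcols(g) <- NULL
        mcols(g)$frame <- as.integer(fr)
        g
      }))
      names(cdsList) <- names(pick)
    }
    GeneSet(genes, cdsList)
  }
}

#' Write a TranscriptSet to GTF
#'
#' Emits one \code{transcript} record plus its \code{exon} records per
#' transcript, coordinates in ascending order, with \code{transcript_id} (and
#' \code{gene_id} when supplied) attributes. \code{readGtf(writeGtf(x))}
#' reproduces coordinates and attributes.
#'
#' @param x a \code{\linkS4class{TranscriptSet}}.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(x, path, source = "tcgtscan") {
  stopifnot(is(x, "TranscriptSet"))
  recs <- lapply(seq_along(x@exons), function(i) {
    g <- sort(x@exons[[i]])
    tx <- range(g)
    out <- c(tx, g)
    mcols(out)$type <- c("transcript", rep("exon", length(g)))
    mcols(out)$transcript_id <- x@txData$transcript_id[i]
    out
  })
  gr <- if (length(recs)) do.call(c, recs) else GRanges()
  if (length(gr) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  mcols(gr)$source <- source
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a sample sheet
#'
#' Two-column tab-separated file mapping \code{sample_id} to \code{group}
#' (e.g. tumor / normal, or tissue / cancer-type labels).
#'
#' @param path TSV path with header columns \code{sample_id}, \code{group}.
#' @return data.frame with character columns \code{sample_id}, \code{group}.
#' @export
readSampleSheet <- function(path) {
  sheet <- read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(sheet)))
    stop("sample sheet must have columns sample_id and group")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (nrow(sheet) == 0L) stop("sample sheet is empty")
  sheet[, c("sample_id", "group")]
}

#' Sizes of each sample group
#'
#' @param sheet sample sheet data.frame (\code{sample_id}, \code{group}).
#' @return named integer vector of samples per group.
#' @export
groupSizes <- function(sheet) {
  tab <- table(sheet$group)
  setNames(as.integer(tab), names(tab))
}
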