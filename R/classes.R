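# S4 containers for the three structured inputs of the pipeline:
# per-sample transcript models, gene models, and curated TE units.
# All genomic coordinates are GRanges (1-based, closed); external formats
# (GTF, RepeatMasker .out, BED) are converted at the I/O boundary only.

#' TranscriptSet: per-sample assembled transcript models
#'
#' Holds the exon structures of assembled transcripts (StringTie-style), one
#' element per transcript, exons ordered 5'->3' along the transcript, plus a
#' parallel table with transcript id, sample of origin, strand and the
#' 1-bp transcription start site (TSS). Unstranded transcripts are allowed in
#' the container but are excluded from chimera calling.
#'
#' @slot exons \code{GRangesList}, one element per transcript, exons ordered
#'   5'->3' (ascending start on \code{+}, descending on \code{-}).
#' @slot txData \code{DataFrame} with columns \code{transcript_id},
#'   \code{sample_id}, \code{chrom}, \code{strand}, \code{tss} (1-based
#'   genomic position of the 5'-most transcribed base), \code{n_exons}.
#' @seealso \code{\link{TranscriptSet}}, \code{\link{readGtf}}
#' @export
setClass("TranscriptSet", slots = c(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData must have the same length")
  if (!identical(names(ex), as.character(td$transcript_id)))
    return("names(exons) must equal txData$transcript_id")
  need <- c("transcript_id", "sample_id", "chrom", "strand", "tss", "n_exons")
  if (!all(need %in% colnames(td)))
    return(paste("txData missing column(s):",
                 paste(setdiff(need, colnames(td)), collapse = ", ")))
  if (anyDuplicated(td$transcript_id))
    return("transcript_id values must be unique")
  if (length(ex) == 0L) return(TRUE)
  lens <- lengths(ex)
  if (any(lens == 0L))
    return(sprintf("transcript %s has no exons", td$transcript_id[which(lens == 0L)[1]]))
  # vectorised per-transcript checks on the unlisted exons
  u <- unlist(ex, use.names = FALSE)
  grp <- rep(seq_along(ex), lens)
  first <- cumsum(lens) - lens + 1L
  chr <- as.character(seqnames(u))
  if (any(chr != chr[first][grp]))
    return(sprintf("transcript %s spans multiple chromosomes",
                   td$transcript_id[grp[which(chr != chr[first][grp])[1]]]))
  st <- td$strand
  dir <- ifelse(st == "-", -1L, 1L)
  s <- start(u) * dir[grp]
  e <- end(u) * dir[grp]
  notFirst <- seq_along(u)[-first]
  if (length(notFirst)) {
    prevEnd <- e[notFirst - 1L]
    if (any(s[notFirst] <= prevEnd))
      return(sprintf("transcript %s: exons overlapping or not in 5'->3' order",
                     td$transcript_id[grp[notFirst[which(s[notFirst] <= prevEnd)[1]]]]))
  }
  tssExp <- ifelse(st == "-", end(u)[first], start(u)[first])
  if (any(td$tss != tssExp))
    return(sprintf("transcript %s: tss does not match first exon terminus",
                   td$transcript_id[which(td$tss != tssExp)[1]]))
  if (any(td$n_exons != lens))
    return("n_exons mismatch")
  TRUE
})

#' Construct a TranscriptSet from raw exon structures
#'
#' Exon order within each transcript is normalised to transcript orientation
#' (5'->3'), and the TSS is derived as the strand-appropriate terminus of the
#' first exon.
#'
#' @param exons \code{GRangesList} of exons, one element per transcript,
#'   named by transcript id; each element must lie on one chromosome and one
#'   strand.
#' @param sampleId sample of origin, recycled to all transcripts (or a vector,
#'   one per transcript).
#' @return A \code{\linkS4class{TranscriptSet}}.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 400)),
#'                               strand = "+"))
#' TranscriptSet(ex, sampleId = "s1")
#' @export
TranscriptSet <- function(exons, sampleId = "sample") {
  stopifnot(is(exons, "GRangesList"))
  if (length(exons) == 0L)
    return(new("TranscriptSet", exons = exons,
               txData = DataFrame(transcript_id = character(0),
                                  sample_id = character(0), chrom = character(0),
                                  strand = character(0), tss = integer(0),
                                  n_exons = integer(0))))
  if (is.null(names(exons))) stop("exons must be named by transcript_id")
  sampleId <- rep_len(sampleId, length(exons))
  lens <- lengths(exons)
  u <- unlist(exons, use.names = FALSE)
  grp <- rep(seq_along(exons), lens)
  first <- cumsum(lens) - lens + 1L
  stAll <- as.character(strand(u))
  if (any(stAll != stAll[first][grp]))
    stop(sprintf("transcript %s: mixed strands",
                 names(exons)[grp[which(stAll != stAll[first][grp])[1]]]))
  st <- stAll[first]
  dir <- ifelse(st == "-", -1L, 1L)
  o <- order(grp, dir[grp] * start(u))
  ordered <- relist(u[o], exons)
  uo <- u[o]
  td <- DataFrame(
    transcript_id = names(exons),
    sample_id = sampleId,
    chrom = as.character(seqnames(u))[first],
    strand = st,
    tss = as.integer(ifelse(st == "-", end(uo)[first], start(uo)[first])),
    n_exons = lens)
  new("TranscriptSet", exons = ordered, txData = td)
}

#' @describeIn TranscriptSet exon structures, a \code{GRangesList} 5'->3'.
#' @param x a \code{TranscriptSet}.
#' @export
txExons <- function(x) { stopifnot(is(x, "TranscriptSet")); x@exons }

#' @describeIn TranscriptSet per-transcript table (\code{DataFrame}).
#' @export
txData <- function(x) { stopifnot(is(x, "TranscriptSet")); x@txData }

setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  cat(sprintf("TranscriptSet with %d transcript(s) from %d sample(s)\n",
              length(object), length(unique(object@txData$sample_id))))
  if (length(object) > 0) {
    n <- min(length(object), 5L)
    td <- object@txData[seq_len(n), , drop = FALSE]
    show(td)
    if (length(object) > n) cat(sprintf("... and %d more\n", length(object) - n))
  }
})

#' GeneSet: reference gene models with canonical CDS
#'
#' Gene bodies, coding exons and ordered CDS segments (with GTF frame) for the
#' annotated genes used as TcGT targets. The canonical CDS per gene is the
#' longest-CDS transcript when the annotation contains several.
#'
#' @slot genes \code{GRanges} of gene bodies (min start to max end over all
#'   features of the gene) with metadata columns \code{gene_id},
#'   \code{gene_name}; named by \code{gene_id}.
#' @slot codingExons \code{GRangesList} named by gene id: reduced union of the
#'   gene's CDS intervals.
#' @slot cds \code{GRangesList} named by gene id: canonical CDS segments
#'   ordered 5'->3' with metadata column \code{frame} (GTF convention: bases
#'   to skip to reach the next codon start). Genes without CDS have a
#'   zero-length element.
#' @seealso \code{\link{GeneSet}}, \code{\link{readGtf}}
#' @export
setClass("GeneSet", slots = c(genes = "GRanges", codingExons = "GRangesList",
                              cds = "GRangesList"))

setValidity("GeneSet", function(object) {
  if (length(object@genes) == 0L) return(TRUE)
  gid <- names(object@genes)
  if (is.null(gid) || anyDuplicated(gid)) return("genes must be uniquely named by gene_id")
  if (!all(c("gene_id", "gene_name") %in% colnames(mcols(object@genes))))
    return("genes must carry gene_id and gene_name metadata")
  if (!identical(sort(names(object@codingExons)), sort(gid)) ||
      !identical(sort(names(object@cds)), sort(gid)))
    return("codingExons and cds must be named by the same gene_ids as genes")
  for (g in gid) {
    cd <- object@cds[[g]]
    if (length(cd) > 0) {
      if (!("frame" %in% colnames(mcols(cd))))
        return(sprintf("gene %s: cds segments lack frame", g))
      if (!all(mcols(cd)$frame %in% 0:2))
        return(sprintf("gene %s: frame outside 0..2", g))
    }
  }
  TRUE
})

#' Construct a GeneSet
#'
#' @param genes \code{GRanges} of gene bodies with \code{gene_id},
#'   \code{gene_name} metadata columns.
#' @param cds \code{GRangesList} named by gene id, CDS segments ordered 5'->3'
#'   with a \code{frame} metadata column. Genes absent from \code{cds} get an
#'   empty element (non-coding).
#' @return A \code{\linkS4class{GeneSet}}.
#' @export
GeneSet <- function(genes, cds) {
  stopifnot(is(genes, "GRanges"), is(cds, "GRangesList"))
  if (is.null(names(genes))) names(genes) <- mcols(genes)$gene_id
  gid <- names(genes)
  if (length(gid) == 0L)
    return(new("GeneSet", genes = genes, codingExons = GRangesList(),
               cds = GRangesList()))
  missing <- setdiff(gid, names(cds))
  if (length(missing)) {
    empty <- GRangesList(lapply(missing, function(x) {
      g <- GRanges()
      mcols(g)$frame <- integer(0)
      g
    }))
    names(empty) <- missing
    cds <- c(cds, empty)
  }
  cds <- cds[gid]
  ce <- GRangesList(lapply(cds, function(x) reduce(x, ignore.strand = FALSE)))
  names(ce) <- gid
  new("GeneSet", genes = genes, codingExons = ce, cds = cds)
}

#' @describeIn GeneSet gene body ranges.
#' @param x a \code{GeneSet}.
#' @export
geneBodies <- function(x) { stopifnot(is(x, "GeneSet")); x@genes }

#' @describeIn GeneSet reduced coding-exon intervals per gene.
#' @export
codingExons <- function(x) { stopifnot(is(x, "GeneSet")); x@codingExons }

#' @describeIn GeneSet canonical CDS segments per gene, 5'->3' with frames.
#' @export
cdsSegments <- function(x) { stopifnot(is(x, "GeneSet")); x@cds }

setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  nc <- sum(lengths(object@cds) > 0)
  cat(sprintf("GeneSet with %d gene(s), %d protein-coding\n", length(object), nc))
  if (length(object) > 0) show(head(object@genes, 5))
})

#' CuratedTESet: curated transposable-element units
#'
#' Repeat units after curation: fragments of a single interrupted insertion
#' are fused into one unit, and flanking LTRs are grouped with their internal
#' ERV counterparts into proviral groups. TSS overlap in detection is tested
#' against the \emph{fragments}, never the fused span (the span may include
#' non-TE interior bases).
#'
#' @slot units \code{GRanges} of unit spans, named by \code{unit_id}, with
#'   metadata \code{unit_id}, \code{unit_name}, \code{unit_class},
#'   \code{role} (one of \code{solo}, \code{ltr5}, \code{internal},
#'   \code{ltr3}, \code{fused-fragment-unit}), \code{erv_group_id}
#'   (\code{NA} unless part of an LTR-internal-LTR group),
#'   \code{n_fragments}.
#' @slot fragments \code{GRangesList} named by unit_id: the original repeat
#'   pieces (ascending, disjoint) making up each unit.
#' @seealso \code{\link{fuseFragments}}, \code{\link{pairLtrInternal}},
#'   \code{\link{curateRepeats}}
#' @export
setClass("CuratedTESet", slots = c(units = "GRanges", fragments = "GRangesList"))

.teRoles <- c("solo", "ltr5", "internal", "ltr3", "fused-fragment-unit")

setValidity("CuratedTESet", function(object) {
  u <- object@units
  fr <- object@fragments
  if (length(u) != length(fr)) return("units and fragments lengths differ")
  if (!identical(names(u), names(fr))) return("units and fragments names differ")
  m <- mcols(u)
  need <- c("unit_id", "unit_name", "unit_class", "role", "erv_group_id", "n_fragments")
  if (!all(need %in% colnames(m)))
    return(paste("units missing metadata:", paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (length(u) && !all(m$role %in% .teRoles)) return("invalid role value")
  grouped <- m$role %in% c("ltr5", "internal", "ltr3")
  if (any(grouped & is.na(m$erv_group_id)))
    return("grouped units must carry an erv_group_id")
  for (i in seq_along(u)) {
    f <- fr[[i]]
    if (length(f) == 0L) return(sprintf("unit %s has no fragments", names(u)[i]))
    if (start(u)[i] > min(start(f)) || end(u)[i] < max(end(f)))
      return(sprintf("unit %s: fragments outside span", names(u)[i]))
    if (length(f) > 1L) {
      o <- order(start(f))
      if (any(start(f)[o][-1] <= end(f)[o][-length(f)]))
        return(sprintf("unit %s: fragments overlap", names(u)[i]))
    }
    if (m$n_fragments[i] != length(f))
      return(sprintf("unit %s: n_fragments mismatch", names(u)[i]))
  }
  TRUE
})

#' @describeIn CuratedTESet unit spans with curation metadata.
#' @param x a \code{CuratedTESet}.
#' @export
teUnits <- function(x) { stopifnot(is(x, "CuratedTESet")); x@units }

#' @describeIn CuratedTESet original repeat fragments per unit.
#' @export
teFragments <- function(x) { stopifnot(is(x, "CuratedTESet")); x@fragments }

setMethod("length", "CuratedTESet", function(x) length(x@units))

setMethod("[", "CuratedTESet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@units))
  new("CuratedTESet", units = x@units[i], fragments = x@fragments[i])
})

setMethod("show", "CuratedTESet", function(object) {
  m <- mcols(object@units)
  cat(sprintf("CuratedTESet with %d unit(s) (%d fused, %d in ERV groups)\n",
              length(object),
              sum(m$n_fragments > 1),
              sum(!is.na(m$erv_group_id))))
  if (length(object) > 0) show(head(object@units, 5))
})

# Internal constructor used by the curation stage.
.newCuratedTESet <- function(spans, fragments) {
  names(fragments) <- names(spans)
  new("CuratedTESet", units = spans, fragments = fragments)
}
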