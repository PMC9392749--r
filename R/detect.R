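# Per-sample TcGT calling. For each assembled transcript, in order:
#   (1) the 1-bp TSS must overlap a curated TE fragment (any TE strand);
#   (2) the first exon must not overlap an annotated gene;
#   (3) a downstream exon must overlap >= 1 bp of coding exons of a gene on
#       the same strand, which becomes the target gene.
# Everything else is discarded with an accounted reason.

.callColumns <- c("sample_id", "transcript_id", "gene_id", "gene_name",
                  "chrom", "strand", "tss", "tss_te_unit", "tss_te_name",
                  "te_chain", "n_exons", "coding_overlap_bp", "monoexonic")

.discardReasons <- c("unstranded", "tss_not_te", "first_exon_in_gene",
                     "no_coding_target")

.emptyCalls <- function() {
  df <- data.frame(sample_id = character(0), transcript_id = character(0),
                   gene_id = character(0), gene_name = character(0),
                   chrom = character(0), strand = character(0),
                   tss = integer(0), tss_te_unit = character(0),
                   tss_te_name = character(0), te_chain = character(0),
                   n_exons = integer(0), coding_overlap_bp = integer(0),
                   monoexonic = logical(0), stringsAsFactors = FALSE)
  df
}

.sortCalls <- function(calls) {
  calls[order(calls$sample_id, calls$chrom, calls$tss, calls$gene_id), ,
        drop = FALSE]
}

#' Detect transpochimeric gene transcripts in one sample set
#'
#' Applies the three-step chimera filter to every transcript and emits one
#' call per transcript that (1) initiates inside a curated TE fragment,
#' (2) has its first exon outside annotated genes, and (3) splices into
#' coding exons of a same-strand gene (the target gene, chosen by maximal
#' coding overlap; ties broken by total gene-body overlap, then gene id).
#' Unstranded transcripts are excluded up front (target-strand concordance is
#' undefined for them). Mono-exonic transcripts are admitted when the TSS is
#' in a TE, the 5' stretch of the exon up to the first coding-overlap base
#' lies outside all gene bodies, and the exon overlaps coding sequence; they
#' are flagged \code{monoexonic = TRUE}.
#'
#' Discarded transcripts are tallied by reason (\code{unstranded},
#' \code{tss_not_te}, \code{first_exon_in_gene}, \code{no_coding_target}) in
#' the \code{"discards"} attribute, retrievable with
#' \code{\link{discardTally}}; the input count is in attribute
#' \code{"n_input"} so that \code{n_input = nrow(calls) + sum(discards)}.
#'
#' @param transcripts a \code{\linkS4class{TranscriptSet}}.
#' @param genes a \code{\linkS4class{GeneSet}} (must be non-empty).
#' @param tes a \code{\linkS4class{CuratedTESet}} (must be non-empty;
#'   overlap is tested against fragments, not fused spans).
#' @param firstExonMask what "annotated gene" means for the first-exon
#'   discard: \code{"body"} (default; whole gene extent, any strand) or
#'   \code{"exons"} (coding exons only).
#' @return data.frame of calls, one row per chimeric transcript, sorted by
#'   (sample_id, chrom, tss, gene_id), with columns
#'   \code{sample_id, transcript_id, gene_id, gene_name, chrom, strand, tss,
#'   tss_te_unit, tss_te_name, te_chain} (comma-separated unit names in
#'   transcript order), \code{n_exons, coding_overlap_bp, monoexonic}.
#' @export
detectTcgts <- function(transcripts, genes, tes,
                        firstExonMask = c("body", "exons")) {
  firstExonMask <- match.arg(firstExonMask)
  stopifnot(is(transcripts, "TranscriptSet"), is(genes, "GeneSet"),
            is(tes, "CuratedTESet"))
  if (length(tes) == 0L) stop("empty curated TE set (curation step missed?)")
  if (length(genes) == 0L) stop("empty gene set")

  discards <- setNames(integer(length(.discardReasons)), .discardReasons)
  nInput <- length(transcripts)
  if (nInput == 0L) {
    out <- .emptyCalls()
    attr(out, "discards") <- discards
    attr(out, "n_input") <- 0L
    return(out)
  }

  td <- txData(transcripts)
  unstranded <- td$strand == "*"
  discards["unstranded"] <- sum(unstranded)

  fragAll <- unlist(teFragments(tes))
  fragUnit <- rep(names(teUnits(tes)), lengths(teFragments(tes)))
  unitName <- setNames(mcols(teUnits(tes))$unit_name, names(teUnits(tes)))

  bodies <- geneBodies(genes)
  ceAll <- unlist(codingExons(genes))
  ceGene <- rep(names(codingExons(genes)), lengths(codingExons(genes)))

  mask <- if (firstExonMask == "body") bodies else ceAll

  # flatten exon structures once; all overlap queries are batched
  exl <- txExons(transcripts)
  lens <- lengths(exl)
  u <- unlist(exl, use.names = FALSE)
  grp <- rep(seq_len(nInput), lens)
  exIdx <- sequence(lens)
  mono <- lens == 1L
  live <- !unstranded

  # (1) TSS in TE fragment; remember the lowest-id unit per transcript
  tssGR <- GRanges(td$chrom, IRanges(td$tss, td$tss))
  h1 <- findOverlaps(tssGR, fragAll, ignore.strand = TRUE)
  tssUnit <- rep(NA_character_, nInput)
  if (length(h1)) {
    hu <- fragUnit[subjectHits(h1)]
    o <- order(queryHits(h1), hu)
    keepFirst <- !duplicated(queryHits(h1)[o])
    tssUnit[queryHits(h1)[o][keepFirst]] <- hu[o][keepFirst]
  }
  tssInTe <- !is.na(tssUnit)
  discards["tss_not_te"] <- sum(live & !tssInTe)
  live <- live & tssInTe

  # coding-exon overlaps of candidate exons (downstream exons; the whole
  # exon for mono-exonic transcripts), same-strand genes only
  candSel <- (exIdx > 1L | mono[grp]) & live[grp]
  candIdx <- which(candSel)
  h3 <- findOverlaps(u[candIdx], ceAll, ignore.strand = TRUE)
  if (length(h3)) {
    txOf <- grp[candIdx][queryHits(h3)]
    sameStrand <- as.character(strand(ceAll))[subjectHits(h3)] == td$strand[txOf]
    h3 <- h3[sameStrand]
    txOf <- txOf[sameStrand]
  } else txOf <- integer(0)
  ovw <- integer(0); ovGene <- character(0)
  ovLo <- integer(0); ovHi <- integer(0)
  if (length(h3)) {
    pi <- pintersect(u[candIdx][queryHits(h3)], ceAll[subjectHits(h3)])
    ovw <- width(pi)
    ovLo <- start(pi); ovHi <- end(pi)
    ovGene <- ceGene[subjectHits(h3)]
  }

  # (2) first exon outside annotated genes (multi-exonic: the first exon;
  # mono-exonic: the 5' stretch up to the first coding-overlap base)
  firstPos <- cumsum(lens) - lens + 1L
  multiIdx <- which(live & !mono)
  feHit <- rep(FALSE, nInput)
  if (length(multiIdx)) {
    hf <- findOverlaps(u[firstPos[multiIdx]], mask, ignore.strand = TRUE)
    feHit[multiIdx[unique(queryHits(hf))]] <- TRUE
  }
  for (i in which(live & mono)) {
    ex1lo <- start(u)[firstPos[i]]; ex1hi <- end(u)[firstPos[i]]
    sel <- txOf == i
    lead <- c(ex1lo, ex1hi)
    if (any(sel)) {
      if (td$strand[i] == "-") {
        hi <- max(ovHi[sel])
        lead <- if (ex1hi > hi) c(hi + 1L, ex1hi) else NULL
      } else {
        lo <- min(ovLo[sel])
        lead <- if (ex1lo < lo) c(ex1lo, lo - 1L) else NULL
      }
    }
    if (!is.null(lead)) {
      lg <- GRanges(td$chrom[i], IRanges(lead[1], lead[2]))
      if (length(findOverlaps(lg, mask, ignore.strand = TRUE)) > 0L)
        feHit[i] <- TRUE
    }
  }
  discards["first_exon_in_gene"] <- sum(live & feHit)
  live <- live & !feHit

  # (3) target gene with maximal coding overlap on the same strand
  hasTarget <- rep(FALSE, nInput)
  covKey <- paste(txOf, ovGene, sep = "\r")
  covSum <- if (length(h3)) rowsum(ovw, covKey) else NULL
  covTx <- if (length(h3))
    as.integer(sub("\r.*$", "", rownames(covSum))) else integer(0)
  covGene <- if (length(h3)) sub("^[^\r]*\r", "", rownames(covSum)) else character(0)
  hasTarget[unique(covTx)] <- TRUE
  discards["no_coding_target"] <- sum(live & !hasTarget)
  live <- live & hasTarget

  # TE chain for surviving transcripts, in transcript order
  liveExon <- live[grp]
  hT <- findOverlaps(u[liveExon], fragAll, ignore.strand = TRUE)
  chainTx <- grp[liveExon][queryHits(hT)]
  chainExIdx <- exIdx[liveExon][queryHits(hT)]
  chainStart <- start(fragAll)[subjectHits(hT)]
  chainUnit <- fragUnit[subjectHits(hT)]

  geneName <- setNames(mcols(bodies)$gene_name, names(bodies))
  rows <- vector("list", nInput)
  for (i in which(live)) {
    sel <- covTx == i
    cov <- setNames(as.vector(covSum[sel, 1]), covGene[sel])
    best <- max(cov)
    tied <- sort(names(cov)[cov == best])
    if (length(tied) > 1L) {
      exsI <- which(grp == i)
      ovb <- findOverlaps(u[exsI], bodies[tied], ignore.strand = TRUE)
      tot <- setNames(numeric(length(tied)), tied)
      if (length(ovb)) {
        w <- width(pintersect(u[exsI][queryHits(ovb)],
                              bodies[tied][subjectHits(ovb)]))
        agg <- rowsum(w, tied[subjectHits(ovb)])
        tot[rownames(agg)] <- agg[, 1]
      }
      tied <- tied[order(-tot, tied)]
    }
    target <- tied[1]
    selC <- chainTx == i
    chain <- character(0)
    if (any(selC)) {
      along <- if (td$strand[i] == "-") -chainStart[selC] else chainStart[selC]
      o <- order(chainExIdx[selC], along)
      chain <- unique(unitName[chainUnit[selC][o]])
    }
    rows[[i]] <- data.frame(
      sample_id = td$sample_id[i], transcript_id = td$transcript_id[i],
      gene_id = target, gene_name = unname(geneName[target]),
      chrom = td$chrom[i], strand = td$strand[i], tss = as.integer(td$tss[i]),
      tss_te_unit = tssUnit[i], tss_te_name = unname(unitName[tssUnit[i]]),
      te_chain = paste(chain, collapse = ","),
      n_exons = lens[i], coding_overlap_bp = as.integer(best),
      monoexonic = mono[i], stringsAsFactors = FALSE)
  }

  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls)) calls <- .emptyCalls()
  calls <- .sortCalls(calls)
  rownames(calls) <- NULL
  attr(calls, "discards") <- discards
  attr(calls, "n_input") <- nInput
  calls
}

#' @describeIn detectTcgts per-reason discard counts of a call table.
#' @param calls a call data.frame from \code{detectTcgts}.
#' @export
discardTally <- function(calls) attr(calls, "discards")

#' Write TcGT calls to TSV
#'
#' Fixed, documented column set; rows sorted by
#' (sample_id, chrom, tss, gene_id); byte-deterministic for identical input.
#'
#' @param calls call data.frame from \code{\link{detectTcgts}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(calls, path) {
  stopifnot(all(.callColumns %in% colnames(calls)))
  out <- .sortCalls(calls[, .callColumns, drop = FALSE])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TcGT calls from TSV
#'
#' @param path TSV written by \code{\link{writeCalls}}. An unknown column
#'   triggers an error naming it.
#' @return call data.frame (lossless round trip of \code{writeCalls}).
#' @export
readCalls <- function(path) {
  df <- read.delim(path, colClasses = "character")
  extra <- setdiff(colnames(df), .callColumns)
  if (length(extra))
    stop(sprintf("unknown column(s) in calls file: %s", paste(extra, collapse = ", ")))
  miss <- setdiff(.callColumns, colnames(df))
  if (length(miss))
    stop(sprintf("missing column(s) in calls file: %s", paste(miss, collapse = ", ")))
  df$tss <- as.integer(df$tss)
  df$n_exons <- as.integer(df$n_exons)
  df$coding_overlap_bp <- as.integer(df$coding_overlap_bp)
  df$monoexonic <- as.logical(df$monoexonic)
  df <- .sortCalls(df[, .callColumns, drop = FALSE])
  rownames(df) <- NULL
  df
}
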