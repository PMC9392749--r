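# ORF prediction and protein-product classification. The predicted chimeric
# ORF is compared with the gene's canonical CDS on genomic coordinates and
# codon frames, not protein strings, so splice-altered isoforms that share
# sequence by coincidence are not mislabelled; protein-string containment is
# a secondary check for the extension/truncation classes.

#' Product class vocabulary
#'
#' The categories a chimeric transcript's predicted protein can take relative
#' to the target gene's canonical protein.
#'
#' @return character vector: \code{canonical}, \code{N-trunc},
#'   \code{C-trunc}, \code{N-C-trunc}, \code{N-ext}, \code{C-ext},
#'   \code{out-of-frame}, \code{non-coding}.
#' @export
productClasses <- function() {
  c("canonical", "N-trunc", "C-trunc", "N-C-trunc", "N-ext", "C-ext",
    "out-of-frame", "non-coding")
}

#' Predict the ORF of a spliced transcript sequence
#'
#' Returns the longest ATG-initiated open reading frame terminated by an
#' in-frame stop codon within the transcript; ties are broken 5'-most.
#' \code{NULL} if no ORF reaches \code{minOrfCodons} codons (stop excluded).
#'
#' @param cdna spliced transcript sequence (characters ACGTN; case
#'   insensitive).
#' @param minOrfCodons minimum ORF length in codons, stop codon excluded
#'   (default 30; screens spurious micro-ORFs).
#' @return \code{NULL}, or a list with \code{start} (1-based position of the
#'   A of ATG), \code{end} (1-based position of the last base of the stop
#'   codon), \code{n_codons} (coding codons, stop excluded) and
#'   \code{protein} (amino acids, no terminal stop).
#' @examples
#' predictOrf("ATGGCTGCTTAA", minOrfCodons = 1)$protein  # "MAA"
#' @export
predictOrf <- function(cdna, minOrfCodons = 30) {
  cdna <- toupper(cdna)
  if (nchar(cdna) < 3L) stop("cdna must be at least 3 bases")
  if (grepl("[^ACGTN]", cdna)) stop("cdna contains characters other than ACGTN")
  n <- nchar(cdna)
  tri <- substring(cdna, seq_len(n - 2L), seq_len(n - 2L) + 2L)
  atg <- which(tri == "ATG")
  stops <- which(tri %in% c("TAA", "TAG", "TGA"))
  if (length(atg) == 0L || length(stops) == 0L) return(NULL)
  best <- NULL
  stopsByFrame <- split(stops, (stops - 1L) %% 3L)
  for (a in atg) {
    fr <- as.character((a - 1L) %% 3L)
    s <- stopsByFrame[[fr]]
    s <- s[s >= a + 3L]
    if (length(s) == 0L) next
    s <- s[1]
    codons <- (s - a) %/% 3L
    if (codons < minOrfCodons) next
    if (is.null(best) || codons > best$n_codons) {
      best <- list(start = a, end = s + 2L, n_codons = codons)
    }
  }
  if (is.null(best)) return(NULL)
  coding <- substr(cdna, best$start, best$end - 3L)
  best$protein <- as.character(translate(DNAString(coding), if.fuzzy.codon = "X"))
  best
}

#' Map cDNA coordinates to genomic CDS segments
#'
#' Projects a cDNA interval (e.g. a predicted ORF's coding part) through the
#' transcript's exon structure into ordered genomic segments.
#'
#' @param exons transcript exons, \code{GRanges} ordered 5'->3'.
#' @param start,end 1-based inclusive cDNA coordinates.
#' @return \code{GRanges} of genomic segments ordered 5'->3'.
#' @export
cdnaToGenomic <- function(exons, start, end) {
  stopifnot(is(exons, "GRanges"), start >= 1, end >= start)
  w <- width(exons)
  if (end > sum(w)) stop("cDNA interval beyond transcript length")
  cumEnd <- cumsum(w)
  cumStart <- cumEnd - w + 1L
  minus <- identical(as.character(strand(exons))[1], "-")
  segs <- list()
  for (i in seq_along(exons)) {
    lo <- max(start, cumStart[i])
    hi <- min(end, cumEnd[i])
    if (lo > hi) next
    offL <- lo - cumStart[i]
    offH <- hi - cumStart[i]
    if (minus) {
      gEnd <- end(exons)[i] - offL
      gStart <- end(exons)[i] - offH
    } else {
      gStart <- start(exons)[i] + offL
      gEnd <- start(exons)[i] + offH
    }
    segs[[length(segs) + 1L]] <-
      GRanges(seqnames(exons)[i], IRanges(gStart, gEnd), strand = strand(exons)[i])
  }
  do.call(c, segs)
}

# Genomic positions (in transcript order) and codon phase (0 = codon start)
# of each base of a CDS. `trim` = leading bases to skip (GTF frame of the
# first segment for canonical CDS; 0 for a predicted ORF's coding part).
.cdsBasePhases <- function(cds, trim = 0L) {
  minus <- identical(as.character(strand(cds))[1], "-")
  pos <- unlist(lapply(seq_along(cds), function(i) {
    if (minus) seq(end(cds)[i], start(cds)[i]) else seq(start(cds)[i], end(cds)[i])
  }))
  if (trim > 0L) pos <- pos[-seq_len(trim)]
  list(pos = pos, phase = (seq_along(pos) - 1L) %% 3L,
       chrom = as.character(seqnames(cds))[1],
       strand = as.character(strand(cds))[1])
}

#' Classify a predicted ORF's product relative to the canonical protein
#'
#' Compares the predicted genomic CDS (stop codon excluded) with the gene's
#' canonical CDS segments by position and codon frame:
#' \describe{
#'   \item{canonical}{identical genomic CDS (same start, stop and frames).}
#'   \item{N-ext / N-trunc}{same stop and frame; start strictly upstream /
#'     downstream in frame.}
#'   \item{C-ext / C-trunc}{same start; stop strictly downstream / upstream
#'     in frame.}
#'   \item{N-C-trunc}{both ends strictly inside, frame preserved.}
#'   \item{out-of-frame}{at least half of the genomically shared bases are
#'     read in a different frame.}
#'   \item{non-coding}{no ORF, or an ORF with zero genomic overlap with the
#'     canonical CDS.}
#' }
#' Mixed frame-preserving combinations not in this table (e.g. extended at
#' one end, truncated at the other) take the N-side label; an anchors-equal
#' CDS with a different interior splice falls to \code{N-C-trunc}. For the
#' extension/truncation classes, protein-string containment between
#' \code{protein} and \code{canonicalProtein} is asserted as a secondary
#' check (a warning is raised when it fails).
#'
#' @param predCds predicted genomic CDS segments 5'->3' (stop codon
#'   excluded), e.g. from \code{\link{cdnaToGenomic}}; or \code{NULL} for no
#'   ORF.
#' @param gene canonical CDS segments of the target gene (\code{GRanges}
#'   5'->3' with \code{frame} metadata, as stored in a
#'   \code{\linkS4class{GeneSet}}).
#' @param protein,canonicalProtein optional amino-acid strings for the
#'   secondary containment check.
#' @param outFrameMinFrac fraction of shared bases that must be
#'   frame-shifted to call \code{out-of-frame} (default 0.5).
#' @return one element of \code{\link{productClasses}()}.
#' @export
classifyProduct <- function(predCds, gene, protein = NULL,
                            canonicalProtein = NULL, outFrameMinFrac = 0.5) {
  if (is.null(gene) || length(gene) == 0L)
    stop("gene has no CDS segments")
  if (is.null(predCds) || length(predCds) == 0L) return("non-coding")
  can <- .cdsBasePhases(gene, trim = mcols(gene)$frame[1])
  pred <- .cdsBasePhases(predCds, trim = 0L)
  if (can$chrom != pred$chrom || can$strand != pred$strand)
    return("non-coding")
  shared <- intersect(pred$pos, can$pos)
  if (length(shared) == 0L) return("non-coding")
  mism <- mean(pred$phase[match(shared, pred$pos)] !=
                 can$phase[match(shared, can$pos)])
  if (mism >= outFrameMinFrac) return("out-of-frame")

  minus <- can$strand == "-"
  rel5 <- function(p, c0) {           # predicted 5' start vs canonical
    if (p == c0) "eq" else if ((p < c0) != minus) "up" else "down"
  }
  rel3 <- function(p, c0) {           # predicted 3' end vs canonical
    if (p == c0) "eq" else if ((p > c0) != minus) "down" else "up"
  }
  sRel <- rel5(pred$pos[1], can$pos[1])
  eRel <- rel3(pred$pos[length(pred$pos)], can$pos[length(can$pos)])

  label <-
    if (sRel == "eq" && eRel == "eq") {
      if (setequal(pred$pos, can$pos)) "canonical" else "N-C-trunc"
    } else if (sRel == "up" && eRel == "eq") "N-ext"
    else if (sRel == "eq" && eRel == "down") "C-ext"
    else if (sRel == "down" && eRel == "eq") "N-trunc"
    else if (sRel == "eq" && eRel == "up") "C-trunc"
    else if (sRel == "down" && eRel == "up") "N-C-trunc"
    else if (sRel == "up") "N-ext"      # mixed: N-side label
    else "N-trunc"

  if (!is.null(protein) && !is.null(canonicalProtein)) {
    ok <- switch(label,
      "N-ext" = endsWith(protein, canonicalProtein),
      "N-trunc" = endsWith(canonicalProtein, protein),
      "C-ext" = startsWith(protein, canonicalProtein) &&
        nchar(protein) > nchar(canonicalProtein),
      "C-trunc" = startsWith(canonicalProtein, protein),
      TRUE)
    if (!isTRUE(ok))
      warning(sprintf("protein containment check failed for class %s", label))
  }
  label
}

#' Classify the protein products of TcGT calls
#'
#' Batch driver: for each call, extracts the spliced transcript sequence,
#' predicts the ORF, maps its coding part to genomic CDS segments and
#' classifies it against the target gene's canonical CDS. Calls on genes
#' lacking CDS annotation are labelled \code{non-coding} with a warning.
#'
#' @param calls call data.frame (see \code{\link{detectTcgts}}).
#' @param transcripts the \code{\linkS4class{TranscriptSet}} the calls came
#'   from (matched by \code{transcript_id}).
#' @param genes a \code{\linkS4class{GeneSet}}.
#' @param genome a \code{DNAStringSet}.
#' @param minOrfCodons minimum ORF length (codons, default 30).
#' @return data.frame with columns \code{sample_id, transcript_id, gene_id,
#'   product_class}, in the order of \code{calls}.
#' @export
classifyCalls <- function(calls, transcripts, genes, genome, minOrfCodons = 30) {
  stopifnot(is(transcripts, "TranscriptSet"), is(genes, "GeneSet"))
  td <- txData(transcripts)
  cls <- character(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    i <- match(calls$transcript_id[k], td$transcript_id)
    if (is.na(i))
      stop(sprintf("transcript %s not in TranscriptSet", calls$transcript_id[k]))
    gid <- calls$gene_id[k]
    cds <- cdsSegments(genes)[[gid]]
    if (is.null(cds) || length(cds) == 0L) {
      warning(sprintf("gene %s has no CDS annotation; calling non-coding", gid))
      cls[k] <- "non-coding"
      next
    }
    ex <- txExons(transcripts)[[i]]
    cdna <- extractSplicedSequence(ex, genome)
    orf <- predictOrf(cdna, minOrfCodons = minOrfCodons)
    if (is.null(orf)) {
      cls[k] <- "non-coding"
      next
    }
    predCds <- cdnaToGenomic(ex, orf$start, orf$end - 3L)
    cls[k] <- classifyProduct(predCds, cds, protein = orf$protein,
                              canonicalProtein = canonicalProtein(genes, gid, genome))
  }
  data.frame(sample_id = calls$sample_id, transcript_id = calls$transcript_id,
             gene_id = calls$gene_id, product_class = cls,
             stringsAsFactors = FALSE)
}
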