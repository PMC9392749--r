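# Genome sequence access: spliced transcript sequence and canonical proteins.

#' Read a genome FASTA
#'
#' @param path FASTA path. Sequence names are truncated at the first
#'   whitespace, matching common contig naming.
#' @return A \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract the spliced sequence of a transcript
#'
#' Exon sequences are concatenated 5'->3' in transcript orientation and
#' reverse-complemented for minus-strand transcripts; output is uppercase.
#'
#' @param exons a \code{GRanges} of exons ordered 5'->3' (as stored in a
#'   \code{\linkS4class{TranscriptSet}}), all on one chromosome/strand.
#' @param genome a \code{DNAStringSet} (see \code{\link{readGenome}}).
#' @return single character string (the cDNA).
#' @examples
#' genome <- Biostrings::DNAStringSet(c(c1 = "ACGTAA"))
#' ex <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 6), strand = "-")
#' extractSplicedSequence(ex, genome)  # "TTACGT"
#' @export
extractSplicedSequence <- function(exons, genome) {
  stopifnot(is(exons, "GRanges"), is(genome, "DNAStringSet"))
  if (length(exons) == 0L) return("")
  chrom <- as.character(seqnames(exons))[1]
  if (!(chrom %in% names(genome)))
    stop(sprintf("contig %s not in genome", chrom))
  contig <- genome[[chrom]]
  if (any(end(exons) > length(contig)) || any(start(exons) < 1L))
    stop(sprintf("exon outside contig %s bounds (length %d)", chrom, length(contig)))
  st <- as.character(strand(exons))[1]
  plus <- sort(exons)
  seq <- unlist(lapply(seq_along(plus), function(i)
    as.character(subseq(contig, start(plus)[i], end(plus)[i]))))
  seq <- paste(seq, collapse = "")
  if (st == "-")
    seq <- as.character(reverseComplement(DNAString(seq)))
  toupper(seq)
}

# Spliced CDS sequence of a gene's canonical CDS (frame of the first segment
# trims any leading partial codon).
.canonicalCdsSeq <- function(gs, geneId, genome) {
  cds <- cdsSegments(gs)[[geneId]]
  if (is.null(cds) || length(cds) == 0L)
    stop(sprintf("gene %s has no CDS segments", geneId))
  seq <- extractSplicedSequence(cds, genome)
  trim <- mcols(cds)$frame[1]
  if (trim > 0) seq <- substr(seq, trim + 1L, nchar(seq))
  seq
}

#' Canonical protein of a gene
#'
#' Splices the canonical CDS segments 5'->3', trims the frame offset of the
#' first segment, and translates. For a well-formed protein-coding gene the
#' result starts with M and contains no internal stop (the CDS excludes the
#' stop codon, Ensembl convention).
#'
#' @param gs a \code{\linkS4class{GeneSet}}.
#' @param geneId gene identifier.
#' @param genome a \code{DNAStringSet}.
#' @return single character string (amino acids).
#' @export
canonicalProtein <- function(gs, geneId, genome) {
  seq <- .canonicalCdsSeq(gs, geneId, genome)
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3L) stop(sprintf("gene %s: CDS shorter than one codon", geneId))
  as.character(translate(DNAString(substr(seq, 1L, n)), if.fuzzy.codon = "X"))
}

#' Validate translatability of all coding genes
#'
#' Checks, for every gene with CDS segments, that the concatenated CDS length
#' is a multiple of 3 after frame handling, that translation starts with M
#' and that it contains no internal stop. Used as a self-check on reference
#' annotations and generated fixtures.
#'
#' @param gs a \code{\linkS4class{GeneSet}}.
#' @param genome a \code{DNAStringSet}.
#' @return named logical vector (TRUE = valid), one element per coding gene,
#'   with failure reasons in a \code{"reasons"} attribute.
#' @export
validateGeneModels <- function(gs, genome) {
  coding <- names(cdsSegments(gs))[lengths(cdsSegments(gs)) > 0]
  ok <- logical(length(coding))
  names(ok) <- coding
  reasons <- character(length(coding))
  for (i in seq_along(coding)) {
    g <- coding[i]
    seq <- .canonicalCdsSeq(gs, g, genome)
    prot <- canonicalProtein(gs, g, genome)
    if (nchar(seq) %% 3 != 0) reasons[i] <- "CDS length not a multiple of 3"
    else if (!startsWith(prot, "M")) reasons[i] <- "does not start with M"
    else if (grepl("*", prot, fixed = TRUE)) reasons[i] <- "internal stop codon"
    ok[i] <- reasons[i] == ""
  }
  attr(ok, "reasons") <- setNames(reasons, coding)
  ok
}
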