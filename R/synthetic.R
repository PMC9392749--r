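# Deterministic synthetic cohorts: a toy genome with planted TcGTs and
# decoys at controlled prevalences, plus machine-readable ground truth, so
# every pipeline stage is testable without external data.
#
# The toy genome background alphabet is {A, C, G} (no T) outside planted
# coding signals: start and stop codons then exist only where planted, which
# makes each event's ORF — and hence its product-class truth — exact by
# construction. Layout (contig chrS1, all plus strand):
#   5000- 8799   LTR43 / LTR43-int / LTR43 provirus (event E2 promoter)
#  12000-12299   AluSx4 (event E3 promoter)
#  15000-15299   AluSx2 (decoy D3 promoter)
#  17000-19599   LTR12C, two fragments sharing a linkage ID (fusion demo)
#  22000-33000   genes G1..G6 (3 exons, 90-codon CDS each);
#                AluY inside G2's first intron (decoy D2 promoter)
#  81000-87799   LTR66, AluSx1, LTR33, L2b, MLT1F1 in a gene desert
#  90000-90462   RTG1, a mono-exonic retrogene (event E1 target)

.SYN <- local({
  geneStart <- c(G1 = 22000L, G2 = 24000L, G3 = 26000L, G4 = 28000L,
                 G5 = 30000L, G6 = 32000L)
  rtgStart <- 90000L
  te <- data.frame(
    name = c("LTR43", "LTR43-int", "LTR43", "AluSx4", "AluSx2",
             "LTR12C", "LTR12C", "AluY", "LTR66", "AluSx1", "LTR33",
             "L2b", "MLT1F1"),
    class = c("LTR/ERVL", "LTR/ERVL", "LTR/ERVL", "SINE/Alu", "SINE/Alu",
              "LTR/ERV1", "LTR/ERV1", "SINE/Alu", "LTR/ERVL", "SINE/Alu",
              "LTR/ERVL", "LINE/L2", "LTR/ERVL-MaLR"),
    start = c(5000L, 5900L, 8400L, 12000L, 15000L, 17000L, 19400L,
              geneStart[["G2"]] + 140L, 81000L, 83000L, 84500L, 86000L, 87500L),
    end = c(5399L, 7899L, 8799L, 12299L, 15299L, 17199L, 19599L,
            geneStart[["G2"]] + 409L, 81599L, 83299L, 84899L, 86349L, 87799L),
    linkage = c(1L, 2L, 3L, 4L, 5L, 6L, 6L, 7L, 8L, 9L, 10L, 11L, 12L),
    divergence = c(12.1, 15.4, 12.3, 8.0, 9.2, 14.7, 14.9, 3.1, 10.5,
                   11.0, 18.2, 21.4, 16.8),
    stringsAsFactors = FALSE)
  list(geneStart = geneStart, rtgStart = rtgStart, te = te,
       # after fusion the 13 rows collapse into 12 units (LTR12C pair fuses)
       nCuratedUnits = 12L,
       minGenomeSize = 95000L)
})

# Exon template of one of the built-in planted events; exon1 start is
# anchor + jitter offset, everything else fixed.
.synEventTemplates <- function() {
  gs <- .SYN$geneStart
  rtg <- .SYN$rtgStart
  list(
    E1 = list(gene_id = "RTG1", tss_te = "LTR66", anchor = 81100L,
              exon1_end = 81550L, max_jitter = 440L,
              downstream = cbind(start = c(83100L, 84600L, 86100L, 87550L, 89980L),
                                 end = c(83199L, 84699L, 86199L, 87649L, 90470L)),
              te_chain = c("LTR66", "AluSx1", "LTR33", "L2b", "MLT1F1"),
              product = "canonical"),
    E2 = list(gene_id = "G1", tss_te = "LTR43", anchor = 5100L,
              exon1_end = 5250L, max_jitter = 140L,
              downstream = cbind(start = gs[["G1"]] + c(420L, 840L),
                                 end = gs[["G1"]] + c(539L, 959L)),
              te_chain = "LTR43",
              product = "N-trunc"),
    E3 = list(gene_id = "G3", tss_te = "AluSx4", anchor = 12100L,
              exon1_end = 12250L, max_jitter = 100L,
              downstream = cbind(start = gs[["G3"]] + c(421L, 840L),
                                 end = gs[["G3"]] + c(539L, 980L)),
              te_chain = "AluSx4",
              product = "out-of-frame"))
}

#' Default planted-event table
#'
#' Three events from the built-in template library: \code{E1}, a canonical
#' chimera starting in a gene-desert LTR66 and splicing through four TE
#' copies into the mono-exonic retrogene RTG1 (tumor prevalence 0.40, absent
#' from normals); \code{E2}, an N-truncating chimera from a proviral 5' LTR
#' (0.25 tumor / 0.05 normal); \code{E3}, an out-of-frame chimera from an Alu
#' copy (0.10 tumor, absent from normals — below the recurrence threshold).
#'
#' @return data.frame with columns \code{event_id, gene_id, tss_te,
#'   tumor_prevalence, normal_prevalence, tss_jitter_bp, bimodal,
#'   product_class_truth}.
#' @export
defaultEvents <- function() {
  tmpl <- .synEventTemplates()
  data.frame(
    event_id = c("E1", "E2", "E3"),
    gene_id = vapply(tmpl, `[[`, character(1), "gene_id"),
    tss_te = vapply(tmpl, `[[`, character(1), "tss_te"),
    tumor_prevalence = c(0.40, 0.25, 0.10),
    normal_prevalence = c(0.00, 0.05, 0.00),
    tss_jitter_bp = c(40L, 40L, 30L),
    bimodal = c(FALSE, FALSE, FALSE),
    product_class_truth = vapply(tmpl, `[[`, character(1), "product"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Specify a synthetic cohort design
#'
#' @param seed integer seed driving all randomness (genome fill, prevalence
#'   draws, TSS jitter).
#' @param nTumor,nNormal samples per group (default 50 each).
#' @param events planted-event table (see \code{\link{defaultEvents}});
#'   \code{event_id} must come from the built-in template library
#'   (\code{E1}, \code{E2}, \code{E3}); prevalences, jitter and bimodality
#'   are free.
#' @param nDecoysPerSample decoy transcripts per sample, cycling through the
#'   three decoy types that mirror the discard reasons: TSS just outside a
#'   TE, first exon inside a gene body, TE start with no coding target
#'   (default 3, one of each).
#' @param genomeSize toy genome length in bp (default 200000; must fit all
#'   planted structures).
#' @return object of class \code{CohortDesign}.
#' @export
cohortDesign <- function(seed = 1, nTumor = 50, nNormal = 50,
                         events = defaultEvents(), nDecoysPerSample = 3,
                         genomeSize = 200000) {
  stopifnot(nTumor >= 1, nNormal >= 1, nDecoysPerSample >= 0)
  if (genomeSize < .SYN$minGenomeSize)
    stop(sprintf("genomeSize %d too small for the planted structures (need >= %d)",
                 genomeSize, .SYN$minGenomeSize))
  bad <- setdiff(events$event_id, names(.synEventTemplates()))
  if (length(bad))
    stop(sprintf("unknown event template(s): %s", paste(bad, collapse = ", ")))
  if (any(events$tumor_prevalence < 0 | events$tumor_prevalence > 1 |
          events$normal_prevalence < 0 | events$normal_prevalence > 1))
    stop("prevalences must be in [0, 1]")
  if (any(events$tss_jitter_bp < 0)) stop("tss_jitter_bp must be >= 0")
  maxJit <- vapply(.synEventTemplates()[events$event_id], `[[`, integer(1),
                   "max_jitter")
  if (any(events$tss_jitter_bp > maxJit))
    stop(sprintf("tss_jitter_bp exceeds the template maximum for: %s",
                 paste(events$event_id[events$tss_jitter_bp > maxJit],
                       collapse = ", ")))
  if (seed >= 2^31 - 2) stop("seed too large")
  structure(list(seed = as.integer(seed), nTumor = as.integer(nTumor),
                 nNormal = as.integer(nNormal), events = events,
                 nDecoysPerSample = as.integer(nDecoysPerSample),
                 genomeSize = as.integer(genomeSize)),
            class = "CohortDesign")
}

# T-free random codons (no ATG, no stop in any frame by construction).
.tFreeCodons <- function(n) {
  b <- c("A", "C", "G")
  paste0(sample(b, n, replace = TRUE), sample(b, n, replace = TRUE),
         sample(b, n, replace = TRUE), collapse = "")
}

# Plant a 3-exon, 90-codon gene at base b into the genome character vector.
.plantGeneV <- function(gv, b, internalAtgCodon = NA) {
  cds <- paste0("ATG", .tFreeCodons(89L))
  if (!is.na(internalAtgCodon)) {
    pre <- substr(cds, 1L, (internalAtgCodon - 1L) * 3L)
    post <- substr(cds, internalAtgCodon * 3L + 1L, nchar(cds))
    cds <- paste0(pre, "ATG", post)
  }
  cdsV <- strsplit(cds, "")[[1]]
  gv[(b + 30L):(b + 119L)] <- cdsV[1:90]
  gv[(b + 420L):(b + 539L)] <- cdsV[91:210]
  gv[(b + 840L):(b + 899L)] <- cdsV[211:270]
  gv[(b + 900L):(b + 902L)] <- c("T", "A", "A")
  gv
}

# Gene model rows for a 3-exon gene at base b.
.geneModelRows <- function(gid, b) {
  list(body = c(b, b + 959L),
       exons = cbind(start = b + c(0L, 420L, 840L), end = b + c(119L, 539L, 959L)),
       cds = cbind(start = b + c(30L, 420L, 840L), end = b + c(119L, 539L, 899L)))
}

#' Generate the synthetic reference (genome, genes, repeats)
#'
#' Deterministic per seed. The reference contains six 3-exon protein-coding
#' genes, a mono-exonic retrogene (RTG1), a gene-desert LTR66 with downstream
#' AluSx1/LTR33/L2b/MLT1F1 copies, a fragmented LTR12C (two RepeatMasker rows
#' sharing a linkage ID), an LTR43/LTR43-int/LTR43 provirus, and Alu copies
#' used by the decoys. Generated structures are self-validated: all canonical
#' proteins translate cleanly and each event template reproduces its
#' product-class truth.
#'
#' @param design a \code{\link{cohortDesign}}.
#' @return list of class \code{TcgtReference} with elements \code{genome}
#'   (\code{DNAStringSet}), \code{genes} (\code{\linkS4class{GeneSet}}),
#'   \code{repeats} (record \code{GRanges}, as from
#'   \code{\link{parseRmskOut}}), \code{rmskLines} (the \code{.out} file
#'   text), \code{templates} (event exon templates) and \code{layout}.
#' @export
generateReference <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  withSeed(design$seed, {
    gv <- sample(c("A", "C", "G"), design$genomeSize, replace = TRUE)
    for (g in names(.SYN$geneStart))
      gv <- .plantGeneV(gv, .SYN$geneStart[[g]],
                        internalAtgCodon = if (g == "G1") 41L else NA)
    # mono-exonic retrogene RTG1: 40 bp UTR, 120-codon CDS, stop, 60 bp UTR
    rtg <- .SYN$rtgStart
    cdsV <- strsplit(paste0("ATG", .tFreeCodons(119L)), "")[[1]]
    gv[(rtg + 40L):(rtg + 399L)] <- cdsV
    gv[(rtg + 400L):(rtg + 402L)] <- c("T", "A", "A")
    # E3's frame-shifted ORF: start codon inside the AluSx4 copy, stop in
    # G3's 3' UTR at the offset that is in frame for the shifted read
    gv[12200:12202] <- c("A", "T", "G")
    g3 <- .SYN$geneStart[["G3"]]
    gv[(g3 + 940L):(g3 + 942L)] <- c("T", "A", "A")
    genomeSeq <- paste(gv, collapse = "")
  })
  genome <- DNAStringSet(setNames(genomeSeq, "chrS1"))

  # gene models
  bodies <- GRanges(); cdsList <- list()
  for (g in names(.SYN$geneStart)) {
    gm <- .geneModelRows(g, .SYN$geneStart[[g]])
    b <- GRanges("chrS1", IRanges(gm$body[1], gm$body[2]), strand = "+")
    mcols(b)$gene_id <- g
    mcols(b)$gene_name <- g
    bodies <- c(bodies, b)
    cd <- GRanges("chrS1", IRanges(gm$cds[, "start"], gm$cds[, "end"]), strand = "+")
    mcols(cd)$frame <- 0L
    cdsList[[g]] <- cd
  }
  rb <- GRanges("chrS1", IRanges(.SYN$rtgStart, .SYN$rtgStart + 462L), strand = "+")
  mcols(rb)$gene_id <- "RTG1"
  mcols(rb)$gene_name <- "RTG1"
  bodies <- c(bodies, rb)
  rcd <- GRanges("chrS1", IRanges(.SYN$rtgStart + 40L, .SYN$rtgStart + 399L),
                 strand = "+")
  mcols(rcd)$frame <- 0L
  cdsList[["RTG1"]] <- rcd
  names(bodies) <- mcols(bodies)$gene_id
  genes <- GeneSet(bodies, GRangesList(cdsList))

  # repeat records and .out text
  te <- .SYN$te
  repeats <- GRanges("chrS1", IRanges(te$start, te$end), strand = "+")
  mcols(repeats)$repeat_name <- te$name
  mcols(repeats)$repeat_class <- te$class
  mcols(repeats)$linkage_id <- te$linkage
  mcols(repeats)$divergence <- te$divergence
  repeats <- sort(repeats, ignore.strand = TRUE)
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)  repeat    class/family   begin  end (left)  ID",
    "")
  rows <- sprintf("%5d %6.1f  0.0  0.0  %s %7d %7d (%d)  +  %s  %s  1  %d  (0)  %d",
                  1000L + te$linkage * 7L, te$divergence, "chrS1",
                  te$start, te$end, design$genomeSize - te$end,
                  te$name, te$class, te$end - te$start + 1L, te$linkage)
  rmskLines <- c(hdr, rows)

  ref <- structure(list(genome = genome, genes = genes, repeats = repeats,
                        rmskLines = rmskLines,
                        templates = .synEventTemplates(),
                        layout = .SYN),
                   class = "TcgtReference")
  .validateReference(ref, design)
  ref
}

# Build the exon GRanges of one event instance (jitter offset applied).
.eventExons <- function(tmpl, offset = 0L) {
  starts <- c(tmpl$anchor + offset, tmpl$downstream[, "start"])
  ends <- c(tmpl$exon1_end, tmpl$downstream[, "end"])
  GRanges("chrS1", IRanges(starts, ends), strand = "+")
}

# Decoy transcript structures; each mirrors one discard reason.
.decoyExons <- function(type) {
  gs <- .SYN$geneStart
  switch(type,
    tss_not_te = GRanges("chrS1",  # 1 bp upstream of the LTR66 fragment
      IRanges(c(80999L, 83100L, 89980L), c(81250L, 83199L, 90470L)), strand = "+"),
    first_exon_in_gene = GRanges("chrS1",  # TSS in the AluY inside G2's intron
      IRanges(c(gs[["G2"]] + 200L, gs[["G4"]] + 420L),
              c(gs[["G2"]] + 350L, gs[["G4"]] + 539L)), strand = "+"),
    no_coding_target = GRanges("chrS1",  # AluSx2 start, exons in the desert
      IRanges(c(15100L, 16000L), c(15250L, 16150L)), strand = "+"),
    stop(sprintf("unknown decoy type %s", type)))
}

.decoyTypes <- c("tss_not_te", "first_exon_in_gene", "no_coding_target")

# Self-check: reference structures satisfy the pipeline contracts and event
# templates reproduce their product truths.
.validateReference <- function(ref, design) {
  ok <- validateGeneModels(ref$genes, ref$genome)
  if (!all(ok))
    stop(paste("reference self-validation: gene model(s) invalid:",
               paste(names(ok)[!ok], collapse = ", ")))
  tes <- curateRepeats(ref$repeats)
  if (length(tes) != .SYN$nCuratedUnits)
    stop("reference self-validation: unexpected curated unit count")
  for (eid in design$events$event_id) {
    tmpl <- ref$templates[[eid]]
    jit <- design$events$tss_jitter_bp[design$events$event_id == eid]
    for (off in unique(c(0L, as.integer(jit)))) {
      ex <- .eventExons(tmpl, off)
      exl <- GRangesList(tmp = ex)
      ts <- TranscriptSet(exl, sampleId = "check")
      calls <- detectTcgts(ts, ref$genes, tes)
      if (nrow(calls) != 1L || calls$gene_id != tmpl$gene_id)
        stop(sprintf("reference self-validation: event %s not detected as planted", eid))
      if (!identical(strsplit(calls$te_chain, ",")[[1]], tmpl$te_chain))
        stop(sprintf("reference self-validation: event %s TE chain mismatch", eid))
      prod <- classifyCalls(calls, ts, ref$genes, ref$genome)
      truth <- design$events$product_class_truth[design$events$event_id == eid]
      if (prod$product_class != truth)
        stop(sprintf("reference self-validation: event %s product %s != %s",
                     eid, prod$product_class, truth))
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic cohort with ground truth
#'
#' Each sample's transcript set contains the canonical transcripts of all
#' reference genes, Bernoulli(prevalence)-planted TcGT transcripts with TSS
#' jitter, and decoy transcripts that must be discarded (one per discard
#' reason, cycling). Every decision is recorded in the ground truth.
#'
#' @param design a \code{\link{cohortDesign}}.
#' @param reference the matching \code{\link{generateReference}} output.
#' @return list of class \code{TcgtCohort} with \code{samples} (named list
#'   of \code{\linkS4class{TranscriptSet}}), \code{sheet} (sample sheet
#'   data.frame) and \code{truth} (see Details). \code{truth} holds
#'   \code{presence} (one row per planted transcript: sample, event, tss,
#'   gene, product truth), \code{event_counts} (realized per-group counts per
#'   event), \code{expected_aggregates} (event -> expected cluster count at
#'   the 100-bp window), \code{expected_gene_table} (gene rows implied by the
#'   realized draws under the >20\%/<10\% filter) and
#'   \code{expected_discards_per_sample}.
#' @export
generateCohort <- function(design, reference) {
  stopifnot(inherits(design, "CohortDesign"), inherits(reference, "TcgtReference"))
  wid <- max(2L, nchar(as.character(max(design$nTumor, design$nNormal))))
  samples <- c(sprintf("tumor%0*d", wid, seq_len(design$nTumor)),
               sprintf("normal%0*d", wid, seq_len(design$nNormal)))
  groups <- c(rep("tumor", design$nTumor), rep("normal", design$nNormal))
  sheet <- data.frame(sample_id = samples, group = groups,
                      stringsAsFactors = FALSE)

  # canonical background transcripts (shared exon structures)
  bgExons <- list()
  for (g in names(.SYN$geneStart)) {
    gm <- .geneModelRows(g, .SYN$geneStart[[g]])
    bgExons[[g]] <- GRanges("chrS1", IRanges(gm$exons[, "start"], gm$exons[, "end"]),
                            strand = "+")
  }
  bgExons[["RTG1"]] <- GRanges("chrS1",
                               IRanges(.SYN$rtgStart, .SYN$rtgStart + 462L),
                               strand = "+")

  ev <- design$events
  presence <- list()
  sampleSets <- vector("list", length(samples))
  names(sampleSets) <- samples

  withSeed(design$seed + 1L, {
    for (si in seq_along(samples)) {
      sid <- samples[si]
      grpPrev <- if (groups[si] == "tumor") ev$tumor_prevalence else ev$normal_prevalence
      exl <- list()
      for (g in names(bgExons))
        exl[[sprintf("%s.%s.ref", sid, g)]] <- bgExons[[g]]
      for (k in seq_len(nrow(ev))) {
        present <- rbinom(1L, 1L, grpPrev[k]) == 1L
        if (!present) next
        jit <- ev$tss_jitter_bp[k]
        off <- if (jit == 0L) 0L
          else if (isTRUE(ev$bimodal[k])) sample(c(0L, as.integer(jit)), 1L)
          else sample.int(jit + 1L, 1L) - 1L
        tmpl <- reference$templates[[ev$event_id[k]]]
        tid <- sprintf("%s.%s", sid, ev$event_id[k])
        exl[[tid]] <- .eventExons(tmpl, off)
        presence[[length(presence) + 1L]] <- data.frame(
          sample_id = sid, group = groups[si], event_id = ev$event_id[k],
          transcript_id = tid, tss = tmpl$anchor + off,
          gene_id = tmpl$gene_id,
          product_class_truth = ev$product_class_truth[k],
          stringsAsFactors = FALSE)
      }
      if (design$nDecoysPerSample > 0L) {
        for (d in seq_len(design$nDecoysPerSample)) {
          type <- .decoyTypes[((d - 1L) %% 3L) + 1L]
          exl[[sprintf("%s.D%d", sid, d)]] <- .decoyExons(type)
        }
      }
      sampleSets[[sid]] <- TranscriptSet(GRangesList(exl), sampleId = sid)
    }
  })

  presence <- if (length(presence)) do.call(rbind, presence)
    else data.frame(sample_id = character(0), group = character(0),
                    event_id = character(0), transcript_id = character(0),
                    tss = integer(0), gene_id = character(0),
                    product_class_truth = character(0), stringsAsFactors = FALSE)

  eventCounts <- do.call(rbind, lapply(seq_len(nrow(ev)), function(k) {
    sub <- presence[presence$event_id == ev$event_id[k], , drop = FALSE]
    data.frame(event_id = ev$event_id[k], gene_id = ev$gene_id[k],
               n_tumor = sum(sub$group == "tumor"),
               n_normal = sum(sub$group == "normal"),
               stringsAsFactors = FALSE)
  }))

  # expected aggregate count per event at the 100-bp single-linkage window
  # (bookkeeping from the realized TSS draws)
  clusterCount <- function(tss, window = 100L) {
    if (length(tss) == 0L) return(0L)
    tss <- sort(unique(tss))
    if (length(tss) == 1L) return(1L)
    sum(diff(tss) > window) + 1L
  }
  expAgg <- vapply(ev$event_id, function(e)
    clusterCount(presence$tss[presence$event_id == e]), integer(1))

  # expected per-gene table under the strict >20% / <10% filter, applied per
  # realized TSS cluster then unioned per gene (events target distinct genes)
  expRows <- list()
  for (k in seq_len(nrow(ev))) {
    sub <- presence[presence$event_id == ev$event_id[k], , drop = FALSE]
    if (nrow(sub) == 0L) next
    tss <- sort(unique(sub$tss))
    cl <- cumsum(c(1L, diff(tss) > 100L))
    passSamples <- character(0)
    for (c0 in unique(cl)) {
      inCl <- sub$tss %in% tss[cl == c0]
      nT <- length(unique(sub$sample_id[inCl & sub$group == "tumor"]))
      nN <- length(unique(sub$sample_id[inCl & sub$group == "normal"]))
      if (nT / design$nTumor > 0.20 && nN / design$nNormal < 0.10)
        passSamples <- union(passSamples, sub$sample_id[inCl])
    }
    if (length(passSamples)) {
      grp <- setNames(sheet$group, sheet$sample_id)
      nT <- sum(grp[passSamples] == "tumor")
      nN <- sum(grp[passSamples] == "normal")
      expRows[[length(expRows) + 1L]] <- data.frame(
        gene_name = ev$gene_id[k], nN = nN, nT = nT,
        pctN = formatPct(nN, design$nNormal),
        pctT = formatPct(nT, design$nTumor),
        product = ev$product_class_truth[k], stringsAsFactors = FALSE)
    }
  }
  expGeneTable <- if (length(expRows)) {
    out <- do.call(rbind, expRows)
    out <- out[order(-out$nT, out$gene_name), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else data.frame(gene_name = character(0), nN = integer(0), nT = integer(0),
                    pctN = numeric(0), pctT = numeric(0), product = character(0),
                    stringsAsFactors = FALSE)

  nDecoyByType <- tabulate(((seq_len(design$nDecoysPerSample) - 1L) %% 3L) + 1L,
                           nbins = 3L)
  expDiscards <- c(
    unstranded = 0L,
    tss_not_te = length(bgExons) + nDecoyByType[1L],
    first_exon_in_gene = nDecoyByType[2L],
    no_coding_target = nDecoyByType[3L])

  structure(list(
    samples = sampleSets, sheet = sheet,
    truth = list(presence = presence, event_counts = eventCounts,
                 expected_aggregates = setNames(expAgg, ev$event_id),
                 expected_gene_table = expGeneTable,
                 expected_discards_per_sample = expDiscards)),
    class = "TcgtCohort")
}

#' Write a synthetic reference and cohort to disk
#'
#' Emits \code{genome.fa}, \code{genes.gtf}, \code{repeats.out},
#' \code{samples/<id>.gtf}, \code{samples.tsv} and (when jsonlite is
#' available) \code{truth.json} under \code{dir}.
#'
#' @param reference from \code{\link{generateReference}}.
#' @param cohort from \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(reference, cohort, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  writeLines(reference$rmskLines, file.path(dir, "repeats.out"))
  .writeGeneGtf(reference$genes, file.path(dir, "genes.gtf"))
  for (sid in names(cohort$samples))
    writeGtf(cohort$samples[[sid]], file.path(dir, "samples", paste0(sid, ".gtf")))
  write.table(cohort$sheet, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}

# Gene annotation GTF: transcript/exon/CDS records with frames.
.writeGeneGtf <- function(genes, path) {
  recs <- list()
  for (g in names(geneBodies(genes))) {
    body <- geneBodies(genes)[g]
    cds <- cdsSegments(genes)[[g]]
    # 3-exon genes follow the template; the retrogene is its own single exon
    if (g %in% names(.SYN$geneStart)) {
      gm <- .geneModelRows(g, start(body))
      exr <- GRanges(seqnames(body), IRanges(gm$exons[, "start"], gm$exons[, "end"]),
                     strand = strand(body))
    } else {
      exr <- GRanges(seqnames(body), IRanges(start(body), end(body)),
                     strand = strand(body))
    }
    tx <- GRanges(seqnames(body), IRanges(start(body), end(body)), strand = strand(body))
    cdr <- GRanges(seqnames(cds), ranges(cds), strand = strand(cds))
    out <- c(tx, exr, cdr)
    mcols(out)$type <- c("transcript", rep("exon", length(exr)), rep("CDS", length(cdr)))
    mcols(out)$phase <- c(rep(NA_integer_, 1L + length(exr)), mcols(cds)$frame)
    mcols(out)$gene_id <- g
    mcols(out)$gene_name <- mcols(body)$gene_name
    mcols(out)$transcript_id <- paste0(g, ".t1")
    recs[[g]] <- out
  }
  gr <- do.call(c, unname(recs))
  mcols(gr)$source <- "tcgtscan"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort and diff against ground truth
#'
#' Generates the reference and cohort for \code{design}, writes them to
#' \code{dir} (a temporary directory by default, exercising the file-format
#' round trips), runs curation, detection, aggregation, the recurrence
#' filter and product classification, and compares every stage with the
#' recorded ground truth.
#'
#' @param design a \code{\link{cohortDesign}}.
#' @param dir staging directory (default: fresh temporary directory).
#' @param window TSS aggregation window in bp (default 100).
#' @return list of class \code{TcgtCheckReport}: \code{ok} (logical),
#'   per-stage diff summaries (\code{detection}, \code{classification},
#'   \code{aggregation}, \code{gene_table}, \code{discards}), plus the
#'   observed \code{calls}, \code{geneTable} and the \code{truth} used.
#' @export
endToEndCheck <- function(design, dir = tempfile("syncohort"), window = 100) {
  reference <- generateReference(design)
  cohort <- generateCohort(design, reference)
  writeCohort(reference, cohort, dir)

  tes <- curateRepeats(parseRmskOut(file.path(dir, "repeats.out")))
  genes <- readGtf(file.path(dir, "genes.gtf"), kind = "genes")
  genome <- readGenome(file.path(dir, "genome.fa"))
  sheet <- readSampleSheet(file.path(dir, "samples.tsv"))

  callsList <- list(); prodList <- list()
  discardsOk <- TRUE
  expDisc <- cohort$truth$expected_discards_per_sample
  for (sid in sheet$sample_id) {
    ts <- readGtf(file.path(dir, "samples", paste0(sid, ".gtf")),
                  kind = "transcripts", sampleId = sid)
    calls <- detectTcgts(ts, genes, tes)
    if (!identical(discardTally(calls)[names(expDisc)], expDisc))
      discardsOk <- FALSE
    callsList[[sid]] <- calls
    if (nrow(calls))
      prodList[[sid]] <- classifyCalls(calls, ts, genes, genome)
  }
  calls <- do.call(rbind, callsList)
  rownames(calls) <- NULL
  prods <- if (length(prodList)) do.call(rbind, prodList)
    else data.frame(sample_id = character(0), transcript_id = character(0),
                    gene_id = character(0), product_class = character(0))

  truth <- cohort$truth
  fp <- setdiff(calls$transcript_id, truth$presence$transcript_id)
  fn <- setdiff(truth$presence$transcript_id, calls$transcript_id)

  m <- match(truth$presence$transcript_id, prods$transcript_id)
  clsMismatch <- sum(is.na(m) |
    prods$product_class[m] != truth$presence$product_class_truth)

  agg <- aggregateCalls(calls, window = window)
  aggByEvent <- vapply(names(truth$expected_aggregates), function(e) {
    tids <- truth$presence$transcript_id[truth$presence$event_id == e]
    length(unique(agg$aggregate_id[agg$transcript_id %in% tids]))
  }, integer(1))
  aggMismatch <- sum(aggByEvent != truth$expected_aggregates)

  counts <- countByGroup(agg, sheet)
  passing <- recurrenceFilter(counts, groupSizes(sheet))
  gt <- geneTable(agg, passing, sheet,
                  productClasses = setNames(prods$product_class,
                                            prods$transcript_id))
  expGt <- truth$expected_gene_table
  gtOk <- nrow(gt) == nrow(expGt) &&
    (nrow(gt) == 0L ||
       identical(gt[, c("gene_name", "nN", "nT", "pctN", "pctT", "product")],
                 expGt[, c("gene_name", "nN", "nT", "pctN", "pctT", "product")]))

  ok <- length(fp) == 0L && length(fn) == 0L && clsMismatch == 0L &&
    aggMismatch == 0L && gtOk && discardsOk
  structure(list(
    ok = ok,
    detection = list(n_false_positives = length(fp), n_false_negatives = length(fn),
                     false_positives = fp, false_negatives = fn),
    classification = list(n_mismatches = clsMismatch),
    aggregation = list(n_mismatches = aggMismatch, observed = aggByEvent,
                       expected = truth$expected_aggregates),
    gene_table = list(matches = gtOk, observed = gt, expected = expGt),
    discards = list(ok = discardsOk),
    calls = calls, geneTable = gt, truth = truth, dir = dir),
    class = "TcgtCheckReport")
}
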