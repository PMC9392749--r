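# Independent brute-force oracles and random fixture builders. The oracles
# share no code with the implementation: plain-vector interval arithmetic,
# pairwise transitive closures and exhaustive scans.

ovBp <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)

# --- brute-force TcGT detection: tests every (transcript, TE, gene) triple.
# Inputs are plain data.frames/lists so the oracle is independent of the S4
# containers' internals.
bfDetect <- function(txList, geneDf, geneCodingList, teFragDf) {
  out <- list()
  for (tx in txList) {
    if (tx$strand == "*") next
    tss <- tx$tss
    inTe <- any(teFragDf$chrom == tx$chrom & teFragDf$start <= tss &
                  teFragDf$end >= tss)
    if (!inTe) next
    mono <- nrow(tx$exons) == 1L
    # coding overlap per same-strand gene (downstream exons; all for mono)
    cand <- if (mono) tx$exons else tx$exons[-1, , drop = FALSE]
    cov <- setNames(integer(nrow(geneDf)), geneDf$gene_id)
    for (gi in seq_len(nrow(geneDf))) {
      if (geneDf$strand[gi] != tx$strand || geneDf$chrom[gi] != tx$chrom) next
      ce <- geneCodingList[[geneDf$gene_id[gi]]]
      if (is.null(ce) || nrow(ce) == 0L) next
      for (e in seq_len(nrow(cand)))
        for (c0 in seq_len(nrow(ce)))
          cov[gi] <- cov[gi] + ovBp(cand$start[e], cand$end[e],
                                    ce$start[c0], ce$end[c0])
    }
    # first-exon test (gene bodies, any strand)
    if (!mono) {
      fe <- tx$exons[1, , drop = FALSE]
      hit <- any(geneDf$chrom == tx$chrom &
                   geneDf$start <= fe$end & geneDf$end >= fe$start)
      if (hit) next
    } else {
      # leading 5' region up to the first coding-overlap base
      lead <- c(tx$exons$start[1], tx$exons$end[1])
      covGenes <- names(cov)[cov > 0]
      if (length(covGenes)) {
        bounds <- integer(0)
        for (g in covGenes) {
          ce <- geneCodingList[[g]]
          for (c0 in seq_len(nrow(ce)))
            if (ovBp(tx$exons$start[1], tx$exons$end[1], ce$start[c0], ce$end[c0]) > 0)
              bounds <- c(bounds, max(tx$exons$start[1], ce$start[c0]),
                          min(tx$exons$end[1], ce$end[c0]))
        }
        if (tx$strand == "-") {
          hi <- max(bounds)
          if (tx$exons$end[1] > hi) lead <- c(hi + 1L, tx$exons$end[1]) else lead <- NULL
        } else {
          lo <- min(bounds)
          if (tx$exons$start[1] < lo) lead <- c(tx$exons$start[1], lo - 1L) else lead <- NULL
        }
      }
      if (!is.null(lead)) {
        hit <- any(geneDf$chrom == tx$chrom &
                     geneDf$start <= lead[2] & geneDf$end >= lead[1])
        if (hit) next
      }
    }
    if (all(cov == 0L)) next
    best <- max(cov)
    tied <- names(cov)[cov == best]
    if (length(tied) > 1L) {
      tot <- vapply(tied, function(g) {
        gi <- match(g, geneDf$gene_id)
        s <- 0L
        for (e in seq_len(nrow(tx$exons)))
          s <- s + ovBp(tx$exons$start[e], tx$exons$end[e],
                        geneDf$start[gi], geneDf$end[gi])
        s
      }, integer(1))
      tied <- tied[order(-tot, tied)]
    }
    out[[length(out) + 1L]] <- data.frame(transcript_id = tx$transcript_id,
                                          gene_id = tied[1],
                                          coding_overlap_bp = best,
                                          stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(transcript_id = character(0), gene_id = character(0),
                  coding_overlap_bp = integer(0), stringsAsFactors = FALSE)
}

# --- transitive-closure clustering of TSS positions (pairwise relation
# |ti - tj| <= window, closed by repeated merging)
bfCluster <- function(tss, window) {
  n <- length(tss)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(tss[i] - tss[j]) <= window && lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# --- exhaustive ORF enumeration: every ATG, scan codon by codon to the
# first stop; longest wins, ties 5'-most.
bfOrf <- function(cdna, minCodons) {
  cdna <- toupper(cdna)
  n <- nchar(cdna)
  best <- NULL
  for (a in seq_len(max(0L, n - 2L))) {
    if (substr(cdna, a, a + 2L) != "ATG") next
    p <- a + 3L
    stopAt <- NA
    while (p + 2L <= n) {
      cod <- substr(cdna, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) { stopAt <- p; break }
      p <- p + 3L
    }
    if (is.na(stopAt)) next
    codons <- (stopAt - a) %/% 3L
    if (codons < minCodons) next
    if (is.null(best) || codons > best$n_codons)
      best <- list(start = a, end = stopAt + 2L, n_codons = codons)
  }
  best
}

# --- transitive closure of the pairwise fusion relation over repeat records
bfFuseComponents <- function(df, maxGap, linkageInformative) {
  n <- nrow(df)
  lab <- seq_len(n)
  related <- function(i, j) {
    if (df$chrom[i] != df$chrom[j] || df$strand[i] != df$strand[j] ||
        df$name[i] != df$name[j]) return(FALSE)
    if (linkageInformative)
      return(!is.na(df$linkage[i]) && !is.na(df$linkage[j]) &&
               df$linkage[i] == df$linkage[j])
    gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j]) - 1L
    gap <= maxGap
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && related(i, j) && lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# ---------------------------------------------------------------- fixtures

# Random annotation scenario for detection property tests: single contig,
# random single-exon coding genes, random TE fragments, random transcripts.
randomScenario <- function(seed, nTx = 40, nGenes = 4, nTe = 8, L = 50000) {
  set.seed(seed)
  geneStart <- sort(sample.int(L - 2000L, nGenes))
  geneStrand <- sample(c("+", "-"), nGenes, replace = TRUE)
  geneDf <- data.frame(gene_id = sprintf("g%02d", seq_len(nGenes)),
                       chrom = "c1", start = geneStart,
                       end = geneStart + sample(200:900, nGenes, replace = TRUE),
                       strand = geneStrand, stringsAsFactors = FALSE)
  geneCodingList <- lapply(seq_len(nGenes), function(i) {
    w <- geneDf$end[i] - geneDf$start[i] + 1L
    cw <- (w %/% 3L) * 3L
    data.frame(start = geneDf$start[i], end = geneDf$start[i] + cw - 1L)
  })
  names(geneCodingList) <- geneDf$gene_id
  teStart <- sort(sample.int(L - 500L, nTe))
  teFragDf <- data.frame(chrom = "c1", start = teStart,
                         end = teStart + sample(80:400, nTe, replace = TRUE),
                         unit = sprintf("u%02d", seq_len(nTe)),
                         name = sample(c("LTR66", "AluSx1", "L2b"), nTe, replace = TRUE),
                         stringsAsFactors = FALSE)
  txList <- lapply(seq_len(nTx), function(i) {
    ne <- sample(1:3, 1)
    st <- sample(c("+", "-"), 1)
    s1 <- sample.int(L - 5000L, 1)
    starts <- s1 + cumsum(c(0L, sample(200:1200, ne - 1, replace = TRUE) +
                              sample(50:200, ne - 1, replace = TRUE)))
    widths <- sample(50:240, ne, replace = TRUE)  # < min inter-exon gap
    exons <- data.frame(start = starts, end = starts + widths)
    list(transcript_id = sprintf("t%03d", i), chrom = "c1", strand = st,
         exons = exons,
         tss = if (st == "-") exons$end[nrow(exons)] else exons$start[1])
  })
  list(geneDf = geneDf, geneCodingList = geneCodingList,
       teFragDf = teFragDf, txList = txList)
}

# Package-object views of a randomScenario
scenarioToObjects <- function(sc) {
  genes <- GenomicRanges::GRanges(sc$geneDf$chrom,
                                  IRanges::IRanges(sc$geneDf$start, sc$geneDf$end),
                                  strand = sc$geneDf$strand)
  S4Vectors::mcols(genes)$gene_id <- sc$geneDf$gene_id
  S4Vectors::mcols(genes)$gene_name <- sc$geneDf$gene_id
  names(genes) <- sc$geneDf$gene_id
  cds <- GenomicRanges::GRangesList(lapply(seq_along(genes), function(i) {
    ce <- sc$geneCodingList[[i]]
    g <- GenomicRanges::GRanges(sc$geneDf$chrom[i],
                                IRanges::IRanges(ce$start, ce$end),
                                strand = sc$geneDf$strand[i])
    S4Vectors::mcols(g)$frame <- 0L
    g
  }))
  names(cds) <- sc$geneDf$gene_id
  gs <- GeneSet(genes, cds)

  frag <- GenomicRanges::GRanges(sc$teFragDf$chrom,
                                 IRanges::IRanges(sc$teFragDf$start, sc$teFragDf$end),
                                 strand = "+")
  S4Vectors::mcols(frag)$repeat_name <- sc$teFragDf$name
  S4Vectors::mcols(frag)$repeat_class <- "LTR/ERVL"
  S4Vectors::mcols(frag)$linkage_id <- seq_along(frag)
  S4Vectors::mcols(frag)$divergence <- 10
  tes <- fuseFragments(GenomicRanges::sort(frag, ignore.strand = TRUE))

  exl <- GenomicRanges::GRangesList(lapply(sc$txList, function(tx)
    GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$exons$start, tx$exons$end),
                           strand = tx$strand)))
  names(exl) <- vapply(sc$txList, `[[`, character(1), "transcript_id")
  ts <- TranscriptSet(exl, sampleId = "s1")
  list(genes = gs, tes = tes, transcripts = ts)
}

# Random repeat-record GRanges for fusion property tests
randomRepeatRecords <- function(seed, n = 30, linked = TRUE) {
  set.seed(seed)
  start <- sort(sample.int(200000L, n))
  gr <- GenomicRanges::GRanges(sample(c("c1", "c2"), n, replace = TRUE),
                               IRanges::IRanges(start, start + sample(50:500, n, TRUE)),
                               strand = sample(c("+", "-"), n, replace = TRUE))
  S4Vectors::mcols(gr)$repeat_name <- sample(c("LTR66", "LTR12C", "AluY"), n, TRUE)
  S4Vectors::mcols(gr)$repeat_class <- "LTR/ERVL"
  S4Vectors::mcols(gr)$linkage_id <- if (linked) sample.int(max(2L, n %/% 3L), n, TRUE)
    else seq_len(n)
  S4Vectors::mcols(gr)$divergence <- runif(n, 5, 25)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

table1Path <- function() system.file("extdata", "table1_crc_genes.tsv",
                                     package = "tcgtscan")
rmskFixturePath <- function() system.file("extdata", "example_rmsk.out",
                                          package = "tcgtscan")

# map the printed product labels of the gene-table fixture onto the
# package's vocabulary
printedLabelMap <- c("canon." = "canonical", "N-trunc." = "N-trunc",
                     "C-trunc." = "C-trunc", "N-C-trunc." = "N-C-trunc",
                     "N-ext." = "N-ext", "C-ext." = "C-ext",
                     "out.frame" = "out-of-frame")
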