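# Cohort-level stage: cluster per-sample calls into aggregates by TSS
# proximity, count distinct samples per group, apply the tumor/normal
# recurrence filter and build the per-gene summary table.

#' Aggregate TcGT calls by gene and TSS proximity
#'
#' Within each (gene, chrom, strand), TSS positions are clustered by
#' single-linkage: calls chain into one aggregate whenever consecutive TSSs
#' (in sorted order) are at most \code{window} bp apart, the transitive
#' closure of the pairwise "within 100 bp" relation. The alternative
#' \code{"fixed-window"} method starts a new cluster when a TSS exceeds the
#' cluster's first TSS by more than \code{window}.
#'
#' @param calls call data.frame (see \code{\link{detectTcgts}}).
#' @param window maximum TSS link distance in bp (default 100).
#' @param method \code{"single-linkage"} (default) or \code{"fixed-window"}.
#' @return \code{calls} with an added \code{aggregate_id} column
#'   (\code{gene_id@chrom:minTSS}, deterministic).
#' @export
aggregateCalls <- function(calls, window = 100,
                           method = c("single-linkage", "fixed-window")) {
  method <- match.arg(method)
  if (window < 0) stop("window must be >= 0")
  if (nrow(calls) == 0L) {
    calls$aggregate_id <- character(0)
    return(calls)
  }
  key <- paste(calls$gene_id, calls$chrom, calls$strand, sep = "\r")
  agg <- character(nrow(calls))
  for (ix in split(seq_len(nrow(calls)), key)) {
    ix <- ix[order(calls$tss[ix])]
    tss <- calls$tss[ix]
    cl <- integer(length(ix))
    cl[1] <- 1L
    if (length(ix) > 1L) for (k in 2:length(ix)) {
      linked <- if (method == "single-linkage") {
        tss[k] - tss[k - 1L] <= window
      } else {
        tss[k] - min(tss[which(cl == cl[k - 1L])]) <= window
      }
      cl[k] <- if (linked) cl[k - 1L] else cl[k - 1L] + 1L
    }
    for (c0 in unique(cl)) {
      members <- ix[cl == c0]
      agg[members] <- sprintf("%s@%s:%d", calls$gene_id[members[1]],
                              calls$chrom[members[1]],
                              min(calls$tss[members]))
    }
  }
  calls$aggregate_id <- agg
  calls
}

#' Count distinct samples per group for each aggregate
#'
#' A sample contributes at most once per aggregate regardless of how many
#' isoform calls it has in it.
#'
#' @param calls aggregated call data.frame (from \code{\link{aggregateCalls}}).
#' @param sheet sample sheet data.frame (\code{sample_id}, \code{group});
#'   every call's sample must be present.
#' @return data.frame with one row per aggregate: \code{aggregate_id,
#'   gene_id, gene_name, chrom, strand, tss_min, tss_max, n_calls} plus one
#'   count column \code{n_<group>} per group in the sheet.
#' @export
countByGroup <- function(calls, sheet) {
  if (!("aggregate_id" %in% colnames(calls)))
    stop("calls must carry aggregate_id (run aggregateCalls first)")
  missing <- setdiff(unique(calls$sample_id), sheet$sample_id)
  if (length(missing))
    stop(sprintf("sample(s) missing from sample sheet: %s",
                 paste(missing, collapse = ", ")))
  groups <- sort(unique(sheet$group))
  grp <- setNames(sheet$group, sheet$sample_id)
  ids <- unique(calls$aggregate_id)
  if (length(ids) == 0L) {
    out <- data.frame(aggregate_id = character(0), gene_id = character(0),
                      gene_name = character(0), chrom = character(0),
                      strand = character(0), tss_min = integer(0),
                      tss_max = integer(0), n_calls = integer(0),
                      stringsAsFactors = FALSE)
    for (g in groups) out[[paste0("n_", g)]] <- integer(0)
    return(out)
  }
  rows <- lapply(ids, function(a) {
    sub <- calls[calls$aggregate_id == a, , drop = FALSE]
    counts <- vapply(groups, function(g)
      length(unique(sub$sample_id[grp[sub$sample_id] == g])), integer(1))
    out <- data.frame(aggregate_id = a, gene_id = sub$gene_id[1],
                      gene_name = sub$gene_name[1], chrom = sub$chrom[1],
                      strand = sub$strand[1], tss_min = min(sub$tss),
                      tss_max = max(sub$tss), n_calls = nrow(sub),
                      stringsAsFactors = FALSE)
    for (g in groups) out[[paste0("n_", g)]] <- counts[[g]]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$chrom, out$tss_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor/normal recurrence filter
#'
#' Keeps aggregates detected in strictly more than \code{minTumorFrac} of
#' tumors AND strictly less than \code{maxNormalFrac} of normal samples
#' (both bounds strict: an aggregate at exactly 20\% of tumors or exactly
#' 10\% of normals fails).
#'
#' @param aggCounts aggregate count table from \code{\link{countByGroup}}.
#' @param nPerGroup named integer vector of cohort sizes per group (see
#'   \code{\link{groupSizes}}); must contain both named groups with n > 0.
#' @param minTumorFrac minimum tumor fraction, exclusive (default 0.20).
#' @param maxNormalFrac maximum normal fraction, exclusive (default 0.10).
#' @param tumorGroup,normalGroup group labels driving the filter (defaults
#'   \code{"tumor"}, \code{"normal"}); other groups are carried through
#'   untouched.
#' @return the passing subset of \code{aggCounts}.
#' @export
recurrenceFilter <- function(aggCounts, nPerGroup, minTumorFrac = 0.20,
                             maxNormalFrac = 0.10, tumorGroup = "tumor",
                             normalGroup = "normal") {
  if (minTumorFrac < 0 || minTumorFrac > 1 || maxNormalFrac < 0 || maxNormalFrac > 1)
    stop("fraction parameters must be within [0, 1]")
  for (g in c(tumorGroup, normalGroup)) {
    if (!(g %in% names(nPerGroup)) || nPerGroup[[g]] <= 0)
      stop(sprintf("nPerGroup must contain group '%s' with n > 0", g))
    if (!(paste0("n_", g) %in% colnames(aggCounts)))
      stop(sprintf("aggCounts lacks column n_%s", g))
  }
  tFrac <- aggCounts[[paste0("n_", tumorGroup)]] / nPerGroup[[tumorGroup]]
  nFrac <- aggCounts[[paste0("n_", normalGroup)]] / nPerGroup[[normalGroup]]
  keep <- tFrac > minTumorFrac & nFrac < maxNormalFrac
  out <- aggCounts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene recurrence summary (Table-1-style)
#'
#' One row per gene with at least one passing aggregate. Sample counts are
#' unions of distinct samples across the gene's passing aggregates (a sample
#' contributing to two passing aggregates of the same gene counts once);
#' percentages are rounded half-up to one decimal; rows are sorted by
#' descending tumor count, then gene name.
#'
#' @param calls aggregated call data.frame (from \code{\link{aggregateCalls}}).
#' @param passing passing aggregate table from \code{\link{recurrenceFilter}}.
#' @param sheet sample sheet data.frame.
#' @param nPerGroup cohort sizes per group; defaults to
#'   \code{groupSizes(sheet)}.
#' @param productClasses optional named character vector mapping
#'   \code{transcript_id} to product class (see \code{\link{classifyCalls}});
#'   reported as the sorted unique set per gene, joined by \code{"; "}.
#' @param tumorGroup,normalGroup group labels (defaults \code{"tumor"},
#'   \code{"normal"}).
#' @param geneUnion \code{"passing"} (default): per-gene sample unions run
#'   over passing aggregates only; \code{"all"}: over all aggregates of genes
#'   that have at least one passing aggregate.
#' @return data.frame with columns \code{gene_name, nN, nT, pctN, pctT,
#'   product, n_aggregates}.
#' @export
geneTable <- function(calls, passing, sheet, nPerGroup = groupSizes(sheet),
                      productClasses = NULL, tumorGroup = "tumor",
                      normalGroup = "normal",
                      geneUnion = c("passing", "all")) {
  geneUnion <- match.arg(geneUnion)
  if (nrow(passing) == 0L)
    return(data.frame(gene_name = character(0), nN = integer(0), nT = integer(0),
                      pctN = numeric(0), pctT = numeric(0),
                      product = character(0), n_aggregates = integer(0),
                      stringsAsFactors = FALSE))
  grp <- setNames(sheet$group, sheet$sample_id)
  genes <- unique(passing$gene_id)
  rows <- lapply(genes, function(g) {
    aggIds <- passing$aggregate_id[passing$gene_id == g]
    members <- if (geneUnion == "passing") {
      calls[calls$aggregate_id %in% aggIds, , drop = FALSE]
    } else {
      calls[calls$gene_id == g, , drop = FALSE]
    }
    nT <- length(unique(members$sample_id[grp[members$sample_id] == tumorGroup]))
    nN <- length(unique(members$sample_id[grp[members$sample_id] == normalGroup]))
    prod <- ""
    if (!is.null(productClasses)) {
      cls <- productClasses[unique(members$transcript_id)]
      prod <- paste(sort(unique(cls[!is.na(cls)])), collapse = "; ")
    }
    data.frame(gene_name = passing$gene_name[passing$gene_id == g][1],
               nN = nN, nT = nT,
               pctN = formatPct(nN, nPerGroup[[normalGroup]]),
               pctT = formatPct(nT, nPerGroup[[tumorGroup]]),
               product = prod, n_aggregates = length(aggIds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nT, out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
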