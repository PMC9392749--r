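# TSS clustering, per-group counting, the recurrence filter and the
# per-gene summary table.

mkCalls <- function(tss, sample_id, gene_id = "gA", transcript_id = NULL,
                    chrom = "c1", strand = "+") {
  n <- length(tss)
  data.frame(sample_id = rep_len(sample_id, n),
             transcript_id = if (is.null(transcript_id))
               sprintf("tx%03d", seq_len(n)) else transcript_id,
             gene_id = rep_len(gene_id, n), gene_name = rep_len(gene_id, n),
             chrom = rep_len(chrom, n), strand = rep_len(strand, n),
             tss = as.integer(tss), tss_te_unit = "TE000001",
             tss_te_name = "LTR66", te_chain = "LTR66", n_exons = 2L,
             coding_overlap_bp = 10L, monoexonic = FALSE,
             stringsAsFactors = FALSE)
}

test_that("TSSs cluster by single linkage at the 100-bp window", {
  a <- aggregateCalls(mkCalls(c(1000, 1050), c("s1", "s2")))
  expect_length(unique(a$aggregate_id), 1L)
  b <- aggregateCalls(mkCalls(c(1000, 1150), c("s1", "s2")))
  expect_length(unique(b$aggregate_id), 2L)
  # chaining: 0/90/180 all link although the extremes are 180 apart
  c0 <- aggregateCalls(mkCalls(c(1000, 1090, 1180), c("s1", "s2", "s3")))
  expect_length(unique(c0$aggregate_id), 1L)
  # the fixed-window alternative splits the chain
  c1 <- aggregateCalls(mkCalls(c(1000, 1090, 1180), c("s1", "s2", "s3")),
                       method = "fixed-window")
  expect_length(unique(c1$aggregate_id), 2L)
  # aggregate ids are deterministic gene@chrom:minTSS labels
  expect_identical(unique(c0$aggregate_id), "gA@c1:1000")
  expect_error(aggregateCalls(mkCalls(1000, "s1"), window = -5), "window")
})

test_that("genes, chromosomes and strands never share an aggregate", {
  calls <- rbind(mkCalls(1000, "s1", gene_id = "gA"),
                 mkCalls(1010, "s1", gene_id = "gB"),
                 mkCalls(1020, "s1", gene_id = "gA", chrom = "c2"),
                 mkCalls(1030, "s1", gene_id = "gA", strand = "-"))
  a <- aggregateCalls(calls)
  expect_length(unique(a$aggregate_id), 4L)
})

test_that("clustering equals the brute-force transitive closure", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:100, 1)
    tss <- sort(sample.int(5000, n, replace = TRUE))
    calls <- mkCalls(tss, sprintf("s%03d", seq_len(n)))
    a <- aggregateCalls(calls, window = 100)
    oracle <- bfCluster(calls$tss, 100)
    obs <- as.integer(factor(a$aggregate_id, levels = unique(a$aggregate_id)))
    # same partition: labels must be a bijection
    expect_identical(length(unique(obs)), length(unique(oracle)))
    expect_true(all(tapply(oracle, obs, function(x) length(unique(x))) == 1L))
    # partition property: every call in exactly one aggregate
    expect_identical(sum(table(a$aggregate_id)), nrow(calls))
  }
})

test_that("aggregate count is non-increasing in the window", {
  set.seed(99)
  calls <- mkCalls(sort(sample.int(3000, 60, replace = TRUE)),
                   sprintf("s%02d", 1:60))
  nAgg <- vapply(c(0, 10, 50, 100, 250, 1000), function(w)
    length(unique(aggregateCalls(calls, window = w)$aggregate_id)), integer(1))
  expect_true(all(diff(nAgg) <= 0))
})

test_that("per-group counts are distinct-sample tallies", {
  sheet <- data.frame(sample_id = c("t1", "t2", "n1"),
                      group = c("tumor", "tumor", "normal"))
  calls <- aggregateCalls(mkCalls(c(1000, 1010, 1020), c("t1", "t2", "n1")))
  counts <- countByGroup(calls, sheet)
  expect_identical(counts$n_tumor, 2L)
  expect_identical(counts$n_normal, 1L)
  # two isoforms of one sample count once
  iso <- aggregateCalls(mkCalls(c(1000, 1010), c("t1", "t1"),
                                transcript_id = c("a", "b")))
  expect_identical(countByGroup(iso, sheet)$n_tumor, 1L)
  # unknown samples are reported by id
  bad <- aggregateCalls(mkCalls(1000, "ghost"))
  expect_error(countByGroup(bad, sheet), "ghost")
})

test_that("per-group counts match a brute-force tally on random cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    samples <- sprintf("s%02d", 1:20)
    sheet <- data.frame(sample_id = samples,
                        group = sample(c("tumor", "normal"), 20, replace = TRUE))
    calls <- aggregateCalls(mkCalls(sample.int(2000, 50, replace = TRUE),
                                    sample(samples, 50, replace = TRUE)))
    counts <- countByGroup(calls, sheet)
    for (k in seq_len(nrow(counts))) {
      members <- calls[calls$aggregate_id == counts$aggregate_id[k], ]
      for (g in c("tumor", "normal")) {
        expected <- length(unique(members$sample_id[
          sheet$group[match(members$sample_id, sheet$sample_id)] == g]))
        expect_identical(counts[[paste0("n_", g)]][k], expected)
      }
    }
  }
})

test_that("the recurrence filter applies strict 20%/10% bounds", {
  nPer <- c(tumor = 286L, normal = 286L)
  row <- function(nT, nN) {
    counts <- countByGroup(
      aggregateCalls(mkCalls(rep(1000, nT + nN),
                             c(sprintf("t%03d", seq_len(nT)),
                               sprintf("n%03d", seq_len(nN))))),
      data.frame(sample_id = c(sprintf("t%03d", 1:286), sprintf("n%03d", 1:286)),
                 group = rep(c("tumor", "normal"), each = 286)))
    counts
  }
  # the headline case: 186/286 tumors, 11/286 normals passes
  expect_identical(nrow(recurrenceFilter(row(186, 11), nPer)), 1L)
  # just under the tumor threshold fails
  expect_identical(nrow(recurrenceFilter(row(57, 0), nPer)), 0L)
})

test_that("recurrence boundaries are strict at exact fractions", {
  nPer <- c(tumor = 100L, normal = 100L)
  sheet <- data.frame(sample_id = c(sprintf("t%03d", 1:100), sprintf("n%03d", 1:100)),
                      group = rep(c("tumor", "normal"), each = 100))
  mk <- function(nT, nN) countByGroup(aggregateCalls(
    mkCalls(rep(1000, nT + nN), c(sprintf("t%03d", seq_len(nT)),
                                  sprintf("n%03d", seq_len(nN))))), sheet)
  expect_identical(nrow(recurrenceFilter(mk(20, 0), nPer)), 0L)   # exactly 20%
  expect_identical(nrow(recurrenceFilter(mk(21, 0), nPer)), 1L)
  expect_identical(nrow(recurrenceFilter(mk(21, 10), nPer)), 0L)  # exactly 10%
  expect_identical(nrow(recurrenceFilter(mk(21, 9), nPer)), 1L)
  expect_error(recurrenceFilter(mk(21, 9), nPer, minTumorFrac = 1.2), "fraction")
  expect_error(recurrenceFilter(mk(21, 9), c(tumor = 100L)), "normal")
})

test_that("loosening either filter bound never removes a gene-table row", {
  set.seed(7)
  samples <- c(sprintf("t%02d", 1:30), sprintf("n%02d", 1:30))
  sheet <- data.frame(sample_id = samples,
                      group = rep(c("tumor", "normal"), each = 30))
  calls <- aggregateCalls(rbind(
    mkCalls(sample(1000:1040, 40, TRUE), sample(samples, 40, TRUE), "gA"),
    mkCalls(sample(5000:5040, 25, TRUE), sample(samples, 25, TRUE), "gB"),
    mkCalls(sample(9000:9040, 10, TRUE), sample(samples, 10, TRUE), "gC")))
  counts <- countByGroup(calls, sheet)
  nPer <- groupSizes(sheet)
  base <- geneTable(calls, recurrenceFilter(counts, nPer), sheet)
  looserT <- geneTable(calls, recurrenceFilter(counts, nPer, minTumorFrac = 0.10),
                       sheet)
  looserN <- geneTable(calls, recurrenceFilter(counts, nPer, maxNormalFrac = 0.50),
                       sheet)
  expect_true(all(base$gene_name %in% looserT$gene_name))
  expect_true(all(base$gene_name %in% looserN$gene_name))
})

test_that("gene-level counts are sample unions across passing aggregates", {
  # two aggregates of one gene share 10 tumor samples, plus 5 unique each
  shared <- sprintf("t%03d", 1:10)
  only1 <- sprintf("t%03d", 11:15)
  only2 <- sprintf("t%03d", 16:20)
  sheet <- data.frame(sample_id = c(sprintf("t%03d", 1:20), "n001"),
                      group = c(rep("tumor", 20), "normal"))
  calls <- aggregateCalls(rbind(
    mkCalls(rep(1000, 15), c(shared, only1),
            transcript_id = sprintf("x%02d", 1:15)),
    mkCalls(rep(9000, 15), c(shared, only2),
            transcript_id = sprintf("y%02d", 1:15))))
  counts <- countByGroup(calls, sheet)
  nPer <- c(tumor = 20L, normal = 1L)
  passing <- recurrenceFilter(counts, nPer)
  expect_identical(nrow(passing), 2L)
  gt <- geneTable(calls, passing, sheet, nPer)
  expect_identical(gt$nT, 20L)  # union, not 30
  expect_identical(gt$n_aggregates, 2L)
  expect_identical(gt$pctT, 100)
  expect_identical(gt$nN, 0L)
  expect_identical(gt$pctN, 0)
})

test_that("gene-table percentages reproduce half-up rounding at cohort size 286", {
  expect_identical(formatPct(186, 286), 65.0)
  expect_identical(formatPct(175, 286), 61.2)
  expect_identical(formatPct(159, 286), 55.6)
  expect_identical(formatPct(85, 286), 29.7)
  expect_identical(formatPct(11, 286), 3.8)
})
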