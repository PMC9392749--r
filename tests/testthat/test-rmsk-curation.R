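# RepeatMasker parsing, fragment fusion, LTR-internal grouping, BED round
# trip, base conservation and idempotence.

mkRecords <- function(start, end, name, strand = "+", linkage = seq_along(start),
                      chrom = "c1", class = "LTR/ERVL") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  S4Vectors::mcols(gr)$repeat_name <- rep_len(name, length(gr))
  S4Vectors::mcols(gr)$repeat_class <- rep_len(class, length(gr))
  S4Vectors::mcols(gr)$linkage_id <- as.integer(linkage)
  S4Vectors::mcols(gr)$divergence <- 10
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

test_that("the packaged .out fixture parses to 12 records in coordinate order", {
  rec <- parseRmskOut(rmskFixturePath())
  expect_length(rec, 12)
  expect_identical(order(as.character(GenomicRanges::seqnames(rec)),
                         BiocGenerics::start(rec)),
                   seq_along(rec))
  ltr66 <- rec[S4Vectors::mcols(rec)$repeat_name == "LTR66"]
  expect_length(ltr66, 2)
  expect_identical(BiocGenerics::start(ltr66)[1], 128000001L)
  expect_identical(unique(S4Vectors::mcols(ltr66)$linkage_id), 7L)
  # strand column C maps to minus
  ltr33 <- rec[S4Vectors::mcols(rec)$repeat_name == "LTR33"]
  expect_identical(as.character(BiocGenerics::strand(ltr33)), "-")
})

test_that("non-numeric coordinates raise an error with the line number", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header", "header", "",
               " 100 10.0 0.0 0.0 chr1 xyz 200 (0) + LTR66 LTR/ERVL 1 200 (0) 1"), f)
  expect_error(parseRmskOut(f), "line 4")
})

test_that("fragments sharing a linkage id fuse; unrelated records do not", {
  rec <- mkRecords(c(1000, 4000), c(1400, 4400), "LTR66", linkage = c(7, 7))
  tes <- fuseFragments(rec)
  expect_length(tes, 1)
  expect_identical(S4Vectors::mcols(teUnits(tes))$n_fragments, 2L)
  expect_identical(S4Vectors::mcols(teUnits(tes))$role, "fused-fragment-unit")

  far <- mkRecords(c(1000, 51000), c(1300, 51300), "AluSx1", linkage = c(1, 2),
                   class = "SINE/Alu")
  expect_length(fuseFragments(far), 2)
})

test_that("positional fallback only engages when linkage ids are uninformative", {
  # all-distinct ids, 2 kb apart, same name -> fallback fuses
  rec <- mkRecords(c(1000, 3000), c(1400, 5000), "LTR12C", linkage = c(1, 2))
  expect_length(fuseFragments(rec), 1)
  expect_length(fuseFragments(rec, maxGap = 100), 2)
  expect_error(fuseFragments(rec, maxGap = -1), "maxGap")
})

test_that("fusion equals the brute-force transitive closure on random records", {
  for (seed in 1:6) {
    for (linked in c(TRUE, FALSE)) {
      rec <- randomRepeatRecords(seed, n = 30, linked = linked)
      tes <- fuseFragments(rec, maxGap = 5000)
      df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rec)),
                       start = BiocGenerics::start(rec),
                       end = BiocGenerics::end(rec),
                       strand = as.character(BiocGenerics::strand(rec)),
                       name = S4Vectors::mcols(rec)$repeat_name,
                       linkage = S4Vectors::mcols(rec)$linkage_id,
                       stringsAsFactors = FALSE)
      lid <- df$linkage
      informative <- !all(is.na(lid)) && anyDuplicated(lid[!is.na(lid)]) > 0
      comp <- bfFuseComponents(df, maxGap = 5000, linkageInformative = informative)
      expect_identical(length(tes), length(unique(comp)))
      # identical fragment partitions: compare sorted per-component base sets
      obsSets <- sort(vapply(seq_along(tes), function(i) {
        f <- teFragments(tes)[[i]]
        paste(sort(paste0(as.character(GenomicRanges::seqnames(f)), ":",
                          BiocGenerics::start(f), "-", BiocGenerics::end(f))),
              collapse = ";")
      }, character(1)))
      expSets <- sort(unname(vapply(split(seq_len(nrow(df)), comp), function(ix) {
        merged <- IRanges::reduce(IRanges::IRanges(df$start[ix], df$end[ix]))
        paste(sort(paste0(df$chrom[ix][1], ":", BiocGenerics::start(merged),
                          "-", BiocGenerics::end(merged))), collapse = ";")
      }, character(1))))
      expect_identical(obsSets, expSets)
    }
  }
})

test_that("curation conserves the covered base set and is idempotent", {
  rec <- parseRmskOut(rmskFixturePath())
  tes <- curateRepeats(rec)
  inBases <- sum(BiocGenerics::width(GenomicRanges::reduce(rec, ignore.strand = TRUE)))
  outBases <- sum(BiocGenerics::width(GenomicRanges::reduce(
    unlist(teFragments(tes)), ignore.strand = TRUE)))
  expect_identical(inBases, outBases)

  # pairing is idempotent
  again <- pairLtrInternal(tes)
  expect_identical(S4Vectors::mcols(teUnits(again)), S4Vectors::mcols(teUnits(tes)))

  # re-fusing the fused output (fragments as records, one linkage per unit)
  # reproduces the same units
  frag <- unlist(teFragments(tes))
  asRecords <- GenomicRanges::GRanges(GenomicRanges::seqnames(frag),
                                      IRanges::IRanges(BiocGenerics::start(frag),
                                                       BiocGenerics::end(frag)),
                                      strand = BiocGenerics::strand(frag))
  S4Vectors::mcols(asRecords)$repeat_name <-
    rep(S4Vectors::mcols(teUnits(tes))$unit_name, lengths(teFragments(tes)))
  S4Vectors::mcols(asRecords)$repeat_class <-
    rep(S4Vectors::mcols(teUnits(tes))$unit_class, lengths(teFragments(tes)))
  S4Vectors::mcols(asRecords)$linkage_id <-
    rep(seq_along(tes), lengths(teFragments(tes)))
  S4Vectors::mcols(asRecords)$divergence <- 10
  refused <- fuseFragments(GenomicRanges::sort(asRecords, ignore.strand = TRUE))
  expect_identical(length(refused), length(tes))
  expect_identical(sum(BiocGenerics::width(unlist(teFragments(refused)))),
                   sum(BiocGenerics::width(unlist(teFragments(tes)))))
})

test_that("LTR-internal-LTR layouts group with strand-aware roles", {
  # full trio on + strand
  rec <- mkRecords(c(1000, 2500, 6000), c(1400, 4500, 6400),
                   c("LTRX", "LTRX-int", "LTRX"), linkage = 1:3)
  tes <- pairLtrInternal(fuseFragments(rec, maxGap = 0))
  m <- S4Vectors::mcols(teUnits(tes))
  expect_identical(m$role, c("ltr5", "internal", "ltr3"))
  expect_length(unique(m$erv_group_id), 1L)
  expect_false(anyNA(m$erv_group_id))

  # same layout on minus strand: genomic-left LTR is the 3' LTR
  recM <- mkRecords(c(1000, 2500, 6000), c(1400, 4500, 6400),
                    c("LTRX", "LTRX-int", "LTRX"), strand = "-", linkage = 1:3)
  mM <- S4Vectors::mcols(teUnits(pairLtrInternal(fuseFragments(recM, maxGap = 0))))
  expect_identical(mM$role, c("ltr3", "internal", "ltr5"))

  # isolated LTR stays solo
  solo <- mkRecords(1000, 1400, "LTR66")
  expect_identical(S4Vectors::mcols(teUnits(pairLtrInternal(fuseFragments(solo, maxGap = 0))))$role,
                   "solo")

  # internal flanked only on the 3' side -> group of two
  two <- mkRecords(c(1000, 4000), c(3000, 4400), c("LTRX-int", "LTRX"),
                   linkage = 1:2)
  m2 <- S4Vectors::mcols(teUnits(pairLtrInternal(fuseFragments(two, maxGap = 0))))
  expect_identical(m2$role, c("internal", "ltr3"))
  expect_identical(m2$erv_group_id[1], m2$erv_group_id[2])

  # an intervening unit of another family blocks adjacency
  blocked <- mkRecords(c(1000, 2500, 2600, 6000), c(1400, 2550, 4500, 6400),
                       c("LTRX", "AluY", "LTRX-int", "LTRX"), linkage = 1:4,
                       class = c("LTR/ERVL", "SINE/Alu", "LTR/ERVL", "LTR/ERVL"))
  mB <- S4Vectors::mcols(teUnits(pairLtrInternal(fuseFragments(blocked, maxGap = 0))))
  expect_identical(mB$role[mB$unit_name == "LTRX"][1], "solo")
  expect_identical(mB$role[mB$unit_name == "LTRX"][2], "ltr3")

  # distance beyond maxGap blocks grouping
  farApart <- mkRecords(c(1000, 9000), c(3000, 9400), c("LTRX-int", "LTRX"),
                        linkage = 1:2)
  mF <- S4Vectors::mcols(teUnits(pairLtrInternal(fuseFragments(farApart, maxGap = 0),
                                                 maxGap = 2000)))
  expect_true(all(is.na(mF$erv_group_id)))
})

test_that("curated units round-trip through BED12", {
  rec <- parseRmskOut(rmskFixturePath())
  tes <- curateRepeats(rec)
  f <- withr::local_tempfile(fileext = ".bed")
  writeCuratedBed(tes, f)
  # the fused LTR66 unit writes two blocks
  lines <- readLines(f)
  ltr66Line <- grep("^chr8\t.*LTR66", lines, value = TRUE)
  expect_identical(as.integer(strsplit(ltr66Line, "\t")[[1]][10]), 2L)
  back <- readCuratedBed(f)
  expect_identical(length(back), length(tes))
  mA <- S4Vectors::mcols(teUnits(tes)); mB <- S4Vectors::mcols(teUnits(back))
  o <- match(mA$unit_id, mB$unit_id)
  expect_identical(mA$unit_name, mB$unit_name[o])
  expect_identical(mA$role, mB$role[o])
  expect_identical(mA$erv_group_id, mB$erv_group_id[o])
  expect_identical(mA$n_fragments, mB$n_fragments[o])
  for (i in seq_along(tes)) {
    a <- teFragments(tes)[[i]]
    b <- teFragments(back)[[o[i]]]
    expect_identical(BiocGenerics::start(a), BiocGenerics::start(b))
    expect_identical(BiocGenerics::end(a), BiocGenerics::end(b))
  }
  # empty set -> header-only file
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeCuratedBed(fuseFragments(GenomicRanges::GRanges()), f2)
  expect_length(readLines(f2), 1L)
  expect_length(readCuratedBed(f2), 0L)
})
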