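# RepeatMasker curation: .out parsing, fragment fusion, LTR-internal pairing,
# and BED12 round trip of curated units. No installed R package parses the
# RepeatMasker .out layout, so the (simple, fixed-column) parser is local.

#' Parse a RepeatMasker .out file
#'
#' Standard whitespace-delimited layout: up to three header lines, then one
#' row per repeat fragment with SW score, divergence, deletion/insertion
#' percentages, query sequence and 1-based inclusive coordinates, strand
#' (\code{+} or \code{C} for the reverse strand), repeat name, class/family,
#' repeat-consensus coordinates and the linkage ID shared by fragments of one
#' interrupted insertion.
#'
#' @param path path to a \code{.out} file.
#' @return \code{GRanges} sorted by (chrom, start) with metadata columns
#'   \code{repeat_name}, \code{repeat_class}, \code{linkage_id} (integer,
#'   \code{NA} if absent) and \code{divergence}.
#' @export
parseRmskOut <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # up to three header lines; records start with the numeric SW score
  isHeader <- seq_along(lines) <= 3 & !grepl("^\\s*\\d", lines)
  body <- which(!isHeader & nzchar(trimws(lines)))
  if (length(body) == 0L)
    return(GRanges(repeat_name = character(0), repeat_class = character(0),
                   linkage_id = integer(0), divergence = numeric(0)))
  fields <- strsplit(trimws(lines[body]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14))
    stop(sprintf("truncated RepeatMasker record at line %d of %s",
                 body[which(nf < 14)[1]], path))
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  beg <- suppressWarnings(as.integer(getf(6)))
  endp <- suppressWarnings(as.integer(getf(7)))
  if (anyNA(beg) || anyNA(endp))
    stop(sprintf("non-numeric coordinate at line %d of %s",
                 body[which(is.na(beg) | is.na(endp))[1]], path))
  strand <- ifelse(getf(9) == "C", "-", "+")
  id <- suppressWarnings(as.integer(vapply(fields, function(f) f[[min(15, length(f))]],
                                           character(1))))
  gr <- GRanges(getf(5), IRanges(beg, endp), strand = strand)
  mcols(gr)$repeat_name <- getf(10)
  mcols(gr)$repeat_class <- getf(11)
  mcols(gr)$linkage_id <- id
  mcols(gr)$divergence <- suppressWarnings(as.numeric(getf(2)))
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  sort(gr, ignore.strand = TRUE)
}

# Union-find over indices; returns component labels.
.unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Fuse fragments of interrupted repeat insertions
#'
#' Records on the same chromosome and strand with the same repeat name are
#' fused into one curated unit when they share a RepeatMasker linkage ID, or
#' (fallback, used when linkage IDs are absent or carry no information
#' because they are all distinct) when consecutive fragments are separated by
#' at most \code{maxGap} bp. Fusion never gains or loses covered bases: the
#' unit keeps the original pieces as its fragment list.
#'
#' @param records \code{GRanges} from \code{\link{parseRmskOut}}.
#' @param maxGap maximum gap (bp) bridged by the positional fallback
#'   (default 10000).
#' @return A \code{\linkS4class{CuratedTESet}}; multi-fragment units get role
#'   \code{fused-fragment-unit}, single-fragment units role \code{solo}.
#' @export
fuseFragments <- function(records, maxGap = 10000) {
  stopifnot(is(records, "GRanges"))
  if (maxGap < 0) stop("maxGap must be >= 0")
  n <- length(records)
  if (n == 0L)
    return(.emptyCuratedTESet())
  lid <- mcols(records)$linkage_id
  # linkage informative only if some id recurs
  linkageInformative <- !all(is.na(lid)) && anyDuplicated(lid[!is.na(lid)]) > 0
  key <- paste(as.character(seqnames(records)), as.character(strand(records)),
               mcols(records)$repeat_name, sep = "\r")
  pairs <- matrix(integer(0), ncol = 2)
  for (ix in split(seq_len(n), key)) {
    if (length(ix) < 2L) next
    ix <- ix[order(start(records)[ix])]
    if (linkageInformative) {
      l <- lid[ix]
      for (grp in split(seq_along(ix), l)) {
        if (length(grp) > 1L)
          pairs <- rbind(pairs, cbind(ix[grp[-length(grp)]], ix[grp[-1]]))
      }
    } else {
      # all-pairs: the closure must also bridge nested/overlapping pieces
      for (a in seq_len(length(ix) - 1L)) for (b in (a + 1L):length(ix)) {
        gap <- max(start(records)[ix[a]], start(records)[ix[b]]) -
          min(end(records)[ix[a]], end(records)[ix[b]]) - 1L
        if (gap <= maxGap) pairs <- rbind(pairs, cbind(ix[a], ix[b]))
      }
    }
  }
  comp <- .unionFind(n, pairs)
  .buildUnits(records, comp)
}

.emptyCuratedTESet <- function() {
  u <- GRanges()
  mcols(u) <- DataFrame(unit_id = character(0), unit_name = character(0),
                        unit_class = character(0), role = character(0),
                        erv_group_id = character(0), n_fragments = integer(0))
  .newCuratedTESet(u, GRangesList())
}

# Assemble CuratedTESet from records and a component labelling.
.buildUnits <- function(records, comp) {
  ix <- split(seq_along(records), comp)
  spanStart <- vapply(ix, function(i) min(start(records)[i]), numeric(1))
  ord <- order(vapply(ix, function(i) as.character(seqnames(records))[i[1]], character(1)),
               spanStart)
  ix <- ix[ord]
  ids <- .padId("TE", seq_along(ix))
  spans <- GRanges(
    unname(vapply(ix, function(i) as.character(seqnames(records))[i[1]],
                  character(1))),
    IRanges(unname(vapply(ix, function(i) min(start(records)[i]), numeric(1))),
            unname(vapply(ix, function(i) max(end(records)[i]), numeric(1)))),
    strand = unname(vapply(ix, function(i) as.character(strand(records))[i[1]],
                           character(1))))
  frags <- GRangesList(lapply(ix, function(i) {
    f <- reduce(sort(records[i]), ignore.strand = TRUE)
    strand(f) <- as.character(strand(records))[i[1]]
    mcols(f) <- NULL
    f
  }))
  names(frags) <- NULL
  nfr <- unname(lengths(frags))
  mcols(spans) <- DataFrame(
    unit_id = ids,
    unit_name = unname(vapply(ix, function(i) mcols(records)$repeat_name[i[1]],
                              character(1))),
    unit_class = unname(vapply(ix, function(i) mcols(records)$repeat_class[i[1]],
                               character(1))),
    role = ifelse(nfr > 1L, "fused-fragment-unit", "solo"),
    erv_group_id = rep(NA_character_, length(ix)),
    n_fragments = nfr)
  names(spans) <- ids
  .newCuratedTESet(spans, frags)
}

.isInternal <- function(name, class, pairingTable = NULL) {
  if (!is.null(pairingTable)) return(name %in% pairingTable$internal)
  grepl("-int$", name) & startsWith(class, "LTR")
}

.isLtrClass <- function(name, class, pairingTable = NULL, internalName = NULL) {
  isLtr <- startsWith(class, "LTR") & !grepl("-int$", name)
  if (!is.null(pairingTable) && !is.null(internalName)) {
    allowed <- pairingTable$ltr[pairingTable$internal == internalName]
    isLtr <- isLtr & (name %in% allowed)
  }
  isLtr
}

#' Group flanking LTRs with their internal ERV counterparts
#'
#' A unit whose name ends in \code{-int} (the protein-coding interior of an
#' endogenous retrovirus) is grouped with same-strand LTR-class units
#' immediately adjacent on its 5' and/or 3' side (gap at most \code{maxGap},
#' no unit of another family in between). Grouped members share an
#' \code{erv_group_id} and get strand-aware roles \code{ltr5} /
#' \code{internal} / \code{ltr3}; ungrouped LTRs keep role \code{solo}.
#' The operation is idempotent.
#'
#' @param tes a \code{\linkS4class{CuratedTESet}} (from
#'   \code{\link{fuseFragments}}).
#' @param maxGap maximum adjacency gap in bp (default 2000).
#' @param pairingTable optional data.frame with columns \code{internal},
#'   \code{ltr} overriding the name-suffix recognition of internal elements
#'   and restricting which LTR names may flank them.
#' @return the \code{CuratedTESet} with roles and \code{erv_group_id} filled.
#' @export
pairLtrInternal <- function(tes, maxGap = 2000, pairingTable = NULL) {
  stopifnot(is(tes, "CuratedTESet"))
  if (maxGap < 0) stop("maxGap must be >= 0")
  u <- tes@units
  if (length(u) == 0L) return(tes)
  m <- mcols(u)
  role <- ifelse(m$n_fragments > 1L, "fused-fragment-unit", "solo")
  ervId <- rep(NA_character_, length(u))
  ord <- order(as.character(seqnames(u)), start(u))
  internal <- which(.isInternal(m$unit_name, m$unit_class, pairingTable))
  taken <- logical(length(u))
  grp <- 0L
  for (i in internal[order(start(u)[internal])]) {
    pos <- match(i, ord)
    members <- i
    roles <- "internal"
    neighbor <- function(offset) {
      j <- pos + offset
      if (j < 1L || j > length(ord)) return(NA_integer_)
      k <- ord[j]
      if (as.character(seqnames(u))[k] != as.character(seqnames(u))[i]) return(NA_integer_)
      k
    }
    sameStrand <- function(k) as.character(strand(u))[k] == as.character(strand(u))[i]
    gapTo <- function(k) {
      if (start(u)[k] > end(u)[i]) start(u)[k] - end(u)[i] - 1L
      else start(u)[i] - end(u)[k] - 1L
    }
    minus <- identical(as.character(strand(u))[i], "-")
    for (side in c(-1L, 1L)) {
      k <- neighbor(side)
      if (!is.na(k) && !taken[k] && sameStrand(k) && gapTo(k) <= maxGap &&
          .isLtrClass(m$unit_name[k], m$unit_class[k], pairingTable, m$unit_name[i])) {
        members <- c(members, k)
        # genomic left neighbor is the 5' LTR on +, the 3' LTR on -
        roles <- c(roles,
                   if ((side == -1L) != minus) "ltr5" else "ltr3")
      }
    }
    if (length(members) > 1L) {
      grp <- grp + 1L
      gid <- .padId("ERV", grp, width = 4)
      role[members] <- roles
      ervId[members] <- gid
      taken[members] <- TRUE
    }
  }
  mcols(u)$role <- role
  mcols(u)$erv_group_id <- ervId
  .newCuratedTESet(u, tes@fragments)
}

#' Full repeat curation: fuse fragments, then pair LTRs with internals
#'
#' @param records \code{GRanges} from \code{\link{parseRmskOut}}.
#' @param fuseGap gap threshold for the fusion fallback (bp, default 10000).
#' @param ltrIntGap adjacency threshold for LTR-internal grouping (bp,
#'   default 2000).
#' @param pairingTable optional LTR/internal pairing table
#'   (see \code{\link{pairLtrInternal}}).
#' @return A \code{\linkS4class{CuratedTESet}}.
#' @export
curateRepeats <- function(records, fuseGap = 10000, ltrIntGap = 2000,
                          pairingTable = NULL) {
  pairLtrInternal(fuseFragments(records, maxGap = fuseGap),
                  maxGap = ltrIntGap, pairingTable = pairingTable)
}

#' Write curated TE units as BED12
#'
#' One BED12 record per unit; blocks are the unit's fragments and the name
#' field encodes \code{unit_name|unit_id|role|erv_group_id}.
#' \code{readCuratedBed(writeCuratedBed(x))} preserves all fields.
#'
#' @param tes a \code{\linkS4class{CuratedTESet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCuratedBed <- function(tes, path) {
  stopifnot(is(tes, "CuratedTESet"))
  track <- "track name=curatedTE description=\"curated repeat units\""
  if (length(tes) == 0L) {
    writeLines(track, path)
    return(invisible(path))
  }
  u <- tes@units
  m <- mcols(u)
  gr <- GRanges(seqnames(u), IRanges(start(u), end(u)), strand = strand(u))
  mcols(gr)$name <- paste(m$unit_name, m$unit_id, m$role,
                          ifelse(is.na(m$erv_group_id), "NA", m$erv_group_id),
                          sep = "|")
  mcols(gr)$blocks <- IRangesList(lapply(seq_along(u), function(i) {
    f <- tes@fragments[[i]]
    IRanges(start(f) - start(u)[i] + 1L, end(f) - start(u)[i] + 1L)
  }))
  tmp <- tempfile(fileext = ".bed")
  rtracklayer::export(gr, tmp, format = "bed")
  writeLines(c(track, readLines(tmp, warn = FALSE)), path)
  unlink(tmp)
  invisible(path)
}

#' Read curated TE units from BED12
#'
#' @param path BED12 path written by \code{\link{writeCuratedBed}} (or any
#'   BED12 whose name field is \code{unit_name|unit_id|role|erv_group_id}).
#' @return A \code{\linkS4class{CuratedTESet}}.
#' @export
readCuratedBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(.emptyCuratedTESet())
  parts <- strsplit(mcols(gr)$name, "|", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("BED name field is not unit_name|unit_id|role|erv_group_id")
  unitName <- vapply(parts, `[[`, character(1), 1)
  unitId <- vapply(parts, `[[`, character(1), 2)
  role <- vapply(parts, `[[`, character(1), 3)
  erv <- vapply(parts, `[[`, character(1), 4)
  erv[erv == "NA"] <- NA_character_
  frags <- GRangesList(lapply(seq_along(gr), function(i) {
    b <- mcols(gr)$blocks[[i]]
    f <- GRanges(seqnames(gr)[i],
                 IRanges(start(gr)[i] + start(b) - 1L, start(gr)[i] + end(b) - 1L),
                 strand = strand(gr)[i])
    f
  }))
  u <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(u) <- DataFrame(unit_id = unitId, unit_name = unitName,
                        unit_class = rep(NA_character_, length(gr)),
                        role = role, erv_group_id = erv,
                        n_fragments = lengths(frags))
  names(u) <- unitId
  .newCuratedTESet(u, frags)
}
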