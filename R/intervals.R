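#' Genomic interval utilities
#'
#' All intervals inside the package are 1-based inclusive (the MAF
#' convention). BED files on disk are 0-based half-open; conversion happens
#' only at the I/O boundary in [read_bed()] / [write_bed()].
#'
#' @name intervals
NULL

#' Construct an interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @param ... further per-interval columns recycled to length.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, ...
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L)) stop("interval start must be >= 1 (1-based inclusive)")
  if (any(end < start)) stop("interval end must be >= start")
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be '+', '-' or '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, ..., stringsAsFactors = FALSE)
}

#' @return integer vector of interval lengths in bp.
#' @rdname genomic_intervals
#' @param intervals an interval data.frame.
#' @export
interval_length <- function(intervals) {
  intervals$end - intervals$start + 1L
}

# Internal: interval data.frame -> GRanges (1-based inclusive, as stored).
as_granges <- function(intervals) {
  strand <- if ("strand" %in% names(intervals)) {
    ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    strand = strand
  )
}

# Internal overlap wrappers: comparing ranges whose chromosome sets differ
# is routine here (e.g. a panel on chr1 vs a cohort on chr1+chr2), so the
# seqlevel-mismatch warning GenomicRanges raises is noise.
overlaps_any <- function(query, subject) {
  suppressWarnings(
    IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
  )
}

find_overlaps <- function(query, subject) {
  suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  )
}

count_overlaps <- function(query, subject) {
  suppressWarnings(
    GenomicRanges::countOverlaps(query, subject, ignore.strand = TRUE)
  )
}

# Internal: GRanges -> interval data.frame.
from_granges <- function(gr, ...) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE, ...
  )
}

#' Merge overlapping or book-ended intervals
#'
#' @param intervals interval data.frame.
#' @return sorted, merged (strand-ignorant) interval data.frame.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(as_granges(intervals), ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  from_granges(gr)
}

#' Normalize chromosome names
#'
#' @param chrom character vector.
#' @param style `"keep"` (no change), `"chr"` (ensure a chr prefix) or
#'   `"plain"` (strip the prefix).
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom, style = c("keep", "chr", "plain")) {
  style <- match.arg(style)
  chrom <- as.character(chrom)
  if (style == "chr") {
    ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  } else if (style == "plain") {
    sub("^chr", "", chrom)
  } else chrom
}

#' Read a BED file
#'
#' Accepts 3- or 6-column BED. On-disk coordinates are 0-based half-open and
#' are converted to the internal 1-based inclusive convention, so a line
#' `chr1 99 139` becomes the interval chr1:100-139 (length 40).
#'
#' @param path BED file path.
#' @return interval data.frame with `chrom`, `start`, `end` (plus `name`,
#'   `score`, `strand` when the file carries 6 columns).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED line ", which(ncol < 3L)[1L], " has fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0L) stop("unparseable BED coordinates at line ", bad[1L])
  bad <- which(start0 >= end0)
  if (length(bad) > 0L) {
    stop("BED line ", bad[1L], ": start >= end (", start0[bad[1L]], " >= ",
         end0[bad[1L]], ")")
  }
  out <- data.frame(chrom = chrom, start = start0 + 1L, end = end0,
                    stringsAsFactors = FALSE)
  if (all(ncol >= 6L)) {
    out$name <- vapply(fields, `[[`, "", 4L)
    out$score <- vapply(fields, `[[`, "", 5L)
    out$strand <- vapply(fields, `[[`, "", 6L)
  }
  out
}

#' Write a BED file
#'
#' Converts internal 1-based inclusive intervals back to 0-based half-open.
#' For a sorted, merged 3-column BED, `write_bed(read_bed(x))` is
#' byte-identical to `x`.
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @param name optional per-interval name column for BED6 output.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name = NULL) {
  if (is.null(name)) {
    lines <- sprintf("%s\t%d\t%d", intervals$chrom,
                     intervals$start - 1L, intervals$end)
  } else {
    strand <- if ("strand" %in% names(intervals)) {
      ifelse(intervals$strand %in% c("+", "-"), intervals$strand, ".")
    } else "."
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$chrom,
                     intervals$start - 1L, intervals$end, name, strand)
  }
  writeLines(lines, path)
  invisible(path)
}
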