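#' Construct a validated table of genomic intervals
#'
#' Intervals are the universal currency of the package: candidate binding
#' regions, ChIP-seq peaks, motif hits and gene spans are all plain data
#' frames in **0-based half-open** coordinates (`start` inclusive, `end`
#' exclusive, as in BED). A single interval is simply a one-row data frame.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive start (`>= 0`).
#' @param end Integer vector, exclusive end (`> start`).
#' @param name Optional character vector of names. Missing names default to
#'   `region_<i>` with a 0-based index, so joins are deterministic.
#' @param strand Optional strand vector over `{"+", "-", "*"}`; `"*"` means
#'   unstranded.
#' @return A data frame with columns `chrom`, `start`, `end`, `name` (and
#'   `strand` when supplied).
#' @examples
#' genomic_intervals("chrS", 10, 17, name = "r1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  .check_coords(chrom, start, end)
  if (is.null(name)) {
    name <- paste0("region_", seq_len(n) - 1L)
  } else {
    name <- rep_len(as.character(name), n)
  }
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), name = name,
                    stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- rep_len(as.character(strand), n)
    if (!all(strand %in% c("+", "-", "*"))) {
      stop("strand must be one of '+', '-', '*'")
    }
    out$strand <- strand
  }
  out
}

.check_coords <- function(chrom, start, end, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  if (anyNA(chrom) || anyNA(start) || anyNA(end)) {
    stop("interval fields must not be NA", ctx)
  }
  if (any(start != floor(start)) || any(end != floor(end))) {
    stop("interval coordinates must be integers", ctx)
  }
  if (any(start < 0)) stop("interval start must be >= 0", ctx)
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("interval end must exceed start (first offender: %s:[%s,%s))%s",
                 chrom[bad[1]], start[bad[1]], end[bad[1]], ctx))
  }
  invisible(TRUE)
}

#' Interval lengths
#'
#' @param x Interval data frame (or any object with `start`/`end` fields).
#' @return Integer vector `end - start`.
#' @export
interval_length <- function(x) {
  as.integer(x$end - x$start)
}

.as_ivl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  stopifnot(!is.null(x$chrom), !is.null(x$start), !is.null(x$end))
  x
}

#' Do two intervals share at least one base?
#'
#' Half-open semantics: `[0,7)` and `[7,10)` are adjacent, not overlapping.
#' Intervals on different chromosomes never overlap.
#'
#' @param a,b Single intervals (one-row data frames or lists with `chrom`,
#'   `start`, `end`).
#' @return `TRUE` iff the intervals are on the same chromosome and
#'   `a$start < b$end && b$start < a$end`.
#' @examples
#' overlaps(list(chrom = "c", start = 0, end = 7),
#'          list(chrom = "c", start = 6, end = 10))  # TRUE
#' overlaps(list(chrom = "c", start = 0, end = 7),
#'          list(chrom = "c", start = 7, end = 10))  # FALSE
#' @export
overlaps <- function(a, b) {
  a <- .as_ivl(a)
  b <- .as_ivl(b)
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# Vectorised form: which rows of `tab` overlap the single interval `ivl`.
.overlapping_rows <- function(ivl, tab) {
  ivl <- .as_ivl(ivl)
  which(tab$chrom == ivl$chrom & tab$start < ivl$end & ivl$start < tab$end)
}
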