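#' Bundle a ChIP-seq peak set for one factor
#'
#' @param factor Factor label, e.g. `"EcR"`, `"Usp"`, `"Jun"`, `"Kay"`
#'   (extensible: any label is accepted).
#' @param peaks Interval data frame (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()]. Stored sorted by (`chrom`, `start`); overlapping peaks
#'   within a set are permitted.
#' @param source_label Free-text provenance (stage / cell type).
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(factor, peaks, source_label = "") {
  stopifnot(is.character(factor), length(factor) == 1L, nzchar(factor),
            is.data.frame(peaks))
  if (nrow(peaks) > 0L) {
    .check_coords(peaks$chrom, peaks$start, peaks$end)
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(factor = factor,
                 peaks = peaks[, c("chrom", "start", "end"), drop = FALSE],
                 source_label = source_label),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peak(s)%s\n", x$factor, nrow(x$peaks),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]")
              else ""))
  invisible(x)
}

# Factors whose peaks overlap the hit (>= 1 shared base, no slop window).
.hit_factors <- function(hit, peaksets) {
  fac <- vapply(peaksets, function(ps) ps$factor, character(1))
  hit <- .as_ivl(hit)
  has <- vapply(peaksets, function(ps) {
    length(.overlapping_rows(hit, ps$peaks)) > 0L
  }, logical(1))
  sort(unique(fac[has]))
}

#' Classify one motif occurrence by ChIP-seq peak overlap
#'
#' Implements the colour scheme used to annotate AP-1 sites: **green** for
#' sites overlapping an EcR peak, **red** for sites overlapping Jun and/or
#' Kay (Fos) peaks but no EcR peak, **blue** for sites overlapping none of
#' EcR/Jun/Kay. Precedence is green > red > blue for multiply-overlapped
#' sites; all overlapping factors (including ones like Usp that never
#' change the category) are reported in `overlapping_factors` so no
#' information is lost.
#'
#' @param hit One motif hit (one-row data frame or list with `chrom`,
#'   `start`, `end`).
#' @param peaksets List of [peak_set()] objects (may be empty: the hit is
#'   then blue).
#' @return The hit as a one-row data frame with added columns `category`
#'   (`"green"`/`"red"`/`"blue"`) and `overlapping_factors`
#'   (comma-separated, sorted; `""` if none).
#' @export
classify_hit <- function(hit, peaksets = list()) {
  fac <- .hit_factors(hit, peaksets)
  category <- if ("EcR" %in% fac) {
    "green"
  } else if (any(c("Jun", "Kay") %in% fac)) {
    "red"
  } else {
    "blue"
  }
  out <- as.data.frame(.as_ivl(hit)[intersect(
    c("motif", "chrom", "start", "end", "strand", "matched_seq"),
    names(.as_ivl(hit)))], stringsAsFactors = FALSE)
  out$category <- category
  out$overlapping_factors <- paste(fac, collapse = ",")
  out
}

#' Annotate every AP-1 occurrence in a region
#'
#' Scans the region for the motif and classifies each occurrence with
#' [classify_hit()]. Category counts over a region are summable:
#' blue + red + green always equals the total hit count.
#'
#' @param region One interval (one-row data frame or list).
#' @param genome A [genome_sequence()].
#' @param motif Motif to scan for, default [ap1_motif()].
#' @param peaksets List of [peak_set()] objects.
#' @return Data frame of annotated hits (possibly zero rows), columns as
#'   in [classify_hit()].
#' @export
annotate_region <- function(region, genome, motif = ap1_motif(),
                            peaksets = list()) {
  hits <- scan_region(motif, genome, region)
  if (nrow(hits) == 0L) {
    hits$category <- character(0)
    hits$overlapping_factors <- character(0)
    return(hits)
  }
  do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    classify_hit(hits[i, , drop = FALSE], peaksets)
  }))
}

#' Tally annotation categories
#'
#' @param annotated Output of [annotate_region()].
#' @return Named integer vector with entries `blue`, `red`, `green`.
#' @export
category_counts <- function(annotated) {
  counts <- table(factor(annotated$category,
                         levels = c("blue", "red", "green")))
  stats::setNames(as.integer(counts), names(counts))
}
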