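#' @keywords internal
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Define a degenerate IUPAC consensus motif
#'
#' A motif is a named consensus over the 15 IUPAC nucleotide codes, compiled
#' to a per-position set of allowed bases (`A`/`C`/`G`/`T` only). An `N` in
#' the consensus allows any of the four unambiguous bases; an `N` in the
#' *genome* matches no motif position at all (see [match_at()]), so a site
#' is never counted unless it can be confirmed from sequence.
#'
#' @param name Motif label, e.g. `"AP1"`.
#' @param consensus Consensus string over IUPAC codes, e.g. `"TGANTCA"`.
#' @return An object of class `iupac_motif` with fields `name`, `consensus`,
#'   `compiled` (list of allowed-base sets) and `palindromic` (`TRUE` iff the
#'   code-level reverse complement of the consensus equals the consensus).
#' @examples
#' ap1 <- iupac_motif("AP1", "TGANTCA")
#' ap1$palindromic  # TRUE: TGANTCA is its own reverse complement
#' @seealso [ap1_motif()], [ecre_motif()], [scan_sequence()]
#' @export
iupac_motif <- function(name, consensus) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(consensus), length(consensus) == 1L)
  consensus <- toupper(consensus)
  if (nchar(consensus) < 1L) stop("motif consensus must be non-empty")
  codes <- strsplit(consensus, "")[[1]]
  bad <- setdiff(codes, names(IUPAC_CODES))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in consensus '", consensus, "': ",
         paste(unique(bad), collapse = ", "))
  }
  structure(
    list(name = name, consensus = consensus,
         compiled = IUPAC_CODES[codes],
         palindromic = reverse_complement(consensus) == consensus),
    class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("<iupac_motif> %s = %s (%d bp%s)\n", x$name, x$consensus,
              nchar(x$consensus),
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' The AP-1 consensus binding motif, TGANTCA
#'
#' Consensus binding site of the AP-1 transcription factor (Jun homodimers
#' or Jun-Fos heterodimers). TGANTCA is self-reverse-complementary, so each
#' genomic occurrence is reported once.
#' @return An `iupac_motif`.
#' @export
ap1_motif <- function() iupac_motif("AP1", "TGANTCA")

#' The canonical palindromic ecdysone-response element consensus
#'
#' Default EcRE consensus `RGGTCANTGACCY`, the canonical hsp27-derived
#' palindrome bound by EcR-Usp heterodimers. The consensus is a package
#' default, not a fixed constant: every screening function accepts any
#' [iupac_motif()] in its place.
#' @return An `iupac_motif`.
#' @export
ecre_motif <- function() iupac_motif("EcRE", "RGGTCANTGACCY")

#' Reverse complement of an IUPAC sequence
#'
#' Complementation acts at the code level (`complement(R) = Y`,
#' `complement(N) = N`), so degenerate consensi round-trip exactly and
#' `reverse_complement()` is an involution.
#'
#' @param seq A single string over IUPAC codes.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("TGANTCA")  # "TGANTCA"
#' reverse_complement("AAAC")     # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  codes <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[codes])), collapse = "")
}

#' Test a motif at a single offset
#'
#' Plus-strand membership test: the match succeeds iff at every position the
#' genome base is an unambiguous `A`/`C`/`G`/`T` contained in the motif's
#' allowed set. A genome `N` fails every position, including motif `N`.
#'
#' @param motif An [iupac_motif()].
#' @param seq Sequence string.
#' @param offset 0-based offset into `seq` (consistent with the package's
#'   half-open coordinate convention); `offset + motif length` must not
#'   exceed `nchar(seq)`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' match_at(ap1_motif(), "TGAATCA", 0)  # TRUE
#' match_at(ap1_motif(), "TGANTCA", 0)  # FALSE: genome N matches nothing
#' @export
match_at <- function(motif, seq, offset) {
  stopifnot(inherits(motif, "iupac_motif"))
  m <- length(motif$compiled)
  stopifnot(offset >= 0, offset + m <= nchar(seq))
  window <- strsplit(substr(toupper(seq), offset + 1L, offset + m), "")[[1]]
  all(mapply(function(base, allowed) base %in% allowed,
             window, motif$compiled))
}

# Vectorised core: 0-based offsets at which `compiled` matches `chars`
# (a character vector of single uppercase bases). Genome characters outside
# A/C/G/T (N in particular) match nothing because allowed sets contain only
# unambiguous bases.
.match_offsets <- function(compiled, chars) {
  m <- length(compiled)
  L <- length(chars)
  if (L < m) return(integer(0))
  n_off <- L - m + 1L
  ok <- rep(TRUE, n_off)
  for (j in seq_len(m)) {
    ok <- ok & (chars[j:(n_off + j - 1L)] %in% compiled[[j]])
  }
  which(ok) - 1L
}

#' Scan a sequence for all occurrences of a degenerate motif
#'
#' Reports every match at every offset on both strands, as plus-strand
#' spans in 0-based half-open coordinates. Overlapping occurrences are all
#' reported. For palindromic motifs (e.g. TGANTCA) the plus- and
#' minus-strand matches coincide span-for-span, so each genomic span is
#' reported exactly once with strand `"+"`; for non-palindromic motifs,
#' matches on the two strands are distinct hits even at the same span.
#'
#' @param motif An [iupac_motif()].
#' @param seq Sequence string (non-empty).
#' @param chrom Chromosome label recorded in the hit table.
#' @return A data frame of hits sorted by `start` (then strand), with
#'   columns `motif`, `chrom`, `start`, `end`, `strand`, `matched_seq`
#'   (the plus-strand genome substring at the span). A motif longer than
#'   `seq` yields zero rows, not an error.
#' @examples
#' scan_sequence(ap1_motif(), "TGACTCA")        # one hit at [0,7)
#' @export
scan_sequence <- function(motif, seq, chrom = "seq") {
  stopifnot(inherits(motif, "iupac_motif"), nchar(seq) > 0)
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  m <- length(motif$compiled)
  plus <- .match_offsets(motif$compiled, chars)
  starts <- plus
  strands <- rep("+", length(plus))
  if (!motif$palindromic) {
    rc <- iupac_motif(motif$name, reverse_complement(motif$consensus))
    minus <- .match_offsets(rc$compiled, chars)
    starts <- c(starts, minus)
    strands <- c(strands, rep("-", length(minus)))
  }
  ord <- order(starts, strands)
  starts <- starts[ord]
  strands <- strands[ord]
  matched <- if (length(starts)) substring(seq, starts + 1L, starts + m)
             else character(0)
  data.frame(
    motif = rep(motif$name, length(starts)),
    chrom = rep(chrom, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts + m),
    strand = strands,
    matched_seq = matched,
    stringsAsFactors = FALSE)
}

#' Count motif occurrences fully contained in a region
#'
#' Only matches lying entirely inside the interval are counted; a site
#' straddling the region boundary is not. This containment rule is what the
#' composite-element screen ([screen_regions()]) uses.
#'
#' @param motif An [iupac_motif()].
#' @param genome A [genome_sequence()].
#' @param region A single interval (one-row data frame or list with
#'   `chrom`, `start`, `end`); must lie within genome bounds.
#' @return Integer count.
#' @export
count_in_region <- function(motif, genome, region) {
  region <- .as_ivl(region)
  nrow(scan_sequence(motif, genome_fetch(genome, region$chrom,
                                         region$start, region$end)))
}

#' Scan a region, reporting hits in genome coordinates
#'
#' Same containment semantics as [count_in_region()]; hit coordinates are
#' shifted back to the genome.
#'
#' @inheritParams count_in_region
#' @return Hit data frame as in [scan_sequence()], in genome coordinates.
#' @export
scan_region <- function(motif, genome, region) {
  region <- .as_ivl(region)
  hits <- scan_sequence(motif, genome_fetch(genome, region$chrom,
                                            region$start, region$end),
                        chrom = region$chrom)
  hits$start <- hits$start + as.integer(region$start)
  hits$end <- hits$end + as.integer(region$start)
  hits
}

#' Write motif hits as BED6
#'
#' Columns: chrom, start, end, name (motif), score (0), strand.
#' @param hits Hit data frame from [scan_sequence()] or [scan_region()].
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  out <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                    name = hits$motif, score = 0L, strand = hits$strand)
  .write_tsv(out, path, col.names = FALSE)
  invisible(path)
}
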