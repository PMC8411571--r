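#' Construct a genome sequence object
#'
#' A genome is a named character vector of uppercase sequences over
#' `{A, C, G, T, N}`. Lookups are bounds-checked: an out-of-range request
#' is an error, never a silent truncation.
#'
#' @param seqs Named character vector (or named list) of sequences.
#' @return A named character vector of class `genome_sequence`.
#' @export
genome_sequence <- function(seqs) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("genome must contain at least one sequence")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("every genome sequence must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence '", names(seqs)[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  }
  structure(seqs, class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Fetch a genome slice by 0-based half-open coordinates
#'
#' @param genome A [genome_sequence()].
#' @param chrom Sequence name.
#' @param start,end 0-based half-open bounds; must satisfy
#'   `0 <= start < end <= nchar(sequence)`.
#' @return A string of exactly `end - start` characters.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: '", chrom, "'")
  }
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L || end <= start) {
    stop(sprintf("interval %s:[%s,%s) out of bounds for sequence of length %d",
                 chrom, start, end, L))
  }
  substr(genome[[chrom]], start + 1L, end)
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased and validated. By default (strict mode) any
#' character outside `{A, C, G, T, N}` is an error; with
#' `ambiguity = "to_n"` the other IUPAC ambiguity codes are mapped to `N`
#' (and then match no motif position, see [match_at()]).
#'
#' @param path FASTA file.
#' @param ambiguity `"error"` (default) or `"to_n"`.
#' @return A [genome_sequence()]. Sequence names are the first
#'   whitespace-delimited word of each header.
#' @export
read_fasta <- function(path, ambiguity = c("error", "to_n")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence name(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (ambiguity == "to_n") {
    amb <- "RYSWKMBDHV"
    seqs <- chartr(amb, strrep("N", nchar(amb)), seqs)
  }
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence()].
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read intervals from BED (3+ columns)
#'
#' BED is 0-based half-open, the package's internal convention, so
#' coordinates pass through unchanged. Parsing is strict: malformed lines
#' are reported by line number. `track`/`browser`/`#` lines are skipped.
#'
#' @param path BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `name` (and
#'   `strand` if a 6th column is present), input order preserved. Missing
#'   names become `region_<i>` with a 0-based index.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_line <- function(f, lineno) {
    if (length(f) < 3L) {
      stop("BED line ", lineno, ": fewer than 3 tab-separated columns")
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) ||
        start != floor(start) || end != floor(end)) {
      stop("BED line ", lineno, ": non-integer coordinate")
    }
    if (start < 0) stop("BED line ", lineno, ": negative start")
    if (end <= start) {
      stop("BED line ", lineno, sprintf(": end (%s) <= start (%s)",
                                        f[3], f[2]))
    }
    f
  }
  fields <- mapply(parse_line, fields, idx, SIMPLIFY = FALSE)
  nc <- vapply(fields, length, integer(1))
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[`, character(1), 3L))
  name <- ifelse(nc >= 4L, vapply(fields, `[`, character(1), 4L), NA)
  name <- ifelse(is.na(name) | !nzchar(name),
                 paste0("region_", seq_along(fields) - 1L), name)
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  if (all(nc >= 6L)) {
    out$strand <- vapply(fields, `[`, character(1), 6L)
  }
  out
}

#' Write intervals to BED
#'
#' Writes `chrom`, `start`, `end`, `name` (plus `score` 0 and `strand` when
#' a `strand` column exists). Output is byte-identical for identical input.
#'
#' @param intervals Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  .check_coords(intervals$chrom, intervals$start, intervals$end)
  cols <- data.frame(chrom = intervals$chrom,
                     start = as.integer(intervals$start),
                     end = as.integer(intervals$end),
                     name = intervals$name %||%
                       paste0("region_", seq_len(nrow(intervals)) - 1L),
                     stringsAsFactors = FALSE)
  if (!is.null(intervals$strand)) {
    cols$score <- 0L
    cols$strand <- intervals$strand
  }
  .write_tsv(cols, path, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3/GTF
#'
#' GFF/GTF coordinates are 1-based inclusive; they are converted at this
#' boundary to the internal 0-based half-open convention
#' (`start - 1`, `end`), so interval lengths are preserved. Features of
#' type `gene` become gene spans; features of type `exon` are attached to
#' their gene via the `Parent` (GFF3) or `gene_id` (GTF) attribute, which
#' must name the gene directly.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @return A list with two data frames: `genes` (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and `exons` (`gene_id`, `chrom`, `start`,
#'   `end`). An exon outside its gene span is an error.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (is.null(df$type)) stop("GFF file has no feature types: ", path)
  gid <- function(rows) {
    for (col in c("gene_id", "ID", "Name")) {
      v <- rows[[col]]
      if (!is.null(v) && !anyNA(v)) return(as.character(v))
    }
    stop("gene feature without gene_id/ID/Name attribute in ", path)
  }
  g <- df[df$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) stop("no 'gene' features in ", path)
  genes <- data.frame(gene_id = gid(g), chrom = g$seqnames,
                      start = g$start - 1L, end = g$end,
                      strand = ifelse(g$strand %in% c("+", "-"),
                                      g$strand, "*"),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in ", path)
  }
  .check_coords(genes$chrom, genes$start, genes$end, where = path)
  e <- df[df$type == "exon", , drop = FALSE]
  if (nrow(e) > 0L) {
    parent <- e$Parent %||% e$gene_id
    if (is.null(parent)) stop("exon feature without Parent/gene_id in ", path)
    parent <- vapply(parent, function(p) as.character(p)[1], character(1))
    exons <- data.frame(gene_id = unname(parent), chrom = e$seqnames,
                        start = e$start - 1L, end = e$end,
                        stringsAsFactors = FALSE)
    .check_coords(exons$chrom, exons$start, exons$end, where = path)
    m <- match(exons$gene_id, genes$gene_id)
    if (anyNA(m)) {
      stop("exon refers to unknown gene '", exons$gene_id[is.na(m)][1],
           "' in ", path)
    }
    outside <- exons$chrom != genes$chrom[m] |
      exons$start < genes$start[m] | exons$end > genes$end[m]
    if (any(outside)) {
      i <- which(outside)[1]
      stop(sprintf("exon %s:[%d,%d) lies outside the span of gene '%s'",
                   exons$chrom[i], exons$start[i], exons$end[i],
                   exons$gene_id[i]))
    }
  } else {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  list(genes = genes, exons = exons)
}

#' Write gene models to GFF3
#'
#' Converts back from the internal 0-based half-open coordinates to GFF's
#' 1-based inclusive convention, so a read/write round trip preserves the
#' original GFF coordinates.
#'
#' @param models List with `genes` and `exons` data frames, as produced by
#'   [read_gff_genes()].
#' @param path Output path.
#' @export
write_gff_genes <- function(models, path) {
  genes <- models$genes
  exons <- models$exons
  lines <- c("##gff-version 3",
             sprintf("%s\tecrap1\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     ifelse(genes$strand == "*", ".", genes$strand),
                     genes$gene_id))
  if (nrow(exons) > 0L) {
    st <- genes$strand[match(exons$gene_id, genes$gene_id)]
    lines <- c(lines,
               sprintf("%s\tecrap1\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       exons$chrom, exons$start + 1L, exons$end,
                       ifelse(st == "*", ".", st), exons$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

.write_tsv <- function(df, path, col.names = TRUE, header_lines = NULL) {
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Write a tabular report as TSV
#'
#' One row per record, header row present, stable column order: identical
#' input yields byte-identical output. If the record table carries a
#' `config` attribute (as the output of [screen_regions()] does), it is
#' written as `# key=value` comment lines above the header so a screen run
#' is reproducible from its report alone.
#'
#' @param records Data frame of records sharing one schema.
#' @param path Output path.
#' @export
write_tsv_report <- function(records, path) {
  stopifnot(is.data.frame(records))
  cfg <- attr(records, "config")
  header_lines <- NULL
  if (!is.null(cfg)) {
    header_lines <- sprintf("# %s=%s", names(cfg),
                            vapply(cfg, function(x) paste(format(x),
                                                          collapse = ","),
                                   character(1)))
  }
  .write_tsv(as.data.frame(records), path, header_lines = header_lines)
  invisible(path)
}
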