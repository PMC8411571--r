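#' Assign screened regions to genes
#'
#' Every gene whose span overlaps a region, or lies within `window` bp of
#' it, is reported (a region may receive multiple assignments — nested
#' genes make a single-winner rule lossy). Relations:
#' `contained_in_gene` (region fully inside the gene span),
#' `overlaps_gene` (partial overlap), `near_gene` (no overlap, edge gap
#' `<= window`). Distance is the gap between closest edges in half-open
#' coordinates (0 for overlapping or touching intervals); computing it
#' from either side gives the same value.
#'
#' @param regions Interval data frame with `name`, `chrom`, `start`, `end`.
#' @param genes Gene data frame (`gene_id`, `chrom`, `start`, `end`), e.g.
#'   `read_gff_genes(path)$genes`.
#' @param window Maximum gap in bp for a `near_gene` call (`>= 0`);
#'   default 10000. "Near" has no canonical definition, so the window is a
#'   prominent, reported parameter rather than a constant.
#' @return Data frame `region_name`, `gene_id`, `relation`, `distance`,
#'   ordered by region input order then gene start; regions with no gene
#'   in range contribute no rows.
#' @export
assign_regions_to_genes <- function(regions, genes, window = 10000L) {
  stopifnot(window >= 0)
  name <- regions$name %||% paste0("region_", seq_len(nrow(regions)) - 1L)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    same <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(NULL)
    same <- same[order(same$start), , drop = FALSE]
    rs <- regions$start[i]; re <- regions$end[i]
    gap <- pmax(same$start - re, rs - same$end, 0L)
    ovl <- same$start < re & rs < same$end
    keep <- ovl | gap <= window
    if (!any(keep)) return(NULL)
    same <- same[keep, , drop = FALSE]
    gap <- gap[keep]; ovl <- ovl[keep]
    contained <- same$start <= rs & re <= same$end
    data.frame(region_name = name[i], gene_id = same$gene_id,
               relation = ifelse(contained, "contained_in_gene",
                                 ifelse(ovl, "overlaps_gene", "near_gene")),
               distance = as.integer(gap), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_name = character(), gene_id = character(),
                      relation = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Gene-span size statistics for a gene group
#'
#' Sizes are gene *spans* (`end - start`), not exon unions: the statistic
#' of interest is gene extent, intron included, because composite elements
#' tend to sit in large introns.
#'
#' @param gene_ids Character vector of gene ids to summarise.
#' @param genes Gene data frame (`gene_id`, `chrom`, `start`, `end`).
#' @param group_label Label carried into the result.
#' @return List of class `gene_size_stats`: `group_label`, `n_genes`,
#'   `mean_span`, `median_span` (bp). Unknown ids are an error.
#' @export
gene_size_stats <- function(gene_ids, genes, group_label = "") {
  m <- match(gene_ids, genes$gene_id)
  if (anyNA(m)) {
    stop("unknown gene id(s): ",
         paste(gene_ids[is.na(m)], collapse = ", "))
  }
  spans <- genes$end[m] - genes$start[m]
  structure(list(group_label = group_label, n_genes = length(spans),
                 mean_span = if (length(spans)) mean(spans) else NA_real_,
                 median_span = if (length(spans)) stats::median(spans)
                               else NA_real_),
            class = "gene_size_stats")
}

#' @export
print.gene_size_stats <- function(x, ...) {
  cat(sprintf("<gene_size_stats> %s: n=%d, mean span %.0f bp, median %.0f bp\n",
              if (nzchar(x$group_label)) x$group_label else "(unlabelled)",
              x$n_genes, x$mean_span, x$median_span))
  invisible(x)
}

#' Motif density over a gene span
#'
#' Occurrences fully contained in the gene span, expressed per 10 kb:
#' `count * 10000 / span_length`. A span of ~50 kb with 5 sites has
#' density 1.0 per 10 kb.
#'
#' @param gene One gene (one-row data frame or list with `chrom`, `start`,
#'   `end`); span must lie within the genome.
#' @param genome A [genome_sequence()].
#' @param motif Motif, default [ap1_motif()].
#' @return Numeric density (occurrences per 10 kb).
#' @export
motif_density <- function(gene, genome, motif = ap1_motif()) {
  gene <- .as_ivl(gene)
  count <- count_in_region(motif, genome, gene)
  count * 10000 / (gene$end - gene$start)
}
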