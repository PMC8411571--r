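# Independent oracles, deliberately naive: every offset is tested on both
# strands with per-character set membership, no vectorisation shared with
# the production scanner.

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_scan <- function(motif, seq, chrom = "seq") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  m <- nchar(motif$consensus)
  plus_sets <- oracle_iupac_sets[strsplit(motif$consensus, "")[[1]]]
  minus_sets <- oracle_iupac_sets[
    strsplit(reverse_complement(motif$consensus), "")[[1]]]
  starts <- integer(0)
  strands <- character(0)
  if (length(chars) >= m) {
    for (off in 0:(length(chars) - m)) {
      win <- chars[(off + 1):(off + m)]
      plus_ok <- TRUE
      minus_ok <- TRUE
      for (j in 1:m) {
        if (!(win[j] %in% plus_sets[[j]])) plus_ok <- FALSE
        if (!(win[j] %in% minus_sets[[j]])) minus_ok <- FALSE
      }
      if (plus_ok) {
        starts <- c(starts, off)
        strands <- c(strands, "+")
      }
      if (minus_ok && !motif$palindromic) {
        # non-palindromic: a minus-strand match is a distinct hit;
        # palindromic: it coincides with the plus hit (span dedup)
        starts <- c(starts, off)
        strands <- c(strands, "-")
      }
    }
  }
  ord <- order(starts, strands)
  data.frame(
    motif = rep(motif$name, length(starts)),
    chrom = rep(chrom, length(starts)),
    start = as.integer(starts[ord]),
    end = as.integer(starts[ord] + m),
    strand = strands[ord],
    matched_seq = if (length(starts)) {
      substring(seq, starts[ord] + 1, starts[ord] + m)
    } else character(0),
    stringsAsFactors = FALSE)
}

# random uniform A/C/G/T sequence
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

expect_same_hits <- function(a, b) {
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_identical(a, b)
}
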