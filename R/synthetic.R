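#' Default motif dictionary for the synthetic generators
#'
#' @return Named list with the AP-1 (`TGANTCA`) and EcRE (`RGGTCANTGACCY`)
#'   motifs.
#' @export
default_motifs <- function() {
  list(AP1 = ap1_motif(), EcRE = ecre_motif())
}

# Sample one concrete instance of a motif (each position drawn from its
# allowed set), written onto the plus strand for the requested hit strand.
.realize_motif <- function(motif, strand) {
  inst <- vapply(motif$compiled, function(allowed) {
    allowed[sample.int(length(allowed), 1L)]
  }, character(1))
  inst <- paste(inst, collapse = "")
  if (strand == "-") reverse_complement(inst) else inst
}

# All occurrences of the given motifs across a list of char vectors,
# palindromes deduplicated by span exactly as scan_sequence() does.
.scan_all <- function(chars_by_chrom, motifs) {
  rows <- list()
  for (chrom in names(chars_by_chrom)) {
    chars <- chars_by_chrom[[chrom]]
    for (motif in motifs) {
      m <- length(motif$compiled)
      off <- .match_offsets(motif$compiled, chars)
      strands <- rep("+", length(off))
      if (!motif$palindromic) {
        rc <- iupac_motif(motif$name, reverse_complement(motif$consensus))
        off2 <- .match_offsets(rc$compiled, chars)
        off <- c(off, off2)
        strands <- c(strands, rep("-", length(off2)))
      }
      if (length(off)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif$name, chrom = chrom, start = off, end = off + m,
          strand = strands, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$motif), , drop = FALSE]
}

#' Generate a random genome with motifs planted at known coordinates
#'
#' The substrate for end-to-end testing: an i.i.d. random background at
#' the requested GC content, with concrete motif instances written at the
#' prescribed positions. With `clean_background = TRUE` (the default) the
#' finished genome contains **no** occurrence of any motif in `motifs`
#' other than the planted ones: after planting, every spurious occurrence
#' is destroyed by mutating one of its constrained, unprotected positions
#' to a disallowed base, re-scanning to a fixpoint. Scanning the result
#' then returns exactly the planted truth table.
#'
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @param lengths Named integer vector of chromosome lengths.
#' @param gc GC content of the background in (0, 1); default 0.5.
#' @param planted Data frame with columns `chrom`, `pos` (0-based start),
#'   `motif` (a name in `motifs`), `strand` (`"+"`/`"-"`); may be `NULL`.
#'   Planted sites must lie fully inside their chromosome and must not
#'   overlap one another. Palindromic motifs are recorded with strand
#'   `"+"` whatever was requested, matching the scanner's span-dedup rule.
#' @param motifs Named list of [iupac_motif()]s to plant/exclude; default
#'   [default_motifs()].
#' @param clean_background Enforce the no-spurious-occurrence guarantee.
#' @param max_clean_iter Safety cap on cleaning sweeps.
#' @return List with `genome` (a [genome_sequence()]) and `truth` (data
#'   frame `motif`, `chrom`, `start`, `end`, `strand`, `matched_seq`,
#'   sorted by chrom then start).
#' @examples
#' fx <- gen_genome(1, c(chrS = 10000),
#'                  planted = data.frame(chrom = "chrS",
#'                                       pos = c(100, 900, 5000, 8000),
#'                                       motif = "AP1", strand = "+"))
#' nrow(scan_sequence(ap1_motif(), fx$genome[["chrS"]], "chrS"))  # 4
#' @export
gen_genome <- function(seed, lengths, gc = 0.5, planted = NULL,
                       motifs = default_motifs(), clean_background = TRUE,
                       max_clean_iter = 50L) {
  stopifnot(length(lengths) >= 1L, !is.null(names(lengths)),
            all(lengths >= 1L), gc > 0, gc < 1)
  if (is.null(planted)) {
    planted <- data.frame(chrom = character(), pos = integer(),
                          motif = character(), strand = character(),
                          stringsAsFactors = FALSE)
  }
  if (nrow(planted)) {
    stopifnot(all(c("chrom", "pos", "motif", "strand") %in% names(planted)))
    bad <- setdiff(planted$motif, names(motifs))
    if (length(bad)) stop("planted motif(s) not in dictionary: ",
                          paste(unique(bad), collapse = ", "))
    if (!all(planted$chrom %in% names(lengths))) {
      stop("planted site on unknown chromosome")
    }
  }
  mlen <- vapply(motifs, function(m) length(m$compiled), integer(1))
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chars <- lapply(lengths, function(L) {
      sample(names(probs), L, replace = TRUE, prob = probs)
    })
    names(chars) <- names(lengths)
    protected <- lapply(lengths, function(L) rep(FALSE, L))
    names(protected) <- names(lengths)
    truth_rows <- list()
    if (nrow(planted)) {
      ord <- order(planted$chrom, planted$pos)
      planted <- planted[ord, , drop = FALSE]
      for (i in seq_len(nrow(planted))) {
        chrom <- planted$chrom[i]
        pos <- as.integer(planted$pos[i])
        motif <- motifs[[planted$motif[i]]]
        m <- mlen[[planted$motif[i]]]
        if (pos < 0 || pos + m > lengths[[chrom]]) {
          stop(sprintf("planted %s at %s:%d does not fit its chromosome",
                       motif$name, chrom, pos))
        }
        span <- (pos + 1L):(pos + m)
        if (any(protected[[chrom]][span])) {
          stop(sprintf("planted motifs overlap at %s:%d", chrom, pos))
        }
        strand <- if (motif$palindromic) "+" else planted$strand[i]
        inst <- .realize_motif(motif, strand)
        chars[[chrom]][span] <- strsplit(inst, "")[[1]]
        protected[[chrom]][span] <- TRUE
        truth_rows[[i]] <- data.frame(
          motif = motif$name, chrom = chrom, start = pos, end = pos + m,
          strand = strand, matched_seq = inst, stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(motif = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 matched_seq = character(), stringsAsFactors = FALSE)
    if (clean_background) {
      truth_key <- paste(truth$motif, truth$chrom, truth$start)
      for (iter in seq_len(max_clean_iter)) {
        found <- .scan_all(chars, motifs)
        spurious <- found[!(paste(found$motif, found$chrom, found$start)
                            %in% truth_key), , drop = FALSE]
        if (nrow(spurious) == 0L) break
        if (iter == max_clean_iter) {
          stop("clean-background enforcement did not converge")
        }
        for (k in seq_len(nrow(spurious))) {
          .destroy_hit(spurious[k, ], chars, protected, motifs) -> chars
        }
      }
    }
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    genome <- genome_sequence(vapply(chars, paste, character(1),
                                     collapse = ""))
    list(genome = genome, truth = truth)
  })
}

# Break one spurious occurrence by mutating a constrained position that is
# not protected by a planted site. Returns the updated char list.
.destroy_hit <- function(hit, chars, protected, motifs) {
  motif <- motifs[[hit$motif]]
  m <- length(motif$compiled)
  # plus-strand allowed set at each genomic offset of the hit
  allowed <- if (hit$strand == "+") {
    motif$compiled
  } else {
    lapply(rev(motif$compiled),
           function(b) unname(IUPAC_COMPLEMENT[b]))
  }
  pos <- hit$start + seq_len(m)         # 1-based genome positions
  free <- !protected[[hit$chrom]][pos]
  constrained <- vapply(allowed, length, integer(1)) < 4L
  usable <- which(free & constrained)
  if (!length(usable)) {
    stop(sprintf(
      "cannot clean spurious %s occurrence at %s:%d without touching a planted site",
      hit$motif, hit$chrom, hit$start))
  }
  j <- usable[sample.int(length(usable), 1L)]
  choices <- setdiff(c("A", "C", "G", "T"), allowed[[j]])
  chars[[hit$chrom]][pos[j]] <- choices[sample.int(length(choices), 1L)]
  chars
}

#' Generate a region set with prescribed (AP-1, EcRE) composition
#'
#' Builds a single-chromosome genome and a set of equally sized,
#' non-overlapping candidate regions, region `i` containing exactly
#' `compositions[[i]][1]` AP-1 sites and `compositions[[i]][2]` EcRE
#' sites, with a clean background everywhere else. Running
#' [screen_regions()] on the output reproduces the prescription exactly;
#' this is how fixtures shaped like the published 502-region / 51-passing
#' screen are built without external data.
#'
#' @param compositions List of integer pairs `c(ap1, ecre)` (or a 2-column
#'   matrix / data frame with columns `ap1`, `ecre`), one per region.
#' @param seed Integer seed.
#' @param region_length,gap Region length and inter-region gap in bp.
#' @param gc Background GC content.
#' @param ap1,ecre Motifs, defaults [ap1_motif()] / [ecre_motif()].
#' @param chrom Chromosome name.
#' @return List: `genome`, `regions` (BED-style data frame), `truth`
#'   (planted hits), `compositions` (normalized data frame).
#' @examples
#' fx <- gen_region_set(list(c(4, 0), c(3, 0), c(5, 1)), seed = 7)
#' screen_regions(fx$regions, fx$genome)$passes  # TRUE FALSE FALSE
#' @export
gen_region_set <- function(compositions, seed, region_length = 1000L,
                           gap = 200L, gc = 0.5, ap1 = ap1_motif(),
                           ecre = ecre_motif(), chrom = "chrS") {
  comp <- .norm_compositions(compositions)
  n <- nrow(comp)
  if (n == 0L) {
    return(list(genome = NULL,
                regions = data.frame(chrom = character(), start = integer(),
                                     end = integer(), name = character(),
                                     stringsAsFactors = FALSE),
                truth = NULL, compositions = comp))
  }
  motifs <- list(AP1 = ap1, EcRE = ecre)
  names(motifs) <- c(ap1$name, ecre$name)
  maxlen <- max(nchar(ap1$consensus), nchar(ecre$consensus))
  starts <- gap + (seq_len(n) - 1L) * (region_length + gap)
  total <- gap + n * (region_length + gap)
  planted <- withr::with_seed(child_seed(seed, "placement"), {
    rows <- list()
    for (i in seq_len(n)) {
      k <- comp$ap1[i] + comp$ecre[i]
      if (k == 0L) next
      slot <- region_length %/% k
      if (slot < maxlen + 2L) {
        stop(sprintf(
          "region %d: composition (%d AP-1, %d EcRE) infeasible in %d bp",
          i, comp$ap1[i], comp$ecre[i], region_length))
      }
      types <- sample(rep(c(ap1$name, ecre$name),
                          c(comp$ap1[i], comp$ecre[i])))
      lens <- nchar(vapply(motifs[types], function(m) m$consensus,
                           character(1)))
      off <- vapply(lens, function(l) {
        sample.int(slot - l, 1L) - 1L   # keeps >=1 bp to the slot edge
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        pos = starts[i] + (seq_len(k) - 1L) * slot + off,
        motif = types, strand = "+", stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  gg <- gen_genome(child_seed(seed, "genome"),
                   lengths = stats::setNames(total, chrom), gc = gc,
                   planted = planted, motifs = motifs,
                   clean_background = TRUE)
  regions <- data.frame(chrom = chrom, start = starts,
                        end = starts + region_length,
                        name = paste0("region_", seq_len(n) - 1L),
                        stringsAsFactors = FALSE)
  list(genome = gg$genome, regions = regions, truth = gg$truth,
       compositions = comp)
}

.norm_compositions <- function(compositions) {
  if (is.data.frame(compositions) || is.matrix(compositions)) {
    comp <- as.data.frame(compositions)
    if (!all(c("ap1", "ecre") %in% names(comp))) names(comp) <- c("ap1", "ecre")
  } else {
    comp <- data.frame(
      ap1 = vapply(compositions, function(x) as.integer(x[1]), integer(1)),
      ecre = vapply(compositions, function(x) as.integer(x[2]), integer(1)))
  }
  stopifnot(all(comp$ap1 >= 0L), all(comp$ecre >= 0L))
  comp
}

#' Place ChIP-seq-style peaks over chosen planted sites
#'
#' Builds one [peak_set()] per factor in the plan, each peak a padded
#' window over a planted motif site, so that downstream classification
#' ([classify_hit()]) reproduces the plan exactly: a site covered by an
#' EcR peak classifies green, a site covered only by Jun/Kay classifies
#' red, an uncovered site classifies blue.
#'
#' @param truth Planted-hit table from [gen_genome()] / [gen_region_set()].
#' @param plan Data frame with columns `site` (row index into `truth`) and
#'   `factor` (peak-set label); a site may appear under several factors.
#'   An empty plan yields an empty list (every site classifies blue).
#' @param pad Peak half-extension beyond the site, bp.
#' @param source_label Provenance label stored on each peak set.
#' @return Named list of [peak_set()] objects, one per distinct factor.
#' @export
gen_peaks <- function(truth, plan, pad = 20L, source_label = "synthetic") {
  if (is.null(plan) || nrow(plan) == 0L) return(list())
  stopifnot(all(c("site", "factor") %in% names(plan)))
  if (any(plan$site < 1L | plan$site > nrow(truth))) {
    stop("plan references a site outside the truth table")
  }
  out <- lapply(split(plan$site, plan$factor), function(sites) {
    data.frame(chrom = truth$chrom[sites],
               start = pmax(0L, truth$start[sites] - pad),
               end = truth$end[sites] + pad, stringsAsFactors = FALSE)
  })
  mapply(function(peaks, fac) peak_set(fac, peaks, source_label),
         out, names(out), SIMPLIFY = FALSE)
}

#' Generate gene models with controlled span lengths
#'
#' Gene spans are drawn from a gamma distribution with the requested mean
#' (shape 4, a right-skewed, realistic span distribution) and laid end to
#' end with exponential gaps, so grouped size statistics (e.g. a 22-kb
#' candidate set against an 11-kb background) can be planted and
#' recovered.
#'
#' @param seed Integer seed.
#' @param n Number of genes.
#' @param mean_span Target mean span, bp.
#' @param shape Gamma shape parameter.
#' @param gap_mean Mean intergenic gap, bp.
#' @param chrom Chromosome name.
#' @param prefix Gene-id prefix.
#' @return Gene data frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
gen_genes <- function(seed, n, mean_span, shape = 4, gap_mean = 2000,
                      chrom = "chrG", prefix = "g") {
  stopifnot(n >= 1L, mean_span > 0)
  withr::with_seed(seed, {
    spans <- pmax(200L, round(stats::rgamma(n, shape = shape,
                                            rate = shape / mean_span)))
    gaps <- round(stats::rexp(n, rate = 1 / gap_mean))
    starts <- cumsum(gaps + c(0L, spans[-n]))
    data.frame(gene_id = paste0(prefix, seq_len(n)), chrom = chrom,
               start = as.integer(starts),
               end = as.integer(starts + spans), strand = "+",
               stringsAsFactors = FALSE)
  })
}

#' Generate a FISH-style image with a known signal-pixel count
#'
#' A flat (optionally noisy) background with exactly `n_signal_px` pixels
#' inside the ROI raised to `signal_level`. In noiseless mode
#' ([quantify_roi_fraction()] at the stated threshold recovers
#' `n_signal_px / roi_area` exactly; with noise, recovery holds as long as
#' the level separation dwarfs the noise sd.
#'
#' @param seed Integer seed.
#' @param shape `c(nrow, ncol)`.
#' @param roi Polygon vertex matrix or `list(x, y, w, h)` rectangle.
#' @param n_signal_px Number of signal pixels to plant inside the ROI.
#' @param threshold Threshold at which the truth is stated.
#' @param background_level,signal_level Intensities; must straddle
#'   `threshold`.
#' @param noise_sd Gaussian noise sd (0 = noiseless).
#' @return List: `image`, `roi`, `threshold`, `truth` (list with
#'   `roi_area_px`, `signal_px`, `value`).
#' @export
gen_fish_image <- function(seed, shape = c(100L, 100L), roi, n_signal_px,
                           threshold = 128, background_level = 50,
                           signal_level = 200, noise_sd = 0) {
  stopifnot(background_level < threshold, signal_level >= threshold)
  mask <- .roi_mask(roi, shape)
  area <- sum(mask)
  if (n_signal_px > area) {
    stop(sprintf("cannot plant %d signal pixels in a %d-px ROI",
                 n_signal_px, area))
  }
  withr::with_seed(seed, {
    img <- matrix(background_level, shape[1], shape[2])
    idx <- sample(which(mask), n_signal_px)
    img[idx] <- signal_level
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          shape[1], shape[2])
    }
    list(image = img, roi = roi, threshold = threshold,
         truth = list(roi_area_px = area, signal_px = n_signal_px,
                      value = n_signal_px / area))
  })
}

#' Generate strip images with planted mean gray values
#'
#' @param seed Integer seed.
#' @param shape `c(nrow, ncol)`.
#' @param strips List of `list(x, y, w, h)` rectangles.
#' @param means Planted mean intensity per strip.
#' @param noise_sd Gaussian noise sd added inside strips.
#' @param background_level Intensity outside the strips.
#' @return List: `image`, `strips`, `truth` (vector of planted means).
#' @export
gen_strip_image <- function(seed, shape = c(100L, 200L), strips, means,
                            noise_sd = 0, background_level = 0) {
  stopifnot(length(strips) == length(means))
  withr::with_seed(seed, {
    img <- matrix(background_level, shape[1], shape[2])
    for (i in seq_along(strips)) {
      r <- strips[[i]]
      .check_rect(r, shape)
      vals <- means[i]
      if (noise_sd > 0) {
        vals <- means[i] + stats::rnorm(r$w * r$h, 0, noise_sd)
      }
      img[(r$y + 1L):(r$y + r$h), (r$x + 1L):(r$x + r$w)] <- vals
    }
    list(image = img, strips = strips, truth = means)
  })
}

#' Generate a PLA scene with a known nuclear/cytoplasmic partition
#'
#' Builds a binary nuclear mask from circular "nuclei" and places point
#' signals so that exactly `n_nuclear` centroids fall on mask pixels and
#' `n_cytoplasmic` fall outside. [classify_pla_signals()] on the output
#' recovers the partition exactly.
#'
#' @param seed Integer seed.
#' @param shape `c(nrow, ncol)`.
#' @param n_nuclear,n_cytoplasmic Planted compartment counts.
#' @param nuclei Data frame `cx`, `cy`, `r` of circle centres/radii;
#'   default: five nuclei on a grid.
#' @return List: `nuclear_mask`, `centroids` (data frame `x`, `y`,
#'   `compartment`), `truth` (list `n_nuclear`, `n_cytoplasmic`,
#'   `pct_cytoplasmic`).
#' @export
gen_pla_image <- function(seed, shape = c(200L, 200L), n_nuclear,
                          n_cytoplasmic, nuclei = NULL) {
  if (is.null(nuclei)) {
    nuclei <- data.frame(cx = c(50, 150, 100, 50, 150),
                         cy = c(50, 50, 100, 150, 150), r = 22)
  }
  h <- shape[1]; w <- shape[2]
  xc <- rep(seq_len(w) - 0.5, each = h)
  yc <- rep(seq_len(h) - 0.5, times = w)
  inside <- rep(FALSE, h * w)
  for (i in seq_len(nrow(nuclei))) {
    inside <- inside | ((xc - nuclei$cx[i])^2 + (yc - nuclei$cy[i])^2 <=
                          nuclei$r[i]^2)
  }
  mask <- matrix(inside, nrow = h)
  n_in <- sum(mask); n_out <- length(mask) - n_in
  if (n_nuclear > n_in || n_cytoplasmic > n_out) {
    stop("not enough mask/background pixels for the requested partition")
  }
  withr::with_seed(seed, {
    pick <- function(pool, n) pool[sample.int(length(pool), n)]
    idx <- c(pick(which(mask), n_nuclear), pick(which(!mask), n_cytoplasmic))
    # pixel index -> centre coordinates (column-major)
    row <- (idx - 1L) %% h + 1L
    col <- (idx - 1L) %/% h + 1L
    centroids <- data.frame(
      x = col - 0.5, y = row - 0.5,
      compartment = rep(c("nuclear", "cytoplasmic"),
                        c(n_nuclear, n_cytoplasmic)),
      stringsAsFactors = FALSE)
    n_total <- n_nuclear + n_cytoplasmic
    list(nuclear_mask = mask, centroids = centroids,
         truth = list(n_nuclear = n_nuclear, n_cytoplasmic = n_cytoplasmic,
                      pct_cytoplasmic = 100 * n_cytoplasmic / n_total))
  })
}
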