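#' Rasterize a polygon ROI to a pixel mask
#'
#' Images are numeric matrices indexed `image[row, col]`; pixel
#' `(row r, col c)` covers `x` in `[c-1, c)` and `y` in `[r-1, r)` with its
#' centre at `(c - 0.5, r - 0.5)`. A pixel belongs to the polygon iff its
#' centre is inside under the even-odd (crossing-number) rule. Fixing the
#' rule and the sample points makes ROI areas reproducible across
#' implementations.
#'
#' @param vertices Numeric matrix (or data frame) with two columns `x`, `y`
#'   — an ordered vertex list of a simple (non-self-intersecting) polygon
#'   with at least 3 vertices, in pixel coordinates within the image.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix of the same dimensions.
#' @export
polygon_mask <- function(vertices, dim) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("polygon needs at least 3 vertices")
  if (anyNA(vertices)) stop("polygon vertices must not be NA")
  .check_simple_polygon(vertices)
  h <- dim[1]; w <- dim[2]
  if (any(vertices[, 1] < 0) || any(vertices[, 1] > w) ||
      any(vertices[, 2] < 0) || any(vertices[, 2] > h)) {
    stop("ROI polygon extends outside the image")
  }
  xc <- rep(seq_len(w) - 0.5, each = h)    # column-major, like the matrix
  yc <- rep(seq_len(h) - 0.5, times = w)
  inside <- rep(FALSE, h * w)
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
    x2 <- vertices[i, 1]; y2 <- vertices[i, 2]
    crosses <- (y1 > yc) != (y2 > yc)
    if (any(crosses)) {
      xint <- x1 + (yc - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses & (xc < xint)
      inside <- xor(inside, flip & !is.na(flip))
    }
    j <- i
  }
  matrix(inside, nrow = h)
}

# Error if any two non-adjacent edges intersect (degenerate "polygon").
.check_simple_polygon <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  intersects <- function(p, q) {
    o1 <- orient(p[1], p[2], p[3], p[4], q[1], q[2])
    o2 <- orient(p[1], p[2], p[3], p[4], q[3], q[4])
    o3 <- orient(q[1], q[2], q[3], q[4], p[1], p[2])
    o4 <- orient(q[1], q[2], q[3], q[4], p[3], p[4])
    o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
  }
  for (i in seq_len(n - 2L)) {
    for (k in seq(i + 2L, n)) {
      if (i == 1L && k == n) next  # adjacent around the wrap
      if (intersects(seg[i, ], seg[k, ])) {
        stop("polygon is self-intersecting (edges ", i, " and ", k, ")")
      }
    }
  }
  invisible(TRUE)
}

# ROI -> logical mask. A polygon ROI is a vertex matrix / data frame; a
# rectangle ROI is list(x, y, w, h) in 0-based pixel offsets.
.roi_mask <- function(roi, dim) {
  if (is.matrix(roi) || is.data.frame(roi)) {
    return(polygon_mask(roi, dim))
  }
  if (is.list(roi) && all(c("x", "y", "w", "h") %in% names(roi))) {
    .check_rect(roi, dim)
    mask <- matrix(FALSE, dim[1], dim[2])
    mask[(roi$y + 1L):(roi$y + roi$h), (roi$x + 1L):(roi$x + roi$w)] <- TRUE
    return(mask)
  }
  stop("roi must be a polygon vertex matrix or a list(x, y, w, h)")
}

.check_rect <- function(rect, dim) {
  with(rect, {
    if (w < 1 || h < 1) stop("rectangle must have positive width and height")
    if (x < 0 || y < 0 || x + w > dim[2] || y + h > dim[1]) {
      stop("rectangle extends outside the image")
    }
  })
  invisible(TRUE)
}

#' Thresholded signal-pixel fraction inside an ROI
#'
#' The hand-selected-tissue quantification: threshold the image so signal
#' pixels separate from background, then divide the number of signal
#' pixels inside the ROI by the ROI's pixel surface area. A pixel counts
#' as signal iff it lies inside the ROI **and** its intensity is
#' `>= threshold` (signal is bright; apply any inversion before calling).
#' The threshold is an explicit parameter so that it can be held constant
#' across all images of one comparison.
#'
#' @param image Numeric matrix of intensities.
#' @param roi Polygon vertex matrix or `list(x, y, w, h)` rectangle; must
#'   lie within the image.
#' @param threshold Intensity cutoff.
#' @return A list of class `quant_result`: `mode = "roi_fraction"`,
#'   `roi_area_px`, `signal_px`, `threshold`, `value`
#'   (`signal_px / roi_area_px`, in `[0, 1]`).
#' @examples
#' img <- matrix(0, 100, 100); img[1:10, 1:30] <- 200
#' quantify_roi_fraction(img, list(x = 0, y = 0, w = 50, h = 50), 128)
#' @export
quantify_roi_fraction <- function(image, roi, threshold) {
  stopifnot(is.matrix(image), is.numeric(image), length(threshold) == 1L)
  mask <- .roi_mask(roi, dim(image))
  area <- sum(mask)
  if (area == 0L) stop("ROI covers no pixel centres")
  signal <- sum(image[mask] >= threshold)
  structure(list(mode = "roi_fraction", roi_area_px = area,
                 signal_px = as.integer(signal),
                 threshold = threshold, value = signal / area),
            class = "quant_result")
}

#' Mean gray value of a fixed-size strip
#'
#' The leading-edge-strip quantification: a rectangle of fixed size is
#' placed over the tissue and the mean intensity inside it is reported.
#' When `fixed_size` is given, a rectangle of any other size is an error —
#' within one analysis batch every strip must have the same size, or the
#' mean gray values are not comparable.
#'
#' @param image Numeric matrix.
#' @param rect `list(x, y, w, h)` in 0-based pixel offsets, fully inside
#'   the image.
#' @param fixed_size Optional `c(w, h)` the rectangle must match.
#' @return A `quant_result` with `mode = "strip_mean"`, `roi_area_px` and
#'   `value` (the arithmetic mean intensity).
#' @export
quantify_strip_intensity <- function(image, rect, fixed_size = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  .check_rect(rect, dim(image))
  if (!is.null(fixed_size) &&
      !(rect$w == fixed_size[1] && rect$h == fixed_size[2])) {
    stop(sprintf("strip is %dx%d but the batch's fixed size is %dx%d",
                 rect$w, rect$h, fixed_size[1], fixed_size[2]))
  }
  vals <- image[(rect$y + 1L):(rect$y + rect$h),
                (rect$x + 1L):(rect$x + rect$w)]
  structure(list(mode = "strip_mean", roi_area_px = length(vals),
                 signal_px = NA_integer_, threshold = NA_real_,
                 value = mean(vals)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  if (x$mode == "roi_fraction") {
    cat(sprintf("<quant_result> roi_fraction: %d / %d px = %.4f (threshold %g)\n",
                x$signal_px, x$roi_area_px, x$value, x$threshold))
  } else {
    cat(sprintf("<quant_result> strip_mean: %.3f over %d px\n",
                x$value, x$roi_area_px))
  }
  invisible(x)
}

#' Compare two measurement groups with an equal-variance t-test
#'
#' Group summaries as mean ± s.e.m. (`sd / sqrt(n)`) and a two-sided
#' Student's t-test assuming equal variances. If both groups have zero
#' variance the test statistic is degenerate: the result carries
#' `t = 0, p = 1` for identical means or `t = +/-Inf, p = 0` otherwise,
#' with `degenerate = TRUE`, rather than failing — clean synthetic data
#' can legitimately produce constant groups.
#'
#' @param values_a,values_b Numeric vectors, each of length `>= 2`.
#' @return List: `mean_a`, `sem_a`, `mean_b`, `sem_b`, `t`, `p`, `df`,
#'   `degenerate`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  na <- length(values_a); nb <- length(values_b)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  pooled_var <- ((na - 1) * stats::var(values_a) +
                 (nb - 1) * stats::var(values_b)) / (na + nb - 2)
  if (pooled_var == 0) {
    d <- mean(values_a) - mean(values_b)
    return(list(mean_a = mean(values_a), sem_a = sem(values_a),
                mean_b = mean(values_b), sem_b = sem(values_b),
                t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0,
                df = na + nb - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(mean_a = mean(values_a), sem_a = sem(values_a),
       mean_b = mean(values_b), sem_b = sem(values_b),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Classify punctate signals as nuclear or cytoplasmic
#'
#' A punctum is nuclear iff the pixel containing its centroid is `TRUE` in
#' the nuclear mask (centroid-in-mask rule: puncta are small relative to
#' nuclei, so the centroid pixel decides). Percent cytoplasmic is reported
#' on the 0-100 scale.
#'
#' @param centroids Data frame with columns `x`, `y` (pixel coordinates,
#'   within the mask's bounds); must be non-empty — the percentage is
#'   undefined for zero signals.
#' @param nuclear_mask Logical matrix (`TRUE` = nucleus).
#' @return List of class `pla_classification`: `n_total`, `n_nuclear`,
#'   `n_cytoplasmic`, `pct_cytoplasmic`.
#' @examples
#' mask <- matrix(FALSE, 10, 10); mask[1:5, 1:5] <- TRUE
#' pts <- data.frame(x = c(2.5, 8.5), y = c(2.5, 8.5))
#' classify_pla_signals(pts, mask)  # 50% cytoplasmic
#' @export
classify_pla_signals <- function(centroids, nuclear_mask) {
  stopifnot(is.data.frame(centroids), is.matrix(nuclear_mask),
            is.logical(nuclear_mask))
  if (nrow(centroids) == 0L) {
    stop("no signals to classify: percentage undefined")
  }
  h <- nrow(nuclear_mask); w <- ncol(nuclear_mask)
  col <- floor(centroids$x) + 1L
  row <- floor(centroids$y) + 1L
  if (any(col < 1L | col > w | row < 1L | row > h)) {
    stop("centroid outside image bounds")
  }
  nuclear <- nuclear_mask[cbind(row, col)]
  n_total <- nrow(centroids)
  n_nuc <- sum(nuclear)
  structure(list(n_total = n_total, n_nuclear = n_nuc,
                 n_cytoplasmic = n_total - n_nuc,
                 pct_cytoplasmic = 100 * (n_total - n_nuc) / n_total),
            class = "pla_classification")
}

#' @export
print.pla_classification <- function(x, ...) {
  cat(sprintf("<pla_classification> %d signals: %d nuclear, %d cytoplasmic (%.1f%% cytoplasmic)\n",
              x$n_total, x$n_nuclear, x$n_cytoplasmic, x$pct_cytoplasmic))
  invisible(x)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel images are collapsed to grayscale by averaging channels.
#' Intensities are returned as stored by the reader (PNG: `[0, 1]`); the
#' quantifiers are scale-agnostic as long as thresholds are given on the
#' same scale.
#'
#' @param path `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix `image[row, col]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the 'png' package is required to read PNG images")
      }
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image extension: .", ext))
  if (length(dim(arr)) == 3L) {
    arr <- apply(arr, c(1, 2), mean)
  }
  arr
}
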