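#' Peak intensity: summed per-base tag count across a peak
#'
#' The binding-strength statistic: for each peak, the tag count at every
#' nucleotide inside the peak is summed.  Computed exactly by segment
#' arithmetic against the coverage step function (overlap length x segment
#' value), which equals the naive per-base loop.
#'
#' A peak on a chromosome absent from the track, or lying entirely outside
#' covered segments, scores 0.
#'
#' @param peaks `GRanges` of peaks.
#' @param cov coverage track: `GRanges` with a numeric `score` column of
#'   non-overlapping segments (see [read_coverage()]).
#' @return numeric vector of intensities, one per peak.
#' @export
peak_intensity <- function(peaks, cov) {
  out <- numeric(length(peaks))
  if (length(cov) == 0L) return(out)
  if (is.null(cov$score)) stop("coverage track lacks a score column")
  # disjoint chromosome sets are legitimate (coverage 0), not a warning
  hit <- suppressWarnings(findOverlaps(peaks, cov))
  if (length(hit) > 0L) {
    w <- width(pintersect(peaks[queryHits(hit)], cov[subjectHits(hit)]))
    contrib <- w * cov$score[subjectHits(hit)]
    agg <- rowsum(contrib, group = queryHits(hit))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Score peaks against a coverage track
#'
#' Convenience wrapper adding an `intensity` metadata column.
#'
#' @inheritParams peak_intensity
#' @return `peaks` with an `intensity` column.
#' @export
score_peaks <- function(peaks, cov) {
  peaks$intensity <- peak_intensity(peaks, cov)
  peaks
}

#' Construct two-factor Venn counts
#'
#' Peak-centric, one-sided overlap bookkeeping for two peak sets A and B:
#' how many A peaks overlap at least one B peak (each A peak counted once)
#' and vice versa.  `fraction_a` is the A-side overlap fraction, also
#' rounded to the nearest integer percent for display, the convention in
#' which a co-occupancy statement like "61% (6022 out of 9941) of RUNX2
#' peaks overlapped with CBFB peaks" is printed.
#'
#' @param total_a,total_b peak counts in A and B.
#' @param a_overlapping_b,b_overlapping_a one-sided overlap counts.
#' @return object of class `venn_counts`: list with the four counts,
#'   `fraction_a`, `fraction_b`, and integer `percent_a`, `percent_b`.
#' @export
venn_counts <- function(total_a, total_b, a_overlapping_b, b_overlapping_a) {
  stopifnot(a_overlapping_b >= 0, a_overlapping_b <= total_a,
            b_overlapping_a >= 0, b_overlapping_a <= total_b)
  frac_a <- if (total_a > 0) a_overlapping_b / total_a else NA_real_
  frac_b <- if (total_b > 0) b_overlapping_a / total_b else NA_real_
  structure(list(total_a = total_a, total_b = total_b,
                 a_overlapping_b = a_overlapping_b,
                 b_overlapping_a = b_overlapping_a,
                 fraction_a = frac_a, fraction_b = frac_b,
                 percent_a = if (is.na(frac_a)) NA_integer_ else as.integer(round(100 * frac_a)),
                 percent_b = if (is.na(frac_b)) NA_integer_ else as.integer(round(100 * frac_b))),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Two-factor peak overlap (one-sided, peak-centric)\n")
  cat(sprintf("  A: %d / %d overlapping B (%s%%)\n", x$a_overlapping_b,
              x$total_a, ifelse(is.na(x$percent_a), "NA", x$percent_a)))
  cat(sprintf("  B: %d / %d overlapping A (%s%%)\n", x$b_overlapping_a,
              x$total_b, ifelse(is.na(x$percent_b), "NA", x$percent_b)))
  invisible(x)
}

#' Venn decomposition of two peak sets
#'
#' Counts, per side, the peaks overlapping at least one peak of the other
#' set (>= 1 shared base).  Counts are invariant under permutation of the
#' input order.
#'
#' @param peaks_a,peaks_b `GRanges` of peaks.
#' @return a [venn_counts()] object.
#' @export
venn_decompose <- function(peaks_a, peaks_b) {
  venn_counts(length(peaks_a), length(peaks_b),
              sum(overlapsAny(peaks_a, peaks_b)),
              sum(overlapsAny(peaks_b, peaks_a)))
}

#' Match overlapping peaks one-to-one by maximal shared bases
#'
#' Each A peak is paired with the single B peak sharing the most bases
#' among its overlappers; ties go to the leftmost (smallest start) B peak.
#' A peaks with no overlapper are unpaired.  Pairs are returned sorted by
#' A-peak coordinate, so repeated runs on identical input give identical
#' pairings.
#'
#' @param peaks_a,peaks_b `GRanges`; `intensity` columns (from
#'   [score_peaks()]) are carried into the output when present.
#' @return data.frame with one row per pair: `a_id`, `b_id`, coordinates,
#'   `shared_bases`, and `intensity_a`/`intensity_b` when available.
#' @export
match_overlapping_peaks <- function(peaks_a, peaks_b) {
  hit <- findOverlaps(peaks_a, peaks_b)
  empty <- data.frame(a_id = character(), b_id = character(),
                      chrom = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), shared_bases = integer(),
                      stringsAsFactors = FALSE)
  if (length(hit) == 0L) return(empty)
  qh <- queryHits(hit); sh <- subjectHits(hit)
  shared <- width(pintersect(peaks_a[qh], peaks_b[sh]))
  # per A peak keep max shared bases, tie -> smallest B start
  ord <- order(qh, -shared, start(peaks_b)[sh])
  first <- !duplicated(qh[ord])
  qh <- qh[ord][first]; sh <- sh[ord][first]; shared <- shared[ord][first]
  ord2 <- order(as.character(seqnames(peaks_a))[qh], start(peaks_a)[qh],
                end(peaks_a)[qh])
  qh <- qh[ord2]; sh <- sh[ord2]; shared <- shared[ord2]
  out <- data.frame(
    a_id = peak_id(peaks_a)[qh], b_id = peak_id(peaks_b)[sh],
    chrom = as.character(seqnames(peaks_a))[qh],
    a_start = start(peaks_a)[qh], a_end = end(peaks_a)[qh],
    b_start = start(peaks_b)[sh], b_end = end(peaks_b)[sh],
    shared_bases = as.integer(shared), stringsAsFactors = FALSE)
  if (!is.null(peaks_a$intensity)) out$intensity_a <- peaks_a$intensity[qh]
  if (!is.null(peaks_b$intensity)) out$intensity_b <- peaks_b$intensity[sh]
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the product-moment correlation of average-tied ranks.  The
#' p-value (two-sided, against rho = 0) uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' for n > 10, and exact enumeration of all distinct rank permutations for
#' n <= 10 (ties handled by permuting the tied-average ranks themselves).
#'
#' Displayed p-values below 2.2e-16 are conventionally floored as
#' "< 2.2e-16"; `format_pvalue()` applies that convention.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list with `rho`, `p_value`, `n`, and `method` ("exact
#'   permutation" or "t approximation").
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- spearman_perm_pvalue(rx, ry, rho)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Display convention for very small p-values
#'
#' @param p numeric p-value(s).
#' @param floor values below this are shown as `"< floor"` (default
#'   2.2e-16, the double-precision display convention).
#' @return character vector.
#' @export
format_pvalue <- function(p, floor = 2.2e-16) {
  ifelse(p < floor, paste0("< ", format(floor)), format(p, digits = 3))
}
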