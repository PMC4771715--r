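#' Do two genomic intervals share at least one base?
#'
#' Overlap requires the same chromosome and >= 1 shared base; no
#' minimum-fraction rule is applied anywhere in the package.  Vectorised
#' over parallel pairs (lengths recycle as in `GRanges` arithmetic).
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b) {
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  same & (start(a) <= end(b)) & (start(b) <= end(a))
}

#' Gap distance between two intervals on the same chromosome
#'
#' The number of bases strictly between the two intervals: 0 when they
#' overlap or abut, larger otherwise.  Intervals on different chromosomes
#' are incomparable and raise an error (use `GenomicRanges::distance()`
#' directly if `NA` propagation is wanted).
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return non-negative integer vector of gap sizes.
#' @export
gap_distance <- function(a, b) {
  d <- GenomicRanges::distance(a, b, ignore.strand = TRUE)
  if (anyNA(d))
    stop("gap_distance: intervals on different chromosomes are incomparable",
         call. = FALSE)
  d
}

#' Strand-aware transcription start sites
#'
#' The TSS is the 5' end of the transcript: `start` on the plus strand,
#' `end` on the minus strand.
#'
#' @param transcripts stranded `GRanges`.
#' @return integer vector of TSS positions (1-based).
#' @export
tss <- function(transcripts) {
  s <- as.character(strand(transcripts))
  if (any(s == "*")) stop("tss: transcripts must be stranded")
  ifelse(s == "+", start(transcripts), end(transcripts))
}
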