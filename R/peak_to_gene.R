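#' Peak-to-gene assignment windows
#'
#' The three assignment zones around a transcript:
#'
#' * promoter — within `promoter_flank` bp of the TSS on either side
#'   (default 5 kb, i.e. 5 kb upstream to 5 kb downstream of the TSS);
#' * gene body — the remainder of the transcript span;
#' * distal — less than `distal_limit` bp (default 25 kb, strict) from the
#'   nearest transcript edge.
#'
#' Precedence is promoter > gene body > distal.
#'
#' @param promoter_flank promoter half-width in bp (> 0).
#' @param distal_limit distal cutoff in bp (>= `promoter_flank`); a peak is
#'   distal when `0 < gap < distal_limit`.
#' @return list of class `assignment_config`.
#' @export
assignment_config <- function(promoter_flank = 5000L, distal_limit = 25000L) {
  promoter_flank <- as.integer(promoter_flank)
  distal_limit <- as.integer(distal_limit)
  if (promoter_flank <= 0L) stop("promoter_flank must be positive")
  if (distal_limit < promoter_flank)
    stop("distal_limit must be >= promoter_flank")
  structure(list(promoter_flank = promoter_flank,
                 distal_limit = distal_limit),
            class = "assignment_config")
}

#' Strand-aware promoter windows
#'
#' The promoter is the symmetric window of `2 * promoter_flank` bases
#' centred on the strand-aware TSS; for minus-strand transcripts the TSS
#' sits at the high-coordinate end, so "upstream" means larger coordinates.
#'
#' @param transcripts stranded `GRanges`.
#' @param cfg an [assignment_config()].
#' @return `GRanges` of promoter windows, parallel to `transcripts`.
#' @export
promoter_windows <- function(transcripts, cfg = assignment_config()) {
  t0 <- tss(transcripts)
  GRanges(seqnames(transcripts),
          IRanges(pmax(1L, t0 - cfg$promoter_flank),
                  t0 + cfg$promoter_flank - 1L),
          strand = strand(transcripts))
}

#' Classify a peak against a transcript
#'
#' Vectorised over parallel peak/transcript pairs.  A pair is `promoter`
#' if the peak overlaps the TSS window, else `gene_body` if it overlaps
#' the transcript span, else `distal` if the gap to the span is positive
#' and strictly below `distal_limit`, else `none` (including pairs on
#' different chromosomes).  The three categories are mutually exclusive by
#' the promoter > gene body > distal precedence.
#'
#' @param peaks,transcripts `GRanges` of equal length (parallel pairs);
#'   either may have length 1.
#' @param cfg an [assignment_config()].
#' @return data.frame with `category` (factor: promoter, gene_body,
#'   distal, none) and `distance` (gap in bp; 0 for promoter/gene body,
#'   `NA` for none).
#' @export
classify_peak_vs_transcript <- function(peaks, transcripts,
                                        cfg = assignment_config()) {
  if (length(peaks) == 1L && length(transcripts) > 1L)
    peaks <- rep(peaks, length(transcripts))
  if (length(transcripts) == 1L && length(peaks) > 1L)
    transcripts <- rep(transcripts, length(peaks))
  stopifnot(length(peaks) == length(transcripts))
  prom <- promoter_windows(transcripts, cfg)
  same <- as.character(seqnames(peaks)) == as.character(seqnames(transcripts))
  in_prom <- same & interval_overlaps(peaks, prom)
  in_body <- same & !in_prom & interval_overlaps(peaks, transcripts)
  d <- GenomicRanges::distance(peaks, transcripts, ignore.strand = TRUE)
  is_distal <- same & !in_prom & !in_body & !is.na(d) & d > 0L &
    d < cfg$distal_limit
  category <- rep("none", length(peaks))
  category[is_distal] <- "distal"
  category[in_body] <- "gene_body"
  category[in_prom] <- "promoter"
  distance <- rep(NA_integer_, length(peaks))
  distance[in_prom | in_body] <- 0L
  distance[is_distal] <- d[is_distal]
  data.frame(category = factor(category,
                               levels = c("promoter", "gene_body",
                                          "distal", "none")),
             distance = distance)
}

#' Assign peaks to transcripts and genes
#'
#' Every peak is compared with every transcript within reach (transcript
#' span extended by `distal_limit`; the search is indexed, not all-pairs).
#' A peak may be assigned to several genes.  Per gene, the best assignment
#' across its transcripts is retained (promoter > gene body > distal, then
#' smallest distance, then transcript id for determinism), and all
#' transcript-level hits are kept in the assignment table.  Distal peaks
#' equidistant from two or more genes are assigned to all of them and
#' flagged (`tied`).
#'
#' @param peaks `GRanges` of peaks (a `name` column is used as peak id
#'   when present).
#' @param transcripts `GRanges` from [read_annotation()].
#' @param cfg an [assignment_config()].
#' @return list with:
#'   * `assignments` — transcript-level table (peak_id, gene_id,
#'      transcript_id, category, distance, tied);
#'   * `gene_best` — one row per bound gene: its best category/distance;
#'   * `bound_genes` — character vector of genes with >= 1 assignment.
#' @export
assign_peaks <- function(peaks, transcripts, cfg = assignment_config()) {
  if (length(transcripts) == 0L) stop("annotation is empty")
  pid <- if (!is.null(peaks$name)) as.character(peaks$name) else peak_id(peaks)
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      transcript_id = character(), category = character(),
                      distance = integer(), tied = logical(),
                      stringsAsFactors = FALSE)
  if (length(peaks) == 0L)
    return(list(assignments = empty,
                gene_best = empty[, c("gene_id", "peak_id", "category",
                                      "distance")],
                bound_genes = character()))
  # reach covers every category: promoter window extends at most
  # promoter_flank (<= distal_limit) beyond the span, distal at most
  # distal_limit - 1
  reach <- GRanges(seqnames(transcripts),
                   IRanges(pmax(1L, start(transcripts) - cfg$distal_limit),
                           end(transcripts) + cfg$distal_limit))
  hit <- findOverlaps(peaks, reach, ignore.strand = TRUE)
  qh <- queryHits(hit); sh <- subjectHits(hit)
  cls <- classify_peak_vs_transcript(peaks[qh], transcripts[sh], cfg)
  keep <- cls$category != "none"
  qh <- qh[keep]; sh <- sh[keep]; cls <- cls[keep, , drop = FALSE]
  asn <- data.frame(peak_id = pid[qh],
                    gene_id = as.character(transcripts$gene_id)[sh],
                    transcript_id = as.character(transcripts$transcript_id)[sh],
                    category = as.character(cls$category),
                    distance = cls$distance,
                    stringsAsFactors = FALSE)
  # flag distal assignments of a peak tied at identical distance to >1 gene
  asn$tied <- logical(nrow(asn))
  if (nrow(asn) > 0L) {
    dk <- asn$category == "distal"
    if (any(dk)) {
      key <- paste(asn$peak_id[dk], asn$distance[dk])
      genes_per_key <- tapply(asn$gene_id[dk], key,
                              function(g) length(unique(g)))
      asn$tied[dk] <- genes_per_key[key] > 1L
    }
  }
  ord <- order(asn$peak_id, asn$gene_id, asn$transcript_id)
  asn <- asn[ord, , drop = FALSE]
  rownames(asn) <- NULL
  if (nrow(asn) == 0L)
    return(list(assignments = asn,
                gene_best = empty[, c("gene_id", "peak_id", "category",
                                      "distance")],
                bound_genes = character()))
  prec <- match(asn$category, c("promoter", "gene_body", "distal"))
  ordg <- order(asn$gene_id, prec, asn$distance, asn$transcript_id)
  best <- asn[ordg, , drop = FALSE][!duplicated(asn$gene_id[ordg]), ,
                                    drop = FALSE]
  gene_best <- best[, c("gene_id", "peak_id", "category", "distance")]
  rownames(gene_best) <- NULL
  list(assignments = asn, gene_best = gene_best,
       bound_genes = sort(unique(asn$gene_id)))
}
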