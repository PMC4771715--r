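#' Call direct targets from dependency calls and bound genes
#'
#' A direct target is a gene that is both factor-dependent (concordant
#' two-hairpin expression change) and bound (at least one associated peak
#' within the assignment windows).  Classification follows the knockdown
#' direction: expression DOWN upon knockdown means the factor activated
#' the gene (`activated`); expression UP means it repressed it
#' (`repressed`).  Genes failing either leg get class `none`.
#'
#' @param dependency_calls data.frame from [concordant_dependent_genes()]
#'   (needs `gene_id`, `dependent`, `direction`).
#' @param bound_genes character vector of bound gene ids (from
#'   [assign_peaks()]`$bound_genes`).
#' @param gene_best optional `gene_best` table from [assign_peaks()];
#'   contributes a `best_peak_category` column.
#' @return object of class `target_calls`: list with `calls` (one row per
#'   gene in `dependency_calls`: gene_id, dependent, direction, bound,
#'   best_peak_category, target_class) and `counts` (named integer
#'   vector: activated, repressed, direct_total, dependent, bound).
#' @export
call_direct_targets <- function(dependency_calls, bound_genes,
                                gene_best = NULL) {
  df <- dependency_calls
  bound <- df$gene_id %in% bound_genes
  cls <- rep("none", nrow(df))
  direct <- df$dependent & bound
  cls[direct & df$direction == "down"] <- "activated"
  cls[direct & df$direction == "up"] <- "repressed"
  best_cat <- rep(NA_character_, nrow(df))
  if (!is.null(gene_best)) {
    idx <- match(df$gene_id, gene_best$gene_id)
    best_cat <- gene_best$category[idx]
  }
  calls <- data.frame(gene_id = df$gene_id,
                      dependent = df$dependent,
                      direction = df$direction,
                      bound = bound,
                      best_peak_category = best_cat,
                      target_class = cls,
                      stringsAsFactors = FALSE)
  counts <- c(activated = sum(cls == "activated"),
              repressed = sum(cls == "repressed"),
              direct_total = sum(cls != "none"),
              dependent = sum(df$dependent),
              bound = length(unique(intersect(df$gene_id, bound_genes))))
  structure(list(calls = calls, counts = counts), class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  cat(sprintf(paste0("Direct-target calls: %d direct targets ",
                     "(%d repressed, %d activated)\n"),
              x$counts[["direct_total"]], x$counts[["repressed"]],
              x$counts[["activated"]]))
  cat(sprintf("  dependent genes: %d; bound genes among tested: %d\n",
              x$counts[["dependent"]], x$counts[["bound"]]))
  invisible(x)
}

#' Upper-tail hypergeometric gene-set enrichment
#'
#' With a universe of N genes, K of them in the gene set and a target list
#' of n genes of which k fall in the set, the enrichment p-value is
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`, accumulated from
#' log-scale terms so tiny tails stay accurate.
#'
#' @param targets character vector of target gene ids (must lie in
#'   `universe`; duplicates ignored).
#' @param geneset character vector of set members (must lie in
#'   `universe`).
#' @param universe character vector of all eligible gene ids.
#' @param name optional set name carried into the result.
#' @return one-row data.frame: `geneset`, `overlap` (k), `geneset_size`
#'   (K), `targets_size` (n), `universe_size` (N), `p_value`.
#' @export
hypergeometric_enrichment <- function(targets, geneset, universe,
                                      name = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  targets <- unique(targets)
  geneset <- unique(geneset)
  bad <- setdiff(geneset, universe)
  if (length(bad) > 0L)
    stop("geneset members outside the universe: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  bad_t <- setdiff(targets, universe)
  if (length(bad_t) > 0L)
    stop("target genes outside the universe: ",
         paste(utils::head(bad_t, 5L), collapse = ", "),
         if (length(bad_t) > 5L) ", ..." else "")
  N <- length(universe); K <- length(geneset); n <- length(targets)
  k <- length(intersect(targets, geneset))
  # P[X >= k] summed from log-space densities
  if (k == 0L) {
    p <- 1
  } else {
    i <- k:min(K, n)
    p <- min(1, sum(exp(dhyper(i, K, N - K, n, log = TRUE))))
  }
  data.frame(geneset = name, overlap = k, geneset_size = K,
             targets_size = n, universe_size = N, p_value = p,
             stringsAsFactors = FALSE)
}

#' Enrichment of a target list over a gene-set collection
#'
#' Runs [hypergeometric_enrichment()] per set and appends
#' Benjamini-Hochberg q-values (raw p-values are kept; the adjustment is
#' an extra column).
#'
#' @param targets character vector of target gene ids.
#' @param genesets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all eligible gene ids.
#' @return data.frame, one row per set, sorted by p-value.
#' @export
enrich_genesets <- function(targets, genesets, universe) {
  if (length(genesets) == 0L)
    return(data.frame(geneset = character(), overlap = integer(),
                      geneset_size = integer(), targets_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  rows <- mapply(function(gs, nm)
    hypergeometric_enrichment(targets, gs, universe, name = nm),
    genesets, names(genesets), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$geneset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
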