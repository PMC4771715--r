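#' Run the full ChIP-seq / knockdown RNA-seq integration pipeline
#'
#' Executes every stage in order: read inputs, score both peak sets
#' against their own coverage tracks, Venn-decompose the two sets, match
#' overlapping peaks and correlate their intensities, assign the primary
#' factor's peaks to genes, call concordant dependent genes from the
#' expression matrix, intersect into direct-target calls, and (when gene
#' sets are supplied) run hypergeometric enrichment of the direct targets.
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config a named list or the path of a YAML file with keys:
#'   * `peaks_a`, `peaks_b` — BED peak files (factor A is the primary
#'     factor whose peaks define bound genes);
#'   * `coverage_a`, `coverage_b` — bedGraph tag-coverage tracks, one per
#'     factor;
#'   * `annotation` — transcript annotation (GFF3 or BED12);
#'   * `expression` — RPKM TSV; `samples` — YAML sample sheet
#'     (see [read_expression()]);
#'   * optional `genesets` — GMT file; `outdir` — where to write result
#'     tables; `promoter_flank` (5000), `distal_limit` (25000),
#'     `fc_threshold` (1.5), `alpha` (0.05), `pseudocount` (1),
#'     `promoter_only` (FALSE — restrict "bound" to promoter peaks).
#' @return list with `peaks_a`, `peaks_b` (scored `GRanges`), `venn`,
#'   `matched_pairs`, `spearman`, `assignment`, `dependency_calls`,
#'   `target_calls`, `enrichment` (or `NULL`), and `summary` (plain list
#'   of the headline counts, the object written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("peaks_a", "peaks_b", "coverage_a", "coverage_b",
                  "annotation", "expression", "samples"))
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'", call. = FALSE)
  get_num <- function(key, default)
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  acfg <- assignment_config(get_num("promoter_flank", 5000),
                            get_num("distal_limit", 25000))
  dcfg <- de_config(get_num("fc_threshold", 1.5),
                    get_num("alpha", 0.05),
                    get_num("pseudocount", 1))
  promoter_only <- isTRUE(config$promoter_only)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  peaks_a <- stage("read_peaks_a", read_peaks(config$peaks_a))
  peaks_b <- stage("read_peaks_b", read_peaks(config$peaks_b))
  cov_a <- stage("read_coverage_a", read_coverage(config$coverage_a))
  cov_b <- stage("read_coverage_b", read_coverage(config$coverage_b))
  anno <- stage("read_annotation", read_annotation(config$annotation))
  expr <- stage("read_expression",
                read_expression(config$expression, config$samples))

  peaks_a <- stage("score_peaks", score_peaks(peaks_a, cov_a))
  peaks_b <- stage("score_peaks", score_peaks(peaks_b, cov_b))
  venn <- stage("venn", venn_decompose(peaks_a, peaks_b))
  pairs <- stage("match_peaks", match_overlapping_peaks(peaks_a, peaks_b))
  spear <- NULL
  if (nrow(pairs) >= 3L &&
      stats::sd(pairs$intensity_a) > 0 && stats::sd(pairs$intensity_b) > 0)
    spear <- stage("spearman",
                   spearman_correlation(pairs$intensity_a, pairs$intensity_b))

  assignment <- stage("assign_peaks", assign_peaks(peaks_a, anno, acfg))
  bound <- assignment$bound_genes
  if (promoter_only)
    bound <- sort(unique(assignment$assignments$gene_id[
      assignment$assignments$category == "promoter"]))

  mat <- expr$matrix
  gene_map <- setNames(as.character(anno$gene_id),
                       as.character(anno$transcript_id))
  if (!all(rownames(mat) %in% anno$gene_id) &&
      all(rownames(mat) %in% names(gene_map)))
    mat <- collapse_to_genes(mat, gene_map)
  dep <- stage("dependency_calls",
               concordant_dependent_genes(mat, expr$samples, dcfg))
  targets <- stage("call_direct_targets",
                   call_direct_targets(dep, bound, assignment$gene_best))

  enrichment <- NULL
  if (!is.null(config$genesets)) {
    universe <- sort(unique(as.character(anno$gene_id)))
    direct <- targets$calls$gene_id[targets$calls$target_class != "none"]
    enrichment <- stage("enrichment",
                        enrich_genesets(direct, read_gmt(config$genesets),
                                        universe))
  }

  summary <- list(
    schema_version = "1.0",
    n_peaks_a = length(peaks_a),
    n_peaks_b = length(peaks_b),
    a_overlapping_b = venn$a_overlapping_b,
    b_overlapping_a = venn$b_overlapping_a,
    overlap_fraction_a = venn$fraction_a,
    overlap_percent_a = venn$percent_a,
    n_matched_pairs = nrow(pairs),
    spearman_rho = if (is.null(spear)) NA else spear$rho,
    spearman_p = if (is.null(spear)) NA else spear$p_value,
    spearman_p_display = if (is.null(spear)) NA else
      format_pvalue(spear$p_value),
    n_bound_genes = length(bound),
    n_dependent = unname(targets$counts[["dependent"]]),
    n_dependent_up = sum(dep$dependent & dep$direction == "up",
                         na.rm = TRUE),
    n_dependent_down = sum(dep$dependent & dep$direction == "down",
                           na.rm = TRUE),
    n_direct_targets = unname(targets$counts[["direct_total"]]),
    n_activated = unname(targets$counts[["activated"]]),
    n_repressed = unname(targets$counts[["repressed"]]),
    parameters = list(promoter_flank = acfg$promoter_flank,
                      distal_limit = acfg$distal_limit,
                      fc_threshold = dcfg$fc_threshold,
                      alpha = dcfg$alpha,
                      pseudocount = dcfg$pseudocount,
                      promoter_only = promoter_only))

  result <- list(peaks_a = peaks_a, peaks_b = peaks_b, venn = venn,
                 matched_pairs = pairs, spearman = spear,
                 assignment = assignment, dependency_calls = dep,
                 target_calls = targets, enrichment = enrichment,
                 summary = summary)
  if (!is.null(config$outdir))
    stage("write_outputs", write_pipeline_outputs(result, config$outdir))
  result
}

# TSV writer with fixed conventions so outputs are byte-stable.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline result tables to a directory
#'
#' Emits `scored_peaks_a.tsv`, `scored_peaks_b.tsv`, `matched_pairs.tsv`,
#' `venn.json`, `assignments.tsv`, `dependency_calls.tsv`,
#' `target_calls.tsv`, `enrichment.tsv` (when computed), and
#' `summary.json`.
#'
#' @param result list returned by [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scored <- function(gr) data.frame(
    peak_id = if (!is.null(gr$name)) gr$name else peak_id(gr),
    chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
    end = end(gr), intensity = gr$intensity, stringsAsFactors = FALSE)
  .write_tsv(scored(result$peaks_a), file.path(outdir, "scored_peaks_a.tsv"))
  .write_tsv(scored(result$peaks_b), file.path(outdir, "scored_peaks_b.tsv"))
  .write_tsv(result$matched_pairs, file.path(outdir, "matched_pairs.tsv"))
  jsonlite::write_json(unclass(result$venn),
                       file.path(outdir, "venn.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_tsv(result$assignment$assignments,
             file.path(outdir, "assignments.tsv"))
  .write_tsv(result$dependency_calls,
             file.path(outdir, "dependency_calls.tsv"))
  .write_tsv(result$target_calls$calls,
             file.path(outdir, "target_calls.tsv"))
  if (!is.null(result$enrichment))
    .write_tsv(result$enrichment, file.path(outdir, "enrichment.tsv"))
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
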