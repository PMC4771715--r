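#' Configuration for the synthetic-data generators
#'
#' Defines the study conditions the generators emulate: two ChIP-seq peak
#' sets with a one-sided overlap fraction and rank-correlated intensities
#' of the overlapping pairs, an annotation of well-separated transcripts
#' on alternating strands, and a three-condition RPKM matrix (control +
#' two knockdown hairpins) with planted dependent genes in both
#' directions.  All randomness flows from the single `seed` (the three
#' generators use fixed small offsets from it, so each is independently
#' reproducible); defaults keep the full pipeline well under a minute.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (one transcript each), default 500.
#' @param chrom chromosome name for the synthetic contig.
#' @param chrom_length optional contig length in bp; computed from the
#'   layout when `NULL`, rejected with the required minimum when too
#'   small.
#' @param n_peaks_a number of factor-A peaks, default 1000.
#' @param n_peaks_b number of factor-B peaks; default 1.25 * `n_peaks_a`
#'   (the partner factor binds more sites, as a cofactor shared with
#'   other factors would).
#' @param target_overlap_fraction fraction of A peaks given an overlapping
#'   B partner (default 0.61); realised as `round(fraction * n_peaks_a)`
#'   pairs over a sampled subset, so the realised fraction is exact to
#'   rounding.
#' @param target_intensity_rho target Spearman correlation of paired
#'   intensities (default 0.84), induced by a Gaussian copula over
#'   log-normal margins using the exact normal-scores relation
#'   r(normal) = `2 * sin(pi * rho_s / 6)`.
#' @param n_bound_genes genes given one promoter peak of factor A,
#'   default 200.
#' @param n_planted_activated,n_planted_repressed bound genes whose
#'   expression is scaled down / up by `effect_fold` in both knockdowns
#'   (defaults 30 and 30; these are the planted direct targets).
#' @param n_dependent_unbound unbound genes that also respond to both
#'   knockdowns (indirect effects; split between directions), default 20.
#' @param effect_fold linear fold effect of the knockdown on planted
#'   genes, default 3; 1 yields the null case (planted genes
#'   indistinguishable from the background).
#' @param replicate_cv multiplicative coefficient of variation of
#'   replicate noise, default 0.2.
#' @param n_replicates replicates per condition, default 3.
#' @param peak_width peak width in bp, default 400.
#' @param promoter_flank,distal_limit assignment windows the layout is
#'   built around (defaults 5000 / 25000); inter-transcript gaps exceed
#'   `2 * (promoter_flank + distal_limit)` so no peak can sit within the
#'   windows of two genes unless planted so.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity margin
#'   (defaults log(300), 1).
#' @param base_meanlog,base_sdlog log-normal control-RPKM distribution of
#'   unplanted genes (defaults log(30), 1).
#' @param planted_meanlog,planted_sdlog control-RPKM distribution of
#'   planted dependent genes (defaults log(60), 0.5) — regulated genes
#'   are drawn from the clearly-expressed range, since silent genes are
#'   undetectable at RPKM level.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, chrom = "chrS",
                       chrom_length = NULL, n_peaks_a = 1000L,
                       n_peaks_b = NULL,
                       target_overlap_fraction = 0.61,
                       target_intensity_rho = 0.84,
                       n_bound_genes = 200L,
                       n_planted_activated = 30L,
                       n_planted_repressed = 30L,
                       n_dependent_unbound = 20L,
                       effect_fold = 3, replicate_cv = 0.2,
                       n_replicates = 3L, peak_width = 400L,
                       promoter_flank = 5000L, distal_limit = 25000L,
                       intensity_meanlog = log(300), intensity_sdlog = 1,
                       base_meanlog = log(30), base_sdlog = 1,
                       planted_meanlog = log(60), planted_sdlog = 0.5) {
  if (is.null(n_peaks_b)) n_peaks_b <- as.integer(ceiling(1.25 * n_peaks_a))
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chrom = chrom, chrom_length = chrom_length,
              n_peaks_a = as.integer(n_peaks_a),
              n_peaks_b = as.integer(n_peaks_b),
              target_overlap_fraction = target_overlap_fraction,
              target_intensity_rho = target_intensity_rho,
              n_bound_genes = as.integer(n_bound_genes),
              n_planted_activated = as.integer(n_planted_activated),
              n_planted_repressed = as.integer(n_planted_repressed),
              n_dependent_unbound = as.integer(n_dependent_unbound),
              effect_fold = effect_fold, replicate_cv = replicate_cv,
              n_replicates = as.integer(n_replicates),
              peak_width = as.integer(peak_width),
              promoter_flank = as.integer(promoter_flank),
              distal_limit = as.integer(distal_limit),
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog,
              base_meanlog = base_meanlog, base_sdlog = base_sdlog,
              planted_meanlog = planted_meanlog,
              planted_sdlog = planted_sdlog)
  with(cfg, {
    stopifnot(n_genes >= 0L, n_peaks_a >= 0L, n_peaks_b >= 0L,
              target_overlap_fraction >= 0, target_overlap_fraction <= 1,
              target_intensity_rho >= -1, target_intensity_rho <= 1,
              effect_fold >= 1, replicate_cv >= 0, n_replicates >= 2L,
              peak_width >= 2L)
    if (n_bound_genes > n_genes) stop("n_bound_genes exceeds n_genes")
    if (n_planted_activated + n_planted_repressed > n_bound_genes)
      stop("planted activated + repressed exceed n_bound_genes")
    if (n_dependent_unbound > n_genes - n_bound_genes)
      stop("n_dependent_unbound exceeds unbound genes")
    if (n_bound_genes > n_peaks_a)
      stop("n_bound_genes exceeds n_peaks_a")
  })
  structure(cfg, class = "sim_config")
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic transcript annotation
#'
#' Non-overlapping single-transcript genes on alternating strands.
#' Transcript lengths are uniform on 8-20 kb and every inter-transcript
#' gap exceeds `2 * (promoter_flank + distal_limit)` (60 kb at defaults),
#' so promoter and distal windows of neighbouring genes can never touch
#' and peak-to-gene assignment on the layout is unambiguous by
#' construction.  Deterministic for a fixed config seed.
#'
#' @param cfg a [sim_config()].
#' @return `GRanges` with `gene_id`/`transcript_id`, plus a
#'   `chrom_length` attribute.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    if (n == 0L) {
      out <- GRanges()
      mcols(out) <- S4Vectors::DataFrame(gene_id = character(),
                                         transcript_id = character())
      S4Vectors::metadata(out)$chrom_length <- cfg$chrom_length %||% 1e5
      return(out)
    }
    min_gap <- 2L * (cfg$promoter_flank + cfg$distal_limit)
    lens <- as.integer(round(runif(n, 8000, 20000)))
    gaps <- min_gap + as.integer(round(runif(n + 1L, 0, 20000)))
    starts <- integer(n); ends <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      starts[i] <- pos + gaps[i] + 1L
      ends[i] <- starts[i] + lens[i] - 1L
      pos <- ends[i]
    }
    need <- pos + gaps[n + 1L]
    if (!is.null(cfg$chrom_length) && cfg$chrom_length < need)
      stop("chrom_length too small for ", n, " genes; need >= ", need)
    out <- GRanges(cfg$chrom, IRanges(starts, ends),
                   strand = rep_len(c("+", "-"), n))
    mcols(out) <- S4Vectors::DataFrame(
      gene_id = sprintf("g%04d", seq_len(n)),
      transcript_id = sprintf("t%04d", seq_len(n)))
    S4Vectors::metadata(out)$chrom_length <- cfg$chrom_length %||% need
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate co-occupied peak sets with matched coverage tracks
#'
#' Places one factor-A peak in the promoter (centred on the TSS) of each
#' of `n_bound_genes` sampled genes and the remaining A peaks in
#' intergenic slots farther than `distal_limit` from every transcript.
#' `round(target_overlap_fraction * n_peaks_a)` A peaks (sampled) receive
#' an overlapping B partner (offset 50-300 bp); remaining B peaks occupy
#' their own intergenic slots, so no unplanned overlap can occur.  Paired
#' intensities come from a Gaussian copula over log-normal margins with
#' normal-scores correlation `2 * sin(pi * rho_s / 6)`, rounded to
#' integers; each factor's coverage track is a rectangular pileup built so
#' that [peak_intensity()] recovers every planted intensity exactly
#' (height `intensity %/% width`, with the remainder stacked on the
#' peak's first bases).
#'
#' @param cfg a [sim_config()].
#' @param annotation `GRanges` from [generate_annotation()].
#' @return list with `peaks_a`, `peaks_b` (named `GRanges` with planted
#'   `intensity`), `coverage_a`, `coverage_b` (scored `GRanges`), and
#'   `truth`: bound_genes (data.frame gene_id/category), pairs
#'   (a_name/b_name and intensities), realized_overlap_fraction,
#'   realized_intensity_rho, n_pairs.
#' @export
generate_cooccupied_peaks <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 1L, {
    w <- cfg$peak_width
    n_a <- cfg$n_peaks_a
    n_b <- cfg$n_peaks_b
    n_paired <- as.integer(round(cfg$target_overlap_fraction * n_a))
    if (n_paired > n_b)
      stop("target overlap infeasible: needs ", n_paired,
           " B partners but n_peaks_b = ", n_b)
    n_bound <- cfg$n_bound_genes
    n_inter_a <- n_a - n_bound
    n_unpaired_b <- n_b - n_paired

    # promoter peaks, centred on the TSS of sampled bound genes
    bound_idx <- sort(sample(length(annotation), n_bound))
    t0 <- tss(annotation[bound_idx])
    prom_starts <- t0 - w %/% 2L

    # intergenic slots: > distal_limit + margin from both flanking
    # transcripts, stride chosen so neighbouring occupants cannot touch
    margin <- 2000L
    stride <- 1500L
    bnd <- c(0L, end(annotation), S4Vectors::metadata(annotation)$chrom_length)
    gap_lo <- utils::head(bnd, -1L) + 1L           # gap i: [gap_lo, gap_hi]
    gap_hi <- c(start(annotation) - 1L, bnd[length(bnd)])
    slots <- unlist(lapply(seq_along(gap_lo), function(i) {
      lo <- gap_lo[i] + cfg$distal_limit + margin
      hi <- gap_hi[i] - cfg$distal_limit - margin - w
      if (hi < lo) integer() else seq.int(lo, hi, by = stride)
    }))
    if (n_inter_a + n_unpaired_b > length(slots))
      stop("layout infeasible: ", n_inter_a + n_unpaired_b,
           " intergenic peaks requested but only ", length(slots),
           " slots available; increase n_genes or reduce peak counts")
    picked <- sample(slots, n_inter_a + n_unpaired_b)
    a_starts <- c(prom_starts, picked[seq_len(n_inter_a)])
    ub_starts <- picked[n_inter_a + seq_len(n_unpaired_b)]

    ord_a <- order(a_starts)
    a_starts <- a_starts[ord_a]
    # which A peaks (post-sort) are promoter-planted, and for which gene
    a_gene <- c(annotation$gene_id[bound_idx],
                rep(NA_character_, n_inter_a))[ord_a]
    paired_of_a <- sort(sample(n_a, n_paired))

    # intensities: Gaussian copula for pairs, iid margins elsewhere
    r_norm <- 2 * sin(pi * cfg$target_intensity_rho / 6)
    z1 <- rnorm(n_paired)
    z2 <- r_norm * z1 + sqrt(1 - r_norm^2) * rnorm(n_paired)
    lognorm <- function(z) pmax(1, round(exp(cfg$intensity_meanlog +
                                               cfg$intensity_sdlog * z)))
    int_a <- pmax(1, round(rlnorm(n_a, cfg$intensity_meanlog,
                                  cfg$intensity_sdlog)))
    int_a[paired_of_a] <- lognorm(z1)
    int_b_paired <- lognorm(z2)
    int_b_unpaired <- pmax(1, round(rlnorm(n_unpaired_b,
                                           cfg$intensity_meanlog,
                                           cfg$intensity_sdlog)))

    # B partners overlap their A peak at a 50-300 bp offset
    off <- sample(50:300, n_paired, replace = TRUE) *
      sample(c(-1L, 1L), n_paired, replace = TRUE)
    b_starts <- c(a_starts[paired_of_a] + off, ub_starts)
    int_b <- c(int_b_paired, int_b_unpaired)
    ord_b <- order(b_starts)
    b_starts <- b_starts[ord_b]
    int_b <- int_b[ord_b]
    b_name_of_pair <- sprintf("peakB_%05d",
                              match(seq_len(n_paired), ord_b))

    peaks_a <- GRanges(cfg$chrom, IRanges(a_starts, width = w),
                       name = sprintf("peakA_%05d", seq_len(n_a)),
                       intensity = int_a)
    peaks_b <- GRanges(cfg$chrom, IRanges(b_starts, width = w),
                       name = sprintf("peakB_%05d", seq_len(n_b)),
                       intensity = int_b)

    pileup <- function(starts, intensities) {
      h <- intensities %/% w
      r <- intensities %% w
      seg <- list()
      if (any(r > 0))
        seg$rem <- GRanges(cfg$chrom,
                           IRanges(starts[r > 0], width = r[r > 0]),
                           score = h[r > 0] + 1)
      if (any(h > 0))
        seg$base <- GRanges(cfg$chrom,
                            IRanges(starts[h > 0] + r[h > 0],
                                    width = w - r[h > 0]),
                            score = h[h > 0])
      GenomicRanges::sort(do.call(c, unname(seg)))
    }

    bound_genes <- data.frame(gene_id = sort(annotation$gene_id[bound_idx]),
                              category = "promoter",
                              stringsAsFactors = FALSE)
    pairs <- data.frame(
      a_name = sprintf("peakA_%05d", paired_of_a),
      b_name = b_name_of_pair,
      intensity_a = int_a[paired_of_a],
      intensity_b = int_b_paired,
      stringsAsFactors = FALSE)
    realized_rho <- if (n_paired >= 3L)
      spearman_correlation(pairs$intensity_a, pairs$intensity_b)$rho
    else NA_real_
    list(peaks_a = peaks_a, peaks_b = peaks_b,
         coverage_a = pileup(a_starts, int_a),
         coverage_b = pileup(b_starts, int_b),
         truth = list(bound_genes = bound_genes,
                      peak_gene = data.frame(
                        peak_id = peaks_a$name[!is.na(a_gene)],
                        gene_id = a_gene[!is.na(a_gene)],
                        stringsAsFactors = FALSE),
                      pairs = pairs,
                      realized_overlap_fraction = n_paired / n_a,
                      realized_intensity_rho = realized_rho,
                      n_pairs = n_paired))
  })
}

#' Generate a knockdown RPKM matrix with planted dependent genes
#'
#' Control RPKM is log-normal per gene; both knockdown conditions scale
#' the planted genes by `effect_fold` (down for activated targets, up for
#' repressed ones, and likewise for the unbound indirect responders) under
#' multiplicative log-normal replicate noise of the configured CV
#' (mean-preserving).  Unplanted genes share one null distribution across
#' all conditions.  Values are rounded to 4 decimals so written matrices
#' are byte-stable.
#'
#' @param cfg a [sim_config()].
#' @param annotation `GRanges` from [generate_annotation()].
#' @param truth the `truth` element of [generate_cooccupied_peaks()]
#'   (supplies the bound-gene list the planted targets are drawn from).
#' @return list with `matrix` (genes x samples RPKM), `samples`
#'   (sample sheet data.frame), and `planted`: data.frames `dependent`
#'   (gene_id, direction) and `direct` (gene_id, class).
#' @export
generate_knockdown_expression <- function(cfg, annotation, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 2L, {
    genes <- as.character(annotation$gene_id)
    bound <- truth$bound_genes$gene_id
    if (!all(bound %in% genes))
      stop("planted bound genes missing from annotation")
    act <- sort(sample(bound, cfg$n_planted_activated))
    rep_ <- sort(sample(setdiff(bound, act), cfg$n_planted_repressed))
    unbound <- setdiff(genes, bound)
    ind <- sort(sample(unbound, cfg$n_dependent_unbound))
    n_ind_dn <- ceiling(cfg$n_dependent_unbound / 2)
    ind_dn <- ind[seq_len(n_ind_dn)]
    ind_up <- setdiff(ind, ind_dn)

    down <- c(act, ind_dn)   # expression falls upon knockdown
    up <- c(rep_, ind_up)    # expression rises upon knockdown
    planted <- c(down, up)
    if (anyDuplicated(planted))
      stop("planted gene lists overlap in opposite directions")

    base <- rlnorm(length(genes), cfg$base_meanlog, cfg$base_sdlog)
    names(base) <- genes
    base[planted] <- rlnorm(length(planted), cfg$planted_meanlog,
                            cfg$planted_sdlog)
    fold <- setNames(rep(1, length(genes)), genes)
    fold[down] <- 1 / cfg$effect_fold
    fold[up] <- cfg$effect_fold

    nr <- cfg$n_replicates
    conds <- c("control", "kdA", "kdB")
    samples <- data.frame(
      sample = paste0(rep(c("ctrl", "kdA", "kdB"), each = nr), "_",
                      rep(seq_len(nr), times = 3L)),
      condition = rep(conds, each = nr),
      replicate = rep(seq_len(nr), times = 3L),
      stringsAsFactors = FALSE)
    sig <- sqrt(log(1 + cfg$replicate_cv^2))
    mat <- sapply(seq_len(nrow(samples)), function(j) {
      mu <- base * (if (samples$condition[j] == "control") 1 else fold)
      noise <- exp(sig * rnorm(length(genes)) - sig^2 / 2)
      round(mu * noise, 4)
    })
    colnames(mat) <- samples$sample
    rownames(mat) <- genes

    dependent <- rbind(
      data.frame(gene_id = down, direction = "down",
                 stringsAsFactors = FALSE),
      data.frame(gene_id = up, direction = "up",
                 stringsAsFactors = FALSE))
    dependent <- dependent[order(dependent$gene_id), , drop = FALSE]
    rownames(dependent) <- NULL
    direct <- rbind(
      data.frame(gene_id = act, class = "activated",
                 stringsAsFactors = FALSE),
      data.frame(gene_id = rep_, class = "repressed",
                 stringsAsFactors = FALSE))
    direct <- direct[order(direct$gene_id), , drop = FALSE]
    rownames(direct) <- NULL
    list(matrix = mat, samples = samples,
         planted = list(dependent = dependent, direct = direct))
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs the three generators and writes every pipeline input to `outdir`:
#' `annotation.gff3`, `peaks_a.bed`, `peaks_b.bed`,
#' `coverage_a.bedGraph`, `coverage_b.bedGraph`, `expression.tsv`,
#' `samples.yaml`, and the ground-truth ledger `planted_truth.json`.
#' Identical configs produce byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return list with `config` (a ready [run_pipeline()] config of file
#'   paths), `truth` (planted ground truth: bound genes, dependent genes
#'   with directions, direct targets with classes, realized calibration),
#'   and `objects` (the in-memory annotation, peaks, coverage, and
#'   expression).
#' @export
simulate_bundle <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  expr <- generate_knockdown_expression(cfg, anno, occ$truth)

  p <- function(f) file.path(outdir, f)
  write_annotation(anno, p("annotation.gff3"))
  write_peaks(occ$peaks_a, p("peaks_a.bed"))
  write_peaks(occ$peaks_b, p("peaks_b.bed"))
  write_coverage(occ$coverage_a, p("coverage_a.bedGraph"))
  write_coverage(occ$coverage_b, p("coverage_b.bedGraph"))
  etab <- data.frame(gene_id = rownames(expr$matrix), expr$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(etab, p("expression.tsv"))
  yaml::write_yaml(list(samples = lapply(seq_len(nrow(expr$samples)),
    function(i) list(sample = expr$samples$sample[i],
                     condition = expr$samples$condition[i],
                     replicate = expr$samples$replicate[i]))),
    p("samples.yaml"))

  truth <- c(occ$truth, expr$planted)
  truth$counts <- list(
    n_bound = nrow(occ$truth$bound_genes),
    n_dependent = nrow(expr$planted$dependent),
    n_direct = nrow(expr$planted$direct),
    n_activated = sum(expr$planted$direct$class == "activated"),
    n_repressed = sum(expr$planted$direct$class == "repressed"))
  jsonlite::write_json(truth, p("planted_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  list(config = list(peaks_a = p("peaks_a.bed"),
                     peaks_b = p("peaks_b.bed"),
                     coverage_a = p("coverage_a.bedGraph"),
                     coverage_b = p("coverage_b.bedGraph"),
                     annotation = p("annotation.gff3"),
                     expression = p("expression.tsv"),
                     samples = p("samples.yaml"),
                     promoter_flank = cfg$promoter_flank,
                     distal_limit = cfg$distal_limit),
       truth = truth,
       objects = list(annotation = anno, peaks_a = occ$peaks_a,
                      peaks_b = occ$peaks_b,
                      coverage_a = occ$coverage_a,
                      coverage_b = occ$coverage_b,
                      expression = expr$matrix,
                      samples = expr$samples))
}
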