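#' Thresholds for the concordant knockdown filter
#'
#' @param fc_threshold linear fold-change threshold (> 1); a gene must
#'   change more than this factor (either direction) under both hairpins.
#'   Default 1.5.
#' @param alpha per-hairpin p-value threshold, default 0.05.  Raw p-values
#'   are used deliberately: the two-hairpin concordance requirement is the
#'   multiplicity guard, and no correction is applied (a caveat worth
#'   keeping in mind for single-hairpin designs).
#' @param pseudocount RPKM pseudocount added before ratios and logs,
#'   default 1.
#' @return list of class `de_config`.
#' @export
de_config <- function(fc_threshold = 1.5, alpha = 0.05, pseudocount = 1) {
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 pseudocount = pseudocount), class = "de_config")
}

#' Pseudocounted log2 fold change
#'
#' `log2((mean_kd + eps) / (mean_ctrl + eps))`; the pseudocount guards
#' zero RPKM on either side.  The linear fold change is `2^|log2fc|`.
#'
#' @param mean_kd,mean_ctrl mean RPKM in knockdown and control (>= 0);
#'   vectorised.
#' @param pseudocount eps > 0, default 1.
#' @return signed log2 ratio(s).
#' @export
log2_fold_change <- function(mean_kd, mean_ctrl, pseudocount = 1) {
  if (any(mean_kd < 0) || any(mean_ctrl < 0)) stop("RPKM means must be >= 0")
  log2((mean_kd + pseudocount) / (mean_ctrl + pseudocount))
}

#' Welch t-test on log2(RPKM + pseudocount)
#'
#' Two-sided unequal-variance t-test on the log scale, the replicate-level
#' test behind the dependency calls.  Degenerate cases: identical groups
#' with zero spread give p = 1; zero spread with different means gives the
#' smallest positive double (the evidence is unbounded).
#'
#' @param ctrl,kd RPKM replicate vectors (>= 2 values each).
#' @param pseudocount eps > 0, default 1.
#' @return two-sided p-value in (0, 1].
#' @export
replicate_test <- function(ctrl, kd, pseudocount = 1) {
  if (length(ctrl) < 2L || length(kd) < 2L)
    stop("replicate_test needs >= 2 replicates per group")
  x <- log2(ctrl + pseudocount)
  y <- log2(kd + pseudocount)
  .welch_p(mean(x), mean(y), stats::var(x), stats::var(y),
           length(x), length(y))
}

# Welch p from summary statistics (vectorised); shared by replicate_test
# and the matrix-wise path in concordant_dependent_genes.
.welch_p <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df = df)
  flat <- se2 == 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- .Machine$double.xmin
  p
}

#' Concordant two-hairpin dependency calls
#'
#' A gene is factor-dependent when, for BOTH knockdown hairpins relative
#' to control: the linear fold change exceeds `fc_threshold` (in either
#' direction), the replicate-level p-value is below `alpha`, and the two
#' log2 fold changes share a sign.  Requiring the same direction under two
#' independent hairpins is the guard against shRNA off-target effects.
#'
#' @param mat numeric RPKM matrix, rownames = gene ids.  Transcript-level
#'   matrices should first go through [collapse_to_genes()].
#' @param samples data.frame with columns `sample`, `condition` (exactly
#'   the values `control`, `kdA`, `kdB`), `replicate`; `sample` values
#'   must name columns of `mat`.
#' @param cfg a [de_config()].
#' @param test_fun replicate-level test, signature
#'   `function(ctrl, kd, pseudocount) -> p`; defaults to
#'   [replicate_test()] (Welch t on log2(RPKM + eps)).  Supplying a
#'   different function swaps the statistic without touching the
#'   concordance logic; the default bypasses the per-gene loop with an
#'   equivalent vectorised path.
#' @return data.frame, one row per gene: `gene_id`, `mean_ctrl`,
#'   `mean_kda`, `mean_kdb`, `log2fc_a`, `log2fc_b`, `p_a`, `p_b`,
#'   `direction` (`up`/`down` for dependent genes, `NA` otherwise, where
#'   up = expression rises upon knockdown), `dependent` (logical).
#' @export
concordant_dependent_genes <- function(mat, samples, cfg = de_config(),
                                       test_fun = NULL) {
  need <- c("control", "kdA", "kdB")
  missing_cond <- setdiff(need, unique(samples$condition))
  if (length(missing_cond) > 0L)
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "))
  cols <- lapply(setNames(need, need),
                 function(cc) samples$sample[samples$condition == cc])
  if (any(vapply(cols, length, 0L) < 2L))
    stop("every condition needs >= 2 replicates")
  eps <- cfg$pseudocount
  sub <- lapply(cols, function(cn) mat[, cn, drop = FALSE])
  mean_ctrl <- rowMeans(sub$control)
  mean_kda <- rowMeans(sub$kdA)
  mean_kdb <- rowMeans(sub$kdB)
  lfc_a <- log2_fold_change(mean_kda, mean_ctrl, eps)
  lfc_b <- log2_fold_change(mean_kdb, mean_ctrl, eps)
  if (is.null(test_fun)) {
    lg <- lapply(sub, function(m) log2(m + eps))
    mns <- lapply(lg, rowMeans)
    vars <- lapply(lg, function(m) apply(m, 1L, stats::var))
    ns <- vapply(lg, ncol, 0L)
    p_a <- .welch_p(mns$control, mns$kdA, vars$control, vars$kdA,
                    ns[["control"]], ns[["kdA"]])
    p_b <- .welch_p(mns$control, mns$kdB, vars$control, vars$kdB,
                    ns[["control"]], ns[["kdB"]])
  } else {
    p_a <- vapply(seq_len(nrow(mat)), function(i)
      test_fun(sub$control[i, ], sub$kdA[i, ], eps), 0.0)
    p_b <- vapply(seq_len(nrow(mat)), function(i)
      test_fun(sub$control[i, ], sub$kdB[i, ], eps), 0.0)
  }
  lthr <- log2(cfg$fc_threshold)
  pass_a <- abs(lfc_a) > lthr & p_a < cfg$alpha
  pass_b <- abs(lfc_b) > lthr & p_b < cfg$alpha
  concord <- sign(lfc_a) == sign(lfc_b) & sign(lfc_a) != 0
  dependent <- pass_a & pass_b & concord
  direction <- rep(NA_character_, nrow(mat))
  direction[dependent] <- ifelse(lfc_a[dependent] > 0, "up", "down")
  data.frame(gene_id = rownames(mat),
             mean_ctrl = mean_ctrl, mean_kda = mean_kda,
             mean_kdb = mean_kdb,
             log2fc_a = lfc_a, log2fc_b = lfc_b,
             p_a = p_a, p_b = p_b,
             direction = direction, dependent = dependent,
             stringsAsFactors = FALSE, row.names = NULL)
}
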