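# Independent brute-force oracles used to check the package's fast paths.
# Deliberately written with different primitives than the implementation.

# Per-base loop: sum the coverage value at every base of the peak.
bf_peak_intensity <- function(peak_start, peak_end, cov_df) {
  # peak_* 1-based closed; cov_df: start, end (1-based closed), score
  total <- 0
  for (pos in peak_start:peak_end) {
    for (i in seq_len(nrow(cov_df))) {
      if (pos >= cov_df$start[i] && pos <= cov_df$end[i]) {
        total <- total + cov_df$score[i]
        break
      }
    }
  }
  total
}

# Average-tied ranks without base::rank: r_i = (#{x < x_i} + 1 + #{x <= x_i}) / 2
bf_ranks <- function(x) {
  vapply(x, function(xi) (sum(x < xi) + 1 + sum(x <= xi)) / 2, 0.0)
}

# Pearson by the summation formula on brute-force ranks.
bf_spearman_rho <- function(x, y) {
  rx <- bf_ranks(x); ry <- bf_ranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Exact two-sided permutation p for small n by recursive enumeration in R.
bf_perm_pvalue <- function(x, y) {
  rx <- bf_ranks(x); ry <- bf_ranks(y)
  rho_obs <- bf_spearman_rho(x, y)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  all_p <- perms(ry)
  rhos <- vapply(all_p, function(p) {
    n <- length(rx)
    num <- sum(rx * p) - n * mean(rx) * mean(p)
    den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(p^2) - n * mean(p)^2))
    num / den
  }, 0.0)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Upper-tail hypergeometric by full enumeration of all C(N, n) draws.
# Gene set is taken as the first K of N labelled elements.
bf_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(if (k <= 0L) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# All-pairs window classifier on plain integers, 1-based closed coords.
# Distal is strict: 0 < gap < distal_limit.
bf_classify <- function(p_start, p_end, t_start, t_end, strand,
                        flank = 5000L, limit = 25000L) {
  t0 <- if (strand == "+") t_start else t_end
  w_lo <- t0 - flank; w_hi <- t0 + flank - 1L
  if (p_start <= w_hi && w_lo <= p_end) return("promoter")
  if (p_start <= t_end && t_start <= p_end) return("gene_body")
  gap <- if (p_end < t_start) t_start - p_end - 1L
         else if (p_start > t_end) p_start - t_end - 1L else 0L
  if (gap > 0L && gap < limit) return("distal")
  "none"
}

# Small deterministic GRanges builder.
gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

# Tiny simulation config used across tests (fast; layout still valid).
small_sim <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_genes = 60L, n_peaks_a = 100L,
               n_bound_genes = 30L, n_planted_activated = 8L,
               n_planted_repressed = 8L, n_dependent_unbound = 4L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cotarget::sim_config, args)
}
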