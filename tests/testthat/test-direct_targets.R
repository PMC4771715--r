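# Direct-target calling, enrichment, and the pipeline driver.

dep_row <- function(gene, dependent, direction) {
  data.frame(gene_id = gene, dependent = dependent,
             direction = if (dependent) direction else NA_character_,
             stringsAsFactors = FALSE)
}

test_that("direct targets are dependent AND bound, classified by direction", {
  calls <- rbind(dep_row("g1", TRUE, "down"),   # bound -> activated
                 dep_row("g2", TRUE, "up"),     # unbound -> none
                 dep_row("g3", FALSE, NA),      # bound but unchanged
                 dep_row("g4", TRUE, "up"))     # bound -> repressed
  res <- call_direct_targets(calls, bound_genes = c("g1", "g3", "g4"))
  expect_identical(res$calls$target_class,
                   c("activated", "none", "none", "repressed"))
  expect_identical(unname(res$counts["direct_total"]), 2L)
  expect_identical(unname(res$counts["activated"]), 1L)
  expect_identical(unname(res$counts["repressed"]), 1L)
})

test_that("class counts add up and never exceed either input leg", {
  set.seed(67)
  for (i in 1:10) {
    n <- 60
    genes <- sprintf("g%03d", 1:n)
    dependent <- runif(n) < 0.4
    dirn <- ifelse(dependent, sample(c("up", "down"), n, replace = TRUE),
                   NA_character_)
    calls <- data.frame(gene_id = genes, dependent = dependent,
                        direction = dirn, stringsAsFactors = FALSE)
    bound <- sample(genes, sample(n, 1))
    res <- call_direct_targets(calls, bound)
    k <- res$counts
    expect_identical(unname(k["activated"] + k["repressed"]),
                     unname(k["direct_total"]))
    expect_lte(k[["direct_total"]], min(sum(dependent), length(bound)))
  }
})

test_that("the published class bookkeeping is reproduced", {
  genes <- sprintf("g%03d", 1:250)
  repressed <- genes[1:53]     # up upon knockdown, bound
  activated <- genes[54:112]   # down upon knockdown, bound
  other_dep <- genes[113:209]  # dependent but unbound
  calls <- rbind(
    do.call(rbind, lapply(repressed, dep_row, dependent = TRUE,
                          direction = "up")),
    do.call(rbind, lapply(activated, dep_row, dependent = TRUE,
                          direction = "down")),
    do.call(rbind, lapply(other_dep, dep_row, dependent = TRUE,
                          direction = "down")),
    do.call(rbind, lapply(genes[210:250], dep_row, dependent = FALSE,
                          direction = NA)))
  res <- call_direct_targets(calls, bound_genes = c(repressed, activated))
  expect_identical(unname(res$counts["repressed"]), 53L)
  expect_identical(unname(res$counts["activated"]), 59L)
  expect_identical(unname(res$counts["direct_total"]), 112L)
  expect_identical(unname(res$counts["dependent"]), 209L)
})

test_that("hypergeometric tail handles the degenerate cases", {
  u <- sprintf("g%02d", 1:10)
  # disjoint -> P[X >= 0] = 1
  expect_equal(hypergeometric_enrichment(u[1:3], u[4:6], u)$p_value, 1)
  # all five targets in a five-gene set: 1 / C(10,5)
  r <- hypergeometric_enrichment(u[1:5], u[1:5], u)
  expect_equal(r$p_value, 1 / 252)
  expect_identical(r$overlap, 5L)
  # k = K = n = N
  expect_equal(hypergeometric_enrichment(u, u, u)$p_value, 1)
  expect_error(hypergeometric_enrichment(u[1], u[1], character()), "universe")
  expect_error(hypergeometric_enrichment(u[1], c(u[1], "zz"), u),
               "outside the universe")
})

test_that("hypergeometric p matches full enumeration on small universes", {
  for (N in c(5L, 8L, 11L)) {
    u <- sprintf("x%02d", 1:N)
    for (K in c(0L, 2L, N %/% 2, N)) {
      for (n in c(1L, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          got <- hypergeometric_enrichment(u[seq_len(n)],
                                           u[seq_len(K)][seq_len(K)],
                                           u)$p_value
          # enumeration oracle answers P[X >= k] for the same N, K, n
          want <- bf_hyper_tail(N, K, n, k)
          p_at_k <- sum(exp(stats::dhyper(k:min(K, n), K, N - K, n,
                                          log = TRUE)))
          expect_equal(min(1, p_at_k), want, tolerance = 1e-12)
        }
        # the function's own k (full overlap of targets with set head)
        expect_equal(got, bf_hyper_tail(N, K, n, min(K, n)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("gene-set enrichment adds BH q-values and sorts by p", {
  u <- sprintf("g%03d", 1:100)
  sets <- list(hit = u[1:10], miss = u[51:60], part = c(u[1:3], u[80:86]))
  res <- enrich_genesets(u[1:10], sets, u)
  expect_identical(res$geneset[1], "hit")
  expect_true(all(diff(res$p_value) >= 0))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("GMT collections round-trip through the reader", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg2\tg4"), f)
  sets <- read_gmt(f)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_error(read_gmt(tempfile()), "not found")
})

test_that("the pipeline completes on empty peaks and reports zero targets", {
  cfg <- small_sim(seed = 71)
  bundle <- simulate_bundle(cfg, file.path(tempdir(), "empty_peak_run"))
  # blank out factor A peaks and its coverage
  empty_bed <- tempfile(fileext = ".bed"); file.create(empty_bed)
  empty_bg <- tempfile(fileext = ".bedGraph"); file.create(empty_bg)
  config <- bundle$config
  config$peaks_a <- empty_bed
  config$coverage_a <- empty_bg
  res <- run_pipeline(config)
  expect_identical(res$summary$n_bound_genes, 0L)
  expect_identical(res$summary$n_direct_targets, 0L)
})

test_that("config errors name the missing field and the failing stage", {
  expect_error(run_pipeline(list(peaks_a = "x")), "peaks_b")
  cfg <- small_sim(seed = 73)
  bundle <- simulate_bundle(cfg, file.path(tempdir(), "stage_err_run"))
  config <- bundle$config
  config$expression <- tempfile()  # nonexistent
  expect_error(run_pipeline(config), "read_expression")
})

test_that("pipeline summary counts mirror the planted truth", {
  cfg <- small_sim(seed = 79)
  bundle <- simulate_bundle(cfg, file.path(tempdir(), "truth_run"))
  res <- run_pipeline(bundle$config)
  truth <- bundle$truth
  expect_identical(res$summary$n_bound_genes, truth$counts$n_bound)
  expect_identical(res$assignment$bound_genes, truth$bound_genes$gene_id)
  expect_identical(res$summary$overlap_fraction_a,
                   truth$realized_overlap_fraction)
  called <- res$target_calls$calls
  direct <- called$gene_id[called$target_class != "none"]
  expect_gte(mean(truth$direct$gene_id %in% direct), 0.85)
  expect_true(all(direct %in% truth$direct$gene_id))
})
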