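# Seeded generators: determinism, layout guarantees, planted-truth
# consistency, and calibration.

test_that("generated annotations keep genes far apart and alternate strands", {
  cfg <- small_sim(seed = 5)
  anno <- generate_annotation(cfg)
  expect_length(anno, cfg$n_genes)
  # exhaustive pairwise gap scan: every inter-transcript gap exceeds
  # twice the combined window reach
  gaps <- start(anno)[-1] - end(anno)[-length(anno)] - 1L
  expect_true(all(gaps > 2L * (cfg$promoter_flank + cfg$distal_limit)))
  expect_identical(unique(as.character(strand(anno))), c("+", "-"))
  expect_length(generate_annotation(small_sim(n_genes = 0L,
                                              n_bound_genes = 0L,
                                              n_planted_activated = 0L,
                                              n_planted_repressed = 0L,
                                              n_dependent_unbound = 0L,
                                              n_peaks_a = 0L,
                                              n_peaks_b = 0L)), 0L)
})

test_that("undersized contigs are rejected with the required minimum", {
  expect_error(generate_annotation(small_sim(chrom_length = 1000)),
               "need >=")
})

test_that("identical seeds give byte-identical fixture files", {
  cfg <- small_sim(seed = 9)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  simulate_bundle(small_sim(seed = 10), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "peaks_a.bed"))),
                         unname(tools::md5sum(file.path(d3, "peaks_a.bed")))))
})

test_that("generated files round-trip into the in-memory objects", {
  cfg <- small_sim(seed = 15)
  out <- file.path(tempdir(), "roundtrip")
  bundle <- simulate_bundle(cfg, out)
  pk <- read_peaks(bundle$config$peaks_a)
  expect_identical(granges(pk), granges(bundle$objects$peaks_a))
  expect_identical(pk$name, bundle$objects$peaks_a$name)
  anno <- read_annotation(bundle$config$annotation)
  expect_identical(granges(anno), granges(bundle$objects$annotation))
  cov <- read_coverage(bundle$config$coverage_b)
  expect_identical(granges(cov), granges(bundle$objects$coverage_b))
  expect_equal(cov$score, bundle$objects$coverage_b$score)
  expr <- read_expression(bundle$config$expression, bundle$config$samples)
  expect_equal(expr$matrix, bundle$objects$expression)
  expect_identical(expr$samples, bundle$objects$samples)
})

test_that("coverage pileups return every planted intensity exactly", {
  cfg <- small_sim(seed = 21)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  expect_identical(peak_intensity(occ$peaks_a, occ$coverage_a),
                   as.numeric(occ$peaks_a$intensity))
  expect_identical(peak_intensity(occ$peaks_b, occ$coverage_b),
                   as.numeric(occ$peaks_b$intensity))
})

test_that("planted bound genes re-derive exactly via peak assignment", {
  cfg <- small_sim(seed = 27)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  res <- assign_peaks(occ$peaks_a, anno,
                      assignment_config(cfg$promoter_flank,
                                        cfg$distal_limit))
  expect_identical(res$bound_genes, occ$truth$bound_genes$gene_id)
})

test_that("overlap fraction and intensity correlation hit their targets", {
  cfg <- small_sim(seed = 33, n_peaks_a = 200L)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  v <- venn_decompose(occ$peaks_a, occ$peaks_b)
  expect_identical(v$a_overlapping_b, as.integer(round(0.61 * 200)))
  expect_equal(occ$truth$realized_overlap_fraction, v$fraction_a)
  # rank correlation of planted pair intensities near the copula target
  expect_lt(abs(occ$truth$realized_intensity_rho - 0.84), 0.15)
  # zero target -> no overlapping peaks at all
  cfg0 <- small_sim(seed = 35, target_overlap_fraction = 0)
  occ0 <- generate_cooccupied_peaks(cfg0, generate_annotation(cfg0))
  expect_identical(venn_decompose(occ0$peaks_a,
                                  occ0$peaks_b)$a_overlapping_b, 0L)
})

test_that("null simulations (fold effect 1) produce alpha-level calls", {
  cfg <- small_sim(seed = 39, n_genes = 150L, n_bound_genes = 40L,
                   n_planted_activated = 10L, n_planted_repressed = 10L,
                   effect_fold = 1)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  expr <- generate_knockdown_expression(cfg, anno, occ$truth)
  calls <- concordant_dependent_genes(expr$matrix, expr$samples)
  # the concordance + fold gates push the null call rate far below alpha
  expect_lte(mean(calls$dependent), 0.05)
})

test_that("expression effects land on the planted genes in both hairpins", {
  cfg <- small_sim(seed = 45)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  expr <- generate_knockdown_expression(cfg, anno, occ$truth)
  truth <- expr$planted$dependent
  mat <- expr$matrix
  ctrl <- rowMeans(mat[, 1:3]); kda <- rowMeans(mat[, 4:6])
  ratio <- kda[truth$gene_id] / ctrl[truth$gene_id]
  expect_true(all(ratio[truth$direction == "down"] < 0.6))
  expect_true(all(ratio[truth$direction == "up"] > 1.7))
  # planted direct targets are exactly the bound intersect dependent genes
  expect_identical(expr$planted$direct$gene_id,
                   intersect(truth$gene_id, occ$truth$bound_genes$gene_id))
})
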