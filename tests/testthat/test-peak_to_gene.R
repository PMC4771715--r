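# Window-based peak classification and gene assignment.

test_that("windows classify with promoter > gene body > distal precedence", {
  txp <- gr("c", 100001, 150000, "+", gene_id = "g1", transcript_id = "t1")
  cfg <- assignment_config()
  # inside the -5 kb flank of the TSS
  expect_identical(
    as.character(classify_peak_vs_transcript(gr("c", 99001, 99500), txp,
                                             cfg)$category), "promoter")
  # inside the span, past the +5 kb promoter edge
  expect_identical(
    as.character(classify_peak_vs_transcript(gr("c", 120001, 121000), txp,
                                             cfg)$category), "gene_body")
  # ends 10 kb upstream of the transcript start
  r <- classify_peak_vs_transcript(gr("c", 89001, 90000), txp, cfg)
  expect_identical(as.character(r$category), "distal")
  expect_identical(r$distance, 10000L)
  # different chromosome -> none
  expect_identical(
    as.character(classify_peak_vs_transcript(gr("c2", 99001, 99500), txp,
                                             cfg)$category), "none")
})

test_that("the distal cutoff is strict: 25 kb away is no longer assigned", {
  txp <- gr("c", 200001, 210000, "+", gene_id = "g", transcript_id = "t")
  # gap of exactly 25000 bases -> none; 24999 -> distal
  at_gap <- function(g) gr("c", 200001 - g - 500, 200000 - g)
  expect_identical(
    as.character(classify_peak_vs_transcript(at_gap(25000), txp)$category),
    "none")
  r <- classify_peak_vs_transcript(at_gap(24999), txp)
  expect_identical(as.character(r$category), "distal")
  expect_identical(r$distance, 24999L)
})

test_that("minus-strand promoters anchor at the high-coordinate TSS", {
  txm <- gr("c", 100001, 150000, "-", gene_id = "g", transcript_id = "t")
  # 3 kb beyond the transcript end = upstream of a minus-strand gene
  expect_identical(
    as.character(classify_peak_vs_transcript(gr("c", 152001, 153000),
                                             txm)$category), "promoter")
  # near the low-coordinate end: 3' side, inside the span -> gene body
  expect_identical(
    as.character(classify_peak_vs_transcript(gr("c", 110001, 111000),
                                             txm)$category), "gene_body")
})

test_that("a peak can bind two genes; far peaks bind none", {
  txs <- c(gr("c", 10001, 30000, "+", gene_id = "gA", transcript_id = "tA"),
           gr("c", 32001, 60000, "+", gene_id = "gB", transcript_id = "tB"))
  # overlaps the TSS windows of neither... place between: promoter window of
  # gB is [27001, 37000]; gene body of gA covers 15001..30000
  both <- assign_peaks(gr("c", 28001, 28400), txs)
  expect_setequal(both$bound_genes, c("gA", "gB"))
  none <- assign_peaks(gr("c", 500001, 500400), txs)
  expect_identical(none$bound_genes, character())
})

test_that("equidistant distal peaks are assigned to both genes and flagged", {
  txs <- c(gr("c", 1, 10000, "+", gene_id = "gL", transcript_id = "tL"),
           gr("c", 50001, 60000, "+", gene_id = "gR", transcript_id = "tR"))
  # midpoint peak: gaps of 10000 on both sides (promoter windows end at
  # coordinate 6000 on the left gene TSS.. see strict windows)
  peak <- gr("c", 20001, 40000)  # 10000 gap to gL end, 10000 to gR start
  res <- assign_peaks(peak, txs)
  distal <- res$assignments[res$assignments$category == "distal", ]
  expect_setequal(distal$gene_id, c("gL", "gR"))
  expect_true(all(distal$tied))
  expect_equal(unique(distal$distance), 10000L)
})

test_that("assignment agrees with a brute-force all-pairs classifier", {
  set.seed(37)
  n_tx <- 40
  starts <- sort(sample(seq(1, 3e6, by = 1000), n_tx))
  txs <- gr("c", starts, starts + sample(2000:20000, n_tx, replace = TRUE),
            strand = sample(c("+", "-"), n_tx, replace = TRUE),
            gene_id = sprintf("g%02d", 1:n_tx),
            transcript_id = sprintf("t%02d", 1:n_tx))
  ps <- sample(seq(1, 3e6, by = 37), 150)
  peaks <- gr("c", ps, ps + 400, name = sprintf("p%03d", 1:150))
  res <- assign_peaks(peaks, txs)
  got <- res$assignments[, c("peak_id", "transcript_id", "category")]
  want <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    rows <- lapply(seq_along(txs), function(j) {
      cat <- bf_classify(start(peaks)[i], end(peaks)[i],
                         start(txs)[j], end(txs)[j],
                         as.character(strand(txs))[j])
      if (cat == "none") return(NULL)
      data.frame(peak_id = peaks$name[i], transcript_id = txs$transcript_id[j],
                 category = cat, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  key <- function(d) sort(paste(d$peak_id, d$transcript_id, d$category))
  expect_identical(key(got), key(want))
})

test_that("bound genes grow monotonically with the distal limit", {
  set.seed(41)
  starts <- sort(sample(seq(1, 2e6, by = 500), 30))
  txs <- gr("c", starts, starts + 5000,
            strand = rep(c("+", "-"), 15),
            gene_id = sprintf("g%02d", 1:30),
            transcript_id = sprintf("t%02d", 1:30))
  ps <- sample(seq(1, 2e6, by = 71), 100)
  peaks <- gr("c", ps, ps + 300)
  prev <- character()
  for (lim in c(5000, 10000, 25000, 50000)) {
    cur <- assign_peaks(peaks, txs, assignment_config(5000, lim))$bound_genes
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("promoter-planted fixtures yield exactly the planted bound genes", {
  cfg <- small_sim(seed = 3, n_genes = 100L, n_peaks_a = 40L,
                   n_bound_genes = 40L, n_planted_activated = 5L,
                   n_planted_repressed = 5L, n_dependent_unbound = 2L)
  anno <- generate_annotation(cfg)
  occ <- generate_cooccupied_peaks(cfg, anno)
  res <- assign_peaks(occ$peaks_a, anno)
  expect_identical(res$bound_genes, occ$truth$bound_genes$gene_id)
  expect_identical(length(res$bound_genes), 40L)
  expect_true(all(res$gene_best$category == "promoter"))
})
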