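test_that("zero-noise cohorts pin planted group means exactly", {
  cfg <- small_config(seed = 5, noise_sd = 0, severity_step = 1)
  co <- simulate_cohort(cfg)
  lv <- co$sample_labels
  # planted miRNAs fall by exactly one unit per severity level
  for (f in head(co$truth$informative$mirna, 4)) {
    means <- tapply(co$matrices$mirna[, f], lv, mean)
    expect_equal(as.numeric(diff(means)), c(-1, -1, -1), tolerance = 1e-12)
  }
  # informative mRNA markers rise by the same step
  f <- co$truth$informative$mrna[1]
  means <- tapply(co$matrices$mrna[, f], lv, mean)
  expect_equal(as.numeric(diff(means)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("simulation is a pure function of its config", {
  a <- simulate_cohort(small_config(seed = 11))
  b <- simulate_cohort(small_config(seed = 11))
  expect_identical(a$matrices, b$matrices)
  expect_identical(a$planted_pairs, b$planted_pairs)
  c2 <- simulate_cohort(small_config(seed = 12))
  expect_false(identical(a$matrices$mrna, c2$matrices$mrna))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_normal = 0), "positive")
  expect_error(simulation_config(subtype_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_features = c(mrna = 300, mirna = 300,
                                                lncrna = 200)),
               "missing platform")
  expect_error(simulation_config(n_features = c(mrna = 30, mirna = 300,
                                                lncrna = 200, circrna = 100),
                                 n_signature_genes = 20),
               "too small")
})

test_that("planted miRNA-mRNA pairs are strongly negatively correlated", {
  # Monte-Carlo over replicate study-sized cohorts at default effects
  rs <- unlist(lapply(1:30, function(s) {
    co <- simulate_cohort(simulation_config(seed = s))
    vapply(seq_len(nrow(co$planted_pairs)), function(i) {
      cor(co$matrices$mirna[, co$planted_pairs$mirna[i]],
          co$matrices$mrna[, co$planted_pairs$mrna[i]])
    }, numeric(1))
  }))
  expect_lt(mean(rs), -0.3)
  expect_lt(max(rs), 0)  # every planted pair, every replicate
})

test_that("planted monotone ordering is empirically recoverable", {
  co <- simulate_cohort(simulation_config(seed = 21))
  lv <- co$sample_labels
  ok <- vapply(co$truth$informative$mrna, function(f) {
    all(diff(tapply(co$matrices$mrna[, f], lv, mean)) > 0)
  }, logical(1))
  ok_mir <- vapply(co$truth$informative$mirna, function(f) {
    all(diff(tapply(co$matrices$mirna[, f], lv, mean)) < 0)
  }, logical(1))
  expect_gte(mean(c(ok, ok_mir)), 0.95)
})

test_that("count mode yields nonnegative integer matrices", {
  co <- simulate_cohort(small_config(seed = 3, mode = "counts"))
  m <- co$matrices$mrna
  expect_true(all(m >= 0))
  expect_identical(m, round(m))
})

test_that("single-cell markers are elevated in their own type", {
  spec <- list(A = stats::setNames(rep(3, 10), sprintf("G%04d", 1:10)),
               B = stats::setNames(rep(3, 10), sprintf("G%04d", 11:20)),
               C = stats::setNames(rep(3, 10), sprintf("G%04d", 21:30)))
  hits <- vapply(1:10, function(s) {
    sc <- simulate_single_cell(200, 50, c("A", "B", "C"), spec, seed = s)
    mk <- find_markers(sc$matrix, sc$labels)
    top <- mk[mk$cell_type == "A", ]
    top10 <- top$gene[order(-top$log2FC)][1:10]
    sum(names(spec$A) %in% top10)
  }, numeric(1))
  expect_gte(mean(hits == 10), 0.9)  # planted markers fill the top-10
})

test_that("single-cell simulator rejects ambiguous marker assignment", {
  spec <- list(A = c(G0001 = 2), B = c(G0001 = 3))
  expect_error(simulate_single_cell(20, 10, c("A", "B"), spec),
               "more than one cell type")
})

test_that("null marker elevation gives no systematic fold change", {
  spec <- list(A = stats::setNames(rep(0, 5), sprintf("G%04d", 1:5)))
  sc <- simulate_single_cell(100, 20, c("A", "B"), spec, seed = 2)
  mk <- find_markers(sc$matrix, sc$labels)
  expect_lt(max(abs(mk$log2FC[mk$gene %in% names(spec$A)])), 0.5)
})

test_that("interaction tables hold planted pairs plus unique decoys", {
  cfg <- small_config(seed = 9)
  co <- simulate_cohort(cfg)
  tab <- simulate_interaction_table(co, cfg)
  expect_equal(nrow(tab), cfg$n_planted_pairs + cfg$n_decoy_pairs)
  expect_false(anyDuplicated(tab) > 0)
  expect_true(all(paste(co$planted_pairs$mirna, co$planted_pairs$mrna) %in%
                    paste(tab$mirna, tab$mrna)))
  # no decoys -> exactly the planted pairs
  cfg0 <- small_config(seed = 9, n_decoy_pairs = 0)
  expect_identical(simulate_interaction_table(co, cfg0), co$planted_pairs)
  # determinism
  expect_identical(tab, simulate_interaction_table(co, cfg))
  # more decoys than background combinations exist
  cfg_big <- small_config(seed = 9, n_decoy_pairs = 1e6)
  expect_error(simulate_interaction_table(co, cfg_big), "background")
})

test_that("cohorts round-trip through delimited files", {
  cfg <- small_config(seed = 13)
  co <- simulate_cohort(cfg)
  tab <- simulate_interaction_table(co, cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, tab)
  expect_length(readLines(file.path(dir, "signatures.gmt")), 2)
  back <- read_cohort(dir)
  for (p in names(co$matrices))
    expect_equal(back$matrices[[p]], co$matrices[[p]])
  expect_equal(as.character(back$sample_labels),
               as.character(co$sample_labels))
  expect_identical(back$signature_gene_sets$exocrine,
                   co$signature_gene_sets$exocrine)
  expect_error(write_cohort(co, ""), "nonempty")
})

test_that("GMT writer round-trips and agrees with an established reader", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_identical(read_gmt(f), sets)
  skip_if_not_installed("fgsea")
  expect_identical(fgsea::gmtPathways(f), sets)
})
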