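test_that("hand-computed fold example yields exactly one call", {
  # one individual, 10 samples: taxon X at 0.10 once and 0.01 nine times
  # mean = 0.019, fold = 0.10/0.019 = 5.26 > 5 -> one call
  x <- c(0.10, rep(0.01, 9))
  m <- rbind(X = x, Y = 1 - x)
  colnames(m) <- sprintf("s%02d", 1:10)
  tab <- toy_table(m)
  meta <- toy_metadata(colnames(m), rep("P1", 10), 24202 + 0:9)
  calls <- detect_blooms(tab, meta, fold_threshold = 5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sample_id, "s01")
  expect_equal(calls$taxon, "X")
  expect_equal(calls$individual_mean, 0.019)
  expect_equal(calls$fold, 0.10 / 0.019)
})

test_that("constant and absent taxa never bloom", {
  m <- rbind(A = rep(0.10, 6), B = rep(0.90, 6), C = rep(0, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  tab <- toy_table(m)
  meta <- toy_metadata(colnames(m), rep("P1", 6), 24202 + 0:5)
  expect_equal(nrow(detect_blooms(tab, meta)), 0L)
})

test_that("call set matches the naive triple-loop oracle on random cohorts", {
  for (seed in 1:10) {
    m <- random_rel_matrix(10, 20, seed)
    set.seed(seed + 500)
    ind <- sample(c("P1", "P2", "P3"), 20, replace = TRUE)
    meta <- toy_metadata(colnames(m), ind, seq_len(20) + 24000)
    calls <- detect_blooms(toy_table(m), meta, fold_threshold = 5)
    oracle <- brute_blooms(m, ind, threshold = 5)
    expect_identical(
      as.data.frame(calls[c("individual_id", "sample_id", "taxon")]),
      `rownames<-`(oracle, NULL))
  }
})

test_that("raising the fold threshold never adds calls", {
  m <- random_rel_matrix(12, 18, 42)
  meta <- toy_metadata(colnames(m), rep(c("P1", "P2"), each = 9), seq_len(18) + 24000)
  tab <- toy_table(m)
  n_calls <- purrr::map_int(c(2, 3, 5, 8, 13),
                            ~ nrow(detect_blooms(tab, meta, fold_threshold = .x)))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("per-taxon rescaling removed by closure leaves calls unchanged", {
  m <- random_rel_matrix(8, 12, 7)
  meta <- toy_metadata(colnames(m), rep("P1", 12), seq_len(12) + 24000)
  base <- detect_blooms(toy_table(m), meta)
  scaled <- sweep(m, 2L, runif(12, 0.5, 2), "*")    # per-sample scaling
  scaled <- sweep(scaled, 2L, colSums(scaled), "/") # closure restores columns
  again <- detect_blooms(toy_table(scaled), meta)
  expect_identical(base[c("sample_id", "taxon")], again[c("sample_id", "taxon")])
})

test_that("ties at exactly the threshold are not blooms", {
  # taxon at 0.05 in one sample, 0.01 in four others: mean 0.018; pick
  # threshold so abundance == threshold * mean exactly
  x <- c(0.05, rep(0.01, 4))
  m <- rbind(X = x, Y = 1 - x)
  colnames(m) <- sprintf("s%d", 1:5)
  meta <- toy_metadata(colnames(m), rep("P1", 5), 24202 + 0:4)
  thr <- 0.05 / mean(x)
  expect_equal(nrow(detect_blooms(toy_table(m), meta, fold_threshold = thr)), 0L)
  expect_equal(nrow(detect_blooms(toy_table(m), meta, fold_threshold = thr * 0.999)), 1L)
})

test_that("summaries count samples once and split per-taxon by individual", {
  calls <- tibble::tibble(
    individual_id = c("P1", "P1", "P1", "P2"),
    sample_id = c("s1", "s1", "s1", "s9"),
    taxon = c("A", "B", "C", "A"),
    abundance = 0.2, individual_mean = 0.01, fold = 20)
  meta <- toy_metadata(sprintf("s%d", 1:10),
                       rep(c("P1", "P2"), each = 5), 24202 + 0:9)
  s <- summarize_blooms(calls, meta, level = "genus")
  expect_equal(s$n_samples_with_bloom, 2L)
  expect_equal(s$fraction_samples_with_bloom, 0.2)
  expect_equal(s$n_taxa_blooming, 3L)
  expect_equal(sum(s$per_taxon$n_blooms), nrow(calls))

  empty <- summarize_blooms(calls[0, ], meta)
  expect_equal(empty$n_samples_with_bloom, 0L)
  expect_equal(empty$n_taxa_blooming, 0L)
})

test_that("bloom fraction recovers the injection rate on synthetic cohorts", {
  # ~200 samples, injection probability 0.1, fold far above threshold
  cfg <- sim_config(n_individuals = 7, n_taxa = 40,
                    samples_per_individual = c(28, 31),
                    bloom_prob = 0.1, bloom_fold = 100,
                    drift_sd = 0, retention_decay = 0,
                    seq_depth = 20000, rng_seed = 31)
  ch <- simulate_cohort(cfg)
  n <- length(sample_ids(ch$counts))
  calls <- detect_blooms(as_relative(ch$counts), ch$metadata, fold_threshold = 5)
  # most injected bloom samples are recovered (dominant-taxon injections can
  # be capped below 5x by closure; rare-taxon count noise can add a call)
  injected <- unique(ch$truth$blooms$sample_id)
  expect_gt(mean(injected %in% calls$sample_id), 0.8)
  frac <- dplyr::n_distinct(calls$sample_id) / n
  ci <- 0.1 + c(-1, 1) * 1.96 * sqrt(0.1 * 0.9 / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})
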