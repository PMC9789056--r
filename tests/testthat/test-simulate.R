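test_that("identical seeds give identical cohorts, different seeds differ", {
  cfg <- sim_config(n_individuals = 2, n_taxa = 15,
                    samples_per_individual = c(5, 8), seq_depth = 500, rng_seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(abund_matrix(a$counts), abund_matrix(b$counts))
  expect_identical(as.data.frame(a$metadata), as.data.frame(b$metadata))
  cfg2 <- sim_config(n_individuals = 2, n_taxa = 15,
                     samples_per_individual = c(5, 8), seq_depth = 500, rng_seed = 12)
  expect_false(identical(abund_matrix(a$counts),
                         abund_matrix(simulate_cohort(cfg2)$counts)))
})

test_that("count columns sum exactly to the sequencing depth", {
  ch <- simulate_cohort(sim_config(n_individuals = 3, n_taxa = 20,
                                   samples_per_individual = c(5, 10),
                                   seq_depth = 1234, rng_seed = 2))
  expect_true(all(colSums(abund_matrix(ch$counts)) == 1234))
  expect_identical(abund_mode(ch$counts), "counts")
})

test_that("a static community yields near-zero within-individual dissimilarity", {
  ch <- simulate_cohort(sim_config(n_individuals = 1, n_taxa = 20,
                                   months = list(24202:24211),
                                   drift_sd = 0, bloom_prob = 0, retention_decay = 0,
                                   seq_depth = 200000, rng_seed = 3))
  dm <- bray_curtis(as_relative(ch$counts))
  expect_lt(max(dm), 0.02)
})

test_that("forced blooms in non-dominant taxa are detected by the >5x rule", {
  cfg <- sim_config(n_individuals = 2, n_taxa = 25,
                    samples_per_individual = c(8, 10),
                    bloom_prob = 1, bloom_fold = 50,
                    drift_sd = 0.05, retention_decay = 0,
                    seq_depth = 50000, rng_seed = 4)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$truth$blooms), length(sample_ids(ch$counts)))
  calls <- detect_blooms(as_relative(ch$counts), ch$metadata, fold_threshold = 5)
  # a 50-fold bloom cannot exceed 5x the individual mean when the taxon is
  # already dominant (closure caps it) or blooms repeatedly (each bloom
  # inflates the mean the others are judged against); every singleton bloom
  # of a minor taxon must be recovered
  mean_of <- function(ind, taxon) mean(ch$truth$latent[[ind]][taxon, ])
  truth <- ch$truth$blooms
  truth$ind <- ch$metadata$individual_id[match(truth$sample_id, ch$metadata$sample_id)]
  n_blooms_of_taxon <- stats::ave(rep(1, nrow(truth)),
                                  paste(truth$ind, truth$taxon), FUN = sum)
  detectable <- n_blooms_of_taxon == 1 &
    purrr::map_dbl(seq_len(nrow(truth)),
                   ~ mean_of(truth$ind[.x], truth$taxon[.x])) < 0.03
  hit <- purrr::map_lgl(seq_len(nrow(truth)), function(i) {
    any(calls$sample_id == truth$sample_id[i] & calls$taxon == truth$taxon[i])
  })
  expect_true(all(hit[detectable]))
  expect_gt(mean(hit), 0.3)
})

test_that("separated baselines put between-individual above within-individual dissimilarity", {
  gaps <- purrr::map_dbl(1:20, function(s) {
    ch <- simulate_cohort(sim_config(n_individuals = 3, n_taxa = 25,
                                     samples_per_individual = c(5, 6),
                                     baseline_sd = 1.5, drift_sd = 0.05,
                                     bloom_prob = 0, seq_depth = 2000, rng_seed = s))
    pr <- enumerate_pairs(bray_curtis(as_relative(ch$counts)), ch$metadata)
    mean(pr$dissimilarity[pr$group == "D"]) -
      mean(pr$dissimilarity[pr$group != "D"])
  })
  expect_gt(mean(gaps > 0), 0.9)
})

test_that("simulated covariates are seeded and the linked factor tracks identity", {
  ch <- simulate_cohort(sim_config(n_individuals = 4, n_taxa = 15,
                                   samples_per_individual = c(8, 10),
                                   seq_depth = 500, rng_seed = 5))
  a <- simulate_covariates(ch$metadata, linked_factor_effect = 5, rng_seed = 9)
  b <- simulate_covariates(ch$metadata, linked_factor_effect = 5, rng_seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(c("participant_id", "date", "workspace", "drug_use", "yogurt",
                    "fruit", "travel", "blood_pressure", "blood_sugar") %in% names(a)))
  # strong linkage: each individual's modal workspace dominates
  strong <- simulate_covariates(ch$metadata, linked_factor_effect = 1000, rng_seed = 9)
  modal_share <- strong |>
    dplyr::count(individual_id, workspace) |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(share = max(n) / sum(n))
  expect_true(all(modal_share$share > 0.9))
})
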