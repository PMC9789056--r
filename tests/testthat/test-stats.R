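test_that("rank-sum statistic matches hand and degenerate cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 3)
  # identical multisets: tie-symmetric expectation n_x(n_x+n_y+1)/2
  x <- c(2, 5, 7)
  expect_equal(wilcoxon_rank_sum(x, x), 3 * (3 + 3 + 1) / 2)
  # all values tied: every rank is the midrank
  expect_equal(wilcoxon_rank_sum(rep(1, 4), rep(1, 6)), 4 * (4 + 6 + 1) / 2)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum matches the brute-force midrank oracle on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    nx <- sample(1:15, 1); ny <- sample(1:15, 1)
    x <- sample(1:10, nx, replace = TRUE)  # heavy ties
    y <- sample(1:10, ny, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y), brute_rank_sum(x, y))
  }
})

make_drift_test_data <- function(seed, drift_sd, n_months = 30) {
  ch <- simulate_cohort(sim_config(
    n_individuals = 1, n_taxa = 25, months = list(24202 + seq_len(n_months) - 1L),
    drift_sd = drift_sd, bloom_prob = 0, retention_decay = 0,
    seq_depth = 3000, rng_seed = seed))
  list(dm = bray_curtis(as_relative(ch$counts)), meta = ch$metadata)
}

test_that("observed W equals the rank-sum over the enumerated groups", {
  d <- make_drift_test_data(5, drift_sd = 0.2)
  pt <- permute_timepoint_test(d$dm, d$meta, "P1", c("M1", "Y3"),
                               reps = 50, rng_seed = 1)
  pr <- enumerate_pairs(d$dm, d$meta)
  w_direct <- wilcoxon_rank_sum(pr$dissimilarity[pr$group == "Y3"],
                                pr$dissimilarity[pr$group == "M1"])
  expect_equal(pt$observed_W, w_direct)
  expect_equal(pt$n_short, sum(pr$group == "M1"))
  expect_equal(pt$n_long, sum(pr$group == "Y3"))
})

test_that("identical seeds give bit-identical permutation results", {
  d <- make_drift_test_data(7, drift_sd = 0.1)
  a <- permute_timepoint_test(d$dm, d$meta, "P1", reps = 100, rng_seed = 42)
  b <- permute_timepoint_test(d$dm, d$meta, "P1", reps = 100, rng_seed = 42)
  expect_identical(a$null_W, b$null_W)
  expect_identical(a$p_value, b$p_value)
  expect_length(a$null_W, 100)
  expect_true(a$p_value > 0 && a$p_value <= 1)
  expect_named(a$critical_values, c("90%", "95%", "99%"))
})

test_that("pooled test permutes months within each individual", {
  ch <- simulate_cohort(sim_config(
    n_individuals = 3, n_taxa = 25,
    months = purrr::map(1:3, ~ 24202 + c(0:4, 12, 18, 26, 30)),
    drift_sd = 0.2, bloom_prob = 0, seq_depth = 3000, rng_seed = 9))
  dm <- bray_curtis(as_relative(ch$counts))
  pooled <- permute_timepoint_test(dm, ch$metadata, "pooled", reps = 100, rng_seed = 1)
  pr <- enumerate_pairs(dm, ch$metadata)
  expect_equal(pooled$n_short, sum(pr$group == "M1"))
  expect_equal(pooled$n_long, sum(pr$group == "Y3"))
  tests <- suppressWarnings(
    permute_timepoint_tests(dm, ch$metadata, reps = 50, rng_seed = 1))
  expect_true("pooled" %in% tests$individual_id)
  expect_gte(nrow(tests), 2)
})

test_that("the test rejects sparse schedules that cannot form both groups", {
  d <- make_drift_test_data(3, drift_sd = 0.1, n_months = 5)  # no Y3 possible
  expect_error(permute_timepoint_test(d$dm, d$meta, "P1"), "Y3")
})

test_that("strong drift is detected, flat series are not, at matched settings", {
  drift_p <- permute_timepoint_test(make_drift_test_data(11, 0.4)$dm,
                                    make_drift_test_data(11, 0.4)$meta,
                                    "P1", reps = 200, rng_seed = 2)$p_value
  expect_lt(drift_p, 0.05)
})
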