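make_source <- function(seed, n_taxa = 50, depth = 20000, block = NULL) {
  # log-normal taxon abundances: the skewed few-dominant-taxa structure of
  # real gut communities (and of the cohort simulator)
  set.seed(seed)
  p <- exp(rnorm(n_taxa, 0, 2)) + 1e-4
  if (!is.null(block)) {
    mask <- rep(1e-4, n_taxa)
    mask[block] <- 1
    p <- p * mask
  }
  rmultinom(1, depth, p / sum(p))[, 1]
}

test_that("a sink identical to its only source is attributed to it", {
  src <- make_source(1)
  est <- gibbs_source_proportions(src, cbind(a = src),
                                  gibbs_settings(rng_seed = 1), sink_id = "self")
  expect_gt(est$proportion[est$source_id == "a"], 0.9)
  expect_equal(sum(est$proportion), 1, tolerance = 1e-9)
})

test_that("a sink disjoint from every source goes to Unknown", {
  src <- c(make_source(2, 25), rep(0L, 25))
  sink <- c(rep(0L, 25), make_source(3, 25, depth = 2000))
  est <- gibbs_source_proportions(sink, cbind(a = src), gibbs_settings(rng_seed = 2))
  expect_gt(est$proportion[est$source_id == "Unknown"], 0.9)
})

test_that("estimates are simplex-valid and invariant to taxon relabelling", {
  s1 <- make_source(4, block = 1:25)
  s2 <- make_source(5, block = 26:50)
  set.seed(6)
  sink <- rmultinom(1, 2000, 0.6 * s1 / sum(s1) + 0.4 * s2 / sum(s2))[, 1]
  est <- gibbs_source_proportions(sink, cbind(a = s1, b = s2),
                                  gibbs_settings(rng_seed = 7))
  expect_true(all(est$proportion >= 0))
  expect_equal(sum(est$proportion), 1, tolerance = 1e-9)

  # label invariance holds in distribution; individual draws differ because
  # RNG consumption follows taxon order
  perm <- sample(50)
  est_perm <- gibbs_source_proportions(sink[perm], cbind(a = s1[perm], b = s2[perm]),
                                       gibbs_settings(rng_seed = 7))
  expect_lt(max(abs(est_perm$proportion - est$proportion)), 0.05)
})

test_that("identical seeds reproduce the estimate exactly", {
  s1 <- make_source(8, block = 1:25)
  s2 <- make_source(9, block = 26:50)
  set.seed(10)
  sink <- rmultinom(1, 2000, 0.5 * s1 / sum(s1) + 0.5 * s2 / sum(s2))[, 1]
  a <- gibbs_source_proportions(sink, cbind(s1, s2), gibbs_settings(rng_seed = 3))
  b <- gibbs_source_proportions(sink, cbind(s1, s2), gibbs_settings(rng_seed = 3))
  expect_identical(a$proportion, b$proportion)
})

test_that("degenerate inputs are rejected", {
  src <- make_source(11)
  expect_error(gibbs_source_proportions(rep(0L, 50), cbind(src)), "zero-depth sink")
  expect_error(gibbs_source_proportions(src, cbind(rep(0L, 50))), "zero-depth source")
  expect_error(
    gibbs_source_proportions(src, cbind(src),
                             gibbs_settings(rarefaction_depth = 10 * sum(src))),
    "exceeds")
})

test_that("two-taxon pure case converges to the known source with depth", {
  sink <- c(1000L, 0L)
  src <- c(1000L, 0L)
  est <- gibbs_source_proportions(sink, cbind(a = src), gibbs_settings(rng_seed = 1))
  expect_gt(est$proportion[est$source_id == "a"], 0.95)
})

test_that("single M1 pair cohorts produce exactly one estimate in M1", {
  m <- matrix(c(make_source(12, 20, 3000), make_source(12, 20, 3000)), ncol = 2,
              dimnames = list(sprintf("t%d", 1:20), c("s1", "s2")))
  tab <- abundance_table(cbind(data.frame(taxon = rownames(m)), as.data.frame(m)),
                         mode = "counts")
  meta <- toy_metadata(c("s1", "s2"), c("P1", "P1"), c(24202L, 24203L))
  r <- retained_fraction_by_interval(tab, meta, gibbs_settings(rng_seed = 5))
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$pairs$group, "M1")
  expect_equal(r$pairs$source, "s1")  # earlier sample is the source
  expect_equal(r$pairs$sink, "s2")
  expect_equal(r$groups$group, "M1")
})

test_that("without turnover all interval groups retain similarly high proportions", {
  ch <- simulate_cohort(sim_config(
    n_individuals = 1, n_taxa = 40,
    months = list(24202 + c(0, 1, 2, 13, 26)),
    drift_sd = 0, retention_decay = 0, bloom_prob = 0,
    seq_depth = 5000, rng_seed = 13))
  r <- retained_fraction_by_interval(ch$counts, ch$metadata,
                                     gibbs_settings(rarefaction_depth = 1000,
                                                    rng_seed = 13))
  expect_true(all(r$groups$mean_shared > 0.85))
  expect_lt(diff(range(r$groups$mean_shared)), 0.1)
})
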