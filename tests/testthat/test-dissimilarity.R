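test_that("Bray-Curtis matches hand-computed values", {
  m <- cbind(a = c(0.6, 0.4), b = c(0.2, 0.8), c = c(0.6, 0.4),
             d = c(1, 0), e = c(0, 1))
  rownames(m) <- c("X", "Y")
  dm <- bray_curtis(toy_table(m))
  expect_equal(dm["a", "c"], 0)                    # identical columns
  expect_equal(dm["d", "e"], 1)                    # disjoint supports
  expect_equal(dm["a", "b"], (0.4 + 0.4) / 2)      # hand arithmetic
  expect_equal(unname(diag(unclass(dm))), rep(0, 5))
})

test_that("Bray-Curtis equals the brute-force per-pair loop on random tables", {
  for (seed in 1:5) {
    m <- random_rel_matrix(8, 8, seed)
    dm <- bray_curtis(toy_table(m))
    expect_lt(max(abs(unclass(dm) - brute_bray_curtis(m))), 1e-12)
  }
})

test_that("counts-mode tables are rejected until converted", {
  tab <- abundance_table(data.frame(taxon = c("A", "B"), s1 = c(3, 1), s2 = c(1, 3)),
                         mode = "counts")
  expect_error(bray_curtis(tab), "relative")
  expect_s3_class(bray_curtis(as_relative(tab)), "dist_mat")
})

test_that("pairs get calendar-month intervals and the printed group bounds", {
  m <- random_rel_matrix(5, 6, 3)
  meta <- toy_metadata(
    colnames(m),
    c("P1", "P1", "P1", "P1", "P1", "P2"),
    c(month_index_from_date("2016-10"), month_index_from_date("2016-11"),
      month_index_from_date("2016-12"), month_index_from_date("2017-12"),
      month_index_from_date("2019-03"), month_index_from_date("2016-10")))
  pr <- enumerate_pairs(bray_curtis(toy_table(m)), meta)
  g <- function(a, b) pr$group[(pr$sample_a == a & pr$sample_b == b) |
                               (pr$sample_a == b & pr$sample_b == a)]
  expect_equal(g("s01", "s02"), "M1")   # Oct 2016 vs Nov 2016, 1 month
  expect_equal(g("s03", "s04"), "Y1")   # Dec 2016 vs Dec 2017, 12 months
  expect_equal(g("s03", "s05"), "Y3")   # Dec 2016 vs Mar 2019, 27 months
  expect_equal(g("s04", "s05"), "Y2")   # Dec 2017 vs Mar 2019, 15 months
  expect_equal(g("s01", "s06"), "D")    # different individuals
  iv <- pr$interval_months[pr$sample_a == "s03" & pr$sample_b == "s05"]
  expect_equal(iv, 27L)
})

test_that("groups partition same-individual pairs; duplicate months are excluded", {
  set.seed(9)
  for (case in 1:5) {
    n_i <- sample(3:8, 3)
    ids <- character(0); inds <- character(0); mons <- integer(0)
    for (k in 1:3) {
      mo <- sort(sample(24202:24240, n_i[k]))
      ids <- c(ids, sprintf("P%d_%d", k, seq_len(n_i[k])))
      inds <- c(inds, rep(sprintf("P%d", k), n_i[k]))
      mons <- c(mons, mo)
    }
    m <- random_rel_matrix(6, length(ids), case)
    colnames(m) <- ids
    meta <- toy_metadata(ids, inds, mons)
    pr <- enumerate_pairs(bray_curtis(toy_table(m)), meta)
    same <- pr[pr$group != "D", ]
    expect_equal(nrow(same), sum(choose(n_i, 2)))
    expect_equal(nrow(pr), choose(length(ids), 2))
    # hand count per group from the metadata alone
    for (g in c("M1", "Y1", "Y2", "Y3")) {
      lo <- c(M1 = 1, Y1 = 2, Y2 = 13, Y3 = 25)[[g]]
      hi <- c(M1 = 1, Y1 = 12, Y2 = 24, Y3 = Inf)[[g]]
      hand <- 0L
      for (k in 1:3) {
        mo <- mons[inds == sprintf("P%d", k)]
        for (i in seq_along(mo)) for (j in seq_len(i - 1L)) {
          d <- abs(mo[i] - mo[j])
          if (d >= lo && d <= hi) hand <- hand + 1L
        }
      }
      expect_equal(sum(same$group == g), hand)
    }
  }
})

test_that("group means rise with interval on drifting cohorts", {
  ok <- purrr::map_lgl(1:20, function(s) {
    ch <- simulate_cohort(sim_config(n_individuals = 2, n_taxa = 25,
                                     months = list(24202 + c(0:3, 10, 14, 20, 26, 30),
                                                   24202 + c(0:2, 8, 15, 18, 27, 31)),
                                     drift_sd = 0.15, bloom_prob = 0,
                                     seq_depth = 3000, rng_seed = s))
    pr <- enumerate_pairs(bray_curtis(as_relative(ch$counts)), ch$metadata)
    mu <- tapply(pr$dissimilarity, pr$group, mean)[c("M1", "Y1", "Y2", "Y3")]
    all(diff(mu) > -0.05)
  })
  expect_gt(mean(ok), 0.8)
})

test_that("distance matrices survive a TSV round-trip", {
  m <- random_rel_matrix(6, 7, 5)
  dm <- bray_curtis(toy_table(m))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, f)
  back <- read_distance_matrix(f)
  expect_equal(unclass(back), unclass(dm), tolerance = 1e-12)
})
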