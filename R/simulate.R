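#' Configuration for the longitudinal cohort simulator
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults emulate a
#' repeated monthly stool-sampling study: 7 individuals sampled at a shared
#' schedule of 37 candidate months inside a 44-calendar-month window
#' (October 2016 to May 2020), each individual contributing between 15 and
#' 31 of those months, 58 genus-level taxa, and a sequencing depth of
#' 30,000 reads per sample.
#'
#' The generative model, per individual: a latent log-abundance vector
#' starts at an individual baseline (community profile plus
#' `N(0, baseline_sd^2)` individual offsets), performs a Gaussian random
#' walk with per-month step `drift_sd` between sampled months, and is closed
#' to the simplex by softmax. Each month the composition is additionally
#' mixed with a freshly drawn "novel" community at rate `retention_decay`
#' per month, so the fraction of the community retained from a sample
#' `d` months earlier decays like `(1 - retention_decay)^d`. With
#' probability `bloom_prob` a sample receives a transient bloom: one
#' uniformly chosen taxon is multiplied by `bloom_fold` before closure, in
#' the observed composition only, so abundance returns to its usual level at
#' the next time point. Counts are multinomial at `seq_depth`.
#'
#' @param n_individuals Number of subjects.
#' @param n_taxa Number of taxa.
#' @param months Either `NULL` (sample each individual's schedule from
#'   `candidate_months`) or a list of integer month-index vectors, one per
#'   individual.
#' @param candidate_months Shared schedule to draw from when `months` is
#'   `NULL`.
#' @param samples_per_individual Length-2 integer range; each individual's
#'   number of samples is drawn uniformly from it.
#' @param baseline_sd SD of individual-specific log-abundance offsets;
#'   larger values separate individuals more strongly.
#' @param drift_sd Per-month SD of the latent random-walk step.
#' @param bloom_prob Per-sample probability of injecting one bloom.
#' @param bloom_fold Multiplier applied to the blooming taxon (pre-closure).
#' @param retention_decay Per-month fraction of the community replaced from
#'   a novel pool, in `[0, 1)`.
#' @param seq_depth Reads per sample (multinomial size).
#' @param rng_seed Seed; identical seeds give identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 7L,
                       n_taxa = 58L,
                       months = NULL,
                       candidate_months = default_candidate_months(),
                       samples_per_individual = c(15L, 31L),
                       baseline_sd = 1.0,
                       drift_sd = 0.1,
                       bloom_prob = 0.2,
                       bloom_fold = 50,
                       retention_decay = 0.02,
                       seq_depth = 30000L,
                       rng_seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_taxa = as.integer(n_taxa),
    months = months, candidate_months = as.integer(candidate_months),
    samples_per_individual = as.integer(samples_per_individual),
    baseline_sd = baseline_sd, drift_sd = drift_sd,
    bloom_prob = bloom_prob, bloom_fold = bloom_fold,
    retention_decay = retention_decay,
    seq_depth = as.integer(seq_depth), rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    stopifnot(n_individuals >= 1, n_taxa >= 2, seq_depth >= 1,
              drift_sd >= 0, baseline_sd >= 0,
              bloom_prob >= 0, bloom_prob <= 1,
              retention_decay >= 0, retention_decay < 1,
              bloom_fold > 0)
  })
  if (!is.null(months)) {
    if (length(months) != cfg$n_individuals) abort("months must have one vector per individual")
    if (any(lengths(months) == 0L)) abort("empty month list for an individual")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_candidate_months <- function() {
  window <- 24202:24245                       # Oct 2016 .. May 2020
  window[-seq(5L, 41L, by = 6L)]              # 37 sampled months, gaps included
}

#' Simulate a longitudinal compositional cohort
#'
#' @param config A [sim_config()].
#' @return A list of class `gd_cohort` with elements `counts` (an
#'   `abund_tbl` in counts mode), `metadata` (a [sample_metadata()] tibble),
#'   and `truth` -- ground truth for parameter-recovery tests: `blooms`
#'   (sample, taxon, fold injected), `latent` (list of taxa x samples
#'   observed-composition matrices per individual) and
#'   `retention_decay`/`drift_sd` echoes, from which the expected retained
#'   fraction for an ordered pair `d` months apart is
#'   `(1 - retention_decay)^d`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  TT <- config$n_taxa
  taxa <- sprintf("taxon_%02d", seq_len(TT))
  community_profile <- sort(rnorm(TT, 0, 2), decreasing = TRUE)  # skewed, few dominant taxa

  months <- config$months
  if (is.null(months)) {
    months <- purrr::map(seq_len(config$n_individuals), function(i) {
      k <- sample(seq(config$samples_per_individual[1L],
                      config$samples_per_individual[2L]), 1L)
      k <- min(k, length(config$candidate_months))
      sort(sample(config$candidate_months, k))
    })
  }

  counts_cols <- list(); meta_rows <- list(); bloom_rows <- list(); latent <- list()
  for (i in seq_len(config$n_individuals)) {
    ind <- sprintf("P%d", i)
    mo <- sort(as.integer(months[[i]]))
    x <- community_profile + rnorm(TT, 0, config$baseline_sd)
    p <- softmax(x)
    comp <- matrix(NA_real_, TT, length(mo), dimnames = list(taxa, NULL))
    for (j in seq_along(mo)) {
      if (j > 1L) {
        gap <- mo[j] - mo[j - 1L]
        x <- log(pmax(p, 1e-12)) + rnorm(TT, 0, config$drift_sd * sqrt(gap))
        p <- softmax(x)
        w <- (1 - config$retention_decay)^gap
        if (w < 1) {
          novel <- softmax(community_profile + rnorm(TT, 0, max(config$baseline_sd, 1)))
          p <- w * p + (1 - w) * novel
        }
      }
      sid <- sprintf("%s_M%d", ind, mo[j])
      p_obs <- p
      if (runif(1) < config$bloom_prob) {
        tx <- sample.int(TT, 1L)
        p_obs[tx] <- p_obs[tx] * config$bloom_fold
        p_obs <- p_obs / sum(p_obs)
        bloom_rows[[length(bloom_rows) + 1L]] <-
          tibble(sample_id = sid, taxon = taxa[tx], fold = config$bloom_fold)
      }
      comp[, j] <- p_obs
      counts_cols[[sid]] <- as.integer(rmultinom(1L, config$seq_depth, p_obs))
      tp <- match(mo[j], config$candidate_months)
      meta_rows[[length(meta_rows) + 1L]] <- tibble(
        sample_id = sid, individual_id = ind, month_index = mo[j],
        timepoint_label = if (is.na(tp)) NA_character_ else sprintf("T%d", tp),
        date = sprintf("%04d-%02d", (mo[j] - 1L) %/% 12L, ((mo[j] - 1L) %% 12L) + 1L)
      )
    }
    colnames(comp) <- names(counts_cols)[seq(length(counts_cols) - length(mo) + 1L, length(counts_cols))]
    latent[[ind]] <- comp
  }

  m <- do.call(cbind, counts_cols)
  rownames(m) <- taxa
  counts <- matrix_to_abund(m, level = "genus", mode = "counts")
  metadata <- sample_metadata(bind_rows(meta_rows))
  truth <- list(
    blooms = if (length(bloom_rows)) bind_rows(bloom_rows) else
      tibble(sample_id = character(), taxon = character(), fold = double()),
    latent = latent,
    retention_decay = config$retention_decay,
    drift_sd = config$drift_sd
  )
  structure(list(counts = counts, metadata = metadata, truth = truth),
            class = "gd_cohort")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Fill in the nine survey covariates on simulated metadata
#'
#' Adds the covariates screened for association with community composition:
#' participant ID and collection date (copied from the metadata), workspace,
#' drug use, yogurt consumption, fruit consumption, travel history, blood
#' pressure and blood sugar. One designated factor is generated with a
#' controllable association to individual identity (each individual has a
#' preferred level whose sampling weight is `1 + linked_factor_effect`
#' against 1 for every other level); all remaining factors are independent
#' of everything, giving a known null for calibration.
#'
#' @param metadata A [sample_metadata()] tibble.
#' @param linked_factor Name of the covariate tied to individual identity.
#' @param linked_factor_effect Non-negative effect size; 0 means fully
#'   independent.
#' @param rng_seed Seed.
#' @return The metadata tibble with the nine covariate columns filled.
#' @export
simulate_covariates <- function(metadata, linked_factor = "workspace",
                                linked_factor_effect = 5, rng_seed = 1L) {
  stopifnot(linked_factor_effect >= 0)
  set.seed(as.integer(rng_seed))
  n <- nrow(metadata)
  inds <- unique(metadata$individual_id)
  pools <- list(
    workspace = sprintf("site_%d", seq_len(max(length(inds), 2L))),
    drug_use = c("yes", "no"),
    yogurt = c("yes", "no"),
    fruit = c("daily", "weekly", "rarely"),
    travel = c("yes", "no")
  )
  if (!linked_factor %in% names(pools)) {
    abort(paste0("linked factor must be one of: ", toString(names(pools))))
  }
  draw_linked <- function(ind, pool) {
    pref <- pool[(match(ind, inds) - 1L) %% length(pool) + 1L]
    w <- rep(1, length(pool))
    w[match(pref, pool)] <- 1 + linked_factor_effect
    sample(pool, 1L, prob = w)
  }
  out <- metadata
  out$participant_id <- out$individual_id
  if (!"date" %in% names(out)) {
    out$date <- sprintf("%04d-%02d", (out$month_index - 1L) %/% 12L,
                        ((out$month_index - 1L) %% 12L) + 1L)
  }
  for (nm in names(pools)) {
    out[[nm]] <- if (nm == linked_factor) {
      purrr::map_chr(out$individual_id, draw_linked, pool = pools[[nm]])
    } else {
      sample(pools[[nm]], n, replace = TRUE)
    }
  }
  out$blood_pressure <- round(rnorm(n, 118, 8), 1)
  out$blood_sugar <- round(rnorm(n, 6.2, 0.8), 2)
  sample_metadata(out)
}
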