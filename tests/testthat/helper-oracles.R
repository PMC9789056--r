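# Independent brute-force oracles and tiny builders used across the suite.
# These deliberately re-derive each quantity from its definition with plain
# loops, so they share no code with the package implementations they check.

# Bray-Curtis by the defining formula, one pair at a time
brute_bray_curtis <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
    }
  }
  d
}

# bloom rule by a naive triple loop over (individual, taxon, sample)
brute_blooms <- function(m, individual_of, threshold = 5) {
  out <- list()
  for (p in unique(individual_of)) {
    cols <- which(individual_of == p)
    for (t in seq_len(nrow(m))) {
      mu <- mean(m[t, cols])
      if (mu == 0) next
      for (s in cols) {
        if (m[t, s] > threshold * mu) {
          out[[length(out) + 1L]] <- data.frame(
            individual_id = p, sample_id = colnames(m)[s],
            taxon = rownames(m)[t], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(individual_id = character(), sample_id = character(),
                      taxon = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$individual_id, df$sample_id, df$taxon), , drop = FALSE]
}

# midrank rank-sum from its definition (count smaller / split ties)
brute_rank_sum <- function(x, y) {
  pool <- c(x, y)
  r <- vapply(x, function(v) sum(pool < v) + (sum(pool == v) + 1) / 2, numeric(1))
  sum(r)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exhaustive one-sided Mantel p over all relabelings
brute_mantel_p <- function(dm, fd) {
  n <- nrow(dm)
  ut <- upper.tri(dm)
  r_obs <- cor(dm[ut], fd[ut])
  perms <- all_perms(n)
  r_all <- apply(perms, 1L, function(p) cor(dm[ut], fd[p, p][ut]))
  mean(r_all >= r_obs - 1e-12)
}

# small relative-abundance table with known individuals
toy_table <- function(m, level = "genus") {
  gutdrift::abundance_table(
    cbind(data.frame(taxon = rownames(m)), as.data.frame(m)),
    level = level, mode = "relative")
}

toy_metadata <- function(sample_id, individual_id, month_index) {
  gutdrift::sample_metadata(data.frame(
    sample_id = sample_id, individual_id = individual_id,
    month_index = month_index, stringsAsFactors = FALSE))
}

# random column-normalised table for property tests
random_rel_matrix <- function(n_taxa, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_taxa * n_samples), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  sweep(m, 2L, colSums(m), "/")
}

# minimal FASTQ writer: list of list(id, seq, qual) records
write_fastq <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$seq, "+", r$qual)
  }))
  writeLines(lines, path)
  path
}

phred_string <- function(scores) {
  intToUtf8(scores + 33L, multiple = FALSE)
}
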