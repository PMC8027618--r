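# Independent oracles used across the suite.

# Closed-form logistic growth from N0 for t hours.
logistic_closed_form <- function(N0, r, K, t) {
  K * N0 * exp(r * t) / (K + N0 * (exp(r * t) - 1))
}

# Brute-force clustering oracle: connected components of the <= d edit-distance
# graph, via igraph (independent of the package's greedy agglomeration).
components_oracle <- function(sequences, d) {
  dm <- utils::adist(sequences)
  g <- igraph::graph_from_adjacency_matrix(dm <= d, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# Partition equality irrespective of labels: canonical signature of a
# membership vector.
partition_signature <- function(membership, keys) {
  groups <- split(keys, membership)
  sorted <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                        character(1)))
  paste(sorted, collapse = "|")
}

# Random variant set: a few seed sequences plus 1..3-edit mutants, weighted
# counts; guaranteed dereplicated.
random_variant_set <- function(n_target, seq_length = 20) {
  n_seeds <- max(2, rpois(1, n_target / 8))
  seeds <- unique(vapply(seq_len(n_seeds), function(i) {
    paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  pool <- seeds
  while (length(pool) < n_target) {
    parent <- sample(pool, 1)
    n_edits <- sample(1:3, 1)
    mutant <- strsplit(parent, "")[[1]]
    for (k in seq_len(n_edits)) {
      op <- sample(c("sub", "ins", "del"), 1)
      pos <- sample(length(mutant), 1)
      if (op == "sub") {
        mutant[pos] <- sample(c("A", "C", "G", "T"), 1)
      } else if (op == "ins" && length(mutant) < seq_length + 4) {
        mutant <- append(mutant, sample(c("A", "C", "G", "T"), 1), after = pos)
      } else if (op == "del" && length(mutant) > 8) {
        mutant <- mutant[-pos]
      }
    }
    pool <- union(pool, paste(mutant, collapse = ""))
  }
  tibble::tibble(sequence = pool,
                 count = sample(1:50, length(pool), replace = TRUE))
}

# Exact expectation of observed variants in a without-replacement subsample of
# size m (hypergeometric): E[S] = sum_i 1 - C(T - x_i, m) / C(T, m).
expected_observed_hyper <- function(x, m) {
  total <- sum(x)
  sum(1 - exp(lchoose(total - x, m) - lchoose(total, m)))
}

# A tiny genome with a planted protospacer and PAM for classifier tests.
planted_genome <- function(spacer, pam = "GG", left = 60, right = 60,
                           seed = 99) {
  withr::with_seed(seed, {
    flank <- function(n) paste(sample(c("A", "C", "T"), n, replace = TRUE),
                               collapse = "")
    paste0(flank(left), spacer, pam, flank(right))
  })
}
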