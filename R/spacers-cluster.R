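#' Single-linkage agglomerative clustering of sequence variants
#'
#' SWARM-style clustering: two dereplicated variants are linked when their
#' edit distance (substitutions and indels) is at most `d`, and clusters are
#' the connected components of the resulting graph, grown greedily from the
#' most abundant unassigned seed. The similarity threshold is therefore not a
#' fixed global identity but is defined locally by the `d`-linkage chain. The
#' centroid of a cluster is its highest-count member (ties broken by the
#' lexicographically smallest sequence).
#'
#' @param variants Tibble of dereplicated variants with columns `sequence`
#'   (unique) and `count`.
#' @param d Maximum edit distance for linkage (default 1, the strictest
#'   setting).
#'
#' @return A tibble with one row per cluster, ordered by seed abundance:
#'   `cluster` (id), `centroid`, `total` (summed member counts), `n_members`,
#'   and a `members` list-column of per-member tibbles. Output is invariant
#'   to the input row order.
#' @examples
#' swarm_cluster(tibble::tibble(sequence = c("ACGT", "ACGA", "TTTT"),
#'                              count = c(10, 2, 5)), d = 1)
#' @export
swarm_cluster <- function(variants, d = 1) {
  check_columns(variants, c("sequence", "count"), "variants")
  check_count(d, "d", lower = 1)
  if (nrow(variants) == 0) {
    return(tibble(cluster = integer(), centroid = character(),
                  total = numeric(), n_members = integer(), members = list()))
  }
  check_dna(variants$sequence, "variants$sequence")
  check_counts_vector(variants$count, "variants$count")
  if (anyDuplicated(variants$sequence) > 0) {
    abort("`variants` must be dereplicated: sequences must be unique.",
          class = "crisprcost_validation_error")
  }
  # canonical processing order makes the result independent of input order
  v <- arrange(as_tibble(variants), dplyr::desc(.data$count), .data$sequence)
  n <- nrow(v)
  dm <- adist(v$sequence)
  adj <- dm <= d
  diag(adj) <- FALSE
  assigned <- rep(NA_integer_, n)
  cluster_id <- 0L
  for (seed in seq_len(n)) {
    if (!is.na(assigned[seed])) next
    cluster_id <- cluster_id + 1L
    frontier <- seed
    assigned[seed] <- cluster_id
    while (length(frontier) > 0) {
      nbrs <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.na(assigned))
      assigned[nbrs] <- cluster_id
      frontier <- nbrs
    }
  }
  members <- split(v, assigned)
  rows <- imap(members, function(m, id) {
    best <- m[m$count == max(m$count), ]
    centroid <- min(best$sequence)
    tibble(cluster = as.integer(id), centroid = centroid,
           total = sum(m$count), n_members = nrow(m),
           members = list(arrange(m, dplyr::desc(.data$count), .data$sequence)))
  })
  arrange(list_rbind(rows), .data$cluster)
}

#' Remove clusters below a minimum size
#'
#' Drops clusters whose total abundance is below `min_size` (default 2, i.e.
#' singletons are removed, the usual guard against sequencing-error variants).
#'
#' @param clusters Output of [swarm_cluster()].
#' @param min_size Minimum total abundance to retain a cluster.
#' @return The filtered cluster tibble.
#' @export
filter_clusters <- function(clusters, min_size = 2) {
  check_columns(clusters, c("cluster", "centroid", "total"), "clusters")
  check_count(min_size, "min_size", lower = 1)
  clusters[clusters$total >= min_size, ]
}

# Global identity between two sequences: 1 - edit distance / longer length.
global_identity <- function(seqs, centroid) {
  1 - as.vector(adist(seqs, centroid)) /
    pmax(nchar(seqs), nchar(centroid))
}

#' Assign per-sample sequence abundances to cluster centroids
#'
#' Each sequence is assigned to the best-matching centroid provided its
#' global identity (1 minus edit distance over the full alignment length) is
#' at least `min_identity`; ties go to the most abundant centroid. Sequences
#' matching no centroid at the threshold are collected in an `"unassigned"`
#' row, so column sums are conserved.
#'
#' @param sequences Tibble with columns `sequence`, `count`, `sample`.
#' @param clusters Output of [swarm_cluster()] (or any tibble with `cluster`,
#'   `centroid` and `total` columns).
#' @param min_identity Minimum global identity in (0, 1] (default 0.99).
#'
#' @return A long abundance table: tibble with columns `cluster`, `sample`,
#'   `count` (summed reads per cluster and sample).
#' @export
assign_abundance <- function(sequences, clusters, min_identity = 0.99) {
  check_columns(sequences, c("sequence", "count", "sample"), "sequences")
  check_columns(clusters, c("cluster", "centroid", "total"), "clusters")
  check_number(min_identity, "min_identity", lower = 1e-12, upper = 1)
  if (nrow(clusters) == 0) {
    abort("no centroids to assign abundances to.",
          class = "crisprcost_validation_error")
  }
  uniq <- distinct(sequences, .data$sequence)
  dm <- adist(uniq$sequence, clusters$centroid)
  ident <- 1 - dm / outer(nchar(uniq$sequence), nchar(clusters$centroid), pmax)
  # best identity; ties resolved toward the most abundant centroid
  pick <- map_chr(seq_len(nrow(uniq)), function(i) {
    ok <- which(ident[i, ] >= min_identity)
    if (length(ok) == 0) return("unassigned")
    best <- ok[ident[i, ok] == max(ident[i, ok])]
    if (length(best) > 1) best <- best[which.max(clusters$total[best])]
    as.character(clusters$cluster[best])
  })
  uniq$cluster <- pick
  sequences %>%
    left_join(uniq, by = "sequence") %>%
    group_by(.data$cluster, .data$sample) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$cluster, .data$sample)
}

#' Pivot a long abundance table to a sample-by-cluster matrix
#'
#' @param abundance Long tibble with `cluster`, `sample`, `count` columns.
#' @param drop_unassigned Drop the `"unassigned"` row first (default TRUE).
#' @return An integer matrix with samples as rows and clusters as columns,
#'   the orientation expected by community-ecology tools.
#' @export
abundance_matrix <- function(abundance, drop_unassigned = TRUE) {
  check_columns(abundance, c("cluster", "sample", "count"), "abundance")
  if (drop_unassigned) {
    abundance <- abundance[abundance$cluster != "unassigned", ]
  }
  wide <- tidyr::pivot_wider(abundance, names_from = "cluster",
                             values_from = "count", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- wide$sample
  m
}
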