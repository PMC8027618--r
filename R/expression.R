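#' Min-max normalise an expression timecourse
#'
#' Rescales a vector to `[0, 1]` via `(x - min) / (max - min)`. Constant
#' vectors cannot be rescaled; they map to all zeros and are flagged through
#' the `"constant"` attribute.
#'
#' @param values Numeric vector with at least two timepoints.
#' @return The normalised vector, with attribute `constant`.
#' @examples
#' minmax_normalize(c(2, 6, 10))
#' @export
minmax_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values))) {
    abort("`values` must be a finite numeric vector with >= 2 timepoints.",
          class = "crisprcost_validation_error")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(rep(0, length(values)), constant = TRUE))
  }
  structure((values - rng[1]) / (rng[2] - rng[1]), constant = FALSE)
}

#' Average replicate counts within a genotype group
#'
#' Arithmetic mean of per-replicate counts for every gene and timepoint in
#' the chosen group.
#'
#' @param expr Long expression tibble (`gene`, `origin`, `genotype`,
#'   `minutes`, `replicate`, `count`).
#' @param group Genotype group to average.
#' @return A tibble `gene`, `origin`, `minutes`, `mean_count`,
#'   `n_replicates`.
#' @export
average_replicates <- function(expr, group = "WT") {
  check_columns(expr, c("gene", "origin", "genotype", "minutes",
                        "replicate", "count"), "expr")
  sub <- expr[expr$genotype == group, ]
  if (nrow(sub) == 0) {
    abort(sprintf("no samples in genotype group `%s`.", group),
          class = "crisprcost_validation_error")
  }
  all_tp <- sort(unique(expr$minutes))
  have_tp <- sort(unique(sub$minutes))
  gap <- setdiff(all_tp, have_tp)
  if (length(gap) > 0) {
    abort(sprintf("group `%s` is missing timepoint(s): %s min.",
                  group, paste(gap, collapse = ", ")),
          class = "crisprcost_validation_error")
  }
  sub %>%
    group_by(.data$gene, .data$origin, .data$minutes) %>%
    summarise(mean_count = mean(.data$count),
              n_replicates = dplyr::n(), .groups = "drop")
}

#' Phage gene expression profiles over the infection timecourse
#'
#' Builds the per-gene normalised temporal profile of every phage gene in the
#' chosen genotype group. The default order follows the convention of
#' normalising each replicate's timecourse by its minimum and maximum first,
#' then averaging the normalised values across replicates
#' (`"normalize-first"`); the alternative (`"average-first"`) averages raw
#' counts across replicates and then normalises the mean timecourse. The two
#' orders differ whenever replicates have different dynamic ranges.
#'
#' @param expr Long expression tibble.
#' @param genotype Group whose infection timecourse defines the programme
#'   (default `"WT"`, i.e. a fully permissive infection).
#' @param order `"normalize-first"` (default) or `"average-first"`.
#' @return A tibble `gene`, `minutes`, `value`, `constant` (TRUE when the
#'   gene's timecourse was flat and mapped to zero).
#' @export
phage_gene_profiles <- function(expr, genotype = "WT",
                                order = c("normalize-first", "average-first")) {
  order <- match.arg(order)
  check_columns(expr, c("gene", "origin", "genotype", "minutes",
                        "replicate", "count"), "expr")
  sub <- expr[expr$origin == "phage" & expr$genotype == genotype, ]
  if (nrow(sub) == 0) {
    abort(sprintf("no phage-gene samples in group `%s`.", genotype),
          class = "crisprcost_validation_error")
  }
  if (order == "normalize-first") {
    sub %>%
      dplyr::arrange(.data$gene, .data$replicate, .data$minutes) %>%
      group_by(.data$gene, .data$replicate) %>%
      mutate(norm = as.numeric(minmax_normalize(.data$count)),
             constant = attr(minmax_normalize(.data$count), "constant")) %>%
      ungroup() %>%
      group_by(.data$gene, .data$minutes) %>%
      summarise(value = mean(.data$norm), constant = all(.data$constant),
                .groups = "drop")
  } else {
    average_replicates(expr[expr$origin == "phage", ], group = genotype) %>%
      dplyr::arrange(.data$gene, .data$minutes) %>%
      group_by(.data$gene) %>%
      mutate(value = as.numeric(minmax_normalize(.data$mean_count)),
             constant = attr(minmax_normalize(.data$mean_count), "constant")) %>%
      ungroup() %>%
      select("gene", "minutes", "value", "constant")
  }
}

#' Hierarchically cluster temporal expression profiles
#'
#' Agglomerative clustering (complete linkage by default) on the Euclidean
#' distance between normalised gene timecourses, cut into `k` groups to
#' delineate phases of the transcriptional programme. Genes are processed in
#' lexicographic order, which fixes merge tie-breaking and makes the result
#' invariant to the input row order.
#'
#' @param profiles Profile tibble from [phage_gene_profiles()] (columns
#'   `gene`, `minutes`, `value`).
#' @param k Number of temporal clusters.
#' @param linkage `hclust` agglomeration method (default `"complete"`).
#' @return An object of class `programme_clustering`: list with `assignments`
#'   (tibble `gene`, `cluster`), `tree` (the `hclust` merge tree), `k`,
#'   `profiles`. Supports [tidy()], [glance()], [autoplot()].
#' @export
cluster_programme <- function(profiles, k = 3, linkage = "complete") {
  check_columns(profiles, c("gene", "minutes", "value"), "profiles")
  check_count(k, "k", lower = 1)
  wide <- tidyr::pivot_wider(
    profiles[, c("gene", "minutes", "value")],
    names_from = "minutes", values_from = "value")
  wide <- arrange(wide, .data$gene)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (nrow(m) < 2) {
    abort("need at least two profiles to cluster.",
          class = "crisprcost_validation_error")
  }
  if (k > nrow(m)) {
    abort(sprintf("`k` (%d) cannot exceed the number of profiles (%d).",
                  k, nrow(m)), class = "crisprcost_validation_error")
  }
  tree <- hclust(dist(m, method = "euclidean"), method = linkage)
  assignment <- cutree(tree, k = k)
  structure(list(
    assignments = tibble(gene = names(assignment),
                         cluster = unname(assignment)),
    tree = tree, k = k, linkage = linkage,
    profiles = as_tibble(profiles)
  ), class = "programme_clustering")
}

#' @export
print.programme_clustering <- function(x, ...) {
  cat(sprintf("Transcriptional programme: %d genes in %d clusters (%s linkage)\n",
              nrow(x$assignments), x$k, x$linkage))
  print(dplyr::count(x$assignments, .data$cluster))
  invisible(x)
}

#' @method tidy programme_clustering
#' @export
tidy.programme_clustering <- function(x, ...) x$assignments

#' @method glance programme_clustering
#' @export
glance.programme_clustering <- function(x, ...) {
  tibble(n_genes = nrow(x$assignments), k = x$k, linkage = x$linkage,
         max_height = max(x$tree$height))
}

#' Per-sample fraction of reads mapping to phage genes
#'
#' @param expr Long expression tibble.
#' @return A tibble with one row per sample: `sample`, `genotype`, `minutes`,
#'   `replicate`, `phage_fraction`, `total`. Host and phage fractions sum
#'   to one.
#' @export
phage_read_fraction <- function(expr) {
  check_columns(expr, c("gene", "origin", "sample", "genotype", "minutes",
                        "replicate", "count"), "expr")
  out <- expr %>%
    group_by(.data$sample, .data$genotype, .data$minutes, .data$replicate) %>%
    summarise(total = sum(.data$count),
              phage_fraction = sum(.data$count[.data$origin == "phage"]) /
                sum(.data$count),
              .groups = "drop")
  if (any(out$total <= 0)) {
    abort(sprintf("sample(s) with zero library size: %s.",
                  paste(out$sample[out$total <= 0], collapse = ", ")),
          class = "crisprcost_validation_error")
  }
  out
}

#' Fold difference of mean phage-read fractions between two groups
#'
#' Ratio of group means, `mean(group_a) / mean(group_b)`, with a seeded
#' percentile bootstrap confidence interval (resampling samples within each
#' group).
#'
#' @param fractions Output of [phage_read_fraction()] (or any tibble with
#'   `genotype` and a value column).
#' @param group_a,group_b Genotype labels of numerator and denominator.
#' @param value Name of the value column (default `"phage_fraction"`).
#' @param n_boot Bootstrap resamples.
#' @param conf_level Confidence level.
#' @param seed Optional RNG seed.
#' @return An object of class `fold_difference` with `estimate`, `conf_int`,
#'   group means and sizes. Supports [tidy()] and [glance()].
#' @export
fold_difference <- function(fractions, group_a = "WT", group_b = "BIM2",
                            value = "phage_fraction", n_boot = 1000,
                            conf_level = 0.95, seed = NULL) {
  check_columns(fractions, c("genotype", value), "fractions")
  va <- fractions[[value]][fractions$genotype == group_a]
  vb <- fractions[[value]][fractions$genotype == group_b]
  if (length(va) == 0 || length(vb) == 0) {
    abort("both groups must be non-empty.",
          class = "crisprcost_validation_error")
  }
  if (mean(vb) <= 0) {
    abort(sprintf("mean of group `%s` is zero: fold difference undefined.",
                  group_b), class = "crisprcost_undefined_ratio_error")
  }
  est <- mean(va) / mean(vb)
  boot <- with_seed_or_not(seed, {
    vapply(seq_len(n_boot), function(i) {
      ra <- mean(sample(va, replace = TRUE))
      rb <- mean(sample(vb, replace = TRUE))
      if (rb > 0) ra / rb else NA_real_
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(estimate = est, conf_int = ci, conf_level = conf_level,
                 group_a = group_a, group_b = group_b,
                 mean_a = mean(va), mean_b = mean(vb),
                 n_a = length(va), n_b = length(vb)),
            class = "fold_difference")
}

#' @export
print.fold_difference <- function(x, ...) {
  cat(sprintf("Fold difference %s / %s: %.3f (%d%% CI %.3f to %.3f)\n",
              x$group_a, x$group_b, x$estimate,
              round(100 * x$conf_level), x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' @method tidy fold_difference
#' @export
tidy.fold_difference <- function(x, ...) {
  tibble(term = sprintf("%s/%s", x$group_a, x$group_b),
         estimate = x$estimate,
         conf.low = x$conf_int[1], conf.high = x$conf_int[2])
}

#' @method glance fold_difference
#' @export
glance.fold_difference <- function(x, ...) {
  tibble(estimate = x$estimate, mean_a = x$mean_a, mean_b = x$mean_b,
         n_a = x$n_a, n_b = x$n_b,
         conf.low = x$conf_int[1], conf.high = x$conf_int[2])
}
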