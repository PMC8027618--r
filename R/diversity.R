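#' Alpha-diversity estimators
#'
#' Abundance-based diversity summaries of a count vector (one sample):
#' * `observed_variants()` — number of clusters/variants with positive count;
#' * `chao1()` — bias-corrected Chao1 richness,
#'   \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, where `F1`/`F2` are the
#'   numbers of singleton and doubleton variants;
#' * `shannon()` — Shannon entropy \eqn{-\sum p_i \log p_i};
#' * `simpson()` — Simpson diversity \eqn{1 - \sum p_i^2};
#' * `simpson_evenness()` — inverse Simpson divided by observed richness.
#'
#' All estimators ignore appended zero counts and are invariant to the order
#' of the vector. Computation is delegated to the standard
#' community-ecology routines (`vegan::diversity()`, `vegan::estimateR()`).
#'
#' @param counts Non-negative count vector with at least one positive entry.
#' @param base Logarithm base for `shannon()` (default `exp(1)`).
#'
#' @return A single numeric value.
#' @examples
#' chao1(c(5, 3, 1, 1)) # 4 + 2*1/2 = 5
#' shannon(rep(10, 4)) # log(4)
#' @name diversity-estimators
NULL

#' @rdname diversity-estimators
#' @export
observed_variants <- function(counts) {
  check_counts_vector(counts)
  sum(counts > 0)
}

#' @rdname diversity-estimators
#' @export
chao1 <- function(counts) {
  check_counts_vector(counts)
  if (any(counts != floor(counts))) {
    abort("`counts` must be whole numbers for Chao1.",
          class = "crisprcost_validation_error")
  }
  # estimateR also computes ACE, which warns (NaN) on subsamples with no rare
  # variants; only the Chao1 component is used here
  est <- suppressWarnings(vegan::estimateR(as.integer(counts)))
  unname(est["S.chao1"])
}

#' @rdname diversity-estimators
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts_vector(counts)
  check_number(base, "base", lower = 1 + 1e-12)
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' @rdname diversity-estimators
#' @export
simpson <- function(counts) {
  check_counts_vector(counts)
  unname(vegan::diversity(counts, index = "simpson"))
}

#' @rdname diversity-estimators
#' @export
simpson_evenness <- function(counts) {
  check_counts_vector(counts)
  unname(vegan::diversity(counts, index = "invsimpson")) / sum(counts > 0)
}

diversity_metric <- function(name) {
  switch(name,
    observed = observed_variants,
    chao1 = chao1,
    shannon = shannon,
    simpson = simpson,
    simpson_evenness = simpson_evenness,
    abort(sprintf("unknown diversity metric `%s`.", name),
          class = "crisprcost_validation_error")
  )
}

#' Rarefaction curves by repeated subsampling
#'
#' For every sample and every depth, draws `reps` subsamples without
#' replacement (hypergeometric) from the sample's counts and averages the
#' chosen diversity metric. Depths at or above the sample total return the
#' full-sample (plug-in) metric exactly, with `at_full_depth = TRUE`.
#'
#' @param abundance Long abundance table (tibble with `cluster`, `sample`,
#'   `count`), as produced by [assign_abundance()].
#' @param depths Positive subsampling depths.
#' @param reps Subsamples per depth (default 33).
#' @param metric One of `"observed"`, `"chao1"`, `"shannon"`, `"simpson"`,
#'   `"simpson_evenness"`.
#' @param seed Optional RNG seed.
#'
#' @return A tibble with columns `sample`, `depth`, `metric`, `mean`, `sd`,
#'   `reps`, `at_full_depth`.
#' @export
rarefaction_curve <- function(abundance, depths, reps = 33,
                              metric = "chao1", seed = NULL) {
  check_columns(abundance, c("cluster", "sample", "count"), "abundance")
  if (nrow(abundance) == 0) {
    abort("`abundance` is empty.", class = "crisprcost_validation_error")
  }
  if (!is.numeric(depths) || length(depths) == 0 || any(depths < 1)) {
    abort("`depths` must be positive integers.",
          class = "crisprcost_validation_error")
  }
  check_count(reps, "reps", lower = 1)
  fn <- diversity_metric(metric)
  mat <- abundance_matrix(abundance)
  with_seed_or_not(seed, {
    rows <- list()
    for (s in rownames(mat)) {
      x <- mat[s, ]
      total <- sum(x)
      for (dep in sort(unique(as.integer(depths)))) {
        if (dep >= total) {
          rows[[length(rows) + 1]] <- tibble(
            sample = s, depth = dep, metric = metric,
            mean = fn(x), sd = 0, reps = reps, at_full_depth = TRUE)
        } else {
          vals <- vapply(seq_len(reps),
                         function(i) fn(subsample_counts(x, dep)), numeric(1))
          rows[[length(rows) + 1]] <- tibble(
            sample = s, depth = dep, metric = metric,
            mean = mean(vals), sd = sd(vals), reps = reps,
            at_full_depth = FALSE)
        }
      }
    }
    list_rbind(rows)
  })
}

#' Plot rarefaction curves
#'
#' @param curve Output of [rarefaction_curve()].
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curve) {
  check_columns(curve, c("sample", "depth", "mean"), "curve")
  ggplot(curve, aes(x = .data$depth, y = .data$mean,
                    colour = .data$sample)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "sampling depth (reads)",
         y = sprintf("mean %s (%d subsamples)",
                     curve$metric[1], curve$reps[1]),
         colour = "sample") +
    theme_bw()
}
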