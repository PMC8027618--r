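# Segment layout of an hclust tree for ggplot drawing (standard recursive
# ordering: leaves at their dendrogram positions, merges at their heights).
dendrogram_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- setNames(seq_len(n), tree$order)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  segs <- list()
  pos <- function(idx) {
    if (idx < 0) c(x = unname(leaf_x[as.character(-idx)]), h = 0)
    else c(x = node_x[idx], h = node_h[idx])
  }
  for (i in seq_len(nrow(tree$merge))) {
    a <- pos(tree$merge[i, 1])
    b <- pos(tree$merge[i, 2])
    node_x[i] <- mean(c(a["x"], b["x"]))
    h <- node_h[i]
    segs[[length(segs) + 1]] <- tibble(
      x = c(a[["x"]], a[["x"]], b[["x"]]),
      xend = c(a[["x"]], b[["x"]], b[["x"]]),
      y = c(a[["h"]], h, b[["h"]]),
      yend = c(h, h, h)
    )
  }
  list(segments = list_rbind(segs),
       leaves = tibble(gene = tree$labels[tree$order], x = seq_len(n)))
}

#' Plot a transcriptional programme: dendrogram and clustered profiles
#'
#' Two-panel view of a [cluster_programme()] result: the merge tree with
#' leaves coloured by cluster, and the normalised temporal profiles faceted
#' by cluster.
#'
#' @param programme A `programme_clustering` object.
#' @param which `"profiles"` (default), `"dendrogram"`, or `"both"` (returns
#'   a list of two plots).
#' @return A ggplot object (or a list of two for `"both"`).
#' @export
plot_programme <- function(programme,
                           which = c("profiles", "dendrogram", "both")) {
  which <- match.arg(which)
  stopifnot(inherits(programme, "programme_clustering"))
  prof <- left_join(programme$profiles, programme$assignments, by = "gene")
  p_prof <- ggplot(prof, aes(x = .data$minutes, y = .data$value,
                             group = .data$gene,
                             colour = factor(.data$cluster))) +
    geom_line(alpha = 0.6) +
    facet_wrap(~ cluster, labeller = ggplot2::label_both) +
    scale_colour_brewer(palette = "Set1", guide = "none") +
    labs(x = "minutes post infection", y = "normalised expression") +
    theme_bw()
  if (which == "profiles") return(p_prof)
  lay <- dendrogram_segments(programme$tree)
  leaves <- left_join(lay$leaves, programme$assignments, by = "gene")
  p_dend <- ggplot() +
    geom_segment(data = lay$segments,
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_point(data = leaves,
               aes(x = .data$x, y = 0, colour = factor(.data$cluster)),
               size = 2) +
    scale_colour_brewer(palette = "Set1", name = "cluster") +
    labs(x = NULL, y = "merge height") +
    theme_bw() +
    theme(axis.text.x = element_blank(), axis.ticks.x = element_blank())
  if (which == "dendrogram") return(p_dend)
  list(dendrogram = p_dend, profiles = p_prof)
}

#' @method autoplot programme_clustering
#' @export
autoplot.programme_clustering <- function(object, ...) {
  plot_programme(object, which = "profiles")
}

#' Plot per-sample phage-read fractions by group and timepoint
#'
#' @param fractions Output of [phage_read_fraction()].
#' @return A ggplot object.
#' @export
plot_phage_fractions <- function(fractions) {
  check_columns(fractions, c("genotype", "minutes", "phage_fraction"),
                "fractions")
  df <- fractions %>%
    group_by(.data$genotype, .data$minutes) %>%
    summarise(mean_fraction = mean(.data$phage_fraction), .groups = "drop")
  ggplot(df, aes(x = factor(.data$minutes), y = .data$mean_fraction,
                 fill = .data$genotype)) +
    geom_col(position = position_dodge()) +
    geom_point(data = fractions,
               aes(x = factor(.data$minutes), y = .data$phage_fraction,
                   group = .data$genotype),
               position = position_dodge(width = 0.9), size = 0.8,
               show.legend = FALSE) +
    scale_fill_brewer(palette = "Pastel1") +
    labs(x = "minutes post infection", y = "phage read fraction",
         fill = NULL) +
    theme_bw()
}

#' Plot a diversity-through-time summary
#'
#' @param diversity_df Tibble with columns `day` and a diversity value column.
#' @param value Name of the value column (default `"shannon"`).
#' @return A ggplot object.
#' @export
plot_diversity_time <- function(diversity_df, value = "shannon") {
  check_columns(diversity_df, c("day", value), "diversity_df")
  ggplot(diversity_df, aes(x = .data$day, y = .data[[value]])) +
    geom_line(colour = "grey30") + geom_point() +
    labs(x = "day", y = sprintf("%s diversity", value)) +
    theme_bw()
}

#' Plot the scenario classification table
#'
#' @param scenarios Output of [run_scenarios()].
#' @return A ggplot object rendering the table as a coloured grid.
#' @export
plot_scenarios <- function(scenarios) {
  check_columns(scenarios, c("scenario", "outcome"), "scenarios")
  df <- scenarios %>%
    mutate(label = sprintf(
      "tau=%.2g p=%.2g q=%.2g\nC:M ratio %.2f -> %.2g",
      .data$tau_tox, .data$p, .data$q_self,
      .data$initial_ratio, .data$final_ratio))
  ggplot(df, aes(x = 1, y = .data$scenario, fill = .data$outcome)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = paste0(.data$outcome, "\n", .data$label)),
              size = 3) +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = NULL) +
    theme_bw() +
    theme(axis.text.x = element_blank(), axis.ticks.x = element_blank())
}
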