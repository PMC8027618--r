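#' Default end-to-end pipeline configuration
#'
#' A nested configuration covering every stage of the synthetic study:
#' serial-transfer dynamics and the scenario contrasts, an amplicon
#' time-series with declining spacer diversity, diversity/rarefaction and
#' self-targeting estimation, competition assays across a phage-titre
#' gradient, and an infection expression time-course. All stochastic stages
#' derive their seeds from the single global `seed`.
#'
#' @param seed Global RNG seed.
#' @return A nested named list of class `run_config`.
#' @export
default_config <- function(seed = 42) {
  check_count(seed, "seed")
  structure(list(
    seed = seed,
    dynamics = list(
      params = unclass(model_params()),
      protocol = unclass(transfer_protocol()),
      init_freqs = c(0.45, 0.45, 0.10)
    ),
    spacers = list(
      days = c(2, 4, 6, 10, 12),
      n_events = c(300, 200, 130, 80, 40),
      read_depth = 2500,
      frac_self = 0.02,
      pam_canonical_ratio = 2,
      selection_against_self_canonical = 0.05,
      spacer_length = 32,
      priming_center = 27847,
      priming_spread = 2000,
      phage_genome_length = 36415,
      host_genome_length = 100000,
      repeat_seq = "GTTCACTGCCGTATAGGCAGCTAAGAAA",
      noise_rate = 0.005,
      d = 1,
      min_size = 2,
      min_identity = 0.99,
      pam_motif = "GG",
      pam_side = "3prime"
    ),
    diversity = list(
      depths = c(200, 500, 1000, 2000),
      reps = 33,
      metric = "chao1"
    ),
    competition = list(
      titres = c(0, 1e6, 1e7, 1e8),
      s_true = c(0.10, -0.15, -0.35, -0.60),
      x0 = 0.5,
      days = 3,
      colonies = 500,
      replicates = 3
    ),
    expression = list(
      n_host_genes = 120,
      n_phage_genes = 30,
      timepoints = c(0, 35, 60, 120),
      n_replicates = 5,
      phage_attenuation = 5,
      nb_dispersion = 0.05,
      library_size = 1e5,
      phage_share = 0.03,
      k = 3,
      linkage = "complete"
    ),
    log_level = "info"
  ), class = "run_config")
}

# Strict schema check: any key absent from the default skeleton is rejected,
# with the offending key path in the error.
validate_config <- function(config, skeleton = default_config(), path = "") {
  if (!is.list(config)) {
    abort(sprintf("config%s must be a list.", path),
          class = "crisprcost_config_error")
  }
  unknown <- setdiff(names(config), names(skeleton))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key%s: %s.",
                  if (length(unknown) > 1) "s" else "",
                  paste0(path, "$", unknown, collapse = ", ")),
          class = "crisprcost_config_error")
  }
  for (key in names(config)) {
    if (is.list(skeleton[[key]]) && !is.null(names(skeleton[[key]]))) {
      validate_config(config[[key]], skeleton[[key]],
                      paste0(path, "$", key))
    }
  }
  invisible(config)
}

# Merge user overrides onto the default configuration (shallow per block).
merge_config <- function(config = list()) {
  base <- default_config(seed = config$seed %||% 42)
  validate_config(config, base)
  for (key in setdiff(names(config), "seed")) {
    if (is.list(base[[key]])) {
      base[[key]][names(config[[key]])] <- config[[key]]
    } else {
      base[[key]] <- config[[key]]
    }
  }
  base
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

pipeline_log <- function(level, cfg_level, msg, log_file = NULL) {
  levels <- c(debug = 1, info = 2, warn = 3)
  line <- sprintf("[%s] %s", level, msg)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  if (levels[[level]] >= levels[[cfg_level %||% "info"]]) {
    inform(line)
  }
}

#' Run the full synthetic-study pipeline
#'
#' Executes the requested stages in dependency order (dynamics; spacer
#' amplicons then diversity and self-targeting estimation; competition
#' fitness; expression), writes every table as TSV/JSON under `out_dir`, and
#' finishes with a `manifest.json` recording the seed, the stages run, their
#' outputs and wall times.
#'
#' @param config Configuration overrides merged onto [default_config()];
#'   unknown keys are rejected before any stage runs.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run.
#' @return Invisibly, a list with `results` (the in-memory stage outputs) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("crisprcost-"),
                         stages = c("dynamics", "spacers", "estimators",
                                    "competition", "expression")) {
  cfg <- merge_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  results <- list(seed = cfg$seed, config = cfg)
  manifest <- list(seed = cfg$seed, package_version =
                     as.character(utils::packageVersion("crisprcost")),
                   stages = list())
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    pipeline_log("info", cfg$log_level, sprintf("stage %s: start", name),
                 log_file)
    out <- tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s FAILED: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "crisprcost_stage_error")
    })
    elapsed <- proc.time()[["elapsed"]] - t0
    manifest$stages[[name]] <<- list(files = out$files,
                                     wall_time_s = round(elapsed, 3))
    pipeline_log("info", cfg$log_level,
                 sprintf("stage %s: done in %.1fs", name, elapsed), log_file)
    out$value
  }

  if ("dynamics" %in% stages) {
    results$dynamics <- run_stage("dynamics", function() {
      params <- do.call(model_params, cfg$dynamics$params)
      protocol <- do.call(transfer_protocol, cfg$dynamics$protocol)
      traj <- run_serial_transfer(params, protocol, cfg$dynamics$init_freqs)
      scen <- run_scenarios(params, protocol, cfg$dynamics$init_freqs)
      readr::write_tsv(as_tibble(traj), file.path(out_dir, "trajectory.tsv"))
      readr::write_tsv(scen, file.path(out_dir, "scenarios.tsv"))
      write_json_out(scen, file.path(out_dir, "scenarios.json"))
      list(value = list(trajectory = traj, scenarios = scen),
           files = c("trajectory.tsv", "scenarios.tsv", "scenarios.json"))
    })
  }

  if ("spacers" %in% stages) {
    results$spacers <- run_stage("spacers", function() {
      sc <- cfg$spacers
      phage_genome <- random_genome(sc$phage_genome_length, seed = cfg$seed + 11)
      host_genome <- random_genome(sc$host_genome_length, seed = cfg$seed + 12)
      recs <- list_rbind(map(seq_along(sc$days), function(i) {
        simulate_spacers(spacer_sim_params(
          n_events = sc$n_events[i], frac_self = sc$frac_self,
          pam_canonical_ratio = sc$pam_canonical_ratio,
          selection_against_self_canonical =
            sc$selection_against_self_canonical,
          read_depth = sc$read_depth,
          priming_center = sc$priming_center,
          priming_spread = sc$priming_spread,
          genome_length = sc$phage_genome_length,
          host_genome_length = sc$host_genome_length,
          spacer_length = sc$spacer_length,
          sample = sprintf("d%02d", sc$days[i]),
          seed = cfg$seed + 100 + i
        ))
      }))
      synth <- synthesize_amplicons(
        recs, phage_genome, host_genome, sc$repeat_seq,
        spacer_length = sc$spacer_length, pam_motif = sc$pam_motif,
        pam_side = sc$pam_side, priming_center = sc$priming_center,
        priming_spread = sc$priming_spread, noise_rate = sc$noise_rate,
        seed = cfg$seed + 13
      )
      reads <- size_filter(synth$reads)
      # dereplicate before repeat-anchored extraction, then restore counts
      derep <- dplyr::count(reads, .data$sequence, .data$sample,
                            name = "count")
      uniq_seqs <- distinct(derep, .data$sequence)
      uniq_seqs$id <- sprintf("u%06d", seq_len(nrow(uniq_seqs)))
      spacers <- extract_spacers(uniq_seqs, sc$repeat_seq)
      spacers <- spacers[!spacers$partial, ]
      per_sample <- spacers %>%
        left_join(uniq_seqs, by = "id") %>%
        left_join(derep, by = "sequence") %>%
        group_by(sequence = .data$spacer, sample = .data$sample) %>%
        summarise(count = sum(.data$count), .groups = "drop")
      variants <- per_sample %>%
        group_by(.data$sequence) %>%
        summarise(count = sum(.data$count), .groups = "drop")
      clusters <- swarm_cluster(variants, d = sc$d)
      clusters <- filter_clusters(clusters, min_size = sc$min_size)
      abundance <- assign_abundance(per_sample, clusters,
                                    min_identity = sc$min_identity)
      centroid_records <- classify_spacers(
        tibble(sequence = clusters$centroid, cluster = clusters$cluster,
               count = clusters$total),
        phage_genome, host_genome, pam_motif = sc$pam_motif,
        pam_side = sc$pam_side, priming_center = sc$priming_center
      )
      centroid_fasta <- file.path(out_dir, "cluster_centroids.fasta")
      seqs <- Biostrings::DNAStringSet(clusters$centroid)
      names(seqs) <- sprintf("cluster%d count=%d", clusters$cluster,
                             as.integer(clusters$total))
      Biostrings::writeXStringSet(seqs, centroid_fasta)
      readr::write_tsv(abundance, file.path(out_dir, "abundance.tsv"))
      readr::write_tsv(centroid_records,
                       file.path(out_dir, "spacer_records.tsv"))
      list(value = list(records = synth$records, reads = reads,
                        clusters = clusters, abundance = abundance,
                        centroid_records = centroid_records),
           files = c("cluster_centroids.fasta", "abundance.tsv",
                     "spacer_records.tsv"))
    })
  }

  if ("estimators" %in% stages) {
    results$estimators <- run_stage("estimators", function() {
      if (is.null(results$spacers)) {
        abort("the estimators stage needs the spacers stage.",
              class = "crisprcost_config_error")
      }
      abundance <- results$spacers$abundance
      mat <- abundance_matrix(abundance)
      div <- list_rbind(map(rownames(mat), function(s) {
        x <- mat[s, ]
        tibble(sample = s,
               day = as.integer(sub("^d", "", s)),
               reads = sum(x),
               observed = observed_variants(x),
               chao1 = chao1(x),
               shannon = shannon(x),
               simpson = simpson(x),
               simpson_evenness = simpson_evenness(x))
      }))
      rare <- rarefaction_curve(abundance, depths = cfg$diversity$depths,
                                reps = cfg$diversity$reps,
                                metric = cfg$diversity$metric,
                                seed = cfg$seed + 400)
      selftarget <- estimate_self_targeting(results$spacers$centroid_records)
      readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))
      readr::write_tsv(rare, file.path(out_dir, "rarefaction.tsv"))
      write_json_out(glance(selftarget),
                     file.path(out_dir, "self_targeting.json"))
      list(value = list(diversity = div, rarefaction = rare,
                        self_targeting = selftarget),
           files = c("diversity.tsv", "rarefaction.tsv",
                     "self_targeting.json"))
    })
  }

  if ("competition" %in% stages) {
    results$competition <- run_stage("competition", function() {
      cc <- cfg$competition
      grid <- tidyr::expand_grid(titre_idx = seq_along(cc$titres),
                                 replicate = seq_len(cc$replicates))
      fits <- list_rbind(pmap(grid, function(titre_idx, replicate) {
        counts <- simulate_competition(
          s_true = cc$s_true[titre_idx], x0 = cc$x0, days = cc$days,
          colonies = cc$colonies,
          seed = cfg$seed + 300 + 10 * titre_idx + replicate)
        fit <- selection_coefficient(counts, pseudo_count = 0.5,
                                     seed = cfg$seed + 500 +
                                       10 * titre_idx + replicate)
        tibble(titre = cc$titres[titre_idx], replicate = replicate,
               s_true = cc$s_true[titre_idx], s_hat = fit$s,
               conf_low = fit$conf_int[1], conf_high = fit$conf_int[2],
               relative_fitness = 1 + fit$s)
      }))
      readr::write_tsv(fits, file.path(out_dir, "fitness.tsv"))
      list(value = fits, files = "fitness.tsv")
    })
  }

  if ("expression" %in% stages) {
    results$expression <- run_stage("expression", function() {
      ec <- cfg$expression
      expr <- simulate_expression(expr_sim_params(
        n_host_genes = ec$n_host_genes, n_phage_genes = ec$n_phage_genes,
        timepoints = ec$timepoints, n_replicates = ec$n_replicates,
        phage_attenuation = ec$phage_attenuation,
        nb_dispersion = ec$nb_dispersion, library_size = ec$library_size,
        phage_share = ec$phage_share, seed = cfg$seed + 200
      ))
      profiles <- phage_gene_profiles(expr, genotype = "WT")
      programme <- cluster_programme(profiles, k = ec$k,
                                     linkage = ec$linkage)
      fractions <- phage_read_fraction(expr)
      fold <- fold_difference(
        fractions[fractions$minutes > 0, ], "WT", "BIM2",
        seed = cfg$seed + 201)
      readr::write_tsv(expr, file.path(out_dir, "expression_counts.tsv"))
      readr::write_tsv(profiles, file.path(out_dir, "phage_profiles.tsv"))
      readr::write_tsv(tidy(programme), file.path(out_dir, "programme.tsv"))
      readr::write_tsv(fractions, file.path(out_dir, "phage_fractions.tsv"))
      write_json_out(glance(fold), file.path(out_dir, "fold_difference.json"))
      list(value = list(expr = expr, profiles = profiles,
                        programme = programme, fractions = fractions,
                        fold = fold),
           files = c("expression_counts.tsv", "phage_profiles.tsv",
                     "programme.tsv", "phage_fractions.tsv",
                     "fold_difference.json"))
    })
  }

  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}

placeholder_panel <- function(name) {
  ggplot() +
    annotate("text", x = 0, y = 0, label = sprintf("missing: %s", name)) +
    theme_bw() +
    theme(axis.text = element_blank(), axis.ticks = element_blank(),
          axis.title = element_blank())
}

#' Build the six-panel report from pipeline results
#'
#' Renders genotype-frequency trajectories, phage titres, diversity through
#' time, phage-read-fraction summaries, the transcriptional programme
#' (dendrogram and clustered profiles) and the scenario classification table.
#' Missing stages yield a placeholder panel carrying an explicit gap marker;
#' the number of gaps is attached as attribute `"n_gaps"`. Regeneration from
#' the same results is idempotent.
#'
#' @param results The `results` element returned by [run_pipeline()].
#' @return A named list of six panels (`frequencies`, `titres`, `diversity`,
#'   `phage_fractions`, `programme`, `scenarios`); `programme` is itself a
#'   list of two ggplots (dendrogram and profiles).
#' @export
make_report <- function(results) {
  gaps <- 0L
  panel <- function(name, have, build) {
    if (isTRUE(have)) build() else {
      gaps <<- gaps + 1L
      placeholder_panel(name)
    }
  }
  out <- list(
    frequencies = panel("frequencies", !is.null(results$dynamics),
                        function() plot_frequencies(results$dynamics$trajectory)),
    titres = panel("titres", !is.null(results$dynamics),
                   function() plot_titres(results$dynamics$trajectory)),
    diversity = panel("diversity", !is.null(results$estimators),
                      function() plot_diversity_time(
                        results$estimators$diversity, value = "shannon")),
    phage_fractions = panel("phage_fractions", !is.null(results$expression),
                            function() plot_phage_fractions(
                              results$expression$fractions)),
    programme = panel("programme", !is.null(results$expression),
                      function() plot_programme(
                        results$expression$programme, which = "both")),
    scenarios = panel("scenarios", !is.null(results$dynamics),
                      function() plot_scenarios(results$dynamics$scenarios))
  )
  attr(out, "n_gaps") <- gaps
  if (gaps > 0) {
    warn(sprintf("report generated with %d missing panel(s).", gaps))
  }
  out
}

#' Run the end-to-end demonstration
#'
#' Generates and analyses the whole synthetic study with one seed: serial
#' transfer dynamics and scenarios, amplicon clustering and diversity,
#' self-targeting and fitness estimation, expression programme clustering,
#' and the six-panel report. Deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param write_plots Also render the report to `report.pdf` in `out_dir`.
#' @return Invisibly, a list with `results`, `manifest`, `report`, `out_dir`.
#' @export
run_demo <- function(out_dir = tempfile("crisprcost-demo-"), seed = 42,
                     write_plots = TRUE) {
  run <- run_pipeline(list(seed = seed), out_dir = out_dir)
  report <- make_report(run$results)
  if (write_plots) {
    grDevices::pdf(file.path(out_dir, "report.pdf"), width = 8, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (p in report) {
      if (inherits(p, "ggplot")) print(p) else for (q in p) print(q)
    }
  }
  invisible(list(results = run$results, manifest = run$manifest,
                 report = report, out_dir = out_dir))
}
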