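#' Parameters for the spacer-acquisition generator
#'
#' Bundles and validates the parameters of [simulate_spacers()], which emulates
#' a deep-sequenced CRISPR locus after a burst of (mostly primed) spacer
#' acquisition: most new spacers target the phage genome near the priming
#' site, a small fraction target the host's own genome, and each acquisition
#' uses either a canonical or a non-canonical PAM.
#'
#' @param n_events Number of spacer-acquisition events (distinct new spacers).
#' @param frac_self Fraction of acquisitions that target the host genome
#'   (self-targeting), in `[0, 1]`.
#' @param pam_canonical_ratio Background ratio `rho` of canonical to
#'   non-canonical PAM acquisitions (> 0).
#' @param selection_against_self_canonical Survival multiplier in `[0, 1]`
#'   applied to the abundance of cells carrying a canonical-PAM self-targeting
#'   spacer (autoimmune lethality) before reads are sampled. `1` means no
#'   selection; `0` removes them entirely.
#' @param read_depth Total reads sampled per sample (multinomial depth).
#' @param priming_center Genome coordinate of the priming protospacer; phage
#'   protospacer positions concentrate around it.
#' @param priming_spread Spread (bp) of the discretised Laplace kernel used
#'   for phage protospacer positions.
#' @param genome_length Length of the phage genome (bp).
#' @param host_genome_length Length of the host genome (bp); self-targeting
#'   protospacers are uniform over it.
#' @param spacer_length Length of generated spacer sequences (nt).
#' @param sample Sample label attached to every record.
#' @param seed RNG seed; identical seeds give identical datasets.
#'
#' @return A validated list of class `spacer_sim_params`.
#' @seealso [simulate_spacers()]
#' @export
spacer_sim_params <- function(n_events = 1e4,
                              frac_self = 0.01,
                              pam_canonical_ratio = 2,
                              selection_against_self_canonical = 1,
                              read_depth = 1e6,
                              priming_center = 27847,
                              priming_spread = 2000,
                              genome_length = 36415,
                              host_genome_length = 6537648,
                              spacer_length = 32,
                              sample = "S1",
                              seed = 1L) {
  check_count(n_events, "n_events", lower = 1)
  check_prob(frac_self, "frac_self")
  check_number(pam_canonical_ratio, "pam_canonical_ratio", lower = 1e-12)
  check_prob(selection_against_self_canonical,
             "selection_against_self_canonical")
  check_count(read_depth, "read_depth", lower = 1)
  check_count(priming_center, "priming_center", lower = 0)
  check_number(priming_spread, "priming_spread", lower = 1e-12)
  check_count(genome_length, "genome_length", lower = 1)
  check_count(host_genome_length, "host_genome_length", lower = 1)
  check_count(spacer_length, "spacer_length", lower = 15)
  if (read_depth < n_events) {
    abort("`read_depth` must be at least `n_events`.",
          class = "crisprcost_validation_error")
  }
  if (priming_center > genome_length) {
    abort("`priming_center` must lie within `genome_length`.",
          class = "crisprcost_validation_error")
  }
  structure(list(
    n_events = n_events, frac_self = frac_self,
    pam_canonical_ratio = pam_canonical_ratio,
    selection_against_self_canonical = selection_against_self_canonical,
    read_depth = read_depth, priming_center = priming_center,
    priming_spread = priming_spread, genome_length = genome_length,
    host_genome_length = host_genome_length, spacer_length = spacer_length,
    sample = sample, seed = seed
  ), class = "spacer_sim_params")
}

# Discretised, genome-truncated Laplace draw around `center` (resampling
# rejection keeps the kernel shape instead of piling mass at the ends).
rlaplace_coord <- function(n, center, spread, min_coord, max_coord) {
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- round(center +
                    rexp(length(todo), rate = 1 / spread) *
                    sample(c(-1L, 1L), length(todo), replace = TRUE))
    ok <- draw >= min_coord & draw <= max_coord
    out[todo[ok]] <- as.integer(draw[ok])
    todo <- todo[!ok]
  }
  out
}

#' Simulate a spacer-acquisition dataset
#'
#' Draws `n_events` distinct spacer acquisitions (target: phage or host; PAM:
#' canonical or non-canonical; phage protospacer coordinates concentrated
#' around the priming site), applies the survival penalty to canonical-PAM
#' self-targeting acquisitions, and samples `read_depth` reads multinomially
#' across the surviving abundance weights. Events drawing zero reads are
#' unobserved and dropped from the returned table.
#'
#' @param params A [spacer_sim_params()] object.
#'
#' @return A tibble of spacer records with columns `spacer_id`, `sequence`,
#'   `target` (`"phage"`/`"host"`), `pam` (`"canonical"`/`"non-canonical"`),
#'   `coordinate` (protospacer position; phage coordinates follow the
#'   priming-centred distribution, host coordinates are uniform), `count`
#'   (reads) and `sample`. Counts sum to `read_depth`.
#' @examples
#' sp <- simulate_spacers(spacer_sim_params(n_events = 100, read_depth = 1000))
#' dplyr::count(sp, target, pam, wt = count)
#' @export
simulate_spacers <- function(params = spacer_sim_params()) {
  if (!inherits(params, "spacer_sim_params")) {
    abort("`params` must be created with `spacer_sim_params()`.",
          class = "crisprcost_validation_error")
  }
  with_seed_or_not(params$seed, {
    n <- params$n_events
    target <- sample(c("host", "phage"), n, replace = TRUE,
                     prob = c(params$frac_self, 1 - params$frac_self))
    p_can <- params$pam_canonical_ratio / (1 + params$pam_canonical_ratio)
    pam <- sample(c("canonical", "non-canonical"), n, replace = TRUE,
                  prob = c(p_can, 1 - p_can))
    coordinate <- integer(n)
    is_phage <- target == "phage"
    max_start <- params$genome_length - params$spacer_length
    if (any(is_phage)) {
      coordinate[is_phage] <- rlaplace_coord(
        sum(is_phage), params$priming_center, params$priming_spread,
        0L, max_start
      )
    }
    if (any(!is_phage)) {
      coordinate[!is_phage] <- as.integer(floor(runif(
        sum(!is_phage), 0, params$host_genome_length - params$spacer_length
      )))
    }
    sequence <- random_dna(n, params$spacer_length)
    while (anyDuplicated(sequence) > 0) {
      dup <- duplicated(sequence)
      sequence[dup] <- random_dna(sum(dup), params$spacer_length)
    }
    weight <- ifelse(target == "host" & pam == "canonical",
                     params$selection_against_self_canonical, 1)
    if (all(weight == 0)) {
      abort("all acquisition events have zero surviving weight; nothing to sequence.",
            class = "crisprcost_validation_error")
    }
    count <- as.vector(rmultinom(1, size = params$read_depth, prob = weight))
    tibble(
      spacer_id = sprintf("sp%06d", seq_len(n)),
      sequence = sequence, target = target, pam = pam,
      coordinate = coordinate, count = count, sample = params$sample
    ) %>% filter(.data$count > 0)
  })
}

#' Sample clone phenotypes from genotype frequencies
#'
#' Emulates phenotyping a fixed number of clones streaked from a population:
#' a multinomial draw of `n_clones` clones from the (sensitive, CRISPR-immune,
#' surface-mutant) frequency vector.
#'
#' @param freqs Numeric vector of three non-negative frequencies (sensitive,
#'   CRISPR-immune, surface mutant) summing to 1 within `1e-9`.
#' @param n_clones Number of clones sampled (default 24).
#' @param seed Optional RNG seed.
#'
#' @return A tibble with columns `phenotype` and `count`; counts sum to
#'   `n_clones`.
#' @examples
#' sample_clone_phenotypes(c(0.2, 0.5, 0.3), n_clones = 24, seed = 1)
#' @export
sample_clone_phenotypes <- function(freqs, n_clones = 24, seed = NULL) {
  if (!is.numeric(freqs) || length(freqs) != 3 || any(!is.finite(freqs))) {
    abort("`freqs` must be three finite frequencies (sensitive, crispr, surface).",
          class = "crisprcost_validation_error")
  }
  if (any(freqs < 0)) {
    abort("`freqs` must be non-negative.",
          class = "crisprcost_validation_error")
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    abort("`freqs` must sum to 1 (tolerance 1e-9).",
          class = "crisprcost_validation_error")
  }
  check_count(n_clones, "n_clones", lower = 1)
  counts <- with_seed_or_not(seed,
                             as.vector(rmultinom(1, n_clones, prob = freqs)))
  tibble(phenotype = c("sensitive", "crispr", "surface"), count = counts)
}
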