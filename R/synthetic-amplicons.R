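#' Generate a random genome sequence
#'
#' @param length Genome length (bp).
#' @param seed Optional RNG seed.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed = NULL) {
  check_count(length, "length", lower = 1)
  with_seed_or_not(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

# Protospacer start positions (0-based) whose PAM dinucleotide at the
# configured side equals / differs from the canonical motif. Forward strand.
pam_position_pools <- function(genome, spacer_length, pam_motif, pam_side) {
  n <- nchar(genome)
  pl <- nchar(pam_motif)
  if (pam_side == "3prime") {
    starts <- 0:(n - spacer_length - pl)
    pam_at <- substring(genome, starts + spacer_length + 1,
                        starts + spacer_length + pl)
  } else {
    starts <- pl:(n - spacer_length)
    pam_at <- substring(genome, starts - pl + 1, starts)
  }
  list(canonical = starts[pam_at == pam_motif],
       noncanonical = starts[pam_at != pam_motif])
}

#' Synthesise merged amplicon reads consistent with reference genomes
#'
#' Turns a table of simulated spacer-acquisition records into the raw inputs
#' of the amplicon workflow: synthetic phage and host genomes, protospacer
#' positions chosen so that each record's target and PAM class is recoverable
#' by [classify_spacers()], and one merged amplicon read
#' (repeat + spacer + repeat) per sequenced read, with optional substitution
#' noise to create satellite variants for clustering.
#'
#' Phage protospacers are drawn (without replacement) from PAM-compatible
#' positions weighted by a Laplace kernel around `priming_center`; host
#' protospacers are drawn uniformly from PAM-compatible positions.
#'
#' @param records Spacer records from [simulate_spacers()] (columns
#'   `spacer_id`, `target`, `pam`, `count`, `sample`).
#' @param phage_genome,host_genome Genome strings (see [random_genome()]).
#' @param repeat_seq CRISPR repeat used to flank each spacer.
#' @param spacer_length Protospacer/spacer length (nt).
#' @param pam_motif,pam_side Canonical PAM convention (see
#'   [classify_spacers()]).
#' @param priming_center,priming_spread Laplace positional kernel for phage
#'   protospacers.
#' @param locus Locus label for the reads.
#' @param noise_rate Fraction of reads receiving one random substitution in
#'   the spacer region.
#' @param seed Optional RNG seed.
#'
#' @return A list with `reads` (tibble `id`, `sequence`, `sample`, `locus`),
#'   `records` (the input with genome-consistent `sequence`, `coordinate` and
#'   `strand`), `phage_genome`, `host_genome`, `repeat_seq`.
#' @export
synthesize_amplicons <- function(records, phage_genome, host_genome,
                                 repeat_seq,
                                 spacer_length = 32,
                                 pam_motif = "GG",
                                 pam_side = c("3prime", "5prime"),
                                 priming_center = 27847,
                                 priming_spread = 2000,
                                 locus = "CRISPR2",
                                 noise_rate = 0.005,
                                 seed = NULL) {
  check_columns(records, c("spacer_id", "target", "pam", "count", "sample"),
                "records")
  check_dna(phage_genome, "phage_genome")
  check_dna(host_genome, "host_genome")
  check_dna(repeat_seq, "repeat_seq")
  pam_side <- match.arg(pam_side)
  check_prob(noise_rate, "noise_rate")
  with_seed_or_not(seed, {
    pools <- list(
      phage = pam_position_pools(phage_genome, spacer_length, pam_motif,
                                 pam_side),
      host = pam_position_pools(host_genome, spacer_length, pam_motif,
                                pam_side)
    )
    rec <- as_tibble(records)
    rec$coordinate <- NA_integer_
    rec$strand <- "+"
    for (tg in c("phage", "host")) {
      for (pc in c("canonical", "non-canonical")) {
        idx <- which(rec$target == tg & rec$pam == pc)
        if (length(idx) == 0) next
        pool <- pools[[tg]][[if (pc == "canonical") "canonical"
                             else "noncanonical"]]
        if (length(pool) < length(idx)) {
          abort(sprintf(
            "genome too short: only %d %s-PAM positions in the %s genome for %d records.",
            length(pool), pc, tg, length(idx)),
            class = "crisprcost_validation_error")
        }
        w <- if (tg == "phage") {
          exp(-abs(pool + spacer_length / 2 - priming_center) / priming_spread)
        } else {
          rep(1, length(pool))
        }
        rec$coordinate[idx] <- sample(pool, length(idx), prob = w)
      }
    }
    genome_of <- c(phage = phage_genome, host = host_genome)
    rec$sequence <- substring(genome_of[rec$target], rec$coordinate + 1,
                              rec$coordinate + spacer_length)
    # distinct spacers: drop the rare chance collisions of genome substrings
    rec <- rec[!duplicated(rec$sequence), ]

    reads <- rec[rep(seq_len(nrow(rec)), rec$count),
                 c("spacer_id", "sequence", "sample")]
    n_reads <- nrow(reads)
    noisy <- which(runif(n_reads) < noise_rate)
    if (length(noisy) > 0) {
      pos <- sample.int(spacer_length, length(noisy), replace = TRUE)
      base <- sample(c("A", "C", "G", "T"), length(noisy), replace = TRUE)
      substr(reads$sequence[noisy], pos, pos) <- base
    }
    reads <- tibble(
      id = sprintf("read%06d", seq_len(n_reads)),
      sequence = paste0(repeat_seq, reads$sequence, repeat_seq),
      sample = reads$sample,
      locus = locus
    )
    list(reads = reads, records = rec, phage_genome = phage_genome,
         host_genome = host_genome, repeat_seq = repeat_seq)
  })
}
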