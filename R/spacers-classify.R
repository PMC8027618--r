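# Exact hits of `pattern` (forward) and its reverse complement (minus strand)
# against a genome string. Coordinates are 0-based, half-open, forward strand.
exact_hits <- function(pattern, genome) {
  g <- Biostrings::DNAString(genome)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(pattern), g)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(pattern)), g)
  bind_rows(
    tibble(start = Biostrings::start(fwd) - 1L,
           end = Biostrings::end(fwd), strand = "+"),
    tibble(start = Biostrings::start(rev) - 1L,
           end = Biostrings::end(rev), strand = "-")
  )
}

# PAM dinucleotide read on the protospacer strand at the configured side.
# `start`/`end` are 0-based half-open forward-strand coordinates.
read_pam <- function(genome, start, end, strand, pam_side, pam_length) {
  n <- nchar(genome)
  if (pam_side == "3prime") {
    if (strand == "+") {
      if (end + pam_length > n) return(NA_character_)
      substr(genome, end + 1, end + pam_length)
    } else {
      if (start - pam_length < 0) return(NA_character_)
      reverse_complement(substr(genome, start - pam_length + 1, start))
    }
  } else {
    if (strand == "+") {
      if (start - pam_length < 0) return(NA_character_)
      substr(genome, start - pam_length + 1, start)
    } else {
      if (end + pam_length > n) return(NA_character_)
      reverse_complement(substr(genome, end + 1, end + pam_length))
    }
  }
}

#' Classify spacers against phage and host genomes with PAM annotation
#'
#' Searches each spacer (and its reverse complement) for an exact match in
#' the phage genome first, then in the host genome. On a hit, the PAM motif
#' adjacent to the protospacer (by default the dinucleotide 3' of the
#' protospacer on the protospacer strand) is read and compared with the
#' canonical motif. Spacers matching neither genome are labelled
#' `target = "unknown"`, `pam = NA`. When a spacer matches a genome more than
#' once, the hit nearest `priming_center` wins (phage) or the first hit wins
#' (host), and the ambiguity is recorded in the `ambiguous` column.
#'
#' @param spacers Tibble with a `sequence` column (additional columns such as
#'   `count` and `sample` are carried through), or a character vector.
#' @param phage_genome,host_genome Genome sequences (single strings).
#' @param pam_motif Canonical PAM motif (default `"GG"`).
#' @param pam_side Side of the protospacer the PAM is read from, on the
#'   protospacer strand: `"3prime"` (default) or `"5prime"`.
#' @param priming_center Phage coordinate used to resolve multiple hits.
#'
#' @return A tibble of spacer records: input columns plus `target`
#'   (`"phage"`/`"host"`/`"unknown"`), `pam` (`"canonical"`/`"non-canonical"`/
#'   `NA`), `coordinate` (0-based start), `end`, `strand`, `pam_seq`,
#'   `ambiguous`.
#' @export
classify_spacers <- function(spacers, phage_genome, host_genome,
                             pam_motif = "GG",
                             pam_side = c("3prime", "5prime"),
                             priming_center = 27847) {
  if (is.character(spacers)) spacers <- tibble(sequence = spacers)
  check_columns(spacers, "sequence", "spacers")
  check_dna(phage_genome, "phage_genome")
  check_dna(host_genome, "host_genome")
  check_dna(pam_motif, "pam_motif")
  pam_side <- match.arg(pam_side)
  if (nchar(phage_genome) == 0 || nchar(host_genome) == 0) {
    abort("genomes must be non-empty.", class = "crisprcost_validation_error")
  }
  short <- nchar(spacers$sequence) < 15
  if (any(short)) {
    abort(sprintf(
      "%d spacer(s) shorter than 15 nt: mapping would be ambiguous.",
      sum(short)), class = "crisprcost_length_error")
  }
  pam_length <- nchar(pam_motif)
  uniq <- distinct(spacers, .data$sequence)
  cls <- map(uniq$sequence, function(sp) {
    for (tg in c("phage", "host")) {
      genome <- if (tg == "phage") phage_genome else host_genome
      hits <- exact_hits(sp, genome)
      if (nrow(hits) == 0) next
      ambiguous <- nrow(hits) > 1
      if (ambiguous && tg == "phage") {
        mid <- (hits$start + hits$end) / 2
        hits <- hits[which.min(abs(mid - priming_center)), ]
      } else {
        hits <- hits[1, ]
      }
      pam_seq <- read_pam(genome, hits$start, hits$end, hits$strand,
                          pam_side, pam_length)
      return(tibble(
        target = tg,
        pam = if (is.na(pam_seq)) NA_character_ else
          if (pam_seq == pam_motif) "canonical" else "non-canonical",
        coordinate = hits$start, end = hits$end, strand = hits$strand,
        pam_seq = pam_seq, ambiguous = ambiguous
      ))
    }
    tibble(target = "unknown", pam = NA_character_,
           coordinate = NA_integer_, end = NA_integer_,
           strand = NA_character_, pam_seq = NA_character_,
           ambiguous = FALSE)
  })
  uniq <- dplyr::bind_cols(uniq, list_rbind(cls))
  left_join(spacers, uniq, by = "sequence")
}
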