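#' Read merged amplicon sequences from FASTA
#'
#' Headers are expected to carry `sample=<id>;locus=<CRISPR1|CRISPR2>` fields
#' (any other `key=value` fields are ignored).
#'
#' @param path Path to a FASTA file of merged amplicon sequences.
#' @return A tibble with columns `id`, `sequence`, `sample`, `locus`.
#' @export
read_amplicon_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  grab <- function(key) {
    m <- regmatches(headers, regexpr(sprintf("%s=[^;[:space:]]+", key), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(sprintf("%s=", key), headers)
    out[hit] <- sub(sprintf("^%s=", key), "", m)
    out
  }
  tibble(
    id = sub("[[:space:]].*$", "", headers),
    sequence = as.character(seqs),
    sample = grab("sample"),
    locus = grab("locus")
  )
}

#' Write amplicon reads to FASTA
#'
#' @param reads Tibble with columns `id`, `sequence`, `sample`, `locus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(reads, path) {
  check_columns(reads, c("id", "sequence", "sample", "locus"), "reads")
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- sprintf("%s sample=%s;locus=%s",
                         reads$id, reads$sample, reads$locus)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Locus-specific merged-read length windows (bp, inclusive).
locus_size_ranges <- list(CRISPR1 = c(30L, 140L), CRISPR2 = c(70L, 500L))

#' Size-select merged amplicon reads by locus
#'
#' Removes reads whose merged length falls outside the locus window
#' (30-140 bp for CRISPR1, 70-500 bp for CRISPR2, bounds inclusive), which
#' discards primer-dimer and spurious-amplification products. Input order is
#' preserved.
#'
#' @param reads Tibble with at least `sequence` and `locus` columns.
#' @param ranges Named list of `c(min, max)` windows per locus.
#' @return The filtered tibble.
#' @export
size_filter <- function(reads, ranges = locus_size_ranges) {
  check_columns(reads, c("sequence", "locus"), "reads")
  unknown <- setdiff(unique(reads$locus), names(ranges))
  if (length(unknown) > 0) {
    abort(sprintf("unknown locus value(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "crisprcost_validation_error")
  }
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$sequence)
  lo <- map_dbl(reads$locus, ~ ranges[[.x]][1])
  hi <- map_dbl(reads$locus, ~ ranges[[.x]][2])
  reads[len >= lo & len <= hi, ]
}

# Non-overlapping repeat occurrences (<= max_mismatches substitutions),
# greedy left to right.
find_repeats <- function(sequence, repeat_seq, max_mismatches) {
  hits <- Biostrings::matchPattern(repeat_seq, Biostrings::DNAString(sequence),
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE)
  if (length(hits) == 0) return(NULL)
  starts <- Biostrings::start(hits)
  ends <- Biostrings::end(hits)
  keep <- integer(0)
  last_end <- 0L
  for (i in order(starts)) {
    if (starts[i] > last_end) {
      keep <- c(keep, i)
      last_end <- ends[i]
    }
  }
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract spacers from merged amplicon reads by repeat anchoring
#'
#' Locates every occurrence of the CRISPR repeat (allowing up to
#' `max_mismatches` substitutions) in each read and returns the inter-repeat
#' segments as spacers, in 5' to 3' order. Segments flanked by a repeat on
#' only one side (the read boundary truncates the array) are returned flagged
#' `partial`.
#'
#' @param reads Tibble with columns `id`, `sequence` (plus any metadata
#'   columns, which are carried through), or a single sequence string.
#' @param repeat_seq The repeat sequence (>= 8 nt).
#' @param max_mismatches Substitutions tolerated per repeat occurrence
#'   (default 2).
#'
#' @return A tibble with one row per extracted spacer: the read's metadata
#'   columns plus `spacer`, `position` (rank within the read) and `partial`.
#'   Reads without repeat hits contribute no rows.
#' @export
extract_spacers <- function(reads, repeat_seq, max_mismatches = 2) {
  if (is.character(reads)) {
    reads <- tibble(id = sprintf("read%d", seq_along(reads)), sequence = reads)
  }
  check_columns(reads, c("id", "sequence"), "reads")
  check_dna(repeat_seq, "repeat_seq")
  if (nchar(repeat_seq) < 8) {
    abort("`repeat_seq` must be at least 8 nt long.",
          class = "crisprcost_validation_error")
  }
  check_count(max_mismatches, "max_mismatches", lower = 0)
  if (length(unique(strsplit(repeat_seq, "")[[1]])) == 1) {
    warn("`repeat_seq` is a homopolymer; repeat anchoring will be unreliable.")
  }
  meta_cols <- setdiff(names(reads), "sequence")
  rows <- map(seq_len(nrow(reads)), function(i) {
    seq_i <- reads$sequence[i]
    rep_hits <- find_repeats(seq_i, repeat_seq, max_mismatches)
    if (is.null(rep_hits)) return(NULL)
    segs <- list()
    if (rep_hits$start[1] > 1) {
      segs[[length(segs) + 1]] <- list(
        spacer = substr(seq_i, 1, rep_hits$start[1] - 1), partial = TRUE)
    }
    if (nrow(rep_hits) > 1) {
      for (j in seq_len(nrow(rep_hits) - 1)) {
        s <- rep_hits$end[j] + 1
        e <- rep_hits$start[j + 1] - 1
        if (e >= s) {
          segs[[length(segs) + 1]] <- list(
            spacer = substr(seq_i, s, e), partial = FALSE)
        }
      }
    }
    if (rep_hits$end[nrow(rep_hits)] < nchar(seq_i)) {
      segs[[length(segs) + 1]] <- list(
        spacer = substr(seq_i, rep_hits$end[nrow(rep_hits)] + 1, nchar(seq_i)),
        partial = TRUE)
    }
    if (length(segs) == 0) return(NULL)
    out <- tibble(
      spacer = map_chr(segs, "spacer"),
      partial = vapply(segs, function(s) s$partial, logical(1)),
      position = seq_along(segs)
    )
    dplyr::bind_cols(reads[rep(i, nrow(out)), meta_cols, drop = FALSE], out)
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(id = character(), spacer = character(),
                  partial = logical(), position = integer()))
  }
  out
}
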