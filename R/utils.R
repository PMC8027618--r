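# Internal validation helpers. All user-facing errors name the offending field.

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field),
          class = "crisprcost_validation_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", field,
                  format(lower), format(upper), format(x)),
          class = "crisprcost_validation_error")
  }
  invisible(x)
}

check_count <- function(x, field, lower = 0L) {
  check_number(x, field, lower = lower)
  if (x != floor(x)) {
    abort(sprintf("`%s` must be a whole number.", field),
          class = "crisprcost_validation_error")
  }
  invisible(as.integer(min(x, .Machine$integer.max)))
}

check_prob <- function(x, field) check_number(x, field, lower = 0, upper = 1)

check_counts_vector <- function(x, field = "counts") {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be a non-empty vector of finite non-negative numbers.",
                  field), class = "crisprcost_validation_error")
  }
  if (sum(x) <= 0) {
    abort(sprintf("`%s` must contain at least one positive count.", field),
          class = "crisprcost_validation_error")
  }
  invisible(x)
}

check_dna <- function(x, field) {
  if (!is.character(x) || any(is.na(x)) || any(!grepl("^[ACGT]+$", x))) {
    abort(sprintf("`%s` must be DNA over the alphabet {A,C,G,T}.", field),
          class = "crisprcost_validation_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, field = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", field),
          class = "crisprcost_validation_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.", field,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "crisprcost_validation_error")
  }
  invisible(df)
}

# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hypergeometric subsample of a count vector to a fixed depth (without
# replacement); exact and O(depth log k).
subsample_counts <- function(x, depth) {
  total <- sum(x)
  if (depth >= total) return(x)
  cs <- cumsum(x)
  idx <- sample.int(total, depth)
  bins <- findInterval(idx - 0.5, cs) + 1L
  tabulate(bins, nbins = length(x))
}
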