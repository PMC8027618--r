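#' Simulate colony counts from a pairwise competition assay
#'
#' Emulates a blue/white competition between a marked and an unmarked strain:
#' the marked-strain frequency starts at `x0`, its log-odds drift linearly at
#' `s_true` per day, and at each of the two plating timepoints the marked
#' colony count is a binomial draw among `colonies` plated colonies.
#'
#' @param s_true True per-day selection coefficient of the marked strain
#'   (change in log-odds of its frequency per day).
#' @param x0 Initial marked fraction, strictly inside (0, 1).
#' @param days Competition duration in days (>= 0).
#' @param colonies Colonies scored per timepoint (> 0).
#' @param seed Optional RNG seed.
#'
#' @return A tibble with one row per timepoint: `day`, `marked`, `unmarked`.
#'   Row counts sum to `colonies` at each timepoint.
#' @examples
#' simulate_competition(s_true = 0.5, x0 = 0.5, days = 3,
#'                      colonies = 500, seed = 1)
#' @seealso [selection_coefficient()]
#' @export
simulate_competition <- function(s_true, x0 = 0.5, days = 3,
                                 colonies = 500, seed = NULL) {
  check_number(s_true, "s_true")
  check_number(x0, "x0", lower = 0, upper = 1)
  if (x0 <= 0 || x0 >= 1) {
    abort("`x0` must be strictly between 0 and 1 (a 0/100 mixture cannot compete).",
          class = "crisprcost_degenerate_input_error")
  }
  check_number(days, "days", lower = 0)
  check_count(colonies, "colonies", lower = 1)
  x_final <- inv_logit(logit(x0) + s_true * days)
  with_seed_or_not(seed, {
    m0 <- rbinom(1, colonies, x0)
    m1 <- rbinom(1, colonies, x_final)
    tibble(
      day = c(0, days),
      marked = c(m0, m1),
      unmarked = c(colonies - m0, colonies - m1)
    )
  })
}
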