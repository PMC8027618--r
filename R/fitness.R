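#' Selection coefficient from competition colony counts
#'
#' The per-day selection coefficient of the marked (focal) strain is the slope
#' of the log-odds of its frequency over the competition:
#' \deqn{s = [\mathrm{logit}(x_t) - \mathrm{logit}(x_0)] / t}
#' with `x` the focal fraction among scored colonies and `t` in days. A
#' percentile bootstrap confidence interval (resampling colonies binomially at
#' each timepoint) is attached.
#'
#' @param counts Competition table as produced by [simulate_competition()]:
#'   tibble with columns `day`, `marked`, `unmarked`; the first and last rows
#'   are used.
#' @param pseudo_count Value added to every colony count when a zero count
#'   makes the logit infinite. Off (`0`) by default; when used, the adjustment
#'   is recorded in the result.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @param conf_level Confidence level.
#' @param seed Optional RNG seed for the bootstrap.
#'
#' @return An object of class `competition_fit` with elements `s` (per day),
#'   `x0`, `x_final`, `days`, `conf_int`, `pseudo_count`. Supports [tidy()],
#'   [glance()] and `print()`.
#' @examples
#' cc <- simulate_competition(s_true = 1, x0 = 0.5, days = 3,
#'                            colonies = 1e4, seed = 1)
#' selection_coefficient(cc)
#' @export
selection_coefficient <- function(counts, pseudo_count = 0, n_boot = 1000,
                                  conf_level = 0.95, seed = NULL) {
  check_columns(counts, c("day", "marked", "unmarked"), "counts")
  if (nrow(counts) < 2) {
    abort("`counts` needs at least two timepoints.",
          class = "crisprcost_validation_error")
  }
  check_number(pseudo_count, "pseudo_count", lower = 0)
  first <- counts[1, ]
  last <- counts[nrow(counts), ]
  days <- last$day - first$day
  if (days <= 0) {
    abort("competition duration must be positive.",
          class = "crisprcost_validation_error")
  }
  raw <- c(first$marked, first$unmarked, last$marked, last$unmarked)
  if (any(raw == 0) && pseudo_count == 0) {
    abort(paste0("a colony count of zero makes the log-odds infinite; ",
                 "rerun with `pseudo_count = 0.5` to apply the standard ",
                 "continuity correction."),
          class = "crisprcost_boundary_error")
  }
  if (pseudo_count > 0) {
    inform(sprintf("applying pseudo-count %.2f to all colony counts.",
                   pseudo_count))
  }
  adj <- raw + pseudo_count
  x0 <- adj[1] / (adj[1] + adj[2])
  x1 <- adj[3] / (adj[3] + adj[4])
  s <- (logit(x1) - logit(x0)) / days
  n0 <- first$marked + first$unmarked
  n1 <- last$marked + last$unmarked
  boot <- with_seed_or_not(seed, {
    m0 <- rbinom(n_boot, n0, x0) + pseudo_count
    m1 <- rbinom(n_boot, n1, x1) + pseudo_count
    b0 <- m0 / (n0 + 2 * pseudo_count)
    b1 <- m1 / (n1 + 2 * pseudo_count)
    keep <- b0 > 0 & b0 < 1 & b1 > 0 & b1 < 1
    (logit(b1[keep]) - logit(b0[keep])) / days
  })
  alpha <- (1 - conf_level) / 2
  ci <- if (length(boot) > 0) {
    unname(quantile(boot, c(alpha, 1 - alpha)))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(s = s, x0 = x0, x_final = x1, days = days,
                 conf_int = ci, conf_level = conf_level,
                 pseudo_count = pseudo_count, n_boot = n_boot),
            class = "competition_fit")
}

#' Relative fitness from a competition
#'
#' When absolute abundances are available (`focal0`, `focal1`, `comp0`,
#' `comp1` columns: start/end population sizes of focal strain and
#' competitor), relative fitness is the ratio of Malthusian growth,
#' `ln(focal fold change) / ln(competitor fold change)`. With colony
#' frequencies only, it is reported as `1 + s` per day, with `s` from
#' [selection_coefficient()].
#'
#' @param counts Competition table (see [selection_coefficient()]), optionally
#'   with absolute-abundance columns.
#' @param ... Passed on to [selection_coefficient()] in the frequency-based
#'   case.
#' @return A single numeric relative fitness.
#' @export
relative_fitness <- function(counts, ...) {
  abs_cols <- c("focal0", "focal1", "comp0", "comp1")
  if (all(abs_cols %in% names(counts))) {
    row <- counts[1, ]
    if (any(unlist(row[abs_cols]) <= 0)) {
      abort("absolute abundances must be positive for Malthusian fitness.",
            class = "crisprcost_validation_error")
    }
    return(log(row$focal1 / row$focal0) / log(row$comp1 / row$comp0))
  }
  1 + selection_coefficient(counts, ...)$s
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Competition fit\n")
  cat(sprintf("  selection coefficient: %.4f per day (%d%% CI %.4f to %.4f)\n",
              x$s, round(100 * x$conf_level), x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  focal fraction: %.3f at T0 -> %.3f after %g day(s)\n",
              x$x0, x$x_final, x$days))
  if (x$pseudo_count > 0) {
    cat(sprintf("  pseudo-count %.2f applied\n", x$pseudo_count))
  }
  invisible(x)
}

#' @method tidy competition_fit
#' @export
tidy.competition_fit <- function(x, ...) {
  tibble(term = "s", estimate = x$s,
         conf.low = x$conf_int[1], conf.high = x$conf_int[2])
}

#' @method glance competition_fit
#' @export
glance.competition_fit <- function(x, ...) {
  tibble(s = x$s, x0 = x$x0, x_final = x$x_final, days = x$days,
         conf.low = x$conf_int[1], conf.high = x$conf_int[2],
         pseudo_count = x$pseudo_count)
}
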