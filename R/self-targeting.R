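#' Estimate the frequency of self-targeting spacer acquisition
#'
#' Canonical-PAM self-targeting spacers are autoimmune and purged so fast that
#' counting them directly underestimates how often cells acquire them.
#' Non-canonical-PAM self-targeting spacers, by contrast, are (nearly) neutral
#' and accumulate at the background acquisition rate. This estimator therefore
#' multiplies the read fraction of non-canonical self-targeting arrays by the
#' background canonical:non-canonical acquisition ratio, measured among
#' phage-targeting spacers (which are not subject to autoimmune selection):
#' \deqn{\hat f_{self} = f_{self}^{nc} \times \hat\rho}
#' where \eqn{\hat\rho} is the ratio of canonical to non-canonical
#' phage-targeting spacer *types* (or reads, if `rho_from = "reads"`), and
#' \eqn{f_{self}^{nc}} is the fraction of all reads in host-targeting
#' non-canonical-PAM records.
#'
#' @param records Spacer record tibble with columns `sequence`, `target`,
#'   `pam`, `count` (as produced by [classify_spacers()] or
#'   [simulate_spacers()]).
#' @param rho_from Count spacer `"types"` (default; distinct sequences, less
#'   distorted by post-acquisition selection) or `"reads"` when estimating the
#'   background PAM ratio.
#'
#' @return An object of class `self_target_estimate` with elements
#'   `f_self_cells` (the estimate), `percent`, `rho_hat`, `f_self_nc`, and the
#'   underlying counts (`n_phage_canonical`, `n_phage_noncanonical`,
#'   `reads_self_nc`, `reads_total`). Supports [tidy()], [glance()] and
#'   `print()`.
#' @examples
#' rec <- simulate_spacers(spacer_sim_params(n_events = 5000, frac_self = 0.01,
#'                                           read_depth = 5e5))
#' estimate_self_targeting(rec)
#' @export
estimate_self_targeting <- function(records, rho_from = c("types", "reads")) {
  check_columns(records, c("sequence", "target", "pam", "count"), "records")
  rho_from <- match.arg(rho_from)
  reads_total <- sum(records$count)
  if (reads_total <= 0) {
    abort("`records` contain no reads.",
          class = "crisprcost_validation_error")
  }
  phage <- records[records$target == "phage" & !is.na(records$pam), ]
  n_can <- n_distinct(phage$sequence[phage$pam == "canonical"])
  n_noncan <- n_distinct(phage$sequence[phage$pam == "non-canonical"])
  reads_can <- sum(phage$count[phage$pam == "canonical"])
  reads_noncan <- sum(phage$count[phage$pam == "non-canonical"])
  if (n_noncan == 0 || n_can == 0) {
    abort(paste0("background PAM ratio is undefined: need at least one ",
                 "phage-targeting spacer of each PAM class."),
          class = "crisprcost_undefined_ratio_error")
  }
  rho_hat <- if (rho_from == "types") n_can / n_noncan
             else reads_can / reads_noncan
  self_nc <- records$target == "host" &
    !is.na(records$pam) & records$pam == "non-canonical"
  reads_self_nc <- sum(records$count[self_nc])
  f_self_nc <- reads_self_nc / reads_total
  f_self_cells <- f_self_nc * rho_hat
  structure(list(
    f_self_cells = f_self_cells,
    percent = 100 * f_self_cells,
    rho_hat = rho_hat,
    f_self_nc = f_self_nc,
    rho_from = rho_from,
    n_phage_canonical = n_can,
    n_phage_noncanonical = n_noncan,
    reads_self_nc = reads_self_nc,
    reads_total = reads_total
  ), class = "self_target_estimate")
}

#' @export
print.self_target_estimate <- function(x, ...) {
  cat("Self-targeting acquisition estimate\n")
  cat(sprintf("  estimated self-targeting cell fraction: %.3g (%.4g%%)\n",
              x$f_self_cells, x$percent))
  cat(sprintf("  background canonical:non-canonical ratio (rho, from %s): %.3g\n",
              x$rho_from, x$rho_hat))
  cat(sprintf("  non-canonical self-targeting read fraction: %.3g (%d / %d reads)\n",
              x$f_self_nc, x$reads_self_nc, x$reads_total))
  cat(sprintf("  phage-targeting spacer types: %d canonical, %d non-canonical\n",
              x$n_phage_canonical, x$n_phage_noncanonical))
  invisible(x)
}

#' @method tidy self_target_estimate
#' @export
tidy.self_target_estimate <- function(x, ...) {
  tibble(
    term = c("f_self_cells", "rho_hat", "f_self_nc"),
    estimate = c(x$f_self_cells, x$rho_hat, x$f_self_nc)
  )
}

#' @method glance self_target_estimate
#' @export
glance.self_target_estimate <- function(x, ...) {
  tibble(
    f_self_cells = x$f_self_cells, percent = x$percent,
    rho_hat = x$rho_hat, f_self_nc = x$f_self_nc,
    n_phage_canonical = x$n_phage_canonical,
    n_phage_noncanonical = x$n_phage_noncanonical,
    reads_self_nc = x$reads_self_nc, reads_total = x$reads_total
  )
}
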