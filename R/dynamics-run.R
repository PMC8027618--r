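#' Run a serial-transfer evolution experiment
#'
#' Alternates [integrate_day()] and [apply_transfer()] for `n_days` transfers
#' and records the end-of-day state (before the transfer) together with the
#' genotype frequencies among bacteria. The model is a deterministic ODE, so
#' trajectories are exactly reproducible.
#'
#' @param params A [model_params()] object.
#' @param protocol A [transfer_protocol()] object.
#' @param init_freqs Initial genotype frequencies (sensitive, CRISPR-immune,
#'   surface mutant) of the inoculum; must sum to 1.
#' @param rtol,atol Integrator tolerances.
#'
#' @return A tibble of class `transfer_trajectory` with one row per day
#'   (day 0 = the inoculated state): columns `day`, `S`, `C`, `M`, `V`, `E`,
#'   `freq_S`, `freq_C`, `freq_M`. The `params` and `protocol` are attached
#'   as attributes.
#' @examples
#' traj <- run_serial_transfer(protocol = transfer_protocol(n_days = 3))
#' glance(traj)
#' @export
run_serial_transfer <- function(params = model_params(),
                                protocol = transfer_protocol(),
                                init_freqs = c(0.45, 0.45, 0.10),
                                rtol = 1e-8, atol = 1e-6) {
  if (!is.numeric(init_freqs) || length(init_freqs) != 3 ||
      any(init_freqs < 0) || abs(sum(init_freqs) - 1) > 1e-9) {
    abort("`init_freqs` must be three non-negative frequencies summing to 1.",
          class = "crisprcost_validation_error")
  }
  vol <- protocol$culture_volume
  state <- population_state(
    S = protocol$S0 / vol * init_freqs[1],
    C = protocol$S0 / vol * init_freqs[2],
    M = protocol$S0 / vol * init_freqs[3],
    V = protocol$V0 / vol
  )
  rows <- vector("list", protocol$n_days + 1)
  rows[[1]] <- state_row(0, state)
  if (protocol$n_days > 0) {
    for (day in seq_len(protocol$n_days)) {
      state <- tryCatch(
        integrate_day(state, params, protocol$day_length,
                      rtol = rtol, atol = atol),
        crisprcost_numerical_error = function(e) {
          abort(sprintf("integration failed on day %d: %s", day,
                        conditionMessage(e)),
                class = "crisprcost_numerical_error")
        }
      )
      rows[[day + 1]] <- state_row(day, state)
      state <- apply_transfer(state, protocol)
    }
  }
  out <- list_rbind(rows)
  structure(out, class = c("transfer_trajectory", class(out)),
            params = params, protocol = protocol)
}

state_row <- function(day, state) {
  y <- as_state_vector(state)
  total <- y[["S"]] + y[["C"]] + y[["M"]]
  f <- if (total > 0) y[c("S", "C", "M")] / total else c(S = NA, C = NA, M = NA)
  tibble(day = day, S = y[["S"]], C = y[["C"]], M = y[["M"]],
         V = y[["V"]], E = y[["E"]],
         freq_S = unname(f[1]), freq_C = unname(f[2]), freq_M = unname(f[3]))
}

#' Classify the fate of the CRISPR-immune genotype in a trajectory
#'
#' `"extinct"` if the final CRISPR density corresponds to less than one cell
#' per culture; otherwise `"decline"` if the final CRISPR:surface-mutant
#' frequency ratio fell below the initial ratio by more than `tol`; otherwise
#' `"no_decline"`.
#'
#' @param trajectory A `transfer_trajectory` tibble (length >= 2).
#' @param culture_volume Culture volume in mL used for the one-cell threshold;
#'   defaults to the protocol attached to the trajectory.
#' @param tol Tolerance on the ratio change.
#'
#' @return One of `"decline"`, `"no_decline"`, `"extinct"`.
#' @export
classify_outcome <- function(trajectory, culture_volume = NULL, tol = 1e-3) {
  check_columns(trajectory, c("day", "C", "freq_C", "freq_M"), "trajectory")
  if (nrow(trajectory) < 2) {
    abort("`trajectory` must contain at least two days.",
          class = "crisprcost_validation_error")
  }
  culture_volume <- culture_volume %||%
    attr(trajectory, "protocol")$culture_volume %||% 6
  last <- trajectory[nrow(trajectory), ]
  if (last$C * culture_volume < 1) return("extinct")
  ratio <- function(row) {
    if (row$freq_M <= 0) Inf else row$freq_C / row$freq_M
  }
  r0 <- ratio(trajectory[1, ])
  r1 <- ratio(last)
  if (is.infinite(r0) && is.infinite(r1)) return("no_decline")
  if (r0 - r1 > tol) "decline" else "no_decline"
}

#' Run the three model scenarios contrasting sources of the CRISPR cost
#'
#' Reruns the serial-transfer competition under three parameterisations that
#' isolate the candidate mechanisms of the infection-induced cost:
#' * `baseline` — induced toxicity on, self-targeting off
#'   (`tau_tox` as given, `q_self = 0`);
#' * `no_cost_no_acquisition` — no induced cost and no spacer acquisition
#'   (`tau_tox = 0`, `p = 0`);
#' * `no_cost_high_self_targeting` — no induced cost but frequent lethal
#'   self-targeting acquisition (`tau_tox = 0`, `p = 0.5`, `q_self = 0.9`).
#'
#' Each run starts from the same standing variation and is classified with
#' [classify_outcome()].
#'
#' @param params Baseline [model_params()]; scenario overrides are applied on
#'   top of it.
#' @param protocol A [transfer_protocol()] object.
#' @param init_freqs Initial genotype frequencies.
#'
#' @return A tibble with one row per scenario: the overridden parameters, the
#'   initial and final CRISPR:surface-mutant frequency ratios, and `outcome`.
#' @examples
#' \donttest{
#' run_scenarios(protocol = transfer_protocol(n_days = 10))
#' }
#' @export
run_scenarios <- function(params = model_params(),
                          protocol = transfer_protocol(),
                          init_freqs = c(0.45, 0.45, 0.10)) {
  overrides <- list(
    baseline = list(q_self = 0),
    no_cost_no_acquisition = list(tau_tox = 0, p = 0),
    no_cost_high_self_targeting = list(tau_tox = 0, p = 0.5, q_self = 0.9)
  )
  rows <- imap(overrides, function(ov, name) {
    pp <- params
    pp[names(ov)] <- ov
    traj <- run_serial_transfer(pp, protocol, init_freqs)
    first <- traj[1, ]; last <- traj[nrow(traj), ]
    tibble(
      scenario = name,
      tau_tox = pp$tau_tox, p = pp$p, q_self = pp$q_self,
      initial_ratio = first$freq_C / first$freq_M,
      final_ratio = last$freq_C / last$freq_M,
      final_freq_C = last$freq_C, final_freq_M = last$freq_M,
      outcome = classify_outcome(traj)
    )
  })
  list_rbind(rows)
}

#' @method glance transfer_trajectory
#' @export
glance.transfer_trajectory <- function(x, ...) {
  tibble(
    n_days = max(x$day),
    peak_freq_C = max(x$freq_C, na.rm = TRUE),
    day_peak_C = x$day[which.max(x$freq_C)],
    final_freq_S = x$freq_S[nrow(x)],
    final_freq_C = x$freq_C[nrow(x)],
    final_freq_M = x$freq_M[nrow(x)],
    final_V = x$V[nrow(x)],
    outcome = classify_outcome(x)
  )
}

#' @method tidy transfer_trajectory
#' @export
tidy.transfer_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("S", "C", "M", "V", "E",
                               "freq_S", "freq_C", "freq_M"),
                      names_to = "quantity", values_to = "value")
}

#' Plot genotype frequencies along a serial-transfer trajectory
#'
#' @param trajectory A `transfer_trajectory` tibble.
#' @return A ggplot object.
#' @export
plot_frequencies <- function(trajectory) {
  df <- tidyr::pivot_longer(as_tibble(trajectory),
                            cols = c("freq_S", "freq_C", "freq_M"),
                            names_to = "genotype", values_to = "frequency")
  df$genotype <- factor(df$genotype, c("freq_S", "freq_C", "freq_M"),
                        c("sensitive", "CRISPR-immune", "surface mutant"))
  ggplot(df, aes(x = .data$day, y = .data$frequency,
                 colour = .data$genotype)) +
    geom_line(linewidth = 0.8) + geom_point(size = 1) +
    scale_colour_brewer(palette = "Dark2") +
    labs(x = "day", y = "genotype frequency", colour = NULL) +
    theme_bw()
}

#' Plot phage titres along a serial-transfer trajectory
#'
#' @param trajectory A `transfer_trajectory` tibble.
#' @param floor Detection floor (PFU/mL) used to keep the log axis finite.
#' @return A ggplot object.
#' @export
plot_titres <- function(trajectory, floor = 1) {
  df <- as_tibble(trajectory)
  df$titre <- pmax(df$V + df$E, floor)
  ggplot(df, aes(x = .data$day, y = .data$titre)) +
    geom_line(colour = "grey30", linewidth = 0.8) + geom_point(size = 1) +
    scale_y_log10() +
    labs(x = "day", y = "phage titre (PFU/mL)") +
    theme_bw()
}

#' @method autoplot transfer_trajectory
#' @export
autoplot.transfer_trajectory <- function(object, ...) {
  plot_frequencies(object)
}
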