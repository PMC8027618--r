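#' Eco-evolutionary model parameters
#'
#' Parameters of the within-day dynamics of sensitive (S), CRISPR-immune (C)
#' and surface-mutant (M) bacteria competing under lytic phage (V) pressure.
#' Growth is logistic with a shared carrying capacity; S infections are lytic;
#' C infections are cleared by CRISPR interference but kill the cell with
#' probability `tau_tox + p * q_self` (induced toxicity plus lethal
#' self-targeting acquisition); M has lost the receptor and is never adsorbed,
#' at a constitutive growth cost `c_sm`.
#'
#' Defaults are order-of-magnitude standards for a *Pseudomonas*-phage batch
#' system; every value can be overridden.
#'
#' @param r Maximal growth rate (per hour).
#' @param K Carrying capacity (CFU/mL).
#' @param c_sm Constitutive fitness cost of surface mutation, in `[0, 1)`.
#' @param a Phage adsorption rate (mL per hour).
#' @param b Burst size (phage per lysis).
#' @param d Free-phage decay rate (per hour).
#' @param tau_tox Probability that an infection of a CRISPR-immune cell kills
#'   it despite clearance (the induced cost), in `[0, 1]`.
#' @param p Probability of spacer acquisition per surviving infection,
#'   in `[0, 1]`.
#' @param q_self Fraction of acquisitions that are self-targeting (lethal),
#'   in `[0, 1]`.
#' @param mu_sm Per-division probability that a sensitive division yields a
#'   surface mutant.
#' @param mu_bim Per-infection probability that a sensitive cell survives the
#'   infection by acquiring CRISPR immunity (such infections do not burst).
#' @param mu_escape Per-burst-progeny probability of an escape-phage mutant
#'   that evades CRISPR interference. Default 0, which reduces the model to
#'   its four-variable core; see the methods vignette before enabling.
#'
#' @return A validated list of class `model_params`.
#' @export
model_params <- function(r = 1, K = 1e9, c_sm = 0.05,
                         a = 1e-8, b = 50, d = 0.1,
                         tau_tox = 0.3, p = 0.01, q_self = 0,
                         mu_sm = 0, mu_bim = 0, mu_escape = 0) {
  check_number(r, "r", lower = 0)
  check_number(K, "K", lower = 1e-12)
  check_number(c_sm, "c_sm", lower = 0, upper = 1 - 1e-12)
  check_number(a, "a", lower = 0)
  check_number(b, "b", lower = 0)
  check_number(d, "d", lower = 0)
  check_prob(tau_tox, "tau_tox")
  check_prob(p, "p")
  check_prob(q_self, "q_self")
  check_prob(mu_sm, "mu_sm")
  check_prob(mu_bim, "mu_bim")
  check_prob(mu_escape, "mu_escape")
  structure(list(r = r, K = K, c_sm = c_sm, a = a, b = b, d = d,
                 tau_tox = tau_tox, p = p, q_self = q_self,
                 mu_sm = mu_sm, mu_bim = mu_bim, mu_escape = mu_escape),
            class = "model_params")
}

#' Serial-transfer protocol
#'
#' The daily batch-transfer regime of the evolution experiment: 1:100 dilution
#' into fresh medium every 24 h for 30 days, with ancestral phage re-added at
#' every transfer to maintain selection.
#'
#' @param dilution Fraction carried over per transfer (0 < dilution < 1).
#' @param phage_added PFU of ancestral phage added per transfer.
#' @param culture_volume Culture volume (mL); converts total PFU/CFU to
#'   per-mL densities.
#' @param n_days Number of transfers.
#' @param day_length Hours per growth cycle.
#' @param S0 Bacterial inoculum (total cells).
#' @param V0 Initial phage (total PFU).
#'
#' @return A validated list of class `transfer_protocol`.
#' @export
transfer_protocol <- function(dilution = 0.01, phage_added = 1e7,
                              culture_volume = 6, n_days = 30,
                              day_length = 24, S0 = 1e6, V0 = 1e7) {
  check_number(dilution, "dilution", lower = 1e-12, upper = 1 - 1e-12)
  check_number(phage_added, "phage_added", lower = 0)
  check_number(culture_volume, "culture_volume", lower = 1e-12)
  check_count(n_days, "n_days", lower = 0)
  check_number(day_length, "day_length", lower = 1e-12)
  check_number(S0, "S0", lower = 0)
  check_number(V0, "V0", lower = 0)
  structure(list(dilution = dilution, phage_added = phage_added,
                 culture_volume = culture_volume, n_days = n_days,
                 day_length = day_length, S0 = S0, V0 = V0),
            class = "transfer_protocol")
}

#' Create a population state
#'
#' @param S,C,M Densities of sensitive, CRISPR-immune and surface-mutant
#'   bacteria (CFU/mL).
#' @param V Phage density (PFU/mL).
#' @param E Escape-phage density (PFU/mL); only non-zero when the escape
#'   extension is in use.
#' @return A named numeric vector of class `population_state`.
#' @export
population_state <- function(S = 0, C = 0, M = 0, V = 0, E = 0) {
  state <- c(S = S, C = C, M = M, V = V, E = E)
  validate_state(state)
  structure(state, class = "population_state")
}

validate_state <- function(state) {
  need <- c("S", "C", "M", "V")
  if (!is.numeric(state) || !all(need %in% names(state))) {
    abort("a population state needs named entries S, C, M, V (optionally E).",
          class = "crisprcost_validation_error")
  }
  if (any(!is.finite(state))) {
    abort("population state contains non-finite densities.",
          class = "crisprcost_validation_error")
  }
  if (any(state < 0)) {
    abort(sprintf("population state contains negative densities (%s).",
                  paste(names(state)[state < 0], collapse = ", ")),
          class = "crisprcost_validation_error")
  }
  invisible(state)
}

as_state_vector <- function(state) {
  out <- c(S = 0, C = 0, M = 0, V = 0, E = 0)
  out[names(state)[names(state) %in% names(out)]] <-
    state[names(state) %in% names(out)]
  out
}

#' Within-day time derivative of the population state
#'
#' The batch-growth dynamics between transfers:
#' \deqn{dS/dt = r S g (1-\mu_{sm}) - a S V - a S E}
#' \deqn{dC/dt = r C g - a C V (\tau + p q) + \mu_{bim} a S V - a C E}
#' \deqn{dM/dt = r (1-c_{sm}) M g + \mu_{sm} r S g}
#' \deqn{dV/dt = b a S V (1-\mu_{bim})(1-\mu_{esc}) - a (S+C) V - d V}
#' with \eqn{g = 1 - N/K}, \eqn{N = S+C+M}. With the default
#' `mu_sm = mu_bim = mu_escape = 0` this is the four-variable core: surface
#' mutants are never adsorbed, CRISPR infections are cleared but kill the cell
#' with probability `tau_tox + p*q_self`, and every adsorption removes a free
#' phage. Escape phage (E) replicate on both S and C and arise as a fraction
#' `mu_escape` of burst progeny.
#'
#' @param state A named state vector (see [population_state()]).
#' @param params A [model_params()] object.
#'
#' @return Named numeric vector of derivatives (per hour) for S, C, M, V, E.
#' @export
phage_derivatives <- function(state, params = model_params()) {
  validate_state(state)
  derivative_core(as_state_vector(state), params)
}

# Derivative arithmetic without validation; the adaptive integrator may probe
# slightly negative densities, which are clamped here.
derivative_core <- function(y, params) {
  y <- pmax(y, 0)
  S <- y[["S"]]; C <- y[["C"]]; M <- y[["M"]]; V <- y[["V"]]; E <- y[["E"]]
  N <- S + C + M
  g <- 1 - N / params$K
  inf_SV <- params$a * S * V
  inf_SE <- params$a * S * E
  inf_CE <- params$a * C * E
  kill_prob <- params$tau_tox + params$p * params$q_self
  dS <- params$r * S * g * (1 - params$mu_sm) - inf_SV - inf_SE
  dC <- params$r * C * g - params$a * C * V * kill_prob +
    params$mu_bim * inf_SV - inf_CE
  dM <- params$r * (1 - params$c_sm) * M * g + params$mu_sm * params$r * S * g
  burst <- params$b * inf_SV * (1 - params$mu_bim)
  dV <- burst * (1 - params$mu_escape) - params$a * (S + C) * V - params$d * V
  dE <- burst * params$mu_escape + params$b * (inf_SE + inf_CE) -
    params$a * (S + C) * E - params$d * E
  c(S = dS, C = dC, M = dM, V = dV, E = dE)
}

#' Integrate the within-day dynamics over one growth cycle
#'
#' Adaptive integration (lsoda) of [phage_derivatives()] over `day_length`
#' hours. Densities are clipped at zero; the number of clipped entries is
#' attached as attribute `"clipped"`.
#'
#' @param state Named state vector at the start of the cycle.
#' @param params A [model_params()] object.
#' @param day_length Hours to integrate.
#' @param rtol,atol Relative/absolute tolerances passed to the integrator.
#'
#' @return The state at the end of the cycle (named numeric, class
#'   `population_state`).
#' @export
integrate_day <- function(state, params = model_params(), day_length = 24,
                          rtol = 1e-8, atol = 1e-6) {
  validate_state(state)
  check_number(day_length, "day_length", lower = 1e-12)
  y <- as_state_vector(state)
  if (all(y == 0)) {
    return(structure(y, class = "population_state"))
  }
  rhs <- function(t, y, parms) list(derivative_core(y, parms))
  sol <- try(deSolve::ode(y = y, times = c(0, day_length), func = rhs,
                          parms = params, method = "lsoda",
                          rtol = rtol, atol = atol, maxsteps = 50000),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < 2 ||
      any(!is.finite(sol[nrow(sol), -1]))) {
    abort(paste0(
      "within-day integration failed; state at failure: ",
      paste(sprintf("%s=%.4g", names(y), y), collapse = ", ")
    ), class = "crisprcost_numerical_error")
  }
  out <- sol[nrow(sol), -1]
  clipped <- sum(out < 0)
  out <- pmax(out, 0)
  structure(out, class = "population_state", clipped = clipped)
}

#' Apply a serial transfer to a state
#'
#' Multiplies every density by the dilution factor and adds the per-transfer
#' phage dose (`phage_added / culture_volume`) to the free-phage density.
#'
#' @param state Named state vector at the end of a growth cycle.
#' @param protocol A [transfer_protocol()] object.
#'
#' @return The post-transfer state.
#' @export
apply_transfer <- function(state, protocol = transfer_protocol()) {
  validate_state(state)
  y <- as_state_vector(state) * protocol$dilution
  y[["V"]] <- y[["V"]] + protocol$phage_added / protocol$culture_volume
  structure(y, class = "population_state")
}
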