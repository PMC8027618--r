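make_records <- function(n_phage_can, n_phage_noncan, reads_self_nc,
                         reads_total) {
  n <- n_phage_can + n_phage_noncan + 2
  filler <- reads_total - reads_self_nc -
    (n_phage_can + n_phage_noncan)
  tibble::tibble(
    sequence = sprintf("SP%04d", seq_len(n)),
    target = c(rep("phage", n_phage_can + n_phage_noncan), "host", "host"),
    pam = c(rep("canonical", n_phage_can),
            rep("non-canonical", n_phage_noncan),
            "non-canonical", "canonical"),
    count = c(rep(1, n_phage_can + n_phage_noncan), reads_self_nc, filler)
  )
}

test_that("self-targeting estimator applies its defining formula", {
  rec <- make_records(20, 10, 34, 1e6)
  est <- estimate_self_targeting(rec)
  expect_equal(est$rho_hat, 2)
  expect_equal(est$f_self_nc, 34 / 1e6)
  expect_equal(est$f_self_cells, 6.8e-5)
  expect_equal(est$percent, 0.0068)
})

test_that("self-targeting estimator identity and edge cases", {
  # rho = 1: the non-canonical read fraction is itself the estimate
  rec <- make_records(10, 10, 50, 1e4)
  est <- estimate_self_targeting(rec)
  expect_equal(est$f_self_cells, est$f_self_nc)

  # no host-targeting records at all
  phage_only <- make_records(5, 5, 0, 100)[1:10, ]
  expect_equal(estimate_self_targeting(phage_only)$f_self_cells, 0)

  # undefined background ratio
  no_noncan <- make_records(5, 1, 10, 100)
  no_noncan <- no_noncan[no_noncan$pam != "non-canonical" |
                           no_noncan$target == "host", ]
  expect_error(estimate_self_targeting(no_noncan),
               class = "crisprcost_undefined_ratio_error")

  zero <- make_records(2, 2, 0, 4)
  zero$count <- 0
  expect_error(estimate_self_targeting(zero),
               class = "crisprcost_validation_error")
})

test_that("rho can alternatively be estimated from reads", {
  rec <- make_records(20, 10, 34, 1e6)
  rec$count[1:20] <- 5   # canonical phage spacers more deeply covered
  est <- estimate_self_targeting(rec, rho_from = "reads")
  expect_equal(est$rho_hat, 100 / 10)
})

test_that("the estimator recovers the generating self-targeting rate", {
  # the estimand is the canonical-PAM self-targeting fraction
  # frac_self * rho / (1 + rho)
  frac_self <- 0.01
  rho <- 2
  truth <- frac_self * rho / (1 + rho)
  ests <- vapply(1:20, function(i) {
    rec <- simulate_spacers(spacer_sim_params(
      n_events = 5000, read_depth = 5e5, frac_self = frac_self,
      pam_canonical_ratio = rho, selection_against_self_canonical = 1,
      seed = 1000 + i))
    estimate_self_targeting(rec)$f_self_cells
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 3 * sd(ests) / sqrt(20))
})

test_that("the estimator is robust to strong selection against canonical self-targeters", {
  frac_self <- 0.02
  rho <- 2
  truth <- frac_self * rho / (1 + rho)
  naive <- numeric(10)
  corrected <- numeric(10)
  for (i in 1:10) {
    rec <- simulate_spacers(spacer_sim_params(
      n_events = 5000, read_depth = 5e5, frac_self = frac_self,
      pam_canonical_ratio = rho, selection_against_self_canonical = 0.02,
      seed = 2000 + i))
    naive[i] <- sum(rec$count[rec$target == "host"]) / sum(rec$count)
    corrected[i] <- estimate_self_targeting(rec)$f_self_cells
  }
  # the raw self-read fraction is biased far below the acquisition rate,
  # the PAM-ratio correction is not
  expect_lt(mean(naive), 0.6 * frac_self)
  expect_lt(abs(mean(corrected) - truth), 3 * sd(corrected) / sqrt(10))
})

test_that("selection coefficient recovers the logit slope", {
  flat <- tibble::tibble(day = c(0, 3), marked = c(500, 500),
                         unmarked = c(500, 500))
  expect_equal(selection_coefficient(flat)$s, 0)

  # marked:unmarked ratio of e^3 after 3 days -> s = 1 per day
  m <- round(1e6 * exp(3) / (1 + exp(3)))
  fast <- tibble::tibble(day = c(0, 3), marked = c(5e5, m),
                         unmarked = c(5e5, 1e6 - m))
  expect_equal(selection_coefficient(fast)$s, 1, tolerance = 1e-4)

  # swapping focal and competitor negates s
  swapped <- fast[, c("day", "unmarked", "marked")]
  names(swapped) <- c("day", "marked", "unmarked")
  expect_equal(selection_coefficient(swapped)$s,
               -selection_coefficient(fast)$s)
})

test_that("zero colony counts trigger the boundary error and pseudo-counts fix it", {
  cc <- tibble::tibble(day = c(0, 3), marked = c(50, 0),
                       unmarked = c(50, 100))
  expect_error(selection_coefficient(cc),
               class = "crisprcost_boundary_error")
  expect_message(fit <- selection_coefficient(cc, pseudo_count = 0.5),
                 "pseudo-count")
  expect_lt(fit$s, 0)
})

test_that("selection coefficient recovers the generating value within binomial error", {
  for (s_true in c(-0.5, 0, 0.5, 1)) {
    cc <- simulate_competition(s_true, x0 = 0.5, days = 3, colonies = 1e5,
                               seed = 3000 + round(10 * s_true))
    fit <- selection_coefficient(cc, seed = 1)
    x1 <- fit$x_final
    se <- sqrt(1 / (1e5 * 0.25) + 1 / (1e5 * x1 * (1 - x1))) / 3
    expect_lt(abs(fit$s - s_true), 3 * se)
    expect_true(fit$conf_int[1] <= fit$s && fit$s <= fit$conf_int[2])
  }
})

test_that("relative fitness uses Malthusian ratios when abundances are known", {
  abs_counts <- tibble::tibble(focal0 = 1e5, focal1 = 1e7,
                               comp0 = 1e5, comp1 = 1e6)
  expect_equal(relative_fitness(abs_counts), 2)

  freq_counts <- tibble::tibble(day = c(0, 2), marked = c(400, 600),
                                unmarked = c(600, 400))
  fit <- selection_coefficient(freq_counts)
  expect_equal(relative_fitness(freq_counts), 1 + fit$s)
})
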