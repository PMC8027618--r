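test_that("spacer generator respects forced parameter limits and determinism", {
  p0 <- spacer_sim_params(n_events = 200, frac_self = 0, read_depth = 5000,
                          seed = 7)
  rec <- simulate_spacers(p0)
  expect_true(all(rec$target == "phage"))
  expect_equal(sum(rec$count), 5000)
  expect_false(anyDuplicated(rec$sequence) > 0)

  rec2 <- simulate_spacers(p0)
  expect_identical(rec, rec2)

  p1 <- spacer_sim_params(n_events = 200, frac_self = 0, read_depth = 5000,
                          seed = 8)
  expect_false(identical(simulate_spacers(p1), rec))
})

test_that("spacer generator parameter validation names the offending field", {
  expect_error(spacer_sim_params(frac_self = 1.5), "frac_self",
               class = "crisprcost_validation_error")
  expect_error(spacer_sim_params(pam_canonical_ratio = 0),
               "pam_canonical_ratio", class = "crisprcost_validation_error")
  expect_error(spacer_sim_params(n_events = 1000, read_depth = 10),
               "read_depth", class = "crisprcost_validation_error")
})

test_that("empirical self fraction and PAM ratio match generating values", {
  rec <- simulate_spacers(spacer_sim_params(
    n_events = 1e4, read_depth = 1e6, frac_self = 0.01,
    pam_canonical_ratio = 2, selection_against_self_canonical = 1, seed = 11))
  n <- 1e4
  f_self <- sum(rec$count[rec$target == "host"]) / sum(rec$count)
  se_self <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(f_self - 0.01), 3 * se_self)

  p_can <- mean(rec$pam == "canonical")
  se_can <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(p_can - 2 / 3), 3 * se_can)
})

test_that("canonical self-targeting abundances are down-weighted by survival", {
  mk <- function(surv) {
    simulate_spacers(spacer_sim_params(
      n_events = 5000, read_depth = 5e5, frac_self = 0.2,
      selection_against_self_canonical = surv, seed = 3))
  }
  full <- mk(1)
  purged <- mk(0)
  share <- function(r) sum(r$count[r$target == "host" & r$pam == "canonical"]) /
    sum(r$count)
  expect_gt(share(full), 0.05)
  expect_identical(share(purged), 0)
})

test_that("phage protospacer coordinates concentrate at the priming site", {
  pp <- spacer_sim_params(n_events = 2000, read_depth = 2e4,
                          priming_center = 27847, priming_spread = 500,
                          seed = 5)
  rec <- simulate_spacers(pp)
  coords <- rec$coordinate[rec$target == "phage"]
  expect_true(all(coords >= 0 & coords <= pp$genome_length - pp$spacer_length))
  # median absolute deviation from the priming site ~ spread * ln 2
  expect_lt(median(abs(coords - 27847)), 3 * 500)
})

test_that("competition counts follow the logit-linear model", {
  cc <- simulate_competition(s_true = 0, x0 = 0.5, days = 3,
                             colonies = 1e5, seed = 1)
  x_end <- cc$marked[2] / (cc$marked[2] + cc$unmarked[2])
  expect_lt(abs(x_end - 0.5), 3 * sqrt(0.25 / 1e5))

  cc2 <- simulate_competition(s_true = 1, x0 = 0.5, days = 3,
                              colonies = 1e5, seed = 2)
  x3 <- cc2$marked[2] / 1e5
  se_logit <- sqrt(1 / (1e5 * x3 * (1 - x3)))
  expect_lt(abs(qlogis(x3) - 3), 3 * se_logit)

  expect_equal(cc$marked + cc$unmarked, c(1e5, 1e5))
})

test_that("competition generator rejects degenerate mixtures", {
  expect_error(simulate_competition(0, x0 = 0, days = 3, colonies = 10),
               class = "crisprcost_degenerate_input_error")
  expect_error(simulate_competition(0, x0 = 1, days = 3, colonies = 10),
               class = "crisprcost_degenerate_input_error")
  zero_day <- simulate_competition(0.8, x0 = 0.4, days = 0, colonies = 1e5,
                                   seed = 4)
  x <- zero_day$marked / 1e5
  expect_lt(abs(x[1] - x[2]), 3 * sqrt(2 * 0.24 / 1e5))
})

test_that("clone phenotype sampling is multinomial with the right mean", {
  expect_equal(sample_clone_phenotypes(c(1, 0, 0), 24, seed = 1)$count,
               c(24L, 0L, 0L))
  draws <- vapply(1:1e4, function(i) {
    sample_clone_phenotypes(c(0.2, 0.5, 0.3), 24)$count
  }, integer(3))
  expect_true(all(colSums(draws) == 24))
  means <- rowMeans(draws)
  expected <- 24 * c(0.2, 0.5, 0.3)
  se <- sqrt(24 * c(0.2, 0.5, 0.3) * (1 - c(0.2, 0.5, 0.3)) / 1e4)
  expect_true(all(abs(means - expected) < 3 * se))

  expect_error(sample_clone_phenotypes(c(-0.1, 0.6, 0.5), 24),
               class = "crisprcost_validation_error")
  expect_error(sample_clone_phenotypes(c(0.3, 0.3, 0.3), 24),
               class = "crisprcost_validation_error")
})

test_that("expression generator honours group structure", {
  par1 <- expr_sim_params(n_host_genes = 30, n_phage_genes = 9,
                          library_size = 2e4, seed = 21)
  expr <- simulate_expression(par1)
  uninf <- expr[expr$genotype == "BIM2-uninfected" & expr$origin == "phage", ]
  expect_true(all(uninf$count == 0))

  # attenuation = 1 makes WT and BIM2 phage means equal (same expectations)
  par_eq <- expr_sim_params(n_host_genes = 30, n_phage_genes = 9,
                            phage_attenuation = 1, nb_dispersion = 0,
                            library_size = 2e4, seed = 22)
  eq <- simulate_expression(par_eq)
  mean_by <- function(g) {
    sub <- eq[eq$origin == "phage" & eq$genotype == g, ]
    sum(sub$count)
  }
  expect_equal(mean_by("WT"), mean_by("BIM2"))

  expect_error(expr_sim_params(n_phage_genes = 5,
                               programme = list(early = 1:2, late = 3:6)),
               "unknown phage gene index",
               class = "crisprcost_validation_error")
  expect_error(expr_sim_params(timepoints = c(0, 60, 35)),
               class = "crisprcost_validation_error")
})

test_that("synthesized amplicons are recoverable by the downstream classifier", {
  phage <- random_genome(8000, seed = 31)
  host <- random_genome(8000, seed = 32)
  recs <- simulate_spacers(spacer_sim_params(
    n_events = 60, read_depth = 1200, frac_self = 0.2, genome_length = 8000,
    host_genome_length = 8000, priming_center = 4000, priming_spread = 800,
    seed = 33))
  synth <- synthesize_amplicons(recs, phage, host,
                                repeat_seq = "GTTCACTGCCGTATAGGCAG",
                                priming_center = 4000, priming_spread = 800,
                                noise_rate = 0, seed = 34)
  expect_equal(nrow(synth$reads), sum(synth$records$count))
  cls <- classify_spacers(synth$records["sequence"], phage, host,
                          priming_center = 4000)
  joined <- dplyr::left_join(synth$records, cls, by = "sequence",
                             suffix = c("_true", "_obs"))
  expect_equal(joined$target_obs, joined$target_true)
  expect_equal(joined$pam_obs, joined$pam_true)
})
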