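test_that("min-max normalisation rescales, flags constants and is idempotent", {
  expect_equal(as.numeric(minmax_normalize(c(2, 6, 10))), c(0, 0.5, 1))

  flat <- minmax_normalize(c(7, 7, 7))
  expect_equal(as.numeric(flat), c(0, 0, 0))
  expect_true(attr(flat, "constant"))

  once <- c(0, 0.5, 1)
  expect_equal(as.numeric(minmax_normalize(once)), once)

  expect_error(minmax_normalize(5), class = "crisprcost_validation_error")
})

test_that("replicate averaging is a plain symmetric mean and reports gaps", {
  expr <- simulate_expression(expr_sim_params(
    n_host_genes = 5, n_phage_genes = 3, n_replicates = 3,
    library_size = 5e3, seed = 41))
  avg <- average_replicates(expr, "WT")
  one <- expr[expr$genotype == "WT" & expr$gene == "phage_001" &
                expr$minutes == 35, ]
  expect_equal(avg$mean_count[avg$gene == "phage_001" & avg$minutes == 35],
               mean(one$count))
  expect_equal(unique(avg$n_replicates), 3)

  shuffled <- expr[sample(nrow(expr)), ]
  expect_equal(dplyr::arrange(average_replicates(shuffled, "WT"), gene,
                              minutes),
               dplyr::arrange(avg, gene, minutes))

  gappy <- expr[!(expr$genotype == "WT" & expr$minutes == 60), ]
  expect_error(average_replicates(gappy, "WT"), "60",
               class = "crisprcost_validation_error")
})

test_that("normalise-then-average differs from average-then-normalise", {
  # two replicates with different dynamic ranges
  expr <- tidyr::expand_grid(
    gene = "phage_001", origin = "phage", genotype = "WT",
    minutes = c(0, 35, 60), replicate = 1:2)
  expr$sample <- sprintf("WT_t%d_r%d", expr$minutes, expr$replicate)
  expr$count <- ifelse(expr$replicate == 1,
                       c(0, 10, 20)[match(expr$minutes, c(0, 35, 60))],
                       c(0, 90, 100)[match(expr$minutes, c(0, 35, 60))])
  nf <- phage_gene_profiles(expr, order = "normalize-first")
  af <- phage_gene_profiles(expr, order = "average-first")
  # at t = 35: normalise-first gives mean(0.5, 0.9) = 0.7,
  # average-first gives 50/60
  expect_equal(nf$value[nf$minutes == 35], 0.7)
  expect_equal(af$value[af$minutes == 35], 50 / 60)
  expect_false(isTRUE(all.equal(nf$value, af$value)))
})

test_that("programme clustering recovers planted classes and validates k", {
  shapes <- list(early = c(1, 0, 0, 0), middle = c(0, 1, 1, 0),
                 late = c(0, 0, 0, 1))
  build <- function(seed) {
    withr::with_seed(seed, {
      genes <- tidyr::expand_grid(cls = names(shapes), idx = 1:8)
      purrr::pmap(genes, function(cls, idx) {
        tibble::tibble(
          gene = sprintf("%s_%02d", cls, idx), class = cls,
          minutes = c(0, 35, 60, 120),
          value = pmin(1, pmax(0, shapes[[cls]] + rnorm(4, 0, 0.05))))
      }) |> purrr::list_rbind()
    })
  }
  prof <- build(51)
  pc <- cluster_programme(prof, k = 3)
  ass <- dplyr::left_join(tidy(pc),
                          dplyr::distinct(prof, gene, class), by = "gene")
  agreement <- max(apply(table(ass$cluster, ass$class), 1, max)) # sanity
  tab <- table(ass$cluster, ass$class)
  # every cluster is dominated by one class and recovery is exact here
  expect_equal(sum(apply(tab, 1, max)), 24)

  expect_error(cluster_programme(prof, k = 30),
               class = "crisprcost_validation_error")
  single <- cluster_programme(prof, k = 1)
  expect_equal(unique(tidy(single)$cluster), 1)

  # identical profiles in two groups, k = 2: groups recovered exactly
  dup <- tibble::tibble(
    gene = rep(c("a1", "a2", "b1", "b2"), each = 2),
    minutes = rep(c(0, 60), 4),
    value = c(0, 1, 0, 1, 1, 0, 1, 0))
  two <- cluster_programme(dup, k = 2)
  got <- tidy(two)
  expect_equal(got$cluster[got$gene == "a1"], got$cluster[got$gene == "a2"])
  expect_equal(got$cluster[got$gene == "b1"], got$cluster[got$gene == "b2"])
  expect_false(got$cluster[got$gene == "a1"] == got$cluster[got$gene == "b1"])
})

test_that("programme clustering is invariant to gene input order", {
  withr::with_seed(53, {
    prof <- tidyr::expand_grid(gene = sprintf("g%02d", 1:12),
                               minutes = c(0, 35, 60, 120))
    prof$value <- runif(nrow(prof))
  })
  a <- cluster_programme(prof, k = 3)
  b <- cluster_programme(prof[sample(nrow(prof)), ], k = 3)
  expect_identical(tidy(a), tidy(b))
})

test_that("phage read fractions partition the library", {
  expr <- simulate_expression(expr_sim_params(
    n_host_genes = 20, n_phage_genes = 8, library_size = 2e4, seed = 61))
  fr <- phage_read_fraction(expr)
  expect_true(all(fr$phage_fraction >= 0 & fr$phage_fraction <= 1))
  host_fraction <- expr |>
    dplyr::group_by(sample) |>
    dplyr::summarise(h = sum(count[origin == "host"]) / sum(count))
  joined <- dplyr::left_join(fr, host_fraction, by = "sample")
  expect_equal(joined$phage_fraction + joined$h, rep(1, nrow(joined)))
  uninf <- fr[fr$genotype == "BIM2-uninfected", ]
  expect_true(all(uninf$phage_fraction == 0))
})

test_that("fold difference recovers arithmetic and identity cases", {
  fr <- tibble::tibble(genotype = rep(c("WT", "BIM2"), each = 4),
                       phage_fraction = c(rep(0.5, 4), rep(0.1, 4)))
  fd <- fold_difference(fr, "WT", "BIM2", seed = 1)
  expect_equal(fd$estimate, 5)

  same <- fold_difference(
    tibble::tibble(genotype = rep(c("WT", "BIM2"), each = 3),
                   phage_fraction = rep(c(0.2, 0.3, 0.4), 2)),
    "WT", "BIM2", seed = 1)
  expect_equal(same$estimate, 1)

  zero <- tibble::tibble(genotype = c("WT", "BIM2"),
                         phage_fraction = c(0.5, 0))
  expect_error(fold_difference(zero, "WT", "BIM2"),
               class = "crisprcost_undefined_ratio_error")

  # bootstrap is seed-deterministic
  f1 <- fold_difference(fr, "WT", "BIM2", seed = 9)
  f2 <- fold_difference(fr, "WT", "BIM2", seed = 9)
  expect_identical(f1$conf_int, f2$conf_int)
})
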