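REPEAT <- "GTTCACTGCCGTATAGGCAG"

test_that("size selection applies locus-specific inclusive windows", {
  reads <- tibble::tibble(
    id = sprintf("r%d", 1:6),
    sequence = c(strrep("A", 150), strrep("A", 140), strrep("A", 30),
                 strrep("C", 70), strrep("C", 500), strrep("C", 501)),
    sample = "s1",
    locus = c("CRISPR1", "CRISPR1", "CRISPR1",
              "CRISPR2", "CRISPR2", "CRISPR2")
  )
  kept <- size_filter(reads)
  expect_equal(kept$id, c("r2", "r3", "r4", "r5"))

  expect_equal(nrow(size_filter(reads[0, ])), 0)
  bad <- reads
  bad$locus[1] <- "CRISPR9"
  expect_error(size_filter(bad), "CRISPR9",
               class = "crisprcost_validation_error")
})

test_that("repeat-anchored extraction returns inter-repeat segments in order", {
  sp1 <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  sp2 <- "TTTTCCCCAAAAGGGGTTTTCCCCAAAAGGGG"
  one <- extract_spacers(paste0(REPEAT, sp1, REPEAT), REPEAT)
  expect_equal(one$spacer, sp1)
  expect_false(one$partial)

  two <- extract_spacers(paste0(REPEAT, sp1, REPEAT, sp2, REPEAT), REPEAT)
  expect_equal(two$spacer, c(sp1, sp2))
  expect_equal(two$position, 1:2)

  none <- extract_spacers("ACGTACGTACGTACGT", REPEAT)
  expect_equal(nrow(none), 0)
})

test_that("extraction tolerates repeat mismatches and flags partial segments", {
  mutated <- REPEAT
  substr(mutated, 3, 3) <- "A"
  sp <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  out <- extract_spacers(paste0("TTAACC", REPEAT, sp, mutated, "GGCCAA"),
                         REPEAT, max_mismatches = 2)
  expect_equal(out$spacer[!out$partial], sp)
  expect_equal(sum(out$partial), 2)
  expect_true(all(c("TTAACC", "GGCCAA") %in% out$spacer[out$partial]))

  expect_error(extract_spacers("ACGT", "ACGT"),
               class = "crisprcost_validation_error")
  expect_warning(extract_spacers(paste0(strrep("A", 12), "CGCGCG"),
                                 strrep("A", 10)),
                 "homopolymer")
})

test_that("swarm clustering matches the worked examples", {
  cl <- swarm_cluster(tibble::tibble(sequence = c("ACGT", "ACGA", "TTTT"),
                                     count = c(10, 2, 5)), d = 1)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$centroid, c("ACGT", "TTTT"))
  expect_equal(cl$total, c(12, 5))

  chain <- swarm_cluster(tibble::tibble(
    sequence = c("AAAA", "AAAT", "AATT"), count = c(3, 2, 1)), d = 1)
  expect_equal(nrow(chain), 1)
  expect_equal(chain$total, 6)

  single <- swarm_cluster(tibble::tibble(sequence = "ACGT", count = 1), d = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$centroid, "ACGT")

  expect_error(swarm_cluster(tibble::tibble(sequence = c("AAAA", "AAAA"),
                                            count = c(1, 1))),
               "dereplicated", class = "crisprcost_validation_error")
})

test_that("swarm clustering links through indels, not just substitutions", {
  cl <- swarm_cluster(tibble::tibble(
    sequence = c("ACGTACGT", "ACGACGT", "ACGTTACGT"), count = c(5, 2, 1)),
    d = 1)
  expect_equal(nrow(cl), 1)
})

test_that("swarm clustering is invariant to input order and conserves counts", {
  withr::with_seed(17, {
    variants <- random_variant_set(60)
    cl <- swarm_cluster(variants, d = 1)
    shuffled <- variants[sample(nrow(variants)), ]
    cl2 <- swarm_cluster(shuffled, d = 1)
    expect_identical(cl, cl2)
    expect_equal(sum(cl$total), sum(variants$count))
  })
})

test_that("swarm clustering equals the connected-components oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(23, {
    for (i in 1:10) {
      variants <- random_variant_set(sample(20:120, 1))
      for (d in 1:2) {
        cl <- swarm_cluster(variants, d = d)
        got <- partition_signature(
          rep(seq_len(nrow(cl)), vapply(cl$members, nrow, integer(1))),
          unlist(lapply(cl$members, function(m) m$sequence)))
        want <- partition_signature(components_oracle(variants$sequence, d),
                                    variants$sequence)
        expect_identical(got, want)
      }
    }
  })
})

test_that("cluster size filtering uses total abundance with inclusive bound", {
  cl <- swarm_cluster(tibble::tibble(sequence = c("AAAA", "CCCC", "GGGG"),
                                     count = c(1, 2, 5)), d = 1)
  expect_equal(nrow(filter_clusters(cl, 2)), 2)
  expect_identical(filter_clusters(cl, 1), cl)
  expect_equal(filter_clusters(cl, 5)$centroid, "GGGG")
})

test_that("abundance assignment respects the identity threshold and conserves counts", {
  centroid <- strrep("ACGTT", 20)  # 100 bp
  two_mm <- centroid
  substr(two_mm, 1, 1) <- "T"; substr(two_mm, 50, 50) <- "G"
  one_mm <- centroid
  substr(one_mm, 10, 10) <- "C"
  clusters <- swarm_cluster(tibble::tibble(sequence = centroid, count = 50),
                            d = 1)
  seqs <- tibble::tibble(
    sequence = c(centroid, one_mm, two_mm),
    count = c(50, 10, 7),
    sample = c("s1", "s1", "s2"))
  ab <- assign_abundance(seqs, clusters, min_identity = 0.99)
  expect_equal(ab$count[ab$cluster == "1" & ab$sample == "s1"], 60)
  expect_equal(ab$count[ab$cluster == "unassigned" & ab$sample == "s2"], 7)
  # conservation per sample
  totals <- dplyr::count(ab, sample, wt = count)
  expect_equal(totals$n, c(60, 7))

  expect_error(assign_abundance(seqs, clusters[0, ]),
               class = "crisprcost_validation_error")
})

test_that("spacer classification reads target, PAM, strand and priming proximity", {
  sp <- "ACGTTGCAACGGTTAACCGGTTACAGTCGATT"
  phage_can <- planted_genome(sp, pam = "GG", seed = 101)
  host_nc <- planted_genome(sp, pam = "TA", seed = 102)
  neutral <- planted_genome("GGGG", pam = "TT", seed = 103)

  hit <- classify_spacers(sp, phage_can, neutral)
  expect_equal(hit$target, "phage")
  expect_equal(hit$pam, "canonical")
  expect_equal(hit$coordinate, 60)
  expect_equal(hit$strand, "+")

  host_hit <- classify_spacers(sp, neutral, host_nc)
  expect_equal(host_hit$target, "host")
  expect_equal(host_hit$pam, "non-canonical")

  miss <- classify_spacers(sp, neutral, neutral)
  expect_equal(miss$target, "unknown")
  expect_true(is.na(miss$pam))

  expect_error(classify_spacers("ACGTACGTAC", phage_can, neutral),
               class = "crisprcost_length_error")
})

test_that("classification is invariant under reverse complement", {
  sp <- "ACGTTGCAACGGTTAACCGGTTACAGTCGATT"
  genome <- planted_genome(sp, pam = "GG", seed = 104)
  fwd <- classify_spacers(sp, genome, planted_genome("GGGG", "TT", seed = 105))
  rc <- classify_spacers(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sp))),
    genome, planted_genome("GGGG", "TT", seed = 105))
  expect_equal(rc$target, fwd$target)
  expect_equal(rc$coordinate, fwd$coordinate)
  expect_equal(rc$strand, "-")
})

test_that("multiple phage hits resolve to the one nearest the priming site", {
  sp <- "ACGTTGCAACGGTTAACCGGTTACAGTCGATT"
  spacer_block <- paste0(sp, "GG")
  withr::with_seed(106, {
    gap <- paste(sample(c("A", "C", "T"), 400, replace = TRUE), collapse = "")
    genome <- paste0(spacer_block, gap, spacer_block)
  })
  near_first <- classify_spacers(sp, genome, planted_genome("GGGG", "TT"),
                                 priming_center = 10)
  expect_equal(near_first$coordinate, 0)
  expect_true(near_first$ambiguous)
  near_second <- classify_spacers(sp, genome, planted_genome("GGGG", "TT"),
                                  priming_center = nchar(genome) - 10)
  expect_equal(near_second$coordinate, nchar(spacer_block) + 400)
})
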