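#' Parameters for the infection time-course expression generator
#'
#' Bundles and validates the parameters of [simulate_expression()], which
#' emulates RNA-seq of phage-infected cultures sampled through a single
#' infection cycle: host genes with stable expression, phage genes following
#' an early/middle/late transcriptional programme, negative-binomial count
#' noise, and an overall attenuation of phage expression in CRISPR-immune
#' (BIM2) hosts that clear the infection.
#'
#' @param n_host_genes,n_phage_genes Gene counts per origin.
#' @param timepoints Minutes post infection (strictly increasing).
#' @param n_replicates Replicate cultures per genotype group.
#' @param genotypes Genotype groups; `"BIM2-uninfected"` receives no phage.
#' @param phage_attenuation Factor by which BIM2-infected phage-gene means are
#'   divided relative to WT-infected (>= 1).
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (`size = 1/nb_dispersion`); `0` gives deterministic (Poisson-free) means.
#' @param library_size Expected total reads per sample.
#' @param phage_share Expected share of the WT-infected library mapping to
#'   phage genes (kept small so that read *fractions* scale nearly linearly
#'   with phage means).
#' @param programme Assignment of phage genes to temporal classes: either a
#'   character vector of length `n_phage_genes` over
#'   `c("early","middle","late")`, or a named list of gene indices, e.g.
#'   `list(early = 1:10, middle = 11:25, late = 26:40)`. `NULL` splits genes
#'   into consecutive thirds.
#' @param seed RNG seed.
#'
#' @return A validated list of class `expr_sim_params`.
#' @export
expr_sim_params <- function(n_host_genes = 150,
                            n_phage_genes = 40,
                            timepoints = c(0, 35, 60, 120),
                            n_replicates = 5,
                            genotypes = c("WT", "BIM2", "BIM2-uninfected"),
                            phage_attenuation = 5,
                            nb_dispersion = 0.05,
                            library_size = 2e5,
                            phage_share = 0.03,
                            programme = NULL,
                            seed = 1L) {
  check_count(n_host_genes, "n_host_genes", lower = 1)
  check_count(n_phage_genes, "n_phage_genes", lower = 1)
  if (!is.numeric(timepoints) || length(timepoints) < 2 ||
      any(diff(timepoints) <= 0)) {
    abort("`timepoints` must be strictly increasing minutes post infection.",
          class = "crisprcost_validation_error")
  }
  check_count(n_replicates, "n_replicates", lower = 1)
  check_number(phage_attenuation, "phage_attenuation", lower = 1)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(library_size, "library_size", lower = 1)
  check_number(phage_share, "phage_share", lower = 0, upper = 0.5)
  programme <- normalise_programme(programme, n_phage_genes)
  structure(list(
    n_host_genes = n_host_genes, n_phage_genes = n_phage_genes,
    timepoints = timepoints, n_replicates = n_replicates,
    genotypes = genotypes, phage_attenuation = phage_attenuation,
    nb_dispersion = nb_dispersion, library_size = library_size,
    phage_share = phage_share, programme = programme, seed = seed
  ), class = "expr_sim_params")
}

normalise_programme <- function(programme, n_phage_genes) {
  classes <- c("early", "middle", "late")
  if (is.null(programme)) {
    return(classes[pmin(3, ceiling(3 * seq_len(n_phage_genes) / n_phage_genes))])
  }
  if (is.list(programme)) {
    idx <- unlist(programme, use.names = FALSE)
    if (any(!idx %in% seq_len(n_phage_genes))) {
      abort(sprintf("`programme` references unknown phage gene index (valid: 1..%d).",
                    n_phage_genes), class = "crisprcost_validation_error")
    }
    if (!all(names(programme) %in% classes)) {
      abort("`programme` list names must be among early/middle/late.",
            class = "crisprcost_validation_error")
    }
    out <- rep(NA_character_, n_phage_genes)
    for (cl in names(programme)) out[programme[[cl]]] <- cl
    if (anyNA(out)) {
      abort("`programme` must assign every phage gene to a class.",
            class = "crisprcost_validation_error")
    }
    return(out)
  }
  if (is.character(programme)) {
    if (length(programme) != n_phage_genes || !all(programme %in% classes)) {
      abort("`programme` must assign each phage gene to early/middle/late.",
            class = "crisprcost_validation_error")
    }
    return(programme)
  }
  abort("`programme` must be NULL, a character vector or a named list of indices.",
        class = "crisprcost_validation_error")
}

# Temporal shapes of the three phage transcriptional classes, one value per
# timepoint, scaled 0..1 within class.
programme_shapes <- function(timepoints) {
  n <- length(timepoints)
  shape_for <- function(peak_pos, onset) {
    pos <- seq_len(n)
    v <- exp(-((pos - peak_pos)^2) / 2)
    v[pos < onset] <- v[pos < onset] * 0.2
    v / max(v)
  }
  list(
    early = shape_for(peak_pos = 2, onset = 2),
    middle = shape_for(peak_pos = max(2, ceiling(n * 0.75)), onset = 2),
    late = shape_for(peak_pos = n, onset = 2)
  )
}

#' Simulate an infection time-course expression dataset
#'
#' Generates a long count table for host and phage genes across genotype
#' groups, timepoints and replicates. Expected counts are negative-binomial
#' around group/timepoint means; uninfected controls have expected phage
#' counts of exactly zero; BIM2-infected phage means equal WT-infected means
#' divided by `phage_attenuation`.
#'
#' @param params An [expr_sim_params()] object.
#'
#' @return A long tibble with columns `gene`, `origin` (`"host"`/`"phage"`),
#'   `sample`, `genotype`, `minutes`, `replicate`, `count`.
#' @examples
#' expr <- simulate_expression(expr_sim_params(n_host_genes = 20,
#'                                             n_phage_genes = 6,
#'                                             library_size = 1e4))
#' phage_read_fraction(expr)
#' @export
simulate_expression <- function(params = expr_sim_params()) {
  if (!inherits(params, "expr_sim_params")) {
    abort("`params` must be created with `expr_sim_params()`.",
          class = "crisprcost_validation_error")
  }
  with_seed_or_not(params$seed, {
    tp <- params$timepoints
    shapes <- programme_shapes(tp)
    host_base <- rlnorm(params$n_host_genes, meanlog = 0, sdlog = 1)
    host_base <- host_base / sum(host_base) *
      (1 - params$phage_share) * params$library_size
    amp <- rlnorm(params$n_phage_genes, meanlog = 0, sdlog = 0.6)
    # gene x timepoint matrix of unnormalised phage means in WT-infected
    phage_shape <- t(vapply(params$programme, function(cl) shapes[[cl]],
                            numeric(length(tp))))
    phage_mu_wt <- phage_shape * amp
    # scale so the *time-averaged* phage total is phage_share of the library
    phage_mu_wt <- phage_mu_wt / mean(colSums(phage_mu_wt)) *
      params$phage_share * params$library_size

    genes <- c(sprintf("host_%03d", seq_len(params$n_host_genes)),
               sprintf("phage_%03d", seq_len(params$n_phage_genes)))
    origin <- rep(c("host", "phage"),
                  c(params$n_host_genes, params$n_phage_genes))

    size <- if (params$nb_dispersion > 0) 1 / params$nb_dispersion else Inf
    draw <- function(mu) {
      if (is.infinite(size)) return(round(mu))
      out <- integer(length(mu))
      pos <- mu > 0
      out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = size)
      out
    }

    grid <- tidyr::expand_grid(
      genotype = params$genotypes,
      minutes = tp,
      replicate = seq_len(params$n_replicates)
    )
    rows <- pmap(grid, function(genotype, minutes, replicate) {
      ti <- match(minutes, tp)
      phage_mu <- switch(genotype,
        "WT" = phage_mu_wt[, ti],
        "BIM2" = phage_mu_wt[, ti] / params$phage_attenuation,
        "BIM2-uninfected" = rep(0, params$n_phage_genes),
        abort(sprintf("unknown genotype `%s`.", genotype),
              class = "crisprcost_validation_error")
      )
      mu <- c(host_base, phage_mu)
      tibble(
        gene = genes, origin = origin,
        sample = sprintf("%s_t%d_r%d", gsub("[^A-Za-z0-9]", "", genotype),
                         minutes, replicate),
        genotype = genotype, minutes = minutes, replicate = replicate,
        count = draw(mu)
      )
    })
    list_rbind(rows)
  })
}
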