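## Simulation studies: parameter recovery and type-I error control for the
## divergence model-averaging pipeline, run on synthetic cross-fostered data.
## These are the package's own validation instruments; the acceptance tests
## and the reproduction script both call them.

## One shared synthetic population: class-I-alpha-like co-amplified locus,
## genotypes, per-individual functional divergence and supertype presence.
setup_study_population <- function(seed, n_individuals = 400,
                                   spec = default_locus_specs()[["MHC-Ia"]]) {
  pool <- generate_allele_pool(spec, seed = child_seed(seed, "pool"))
  geno <- simulate_population(list(pool), n_individuals,
                              seed = child_seed(seed, "pop"))
  geno <- geno[geno$locus == spec$name, ]
  aln <- list()
  aln[[spec$name]] <- translate_nt(pool$sequences)
  div <- divergence_table(geno, aln, mode = "per_site")
  dm <- build_descriptor_matrix(aln[[spec$name]], spec$selected_sites)
  assign <- assign_supertypes(dm, k = spec$n_motifs,
                              seed = child_seed(seed, "st"))
  sf <- supertype_frequencies(assign, geno)
  list(pool = pool, genotypes = geno, divergence = div,
       presence = sf$presence,
       common = filter_common_supertypes(sf$frequencies), locus = spec$name)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates fully cross-fostered breeding records with a known
#' genetic-father divergence slope on the fledging logit, runs the
#' cross-fostered divergence model-averaging analysis on each replicate, and
#' summarizes bias, Monte-Carlo error, 95% CI coverage and power for the
#' genetic-father term. The replicate analyses enumerate the linear
#' divergence terms of the four parents (16 sub-models) and fit with the fast
#' `nAGQ = 0` approximation; see the package vignette for these choices.
#'
#' @param n_reps Number of simulation replicates.
#' @param n_nests Nests per replicate (all fully cross-fostered).
#' @param beta True genetic-father slope on the standardized-divergence logit
#'   scale (default -0.461, a moderate effect).
#' @param seed Integer seed governing the whole study.
#' @param n_individuals Size of the genotyped parent population.
#' @param sigma_year,sigma_individual Random-intercept SDs of the generator.
#' @param nAGQ Integration setting for the replicate fits.
#' @return Object of class `mhc_sim_study`: list with the per-replicate
#'   results (`replicates`) and summary statistics (`mean_estimate`, `mc_se`,
#'   `coverage`, `power`, ...).
#' @export
mhc_recovery_study <- function(n_reps = 200, n_nests = 250, beta = -0.461,
                               seed = 1, n_individuals = 400,
                               sigma_year = 0.3, sigma_individual = 0.5,
                               nAGQ = 0) {
  popn <- setup_study_population(seed, n_individuals)
  eff <- effect_config(beta_div_genetic_father = beta,
                       sigma_year = sigma_year,
                       sigma_individual = sigma_individual)
  term <- "div_genetic_father"
  res <- lapply(seq_len(n_reps), function(r) {
    nests <- suppressMessages(simulate_breeding(
      popn$genotypes, popn$divergence, eff,
      n_nests = n_nests, crossfoster_plan = "full",
      effect_locus = popn$locus, seed = child_seed(seed, paste0("rep", r))))
    avg <- run_divergence_analysis(nests, popn$divergence, popn$locus,
                                   response = "fledging",
                                   mode = "crossfostered",
                                   include_quadratics = FALSE,
                                   include_interactions = FALSE,
                                   nAGQ = nAGQ)
    cf <- avg$coefficients
    row <- cf[cf$term == term, ]
    data.frame(rep = r, estimate = row$estimate, se_unc = row$se_unc,
               covered = row$ci_lo <= beta & beta <= row$ci_hi,
               significant = row$significant)
  })
  reps <- do.call(rbind, res)
  out <- list(replicates = reps, truth = beta, term = term,
              n_reps = n_reps, n_nests = n_nests,
              mean_estimate = mean(reps$estimate),
              sd_estimate = sd(reps$estimate),
              mc_se = sd(reps$estimate) / sqrt(n_reps),
              coverage = mean(reps$covered),
              power = mean(reps$significant))
  class(out) <- "mhc_sim_study"
  out
}

#' Type-I-error simulation study
#'
#' Same design as [mhc_recovery_study()] but with every MHC effect set to
#' zero: summarizes how often each averaged divergence term is (spuriously)
#' significant, and how often the BH-adjusted per-supertype test family
#' yields at least one discovery.
#'
#' @inheritParams mhc_recovery_study
#' @param supertype_tests Also run the per-supertype analysis each replicate.
#' @return Object of class `mhc_sim_study` with `term_sig_rates` (named),
#'   `max_term_sig_rate` and, when requested, `st_family_discovery_rate`.
#' @export
mhc_type1_study <- function(n_reps = 200, n_nests = 250, seed = 1,
                            n_individuals = 400, sigma_year = 0.3,
                            sigma_individual = 0.5, nAGQ = 0,
                            supertype_tests = TRUE) {
  popn <- setup_study_population(seed, n_individuals)
  eff <- effect_config(sigma_year = sigma_year,
                       sigma_individual = sigma_individual)
  terms <- c("div_genetic_father", "div_genetic_mother",
             "div_social_father", "div_social_mother")
  sig <- matrix(NA, n_reps, length(terms), dimnames = list(NULL, terms))
  st_disc <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    nests <- suppressMessages(simulate_breeding(
      popn$genotypes, popn$divergence, eff,
      n_nests = n_nests, crossfoster_plan = "full",
      effect_locus = popn$locus, seed = child_seed(seed, paste0("null", r))))
    avg <- run_divergence_analysis(nests, popn$divergence, popn$locus,
                                   response = "fledging",
                                   mode = "crossfostered",
                                   include_quadratics = FALSE,
                                   include_interactions = FALSE,
                                   nAGQ = nAGQ)
    cf <- avg$coefficients
    for (tm in terms)
      sig[r, tm] <- isTRUE(cf$significant[cf$term == tm])
    if (supertype_tests && length(popn$common)) {
      ## father x mother presence models on the genetic parents: the same
      ## null family the per-supertype BH correction protects
      st <- run_supertype_analysis(nests, popn$presence,
                                   supertypes = popn$common,
                                   response = "fledging",
                                   mode = "full", nAGQ = nAGQ)
      st_disc[r] <- nrow(st) > 0 && any(st$significant)
    }
  }
  rates <- colMeans(sig)
  out <- list(n_reps = n_reps, n_nests = n_nests,
              term_sig_rates = rates, max_term_sig_rate = max(rates),
              st_family_discovery_rate =
                if (supertype_tests) mean(st_disc) else NA_real_)
  class(out) <- "mhc_sim_study"
  out
}

#' @export
print.mhc_sim_study <- function(x, ...) {
  cat("Simulation study (", x$n_reps, " replicates, ", x$n_nests,
      " nests each)\n", sep = "")
  if (!is.null(x$mean_estimate)) {
    cat(sprintf("  truth %.3f | mean estimate %.3f (MC SE %.4f) | coverage %.3f | power %.3f\n",
                x$truth, x$mean_estimate, x$mc_se, x$coverage, x$power))
  }
  if (!is.null(x$term_sig_rates)) {
    cat("  per-term significance rates under the null:\n")
    print(round(x$term_sig_rates, 4))
    if (!is.na(x$st_family_discovery_rate))
      cat(sprintf("  supertype BH family discovery rate: %.3f\n",
                  x$st_family_discovery_rate))
  }
  invisible(x)
}

#' Noiseless end-to-end genotyping recovery
#'
#' Generates allele pools and genotypes for the three default loci, simulates
#' amplicon spectra with all error and chimera rates at zero, runs the full
#' genotyper, and reports the fraction of sample x locus genotypes recovered
#' exactly (allele sets identical to the truth).
#'
#' @param n_individuals Number of individuals (default 200).
#' @param seed Integer seed.
#' @param noise A [noise_config()]; defaults to the noiseless setting.
#' @return List with `recovery` (fraction exact), `n_amplicons`, `calls` and
#'   `concordance` (replicate reproducibility, `NA` when nothing replicated).
#' @export
noiseless_recovery <- function(n_individuals = 200, seed = 1,
                               noise = noise_config(sub_rate = 0,
                                                    chimera_rate = 0,
                                                    replicate_fraction = 0)) {
  specs <- default_locus_specs()
  pools <- lapply(specs, generate_allele_pool,
                  seed = child_seed(seed, "pools"))
  names(pools) <- names(specs)
  geno <- simulate_population(pools, n_individuals,
                              seed = child_seed(seed, "pop"))
  variants <- simulate_amplicon_reads(geno, pools, noise,
                                      seed = child_seed(seed, "reads"))
  params <- lapply(specs, function(sp)
    genotyper_params(expected_length_nt = sp$exon_length_nt,
                     max_alleles = if (sp$coamplified) 4L else 2L))
  names(params) <- names(specs)
  calls <- call_genotypes(variants, params)
  seq_to_label <- lapply(pools, function(p)
    setNames(names(p$sequences), unname(p$sequences)))
  truth_key <- paste(geno$sample_id, geno$locus)
  truth_set <- setNames(geno$alleles, truth_key)
  called_set <- vapply(seq_len(nrow(calls)), function(i) {
    labs <- seq_to_label[[calls$locus[i]]][split_alleles(calls$alleles[i])[[1]]]
    join_alleles(labs[!is.na(labs)])
  }, "")
  call_key <- paste(calls$sample_id, calls$locus)
  exact <- called_set == unname(truth_set[call_key])
  missing <- sum(!truth_key %in% call_key)   # amplicons with no call at all
  list(recovery = sum(exact) / (length(exact) + missing),
       n_amplicons = length(truth_key), calls = calls,
       concordance = replicate_concordance(calls))
}
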