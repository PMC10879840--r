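test_that("allele pools are deterministic, in-frame and distinct", {
  sp <- locus_spec("DAB2", 258, 22, c(9, 11, 13, 26, 30, 37, 47, 57, 67, 71),
                   n_motifs = 10)
  p1 <- generate_allele_pool(sp, seed = 7)
  p2 <- generate_allele_pool(sp, seed = 7)
  expect_identical(p1$sequences, p2$sequences)
  expect_length(p1$sequences, 22)
  expect_true(all(nchar(p1$sequences) == 258))
  aa <- mhcassoc:::translate_nt(p1$sequences)
  expect_false(any(mhcassoc:::has_stop(aa)))
  ## all translations pairwise distinct
  expect_equal(length(unique(aa)), 22)
  ## variation concentrated at selected sites: motif-mates share the
  ## selected-site residues
  sm <- mhcassoc:::aa_site_matrix(aa)[, sp$selected_sites]
  keys <- apply(sm, 1, paste, collapse = "")
  expect_lte(length(unique(keys)), 10)
  expect_gte(length(unique(keys)), 8)
})

test_that("a one-allele pool gives zero distances and full homozygosity", {
  sp <- locus_spec("X", 30, 1, c(2, 5))
  pool <- generate_allele_pool(sp, seed = 1)
  expect_length(pool$sequences, 1)
  geno <- simulate_population(list(X = pool), 25, seed = 1)
  expect_true(all(geno$n_distinct == 1))
})

test_that("population sampling is Hardy-Weinberg and respects copy limits", {
  sp <- locus_spec("X", 30, 2, c(2, 5), n_motifs = 2)
  pool <- generate_allele_pool(sp, seed = 3)
  n <- 4000
  geno <- simulate_population(list(X = pool), n, seed = 2)
  het <- mean(geno$n_distinct == 2)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 3 * se)
  ## bad frequencies rejected
  expect_error(simulate_population(list(X = pool), 5,
                                   allele_freqs = list(X = c(`X*01` = 0.6,
                                                             `X*02` = 0.6))),
               "sum to 1")
  ## co-amplified locus: at most four distinct alleles
  spc <- locus_spec("C", 30, 8, c(2, 5), coamplified = TRUE, n_motifs = 4)
  poolc <- generate_allele_pool(spc, seed = 4)
  genoc <- simulate_population(list(C = poolc), 200, seed = 5)
  expect_true(all(genoc$n_distinct <= 4))
})

test_that("noiseless amplicons reproduce exactly the true allele set", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 25, seed = 2)
  nz <- noise_config(sub_rate = 0, chimera_rate = 0, replicate_fraction = 0)
  v <- simulate_amplicon_reads(geno, list(DAB2 = pool), nz, seed = 3)
  for (i in seq_len(nrow(geno))) {
    truth <- sort(unname(pool$sequences[strsplit(geno$alleles[i], ";")[[1]]]))
    got <- sort(v$sequence[v$sample_id == geno$sample_id[i]])
    expect_identical(got, truth)
  }
})

test_that("chimeric artifact variants are crossovers of deeper true variants", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 40, seed = 6)
  nz <- noise_config(sub_rate = 0, chimera_rate = 0.05, replicate_fraction = 0)
  v <- simulate_amplicon_reads(geno, list(DAB2 = pool), nz, seed = 7)
  found_chimera <- FALSE
  for (sid in unique(v$sample_id)) {
    tab <- v[v$sample_id == sid, ]
    truth <- unname(pool$sequences[strsplit(
      geno$alleles[geno$sample_id == sid], ";")[[1]]])
    extra <- setdiff(tab$sequence, truth)
    for (ch in extra) {
      found_chimera <- TRUE
      L <- nchar(ch)
      ok <- any(vapply(seq_len(L - 1), function(k)
        any(substr(truth, 1, k) == substr(ch, 1, k)) &&
        any(substr(truth, k + 1, L) == substr(ch, k + 1, L)), logical(1)))
      expect_true(ok)
    }
  }
  expect_true(found_chimera)
})

test_that("replicate_fraction = 1 yields two independently noisy tables", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 10, seed = 2)
  nz <- noise_config(replicate_fraction = 1)
  v <- simulate_amplicon_reads(geno, list(DAB2 = pool), nz, seed = 3)
  reps <- table(unique(v[, c("sample_id", "replicate")])$sample_id)
  expect_true(all(reps == 2))
  one <- v[v$sample_id == geno$sample_id[1], ]
  d1 <- one$depth[one$replicate == 1]
  d2 <- one$depth[one$replicate == 2]
  expect_false(identical(d1, d2))
})

test_that("zero requested depth warns and returns an empty table", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 3, seed = 2)
  expect_warning(
    v <- simulate_amplicon_reads(geno, list(DAB2 = pool),
                                 noise_config(mean_depth = 0), seed = 1),
    "zero requested depth")
  expect_equal(nrow(v), 0)
})

test_that("null breeding simulation matches its analytic expectations", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 200, seed = 2)
  div <- divergence_table(geno, pool_alignment(pool))
  eff <- effect_config(clutch_log_mean = log(6), fledge_logit_mean = qlogis(0.6),
                       sigma_year = 0, sigma_individual = 0,
                       covariate_effects = c(mother_age = 0, father_age = 0,
                                             laying_date = 0, laying_date_sq = 0))
  n <- 5000
  nests <- simulate_breeding(geno, div, eff, n_nests = n,
                             crossfoster_plan = "none", seed = 8)
  ## zero-truncated Poisson(6): mean 6/(1-exp(-6))
  mu_trunc <- 6 / (1 - exp(-6))
  expect_lt(abs(mean(nests$clutch) - mu_trunc), 3 * sd(nests$clutch) / sqrt(n))
  succ <- sum(nests$fledged) / sum(nests$clutch)
  se_succ <- sqrt(0.6 * 0.4 / sum(nests$clutch))
  expect_lt(abs(succ - 0.6), 3 * se_succ)
  ## no cross-fostering: genetic == social
  expect_identical(nests$genetic_mother, nests$social_mother)
  expect_identical(nests$genetic_father, nests$social_father)
})

test_that("full cross-fostering swaps whole clutches between nest pairs", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 100, seed = 2)
  div <- divergence_table(geno, pool_alignment(pool))
  nests <- suppressMessages(
    simulate_breeding(geno, div, effect_config(), n_nests = 120,
                      crossfoster_plan = "full", seed = 4))
  full <- nests[nests$crossfoster == "full", ]
  expect_gt(nrow(full), 100)
  expect_true(all(full$genetic_father != full$social_father |
                  full$genetic_mother != full$social_mother))
  ## swaps are reciprocal: every social couple is some other nest's genetic
  gk <- paste(full$genetic_mother, full$genetic_father, full$year)
  sk <- paste(full$social_mother, full$social_father, full$year)
  expect_true(all(sk %in% gk))
  ## determinism
  nests2 <- suppressMessages(
    simulate_breeding(geno, div, effect_config(), n_nests = 120,
                      crossfoster_plan = "full", seed = 4))
  expect_identical(nests, nests2)
})
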