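params12 <- genotyper_params(expected_length_nt = 12, max_alleles = 4)

test_that("variant pre-filtering applies length, frequency and depth rules", {
  tab <- vtab(c(900, 100, 80, 50, 40))
  tab$sequence[3] <- substr(tab$sequence[3], 1, 10)   # off-length
  ft <- filter_variants(tab, params12)
  expect_equal(nrow(ft), 4)
  expect_false(attr(ft, "uncallable"))
  ## both of (900, 100) survive a 1% frequency floor
  ft2 <- filter_variants(vtab(c(900, 100)), params12)
  expect_equal(nrow(ft2), 2)
  ## below the frequency floor and depth-1 singletons go
  ft3 <- filter_variants(vtab(c(990, 9, 1)), params12)
  expect_equal(ft3$depth, 990)
  ## low total depth is uncallable, not an error
  ft4 <- filter_variants(vtab(c(30, 10)), params12)
  expect_true(attr(ft4, "uncallable"))
  expect_true("low_depth" %in% attr(ft4, "qc"))
})

test_that("degree-of-change calling finds the depth cliff", {
  expect_equal(doc_genotype(vtab(c(1200, 1100, 60, 40, 5)), 4)$n_alleles, 2)
  expect_equal(doc_genotype(vtab(1000), 4)$n_alleles, 1)
  expect_equal(doc_genotype(vtab(c(800, 790, 770, 760, 30, 20)), 4)$n_alleles, 4)
  ## a clean two-variant amplicon calls both
  expect_equal(doc_genotype(vtab(c(520, 480)), 2)$n_alleles, 2)
})

test_that("degree-of-change matches the brute-force maximizer on small tables", {
  ## quick sweep; the full <=6-variant grid runs in the acceptance suite
  grid <- c(2, 5, 20, 60, 200, 1000)
  for (nv in 1:4) {
    ## all multisets of size nv from the grid (stars-and-bars enumeration)
    idx <- utils::combn(length(grid) + nv - 1, nv) - seq_len(nv) + 1
    combos <- lapply(seq_len(ncol(idx)), function(j)
      sort(grid[idx[, j]], decreasing = TRUE))
    for (depths in combos) {
      tab <- vtab(depths)
      got <- doc_genotype(tab, 4)
      want <- doc_oracle(tab$depth, tab$sequence, 4)
      expect_equal(got$n_alleles, want$n, info = paste(depths, collapse = ","))
      expect_equal(sort(got$alleles), want$set,
                   info = paste(depths, collapse = ","))
    }
  }
})

test_that("threshold calling applies the frequency cutoff and cap", {
  tab <- vtab(c(499, 457, 25, 17, 2))
  expect_equal(threshold_genotype(tab, 0.05, 4)$n_alleles, 2)
  expect_equal(threshold_genotype(vtab(c(500, 500)), 0.3, 4)$n_alleles, 2)
  capped <- threshold_genotype(vtab(rep(200, 5)), 0.1, 4)
  expect_equal(capped$n_alleles, 4)
  expect_true("max_alleles_capped" %in% capped$qc)
  none <- threshold_genotype(vtab(c(10, 10)), 0.9, 4)
  expect_equal(none$n_alleles, 0)
  expect_true("uncallable" %in% none$qc)
})

test_that("raising the threshold never increases the allele count", {
  set.seed(9)
  for (r in 1:20) {
    depths <- sort(rpois(sample(2:8, 1), 300) + 1, decreasing = TRUE)
    tab <- vtab(depths)
    counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4),
                     function(t) threshold_genotype(tab, t, 4)$n_alleles,
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("chimera detection flags single-breakpoint crossovers only", {
  a <- "AAAAAATTTTTT"
  b <- "CCCCCCGGGGGG"
  chim <- paste0(substr(a, 1, 7), substr(b, 8, 12))   # A-prefix + B-suffix
  tab <- data.frame(sequence = c(a, b, chim), depth = c(1000L, 900L, 40L))
  expect_equal(detect_chimeras(c(a, b, chim), tab), chim)
  ## nothing flagged without a crossover
  tab2 <- data.frame(sequence = c(a, b), depth = c(1000L, 900L))
  expect_length(detect_chimeras(c(a, b), tab2), 0)
  ## flagged once even when several breakpoints reconstruct it
  a2 <- "AAACCCTTTGGG"; b2 <- "AAACCCGGGTTT"   # share a 6-nt prefix
  chim2 <- paste0(substr(a2, 1, 8), substr(b2, 9, 12))
  tab3 <- data.frame(sequence = c(a2, b2, chim2), depth = c(800L, 700L, 30L))
  expect_equal(detect_chimeras(c(a2, b2, chim2), tab3), chim2)
})

test_that("functionality screening removes frameshifts and stop codons", {
  clean <- "ATGGCTGCTGCT"
  stopv <- "ATGTAAGCTGCT"     # internal TAA
  short <- "ATGGCTGCTGC"      # 1-nt deletion
  expect_equal(screen_functionality(c(clean, stopv, short)), clean)
  expect_equal(screen_functionality(clean), clean)
})

test_that("consensus reconciles the two methods by intersection", {
  d <- list(alleles = c("A", "B"), qc = character(0))
  t1 <- list(alleles = c("A", "B"), qc = character(0))
  expect_true(consensus_genotype(d, t1)$method_agreement)
  t2 <- list(alleles = c("A", "B", "C"), qc = character(0))
  cg <- consensus_genotype(d, t2)
  expect_equal(cg$alleles, c("A", "B"))
  expect_true("discordant" %in% cg$qc)
  t3 <- list(alleles = c("C", "D"), qc = character(0))
  cg3 <- consensus_genotype(d, t3)
  expect_equal(cg3$n_alleles, 0)
  expect_true("uncallable" %in% cg3$qc)
})

test_that("replicate concordance is the fraction of identical replicate pairs", {
  reps <- data.frame(
    sample_id = rep(sprintf("s%02d", 1:50), each = 2),
    locus = "L", replicate = rep(1:2, 50),
    alleles = rep("A;B", 100), stringsAsFactors = FALSE)
  expect_equal(replicate_concordance(reps), 1.0)
  reps$alleles[2] <- "A;C"   # one discordant pair
  expect_equal(replicate_concordance(reps), 0.98)
})

test_that("calls are invariant to input row order", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 6, seed = 2)
  v <- simulate_amplicon_reads(geno, list(DAB2 = pool), noise_config(
    replicate_fraction = 0), seed = 3)
  params <- list(DAB2 = genotyper_params(258, 2L))
  c1 <- call_genotypes(v, params)
  set.seed(1)
  c2 <- call_genotypes(v[sample(nrow(v)), ], params)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("noiseless simulation genotypes back to the truth end to end", {
  nr <- noiseless_recovery(n_individuals = 24, seed = 3)
  expect_equal(nr$recovery, 1.0)
  ## replicated noiseless amplicons are perfectly reproducible
  nr2 <- noiseless_recovery(n_individuals = 12, seed = 4,
                            noise = noise_config(sub_rate = 0,
                                                 chimera_rate = 0,
                                                 replicate_fraction = 1))
  expect_equal(nr2$concordance, 1.0)
})
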