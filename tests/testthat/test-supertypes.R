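test_that("site screening passes external lists through and validates them", {
  aln <- c(A = "ACDEF", B = "AWDEF", C = "ACDKF")
  expect_equal(screen_selected_sites(aln, "external_list", sites = c(7, 9, 24) %% 5 + 1),
               sort(unique(c(7, 9, 24) %% 5 + 1)))
  expect_error(screen_selected_sites(aln, "external_list", sites = integer(0)),
               "empty site list")
  expect_error(screen_selected_sites(aln, "external_list", sites = 99),
               "outside")
})

test_that("the entropy heuristic recovers the variable sites", {
  set.seed(3)
  res <- rownames(grantham_matrix())
  base <- sample(res, 20, TRUE)
  truth_sites <- c(4, 9, 15)
  seqs <- vapply(1:12, function(i) {
    s <- base
    s[truth_sites] <- sample(res, 3, TRUE)
    paste(s, collapse = "")
  }, "")
  names(seqs) <- paste0("a", 1:12)
  got <- screen_selected_sites(seqs, "heuristic", m = 3)
  expect_setequal(got, truth_sites)
  mono <- setNames(rep(paste(base, collapse = ""), 3), c("x", "y", "z"))
  expect_error(screen_selected_sites(mono, "heuristic", m = 2), "monomorphic")
})

test_that("descriptor matrices have the right shape and standardization", {
  pool <- small_pool(seed = 2, n_alleles = 31)
  sp15 <- c(5, 9, 11, 13, 26, 28, 30, 32, 37, 47, 56, 60, 67, 70, 74)
  aln <- pool_alignment(pool)[["DAB2"]]
  dm <- build_descriptor_matrix(aln, sp15)
  expect_equal(dim(dm), c(31, 75))
  nonconst <- apply(dm, 2, function(x) any(x != 0))
  expect_true(all(abs(colMeans(dm[, nonconst])) < 1e-9))
  expect_true(all(abs(apply(dm[, nonconst], 2, sd) - 1) < 1e-9))
  ## alleles identical at the selected sites share a row
  sm <- mhcassoc:::aa_site_matrix(aln)[, pool$spec$selected_sites]
  keys <- apply(sm, 1, paste, collapse = "")
  twins <- which(keys == keys[duplicated(keys)][1])
  expect_equal(dm[twins[1], ], dm[twins[2], ])
})

test_that("k selection finds clean cluster structure by both criteria", {
  ## descriptor-matrix-like regime: 3 clusters in 40 dimensions; the k-means
  ## BIC convention only has an interior minimum when within-cluster
  ## variance is spread over many coordinates, which is the regime the
  ## supertyping substrate lives in
  set.seed(7)
  centers <- matrix(rnorm(3 * 40, 0, 2.5), nrow = 3)
  pts <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(12 * 40, 0, 0.6), ncol = 40), 2, centers[i, ], `+`)))
  rownames(pts) <- sprintf("a%02d", 1:36)
  k_bic <- select_k(pts, 2:6, method = "BIC", seed = 1, n_restarts = 20)
  k_sil <- select_k(pts, 2:6, method = "silhouette", seed = 1, n_restarts = 20)
  expect_equal(as.integer(k_bic), 3)
  expect_equal(as.integer(k_sil), 3)
  ## the reported silhouette agrees with an independently coded silhouette
  km <- stats::kmeans(pts, 3, nstart = 20)
  dmat <- as.matrix(dist(pts))
  sil_hand <- mean(vapply(seq_len(nrow(pts)), function(i) {
    own <- km$cluster == km$cluster[i]; own[i] <- FALSE
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(km$cluster), km$cluster[i]), function(cl)
      mean(dmat[i, km$cluster == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_equal(unname(attr(k_sil, "criterion")["k3"]), sil_hand,
               tolerance = 1e-8)
  ## duplicating every point leaves the silhouette choice unchanged (all
  ## pairwise-mean distances are preserved exactly)
  dup <- rbind(pts, pts)
  rownames(dup) <- sprintf("a%02d", 1:72)
  expect_equal(as.integer(select_k(dup, 2:6, method = "silhouette", seed = 1,
                                   n_restarts = 20)), 3)
  ## weak single-blob structure warns
  blob <- matrix(rnorm(300), ncol = 10,
                 dimnames = list(sprintf("b%02d", 1:30), NULL))
  expect_warning(select_k(blob, 2:5, method = "silhouette", seed = 1,
                          n_restarts = 20), "weak cluster structure")
})

test_that("supertype assignment recovers the seeded motifs", {
  pool <- small_pool()   # 22 alleles, 10 motifs
  aln <- pool_alignment(pool)[["DAB2"]]
  dm <- build_descriptor_matrix(aln, pool$spec$selected_sites)
  asg <- assign_supertypes(dm, 10, seed = 1)
  expect_equal(attr(asg, "k"), 10)
  expect_equal(ari(pool$motif[asg$allele], asg$supertype), 1)
  ## a different seed gives the same partition up to relabeling
  asg2 <- assign_supertypes(dm, 10, seed = 99)
  expect_equal(ari(asg$supertype, asg2$supertype), 1)
  ## same seed: byte-identical
  expect_identical(asg, assign_supertypes(dm, 10, seed = 1))
})

test_that("supertype frequencies count carriers over genotyped individuals", {
  asg <- structure(data.frame(allele = c("A", "B", "C"),
                              supertype = c("ST1", "ST1", "ST2")),
                   class = c("supertype_assignment", "data.frame"))
  geno <- data.frame(sample_id = sprintf("s%03d", 1:200), locus = "L",
                     alleles = c(rep("A;C", 60), rep("A;B", 140)))
  sf <- supertype_frequencies(asg, geno)
  expect_equal(unname(sf$frequencies["ST2"]), 0.30)
  expect_equal(unname(sf$frequencies["ST1"]), 1.0)
  expect_equal(colnames(sf$presence), c("sample_id", "ST1", "ST2"))
  expect_equal(sum(sf$presence$ST2), 60)
})

test_that("the frequency floor is strict and an empty survivor set messages", {
  fr <- c(ST1 = 0.10, ST2 = 0.11, ST3 = 0.5)
  expect_equal(filter_common_supertypes(fr), c("ST2", "ST3"))
  expect_message(out <- filter_common_supertypes(c(ST1 = 0.05)),
                 "no supertype exceeds")
  expect_length(out, 0)
})
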