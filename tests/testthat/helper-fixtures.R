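## Shared fixtures, all generated in code.

## A variant table from a depth vector; sequences are distinct same-length
## placeholders unless supplied.
vtab <- function(depths, seqs = NULL, len = 12) {
  if (is.null(seqs))
    seqs <- vapply(seq_along(depths), function(i)
      paste(rep(c("ACGGTA", "CGTACG", "GATTAC", "TTGACA", "AACCGG",
                  "GGTTAA")[((i - 1) %% 6) + 1],
                len / 6), collapse = ""), "")
  ## make sequences distinct by suffix substitution
  for (i in seq_along(seqs)) {
    base <- strsplit(seqs[i], "")[[1]]
    base[((i - 1) %% len) + 1] <- c("A", "C", "G", "T")[((i - 1) %% 4) + 1]
    seqs[i] <- paste(base, collapse = "")
  }
  stopifnot(!anyDuplicated(seqs))
  data.frame(sequence = seqs, depth = as.integer(depths),
             stringsAsFactors = FALSE)
}

## Small DAB2-like pool + population used in several files.
small_pool <- function(seed = 5, n_alleles = 22) {
  sp <- locus_spec("DAB2", 258, n_alleles,
                   c(9, 11, 13, 26, 30, 37, 47, 57, 67, 71),
                   coamplified = FALSE, n_motifs = min(10, n_alleles))
  generate_allele_pool(sp, seed = seed)
}

pool_alignment <- function(pool) {
  aln <- list()
  aln[[pool$locus]] <- mhcassoc:::translate_nt(pool$sequences)
  aln
}

## Adjusted Rand index between two labelings (independent of the package).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

## Independent brute-force degree-of-change maximizer: works from cumulative
## depths and the flat-tail convention, with the same tie-extension rule.
doc_oracle <- function(depths, seqs, max_alleles) {
  o <- order(-depths, seqs)
  d <- depths[o]; s <- seqs[o]
  nv <- length(d)
  if (nv == 1) return(list(n = 1L, set = s))
  C <- c(0, cumsum(d), sum(d))   # C_0..C_nv, plus flat C_{nv+1}
  best_i <- 0; best <- -Inf
  for (i in seq_len(min(max_alleles, nv))) {
    num <- C[i + 1] - C[i]
    den <- C[i + 2] - C[i + 1]
    doc <- if (den == 0) Inf else num / den
    if (doc > best) { best <- doc; best_i <- i }
  }
  n <- best_i
  set <- s[seq_len(n)]
  if (n < nv && d[n] == d[n + 1]) {
    tied <- which(d == d[n])
    if (max(tied) <= max_alleles) {
      n <- max(tied); set <- s[seq_len(n)]
    } else {
      fixed <- s[seq_len(min(tied) - 1)]
      set <- c(fixed, sort(s[tied])[seq_len(n - length(fixed))])
    }
  }
  list(n = length(set), set = sort(set))
}

## A fake converged fit with chosen likelihood and coefficients, for testing
## the model-averaging algebra in isolation.
fake_fit <- function(logL, beta, se, n = 100, k = length(beta)) {
  structure(list(beta = beta, se = setNames(se, names(beta)), logLik = logL,
                 n_obs = n, k_params = k, n_vc = 0, converged = TRUE),
            class = "mhc_glmm")
}

## Independent Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
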