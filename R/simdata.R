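## Synthetic-data generation: allele pools, diploid genotypes, noisy amplicon
## variant spectra and cross-fostered breeding records with known injected
## effects. The defaults mirror the barn-owl study system: three amplicons
## (class I alpha with two co-amplified genes, class IIb DAB1 and DAB2),
## allele pool sizes 98/31/22, 8/15/10 positively selected codons, 9/14/10
## binding motifs, mean clutch 6.23 and mean fledging success 3.62/6.23.

#' Locus specification for the synthetic generator
#'
#' @param name Locus label, e.g. `"MHC-Ia"`, `"DAB1"`, `"DAB2"`.
#' @param exon_length_nt Exon length in nucleotides; must be a codon multiple.
#' @param n_alleles Number of distinct alleles in the population pool.
#' @param selected_sites Integer vector of 1-based codon positions treated as
#'   positively selected; pool variation is concentrated there.
#' @param coamplified Logical; `TRUE` means two genes are co-amplified in one
#'   amplicon so an individual carries four gene copies (up to four distinct
#'   alleles), as for the class I alpha amplicon.
#' @param n_motifs Number of distinct binding motifs (residue combinations at
#'   the selected sites) seeded into the pool; this is the supertype structure
#'   the clustering stage should recover.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(name, exon_length_nt, n_alleles, selected_sites,
                       coamplified = FALSE, n_motifs = max(2L, n_alleles %/% 3L)) {
  stopifnot(is.character(name), length(name) == 1L,
            exon_length_nt > 0, n_alleles >= 1)
  if (exon_length_nt %% 3 != 0)
    stop("exon_length_nt must be divisible by 3")
  n_codons <- exon_length_nt %/% 3
  selected_sites <- sort(unique(as.integer(selected_sites)))
  if (length(selected_sites) == 0L ||
      any(selected_sites < 1L | selected_sites > n_codons))
    stop("selected_sites must lie in 1..", n_codons)
  if (n_alleles > 61^n_codons)
    stop("n_alleles exceeds the codon sequence space for this exon length")
  n_motifs <- max(1L, min(as.integer(n_motifs), n_alleles))
  structure(list(name = name, exon_length_nt = as.integer(exon_length_nt),
                 n_alleles = as.integer(n_alleles),
                 selected_sites = selected_sites,
                 coamplified = isTRUE(coamplified),
                 n_motifs = n_motifs),
            class = "locus_spec")
}

#' Default locus specifications
#'
#' Three loci matching the study system: a co-amplified class I alpha amplicon
#' (exon 3, pool of 98 alleles, 8 selected codons, 9 motifs) and the two class
#' IIb exon-2 amplicons DAB1 (31 alleles, 15 sites, 14 motifs) and DAB2
#' (22 alleles, 10 sites, 10 motifs).
#'
#' @return Named list of [locus_spec()] objects.
#' @export
default_locus_specs <- function() {
  list(
    `MHC-Ia` = locus_spec("MHC-Ia", 270, 98,
                          c(9, 24, 35, 45, 59, 62, 73, 84),
                          coamplified = TRUE, n_motifs = 9),
    DAB1 = locus_spec("DAB1", 258, 31,
                      c(5, 9, 11, 13, 26, 28, 30, 32, 37, 47, 56, 60, 67, 70, 74),
                      coamplified = FALSE, n_motifs = 14),
    DAB2 = locus_spec("DAB2", 258, 22,
                      c(9, 11, 13, 26, 30, 37, 47, 57, 67, 71),
                      coamplified = FALSE, n_motifs = 10))
}

#' Amplicon noise model configuration
#'
#' @param mean_depth Mean total reads per amplicon (negative-binomial mean).
#' @param depth_dispersion Negative-binomial size parameter; smaller values
#'   give more overdispersed total depth.
#' @param sub_rate Per-base substitution error rate generating low-depth
#'   1-2-substitution derivative variants.
#' @param chimera_rate Probability that a read is a single-breakpoint
#'   crossover of two of the individual's true alleles.
#' @param allelic_imbalance Dirichlet concentration per gene copy governing
#'   per-allele amplification shares; larger means more even shares.
#' @param replicate_fraction Share of individuals amplified twice
#'   (independent PCR replicates).
#' @param n_error_variants Number of distinct derivative variants spawned per
#'   true allele when `sub_rate > 0`.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(mean_depth = 1000, depth_dispersion = 10,
                         sub_rate = 0.0015, chimera_rate = 0.01,
                         allelic_imbalance = 25, replicate_fraction = 0.1,
                         n_error_variants = 2) {
  stopifnot(mean_depth >= 0, depth_dispersion > 0,
            sub_rate >= 0, sub_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            allelic_imbalance > 0,
            replicate_fraction >= 0, replicate_fraction <= 1)
  structure(as.list(environment()), class = "noise_config")
}

#' Injected-effect configuration for breeding simulation
#'
#' Effects are on the linear-predictor scale of the fledging (logit) and
#' clutch (log) models. Divergence slopes apply to Gelman-standardized
#' (centered, divided by twice the SD) per-parent functional divergence, so
#' they are directly comparable to standardized model estimates.
#'
#' @param beta_div_genetic_father,beta_div_genetic_mother Logit-scale slopes
#'   of the genetic parents' divergence on fledging success.
#' @param beta_div_social_father,beta_div_social_mother Logit-scale slopes of
#'   the social (rearing) parents' divergence on fledging success.
#' @param supertype_effects Named list mapping supertype label to
#'   `c(father, mother, interaction)` logit-scale effects of presence in the
#'   genetic parents.
#' @param clutch_log_mean Log of the expected clutch size (default
#'   `log(6.23)`, the population mean).
#' @param fledge_logit_mean Logit of the baseline fledging success (default
#'   `qlogis(3.62/6.23)`).
#' @param sigma_year,sigma_individual SDs of the year and parent random
#'   intercepts (the study reports none; these are declared defaults).
#' @param covariate_effects Named numeric: slopes of `mother_age`,
#'   `father_age`, `laying_date` and `laying_date_sq` on the standardized
#'   scale, shared by both responses.
#' @param n_years Number of breeding seasons the records span.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(beta_div_genetic_father = 0,
                          beta_div_genetic_mother = 0,
                          beta_div_social_father = 0,
                          beta_div_social_mother = 0,
                          supertype_effects = list(),
                          clutch_log_mean = log(6.23),
                          fledge_logit_mean = qlogis(3.62 / 6.23),
                          sigma_year = 0.3, sigma_individual = 0.5,
                          covariate_effects = c(mother_age = 0.05,
                                                father_age = 0.05,
                                                laying_date = -0.2,
                                                laying_date_sq = -0.1),
                          n_years = 23) {
  stopifnot(sigma_year >= 0, sigma_individual >= 0)
  eff <- as.list(environment())
  num <- unlist(eff[c("beta_div_genetic_father", "beta_div_genetic_mother",
                      "beta_div_social_father", "beta_div_social_mother",
                      "clutch_log_mean", "fledge_logit_mean",
                      "sigma_year", "sigma_individual")])
  if (any(!is.finite(num))) stop("all effects must be finite")
  structure(eff, class = "effect_config")
}

#' Generate a pool of labelled in-frame alleles
#'
#' Builds `n_alleles` distinct nucleotide sequences from a common background
#' sequence. Variation is concentrated at the selected codon positions: the
#' pool carries `n_motifs` distinct residue combinations ("binding motifs") at
#' those sites, and alleles within a motif differ by a small number of
#' off-site codon substitutions. All sequences translate without stop codons.
#'
#' @param spec A [locus_spec()].
#' @param seed Integer seed; identical seeds give identical pools.
#' @param off_site_subs Mean number of codon substitutions outside the
#'   selected sites distinguishing alleles within a motif.
#' @return An object of class `allele_pool`: list with `locus`, named
#'   character `sequences`, integer `motif` per allele, and the `spec`.
#' @export
generate_allele_pool <- function(spec, seed, off_site_subs = 1.5) {
  stopifnot(inherits(spec, "locus_spec"))
  codons <- sense_codons()
  n_codons <- spec$exon_length_nt %/% 3
  sel <- spec$selected_sites
  off <- setdiff(seq_len(n_codons), sel)
  with_seed(seed, {
    base <- sample(codons, n_codons, replace = TRUE)
    ## distinct residue motifs at the selected sites
    motifs <- list()
    tries <- 0
    while (length(motifs) < spec$n_motifs && tries < 5000) {
      cand <- sample(codons, length(sel), replace = TRUE)
      key <- paste(translate_nt(paste(cand, collapse = "")), collapse = "")
      if (!key %in% vapply(motifs, attr, "", "aa"))
        motifs[[length(motifs) + 1L]] <- structure(cand, aa = key)
      tries <- tries + 1
    }
    if (length(motifs) < spec$n_motifs)
      stop("could not generate ", spec$n_motifs, " distinct motifs")
    motif_of <- rep(seq_len(spec$n_motifs), length.out = spec$n_alleles)
    seqs <- character(spec$n_alleles)
    seen_aa <- character(0)
    for (i in seq_len(spec$n_alleles)) {
      for (attempt in 1:200) {
        cod <- base
        cod[sel] <- motifs[[motif_of[i]]]
        nsub <- if (i %% spec$n_motifs == motif_of[i] %% spec$n_motifs && attempt == 1 &&
                    i <= spec$n_motifs) 0L else rpois(1, off_site_subs) + (attempt > 1)
        nsub <- min(nsub, length(off))
        if (nsub > 0) {
          pos <- sample(off, nsub)
          cod[pos] <- sample(codons, nsub, replace = TRUE)
        }
        s <- paste(cod, collapse = "")
        aa <- translate_nt(s)
        if (!aa %in% seen_aa) {
          seqs[i] <- s
          seen_aa <- c(seen_aa, aa)
          break
        }
      }
      if (seqs[i] == "")
        stop("could not generate ", spec$n_alleles,
             " alleles with distinct translations")
    }
    names(seqs) <- sprintf("%s*%02d", spec$name, seq_len(spec$n_alleles))
    structure(list(locus = spec$name, sequences = seqs,
                   motif = setNames(motif_of, names(seqs)), spec = spec),
              class = "allele_pool")
  })
}

#' Translate a pool's alleles to an amino-acid alignment
#'
#' @param pool An [generate_allele_pool()] result.
#' @return Named list (keyed by locus) holding the named amino-acid
#'   alignment, the shape the divergence and supertype stages consume.
#' @export
translate_alleles <- function(pool) {
  out <- list()
  out[[pool$locus]] <- translate_nt(pool$sequences)
  out
}

#' @export
print.allele_pool <- function(x, ...) {
  cat("Allele pool:", x$locus, "-", length(x$sequences), "alleles,",
      x$spec$n_motifs, "motifs,", x$spec$exon_length_nt, "nt\n")
  invisible(x)
}

#' Simulate diploid (or co-amplified tetraploid-like) genotypes
#'
#' Hardy-Weinberg sampling: each individual receives two gene copies per
#' independent locus, or four for a co-amplified pair of genes, drawn with
#' replacement from the pool allele frequencies.
#'
#' @param pools Named list of [generate_allele_pool()] outputs.
#' @param n_individuals Number of individuals.
#' @param allele_freqs Optional named list (per locus) of allele frequencies
#'   over pool labels; must sum to 1. Default uniform.
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `sex` (alternating F/M),
#'   `locus`, `alleles` (semicolon-joined distinct labels), `n_distinct`,
#'   `copies` (semicolon-joined labels with multiplicity).
#' @export
simulate_population <- function(pools, n_individuals, allele_freqs = NULL,
                                seed = 1) {
  stopifnot(n_individuals >= 1)
  with_seed(seed, {
    ids <- sprintf("ind%04d", seq_len(n_individuals))
    sex <- rep(c("F", "M"), length.out = n_individuals)
    out <- lapply(pools, function(pool) {
      labs <- names(pool$sequences)
      fr <- allele_freqs[[pool$locus]]
      if (is.null(fr)) fr <- setNames(rep(1 / length(labs), length(labs)), labs)
      if (abs(sum(fr) - 1) > 1e-8)
        stop("allele frequencies for ", pool$locus, " do not sum to 1")
      fr <- fr[labs]
      n_copies <- if (pool$spec$coamplified) 4L else 2L
      draws <- matrix(sample(labs, n_individuals * n_copies, replace = TRUE,
                             prob = fr), nrow = n_individuals)
      data.frame(sample_id = ids, sex = sex, locus = pool$locus,
                 alleles = apply(draws, 1, join_alleles),
                 n_distinct = apply(draws, 1, function(z) length(unique(z))),
                 copies = apply(draws, 1, function(z)
                   paste(sort(z), collapse = ";")),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

## One or two substitutions applied to a nucleotide sequence.
mutate_seq <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate per-amplicon variant-depth spectra
#'
#' For every individual x locus (x replicate), draws a negative-binomial total
#' depth, splits it across the individual's gene copies with a Dirichlet
#' allelic-imbalance draw, and adds two artifact classes the genotyper must
#' remove: low-depth 1-2-substitution derivatives of true alleles, and
#' single-breakpoint chimeras of two true alleles.
#'
#' @param genotypes Output of [simulate_population()].
#' @param pools Named list of allele pools.
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `locus`, `replicate`,
#'   `sequence`, `depth` (a `VariantTable` stack).
#' @export
simulate_amplicon_reads <- function(genotypes, pools, noise = noise_config(),
                                    seed = 1) {
  stopifnot(inherits(noise, "noise_config"))
  if (noise$mean_depth == 0) {
    warning("zero requested depth: returning empty variant table")
    return(data.frame(sample_id = character(), locus = character(),
                      replicate = integer(), sequence = character(),
                      depth = integer()))
  }
  with_seed(seed, {
    ids <- unique(genotypes$sample_id)
    replicated <- ids[runif(length(ids)) < noise$replicate_fraction]
    rows <- vector("list", nrow(genotypes) * 2L)
    ri <- 0L
    for (g in seq_len(nrow(genotypes))) {
      rec <- genotypes[g, ]
      pool <- pools[[rec$locus]]
      copies <- strsplit(rec$copies, ";")[[1]]
      tab_copies <- table(copies)
      true_seqs <- pool$sequences[names(tab_copies)]
      n_rep <- if (rec$sample_id %in% replicated) 2L else 1L
      for (r in seq_len(n_rep)) {
        total <- rnbinom(1, size = noise$depth_dispersion, mu = noise$mean_depth)
        if (total == 0) next
        shares <- rgamma(length(tab_copies),
                         shape = noise$allelic_imbalance * as.numeric(tab_copies))
        shares <- shares / sum(shares)
        d_true <- as.integer(round(total * shares))
        seqs <- unname(true_seqs)
        depth <- d_true
        L <- nchar(seqs[1])
        if (noise$sub_rate > 0) {
          p_err <- 1 - (1 - noise$sub_rate)^L
          for (i in seq_along(seqs)) {
            n_err <- rbinom(1, depth[i], p_err)
            if (n_err == 0) next
            k <- min(noise$n_error_variants, n_err)
            split <- as.vector(rmultinom(1, n_err, rep(1, k)))
            depth[i] <- depth[i] - n_err
            for (j in seq_len(k)) {
              if (split[j] == 0) next
              ev <- mutate_seq(seqs[i], sample(1:2, 1))
              seqs <- c(seqs, ev)
              depth <- c(depth, split[j])
            }
          }
        }
        if (noise$chimera_rate > 0 && length(true_seqs) >= 2) {
          n_chim <- rbinom(1, total, noise$chimera_rate)
          if (n_chim > 0) {
            par <- sample(seq_along(true_seqs), 2)
            bp <- sample(L - 1, 1)
            chim <- paste0(substr(true_seqs[par[1]], 1, bp),
                           substr(true_seqs[par[2]], bp + 1, L))
            if (!chim %in% unname(true_seqs)) {
              seqs <- c(seqs, chim)
              depth <- c(depth, n_chim)
            }
          }
        }
        keep <- depth > 0
        if (!any(keep)) next
        dd <- aggregate(list(depth = depth[keep]),
                        by = list(sequence = seqs[keep]), FUN = sum)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(sample_id = rec$sample_id, locus = rec$locus,
                                 replicate = r, sequence = dd$sequence,
                                 depth = as.integer(dd$depth),
                                 stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows[seq_len(ri)])
    out <- out[order(out$sample_id, out$locus, out$replicate, -out$depth,
                     out$sequence), ]
    rownames(out) <- NULL
    out
  })
}

## Gelman standardization used when injecting effects: (x - mean) / (2 sd).
std2 <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / (2 * s)
}

#' Simulate cross-fostered breeding records with injected MHC effects
#'
#' Couples are formed at random with respect to MHC; each nest gets a year,
#' laying date, parental ages, a zero-truncated Poisson clutch and a binomial
#' fledged count whose logit combines genetic-parent divergence effects,
#' social-parent divergence effects, optional supertype presence effects (on
#' the genetic parents), covariates, and year + parent random intercepts.
#' Random intercepts and caregiving covariates attach to the social (rearing)
#' parents. Full cross-fostering swaps entire clutches between nests matched
#' within year on hatch order, so genetic and social parents differ.
#'
#' @param genotypes Output of [simulate_population()] (for ids and sex).
#' @param divergences Data frame `sample_id`, `locus`,
#'   `functional_divergence` (see [divergence_table()]); the locus driving the
#'   injected divergence effects is chosen via `effect_locus`.
#' @param effects An [effect_config()].
#' @param n_nests Number of breeding records.
#' @param crossfoster_plan Either a single string (`"none"`, `"partial"`,
#'   `"full"`) applying to all nests, or a named numeric vector of proportions
#'   over those three categories.
#' @param supertype_presence Optional data frame `sample_id` x supertype 0/1
#'   columns (see [supertype_frequencies()]) used for injected supertype
#'   effects.
#' @param effect_locus Locus whose divergence carries the injected slopes.
#' @param seed Integer seed.
#' @return Data frame of nest records (one row per breeding attempt) with
#'   both parent sets, covariates and outcomes; the injected truth is attached
#'   as `attr(x, "truth")`.
#' @export
simulate_breeding <- function(genotypes, divergences, effects = effect_config(),
                              n_nests = 250,
                              crossfoster_plan = "full",
                              supertype_presence = NULL,
                              effect_locus = divergences$locus[1],
                              seed = 1) {
  stopifnot(inherits(effects, "effect_config"))
  ind <- unique(genotypes[, c("sample_id", "sex")])
  mothers <- ind$sample_id[ind$sex == "F"]
  fathers <- ind$sample_id[ind$sex == "M"]
  if (length(mothers) == 0 || length(fathers) == 0)
    stop("need both female and male individuals")
  dv <- divergences[divergences$locus == effect_locus, ]
  div_raw <- setNames(dv$functional_divergence, dv$sample_id)
  if (is.character(crossfoster_plan) && length(crossfoster_plan) == 1L) {
    plan <- setNames(as.numeric(c("none", "partial", "full") == crossfoster_plan),
                     c("none", "partial", "full"))
    if (sum(plan) == 0) stop("unknown crossfoster_plan '", crossfoster_plan, "'")
  } else {
    plan <- crossfoster_plan[c("none", "partial", "full")]
    plan[is.na(plan)] <- 0
    plan <- plan / sum(plan)
  }
  with_seed(seed, {
    year <- sample(seq_len(effects$n_years), n_nests, replace = TRUE)
    laying <- pmin(pmax(round(rnorm(n_nests, 110, 25)), 50), 220)
    gm <- sample(mothers, n_nests, replace = TRUE)
    gf <- sample(fathers, n_nests, replace = TRUE)
    mother_age <- 1 + rpois(n_nests, 1.5)
    father_age <- 1 + rpois(n_nests, 1.5)
    cf <- sample(names(plan), n_nests, replace = TRUE, prob = plan)
    ## full swaps: pair nests within year by laying order
    sm <- gm; sf <- gf
    n_unpaired <- 0L
    for (y in unique(year)) {
      idx <- which(year == y & cf == "full")
      idx <- idx[order(laying[idx])]
      if (length(idx) %% 2 == 1) {
        n_unpaired <- n_unpaired + 1L
        cf[idx[length(idx)]] <- "none"
        idx <- idx[-length(idx)]
      }
      if (length(idx) >= 2) {
        a <- idx[seq(1, length(idx), by = 2)]
        b <- idx[seq(2, length(idx), by = 2)]
        sm[a] <- gm[b]; sf[a] <- gf[b]
        sm[b] <- gm[a]; sf[b] <- gf[a]
      }
    }
    if (n_unpaired > 0)
      message(n_unpaired, " full-swap group(s) had an odd nest count: ",
              "one nest per group left unswapped")
    u_year <- setNames(rnorm(effects$n_years, 0, effects$sigma_year),
                       seq_len(effects$n_years))
    all_ids <- ind$sample_id
    u_ind_c <- setNames(rnorm(length(all_ids), 0, effects$sigma_individual), all_ids)
    u_ind_f <- setNames(rnorm(length(all_ids), 0, effects$sigma_individual), all_ids)
    ce <- effects$covariate_effects
    ma_s <- std2(mother_age); fa_s <- std2(father_age); ld_s <- std2(laying)
    covar <- ce[["mother_age"]] * ma_s + ce[["father_age"]] * fa_s +
      ce[["laying_date"]] * ld_s + ce[["laying_date_sq"]] * std2(ld_s^2)
    eta_clutch <- effects$clutch_log_mean + covar +
      u_year[as.character(year)] + u_ind_c[sm] + u_ind_f[sf]
    clutch <- rpois(n_nests, exp(eta_clutch))
    while (any(clutch == 0))   # zero-truncation: clutch is >= 1 by definition
      clutch[clutch == 0] <- rpois(sum(clutch == 0), exp(eta_clutch[clutch == 0]))
    ## divergence standardized per parent role over the realized draws --
    ## the same Gelman rescaling the analysis stage applies, so the injected
    ## slopes live on the scale the standardized estimates are reported on
    eta_f <- effects$fledge_logit_mean + covar +
      effects$beta_div_genetic_father * std2(div_raw[gf]) +
      effects$beta_div_genetic_mother * std2(div_raw[gm]) +
      effects$beta_div_social_father * std2(div_raw[sf]) +
      effects$beta_div_social_mother * std2(div_raw[sm]) +
      u_year[as.character(year)] + u_ind_f[sm] + u_ind_f[sf]
    if (length(effects$supertype_effects) && !is.null(supertype_presence)) {
      sp <- supertype_presence
      rownames(sp) <- sp$sample_id
      for (st in names(effects$supertype_effects)) {
        e <- effects$supertype_effects[[st]]
        pf <- sp[gf, st]; pm <- sp[gm, st]
        eta_f <- eta_f + e[1] * pf + e[2] * pm +
          (if (length(e) >= 3) e[3] * pf * pm else 0)
      }
    }
    fledged <- rbinom(n_nests, clutch, plogis(unname(eta_f)))
    out <- data.frame(
      nest_id = sprintf("nest%04d", seq_len(n_nests)),
      year = year, laying_date_julian = laying,
      clutch = clutch, fledged = fledged,
      genetic_mother = gm, genetic_father = gf,
      social_mother = sm, social_father = sf,
      mother_age = mother_age, father_age = father_age,
      crossfoster = cf, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(effects = effects, effect_locus = effect_locus)
    out
  })
}
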