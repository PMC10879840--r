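## Allele calling from per-amplicon variant-depth spectra.
##
## Two independent callers are run per amplicon -- the Degree-of-Change
## inflection method and the frequency Threshold method -- then screened for
## chimeric and non-functional variants and reconciled into a consensus call.

#' Genotyper parameters
#'
#' @param expected_length_nt Expected amplicon variant length; off-length
#'   variants are removed as artifacts.
#' @param max_alleles Maximum alleles per amplicon: 4 for a co-amplified pair
#'   of genes, 2 for a single locus.
#' @param min_total_depth Amplicons below this total depth are uncallable.
#' @param min_variant_freq Pre-filter: variants below this within-amplicon
#'   frequency are removed.
#' @param t_art Threshold-method artifact cutoff: variants with frequency
#'   `>= t_art` are called alleles.
#' @param chimera_depth_ratio A called variant can only be flagged as a
#'   chimera when its depth is below this fraction of both putative parents'
#'   depths (see [detect_chimeras()]).
#' @return Object of class `genotyper_params`.
#' @export
genotyper_params <- function(expected_length_nt, max_alleles = 2L,
                             min_total_depth = 50, min_variant_freq = 0.01,
                             t_art = 0.05, chimera_depth_ratio = 1 / 3) {
  stopifnot(min_total_depth >= 1,
            min_variant_freq > 0, min_variant_freq < 1,
            t_art > 0, t_art < 1, max_alleles >= 1,
            chimera_depth_ratio > 0, chimera_depth_ratio <= 1)
  structure(list(expected_length_nt = as.integer(expected_length_nt),
                 max_alleles = as.integer(max_alleles),
                 min_total_depth = min_total_depth,
                 min_variant_freq = min_variant_freq, t_art = t_art,
                 chimera_depth_ratio = chimera_depth_ratio),
            class = "genotyper_params")
}

## Canonical within-amplicon ordering: depth descending, then sequence.
sort_variants <- function(tab) {
  if (anyDuplicated(tab$sequence)) {
    d <- rowsum(tab$depth, tab$sequence)
    tab <- data.frame(sequence = rownames(d), depth = as.vector(d),
                      stringsAsFactors = FALSE)
  }
  tab <- tab[order(-tab$depth, tab$sequence), c("sequence", "depth")]
  rownames(tab) <- NULL
  tab
}

#' Pre-filter an amplicon variant table
#'
#' Removes variants of unexpected length, variants below the minimum
#' within-amplicon frequency, and depth-1 singletons. Amplicons whose total
#' depth falls below `min_total_depth` are flagged uncallable (no error).
#'
#' @param tab Data frame with columns `sequence`, `depth` (one amplicon).
#' @param params A [genotyper_params()].
#' @return The filtered table (canonically sorted), with attributes
#'   `uncallable` (logical) and `qc` (character vector of applied flags).
#' @export
filter_variants <- function(tab, params) {
  stopifnot(nrow(tab) > 0)
  tab <- sort_variants(tab)
  qc <- character(0)
  total <- sum(tab$depth)
  if (total < params$min_total_depth) {
    qc <- c(qc, "low_depth")
    out <- tab[0, ]
    attr(out, "uncallable") <- TRUE
    attr(out, "qc") <- qc
    return(out)
  }
  keep <- nchar(tab$sequence) == params$expected_length_nt &
    tab$depth / total >= params$min_variant_freq &
    tab$depth > 1
  out <- tab[keep, ]
  rownames(out) <- NULL
  if (nrow(out) == 0) qc <- c(qc, "all_variants_removed")
  attr(out, "uncallable") <- nrow(out) == 0
  attr(out, "qc") <- qc
  out
}

#' Degree-of-Change allele calling
#'
#' With variants sorted by depth, cumulative depths `C_i` define the
#' degree-of-change statistic `DOC_i = (C_i - C_{i-1}) / (C_{i+1} - C_i)`,
#' i.e. the ratio of successive depth increments; the call size `n` is the
#' `i <= max_alleles` maximizing it (the depth cliff separating alleles from
#' artifacts). When every variant survives filtering and there are at most
#' `max_alleles` of them, `C` is flat beyond the last variant and the DOC
#' there is infinite, so a clean amplicon calls all its variants. A
#' single-variant table calls one allele.
#'
#' @param tab Filtered variant table (see [filter_variants()]).
#' @param max_alleles Cap on the number of alleles.
#' @return List with `n_alleles`, `alleles` (character), `doc_profile`
#'   (numeric DOC_i values) and `qc` flags (`tie_break` when a depth tie at
#'   the cut was resolved lexicographically).
#' @export
doc_genotype <- function(tab, max_alleles) {
  tab <- sort_variants(tab)
  nv <- nrow(tab)
  stopifnot(nv >= 1)
  if (nv == 1L)
    return(list(n_alleles = 1L, alleles = tab$sequence, doc_profile = numeric(0),
                qc = character(0)))
  d <- tab$depth
  imax <- min(max_alleles, nv)
  doc <- vapply(seq_len(imax), function(i) {
    if (i < nv) d[i] / d[i + 1] else Inf
  }, numeric(1))
  n <- which.max(doc)
  qc <- character(0)
  alleles <- tab$sequence[seq_len(n)]
  ## depth tie straddling the cut
  if (n < nv && d[n] == d[n + 1]) {
    tied <- which(d == d[n])
    if (max(tied) <= max_alleles) {
      n <- max(tied)
      alleles <- tab$sequence[seq_len(n)]
    } else {
      fixed <- tab$sequence[seq_len(min(tied) - 1)]
      room <- n - length(fixed)
      pick <- sort(tab$sequence[tied])[seq_len(room)]
      alleles <- c(fixed, pick)
      qc <- c(qc, "tie_break")
    }
  }
  list(n_alleles = length(alleles), alleles = alleles,
       doc_profile = doc, qc = qc)
}

#' Threshold-method allele calling
#'
#' Calls every variant whose within-amplicon frequency is at least `t_art`,
#' capped at `max_alleles` by depth rank.
#'
#' @inheritParams doc_genotype
#' @param t_art Per-amplicon frequency cutoff.
#' @return List with `n_alleles`, `alleles`, `qc` flags (`uncallable` if no
#'   variant reaches the threshold, `max_alleles_capped` if the cap applied).
#' @export
threshold_genotype <- function(tab, t_art, max_alleles) {
  tab <- sort_variants(tab)
  freq <- tab$depth / sum(tab$depth)
  keep <- which(freq >= t_art)
  qc <- character(0)
  if (length(keep) == 0)
    return(list(n_alleles = 0L, alleles = character(0), qc = "uncallable"))
  if (length(keep) > max_alleles) {
    keep <- keep[seq_len(max_alleles)]
    qc <- c(qc, "max_alleles_capped")
  }
  list(n_alleles = length(keep), alleles = tab$sequence[keep], qc = qc)
}

#' Flag chimeric called variants
#'
#' A called variant is chimeric if some single breakpoint splits it into a
#' prefix matching one deeper-ranked variant and a suffix matching another
#' (distinct) deeper variant in the full amplicon table. Because PCR
#' crossover artifacts are rare relative to their template alleles, a
#' candidate is only flagged when its depth is below `max_ratio` times the
#' depth of both putative parents; a variant at depth comparable to its
#' parents is a genuine allele even if it happens to be reconstructable.
#'
#' @param alleles Character vector of called variant sequences.
#' @param tab Full (filtered) variant table providing depth ranks.
#' @param max_ratio Maximum depth of a chimera relative to its shallower
#'   parent (default 1/3).
#' @return Character vector of flagged (chimeric) sequences.
#' @export
detect_chimeras <- function(alleles, tab, max_ratio = 1 / 3) {
  tab <- sort_variants(tab)
  depth_of <- setNames(tab$depth, tab$sequence)
  flagged <- character(0)
  for (v in alleles) {
    dv <- depth_of[[v]] %||% 0
    deeper <- tab$sequence[tab$depth * max_ratio > dv & tab$sequence != v]
    if (length(deeper) < 2) next
    L <- nchar(v)
    same_len <- deeper[nchar(deeper) == L]
    if (length(same_len) < 2) next
    for (k in seq_len(L - 1)) {
      pre <- substr(v, 1, k)
      suf <- substr(v, k + 1, L)
      pa <- same_len[substr(same_len, 1, k) == pre]
      pb <- same_len[substr(same_len, k + 1, L) == suf]
      if (length(pa) && length(pb) && length(union(pa, pb)) >= 2 &&
          any(outer(pa, pb, "!="))) {
        flagged <- c(flagged, v)
        break
      }
    }
  }
  unique(flagged)
}

#' Screen called alleles for functionality
#'
#' Removes alleles whose length is not a codon multiple (frameshift proxy) or
#' whose in-frame translation contains a stop codon.
#'
#' @param alleles Character vector of called nucleotide sequences.
#' @return The retained (functional) alleles.
#' @export
screen_functionality <- function(alleles) {
  if (length(alleles) == 0) return(alleles)
  inframe <- nchar(alleles) %% 3 == 0
  ok <- inframe
  if (any(inframe))
    ok[inframe] <- !has_stop(translate_nt(alleles[inframe]))
  alleles[ok]
}

#' Reconcile the two calling methods into a consensus genotype
#'
#' Identical calls are accepted as-is; otherwise the non-empty intersection is
#' taken with a `discordant` flag; a disjoint pair is uncallable.
#'
#' @param doc_call,threshold_call Call lists (`alleles`, `qc`) from
#'   [doc_genotype()] and [threshold_genotype()].
#' @return List with `alleles`, `n_alleles`, `method_agreement`, `qc`.
#' @export
consensus_genotype <- function(doc_call, threshold_call) {
  a <- sort(doc_call$alleles)
  b <- sort(threshold_call$alleles)
  qc <- union(doc_call$qc, threshold_call$qc)
  if (identical(a, b)) {
    return(list(alleles = a, n_alleles = length(a), method_agreement = TRUE,
                qc = qc))
  }
  inter <- intersect(a, b)
  if (length(inter) == 0)
    return(list(alleles = character(0), n_alleles = 0L,
                method_agreement = FALSE, qc = union(qc, "uncallable")))
  list(alleles = sort(inter), n_alleles = length(inter),
       method_agreement = FALSE, qc = union(qc, "discordant"))
}

## Full single-amplicon pipeline: filter, call twice, screen, reconcile.
call_amplicon <- function(tab, params) {
  ft <- filter_variants(tab, params)
  if (isTRUE(attr(ft, "uncallable")))
    return(list(alleles = character(0), n_alleles = 0L,
                method_agreement = NA, qc = union(attr(ft, "qc"), "uncallable")))
  screen <- function(call) {
    chim <- detect_chimeras(call$alleles, ft,
                            max_ratio = params$chimera_depth_ratio)
    if (length(chim)) {
      call$alleles <- setdiff(call$alleles, chim)
      call$qc <- c(call$qc, "chimera_removed")
    }
    kept <- screen_functionality(call$alleles)
    if (length(kept) < length(call$alleles))
      call$qc <- c(call$qc, "nonfunctional_removed")
    call$alleles <- kept
    call$n_alleles <- length(kept)
    call
  }
  dc <- screen(doc_genotype(ft, params$max_alleles))
  tc <- screen(threshold_genotype(ft, params$t_art, params$max_alleles))
  out <- consensus_genotype(dc, tc)
  out$qc <- union(out$qc, attr(ft, "qc"))
  if (out$n_alleles == 0) out$qc <- union(out$qc, "uncallable")
  out
}

#' Call genotypes for a stacked variant table
#'
#' Runs the full per-amplicon pipeline (pre-filter, Degree-of-Change and
#' Threshold calls, chimera and functionality screens, consensus) for every
#' `sample_id` x `locus` x `replicate` amplicon. When a sample was amplified
#' twice, the replicate with the higher total depth provides the reported
#' genotype; [replicate_concordance()] measures their agreement.
#'
#' @param variants Data frame with columns `sample_id`, `locus`, `replicate`,
#'   `sequence`, `depth`.
#' @param params_by_locus Named list of [genotyper_params()] per locus.
#' @return Object of class `genotype_calls`: data frame with one row per
#'   sample x locus (`alleles` semicolon-joined sequences, `n_alleles`,
#'   `method_agreement`, `qc_flags`), with the per-replicate calls in
#'   `attr(x, "replicate_calls")`.
#' @export
call_genotypes <- function(variants, params_by_locus) {
  need <- c("sample_id", "locus", "replicate", "sequence", "depth")
  stopifnot(all(need %in% names(variants)))
  key <- interaction(variants$sample_id, variants$locus, variants$replicate,
                     drop = TRUE)
  pieces <- split(variants, key)
  rep_rows <- lapply(pieces, function(tab) {
    p <- params_by_locus[[tab$locus[1]]]
    if (is.null(p)) stop("no genotyper_params for locus '", tab$locus[1], "'")
    call <- call_amplicon(tab[, c("sequence", "depth")], p)
    data.frame(sample_id = tab$sample_id[1], locus = tab$locus[1],
               replicate = tab$replicate[1],
               alleles = paste(call$alleles, collapse = ";"),
               n_alleles = call$n_alleles,
               method_agreement = call$method_agreement,
               qc_flags = paste(sort(unique(call$qc)), collapse = ","),
               total_depth = sum(tab$depth), stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, c(rep_rows, list(make.row.names = FALSE)))
  reps <- reps[order(reps$sample_id, reps$locus, reps$replicate), ]
  ## reported call: deepest replicate
  o <- order(reps$sample_id, reps$locus, -reps$total_depth)
  first <- !duplicated(reps[o, c("sample_id", "locus")])
  final <- reps[o, ][first, setdiff(names(reps), c("replicate", "total_depth"))]
  rownames(final) <- NULL
  structure(final, replicate_calls = reps, class = c("genotype_calls",
                                                     "data.frame"))
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat("Genotype calls:", nrow(x), "sample x locus amplicons;",
      sum(x$n_alleles == 0), "uncallable\n")
  print.data.frame(head(as.data.frame(x)[, c("sample_id", "locus", "n_alleles",
                                             "method_agreement", "qc_flags")]),
                   ...)
  invisible(x)
}

#' Replicate reproducibility
#'
#' Fraction of replicated sample x locus amplicons whose final allele sets
#' are identical between the two independent replicates.
#'
#' @param calls A [call_genotypes()] result (its `replicate_calls` attribute
#'   is used) or a data frame of per-replicate calls.
#' @return A fraction in `[0, 1]` (`NA` if nothing was replicated).
#' @export
replicate_concordance <- function(calls) {
  reps <- attr(calls, "replicate_calls") %||% calls
  key <- paste(reps$sample_id, reps$locus)
  dup <- names(which(table(key) >= 2))
  if (length(dup) == 0) return(NA_real_)
  same <- vapply(dup, function(k) {
    sets <- reps$alleles[key == k]
    sets <- vapply(strsplit(sets, ";"), function(z) join_alleles(z), "")
    length(unique(sets)) == 1L
  }, logical(1))
  mean(same)
}
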