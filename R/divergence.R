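## Pairwise allele distances (amino-acid p-distance, Grantham functional
## distance) and per-individual MHC divergence.

#' Grantham distance between two residues
#'
#' @param res_a,res_b One-letter residue codes (vectorized, recycled).
#' @return Non-negative numeric; zero iff the residues are identical.
#' @examples
#' grantham_distance("L", "S")
#' @export
grantham_distance <- function(res_a, res_b) {
  m <- grantham_matrix()
  bad <- setdiff(unique(c(res_a, res_b)), rownames(m))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  m[cbind(res_a, res_b)]
}

#' Distance between two aligned amino-acid sequences
#'
#' `p_distance` is the proportion of differing sites; `grantham` is the
#' Grantham distance summed over sites and, in the default `per_site` mode,
#' divided by the alignment length.
#'
#' @param seq1,seq2 Equal-length amino-acid strings.
#' @param metric `"p_distance"` or `"grantham"`.
#' @param mode For the Grantham metric: `"per_site"` (default) or `"raw"`
#'   (summed). The choice only rescales values.
#' @return A single non-negative number.
#' @export
sequence_distance <- function(seq1, seq2,
                              metric = c("p_distance", "grantham"),
                              mode = c("per_site", "raw")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (nchar(seq1) != nchar(seq2))
    stop("sequences must have equal length")
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  if (metric == "p_distance") return(mean(a != b))
  d <- sum(grantham_distance(a, b))
  if (mode == "per_site") d / length(a) else d
}

#' Per-individual MHC divergence
#'
#' Mean pairwise distance over all unordered pairs of an individual's
#' distinct alleles (a homozygote scores 0). For a co-amplified class I
#' amplicon with up to four alleles this is the total average distance over
#' all pairs; for a two-allele locus it is the one heterozygous pair.
#'
#' @param alleles Character vector of the individual's distinct allele labels.
#' @param aa_alignment Named character vector of equal-length amino-acid
#'   sequences covering those labels.
#' @inheritParams sequence_distance
#' @return A single non-negative number.
#' @export
individual_divergence <- function(alleles, aa_alignment,
                                  metric = c("p_distance", "grantham"),
                                  mode = c("per_site", "raw")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  alleles <- unique(alleles)
  missing <- setdiff(alleles, names(aa_alignment))
  if (length(missing))
    stop("allele(s) absent from alignment: ", paste(missing, collapse = ", "))
  if (length(alleles) < 2) return(0)
  pairs <- combn(alleles, 2)
  mean(apply(pairs, 2, function(p)
    sequence_distance(aa_alignment[[p[1]]], aa_alignment[[p[2]]],
                      metric, mode)))
}

#' Divergence table for a genotyped population
#'
#' Computes, per sample x locus, the amino-acid p-distance and the Grantham
#' functional divergence over the individual's called alleles.
#'
#' @param genotypes Data frame with columns `sample_id`, `locus`, `alleles`
#'   (semicolon-joined allele labels).
#' @param aa_alignments Named list (per locus) of named amino-acid alignments.
#' @param mode Grantham normalization, `"per_site"` or `"raw"`.
#' @return Data frame `sample_id`, `locus`, `p_distance`,
#'   `functional_divergence`.
#' @export
divergence_table <- function(genotypes, aa_alignments, mode = "per_site") {
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    aln <- aa_alignments[[g$locus]]
    if (is.null(aln)) stop("no alignment for locus '", g$locus, "'")
    al <- strsplit(g$alleles, ";")[[1]]
    if (length(al) == 0 || identical(al, ""))
      return(data.frame(sample_id = g$sample_id, locus = g$locus,
                        p_distance = NA_real_,
                        functional_divergence = NA_real_))
    data.frame(sample_id = g$sample_id, locus = g$locus,
               p_distance = individual_divergence(al, aln, "p_distance"),
               functional_divergence =
                 individual_divergence(al, aln, "grantham", mode))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlation between the two divergence metrics
#'
#' Pearson correlation, per locus, of per-individual p-distance and Grantham
#' functional divergence -- a QC statistic (the study proceeds with the
#' functional divergence alone when the two correlate strongly, r > 0.85).
#'
#' @param div A [divergence_table()] result.
#' @return Named numeric vector of correlations per locus.
#' @export
metric_correlation <- function(div) {
  vapply(split(div, div$locus), function(d) {
    d <- d[stats::complete.cases(d[, c("p_distance", "functional_divergence")]), ]
    if (nrow(d) < 3 || sd(d$p_distance) == 0 ||
        sd(d$functional_divergence) == 0) return(NA_real_)
    cor(d$p_distance, d$functional_divergence)
  }, numeric(1))
}
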