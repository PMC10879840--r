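## Supertype construction: descriptor matrices over positively selected
## sites, k selection by BIC or silhouette over k-means partitions, and
## discriminant re-assignment (simplified DAPC), plus population frequencies.

#' Positively selected site list
#'
#' The supported path for real data is an externally supplied list of codon
#' positions (site-model inference itself is out of scope here). For
#' synthetic, self-contained runs a diversity heuristic is available: sites
#' ranked by Shannon entropy of their residues, top `m` returned. The
#' heuristic is *not* equivalent to codon-model selection inference and is
#' labelled as such.
#'
#' @param aa_alignment Named character vector of aligned amino-acid sequences.
#' @param method `"external_list"` (pass `sites`) or `"heuristic"` (pass `m`).
#' @param sites Integer codon positions (1-based) for `external_list`.
#' @param m Number of top-entropy sites for the heuristic.
#' @return Sorted integer vector of 1-based codon positions.
#' @export
screen_selected_sites <- function(aa_alignment,
                                  method = c("external_list", "heuristic"),
                                  sites = NULL, m = NULL) {
  method <- match.arg(method)
  L <- unique(nchar(aa_alignment))
  stopifnot(length(L) == 1L)
  if (method == "external_list") {
    if (is.null(sites) || length(sites) == 0)
      stop("empty site list: supply 1-based codon positions")
    sites <- sort(unique(as.integer(sites)))
    if (any(sites < 1 | sites > L))
      stop("site positions outside 1..", L)
    return(sites)
  }
  if (is.null(m) || m < 1) stop("heuristic screening needs m >= 1")
  sm <- aa_site_matrix(aa_alignment)
  ent <- apply(sm, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log(p))
  })
  if (all(ent == 0))
    stop("alignment is monomorphic: no variable sites to rank")
  m <- min(m, sum(ent > 0))
  ## ties broken toward the lower position for determinism
  sort(order(-ent, seq_along(ent))[seq_len(m)])
}

#' Build the physicochemical descriptor matrix
#'
#' Each allele is described by the five z-scale descriptor values of its
#' residue at every selected site, flattened to an alleles x (sites * 5)
#' matrix and column-standardized (columns that are constant across alleles
#' are set to zero).
#'
#' @param aa_alignment Named character vector of aligned amino-acid sequences.
#' @param sites 1-based codon positions to describe.
#' @return Standardized numeric matrix, rows named by allele label, with the
#'   unstandardized matrix in `attr(x, "raw")`.
#' @export
build_descriptor_matrix <- function(aa_alignment, sites) {
  stopifnot(length(sites) >= 1)
  z <- zscale_table()
  sm <- aa_site_matrix(aa_alignment)[, sites, drop = FALSE]
  bad <- setdiff(unique(as.vector(sm)), rownames(z))
  if (length(bad))
    stop("residue(s) without descriptor values: ", paste(bad, collapse = ", "))
  cols <- lapply(seq_along(sites), function(j) {
    block <- z[sm[, j], , drop = FALSE]
    colnames(block) <- paste0("s", sites[j], "_", colnames(z))
    block
  })
  raw <- do.call(cbind, cols)
  rownames(raw) <- rownames(sm)
  std <- apply(raw, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(std) <- rownames(raw)
  attr(std, "raw") <- raw
  std
}

## Number of distinct descriptor rows (alleles identical at the selected
## sites collapse to one point; k cannot exceed this).
n_distinct_rows <- function(mat) sum(!duplicated(round(mat, 10)))

## k-means++ seeding feeding stats::kmeans; best of n_restarts by WSS.
kmeans_best <- function(mat, k, n_restarts = 100) {
  n <- nrow(mat)
  if (k > n_distinct_rows(mat))
    stop("k = ", k, " exceeds the ", n_distinct_rows(mat),
         " distinct descriptor rows")
  if (k == 1)
    return(list(cluster = setNames(rep(1L, n), rownames(mat)),
                tot.withinss = sum(scale(mat, scale = FALSE)^2)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- matrix(NA_real_, k, ncol(mat))
    centers[1, ] <- mat[sample(n, 1), ]
    for (j in 2:k) {
      d2 <- apply(mat, 1, function(row)
        min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - row)^2)))
      if (sum(d2) == 0) centers[j, ] <- mat[sample(n, 1), ]
      else centers[j, ] <- mat[sample(n, 1, prob = d2), ]
    }
    km <- suppressWarnings(
      kmeans(mat, centers = centers, iter.max = 50, nstart = 1))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster <- setNames(best$cluster, rownames(mat))
  best
}

#' Select the number of supertypes
#'
#' For each candidate `k`, the best of `n_restarts` k-means partitions
#' (k-means++ seeding) is scored either by the k-means BIC
#' `n*log(WSS/n) + k*log(n)` (minimized) or by the mean silhouette width
#' (maximized). A best silhouette below `silhouette_floor` triggers a
#' weak-structure warning.
#'
#' @param mat Descriptor matrix from [build_descriptor_matrix()].
#' @param k_range Candidate cluster numbers (values beyond `nrow - 1` are
#'   truncated with a warning).
#' @param method `"BIC"` or `"silhouette"`.
#' @param seed Integer seed (the selection is deterministic given it).
#' @param n_restarts k-means restarts per `k`.
#' @param silhouette_floor Weak-structure warning threshold.
#' @return The selected `k` (integer) with the criterion profile in
#'   `attr(k, "criterion")`.
#' @export
select_k <- function(mat, k_range = 2:10, method = c("BIC", "silhouette"),
                     seed = 1, n_restarts = 100, silhouette_floor = 0.25) {
  method <- match.arg(method)
  n <- nrow(mat)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range > n - 1)) {
    warning("k_range truncated to n_alleles - 1 = ", n - 1)
    k_range <- k_range[k_range <= n - 1]
  }
  nd <- n_distinct_rows(mat)
  if (any(k_range > nd)) {
    warning("k_range truncated to the ", nd, " distinct descriptor rows")
    k_range <- k_range[k_range <= nd]
  }
  stopifnot(length(k_range) >= 1, all(k_range >= 1))
  with_seed(seed, {
    dmat <- if (method == "silhouette") dist(mat) else NULL
    crit <- vapply(k_range, function(k) {
      km <- kmeans_best(mat, k, n_restarts)
      if (method == "BIC") {
        n * log(max(km$tot.withinss, 1e-12) / n) + k * log(n)
      } else {
        if (k == 1) return(-Inf)
        mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
      }
    }, numeric(1))
    k <- if (method == "BIC") k_range[which.min(crit)]
         else k_range[which.max(crit)]
    if (method == "silhouette" && max(crit) < silhouette_floor)
      warning("weak cluster structure: best mean silhouette ",
              round(max(crit), 3), " < ", silhouette_floor)
    structure(as.integer(k),
              criterion = setNames(crit, paste0("k", k_range)))
  })
}

#' Assign alleles to supertypes
#'
#' k-means partition (best of restarts, k-means++ seeding) followed by a
#' simplified discriminant-analysis-of-principal-components step: PCA
#' retaining at least 90% of the variance, linear discriminant axes on the
#' k-means classes, and re-assignment of every allele to the nearest class
#' centroid in discriminant space. Supertypes are re-labelled canonically by
#' first occurrence in lexicographic allele order, so the assignment is
#' deterministic given the seed.
#'
#' @param mat Descriptor matrix from [build_descriptor_matrix()].
#' @param k Number of supertypes (from [select_k()] or fixed).
#' @param seed Integer seed.
#' @param n_restarts k-means restarts.
#' @param pca_var Minimum variance fraction the retained PCs must explain.
#' @return Object of class `supertype_assignment`: data frame with columns
#'   `allele`, `supertype` (`"ST1"`, `"ST2"`, ...), plus attributes `k`,
#'   `reassigned` (alleles moved by the discriminant step).
#' @export
assign_supertypes <- function(mat, k, seed = 1, n_restarts = 100,
                              pca_var = 0.90) {
  stopifnot(k >= 1, nrow(mat) >= k)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  with_seed(seed, {
    km <- kmeans_best(mat, k, n_restarts)
    cl <- km$cluster
    moved <- character(0)
    if (k > 1 && min(table(cl)) >= 2) {
      pc <- prcomp(mat, center = TRUE, scale. = FALSE)
      v <- pc$sdev^2 / sum(pc$sdev^2)
      npc <- which(cumsum(v) >= pca_var)[1]
      npc <- min(max(npc, 1L), nrow(mat) - 1L)
      scores <- pc$x[, seq_len(npc), drop = FALSE]
      ld <- try(MASS::lda(scores, grouping = factor(cl)), silent = TRUE)
      if (!inherits(ld, "try-error")) {
        proj <- scores %*% ld$scaling
        cent <- apply(proj, 2, function(col) tapply(col, cl, mean))
        cent <- matrix(cent, nrow = length(unique(cl)),
                       dimnames = list(sort(unique(cl)), colnames(proj)))
        new_cl <- apply(proj, 1, function(row)
          as.integer(rownames(cent)[which.min(colSums((t(cent) - row)^2))]))
        moved <- names(cl)[new_cl != cl]
        cl <- setNames(new_cl, names(cl))
      }
    }
    ## canonical labels: order of first appearance over sorted allele names
    first <- cl[!duplicated(cl)]
    relabel <- setNames(seq_along(first), first)
    st <- sprintf("ST%d", relabel[as.character(cl)])
    out <- data.frame(allele = names(cl), supertype = st,
                      stringsAsFactors = FALSE)
    structure(out, k = length(unique(st)), reassigned = moved,
              class = c("supertype_assignment", "data.frame"))
  })
}

#' Supertype population frequencies and per-individual presence
#'
#' A supertype's frequency is the number of genotyped individuals carrying at
#' least one allele of it, divided by the number genotyped at that locus.
#'
#' @param assignment A [assign_supertypes()] result (allele -> supertype).
#' @param genotypes Data frame `sample_id`, `locus`, `alleles`
#'   (semicolon-joined labels matching the assignment's alleles).
#' @return List with `frequencies` (named numeric) and `presence` (data frame
#'   `sample_id` + one 0/1 column per supertype).
#' @export
supertype_frequencies <- function(assignment, genotypes) {
  st_of <- setNames(assignment$supertype, assignment$allele)
  sts <- sort(unique(assignment$supertype))
  allele_lists <- split_alleles(genotypes$alleles)
  pres <- t(vapply(allele_lists, function(al) {
    carried <- unique(st_of[al[al %in% names(st_of)]])
    as.integer(sts %in% carried)
  }, integer(length(sts))))
  colnames(pres) <- sts
  presence <- data.frame(sample_id = genotypes$sample_id, pres,
                         check.names = FALSE, stringsAsFactors = FALSE)
  freqs <- colMeans(pres)
  list(frequencies = freqs, presence = presence)
}

#' Filter supertypes by population frequency
#'
#' Retains supertypes with frequency strictly above the floor (a frequency of
#' exactly the floor is excluded).
#'
#' @param frequencies Named numeric vector of supertype frequencies.
#' @param floor Frequency floor (default 0.10).
#' @return Character vector of retained supertype labels (possibly empty,
#'   with a message).
#' @export
filter_common_supertypes <- function(frequencies, floor = 0.10) {
  keep <- names(frequencies)[frequencies > floor]
  if (length(keep) == 0)
    message("no supertype exceeds the frequency floor of ", floor,
            "; supertype testing will be skipped")
  keep
}
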