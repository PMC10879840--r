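## File formats, run configuration and the end-to-end pipeline driver:
## simulate -> genotype -> divergence -> supertypes -> associate -> report.

#' Read a FASTA file of allele sequences
#'
#' @param path FASTA file path.
#' @param aligned Require all records to share one length (for stages that
#'   consume alignments); the error names the offending record.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicated record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- setNames(as.character(x), ids)
  if (aligned && length(unique(nchar(out))) > 1) {
    ref <- nchar(out)[1]
    bad <- names(out)[nchar(out) != ref][1]
    stop("mixed-length records in alignment (e.g. '", bad, "')")
  }
  out
}

#' Write allele sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

## Delimited IO with a '# seed=... config_hash=...' provenance header.
write_table_hdr <- function(df, path, sep = ",", seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed) || !is.null(hash))
    writeLines(paste0("# seed=", seed %||% "NA",
                      " config_hash=", hash %||% "NA"), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_hdr <- function(path, sep = ",") {
  read.delim(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Run configuration
#'
#' Assembles (or reads from a YAML file) the configuration of a full
#' synthetic run. Defaults mirror the study system: 1190 genotyped
#' individuals, 1079 breeding records over 23 years of which roughly a third
#' each are un-, partially and fully cross-fostered, the three default loci,
#' BIC k-selection for the class I amplicon and silhouette for the class IIb
#' loci.
#'
#' @param path Optional YAML file; entries override the defaults.
#' @param ... Named overrides applied on top (highest precedence).
#' @return A list of class `run_config` with a `config_hash` attribute.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    n_individuals = 1190L,
    n_nests = 1079L,
    crossfoster_plan = c(none = 370, partial = 380, full = 329) / 1079,
    loci = names(default_locus_specs()),
    k_method = c(`MHC-Ia` = "BIC", DAB1 = "silhouette", DAB2 = "silhouette"),
    site_method = "external_list",   # truth sites from the locus specs
    effect_locus = "MHC-Ia",
    responses = c("clutch", "fledging"),
    modes = c("full", "crossfostered"),
    include_quadratics = TRUE,
    include_interactions = TRUE,
    noise = list(), effects = list(),
    out_dir = NULL)
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  cfg <- modifyList(cfg, list(...))
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")], tmp)
  attr(cfg, "config_hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> genotype -> divergence -> supertype -> associate and
#' aggregates a run report: genotyping QC (replicate concordance, uncallable
#' counts), divergence summaries and metric correlations, supertype counts
#' and frequencies, and the association outputs for every requested response
#' x dataset mode. With `out_dir` set, all stage outputs are written
#' (FASTA/CSV/TSV, provenance headers carrying the seed and config hash).
#'
#' @param config A [run_config()].
#' @return Object of class `mhc_run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  hash <- attr(config, "config_hash")
  specs <- default_locus_specs()[config$loci]
  if (any(vapply(specs, is.null, logical(1))))
    stop("unknown locus in config$loci")
  noise <- do.call(noise_config, config$noise)
  effects <- do.call(effect_config, config$effects)

  ## --- simulate ---------------------------------------------------------
  pools <- lapply(specs, generate_allele_pool, seed = child_seed(seed, "pools"))
  geno_true <- simulate_population(pools, config$n_individuals,
                                   seed = child_seed(seed, "pop"))
  variants <- simulate_amplicon_reads(geno_true, pools, noise,
                                      seed = child_seed(seed, "reads"))

  ## --- genotype ---------------------------------------------------------
  params <- lapply(specs, function(sp)
    genotyper_params(sp$exon_length_nt,
                     max_alleles = if (sp$coamplified) 4L else 2L))
  calls <- call_genotypes(variants, params)
  concordance <- replicate_concordance(calls)

  ## called sequences -> labels (novel variants get fresh labels)
  alignments <- list(); geno_called <- list()
  for (lc in names(specs)) {
    pool <- pools[[lc]]
    seq2lab <- setNames(names(pool$sequences), unname(pool$sequences))
    sub <- calls[calls$locus == lc & calls$n_alleles > 0, ]
    seqs <- unique(unlist(split_alleles(sub$alleles)))
    novel <- setdiff(seqs, names(seq2lab))
    if (length(novel))
      seq2lab[novel] <- sprintf("%s*nov%02d", lc, seq_along(novel))
    lab_alleles <- vapply(split_alleles(sub$alleles), function(s)
      join_alleles(unname(seq2lab[s])), "")
    geno_called[[lc]] <- data.frame(sample_id = sub$sample_id, locus = lc,
                                    alleles = lab_alleles,
                                    n_alleles = sub$n_alleles,
                                    stringsAsFactors = FALSE)
    nt <- setNames(names(seq2lab), seq2lab)   # label -> sequence
    keep <- nt[nchar(nt) %% 3 == 0]
    aa <- translate_nt(keep)
    alignments[[lc]] <- aa[!has_stop(aa)]
  }
  genotypes <- do.call(rbind, c(geno_called, list(make.row.names = FALSE)))

  ## --- divergence -------------------------------------------------------
  div <- divergence_table(genotypes, alignments)
  div_summary <- do.call(rbind, lapply(split(div, div$locus), function(d)
    data.frame(locus = d$locus[1],
               mean_functional_divergence = mean(d$functional_divergence),
               sd_functional_divergence = sd(d$functional_divergence))))
  metric_r <- metric_correlation(div)

  ## --- supertypes -------------------------------------------------------
  st <- list()
  for (lc in names(specs)) {
    aln <- alignments[[lc]]
    used <- unique(unlist(split_alleles(genotypes$alleles[genotypes$locus == lc])))
    aln <- aln[names(aln) %in% used]
    sites <- if (identical(config$site_method, "external_list")) {
      screen_selected_sites(aln, "external_list", sites = specs[[lc]]$selected_sites)
    } else {
      screen_selected_sites(aln, "heuristic",
                            m = length(specs[[lc]]$selected_sites))
    }
    dm <- build_descriptor_matrix(aln, sites)
    k <- select_k(dm, k_range = 2:min(20, nrow(dm) - 1),
                  method = config$k_method[[lc]] %||% "silhouette",
                  seed = child_seed(seed, paste0("k", lc)))
    assign <- assign_supertypes(dm, k, seed = child_seed(seed, paste0("st", lc)))
    sf <- supertype_frequencies(assign, genotypes[genotypes$locus == lc, ])
    st[[lc]] <- list(k = as.integer(k), assignment = assign,
                     frequencies = sf$frequencies, presence = sf$presence,
                     common = filter_common_supertypes(sf$frequencies),
                     mean_per_individual =
                       mean(rowSums(sf$presence[, -1, drop = FALSE])))
  }

  ## --- breeding + association ------------------------------------------
  nests <- simulate_breeding(geno_true, div, effects,
                             n_nests = config$n_nests,
                             crossfoster_plan = config$crossfoster_plan,
                             supertype_presence =
                               st[[config$effect_locus]]$presence,
                             effect_locus = config$effect_locus,
                             seed = child_seed(seed, "nests"))
  assoc <- list()
  for (resp in config$responses) {
    for (mode in config$modes) {
      if (mode == "crossfostered" && resp == "clutch") next
      for (lc in names(specs)) {
        key <- paste(resp, mode, lc, sep = ".")
        avg <- try(run_divergence_analysis(
          nests, div, lc, resp, mode,
          include_quadratics = config$include_quadratics,
          include_interactions = config$include_interactions), silent = TRUE)
        stt <- try(run_supertype_analysis(nests, st[[lc]]$presence,
                                          supertypes = st[[lc]]$common,
                                          response = resp, mode = mode),
                   silent = TRUE)
        assoc[[key]] <- list(
          divergence = if (inherits(avg, "try-error"))
            attr(avg, "condition")$message else avg,
          supertypes = if (inherits(stt, "try-error"))
            attr(stt, "condition")$message else stt)
      }
    }
  }

  ## --- outputs ----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    for (lc in names(pools))
      write_fasta(pools[[lc]]$sequences, p(paste0("alleles_", lc, ".fasta")))
    write_table_hdr(variants, p("variants.tsv"), sep = "\t", seed, hash)
    write_table_hdr(genotypes, p("genotypes.csv"), ",", seed, hash)
    write_table_hdr(div, p("divergence.csv"), ",", seed, hash)
    write_table_hdr(nests, p("nests.csv"), ",", seed, hash)
    sts <- do.call(rbind, lapply(names(st), function(lc)
      cbind(locus = lc, as.data.frame(st[[lc]]$assignment))))
    write_table_hdr(sts, p("supertypes.csv"), ",", seed, hash)
    for (lc in names(st))
      write_table_hdr(st[[lc]]$presence, p(paste0("presence_", lc, ".csv")),
                      ",", seed, hash)
    for (key in names(assoc)) {
      a <- assoc[[key]]$divergence
      if (inherits(a, "avg_glmm")) {
        write_table_hdr(a$model_selection,
                        p(paste0("model_selection_", key, ".csv")), ",",
                        seed, hash)
        write_table_hdr(a$coefficients,
                        p(paste0("averaged_coefficients_", key, ".csv")), ",",
                        seed, hash)
      }
      s <- assoc[[key]]$supertypes
      if (is.data.frame(s) && nrow(s))
        write_table_hdr(as.data.frame(s),
                        p(paste0("supertype_tests_", key, ".csv")), ",",
                        seed, hash)
    }
    truth <- attr(nests, "truth")
    jsonlite::write_json(
      list(seed = seed, config_hash = hash,
           effects = truth$effects[!vapply(truth$effects, is.list, logical(1))],
           effect_locus = truth$effect_locus),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
  }

  structure(list(
    seed = seed, config_hash = hash,
    genotyping = list(n_amplicons = nrow(calls),
                      n_uncallable = sum(calls$n_alleles == 0),
                      replicate_concordance = concordance),
    divergence = list(summary = div_summary, metric_correlation = metric_r),
    supertypes = lapply(st, function(s)
      list(k = s$k, frequencies = s$frequencies,
           common = s$common, mean_per_individual = s$mean_per_individual)),
    association = assoc), class = "mhc_run_report")
}

#' @export
print.mhc_run_report <- function(x, ...) {
  cat("MHC pipeline run (seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  cat("Genotyping: ", x$genotyping$n_amplicons, " amplicons, ",
      x$genotyping$n_uncallable, " uncallable; replicate concordance ",
      round(x$genotyping$replicate_concordance, 3), "\n", sep = "")
  cat("Divergence (mean by locus):\n")
  print(x$divergence$summary, row.names = FALSE)
  cat("Metric correlation (p-distance vs functional):\n")
  print(round(x$divergence$metric_correlation, 3))
  for (lc in names(x$supertypes)) {
    s <- x$supertypes[[lc]]
    cat(lc, ": ", s$k, " supertypes, ", length(s$common),
        " above the 0.10 frequency floor; mean per individual ",
        round(s$mean_per_individual, 2), "\n", sep = "")
  }
  cat("Association analyses run: ", length(x$association), "\n", sep = "")
  invisible(x)
}
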