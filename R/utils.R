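## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a locally-seeded RNG, restoring the caller's stream after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a reproducible child seed from a base seed and a stage label,
## kept inside 32-bit integer range.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}

## The 61 sense codons of the standard genetic code.
sense_codons <- function() {
  bases <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

## Translate in-frame nucleotide sequences to amino acids (standard code).
## Plain lookup against Biostrings' GENETIC_CODE: called in per-amplicon
## loops, so the heavier XStringSet machinery is avoided.
translate_nt <- function(x) {
  stopifnot(all(nchar(x) %% 3 == 0))
  gc_tab <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    starts <- seq(1, nchar(s), 3)
    aa <- gc_tab[substring(s, starts, starts + 2)]
    if (anyNA(aa)) stop("sequence contains an untranslatable codon")
    paste(aa, collapse = "")
  }, "", USE.NAMES = !is.null(names(x)))
}

has_stop <- function(aa) grepl("\\*", aa, fixed = FALSE)

split_alleles <- function(x) strsplit(x, ";", fixed = TRUE)

join_alleles <- function(x) paste(sort(unique(x)), collapse = ";")

## Sequence of per-site characters as a matrix (alleles x sites).
aa_site_matrix <- function(aa) {
  L <- unique(nchar(aa))
  if (length(L) != 1L) {
    bad <- names(aa)[nchar(aa) != nchar(aa)[1]][1]
    stop("sequences are not aligned to equal length (see record '",
         bad %||% "?", "')")
  }
  m <- do.call(rbind, strsplit(aa, ""))
  rownames(m) <- names(aa)
  m
}
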