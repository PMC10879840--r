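## Study-level analysis drivers: the divergence multimodel-inference run and
## the per-supertype presence/absence tests with BH correction and Tukey-style
## EMM contrasts, on the full or the fully-cross-fostered dataset.

## Merge per-parent divergence onto nest records and standardize predictors.
build_assoc_data <- function(nests, divergence, locus,
                             mode = c("full", "crossfostered"),
                             random_ids = c("social", "genetic")) {
  mode <- match.arg(mode)
  random_ids <- match.arg(random_ids)
  dv <- divergence[divergence$locus == locus, ]
  div_of <- setNames(dv$functional_divergence, dv$sample_id)
  d <- nests
  if (mode == "crossfostered") {
    d <- d[d$crossfoster == "full", ]
    d$div_genetic_father <- unname(div_of[d$genetic_father])
    d$div_genetic_mother <- unname(div_of[d$genetic_mother])
    d$div_social_father <- unname(div_of[d$social_father])
    d$div_social_mother <- unname(div_of[d$social_mother])
    div_cols <- c("div_genetic_father", "div_genetic_mother",
                  "div_social_father", "div_social_mother")
  } else {
    d$div_father <- unname(div_of[d$genetic_father])
    d$div_mother <- unname(div_of[d$genetic_mother])
    div_cols <- c("div_father", "div_mother")
  }
  d <- d[stats::complete.cases(d[, div_cols]), ]
  aliased <- FALSE
  if (mode == "crossfostered" &&
      identical(d$genetic_father, d$social_father) &&
      identical(d$genetic_mother, d$social_mother)) {
    message("genetic and social parents are identical: ",
            "dropping social-parent terms")
    div_cols <- c("div_genetic_father", "div_genetic_mother")
    aliased <- TRUE
  }
  d$mother_id <- if (random_ids == "social") d$social_mother else d$genetic_mother
  d$father_id <- if (random_ids == "social") d$social_father else d$genetic_father
  d$year <- factor(d$year)
  std <- standardize_predictors(
    d, c(div_cols, "mother_age", "father_age", "laying_date_julian"))
  list(data = std$data, scaling = std$scaling, div_cols = div_cols,
       aliased = aliased, mode = mode)
}

response_lhs <- function(response) {
  switch(response,
         fledging = "cbind(fledged, clutch - fledged)",
         clutch = "clutch",
         stop("unknown response '", response, "'"))
}

covariate_rhs <- function() {
  "mother_age + father_age + laying_date_julian + I(laying_date_julian^2)"
}

random_rhs <- function() "(1 | mother_id) + (1 | father_id) + (1 | year)"

#' Divergence multimodel-inference analysis
#'
#' Builds the full model for one locus and response -- parental functional
#' divergence (linear, optional quadratic, optional mother x father
#' interaction), the always-included covariates (parental ages, laying date
#' and its quadratic) and crossed random intercepts for mother, father and
#' year -- enumerates all marginality-respecting sub-models, fits each,
#' retains the delta-AICc <= 2 set and fully averages it. In `full` mode the
#' MHC terms are those of the genetic parents; `crossfostered` mode restricts
#' to fully cross-fostered nests and includes the divergence of both genetic
#' and social parents in the same models.
#'
#' @param nests Nest-record data frame (see [simulate_breeding()] for the
#'   schema).
#' @param divergence A [divergence_table()] result.
#' @param locus Locus label selecting the divergence values.
#' @param response `"fledging"` (binomial, clutch as trials) or `"clutch"`
#'   (Poisson).
#' @param mode `"full"` or `"crossfostered"`.
#' @param include_quadratics,include_interactions Include quadratic terms /
#'   the within-parent-set mother x father interaction in the optional set.
#' @param random_ids Whether the mother/father random intercepts use the
#'   social (rearing, default) or genetic parent identities.
#' @param nAGQ Passed to [fit_glmm()].
#' @param delta_cutoff Retention cutoff on delta-AICc.
#' @param min_records Refuse to fit below this many usable records.
#' @return An [model_average()] object (`avg_glmm`) with the scaling metadata
#'   and analysis data attached as attributes.
#' @export
run_divergence_analysis <- function(nests, divergence, locus,
                                    response = c("fledging", "clutch"),
                                    mode = c("full", "crossfostered"),
                                    include_quadratics = TRUE,
                                    include_interactions = TRUE,
                                    random_ids = c("social", "genetic"),
                                    nAGQ = 1, delta_cutoff = 2,
                                    min_records = 30) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  bd <- build_assoc_data(nests, divergence, locus, mode, random_ids)
  if (nrow(bd$data) < min_records)
    stop("only ", nrow(bd$data), " usable records (< ", min_records,
         "): refusing an underpowered analysis")
  parents <- if (bd$mode == "crossfostered" && !bd$aliased) {
    list(genetic = c("div_genetic_father", "div_genetic_mother"),
         social = c("div_social_father", "div_social_mother"))
  } else if (bd$mode == "crossfostered") {
    list(genetic = c("div_genetic_father", "div_genetic_mother"))
  } else {
    list(genetic = c("div_father", "div_mother"))
  }
  td <- divergence_terms(parents, include_quadratics, include_interactions)
  subsets <- enumerate_submodels(td$optional, td$deps)
  family <- if (response == "fledging") "binomial" else "poisson"
  lhs <- response_lhs(response)
  fits <- lapply(subsets, function(terms) {
    rhs <- paste(c(terms, covariate_rhs(), random_rhs()), collapse = " + ")
    fit_glmm(as.formula(paste(lhs, "~", rhs)), bd$data, family, nAGQ = nAGQ)
  })
  names(fits) <- vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = "+") else "null", "")
  avg <- model_average(fits, subsets, delta_cutoff)
  attr(avg, "scaling") <- bd$scaling
  attr(avg, "data") <- bd$data
  attr(avg, "locus") <- locus
  attr(avg, "response") <- response
  attr(avg, "mode") <- mode
  avg
}

#' Per-supertype presence/absence tests
#'
#' One GLMM per supertype: presence (0/1) in the father and the mother plus
#' their interaction (in `crossfostered` mode, the genetic and the social
#' parent quartet with both within-set interactions), the standard covariates
#' and random intercepts. Wald p-values of all focal terms are
#' Benjamini-Hochberg adjusted within the (locus x response x dataset) family;
#' a significant interaction triggers Tukey-style EMM contrasts.
#'
#' @param nests Nest-record data frame.
#' @param presence Per-individual presence data frame (`sample_id` + one 0/1
#'   column per supertype), from [supertype_frequencies()].
#' @param supertypes Supertype columns to test (pre-filter with
#'   [filter_common_supertypes()]); default all presence columns.
#' @inheritParams run_divergence_analysis
#' @param alpha Significance level applied to adjusted p-values.
#' @return Object of class `supertype_tests`: data frame with one row per
#'   supertype x focal term (`beta`, `se`, `z`, `p`, `p_adj`, `significant`),
#'   EMM contrast results for significant interactions in
#'   `attr(x, "contrasts")`.
#' @export
run_supertype_analysis <- function(nests, presence, supertypes = NULL,
                                   response = c("fledging", "clutch"),
                                   mode = c("full", "crossfostered"),
                                   random_ids = c("social", "genetic"),
                                   nAGQ = 1, alpha = 0.05) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  random_ids <- match.arg(random_ids)
  sts <- supertypes %||% setdiff(names(presence), "sample_id")
  if (length(sts) == 0) {
    message("no supertypes to test")
    return(structure(data.frame(), class = c("supertype_tests", "data.frame")))
  }
  pres <- presence
  rownames(pres) <- pres$sample_id
  d0 <- nests
  if (mode == "crossfostered") d0 <- d0[d0$crossfoster == "full", ]
  d0$mother_id <- if (random_ids == "social") d0$social_mother else d0$genetic_mother
  d0$father_id <- if (random_ids == "social") d0$social_father else d0$genetic_father
  d0$year <- factor(d0$year)
  std <- standardize_predictors(d0, c("mother_age", "father_age",
                                      "laying_date_julian"))
  d0 <- std$data
  family <- if (response == "fledging") "binomial" else "poisson"
  lhs <- response_lhs(response)
  rows <- list(); contrasts <- list(); fits <- list()
  for (st in sts) {
    d <- d0
    if (mode == "crossfostered") {
      d$st_gf <- factor(pres[d$genetic_father, st], levels = 0:1)
      d$st_gm <- factor(pres[d$genetic_mother, st], levels = 0:1)
      d$st_sf <- factor(pres[d$social_father, st], levels = 0:1)
      d$st_sm <- factor(pres[d$social_mother, st], levels = 0:1)
      focal <- c("st_gf1", "st_gm1", "st_gf1:st_gm1",
                 "st_sf1", "st_sm1", "st_sf1:st_sm1")
      rhs <- paste("st_gf * st_gm + st_sf * st_sm +", covariate_rhs(), "+",
                   random_rhs())
    } else {
      d$st_father <- factor(pres[d$genetic_father, st], levels = 0:1)
      d$st_mother <- factor(pres[d$genetic_mother, st], levels = 0:1)
      focal <- c("st_father1", "st_mother1", "st_father1:st_mother1")
      rhs <- paste("st_father * st_mother +", covariate_rhs(), "+",
                   random_rhs())
    }
    d <- d[stats::complete.cases(d[, grep("^st_", names(d), value = TRUE)]), ]
    fit <- try(fit_glmm(as.formula(paste(lhs, "~", rhs)), d, family,
                        nAGQ = nAGQ), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) {
      message("supertype ", st, ": model did not converge, skipped")
      next
    }
    fits[[st]] <- fit
    present <- intersect(focal, names(fit$beta))
    z <- fit$beta[present] / fit$se[present]
    rows[[st]] <- data.frame(
      supertype = st, term = present, beta = unname(fit$beta[present]),
      se = unname(fit$se[present]), z = unname(z),
      p = unname(2 * pnorm(-abs(z))), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(structure(data.frame(), class = c("supertype_tests", "data.frame")))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  ## Tukey EMM contrasts for significant interactions
  for (i in which(out$significant & grepl(":", out$term))) {
    st <- out$supertype[i]
    facs <- strsplit(gsub("1", "", out$term[i]), ":")[[1]]
    ct <- try(emm_contrasts(fits[[st]], facs), silent = TRUE)
    if (!inherits(ct, "try-error"))
      contrasts[[paste(st, out$term[i])]] <- ct
  }
  structure(out, contrasts = contrasts, fits = fits,
            class = c("supertype_tests", "data.frame"))
}

#' @export
print.supertype_tests <- function(x, digits = 3, ...) {
  cat("Per-supertype presence/absence tests (BH-adjusted)\n")
  df <- as.data.frame(x)
  if (nrow(df)) {
    df[, c("beta", "se", "z", "p", "p_adj")] <-
      round(df[, c("beta", "se", "z", "p", "p_adj")], digits)
    print(df, row.names = FALSE)
  }
  ct <- attr(x, "contrasts")
  if (length(ct)) cat("\nEMM contrasts computed for:",
                      paste(names(ct), collapse = ", "), "\n")
  invisible(x)
}

#' Estimated marginal means and Tukey-style pairwise contrasts
#'
#' EMMs on the link scale for all combinations of the interaction factors,
#' averaged over the covariates, with multiplicity-adjusted pairwise
#' contrasts (multivariate-t adjustment, the large-sample analogue of Tukey's
#' procedure appropriate for GLMMs). For logit models, odds ratios
#' `exp(contrast)` with delta-method SEs are appended.
#'
#' @param fit An [fit_glmm()] result whose model contains the factors.
#' @param factors Character vector of (factor) predictor names.
#' @return List with `emmeans` and `contrasts` data frames.
#' @export
emm_contrasts <- function(fit, factors) {
  spec <- as.formula(paste("~", paste(factors, collapse = " * ")))
  emm <- emmeans::emmeans(fit$model, spec, data = fit$data)
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "mvt")
  emm_df <- as.data.frame(emm)
  prs_df <- as.data.frame(prs)
  if (fit$family == "binomial") {
    prs_df$odds_ratio <- exp(prs_df$estimate)
    prs_df$or_se <- prs_df$odds_ratio * prs_df$SE
  }
  list(emmeans = emm_df, contrasts = prs_df)
}
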