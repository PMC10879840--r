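## Mixed-model fitting, AICc, marginality-constrained sub-model enumeration
## and full model averaging. `model_average()` returns the package's central
## fitted object, class "avg_glmm".

#' Gelman-standardize predictors
#'
#' Continuous predictors are centered and divided by twice their standard
#' deviation (so a 1-unit change spans 2 SD, making coefficients comparable
#' with those of untouched 0/1 indicators, which are left as-is).
#'
#' @param data A data frame.
#' @param cols Columns to rescale.
#' @param keep_binary Leave 0/1 indicator columns untouched (default).
#' @return List with `data` (transformed) and `scaling` (data frame `col`,
#'   `center`, `scale`, where `scale` is `2 * sd`; binary columns get
#'   center 0, scale 1).
#' @export
standardize_predictors <- function(data, cols, keep_binary = TRUE) {
  scaling <- data.frame(col = cols, center = NA_real_, scale = NA_real_)
  for (i in seq_along(cols)) {
    cl <- cols[i]
    x <- data[[cl]]
    if (is.null(x)) stop("column '", cl, "' not found")
    if (keep_binary && all(x %in% c(0, 1)) && length(unique(x)) == 2) {
      scaling$center[i] <- 0; scaling$scale[i] <- 1
      next
    }
    s <- sd(x)
    if (s == 0) stop("predictor '", cl, "' is constant")
    scaling$center[i] <- mean(x)
    scaling$scale[i] <- 2 * s
    data[[cl]] <- (x - mean(x)) / (2 * s)
  }
  list(data = data, scaling = scaling)
}

#' Back-transform a standardized value
#'
#' @param scaling The `scaling` element of [standardize_predictors()].
#' @param col Column name.
#' @param value Standardized value(s).
#' @return Value(s) on the original scale.
#' @export
unstandardize <- function(scaling, col, value) {
  r <- scaling[scaling$col == col, ]
  if (nrow(r) != 1) stop("no scaling recorded for '", col, "'")
  value * r$scale + r$center
}

#' Fit a (mixed) generalized linear model
#'
#' Random-intercept terms in the formula are fitted with [lme4::glmer()]
#' (Laplace approximation by default; `nAGQ = 0` selects the faster
#' penalized-least-squares approximation used by the simulation harnesses).
#' A formula without random terms falls back to [stats::glm()], which is also
#' the exact limit of the mixed fit when all variance components are zero.
#'
#' @param formula Model formula; for the binomial family use a
#'   `cbind(successes, failures)` response.
#' @param data Data frame.
#' @param family `"binomial"` (logit) or `"poisson"` (log).
#' @param nAGQ Integration setting passed to `glmer` (1 = Laplace).
#' @return Object of class `mhc_glmm`: list with `model`, `beta`, `se`,
#'   `vcov`, `logLik`, `n_obs`, `k_params`, `n_vc` (variance components),
#'   `converged`.
#' @export
fit_glmm <- function(formula, data, family = c("binomial", "poisson"),
                     nAGQ = 1) {
  family <- match.arg(family)
  fam <- if (family == "binomial") stats::binomial() else stats::poisson()
  has_re <- length(lme4::findbars(formula)) > 0
  if (has_re) {
    ## at nAGQ = 0 the post-fit gradient/Hessian check is skipped: it does
    ## not change estimates or vcov and the harnesses fit thousands of models
    ctrl <- if (nAGQ == 0)
      lme4::glmerControl(calc.derivs = FALSE) else lme4::glmerControl()
    m <- suppressMessages(suppressWarnings(
      lme4::glmer(formula, data = data, family = fam, nAGQ = nAGQ,
                  control = ctrl)))
    msgs <- unlist(m@optinfo$conv$lme4$messages)
    converged <- is.finite(as.numeric(logLik(m))) &&
      !any(grepl("failed to converge", msgs %||% character(0)))
    beta <- lme4::fixef(m)
    vc <- as.data.frame(lme4::VarCorr(m))
    n_vc <- nrow(vc)
  } else {
    m <- stats::glm(formula, data = data, family = fam)
    converged <- m$converged
    beta <- coef(m)
    n_vc <- 0L
  }
  V <- as.matrix(vcov(m))
  structure(list(model = m, beta = beta, se = sqrt(diag(V)), vcov = V,
                 logLik = as.numeric(logLik(m)), n_obs = nrow(data),
                 k_params = length(beta) + n_vc, n_vc = n_vc,
                 converged = converged, formula = formula, family = family,
                 data = data),
            class = "mhc_glmm")
}

#' @export
print.mhc_glmm <- function(x, ...) {
  cat("GLMM fit (", x$family, "), n = ", x$n_obs, ", k = ", x$k_params,
      ", logLik = ", round(x$logLik, 2),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, with `k` counting fixed effects
#' plus variance components.
#'
#' @param fit An [fit_glmm()] result, or anything with `logLik`, `k_params`,
#'   `n_obs` fields.
#' @param logL,k,n Alternatively, supply the pieces directly.
#' @return The AICc value.
#' @export
aicc <- function(fit = NULL, logL = fit$logLik, k = fit$k_params,
                 n = fit$n_obs) {
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate sub-models under marginality
#'
#' All subsets of the optional terms such that every term's prerequisites are
#' present (an interaction requires both main effects; a quadratic requires
#' its linear term). Covariates and random effects live outside this set and
#' are part of every model, including the null (empty subset).
#'
#' @param optional Character vector of optional term labels.
#' @param deps Named list: for each term, the character vector of terms it
#'   requires.
#' @return List of character vectors (the first is the null model).
#' @export
enumerate_submodels <- function(optional, deps = list()) {
  n <- length(optional)
  if (n == 0) return(list(character(0)))
  out <- list()
  for (mask in 0:(2^n - 1)) {
    on <- optional[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- all(vapply(on, function(t)
      all((deps[[t]] %||% character(0)) %in% on), logical(1)))
    if (ok) out[[length(out) + 1L]] <- on
  }
  out
}

## Marginality dependencies for divergence-model term sets.
divergence_terms <- function(parents, include_quadratics = TRUE,
                             include_interactions = TRUE) {
  ## parents: named list of pairs, e.g. list(genetic = c(f, m), ...)
  optional <- character(0)
  deps <- list()
  for (pair in parents) {
    lin <- pair
    optional <- c(optional, lin)
    if (include_quadratics) {
      qd <- paste0("I(", pair, "^2)")
      optional <- c(optional, qd)
      deps[[qd[1]]] <- pair[1]
      deps[[qd[2]]] <- pair[2]
    }
    if (include_interactions) {
      ia <- paste(pair, collapse = ":")
      optional <- c(optional, ia)
      deps[[ia]] <- pair
    }
  }
  list(optional = optional, deps = deps)
}

#' Full model averaging over an AICc-ranked candidate set
#'
#' Candidate fits are ranked by AICc; models within `delta_cutoff` of the
#' best are retained and given renormalized Akaike weights
#' `w_i = exp(-delta_i/2) / sum exp(-delta_j/2)`. Coefficients are *fully*
#' averaged: a term absent from a model contributes an estimate of 0 there.
#' The unconditional standard error follows the Burnham-Anderson form
#' `SE_unc = sum_i w_i * sqrt(SE_i^2 + (b_i - b_bar)^2)` and 95% confidence
#' intervals are `b_bar +/- 1.96 SE_unc`; a term is flagged significant when
#' its interval excludes zero. Non-converged fits are dropped from the
#' candidate set with a message.
#'
#' @param fits Named list of [fit_glmm()] objects (names are model ids).
#' @param optional_sets Optional list (parallel to `fits`) of the optional
#'   terms each model contains, for the selection table.
#' @param delta_cutoff Retention cutoff on delta-AICc (default 2).
#' @return Object of class `avg_glmm`; see [coef.avg_glmm()],
#'   [confint.avg_glmm()], [summary.avg_glmm()].
#' @export
model_average <- function(fits, optional_sets = NULL, delta_cutoff = 2) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("m", seq_along(fits))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv)) {
    message("dropping ", sum(!conv), " non-converged sub-model(s): ",
            paste(names(fits)[!conv], collapse = ", "))
    fits <- fits[conv]
    optional_sets <- optional_sets[conv]
  }
  stopifnot(length(fits) >= 1)
  ic <- vapply(fits, aicc, numeric(1))
  delta <- ic - min(ic)
  retained <- delta <= delta_cutoff
  w <- exp(-delta[retained] / 2)
  w <- w / sum(w)
  msel <- data.frame(
    model = names(fits),
    terms = vapply(seq_along(fits), function(i)
      paste(optional_sets[[i]] %||% "?", collapse = " + "), ""),
    k = vapply(fits, function(f) f$k_params, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = ic, delta = delta,
    weight = ifelse(retained, NA_real_, NA_real_),
    retained = retained, stringsAsFactors = FALSE)
  msel$weight[retained] <- w
  msel <- msel[order(msel$AICc), ]
  rownames(msel) <- NULL
  rfits <- fits[retained]
  terms_all <- unique(unlist(lapply(rfits, function(f) names(f$beta))))
  est <- se_unc <- setNames(numeric(length(terms_all)), terms_all)
  imp <- setNames(numeric(length(terms_all)), terms_all)
  for (tm in terms_all) {
    b <- vapply(rfits, function(f) unname(f$beta[tm]) %||% NA_real_, numeric(1))
    s <- vapply(rfits, function(f) unname(f$se[tm]) %||% NA_real_, numeric(1))
    present <- !is.na(b)
    b[!present] <- 0; s[!present] <- 0      # full averaging
    est[tm] <- sum(w * b)
    se_unc[tm] <- sum(w * sqrt(s^2 + (b - est[tm])^2))
    imp[tm] <- sum(w[present])
  }
  coefs <- data.frame(term = terms_all, estimate = est, se_unc = se_unc,
                      ci_lo = est - 1.96 * se_unc, ci_hi = est + 1.96 * se_unc,
                      weight_sum = imp, stringsAsFactors = FALSE)
  coefs$significant <- coefs$ci_lo > 0 | coefs$ci_hi < 0
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, model_selection = msel,
                 n_candidates = length(fits), n_retained = sum(retained),
                 delta_cutoff = delta_cutoff, fits = rfits,
                 weights = setNames(w, names(rfits))),
            class = "avg_glmm")
}

#' @export
print.avg_glmm <- function(x, digits = 3, ...) {
  cat("Model-averaged GLMM (full averaging over delta-AICc <= ",
      x$delta_cutoff, " set)\n", sep = "")
  cat("Candidates: ", x$n_candidates, ", retained: ", x$n_retained, "\n\n",
      sep = "")
  cf <- x$coefficients
  cf[, 2:6] <- round(cf[, 2:6], digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname model_average
#' @param object,x An `avg_glmm` object.
#' @param ... Unused.
coef.avg_glmm <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
#' @rdname model_average
#' @param parm Term names (default all).
#' @param level Confidence level (fixed at the 1.96 z-interval; values other
#'   than 0.95 rescale the interval accordingly).
confint.avg_glmm <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  if (!is.null(parm)) cf <- cf[cf$term %in% parm, ]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf$estimate - z * cf$se_unc, cf$estimate + z * cf$se_unc)
  dimnames(out) <- list(cf$term,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  out
}

#' @export
#' @rdname model_average
summary.avg_glmm <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 model_selection = object$model_selection,
                 n_candidates = object$n_candidates,
                 n_retained = object$n_retained), class = "summary.avg_glmm")
}

#' @export
print.summary.avg_glmm <- function(x, digits = 3, ...) {
  cat("Candidate models (", x$n_candidates, "; retained ", x$n_retained,
      "):\n", sep = "")
  ms <- x$model_selection
  ms[, c("logLik", "AICc", "delta", "weight")] <-
    round(ms[, c("logLik", "AICc", "delta", "weight")], digits)
  print(ms, row.names = FALSE)
  cat("\nFull-averaged coefficients:\n")
  cf <- x$coefficients
  cf[, 2:6] <- round(cf[, 2:6], digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname model_average
plot.avg_glmm <- function(x, ...) {
  cf <- x$coefficients
  cf <- cf[cf$term != "(Intercept)", ]
  n <- nrow(cf)
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  plot(cf$estimate, seq_len(n), xlim = range(c(cf$ci_lo, cf$ci_hi, 0)),
       yaxt = "n", ylab = "", xlab = "standardized estimate (95% CI)",
       pch = 16, ...)
  graphics::segments(cf$ci_lo, seq_len(n), cf$ci_hi, seq_len(n))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(n), labels = cf$term, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Variance inflation factors from a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j` on
#' the remaining predictors. Perfect collinearity (a duplicated or aliased
#' predictor) is an error.
#'
#' @param design Numeric matrix or data frame of predictors (no response).
#' @return Named numeric vector of VIFs, with `max_vif` as an attribute.
#' @export
vif_check <- function(design) {
  X <- as.matrix(design)
  stopifnot(ncol(X) >= 2)
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  names(vifs) <- colnames(X)
  if (any(!is.finite(vifs)) || any(vifs > 1e8))
    stop("perfect collinearity in design (VIF effectively infinite for: ",
         paste(names(vifs)[!is.finite(vifs) | vifs > 1e8], collapse = ", "), ")")
  attr(vifs, "max_vif") <- max(vifs)
  vifs
}
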