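#' Random-intercept linear mixed model with Wald chi-square tests
#'
#' Fits `y ~ X + (1 | group)` by maximum likelihood (the deviance is
#' profiled over the between/within variance ratio) and reports, per fixed
#' coefficient, the Wald chi-square `(estimate / se)^2` on 1 df, or
#' optionally a likelihood-ratio test. REML is available but ML is the
#' default.
#'
#' @param y Numeric response.
#' @param X Fixed-effect design matrix (no intercept column; one is added).
#' @param groups Grouping factor for the random intercept.
#' @param method `"wald"` (default) or `"lrt"` per-coefficient tests.
#' @param reml Use REML instead of ML (default FALSE).
#' @return A `mixed_model_fit`: list with `fixed_effects` (data frame:
#'   term, estimate, se, chi2, p), `var_between`, `var_resid`, `logLik`,
#'   `n_groups`.
#' @export
lmm_random_intercept <- function(y, X, groups, method = c("wald", "lrt"),
                                 reml = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(seq_len(ncol(X) + 1), piv) - 1
    stop("singular fixed-effect design; collinear columns: ",
         paste(colnames(X)[bad[bad > 0]], collapse = ", "))
  }
  dat <- data.frame(.y = y, X, .g = groups, check.names = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                                collapse = " + "),
                                  "+ (1 | .g)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  chi2 <- (beta / se)^2
  pv <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  if (method == "lrt") {
    terms <- names(beta)[-1]
    for (tm in terms) {
      red <- stats::update(fit, stats::as.formula(paste(". ~ . -", tm)))
      lr <- 2 * (as.numeric(stats::logLik(fit)) -
                 as.numeric(stats::logLik(red)))
      chi2[tm] <- max(lr, 0)
      pv[tm] <- stats::pchisq(chi2[tm], 1, lower.tail = FALSE)
    }
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_between <- vc$vcov[vc$grp == ".g"][1]
  var_resid <- vc$vcov[vc$grp == "Residual"][1]
  structure(list(fixed_effects = data.frame(term = names(beta),
                                            estimate = as.numeric(beta),
                                            se = se, chi2 = chi2, p = pv,
                                            row.names = NULL),
                 var_between = var_between, var_resid = var_resid,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_groups = nlevels(groups), method = method, reml = reml),
            class = "mixed_model_fit")
}

#' Genotype-phenotype association via genetic principal components
#'
#' Regresses an individual phenotype on the first two genetic principal
#' components with population as a random intercept, reporting a
#' chi-square and p-value per component. Named populations (e.g. a known
#' genetic outlier) can be excluded before fitting.
#'
#' @param phenotype Numeric phenotype, one value per individual.
#' @param genetic_pcs Matrix of PC scores (first two columns used).
#' @param population_labels Population of each individual.
#' @param exclude Populations to drop before fitting.
#' @param method Passed to [lmm_random_intercept()].
#' @return List with `fit` (the mixed model), `results` (data frame:
#'   term, chi2, p) and `n_used`.
#' @export
run_association <- function(phenotype, genetic_pcs, population_labels,
                            exclude = NULL, method = "wald") {
  pcs <- as.matrix(genetic_pcs)[, 1:2, drop = FALSE]
  colnames(pcs) <- c("PC1", "PC2")
  stopifnot(length(phenotype) == nrow(pcs),
            length(population_labels) == nrow(pcs))
  keep <- !(population_labels %in% exclude)
  if (length(unique(population_labels[keep])) < 3)
    stop("fewer than 3 populations remain after exclusion")
  fit <- lmm_random_intercept(phenotype[keep], pcs[keep, , drop = FALSE],
                              population_labels[keep], method = method)
  fe <- fit$fixed_effects
  res <- fe[fe$term %in% c("PC1", "PC2"), c("term", "chi2", "p")]
  list(fit = fit, results = res, n_used = sum(keep))
}
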