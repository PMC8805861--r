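#' Residualize values on covariates
#'
#' Removes covariate effects (age, sex, motion summaries, ...) by ordinary
#' least squares: returns the residuals of a fit of `values` on the
#' covariates plus an intercept. Residuals have mean zero; covariates
#' orthogonal to the values leave only the demeaning.
#'
#' @param values Numeric vector (one value per subject) or matrix
#'   (subjects x variables; each column is residualized).
#' @param covariates Numeric matrix or data.frame (subjects x covariates),
#'   or `NULL` for demeaning only.
#' @return Residualized values of the same shape.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  n <- nrow(v)
  if (is.null(covariates)) {
    res <- sweep(v, 2L, colMeans(v))
  } else {
    X <- as.matrix(as.data.frame(covariates))
    storage.mode(X) <- "double"
    if (nrow(X) != n) stop("covariates must have one row per subject")
    X <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop(sprintf("covariate matrix is rank deficient; collinear column(s): %s",
                   paste(dropped, collapse = ", ")))
    }
    res <- qr.resid(qrX, v)
  }
  if (is.vector(values)) drop(res) else res
}

check_groups <- function(groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  groups
}

# permutation engine: values (n_subj x k), group indicator; returns observed
# differences (group2 - group1), two-tailed p per column, and null percentiles
perm_engine <- function(vals, groups, n_perm, seed) {
  groups <- check_groups(groups)
  g2 <- as.integer(groups) == 2L
  n <- nrow(vals)
  contrast <- ifelse(g2, 1 / sum(g2), -1 / sum(!g2))
  obs <- drop(crossprod(contrast, vals))
  null <- with_seed(seed, {
    P <- vapply(seq_len(n_perm), function(b) contrast[sample.int(n)], numeric(n))
    crossprod(P, vals)   # n_perm x k null differences
  })
  p <- (colSums(abs(null) >= matrix(abs(obs), n_perm, ncol(vals), byrow = TRUE)) + 1) /
    (n_perm + 1)
  ci <- apply(null, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  list(observed = obs, p = p, ci_lower = ci[1L, ], ci_upper = ci[2L, ],
       null = null)
}

#' Permutation test of group differences in global measure curves
#'
#' At each density, compares the covariate-adjusted group means of a global
#' network measure between two groups with a label-shuffling permutation
#' test. Values are residualized on the covariates once, then group labels
#' are permuted (simplified Freedman-Lane scheme). The two-tailed p-value is
#' `(#{|null| >= |observed|} + 1) / (n_perm + 1)`, and the 2.5/97.5
#' percentiles of the null form the 95% envelope.
#'
#' @param values Numeric matrix, subjects x densities (or a vector for a
#'   single density/AUC value).
#' @param groups Two-level factor (difference reported as level2 - level1).
#' @param covariates Optional subjects x covariates matrix or data.frame.
#' @param n_perm Number of permutations (10000 for confirmatory analyses; a
#'   warning is issued below 100).
#' @param seed Integer seed; the caller's RNG state is restored.
#' @param densities Optional density labels for the columns.
#' @return An object of class `group_comparison`: data.frame with columns
#'   `density`, `observed`, `p`, `ci_lower`, `ci_upper`, plus attributes
#'   `n_perm` and `seed`.
#' @export
permutation_test_global <- function(values, groups, covariates = NULL,
                                    n_perm = 10000L, seed = 1L,
                                    densities = NULL) {
  if (n_perm < 100L) warning("n_perm < 100: p-values will be very coarse")
  vals <- as.matrix(values)
  vals <- residualize(vals, covariates)
  res <- perm_engine(vals, groups, n_perm, seed)
  if (is.null(densities)) {
    densities <- suppressWarnings(as.numeric(colnames(vals)))
    if (!length(densities) || anyNA(densities)) densities <- seq_len(ncol(vals))
  }
  out <- data.frame(density = densities, observed = res$observed, p = res$p,
                    ci_lower = res$ci_lower, ci_upper = res$ci_upper)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("group_comparison", class(out))
  out
}

#' Permutation test of group differences in nodal AUC values
#'
#' One covariate-adjusted permutation test per region on the AUC of a nodal
#' measure over the density range, followed by Benjamini-Hochberg FDR
#' correction across regions.
#'
#' @param auc_values Numeric matrix, subjects x regions.
#' @param groups Two-level factor.
#' @param covariates Optional subjects x covariates matrix or data.frame.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param q FDR level for the rejection decisions.
#' @return An object of class `group_comparison`: data.frame with columns
#'   `region`, `observed`, `p`, `ci_lower`, `ci_upper`, `p_fdr`,
#'   `significant`.
#' @export
permutation_test_nodal_auc <- function(auc_values, groups, covariates = NULL,
                                       n_perm = 10000L, seed = 1L, q = 0.05) {
  if (n_perm < 100L) warning("n_perm < 100: p-values will be very coarse")
  vals <- as.matrix(auc_values)
  regions <- colnames(vals)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(vals)))
  vals <- residualize(vals, covariates)
  res <- perm_engine(vals, groups, n_perm, seed)
  fdr <- fdr_bh(res$p, q = q)
  out <- data.frame(region = regions, observed = res$observed, p = res$p,
                    ci_lower = res$ci_lower, ci_upper = res$ci_upper,
                    p_fdr = fdr$p_adjusted, significant = fdr$rejected,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "q") <- q
  class(out) <- c("group_comparison", class(out))
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up procedure over a vector of p-values (one per region),
#' controlling the false discovery rate at level `q`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `rejected` (logical mask) and `p_adjusted` (BH-adjusted
#'   p-values).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (!length(pvalues))
    return(list(rejected = logical(0), p_adjusted = numeric(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Brain-behavior correlation with covariate adjustment
#'
#' Pearson correlation between a network measure and a clinical score, both
#' residualized on the covariates, with a permutation p-value obtained by
#' shuffling the residualized scores. Intended for regions that survive the
#' group comparison.
#'
#' @param values Numeric vector of per-subject network values.
#' @param scores Numeric vector of per-subject clinical scores.
#' @param covariates Optional covariate table.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n`.
#' @export
clinical_correlation <- function(values, scores, covariates = NULL,
                                 n_perm = 10000L, seed = 1L) {
  ok <- is.finite(values) & is.finite(scores)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(as.data.frame(covariates))
  if (sum(ok) < 4L) stop("need at least 4 complete pairs")
  v <- values[ok]; s <- scores[ok]
  if (stats::sd(s) == 0) stop("clinical score is constant")
  if (stats::sd(v) == 0) stop("network value is constant")
  cov_ok <- if (is.null(covariates)) NULL else as.data.frame(covariates)[ok, , drop = FALSE]
  v <- residualize(v, cov_ok)
  s <- residualize(s, cov_ok)
  r_obs <- stats::cor(v, s)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(b) stats::cor(v, s[sample.int(length(s))]),
                                 numeric(1)))
  p <- (sum(abs(null) >= abs(r_obs)) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n = sum(ok))
}
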