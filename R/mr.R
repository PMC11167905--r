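# Per-gene causal estimation: Wald ratio, IVW with multiplicative random
# effects, Cochran's Q, MR-Egger intercept, and FDR control.

#' Wald ratio estimate from a single harmonized pair
#'
#' The single-instrument causal estimate: outcome effect divided by
#' exposure effect, with the first-order delta-method standard error
#' `se_outcome / |beta_exposure|` (exposure uncertainty ignored). A
#' second-order option additionally propagates the exposure variance.
#'
#' @param pair One-row harmonized pair (see [harmonize_pair()]).
#' @param second_order Use the second-order delta-method se.
#' @return `list(beta, se, pvalue)`; log-odds of outcome per SD expression.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  if (pair$beta_exposure == 0) stop("Wald ratio undefined for zero exposure beta")
  beta <- pair$beta_outcome / pair$beta_exposure
  se <- pair$se_outcome / abs(pair$beta_exposure)
  if (second_order) {
    se <- sqrt(se^2 + (pair$beta_outcome^2 * pair$se_exposure^2) /
                 pair$beta_exposure^4)
  }
  list(beta = beta, se = se, pvalue = 2 * stats::pnorm(-abs(beta / se)))
}

#' Inverse-variance-weighted estimate with random effects
#'
#' Meta-analyses per-SNP Wald ratios with weights `1 / se_j^2` (ratio
#' standard errors from the delta method). Heterogeneity is measured by
#' Cochran's Q on `n - 1` degrees of freedom. The default random-effects
#' flavor is multiplicative over-dispersion: the fixed-effect standard
#' error is inflated by `sqrt(max(1, Q / df))`, so it can never fall below
#' the fixed-effect value. A DerSimonian-Laird additive flavor is
#' available.
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @param re_flavor `"multiplicative"` (default) or `"additive"`.
#' @return `list(beta, se, pvalue, q, q_df, q_pvalue)`.
#' @export
ivw_random_effects <- function(pairs,
                               re_flavor = c("multiplicative", "additive")) {
  re_flavor <- match.arg(re_flavor)
  n <- nrow(pairs)
  if (n < 2) stop("IVW requires at least two pairs; use wald_ratio()")
  ratios <- pairs$beta_outcome / pairs$beta_exposure
  ses <- pairs$se_outcome / abs(pairs$beta_exposure)
  w <- 1 / ses^2
  beta <- sum(w * ratios) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  q <- sum(w * (ratios - beta)^2)
  q_df <- n - 1
  if (re_flavor == "multiplicative") {
    se <- se_fe * sqrt(max(1, q / q_df))
  } else {
    tau2 <- max(0, (q - q_df) / (sum(w) - sum(w^2) / sum(w)))
    w_re <- 1 / (ses^2 + tau2)
    beta <- sum(w_re * ratios) / sum(w_re)
    se <- sqrt(1 / sum(w_re))
  }
  list(beta = beta, se = se,
       pvalue = 2 * stats::pnorm(-abs(beta / se)),
       q = q, q_df = q_df,
       q_pvalue = stats::pchisq(q, q_df, lower.tail = FALSE))
}

#' MR-Egger intercept (directional pleiotropy diagnostic)
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept, after orienting every pair so the exposure effect is
#' positive. Weights are `1 / se_outcome^2`; the coefficient standard
#' errors use multiplicative over-dispersion floored at 1. A nonzero
#' intercept indicates directional pleiotropy of the instruments.
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @return `list(intercept, se, pvalue)`; p from a t distribution on
#'   `n - 2` degrees of freedom.
#' @export
egger_intercept <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) stop("MR-Egger requires at least three pairs")
  flip <- sign(pairs$beta_exposure)
  if (any(flip == 0)) stop("MR-Egger undefined for zero exposure beta")
  bx <- pairs$beta_exposure * flip
  by <- pairs$beta_outcome * flip
  w <- 1 / pairs$se_outcome^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coefs
  sigma2 <- sum(w * resid^2) / (n - 2)
  unscaled <- sqrt(diag(solve(XtWX)))
  se <- unscaled * max(1, sqrt(sigma2))
  tstat <- coefs[1] / se[1]
  list(intercept = unname(coefs[1]), se = unname(se[1]),
       pvalue = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

.mr_na_row <- function(gene, tissue_label) {
  data.frame(gene = gene, tissue = tissue_label, method = NA_character_,
             n_snps = 0L, beta = NA_real_, se = NA_real_, pvalue = NA_real_,
             or_value = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
             q_statistic = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
             egger_intercept = NA_real_, egger_intercept_se = NA_real_,
             egger_intercept_pvalue = NA_real_, fdr_pvalue = NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-gene MR estimate with diagnostics
#'
#' Harmonizes the gene's instruments against the outcome study and routes
#' to the appropriate estimator: one usable pair gives the Wald ratio, two
#' or more the IVW random-effects estimate; the Egger intercept is attached
#' when at least three pairs are available. Zero usable pairs mark the
#' gene not-testable (`method = NA`), which excludes it from the FDR
#' family. `fdr_pvalue` is filled later by [bh_adjust()] across all
#' testable genes of a tissue.
#'
#' @param instruments Instrument summary records for one gene.
#' @param outcome_records Outcome summary records.
#' @param gene Gene symbol for the result row.
#' @param tissue_label Tissue label for the result row.
#' @param palindrome_eaf_limit,re_flavor,second_order Passed through to the
#'   harmonization and estimation steps.
#' @return A one-row `data.frame` (MR result fields); odds ratio and its
#'   95 percent CI are `exp(beta)`, `exp(beta +/- 1.96 se)`.
#' @export
run_mr_gene <- function(instruments, outcome_records, gene = "gene",
                        tissue_label = "tissue",
                        palindrome_eaf_limit = 0.42,
                        re_flavor = "multiplicative",
                        second_order = FALSE) {
  pairs <- usable_pairs(harmonize_set(instruments, outcome_records,
                                      palindrome_eaf_limit))
  pairs <- pairs[pairs$beta_exposure != 0, , drop = FALSE]
  out <- .mr_na_row(gene, tissue_label)
  n <- nrow(pairs)
  if (n == 0) return(out)
  out$n_snps <- n
  if (n == 1) {
    est <- wald_ratio(pairs, second_order)
    out$method <- "wald_ratio"
  } else {
    est <- ivw_random_effects(pairs, re_flavor)
    out$method <- "ivw_random_effects"
    out$q_statistic <- est$q
    out$q_df <- as.integer(est$q_df)
    out$q_pvalue <- est$q_pvalue
  }
  out$beta <- est$beta
  out$se <- est$se
  out$pvalue <- est$pvalue
  out$or_value <- exp(est$beta)
  out$ci95_low <- exp(est$beta - 1.96 * est$se)
  out$ci95_high <- exp(est$beta + 1.96 * est$se)
  if (n >= 3) {
    eg <- egger_intercept(pairs)
    out$egger_intercept <- eg$intercept
    out$egger_intercept_se <- eg$se
    out$egger_intercept_pvalue <- eg$pvalue
  }
  out
}
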