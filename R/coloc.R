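# Bayesian colocalization via per-SNP approximate Bayes factors and
# enumeration of the five single-causal-variant hypotheses.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of causality — `p1` for trait 1 (eQTL) only,
#' `p2` for trait 2 (GWAS) only, `p12` for both — plus the prior variances
#' of the causal effect used in the approximate Bayes factor: `w_quant` on
#' the per-SD scale for quantitative traits, `w_cc` on the log-odds scale
#' for case-control traits.
#'
#' @param p1,p2,p12 Per-SNP causal priors (defaults `1e-4`, `1e-4`, `1e-5`).
#' @param w_quant,w_cc Prior effect variances (defaults `0.15^2`, `0.2^2`).
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w_quant = 0.15^2, w_cc = 0.2^2) {
  if (any(c(p1, p2, p12) <= 0)) stop("priors must be positive")
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  if (w_quant <= 0 || w_cc <= 0) stop("prior effect variances must be positive")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 w_quant = w_quant, w_cc = w_cc),
            class = "coloc_priors")
}

#' Log approximate Bayes factor for one association estimate
#'
#' Wakefield-style asymptotic Bayes factor against the null of no effect,
#' from the estimate, its standard error, and a normal prior on the true
#' effect with variance `w`: with `V = se^2`, `z = beta / se` and
#' `r = w / (V + w)`, `lABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @param w Prior effect variance (> 0).
#' @return Natural-log Bayes factor (vectorized over `beta`, `se`).
#' @export
log_abf <- function(beta, se, w) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(w <= 0)) stop("prior variance w must be positive")
  V <- se^2
  r <- w / (V + w)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

.trait_w <- function(df, priors) {
  tt <- if ("trait_type" %in% names(df)) df$trait_type else "quantitative"
  ifelse(tt == "case_control", priors$w_cc, priors$w_quant)
}

#' Colocalization of two traits in one region
#'
#' Matches the two studies' records by `snp_id` (inner join), computes
#' per-SNP log approximate Bayes factors for each trait, and enumerates the
#' five hypotheses: H0 neither trait has a causal variant; H1/H2 only
#' trait 1/2; H3 both, at distinct variants; H4 both, at one shared
#' variant. With `S1 = sum_i BF1_i`, `S2 = sum_j BF2_j` and
#' `S12 = sum_i BF1_i * BF2_i`, the un-normalized hypothesis weights are
#' `1`, `p1*S1`, `p2*S2`, `p1*p2*(S1*S2 - S12)` and `p12*S12`; posteriors
#' are the normalized weights. All sums run in log space with log-sum-exp,
#' and the H3 difference uses a guarded log-difference clamped at `-Inf`.
#'
#' @param eqtl,gwas Summary-record `data.frame`s for the two traits.
#' @param priors A [coloc_priors()].
#' @param gene Gene label for the result row.
#' @param pph4_threshold Decision threshold on PPH4 (inclusive;
#'   default 0.75).
#' @return One-row `data.frame`: gene, n_snps, pph0..pph4,
#'   passes_threshold. Attribute `"log_sums"` keeps `logS1`, `logS2`,
#'   `logS12` for diagnostics. `n_snps = 0` (empty join) yields all-`NA`
#'   posteriors: the gene is not colocalizable.
#' @export
coloc_abf <- function(eqtl, gwas, priors = coloc_priors(), gene = "gene",
                      pph4_threshold = 0.75) {
  keep_e <- !is.na(eqtl$beta) & !is.na(eqtl$se)
  keep_g <- !is.na(gwas$beta) & !is.na(gwas$se)
  if (any(!keep_e) || any(!keep_g)) {
    message("coloc: dropped ", sum(!keep_e) + sum(!keep_g),
            " records lacking beta/se")
  }
  eqtl <- eqtl[keep_e, , drop = FALSE]
  gwas <- gwas[keep_g, , drop = FALSE]
  common <- intersect(eqtl$snp_id, gwas$snp_id)
  m <- length(common)
  if (m == 0) {
    out <- data.frame(gene = gene, n_snps = 0L, pph0 = NA_real_,
                      pph1 = NA_real_, pph2 = NA_real_, pph3 = NA_real_,
                      pph4 = NA_real_, passes_threshold = FALSE,
                      stringsAsFactors = FALSE)
    return(out)
  }
  e <- eqtl[match(common, eqtl$snp_id), , drop = FALSE]
  g <- gwas[match(common, gwas$snp_id), , drop = FALSE]
  expected <- m * (priors$p1 + priors$p2 + priors$p12)
  if (expected >= 1) {
    warning("region of ", m, " SNPs implies prior mass >= 1 under these priors")
  }
  l1 <- log_abf(e$beta, e$se, .trait_w(e, priors))
  l2 <- log_abf(g$beta, g$se, .trait_w(g, priors))
  logS1 <- .logsumexp(l1)
  logS2 <- .logsumexp(l2)
  logS12 <- .logsumexp(l1 + l2)
  # H3 sums BF1_i * BF2_j over distinct pairs (algebraically
  # S1*S2 - S12). The explicit pairwise log-sum-exp is exact even when one
  # SNP dominates both traits and the difference form would cancel; the
  # guarded log-difference is kept for very large regions.
  logH3 <- if (m <= 3000) {
    pairs <- outer(l1, l2, "+")
    diag(pairs) <- -Inf
    .logsumexp(pairs)
  } else {
    .logdiffexp(logS1 + logS2, logS12)
  }
  lw <- c(h0 = 0,
          h1 = log(priors$p1) + logS1,
          h2 = log(priors$p2) + logS2,
          h3 = log(priors$p1) + log(priors$p2) + logH3,
          h4 = log(priors$p12) + logS12)
  pp <- exp(lw - .logsumexp(lw))
  pp <- pp / sum(pp)
  out <- data.frame(gene = gene, n_snps = m,
                    pph0 = pp[["h0"]], pph1 = pp[["h1"]], pph2 = pp[["h2"]],
                    pph3 = pp[["h3"]], pph4 = pp[["h4"]],
                    passes_threshold = pp[["h4"]] >= pph4_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "log_sums") <- c(logS1 = logS1, logS2 = logS2, logS12 = logS12)
  out
}

#' Extract and match the cis window of two studies around a TSS
#'
#' Applies the closed-window filter `[tss - window_bp, tss + window_bp]`
#' to both studies (the same convention as instrument selection), then
#' inner-joins them on `snp_id`.
#'
#' @param gwas_all,eqtl_all Summary-record `data.frame`s.
#' @param gene_tss 1-based TSS position.
#' @param window_bp Half-width in bp (default 100 kb).
#' @param chrom Optional chromosome filter.
#' @return `list(eqtl = ..., gwas = ...)` with matching `snp_id` order; the
#'   list may have zero rows (gene not colocalizable).
#' @export
coloc_window_extract <- function(gwas_all, eqtl_all, gene_tss,
                                 window_bp = 100000, chrom = NULL) {
  win <- function(df) {
    if (!is.null(chrom)) df <- df[df$chrom == as.character(chrom), , drop = FALSE]
    df[df$pos >= gene_tss - window_bp & df$pos <= gene_tss + window_bp, ,
       drop = FALSE]
  }
  g <- win(gwas_all)
  e <- win(eqtl_all)
  common <- intersect(e$snp_id, g$snp_id)
  list(eqtl = e[match(common, e$snp_id), , drop = FALSE],
       gwas = g[match(common, g$snp_id), , drop = FALSE])
}
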