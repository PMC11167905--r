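# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately not sharing code with the package.

# Greedy clumping, re-derived from the rule: repeatedly take the remaining
# record with the smallest p (ties by snp_id), discard everything with
# r^2 >= threshold against it.
oracle_clump <- function(snps, ld, r2_threshold) {
  remaining <- snps
  kept <- snps[0, , drop = FALSE]
  while (nrow(remaining) > 0) {
    remaining <- remaining[order(remaining$pvalue, remaining$snp_id), ,
                           drop = FALSE]
    best <- remaining[1, , drop = FALSE]
    kept <- rbind(kept, best)
    r2 <- ld[best$snp_id, remaining$snp_id]^2
    remaining <- remaining[r2 < r2_threshold, , drop = FALSE]
  }
  kept
}

# Benjamini-Hochberg step-up from the textbook definition:
# adj_(i) = min_{j >= i} m p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- pmin(1, rev(cummin(rev(m * sorted / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Textbook BH step-up rejection set at level alpha: reject the k smallest
# p-values where k = max{ i : p_(i) <= i alpha / m }.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  sorted <- sort(p)
  pass <- which(sorted <= seq_len(m) * alpha / m)
  if (length(pass) == 0) return(rep(FALSE, m))
  p <= sorted[max(pass)]
}

# Weighted regression by explicit normal equations (optionally through the
# origin), with coefficient standard errors under multiplicative
# over-dispersion floored at 1.
oracle_wls <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  A <- t(X) %*% (w * X)
  b <- solve(A, t(X) %*% (w * y))
  resid <- y - X %*% b
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(w * resid^2) / df else NA_real_
  se <- sqrt(diag(solve(A)))
  list(coef = drop(b), se_unscaled = se,
       se_md = se * max(1, sqrt(sigma2)), sigma2 = sigma2)
}

# Exhaustive five-hypothesis enumeration over every per-trait causal-SNP
# configuration, in log space: H1 picks one causal SNP for trait 1, H2 for
# trait 2, H3 an ordered pair of distinct SNPs, H4 one shared SNP.
oracle_coloc_enum <- function(l1, l2, p1, p2, p12) {
  m <- length(l1)
  lse <- function(x) {
    if (length(x) == 0) return(-Inf)
    mx <- max(x)
    if (!is.finite(mx)) return(mx)
    mx + log(sum(exp(x - mx)))
  }
  h3_terms <- c()
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) h3_terms <- c(h3_terms, l1[i] + l2[j])
    }
  }
  lw <- c(0,
          log(p1) + lse(l1),
          log(p2) + lse(l2),
          log(p1) + log(p2) + lse(h3_terms),
          log(p12) + lse(l1 + l2))
  pp <- exp(lw - lse(lw))
  pp / sum(pp)
}

# Exact hypergeometric upper tail by direct combinatorial enumeration.
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small builders -------------------------------------------------------

make_records <- function(snp_id, beta, se, pos = seq_along(snp_id),
                         chrom = "1", ea = "A", oa = "G",
                         eaf = 0.3, n = 10000,
                         trait_type = "quantitative") {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)), n = n,
             trait_type = trait_type, case_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

make_pairs <- function(bx, by, sx = 0.02, sy = 0.01) {
  k <- length(bx)
  data.frame(snp_id = sprintf("rs%d", seq_len(k)),
             effect_allele = "A", other_allele = "G",
             beta_exposure = bx, se_exposure = rep_len(sx, k),
             beta_outcome = by, se_outcome = rep_len(sy, k),
             eaf_exposure = 0.3, eaf_outcome = 0.3,
             pvalue_exposure = NA_real_, pvalue_outcome = NA_real_,
             action = "none", stringsAsFactors = FALSE)
}

# A random valid correlation matrix with unit diagonal.
random_ld <- function(m, snp_ids = sprintf("rs%d", seq_len(m))) {
  A <- matrix(rnorm(m * (m + 2)), m + 2, m)
  S <- crossprod(A)
  D <- 1 / sqrt(diag(S))
  r <- S * tcrossprod(D)
  diag(r) <- 1
  ld_matrix((r + t(r)) / 2, snp_ids)
}

h_truth <- function(scenario, gene = "G1", snp_exp = NA, snp_out = NA,
                    b_exp = 0, theta = 0, seed = 1) {
  simulation_truth(gene, scenario, snp_exp, snp_out, b_exp, theta, seed)
}
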