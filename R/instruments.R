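# Instrument selection: cis-window + significance filter, LD clumping,
# and the exclusion screen.

#' Select cis instruments for a gene
#'
#' Retains exposure SNPs lying in the closed window
#' `[tss - window_bp, tss + window_bp]` with an FDR below `fdr_threshold`.
#' When the study ships genome-wide FDR values, pass them in an `fdr`
#' column and set `fdr_column_present = TRUE`; otherwise Benjamini-Hochberg
#' adjustment is computed within the gene's cis window first.
#'
#' @param exposure Summary-record `data.frame` for the exposure study.
#' @param gene_tss 1-based TSS position of the gene.
#' @param window_bp Half-width of the cis window in bp (default 100 kb).
#' @param fdr_threshold FDR significance threshold (default 0.05).
#' @param fdr_column_present If `TRUE`, use the `fdr` column as-is.
#' @param chrom Optional chromosome; rows on other chromosomes are dropped
#'   before windowing.
#' @return Retained rows of `exposure`, with an `fdr` column.
#' @export
select_cis_instruments <- function(exposure, gene_tss, window_bp = 100000,
                                   fdr_threshold = 0.05,
                                   fdr_column_present = "fdr" %in% names(exposure),
                                   chrom = NULL) {
  df <- exposure
  if (!is.null(chrom)) df <- df[df$chrom == as.character(chrom), , drop = FALSE]
  in_window <- df$pos >= gene_tss - window_bp & df$pos <= gene_tss + window_bp
  df <- df[in_window, , drop = FALSE]
  if (nrow(df) == 0) return(df)
  if (!fdr_column_present) df$fdr <- bh_adjust(df$pvalue)
  df[df$fdr < fdr_threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Classical index-SNP pruning: repeatedly keep the remaining SNP with the
#' smallest p-value (ties broken by lexicographic `snp_id`) and discard all
#' SNPs with squared correlation at or above `r2_threshold` against it.
#' Output rows keep retention order. The result never contains a pair with
#' `r^2 >= r2_threshold`.
#'
#' @param snps Summary-record `data.frame` with `snp_id` and `pvalue`.
#' @param ld An [ld_matrix()] covering the SNPs.
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @param missing_ld `"error"` to fail on SNPs absent from `ld`, or
#'   `"drop"` to remove them with a warning.
#' @return Retained rows of `snps`.
#' @export
clump <- function(snps, ld, r2_threshold = 0.001,
                  missing_ld = c("error", "drop")) {
  missing_ld <- match.arg(missing_ld)
  if (nrow(snps) == 0) return(snps)
  present <- snps$snp_id %in% rownames(ld)
  if (!all(present)) {
    msg <- paste(snps$snp_id[!present], collapse = ", ")
    if (missing_ld == "error") stop("SNPs absent from LD matrix: ", msg)
    warning("dropping SNPs absent from LD matrix: ", msg)
    snps <- snps[present, , drop = FALSE]
    if (nrow(snps) == 0) return(snps)
  }
  r2 <- unclass(ld[snps$snp_id, snps$snp_id, drop = FALSE])^2
  ord <- order(snps$pvalue, snps$snp_id)
  alive <- rep(TRUE, nrow(snps))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[r2[i, ] >= r2_threshold] <- FALSE
  }
  snps[keep, , drop = FALSE]
}

#' Remove excluded SNPs from an instrument set
#'
#' Set difference against a static exclusion list (the stand-in for a
#' phenome-scan screen of variants directly associated with the outcome).
#' Removal reasons are recorded in the `"exclusion_log"` attribute.
#'
#' @param snps Summary-record `data.frame`.
#' @param exclusion_list `data.frame` with `snp_id` and `reason`, or `NULL`.
#' @return `snps` without the excluded rows.
#' @export
apply_exclusions <- function(snps, exclusion_list = NULL) {
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0) {
    attr(snps, "exclusion_log") <- exclusion_list
    return(snps)
  }
  hit <- snps$snp_id %in% exclusion_list$snp_id
  log <- exclusion_list[exclusion_list$snp_id %in% snps$snp_id, , drop = FALSE]
  out <- snps[!hit, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Build the final instrument set for one gene
#'
#' Runs the full selection stage: cis-window + FDR filter, LD clumping,
#' then the exclusion screen.
#'
#' @inheritParams select_cis_instruments
#' @inheritParams clump
#' @inheritParams apply_exclusions
#' @return Summary-record `data.frame` of retained instruments (possibly
#'   zero rows, in which case the gene is not testable).
#' @export
build_instruments <- function(exposure, gene_tss, ld,
                              window_bp = 100000, fdr_threshold = 0.05,
                              r2_threshold = 0.001, exclusion_list = NULL,
                              fdr_column_present = "fdr" %in% names(exposure),
                              chrom = NULL, missing_ld = "error") {
  sel <- select_cis_instruments(exposure, gene_tss, window_bp,
                                fdr_threshold, fdr_column_present, chrom)
  if (nrow(sel) == 0) return(sel)
  cl <- clump(sel, ld, r2_threshold, missing_ld)
  apply_exclusions(cl, exclusion_list)
}
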