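# Readers and writers for the pipeline's plain-text interchange formats.

.SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

#' Read per-SNP summary statistics
#'
#' Expects a tab-separated file with the fixed header `snp_id, chrom, pos,
#' effect_allele, other_allele, eaf, beta, se, pvalue, n` (extra columns
#' are kept). Basic sanity constraints (positive `se`, frequencies strictly
#' inside (0, 1), distinct alleles) are enforced.
#'
#' @param path TSV file path.
#' @param trait_type `"quantitative"` (eQTL) or `"case_control"` (GWAS);
#'   recorded on every row, it selects the prior effect variance used by
#'   colocalization.
#' @param case_fraction Optional case fraction for case-control studies.
#' @return A `data.frame` of summary records.
#' @export
read_summary_stats <- function(path, trait_type = c("quantitative",
                                                    "case_control"),
                               case_fraction = NA_real_) {
  trait_type <- match.arg(trait_type)
  df <- .read_tsv(path)
  missing <- setdiff(.SUMSTAT_COLS, names(df))
  if (length(missing) > 0) {
    stop("summary-statistics file ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  validate_summary_records(df)
  df$trait_type <- trait_type
  df$case_fraction <- if (trait_type == "case_control") case_fraction else NA_real_
  df
}

#' Validate summary records
#'
#' Checks the record-level invariants: positive standard errors, allele
#' frequencies strictly inside (0, 1), distinct alleles, and p-values
#' consistent with the two-sided normal tail of `beta / se`.
#'
#' @param df Summary-record `data.frame`.
#' @param p_rel_tol Relative tolerance for the p-value consistency check.
#' @return `df`, invisibly; stops on violation.
#' @export
validate_summary_records <- function(df, p_rel_tol = 1e-6) {
  if (any(df$se <= 0)) stop("summary records contain non-positive se")
  if (any(df$eaf <= 0 | df$eaf >= 1)) {
    stop("summary records contain eaf outside (0, 1)")
  }
  if (any(df$effect_allele == df$other_allele)) {
    stop("summary records with identical effect and other allele")
  }
  expected <- 2 * stats::pnorm(-abs(df$beta / df$se))
  denom <- pmax(expected, .Machine$double.xmin)
  bad <- expected > 1e-300 & abs(df$pvalue - expected) / denom > p_rel_tol
  if (any(bad)) {
    stop(sum(bad), " p-values inconsistent with the normal tail of beta/se")
  }
  invisible(df)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `symbol, chrom, tss` (and optionally
#' `strand`). TSS positions are 1-based.
#'
#' @param path TSV file path.
#' @return A `data.frame` with canonicalized symbols.
#' @export
read_gene_annotations <- function(path) {
  df <- .read_tsv(path)
  need <- c("symbol", "chrom", "tss")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("annotation file lacks columns: ", paste(missing, collapse = ", "))
  }
  df$symbol <- canonicalize_symbols(df$symbol, unique = FALSE)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$symbol)) stop("duplicate gene symbols in annotations")
  df
}

#' Read a SNP exclusion list
#'
#' Two-column TSV (`snp_id`, `reason`) listing variants to remove from the
#' instrument sets, e.g. variants directly associated with the outcome or
#' a phenotype directly linked to it.
#'
#' @param path TSV file path; `NULL` gives an empty list.
#' @return A `data.frame` with columns `snp_id`, `reason`.
#' @export
read_exclusion_list <- function(path) {
  if (is.null(path)) {
    return(data.frame(snp_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- .read_tsv(path)
  if (!all(c("snp_id", "reason") %in% names(df))) {
    stop("exclusion list needs columns snp_id, reason")
  }
  df[c("snp_id", "reason")]
}

#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member symbols.
#' Member symbols are canonicalized and de-duplicated; empty sets are
#' dropped with a warning.
#'
#' @param path GMT file path.
#' @return `read_gmt`: a named list of character vectors (the description
#'   is kept in attribute `"descriptions"`). `write_gmt`: the path,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0)))
  }
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop("malformed GMT line ", i, " in ", path,
           ": need at least name and description")
    }
    members <- canonicalize_symbols(fields[-(1:2)])
    if (length(members) == 0) {
      warning("GMT set '", fields[1], "' is empty; dropped")
      next
    }
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  structure(sets, descriptions = desc)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
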