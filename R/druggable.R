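#' Catalogs of druggable genes
#'
#' A `gene_catalog` is a named set of gene symbols from one source (for
#' example a drug-gene interaction database export, or a curated druggable
#' genome review), with an optional alias table mapping non-canonical
#' symbols to canonical ones. Symbols are whitespace-trimmed and
#' uppercase-normalized on construction.
#'
#' @param source_name Label for the source.
#' @param symbols Character vector of gene symbols.
#' @param alias_map Optional named character vector: `names()` are aliases,
#'   values the canonical symbols they resolve to.
#' @return A list of class `gene_catalog`.
#' @export
gene_catalog <- function(source_name, symbols, alias_map = NULL) {
  symbols <- canonicalize_symbols(symbols)
  if (length(symbols) == 0) stop("catalog '", source_name, "' is empty")
  if (!is.null(alias_map)) {
    alias <- canonicalize_symbols(names(alias_map), unique = FALSE)
    canonical <- canonicalize_symbols(unname(alias_map), unique = FALSE)
    alias_map <- stats::setNames(canonical, alias)
    symbols <- sort(unique(ifelse(symbols %in% names(alias_map),
                                  unname(alias_map[symbols]), symbols)))
  }
  structure(list(source_name = source_name, symbols = symbols,
                 alias_map = alias_map),
            class = "gene_catalog")
}

#' Normalize gene symbols
#'
#' Trims whitespace, uppercases, and drops empty strings; by default also
#' de-duplicates and sorts.
#'
#' @param x Character vector of symbols.
#' @param unique Collapse duplicates and sort (default `TRUE`).
#' @return Character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(x, unique = TRUE) {
  x <- toupper(trimws(as.character(x)))
  x <- x[!is.na(x) & nzchar(x)]
  if (unique) sort(unique(x)) else x
}

#' Consolidate druggable-gene catalogs into one canonical symbol set
#'
#' Takes the union of the catalogs after alias canonicalization, collapsing
#' duplicates. The merge is idempotent and invariant to catalog order.
#'
#' @param catalogs List of [gene_catalog()] objects (at least one).
#' @return Sorted character vector of unique canonical symbols.
#' @export
merge_druggable_lists <- function(catalogs) {
  if (inherits(catalogs, "gene_catalog")) catalogs <- list(catalogs)
  if (length(catalogs) < 1) stop("at least one catalog is required")
  syms <- sort(unique(unlist(lapply(catalogs, function(cat) {
    stopifnot(inherits(cat, "gene_catalog"))
    cat$symbols
  }))))
  if (length(syms) == 0) stop("merged druggable list is empty")
  syms
}

#' Intersect the druggable genome with genes measured in an eQTL study
#'
#' Returns the per-tissue candidate gene list that enters Mendelian
#' randomization: druggable genes for which the eQTL study actually carries
#' cis associations.
#'
#' @param druggable Canonical druggable symbols ([merge_druggable_lists()]).
#' @param eqtl_genes Symbols of genes present in the eQTL dataset.
#' @return Sorted character vector of candidate symbols (possibly empty,
#'   with a warning).
#' @export
intersect_with_eqtl_genes <- function(druggable, eqtl_genes) {
  out <- sort(intersect(canonicalize_symbols(druggable),
                        canonicalize_symbols(eqtl_genes)))
  if (length(out) == 0) {
    warning("no overlap between druggable genes and eQTL genes")
  }
  out
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @param source_name Catalog label; defaults to the file name.
#' @param alias_map Optional alias map (see [gene_catalog()]) or path to a
#'   two-column TSV (alias, canonical).
#' @return A [gene_catalog()].
#' @export
read_gene_list <- function(path, source_name = basename(path),
                           alias_map = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.character(alias_map) && length(alias_map) == 1 &&
      file.exists(alias_map)) {
    tab <- .read_tsv(alias_map)
    if (ncol(tab) < 2) stop("alias TSV needs two columns: alias, canonical")
    alias_map <- stats::setNames(tab[[2]], tab[[1]])
  }
  gene_catalog(source_name, lines, alias_map)
}
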