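# Two-tissue discovery pipeline: candidate druggable genes -> instruments
# -> harmonization -> MR -> FDR -> colocalization -> cross-tissue
# intersection -> enrichment, with a run manifest for auditability.

#' Default pipeline configuration
#'
#' All tunable thresholds and priors of the discovery run with their
#' defaults: a +/- 100 kb cis window, eQTL FDR 0.05, clumping at r^2 0.001,
#' MR FDR 0.05, PPH4 threshold 0.75 (inclusive) and colocalization priors
#' `p1 = p2 = 1e-4`, `p12 = 1e-5`.
#'
#' @return A nested named list (`paths`, `thresholds`, `priors`,
#'   `options`, `seed`).
#' @export
default_config <- function() {
  list(
    paths = list(exposure = list(), outcome = NULL, annotations = NULL,
                 druggable = list(), ld_dir = NULL, exclusions = NULL,
                 gene_sets = NULL),
    thresholds = list(window_bp = 100000, eqtl_fdr = 0.05,
                      clump_r2 = 0.001, mr_fdr = 0.05, pph4_min = 0.75),
    priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                  w_quant = 0.0225, w_cc = 0.04),
    options = list(palindrome_eaf_limit = 0.42,
                   re_flavor = "multiplicative",
                   fdr_family = "per_tissue",
                   coloc_all_genes = FALSE,
                   missing_ld = "error",
                   min_set_size = 3,
                   case_fraction = 0.17),
    seed = 1L
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Parsing is strict: unknown keys at any level are rejected, thresholds
#' must lie in their documented domains. Missing keys take their defaults.
#'
#' @param config Nested list, or path to a YAML file.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- default_config()
  check_keys <- function(x, ref, where) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown) > 0) {
      stop("unknown config key", if (length(unknown) > 1) "s", " in ",
           where, ": ", paste(unknown, collapse = ", "))
    }
  }
  check_keys(config, defaults, "config")
  for (section in c("thresholds", "priors", "options")) {
    if (!is.null(config[[section]])) {
      check_keys(config[[section]], defaults[[section]], section)
    }
  }
  if (!is.null(config$paths)) check_keys(config$paths, defaults$paths, "paths")
  cfg <- utils::modifyList(defaults, config)
  th <- cfg$thresholds
  if (th$window_bp <= 0) stop("window_bp must be positive")
  for (k in c("eqtl_fdr", "mr_fdr")) {
    if (th[[k]] <= 0 || th[[k]] > 1) stop(k, " must lie in (0, 1]")
  }
  if (th$clump_r2 <= 0 || th$clump_r2 > 1) stop("clump_r2 must lie in (0, 1]")
  pr <- cfg$priors
  do.call(coloc_priors, pr)   # validates prior domains
  if (!cfg$options$re_flavor %in% c("multiplicative", "additive")) {
    stop("re_flavor must be 'multiplicative' or 'additive'")
  }
  cfg
}

#' Assemble in-memory pipeline inputs
#'
#' `bundle_inputs()` adapts a [simulate_study()] bundle; `load_inputs()`
#' reads the files referenced by a configuration's `paths` section.
#'
#' @param bundle A `study_bundle`.
#' @return A list with elements `annotations`, `exposure` (named list per
#'   tissue), `outcome`, `ld` (named list per gene), `druggable` (list of
#'   catalogs), `exclusions`, `gene_sets`.
#' @export
bundle_inputs <- function(bundle) {
  stopifnot(inherits(bundle, "study_bundle"))
  bundle[c("annotations", "exposure", "outcome", "ld", "druggable",
           "exclusions", "gene_sets")]
}

#' @rdname bundle_inputs
#' @param config A validated configuration (see [validate_config()]).
#' @export
load_inputs <- function(config) {
  p <- config$paths
  if (length(p$exposure) == 0 || is.null(p$outcome) || is.null(p$annotations)) {
    stop("config paths must provide exposure (per tissue), outcome and ",
         "annotations")
  }
  annotations <- read_gene_annotations(p$annotations)
  exposure <- lapply(p$exposure, read_summary_stats,
                     trait_type = "quantitative")
  outcome <- read_summary_stats(p$outcome, trait_type = "case_control",
                                case_fraction = config$options$case_fraction)
  druggable <- lapply(seq_along(p$druggable), function(i) {
    read_gene_list(p$druggable[[i]], source_name = paste0("list_", i))
  })
  ld <- list()
  if (!is.null(p$ld_dir)) {
    files <- sort(list.files(p$ld_dir, pattern = "\\.ld$", full.names = TRUE))
    ld <- stats::setNames(lapply(files, read_ld_matrix),
                          sub("\\.ld$", "", basename(files)))
  }
  exclusions <- read_exclusion_list(p$exclusions)
  gene_sets <- if (!is.null(p$gene_sets)) read_gmt(p$gene_sets) else NULL
  list(annotations = annotations, exposure = exposure, outcome = outcome,
       ld = ld, druggable = druggable, exclusions = exclusions,
       gene_sets = gene_sets)
}

# Genes with at least one exposure record inside their cis window.
.eqtl_genes <- function(exposure, annotations, window_bp) {
  present <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    any(exposure$chrom == a$chrom &
          exposure$pos >= a$tss - window_bp &
          exposure$pos <= a$tss + window_bp)
  }, TRUE)
  annotations$symbol[present]
}

.stage_row <- function(stage, n_in, n_out) {
  data.frame(stage = stage, n_in = n_in, n_out = n_out,
             n_dropped = n_in - n_out, stringsAsFactors = FALSE)
}

#' Run the discovery pipeline
#'
#' Executes the full per-tissue analysis and the cross-tissue synthesis.
#' Per tissue: druggable genes are intersected with the genes measured in
#' the tissue's eQTL study; each candidate gene gets cis instruments
#' (FDR + window, LD clumping, exclusion screen), is harmonized against
#' the outcome GWAS and estimated by Wald ratio or IVW random effects;
#' p-values are BH-adjusted across the tissue's testable genes;
#' MR-significant genes are colocalized over the full cis window. A gene
#' is significant when it passes both the MR FDR threshold and the PPH4
#' threshold. The cross-tissue table lists genes significant in every
#' tissue, and over-representation analysis is run on the union of
#' significant genes against the supplied gene sets. Per-gene failures are
#' recorded and do not abort the run.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param inputs Optional pre-assembled inputs ([bundle_inputs()] /
#'   [load_inputs()]); when `NULL` they are loaded from `config$paths`.
#' @param output_dir Optional directory; when given, all result tables and
#'   the manifest are written there with [write_results()].
#' @return A list of class `targetmr_results`: `mr` (named list of
#'   per-tissue MR tables), `coloc`, `significant`, `cross_tissue`,
#'   `enrichment`, `dropped` (per-gene drop log), `manifest`.
#' @export
run_pipeline <- function(config, inputs = NULL, output_dir = NULL) {
  cfg <- validate_config(config)
  if (is.null(inputs)) inputs <- load_inputs(cfg)
  th <- cfg$thresholds
  opt <- cfg$options
  priors <- do.call(coloc_priors, cfg$priors)
  tissues <- names(inputs$exposure)
  if (length(tissues) == 0) stop("at least one exposure tissue is required")

  druggable <- merge_druggable_lists(inputs$druggable)
  mr_tabs <- coloc_tabs <- list()
  significant <- list()
  stage_tabs <- list()
  dropped_log <- list()

  for (tis in tissues) {
    expo <- inputs$exposure[[tis]]
    eqtl_genes <- .eqtl_genes(expo, inputs$annotations, th$window_bp)
    candidates <- intersect_with_eqtl_genes(druggable, eqtl_genes)
    stages <- .stage_row("candidate_selection", length(druggable),
                         length(candidates))
    mr_rows <- list()
    drops <- list()
    for (g in candidates) {
      a <- inputs$annotations[inputs$annotations$symbol == g, ]
      res <- tryCatch({
        ld <- inputs$ld[[g]]
        if (is.null(ld)) stop("no LD matrix for gene")
        instr <- build_instruments(
          expo, a$tss, ld,
          window_bp = th$window_bp, fdr_threshold = th$eqtl_fdr,
          r2_threshold = th$clump_r2, exclusion_list = inputs$exclusions,
          chrom = a$chrom, missing_ld = opt$missing_ld)
        run_mr_gene(instr, inputs$outcome, gene = g, tissue_label = tis,
                    palindrome_eaf_limit = opt$palindrome_eaf_limit,
                    re_flavor = opt$re_flavor)
      }, error = function(e) {
        data.frame(gene = g, tissue = tis, reason = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      if ("reason" %in% names(res)) {
        drops[[g]] <- res
      } else if (is.na(res$method)) {
        drops[[g]] <- data.frame(gene = g, tissue = tis,
                                 reason = "no_usable_instruments",
                                 stringsAsFactors = FALSE)
      } else {
        mr_rows[[g]] <- res
      }
    }
    mr_tab <- if (length(mr_rows) > 0) do.call(rbind, mr_rows) else .mr_na_row("x", "y")[0, ]
    rownames(mr_tab) <- NULL
    if (nrow(mr_tab) > 0) mr_tab$fdr_pvalue <- bh_adjust(mr_tab$pvalue)
    stages <- rbind(stages, .stage_row("instrument_and_mr",
                                       length(candidates), nrow(mr_tab)))
    mr_sig <- mr_tab$gene[!is.na(mr_tab$fdr_pvalue) &
                            mr_tab$fdr_pvalue < th$mr_fdr]
    stages <- rbind(stages, .stage_row("mr_fdr", nrow(mr_tab),
                                       length(mr_sig)))

    coloc_genes <- if (isTRUE(opt$coloc_all_genes)) mr_tab$gene else mr_sig
    coloc_rows <- lapply(coloc_genes, function(g) {
      a <- inputs$annotations[inputs$annotations$symbol == g, ]
      region <- coloc_window_extract(inputs$outcome, expo, a$tss,
                                     window_bp = th$window_bp,
                                     chrom = a$chrom)
      coloc_abf(region$eqtl, region$gwas, priors, gene = g,
                pph4_threshold = th$pph4_min)
    })
    coloc_tab <- if (length(coloc_rows) > 0) do.call(rbind, coloc_rows) else
      coloc_abf(data.frame(snp_id = character(0), beta = numeric(0),
                           se = numeric(0)),
                data.frame(snp_id = character(0), beta = numeric(0),
                           se = numeric(0)), priors)[0, ]
    rownames(coloc_tab) <- NULL
    coloc_pass <- coloc_tab$gene[coloc_tab$passes_threshold]
    sig <- sort(intersect(mr_sig, coloc_pass))
    stages <- rbind(stages, .stage_row("coloc_pph4", length(mr_sig),
                                       length(sig)))
    mr_tabs[[tis]] <- mr_tab
    coloc_tabs[[tis]] <- coloc_tab
    significant[[tis]] <- sig
    stage_tabs[[tis]] <- stages
    dropped_log[[tis]] <- if (length(drops) > 0) do.call(rbind, drops) else
      data.frame(gene = character(0), tissue = character(0),
                 reason = character(0), stringsAsFactors = FALSE)
  }

  cross <- Reduce(intersect, significant)
  cross_tab <- do.call(rbind, lapply(cross, function(g) {
    rows <- lapply(tissues, function(tis) {
      mr <- mr_tabs[[tis]][mr_tabs[[tis]]$gene == g, ]
      cl <- coloc_tabs[[tis]][coloc_tabs[[tis]]$gene == g, ]
      data.frame(gene = g, tissue = tis, n_snps = mr$n_snps,
                 or_value = mr$or_value, ci95_low = mr$ci95_low,
                 ci95_high = mr$ci95_high, pvalue = mr$pvalue,
                 fdr_pvalue = mr$fdr_pvalue, pph4 = cl$pph4,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(cross_tab)) {
    cross_tab <- data.frame(gene = character(0), tissue = character(0),
                            n_snps = integer(0), or_value = numeric(0),
                            ci95_low = numeric(0), ci95_high = numeric(0),
                            pvalue = numeric(0), fdr_pvalue = numeric(0),
                            pph4 = numeric(0), stringsAsFactors = FALSE)
  }

  hits <- sort(unique(unlist(significant)))
  universe <- sort(unique(unlist(lapply(mr_tabs, function(x) x$gene))))
  enrichment <- if (!is.null(inputs$gene_sets) && length(hits) > 0) {
    ora(hits, universe, inputs$gene_sets,
        min_set_size = opt$min_set_size)
  } else {
    ora(character(0), "PLACEHOLDER", list())[0, ]
  }

  manifest <- list(
    config_hash = .fnv1a32(paste(deparse(cfg[c("thresholds", "priors",
                                               "options", "seed")]),
                                 collapse = "")),
    seed = cfg$seed,
    tissues = tissues,
    stages = stage_tabs,
    n_significant = vapply(significant, length, 0L),
    n_cross_tissue = length(cross))

  structure(list(mr = mr_tabs, coloc = coloc_tabs,
                 significant = significant, cross_tissue = cross_tab,
                 enrichment = enrichment, dropped = dropped_log,
                 manifest = manifest, config = cfg),
            class = "targetmr_results")
}

#' Write pipeline results to a directory
#'
#' Emits per-tissue MR and colocalization TSVs, forest-table TSVs (gene,
#' n_snps, OR, CI, p, FDR), significant-gene lists, the cross-tissue
#' table, the enrichment table, the per-gene drop log and a plain-text run
#' manifest. Output is byte-identical across reruns with identical inputs.
#'
#' @param results A `targetmr_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "targetmr_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tis in names(results$mr)) {
    mr <- results$mr[[tis]]
    .write_tsv(mr, file.path(dir, paste0("mr_", tis, ".tsv")))
    forest <- mr[c("gene", "n_snps", "or_value", "ci95_low", "ci95_high",
                   "pvalue", "fdr_pvalue")]
    .write_tsv(forest[order(forest$gene), ],
               file.path(dir, paste0("forest_", tis, ".tsv")))
    .write_tsv(results$coloc[[tis]],
               file.path(dir, paste0("coloc_", tis, ".tsv")))
    writeLines(results$significant[[tis]],
               file.path(dir, paste0("significant_", tis, ".txt")))
    .write_tsv(results$dropped[[tis]],
               file.path(dir, paste0("dropped_", tis, ".tsv")))
  }
  .write_tsv(results$cross_tissue, file.path(dir, "cross_tissue.tsv"))
  .write_tsv(results$enrichment, file.path(dir, "enrichment.tsv"))
  mani <- results$manifest
  lines <- c(paste0("config_hash: ", mani$config_hash),
             paste0("seed: ", mani$seed),
             paste0("tissues: ", paste(mani$tissues, collapse = ",")))
  for (tis in mani$tissues) {
    st <- mani$stages[[tis]]
    lines <- c(lines, vapply(seq_len(nrow(st)), function(i) {
      sprintf("%s/%s: in=%d out=%d dropped=%d", tis, st$stage[i],
              st$n_in[i], st$n_out[i], st$n_dropped[i])
    }, ""))
  }
  lines <- c(lines,
             paste0("n_significant: ",
                    paste(sprintf("%s=%d", names(mani$n_significant),
                                  mani$n_significant), collapse = " ")),
             paste0("n_cross_tissue: ", mani$n_cross_tissue))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Report MR results for named comparator genes
#'
#' Extracts the comparators' MR rows per tissue regardless of
#' significance — the usual check against targets of established drugs.
#' Each row is flagged `significant` (passes FDR), `nominal-only` (raw
#' p below the threshold but FDR above it), `not-significant`, or
#' `not-testable` (absent from the results).
#'
#' @param gene_list Character vector of comparator gene symbols.
#' @param mr_results Named list of per-tissue MR tables (as in
#'   `targetmr_results$mr`), or a single MR table.
#' @param mr_fdr FDR significance threshold (default 0.05).
#' @param p_nominal Raw-p threshold for the nominal flag (default 0.05).
#' @return A `data.frame`: gene, tissue, n_snps, or_value, pvalue,
#'   fdr_pvalue, status.
#' @export
comparator_report <- function(gene_list, mr_results, mr_fdr = 0.05,
                              p_nominal = 0.05) {
  if (is.data.frame(mr_results)) mr_results <- list(all = mr_results)
  gene_list <- canonicalize_symbols(gene_list)
  rows <- list()
  for (tis in names(mr_results)) {
    tab <- mr_results[[tis]]
    for (g in gene_list) {
      hit <- tab[tab$gene == g, , drop = FALSE]
      if (nrow(hit) == 0 || is.na(hit$method[1])) {
        rows[[paste(tis, g)]] <- data.frame(
          gene = g, tissue = tis, n_snps = NA_integer_,
          or_value = NA_real_, pvalue = NA_real_, fdr_pvalue = NA_real_,
          status = "not-testable", stringsAsFactors = FALSE)
      } else {
        status <- if (hit$fdr_pvalue < mr_fdr) "significant"
          else if (hit$pvalue < p_nominal) "nominal-only"
          else "not-significant"
        rows[[paste(tis, g)]] <- data.frame(
          gene = g, tissue = tis, n_snps = hit$n_snps,
          or_value = hit$or_value, pvalue = hit$pvalue,
          fdr_pvalue = hit$fdr_pvalue, status = status,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(0), tissue = character(0),
               n_snps = integer(0), or_value = numeric(0),
               pvalue = numeric(0), fdr_pvalue = numeric(0),
               status = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
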