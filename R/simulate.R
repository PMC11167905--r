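#' Ground-truth record for one simulated cis region
#'
#' Encodes which of the five colocalization hypotheses a simulated gene
#' region realizes and, where applicable, the causal variants and effect
#' sizes used by the generator:
#' \describe{
#'   \item{H0}{no causal variant for either trait}
#'   \item{H1}{a causal eQTL variant, no disease signal}
#'   \item{H2}{a causal disease variant, no eQTL signal}
#'   \item{H3}{distinct causal variants for the two traits}
#'   \item{H4}{one shared causal variant; the disease effect at it is
#'     routed through expression as `theta * beta_exposure_causal`}
#' }
#'
#' @param gene Gene symbol.
#' @param scenario One of `"H0" ... "H4"`.
#' @param causal_exposure_snp,causal_outcome_snp SNP ids or `NA`.
#' @param beta_exposure_causal Causal eQTL effect, expression SD per allele.
#' @param theta True causal effect of expression on the outcome, log-odds
#'   per expression SD. Nonzero only under H4, where the outcome signal is
#'   routed through the exposure.
#' @param seed Integer sub-seed used for this region's random stream.
#' @return A one-row `data.frame` with class `simulation_truth`.
#' @export
simulation_truth <- function(gene, scenario,
                             causal_exposure_snp = NA_character_,
                             causal_outcome_snp = NA_character_,
                             beta_exposure_causal = 0,
                             theta = 0,
                             seed = 0L) {
  scenario <- match.arg(scenario, c("H0", "H1", "H2", "H3", "H4"))
  has_exp <- !is.na(causal_exposure_snp)
  has_out <- !is.na(causal_outcome_snp)
  ok <- switch(scenario,
    H0 = !has_exp && !has_out,
    H1 = has_exp && !has_out,
    H2 = !has_exp && has_out,
    H3 = has_exp && has_out &&
      !identical(causal_exposure_snp, causal_outcome_snp),
    H4 = has_exp && has_out &&
      identical(causal_exposure_snp, causal_outcome_snp))
  if (!ok) stop("causal SNP fields inconsistent with scenario ", scenario)
  if (theta != 0 && scenario != "H4") {
    stop("theta must be zero unless the outcome signal is routed through ",
         "the exposure (H4)")
  }
  out <- data.frame(gene = gene, scenario = scenario,
                    causal_exposure_snp = causal_exposure_snp,
                    causal_outcome_snp = causal_outcome_snp,
                    beta_exposure_causal = beta_exposure_causal,
                    theta = theta, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("simulation_truth", "data.frame")
  out
}

# Non-palindromic allele pairs used by the generator; strand flips stay
# unambiguous because no pair is its own reverse complement.
.ALLELE_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Invariant per-region scaffold: positions, allele pairs and allele
# frequencies, drawn once so exposure and outcome studies agree.
.region_frame <- function(ld, seed, chrom, tss, span_bp) {
  m <- nrow(ld)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  pos <- sort(sample.int(2L * span_bp + 1L, m)) + (tss - span_bp) - 1L
  pair <- .ALLELE_PAIRS[sample.int(4L, m, replace = TRUE)]
  swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ea <- vapply(seq_len(m), function(i) pair[[i]][1 + swap[i]], "")
  oa <- vapply(seq_len(m), function(i) pair[[i]][2 - swap[i]], "")
  data.frame(snp_id = rownames(ld), chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa,
             eaf = stats::runif(m, 0.05, 0.95), stringsAsFactors = FALSE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
}

# One study's observed summary statistics for a region, under the
# standardized-genotype model: true marginal effects are r %*% b_causal,
# estimates are multivariate normal around them with covariance r / n.
.draw_summary <- function(frame, ld_chol, b_causal, n, seed,
                          trait_type, case_fraction) {
  m <- nrow(frame)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  mu <- drop(crossprod(ld_chol, ld_chol %*% b_causal))  # r %*% b
  beta <- mu + drop(crossprod(ld_chol, stats::rnorm(m))) / sqrt(n)
  se <- rep(1 / sqrt(n), m)
  out <- frame
  out$beta <- beta
  out$se <- se
  out$pvalue <- 2 * stats::pnorm(-abs(beta / se))
  out$n <- n
  out$trait_type <- trait_type
  out$case_fraction <- if (trait_type == "case_control") case_fraction else NA_real_
  out
}

# Relabel a fraction of records on the swapped or complementary strand so
# the harmonization stage has real work to do. Effects stay equivalent.
.perturb_alleles <- function(df, swap_fraction, strand_fraction, seed) {
  if (swap_fraction <= 0 && strand_fraction <= 0) return(df)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m <- nrow(df)
  swap <- stats::runif(m) < swap_fraction
  flip <- stats::runif(m) < strand_fraction
  ea <- df$effect_allele; oa <- df$other_allele
  df$effect_allele <- ifelse(swap, oa, ea)
  df$other_allele <- ifelse(swap, ea, oa)
  df$beta <- ifelse(swap, -df$beta, df$beta)
  df$eaf <- ifelse(swap, 1 - df$eaf, df$eaf)
  df$effect_allele[flip] <- unname(.COMPLEMENT[df$effect_allele[flip]])
  df$other_allele[flip] <- unname(.COMPLEMENT[df$other_allele[flip]])
  df
}

.causal_vector <- function(frame, snp, effect) {
  b <- numeric(nrow(frame))
  if (!is.na(snp)) {
    i <- match(snp, frame$snp_id)
    if (is.na(i)) stop("causal SNP ", snp, " not present in LD matrix")
    b[i] <- effect
  }
  b
}

.ld_chol <- function(ld, eig_floor = 1e-8) {
  ld <- repair_ld(ld, eig_floor)
  ev <- eigen(unclass(ld), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eig_floor / 2) {
    stop("LD matrix is singular after repair; cannot simulate")
  }
  chol(unclass(ld))
}

#' Simulate two-trait summary statistics for one cis region
#'
#' Generates marginal (single-SNP) association estimates for a quantitative
#' exposure (cis-eQTL study) and a case-control outcome (disease GWAS)
#' under a standardized-genotype model. True marginal effects are
#' `r %*% b`, where `b` places the causal effect dictated by `truth` at its
#' causal SNP; observed estimates are drawn multivariate normal with
#' covariance `r / n`, so `se = 1 / sqrt(n)` and z-scores inherit the LD
#' correlation. Under H4 the outcome effect at the shared variant is
#' `theta * beta_exposure_causal`.
#'
#' @param truth A [simulation_truth()] row.
#' @param ld An [ld_matrix()] containing any causal SNPs.
#' @param n_exposure,n_outcome Study sample sizes.
#' @param seed Integer seed; identical arguments give identical output.
#' @param chrom,tss,span_bp Region placement: SNP positions are drawn
#'   uniformly in `[tss - span_bp, tss + span_bp]`.
#' @param beta_outcome_direct Marginal log-odds at a direct (H2/H3) outcome
#'   causal variant; defaults to `8 / sqrt(n_outcome)`, i.e. a genome-wide
#'   significant hit with `|z| ~ 8`.
#' @param case_fraction Case fraction recorded on outcome records.
#' @param swap_fraction,strand_fraction Fractions of outcome records
#'   reported on swapped or complementary-strand alleles (harmonization
#'   exercise; effects are preserved).
#' @return `list(exposure = <data.frame>, outcome = <data.frame>)`, each
#'   with columns snp_id, chrom, pos, effect_allele, other_allele, eaf,
#'   beta, se, pvalue, n, trait_type, case_fraction.
#' @export
simulate_region <- function(truth, ld, n_exposure, n_outcome, seed,
                            chrom = "1", tss = 1e6, span_bp = 95000,
                            beta_outcome_direct = NULL,
                            case_fraction = 0.17,
                            swap_fraction = 0, strand_fraction = 0) {
  stopifnot(inherits(truth, "simulation_truth"), nrow(truth) == 1)
  if (is.null(beta_outcome_direct)) beta_outcome_direct <- 8 / sqrt(n_outcome)
  U <- .ld_chol(ld)
  frame <- .region_frame(ld, sub_seed(seed, 0), chrom, tss, span_bp)
  b_exp <- .causal_vector(frame, truth$causal_exposure_snp,
                          truth$beta_exposure_causal)
  out_effect <- if (truth$scenario == "H4") {
    truth$theta * truth$beta_exposure_causal
  } else {
    beta_outcome_direct
  }
  b_out <- .causal_vector(frame, truth$causal_outcome_snp, out_effect)
  exposure <- .draw_summary(frame, U, b_exp, n_exposure, sub_seed(seed, 1),
                            "quantitative", NA_real_)
  outcome <- .draw_summary(frame, U, b_out, n_outcome, sub_seed(seed, 2),
                           "case_control", case_fraction)
  outcome <- .perturb_alleles(outcome, swap_fraction, strand_fraction,
                              sub_seed(seed, 3))
  list(exposure = exposure, outcome = outcome)
}

# Largest-remainder apportionment of n among proportions p (names kept).
.largest_remainder <- function(p, n) {
  quota <- p * n
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)  # ties: first category
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Default generator parameters
#'
#' The study conditions the bundle generator emulates: a large blood
#' cis-eQTL study (n = 31,684), a much smaller brain (prefrontal-cortex)
#' study (n = 1,387) and a large case-control disease GWAS (n = 589,356),
#' with 50-SNP cis regions under AR-1
#' LD decay 0.5, strong causal cis-eQTL effects (0.3 expression SD per
#' allele) and a causal expression-to-disease effect of 0.4 log-odds per
#' expression SD under H4.
#'
#' @return Named list of parameters accepted by [simulate_study()].
#' @export
default_sim_params <- function() {
  list(
    tissues = c("blood", "brain"),
    n_exposure = c(blood = 31684, brain = 1387),
    n_outcome = 589356,
    case_fraction = 0.17,
    m_per_gene = 50,
    rho = 0.5,
    span_bp = 95000,
    beta_exposure_causal = 0.3,
    theta = 0.4,
    beta_outcome_direct = NULL,   # 8 / sqrt(n_outcome)
    swap_fraction = 0.15,
    strand_fraction = 0.15,
    brain_coverage = 0.85
  )
}

#' Simulate a full two-tissue study bundle with known ground truth
#'
#' Builds everything the discovery pipeline consumes: gene annotations,
#' per-tissue exposure (cis-eQTL) tables, one outcome (GWAS) table, an LD
#' matrix per gene, two partially overlapping druggable-gene lists, a SNP
#' exclusion list, GMT gene sets and the truth table. Scenarios are
#' apportioned across genes by deterministic largest-remainder rounding of
#' `scenario_mix`; each gene keeps its scenario in both tissues, so any H4
#' gene exercises the cross-tissue intersection.
#'
#' @param n_genes Number of genes (>= 1).
#' @param scenario_mix Named proportions over H0..H4 summing to 1.
#' @param params Parameter list; see [default_sim_params()]. Partial lists
#'   are merged over the defaults.
#' @param seed Global integer seed; per-gene streams are derived with
#'   [sub_seed()].
#' @return A list of class `study_bundle`.
#' @export
simulate_study <- function(n_genes,
                           scenario_mix = c(H0 = 0.5, H1 = 0.1, H2 = 0.1,
                                            H3 = 0.1, H4 = 0.2),
                           params = list(), seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  n_genes <- as.integer(n_genes)
  scen_names <- c("H0", "H1", "H2", "H3", "H4")
  mix <- stats::setNames(numeric(5), scen_names)
  if (is.null(names(scenario_mix)) && length(scenario_mix) == 5) {
    names(scenario_mix) <- scen_names
  }
  mix[names(scenario_mix)] <- scenario_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("scenario_mix must sum to 1 (1e-9)")
  p <- utils::modifyList(default_sim_params(), params)
  if (is.null(p$beta_outcome_direct)) {
    p$beta_outcome_direct <- 8 / sqrt(p$n_outcome)
  }

  counts <- .largest_remainder(mix, n_genes)
  names(counts) <- scen_names
  if (counts[["H4"]] == 0 && mix[["H4"]] > 0) {
    # the bundle must carry at least one shared-causal gene when requested
    top <- which.max(counts)
    counts[top] <- counts[top] - 1L
    counts[["H4"]] <- 1L
  }
  scenarios <- rep(scen_names, counts)

  genes <- sprintf("GENE%03d", seq_len(n_genes))
  chrom <- as.character(((seq_len(n_genes) - 1L) %% 22L) + 1L)
  tss <- 1e6 + ((seq_len(n_genes) - 1L) %/% 22L) * 2e6
  annotations <- data.frame(symbol = genes, chrom = chrom, tss = tss,
                            strand = rep(c("+", "-"), length.out = n_genes),
                            stringsAsFactors = FALSE)

  min_sep <- if (p$rho > 0) ceiling(log(0.01) / (2 * log(p$rho))) else 1L
  exposure <- stats::setNames(
    vector("list", length(p$tissues)), p$tissues)
  for (t in p$tissues) exposure[[t]] <- vector("list", n_genes)
  outcome <- vector("list", n_genes)
  ld_list <- stats::setNames(vector("list", n_genes), genes)
  truth <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    gseed <- sub_seed(seed, g)
    snp_ids <- sprintf("rs%d", g * 1000L + seq_len(p$m_per_gene))
    ld <- make_ld_matrix(p$m_per_gene, p$rho, snp_ids)
    ld_list[[g]] <- ld
    scen <- scenarios[g]

    old <- .save_rng(); set.seed(gseed)
    c1 <- c2 <- NA_character_
    if (scen %in% c("H1", "H3", "H4")) {
      i1 <- sample(seq_len(p$m_per_gene), 1)
      c1 <- snp_ids[i1]
    }
    if (scen == "H2") c2 <- snp_ids[sample(seq_len(p$m_per_gene), 1)]
    if (scen == "H3") {
      far <- which(abs(seq_len(p$m_per_gene) - i1) >= min_sep)
      c2 <- snp_ids[far[sample(length(far), 1)]]
    }
    if (scen == "H4") c2 <- c1
    .restore_rng(old)

    tr <- simulation_truth(
      gene = genes[g], scenario = scen,
      causal_exposure_snp = c1, causal_outcome_snp = c2,
      beta_exposure_causal = if (scen %in% c("H1", "H3", "H4")) p$beta_exposure_causal else 0,
      theta = if (scen == "H4") p$theta else 0,
      seed = gseed)
    truth[[g]] <- tr

    frame <- .region_frame(ld, sub_seed(gseed, 0), chrom[g], tss[g], p$span_bp)
    U <- .ld_chol(ld)
    b_exp <- .causal_vector(frame, c1, tr$beta_exposure_causal)
    out_effect <- if (scen == "H4") p$theta * p$beta_exposure_causal else p$beta_outcome_direct
    b_out <- .causal_vector(frame, c2, out_effect)
    for (ti in seq_along(p$tissues)) {
      tis <- p$tissues[ti]
      exposure[[tis]][[g]] <- .draw_summary(
        frame, U, b_exp, p$n_exposure[[tis]], sub_seed(gseed, ti),
        "quantitative", NA_real_)
    }
    oc <- .draw_summary(frame, U, b_out, p$n_outcome, sub_seed(gseed, 6),
                        "case_control", p$case_fraction)
    outcome[[g]] <- .perturb_alleles(oc, p$swap_fraction, p$strand_fraction,
                                     sub_seed(gseed, 7))
  }

  truth <- do.call(rbind, truth)

  # second tissue covers only part of the transcriptome, but always the
  # shared-causal genes, so the cross-tissue intersection is exercised
  if (length(p$tissues) > 1 && p$brain_coverage < 1) {
    old <- .save_rng(); set.seed(sub_seed(seed, 900001))
    keep_n <- max(1L, round(p$brain_coverage * n_genes))
    keep <- sort(sample(seq_len(n_genes), keep_n))
    keep <- sort(union(keep, which(truth$scenario == "H4")))
    .restore_rng(old)
    for (tis in p$tissues[-1]) exposure[[tis]] <- exposure[[tis]][keep]
  }
  exposure <- lapply(exposure, function(x) {
    do.call(rbind, x[!vapply(x, is.null, TRUE)])
  })
  outcome <- do.call(rbind, outcome)

  # two partially overlapping druggable lists covering every simulated gene
  a_hi <- ceiling(0.7 * n_genes)
  b_lo <- max(1L, floor(0.4 * n_genes))
  drug_a <- gene_catalog("list_a", c(genes[seq_len(a_hi)],
                                     sprintf("DRUGX%d", 1:5)))
  drug_b <- gene_catalog("list_b", c(genes[b_lo:n_genes],
                                     sprintf("DRUGY%d", 1:3)))

  # exclusion screen stand-in: one non-causal SNP from each of the first
  # two genes, flagged as directly disease-associated phenotypes
  excl <- do.call(rbind, lapply(seq_len(min(2L, n_genes)), function(g) {
    snps <- sprintf("rs%d", g * 1000L + seq_len(p$m_per_gene))
    causal <- truth$causal_exposure_snp[g]
    pick <- setdiff(snps, causal)[1]
    data.frame(snp_id = pick, reason = c("headache", "migraine")[g],
               stringsAsFactors = FALSE)
  }))

  h4_genes <- truth$gene[truth$scenario == "H4"]
  old <- .save_rng(); set.seed(sub_seed(seed, 900002))
  sets <- list(
    SHARED_CAUSAL_SET = unique(c(h4_genes, sample(genes, min(2, n_genes)))),
    RANDOM_SET_1 = sort(sample(genes, max(3L, round(0.2 * n_genes)))),
    RANDOM_SET_2 = sort(sample(genes, max(3L, round(0.3 * n_genes)))),
    TINY_SET = genes[seq_len(min(2L, n_genes))])
  .restore_rng(old)

  structure(list(
    annotations = annotations, truth = truth, exposure = exposure,
    outcome = outcome, ld = ld_list,
    druggable = list(drug_a, drug_b), exclusions = excl,
    gene_sets = sets, params = p, seed = as.integer(seed)),
    class = "study_bundle")
}

#' Write a study bundle to disk as plain-text files
#'
#' Summary statistics go out as TSV with the fixed ten-column header
#' (snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#' pvalue, n); LD matrices as whitespace-delimited square matrices with a
#' SNP-id header row; gene sets as GMT. A ready-to-run pipeline
#' configuration (`config.yaml`) pointing at the written files is included.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ld"), showWarnings = FALSE)
  sumstat_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pvalue", "n")
  paths <- list(outcome = file.path(dir, "outcome.tsv"),
                annotations = file.path(dir, "genes.tsv"),
                exclusions = file.path(dir, "exclusions.tsv"),
                gene_sets = file.path(dir, "gene_sets.gmt"),
                ld_dir = file.path(dir, "ld"),
                truth = file.path(dir, "truth.tsv"))
  exposure_paths <- list()
  for (tis in names(bundle$exposure)) {
    pth <- file.path(dir, paste0("exposure_", tis, ".tsv"))
    .write_tsv(bundle$exposure[[tis]][sumstat_cols], pth, digits = 17)
    exposure_paths[[tis]] <- pth
  }
  .write_tsv(bundle$outcome[sumstat_cols], paths$outcome, digits = 17)
  .write_tsv(bundle$annotations, paths$annotations)
  .write_tsv(bundle$exclusions, paths$exclusions)
  .write_tsv(bundle$truth, paths$truth, digits = 17)
  write_gmt(bundle$gene_sets, paths$gene_sets)
  for (g in names(bundle$ld)) {
    write_ld_matrix(bundle$ld[[g]], file.path(dir, "ld", paste0(g, ".ld")))
  }
  drugs <- character(0)
  for (i in seq_along(bundle$druggable)) {
    pth <- file.path(dir, paste0("druggable_", i, ".txt"))
    writeLines(sort(bundle$druggable[[i]]$symbols), pth)
    drugs <- c(drugs, pth)
  }
  cfg <- default_config()
  cfg$paths <- list(exposure = exposure_paths,
                    outcome = paths$outcome,
                    annotations = paths$annotations,
                    druggable = as.list(drugs),
                    ld_dir = paths$ld_dir,
                    exclusions = paths$exclusions,
                    gene_sets = paths$gene_sets)
  cfg$seed <- bundle$seed
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
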