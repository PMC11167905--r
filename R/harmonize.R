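# Allele harmonization: express exposure and outcome estimates on a
# common effect allele, resolving swapped reports, strand flips and
# palindromic ambiguity.

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.hpair <- function(exposure, outcome, action, beta_o, eaf_o) {
  data.frame(
    snp_id = exposure$snp_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_exposure = exposure$beta, se_exposure = exposure$se,
    beta_outcome = beta_o, se_outcome = outcome$se,
    eaf_exposure = exposure$eaf, eaf_outcome = eaf_o,
    pvalue_exposure = exposure$pvalue, pvalue_outcome = outcome$pvalue,
    action = action, stringsAsFactors = FALSE)
}

#' Harmonize one exposure/outcome record pair onto a common effect allele
#'
#' If the outcome study reported the swapped allele pair, the outcome beta
#' is negated and its frequency reflected; if it reported the complementary
#' strand, alleles are complemented and re-checked. Palindromic variants
#' (A/T or C/G) carry no strand information in their allele labels, so they
#' are oriented by allele frequency, and only when both studies'
#' frequencies are decisive (outside `[limit, 1 - limit]`); otherwise the
#' pair is dropped. Standard errors are never changed.
#'
#' @param exposure,outcome One summary record each (same `snp_id`).
#' @param palindrome_eaf_limit Frequency band half-width below 0.5 inside
#'   which a palindromic SNP is considered unorientable (default 0.42, so
#'   frequencies in `[0.42, 0.58]` are ambiguous).
#' @return A one-row `data.frame` (`harmonized_pair` fields) whose `action`
#'   records what was done: `none`, `sign_flip`, `strand_flip`,
#'   `strand_flip_and_sign_flip`, or `dropped(<reason>)`.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  if (!identical(as.character(exposure$snp_id), as.character(outcome$snp_id))) {
    stop("cannot harmonize records with different snp_id")
  }
  ea_x <- toupper(exposure$effect_allele); oa_x <- toupper(exposure$other_allele)
  ea_y <- toupper(outcome$effect_allele); oa_y <- toupper(outcome$other_allele)
  lim_lo <- palindrome_eaf_limit; lim_hi <- 1 - palindrome_eaf_limit

  if (.is_palindromic(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(.hpair(exposure, outcome, "dropped(incompatible_alleles)",
                    NA_real_, NA_real_))
    }
    beta_o <- outcome$beta; eaf_o <- outcome$eaf
    if (ea_y != ea_x) {  # swapped labels: align first
      beta_o <- -beta_o; eaf_o <- 1 - eaf_o
    }
    decisive <- function(f) !is.na(f) && (f < lim_lo || f > lim_hi)
    if (!decisive(exposure$eaf) || !decisive(eaf_o)) {
      return(.hpair(exposure, outcome, "dropped(ambiguous_palindrome)",
                    NA_real_, NA_real_))
    }
    if ((exposure$eaf < 0.5) != (eaf_o < 0.5)) {
      # frequencies disagree: the outcome is on the other strand, which for
      # a palindrome is equivalent to one more allele swap
      return(.hpair(exposure, outcome, "strand_flip_and_sign_flip",
                    -beta_o, 1 - eaf_o))
    }
    action <- if (ea_y == ea_x) "none" else "sign_flip"
    return(.hpair(exposure, outcome, action, beta_o, eaf_o))
  }

  comp_ea <- unname(.COMPLEMENT[ea_y]); comp_oa <- unname(.COMPLEMENT[oa_y])
  if (ea_y == ea_x && oa_y == oa_x) {
    .hpair(exposure, outcome, "none", outcome$beta, outcome$eaf)
  } else if (ea_y == oa_x && oa_y == ea_x) {
    .hpair(exposure, outcome, "sign_flip", -outcome$beta, 1 - outcome$eaf)
  } else if (!is.na(comp_ea) && comp_ea == ea_x && comp_oa == oa_x) {
    .hpair(exposure, outcome, "strand_flip", outcome$beta, outcome$eaf)
  } else if (!is.na(comp_ea) && comp_ea == oa_x && comp_oa == ea_x) {
    .hpair(exposure, outcome, "strand_flip_and_sign_flip",
           -outcome$beta, 1 - outcome$eaf)
  } else {
    .hpair(exposure, outcome, "dropped(incompatible_alleles)",
           NA_real_, NA_real_)
  }
}

#' Harmonize an instrument set against an outcome study
#'
#' Pairs instruments with outcome records by `snp_id`; instruments absent
#' from the outcome study are reported as `dropped(missing_in_outcome)`.
#'
#' @param instruments Summary-record `data.frame` (exposure study).
#' @param outcome_records Summary-record `data.frame` (outcome study).
#' @param palindrome_eaf_limit See [harmonize_pair()].
#' @return A `data.frame` of harmonized pairs (all rows, including dropped
#'   ones; filter on `action` not starting with `"dropped"` for usable
#'   pairs). Attribute `"n_dropped"` counts drops by reason.
#' @export
harmonize_set <- function(instruments, outcome_records,
                          palindrome_eaf_limit = 0.42) {
  if (nrow(instruments) == 0) {
    out <- .hpair(instruments, instruments, character(0),
                  numeric(0), numeric(0))
    attr(out, "n_dropped") <- table(character(0))
    return(out)
  }
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    x <- instruments[i, , drop = FALSE]
    j <- match(x$snp_id, outcome_records$snp_id)
    if (is.na(j)) {
      y <- x; y$beta <- NA_real_; y$se <- NA_real_
      y$eaf <- NA_real_; y$pvalue <- NA_real_
      return(.hpair(x, y, "dropped(missing_in_outcome)", NA_real_, NA_real_))
    }
    harmonize_pair(x, outcome_records[j, , drop = FALSE],
                   palindrome_eaf_limit)
  })
  out <- do.call(rbind, rows)
  dropped <- startsWith(out$action, "dropped")
  attr(out, "n_dropped") <- table(sub("^dropped\\((.*)\\)$", "\\1",
                                      out$action[dropped]))
  out
}

#' Usable (non-dropped) harmonized pairs
#'
#' @param pairs Output of [harmonize_set()].
#' @return Rows whose `action` is not a drop.
#' @export
usable_pairs <- function(pairs) {
  pairs[!startsWith(pairs$action, "dropped"), , drop = FALSE]
}
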