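---
title: "Methods: druggable-genome MR and colocalization for target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: druggable-genome MR and colocalization for target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The scientific problem

Genes encoding druggable proteins whose expression causally influences a
disease are natural therapeutic targets. `targetmr` implements the standard
summary-statistics workflow for nominating such targets: cis-eQTL variants
are used as instrumental variables for gene expression in a two-sample
Mendelian randomization (MR) against a disease GWAS, and Bayesian
colocalization then checks that the expression and disease signals in each
cis region are driven by one shared causal variant rather than by distinct
variants in linkage disequilibrium (LD). Genes passing both filters in
every tissue analyzed form the cross-tissue candidate set.

The pipeline consumes only marginal (single-SNP) association summary
statistics — effect `beta`, standard error `se`, p-value, effect/other
allele, allele frequency, sample size — for an exposure study per tissue
(cis-eQTLs, quantitative scale) and one outcome study (disease GWAS,
log-odds scale), plus a gene annotation table (symbol, chromosome, TSS),
one LD correlation matrix per cis region, druggable-gene lists, an
optional SNP exclusion list, and GMT gene sets for enrichment.

## Stages and their models

**Candidate genes.** Druggable-gene catalogs are canonicalized (trim,
uppercase, optional alias table — no live nomenclature lookup, so runs are
hermetic) and merged by union; the per-tissue candidate list is the
intersection with genes that actually carry cis associations in that
tissue's eQTL study.

**Instruments.** For a gene with transcription start site $t$, instruments
are exposure SNPs in the closed window $[t - W,\; t + W]$ (default
$W = 100$ kb; the closed interval is the conservative reading of
"$\pm$ 100 kb", and positions are 1-based) with FDR $< 0.05$. If the study
does not ship an FDR column, Benjamini–Hochberg adjustment is computed
within the gene's cis window. Retained SNPs are pruned by greedy LD
clumping: repeatedly keep the remaining SNP with the smallest p-value
(ties broken lexicographically by SNP id, which makes the output invariant
to input order) and discard everything with $r^2 \ge 0.001$ against it.
LD is an explicit input matrix rather than a reference-panel lookup, again
for hermetic testing. A static exclusion list (variants directly
associated with the outcome or with a phenotype directly linked to it)
replaces interactive phenome-scan queries; semantics are preserved, the
network dependency is not.

**Harmonization.** Exposure/outcome pairs are expressed on a common effect
allele: swapped reports negate the outcome beta and reflect its frequency;
complementary-strand reports are complemented and re-checked. Palindromic
variants (A/T, C/G) carry no strand information in their labels, so they
are oriented by allele frequency, and only when both studies' frequencies
lie outside $[0.42, 0.58]$ (the common two-sample-MR default; the band
half-width is configurable); otherwise the pair is dropped with an
explicit reason. Harmonization never changes a standard error, and
harmonizing an already-harmonized pair is a no-op.

**MR estimation.** With one instrument the causal effect of expression on
disease is the Wald ratio
$\hat\theta = \hat\beta_{out} / \hat\beta_{exp}$ with first-order
delta-method standard error $se_{out} / |\hat\beta_{exp}|$. With $k \ge 2$
instruments the inverse-variance-weighted (IVW) estimate pools the
per-SNP ratios $\hat\theta_j$ with weights $w_j = 1/se_j^2$:
$\hat\theta = \sum w_j \hat\theta_j / \sum w_j$. Heterogeneity is
Cochran's $Q = \sum w_j (\hat\theta_j - \hat\theta)^2$ on $k - 1$ degrees
of freedom. "Random effects" is implemented as multiplicative
over-dispersion — the fixed-effect standard error is inflated by
$\sqrt{\max(1, Q/(k-1))}$, the common default in two-sample MR software —
so the reported se never falls below the fixed-effect value; an additive
DerSimonian–Laird flavor is available behind `re_flavor = "additive"`.
Directional pleiotropy is diagnosed (never silently acted on: flagged
genes stay in the results) by the MR-Egger intercept, a weighted
regression of outcome on exposure effects with a free intercept after
orienting all exposure effects positive. Odds ratios and their 95%
intervals are $\exp(\hat\theta)$, $\exp(\hat\theta \pm 1.96\,se)$.
P-values are BH-adjusted across the testable genes of one tissue (the FDR
family is per tissue, since significant counts are reported per tissue);
genes with zero usable instruments are excluded from the family.

On the delta method: the first-order se ignores exposure-side noise and is
the field's standard. When $\theta \cdot se_{exp}$ is not small against
$se_{out}$ — e.g. equal-sized studies and a substantial causal effect —
first-order intervals are measurably anti-conservative (we observe ~91%
coverage at nominal 95% in that regime), which is why
`second_order = TRUE` propagates the exposure variance and is what the
calibration simulations assert. The pipeline default stays first-order to
match standard practice.

**Colocalization.** Per SNP and trait, the Wakefield-style log approximate
Bayes factor against no effect is, with $V = se^2$, $z = \beta/se$ and
$r = w/(V + w)$,
$$\mathrm{lABF} = \tfrac12\left(\log(1 - r) + r z^2\right),$$
where $w$ is the prior variance of the causal effect: $0.15^2$ per SD for
quantitative traits and $0.2^2$ on the log-odds scale for case-control
traits — the customary defaults of Bayes-factor colocalization, exposed as
configuration because analyses rarely state them explicitly. With per-SNP priors $p_1, p_2$ (causal for one trait) and
$p_{12}$ (causal for both; defaults $10^{-4}, 10^{-4}, 10^{-5}$), the five
single-causal-variant hypotheses have un-normalized weights
$$1,\quad p_1 S_1,\quad p_2 S_2,\quad p_1 p_2 (S_1 S_2 - S_{12}),\quad
  p_{12} S_{12},$$
with $S_1 = \sum_i BF_{1i}$, $S_2 = \sum_j BF_{2j}$,
$S_{12} = \sum_i BF_{1i} BF_{2i}$; posteriors PPH0–PPH4 are the
normalized weights. A gene "colocalizes" when PPH4 $\ge 0.75$
(inclusive). Colocalization uses the full cis window, not just the
clumped instruments, and runs by default only for MR-significant genes
(a flag enables all-gene colocalization for calibration studies). Studies
are matched by SNP id; position+allele matching is out of scope and
documented as such.

*Numerical note.* All hypothesis arithmetic runs in log space. The H3 term
$S_1 S_2 - S_{12}$ is not computed as a difference: when one SNP dominates
both traits, $S_1 S_2$ and $S_{12}$ agree to more than double precision
and the difference would underflow to $-\infty$. Instead H3 is the exact
pairwise log-sum-exp $\log \sum_{i \ne j} \exp(l_{1i} + l_{2j})$, which is
the same algebra with no cancellation ($O(m^2)$, immaterial at cis-region
sizes; a guarded log-difference clamped at $-\infty$ is the fallback above
3,000 SNPs). A single-SNP region yields PPH3 $= 0$ exactly.

**Enrichment.** Over-representation of the significant genes against
user-supplied GMT sets uses the hypergeometric upper tail $P(X \ge k)$
with BH correction across sets. The universe is the set of genes that
actually entered MR (tissue union) — the defensible null, since only those
genes could have become hits; sets smaller than 3 after universe
intersection are skipped (configurable). Gene-set database retrieval is
out of scope; sets are supplied as files.

**Pipeline.** A gene is *significant* in a tissue when it passes both the
MR FDR threshold and the PPH4 threshold — a sequential decision rule:
colocalization confirms, it never rescues; the cross-tissue table lists
genes significant in
every tissue. The run manifest records a config fingerprint, the seed and
per-stage gene counts with the conservation property
`n_in = n_out + n_dropped` at every stage, so a run is auditable; reruns
on identical inputs are byte-identical (all tables are written with fixed
numeric formatting). Per-gene failures are logged with gene and tissue
context and never abort the run. A thin command-line wrapper
(`inst/cli/targetmr`; subcommands `simulate`, `run`, `config`) exposes the
same functions.

## The synthetic-data generator

The generator exists because the real consortium inputs (tens of
thousands of eQTL samples, half a million GWAS samples) cannot ship with a
package; it emulates their *statistical structure* so every stage has a
parameter-recovery test surface with known ground truth.

Each gene region carries `m_per_gene` SNPs (default 50) under AR-1 LD,
$r_{ij} = \rho^{|i-j|}$ with $\rho = 0.5$ — a stylized but standard model
of LD decay. Genotypes are standardized, so the true marginal effect
vector is $r\,b$ for a causal vector $b$, observed effects are drawn
multivariate normal with covariance $r/n$, $se = 1/\sqrt{n}$, and
p-values are the two-sided normal tails. This parameterization avoids
allele-frequency-dependent variance entirely; frequencies (Uniform(0.05,
0.95)) exist only to exercise harmonization logic, and a configurable
fraction of outcome records (default 15% + 15%) is reported on swapped or
complementary-strand alleles. Allele pairs are drawn non-palindromic so
the generator's guarantee — zero harmonization drops — holds by
construction; palindromic handling is tested directly on crafted records.

Each gene realizes one of the five colocalization scenarios H0–H4
(apportioned by deterministic largest-remainder rounding of the requested
mix; the default mix is 50/10/10/10/20%). Under H4 the outcome effect at
the shared variant is $\theta \cdot \beta_{exp}$ — the signal is routed
through expression, $\theta$ being the quantity MR estimates. Under H2/H3
the outcome variant has a direct effect sized to $|z| \approx 8$ (a clear
genome-wide hit); under H1/H3/H4 the causal cis-eQTL effect defaults to
0.3 SD per allele, a strong cis effect. Default sample sizes mirror the
emulated studies: 31,684 (blood eQTL), 1,387 (brain eQTL), 589,356
(GWAS, one shared outcome table for both tissues). H3's two causal
variants are placed at least $\lceil \log 0.01 / (2 \log \rho) \rceil$
SNPs apart so their $r^2 < 0.01$. The second tissue covers 85% of genes
(always including the H4 genes) and two druggable lists overlap partially,
so the merge and intersection stages do real work.

Reproducibility: one global integer seed; per-gene and per-stage streams
are derived with a splitmix-style 32-bit hash (`sub_seed`), so gene $k$'s
data do not depend on how many genes precede it, and identical calls are
byte-identical.

What the generator does **not** emulate: realistic allele-frequency/effect
coupling, coalescent LD, sample overlap between studies, population
stratification, multi-causal regions, or winner's-curse ascertainment of
the published eQTL effects. Passing tests therefore validate the
statistical machinery, not robustness to those real-data pathologies.

## Validation design and problem sizes

The package is validated by oracle equivalence and seeded simulation,
run at sizes chosen to keep the full suite around half a minute:

- colocalization posteriors equal brute-force enumeration over every
  causal-SNP configuration on regions of up to 12 SNPs (tolerance 1e-8),
  and posteriors always sum to 1 within 1e-12;
- IVW equals an independent weighted-least-squares solve through the
  origin within 1e-10 (1,000 random instances), the Egger intercept an
  independent normal-equations solve; BH and the hypergeometric tail match
  their step-up / enumeration definitions, the latter additionally checked
  against 100,000 resampling draws;
- 200 seeded shared-causal replicates give 95%-CI coverage of
  $\theta = 0.4$ inside [92%, 99%] (second-order interval; see the delta
  note above) and 200 valid-instrument null replicates give a raw-p
  rejection rate at 0.05 inside its binomial 99% envelope;
- 200 replicates per scenario at $m = 50$, $\rho = 0.5$, $|z| \approx 8$:
  median PPH4 $\ge 0.75$ under a shared causal variant, median PPH3 above
  median PPH4 under distinct variants, and PPH0 the largest median under
  the null;
- a 50-gene two-tissue bundle recovers its planted H4 genes in the
  cross-tissue table with conserved manifest counts, and
  simulate-then-run is byte-identical across reruns.

## Known limitations

- Joining across studies is by SNP id only; no indel handling, no
  proxy-SNP search, no reference-panel strand inference.
- Single-causal-variant colocalization: multi-causal regions dilute PPH4
  (no SuSiE-style decomposition, no conditioning or masking).
- The case-control outcome is treated on the log-odds scale with the
  normal summary-statistic approximation throughout; `n` is the total
  sample size and the case fraction is carried but not used to rescale
  priors.
- Weighted-median/mode estimators, MR-PRESSO and Steiger filtering are
  deliberately absent (not part of the emulated design); the Egger
  intercept flags pleiotropy but nothing is auto-excluded.
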