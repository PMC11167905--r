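test_that("null regions produce standard-normal z-scores", {
  zsq <- c()
  for (s in 1:10) {
    reg <- simulate_region(h_truth("H0"), make_ld_matrix(100, 0),
                           n_exposure = 1e4, n_outcome = 1e4, seed = s)
    zsq <- c(zsq, (reg$exposure$beta / reg$exposure$se)^2)
  }
  expect_length(zsq, 1000)
  expect_gt(mean(zsq), 0.85)
  expect_lt(mean(zsq), 1.15)
})

test_that("shared-causal regions route the outcome effect through the exposure", {
  ld <- make_ld_matrix(10, 0)
  tr <- h_truth("H4", snp_exp = "snp05", snp_out = "snp05",
                b_exp = 0.5, theta = 0.4)
  reg <- simulate_region(tr, ld, n_exposure = 1e5, n_outcome = 1e5, seed = 7)
  i <- match("snp05", reg$outcome$snp_id)
  se <- reg$outcome$se[i]
  expect_lt(abs(reg$outcome$beta[i] - 0.5 * 0.4), 5 * se)
  # exposure carries its causal effect too
  j <- match("snp05", reg$exposure$snp_id)
  expect_lt(abs(reg$exposure$beta[j] - 0.5), 5 * reg$exposure$se[j])
})

test_that("identical seed and arguments reproduce the region exactly", {
  ld <- make_ld_matrix(8, 0.6)
  tr <- h_truth("H1", snp_exp = "snp03", b_exp = 0.3)
  a <- simulate_region(tr, ld, 5000, 20000, seed = 11)
  b <- simulate_region(tr, ld, 5000, 20000, seed = 11)
  expect_identical(a, b)
  c <- simulate_region(tr, ld, 5000, 20000, seed = 12)
  expect_false(identical(a$exposure$beta, c$exposure$beta))
})

test_that("standard errors scale as the inverse square root of n", {
  ld <- make_ld_matrix(4, 0.2)
  tr <- h_truth("H0")
  se_n <- simulate_region(tr, ld, 1e4, 1e4, seed = 3)$exposure$se
  se_2n <- simulate_region(tr, ld, 2e4, 1e4, seed = 3)$exposure$se
  se_4n <- simulate_region(tr, ld, 4e4, 1e4, seed = 3)$exposure$se
  expect_identical(se_4n, se_n / 2)
  expect_equal(se_2n, se_n / sqrt(2), tolerance = 1e-15)
})

test_that("simulated z-scores reproduce the LD correlation entrywise", {
  ld <- make_ld_matrix(4, 0.8)
  z <- matrix(NA_real_, 2000, 4)
  tr <- h_truth("H0")
  for (s in seq_len(2000)) {
    reg <- simulate_region(tr, ld, 1000, 1000, seed = s)
    z[s, ] <- reg$exposure$beta / reg$exposure$se
  }
  expect_lt(max(abs(cor(z) - unclass(ld))), 0.05)
})

test_that("uncorrelated SNPs have mean-zero marginal effects", {
  ld <- make_ld_matrix(6, 0)
  tr <- h_truth("H1", snp_exp = "snp01", b_exp = 0.5)
  beta2 <- vapply(1:400, function(s) {
    simulate_region(tr, ld, 1e4, 1e4, seed = s)$exposure$beta[2]
  }, 0)
  # MC standard error of the mean is 1/sqrt(n * 400)
  expect_lt(abs(mean(beta2)), 4 / sqrt(1e4 * 400))
})

test_that("scenario labels constrain the causal-SNP fields", {
  expect_error(simulation_truth("G", "H0", causal_exposure_snp = "rs1"),
               "inconsistent")
  expect_error(simulation_truth("G", "H4", causal_exposure_snp = "rs1",
                                causal_outcome_snp = "rs2"), "inconsistent")
  expect_error(simulation_truth("G", "H3", causal_exposure_snp = "rs1",
                                causal_outcome_snp = "rs1"), "inconsistent")
  expect_error(simulation_truth("G", "H1", causal_exposure_snp = "rs1",
                                theta = 0.4), "theta")
  ok <- simulation_truth("G", "H4", causal_exposure_snp = "rs1",
                         causal_outcome_snp = "rs1", theta = 0.4)
  expect_s3_class(ok, "simulation_truth")
})

test_that("study bundles apportion scenarios by largest remainder", {
  b <- simulate_study(50, c(H0 = 0.5, H1 = 0.1, H2 = 0.1, H3 = 0.1,
                            H4 = 0.2), seed = 1)
  expect_equal(nrow(b$truth), 50)
  counts <- table(factor(b$truth$scenario, levels = paste0("H", 0:4)))
  expect_equal(as.integer(counts), c(25L, 5L, 5L, 5L, 10L))
  # every gene annotated, every truth gene druggable in the merged list
  expect_setequal(b$truth$gene, b$annotations$symbol)
  merged <- merge_druggable_lists(b$druggable)
  expect_true(all(b$truth$gene %in% merged))
})

test_that("an all-null mix yields no causal SNPs anywhere", {
  b <- simulate_study(10, c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0),
                      seed = 2)
  expect_true(all(is.na(b$truth$causal_exposure_snp)))
  expect_true(all(is.na(b$truth$causal_outcome_snp)))
  expect_true(all(b$truth$theta == 0))
})

test_that("bundle generation is deterministic and p-values are consistent", {
  a <- simulate_study(8, seed = 5)
  b <- simulate_study(8, seed = 5)
  expect_identical(a, b)
  expect_silent(validate_summary_records(a$exposure$blood))
  expect_silent(validate_summary_records(a$outcome))
  expect_error(simulate_study(0), "n_genes")
  expect_error(simulate_study(5, c(H0 = 0.9, H1 = 0, H2 = 0, H3 = 0,
                                   H4 = 0.2)), "sum to 1")
})

test_that("written bundles are byte-stable and readable", {
  b <- simulate_study(4, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg1 <- write_bundle(b, d1)
  write_bundle(simulate_study(4, seed = 9), d2)
  for (f in c("outcome.tsv", "exposure_blood.tsv", "genes.tsv",
              "gene_sets.gmt", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  inputs <- load_inputs(validate_config(cfg1))
  expect_named(inputs$exposure, c("blood", "brain"))
  expect_equal(sort(names(inputs$ld)), sort(b$annotations$symbol))
  expect_equal(inputs$outcome$beta, b$outcome$beta, tolerance = 1e-12)
})
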