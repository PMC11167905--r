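test_that("Wald ratio follows its closed form", {
  p <- make_pairs(0.5, 0.2, sy = 0.05)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.4)
  expect_equal(w$se, 0.1)
  expect_equal(exp(w$beta), 1.4918, tolerance = 1e-4)
  expect_equal(wald_ratio(make_pairs(0.5, 0))$pvalue, 1)
  expect_equal(wald_ratio(make_pairs(0.5, 0))$beta, 0)
  expect_equal(wald_ratio(make_pairs(-0.5, 0.2))$beta, -0.4)
  expect_equal(wald_ratio(make_pairs(-0.5, 0.2))$se,
               wald_ratio(make_pairs(0.5, 0.2))$se)
  expect_error(wald_ratio(make_pairs(0, 0.2)), "zero exposure")
})

test_that("IVW pools ratios with inverse-variance weights", {
  # ratios both 0.4 with ratio se (0.1, 0.2): exposure beta 1 for clarity
  p <- make_pairs(c(1, 1), c(0.4, 0.4), sy = c(0.1, 0.2))
  est <- ivw_random_effects(p)
  expect_equal(est$beta, 0.4)
  expect_equal(est$q, 0)
  expect_equal(est$se, 1 / sqrt(125), tolerance = 1e-10)

  p2 <- make_pairs(c(1, 1), c(0.3, 0.5), sy = 0.1)
  est2 <- ivw_random_effects(p2)
  expect_equal(est2$beta, 0.4)
  expect_equal(est2$q, 2)
  expect_equal(est2$q_df, 1)
  expect_equal(est2$q_pvalue, 0.15729921, tolerance = 1e-7)
  expect_error(ivw_random_effects(make_pairs(1, 1)), "at least two")
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- make_pairs(runif(k, 0.1, 1) * sample(c(-1, 1), k, TRUE),
                    rnorm(k, 0, 0.3), sx = 0.02,
                    sy = runif(k, 0.01, 0.2))
    est <- ivw_random_effects(p)
    fit <- oracle_wls(p$beta_exposure, p$beta_outcome,
                      1 / p$se_outcome^2, intercept = FALSE)
    expect_equal(est$beta, unname(fit$coef), tolerance = 1e-10)
    # random-effects se never shrinks below the fixed-effect se
    w <- p$beta_exposure^2 / p$se_outcome^2
    expect_gte(est$se + 1e-15, 1 / sqrt(sum(w)))
    # multiplicative flavor: se equals the over-dispersion-floored WLS se
    expect_equal(est$se, unname(fit$se_md), tolerance = 1e-10)
  }
})

test_that("additive random effects reduce to fixed effects when Q <= df", {
  p <- make_pairs(c(1, 1), c(0.4, 0.4), sy = c(0.1, 0.2))
  add <- ivw_random_effects(p, re_flavor = "additive")
  expect_equal(add$beta, 0.4)
  expect_equal(add$se, 1 / sqrt(125), tolerance = 1e-10)
  p2 <- make_pairs(c(1, 1, 1), c(0.1, 0.4, 0.9), sy = 0.05)
  add2 <- ivw_random_effects(p2, re_flavor = "additive")
  expect_gt(add2$se, 1 / sqrt(3 / 0.05^2))
})

test_that("the Egger intercept recovers exact linear structure", {
  p0 <- make_pairs(c(0.2, 0.5, 0.8), 0.4 * c(0.2, 0.5, 0.8), sy = 0.05)
  e0 <- egger_intercept(p0)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  p1 <- make_pairs(c(0.2, 0.5, 0.8), 0.1 + 0.4 * c(0.2, 0.5, 0.8),
                   sy = 0.05)
  e1 <- egger_intercept(p1)
  expect_equal(e1$intercept, 0.1, tolerance = 1e-10)
  expect_error(egger_intercept(make_pairs(c(1, 1), c(1, 1))), "three")
})

test_that("Egger matches an independent normal-equations solve", {
  set.seed(13)
  for (i in 1:30) {
    k <- sample(3:10, 1)
    bx <- runif(k, 0.1, 1) * sample(c(-1, 1), k, TRUE)
    p <- make_pairs(bx, 0.05 + 0.3 * bx + rnorm(k, 0, 0.1),
                    sy = runif(k, 0.02, 0.2))
    got <- egger_intercept(p)
    flip <- sign(p$beta_exposure)
    ref <- oracle_wls(p$beta_exposure * flip, p$beta_outcome * flip,
                      1 / p$se_outcome^2, intercept = TRUE)
    expect_equal(got$intercept, unname(ref$coef[1]), tolerance = 1e-10)
    expect_equal(got$se, unname(ref$se_md[1]), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # thresholding adjusted p at alpha equals the step-up rejection set
    expect_identical(adj <= 0.05 + 1e-12, oracle_bh_reject(p, 0.05))
  }
})

test_that("per-gene MR routes by instrument count", {
  ld <- make_ld_matrix(10, 0)
  tr <- h_truth("H4", snp_exp = "snp05", snp_out = "snp05",
                b_exp = 0.5, theta = 0.4)
  reg <- simulate_region(tr, ld, 1e5, 1e5, seed = 21)
  one <- run_mr_gene(reg$exposure[5, ], reg$outcome, gene = "g")
  expect_equal(one$method, "wald_ratio")
  expect_equal(one$n_snps, 1L)
  expect_true(is.na(one$q_statistic) && is.na(one$egger_intercept))
  five <- run_mr_gene(reg$exposure[1:5, ], reg$outcome, gene = "g")
  expect_equal(five$method, "ivw_random_effects")
  expect_equal(five$q_df, 4L)
  expect_false(is.na(five$egger_intercept))
  none <- run_mr_gene(reg$exposure[0, ], reg$outcome, gene = "g")
  expect_true(is.na(none$method))
  expect_equal(none$n_snps, 0L)
})

test_that("MR result invariants hold on simulated genes", {
  b <- simulate_study(6, seed = 8)
  res <- run_pipeline(default_config(), inputs = bundle_inputs(b))
  for (tis in names(res$mr)) {
    tab <- res$mr[[tis]]
    if (nrow(tab) == 0) next
    expect_equal(tab$or_value, exp(tab$beta), tolerance = 1e-12)
    multi <- tab[tab$n_snps >= 2, ]
    if (nrow(multi) > 0) expect_equal(multi$q_df, multi$n_snps - 1L)
    expect_true(all(tab$fdr_pvalue >= tab$pvalue - 1e-15))
  }
})
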