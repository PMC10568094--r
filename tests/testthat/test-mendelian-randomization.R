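make_instruments <- function(bx, by, sey = rep(0.05, length(bx)),
                             sex = rep(0.02, length(bx))) {
  out <- data.frame(id = sprintf("i%02d", seq_along(bx)),
                    beta_exposure = bx, se_exposure = sex,
                    beta_outcome = by, se_outcome = sey,
                    action = "kept", stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  out
}

test_that("inverse normal transform: symmetry, rank invariance, Blom scores", {
  expect_equal(inverse_normal_transform(c(-1, 0, 1)),
               -rev(inverse_normal_transform(c(-1, 0, 1))))
  x <- withr::with_seed(101, rnorm(50))
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(exp(x)))
  # n = 5 distinct values: hand-computed Blom scores
  v <- c(10, 3, 7, 1, 5)
  hand <- qnorm((rank(v) - 3 / 8) / (5 + 1 / 4))
  expect_equal(inverse_normal_transform(v), hand, tolerance = 1e-10)
  withna <- c(2, NA, 1)
  out <- inverse_normal_transform(withna)
  expect_true(is.na(out[2]) && !anyNA(out[-2]))
  expect_error(inverse_normal_transform(c(NA_real_, NA_real_)), "non-missing")
})

test_that("instrument selection thresholds, clumps, and excludes NOD2/MHC", {
  # nothing genome-wide significant: empty list
  geno <- make_test_geno(200, 6, seed = 102, spacing = 2000000L)
  stats <- fake_stats(geno, p = rep(1e-4, 6))
  expect_identical(select_instruments(stats, geno), character(0))

  # a single hit inside NOD2 is excluded
  g16 <- make_test_geno(200, 1, seed = 103, chrom = "16", start = 50700000)
  s16 <- fake_stats(g16, p = 1e-10)
  expect_identical(select_instruments(s16, g16), character(0))

  # three independent hits on separate chromosomes: all selected
  g3 <- make_test_geno(300, 3, seed = 104, spacing = 5000000L)
  s3 <- fake_stats(g3, p = rep(1e-10, 3))
  expect_setequal(select_instruments(s3, g3), g3$variant_map$id)
})

test_that("harmonization keeps, flips, and drops as documented", {
  ex_geno <- make_test_geno(50, 3, seed = 105)
  ex <- fake_stats(ex_geno, p = rep(1e-10, 3), beta = c(0.5, 0.4, 0.3))
  ot <- ex
  ot$beta <- c(0.2, -0.1, 0.15)
  # variant 2: swap allele labels in the outcome
  ot$effect_allele[2] <- ex$other_allele[2]
  ot$other_allele[2] <- ex$effect_allele[2]
  # variant 3 palindromic in the exposure map
  ex$effect_allele[3] <- "A"; ex$other_allele[3] <- "T"
  hs <- harmonize(ex, ot, ex$id)
  expect_identical(hs$action, c("kept", "flipped", "dropped_palindromic"))
  expect_equal(hs$beta_outcome[1], 0.2)
  expect_equal(hs$beta_outcome[2], 0.1)  # sign flipped
  # missing from the outcome: dropped with a log entry
  hs2 <- harmonize(ex, ot[1, ], ex$id[1:2])
  expect_identical(hs2$action[2], "dropped_missing")
})

test_that("Wald ratio arithmetic and invariances", {
  one <- make_instruments(0.5, 0.25, sey = 0.1)
  res <- wald_ratio(one[1, ])
  expect_equal(res$estimate, 0.5)
  expect_equal(res$se, 0.2)
  expect_equal(wald_ratio(make_instruments(0.5, 0, sey = 0.1)[1, ])$estimate, 0)
  flip <- wald_ratio(make_instruments(-0.5, -0.25, sey = 0.1)[1, ])
  expect_equal(flip$estimate, res$estimate)
  expect_error(wald_ratio(make_instruments(0, 0.1)[1, ]), "zero")
})

test_that("IVW matches the weighted least squares normal equations exactly", {
  bx <- c(0.30, 0.45, 0.22, 0.60, 0.38)
  by <- c(0.15, 0.20, 0.13, 0.31, 0.17)
  sey <- c(0.04, 0.06, 0.05, 0.08, 0.03)
  ins <- make_instruments(bx, by, sey)
  res <- ivw(ins)
  w <- 1 / sey^2
  o <- oracle_wls(bx, by, w, intercept = FALSE)
  expect_equal(res$estimate, o$coef, tolerance = 1e-10)
  expect_equal(res$se, o$se_unit, tolerance = 1e-10)  # fixed-effect: no scaling
  expect_equal(res$Q, sum(w * o$resid^2), tolerance = 1e-10)
  expect_identical(res$Q_df, 4L)

  # duplicated single instrument reduces to the Wald ratio
  dup <- make_instruments(c(0.5, 0.5), c(0.25, 0.25), sey = c(0.1, 0.1))
  expect_equal(ivw(dup)$estimate, wald_ratio(dup[1, ])$estimate,
               tolerance = 1e-12)
  # identical ratios: zero heterogeneity
  prop <- make_instruments(bx, 0.4 * bx, sey)
  expect_equal(ivw(prop)$Q, 0, tolerance = 1e-10)
  expect_error(ivw(make_instruments(0.5, 0.2)), "wald_ratio")
})

test_that("MR-Egger matches the weighted regression oracle and shifts its intercept", {
  bx <- c(0.30, 0.45, 0.22, 0.60, 0.38)
  by <- c(0.18, 0.21, 0.16, 0.30, 0.20)
  sey <- c(0.04, 0.06, 0.05, 0.08, 0.03)
  ins <- make_instruments(bx, by, sey)
  res <- mr_egger(ins)
  w <- 1 / sey^2
  o <- oracle_wls(bx, by, w, intercept = TRUE)
  sigma <- max(1, sqrt(sum(w * o$resid^2) / 3))
  expect_equal(res$estimate, o$coef[2], tolerance = 1e-10)
  expect_equal(res$intercept, o$coef[1], tolerance = 1e-10)
  expect_equal(res$se, sigma * o$se_unit[2], tolerance = 1e-10)
  expect_equal(res$intercept_se, sigma * o$se_unit[1], tolerance = 1e-10)
  expect_identical(res$Q_df, 3L)

  shifted <- make_instruments(bx, by + 0.07, sey)
  res2 <- mr_egger(shifted)
  expect_equal(res2$intercept, res$intercept + 0.07, tolerance = 1e-10)
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-10)
  expect_error(mr_egger(make_instruments(c(0.3, 0.4), c(0.1, 0.2))), ">= 3")
})

test_that("constraining the Egger intercept to zero reproduces IVW", {
  bx <- c(0.31, 0.44, 0.29, 0.58)
  by <- c(0.12, 0.19, 0.10, 0.25)
  sey <- c(0.05, 0.04, 0.06, 0.07)
  ins <- make_instruments(bx, by, sey)
  # zero-intercept weighted refit is exactly the IVW estimator
  o <- oracle_wls(bx, by, 1 / sey^2, intercept = FALSE)
  expect_equal(ivw(ins)$estimate, o$coef, tolerance = 1e-12)
})

test_that("Q is permutation invariant and estimators survive allele relabeling", {
  bx <- c(0.3, 0.5, 0.25, 0.45, 0.6)
  by <- c(0.12, 0.22, 0.09, 0.21, 0.28)
  sey <- c(0.04, 0.05, 0.03, 0.06, 0.05)
  ins <- make_instruments(bx, by, sey)
  perm <- ins[c(3, 1, 5, 2, 4), ]
  expect_equal(ivw(ins)$Q, ivw(perm)$Q, tolerance = 1e-12)
  expect_equal(mr_egger(ins)$estimate, mr_egger(perm)$estimate, tolerance = 1e-12)

  # relabeling which allele is "effect" (betas negated) after harmonization
  # leaves every estimator unchanged
  neg <- make_instruments(-bx, -by, sey)
  expect_equal(ivw(neg)$estimate, ivw(ins)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$estimate, mr_egger(ins)$estimate, tolerance = 1e-12)
})

test_that("Egger intercept test is calibrated under no pleiotropy", {
  covered <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    sim <- withr::with_seed(2000 + r, {
      k <- 50
      bx <- runif(k, 0.1, 0.6)
      sey <- runif(k, 0.03, 0.08)
      by <- 0.3 * bx + rnorm(k, 0, sey)
      make_instruments(bx, by, sey)
    })
    res <- mr_egger(sim)
    lo <- res$intercept - qt(0.975, 48) * res$intercept_se
    hi <- res$intercept + qt(0.975, 48) * res$intercept_se
    if (lo <= 0 && hi >= 0) covered <- covered + 1L
  }
  expect_gt(covered / reps, 0.90)
  expect_lt(covered / reps, 0.995)
})

test_that("IVW has power for a causal effect and stays null-calibrated", {
  detect_causal <- 0L; false_null <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    sims <- withr::with_seed(3000 + r, {
      k <- 20
      bx <- runif(k, 0.15, 0.5)
      sey <- runif(k, 0.04, 0.08)
      list(causal = make_instruments(bx, 0.3 * bx + rnorm(k, 0, sey), sey),
           null = make_instruments(bx, rnorm(k, 0, sey), sey))
    })
    if (ivw(sims$causal)$p < 0.0083) detect_causal <- detect_causal + 1L
    if (ivw(sims$null)$p < 0.0083) false_null <- false_null + 1L
  }
  expect_gte(detect_causal / reps, 0.9)
  expect_lte(false_null / reps, 0.1)
})

test_that("the linear biomarker scan matches lm on a small fixture", {
  withr::local_seed(106)
  geno <- make_test_geno(150, 8, seed = 107)
  pcs <- matrix(rnorm(150 * 2), 150, 2)
  yq <- 0.4 * geno$dosages[, 2] + 0.2 * pcs[, 1] + rnorm(150)
  stats <- run_linear_gwas(geno, yq, pcs, maf_min = 0.01)
  for (j in c(1, 2, 5)) {
    fit <- lm(yq ~ geno$dosages[, j] + pcs)
    expect_equal(stats$beta[j], unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(stats$se[j], unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-8)
  }
})

test_that("the MR panel reports the Bonferroni threshold and per-method rows", {
  g3 <- make_test_geno(300, 4, seed = 108, spacing = 5000000L)
  ex <- fake_stats(g3, p = c(1e-10, 1e-10, 1e-10, 0.5),
                   beta = c(0.5, 0.4, 0.45, 0.1))
  outcomes <- lapply(1:6, function(i) {
    o <- ex
    o$beta <- 0.2 * ex$beta + 0.01 * i
    o
  })
  names(outcomes) <- paste0("bm", 1:6)
  panel <- run_mr_panel(ex, outcomes, g3)
  expect_equal(attr(panel, "bonferroni_threshold"), 0.05 / 6, tolerance = 1e-12)
  expect_equal(round(attr(panel, "bonferroni_threshold"), 4), 0.0083)
  expect_setequal(unique(panel$method), c("ivw", "egger"))
  expect_true(all(panel$n_instruments == 3))

  one <- run_mr_panel(ex, outcomes[1], g3)
  expect_equal(attr(one, "bonferroni_threshold"), 0.05)
  expect_error(run_mr_panel(ex, list(), g3), "at least one")
  # no significant exposure variant: no instruments for the panel
  ex_null <- ex; ex_null$p <- rep(0.5, 4)
  expect_error(run_mr_panel(ex_null, outcomes, g3), "no instruments")
})
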