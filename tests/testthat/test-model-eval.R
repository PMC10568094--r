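make_eval_fixture <- function(n = 200, seed = 81) {
  withr::with_seed(seed, {
    pcs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
    score <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.2 + 0.8 * score + 0.3 * pcs[, 1]))
    list(y = y, pcs = pcs, score = score)
  })
}

test_that("Nagelkerke R2 matches a direct-likelihood oracle and its edge cases", {
  fx <- make_eval_fixture()
  base <- cbind(intercept = 1, fx$pcs)
  alt <- cbind(base, score = fx$score)
  vr <- nagelkerke_r2(fx$y, base, alt)
  expect_equal(vr$r2, oracle_nagelkerke(fx$y, base, alt), tolerance = 1e-8)
  expect_gte(vr$loglik_alt, vr$loglik_baseline)

  # identical designs: exactly zero
  expect_equal(nagelkerke_r2(fx$y, base, base)$r2, 0, tolerance = 1e-12)

  # perfectly separating column saturates (capped ridge fit)
  sep <- cbind(base, sep = ifelse(fx$y == 1, 5, -5))
  expect_gte(nagelkerke_r2(fx$y, base, sep)$r2, 0.99)

  # non-nested designs refuse to compare
  expect_error(nagelkerke_r2(fx$y, cbind(other = fx$score), base), "nested")
})

test_that("Nagelkerke R2 is invariant under affine transforms of the score", {
  fx <- make_eval_fixture(seed = 82)
  base <- cbind(intercept = 1, fx$pcs)
  r_raw <- nagelkerke_r2(fx$y, base, cbind(base, s = fx$score))$r2
  r_aff <- nagelkerke_r2(fx$y, base, cbind(base, s = 3.7 * fx$score - 11))$r2
  expect_equal(r_raw, r_aff, tolerance = 1e-7)
})

test_that("marginal variance is monotone in added blocks and validates input", {
  cfg <- sim_config(n_samples = 1500, n_variants = 50, seed = 83L,
                    causal_effects = data.frame(index = c(2, 25),
                                                beta = c(0.7, 0.5)))
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  prs <- drop(geno$dosages[, c(2, 25)] %*% c(0.7, 0.5))
  fs <- factor_set(ph, prs = prs)
  expect_error(marginal_variance(ph, fs, character(0)), "empty")
  expect_error(marginal_variance(ph, fs, "nonsense"), "unknown factor")
  r_all <- marginal_variance(ph, fs, c("prs", "biomarkers", "smoking"))$r2
  for (blk in c("prs", "biomarkers", "smoking"))
    expect_gte(r_all + 1e-9, marginal_variance(ph, fs, blk)$r2)
})

test_that("conditioning on an independent block leaves R2 almost unchanged", {
  withr::local_seed(84)
  n <- 4000
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.7 * score))
  ph <- data.frame(subtype = y)
  noise <- matrix(rnorm(n * 4), n, 4)  # independent of score and outcome
  fs <- factor_set(ph, prs = score)
  fs$blocks$noise <- noise
  marg <- marginal_variance(ph, fs, "prs")$r2
  cond <- conditional_variance(ph, fs, "prs", "noise")$r2
  expect_lt(abs(marg - cond), 0.02)
  expect_error(conditional_variance(ph, fs, "prs", c("prs", "noise")),
               "conditioning set")
})

test_that("conditioning on liability-derived biomarkers shrinks the genetic R2", {
  cfg <- sim_config(n_samples = 2000, n_variants = 50, seed = 85L,
                    causal_effects = data.frame(index = c(3, 20, 30),
                                                beta = c(1.0, 0.8, 0.7)))
  geno <- simulate_genotypes(cfg)
  strict <- 0L
  for (s in 1:5) {
    cfg$pheno_seed <- 9000L + s
    ph <- simulate_phenotypes(geno, cfg)
    fs <- factor_set(ph, prs = attr(ph, "true_score"))
    marg <- marginal_variance(ph, fs, "prs")$r2
    cond <- conditional_variance(ph, fs, "prs", "biomarkers")$r2
    if (cond < marg) strict <- strict + 1L
  }
  expect_identical(strict, 5L)
})

test_that("OR per SD is scale-invariant and matches the logistic oracle", {
  fx <- make_eval_fixture(n = 30, seed = 86)
  res <- or_per_sd(fx$y, fx$score, fx$pcs)
  fit <- glm(fx$y ~ scale(fx$score) + fx$pcs, family = binomial())
  expect_equal(log(res$or), unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(res$se, unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-5)

  res2 <- or_per_sd(fx$y, 2 * fx$score, fx$pcs)
  expect_equal(res2$or, res$or, tolerance = 1e-8)
  expect_error(or_per_sd(fx$y, rep(1, 30)), "zero-variance")
})

test_that("AUC equals the exhaustive pair count and Youden picks the best cut", {
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.2, 0.9, 0.5, 0.45, 0.8, 0.7)
  res <- auc_and_youden(y, s)
  expect_equal(res$auc, oracle_auc(y, s))
  # brute-force Youden over all cuts
  js <- vapply(sort(unique(s)), function(t)
    mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1, 0)
  expect_equal(res$sensitivity + res$specificity - 1, max(js))

  perfect <- auc_and_youden(y, y)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  withr::local_seed(87)
  rand <- auc_and_youden(rbinom(2000, 1, 0.5), rnorm(2000))
  expect_lt(abs(rand$auc - 0.5), 0.05)
  expect_error(auc_and_youden(rep(1, 5), 1:5), "single class")
})

test_that("bootstrap percentile intervals behave and are seeded", {
  const <- bootstrap_metric(1:50, function(d) 7, n_boot = 100, seed = 1)
  expect_equal(const$ci_low, 7)
  expect_equal(const$ci_high, 7)

  xb <- withr::with_seed(89, rnorm(100))
  b1 <- bootstrap_metric(xb, mean, n_boot = 200, seed = 5)
  b2 <- bootstrap_metric(xb, mean, n_boot = 200, seed = 5)
  expect_identical(b1$values, b2$values)

  x <- withr::with_seed(88, rnorm(500))
  bb <- bootstrap_metric(x, mean, n_boot = 1000, seed = 6)
  se <- sd(x) / sqrt(500)
  expect_lt(abs(bb$ci_low - (mean(x) - 1.96 * se)), 0.01)
  expect_lt(abs(bb$ci_high - (mean(x) + 1.96 * se)), 0.01)

  expect_warning(
    bf <- bootstrap_metric(1:20, function(d) if (sum(d) %% 2) stop("x") else 1,
                           n_boot = 50, seed = 7),
    "failed")
  expect_identical(bf$n_failed, sum(is.na(bf$values)))
})

test_that("repeated CV is seeded, honours folds, and does not leak optimism", {
  cv1 <- repeated_cv(1:100, function(tr, te, d) mean(d[te]), n_reps = 20, seed = 9)
  cv2 <- repeated_cv(1:100, function(tr, te, d) mean(d[te]), n_reps = 20, seed = 9)
  expect_identical(cv1$values, cv2$values)
  const <- repeated_cv(1:100, function(tr, te, d) 3, n_reps = 10, seed = 9)
  expect_equal(const$ci_low, 3)
  expect_equal(const$ci_high, 3)
  expect_error(repeated_cv(1:3, function(tr, te, d) 1, folds = 2), "too small")

  # null phenotypes: trained factor models explain nothing out of sample
  withr::local_seed(90)
  n <- 2000
  ph <- data.frame(subtype = rbinom(n, 1, 0.5),
                   smoking = sample(c("Never", "Quit", "Current"), n, TRUE),
                   b1 = rnorm(n), b2 = rnorm(n))
  fs <- factor_set(ph, biomarkers = c("b1", "b2"))
  pipe <- cv_factor_pipeline(ph, fs, c("biomarkers", "smoking"))
  cv <- repeated_cv(seq_len(n), pipe, n_reps = 25, seed = 91)
  expect_lt(cv$mean, 0.02)
})

test_that("label flipping follows the requested fraction and direction ratio", {
  labels <- rep(c(1L, 0L), c(560, 440))
  fl <- flip_labels(labels, noise_plan(0.2, 9, seed = 10))
  expect_length(fl$cd_to_uc, 180L)
  expect_length(fl$uc_to_cd, 20L)
  expect_true(all(labels[fl$cd_to_uc] == 1))
  expect_true(all(labels[fl$uc_to_cd] == 0))
  expect_identical(sum(fl$labels != labels), 200L)

  expect_identical(flip_labels(labels, noise_plan(0, 1))$labels, labels)
  bal <- rep(c(1L, 0L), 50)
  expect_identical(flip_labels(bal, noise_plan(1, 1))$labels, 1L - bal)
  expect_error(flip_labels(labels, noise_plan(0.9, 9)), "more flips")
})

test_that("experiment wrappers: identity at zero noise, size and ratio edges", {
  # cheap mock cohorts: pipeline correlates a planted score with labels
  n <- 400
  geno <- make_test_geno(n, 4, seed = 92)
  ph <- withr::with_seed(93, data.frame(
    subtype = rbinom(n, 1, plogis(1.2 * scale(geno$dosages[, 1])))))
  cohort <- list(genotypes = geno, phenotypes = ph,
                 pcs = matrix(0, n, 0))
  pipe <- function(train, test) {
    b <- coef(glm(train$phenotypes$subtype ~ train$genotypes$dosages[, 1],
                  family = binomial()))[2]
    s <- b * test$genotypes$dosages[, 1]
    nagelkerke_r2(test$phenotypes$subtype,
                  matrix(1, nrow(test$phenotypes), 1,
                         dimnames = list(NULL, "intercept")),
                  cbind(intercept = 1, s = s))$r2
  }
  ne <- noise_experiment(cohort, cohort, pipe, fractions = c(0, 0.5), seed = 94)
  expect_equal(ne$retained[1], 1)
  expect_lt(ne$retained[2], ne$retained[1])

  ts <- training_size_experiment(cohort, cohort, pipe, sizes = c(100, n),
                                 seeds = 1:2)
  expect_equal(ts$mean_r2[ts$size == n], pipe(cohort, cohort))
  expect_error(training_size_experiment(cohort, cohort, pipe, sizes = n + 1),
               "exceeds")

  expect_error(case_ratio_experiment(cohort, cohort, pipe, ratios = 1),
               "infeasible")
  native <- mean(ph$subtype)
  cr <- case_ratio_experiment(cohort, cohort, pipe, ratios = native)
  expect_identical(cr$n_train, as.integer(n))  # native ratio: no resampling
})

test_that("contingency test matches the textbook formula and flags sparse tables", {
  tab_smoking <- rep(c("Never", "Quit", "Current"), c(30, 20, 10))
  tab_loc <- c(rep(c("colonic", "small_bowel"), c(10, 20)),
               rep(c("colonic", "small_bowel"), c(12, 8)),
               rep(c("colonic", "small_bowel"), c(2, 8)))
  res <- contingency_chi2(tab_smoking, tab_loc)
  O <- table(tab_smoking, tab_loc)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$p, pchisq(res$chi2, 2, lower.tail = FALSE))

  flat <- contingency_chi2(rep(c("Never", "Quit"), each = 20),
                           rep(c("colonic", "small_bowel"), 20))
  expect_equal(flat$chi2, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)

  expect_warning(contingency_chi2(rep(c("Never", "Quit"), c(39, 1)),
                                  rep(c("colonic", "small_bowel"), 20)),
                 "below 1")
})
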