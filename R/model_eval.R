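#' Design blocks for variance-explained models
#'
#' Assembles the named design blocks the variance decomposition works with:
#' a baseline block (intercept plus the first `n_pcs` principal components,
#' always available), and optional `prs` (one column), `biomarkers`
#' (standardized titer columns, mean-imputed where missing) and `smoking`
#' (two dummies, Never as reference) blocks, all row-aligned with the
#' phenotype table.
#'
#' @param phenotypes phenotype data.frame.
#' @param prs optional per-sample score vector.
#' @param pcs optional PC score matrix.
#' @param n_pcs number of PCs in the baseline (default all columns of `pcs`).
#' @param biomarkers names of biomarker columns to include.
#' @return A list of class `factor_set` with elements `blocks` and `y`.
#' @export
factor_set <- function(phenotypes, prs = NULL, pcs = NULL, n_pcs = NULL,
                       biomarkers = intersect(default_biomarker_spec()$marker,
                                              names(phenotypes))) {
  n <- nrow(phenotypes)
  baseline <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (!is.null(n_pcs)) pcs <- pcs[, seq_len(n_pcs), drop = FALSE]
    stopifnot(nrow(pcs) == n)
    baseline <- cbind(baseline, pcs)
  }
  blocks <- list(baseline = baseline)
  if (!is.null(prs)) {
    stopifnot(length(prs) == n)
    blocks$prs <- matrix(as.numeric(prs), n, 1, dimnames = list(NULL, "prs"))
  }
  if (length(biomarkers)) {
    bm <- as.matrix(phenotypes[, biomarkers, drop = FALSE])
    for (j in seq_len(ncol(bm))) {
      x <- bm[, j]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      s <- sd(x)
      bm[, j] <- if (s > 0) (x - mean(x)) / s else 0
    }
    blocks$biomarkers <- bm
  }
  if ("smoking" %in% names(phenotypes))
    blocks$smoking <- smoking_dummies(phenotypes$smoking)
  structure(list(blocks = blocks, y = as.numeric(phenotypes$subtype), n = n),
            class = "factor_set")
}

variance_result <- function(r2, mode, factor, n, l0, l1,
                            ci = c(NA_real_, NA_real_), ci_method = NA_character_) {
  structure(list(r2 = r2, mode = mode, factor = factor, n = n,
                 loglik_baseline = l0, loglik_alt = l1,
                 ci_low = ci[1], ci_high = ci[2], ci_method = ci_method),
            class = "variance_result")
}

#' @export
print.variance_result <- function(x, ...) {
  cat(sprintf("%s variance explained by %s: Nagelkerke R2 = %.4f (n = %d)\n",
              x$mode, x$factor, x$r2, x$n))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% interval [%.4f, %.4f] (%s)\n", x$ci_low, x$ci_high,
                x$ci_method))
  invisible(x)
}

#' Nagelkerke pseudo R-squared of nested logistic models
#'
#' Fits the baseline and alternative designs by maximum likelihood and
#' computes `R2_CS = 1 - exp(2*(l0 - l1)/n)` rescaled by its maximum
#' `1 - exp(2*l0/n)` (Nagelkerke). The alternative design must contain every
#' baseline column; separation is handled by the capped ridge fit, whose
#' penalized likelihoods are used.
#'
#' @param y binary outcome vector.
#' @param baseline_design,alt_design numeric design matrices (with intercept).
#' @param mode,factor labels stored on the result.
#' @return A `variance_result`.
#' @export
nagelkerke_r2 <- function(y, baseline_design, alt_design,
                          mode = "marginal", factor = "factor") {
  baseline_design <- as.matrix(baseline_design)
  alt_design <- as.matrix(alt_design)
  if (!all(colnames(baseline_design) %in% colnames(alt_design)))
    stop("designs are not nested: alternative must contain all baseline columns")
  f0 <- suppressWarnings(fit_logistic(baseline_design, y))
  f1 <- suppressWarnings(fit_logistic(alt_design, y))
  n <- length(y)
  l0 <- f0$loglik; l1 <- max(f1$loglik, f0$loglik)  # nested fits: l1 >= l0
  r2 <- nagelkerke_from_loglik(l0, l1, n)
  variance_result(min(max(r2, 0), 1), mode, factor, n, l0, l1)
}

#' Marginal variance explained by factor blocks
#'
#' Baseline = intercept + PCs; alternative adds the named blocks.
#'
#' @param phenotypes phenotype data.frame (provides the subtype outcome).
#' @param factors a [factor_set()].
#' @param which character vector of block names (subset of the non-baseline
#'   blocks) whose joint marginal contribution is wanted.
#' @return A `variance_result`.
#' @export
marginal_variance <- function(phenotypes, factors, which) {
  stopifnot(inherits(factors, "factor_set"))
  if (!length(which)) stop("empty factor subset")
  bad <- setdiff(which, setdiff(names(factors$blocks), "baseline"))
  if (length(bad)) stop("unknown factor block: ", paste(bad, collapse = ", "))
  y <- as.numeric(phenotypes$subtype)
  base <- factors$blocks$baseline
  alt <- do.call(cbind, c(list(base), factors$blocks[which]))
  nagelkerke_r2(y, base, alt, mode = "marginal",
                factor = paste(which, collapse = "+"))
}

#' Conditional variance explained by a factor block
#'
#' Baseline = intercept + PCs + conditioning blocks; the alternative adds the
#' target block, so the R^2 is the target's contribution beyond what the
#' conditioning factors already explain.
#'
#' @inheritParams marginal_variance
#' @param target_block name of the block of interest.
#' @param conditioning_blocks names of the blocks conditioned on.
#' @return A `variance_result` with mode `"conditional"`.
#' @export
conditional_variance <- function(phenotypes, factors, target_block,
                                 conditioning_blocks) {
  stopifnot(inherits(factors, "factor_set"))
  if (target_block %in% conditioning_blocks)
    stop("target block also appears in the conditioning set")
  y <- as.numeric(phenotypes$subtype)
  base <- do.call(cbind, c(list(factors$blocks$baseline),
                           factors$blocks[conditioning_blocks]))
  alt <- cbind(base, factors$blocks[[target_block]])
  nagelkerke_r2(y, base, alt, mode = "conditional", factor = target_block)
}

#' Odds ratio per standard deviation of a score
#'
#' Standardizes the score to unit SD, fits `y ~ score + PCs`, and reports
#' `exp(beta)` with its Wald 95% confidence interval.
#'
#' @param y binary outcome.
#' @param score numeric score vector.
#' @param pcs optional PC matrix used as covariates.
#' @return list `or`, `ci_low`, `ci_high`, `beta`, `se`, `p`.
#' @export
or_per_sd <- function(y, score, pcs = NULL) {
  if (sd(score) == 0) stop("zero-variance score")
  z <- (score - mean(score)) / sd(score)
  x <- cbind(intercept = 1, score = z)
  if (!is.null(pcs)) x <- cbind(x, as.matrix(pcs))
  fit <- suppressWarnings(fit_logistic(x, y))
  b <- fit$coef["score"]; se <- fit$se["score"]
  list(or = unname(exp(b)), ci_low = unname(exp(b - 1.96 * se)),
       ci_high = unname(exp(b + 1.96 * se)), beta = unname(b),
       se = unname(se), p = unname(2 * pnorm(-abs(b / se))))
}

#' AUC and the Youden operating point
#'
#' AUC by the rank (Mann-Whitney) statistic with midranks for ties; the
#' Youden threshold maximizes sensitivity + specificity - 1 (classifying
#' `score >= threshold` as CD), taking the lowest threshold on ties.
#'
#' @param y binary outcome.
#' @param score numeric score.
#' @return list `auc`, `threshold`, `sensitivity`, `specificity`.
#' @export
auc_and_youden <- function(y, score) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(score)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(score))
  # classify score >= t: cumulative counts from the top
  sens <- vapply(thr, function(t) mean(score[y == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(score[y == 0] < t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # ties -> lower threshold (thr sorted asc)
  list(auc = auc, threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Bootstrap mean and percentile interval of a metric
#'
#' Resamples rows (data.frames/matrices) or elements (vectors/lists) with
#' replacement at the original size; metric failures drop the replicate with
#' a warning and are counted.
#'
#' @param data the dataset handed to `metric`.
#' @param metric function of one (resampled) dataset returning a scalar.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list `mean`, `ci_low`, `ci_high`, `values`, `n_failed`.
#' @export
bootstrap_metric <- function(data, metric, n_boot = 1000L, seed = 1L,
                             conf = 0.95) {
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else length(data)
  take <- function(d, idx) {
    if (is.data.frame(d) || is.matrix(d)) d[idx, , drop = FALSE] else d[idx]
  }
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(metric(take(data, idx))),
               error = function(e) NA_real_)
    }, 0)
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > 0)
    warning(n_failed, " bootstrap replicates failed and were dropped")
  vals_ok <- vals[!is.na(vals)]
  a <- (1 - conf) / 2
  list(mean = mean(vals_ok),
       ci_low = unname(quantile(vals_ok, a)),
       ci_high = unname(quantile(vals_ok, 1 - a)),
       values = vals, n_failed = n_failed)
}

#' Repeated k-fold cross-validation of a pipeline
#'
#' Per replicate, samples are randomly split into `folds` folds; each fold
#' serves once as the test set with the rest as training, and
#' `pipeline(train_idx, test_idx, data)` is recorded. The default (2 folds)
#' is the repeated half-split design: fit on 50%, evaluate on the rest.
#'
#' @param data dataset passed through to the pipeline.
#' @param pipeline function `(train_idx, test_idx, data) -> scalar`.
#' @param n_reps number of replicates.
#' @param folds folds per replicate.
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @return list `mean`, `ci_low`, `ci_high`, `values`.
#' @export
repeated_cv <- function(data, pipeline, n_reps = 1000L, folds = 2L, seed = 1L,
                        conf = 0.95) {
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else
    if (is.list(data) && !is.null(data$phenotypes)) nrow(data$phenotypes) else
      length(data)
  if (n < 2 * folds) stop("fold too small for the design")
  vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_reps), function(r) {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      vapply(seq_len(folds), function(f) {
        as.numeric(pipeline(which(fold_id != f), which(fold_id == f), data))
      }, 0)
    }))
  })
  a <- (1 - conf) / 2
  list(mean = mean(vals), ci_low = unname(quantile(vals, a)),
       ci_high = unname(quantile(vals, 1 - a)), values = vals)
}

#' Misdiagnosis noise plan and label flipping
#'
#' `round(flip_fraction * n)` labels are flipped in total, split between the
#' two directions by `cd_to_uc_ratio`: `round(n_flip * ratio / (1 + ratio))`
#' CD samples become UC and the remainder of the flips turn UC into CD
#' (ratio 9 reproduces the clinical pattern of 9 CD misdiagnosed as UC per
#' misdiagnosed UC; ratio 1 is symmetric). Flipped samples are drawn
#' uniformly without replacement within each class.
#'
#' @param flip_fraction fraction of samples whose label flips, in `[0, 1]`.
#' @param cd_to_uc_ratio ratio of CD-to-UC flips over UC-to-CD flips.
#' @param seed RNG seed.
#' @return `noise_plan` returns the plan; `flip_labels` returns a list with
#'   `labels` (flipped vector), `cd_to_uc` and `uc_to_cd` (flipped indices).
#' @export
noise_plan <- function(flip_fraction, cd_to_uc_ratio = 1, seed = 1L) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1, cd_to_uc_ratio >= 0)
  structure(list(flip_fraction = flip_fraction,
                 cd_to_uc_ratio = cd_to_uc_ratio, seed = as.integer(seed)),
            class = "noise_plan")
}

#' @rdname noise_plan
#' @param labels binary subtype vector (CD = 1, UC = 0).
#' @param plan a `noise_plan`.
#' @export
flip_labels <- function(labels, plan) {
  stopifnot(inherits(plan, "noise_plan"), all(labels %in% c(0, 1)))
  n <- length(labels)
  n_flip <- round(plan$flip_fraction * n)
  n_cd2uc <- round(n_flip * plan$cd_to_uc_ratio / (1 + plan$cd_to_uc_ratio))
  n_uc2cd <- n_flip - n_cd2uc
  cd_idx <- which(labels == 1); uc_idx <- which(labels == 0)
  if (n_cd2uc > length(cd_idx) || n_uc2cd > length(uc_idx))
    stop("more flips requested than class members")
  with_seed(plan$seed, {
    cd2uc <- if (n_cd2uc > 0) sample(cd_idx, n_cd2uc) else integer(0)
    uc2cd <- if (n_uc2cd > 0) sample(uc_idx, n_uc2cd) else integer(0)
    out <- labels
    out[cd2uc] <- 0L
    out[uc2cd] <- 1L
    list(labels = out, cd_to_uc = sort(cd2uc), uc_to_cd = sort(uc2cd))
  })
}

#' Misdiagnosis-noise robustness experiment
#'
#' Retrains the pipeline on training labels corrupted at each flip fraction
#' and evaluates on the clean test set, reporting the ratio of the noisy-
#' trained to the clean-trained variance explained (retained R^2).
#'
#' @param train,test cohort lists (`genotypes`, `phenotypes`, `pcs`).
#' @param pipeline function `(train, test) -> scalar R^2` (see
#'   [prs_pipeline()]).
#' @param fractions flip fractions to scan.
#' @param ratio CD-to-UC flip ratio.
#' @param seed base RNG seed (each fraction uses `seed`).
#' @param r2_clean optionally precomputed clean-trained R^2.
#' @return data.frame `fraction`, `r2`, `retained`.
#' @export
noise_experiment <- function(train, test, pipeline, fractions, ratio = 1,
                             seed = 1L, r2_clean = NULL) {
  if (is.null(r2_clean)) r2_clean <- as.numeric(pipeline(train, test))
  r2 <- vapply(fractions, function(f) {
    if (f == 0) return(r2_clean)
    fl <- flip_labels(train$phenotypes$subtype, noise_plan(f, ratio, seed))
    tr <- train
    tr$phenotypes$subtype <- fl$labels
    as.numeric(pipeline(tr, test))
  }, 0)
  data.frame(fraction = fractions, r2 = r2, retained = r2 / r2_clean)
}

#' Training-size experiment
#'
#' Subsamples the training cohort to each size (error if a size exceeds the
#' cohort), retrains, and evaluates on the fixed test set; reports the mean
#' over seeds per size.
#'
#' @inheritParams noise_experiment
#' @param sizes training sizes to scan.
#' @param seeds RNG seeds (one subsample per seed per size).
#' @return data.frame `size`, `mean_r2`, `sd_r2`; per-run values in the
#'   `values` attribute.
#' @export
training_size_experiment <- function(train, test, pipeline, sizes,
                                     seeds = 1:10) {
  n <- nrow(train$phenotypes)
  if (any(sizes > n)) stop("training size exceeds cohort size")
  vals <- matrix(NA_real_, length(sizes), length(seeds),
                 dimnames = list(as.character(sizes), NULL))
  for (si in seq_along(sizes)) {
    if (sizes[si] == n) {
      # the full cohort is the same subsample for every seed
      vals[si, ] <- as.numeric(pipeline(train, test))
      next
    }
    for (ki in seq_along(seeds)) {
      idx <- with_seed(seeds[ki], sample.int(n, sizes[si]))
      tr <- list(genotypes = subset_genotypes(train$genotypes, samples = idx),
                 phenotypes = train$phenotypes[idx, , drop = FALSE],
                 pcs = train$pcs[idx, , drop = FALSE])
      vals[si, ki] <- as.numeric(pipeline(tr, test))
    }
  }
  out <- data.frame(size = sizes, mean_r2 = rowMeans(vals),
                    sd_r2 = apply(vals, 1, sd))
  attr(out, "values") <- vals
  out
}

#' Training case-ratio experiment
#'
#' Resamples the training cohort to each CD fraction at a fixed total size
#' (the largest size feasible for every requested ratio) by downsampling the
#' over-represented class; the native ratio is used without resampling.
#'
#' @inheritParams noise_experiment
#' @param ratios target CD fractions (e.g. `c(0.50, 0.56, 0.64)`).
#' @return data.frame `ratio`, `n_train`, `r2`.
#' @export
case_ratio_experiment <- function(train, test, pipeline, ratios, seed = 1L) {
  y <- train$phenotypes$subtype
  n_cd <- sum(y == 1); n_uc <- sum(y == 0)
  native <- n_cd / (n_cd + n_uc)
  feas <- vapply(ratios, function(r) {
    if (r <= 0 || r >= 1) stop("infeasible ratio: ", r)
    floor(min(n_cd / r, n_uc / (1 - r)))
  }, 0)
  n_total <- min(feas)
  res <- lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    if (abs(r - native) < 1e-9) {
      idx <- seq_along(y)
    } else {
      k_cd <- round(n_total * r); k_uc <- n_total - k_cd
      idx <- with_seed(seed + i, c(sample(which(y == 1), k_cd),
                                   sample(which(y == 0), k_uc)))
    }
    tr <- list(genotypes = subset_genotypes(train$genotypes, samples = idx),
               phenotypes = train$phenotypes[idx, , drop = FALSE],
               pcs = train$pcs[idx, , drop = FALSE])
    data.frame(ratio = r, n_train = length(idx),
               r2 = as.numeric(pipeline(tr, test)))
  })
  do.call(rbind, res)
}

#' Smoking-by-location contingency test
#'
#' Pearson chi-square (no continuity correction) on the smoking x CD-location
#' table, plus the colonic fraction per smoking level. A warning is attached
#' when any expected cell count falls below 1.
#'
#' @param smoking three-level smoking vector (CD samples).
#' @param location `"colonic"` / `"small_bowel"` vector, same length.
#' @return list `chi2`, `df`, `p`, `table`, `colonic_fraction`.
#' @export
contingency_chi2 <- function(smoking, location) {
  keep <- !is.na(smoking) & !is.na(location)
  tab <- table(smoking = smoking[keep], location = location[keep])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty row or column")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) < 1)
    warning("expected cell count below 1; chi-square approximation is poor")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  colonic <- if ("colonic" %in% colnames(tab))
    tab[, "colonic"] / rowSums(tab) else rep(NA_real_, nrow(tab))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, colonic_fraction = colonic)
}
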