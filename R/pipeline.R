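#' End-to-end polygenic score construction
#'
#' The full training stage: case-case GWAS with PC covariates, greedy
#' clumping outside the MHC (250 kb, r^2 > 0.2), three-pass clumping inside
#' the MHC (5 Mb radius, r^2 0.1/0.05/0.05), p-value thresholding, and score
#' model assembly with optional fine-map overrides (NOD2).
#'
#' @param train cohort list with `genotypes`, `phenotypes`, `pcs`.
#' @param gwas_cfg a [gwas_config()].
#' @param clump_cfg a [clump_config()] for non-MHC regions.
#' @param mhc_cfg an [mhc_clump_config()].
#' @param p_threshold inclusion p-value cut-off.
#' @param overrides optional override list for [build_score_model()].
#' @return list `model` ([score_model()]), `stats` ([summary_stats()]),
#'   `clumps_nonmhc`, `clumps_mhc`.
#' @export
build_prs_model <- function(train, gwas_cfg = gwas_config(),
                            clump_cfg = clump_config(),
                            mhc_cfg = mhc_clump_config(),
                            p_threshold = 0.1, overrides = NULL) {
  stats <- run_gwas(train$genotypes, train$phenotypes, gwas_cfg, train$pcs)
  mhc <- in_region(stats$chrom, stats$pos, mhc_region(), use_flank = FALSE)
  clump_cfg$p_threshold <- p_threshold
  mhc_cfg$p_threshold <- p_threshold
  cs_non <- clump(stats[!mhc, , drop = FALSE], train$genotypes, clump_cfg)
  cs_mhc <- clump_mhc(stats[mhc, , drop = FALSE], train$genotypes, mhc_cfg)
  model <- build_score_model(list(cs_non, cs_mhc), stats,
                             p_threshold = p_threshold, overrides = overrides)
  list(model = model, stats = stats, clumps_nonmhc = cs_non,
       clumps_mhc = cs_mhc)
}

#' Train-and-evaluate pipeline factory for experiments
#'
#' Returns a function `(train, test) -> marginal PRS Nagelkerke R^2`: it
#' builds the score model on the training cohort (labels taken from
#' `train$phenotypes$subtype`, so the noise experiment can corrupt them),
#' scores the test cohort, and evaluates the marginal variance explained
#' against the test cohort's PC baseline.
#'
#' @inheritParams build_prs_model
#' @return A pipeline function usable with [noise_experiment()],
#'   [training_size_experiment()] and [case_ratio_experiment()].
#' @export
prs_pipeline <- function(gwas_cfg = gwas_config(), clump_cfg = clump_config(),
                         mhc_cfg = mhc_clump_config(), p_threshold = 0.1,
                         overrides = NULL) {
  function(train, test) {
    built <- build_prs_model(train, gwas_cfg, clump_cfg, mhc_cfg,
                             p_threshold, overrides)
    if (!nrow(built$model)) return(0)
    prs <- score_samples(test$genotypes, built$model)
    fs <- factor_set(test$phenotypes, prs = prs, pcs = test$pcs,
                     n_pcs = gwas_cfg$n_pcs)
    marginal_variance(test$phenotypes, fs, "prs")$r2
  }
}

#' Cross-validation pipeline over phenotype factor blocks
#'
#' For use with [repeated_cv()] on a single cohort: per split, the selected
#' blocks' logistic coefficients are fitted on the training half (together
#' with the PC baseline); the trained factor score is then evaluated on the
#' test half as Nagelkerke R^2 over the test PC baseline. A frozen PRS
#' column (trained on an external cohort) passes through unrefitted, the way
#' the genetics model is trained once and carried into cross-validation of
#' the cohort-specific factors.
#'
#' @param phenotypes phenotype data.frame of the evaluation cohort.
#' @param factors a [factor_set()] built on the full cohort.
#' @param which block names entering the model.
#' @return A function `(train_idx, test_idx, data) -> R^2`.
#' @export
cv_factor_pipeline <- function(phenotypes, factors, which) {
  stopifnot(inherits(factors, "factor_set"))
  y <- as.numeric(phenotypes$subtype)
  base <- factors$blocks$baseline
  xblk <- do.call(cbind, factors$blocks[which])
  function(train_idx, test_idx, data) {
    fit <- suppressWarnings(
      fit_logistic(cbind(base, xblk)[train_idx, , drop = FALSE], y[train_idx]))
    k <- ncol(base)
    score <- drop(xblk[test_idx, , drop = FALSE] %*% fit$coef[-seq_len(k)])
    nagelkerke_r2(y[test_idx], base[test_idx, , drop = FALSE],
                  cbind(base[test_idx, , drop = FALSE], score = score))$r2
  }
}
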