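#' Rank-based inverse normal transform
#'
#' Maps values through `qnorm((rank - 3/8) / (n + 1/4))` (Blom offsets) with
#' midranks for ties; missing values stay missing. Used to normalize serum
#' biomarker titers before their GWAS.
#'
#' @param values numeric vector (ties and missing allowed).
#' @return Transformed vector, same length and missingness.
#' @export
inverse_normal_transform <- function(values) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n < 2) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  r <- rank(values[obs], ties.method = "average")
  out[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Linear association scan for a quantitative trait
#'
#' Per-variant ordinary least squares of a (typically inverse-normal
#' transformed) quantitative trait on dosage, residualizing both on the
#' covariates first; used to produce biomarker outcome summary statistics
#' for two-sample MR.
#'
#' @param geno a [genotype_matrix()].
#' @param values quantitative trait vector.
#' @param pcs optional covariate matrix (PCs).
#' @param maf_min minimum MAF for a variant to be tested.
#' @return A [summary_stats()] data.frame (beta on the trait scale).
#' @export
run_linear_gwas <- function(geno, values, pcs = NULL, maf_min = 0.005) {
  keep <- !is.na(values)
  y <- values[keep]
  dos <- geno$dosages[keep, , drop = FALSE]
  n <- length(y)
  covs <- cbind(intercept = rep(1, n))
  if (!is.null(pcs)) covs <- cbind(covs, as.matrix(pcs)[keep, , drop = FALSE])
  k <- ncol(covs)
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  pass <- which(!is.na(maf) & maf >= maf_min)
  if (!length(pass)) stop("no variants pass the MAF filter")
  dos <- dos[, pass, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- mu[j]
  }
  q <- qr(covs)
  ry <- qr.resid(q, y)
  rg <- qr.resid(q, dos)
  ss_g <- colSums(rg^2)
  beta <- colSums(rg * ry) / ss_g
  df <- n - k - 1
  rss <- sum(ry^2) - beta^2 * ss_g
  se <- sqrt(pmax(rss, 0) / df / ss_g)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  out <- data.frame(geno$variant_map[pass, , drop = FALSE], beta = beta,
                    se = se, p = p, maf = maf[pass],
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    stringsAsFactors = FALSE)
  summary_stats(out)
}

#' Instrument selection for two-sample MR
#'
#' Extracts exposure variants at genome-wide significance, clumps them
#' (r^2 < 0.01, 500 kb window by default, reusing the greedy clumping rule),
#' and removes instruments inside the excluded regions (NOD2 and the MHC by
#' default, a conservative guard against their strong horizontal
#' pleiotropy). An empty result is returned as an empty list, mirroring the
#' situation where no variant reaches significance for a trait.
#'
#' @param exposure_stats exposure [summary_stats()].
#' @param ld_geno [genotype_matrix()] for LD.
#' @param p_sig significance threshold for instruments.
#' @param clump_r2 clumping r^2 threshold.
#' @param window_bp clumping radius.
#' @param exclude list of [gene_region()]s to remove.
#' @return Character vector of instrument variant ids (possibly empty).
#' @export
select_instruments <- function(exposure_stats, ld_geno, p_sig = 5e-8,
                               clump_r2 = 0.01, window_bp = 500000L,
                               exclude = list(nod2_region(), mhc_region())) {
  sig <- exposure_stats[!is.na(exposure_stats$p) & exposure_stats$p < p_sig, ,
                        drop = FALSE]
  if (!nrow(sig)) return(character(0))
  cs <- clump(sig, ld_geno,
              clump_config(radius_bp = window_bp, r2_threshold = clump_r2,
                           p_threshold = 1))
  ids <- cs$index_id
  if (length(exclude)) {
    rows <- match(ids, exposure_stats$id)
    drop <- rep(FALSE, length(ids))
    for (reg in exclude)
      drop <- drop | in_region(exposure_stats$chrom[rows],
                               exposure_stats$pos[rows], reg, use_flank = TRUE)
    ids <- ids[!drop]
  }
  ids
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effect to the exposure's effect allele: identical
#' labels are kept, swapped labels flip the outcome beta's sign, palindromic
#' variants (A/T, C/G) are dropped (no allele frequencies are assumed
#' available to orient them), and variants absent from the outcome stats are
#' dropped with a log entry.
#'
#' @param exposure_stats,outcome_stats [summary_stats()] tables.
#' @param instruments instrument variant ids.
#' @return An `instrument_set` data.frame: `id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `action` (one of `kept`,
#'   `flipped`, `dropped_palindromic`, `dropped_missing`); dropped rows carry
#'   `NA` betas.
#' @export
harmonize <- function(exposure_stats, outcome_stats, instruments) {
  ei <- match(instruments, exposure_stats$id)
  if (anyNA(ei)) stop("instruments missing from exposure stats: ",
                      paste(instruments[is.na(ei)], collapse = ", "))
  oi <- match(instruments, outcome_stats$id)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  rows <- lapply(seq_along(instruments), function(i) {
    ex <- exposure_stats[ei[i], ]
    pal <- comp[ex$effect_allele] == ex$other_allele
    if (is.na(oi[i]))
      return(data.frame(id = ex$id, beta_exposure = NA_real_,
                        se_exposure = NA_real_, beta_outcome = NA_real_,
                        se_outcome = NA_real_, action = "dropped_missing"))
    if (pal)
      return(data.frame(id = ex$id, beta_exposure = NA_real_,
                        se_exposure = NA_real_, beta_outcome = NA_real_,
                        se_outcome = NA_real_, action = "dropped_palindromic"))
    ot <- outcome_stats[oi[i], ]
    if (ot$effect_allele == ex$effect_allele && ot$other_allele == ex$other_allele) {
      data.frame(id = ex$id, beta_exposure = ex$beta, se_exposure = ex$se,
                 beta_outcome = ot$beta, se_outcome = ot$se, action = "kept")
    } else if (ot$effect_allele == ex$other_allele &&
               ot$other_allele == ex$effect_allele) {
      data.frame(id = ex$id, beta_exposure = ex$beta, se_exposure = ex$se,
                 beta_outcome = -ot$beta, se_outcome = ot$se, action = "flipped")
    } else {
      data.frame(id = ex$id, beta_exposure = NA_real_, se_exposure = NA_real_,
                 beta_outcome = NA_real_, se_outcome = NA_real_,
                 action = "dropped_mismatch")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("instrument_set", "data.frame")
  out
}

usable_instruments <- function(instruments) {
  instruments[instruments$action %in% c("kept", "flipped"), , drop = FALSE]
}

mr_result <- function(method, estimate, se, p, n_instruments,
                      intercept = NA_real_, intercept_se = NA_real_,
                      intercept_p = NA_real_, Q = NA_real_,
                      Q_df = NA_integer_, Q_p = NA_real_) {
  structure(list(method = method, estimate = estimate, se = se, p = p,
                 n_instruments = n_instruments, intercept = intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p,
                 Q = Q, Q_df = Q_df, Q_p = Q_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): estimate %.4f (se %.4f), p = %.3g, %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' `estimate = beta_outcome / beta_exposure` with first-order standard error
#' `se_outcome / |beta_exposure|`; p from the normal distribution.
#'
#' @param instrument one-row `instrument_set` (or list with the same fields).
#' @return An `mr_result`.
#' @export
wald_ratio <- function(instrument) {
  bx <- instrument$beta_exposure; by <- instrument$beta_outcome
  sey <- instrument$se_outcome
  if (is.na(bx) || bx == 0) stop("exposure beta is zero: Wald ratio undefined")
  est <- by / bx
  se <- sey / abs(bx)
  mr_result("wald", est, se, 2 * pnorm(-abs(est / se)), 1L)
}

#' Fixed-effect inverse-variance weighted MR
#'
#' Weighted zero-intercept regression of outcome on exposure betas with
#' weights `1/se_outcome^2` and fixed-effect standard error (no residual
#' scaling). Cochran's Q with `n - 1` df measures instrument heterogeneity.
#'
#' @param instruments an `instrument_set` (>= 2 usable instruments).
#' @return An `mr_result`.
#' @export
ivw <- function(instruments) {
  ins <- usable_instruments(instruments)
  if (nrow(ins) < 2)
    stop("IVW needs >= 2 instruments; use wald_ratio for a single instrument")
  w <- 1 / ins$se_outcome^2
  est <- sum(w * ins$beta_exposure * ins$beta_outcome) /
    sum(w * ins$beta_exposure^2)
  se <- 1 / sqrt(sum(w * ins$beta_exposure^2))
  q <- sum(w * (ins$beta_outcome - est * ins$beta_exposure)^2)
  qdf <- nrow(ins) - 1L
  mr_result("ivw", est, se, 2 * pnorm(-abs(est / se)), nrow(ins),
            Q = q, Q_df = qdf, Q_p = pchisq(q, qdf, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas with a free intercept
#' (weights `1/se_outcome^2`), after orienting every exposure beta
#' non-negative. The slope is the causal estimate; the intercept and its
#' test measure directional pleiotropy. Standard errors use multiplicative
#' residual scaling bounded below by 1, with t-tests on `n - 2` df;
#' Cochran's Q for Egger has `n - 2` df.
#'
#' @param instruments an `instrument_set` (>= 3 usable instruments).
#' @return An `mr_result` with intercept fields.
#' @export
mr_egger <- function(instruments) {
  ins <- usable_instruments(instruments)
  n <- nrow(ins)
  if (n < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(ins$beta_exposure)
  flip[flip == 0] <- 1
  bx <- ins$beta_exposure * flip
  by <- ins$beta_outcome * flip
  w <- 1 / ins$se_outcome^2
  # weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / det
  inter <- (sxx * swy - swx * sxy) / det
  resid <- by - inter - slope * bx
  q <- sum(w * resid^2)
  sigma <- max(1, sqrt(q / (n - 2)))
  se_slope <- sigma * sqrt(sw / det)
  se_inter <- sigma * sqrt(sxx / det)
  mr_result("egger", slope, se_slope,
            2 * pt(-abs(slope / se_slope), n - 2), n,
            intercept = inter, intercept_se = se_inter,
            intercept_p = 2 * pt(-abs(inter / se_inter), n - 2),
            Q = q, Q_df = n - 2L,
            Q_p = pchisq(q, n - 2, lower.tail = FALSE))
}

#' MR panel over a set of biomarker outcomes
#'
#' Runs the whole two-sample MR of IBD subtype (exposure) on each serum
#' biomarker outcome: instrument selection on the exposure stats, allele
#' harmonization against each outcome, then Wald ratio / IVW / MR-Egger as
#' the usable instrument count permits. The family-wise Bonferroni
#' threshold `alpha / n_biomarkers` is attached.
#'
#' @param exposure_stats exposure [summary_stats()] (subtype GWAS).
#' @param outcome_stats_list named list of outcome [summary_stats()], one per
#'   biomarker.
#' @param ld_geno [genotype_matrix()] for instrument clumping.
#' @param alpha family-wise error rate before Bonferroni division.
#' @param ... passed to [select_instruments()].
#' @return data.frame `biomarker`, `method`, `estimate`, `se`, `p`, `Q`,
#'   `Q_p`, `intercept`, `intercept_p`, `n_instruments`, with attribute
#'   `bonferroni_threshold`.
#' @export
run_mr_panel <- function(exposure_stats, outcome_stats_list, ld_geno,
                         alpha = 0.05, ...) {
  if (!length(outcome_stats_list)) stop("at least one biomarker outcome needed")
  inst <- select_instruments(exposure_stats, ld_geno, ...)
  if (!length(inst)) stop("no instruments for the exposure")
  thr <- alpha / length(outcome_stats_list)
  rows <- lapply(names(outcome_stats_list), function(bm) {
    hs <- harmonize(exposure_stats, outcome_stats_list[[bm]], inst)
    ins <- usable_instruments(hs)
    res <- list()
    if (nrow(ins) == 1) res <- list(wald_ratio(ins[1, ]))
    if (nrow(ins) >= 2) res <- c(res, list(ivw(hs)))
    if (nrow(ins) >= 3) res <- c(res, list(mr_egger(hs)))
    if (!length(res))
      return(data.frame(biomarker = bm, method = "none", estimate = NA_real_,
                        se = NA_real_, p = NA_real_, Q = NA_real_,
                        Q_p = NA_real_, intercept = NA_real_,
                        intercept_p = NA_real_, n_instruments = 0L))
    do.call(rbind, lapply(res, function(r)
      data.frame(biomarker = bm, method = r$method, estimate = r$estimate,
                 se = r$se, p = r$p, Q = r$Q, Q_p = r$Q_p,
                 intercept = r$intercept, intercept_p = r$intercept_p,
                 n_instruments = r$n_instruments)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "instruments") <- inst
  out
}
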