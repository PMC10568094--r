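#' GWAS configuration
#'
#' @param maf_min minimum minor allele frequency for a variant to be tested
#'   (computed on the analysis subset after missing-genotype removal).
#' @param n_pcs number of principal components used as covariates.
#' @param trait `"subtype"` (CD = 1 vs UC = 0) or `"cd_location"` (colonic = 1
#'   vs small_bowel = 0, CD samples only).
#' @param gw_sig_threshold genome-wide significance threshold.
#' @return A list of class `gwas_config`.
#' @export
gwas_config <- function(maf_min = 0.005, n_pcs = 10L,
                        trait = c("subtype", "cd_location"),
                        gw_sig_threshold = 5e-8) {
  trait <- match.arg(trait)
  stopifnot(maf_min > 0, maf_min < 0.5, n_pcs >= 0)
  structure(list(maf_min = maf_min, n_pcs = as.integer(n_pcs), trait = trait,
                 gw_sig_threshold = gw_sig_threshold),
            class = "gwas_config")
}

gwas_trait_vector <- function(phenotypes, trait) {
  if (trait == "subtype") {
    y <- phenotypes$subtype
  } else {
    y <- ifelse(phenotypes$cd_location == "colonic", 1L,
                ifelse(phenotypes$cd_location == "small_bowel", 0L, NA_integer_))
  }
  as.numeric(y)
}

#' Per-variant logistic association scan
#'
#' For each variant passing the MAF filter, fits
#' `trait ~ intercept + dosage + PC1..PCk` by maximum likelihood and reports
#' the log odds ratio per effect allele with its Wald standard error and
#' p-value. Variants whose fit does not converge (e.g. quasi-separation) are
#' flagged and emitted with missing statistics.
#'
#' @param geno a [genotype_matrix()].
#' @param phenotypes phenotype data.frame row-aligned with `geno`.
#' @param config a [gwas_config()].
#' @param pcs optional n x >=`n_pcs` matrix of PC scores (from
#'   [compute_pcs()]); required when `config$n_pcs > 0`.
#' @return A [summary_stats()] data.frame with an extra `converged` column.
#' @export
run_gwas <- function(geno, phenotypes, config = gwas_config(), pcs = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- gwas_trait_vector(phenotypes, config$trait)
  keep <- !is.na(y)
  if (sum(keep) < 2 * (config$n_pcs + 2))
    stop("too few samples with non-missing trait")
  y <- y[keep]
  lv <- unique(y)
  if (length(lv) < 2) stop("trait has a single level")
  dos <- geno$dosages[keep, , drop = FALSE]

  covs <- matrix(1, nrow = sum(keep), ncol = 1, dimnames = list(NULL, "intercept"))
  if (config$n_pcs > 0) {
    if (is.null(pcs)) stop("pcs matrix required when n_pcs > 0")
    pcs <- as.matrix(pcs)[keep, seq_len(config$n_pcs), drop = FALSE]
    covs <- cbind(covs, pcs)
  }

  eaf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  pass <- which(!is.na(maf) & maf >= config$maf_min)
  if (!length(pass)) stop("no variants pass the MAF filter")

  scan <- cpp_logistic_scan(dos[, pass, drop = FALSE], covs, y)
  beta <- scan$beta; se <- scan$se
  ok <- scan$converged == 1L & is.finite(se) & se > 0
  beta[!ok] <- NA_real_; se[!ok] <- NA_real_
  p <- 2 * pnorm(-abs(beta / se))
  p[ok & p < .Machine$double.xmin] <- .Machine$double.xmin

  map <- geno$variant_map[pass, , drop = FALSE]
  out <- data.frame(map, beta = beta, se = se, p = p, maf = maf[pass],
                    n_cases = sum(y == 1), n_controls = sum(y == 0),
                    converged = ok, stringsAsFactors = FALSE)
  summary_stats(out)
}

#' Genome-wide SNP-by-smoking interaction scan
#'
#' For CD location as the trait: per variant, a likelihood-ratio test
#' comparing `location ~ g + smoking + PCs` against
#' `location ~ g + smoking + g:smoking + PCs` (2 df for the two smoking
#' dummies, Never as reference). p-values come from the chi-square
#' distribution of the LRT statistic.
#'
#' @param geno genotypes of the CD samples.
#' @param phenotypes CD-only phenotype table with `cd_location` and `smoking`.
#' @param config a [gwas_config()] (trait is forced to `cd_location`).
#' @param pcs optional PC score matrix.
#' @return data.frame `id`, `lrt`, `df`, `p`, `converged`.
#' @export
run_interaction_scan <- function(geno, phenotypes, config = gwas_config(trait = "cd_location"),
                                 pcs = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- gwas_trait_vector(phenotypes, "cd_location")
  keep <- !is.na(y) & !is.na(phenotypes$smoking)
  y <- y[keep]
  if (length(unique(y)) < 2) stop("trait has a single level")
  dos <- geno$dosages[keep, , drop = FALSE]
  smoke <- smoking_dummies(phenotypes$smoking[keep])

  covs <- cbind(intercept = 1, smoke)
  if (config$n_pcs > 0) {
    if (is.null(pcs)) stop("pcs matrix required when n_pcs > 0")
    covs <- cbind(covs, as.matrix(pcs)[keep, seq_len(config$n_pcs), drop = FALSE])
  }
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  pass <- which(!is.na(maf) & maf >= config$maf_min)
  if (!length(pass)) stop("no variants pass the MAF filter")

  scan <- cpp_interaction_scan(dos[, pass, drop = FALSE], covs, smoke, y)
  p <- pchisq(scan$lrt, df = scan$df, lower.tail = FALSE)
  data.frame(id = geno$variant_map$id[pass], lrt = scan$lrt, df = scan$df,
             p = p, converged = scan$converged == 1L, stringsAsFactors = FALSE)
}

#' Smoking design block
#'
#' Two dummy columns (`Quit`, `Current`) with Never as the reference level.
#'
#' @param smoking character vector of `Never`/`Quit`/`Current`.
#' @return n x 2 numeric matrix.
#' @export
smoking_dummies <- function(smoking) {
  lev <- c("Never", "Quit", "Current")
  if (!all(smoking %in% lev))
    stop("smoking must be one of: ", paste(lev, collapse = ", "))
  cbind(smokingQuit = as.numeric(smoking == "Quit"),
        smokingCurrent = as.numeric(smoking == "Current"))
}

#' Genome-wide significant hits grouped into loci
#'
#' Filters to `p < threshold` and merges hits on the same chromosome within
#' 1 Mb of each other into loci.
#'
#' @param stats a [summary_stats()] data.frame.
#' @param threshold p-value threshold (default 5e-8).
#' @param merge_bp hits closer than this are one locus.
#' @return data.frame `id`, `chrom`, `pos`, `p`, `locus` (integer label);
#'   zero rows if there are no hits.
#' @export
genome_wide_hits <- function(stats, threshold = 5e-8, merge_bp = 1e6) {
  hits <- stats[!is.na(stats$p) & stats$p < threshold, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), p = numeric(0), locus = integer(0)))
  hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  locus <- integer(nrow(hits)); locus[1] <- 1L
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      same <- hits$chrom[i] == hits$chrom[i - 1] &&
        (hits$pos[i] - hits$pos[i - 1]) <= merge_bp
      locus[i] <- if (same) locus[i - 1] else locus[i - 1] + 1L
    }
  }
  data.frame(id = hits$id, chrom = hits$chrom, pos = hits$pos, p = hits$p,
             locus = locus, stringsAsFactors = FALSE)
}
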