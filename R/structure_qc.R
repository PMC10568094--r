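#' QC and pruning configuration
#'
#' Defaults follow common ImmunoChip practice: drop variants inside the MHC,
#' with MAF < 0.05, call rate < 0.99, or violating Hardy-Weinberg equilibrium
#' at p < 1e-5 before computing population-structure PCs; then LD prune at
#' r^2 = 0.1 in 100-variant windows stepping by 5, repeated three times.
#'
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum per-variant call rate.
#' @param hwe_p_min minimum exact HWE p-value.
#' @param exclude_regions data.frame (`chrom`, `start`, `end`); default is the
#'   MHC at chr6:25,000,000-34,000,000 (GRCh37 convention).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, call_rate_min = 0.99, hwe_p_min = 1e-5,
                      exclude_regions = data.frame(chrom = "6",
                                                   start = 25e6, end = 34e6)) {
  stopifnot(maf_min > 0, maf_min < 1, call_rate_min > 0, call_rate_min <= 1,
            hwe_p_min > 0, hwe_p_min < 1)
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, exclude_regions = exclude_regions),
            class = "qc_config")
}

#' @rdname qc_config
#' @param r2_threshold pairwise dosage r^2 above which one of a pair is dropped.
#' @param window_variants sliding window size in variants.
#' @param step_variants window step in variants.
#' @param passes number of whole-scan repetitions.
#' @export
prune_config <- function(r2_threshold = 0.1, window_variants = 100L,
                         step_variants = 5L, passes = 3L) {
  stopifnot(r2_threshold > 0, r2_threshold < 1,
            step_variants <= window_variants, passes >= 1)
  structure(list(r2_threshold = r2_threshold,
                 window_variants = as.integer(window_variants),
                 step_variants = as.integer(step_variants),
                 passes = as.integer(passes)),
            class = "prune_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact test over the conditional distribution of heterozygote counts given
#' the allele counts (Wigginton-style enumeration). Dosages are rounded to
#' {0, 1, 2}; missing values are dropped. Monomorphic variants return p = 1
#' by convention.
#'
#' @param dosages numeric vector of dosages for one variant.
#' @return Two-sided exact p-value.
#' @export
hwe_test <- function(dosages) {
  d <- round(dosages[!is.na(dosages)])
  if (!length(d)) stop("no non-missing dosages")
  if (!all(d %in% 0:2)) stop("dosages must round to 0, 1, or 2")
  n_aa <- sum(d == 0); n_ab <- sum(d == 1); n_bb <- sum(d == 2)
  n <- n_aa + n_ab + n_bb
  n_b <- n_ab + 2 * n_bb            # minor-allele count (orient below)
  if (n_b > n) n_b <- 2 * n - n_b   # use rarer allele
  if (n_b == 0) return(1)
  # support: heterozygote counts with the same parity as n_b
  het <- seq(n_b %% 2, min(n_b, 2 * n - n_b), by = 2)
  # log probability up to a constant: P(het) ∝ n! / (n_aa! n_ab! n_bb!) * 2^het
  log_p <- vapply(het, function(h) {
    hom_rare <- (n_b - h) / 2
    hom_com <- n - h - hom_rare
    h * log(2) - lfactorial(hom_rare) - lfactorial(h) - lfactorial(hom_com)
  }, 0)
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  p_obs <- p[het == n_ab]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Variant quality control
#'
#' Removes variants inside excluded regions, with low MAF, low call rate, or
#' out of Hardy-Weinberg equilibrium. The removal log records one reason per
#' removed variant, the first failing rule in the order region, MAF,
#' call rate, HWE.
#'
#' @param geno a [genotype_matrix()].
#' @param qc a [qc_config()].
#' @return list with `genotypes` (filtered) and `removed` (data.frame
#'   `id`, `reason`).
#' @export
variant_qc <- function(geno, qc = qc_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map <- geno$variant_map
  m <- nrow(map)
  reason <- rep(NA_character_, m)

  ex <- qc$exclude_regions
  if (!is.null(ex) && nrow(ex) > 0) {
    for (r in seq_len(nrow(ex))) {
      hit <- map$chrom == as.character(ex$chrom[r]) &
        map$pos >= ex$start[r] & map$pos <= ex$end[r]
      reason[hit & is.na(reason)] <- "region"
    }
  }
  dos <- geno$dosages
  todo <- is.na(reason)
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  reason[todo & (is.na(maf) | maf < qc$maf_min)] <- "maf"
  todo <- is.na(reason)
  call_rate <- colMeans(!is.na(dos))
  reason[todo & call_rate < qc$call_rate_min] <- "call_rate"
  todo <- is.na(reason)
  if (any(todo)) {
    hwe_p <- vapply(which(todo), function(j) hwe_test(dos[, j]), 0)
    fail <- which(todo)[hwe_p < qc$hwe_p_min]
    reason[fail] <- "hwe"
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("empty matrix: all variants removed by QC")
  out <- subset_genotypes(geno, variants = which(keep))
  # carry simulation annotations through the filter
  for (a in c("maf", "region", "block")) {
    av <- attr(geno, a)
    if (!is.null(av)) attr(out, a) <- av[keep]
  }
  list(genotypes = out,
       removed = data.frame(id = map$id[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Iterated sliding-window LD pruning
#'
#' Greedy pruning on dosage (composite) r^2: within each window, while any
#' surviving pair exceeds the threshold, the pair with the largest r^2 is
#' found and its lower-MAF member dropped (tie: the later map position); the
#' window then slides by `step_variants`. The whole scan is repeated
#' `passes` times on the surviving set.
#'
#' @param geno a [genotype_matrix()] (at least 2 samples).
#' @param prune a [prune_config()].
#' @return Character vector of retained variant ids, in map order.
#' @export
ld_prune <- function(geno, prune = prune_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  if (nrow(dos) < 2) stop("LD pruning needs at least 2 samples")
  m <- ncol(dos)
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  # standardize once; mean-impute missing so crossprod gives correlations
  z <- scale(dos)
  z[is.na(z)] <- 0
  const <- attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))
  alive <- rep(TRUE, m)

  for (pass in seq_len(prune$passes)) {
    idx <- which(alive)
    if (length(idx) < 2) break
    starts <- seq(1L, length(idx), by = prune$step_variants)
    for (s in starts) {
      w <- idx[s:min(s + prune$window_variants - 1L, length(idx))]
      w <- w[alive[w]]
      if (length(w) < 2) next
      zc <- z[, w, drop = FALSE]
      r2 <- (crossprod(zc) / (nrow(zc) - 1))^2
      diag(r2) <- 0
      r2[const[w], ] <- 0; r2[, const[w]] <- 0
      repeat {
        mx <- which.max(r2)
        if (r2[mx] <= prune$r2_threshold) break
        ij <- arrayInd(mx, dim(r2))
        vi <- w[ij[1]]; vj <- w[ij[2]]
        drop_local <- if (maf[vi] < maf[vj]) ij[1]
          else if (maf[vj] < maf[vi]) ij[2]
          else if (geno$variant_map$pos[vi] > geno$variant_map$pos[vj]) ij[1]
          else ij[2]
        alive[w[drop_local]] <- FALSE
        r2[drop_local, ] <- 0; r2[, drop_local] <- 0
      }
    }
  }
  geno$variant_map$id[alive]
}

# Randomized range-finder SVD for the top-k left singular vectors; used when
# the standardized matrix is too large for a dense SVD. Deterministic via an
# internal seed.
randomized_svd <- function(z, k, oversample = 10L, power_iter = 4L, seed = 271828L) {
  with_seed(seed, {
    m <- ncol(z)
    l <- min(m, k + oversample)
    omega <- matrix(rnorm(m * l), m, l)
    y <- z %*% omega
    for (i in seq_len(power_iter)) {
      y <- qr.Q(qr(y))
      y <- z %*% crossprod(z, y)
    }
    q <- qr.Q(qr(y))
    b <- crossprod(q, z)            # l x m
    sv <- svd(b, nu = k, nv = k)
    list(u = q %*% sv$u[, seq_len(k), drop = FALSE],
         d = sv$d[seq_len(k)],
         v = sv$v[, seq_len(k), drop = FALSE])
  })
}

#' Principal components of a genotype matrix
#'
#' Columns are mean-centered and variance-standardized (missing dosages are
#' mean-imputed, i.e. zero after centering); PC scores are the left singular
#' vectors scaled by their singular values, ordered by decreasing eigenvalue.
#' Sign convention: the largest-magnitude variant loading of each component
#' is positive. For large matrices the top components are computed with a
#' seeded randomized range-finder SVD (power iterations), which is accurate
#' for the leading structure PCs and keeps the cost linear in matrix size.
#'
#' @param geno a [genotype_matrix()], typically QC'd and LD-pruned.
#' @param k number of components.
#' @return list with `scores` (n x k), `eigenvalues` (length k), `loadings`.
#' @export
compute_pcs <- function(geno, k = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  n <- nrow(dos); m <- ncol(dos)
  if (k > min(n, m)) stop("k exceeds min(n_samples, n_variants)")
  if (k == 0)
    return(list(scores = matrix(0, n, 0), eigenvalues = numeric(0),
                loadings = matrix(0, m, 0)))
  z <- scale(dos)
  z[is.na(z)] <- 0
  z[, attr(z, "scaled:scale") == 0] <- 0
  if (min(n, m) <= 1200) {
    sv <- svd(z, nu = k, nv = k)
    u <- sv$u; d <- sv$d[seq_len(k)]; v <- sv$v
  } else {
    rs <- randomized_svd(z, k)
    u <- rs$u; d <- rs$d; v <- rs$v
  }
  # sign convention
  for (j in seq_len(k)) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- u %*% diag(d, k, k)
  rownames(scores) <- geno$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, eigenvalues = d^2 / (n - 1), loadings = v)
}
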