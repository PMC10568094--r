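# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity by the most direct route available (glm, optim,
# explicit normal equations, exhaustive loops) and share no code with the
# package's own implementations.

# --- small genotype fixtures ------------------------------------------------

# random unlinked genotype matrix with a simple one-chromosome map
make_test_geno <- function(n, m, seed = 1, maf = NULL, chrom = "1",
                           spacing = 10000L, start = 1e6) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
    dos <- sapply(seq_len(m), function(j) rbinom(n, 2, maf[j]))
    map <- data.frame(id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                      pos = as.integer(start + (seq_len(m) - 1) * spacing),
                      effect_allele = "A", other_allele = "G")
    genotype_matrix(dos, map)
  })
}

# continuous-dosage columns with an exact target correlation matrix
# (dosages may be any reals in [0, 2]; correlation is what clumping uses)
make_correlated_geno <- function(n, corr, seed = 1, chrom = "1",
                                 spacing = 10000L) {
  withr::with_seed(seed, {
    m <- nrow(corr)
    z <- matrix(rnorm(n * m), n, m)
    z <- scale(z, center = TRUE, scale = FALSE)
    z <- z %*% solve(chol(crossprod(z) / (n - 1)))  # exactly uncorrelated
    x <- z %*% chol(corr)
    x <- apply(x, 2, function(v) (v - min(v)) / (max(v) - min(v)) * 2)
    map <- data.frame(id = sprintf("c%02d", seq_len(m)), chrom = chrom,
                      pos = as.integer(1e6 + (seq_len(m) - 1) * spacing),
                      effect_allele = "A", other_allele = "G")
    genotype_matrix(x, map)
  })
}

fake_stats <- function(geno, p, beta = NULL, se = NULL) {
  m <- nrow(geno$variant_map)
  if (is.null(beta)) beta <- rep(0.1, m)
  if (is.null(se)) se <- rep(0.05, m)
  summary_stats(data.frame(geno$variant_map, beta = beta, se = se, p = p,
                           maf = pmin(colMeans(geno$dosages) / 2,
                                      1 - colMeans(geno$dosages) / 2)))
}

# --- clumping oracle --------------------------------------------------------

# exhaustive restatement of the greedy clumping rule
oracle_clump <- function(stats, geno, radius_bp, r2_threshold, p_threshold) {
  cand <- stats[!is.na(stats$p) & stats$p <= p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(list())
  cand <- cand[order(cand$p, cand$pos, cand$id), , drop = FALSE]
  dos <- geno$dosages[, match(cand$id, geno$variant_map$id), drop = FALSE]
  taken <- rep(FALSE, nrow(cand))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    taken[i] <- TRUE
    members <- character(0)
    for (j in seq_len(nrow(cand))) {
      if (taken[j]) next
      if (cand$chrom[j] != cand$chrom[i]) next
      if (abs(cand$pos[j] - cand$pos[i]) > radius_bp) next
      r <- suppressWarnings(cor(dos[, i], dos[, j]))
      if (!is.na(r) && r^2 > r2_threshold) {
        taken[j] <- TRUE
        members <- c(members, cand$id[j])
      }
    }
    out[[cand$id[i]]] <- members
  }
  out
}

# --- LD pruning oracle ------------------------------------------------------

oracle_prune <- function(geno, r2_threshold, window, step, passes) {
  dos <- geno$dosages
  maf <- pmin(colMeans(dos, na.rm = TRUE) / 2, 1 - colMeans(dos, na.rm = TRUE) / 2)
  pos <- geno$variant_map$pos
  alive <- rep(TRUE, ncol(dos))
  r2_of <- function(a, b) {
    r <- suppressWarnings(cor(dos[, a], dos[, b], use = "complete.obs"))
    if (is.na(r)) 0 else r^2
  }
  for (pass in seq_len(passes)) {
    idx <- which(alive)
    if (length(idx) < 2) break
    for (s in seq(1, length(idx), by = step)) {
      w <- idx[s:min(s + window - 1, length(idx))]
      repeat {
        w_alive <- w[alive[w]]
        if (length(w_alive) < 2) break
        best <- c(NA, NA); best_r2 <- -1
        for (a in seq_along(w_alive)) for (b in seq_along(w_alive)) {
          if (a >= b) next
          r2 <- r2_of(w_alive[a], w_alive[b])
          if (r2 > best_r2) { best_r2 <- r2; best <- c(w_alive[a], w_alive[b]) }
        }
        if (best_r2 <= r2_threshold) break
        vi <- best[1]; vj <- best[2]
        drop <- if (maf[vi] < maf[vj]) vi else if (maf[vj] < maf[vi]) vj
          else if (pos[vi] > pos[vj]) vi else vj
        alive[drop] <- FALSE
      }
    }
  }
  geno$variant_map$id[alive]
}

# --- likelihood oracles -----------------------------------------------------

oracle_logistic_loglik <- function(x, y) {
  # direct numerical maximization of the binomial log-likelihood
  x <- as.matrix(x)
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(rep(0, ncol(x)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  -fit$value
}

oracle_nagelkerke <- function(y, x0, x1) {
  n <- length(y)
  l0 <- oracle_logistic_loglik(x0, y)
  l1 <- oracle_logistic_loglik(x1, y)
  (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n))
}

# --- weighted least squares oracle (IVW / Egger) ----------------------------

oracle_wls <- function(bx, by, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, bx) else cbind(bx)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * by))
  cov_unit <- solve(XtWX)
  list(coef = unname(drop(coef)), se_unit = unname(sqrt(diag(cov_unit))),
       resid = unname(drop(by - X %*% coef)))
}

# --- AUC by exhaustive pair counting ----------------------------------------

oracle_auc <- function(y, score) {
  pos <- score[y == 1]; neg <- score[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
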