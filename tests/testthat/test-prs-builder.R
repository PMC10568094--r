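test_that("uncorrelated variants each index their own clump", {
  geno <- make_test_geno(400, 8, seed = 61, spacing = 1000L)
  stats <- fake_stats(geno, p = runif(8, 1e-6, 0.05))
  cs <- clump(stats, geno, clump_config(p_threshold = 0.1, r2_threshold = 0.2))
  expect_identical(nrow(cs), 8L)
  expect_true(all(cs$n_members == 0))
})

test_that("a correlated pair clumps under the smaller p-value index", {
  sigma <- matrix(c(1, 0.95, 0.95, 1), 2)
  geno <- make_correlated_geno(500, sigma, seed = 62, spacing = 10000L)
  stats <- fake_stats(geno, p = c(1e-8, 1e-4))
  cs <- clump(stats, geno, clump_config(p_threshold = 0.1))
  expect_identical(nrow(cs), 1L)
  expect_identical(cs$index_id, "c01")
  expect_identical(clump_members(cs)[[1]], "c02")
})

test_that("clump invariants hold and the p threshold is applied first", {
  geno <- make_test_geno(300, 20, seed = 63, spacing = 50000L)
  stats <- fake_stats(geno, p = withr::with_seed(64, runif(20)))
  cs <- clump(stats, geno, clump_config(p_threshold = 0.3))
  mem <- clump_members(cs)
  all_ids <- c(cs$index_id, unlist(mem))
  expect_identical(anyDuplicated(all_ids), 0L)  # no variant in two clumps
  surviving <- stats$id[stats$p <= 0.3]
  expect_setequal(all_ids, surviving)
  for (i in seq_len(nrow(cs))) {
    ip <- cs$index_p[i]
    for (mid in mem[[i]]) {
      expect_lte(ip, stats$p[stats$id == mid])
      expect_lte(abs(stats$pos[stats$id == mid] -
                       stats$pos[stats$id == cs$index_id[i]]), 250000)
    }
  }
  expect_error(clump(stats, subset_genotypes(geno, variants = 1:10),
                     clump_config(p_threshold = 1)), "absent from LD")
})

test_that("greedy clumping equals the exhaustive oracle on random instances", {
  for (seed in 71:90) {
    m <- withr::with_seed(seed, sample(5:40, 1))
    sigma <- withr::with_seed(seed, {
      a <- matrix(rnorm(m * m, 0, 0.5), m, m)
      cov2cor(crossprod(a) + diag(m))
    })
    geno <- make_correlated_geno(150, sigma, seed = seed,
                                 spacing = 40000L)
    p <- withr::with_seed(seed + 1000, runif(m)^2)
    stats <- fake_stats(geno, p = p)
    cfg <- clump_config(radius_bp = 150000L, r2_threshold = 0.25,
                        p_threshold = 0.6)
    cs <- clump(stats, geno, cfg)
    oracle <- oracle_clump(stats, geno, 150000, 0.25, 0.6)
    expect_setequal(cs$index_id, names(oracle))
    for (i in seq_len(nrow(cs)))
      expect_setequal(clump_members(cs)[[i]], oracle[[cs$index_id[i]]])
  }
})

test_that("multi-pass MHC clumping composes passes and accumulates members", {
  # single variant: one clump regardless of schedule
  geno1 <- make_test_geno(100, 1, seed = 65, chrom = "6", start = 30e6)
  stats1 <- fake_stats(geno1, p = 0.001)
  cs1 <- clump_mhc(stats1, geno1, mhc_clump_config())
  expect_identical(nrow(cs1), 1L)

  # three variants with all pairwise r^2 ~ 0.08: pass 1 (r^2 > 0.1) keeps all
  # three indices; passes 2-3 (r^2 > 0.05) merge them into one clump
  sigma <- matrix(sqrt(0.08), 3, 3); diag(sigma) <- 1
  geno3 <- make_correlated_geno(4000, sigma, seed = 66, chrom = "6",
                                spacing = 1000000L)
  geno3$variant_map$pos <- as.integer(c(26e6, 27e6, 28e6))
  geno3 <- genotype_matrix(geno3$dosages, geno3$variant_map)
  r2_obs <- cor(geno3$dosages)^2
  expect_true(all(r2_obs[upper.tri(r2_obs)] > 0.05 &
                    r2_obs[upper.tri(r2_obs)] < 0.1))
  stats3 <- fake_stats(geno3, p = c(1e-8, 1e-6, 1e-4))
  cs3 <- clump_mhc(stats3, geno3, mhc_clump_config(p_threshold = 0.1))
  expect_identical(attr(cs3, "pass_counts"), c(3L, 1L, 1L))
  expect_identical(cs3$index_id, "c01")
  expect_setequal(clump_members(cs3)[[1]], c("c02", "c03"))
})

test_that("MHC pass-by-pass index counts match the oracle run with the schedule", {
  cfg0 <- sim_config(n_samples = 500, n_variants = 200, ld_block_size = 20,
                     within_block_corr = 0.9, seed = 67L)
  geno <- simulate_genotypes(cfg0)
  mhc <- which(variant_regions(geno) == "MHC")
  sub <- subset_genotypes(geno, variants = mhc)
  stats <- fake_stats(sub, p = withr::with_seed(68, runif(length(mhc))^3))
  cfg <- mhc_clump_config(p_threshold = 0.5)
  cs <- clump_mhc(stats, sub, cfg)

  cur <- stats[stats$p <= 0.5, , drop = FALSE]
  counts <- integer(0)
  for (r2 in cfg$r2_schedule) {
    o <- oracle_clump(cur, sub, cfg$radius_bp, r2, 1)
    counts <- c(counts, length(o))
    cur <- cur[cur$id %in% names(o), , drop = FALSE]
  }
  expect_identical(attr(cs, "pass_counts"), counts)
  expect_setequal(cs$index_id, cur$id)
})

test_that("score model assembly thresholds, overrides, and stays monotone", {
  expect_identical(nrow(build_score_model(list(), fake_stats(
    make_test_geno(10, 2, seed = 69), p = c(0.5, 0.5)))), 0L)

  fx <- make_fixture("tiny")
  ph <- fx$phenotypes
  stats <- run_gwas(fx$genotypes, ph, gwas_config(n_pcs = 0, maf_min = 0.01))
  cs <- clump(stats, fx$genotypes, clump_config(p_threshold = 1))
  n_by_thr <- vapply(c(0.1, 0.01, 0.001), function(pt)
    nrow(build_score_model(list(cs), stats, p_threshold = pt)), 0)
  expect_true(all(diff(n_by_thr) <= 0))

  # override: entries inside the region + flank are replaced wholesale
  reg <- variant_regions(fx$genotypes)
  nod2_ids <- fx$genotypes$variant_map$id[reg == "NOD2"]
  fine <- data.frame(id = nod2_ids[1:10],
                     effect_allele = "A", weight = seq(0.1, 1, by = 0.1))
  model <- build_score_model(list(cs), stats, p_threshold = 1,
                             overrides = list(list(region = nod2_region(),
                                                   entries = fine)))
  expect_true(all(fine$id %in% model$id))
  expect_identical(sum(model$region == "NOD2"), 10L)
  expect_equal(model$weight[match(fine$id, model$id)], fine$weight)
  # no P+T entry inside the NOD2 flank survives
  pnt <- model[model$region != "NOD2", ]
  pos <- stats$pos[match(pnt$id, stats$id)]
  chrom <- stats$chrom[match(pnt$id, stats$id)]
  expect_false(any(chrom == "16" & pos >= 50693588 - 3e5 & pos <= 50733081 + 3e5))
})

test_that("scoring is linear, reconciles swapped alleles, and mean-imputes", {
  geno <- make_test_geno(30, 5, seed = 70)
  model <- score_model(data.frame(id = geno$variant_map$id,
                                  effect_allele = "A",
                                  weight = c(0.5, -0.2, 0.3, 0, 0.1)))
  sc <- score_samples(geno, model)
  expect_equal(unname(sc), unname(drop(geno$dosages %*% model$weight)))

  zero <- model; zero$weight <- 0
  expect_true(all(score_samples(geno, score_model(zero)) == 0))

  # a single entry of weight log(2) on a homozygous carrier scores 2*log(2)
  hom <- geno
  hom$dosages[1, 1] <- 2
  hom <- genotype_matrix(hom$dosages, hom$variant_map)
  single <- score_model(data.frame(id = geno$variant_map$id[1],
                                   effect_allele = "A", weight = log(2)))
  expect_equal(unname(score_samples(hom, single)[1]), 2 * log(2),
               tolerance = 1e-12)
  expect_equal(2 * log(2), 1.386, tolerance = 1e-3)

  # swapped allele labels: automatic reconciliation equals the hand-flipped model
  swapped <- model
  swapped$effect_allele[2] <- "G"
  hand <- model
  hand$weight[2] <- -hand$weight[2]  # what the swap means for dosage of A
  expect_equal(score_samples(geno, score_model(swapped)),
               score_samples(geno, score_model(hand)))
  bad <- model; bad$effect_allele[2] <- "T"
  expect_error(score_samples(geno, score_model(bad)), "unresolvable allele")

  # linearity in the weights
  doubled <- model; doubled$weight <- 2 * doubled$weight
  expect_equal(score_samples(geno, score_model(doubled)), 2 * sc)

  # missing dosage contributes weight * 2 * effect-allele frequency
  dos <- geno$dosages
  dos[3, 1] <- NA
  gm <- genotype_matrix(dos, geno$variant_map)
  eaf <- mean(dos[, 1], na.rm = TRUE) / 2
  expected3 <- sum(c(2 * eaf, dos[3, -1]) * model$weight)
  expect_equal(unname(score_samples(gm, model)[3]), expected3)
})

test_that("locus models restrict correctly and degrade to empty with a warning", {
  geno <- make_test_geno(200, 12, seed = 72, chrom = "2", spacing = 100000L)
  stats <- fake_stats(geno, p = withr::with_seed(73, runif(12, 0, 0.05)),
                      beta = rep(0.2, 12))
  empty_reg <- gene_region("EMPTY", "9", 1e6, 2e6)
  expect_warning(m0 <- locus_score_model(stats, geno, empty_reg), "no variants")
  expect_identical(nrow(m0), 0L)

  whole <- gene_region("ALL2", "2", 1, 3e8, flank_bp = 0L)
  m1 <- locus_score_model(stats, geno, whole, clump_config(p_threshold = 0.1))
  cs <- clump(stats, geno, clump_config(p_threshold = 0.1))
  m2 <- build_score_model(list(cs), stats, p_threshold = 0.1)
  expect_setequal(m1$id, m2$id)
  expect_equal(m1$weight[order(m1$id)], m2$weight[order(m2$id)])
})
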