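# ibdprofiler

Differentiating Crohn's disease (CD) from ulcerative colitis (UC) is hard in
5–15% of inflammatory bowel disease (IBD) patients, and getting it wrong has
therapeutic consequences. `ibdprofiler` implements a molecular profiling
pipeline for this *case–case* problem: it quantifies how much a
clumping-and-thresholding polygenic risk score, a panel of serum antibody
biomarkers (ASCA IgA/IgG/IgM, pANCA, anti-CBir1, anti-OmpC, anti-I2), and
smoking status each contribute — alone and jointly — to telling CD from UC
within an IBD cohort. It is aimed at statistical geneticists and
translational IBD researchers who want the full evaluation machinery
(variance decomposition, robustness experiments, Mendelian randomization)
in reproducible, tested R code, together with a synthetic ImmunoChip-style
cohort generator so everything runs without access-restricted patient data.

## The model in brief

Per variant, a case–case logistic scan (CD = 1, UC = 0) with the top ten
principal components as covariates yields log odds ratios β̂. The polygenic
risk score is the P+T sum

&nbsp;&nbsp;&nbsp;&nbsp;PRS_i = Σ_j β̂_j · G_ij

over index variants from greedy LD clumping: radius 250 kb and r² > 0.2
outside the MHC; inside the MHC, three passes with a 5 Mb radius at
r² > 0.1, 0.05, 0.05 (each pass re-clumping the survivors); then a p-value
cut-off. NOD2 entries can be replaced by an external fine-map variant list.
Every performance number is a Nagelkerke pseudo-R² of nested logistic fits,

&nbsp;&nbsp;&nbsp;&nbsp;R²_CS = 1 − exp(2(ℓ₀ − ℓ₁)/n),&nbsp;&nbsp;
R²_N = R²_CS / (1 − exp(2ℓ₀/n)),

with the baseline ℓ₀ being intercept + 10 PCs (marginal) or baseline plus
the other factor blocks (conditional). Uncertainty comes from bootstrap
resampling or repeated 2-fold cross-validation; robustness experiments
retrain the pipeline under misdiagnosis label noise (e.g. the clinical
pattern of 9 CD-misdiagnosed-as-UC per UC-misdiagnosed-as-CD), varying
training size, and varying CD:UC composition. A two-sample Mendelian
randomization module (Wald ratio, fixed-effect IVW, MR-Egger with intercept
and Cochran's Q tests) probes whether subtype causally shifts the
inverse-normal transformed biomarkers.

## Worked example

Simulate a 2,000-sample cohort under the default study conditions (latent
genetic R² = 0.2 concentrated in NOD2-, MHC-like and ten tail loci), train
the score on half, and evaluate the held-out half:

```r
library(ibdprofiler)

cfg   <- default_sim_config(n_samples = 2000, seed = 7L)
geno  <- simulate_genotypes(cfg)
pheno <- simulate_phenotypes(geno, cfg)

train_idx <- 1:1000
qc     <- variant_qc(subset_genotypes(geno, samples = train_idx),
                     qc_config(exclude_regions = NULL))
pruned <- ld_prune(qc$genotypes)
pcs    <- compute_pcs(subset_genotypes(qc$genotypes, variants = pruned), k = 10)
train  <- list(genotypes = subset_genotypes(geno, samples = train_idx),
               phenotypes = pheno[train_idx, ], pcs = pcs$scores)

built <- build_prs_model(train, p_threshold = 0.001)
head(built$model, 4)
#>          id effect_allele    weight region
#> 1  var03554             A 0.8497717   NOD2
#> 2  var03547             A 0.8088107   NOD2
#> 3  var03552             A 0.5526150   NOD2
#> 4  var03561             A 0.4323603   NOD2

test_geno  <- subset_genotypes(geno, samples = 1001:2000)
test_pheno <- pheno[1001:2000, ]
prs    <- score_samples(test_geno, built$model)
pcs_te <- compute_pcs(subset_genotypes(test_geno, variants = pruned), k = 10)$scores
fs     <- factor_set(test_pheno, prs = prs, pcs = pcs_te)

marginal_variance(test_pheno, fs, "prs")
#> marginal variance explained by prs: Nagelkerke R2 = 0.0832 (n = 1000)
marginal_variance(test_pheno, fs, c("prs", "biomarkers", "smoking"))
#> marginal variance explained by prs+biomarkers+smoking: Nagelkerke R2 = 0.4411 (n = 1000)
conditional_variance(test_pheno, fs, "prs", "biomarkers")
#> conditional variance explained by prs: Nagelkerke R2 = 0.0473 (n = 1000)

or_per_sd(test_pheno$subtype, prs, pcs_te)$or
#> [1] 1.734
```

Reading this: on held-out samples the 10-variant genetic score alone
explains about 8% of the CD/UC variation (at n = 1,000 training samples —
the 4,000-sample conditions recover ~15%), the joint model with biomarkers
and smoking about 44%, and conditioning on biomarkers roughly halves the
genetic contribution without removing it — genetics carries subtype
information the serology does not. The odds of CD rise ~1.7-fold per
standard deviation of this small-cohort score.

The methods vignette (`vignettes/ibd-subtype-profiling.Rmd`) documents the
generating model, parameter choices, numerical policies and limitations.

## File formats

Variant-major dosage TSV (columns `id`, `chrom`, `pos`, `effect_allele`,
`other_allele`, then one column per sample; `NA` = missing), PLINK text
`.ped`/`.map` pairs, summary-statistics TSV (`id`, `chrom`, `pos`, alleles,
`beta`, `se`, `p`, `maf`, …), score-model TSV (variant, effect allele,
weight — compatible in spirit with `plink --score`), and phenotype TSV.
Readers and writers round-trip exactly and validate ranges on the way in.

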