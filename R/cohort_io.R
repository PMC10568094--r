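#' Genotype matrix with variant map
#'
#' The central genotype container: an `n_samples x n_variants` additive dosage
#' matrix (count of the effect allele, values in `[0, 2]`, `NA` for missing)
#' together with a variant map giving identity, position and alleles for each
#' column. Column order of `dosages` and row order of `variant_map` are the
#' single source of variant ordering for all downstream steps.
#'
#' @param dosages numeric matrix, samples x variants, values in `[0, 2]` or `NA`.
#' @param variant_map data.frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`; one row per dosage column, same order.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variant_map`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variant_map, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  variant_map <- validate_variant_map(variant_map)
  if (nrow(variant_map) != ncol(dosages))
    stop("variant_map has ", nrow(variant_map), " rows but dosages has ",
         ncol(dosages), " columns")
  if (anyDuplicated(sample_ids))
    stop("sample ids are not unique")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length does not match dosage rows")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosage out of range [0, 2]: found ", format(if (rng[2] > 2) rng[2] else rng[1]))
  dimnames(dosages) <- list(sample_ids, variant_map$id)
  structure(list(dosages = dosages, variant_map = variant_map,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

validate_variant_map <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols))
    stop("variant map lacks columns: ", paste(missing_cols, collapse = ", "))
  map$id <- as.character(map$id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$effect_allele <- toupper(as.character(map$effect_allele))
  map$other_allele <- toupper(as.character(map$other_allele))
  if (anyDuplicated(map$id))
    stop("duplicate variant id: ", map$id[anyDuplicated(map$id)][1])
  if (any(map$pos < 1L, na.rm = TRUE)) stop("variant position must be >= 1")
  bad <- !(map$effect_allele %in% c("A", "C", "G", "T")) |
         !(map$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("allele not in {A,C,G,T} for variant ", map$id[which(bad)[1]])
  same <- map$effect_allele == map$other_allele
  if (any(same))
    stop("effect and other allele identical for variant ", map$id[which(same)[1]])
  rownames(map) <- NULL
  map
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " variants\n", sep = "")
  n_miss <- sum(is.na(x$dosages))
  if (n_miss) cat("  missing dosages: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param geno a [genotype_matrix()].
#' @param samples sample indices, logical mask, or sample ids.
#' @param variants variant indices, logical mask, or variant ids.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(geno, samples = NULL, variants = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(geno$sample_ids)
        else if (is.character(samples)) match(samples, geno$sample_ids)
        else samples
  vi <- if (is.null(variants)) seq_len(nrow(geno$variant_map))
        else if (is.character(variants)) match(variants, geno$variant_map$id)
        else variants
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(vi)) stop("unknown variant id in subset")
  genotype_matrix(geno$dosages[si, vi, drop = FALSE],
                  geno$variant_map[vi, , drop = FALSE],
                  geno$sample_ids[si])
}

#' Read genotypes from a text file
#'
#' Two dialects are supported. `dosage_tsv` is a variant-major TSV: columns
#' `id`, `chrom`, `pos`, `effect_allele`, `other_allele` followed by one
#' column per sample (header row carries the sample ids); missing dosages are
#' coded `NA`. `plink_text` reads a PLINK `.ped`/`.map` pair (`path` names the
#' `.ped`; the `.map` is found by extension swap): allele pairs are converted
#' to effect-allele dosage with the minor allele as effect allele, `0 0` as
#' missing.
#'
#' @param path path to the dosage TSV or the `.ped` file.
#' @param format `"dosage_tsv"` or `"plink_text"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "plink_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         dosage_tsv = read_dosage_tsv(path),
         plink_text = read_plink_text(path))
}

read_dosage_tsv <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, na.strings = "NA"),
    error = function(e) stop("malformed dosage file ", path, ": ", conditionMessage(e)))
  meta_cols <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(meta_cols %in% names(tab)))
    stop("dosage file must start with columns: ", paste(meta_cols, collapse = ", "))
  sample_cols <- setdiff(names(tab), meta_cols)
  if (!length(sample_cols)) stop("dosage file has no sample columns")
  dos <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(dos)) {
    bad_row <- which(apply(dos, 1, function(r) any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r))))[1]
    stop("malformed dosage value at data line ", bad_row, " of ", path)
  }
  storage.mode(dos) <- "double"
  rng <- range(dos, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)[1, ]
    stop("dosage out of range at data line ", bad[1], ": ", dos[bad[1], bad[2]])
  }
  genotype_matrix(t(dos), tab[, meta_cols], sample_ids = sample_cols)
}

read_plink_text <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path)) map_path <- paste0(ped_path, ".map")
  if (!file.exists(map_path)) stop("missing .map companion for ", ped_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed .map file: expected 4 columns")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  n_var <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_var)
    stop("malformed .ped: expected ", 6 + 2 * n_var, " columns, found ", ncol(ped))
  sample_ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_var) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_var), drop = FALSE])
  dos <- matrix(NA_real_, nrow(ped), n_var)
  eff <- oth <- character(n_var)
  for (j in seq_len(n_var)) {
    als <- c(a1[, j], a2[, j])
    obs <- setdiff(unique(als), "0")
    if (!all(obs %in% c("A", "C", "G", "T")))
      stop("allele not in {A,C,G,T} for variant ", map$id[j])
    if (length(obs) > 2) stop("more than two alleles for variant ", map$id[j])
    if (length(obs) == 0) obs <- c("A", "C")  # fully missing column
    counts <- table(factor(als[als != "0"], levels = obs))
    # minor allele is the effect allele
    eff[j] <- names(counts)[which.min(counts)]
    oth[j] <- if (length(obs) == 2) setdiff(obs, eff[j]) else
      setdiff(c("A", "C", "G", "T"), eff[j])[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos[, j] <- (a1[, j] == eff[j]) + (a2[, j] == eff[j])
    dos[miss, j] <- NA_real_
  }
  vm <- data.frame(id = map$id, chrom = as.character(map$chrom), pos = map$pos,
                   effect_allele = eff, other_allele = oth,
                   stringsAsFactors = FALSE)
  genotype_matrix(dos, vm, sample_ids = sample_ids)
}

#' Write genotypes as a variant-major dosage TSV
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  out <- cbind(geno$variant_map,
               as.data.frame(t(geno$dosages), check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score models: variant weights for polygenic scoring
#'
#' A score model is a data.frame with columns `id`, `effect_allele`, `weight`
#' (the per-allele log odds ratio) and optionally `region` (e.g. `"MHC"`,
#' `"NOD2"`, `"other"`), carrying attributes `p_threshold` and `note`. The
#' on-disk form is a tab-separated text file, compatible in spirit with
#' PLINK `--score` input (variant, allele, weight).
#'
#' @param entries data.frame with at least `id`, `effect_allele`, `weight`.
#' @param p_threshold p-value threshold used to build the model (metadata).
#' @param note free-text provenance note (metadata).
#' @return A `score_model` data.frame.
#' @export
score_model <- function(entries, p_threshold = NA_real_, note = "") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("id", "effect_allele", "weight")
  if (!all(need %in% names(entries)))
    stop("score model needs columns: ", paste(need, collapse = ", "))
  if (!"region" %in% names(entries))
    entries$region <- rep("other", nrow(entries))
  entries$id <- as.character(entries$id)
  entries$effect_allele <- toupper(as.character(entries$effect_allele))
  entries$weight <- as.numeric(entries$weight)
  if (anyDuplicated(entries$id))
    stop("duplicate variant id in score model: ",
         entries$id[anyDuplicated(entries$id)][1])
  if (any(!is.finite(entries$weight)))
    stop("non-finite weight for variant ",
         entries$id[which(!is.finite(entries$weight))[1]])
  rownames(entries) <- NULL
  structure(entries, p_threshold = p_threshold, note = note,
            class = c("score_model", "data.frame"))
}

#' @rdname score_model
#' @param model a `score_model`.
#' @param path file path.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname score_model
#' @export
read_score_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  score_model(tab)
}

#' Read and write per-variant association summary statistics
#'
#' Tab-separated with header columns `id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `p`, `maf`, `n_cases`, `n_controls`. `beta`
#' is the log odds ratio for the effect allele. Files whose effect column is
#' an odds ratio can be imported with `or_column = TRUE`, which stores
#' `log(OR)`.
#'
#' @param path file path.
#' @param or_column if `TRUE` the file's `beta` column holds odds ratios and
#'   is log-transformed on import.
#' @return A `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path, or_column = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (or_column) {
    if (any(tab$beta <= 0, na.rm = TRUE)) stop("odds ratio column must be positive")
    tab$beta <- log(tab$beta)
  }
  summary_stats(tab)
}

#' @rdname read_summary_stats
#' @param stats a `summary_stats` data.frame.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname read_summary_stats
#' @param tab data.frame of per-variant results to validate and class.
#' @export
summary_stats <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "p", "maf")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("summary stats lack columns: ", paste(missing_cols, collapse = ", "))
  if (!"n_cases" %in% names(tab)) tab$n_cases <- NA_integer_
  if (!"n_controls" %in% names(tab)) tab$n_controls <- NA_integer_
  tab$id <- as.character(tab$id)
  tab$chrom <- as.character(tab$chrom)
  fin <- is.finite(tab$se)
  if (any(tab$se[fin] <= 0))
    stop("se must be > 0 (variant ", tab$id[fin][which(tab$se[fin] <= 0)[1]], ")")
  fin <- is.finite(tab$p)
  if (any(tab$p[fin] <= 0 | tab$p[fin] > 1))
    stop("p-value outside (0, 1] (variant ",
         tab$id[fin][which(tab$p[fin] <= 0 | tab$p[fin] > 1)[1]], ")")
  rownames(tab) <- NULL
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Read and write phenotype tables
#'
#' One row per sample with columns `sample_id`, `subtype` (CD = 1, UC = 0),
#' `smoking` (`Never` / `Quit` / `Current`), `cd_location` (`colonic` /
#' `small_bowel`, `NA` for UC), `ancestry` (`nonjewish` / `jewish`) and the
#' serum biomarker titers.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @return `read_phenotypes` returns the validated data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

validate_phenotypes <- function(pheno) {
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  if (!"subtype" %in% names(pheno)) stop("phenotypes lack a subtype column")
  if (!all(pheno$subtype %in% c(0L, 1L)))
    stop("subtype must be binary (CD = 1, UC = 0)")
  if ("smoking" %in% names(pheno)) {
    lev <- c("Never", "Quit", "Current")
    if (!all(pheno$smoking %in% lev))
      stop("smoking must be one of: ", paste(lev, collapse = ", "))
  }
  if ("cd_location" %in% names(pheno)) {
    uc_loc <- !is.na(pheno$cd_location) & pheno$subtype == 0
    if (any(uc_loc)) stop("cd_location must be NA for UC samples")
  }
  pheno
}
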