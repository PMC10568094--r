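#' Clumping configurations
#'
#' Standard clumping collapses association signals into independent index
#' variants: radius 250 kb, pairwise r^2 > 0.2 (the in-sample LD of the
#' training genotypes), after restricting to variants with p <= `p_threshold`.
#' The MHC needs its own scheme because of long-range LD: clumping is run
#' three times with a 5 Mb radius, at r^2 > 0.1 the first time and r^2 > 0.05
#' the next two, each later pass re-clumping the surviving index variants.
#'
#' @param radius_bp base-pair radius around the index variant.
#' @param r2_threshold pairwise dosage r^2 above which a variant joins the
#'   index variant's clump.
#' @param p_threshold association p-value cut-off applied before clumping.
#' @return A list of class `clump_config` / `mhc_clump_config`.
#' @export
clump_config <- function(radius_bp = 250000L, r2_threshold = 0.2,
                         p_threshold = 0.1) {
  stopifnot(radius_bp > 0, r2_threshold > 0, r2_threshold < 1,
            p_threshold > 0, p_threshold <= 1)
  structure(list(radius_bp = as.integer(radius_bp),
                 r2_threshold = r2_threshold, p_threshold = p_threshold),
            class = "clump_config")
}

#' @rdname clump_config
#' @param r2_schedule r^2 thresholds for the successive passes.
#' @param region data.frame (`chrom`, `start`, `end`) delimiting the MHC.
#' @export
mhc_clump_config <- function(radius_bp = 5000000L,
                             r2_schedule = c(0.1, 0.05, 0.05),
                             p_threshold = 0.1,
                             region = data.frame(chrom = "6", start = 25e6,
                                                 end = 34e6)) {
  stopifnot(length(r2_schedule) >= 1, all(r2_schedule > 0), all(r2_schedule < 1))
  structure(list(radius_bp = as.integer(radius_bp), r2_schedule = r2_schedule,
                 p_threshold = p_threshold, region = region),
            class = "mhc_clump_config")
}

#' Gene region with flanks
#'
#' @param name gene label (e.g. `"NOD2"`).
#' @param chrom,start_bp,end_bp region coordinates (1-based inclusive).
#' @param flank_bp flank added on both sides when restricting variants.
#' @return A list of class `gene_region`.
#' @export
gene_region <- function(name, chrom, start_bp, end_bp, flank_bp = 300000L) {
  stopifnot(start_bp <= end_bp)
  structure(list(name = name, chrom = as.character(chrom),
                 start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
                 flank_bp = as.numeric(flank_bp)),
            class = "gene_region")
}

#' @rdname gene_region
#' @export
nod2_region <- function(flank_bp = 300000L)
  gene_region("NOD2", "16", 50693588, 50733081, flank_bp)

#' @rdname gene_region
#' @export
mhc_region <- function()
  gene_region("MHC", "6", 25e6, 34e6, flank_bp = 0L)

in_region <- function(chrom, pos, region, use_flank = TRUE) {
  fl <- if (use_flank) region$flank_bp else 0
  chrom == region$chrom & pos >= region$start_bp - fl & pos <= region$end_bp + fl
}

# standardized dosage columns for fast pairwise r^2 against an index variant
standardize_dosages <- function(dos) {
  z <- scale(dos)
  z[is.na(z)] <- 0
  z[, attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))] <- 0
  z
}

#' Greedy LD clumping
#'
#' Variants surviving the p-value cut-off are sorted by ascending p (ties:
#' ascending position, then id). Repeatedly, the best unassigned variant
#' becomes an index, and every unassigned variant on the same chromosome
#' within `radius_bp` whose dosage r^2 with the index exceeds
#' `r2_threshold` joins its clump.
#'
#' @param stats [summary_stats()] for the candidate variants.
#' @param ld_geno [genotype_matrix()] providing in-sample LD (training
#'   cohort); must contain every candidate variant.
#' @param config a [clump_config()].
#' @return A `clump_set`: data.frame (`index_id`, `index_p`, `n_members`)
#'   with a `members` attribute (list of member id vectors, same order).
#' @export
clump <- function(stats, ld_geno, config = clump_config()) {
  stopifnot(inherits(ld_geno, "genotype_matrix"))
  cand <- stats[!is.na(stats$p) & stats$p <= config$p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(empty_clump_set())
  col <- match(cand$id, ld_geno$variant_map$id)
  if (anyNA(col))
    stop("variants absent from LD genotypes: ",
         paste(head(cand$id[is.na(col)], 5), collapse = ", "))
  ord <- order(cand$p, cand$pos, cand$id)
  cand <- cand[ord, , drop = FALSE]
  col <- col[ord]
  z <- standardize_dosages(ld_geno$dosages[, col, drop = FALSE])
  nm1 <- nrow(z) - 1

  k <- nrow(cand)
  assigned <- rep(FALSE, k)
  idx_ids <- character(0); idx_p <- numeric(0); members <- list()
  for (i in seq_len(k)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    near <- which(!assigned & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= config$radius_bp)
    mem <- character(0)
    if (length(near)) {
      r2 <- drop(crossprod(z[, near, drop = FALSE], z[, i]) / nm1)^2
      take <- near[r2 > config$r2_threshold]
      assigned[take] <- TRUE
      mem <- cand$id[take]
    }
    idx_ids <- c(idx_ids, cand$id[i])
    idx_p <- c(idx_p, cand$p[i])
    members[[length(members) + 1]] <- mem
  }
  clump_set(idx_ids, idx_p, members)
}

clump_set <- function(index_id, index_p, members) {
  out <- data.frame(index_id = index_id, index_p = index_p,
                    n_members = lengths(members), stringsAsFactors = FALSE)
  attr(out, "members") <- members
  class(out) <- c("clump_set", "data.frame")
  out
}

empty_clump_set <- function() clump_set(character(0), numeric(0), list())

#' @rdname clump
#' @export
clump_members <- function(clumps) attr(clumps, "members")

#' Multi-pass clumping for the MHC
#'
#' Pass 1 clumps the region's variants at `r2_schedule[1]`; each later pass
#' re-clumps only the surviving index variants at the next r^2 value.
#' Members accumulate: when an index is absorbed, its member set follows it.
#'
#' @param stats [summary_stats()]; only rows inside `config$region` are used.
#' @param ld_geno training-cohort [genotype_matrix()].
#' @param config an [mhc_clump_config()].
#' @return A `clump_set` of the final indices with accumulated members.
#' @export
clump_mhc <- function(stats, ld_geno, config = mhc_clump_config()) {
  reg <- config$region
  inside <- stats$chrom == as.character(reg$chrom) &
    stats$pos >= reg$start & stats$pos <= reg$end
  cur <- stats[inside, , drop = FALSE]
  acc <- list()  # id -> accumulated members
  pass_counts <- integer(0)
  for (r2 in config$r2_schedule) {
    cc <- clump_config(radius_bp = config$radius_bp, r2_threshold = r2,
                       p_threshold = config$p_threshold)
    cs <- clump(cur, ld_geno, cc)
    mem <- clump_members(cs)
    new_acc <- list()
    for (i in seq_along(mem)) {
      id <- cs$index_id[i]
      pool <- mem[[i]]
      inherited <- unlist(c(acc[pool], acc[id]), use.names = FALSE)
      new_acc[[id]] <- unique(c(pool, inherited))
    }
    acc <- new_acc
    pass_counts <- c(pass_counts, nrow(cs))
    cur <- cur[cur$id %in% cs$index_id, , drop = FALSE]
  }
  ord <- order(cur$p, cur$pos, cur$id)
  ids <- cur$id[ord]
  out <- clump_set(ids, cur$p[ord],
                   lapply(ids, function(id) acc[[id]] %||% character(0)))
  attr(out, "pass_counts") <- pass_counts
  out
}

#' Build a P+T score model from clump sets
#'
#' One entry per index variant with p <= `p_threshold`, weighted by its
#' association log-OR. For each override region, all P+T entries inside the
#' region plus flank are removed and replaced by the supplied fine-map
#' variant/weight list (how the NOD2 score is built from fine-mapped
#' putatively causal variants).
#'
#' @param clumpsets list of `clump_set`s (e.g. non-MHC and MHC).
#' @param stats [summary_stats()] holding the weights (log-OR) and positions.
#' @param p_threshold p-value cut-off for index inclusion.
#' @param overrides optional list; each element is a list with `region` (a
#'   [gene_region()]) and `entries` (data.frame `id`, `effect_allele`,
#'   `weight`).
#' @return A [score_model()].
#' @export
build_score_model <- function(clumpsets, stats, p_threshold = 0.1,
                              overrides = NULL) {
  if (inherits(clumpsets, "clump_set")) clumpsets <- list(clumpsets)
  idx <- unlist(lapply(clumpsets, function(cs) cs$index_id), use.names = FALSE)
  if (length(idx)) {
    rows <- match(idx, stats$id)
    if (anyNA(rows)) stop("index variants missing from summary stats: ",
                          paste(head(idx[is.na(rows)], 5), collapse = ", "))
    tab <- stats[rows, , drop = FALSE]
    tab <- tab[!is.na(tab$p) & tab$p <= p_threshold & !is.na(tab$beta), , drop = FALSE]
    entries <- data.frame(id = tab$id, effect_allele = tab$effect_allele,
                          weight = tab$beta,
                          region = region_label(tab$chrom, tab$pos),
                          stringsAsFactors = FALSE)
  } else {
    entries <- data.frame(id = character(0), effect_allele = character(0),
                          weight = numeric(0), region = character(0),
                          stringsAsFactors = FALSE)
  }
  if (!is.null(overrides)) {
    for (ov in overrides) {
      pos <- stats$pos[match(entries$id, stats$id)]
      chrom <- stats$chrom[match(entries$id, stats$id)]
      drop <- !is.na(pos) & in_region(chrom, pos, ov$region, use_flank = TRUE)
      entries <- entries[!drop, , drop = FALSE]
      add <- as.data.frame(ov$entries, stringsAsFactors = FALSE)
      add$region <- ov$region$name
      entries <- rbind(entries, add[, c("id", "effect_allele", "weight", "region")])
    }
  }
  score_model(entries, p_threshold = p_threshold,
              note = "clumping+thresholding")
}

region_label <- function(chrom, pos) {
  lab <- rep("other", length(chrom))
  lab[in_region(chrom, pos, mhc_region(), use_flank = FALSE)] <- "MHC"
  lab[in_region(chrom, pos, nod2_region(0L), use_flank = FALSE)] <- "NOD2"
  lab
}

#' Score samples with a score model
#'
#' `score_i = sum_j weight_j * dosage_ij` over the model's variants. Effect
#' alleles are reconciled against the genotype map: if the model's effect
#' allele is the map's other allele (and vice versa) the weight's sign is
#' flipped; any other mismatch is an error. Missing dosages contribute
#' `weight * 2 * effect-allele frequency` of the scoring cohort
#' (mean imputation).
#'
#' @param geno a [genotype_matrix()] containing every model variant.
#' @param model a [score_model()].
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(geno, model) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(model, "score_model"))
  if (!nrow(model))
    return(stats::setNames(numeric(nrow(geno$dosages)), geno$sample_ids))
  col <- match(model$id, geno$variant_map$id)
  if (anyNA(col))
    stop("model variants missing from genotypes: ",
         paste(head(model$id[is.na(col)], 5), collapse = ", "))
  map <- geno$variant_map[col, , drop = FALSE]
  same <- model$effect_allele == map$effect_allele
  swapped <- model$effect_allele == map$other_allele &
    !same & map$effect_allele %in% c("A", "C", "G", "T")
  if (any(!same & !swapped))
    stop("unresolvable allele mismatch for variant ",
         model$id[which(!same & !swapped)[1]])
  w <- ifelse(same, model$weight, -model$weight)
  dos <- geno$dosages[, col, drop = FALSE]
  if (anyNA(dos)) {
    eaf <- colMeans(dos, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- 2 * eaf[j]
  }
  stats::setNames(drop(dos %*% w), geno$sample_ids)
}

#' Score model restricted to one gene locus
#'
#' Restricts the summary statistics to `region` plus its flank, then clumps,
#' thresholds and builds a score model exactly as [build_score_model()].
#'
#' @param stats [summary_stats()].
#' @param ld_geno training-cohort [genotype_matrix()].
#' @param region a [gene_region()] (300 kb default flank).
#' @param config a [clump_config()].
#' @return A [score_model()]; empty (with a warning) if the region holds no
#'   variants.
#' @export
locus_score_model <- function(stats, ld_geno, region,
                              config = clump_config()) {
  inside <- in_region(stats$chrom, stats$pos, region, use_flank = TRUE)
  sub <- stats[inside, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no variants in region ", region$name)
    return(score_model(data.frame(id = character(0),
                                  effect_allele = character(0),
                                  weight = numeric(0)),
                       p_threshold = config$p_threshold))
  }
  cs <- clump(sub, ld_geno, config)
  build_score_model(list(cs), sub, p_threshold = config$p_threshold)
}
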