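# Derivation of cell-lineage-specific gene modules from a reference
# expression atlas (genes x tissues) by tissue-specificity criteria:
# cross-tissue Z score, expression rank, and a specificity score counting
# tissues with elevated expression.

#' Collapse a multi-feature atlas to one dominant feature per gene
#'
#' Promoter-level atlases measure several features (e.g. CAGE peaks) per
#' gene; for each gene only the feature with the highest mean expression
#' across tissues is retained. Exact ties are broken by the
#' lexicographically smallest feature id. Genes listed in the map but
#' absent from the matrix are dropped with a warning.
#'
#' @param values Numeric matrix, features x tissues, rownames = feature ids.
#' @param feature_map data.frame with columns `feature_id`, `gene_id`; each
#'   feature must map to exactly one gene.
#' @return Gene x tissue matrix (rownames = gene ids) with a
#'   `"feature_used"` attribute naming the retained feature per gene.
#' @export
collapse_to_dominant_feature <- function(values, feature_map) {
  if (!all(c("feature_id", "gene_id") %in% names(feature_map)))
    stopf("feature_map needs columns feature_id and gene_id")
  if (anyDuplicated(feature_map$feature_id))
    stopf("each feature must map to exactly one gene")
  present <- feature_map$feature_id %in% rownames(values)
  lost <- setdiff(feature_map$gene_id, feature_map$gene_id[present])
  if (length(lost))
    warnf("dropping %d gene(s) with no measured feature: %s", length(lost),
          paste(utils::head(lost, 5), collapse = ", "))
  fm <- feature_map[present, , drop = FALSE]
  if (!nrow(fm)) stopf("no features left after matching to the matrix")
  means <- rowMeans(values)[fm$feature_id]
  # order: gene, then -mean, then feature id; first row per gene wins
  ord <- order(fm$gene_id, -means, fm$feature_id)
  fm <- fm[ord, , drop = FALSE]
  keep <- fm[!duplicated(fm$gene_id), , drop = FALSE]
  out <- values[keep$feature_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  attr(out, "feature_used") <- stats::setNames(keep$feature_id, keep$gene_id)
  out
}

#' Z-score an atlas across tissues
#'
#' Scales each gene to mean 0, SD 1 across tissues. Zero-variance
#' (housekeeping-like) genes get an all-zero Z row and are flagged as
#' ineligible for module membership rather than raising an error.
#'
#' @param atlas Gene x tissue non-negative numeric matrix.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Z matrix of the same shape with attribute `"zero_variance"`, a
#'   character vector of excluded gene ids.
#' @export
zscore_tissues <- function(atlas, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (ncol(atlas) < 2) stopf("need at least 2 tissues to Z score")
  z <- scale_rows(atlas, population = sd_type == "population")
  zero <- rownames(atlas)[apply(atlas, 1, function(r) max(r) == min(r))]
  attr(z, "zero_variance") <- zero
  z
}

#' Per-gene tissue specificity statistics
#'
#' For each gene: the cross-tissue Z scores, the rank of every tissue by
#' expression (1 = highest; ties broken higher-value-first then by tissue
#' column order), and the specificity score = number of tissues with
#' Z > `z_spec` (lower = more specific).
#'
#' @param zatlas Z-scored atlas from [zscore_tissues()].
#' @param z_spec Z threshold defining "elevated" for the specificity count
#'   (default 3).
#' @return List with `z`, `rank` (both gene x tissue matrices) and
#'   `specificity` (named integer vector).
#' @export
gene_specificity <- function(zatlas, z_spec = 3) {
  rk <- t(apply(-zatlas, 1, rank, ties.method = "first"))
  dimnames(rk) <- dimnames(zatlas)
  spec <- as.integer(rowSums(zatlas > z_spec))
  names(spec) <- rownames(zatlas)
  list(z = zatlas, rank = rk, specificity = spec)
}

#' Derive the marker-gene module of one tissue
#'
#' A gene belongs to the module of `tissue` when (i) its expression in that
#' tissue ranks in the top `rank_max` tissues, (ii) its Z score there
#' exceeds `z_min`, and (iii) its specificity score (tissues with
#' Z > `z_spec`) is below `spec_max`. Inequalities are strict exactly as
#' stated. Zero-variance genes are ineligible. Genes are returned sorted by
#' descending Z in the target tissue.
#'
#' @param zatlas Z-scored atlas from [zscore_tissues()].
#' @param tissue Tissue (column) identifier.
#' @param z_min Minimum Z in the target tissue (default 5, strict `>`).
#' @param rank_max Maximum rank of the target tissue (default 3, `<=`).
#' @param spec_max Specificity score must be `<` this (default 10).
#' @param z_spec Elevation threshold for the specificity count (default 3).
#' @return A gene module: list with `label`, `genes` (ids, Z-descending),
#'   `z` (named Z values) and `provenance` (criteria snapshot).
#' @export
derive_module <- function(zatlas, tissue, z_min = 5, rank_max = 3,
                          spec_max = 10, z_spec = 3) {
  gs <- gene_specificity(zatlas, z_spec = z_spec)
  .module_from_specificity(gs, attr(zatlas, "zero_variance"), tissue,
                           z_min, rank_max, spec_max, z_spec)
}

.module_from_specificity <- function(gs, zero_variance, tissue, z_min,
                                     rank_max, spec_max, z_spec) {
  if (!tissue %in% colnames(gs$z))
    stopf("unknown tissue '%s'", tissue)
  zt <- gs$z[, tissue]
  keep <- !(rownames(gs$z) %in% zero_variance) &
    gs$rank[, tissue] <= rank_max & zt > z_min & gs$specificity < spec_max
  genes <- rownames(gs$z)[keep]
  genes <- genes[order(-zt[genes])]
  list(label = tissue,
       genes = genes,
       z = zt[genes],
       provenance = list(z_min = z_min, rank_max = rank_max,
                         spec_max = spec_max, z_spec = z_spec,
                         n_tissues = ncol(gs$z)))
}

#' Derive modules for several tissues at once
#'
#' @inheritParams derive_module
#' @param tissues Character vector of tissue ids (default: all columns).
#' @return Named list of gene modules.
#' @export
derive_modules <- function(zatlas, tissues = colnames(zatlas), z_min = 5,
                           rank_max = 3, spec_max = 10, z_spec = 3) {
  gs <- gene_specificity(zatlas, z_spec = z_spec)
  zero <- attr(zatlas, "zero_variance")
  mods <- lapply(tissues, function(t)
    .module_from_specificity(gs, zero, t, z_min, rank_max, spec_max, z_spec))
  names(mods) <- tissues
  mods
}
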