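# Three-group differential expression on RNA-seq counts: median-of-ratios
# normalisation, per-gene negative-binomial GLMs with a likelihood-ratio
# test across pathotypes and pairwise tests, BH FDR, six-way colour-class
# assignment for the polar projection, and clustering of significant genes.

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the gene-wise geometric mean,
#' computed over genes with non-zero counts in every sample, then rescaled
#' so the geometric mean of the factors is 1. When no gene is non-zero in
#' all samples, falls back to library-size normalisation with a warning.
#'
#' @param counts Gene x sample non-negative integer matrix.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  loggm <- rowMeans(log(counts))
  use <- is.finite(loggm)
  if (!any(use)) {
    warnf("no gene with non-zero counts in all samples; using library-size factors")
    sf <- colSums(counts)
    if (any(sf == 0)) stopf("sample with all-zero counts")
    sf <- sf / mean(sf)
  } else {
    sf <- apply(counts[use, , drop = FALSE], 2, function(col)
      stats::median(col / exp(loggm[use])))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments negative-binomial dispersion per gene
#'
#' Estimates the NB dispersion alpha (variance = mu + alpha * mu^2) from
#' size-factor-normalised counts using within-group means and variances:
#' per group, alpha_k = (var_k - mean_k) / mean_k^2; the gene estimate is
#' the (n_k - 1)-weighted average, floored at `floor`. No empirical-Bayes
#' shrinkage is applied. Covariates other than the group factor are ignored
#' for dispersion estimation.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Group label per sample.
#' @param size_factors Optional precomputed size factors.
#' @param floor Lower bound on alpha (default 1e-8; effectively Poisson).
#' @return Named numeric vector of dispersions with attribute `"df"`, the
#'   residual degrees of freedom (n - n_groups) behind the estimate.
#' @export
estimate_dispersion <- function(counts, groups, size_factors = NULL,
                                floor = 1e-8) {
  sf <- size_factors %||% size_factors(counts)
  g <- factor(groups)
  norm <- sweep(counts, 2, sf, "/")
  num <- rep(0, nrow(counts)); den <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    if (length(idx) < 2) next
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- 0
    num <- num + a * (length(idx) - 1)
    den <- den + (length(idx) - 1)
  }
  if (den == 0) stopf("need at least one group with >= 2 samples")
  alpha <- pmax(num / den, floor)
  attr(alpha, "df") <- ncol(counts) - nlevels(g)
  stats::setNames(alpha, rownames(counts))
}

# One NB GLM likelihood-ratio test per gene. The LRT deviance difference is
# referred by default to an F distribution with (df1, dispersion df)
# degrees of freedom, which accounts for the sampling noise of the plug-in
# dispersion at cohort-scale group sizes; `test = "chisq"` gives the
# asymptotic chi-square reference.
.nb_lrt_engine <- function(counts, x_full, x_reduced, sf, dispersion,
                           df1, df2, test) {
  off <- log(sf)
  n <- ncol(counts)
  out <- data.frame(stat = rep(NA_real_, nrow(counts)), p = NA_real_,
                    converged = FALSE)
  rownames(out) <- rownames(counts)
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    fam <- MASS::negative.binomial(1 / dispersion[i])
    fit <- tryCatch({
      ff <- suppressWarnings(stats::glm.fit(x_full, y, family = fam,
                                            offset = off))
      fr <- suppressWarnings(stats::glm.fit(x_reduced, y, family = fam,
                                            offset = off))
      if (!ff$converged || !fr$converged) NULL
      else max(fr$deviance - ff$deviance, 0)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    out$stat[i] <- fit
    out$p[i] <- if (test == "chisq")
      stats::pchisq(fit, df1, lower.tail = FALSE)
    else
      stats::pf(fit / df1, df1, df2, lower.tail = FALSE)
    out$converged[i] <- TRUE
  }
  out
}

.design_matrices <- function(groups, covariates, n) {
  g <- factor(groups)
  df <- data.frame(.group = g)
  covnames <- character(0)
  if (!is.null(covariates) && length(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stopf("covariates must have one row per sample")
    covnames <- names(covariates)
    df <- cbind(df, covariates)
  }
  rhs_red <- if (length(covnames))
    paste("~", paste(covnames, collapse = " + ")) else "~ 1"
  x_reduced <- stats::model.matrix(stats::as.formula(rhs_red), df)
  x_full <- stats::model.matrix(
    stats::as.formula(paste(rhs_red, "+ .group")), df)
  list(full = x_full, reduced = x_reduced, group = g)
}

#' Negative-binomial likelihood-ratio test across groups
#'
#' Fits per-gene NB GLMs of counts on pathotype (plus optional covariates
#' such as batch and sex) with log size-factor offsets and a fixed per-gene
#' dispersion shared between the full and reduced model, and tests the
#' group effect by likelihood ratio. Non-convergent genes are flagged and
#' returned with missing p values.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Group label per sample (2 or more levels, each with at
#'   least 2 samples).
#' @param covariates Optional data.frame of per-sample covariates kept in
#'   both models.
#' @param size_factors,dispersion Optional precomputed normalisation and
#'   dispersion; computed from the data when `NULL`.
#' @param test `"F"` (default) refers the statistic / df1 to an
#'   F(df1, dispersion df) distribution; `"chisq"` uses the asymptotic
#'   chi-square reference.
#' @return data.frame with per-gene `stat`, `p`, `converged`, plus the
#'   dispersion used, with attributes `size_factors` and `df`.
#' @export
fit_nb_lrt <- function(counts, groups, covariates = NULL,
                       size_factors = NULL, dispersion = NULL,
                       test = c("F", "chisq")) {
  test <- match.arg(test)
  g <- factor(groups)
  if (any(table(g) < 2)) stopf("every group needs at least 2 samples")
  sf <- size_factors %||% size_factors(counts)
  disp <- dispersion %||% estimate_dispersion(counts, g, sf)
  dm <- .design_matrices(g, covariates, ncol(counts))
  df1 <- nlevels(g) - 1
  df2 <- attr(disp, "df") %||% (ncol(counts) - nlevels(g))
  res <- .nb_lrt_engine(counts, dm$full, dm$reduced, sf, disp, df1, df2, test)
  res$dispersion <- as.numeric(disp)
  attr(res, "size_factors") <- sf
  attr(res, "df") <- c(df1 = df1, df2 = df2)
  res
}

#' Pairwise negative-binomial tests between two groups
#'
#' Restricts the cohort to one pair of groups and runs the NB
#' likelihood-ratio test with a two-level design (df = 1). Size factors and
#' dispersions estimated on the full cohort may be supplied so all pairwise
#' comparisons share the same normalisation.
#'
#' @inheritParams fit_nb_lrt
#' @param pair Character vector of two group labels.
#' @return As [fit_nb_lrt()], on the subset of samples in `pair`.
#' @export
pairwise_nb_test <- function(counts, groups, pair, covariates = NULL,
                             size_factors = NULL, dispersion = NULL,
                             test = c("F", "chisq")) {
  test <- match.arg(test)
  if (length(pair) != 2 || !all(pair %in% groups))
    stopf("pair must name two groups present in `groups`")
  idx <- which(groups %in% pair)
  sf <- (size_factors %||% size_factors(counts))[idx]
  disp <- dispersion %||% estimate_dispersion(counts, groups)
  df2 <- attr(disp, "df") %||% (length(groups) - length(unique(groups)))
  sub <- counts[, idx, drop = FALSE]
  cov_sub <- if (!is.null(covariates))
    as.data.frame(covariates)[idx, , drop = FALSE] else NULL
  dm <- .design_matrices(droplevels(factor(groups[idx])), cov_sub, length(idx))
  res <- .nb_lrt_engine(sub, dm$full, dm$reduced, sf, disp, 1, df2, test)
  res$dispersion <- as.numeric(disp)
  attr(res, "df") <- c(df1 = 1, df2 = df2)
  res
}

#' Benjamini-Hochberg q values
#'
#' Step-up BH adjustment with monotone enforcement. Missing p values are
#' excluded from the family and returned missing.
#'
#' @param p Numeric vector of p values in \[0, 1\] (NA allowed).
#' @return Numeric vector of q values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Fixed tie-break order for the per-gene reference (minimum-mean) group.
.REF_ORDER <- c("fibroid", "myeloid", "lymphoid")

#' Assign three-way colour classes to genes
#'
#' Implements the six-way colour coding of the three-group volcano: a gene
#' is `gray` unless its likelihood-ratio q value is below `q_threshold`.
#' For significant genes the reference is the group with the minimum mean
#' expression (ties broken fibroid < myeloid < lymphoid); the gene is
#' coloured by which of the other two groups are significantly upregulated
#' versus the reference (pairwise q < `q_threshold` and a positive fold
#' change): one group gives a primary colour (lymphoid = blue, myeloid =
#' red, fibroid = green), two groups a secondary colour (lymphoid+myeloid =
#' purple, myeloid+fibroid = yellow, lymphoid+fibroid = cyan). A
#' significant LRT with no group up versus the reference is an anomaly and
#' stays gray (flagged in the `"anomalies"` attribute).
#'
#' @param group_means Gene x 3 matrix of normalised group mean counts with
#'   columns `lymphoid`, `myeloid`, `fibroid`.
#' @param lrt_q Per-gene likelihood-ratio q values.
#' @param pairwise_q Gene x 3 matrix of pairwise q values with columns
#'   `lymphoid.myeloid`, `myeloid.fibroid`, `lymphoid.fibroid`.
#' @param q_threshold Significance threshold (default 0.05).
#' @return Character vector of colour classes with attributes `ref_group`
#'   and `anomalies`.
#' @export
assign_color_class <- function(group_means, lrt_q, pairwise_q,
                               q_threshold = 0.05) {
  stopifnot(ncol(group_means) == 3, ncol(pairwise_q) == 3)
  n <- nrow(group_means)
  color <- rep("gray", n)
  ref <- rep(NA_character_, n)
  anom <- logical(n)
  pair_key <- function(a, b) {
    k1 <- paste(a, b, sep = "."); k2 <- paste(b, a, sep = ".")
    if (k1 %in% colnames(pairwise_q)) k1 else k2
  }
  primary <- c(lymphoid = "blue", myeloid = "red", fibroid = "green")
  secondary <- c("lymphoid.myeloid" = "purple", "myeloid.fibroid" = "yellow",
                 "fibroid.lymphoid" = "cyan")
  for (i in seq_len(n)) {
    if (is.na(lrt_q[i]) || lrt_q[i] >= q_threshold) next
    m <- group_means[i, .REF_ORDER]
    ref_g <- .REF_ORDER[which.min(m)]   # which.min takes the first tie
    ref[i] <- ref_g
    others <- setdiff(colnames(group_means), ref_g)
    up <- vapply(others, function(g) {
      qv <- pairwise_q[i, pair_key(g, ref_g)]
      !is.na(qv) && qv < q_threshold &&
        group_means[i, g] > group_means[i, ref_g]
    }, logical(1))
    ups <- others[up]
    if (length(ups) == 1) color[i] <- primary[[ups]]
    else if (length(ups) == 2) {
      key <- intersect(names(secondary),
                       c(paste(ups[1], ups[2], sep = "."),
                         paste(ups[2], ups[1], sep = ".")))
      color[i] <- secondary[[key]]
    } else anom[i] <- TRUE
  }
  attr(color, "ref_group") <- ref
  attr(color, "anomalies") <- which(anom)
  color
}

#' Group mean Z scores on the log-normalised matrix
#'
#' Z-scales each gene across all samples of the log-transformed normalised
#' matrix, then averages within groups; these per-group mean Z values feed
#' the polar projection.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Group label per sample.
#' @param size_factors Optional precomputed size factors.
#' @return Gene x group matrix of mean Z scores.
#' @export
group_mean_z <- function(counts, groups, size_factors = NULL) {
  sf <- size_factors %||% size_factors(counts)
  z <- scale_rows(rle_transform(counts, sf))
  g <- factor(groups)
  out <- vapply(levels(g), function(lev)
    rowMeans(z[, g == lev, drop = FALSE]), numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Full three-way differential expression analysis
#'
#' Runs the complete chain on a three-group cohort: size factors,
#' dispersion, likelihood-ratio test across the three pathotypes, the three
#' pairwise tests (each with its own BH family), group means and mean Z
#' scores, log2 fold changes versus the per-gene minimum-mean reference,
#' and colour-class assignment.
#'
#' @inheritParams fit_nb_lrt
#' @param q_threshold Significance threshold for classes (default 0.05).
#' @param lfc_threshold Optional absolute log2-fold-change filter applied
#'   on top of `q_threshold` when declaring significance (default 0 = off).
#' @return data.frame (one row per gene): group means, mean Z per group,
#'   `lrt_p`, `lrt_q`, pairwise p/q columns, `ref_group`, `log2fc_vs_ref`
#'   (maximum across non-reference groups), `color_class`, `dispersion`,
#'   `converged`; attributes `size_factors` and `groups`.
#' @export
run_threeway_de <- function(counts, groups, covariates = NULL,
                            q_threshold = 0.05, lfc_threshold = 0,
                            test = c("F", "chisq")) {
  test <- match.arg(test)
  g <- factor(groups, levels = intersect(.REF_ORDER, unique(groups)))
  if (nlevels(g) != 3)
    stopf("expected the three pathotype groups, got: %s",
          paste(levels(g), collapse = ", "))
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, g, sf)
  lrt <- fit_nb_lrt(counts, g, covariates, sf, disp, test = test)
  norm <- sweep(counts, 2, sf, "/")
  means <- vapply(levels(g), function(lev)
    rowMeans(norm[, g == lev, drop = FALSE]), numeric(nrow(counts)))
  zmeans <- group_mean_z(counts, g, sf)
  pairs <- list(c("lymphoid", "myeloid"), c("myeloid", "fibroid"),
                c("lymphoid", "fibroid"))
  pw_p <- sapply(pairs, function(pr)
    pairwise_nb_test(counts, as.character(g), pr, covariates, sf, disp,
                     test = test)$p)
  colnames(pw_p) <- vapply(pairs, paste, character(1), collapse = ".")
  pw_q <- apply(pw_p, 2, bh_fdr)
  lrt_q <- bh_fdr(lrt$p)

  # log2 fold change of each non-reference group vs the per-gene reference
  ref_idx <- apply(means[, .REF_ORDER, drop = FALSE], 1, which.min)
  ref_group <- .REF_ORDER[ref_idx]
  ref_mean <- means[cbind(seq_len(nrow(means)), match(ref_group, colnames(means)))]
  lfc <- log2((means + 0.5) / (ref_mean + 0.5))
  colnames(lfc) <- paste0("log2fc_", colnames(means))

  eff_q <- lrt_q
  if (lfc_threshold > 0) {
    max_lfc <- apply(lfc, 1, max)
    eff_q[max_lfc <= lfc_threshold] <- 1
  }
  color <- assign_color_class(means, eff_q, pw_q, q_threshold)

  out <- data.frame(
    gene_id = rownames(counts),
    mean_lymphoid = means[, "lymphoid"], mean_myeloid = means[, "myeloid"],
    mean_fibroid = means[, "fibroid"],
    z_lymphoid = zmeans[, "lymphoid"], z_myeloid = zmeans[, "myeloid"],
    z_fibroid = zmeans[, "fibroid"],
    lrt_stat = lrt$stat, lrt_p = lrt$p, lrt_q = lrt_q,
    p_lymphoid.myeloid = pw_p[, 1], q_lymphoid.myeloid = pw_q[, 1],
    p_myeloid.fibroid = pw_p[, 2], q_myeloid.fibroid = pw_q[, 2],
    p_lymphoid.fibroid = pw_p[, 3], q_lymphoid.fibroid = pw_q[, 3],
    ref_group = ref_group, lfc, color_class = as.character(color),
    dispersion = lrt$dispersion, converged = lrt$converged,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "size_factors") <- sf
  attr(out, "groups") <- as.character(g)
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Cluster differentially expressed genes
#'
#' Agglomerative clustering of Z-scaled gene rows with Euclidean distance
#' and Ward linkage, cut into `k` clusters.
#'
#' @param expr Gene x sample matrix restricted to the genes of interest
#'   (usually DE genes on the log scale).
#' @param k Number of clusters (default 4).
#' @return List with `labels` (named cluster assignment), `hclust` (the
#'   tree) and `order` (dendrogram leaf order, for heatmap payloads).
#' @export
cluster_de_genes <- function(expr, k = 4) {
  if (nrow(expr) < 2) stopf("need at least 2 genes to cluster")
  if (k > nrow(expr)) stopf("k = %d exceeds the %d genes", k, nrow(expr))
  z <- scale_rows(expr)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, hclust = hc, order = hc$order)
}
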