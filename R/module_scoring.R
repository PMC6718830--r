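# Eigengene-style module scoring: one summary value per sample from the
# first singular vector of a module's expression submatrix, plus the group
# comparison and tertile utilities used to relate scores to pathotype and
# clinical measures.

#' Variance-stabilising log transform of normalised counts
#'
#' Divides counts by per-sample size factors and applies `log2(x + 1)`.
#' This preserves the variance-stabilised, log-like scale that module
#' scoring assumes; it does not reproduce shrinkage-based regularised-log
#' transforms.
#'
#' @param counts Gene x sample non-negative integer matrix.
#' @param size_factors Per-sample positive reals; computed with
#'   [size_factors()] when `NULL`.
#' @return Gene x sample numeric matrix.
#' @export
rle_transform <- function(counts, size_factors = NULL) {
  sf <- size_factors %||% size_factors(counts)
  if (any(sf <= 0)) stopf("size factors must be positive")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' SVD (eigengene) score of a gene module
#'
#' Scores a module as the first right-singular vector of its row-centred
#' gene x sample submatrix, giving one value per sample with unit norm.
#' The sign is fixed so that the score correlates positively with the
#' module-mean expression profile. Module genes missing from the matrix are
#' dropped with a warning when fewer than half are missing; more missing is
#' an error.
#'
#' @param expr Gene x sample numeric matrix on a log-like scale (e.g. from
#'   [rle_transform()]).
#' @param module A gene module (list with `label` and `genes`) or a plain
#'   character vector of gene ids.
#' @return Named numeric vector of per-sample scores (unit norm), with
#'   attributes `missing_frac` and `var_explained` (share of total variance
#'   carried by the first singular value).
#' @export
svd_score <- function(expr, module) {
  genes <- if (is.list(module)) module$genes else module
  label <- if (is.list(module)) module$label else "module"
  if (ncol(expr) < 2) stopf("need at least 2 samples")
  present <- intersect(genes, rownames(expr))
  missing_frac <- 1 - length(present) / length(genes)
  if (missing_frac >= 0.5)
    stopf("module '%s': %.0f%% of genes absent from the expression matrix",
          label, 100 * missing_frac)
  if (length(present) < 2)
    stopf("module '%s' has fewer than 2 genes in the expression matrix", label)
  if (missing_frac > 0)
    warnf("module '%s': dropping %d absent gene(s)", label,
          length(genes) - length(present))
  x <- expr[present, , drop = FALSE]
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = 0, nv = 1)
  score <- sv$v[, 1]
  profile <- colMeans(x)
  r <- suppressWarnings(stats::cor(score, profile))
  if (!is.na(r) && r < 0) score <- -score
  names(score) <- colnames(expr)
  attr(score, "missing_frac") <- missing_frac
  attr(score, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  score
}

#' Score several modules
#'
#' @inheritParams svd_score
#' @param modules Named list of gene modules.
#' @return Module x sample numeric matrix.
#' @export
score_modules <- function(expr, modules) {
  if (!length(modules)) stopf("no modules supplied")
  labels <- vapply(modules, function(m)
    if (is.list(m)) m$label else NA_character_, character(1))
  labels[is.na(labels)] <- names(modules)[is.na(labels)]
  out <- t(vapply(modules, function(m) as.numeric(svd_score(expr, m)),
                  numeric(ncol(expr))))
  dimnames(out) <- list(labels, colnames(expr))
  out
}

#' Compare module scores across pathotypes
#'
#' One-way ANOVA per module, followed by all pairwise two-sample t tests
#' (pooled variance) with Bonferroni multiplication by the number of
#' comparisons, capped at 1.
#'
#' @param scores Module x sample matrix (or a single named score vector).
#' @param pathotype Character/factor vector of group labels per sample.
#' @return List with `anova` (data.frame: module, f, p) and `pairwise`
#'   (data.frame: module, group1, group2, p, p_bonferroni).
#' @export
anova_across_pathotypes <- function(scores, pathotype) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
    dimnames = list("module", names(scores)))
  g <- factor(pathotype)
  if (nlevels(g) < 2) stopf("need at least 2 groups")
  if (any(table(g) < 2)) stopf("every group needs at least 2 samples")
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(pairs)
  an <- data.frame(module = rownames(scores), f = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
  pw <- do.call(rbind, lapply(rownames(scores), function(mod) {
    y <- scores[mod, ]
    ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
    an[an$module == mod, c("f", "p")] <<- c(unname(ft$statistic), ft$p.value)
    do.call(rbind, lapply(pairs, function(pr) {
      tt <- stats::t.test(y[g == pr[1]], y[g == pr[2]], var.equal = TRUE)
      data.frame(module = mod, group1 = pr[1], group2 = pr[2],
                 p = tt$p.value, p_bonferroni = min(1, tt$p.value * m),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(anova = an, pairwise = pw)
}

#' Tertile summary and linear-regression p for a score against a clinical value
#'
#' Splits samples at the empirical 1/3 and 2/3 quantiles of the module
#' score and summarises the clinical variable per tertile; the p value is
#' the two-sided slope test from a simple linear regression of the clinical
#' value on the continuous score.
#'
#' @param score Numeric module score per sample.
#' @param clinical Numeric clinical values, aligned with `score`.
#' @return List with `tertiles` (data.frame: tertile, n, mean, sd),
#'   `slope`, `p`, `n`, and `degenerate` (`TRUE` for a constant score, in
#'   which case `slope` and `p` are `NA`).
#' @export
tertile_table <- function(score, clinical) {
  keep <- is.finite(score) & is.finite(clinical)
  score <- score[keep]; clinical <- clinical[keep]
  n <- length(score)
  if (n < 6) stopf("need at least 6 complete pairs, got %d", n)
  if (stats::sd(score) == 0) {
    return(list(tertiles = NULL, slope = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  }
  cuts <- stats::quantile(score, c(1 / 3, 2 / 3), names = FALSE)
  tert <- cut(score, c(-Inf, cuts, Inf), labels = c("low", "mid", "high"))
  tl <- data.frame(
    tertile = levels(tert),
    n = as.integer(table(tert)),
    mean = as.numeric(tapply(clinical, tert, mean)),
    sd = as.numeric(tapply(clinical, tert, stats::sd)),
    stringsAsFactors = FALSE)
  fit <- summary(stats::lm(clinical ~ score))
  list(tertiles = tl, slope = fit$coefficients["score", "Estimate"],
       p = fit$coefficients["score", "Pr(>|t|)"], n = n, degenerate = FALSE)
}
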