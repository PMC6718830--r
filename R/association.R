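# Module-trait association statistics: Spearman correlation with per-family
# BH FDR, synovium/blood concordance labels, hypergeometric cell-type
# annotation of gene modules, and binary group comparisons of module scores.

#' Spearman correlation of module scores against clinical traits
#'
#' Correlates every module score with every requested clinical trait using
#' pairwise-complete observations (missing clinical values are never
#' imputed). The BH family is all modules for one trait within one
#' compartment. Tests with a constant vector are flagged degenerate; tests
#' with fewer than 6 complete pairs are flagged insufficient. Both are
#' excluded from the FDR family.
#'
#' @param scores Module x sample matrix (samples in columns).
#' @param clinical data.frame with `sample_id` plus numeric trait columns.
#' @param traits Trait columns to test (default: all numeric columns).
#' @param compartment Label recorded per row (e.g. `"synovium"`, `"blood"`).
#' @return data.frame rows (module, trait, compartment): `n`, `rho`, `p`,
#'   `q`, `flag` (`"ok"`, `"degenerate"` or `"insufficient"`).
#' @export
spearman_module_trait <- function(scores, clinical, traits = NULL,
                                  compartment = "synovium") {
  idx <- match(colnames(scores), clinical$sample_id)
  if (anyNA(idx))
    stopf("clinical table lacks sample(s): %s",
          paste(utils::head(colnames(scores)[is.na(idx)], 5), collapse = ", "))
  clin <- clinical[idx, , drop = FALSE]
  if (is.null(traits)) {
    num <- vapply(clin, is.numeric, logical(1))
    traits <- setdiff(names(clin)[num], "sample_id")
  }
  rows <- expand.grid(module = rownames(scores), trait = traits,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    s <- scores[rows$module[i], ]
    v <- clin[[rows$trait[i]]]
    keep <- is.finite(s) & !is.na(v)
    n <- sum(keep)
    if (n < 6)
      return(data.frame(n = n, rho = NA_real_, p = NA_real_,
                        flag = "insufficient", stringsAsFactors = FALSE))
    if (stats::sd(s[keep]) == 0 || stats::sd(v[keep]) == 0)
      return(data.frame(n = n, rho = NA_real_, p = NA_real_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(s[keep], v[keep], method = "spearman", exact = FALSE))
    data.frame(n = n, rho = unname(ct$estimate), p = ct$p.value, flag = "ok",
               stringsAsFactors = FALSE)
  }))
  out <- cbind(rows, compartment = compartment, res)
  out$q <- NA_real_
  for (tr in unique(out$trait)) {
    sel <- out$trait == tr
    out$q[sel] <- bh_fdr(out$p[sel])
  }
  attr(out, "fdr_family") <- "all modules, per trait, per compartment"
  out
}

#' Classify synovium/blood concordance of module-trait correlations
#'
#' A (module, trait) pair is `both` when it is significant
#' (q < `q_threshold`) in both compartments with the same correlation sign;
#' `synovium_only` / `blood_only` when significant in exactly one
#' compartment; otherwise `neither`. Sign-discordant dual-significant
#' pairs are labelled `neither`.
#'
#' @param synovium,blood Association tables from [spearman_module_trait()],
#'   keyed by (module, trait); keys must match.
#' @param q_threshold Significance threshold (default 0.05).
#' @return data.frame (module, trait): per-compartment rho and q plus
#'   `concordance`.
#' @export
concordance_classify <- function(synovium, blood, q_threshold = 0.05) {
  key_s <- paste(synovium$module, synovium$trait, sep = "\r")
  key_b <- paste(blood$module, blood$trait, sep = "\r")
  miss <- c(setdiff(key_s, key_b), setdiff(key_b, key_s))
  if (length(miss))
    stopf("module-trait keys not tested in both compartments: %s",
          paste(gsub("\r", ":", utils::head(miss, 5)), collapse = ", "))
  b <- blood[match(key_s, key_b), ]
  sig_s <- !is.na(synovium$q) & synovium$q < q_threshold
  sig_b <- !is.na(b$q) & b$q < q_threshold
  same_sign <- sign(synovium$rho) == sign(b$rho)
  lab <- ifelse(sig_s & sig_b & same_sign, "both",
         ifelse(sig_s & !sig_b, "synovium_only",
         ifelse(!sig_s & sig_b, "blood_only", "neither")))
  lab[sig_s & sig_b & !same_sign] <- "neither"
  data.frame(module = synovium$module, trait = synovium$trait,
             rho_synovium = synovium$rho, q_synovium = synovium$q,
             rho_blood = b$rho, q_blood = b$q, concordance = lab,
             stringsAsFactors = FALSE)
}

#' Hypergeometric cell-type annotation of a gene module
#'
#' Tests the overlap of a module with each labelled marker set by the
#' upper-tail hypergeometric probability P(X >= k) with population size
#' |universe|, success count |marker set| and draw count |module|, with BH
#' adjustment across labels. The best (smallest p) label annotates the
#' module.
#'
#' @param module_genes Character vector of gene ids (subset of `universe`).
#' @param marker_sets Named list of marker gene vectors (subsets of
#'   `universe`), e.g. cell types from single-cell profiling.
#' @param universe Character vector of all testable gene ids.
#' @return data.frame per label: `n_set`, `overlap`, `p`, `q`; attribute
#'   `"best_label"`.
#' @export
hypergeom_annotate <- function(module_genes, marker_sets, universe) {
  if (!length(universe)) stopf("empty gene universe")
  if (!length(module_genes)) stopf("empty module")
  universe <- unique(universe)
  if (!all(module_genes %in% universe))
    stopf("module genes outside the universe: %s",
          paste(utils::head(setdiff(module_genes, universe), 5), collapse = ", "))
  module_genes <- unique(module_genes)
  N <- length(universe); m <- length(module_genes)
  res <- do.call(rbind, lapply(names(marker_sets), function(lab) {
    set <- unique(intersect(marker_sets[[lab]], universe))
    k <- length(intersect(module_genes, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), m,
                       lower.tail = FALSE)
    data.frame(label = lab, n_set = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p)
  attr(res, "best_label") <- res$label[which.min(res$p)]
  res
}

#' Compare module scores between two clinical groups
#'
#' Welch two-sample t test of SVD module scores between a binary grouping
#' (ACPA status, erosion progression, EULAR responder vs non-responder),
#' with a standardised mean difference as effect size and BH adjustment
#' across modules. This is a module-level group test on summary scores; it
#' does not reproduce variance-inflation-based set tests.
#'
#' @param scores Module x sample matrix.
#' @param grouping Factor-like vector with exactly two levels, aligned
#'   with the columns of `scores`; both groups need n >= 3.
#' @return data.frame per module: `effect` (standardised difference,
#'   level1 minus level2), `p`, `q`.
#' @export
group_module_test <- function(scores, grouping) {
  g <- factor(grouping)
  g <- droplevels(g[!is.na(g)])
  if (nlevels(g) != 2) stopf("grouping must have exactly two levels")
  keep <- !is.na(grouping)
  if (any(table(factor(grouping[keep])) < 3))
    stopf("both groups need at least 3 samples")
  s <- scores[, keep, drop = FALSE]
  gg <- factor(grouping[keep])
  res <- do.call(rbind, lapply(rownames(scores), function(mod) {
    a <- s[mod, gg == levels(gg)[1]]
    b <- s[mod, gg == levels(gg)[2]]
    sd_pool <- sqrt(((length(a) - 1) * stats::var(a) +
                     (length(b) - 1) * stats::var(b)) /
                    (length(a) + length(b) - 2))
    eff <- if (sd_pool == 0) 0 else (mean(a) - mean(b)) / sd_pool
    p <- if (sd_pool == 0) 1 else stats::t.test(a, b)$p.value
    data.frame(module = mod, effect = eff, p = p, stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p)
  res
}
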