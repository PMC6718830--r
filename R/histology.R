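# Histological pathotype classification from semiquantitative
# immunohistochemistry scores, and pathotype-shift vs clinical-response
# statistics.

HISTOLOGY_SCORE_COLS <- c("CD3", "CD20", "CD68L", "CD68SL", "CD138")

#' Validate a histology score table
#'
#' Checks that all semiquantitative scores are integers in 0-4 (CD3, CD20,
#' CD68 lining/sublining, CD138) and that the CD20+ aggregate grade is an
#' integer in 0-3 (0 = no aggregates scored).
#'
#' @param histology data.frame with columns `sample_id`, `CD3`, `CD20`,
#'   `CD68L`, `CD68SL`, `CD138`, `cd20_aggregate_grade`.
#' @return The validated data.frame, invisibly.
#' @export
validate_histology <- function(histology) {
  req <- c("sample_id", HISTOLOGY_SCORE_COLS, "cd20_aggregate_grade")
  missing <- setdiff(req, names(histology))
  if (length(missing))
    stopf("histology table lacks column(s): %s", paste(missing, collapse = ", "))
  for (col in HISTOLOGY_SCORE_COLS) {
    v <- histology[[col]]
    if (anyNA(v) || any(v != round(v)) || any(v < 0 | v > 4))
      stopf("column %s must hold integer scores in 0-4", col)
  }
  g <- histology$cd20_aggregate_grade
  if (anyNA(g) || any(g != round(g)) || any(g < 0 | g > 3))
    stopf("cd20_aggregate_grade must hold integers in 0-3")
  invisible(histology)
}

#' Classify biopsies into histological pathotypes
#'
#' Applies the three pathotype rules to semiquantitative IHC scores, in
#' precedence order lymphoid > myeloid > fibroid:
#'
#' * **lymphoid** (lympho-myeloid): grade 2-3 CD20+ aggregates with
#'   CD20 >= 2, or CD138 > 2;
#' * **myeloid** (diffuse-myeloid): CD68SL >= 2, CD138 <= 2 and
#'   (CD20 <= 1 or CD3 >= 1), provided the lymphoid rule did not fire;
#' * **fibroid** (pauci-immune): CD68SL < 2 and CD3, CD20, CD138 all < 1.
#'
#' Samples matching no rule are returned as `"ungraded"`; score combinations
#' in rule gaps are a legal outcome, not an error.
#'
#' @param histology A validated histology table (see [validate_histology()]).
#' @return data.frame with columns `sample_id`, `pathotype` (one of
#'   `"lymphoid"`, `"myeloid"`, `"fibroid"`, `"ungraded"`) and `fired_rule`,
#'   naming the branch taken.
#' @export
classify_pathotype <- function(histology) {
  validate_histology(histology)
  cd3 <- histology$CD3; cd20 <- histology$CD20; cd68sl <- histology$CD68SL
  cd138 <- histology$CD138; agg <- histology$cd20_aggregate_grade

  l_agg <- agg >= 2 & cd20 >= 2
  l_pc <- cd138 > 2
  is_l <- l_agg | l_pc
  is_m <- !is_l & cd68sl >= 2 & cd138 <= 2 & (cd20 <= 1 | cd3 >= 1)
  is_f <- !is_l & !is_m & cd68sl < 2 & cd3 < 1 & cd20 < 1 & cd138 < 1

  label <- rep("ungraded", nrow(histology))
  rule <- rep("no rule fired", nrow(histology))
  label[is_l] <- "lymphoid"
  rule[is_l & l_agg] <- "L: grade 2-3 CD20+ aggregates with CD20 >= 2"
  rule[is_l & !l_agg] <- "L: CD138 > 2"
  label[is_m] <- "myeloid"
  rule[is_m] <- "M: CD68SL >= 2, CD138 <= 2, CD20 <= 1 or CD3 >= 1"
  label[is_f] <- "fibroid"
  rule[is_f] <- "F: CD68SL < 2 and CD3, CD20, CD138 < 1"

  data.frame(sample_id = histology$sample_id, pathotype = label,
             fired_rule = rule, stringsAsFactors = FALSE)
}

#' Inflammation ordinal of a pathotype
#'
#' Orders pathotypes by degree of inflammatory infiltrate: fibroid = 0,
#' myeloid = 1, lymphoid = 2. Ungraded samples have no ordinal and raise an
#' error; they are excluded from shift analyses.
#'
#' @param label Character vector of pathotype labels.
#' @return Integer vector of ordinals.
#' @export
inflammation_ordinal <- function(label) {
  ord <- match(label, PATHOTYPE_LEVELS) - 1L
  if (anyNA(ord))
    stopf("no inflammation ordinal for label(s): %s",
          paste(unique(label[is.na(ord)]), collapse = ", "))
  ord
}

#' Correlate pathotype shift with change in disease activity
#'
#' Computes the per-patient shift in inflammation ordinal between baseline
#' and follow-up biopsies (baseline minus follow-up, so positive = became
#' less inflammatory) and its Pearson correlation with the change in DAS28
#' (baseline minus follow-up, positive = improvement). Samples ungraded at
#' either timepoint are dropped pairwise.
#'
#' @param baseline,followup Pathotype call tables from [classify_pathotype()]
#'   (columns `sample_id`, `pathotype`).
#' @param delta_das28 Named numeric vector (names = sample ids) or a numeric
#'   vector aligned with `baseline$sample_id`.
#' @return List with `r`, `p`, `n`, `shift` (named vector used), and
#'   `degenerate` (`TRUE` when either variable has zero variance, in which
#'   case `r` and `p` are `NA` rather than an error).
#' @export
shift_vs_response <- function(baseline, followup, delta_das28) {
  ids <- intersect(baseline$sample_id, followup$sample_id)
  if (is.null(names(delta_das28))) {
    if (length(delta_das28) != nrow(baseline))
      stopf("delta_das28 must be named or aligned with baseline")
    names(delta_das28) <- baseline$sample_id
  }
  b <- baseline$pathotype[match(ids, baseline$sample_id)]
  f <- followup$pathotype[match(ids, followup$sample_id)]
  keep <- b != "ungraded" & f != "ungraded" & !is.na(delta_das28[ids])
  ids <- ids[keep]
  if (length(ids) < 3)
    stopf("fewer than 3 complete graded pairs (%d)", length(ids))
  shift <- inflammation_ordinal(b[keep]) - inflammation_ordinal(f[keep])
  names(shift) <- ids
  dd <- as.numeric(delta_das28[ids])
  if (stats::sd(shift) == 0 || stats::sd(dd) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(ids), shift = shift,
                degenerate = TRUE))
  ct <- stats::cor.test(shift, dd, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids),
       shift = shift, degenerate = FALSE)
}

#' Fisher exact test of shift direction against a binary status
#'
#' Builds the 2x2 contingency table of pathotype shift direction (e.g.
#' improved vs not) against a binary status such as ACPA positivity and
#' returns the two-sided Fisher exact p value.
#'
#' @param shift_direction Factor-like vector with two levels, or a 2x2
#'   matrix of counts (in which case `status` is ignored).
#' @param status Factor-like vector with two levels.
#' @return List with `p` and the 2x2 `table`.
#' @export
contingency_by_acpa <- function(shift_direction, status = NULL) {
  tab <- if (is.matrix(shift_direction)) shift_direction
         else table(shift_direction, status)
  if (!all(dim(tab) == c(2, 2)))
    stopf("need a 2x2 contingency table, got %s", paste(dim(tab), collapse = "x"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency table has an empty margin")
  list(p = stats::fisher.test(tab)$p.value, table = tab)
}
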