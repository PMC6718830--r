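# Synthetic-data generators with planted ground truth: a reference
# expression atlas with planted tissue-specific markers, a three-pathotype
# RNA-seq cohort with planted differential genes and module activities,
# histology consistent with the classification rules, clinical traits with
# calibrated correlations, and 6-month follow-up pathotypes with a planted
# response relationship.

#' Specification of a synthetic reference atlas
#'
#' Defines a gene x tissue expression atlas in which each tissue carries a
#' set of planted marker genes elevated only there, plus a set of "broad"
#' genes elevated across many tissues (which the specificity score must
#' exclude from modules). Effects are on the Z scale of the within-gene
#' noise. With a single elevated tissue the attainable cross-tissue Z is
#' bounded by roughly sqrt(n_tissues), so recovering markers at Z > 5
#' requires a panel of the size of real promoter-level atlases; the default
#' is 200 tissues.
#'
#' @param n_tissues Number of tissues (default 200).
#' @param n_genes Number of genes (default 2000).
#' @param n_markers_per_tissue Planted markers per tissue (default 5).
#' @param marker_effect Marker elevation in noise-SD units (default 8; must
#'   exceed 5 or the markers are unrecoverable under the module criteria).
#' @param n_broad_genes Genes elevated in many tissues (default 50).
#' @param broad_effect Elevation of broad genes in noise-SD units
#'   (default 10).
#' @param n_broad_tissues Tissues in which each broad gene is elevated
#'   (default 12, so broad genes show Z > 3 in >= 10 tissues).
#' @param noise_sd Within-gene expression noise SD (default 1).
#' @param baseline_range Range of per-gene baseline expression levels
#'   (default c(5, 10); keeps values non-negative).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param tissue_names Optional tissue labels (default T001, T002, ...).
#' @return An `"atlas_spec"` list.
#' @export
atlas_spec <- function(n_tissues = 200, n_genes = 2000,
                       n_markers_per_tissue = 5, marker_effect = 8,
                       n_broad_genes = 50, broad_effect = 10,
                       n_broad_tissues = 12, noise_sd = 1,
                       baseline_range = c(5, 10), seed = 1,
                       tissue_names = NULL) {
  spec <- list(
    n_tissues = assert_count(n_tissues, "n_tissues", 2),
    n_genes = assert_count(n_genes, "n_genes"),
    n_markers_per_tissue = assert_count(n_markers_per_tissue,
                                        "n_markers_per_tissue", 0),
    marker_effect = assert_number(marker_effect, "marker_effect"),
    n_broad_genes = assert_count(n_broad_genes, "n_broad_genes", 0),
    broad_effect = assert_number(broad_effect, "broad_effect", 0),
    n_broad_tissues = assert_count(n_broad_tissues, "n_broad_tissues", 0),
    noise_sd = assert_number(noise_sd, "noise_sd", 0, strict = TRUE),
    baseline_range = baseline_range,
    seed = assert_count(seed, "seed", 0),
    tissue_names = tissue_names)
  if (spec$marker_effect <= 5)
    stopf("invariant violated: marker_effect must exceed 5 (markers with smaller effects are unrecoverable under the Z > 5 criterion)")
  if (spec$n_markers_per_tissue * spec$n_tissues + spec$n_broad_genes >
      spec$n_genes)
    stopf("invariant violated: n_markers_per_tissue * n_tissues + n_broad_genes must not exceed n_genes")
  if (spec$n_broad_tissues >= spec$n_tissues)
    stopf("invariant violated: n_broad_tissues must be below n_tissues")
  if (!is.null(tissue_names) && length(tissue_names) != spec$n_tissues)
    stopf("tissue_names must have length n_tissues")
  structure(spec, class = "atlas_spec")
}

#' Generate a synthetic reference atlas with planted markers
#'
#' @param spec An [atlas_spec()].
#' @return List with `atlas` (gene x tissue non-negative matrix) and
#'   `truth`: `marker_map` (tissue -> marker gene ids), `marker_genes`,
#'   `broad_genes`, and the spec.
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(substream_seed(spec$seed, 1))
  genes <- gene_ids(spec$n_genes)
  tissues <- spec$tissue_names %||% sprintf("T%03d", seq_len(spec$n_tissues))
  baseline <- stats::runif(spec$n_genes, spec$baseline_range[1],
                           spec$baseline_range[2])
  m <- baseline + spec$noise_sd *
    matrix(stats::rnorm(spec$n_genes * spec$n_tissues), spec$n_genes)
  dimnames(m) <- list(genes, tissues)

  n_mark <- spec$n_markers_per_tissue * spec$n_tissues
  planted <- sample(spec$n_genes, n_mark + spec$n_broad_genes)
  marker_idx <- planted[seq_len(n_mark)]
  broad_idx <- planted[seq_len(spec$n_broad_genes) + n_mark]

  marker_map <- list()
  if (n_mark) {
    home <- rep(seq_len(spec$n_tissues), each = spec$n_markers_per_tissue)
    m[cbind(marker_idx, home)] <- m[cbind(marker_idx, home)] +
      spec$marker_effect * spec$noise_sd
    marker_map <- split(genes[marker_idx], tissues[home])
    marker_map <- marker_map[tissues[tissues %in% names(marker_map)]]
  }
  for (i in broad_idx) {
    elev <- sample(spec$n_tissues, spec$n_broad_tissues)
    m[i, elev] <- m[i, elev] + spec$broad_effect * spec$noise_sd
  }
  m[m < 0] <- 0
  list(atlas = m,
       truth = list(marker_map = marker_map,
                    marker_genes = genes[marker_idx],
                    broad_genes = genes[broad_idx],
                    spec = spec))
}

DE_CLASSES <- c("L", "M", "F", "LM", "MF", "LF")
.CLASS_GROUPS <- list(L = "lymphoid", M = "myeloid", F = "fibroid",
                      LM = c("lymphoid", "myeloid"),
                      MF = c("myeloid", "fibroid"),
                      LF = c("lymphoid", "fibroid"))
.CLASS_COLOR <- c(L = "blue", M = "red", F = "green",
                  LM = "purple", MF = "yellow", LF = "cyan")

#' Specification of a synthetic three-pathotype cohort
#'
#' Defines an RNA-seq count cohort with three pathotype groups, planted
#' differentially expressed genes in the six up-regulation classes (one or
#' two groups up), planted per-sample module activities driving module
#' genes, histology consistent with each sample's pathotype, and clinical
#' traits with calibrated Spearman correlations against module activities.
#'
#' @param n_per_group Named counts for (lymphoid, myeloid, fibroid);
#'   default c(30, 20, 15), each at least 3.
#' @param n_genes Number of genes (default 2000).
#' @param de_class_sizes Named counts per class `L, M, F, LM, MF, LF`
#'   (default 50 each); their sum must stay below `n_genes`.
#' @param log2_effect Planted log2 fold change of up-regulated classes
#'   (default 2; 0 gives a null cohort).
#' @param dispersion NB dispersion alpha (default 0.1).
#' @param library_size_range Uniform range of per-sample depth factors
#'   (default c(0.7, 1.4)).
#' @param mean_log_mu,sd_log_mu Log-normal grid for gene base means
#'   (defaults log(50) and 1.2).
#' @param clinical_effect_map Optional data.frame with columns `module`,
#'   `trait`, `rho`: planted Spearman correlation between a module activity
#'   and a clinical trait.
#' @param ungraded_frac Fraction of biopsies drawn from rule-gap score
#'   regions so every classifier branch is exercised (default 0.05).
#' @param activity_sd SD of planted per-sample module activity on the log2
#'   expression scale (default 1).
#' @param batch If `TRUE`, adds a binary batch with a mild planted depth
#'   effect and a `batch` annotation column.
#' @param seed Integer seed.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_per_group = c(lymphoid = 30, myeloid = 20,
                                        fibroid = 15),
                        n_genes = 2000,
                        de_class_sizes = c(L = 50, M = 50, F = 50,
                                           LM = 50, MF = 50, LF = 50),
                        log2_effect = 2, dispersion = 0.1,
                        library_size_range = c(0.7, 1.4),
                        mean_log_mu = log(50), sd_log_mu = 1.2,
                        clinical_effect_map = NULL, ungraded_frac = 0.05,
                        activity_sd = 1, batch = FALSE, seed = 1) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("lymphoid", "myeloid", "fibroid")
  if (!setequal(names(n_per_group), c("lymphoid", "myeloid", "fibroid")))
    stopf("n_per_group must name the lymphoid, myeloid and fibroid groups")
  if (any(n_per_group < 3)) stopf("invariant violated: group sizes must be >= 3")
  if (is.null(names(de_class_sizes))) names(de_class_sizes) <- DE_CLASSES
  if (!setequal(names(de_class_sizes), DE_CLASSES))
    stopf("de_class_sizes must name the classes %s",
          paste(DE_CLASSES, collapse = ", "))
  n_genes <- assert_count(n_genes, "n_genes")
  if (sum(de_class_sizes) >= n_genes)
    stopf("invariant violated: sum of de_class_sizes must stay below n_genes")
  if (!is.null(clinical_effect_map)) {
    if (!all(c("module", "trait", "rho") %in% names(clinical_effect_map)))
      stopf("clinical_effect_map needs columns module, trait, rho")
    if (anyDuplicated(clinical_effect_map$trait))
      stopf("each trait may carry at most one planted correlation")
    if (any(abs(clinical_effect_map$rho) >= 1))
      stopf("planted rho must lie in (-1, 1)")
  }
  structure(list(
    n_per_group = n_per_group[c("lymphoid", "myeloid", "fibroid")],
    n_genes = n_genes,
    de_class_sizes = de_class_sizes[DE_CLASSES],
    log2_effect = assert_number(log2_effect, "log2_effect", 0),
    dispersion = assert_number(dispersion, "dispersion", 0, strict = TRUE),
    library_size_range = library_size_range,
    mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
    clinical_effect_map = clinical_effect_map,
    ungraded_frac = assert_number(ungraded_frac, "ungraded_frac", 0),
    activity_sd = assert_number(activity_sd, "activity_sd", 0),
    batch = isTRUE(batch),
    seed = assert_count(seed, "seed", 0)), class = "cohort_spec")
}

# Draw histology scores inside the rule region of each target label.
# "ungraded" draws from a rule gap (low sublining macrophages with T cells
# present) so the no-rule branch is exercised.
.sample_histology_scores <- function(labels) {
  n <- length(labels)
  out <- data.frame(CD3 = integer(n), CD20 = integer(n), CD68L = integer(n),
                    CD68SL = integer(n), CD138 = integer(n),
                    cd20_aggregate_grade = integer(n))
  for (i in seq_len(n)) {
    out[i, ] <- switch(labels[i],
      lymphoid = c(sample(1:4, 1), sample(2:4, 1), sample(0:4, 1),
                   sample(1:4, 1), sample(0:4, 1), sample(2:3, 1)),
      myeloid = c(sample(0:4, 1), sample(0:1, 1), sample(0:4, 1),
                  sample(2:4, 1), sample(0:2, 1), 0L),
      fibroid = c(0L, 0L, sample(0:2, 1), sample(0:1, 1), 0L, 0L),
      ungraded = c(sample(1:4, 1), sample(0:1, 1), sample(0:2, 1),
                   sample(0:1, 1), sample(0:2, 1), 0L),
      stopf("unknown pathotype label '%s'", labels[i]))
  }
  out
}

# Pearson correlation giving a target Spearman under bivariate normality.
.spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws NB counts `NB(mean = mu_g * s_j * 2^effects, dispersion)` where
#' the planted effects are the class up-regulation (`log2_effect` in the
#' sample's group for genes of a matching class) and, for module genes, the
#' sample's planted module activity. Histology scores satisfy the
#' classification rule of each sample's assigned pathotype (apart from the
#' `ungraded_frac` rule-gap draws), and clinical traits attain their
#' planted Spearman correlations against module activity up to sampling
#' noise.
#'
#' @param spec A [cohort_spec()].
#' @param modules Optional named list of gene modules (as from
#'   [derive_module()]) whose genes get planted per-sample activity; all
#'   module genes must belong to the cohort gene universe.
#' @return List with `counts` (gene x sample integer matrix),
#'   `annotations` (sample_id, pathotype, sex, batch), `histology`,
#'   `clinical`, and `truth` (`de_class_map`, `class_color`,
#'   `module_activity` sample x module matrix, `planted_rho`, `mu`,
#'   `library_size`).
#' @export
generate_cohort <- function(spec, modules = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  genes <- gene_ids(spec$n_genes)
  module_genes <- lapply(modules, function(m) if (is.list(m)) m$genes else m)
  names(module_genes) <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    lab <- if (is.list(m)) m$label else names(modules)[i]
    if (is.null(lab) || is.na(lab)) paste0("module", i) else lab
  }, character(1))
  bad <- setdiff(unlist(module_genes), genes)
  if (length(bad))
    stopf("module gene(s) outside the cohort gene universe: %s",
          paste(utils::head(bad, 5), collapse = ", "))

  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  ids <- sample_ids(n)

  # gene base means on a shuffled log-normal quantile grid
  set.seed(substream_seed(spec$seed, 1))
  mu <- stats::qlnorm(stats::ppoints(spec$n_genes), spec$mean_log_mu,
                      spec$sd_log_mu)[sample(spec$n_genes)]
  names(mu) <- genes
  free <- setdiff(genes, unlist(module_genes))
  n_de <- sum(spec$de_class_sizes)
  de_genes <- sample(free, n_de)
  de_class <- rep(DE_CLASSES, spec$de_class_sizes)
  de_class_map <- stats::setNames(de_class, de_genes)

  set.seed(substream_seed(spec$seed, 2))
  activity <- matrix(stats::rnorm(n * length(module_genes),
                                  sd = spec$activity_sd),
                     nrow = n,
                     dimnames = list(ids, names(module_genes)))
  if (!length(module_genes)) activity <- matrix(0, n, 0, dimnames = list(ids, NULL))

  set.seed(substream_seed(spec$seed, 3))
  s <- stats::runif(n, spec$library_size_range[1], spec$library_size_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  batch <- if (spec$batch) sample(c("b1", "b2"), n, replace = TRUE)
           else rep("b1", n)
  log2mu <- outer(log2(mu), log2(s), "+")
  if (spec$batch) log2mu <- log2mu +
    matrix(0.25 * (batch == "b2"), spec$n_genes, n, byrow = TRUE)
  for (cl in DE_CLASSES) {
    gsel <- de_genes[de_class == cl]
    csel <- groups %in% .CLASS_GROUPS[[cl]]
    log2mu[gsel, csel] <- log2mu[gsel, csel] + spec$log2_effect
  }
  for (mod in names(module_genes)) {
    gsel <- module_genes[[mod]]
    log2mu[gsel, ] <- log2mu[gsel, ] +
      matrix(activity[, mod], length(gsel), n, byrow = TRUE)
  }
  counts <- matrix(stats::rnbinom(spec$n_genes * n, mu = 2^log2mu,
                                  size = 1 / spec$dispersion),
                   spec$n_genes, n, dimnames = list(genes, ids))

  set.seed(substream_seed(spec$seed, 4))
  histo_label <- groups
  if (spec$ungraded_frac > 0)
    histo_label[stats::runif(n) < spec$ungraded_frac] <- "ungraded"
  histology <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE),
                     .sample_histology_scores(histo_label))

  clinical <- .generate_clinical(spec, ids, activity)

  list(counts = counts,
       annotations = data.frame(sample_id = ids, pathotype = groups,
                                sex = sex, batch = batch,
                                stringsAsFactors = FALSE),
       histology = histology,
       clinical = clinical,
       truth = list(de_class_map = de_class_map,
                    class_color = stats::setNames(.CLASS_COLOR[de_class_map],
                                                  names(de_class_map)),
                    module_activity = activity,
                    planted_rho = spec$clinical_effect_map,
                    histology_label = stats::setNames(histo_label, ids),
                    mu = mu, library_size = stats::setNames(s, ids),
                    spec = spec))
}

# Clinical traits: plausible baseline distributions, with traits named in
# the effect map rebuilt as calibrated mixtures of module activity and
# Gaussian noise (then monotonically mapped back to the trait's scale,
# which leaves Spearman correlations untouched).
.CLINICAL_BASE <- list(
  DAS28_ESR = function(n) stats::rnorm(n, 5.8, 1.3),
  DAS28_CRP = function(n) stats::rnorm(n, 5.2, 1.2),
  ESR = function(n) stats::rlnorm(n, log(30), 0.6),
  CRP = function(n) stats::rlnorm(n, log(10), 0.9),
  CCP_titer = function(n) stats::rlnorm(n, log(60), 1.4),
  RF_titer = function(n) stats::rlnorm(n, log(40), 1.2),
  VAS_pain = function(n) pmin(100, pmax(0, stats::rnorm(n, 60, 20))),
  HAQ = function(n) pmin(3, pmax(0, stats::rnorm(n, 1.2, 0.6))),
  US_ST_biopsy = function(n) sample(0:3, n, TRUE),
  US_PD_biopsy = function(n) sample(0:3, n, TRUE),
  US_ST_12 = function(n) stats::rnorm(n, 1.3, 0.6),
  US_PD_12 = function(n) stats::rnorm(n, 0.9, 0.5),
  sharp_total = function(n) stats::rlnorm(n, log(8), 1),
  delta_DAS28_CRP = function(n) stats::rnorm(n, 1.5, 1.2),
  delta_ESR = function(n) stats::rnorm(n, 10, 12))

.generate_clinical <- function(spec, ids, activity) {
  set.seed(substream_seed(spec$seed, 5))
  n <- length(ids)
  clin <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (tr in names(.CLINICAL_BASE)) clin[[tr]] <- .CLINICAL_BASE[[tr]](n)
  em <- spec$clinical_effect_map
  if (!is.null(em)) {
    for (i in seq_len(nrow(em))) {
      mod <- em$module[i]; tr <- em$trait[i]
      if (!mod %in% colnames(activity))
        stopf("clinical_effect_map references unknown module '%s'", mod)
      if (!tr %in% names(.CLINICAL_BASE))
        stopf("clinical_effect_map references unknown trait '%s'", tr)
      r <- .spearman_to_pearson(em$rho[i])
      a <- as.numeric(scale(activity[, mod]))
      latent <- r * a + sqrt(1 - r^2) * stats::rnorm(n)
      # monotone map onto the trait's own marginal scale
      base <- sort(clin[[tr]])
      clin[[tr]] <- base[rank(latent, ties.method = "first")]
    }
  }
  # discrete clinical groupings, mildly linked to the first module activity
  driver <- if (ncol(activity)) as.numeric(scale(activity[, 1])) else rep(0, n)
  clin$ACPA_status <- ifelse(stats::runif(n) < stats::plogis(driver), "pos", "neg")
  clin$erosion_progressor <- ifelse(
    stats::runif(n) < stats::plogis(driver - 0.5), "yes", "no")
  clin$EULAR_response <- sample(c("good", "moderate", "none"), n, TRUE,
                                prob = c(0.35, 0.4, 0.25))
  clin
}

#' Generate 6-month follow-up histology and DAS28 response
#'
#' Resamples a follow-up pathotype for every graded baseline biopsy (one
#' ordinal step up, down, or unchanged, truncated at the scale ends), draws
#' rule-consistent follow-up histology scores, and generates the change in
#' DAS28 (baseline minus 6 months, positive = improvement) as
#' `response_strength * shift + noise`, planting a positive correlation
#' between the inflammation-ordinal shift and clinical response. Baseline
#' ungraded samples stay ungraded with pure-noise response.
#'
#' @param baseline_histology Histology table at baseline.
#' @param response_strength Coupling between pathotype shift and change in
#'   DAS28 (0 = uncorrelated).
#' @param noise_sd SD of the response noise (default 1).
#' @param seed Integer seed.
#' @return List with `histology` (follow-up scores), `calls` (follow-up
#'   pathotype calls), `shift` (named baseline-minus-follow-up ordinals,
#'   NA for ungraded) and `delta_das28` (named numeric).
#' @export
generate_followup <- function(baseline_histology, response_strength = 1,
                              noise_sd = 1, seed = 1) {
  response_strength <- assert_number(response_strength, "response_strength")
  base_calls <- classify_pathotype(baseline_histology)
  n <- nrow(base_calls)
  set.seed(substream_seed(seed, 6))
  graded <- base_calls$pathotype != "ungraded"
  ord <- rep(NA_integer_, n)
  ord[graded] <- inflammation_ordinal(base_calls$pathotype[graded])
  step <- sample(c(-1L, 0L, 1L), n, TRUE, prob = c(0.3, 0.4, 0.3))
  new_ord <- pmin(pmax(ord - step, 0L), 2L)
  shift <- ord - new_ord
  new_label <- ifelse(graded, PATHOTYPE_LEVELS[new_ord + 1L], "ungraded")
  followup <- cbind(
    data.frame(sample_id = base_calls$sample_id, stringsAsFactors = FALSE),
    .sample_histology_scores(new_label))
  delta <- response_strength * ifelse(is.na(shift), 0, shift) +
    stats::rnorm(n, 0, noise_sd)
  list(histology = followup,
       calls = classify_pathotype(followup),
       shift = stats::setNames(shift, base_calls$sample_id),
       delta_das28 = stats::setNames(delta, base_calls$sample_id))
}
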