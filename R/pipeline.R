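# End-to-end pipeline orchestration: simulate (optional) -> classify ->
# derive modules -> score -> differential expression -> polar projection ->
# associate -> annotate, with every stage output written to plain-text
# files plus a JSON run manifest. Reruns with an identical configuration
# reproduce identical numeric tables.

#' Build a pipeline configuration
#'
#' With `simulate = TRUE` (default) the pipeline generates its own inputs
#' from [atlas_spec()] / [cohort_spec()]; otherwise `paths` must point to
#' existing counts (TSV), histology (CSV), clinical (CSV), atlas (TSV) and
#' optional modules (GMT) files.
#'
#' @param output_dir Directory for stage outputs (created if needed).
#' @param simulate Generate synthetic inputs with planted truth?
#' @param seed Integer seed for every stochastic stage.
#' @param atlas,cohort Specs used when simulating (defaults applied when
#'   `NULL`).
#' @param module_tissues Tissues whose modules are derived and scored
#'   (default: the first 4 atlas tissues).
#' @param paths Named list of input file paths when `simulate = FALSE`
#'   (`counts`, `histology`, `clinical`, `atlas`, optionally `modules`).
#' @param thresholds Named list: `q_de`, `q_assoc`, `z_min`, `rank_max`,
#'   `spec_max` (defaults 0.05, 0.05, 5, 3, 10).
#' @param radial_mode `"zscore"` or `"fold"` for the polar payload.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(output_dir, simulate = TRUE, seed = 1,
                            atlas = NULL, cohort = NULL,
                            module_tissues = NULL, paths = list(),
                            thresholds = list(), radial_mode = "zscore") {
  th <- utils::modifyList(list(q_de = 0.05, q_assoc = 0.05, z_min = 5,
                               rank_max = 3, spec_max = 10), thresholds)
  if (any(unlist(th) <= 0)) stopf("all thresholds must be positive")
  if (!simulate) {
    req <- c("counts", "histology", "clinical", "atlas")
    missing <- setdiff(req, names(paths))
    if (length(missing))
      stopf("paths must supply: %s", paste(missing, collapse = ", "))
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent))
      stopf("input file(s) not found: %s", paste(absent, collapse = ", "))
  }
  structure(list(output_dir = output_dir, simulate = isTRUE(simulate),
                 seed = assert_count(seed, "seed", 0),
                 atlas = atlas, cohort = cohort,
                 module_tissues = module_tissues, paths = paths,
                 thresholds = th,
                 radial_mode = match.arg(radial_mode, c("zscore", "fold"))),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same fields as [pipeline_config()]; `atlas` and `cohort`
#' entries are passed to [atlas_spec()] / [cohort_spec()] as argument
#' lists.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$atlas)) y$atlas <- do.call(atlas_spec, y$atlas)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes each stage's output under
#' `config$output_dir`: the (optionally simulated) inputs, pathotype calls,
#' derived modules (GMT), module scores (TSV), the differential-expression
#' table (TSV), 2D/3D polar payloads (JSON), module-trait associations
#' (CSV), module annotations (CSV), and `manifest.json` recording the
#' package version, seed, thresholds and input file hashes. Any stage
#' error aborts with the stage name and context.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list with the in-memory stage results and the
#'   output file paths.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  th <- config$thresholds

  if (config$simulate) {
    aspec <- config$atlas %||% atlas_spec(seed = config$seed)
    atlas <- .stage("simulate", generate_atlas(aspec))
    tissues <- config$module_tissues %||%
      utils::head(colnames(atlas$atlas), 4)
    zatlas <- .stage("derive-modules", zscore_tissues(atlas$atlas))
    modules <- .stage("derive-modules",
      derive_modules(zatlas, tissues, z_min = th$z_min,
                     rank_max = th$rank_max, spec_max = th$spec_max))
    cspec <- config$cohort %||% cohort_spec(
      seed = config$seed,
      clinical_effect_map = data.frame(module = tissues[1],
                                       trait = "CCP_titer", rho = 0.5,
                                       stringsAsFactors = FALSE))
    cohort <- .stage("simulate", generate_cohort(cspec, modules))
    counts <- cohort$counts
    histology <- cohort$histology
    clinical <- cohort$clinical
    write_matrix_tsv(atlas$atlas, out("atlas.tsv"))
    write_matrix_tsv(counts, out("counts.tsv"))
    write_sample_csv(histology, out("histology.csv"))
    write_sample_csv(clinical, out("clinical.csv"))
    jsonlite::write_json(
      list(marker_map = atlas$truth$marker_map,
           broad_genes = atlas$truth$broad_genes,
           de_class_map = as.list(cohort$truth$de_class_map),
           planted_rho = cohort$truth$planted_rho),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
    marker_sets <- atlas$truth$marker_map
  } else {
    counts <- .stage("read-inputs",
                     read_matrix_tsv(config$paths$counts, integer_counts = TRUE))
    histology <- .stage("read-inputs", read_sample_csv(config$paths$histology))
    clinical <- .stage("read-inputs", read_sample_csv(config$paths$clinical))
    raw_atlas <- .stage("read-inputs", read_matrix_tsv(config$paths$atlas))
    zatlas <- .stage("derive-modules", zscore_tissues(raw_atlas))
    tissues <- config$module_tissues %||% utils::head(colnames(raw_atlas), 4)
    modules <- .stage("derive-modules",
      derive_modules(zatlas, tissues, z_min = th$z_min,
                     rank_max = th$rank_max, spec_max = th$spec_max))
    marker_sets <- if (!is.null(config$paths$modules))
      read_gmt(config$paths$modules) else NULL
    cohort <- NULL
  }

  calls <- .stage("classify", classify_pathotype(histology))
  utils::write.csv(calls, out("pathotype_calls.csv"), row.names = FALSE)
  write_gmt(modules, out("modules.gmt"))

  groups <- if (!is.null(cohort)) cohort$annotations$pathotype
            else calls$pathotype[match(colnames(counts), calls$sample_id)]
  graded <- groups %in% PATHOTYPE_LEVELS
  if (!all(graded)) {
    counts_g <- counts[, graded, drop = FALSE]
    groups_g <- groups[graded]
  } else {
    counts_g <- counts; groups_g <- groups
  }

  sf <- .stage("score", size_factors(counts))
  expr <- .stage("score", rle_transform(counts, sf))
  scores <- .stage("score", score_modules(expr, modules))
  write_matrix_tsv(scores, out("module_scores.tsv"))

  de <- .stage("de", run_threeway_de(counts_g, groups_g,
                                     q_threshold = th$q_de))
  utils::write.table(de, out("de_results.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  payload <- .stage("project", build_payload(de, config$radial_mode))
  jsonlite::write_json(polar_2d_payload(payload), out("polar_2d.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cylinder_3d_payload(payload), out("polar_3d.json"),
                       auto_unbox = TRUE, digits = NA)

  assoc <- .stage("associate",
                  spearman_module_trait(scores, clinical,
                                        compartment = "synovium"))
  utils::write.csv(assoc, out("associations.csv"), row.names = FALSE)

  annotation <- NULL
  if (!is.null(marker_sets)) {
    annotation <- .stage("annotate", do.call(rbind, lapply(
      names(modules), function(mod) {
        res <- hypergeom_annotate(modules[[mod]]$genes, marker_sets,
                                  rownames(zatlas))
        cbind(module = mod, res)
      })))
    utils::write.csv(annotation, out("module_annotation.csv"),
                     row.names = FALSE)
  }

  inputs <- c("atlas.tsv", "counts.tsv", "histology.csv", "clinical.csv")
  inputs <- inputs[file.exists(out(inputs))]
  manifest <- list(
    package = "tripathotype",
    version = as.character(utils::packageVersion("tripathotype")),
    seed = config$seed,
    thresholds = th,
    radial_mode = config$radial_mode,
    simulate = config$simulate,
    input_md5 = as.list(tools::md5sum(out(inputs))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(calls = calls, modules = modules, scores = scores, de = de,
                 payload = payload, associations = assoc,
                 annotation = annotation, cohort = cohort,
                 manifest = manifest, output_dir = config$output_dir))
}
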