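# End-to-end pipeline: catalog -> refit -> profiles -> interactions ->
# stratified summaries, with a checksummed artifact manifest. All outputs are
# plain text and byte-identical across runs with the same config and seed.

#' Assemble and validate a pipeline configuration
#'
#' @param ssm Path to the SSM TSV input.
#' @param reference Named list mapping each scheme to its reference
#'   signature TSV (a single path is accepted when one scheme is run).
#' @param out_dir Output directory (created if needed).
#' @param schemes Channel schemes to run.
#' @param annotations Optional annotation TSV (`sample_id`, `grade`,
#'   `subtype`, `hrd_score`, `biallelic_hrd_gene`).
#' @param stratifier Optional annotation column for stratified comparison
#'   (`"grade"`, `"hrd_status"`, or any annotation column).
#' @param threshold,min_mutations Presence-calling parameters.
#' @param prune_threshold NNLS refit pruning threshold.
#' @param alpha,adjust Interaction-calling parameters.
#' @param seed Integer seed governing every stochastic step.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(ssm, reference, out_dir,
                            schemes = c("SBS96", "DBS78", "ID83"),
                            annotations = NULL, stratifier = NULL,
                            threshold = 0.05, min_mutations = 10L,
                            prune_threshold = 0.01,
                            alpha = 0.05, adjust = "BH", seed = 1L) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (!is.list(reference)) {
    if (length(schemes) != 1L)
      stop("reference must be a named list with one path per scheme")
    reference <- stats::setNames(list(reference), schemes)
  }
  missing_ref <- setdiff(schemes, names(reference))
  if (length(missing_ref) > 0)
    stop("no reference signatures configured for scheme(s): ",
         paste(missing_ref, collapse = ", "))
  for (p in c(ssm, unlist(reference[schemes]), annotations)) {
    if (!file.exists(p)) stop("configured input file does not exist: ", p)
  }
  stopifnot(threshold > 0, threshold < 1, min_mutations >= 0,
            alpha > 0, alpha < 1, adjust %in% c("BH", "none"))
  if (!is.null(stratifier) && is.null(annotations))
    stop("a stratifier requires an annotations file")
  structure(list(
    ssm = ssm, reference = reference, out_dir = out_dir, schemes = schemes,
    annotations = annotations, stratifier = stratifier,
    threshold = threshold, min_mutations = as.integer(min_mutations),
    prune_threshold = prune_threshold, alpha = alpha, adjust = adjust,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]. Relative input paths are resolved against the YAML
#'   file's directory.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  raw$ssm <- resolve(raw$ssm)
  raw$annotations <- resolve(raw$annotations)
  if (!is.null(raw$reference)) raw$reference <- lapply(raw$reference, resolve)
  raw$schemes <- unlist(raw$schemes)
  do.call(pipeline_config, raw)
}

#' Run the full signature-analysis pipeline
#'
#' Executes, per configured scheme: catalog construction from the SSM file,
#' NNLS exposure refitting against the scheme's reference signatures,
#' per-sample profile and presence derivation, pairwise interaction testing,
#' and (when configured) stratified cohort comparison. Every output table is
#' written as TSV under `out_dir` and listed, with its MD5 checksum, in
#' `manifest.json`. The run is fully deterministic given the config and
#' seed. Any stage failure raises an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("read_ssm", read_ssm(config$ssm))
  annotations <- NULL
  if (!is.null(config$annotations)) {
    annotations <- stage("annotations",
      readr::read_tsv(config$annotations, show_col_types = FALSE,
                      progress = FALSE))
    if ("biallelic_hrd_gene" %in% names(annotations))
      annotations$biallelic_hrd_gene <- as.logical(annotations$biallelic_hrd_gene)
    if (all(c("biallelic_hrd_gene", "hrd_score") %in% names(annotations)))
      annotations <- split_hrd_status(annotations)
  }

  for (scheme in config$schemes) {
    sfx <- tolower(scheme)
    catalog <- stage(paste0("catalog_", sfx),
                     build_catalog(records, scheme))
    emit(tibble::as_tibble(catalog), paste0("catalog_", sfx, ".tsv"))
    reference <- stage(paste0("reference_", sfx),
                       read_signatures(config$reference[[scheme]], scheme))
    exposures <- stage(paste0("refit_", sfx),
                       refit_exposures(catalog, reference,
                                       config$prune_threshold))
    emit(exposures$absolute, paste0("exposures_absolute_", sfx, ".tsv"))
    emit(exposures$relative, paste0("exposures_relative_", sfx, ".tsv"))
    profiles <- stage(paste0("profiles_", sfx),
                      sample_profiles(exposures, catalog,
                                      threshold = config$threshold,
                                      min_mutations = config$min_mutations))
    emit(profiles, paste0("profiles_", sfx, ".tsv"))
    presence <- attr(profiles, "presence")
    emit(presence, paste0("presence_", sfx, ".tsv"))
    interactions <- stage(paste0("interactions_", sfx),
                          interaction_matrix(presence, alpha = config$alpha,
                                             adjust = config$adjust))
    emit(tibble::as_tibble(interactions),
         paste0("interactions_", sfx, ".tsv"))
    if (!is.null(config$stratifier)) {
      strata <- stage(paste0("stratify_", sfx),
                      stratified_compare(profiles, annotations,
                                         config$stratifier,
                                         seed = config$seed))
      emit(strata$summaries, paste0("stratified_summary_", sfx, ".tsv"))
      emit(strata$enrichment, paste0("stratified_enrichment_", sfx, ".tsv"))
      if (nrow(strata$distribution_tests) > 0)
        emit(strata$distribution_tests,
             paste0("stratified_distributions_", sfx, ".tsv"))
    }
  }

  manifest <- tibble::tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  manifest_payload <- list(
    seed = config$seed,
    schemes = config$schemes,
    parameters = list(
      threshold = config$threshold, min_mutations = config$min_mutations,
      prune_threshold = config$prune_threshold,
      alpha = config$alpha, adjust = config$adjust
    ),
    outputs = manifest
  )
  jsonlite::write_json(manifest_payload,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
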