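# End-to-end orchestration from a single structured configuration: TSS
# calling per condition, term-seq 3'-terminus calling, processing-site
# integration, TU annotation, promoter modeling and terminator mapping, with
# a manifest sufficient for deterministic re-runs.

.default_thresholds <- function() {
  list(fdr = 0.05, percentile = 95, windows = c(13L, 51L, 251L, 501L, 1001L),
       min_replicates = 2L, max_leader = 650L, leaderless_max = 5L,
       coalesce = 10L, refine = 15L, spacer = 12:22, disc = 3:12,
       fold = 10)
}

#' Validate a pipeline run configuration
#'
#' @param config List with `conditions` (named; each holding lists `treated`,
#'   `untreated`, `term` of `end_coverage_track`), optional `genome`
#'   (`DNAStringSet`), `genes` (gene table), `terminators` (prediction
#'   table), `thresholds` (partial override of the defaults), `seed`.
#' @return The completed config (thresholds filled in).
#' @export
validate_run_config <- function(config) {
  if (is.null(config$conditions) || !length(config$conditions)) {
    stop("config validation error: no conditions")
  }
  th <- utils::modifyList(.default_thresholds(), config$thresholds %||% list())
  if (any(vapply(th[c("fdr", "percentile", "min_replicates", "max_leader",
                      "coalesce", "refine", "fold")], function(x) x <= 0,
                 logical(1)))) {
    stop("config validation error: thresholds must be positive")
  }
  for (cn in names(config$conditions)) {
    cond <- config$conditions[[cn]]
    if (length(cond$treated %||% list()) < 2 ||
        length(cond$untreated %||% list()) < 2) {
      stop("config validation error: condition ", cn,
           " needs >= 2 treated and >= 2 untreated libraries")
    }
  }
  config$thresholds <- th
  config$seed <- config$seed %||% 1L
  config
}

#' Read a YAML run configuration (sample sheet of coverage files)
#'
#' The YAML mirrors [validate_run_config()]'s structure, with library entries
#' given as file pairs: `{plus: ..., minus: ..., dialect: ..., replicate: ...}`.
#'
#' @param path YAML file.
#' @param seqlengths Named replicon lengths for the coverage readers.
#' @return A config list ready for [run_pipeline()] (tracks loaded).
#' @export
read_run_config <- function(path, seqlengths) {
  y <- yaml::read_yaml(path)
  load_lib <- function(entry, kind, cn) {
    read_end_coverage(c(plus = entry$plus, minus = entry$minus),
                      dialect = entry$dialect %||% "bedgraph_pair",
                      seqlengths = seqlengths,
                      library_id = entry$id %||% basename(entry$plus),
                      condition_id = cn,
                      replicate_id = as.character(entry$replicate %||% ""),
                      library_kind = kind)
  }
  conditions <- lapply(names(y$conditions), function(cn) {
    cond <- y$conditions[[cn]]
    list(treated = lapply(cond$treated, load_lib, kind = "tss_treated",
                          cn = cn),
         untreated = lapply(cond$untreated, load_lib, kind = "tss_untreated",
                            cn = cn),
         term = lapply(cond$term, load_lib, kind = "termseq", cn = cn))
  })
  names(conditions) <- names(y$conditions)
  list(conditions = conditions, thresholds = y$thresholds, seed = y$seed)
}

#' Run the full transcript-boundary pipeline
#'
#' Stage order: per-condition TSS calling, condition merge, term-seq
#' 3'-terminus calling, 5'-monophosphoryl integration and
#' processing-vs-termination classification with cross-condition pooling,
#' TSS-to-gene annotation, promoter-window extraction and model building
#' (when a genome is supplied), and terminator mapping (when predictions are
#' supplied). Outputs are pure functions of (inputs, thresholds, seed).
#'
#' @param config See [validate_run_config()].
#' @param out_dir Optional directory for TSV/PFM outputs.
#' @return List of class `tuatlas_run`: stage outputs plus a `manifest` of
#'   counts, thresholds, seed and a config digest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  th <- config$thresholds
  spec <- dynamic_lambda_spec(th$windows)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tss_per_cond <- stage("tss_calling", lapply(
    names(config$conditions), function(cn) {
      cond <- config$conditions[[cn]]
      call_tss_condition(cond$treated, cond$untreated, condition_id = cn,
                         fdr_threshold = th$fdr, percentile = th$percentile)
    }))
  names(tss_per_cond) <- names(config$conditions)
  merged_tss <- stage("merge_conditions", merge_conditions(tss_per_cond))
  prelim_per_cond <- stage("tts_calling", lapply(
    names(config$conditions), function(cn) {
      cond <- config$conditions[[cn]]
      if (!length(cond$term %||% list())) return(NULL)
      call_tts_condition(cond$term, percentile = th$percentile,
                         fdr_threshold = th$fdr, spec = spec,
                         min_replicates = th$min_replicates,
                         condition_id = cn)
    }))
  names(prelim_per_cond) <- names(config$conditions)
  genes <- config$genes %||% .gene_record_df(character(), character(),
                                             integer(), integer(),
                                             character(), character())
  classifications <- stage("end_integration", {
    out <- list()
    for (cn in names(config$conditions)) {
      if (is.null(prelim_per_cond[[cn]])) next
      mono <- call_monophosphate_sites(
        config$conditions[[cn]]$untreated,
        tss_catalog = rbind(tss_per_cond[[cn]],
                            merged_tss[, names(tss_per_cond[[cn]])]),
        percentile = th$percentile, fdr_threshold = th$fdr, spec = spec,
        min_replicates = th$min_replicates, condition_id = cn)
      out[[cn]] <- classify_termini(prelim_per_cond[[cn]], mono, genes)
    }
    pool_processing_sites(out)
  })
  tts_final <- do.call(rbind, lapply(classifications, function(cl) cl$tts))
  annotation <- stage("tu_annotation", {
    if (nrow(genes) && nrow(merged_tss)) {
      assign_tss_to_genes(merged_tss, genes, th$max_leader, th$leaderless_max)
    } else NULL
  })
  refined <- stage("refine_tss", refine_for_promoter_model(merged_tss,
                                                           th$refine))
  promoters <- stage("coalesce_tss", coalesce_tss(merged_tss, th$coalesce))
  promoter_model <- stage("promoter_model", {
    if (!is.null(config$genome) && nrow(refined) >= 50) {
      windows <- extract_promoter_windows(refined, config$genome)
      if (nrow(windows) >= 50) {
        build_promoter_model(windows, disc_range = th$disc,
                             spacer_range = th$spacer, seed = config$seed)
      } else NULL
    } else NULL
  })
  terminator_matches <- stage("terminator_analysis", {
    if (!is.null(config$terminators) && !is.null(tts_final) &&
        nrow(tts_final)) {
      map_tts_to_terminators(tts_final, config$terminators)
    } else NULL
  })
  manifest <- list(
    seed = config$seed, thresholds = th,
    config_digest = sum(utils::object.size(config)),
    counts = list(
      conditions = length(config$conditions),
      tss_per_condition = vapply(tss_per_cond, nrow, integer(1)),
      merged_tss = nrow(merged_tss),
      refined_tss = nrow(refined),
      promoters = nrow(promoters),
      prelim_3prime = vapply(prelim_per_cond, function(x) {
        if (is.null(x)) 0L else nrow(x)
      }, integer(1)),
      tts = if (is.null(tts_final)) 0L else nrow(tts_final),
      processing = sum(vapply(classifications, function(cl) {
        nrow(cl$processing)
      }, integer(1))),
      tss_gene_pairs = if (is.null(annotation)) 0L else nrow(
        annotation$pairs),
      terminator_matches = if (is.null(terminator_matches)) 0L else nrow(
        terminator_matches)))
  run <- structure(list(tss_per_condition = tss_per_cond,
                        merged_tss = merged_tss, refined_tss = refined,
                        promoters = promoters,
                        prelim_3prime = prelim_per_cond,
                        classifications = classifications, tts = tts_final,
                        annotation = annotation,
                        promoter_model = promoter_model,
                        terminator_matches = terminator_matches,
                        manifest = manifest), class = "tuatlas_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_site_catalog(merged_tss, file.path(out_dir, "tss_merged.tsv"))
    if (!is.null(tts_final)) {
      write_site_catalog(tts_final, file.path(out_dir, "tts.tsv"))
    }
    if (!is.null(run$promoter_model)) {
      write_pfm(run$promoter_model$minus10,
                file.path(out_dir, "minus10_pfm.txt"))
      write_pfm(run$promoter_model$minus35,
                file.path(out_dir, "minus35_pfm.txt"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.tuatlas_run <- function(x, ...) {
  cat("<tuatlas_run>\n")
  utils::str(x$manifest$counts, give.attr = FALSE)
  invisible(x)
}
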