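# Classification of preliminary 3' termini into RNA processing sites versus
# transcription termination sites, by integrating 5'-monophosphoryl sites
# called from RppH-untreated TSS-seq coverage, the tRNA rule, and
# cross-condition pooling of processing sites.

#' Call 5'-monophosphoryl RNA sites from RppH-untreated TSS-seq libraries
#'
#' Applies the same Poisson / BH / replicate-consensus machinery used for
#' preliminary 3' termini to the untreated 5'-end tracks of a condition, then
#' removes every position present in the TSS catalog (primary and, by
#' default, secondary TSSs).
#'
#' @param untreated List of `tss_untreated` `end_coverage_track` replicates.
#' @param tss_catalog Merged TSS catalog whose positions are excluded.
#' @param include_secondary Also exclude secondary TSS positions (default
#'   TRUE).
#' @inheritParams call_tts_condition
#' @return Site catalog of `monophosphate_5p` sites.
#' @export
call_monophosphate_sites <- function(untreated, tss_catalog = NULL,
                                     include_secondary = TRUE,
                                     percentile = 95, fdr_threshold = 0.05,
                                     spec = dynamic_lambda_spec(),
                                     min_replicates = 2, condition_id = "") {
  per_sample <- lapply(untreated, call_three_prime_ends,
                       percentile = percentile,
                       fdr_threshold = fdr_threshold, spec = spec,
                       site_kind = "monophosphate_5p")
  mono <- combine_replicates(per_sample, min_replicates, condition_id,
                             site_kind = "monophosphate_5p")
  if (!is.null(tss_catalog) && nrow(tss_catalog) && nrow(mono)) {
    tss <- tss_catalog
    if (!include_secondary) {
      tss <- tss[tss$site_kind != "tss_secondary", , drop = FALSE]
    }
    drop <- .pos_key(mono$replicon_id, mono$strand, mono$position) %in%
      .pos_key(tss$replicon_id, tss$strand, tss$position)
    mono <- mono[!drop, , drop = FALSE]
    rownames(mono) <- NULL
  }
  mono
}

#' Classify preliminary 3' termini as processing sites or TTSs
#'
#' A preliminary 3' terminus with a 5'-monophosphoryl site at the immediately
#' downstream position (same strand) is a processing site, as is any 3'
#' terminus overlapping a same-strand tRNA. A 3' terminus whose paired
#' 5'-monophosphoryl site sits at its own position or immediately upstream
#' violates the expected cleavage geometry and is removed (reason
#' `upstream_5p_conflict`). Everything else is a TTS.
#'
#' @param prelim Site catalog of `prelim_3prime` sites (one condition).
#' @param mono Site catalog of `monophosphate_5p` sites (same condition).
#' @param genes Gene table (see [read_gene_annotations()]); only tRNA rows are
#'   used.
#' @param pair_offset Adjacency tolerance in nt (default 1).
#' @return List of class `termini_classification`: `processing`, `tts`,
#'   `removed` (with a `reason` column); the three parts partition `prelim`.
#' @export
classify_termini <- function(prelim, mono, genes, pair_offset = 1L) {
  n <- nrow(prelim)
  mono_key <- if (nrow(mono)) .pos_key(mono$replicon_id, mono$strand,
                                       mono$position) else character()
  down <- downstream_pos(prelim$position, prelim$strand, pair_offset)
  up <- downstream_pos(prelim$position, prelim$strand, -pair_offset)
  has_down <- .pos_key(prelim$replicon_id, prelim$strand, down) %in% mono_key
  has_self <- .pos_key(prelim$replicon_id, prelim$strand,
                       prelim$position) %in% mono_key
  has_up <- .pos_key(prelim$replicon_id, prelim$strand, up) %in% mono_key
  trna <- genes[genes$feature_class == "tRNA", , drop = FALSE]
  in_trna <- vapply(seq_len(n), function(i) {
    any(trna$replicon_id == prelim$replicon_id[i] &
          trna$strand == prelim$strand[i] &
          trna$start <= prelim$position[i] & trna$end >= prelim$position[i])
  }, logical(1))
  is_processing <- has_down | in_trna
  is_removed <- !is_processing & (has_self | has_up)
  cls <- prelim
  cls$site_kind[is_processing] <- "processing"
  cls$site_kind[!is_processing & !is_removed] <- "tts"
  removed <- prelim[is_removed, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "upstream_5p_conflict"
  else removed$reason <- character(0)
  structure(list(processing = cls[is_processing, , drop = FALSE],
                 tts = cls[!is_processing & !is_removed, , drop = FALSE],
                 removed = removed),
            class = "termini_classification")
}

#' Pool processing sites across conditions and purge condition TTS lists
#'
#' A 3' terminus identified as a processing site under any condition is most
#' likely a processing site everywhere; the union of processing positions is
#' removed from every condition's TTS list (reason `pooled_processing`).
#'
#' @param classifications Named list of `termini_classification`, one per
#'   condition.
#' @return Named list with per-condition `tts` (purged), `processing`,
#'   `removed`, plus the pooled processing-position key set as attribute
#'   `"pooled"`.
#' @export
pool_processing_sites <- function(classifications) {
  pooled <- unique(unlist(lapply(classifications, function(cl) {
    if (nrow(cl$processing)) {
      .pos_key(cl$processing$replicon_id, cl$processing$strand,
               cl$processing$position)
    } else character()
  })))
  out <- lapply(classifications, function(cl) {
    key <- .pos_key(cl$tts$replicon_id, cl$tts$strand, cl$tts$position)
    hit <- key %in% pooled
    moved <- cl$tts[hit, , drop = FALSE]
    if (nrow(moved)) moved$reason <- "pooled_processing"
    else moved$reason <- character(0)
    cl$removed <- rbind(cl$removed, moved)
    cl$tts <- cl$tts[!hit, , drop = FALSE]
    rownames(cl$tts) <- NULL
    cl
  })
  attr(out, "pooled") <- pooled
  out
}
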