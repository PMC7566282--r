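# TSS calling: prefilter candidate positions, test RppH-treated exceedance
# over the untreated 5'-monophosphoryl background under paired and unpaired
# negative-binomial designs, resolve adjacent calls into primary/secondary
# sites, merge conditions, refine for promoter modeling, and coalesce into
# promoters.

# Count matrix (positions x libraries) at the candidate positions.
.counts_matrix <- function(tracks, candidates) {
  mat <- matrix(0, nrow(candidates), length(tracks))
  colnames(mat) <- vapply(tracks, function(t) t$library_id, character(1))
  for (rs in split(seq_len(nrow(candidates)),
                   paste(candidates$replicon, candidates$strand))) {
    rep_id <- candidates$replicon[rs[1]]
    strand <- candidates$strand[rs[1]]
    pos <- candidates$pos[rs]
    for (j in seq_along(tracks)) {
      mat[rs, j] <- track_dense(tracks[[j]], rep_id, strand)[pos]
    }
  }
  mat
}

#' Prefilter candidate TSS positions for one condition
#'
#' Keeps positions that (a) have nonzero coverage in at least one library of
#' the condition (treated or untreated) and (b) have a replicate-averaged
#' RppH-treated count at or above the given percentile of the values surviving
#' (a). The percentile uses linear interpolation.
#'
#' @param treated,untreated Lists of `end_coverage_track` (>= 2 each).
#' @param percentile Coverage percentile cutoff (default 95).
#' @param prefilter_source `"treated"` (default): percentile computed over
#'   replicate-averaged treated counts; `"all"`: over the replicate-averaged
#'   mean of all libraries.
#' @return data.frame of candidates: `replicon`, `strand`, `pos`,
#'   `mean_treated`.
#' @export
prefilter_positions <- function(treated, untreated, percentile = 95,
                                prefilter_source = c("treated", "all")) {
  prefilter_source <- match.arg(prefilter_source)
  stopifnot(length(treated) >= 1, length(untreated) >= 1)
  seqlengths <- treated[[1]]$seqlengths
  out <- list()
  for (rep_id in names(seqlengths)) {
    for (strand in c("+", "-")) {
      Tm <- vapply(treated, function(t) track_dense(t, rep_id, strand),
                   numeric(seqlengths[[rep_id]]))
      Um <- vapply(untreated, function(t) track_dense(t, rep_id, strand),
                   numeric(seqlengths[[rep_id]]))
      nz <- rowSums(Tm) + rowSums(Um) > 0
      if (!any(nz)) next
      pos <- which(nz)
      out[[paste(rep_id, strand)]] <- data.frame(
        replicon = rep_id, strand = strand, pos = pos,
        mean_treated = rowMeans(Tm)[pos],
        mean_all = rowMeans(cbind(Tm, Um))[pos])
    }
  }
  if (!length(out)) {
    warning("no nonzero positions in any library of the condition")
    return(data.frame(replicon = character(), strand = character(),
                      pos = integer(), mean_treated = numeric()))
  }
  surv <- do.call(rbind, out)
  src <- if (prefilter_source == "treated") surv$mean_treated else surv$mean_all
  cutoff <- .percentile(src, percentile)
  cand <- surv[src >= cutoff, c("replicon", "strand", "pos", "mean_treated")]
  rownames(cand) <- NULL
  cand
}

#' Test treated-over-untreated exceedance at candidate positions
#'
#' Per-position one-sided (greater) negative-binomial Wald test of RppH-treated
#' versus untreated 5'-end counts, in both a paired design (replicate as a
#' blocking covariate) and an unpaired design, with Benjamini-Hochberg
#' adjustment across all tested positions of the condition per design.
#'
#' @param candidates Candidate positions from [prefilter_positions()].
#' @param treated,untreated Lists of `end_coverage_track`; `replicate_id`
#'   metadata pairs the libraries in the paired design.
#' @param dispersion Optional fixed NB dispersion; estimated by pooled
#'   method-of-moments (floored at 1e-8) when `NULL`.
#' @param size_factors Optional fixed per-library size factors (treated then
#'   untreated); estimated by median-of-ratios over the zero-filter-survivor
#'   positions of the tracks when `NULL`.
#' @return data.frame: candidates plus `log2_fold`, `p_value_paired`,
#'   `p_value_unpaired`, `fdr_paired`, `fdr_unpaired`, `mean_treated_norm`.
#' @export
test_end_exceedance <- function(candidates, treated, untreated,
                                dispersion = NULL, size_factors = NULL) {
  stopifnot(length(treated) >= 2, length(untreated) >= 2)
  n_t <- length(treated)
  n_u <- length(untreated)
  mat <- cbind(.counts_matrix(treated, candidates),
               .counts_matrix(untreated, candidates))
  group <- rep(c("treated", "untreated"), c(n_t, n_u))
  sf <- size_factors %||% .track_size_factors(c(treated, untreated))
  nmat <- sweep(mat, 2, sf, "/")
  alpha <- dispersion %||% .pooled_dispersion(nmat, group)
  treat <- as.numeric(group == "treated")
  X_unpaired <- cbind(intercept = 1, treat = treat)
  reps <- c(vapply(treated, function(t) t$replicate_id, character(1)),
            vapply(untreated, function(t) t$replicate_id, character(1)))
  paired_ok <- n_t == n_u && !any(reps == "") &&
    setequal(reps[group == "treated"], reps[group == "untreated"])
  X_paired <- if (paired_ok) {
    rf <- factor(reps)
    cbind(stats::model.matrix(~rf), treat = treat)
  } else NULL
  res <- candidates
  unp <- .nb_wald_matrix(mat, X_unpaired, sf, alpha)
  res$log2_fold <- unp$lfc
  res$p_value_unpaired <- unp$p
  res$p_value_paired <- if (is.null(X_paired)) unp$p else
    .nb_wald_matrix(mat, X_paired, sf, alpha)$p
  res$fdr_unpaired <- stats::p.adjust(res$p_value_unpaired, "BH")
  res$fdr_paired <- stats::p.adjust(res$p_value_paired, "BH")
  res$mean_treated_norm <- rowMeans(nmat[, group == "treated", drop = FALSE])
  res
}

#' Call TSSs for one condition from exceedance results
#'
#' A position is a TSS when its adjusted P value is below `fdr_threshold` in
#' the paired or the unpaired design (or both) and its fold change is positive.
#'
#' @param exceedance Output of [test_end_exceedance()].
#' @param condition_id Condition label recorded on the calls.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Site catalog of `tss_primary` calls (adjacent-run resolution into
#'   primary/secondary is a separate step, [resolve_adjacent_tss()]).
#' @export
call_tss_for_condition <- function(exceedance, condition_id = "",
                                   fdr_threshold = 0.05) {
  hit <- (exceedance$fdr_paired < fdr_threshold |
            exceedance$fdr_unpaired < fdr_threshold) &
    exceedance$log2_fold > 0
  hit[is.na(hit)] <- FALSE
  x <- exceedance[hit, , drop = FALSE]
  site_calls(x$replicon, x$pos, x$strand, "tss_primary",
             p_value = pmin(x$p_value_paired, x$p_value_unpaired),
             fdr = pmin(x$fdr_paired, x$fdr_unpaired),
             mean_signal = x$mean_treated_norm,
             conditions_detected = condition_id, n_conditions = 1L)
}

#' Resolve runs of adjacent TSS calls into primary and secondary sites
#'
#' Within each maximal run of contiguous same-strand calls, the position with
#' the highest replicate-averaged treated coverage becomes the primary TSS and
#' the rest become secondary; ties go to the strand-aware upstream-most
#' position.
#'
#' @param catalog Site catalog of TSS calls (with `mean_signal`).
#' @return Catalog with `site_kind` set to `tss_primary`/`tss_secondary`.
#' @export
resolve_adjacent_tss <- function(catalog) {
  if (!nrow(catalog)) return(catalog)
  catalog <- catalog[order(catalog$replicon_id, catalog$strand,
                           catalog$position), ]
  grp <- paste(catalog$replicon_id, catalog$strand)
  kind <- character(nrow(catalog))
  for (g in split(seq_len(nrow(catalog)), grp)) {
    pos <- catalog$position[g]
    run <- cumsum(c(TRUE, diff(pos) != 1L))
    for (r in split(g, run)) {
      best <- which(catalog$mean_signal[r] == max(catalog$mean_signal[r]))
      if (length(best) > 1) {
        strand <- catalog$strand[r[1]]
        up <- .upstream_most(catalog$position[r][best], strand)
        best <- best[catalog$position[r][best] == up][1]
      }
      kind[r] <- "tss_secondary"
      kind[r[best]] <- "tss_primary"
    }
  }
  catalog$site_kind <- kind
  catalog$site_id <- .site_id(kind, catalog$replicon_id, catalog$strand,
                              catalog$position)
  rownames(catalog) <- NULL
  catalog
}

#' Merge per-condition TSS catalogs
#'
#' Secondary TSSs are removed first, then the number of conditions under which
#' each remaining (primary) TSS was identified is counted. `mean_signal` is
#' the maximum over the conditions of detection.
#'
#' @param catalogs List of per-condition catalogs ([resolve_adjacent_tss()]
#'   output).
#' @return Merged site catalog with `n_conditions` populated.
#' @export
merge_conditions <- function(catalogs) {
  prim <- lapply(catalogs, function(x) {
    x[x$site_kind == "tss_primary", , drop = FALSE]
  })
  all <- do.call(rbind, prim)
  if (!nrow(all)) return(site_calls(character(), integer(), character(),
                                    character()))
  key <- .pos_key(all$replicon_id, all$strand, all$position)
  merged <- lapply(split(seq_len(nrow(all)), key), function(i) {
    d <- all[i, , drop = FALSE]
    d$n_conditions <- length(i)
    d$conditions_detected <- paste(sort(unique(
      d$conditions_detected[nzchar(d$conditions_detected)])), collapse = ",")
    d$mean_signal <- max(d$mean_signal)
    d$p_value <- min(d$p_value)
    d$fdr <- min(d$fdr)
    d[1, , drop = FALSE]
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$replicon_id, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

# Priority-greedy conflict resolution shared by refinement: sites are visited
# in decreasing priority; a site is retained unless it lies within `window` bp
# of an already-retained same-strand site on the same replicon.
.greedy_exclude <- function(catalog, window, priority_order) {
  keep <- logical(nrow(catalog))
  for (g in split(priority_order, paste(catalog$replicon_id[priority_order],
                                        catalog$strand[priority_order]))) {
    taken <- integer()
    for (i in g) {
      if (!length(taken) ||
          all(abs(catalog$position[taken] - catalog$position[i]) > window)) {
        keep[i] <- TRUE
        taken <- c(taken, i)
      }
    }
  }
  keep
}

#' Refine a merged TSS catalog for promoter modeling
#'
#' Among TSSs within `window` bp of each other (same strand), the site
#' identified under the most conditions is retained and the others are
#' removed; ties go to the strand-aware upstream-most site. The result
#' contains no two same-strand sites within `window` bp.
#'
#' @param merged Merged catalog from [merge_conditions()].
#' @param window Exclusion window in bp (default 15).
#' @return Refined site catalog.
#' @export
refine_for_promoter_model <- function(merged, window = 15) {
  if (!nrow(merged)) return(merged)
  upstream_rank <- ifelse(merged$strand == "+", merged$position,
                          -merged$position)
  ord <- order(-merged$n_conditions, upstream_rank, merged$position)
  keep <- .greedy_exclude(merged, window, ord)
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coalesce TSSs within a window into single promoters
#'
#' Greedy clustering by descending read count: the highest-count unassigned
#' TSS seeds a promoter and absorbs every TSS within `window` bp (same
#' strand); the seed position (the maximum-count position) represents the
#' cluster. Read count is the size-factor-normalized replicate-averaged
#' treated count (`mean_signal`).
#'
#' @param catalog Site catalog (typically chromosomal primary TSSs).
#' @param window Clustering window in bp (default 10).
#' @return Site catalog of promoter representatives with `n_sites` members.
#' @export
coalesce_tss <- function(catalog, window = 10) {
  if (!nrow(catalog)) {
    catalog$n_sites <- integer(0)
    return(catalog)
  }
  upstream_rank <- ifelse(catalog$strand == "+", catalog$position,
                          -catalog$position)
  ord <- order(-catalog$mean_signal, upstream_rank, catalog$position)
  n_sites <- integer(nrow(catalog))
  keep <- logical(nrow(catalog))
  for (g in split(ord, paste(catalog$replicon_id[ord], catalog$strand[ord]))) {
    assigned <- logical(length(g))
    for (k in seq_along(g)) {
      if (assigned[k]) next
      i <- g[k]
      keep[i] <- TRUE
      member <- !assigned &
        abs(catalog$position[g] - catalog$position[i]) <= window
      assigned[member] <- TRUE
      n_sites[i] <- sum(member)
    }
  }
  out <- catalog[keep, , drop = FALSE]
  out$n_sites <- n_sites[keep]
  out <- out[order(out$replicon_id, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Validate a TSS catalog against independent reference sites
#'
#' Distance mode: for every reference position, the distance to the nearest
#' TSS is computed for the real catalog and for a rotated control in which all
#' catalog coordinates are shifted by a quarter of the replicon length
#' (modulo its length); paired distances are compared by a two-sided Wilcoxon
#' signed-rank test. Region mode: TSS counts falling inside each reference
#' region, real versus rotated.
#'
#' @param catalog Site catalog.
#' @param reference For `"distance"`: data.frame with `replicon_id`,
#'   `position`; for `"contained_in_regions"`: data.frame with `replicon_id`,
#'   `start`, `end`.
#' @param mode `"distance"` or `"contained_in_regions"`.
#' @param replicon_lengths Named vector of replicon lengths (for rotation).
#' @return List with per-reference values, medians/counts and the Wilcoxon
#'   p-value (distance mode).
#' @export
validate_against_reference <- function(catalog, reference,
                                       mode = c("distance",
                                                "contained_in_regions"),
                                       replicon_lengths) {
  mode <- match.arg(mode)
  if (!nrow(catalog)) stop("empty catalog")
  rotate <- function(pos, L) ((pos - 1L + L %/% 4L) %% L) + 1L
  rot <- catalog
  rot$position <- rotate(catalog$position,
                         replicon_lengths[catalog$replicon_id])
  if (mode == "distance") {
    nearest <- function(cat) {
      vapply(seq_len(nrow(reference)), function(i) {
        p <- cat$position[cat$replicon_id == reference$replicon_id[i]]
        if (!length(p)) return(NA_real_)
        min(abs(p - reference$position[i]))
      }, numeric(1))
    }
    d_real <- nearest(catalog)
    d_rot <- nearest(rot)
    pv <- tryCatch(
      stats::wilcox.test(d_real, d_rot, paired = TRUE, exact = FALSE)$p.value,
      error = function(e) NA_real_)
    list(mode = mode, distance_real = d_real, distance_rotated = d_rot,
         median_real = stats::median(d_real, na.rm = TRUE),
         median_rotated = stats::median(d_rot, na.rm = TRUE), p_value = pv)
  } else {
    count_in <- function(cat) {
      vapply(seq_len(nrow(reference)), function(i) {
        sum(cat$replicon_id == reference$replicon_id[i] &
              cat$position >= reference$start[i] &
              cat$position <= reference$end[i])
      }, numeric(1))
    }
    n_real <- count_in(catalog)
    n_rot <- count_in(rot)
    pv <- tryCatch(
      stats::wilcox.test(n_real, n_rot, paired = TRUE, exact = FALSE)$p.value,
      error = function(e) NA_real_)
    list(mode = mode, count_real = n_real, count_rotated = n_rot,
         total_real = sum(n_real), total_rotated = sum(n_rot), p_value = pv)
  }
}

#' Full TSS calling for one condition
#'
#' Convenience wrapper: prefilter, exceedance test, FDR-threshold calling and
#' adjacent-site resolution.
#'
#' @inheritParams prefilter_positions
#' @inheritParams test_end_exceedance
#' @param condition_id Condition label.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Site catalog with primary and secondary TSSs.
#' @export
call_tss_condition <- function(treated, untreated, condition_id = "",
                               fdr_threshold = 0.05, percentile = 95,
                               prefilter_source = "treated",
                               dispersion = NULL) {
  cand <- prefilter_positions(treated, untreated, percentile,
                              prefilter_source)
  if (!nrow(cand)) {
    return(site_calls(character(), integer(), character(), character()))
  }
  exc <- test_end_exceedance(cand, treated, untreated, dispersion)
  resolve_adjacent_tss(call_tss_for_condition(exc, condition_id,
                                              fdr_threshold))
}
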