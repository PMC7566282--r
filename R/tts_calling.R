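# RNA 3'-terminus calling from term-seq coverage: per-library Poisson test
# against a dynamic lambda (the largest of the strand-specific genome-wide
# mean, per-replicon mean, and centered-window means), Benjamini-Hochberg
# correction per library, and a >=2-replicate consensus per condition.

#' Upper-tail Poisson probability P(X >= x)
#'
#' @param x Observed count (non-negative integer, vectorized).
#' @param lam Poisson rate (> 0, vectorized).
#' @return P(X >= x) for X ~ Poisson(lam).
#' @export
poisson_tail_p <- function(x, lam) {
  if (any(lam <= 0)) stop("domain error: lam must be > 0")
  if (any(x < 0 | x != floor(x))) stop("x must be a non-negative integer")
  stats::ppois(x - 1, lam, lower.tail = FALSE)
}

#' Dynamic lambda specification
#'
#' @param window_sizes Ordered odd window widths centered on the tested
#'   position (default 13, 51, 251, 501, 1001 bp).
#' @param include_replicon_mean,include_genome_mean Include the per-replicon
#'   and genome-wide strand-specific mean read counts among the candidates.
#' @return A list of class `dynamic_lambda_spec`.
#' @export
dynamic_lambda_spec <- function(window_sizes = c(13L, 51L, 251L, 501L, 1001L),
                                include_replicon_mean = TRUE,
                                include_genome_mean = TRUE) {
  if (any(window_sizes %% 2 == 0)) {
    stop("window sizes must be odd so windows center on the tested position")
  }
  structure(list(window_sizes = as.integer(window_sizes),
                 include_replicon_mean = include_replicon_mean,
                 include_genome_mean = include_genome_mean),
            class = "dynamic_lambda_spec")
}

#' Dynamic lambda at given positions of a track
#'
#' For each queried position the rate is the maximum over the strand-specific
#' genome-wide mean (all replicons pooled), the replicon mean, and the mean
#' count within each window centered on the position. Window means include
#' the tested position's own count, count zeros, and are truncated at replicon
#' ends (the denominator is the number of positions actually in range).
#'
#' @param track An `end_coverage_track`.
#' @param keys data.frame with columns `replicon`, `strand`, `pos`.
#' @param spec A [dynamic_lambda_spec()].
#' @return Numeric vector of rates, one per row of `keys`.
#' @export
dynamic_lambda <- function(track, keys, spec = dynamic_lambda_spec()) {
  lam <- numeric(nrow(keys))
  genome_len <- sum(track$seqlengths)
  for (strand in unique(keys$strand)) {
    strand_total <- sum(track$counts$count[track$counts$strand == strand])
    genome_mean <- strand_total / genome_len
    for (rep_id in unique(keys$replicon[keys$strand == strand])) {
      sel <- which(keys$strand == strand & keys$replicon == rep_id)
      v <- track_dense(track, rep_id, strand)
      L <- length(v)
      cs <- cumsum(v)
      pos <- keys$pos[sel]
      cand <- matrix(-Inf, length(sel),
                     length(spec$window_sizes) + 2L)
      for (w in seq_along(spec$window_sizes)) {
        half <- spec$window_sizes[w] %/% 2L
        lo <- pmax(1L, pos - half)
        hi <- pmin(L, pos + half)
        below <- numeric(length(lo))
        below[lo > 1L] <- cs[lo[lo > 1L] - 1L]
        cand[, w] <- (cs[hi] - below) / (hi - lo + 1L)
      }
      if (spec$include_replicon_mean) {
        cand[, length(spec$window_sizes) + 1L] <- sum(v) / L
      }
      if (spec$include_genome_mean) {
        cand[, length(spec$window_sizes) + 2L] <- genome_mean
      }
      lam[sel] <- apply(cand, 1, max)
    }
  }
  lam
}

#' Call preliminary 3' ends from one term-seq library
#'
#' Candidates are positions with a count strictly greater than the given
#' percentile of all nonzero counts of the library (both strands, all
#' replicons pooled); each is tested with a one-sided Poisson test against its
#' dynamic lambda, with BH adjustment across the library's tested positions.
#'
#' @param track A `termseq` (or untreated 5'-end) `end_coverage_track`.
#' @param percentile Nonzero-count percentile defining candidates (default 95).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param spec A [dynamic_lambda_spec()].
#' @param site_kind Kind recorded on the calls (default `"prelim_3prime"`).
#' @return Site catalog of per-sample calls.
#' @export
call_three_prime_ends <- function(track, percentile = 95,
                                  fdr_threshold = 0.05,
                                  spec = dynamic_lambda_spec(),
                                  site_kind = "prelim_3prime") {
  cc <- track$counts
  if (!nrow(cc)) {
    warning("all-zero track ", track$library_id)
    return(site_calls(character(), integer(), character(), character()))
  }
  cutoff <- .percentile(cc$count, percentile)
  cand <- cc[cc$count > cutoff, , drop = FALSE]
  if (!nrow(cand)) {
    return(site_calls(character(), integer(), character(), character()))
  }
  lam <- dynamic_lambda(track, cand, spec)
  p <- poisson_tail_p(cand$count, lam)
  fdr <- stats::p.adjust(p, "BH")
  hit <- fdr < fdr_threshold
  site_calls(cand$replicon[hit], cand$pos[hit], cand$strand[hit], site_kind,
             p_value = p[hit], fdr = fdr[hit], mean_signal = cand$count[hit],
             conditions_detected = track$condition_id, n_conditions = 1L)
}

#' Replicate consensus of per-sample 3'-end calls
#'
#' Exact-position, same-strand intersection: a site is retained when called
#' in at least `min_replicates` biological replicates of the condition.
#'
#' @param site_lists List of per-sample site catalogs.
#' @param min_replicates Minimum number of replicates (default 2).
#' @param condition_id Condition label recorded on the output.
#' @param site_kind Kind recorded on the consensus calls.
#' @return Consensus site catalog; `mean_signal` is the mean over detecting
#'   replicates.
#' @export
combine_replicates <- function(site_lists, min_replicates = 2,
                               condition_id = "",
                               site_kind = "prelim_3prime") {
  if (length(site_lists) < 2 && min_replicates > 1) {
    stop("need >= 2 samples (or set min_replicates = 1 explicitly)")
  }
  all <- do.call(rbind, site_lists)
  if (is.null(all) || !nrow(all)) {
    return(site_calls(character(), integer(), character(), character()))
  }
  key <- .pos_key(all$replicon_id, all$strand, all$position)
  n_by <- table(key)
  keep_keys <- names(n_by)[n_by >= min_replicates]
  if (!length(keep_keys)) {
    return(site_calls(character(), integer(), character(), character()))
  }
  rows <- lapply(keep_keys, function(k) {
    d <- all[key == k, , drop = FALSE]
    data.frame(replicon_id = d$replicon_id[1], position = d$position[1],
               strand = d$strand[1], p_value = min(d$p_value),
               fdr = min(d$fdr), mean_signal = mean(d$mean_signal),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  site_calls(d$replicon_id, d$position, d$strand, site_kind,
             p_value = d$p_value, fdr = d$fdr, mean_signal = d$mean_signal,
             conditions_detected = condition_id, n_conditions = 1L)
}

#' Call preliminary 3' termini for one condition
#'
#' Runs [call_three_prime_ends()] on each replicate library and applies the
#' replicate consensus.
#'
#' @param tracks List of term-seq `end_coverage_track` replicates.
#' @inheritParams call_three_prime_ends
#' @inheritParams combine_replicates
#' @return Consensus site catalog of `prelim_3prime` sites.
#' @export
call_tts_condition <- function(tracks, percentile = 95, fdr_threshold = 0.05,
                               spec = dynamic_lambda_spec(),
                               min_replicates = 2, condition_id = "") {
  per_sample <- lapply(tracks, call_three_prime_ends, percentile = percentile,
                       fdr_threshold = fdr_threshold, spec = spec)
  combine_replicates(per_sample, min_replicates, condition_id)
}
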