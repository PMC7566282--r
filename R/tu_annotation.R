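# Transcription-unit annotation: assign TSSs to downstream genes, compute
# 5'-UTR lengths and leaderless status, categorize unassigned TSSs, flag
# regulated promoters, and select constant-promoter candidates.

#' Assign TSSs to the nearest downstream start codon
#'
#' Each TSS is assigned to the nearest same-strand downstream start codon
#' within `max_leader` bp (distance measured to the first base of the
#' annotated start codon; 0 is allowed and intragenic TSSs are eligible).
#' Unassigned TSSs are categorized as `intragenic` (within a same-strand
#' gene), `antisense` (within an opposite-strand gene) or `intergenic`.
#'
#' @param catalog TSS site catalog.
#' @param genes Gene table; only `protein_coding` genes receive assignments.
#' @param max_leader Maximum 5'-UTR length in bp (default 650).
#' @param leaderless_max Maximum leader of a leaderless transcript (default 5
#'   nt).
#' @return List with `pairs` (tss_id, gene_id, utr_length, leaderless,
#'   tss_location) and `unassigned` (tss_id, category);
#'   `nrow(pairs) + nrow(unassigned) == nrow(catalog)`.
#' @export
assign_tss_to_genes <- function(catalog, genes, max_leader = 650,
                                leaderless_max = 5) {
  coding <- genes[genes$feature_class == "protein_coding", , drop = FALSE]
  n <- nrow(catalog)
  pair_rows <- vector("list", n)
  unass_rows <- vector("list", n)
  inside <- function(g, rep_id, pos) {
    g$replicon_id == rep_id & g$start <= pos & g$end >= pos
  }
  for (i in seq_len(n)) {
    rep_id <- catalog$replicon_id[i]
    pos <- catalog$position[i]
    strand <- catalog$strand[i]
    same <- coding[coding$replicon_id == rep_id & coding$strand == strand, ,
                   drop = FALSE]
    dist <- if (strand == "+") same$start_codon_pos - pos
            else pos - same$start_codon_pos
    elig <- which(dist >= 0 & dist <= max_leader)
    if (length(elig)) {
      best <- elig[dist[elig] == min(dist[elig])]
      if (length(best) > 1) {
        # annotation artifact: genes sharing a start coordinate; take the
        # longest, then gene_id for determinism
        len <- same$end[best] - same$start[best]
        best <- best[order(-len, same$gene_id[best])][1]
      }
      in_gene <- any(inside(genes, rep_id, pos) &
                       genes$gene_id != same$gene_id[best])
      pair_rows[[i]] <- data.frame(
        tss_id = catalog$site_id[i], gene_id = same$gene_id[best],
        replicon_id = rep_id, position = pos, strand = strand,
        utr_length = dist[best],
        leaderless = dist[best] <= leaderless_max,
        tss_location = if (in_gene) "intragenic_upstream_gene"
                       else "intergenic",
        stringsAsFactors = FALSE)
    } else {
      in_same <- any(inside(genes[genes$strand == strand, , drop = FALSE],
                            rep_id, pos))
      in_opp <- any(inside(genes[genes$strand != strand, , drop = FALSE],
                           rep_id, pos))
      category <- if (in_same) "intragenic"
                  else if (in_opp) "antisense" else "intergenic"
      unass_rows[[i]] <- data.frame(tss_id = catalog$site_id[i],
                                    replicon_id = rep_id, position = pos,
                                    strand = strand, category = category,
                                    stringsAsFactors = FALSE)
    }
  }
  empty_pairs <- data.frame(tss_id = character(), gene_id = character(),
                            replicon_id = character(), position = integer(),
                            strand = character(), utr_length = integer(),
                            leaderless = logical(),
                            tss_location = character(),
                            stringsAsFactors = FALSE)
  empty_un <- data.frame(tss_id = character(), replicon_id = character(),
                         position = integer(), strand = character(),
                         category = character(), stringsAsFactors = FALSE)
  pairs <- do.call(rbind, c(list(empty_pairs), pair_rows[!vapply(
    pair_rows, is.null, logical(1))]))
  unassigned <- do.call(rbind, c(list(empty_un), unass_rows[!vapply(
    unass_rows, is.null, logical(1))]))
  rownames(pairs) <- rownames(unassigned) <- NULL
  list(pairs = pairs, unassigned = unassigned)
}

#' Summary statistics of 5'-UTR lengths
#'
#' @param pairs `pairs` data.frame from [assign_tss_to_genes()].
#' @param long_cut Boundary of the long/short UTR split (default 100 bp).
#' @return List: `median`, `mean`, `n_long` (> `long_cut`), `n_short`
#'   (<= `long_cut`), `n_leaderless`, `histogram` (table of lengths).
#' @export
compute_utr_stats <- function(pairs, long_cut = 100) {
  if (!nrow(pairs)) stop("no TSS-gene pairs")
  u <- pairs$utr_length
  list(median = stats::median(u), mean = mean(u),
       n_long = sum(u > long_cut), n_short = sum(u <= long_cut),
       n_leaderless = sum(pairs$leaderless), histogram = table(u))
}

#' Flag regulated promoters from per-condition activities
#'
#' A promoter is regulated when its activity under some condition both
#' exceeds the chromosomal mean promoter activity for that condition and is
#' at least `fold` times its activity under another condition (zero
#' activities replaced by `pseudocount`).
#'
#' @param activity Matrix (promoters x conditions) of size-factor-normalized
#'   replicate-mean treated counts.
#' @param chrom_mean Per-condition chromosomal mean promoter activity;
#'   computed as `colMeans(activity)` when `NULL`.
#' @param fold Fold-change threshold (default 10).
#' @param pseudocount Replacement for zero activities (default 0.5).
#' @return Logical vector, one flag per promoter.
#' @export
find_regulated_promoters <- function(activity, chrom_mean = NULL, fold = 10,
                                     pseudocount = 0.5) {
  activity <- as.matrix(activity)
  if (ncol(activity) < 2) stop("need >= 2 conditions")
  chrom_mean <- chrom_mean %||% colMeans(activity)
  denom <- pmax(activity, pseudocount)
  vapply(seq_len(nrow(activity)), function(i) {
    a <- activity[i, ]
    d <- denom[i, ]
    any(vapply(seq_along(a), function(c1) {
      a[c1] > chrom_mean[c1] && any(a[c1] >= fold * d[-c1])
    }, logical(1)))
  }, logical(1))
}

#' Select constant-promoter candidates
#'
#' Genes whose expression is flat across the three growth-phase comparisons
#' (`lfc_low < log2FC < lfc_high` and `padj > padj_min` in every comparison)
#' are intersected with TSS-gene pairs whose TSS is intergenic-located or
#' leaderless and was detected under all required conditions. This is the
#' automated candidate stage; any further curation is manual by nature.
#'
#' @param pairs `pairs` data.frame from [assign_tss_to_genes()].
#' @param de_table data.frame with columns `gene_id`, `comparison`, `log2FC`,
#'   `padj` covering `comparisons`.
#' @param tss_conditions Named list or data.frame mapping `tss_id` to the
#'   comma-separated conditions of detection (`conditions_detected`).
#' @param comparisons Character vector of required comparison labels.
#' @param required_conditions Conditions in which the TSS must be detected.
#' @param lfc_low,lfc_high Exclusive log2 fold-change bounds (default
#'   -0.45, 0.45).
#' @param padj_min Exclusive adjusted-P lower bound (default 0.05).
#' @param max_utr,predominance Optional automated approximations of the
#'   manual curation step: maximum UTR length and minimum share of the
#'   gene's total TSS activity (both `NULL` by default).
#' @param activity Optional named vector of per-TSS activity (needed for
#'   `predominance`).
#' @return `pairs` rows of the candidate promoters.
#' @export
select_constant_promoters <- function(pairs, de_table, tss_conditions,
                                      comparisons = unique(
                                        de_table$comparison),
                                      required_conditions = NULL,
                                      lfc_low = -0.45, lfc_high = 0.45,
                                      padj_min = 0.05, max_utr = NULL,
                                      predominance = NULL, activity = NULL) {
  need <- c("gene_id", "comparison", "log2FC", "padj")
  if (!all(need %in% names(de_table))) {
    stop("de_table must have columns: ", paste(need, collapse = ", "))
  }
  missing_cmp <- setdiff(comparisons, unique(de_table$comparison))
  if (length(missing_cmp)) {
    stop("missing comparison(s) in de_table: ",
         paste(missing_cmp, collapse = ", "))
  }
  de <- de_table[de_table$comparison %in% comparisons, , drop = FALSE]
  gene_ok <- tapply(seq_len(nrow(de)), de$gene_id, function(i) {
    length(unique(de$comparison[i])) == length(comparisons) &&
      all(de$log2FC[i] > lfc_low & de$log2FC[i] < lfc_high &
            de$padj[i] > padj_min)
  })
  flat_genes <- names(gene_ok)[unlist(gene_ok)]
  cond_of <- if (is.data.frame(tss_conditions)) {
    structure(as.character(tss_conditions$conditions_detected),
              names = tss_conditions$tss_id)
  } else unlist(tss_conditions)
  keep <- pairs$gene_id %in% flat_genes &
    (pairs$tss_location == "intergenic" | pairs$leaderless)
  if (!is.null(required_conditions)) {
    det <- strsplit(ifelse(is.na(cond_of[pairs$tss_id]), "",
                           cond_of[pairs$tss_id]), ",")
    keep <- keep & vapply(det, function(d) {
      all(required_conditions %in% d)
    }, logical(1))
  }
  if (!is.null(max_utr)) keep <- keep & pairs$utr_length <= max_utr
  out <- pairs[keep, , drop = FALSE]
  if (!is.null(predominance) && !is.null(activity) && nrow(out)) {
    act <- activity[out$tss_id]
    act[is.na(act)] <- 0
    gene_tot <- tapply(act, out$gene_id, sum)
    share <- act / gene_tot[out$gene_id]
    out <- out[share >= predominance, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
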