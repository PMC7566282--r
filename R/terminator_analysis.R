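# Mapping of called TTSs onto predicted intrinsic terminators (U-tract window
# rule with bidirectional "r" rescue), genomic orientation classes, and
# hairpin / flanking-tract characterization.

#' Map TTSs onto predicted intrinsic terminators
#'
#' A TTS maps to a terminator when it falls in positions 1..`max_offset` of
#' the terminator's 3'-flanking sequence (the 8-nt U tract plus the 4 nt
#' downstream), strand-aware. A TTS on the opposite strand falling in the
#' mirrored window off the hairpin's other end is rescued as the
#' reverse-complement terminator and reported with an "r" suffix. A TTS may
#' match several terminators; all matches are reported.
#'
#' @param tts Site catalog of TTS calls.
#' @param predictions Terminator predictions ([read_transterm_output()]).
#' @param max_offset U-tract window width (default 12).
#' @return data.frame: `tts_id`, `terminator_id` (suffixed "r" for rescue
#'   matches), `u_tract_offset` (1..`max_offset`), `match_type`.
#' @export
map_tts_to_terminators <- function(tts, predictions, max_offset = 12L) {
  empty <- data.frame(tts_id = character(), terminator_id = character(),
                      u_tract_offset = integer(), match_type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tts) || !nrow(predictions)) return(empty)
  tts_key <- .pos_key(tts$replicon_id, tts$strand, tts$position)
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    offs <- seq_len(max_offset)
    if (p$strand == "+") {
      fwd_pos <- p$hairpin_end + offs
      fwd_strand <- "+"
      res_pos <- p$hairpin_start - offs
      res_strand <- "-"
    } else {
      fwd_pos <- p$hairpin_start - offs
      fwd_strand <- "-"
      res_pos <- p$hairpin_end + offs
      res_strand <- "+"
    }
    hit_f <- match(.pos_key(p$replicon_id, fwd_strand, fwd_pos), tts_key)
    hit_r <- match(.pos_key(p$replicon_id, res_strand, res_pos), tts_key)
    for (k in which(!is.na(hit_f))) {
      rows[[length(rows) + 1L]] <- data.frame(
        tts_id = tts$site_id[hit_f[k]], terminator_id = p$terminator_id,
        u_tract_offset = k, match_type = "forward",
        stringsAsFactors = FALSE)
    }
    for (k in which(!is.na(hit_r))) {
      rows[[length(rows) + 1L]] <- data.frame(
        tts_id = tts$site_id[hit_r[k]],
        terminator_id = paste0(p$terminator_id, "r"),
        u_tract_offset = k, match_type = "rescue",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the genomic orientation of a site relative to annotated genes
#'
#' `internal`: the site lies within a same-strand gene more than
#' `internal_margin` bp after its start codon. Otherwise the nearest gene on
#' each genomic side decides: `convergent` when both flanks point toward the
#' site, `divergent` when both point away, `in_line` otherwise (including
#' sites beyond the outermost gene of a replicon, which have a single flank).
#'
#' @param sites Site catalog (TTSs or terminator positions).
#' @param genes Gene table.
#' @param internal_margin Minimum distance after an in-line start codon for
#'   the `internal` class (default 50 bp).
#' @return Character vector of orientation classes, one per site.
#' @export
classify_orientation <- function(sites, genes, internal_margin = 50L) {
  vapply(seq_len(nrow(sites)), function(i) {
    rep_id <- sites$replicon_id[i]
    pos <- sites$position[i]
    strand <- sites$strand[i]
    g <- genes[genes$replicon_id == rep_id, , drop = FALSE]
    if (!nrow(g)) stop("no genes on replicon ", rep_id)
    same <- g[g$strand == strand & g$start <= pos & g$end >= pos, ,
              drop = FALSE]
    if (nrow(same)) {
      after_start <- if (strand == "+") pos - same$start else same$end - pos
      if (any(after_start > internal_margin)) return("internal")
    }
    left <- g[g$end < pos, , drop = FALSE]
    right <- g[g$start > pos, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) return("in_line")
    lg <- left[which.max(left$end), ]
    rg <- right[which.min(right$start), ]
    if (lg$strand == "+" && rg$strand == "-") return("convergent")
    if (lg$strand == "-" && rg$strand == "+") return("divergent")
    "in_line"
  }, character(1))
}

#' Hairpin properties of a predicted terminator
#'
#' Stem and loop lengths come from the prediction when present; otherwise the
#' hairpin sequence is re-parsed by maximal complementary pairing from the
#' ends inward (G.U wobble allowed, minimum 3-nt loop). The free energy of
#' formation is a nearest-neighbor sum of embedded stack energies plus a
#' hairpin-loop initiation term (see `R/rna_energy.R`).
#'
#' @param prediction One-row terminator prediction.
#' @param genome `DNAStringSet`.
#' @return List: `stem_len`, `loop_len`, `delta_g` (kcal/mol).
#' @export
hairpin_properties <- function(prediction, genome) {
  stopifnot(nrow(prediction) == 1)
  chr <- genome[[prediction$replicon_id]]
  s <- as.character(Biostrings::subseq(chr, prediction$hairpin_start,
                                       prediction$hairpin_end))
  if (prediction$strand == "-") s <- .revcomp(s)
  rna <- chartr("T", "U", s)
  L <- nchar(rna)
  stem <- prediction$stem_len
  loop <- prediction$loop_len
  if (is.na(stem) || is.na(loop) || 2 * stem + loop != L) {
    # re-derive by pairing from the ends inward
    b <- strsplit(rna, "")[[1]]
    stem <- 0L
    while (stem + 1L <= (L - 3L) / 2) {
      pair <- .rna_pair_name(b[stem + 1L], b[L - stem])
      if (is.na(pair)) break
      stem <- stem + 1L
    }
    loop <- L - 2L * stem
    if (stem < 1L) stop("hairpin has no paired stem")
  }
  if (loop < 3) stop("hairpin loop shorter than 3 nt after parsing")
  top <- substr(rna, 1L, stem)
  bottom <- paste(rev(strsplit(substr(rna, L - stem + 1L, L), "")[[1]]),
                  collapse = "")
  list(stem_len = as.integer(stem), loop_len = as.integer(loop),
       delta_g = .hairpin_dg(top, bottom, loop))
}

#' Histogram of TTS positions within the terminator U tract
#'
#' @param matches Output of [map_tts_to_terminators()].
#' @param max_offset U-tract window width (default 12).
#' @return List: `counts` (named vector over offsets 1..`max_offset`) and
#'   `mode`.
#' @export
u_tract_position_histogram <- function(matches, max_offset = 12L) {
  if (!nrow(matches)) stop("no matches")
  counts <- table(factor(matches$u_tract_offset, levels = seq_len(max_offset)))
  list(counts = counts, mode = as.integer(names(which.max(counts))))
}

#' Position frequency matrix of terminator flanking sequences
#'
#' Extracts the `width`-nt flank on the requested side of each terminator
#' hairpin in transcript orientation (`5prime_a_tract`: immediately upstream;
#' `3prime_u_tract`: immediately downstream) and tabulates per-position base
#' frequencies.
#'
#' @param predictions Terminator predictions (optionally pre-filtered to the
#'   matched set).
#' @param genome `DNAStringSet`.
#' @param side `"5prime_a_tract"` or `"3prime_u_tract"`.
#' @param orientation Optional character vector of orientation classes
#'   (parallel to `predictions`) used with `orientation_filter`.
#' @param orientation_filter Keep only terminators of this class.
#' @param width Flank width in nt (default 10).
#' @return 4 x `width` frequency matrix (rows A, C, G, T; columns sum to 1).
#' @export
flank_frequency_matrix <- function(predictions, genome,
                                   side = c("5prime_a_tract",
                                            "3prime_u_tract"),
                                   orientation = NULL,
                                   orientation_filter = NULL, width = 10L) {
  side <- match.arg(side)
  if (!is.null(orientation_filter)) {
    if (is.null(orientation)) stop("orientation vector required for filter")
    predictions <- predictions[orientation == orientation_filter, ,
                               drop = FALSE]
  }
  if (!nrow(predictions)) stop("no terminators selected")
  flanks <- vapply(seq_len(nrow(predictions)), function(i) {
    p <- predictions[i, ]
    chr <- genome[[p$replicon_id]]
    upstream <- xor(side == "5prime_a_tract", p$strand == "-")
    if (upstream) {
      from <- p$hairpin_start - width
      to <- p$hairpin_start - 1L
    } else {
      from <- p$hairpin_end + 1L
      to <- p$hairpin_end + width
    }
    if (from < 1L || to > length(chr)) return(NA_character_)
    s <- as.character(Biostrings::subseq(chr, from, to))
    if (p$strand == "-") s <- .revcomp(s)
    s
  }, character(1))
  flanks <- flanks[!is.na(flanks)]
  if (!length(flanks)) stop("all flanks out of range")
  codes <- .seq_codes(flanks)
  C <- .count_matrix(codes)
  freq <- C / length(flanks)
  dimnames(freq) <- list(.BASES, NULL)
  freq
}
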