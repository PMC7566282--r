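# Intrinsic-terminator predictions (TransTermHP report or equivalent TSV).

.terminator_df <- function(terminator_id, replicon_id, strand, hairpin_start,
                           hairpin_end, stem_len, loop_len, confidence,
                           tail_seq) {
  .check_strand(strand)
  hairpin_start <- as.integer(hairpin_start)
  hairpin_end <- as.integer(hairpin_end)
  if (any(hairpin_start > hairpin_end)) {
    stop("validation error: hairpin_start > hairpin_end")
  }
  if (any(stem_len < 1)) stop("validation error: stem_len < 1")
  if (any(loop_len < 3)) stop("validation error: loop_len < 3")
  data.frame(terminator_id = as.character(terminator_id),
             replicon_id = as.character(replicon_id),
             strand = as.character(strand),
             hairpin_start = hairpin_start, hairpin_end = hairpin_end,
             stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
             confidence = as.integer(confidence),
             tail_seq = as.character(tail_seq), stringsAsFactors = FALSE)
}

# 12-nt 3'-flanking sequence (8-nt U tract + 4 nt downstream) in transcript
# orientation: positions hairpin_end+1..hairpin_end+12 on "+", the
# reverse-complement of hairpin_start-12..hairpin_start-1 on "-".
.terminator_tail_from_genome <- function(pred, genome) {
  vapply(seq_len(nrow(pred)), function(i) {
    chr <- genome[[pred$replicon_id[i]]]
    L <- length(chr)
    if (pred$strand[i] == "+") {
      from <- pred$hairpin_end[i] + 1L
      to <- min(L, from + 11L)
      if (from > L) return("")
      as.character(Biostrings::subseq(chr, from, to))
    } else {
      to <- pred$hairpin_start[i] - 1L
      from <- max(1L, to - 11L)
      if (to < 1L) return("")
      .revcomp(as.character(Biostrings::subseq(chr, from, to)))
    }
  }, character(1))
}

#' Read intrinsic-terminator predictions
#'
#' Accepts either the TransTermHP report layout (`SEQUENCE ...` headers, `TERM`
#' lines each followed by a context line of five whitespace-separated fields:
#' 5' flank, 5' stem arm, loop, 3' stem arm, 3' flank) or a TSV with header
#' columns `terminator_id`, `replicon_id`, `strand`, `hairpin_start`,
#' `hairpin_end`, `stem_len`, `loop_len`, `confidence` (optional `tail_seq`).
#'
#' @param path Input file.
#' @param genome Optional `DNAStringSet`; when supplied, the 12-nt 3'-flanking
#'   `tail_seq` (8-nt U tract plus 4 nt downstream) is extracted from it,
#'   strand-aware.
#' @return data.frame of terminator predictions.
#' @export
read_transterm_output <- function(path, genome = NULL) {
  lines <- readLines(path)
  is_report <- any(grepl("^\\s*TERM\\b", lines))
  if (is_report) {
    replicon <- NA_character_
    recs <- list()
    i <- 1L
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^SEQUENCE\\b", ln)) {
        replicon <- strsplit(trimws(ln), "[ \t]+")[[1]][2]
      } else if (grepl("^\\s*TERM\\b", ln)) {
        f <- strsplit(trimws(ln), "[ \t]+")[[1]]
        # TERM <n> <start> - <end> <strand> <loc> <conf> <hp dG> <tail dG> ...
        if (length(f) < 10 || f[4] != "-") {
          stop(sprintf("parse error in %s at line %d: malformed TERM record",
                       path, i))
        }
        conf <- suppressWarnings(as.integer(f[8]))
        a <- suppressWarnings(as.integer(f[3]))
        b <- suppressWarnings(as.integer(f[5]))
        if (is.na(a) || is.na(b) || is.na(conf)) {
          stop(sprintf(
            "parse error in %s at line %d: missing coordinates or confidence",
            path, i))
        }
        if (i + 1L > length(lines)) {
          stop(sprintf("parse error in %s at line %d: truncated record",
                       path, i))
        }
        ctx <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
        if (length(ctx) != 5) {
          stop(sprintf("parse error in %s at line %d: expected 5 context %s",
                       path, i + 1L, "fields (flank, stem, loop, stem, flank)"))
        }
        if (is.na(replicon)) {
          stop(sprintf("parse error in %s at line %d: TERM before SEQUENCE",
                       path, i))
        }
        recs[[length(recs) + 1L]] <- data.frame(
          terminator_id = paste0("TERM_", f[2]), replicon_id = replicon,
          strand = f[6], hairpin_start = min(a, b), hairpin_end = max(a, b),
          stem_len = nchar(ctx[2]), loop_len = nchar(ctx[3]),
          confidence = conf, tail_seq = substr(ctx[5], 1, 12),
          stringsAsFactors = FALSE)
        i <- i + 1L
      }
      i <- i + 1L
    }
    if (!length(recs)) {
      pred <- .terminator_df(character(), character(), character(), integer(),
                             integer(), integer(), integer(), integer(),
                             character())
    } else {
      pred <- do.call(rbind, recs)
      pred <- .terminator_df(pred$terminator_id, pred$replicon_id, pred$strand,
                             pred$hairpin_start, pred$hairpin_end,
                             pred$stem_len, pred$loop_len, pred$confidence,
                             pred$tail_seq)
    }
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    need <- c("terminator_id", "replicon_id", "strand", "hairpin_start",
              "hairpin_end", "stem_len", "loop_len", "confidence")
    if (!all(need %in% names(tab))) {
      stop("parse error: terminator TSV must have columns: ",
           paste(need, collapse = ", "))
    }
    if (anyNA(tab$confidence)) {
      stop("parse error: record missing confidence in ", path)
    }
    pred <- .terminator_df(tab$terminator_id, tab$replicon_id, tab$strand,
                           tab$hairpin_start, tab$hairpin_end, tab$stem_len,
                           tab$loop_len, tab$confidence,
                           tab$tail_seq %||% rep("", nrow(tab)))
  }
  if (!is.null(genome) && nrow(pred)) {
    pred$tail_seq <- .terminator_tail_from_genome(pred, genome)
  }
  pred
}
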