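# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  invisible(strand)
}

#' Shift a position downstream in transcript orientation
#'
#' "Downstream" of position p means p + k on the plus strand and p - k on the
#' minus strand, everywhere in the pipeline.
#'
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector of "+"/"-".
#' @param k Shift in nucleotides (negative values move upstream).
#' @return Integer vector of shifted positions.
#' @export
downstream_pos <- function(pos, strand, k = 1L) {
  .check_strand(strand)
  ifelse(strand == "+", pos + k, pos - k)
}

# 5'-most (upstream-most) position among `pos` in transcript orientation.
.upstream_most <- function(pos, strand) {
  if (strand == "+") min(pos) else max(pos)
}

# Linear-interpolation percentile (R quantile type 7), the convention used by
# every percentile prefilter in the pipeline.
.percentile <- function(x, pct) {
  stats::quantile(x, probs = pct / 100, type = 7, names = FALSE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic site identifiers: kind_replicon_strand_position.
.site_id <- function(kind, replicon, strand, pos) {
  sprintf("%s_%s_%s_%d", kind, replicon, ifelse(strand == "+", "p", "m"), pos)
}

# Key strings for exact (replicon, strand, position) matching.
.pos_key <- function(replicon, strand, pos) {
  paste(replicon, strand, pos, sep = "\r")
}
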