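# End-coverage tracks: strand-specific per-position counts of RNA end events
# (5' ends for TSS-seq libraries, 3' ends for strand-corrected term-seq).
# Internal coordinates are 1-based inclusive (GenBank convention); BED-family
# I/O converts at the boundary.

#' Construct a strand-specific end-coverage track
#'
#' A track records, for one sequencing library, the number of RNA end events
#' whose terminal nucleotide maps to each genomic position and strand. For
#' `tss_treated`/`tss_untreated` libraries the count at (p, s) is the number of
#' RNA 5' termini starting at p; for `termseq` libraries it is the number of
#' RNA 3' termini ending at p (strand correction already applied upstream).
#'
#' @param counts data.frame with columns `replicon`, `strand` ("+"/"-"),
#'   `pos` (1-based) and `count` (non-negative integer). Zero rows are dropped;
#'   duplicate keys are summed.
#' @param seqlengths Named integer vector of replicon lengths.
#' @param library_id,condition_id,replicate_id Library metadata strings.
#' @param library_kind One of `"tss_treated"`, `"tss_untreated"`, `"termseq"`.
#' @return An object of class `end_coverage_track`.
#' @export
end_coverage_track <- function(counts, seqlengths, library_id,
                               condition_id = "", replicate_id = "",
                               library_kind = c("tss_treated", "tss_untreated",
                                                "termseq")) {
  library_kind <- match.arg(library_kind)
  stopifnot(is.data.frame(counts),
            all(c("replicon", "strand", "pos", "count") %in% names(counts)))
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths)))) {
    stop("seqlengths must be a named vector of replicon lengths")
  }
  counts$replicon <- as.character(counts$replicon)
  counts$strand <- as.character(counts$strand)
  counts$pos <- as.integer(counts$pos)
  counts$count <- as.numeric(counts$count)
  .check_strand(counts$strand)
  if (any(counts$count < 0)) stop("validation error: negative count in track")
  if (any(counts$count != floor(counts$count))) {
    stop("validation error: non-integer count in track")
  }
  unknown <- setdiff(unique(counts$replicon), names(seqlengths))
  if (length(unknown)) {
    stop("counts reference replicons absent from seqlengths: ",
         paste(unknown, collapse = ", "))
  }
  lim <- seqlengths[counts$replicon]
  if (any(counts$pos < 1L | counts$pos > lim)) {
    stop("validation error: position outside replicon length")
  }
  counts <- counts[counts$count > 0, , drop = FALSE]
  if (nrow(counts)) {
    key <- .pos_key(counts$replicon, counts$strand, counts$pos)
    if (anyDuplicated(key)) {
      agg <- rowsum(counts$count, key)
      first <- counts[!duplicated(key), c("replicon", "strand", "pos")]
      counts <- cbind(first, count = agg[.pos_key(first$replicon, first$strand,
                                                  first$pos), 1])
    }
    counts <- counts[order(counts$replicon, counts$strand, counts$pos), ]
    rownames(counts) <- NULL
  }
  structure(list(library_id = library_id, condition_id = condition_id,
                 replicate_id = replicate_id, library_kind = library_kind,
                 seqlengths = structure(as.integer(seqlengths),
                                        names = names(seqlengths)),
                 counts = counts),
            class = "end_coverage_track")
}

#' @export
print.end_coverage_track <- function(x, ...) {
  cat(sprintf("<end_coverage_track> %s (%s, condition=%s, replicate=%s)\n",
              x$library_id, x$library_kind, x$condition_id, x$replicate_id))
  cat(sprintf("  %d replicons, %d nonzero positions, %g total end events\n",
              length(x$seqlengths), nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

#' Dense per-base counts for one replicon and strand
#'
#' @param track An `end_coverage_track`.
#' @param replicon Replicon id.
#' @param strand "+" or "-".
#' @return Numeric vector of length `seqlengths[replicon]`.
#' @export
track_dense <- function(track, replicon, strand) {
  L <- track$seqlengths[[replicon]]
  v <- numeric(L)
  sel <- track$counts$replicon == replicon & track$counts$strand == strand
  v[track$counts$pos[sel]] <- track$counts$count[sel]
  v
}

.read_numeric_table <- function(path, n_cols, what) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(list(fields = matrix(character(), 0, n_cols), lineno = integer()))
  }
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != n_cols)) {
    bad <- idx[which(nf != n_cols)[1]]
    stop(sprintf("parse error in %s at line %d: expected %d fields", what,
                 bad, n_cols))
  }
  list(fields = do.call(rbind, parts), lineno = idx)
}

.parse_num <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop(sprintf("parse error in %s at line %d: non-numeric %s",
                 path, lineno[which(is.na(v))[1]], what))
  }
  v
}

#' Read strand-specific end coverage from disk
#'
#' Two dialects are supported, each as a (plus, minus) file pair:
#' `bedgraph_pair` (4-column bedGraph, 0-based half-open intervals, expanded to
#' per-base 1-based counts) and `per_base_depth` (3 columns: replicon, 1-based
#' position, count; the product of `genomeCoverageBed -5 -d`).
#'
#' @param paths Character vector of length 2: `c(plus = ..., minus = ...)`.
#' @param dialect `"bedgraph_pair"` or `"per_base_depth"`.
#' @param seqlengths Named integer vector of replicon lengths.
#' @param library_id,condition_id,replicate_id,library_kind Metadata passed to
#'   [end_coverage_track()].
#' @return An `end_coverage_track`.
#' @export
read_end_coverage <- function(paths, dialect = c("bedgraph_pair",
                                                 "per_base_depth"),
                              seqlengths, library_id,
                              condition_id = "", replicate_id = "",
                              library_kind = "tss_treated") {
  dialect <- match.arg(dialect)
  if (length(paths) != 2) {
    stop("paths must be a (plus, minus) pair of files")
  }
  if (is.null(names(paths))) names(paths) <- c("+", "-")
  names(paths) <- sub("^plus$", "+", sub("^minus$", "-", names(paths)))
  stopifnot(all(file.exists(paths)))
  per_strand <- lapply(names(paths), function(s) {
    path <- paths[[s]]
    if (dialect == "bedgraph_pair") {
      tab <- .read_numeric_table(path, 4L, path)
      if (!nrow(tab$fields)) {
        return(data.frame(replicon = character(), strand = character(),
                          pos = integer(), count = numeric()))
      }
      start0 <- .parse_num(tab$fields[, 2], path, tab$lineno, "start")
      end0 <- .parse_num(tab$fields[, 3], path, tab$lineno, "end")
      val <- .parse_num(tab$fields[, 4], path, tab$lineno, "count")
      if (any(val < 0)) stop("validation error: negative count in ", path)
      widths <- end0 - start0
      data.frame(
        replicon = rep(tab$fields[, 1], widths),
        strand = s,
        pos = unlist(lapply(seq_along(start0),
                            function(i) seq.int(start0[i] + 1L, end0[i]))),
        count = rep(val, widths))
    } else {
      tab <- .read_numeric_table(path, 3L, path)
      if (!nrow(tab$fields)) {
        return(data.frame(replicon = character(), strand = character(),
                          pos = integer(), count = numeric()))
      }
      pos <- .parse_num(tab$fields[, 2], path, tab$lineno, "position")
      val <- .parse_num(tab$fields[, 3], path, tab$lineno, "count")
      if (any(val < 0)) stop("validation error: negative count in ", path)
      data.frame(replicon = tab$fields[, 1], strand = s, pos = as.integer(pos),
                 count = val)
    }
  })
  end_coverage_track(do.call(rbind, per_strand), seqlengths, library_id,
                     condition_id, replicate_id, library_kind)
}

#' Write an end-coverage track to disk
#'
#' Inverse of [read_end_coverage()]; only nonzero positions are written (runs
#' of equal counts are merged into bedGraph intervals).
#'
#' @param track An `end_coverage_track`.
#' @param paths Character vector `c(plus = ..., minus = ...)` of output files.
#' @param dialect `"bedgraph_pair"` or `"per_base_depth"`.
#' @return `paths`, invisibly.
#' @export
write_end_coverage <- function(track, paths,
                               dialect = c("bedgraph_pair", "per_base_depth")) {
  dialect <- match.arg(dialect)
  stopifnot(length(paths) == 2)
  if (is.null(names(paths))) names(paths) <- c("+", "-")
  names(paths) <- sub("^plus$", "+", sub("^minus$", "-", names(paths)))
  for (s in names(paths)) {
    cc <- track$counts[track$counts$strand == s, , drop = FALSE]
    if (dialect == "per_base_depth") {
      utils::write.table(cc[, c("replicon", "pos", "count")], paths[[s]],
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    } else {
      out <- lapply(split(cc, cc$replicon), function(d) {
        d <- d[order(d$pos), ]
        run <- cumsum(c(TRUE, diff(d$pos) != 1L | diff(d$count) != 0))
        data.frame(replicon = d$replicon[1],
                   start0 = tapply(d$pos, run, min) - 1L,
                   end0 = as.integer(tapply(d$pos, run, max)),
                   count = tapply(d$count, run, function(x) x[1]))
      })
      out <- if (length(out)) do.call(rbind, out) else
        data.frame(replicon = character(), start0 = integer(),
                   end0 = integer(), count = numeric())
      utils::write.table(out, paths[[s]], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(paths)
}
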