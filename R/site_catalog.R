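# Site catalogs: called genomic RNA ends (TSSs, preliminary 3' termini,
# 5'-monophosphoryl sites, processing sites, TTSs) with their statistics.

.SITE_KINDS <- c("tss_primary", "tss_secondary", "prelim_3prime",
                 "monophosphate_5p", "processing", "tts")

#' Construct a site-call catalog
#'
#' @param replicon_id,position,strand Site coordinates (1-based, "+"/"-").
#' @param site_kind One of `"tss_primary"`, `"tss_secondary"`,
#'   `"prelim_3prime"`, `"monophosphate_5p"`, `"processing"`, `"tts"`.
#' @param p_value,fdr Test statistics in \[0, 1\].
#' @param mean_signal Size-factor-normalized replicate-mean signal.
#' @param conditions_detected Comma-separated condition ids per site.
#' @param n_conditions Number of conditions in which the site was called.
#' @return data.frame with one row per site and a stable `site_id`.
#' @export
site_calls <- function(replicon_id, position, strand, site_kind,
                       p_value = NA_real_, fdr = NA_real_,
                       mean_signal = NA_real_, conditions_detected = "",
                       n_conditions = NA_integer_) {
  n <- length(position)
  if (n == 0) {
    return(data.frame(site_id = character(), replicon_id = character(),
                      position = integer(), strand = character(),
                      site_kind = character(), p_value = numeric(),
                      fdr = numeric(), mean_signal = numeric(),
                      conditions_detected = character(),
                      n_conditions = integer(), stringsAsFactors = FALSE))
  }
  .check_strand(strand)
  stopifnot(all(site_kind %in% .SITE_KINDS))
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(p_value) || !ok(fdr)) stop("p_value and fdr must lie in [0, 1]")
  df <- data.frame(site_id = .site_id(site_kind, replicon_id, strand,
                                      as.integer(position)),
                   replicon_id = as.character(replicon_id),
                   position = as.integer(position),
                   strand = as.character(strand),
                   site_kind = as.character(site_kind),
                   p_value = as.numeric(p_value), fdr = as.numeric(fdr),
                   mean_signal = as.numeric(mean_signal),
                   conditions_detected = as.character(conditions_detected),
                   n_conditions = as.integer(n_conditions),
                   stringsAsFactors = FALSE)
  df <- df[order(df$replicon_id, df$position, df$strand), ]
  rownames(df) <- NULL
  df
}

#' Write a site catalog to BED6 or TSV
#'
#' BED6 emits 0-based half-open single-base intervals with score
#' `round(-10 * log10(fdr))` capped at 1000; TSV carries every catalog column.
#'
#' @param sites Site catalog (see [site_calls()]).
#' @param path Output file.
#' @param format `"tsv"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(sites, path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  sites <- sites[order(sites$replicon_id, sites$position), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    score <- ifelse(is.na(sites$fdr), 0,
                    pmin(1000, round(-10 * log10(pmax(sites$fdr, 1e-100)))))
    bed <- data.frame(sites$replicon_id, sites$position - 1L, sites$position,
                      sites$site_id, as.integer(score), sites$strand)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#chrom\tstart\tend\tname\tscore\tstrand"), con)
    if (nrow(bed)) {
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a site catalog written by [write_site_catalog()]
#'
#' @param path TSV catalog file.
#' @return Site catalog data.frame.
#' @export
read_site_catalog <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = NA)
  tab$conditions_detected <- as.character(tab$conditions_detected %||% "")
  tab$conditions_detected[is.na(tab$conditions_detected)] <- ""
  tab
}
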