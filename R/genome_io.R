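# Genome sequences and gene annotations.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`, one element per replicon, names set to
#'   the first whitespace-delimited token of each header. Only A/C/G/T/N are
#'   accepted; other IUPAC ambiguity codes are rejected.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) stop("duplicate replicon ids in ", path)
  freq <- Biostrings::alphabetFrequency(genome)
  other <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"),
                                       drop = FALSE])
  if (any(other > 0)) {
    stop("validation error: ambiguity codes other than N in genome ", path)
  }
  genome
}

.gene_record_df <- function(gene_id, replicon_id, start, end, strand,
                            feature_class) {
  .check_strand(strand)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("validation error: gene start > end")
  feature_class <- ifelse(
    feature_class %in% c("protein_coding", "tRNA", "rRNA"), feature_class,
    "other")
  data.frame(gene_id = as.character(gene_id),
             replicon_id = as.character(replicon_id),
             start = start, end = end, strand = as.character(strand),
             feature_class = feature_class,
             # first base of the start codon: leftmost base on +, rightmost
             # on - (coordinates are 1-based inclusive)
             start_codon_pos = ifelse(strand == "+", start, end),
             stringsAsFactors = FALSE)
}

#' Read gene annotations
#'
#' @param path GFF3 file or a BED-like TSV with header columns `gene_id`,
#'   `replicon_id`, `start`, `end`, `strand`, `feature_class`.
#' @param format `"gff3"` or `"bed_like_tsv"`.
#' @param feature_types For GFF3, the feature types retained (in addition,
#'   `gene` records with a `gene_biotype`/`biotype` attribute are classed by
#'   that attribute).
#' @return data.frame of gene records with strand-aware `start_codon_pos`.
#' @export
read_gene_annotations <- function(path, format = c("gff3", "bed_like_tsv"),
                                  feature_types = c("gene", "pseudogene",
                                                    "tRNA", "rRNA")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- as.data.frame(S4Vectors::mcols(gr))
    keep <- as.character(meta$type) %in% feature_types
    gr <- gr[keep]; meta <- meta[keep, , drop = FALSE]
    if (!length(gr)) {
      return(.gene_record_df(character(), character(), integer(), integer(),
                             character(), character()))
    }
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) stop("unknown strand symbol in ", path)
    type <- as.character(meta$type)
    biotype <- meta$gene_biotype %||% meta$biotype %||% rep(NA_character_,
                                                            length(gr))
    cls <- ifelse(type %in% c("tRNA", "rRNA"), type,
           ifelse(!is.na(biotype) & biotype %in% c("tRNA", "rRNA"), biotype,
           ifelse(type %in% c("gene"), "protein_coding", "other")))
    ids <- meta$ID %||% rep(NA_character_, length(gr))
    if (!is.null(meta$locus_tag)) {
      ids <- ifelse(is.na(ids), meta$locus_tag, ids)
    }
    ids[is.na(ids)] <- sprintf("gene_%05d", which(is.na(ids)))
    .gene_record_df(ids, as.character(GenomeInfoDb::seqnames(gr)),
                    BiocGenerics::start(gr), BiocGenerics::end(gr),
                    strand, cls)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    need <- c("gene_id", "replicon_id", "start", "end", "strand",
              "feature_class")
    if (!all(need %in% names(tab))) {
      stop("bed_like_tsv must have columns: ", paste(need, collapse = ", "))
    }
    .gene_record_df(tab$gene_id, tab$replicon_id, tab$start, tab$end,
                    tab$strand, tab$feature_class)
  }
}
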