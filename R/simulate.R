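# Synthetic genomes, annotations, promoter sets and end-coverage tracks with
# planted ground truth, so that every pipeline stage can be validated without
# external data. Counts follow a negative binomial with mean m and dispersion
# alpha (variance m + alpha * m^2; alpha = 0 degenerates to Poisson), the
# same parameterization the exceedance test assumes. Planted events add to,
# never replace, the background.

.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Noise model for simulated end-coverage libraries
#'
#' @param nb_dispersion NB dispersion alpha (default 0.1).
#' @param background_rate Mean background end events per position for TSS-seq
#'   libraries (default 0.1).
#' @param termseq_background_rate Background rate for term-seq libraries
#'   (default 1).
#' @param monophosphate_background_rate Mean of standalone 5'-monophosphoryl
#'   background pileups (default 80).
#' @param size_factors Per-replicate library size factors (recycled; default
#'   1).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(nb_dispersion = 0.1, background_rate = 0.1,
                        termseq_background_rate = 1,
                        monophosphate_background_rate = 80,
                        size_factors = 1) {
  stopifnot(nb_dispersion >= 0, background_rate >= 0,
            termseq_background_rate >= 0, all(size_factors > 0))
  structure(list(nb_dispersion = nb_dispersion,
                 background_rate = background_rate,
                 termseq_background_rate = termseq_background_rate,
                 monophosphate_background_rate =
                   monophosphate_background_rate,
                 size_factors = size_factors), class = "noise_model")
}

#' Simulate a genome with non-overlapping genes
#'
#' Background sequence is i.i.d. at the stated GC content; genes are packed
#' left to right with random intergenic gaps and a mix of orientations, so
#' in-line, convergent and divergent junctions all occur. The first
#' `n_trna` genes are annotated as tRNAs (short features).
#'
#' @param n_genes Number of genes (default 60).
#' @param length Replicon length in bp (default 1e5).
#' @param gc GC content in (0, 1) (default 0.5).
#' @param seed RNG seed.
#' @param n_trna Number of tRNA features among the genes (default 2).
#' @param replicon_id Replicon name (default "chr").
#' @return List: `genome` (`DNAStringSet`), `genes` (gene table), `truth`
#'   (empty `simulation_truth` skeleton carrying the seed).
#' @export
simulate_genome <- function(n_genes = 60, length = 1e5, gc = 0.5, seed = 1,
                            n_trna = 2, replicon_id = "chr") {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  genes <- NULL
  if (n_genes > 0) {
    pos <- 400L
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gap <- sample(300:800, 1)
      glen <- if (i <= n_trna) sample(75:90, 1) else sample(600:1200, 1)
      start <- pos + gap
      end <- start + glen - 1L
      if (end > length - 400L) {
        stop("infeasible packing: ", n_genes, " genes do not fit in ",
             length, " bp")
      }
      rows[[i]] <- data.frame(
        gene_id = sprintf("g%03d", i), replicon_id = replicon_id,
        start = start, end = end,
        strand = sample(c("+", "-"), 1),
        feature_class = if (i <= n_trna) "tRNA" else "protein_coding",
        stringsAsFactors = FALSE)
      pos <- end
    }
    genes <- do.call(rbind, rows)
    genes <- .gene_record_df(genes$gene_id, genes$replicon_id, genes$start,
                             genes$end, genes$strand, genes$feature_class)
  } else {
    genes <- .gene_record_df(character(), character(), integer(), integer(),
                             character(), character())
  }
  genome <- Biostrings::DNAStringSet(structure(seq, names = replicon_id))
  truth <- structure(list(
    planted_tss = NULL, planted_tts = NULL, planted_processing = NULL,
    planted_mono = NULL, planted_genes = genes, terminators = NULL,
    seqlengths = structure(as.integer(length), names = replicon_id),
    seed = seed), class = "simulation_truth")
  list(genome = genome, genes = genes, truth = truth)
}

#' Plant intrinsic-terminator hairpins into a simulated genome
#'
#' Writes a GC-rich stem-loop followed by an 8-nt U tract (T on the coding
#' strand) just downstream of the ends of `n` plus-strand genes, and records
#' the corresponding predictions as a terminator table.
#'
#' @param sim Output of [simulate_genome()].
#' @param n Number of terminators to plant (default 10).
#' @param stem_len,loop_len Hairpin geometry (defaults 8 bp / 4 nt).
#' @param seed RNG seed.
#' @return `sim` with modified `genome`, a `terminators` prediction table on
#'   `truth`, and the planting positions.
#' @export
plant_terminators <- function(sim, n = 10, stem_len = 8, loop_len = 4,
                              seed = 1) {
  set.seed(seed + 1000L)
  rep_id <- names(sim$truth$seqlengths)[1]
  plus_genes <- sim$genes[sim$genes$strand == "+" &
                            sim$genes$feature_class == "protein_coding", ]
  if (nrow(plus_genes) < n) stop("not enough plus-strand genes")
  host <- plus_genes[sort(sample.int(nrow(plus_genes), n)), ]
  s <- strsplit(as.character(sim$genome[[rep_id]]), "")[[1]]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    stem <- sample(c("G", "C"), stem_len, replace = TRUE)
    loop <- sample(c("A", "C", "G", "T"), loop_len, replace = TRUE)
    rc <- rev(chartr("ACGT", "TGCA", stem))
    hp <- c(stem, loop, rc)
    start <- host$end[i] + 20L
    end <- start + length(hp) - 1L
    tail <- c(rep("T", 8), sample(c("A", "C", "G", "T"), 4, replace = TRUE))
    s[start:end] <- hp
    s[(end + 1L):(end + 12L)] <- tail
    rows[[i]] <- data.frame(
      terminator_id = sprintf("TERMSIM_%02d", i), replicon_id = rep_id,
      strand = "+", hairpin_start = start, hairpin_end = end,
      stem_len = stem_len, loop_len = loop_len, confidence = 90L,
      tail_seq = paste(tail, collapse = ""), stringsAsFactors = FALSE)
  }
  sim$genome <- Biostrings::DNAStringSet(
    structure(paste(s, collapse = ""), names = rep_id))
  sim$truth$terminators <- do.call(rbind, rows)
  sim
}

#' Plant TSS, TTS, processing-pair and 5'-monophosphoryl ground truth
#'
#' TSSs are placed in the intergenic gap upstream of protein-coding genes
#' (leader lengths drawn uniformly), TTSs at the planted terminators' U
#' tracts (`hairpin_end + tts_offset`) plus additional free intergenic
#' positions, processing pairs as (3'-OH at p, 5'-P at p+1 downstream)
#' signals, and a few standalone monophosphoryl background sites.
#'
#' @param sim Output of [plant_terminators()].
#' @param n_tss,n_tts,n_processing,n_mono Numbers of planted events (defaults
#'   40, 25, 10, 5); `n_tts` includes one TTS per planted terminator.
#' @param treated_mean,untreated_mean Planted TSS means in the RppH-treated
#'   and untreated libraries (defaults 200, 2).
#' @param tts_mean,processing_mean Planted 3'-pileup means (defaults 100).
#' @param utr_range Range of planted leader lengths (default 20:250).
#' @param tts_offset U-tract stop position after the hairpin (default 7).
#' @param seed RNG seed.
#' @return `sim` with a fully populated `truth`.
#' @export
plant_truth <- function(sim, n_tss = 40, n_tts = 25, n_processing = 10,
                        n_mono = 5, treated_mean = 200, untreated_mean = 2,
                        tts_mean = 100, processing_mean = 100,
                        utr_range = 20:250, tts_offset = 7, seed = 1) {
  set.seed(seed + 2000L)
  rep_id <- names(sim$truth$seqlengths)[1]
  L <- sim$truth$seqlengths[[1]]
  coding <- sim$genes[sim$genes$feature_class == "protein_coding", ]
  if (nrow(coding) < n_tss) stop("not enough genes for planted TSSs")
  host <- coding[sort(sample.int(nrow(coding), n_tss)), ]
  utr <- sample(utr_range, n_tss, replace = TRUE)
  tss_pos <- ifelse(host$strand == "+", host$start_codon_pos - utr,
                    host$start_codon_pos + utr)
  planted_tss <- data.frame(replicon = rep_id, pos = as.integer(tss_pos),
                            strand = host$strand, treated_mean = treated_mean,
                            untreated_mean = untreated_mean,
                            gene_id = host$gene_id, utr = utr,
                            stringsAsFactors = FALSE)
  term <- sim$truth$terminators
  n_free_tts <- n_tts - nrow(term)
  if (n_free_tts < 0) stop("n_tts smaller than the number of terminators")
  used <- c(planted_tss$pos, unlist(lapply(seq_len(nrow(term)), function(i) {
    term$hairpin_start[i]:(term$hairpin_end[i] + 12L)
  })))
  free_pool <- setdiff(seq(2000L, L - 2000L), used)
  free_pos <- sort(sample(free_pool, n_free_tts + n_processing + n_mono))
  free_pos <- free_pos[sample.int(length(free_pos))]
  idx <- 0L
  take <- function(k) {
    out <- free_pos[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  planted_tts <- rbind(
    data.frame(replicon = rep_id,
               pos = as.integer(term$hairpin_end + tts_offset),
               strand = term$strand, mean = tts_mean,
               terminator_id = term$terminator_id, stringsAsFactors = FALSE),
    data.frame(replicon = rep_id, pos = take(n_free_tts),
               strand = sample(c("+", "-"), n_free_tts, replace = TRUE),
               mean = tts_mean, terminator_id = NA_character_,
               stringsAsFactors = FALSE))
  proc_pos <- take(n_processing)
  proc_strand <- sample(c("+", "-"), n_processing, replace = TRUE)
  planted_processing <- data.frame(
    replicon = rep_id, pos3 = proc_pos,
    pos5 = as.integer(downstream_pos(proc_pos, proc_strand, 1L)),
    strand = proc_strand, mean = processing_mean, stringsAsFactors = FALSE)
  planted_mono <- data.frame(
    replicon = rep_id, pos = take(n_mono),
    strand = sample(c("+", "-"), n_mono, replace = TRUE),
    mean = sim$noise$monophosphate_background_rate %||% 80,
    stringsAsFactors = FALSE)
  sim$truth$planted_tss <- planted_tss
  sim$truth$planted_tts <- planted_tts
  sim$truth$planted_processing <- planted_processing
  sim$truth$planted_mono <- planted_mono
  sim
}

# means vectors (per position, both strands) for one library kind
.planted_means <- function(truth, kind) {
  L <- truth$seqlengths[[1]]
  mu <- list(`+` = numeric(L), `-` = numeric(L))
  add <- function(pos, strand, m) {
    for (s in c("+", "-")) {
      sel <- strand == s
      if (any(sel)) {
        mu[[s]][pos[sel]] <<- mu[[s]][pos[sel]] + m[sel]
      }
    }
  }
  rep_n <- function(m, k) if (length(m) == 1) rep(m, k) else m
  if (kind %in% c("tss_treated", "tss_untreated")) {
    ts <- truth$planted_tss
    if (!is.null(ts) && nrow(ts)) {
      m <- if (kind == "tss_treated") ts$treated_mean else ts$untreated_mean
      add(ts$pos, ts$strand, rep_n(m, nrow(ts)))
    }
    # 5'-monophosphoryl signals appear equally in treated and untreated
    # libraries: RppH exposes triphosphates, monophosphates ligate either way
    pr <- truth$planted_processing
    if (!is.null(pr) && nrow(pr)) {
      add(pr$pos5, pr$strand, rep_n(pr$mean, nrow(pr)))
    }
    mo <- truth$planted_mono
    if (!is.null(mo) && nrow(mo)) add(mo$pos, mo$strand, rep_n(mo$mean,
                                                               nrow(mo)))
  } else if (kind == "termseq") {
    tt <- truth$planted_tts
    if (!is.null(tt) && nrow(tt)) add(tt$pos, tt$strand, rep_n(tt$mean,
                                                               nrow(tt)))
    pr <- truth$planted_processing
    if (!is.null(pr) && nrow(pr)) add(pr$pos3, pr$strand, rep_n(pr$mean,
                                                                nrow(pr)))
  }
  mu
}

.simulate_track <- function(truth, noise, kind, condition_id, replicate,
                            background_rate) {
  L <- truth$seqlengths[[1]]
  rep_id <- names(truth$seqlengths)[1]
  sf <- noise$size_factors[(replicate - 1L) %% length(noise$size_factors) + 1L]
  mu <- .planted_means(truth, kind)
  rows <- lapply(c("+", "-"), function(s) {
    m <- sf * (background_rate + mu[[s]])
    cnt <- .rnb(L, m, noise$nb_dispersion)
    nz <- which(cnt > 0)
    data.frame(replicon = rep_id, strand = s, pos = nz, count = cnt[nz],
               stringsAsFactors = FALSE)
  })
  end_coverage_track(do.call(rbind, rows), truth$seqlengths,
                     library_id = sprintf("%s_%s_rep%d", condition_id, kind,
                                          replicate),
                     condition_id = condition_id,
                     replicate_id = sprintf("rep%d", replicate),
                     library_kind = kind)
}

#' Simulate RppH-treated and untreated TSS-seq libraries
#'
#' @param truth A populated `simulation_truth`.
#' @param noise A [noise_model()].
#' @param n_replicates Biological replicates (default 3).
#' @param condition_id Condition label (default "cond1").
#' @param seed RNG seed.
#' @return List with `treated` and `untreated` lists of
#'   `end_coverage_track`.
#' @export
simulate_tss_libraries <- function(truth, noise = noise_model(),
                                   n_replicates = 3, condition_id = "cond1",
                                   seed = 1) {
  set.seed(seed + 3000L)
  list(
    treated = lapply(seq_len(n_replicates), function(r) {
      .simulate_track(truth, noise, "tss_treated", condition_id, r,
                      noise$background_rate)
    }),
    untreated = lapply(seq_len(n_replicates), function(r) {
      .simulate_track(truth, noise, "tss_untreated", condition_id, r,
                      noise$background_rate)
    }))
}

#' Simulate term-seq libraries
#'
#' @inheritParams simulate_tss_libraries
#' @return List of `termseq` `end_coverage_track` replicates.
#' @export
simulate_term_libraries <- function(truth, noise = noise_model(),
                                    n_replicates = 3, condition_id = "cond1",
                                    seed = 1) {
  set.seed(seed + 4000L)
  lapply(seq_len(n_replicates), function(r) {
    .simulate_track(truth, noise, "termseq", condition_id, r,
                    noise$termseq_background_rate)
  })
}

#' Simulate promoter windows with planted -35/-10 hexamers
#'
#' Each window is uniform random background of width `W`; a -10 hexamer is
#' placed at the offset implied by a discriminator length drawn from
#' `disc_dist` and a -35 hexamer upstream of it at a spacer drawn from
#' `spacer_dist`. Each motif base is emitted as the consensus base with its
#' per-position identity and otherwise uniformly among the three other bases
#' (identity 0.25 therefore means no information).
#'
#' @param n Number of windows.
#' @param minus35_consensus,minus10_consensus Length-6 consensus strings.
#' @param identity35,identity10 Per-position emission identities in
#'   \[0.25, 1\] (length 6).
#' @param spacer_dist,disc_dist Named probability vectors over lengths.
#' @param W Window width (default 61).
#' @param seed RNG seed.
#' @return List: `windows` (character), `truth` (data.frame with planted
#'   offsets, spacers, discriminators).
#' @export
simulate_promoter_set <- function(n, minus35_consensus = "TTGACA",
                                  minus10_consensus = "TATAAT",
                                  identity35 = rep(1, 6),
                                  identity10 = rep(1, 6),
                                  spacer_dist = c(`17` = 1),
                                  disc_dist = c(`6` = 1),
                                  W = 61, seed = 1) {
  stopifnot(nchar(minus35_consensus) == 6, nchar(minus10_consensus) == 6,
            length(identity35) == 6, length(identity10) == 6,
            all(identity35 >= 0.25 & identity35 <= 1),
            all(identity10 >= 0.25 & identity10 <= 1))
  max_reach <- max(as.integer(names(spacer_dist))) +
    max(as.integer(names(disc_dist))) + 12L
  if (max_reach > W - 1L) {
    stop("infeasible geometry: spacer + discriminator + 12 exceeds W - 1")
  }
  set.seed(seed)
  emit <- function(consensus, identity) {
    cons <- strsplit(consensus, "")[[1]]
    vapply(1:6, function(l) {
      if (stats::runif(1) < identity[l]) cons[l]
      else sample(setdiff(.BASES, cons[l]), 1)
    }, character(1))
  }
  disc <- as.integer(sample(names(disc_dist), n, replace = TRUE,
                            prob = disc_dist))
  spacer <- as.integer(sample(names(spacer_dist), n, replace = TRUE,
                              prob = spacer_dist))
  windows <- character(n)
  o10 <- W - 6L - disc
  o35 <- o10 - 6L - spacer
  for (i in seq_len(n)) {
    w <- sample(.BASES, W, replace = TRUE)
    w[o10[i]:(o10[i] + 5L)] <- emit(minus10_consensus, identity10)
    w[o35[i]:(o35[i] + 5L)] <- emit(minus35_consensus, identity35)
    windows[i] <- paste(w, collapse = "")
  }
  list(windows = windows,
       truth = data.frame(id = sprintf("prom_%04d", seq_len(n)),
                          minus10_offset = o10, minus35_offset = o35,
                          spacer = spacer, discriminator = disc,
                          stringsAsFactors = FALSE))
}

#' Default simulation scenario with full planted ground truth
#'
#' The reference study conditions used throughout the validation suite:
#' a 100-kb genome with 60 genes (2 tRNAs), 10 planted intrinsic
#' terminators, 40 TSSs (treated mean 200, untreated mean 2), 25 TTSs (10 at
#' terminator U tracts, stop 7 nt after the hairpin), 10 processing pairs
#' and 5 monophosphoryl background sites, 3 replicates per library kind,
#' NB dispersion 0.1.
#'
#' @param seed RNG seed.
#' @param length Genome length (default 1e5).
#' @param n_genes Gene count (default 60).
#' @param noise A [noise_model()].
#' @param n_terminators,n_tss,n_tts,n_processing,n_mono Planted-event load
#'   (reference defaults 10, 40, 25, 10, 5); scale these down together with
#'   `length`/`n_genes` for compact scenarios.
#' @return List: `genome`, `genes`, `truth`, `tss` (treated/untreated),
#'   `term` (termseq replicates), `terminators`.
#' @export
default_scenario <- function(seed = 1, length = 1e5, n_genes = 60,
                             noise = noise_model(), n_terminators = 10,
                             n_tss = 40, n_tts = 25, n_processing = 10,
                             n_mono = 5) {
  sim <- simulate_genome(n_genes = n_genes, length = length, seed = seed)
  sim$noise <- noise
  sim <- plant_terminators(sim, n = n_terminators, seed = seed)
  sim <- plant_truth(sim, n_tss = n_tss, n_tts = n_tts,
                     n_processing = n_processing, n_mono = n_mono,
                     seed = seed)
  tss <- simulate_tss_libraries(sim$truth, noise, 3, "cond1", seed)
  term <- simulate_term_libraries(sim$truth, noise, 3, "cond1", seed)
  list(genome = sim$genome, genes = sim$genes, truth = sim$truth,
       tss = tss, term = term, terminators = sim$truth$terminators,
       noise = noise)
}

#' Write a simulation truth table as TSV
#'
#' @param truth A `simulation_truth`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (nm in c("planted_tss", "planted_tts", "planted_processing",
               "planted_mono")) {
    if (!is.null(truth[[nm]])) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(truth[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
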