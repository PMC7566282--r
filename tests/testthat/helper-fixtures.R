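# Shared fixture builders: all synthetic, generated in code at test time.

# sparse track from a (replicon, strand, pos, count) spec
make_track <- function(df, seqlengths, library_id = "lib",
                       condition_id = "c1", replicate_id = "rep1",
                       library_kind = "termseq") {
  end_coverage_track(df, seqlengths, library_id, condition_id, replicate_id,
                     library_kind)
}

# dense-background track: counts drawn per position on both strands
make_bg_track <- function(L, rate, seed, library_id = "lib",
                          replicate_id = "rep1", dispersion = 0,
                          library_kind = "termseq", condition_id = "c1",
                          spikes = NULL) {
  set.seed(seed)
  cnt <- if (dispersion > 0) {
    stats::rnbinom(2 * L, size = 1 / dispersion, mu = rate)
  } else stats::rpois(2 * L, rate)
  df <- data.frame(replicon = "chr", strand = rep(c("+", "-"), each = L),
                   pos = rep(seq_len(L), 2), count = cnt)
  if (!is.null(spikes)) df <- rbind(df, spikes)
  make_track(df, c(chr = L), library_id, condition_id, replicate_id,
             library_kind)
}

# paired treated/untreated TSS-seq library sets over a small genome
make_tss_libs <- function(L, rate, seed, n_rep = 3, planted = NULL,
                          dispersion = 0) {
  treated <- lapply(seq_len(n_rep), function(r) {
    sp <- if (is.null(planted)) NULL else {
      set.seed(seed + 70 + r)
      data.frame(replicon = "chr", strand = planted$strand,
                 pos = planted$pos,
                 count = stats::rpois(nrow(planted), planted$treated_mean))
    }
    make_bg_track(L, rate, seed + r, sprintf("t%d", r), sprintf("rep%d", r),
                  dispersion, "tss_treated", spikes = sp)
  })
  untreated <- lapply(seq_len(n_rep), function(r) {
    sp <- if (is.null(planted)) NULL else {
      set.seed(seed + 170 + r)
      data.frame(replicon = "chr", strand = planted$strand,
                 pos = planted$pos,
                 count = stats::rpois(nrow(planted), planted$untreated_mean))
    }
    make_bg_track(L, rate, seed + 100 + r, sprintf("u%d", r),
                  sprintf("rep%d", r), dispersion, "tss_untreated",
                  spikes = sp)
  })
  list(treated = treated, untreated = untreated)
}

# Brute-force Benjamini-Hochberg: reject the largest k with p_(k) <= k q / m.
bh_reject_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# Exhaustive oracle for the 15-bp refinement: among all subsets with pairwise
# same-strand distance > window, take the one whose incidence vector in
# priority order (conditions desc, strand-aware upstream-most, position) is
# lexicographically largest.
refine_oracle <- function(catalog, window = 15) {
  n <- nrow(catalog)
  upstream_rank <- ifelse(catalog$strand == "+", catalog$position,
                          -catalog$position)
  ord <- order(-catalog$n_conditions, upstream_rank, catalog$position)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          if (a < b && catalog$strand[idx[a]] == catalog$strand[idx[b]] &&
              catalog$replicon_id[idx[a]] == catalog$replicon_id[idx[b]] &&
              abs(catalog$position[idx[a]] - catalog$position[idx[b]]) <=
                window) {
            ok <- FALSE
          }
        }
      }
    }
    if (!ok) next
    vec <- as.integer(ord %in% idx)
    if (is.null(best) || .lex_greater(vec, best$vec)) {
      best <- list(vec = vec, idx = idx)
    }
  }
  sort(best$idx)
}

.lex_greater <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

# random small site catalog for property tests
random_catalog <- function(n, L = 300, seed = 1) {
  set.seed(seed)
  pos <- sample(seq_len(L), n)
  site_calls("chr", pos, sample(c("+", "-"), n, TRUE), "tss_primary",
             mean_signal = stats::runif(n, 1, 100),
             n_conditions = sample(1:6, n, TRUE))
}
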