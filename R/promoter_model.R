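# Information-theoretic flexible two-hexamer sigma-A promoter model:
# iterative alignment of -10 hexamers maximizing information content
# ("malign"), preliminary -35 construction, and a spacer-penalized scan
# ("multiscan") with gap-surprisal penalties. Offsets are 1-based positions
# of a hexamer's first base within a promoter window whose last character is
# the TSS.

.BASES <- c("A", "C", "G", "T")

# character windows -> integer code matrix (A=1, C=2, G=3, T=4)
.seq_codes <- function(seqs) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  codes <- match(mat, .BASES)
  if (anyNA(codes)) stop("sequences may contain only A/C/G/T")
  matrix(codes, nrow = nrow(mat))
}

.entropy_bits <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(2)
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

# small-sample entropy correction for 4 symbols (large-n approximation)
.e_small_sample <- function(n) 3 / (2 * log(2) * n)

# 4 x width count matrix of hexamers given as rows of a code matrix
.count_matrix <- function(hexcodes) {
  w <- ncol(hexcodes)
  C <- matrix(0L, 4, w)
  for (l in seq_len(w)) C[, l] <- tabulate(hexcodes[, l], 4L)
  C
}

.total_information <- function(C, correct = FALSE) {
  n <- sum(C[, 1])
  e <- if (correct && n > 0) .e_small_sample(n) else 0
  sum(vapply(seq_len(ncol(C)), function(l) 2 - .entropy_bits(C[, l]) - e,
             numeric(1)))
}

#' Information content of an aligned hexamer set
#'
#' R = sum over positions of (2 - H_l - e(n)) bits, with H_l the Shannon
#' entropy of position l and e(n) the small-sample correction for four
#' symbols, e(n) = 3 / (2 ln(2) n).
#'
#' @param hexamers Character vector of equal-width (6) sequences.
#' @param correct_small_sample Apply e(n) (default TRUE).
#' @return Information content in bits.
#' @export
information_content <- function(hexamers, correct_small_sample = TRUE) {
  if (length(hexamers) < 2) stop("need >= 2 sequences")
  if (any(nchar(hexamers) != 6)) stop("hexamers must have width 6")
  C <- .count_matrix(.seq_codes(hexamers))
  .total_information(C, correct_small_sample)
}

#' Build an information-weight matrix from aligned hexamers
#'
#' Frequencies are pseudocounted (`pseudocount` per base per position);
#' individual-information weights are `riw[b, l] = 2 + log2 f(b, l) - e(n)`,
#' and `r_sequence = sum_l (2 - H_l - e(n))`.
#'
#' @param hexamers Character vector of aligned equal-width sequences.
#' @param pseudocount Pseudocount per base per position (default 0.25).
#' @return Object of class `information_matrix`: `width`, `n`, `freq`, `riw`,
#'   `r_sequence`, `counts`.
#' @export
information_matrix <- function(hexamers, pseudocount = 0.25) {
  codes <- if (is.matrix(hexamers)) hexamers else .seq_codes(hexamers)
  .information_matrix_codes(codes, pseudocount)
}

.information_matrix_codes <- function(codes, pseudocount = 0.25) {
  C <- .count_matrix(codes)
  n <- nrow(codes)
  e <- .e_small_sample(n)
  freq <- (C + pseudocount) / (n + 4 * pseudocount)
  dimnames(freq) <- list(.BASES, NULL)
  riw <- 2 + log2(freq) - e
  H <- vapply(seq_len(ncol(freq)), function(l) {
    -sum(freq[, l] * log2(freq[, l]))
  }, numeric(1))
  structure(list(width = ncol(C), n = n, counts = C, freq = freq, riw = riw,
                 r_sequence = sum(2 - H - e), pseudocount = pseudocount),
            class = "information_matrix")
}

#' @export
print.information_matrix <- function(x, ...) {
  cat(sprintf("<information_matrix> width %d, n = %d, R = %.2f bits\n",
              x$width, x$n, x$r_sequence))
  print(round(x$freq, 3))
  invisible(x)
}

#' Individual information of a sequence against a model
#'
#' Ri = sum over positions of riw at the sequence's bases, i.e.
#' `sum_l (2 + log2 f(b_l, l) - e(n))` with pseudocounted frequencies.
#'
#' @param matrix An `information_matrix`.
#' @param hexamer Character scalar (or vector) of the model's width.
#' @return Ri in bits (vectorized over `hexamer`).
#' @export
individual_information <- function(matrix, hexamer) {
  codes <- .seq_codes(hexamer)
  if (ncol(codes) != matrix$width) stop("sequence width does not match model")
  vapply(seq_len(nrow(codes)), function(i) {
    sum(matrix$riw[cbind(codes[i, ], seq_len(matrix$width))])
  }, numeric(1))
}

# Tie-aware argmax: scores within tol of the maximum are ties, resolved to
# the LAST candidate. With candidates in ascending offset order this prefers
# the largest (TSS-proximal) offset, so that translationally equivalent
# registers of a partially informative motif do not pad the discriminator
# with uninformative columns.
.argmax_last <- function(s, tol = 1e-9) {
  max(which(s >= max(s) - tol))
}

# Best offset of a hexamer within one sequence against profile counts C:
# maximizes the total information of C plus the candidate hexamer. Ties go to
# the largest offset (hex rows must be in ascending offset order).
.best_offset_idx <- function(C, hexm) {
  E <- matrix(0, ncol(C), 4)
  for (l in seq_len(ncol(C))) {
    for (b in 1:4) {
      cnt <- C[, l]
      cnt[b] <- cnt[b] + 1L
      E[l, b] <- .entropy_bits(cnt)
    }
  }
  s <- numeric(nrow(hexm))
  for (l in seq_len(ncol(C))) s <- s + (2 - E[l, hexm[, l]])
  .argmax_last(s)
}

# hexamer code rows for every allowed offset of sequence i
.hex_rows <- function(codes_row, offsets, width) {
  t(vapply(offsets, function(o) codes_row[o:(o + width - 1L)],
           integer(width)))
}

#' Iterative alignment maximizing information content (malign)
#'
#' A heuristic consensus is built by drawing `n_seed` sequences at random and
#' exhaustively scoring every combination of their allowed offsets, keeping
#' the maximum-information alignment. Every sequence is then aligned once
#' against the growing profile, the seed contribution is removed, and
#' iterative re-placement passes continue until the per-pass improvement in
#' information content drops below `tol` bits (each re-placement maximizes
#' the profile's total information, so passes never decrease it).
#'
#' @param windows Character vector of equal-length sequences.
#' @param width Motif width (default 6).
#' @param offset_range Allowed 1-based start offsets: an integer vector
#'   shared by all sequences, or a list of per-sequence vectors.
#' @param seed Integer RNG seed for the heuristic draw.
#' @param tol Convergence threshold in bits per pass (default 0.01).
#' @param max_passes Pass cap (default 100).
#' @param n_seed Number of sequences in the heuristic draw (default 5).
#' @param init_offsets Optional initial offsets (one per sequence); when
#'   supplied, the heuristic and initial-alignment stages are skipped and
#'   only re-placement passes run (used to optimize a template-seeded motif).
#' @return List: `offsets` (1-based per sequence), `matrix`
#'   (`information_matrix`), `passes`, `information` (corrected bits).
#' @param n_restarts Independent heuristic draws; the highest-information
#'   fit wins (default 3; ignored when `init_offsets` is given). Restarts
#'   guard against mixed-register local optima of the coordinate ascent.
#' @export
malign <- function(windows, width = 6, offset_range, seed = 1, tol = 0.01,
                   max_passes = 100, n_seed = 5, init_offsets = NULL,
                   n_restarts = 3) {
  if (is.null(init_offsets) && n_restarts > 1) {
    fits <- lapply(seq_len(n_restarts) - 1L, function(k) {
      .malign_once(windows, width, offset_range, seed + k, tol, max_passes,
                   n_seed, NULL)
    })
    info <- vapply(fits, function(f) f$information, numeric(1))
    return(fits[[.argmax_last(info)]])
  }
  .malign_once(windows, width, offset_range, seed, tol, max_passes, n_seed,
               init_offsets)
}

.malign_once <- function(windows, width = 6, offset_range, seed = 1,
                         tol = 0.01, max_passes = 100, n_seed = 5,
                         init_offsets = NULL) {
  codes <- .seq_codes(windows)
  n <- nrow(codes)
  offsets_list <- if (is.list(offset_range)) offset_range
                  else rep(list(sort(as.integer(offset_range))), n)
  offsets_list <- lapply(offsets_list, function(o) sort(as.integer(o)))
  if (length(offsets_list) != n) {
    stop("offset_range list must have one entry per sequence")
  }
  if (any(lengths(offsets_list) == 0)) {
    stop("offset_range empty after windowing for some sequence")
  }
  bad <- vapply(seq_len(n), function(i) {
    max(offsets_list[[i]]) + width - 1L > ncol(codes) ||
      min(offsets_list[[i]]) < 1L
  }, logical(1))
  if (any(bad)) stop("offsets out of window bounds")
  hex <- lapply(seq_len(n), function(i) {
    .hex_rows(codes[i, ], offsets_list[[i]], width)
  })
  cur <- integer(n) # index into offsets_list[[i]]

  if (is.null(init_offsets)) {
    if (n < 2) stop("need >= 2 sequences")
    set.seed(seed)
    chosen <- if (n <= n_seed) seq_len(n) else sort(sample.int(n, n_seed))
    k <- lengths(offsets_list[chosen])
    if (prod(k) > 2e6) {
      stop("offset landscape too large for the exhaustive seed stage")
    }
    grid <- as.matrix(expand.grid(lapply(k, seq_len)))
    R <- numeric(nrow(grid))
    for (l in seq_len(width)) {
      B <- matrix(vapply(seq_along(chosen), function(j) {
        hex[[chosen[j]]][grid[, j], l]
      }, integer(nrow(grid))), nrow = nrow(grid))
      cnt <- matrix(vapply(1:4, function(b) rowSums(B == b),
                           numeric(nrow(grid))), nrow = nrow(grid))
      p <- cnt / base::length(chosen)
      plogp <- ifelse(p > 0, p * log2(p), 0)
      R <- R + 2 + rowSums(plogp)
    }
    best_tuple <- grid[.argmax_last(R), ]
    seed_hex <- do.call(rbind, lapply(seq_along(chosen), function(j) {
      hex[[chosen[j]]][best_tuple[j], , drop = FALSE]
    }))
    C <- .count_matrix(seed_hex)
    # align every sequence once against the growing profile
    for (i in seq_len(n)) {
      cur[i] <- .best_offset_idx(C, hex[[i]])
      C <- C + .count_matrix(hex[[i]][cur[i], , drop = FALSE])
    }
    # eliminate the heuristic consensus contribution
    C <- C - .count_matrix(seed_hex)
  } else {
    stopifnot(length(init_offsets) == n)
    cur <- vapply(seq_len(n), function(i) {
      j <- match(init_offsets[i], offsets_list[[i]])
      if (is.na(j)) stop("init_offsets outside offset_range")
      j
    }, integer(1))
    C <- .count_matrix(t(vapply(seq_len(n), function(i) hex[[i]][cur[i], ],
                                integer(width))))
  }

  # Re-placement passes alternate with register canonicalization: a motif
  # whose flanking columns are uninformative makes the alignment register
  # translationally degenerate (shifting every placement together leaves the
  # information content unchanged). Among information-equivalent registers,
  # report the TSS-proximal one, so discriminator/spacer lengths are
  # identifiable and not padded by uninformative columns. Sequences that
  # cannot shift are re-placed against the shifted profile; a shift is kept
  # only if it costs less than `register_tol` bits. A further pass after the
  # shift lets stragglers caught in the wrong register re-join.
  register_tol <- 0.1
  passes <- 0L
  for (round in 1:3) {
    repeat {
      r_before <- .total_information(C)
      for (i in seq_len(n)) {
        C <- C - .count_matrix(hex[[i]][cur[i], , drop = FALSE])
        cur[i] <- .best_offset_idx(C, hex[[i]])
        C <- C + .count_matrix(hex[[i]][cur[i], , drop = FALSE])
      }
      passes <- passes + 1L
      if (.total_information(C) - r_before < tol || passes >= max_passes) {
        break
      }
    }
    shifted <- FALSE
    for (shift_try in seq_len(max(lengths(offsets_list)))) {
      r_now <- .total_information(C)
      can <- vapply(seq_len(n), function(i) {
        cur[i] < length(offsets_list[[i]]) &&
          offsets_list[[i]][cur[i] + 1L] == offsets_list[[i]][cur[i]] + 1L
      }, logical(1))
      if (!any(can)) break
      new_cur <- cur
      new_cur[can] <- cur[can] + 1L
      C2 <- .count_matrix(matrix(vapply(which(can), function(i) {
        hex[[i]][new_cur[i], ]
      }, integer(width)), ncol = width, byrow = TRUE))
      for (i in which(!can)) {
        new_cur[i] <- .best_offset_idx(C2, hex[[i]])
        C2 <- C2 + .count_matrix(hex[[i]][new_cur[i], , drop = FALSE])
      }
      if (.total_information(C2) >= r_now - register_tol) {
        cur <- new_cur
        C <- C2
        shifted <- TRUE
      } else break
    }
    if (!shifted || passes >= max_passes) break
  }
  final_offsets <- vapply(seq_len(n), function(i) offsets_list[[i]][cur[i]],
                          integer(1))
  hexm <- t(vapply(seq_len(n), function(i) hex[[i]][cur[i], ],
                   integer(width)))
  list(offsets = final_offsets,
       matrix = .information_matrix_codes(hexm),
       passes = passes,
       information = .total_information(.count_matrix(hexm), correct = TRUE))
}

#' Gap-surprisal penalties from a spacer-length histogram
#'
#' GS(d) = -log2(n_d / N) - min_d'(-log2(n_d' / N)); the modal spacing gets a
#' penalty of zero and unobserved spacings within `range` are assigned the
#' pseudocount.
#'
#' @param spacer_hist Named counts (names are spacer lengths).
#' @param range Optional integer vector of allowed lengths to fill in.
#' @param pseudocount Count assigned to unobserved lengths (default 0.5).
#' @return Named numeric vector of penalties in bits (>= 0, 0 at the mode).
#' @export
gap_surprisal <- function(spacer_hist, range = NULL, pseudocount = 0.5) {
  h <- spacer_hist
  if (!length(h)) stop("histogram is empty")
  counts <- as.numeric(h)
  names(counts) <- names(h)
  if (!is.null(range)) {
    full <- structure(rep(pseudocount, length(range)),
                      names = as.character(range))
    full[names(counts)] <- counts
    counts <- full
  }
  s <- -log2(counts / sum(counts))
  s - min(s)
}

#' Spacer-penalized -35 placement (multiscan)
#'
#' Given fixed -10 offsets and a preliminary -35 matrix, places each
#' sequence's -35 hexamer to maximize Ri(-35) - GS(spacer), re-deriving the
#' matrix and the gap-surprisal table from the current placements until the
#' placements are stable. Sequences whose total score
#' Ri(-10) + Ri(-35) - GS(spacer) is non-positive are dropped when
#' `drop_nonconforming` is set.
#'
#' @param windows Character vector of promoter windows (TSS is the last
#'   character).
#' @param minus10_offsets 1-based -10 hexamer start offsets, one per window.
#' @param prelim_minus35 `information_matrix` used for the initial placement.
#' @param spacer_range Allowed -35/-10 spacer lengths (default 12:22).
#' @param drop_nonconforming Drop non-positive-scoring sequences (default
#'   TRUE).
#' @param tss_ids Optional sequence identifiers.
#' @param pseudocount Frequency pseudocount (default 0.25).
#' @param max_iter Placement iteration cap (default 50).
#' @return Object of class `promoter_model`: `minus10`, `minus35`
#'   (`information_matrix`), `spacer_hist`, `discriminator_hist`,
#'   `gap_penalty`, `contributing` (per-sequence placements and scores),
#'   `dropped`.
#' @export
multiscan <- function(windows, minus10_offsets, prelim_minus35,
                      spacer_range = 12:22, drop_nonconforming = TRUE,
                      tss_ids = NULL, pseudocount = 0.25, max_iter = 50) {
  W <- unique(nchar(windows))
  stopifnot(length(W) == 1)
  tss_ids <- tss_ids %||% sprintf("seq_%04d", seq_along(windows))
  codes <- .seq_codes(windows)
  n <- length(windows)
  minus10_offsets <- as.integer(minus10_offsets)
  feas <- lapply(seq_len(n), function(i) {
    o35 <- minus10_offsets[i] - 6L - spacer_range
    ok <- o35 >= 1L
    list(o35 = o35[ok], spacer = spacer_range[ok])
  })
  drop_geom <- vapply(feas, function(f) length(f$o35) == 0, logical(1))
  if (any(drop_geom)) {
    warning(sum(drop_geom), " sequence(s) dropped: spacer range infeasible")
  }
  active <- which(!drop_geom)
  hex35 <- lapply(active, function(i) {
    .hex_rows(codes[i, ], sort(feas[[i]]$o35), 6L)
  })
  off35_sorted <- lapply(active, function(i) sort(feas[[i]]$o35))
  # initial placement: best Ri against the preliminary matrix, no penalty
  place <- vapply(seq_along(active), function(j) {
    ri <- vapply(seq_len(nrow(hex35[[j]])), function(r) {
      sum(prelim_minus35$riw[cbind(hex35[[j]][r, ], 1:6)])
    }, numeric(1))
    .argmax_last(ri)
  }, integer(1))
  spacer_of <- function(j, idx) {
    minus10_offsets[active[j]] - 6L - off35_sorted[[j]][idx]
  }
  for (iter in seq_len(max_iter)) {
    hexm <- t(vapply(seq_along(active), function(j) hex35[[j]][place[j], ],
                     integer(6)))
    m35 <- .information_matrix_codes(hexm, pseudocount)
    spacers <- vapply(seq_along(active), function(j) spacer_of(j, place[j]),
                      integer(1))
    gs <- gap_surprisal(table(spacers), range = spacer_range)
    new_place <- vapply(seq_along(active), function(j) {
      sc <- vapply(seq_len(nrow(hex35[[j]])), function(r) {
        sum(m35$riw[cbind(hex35[[j]][r, ], 1:6)]) -
          gs[[as.character(spacer_of(j, r))]]
      }, numeric(1))
      .argmax_last(sc)
    }, integer(1))
    if (all(new_place == place)) break
    place <- new_place
  }
  build <- function(act_idx, place_idx) {
    hex10 <- t(vapply(act_idx, function(i) {
      codes[i, minus10_offsets[i]:(minus10_offsets[i] + 5L)]
    }, integer(6)))
    m10 <- .information_matrix_codes(hex10, pseudocount)
    hexm <- t(vapply(seq_along(act_idx), function(j) {
      hex35[[match(act_idx[j], active)]][place_idx[j], ]
    }, integer(6)))
    m35 <- .information_matrix_codes(hexm, pseudocount)
    spacers <- vapply(seq_along(act_idx), function(j) {
      spacer_of(match(act_idx[j], active), place_idx[j])
    }, integer(1))
    gs <- gap_surprisal(table(spacers), range = spacer_range)
    ri10 <- vapply(seq_along(act_idx), function(j) {
      sum(m10$riw[cbind(hex10[j, ], 1:6)])
    }, numeric(1))
    ri35 <- vapply(seq_along(act_idx), function(j) {
      sum(m35$riw[cbind(hexm[j, ], 1:6)])
    }, numeric(1))
    score <- ri10 + ri35 - gs[as.character(spacers)]
    list(m10 = m10, m35 = m35, spacers = spacers, gs = gs, ri10 = ri10,
         ri35 = ri35, score = score)
  }
  act <- active
  plc <- place
  dropped <- tss_ids[drop_geom]
  repeat {
    b <- build(act, plc)
    if (!drop_nonconforming || all(b$score > 0)) break
    keep <- b$score > 0
    if (sum(keep) < 2) stop("too few conforming sequences")
    dropped <- c(dropped, tss_ids[act[!keep]])
    act <- act[keep]
    plc <- plc[keep]
  }
  o35_final <- vapply(seq_along(act), function(j) {
    off35_sorted[[match(act[j], active)]][plc[j]]
  }, integer(1))
  disc <- W - 6L - minus10_offsets[act]
  structure(list(
    minus10 = b$m10, minus35 = b$m35,
    spacer_hist = table(b$spacers),
    discriminator_hist = table(disc),
    gap_penalty = b$gs,
    contributing = data.frame(tss_id = tss_ids[act],
                              minus10_offset = minus10_offsets[act],
                              minus35_offset = o35_final,
                              spacer = b$spacers, discriminator = disc,
                              ri_minus10 = b$ri10, ri_minus35 = b$ri35,
                              score = b$score, stringsAsFactors = FALSE),
    dropped = dropped, window_width = W), class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("<promoter_model> %d contributing promoters (%d dropped)\n",
              nrow(x$contributing), length(x$dropped)))
  cat(sprintf("  -10 R = %.2f bits, -35 R = %.2f bits\n",
              x$minus10$r_sequence, x$minus35$r_sequence))
  cat("  spacer mode:", names(which.max(x$spacer_hist)),
      " discriminator mode:", names(which.max(x$discriminator_hist)), "\n")
  invisible(x)
}

#' Extract fixed-width promoter windows upstream of TSSs
#'
#' Windows are in transcript orientation with the TSS as the last character
#' (genomic TSS-W+1..TSS on "+", the reverse complement of TSS..TSS+W-1 on
#' "-"). TSSs too close to a replicon end, and windows containing N, are
#' skipped with a warning.
#'
#' @param catalog TSS site catalog.
#' @param genome `DNAStringSet`.
#' @param W Window width in nt (default 61).
#' @return data.frame: `tss_id`, `window`.
#' @export
extract_promoter_windows <- function(catalog, genome, W = 61) {
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    chr <- genome[[catalog$replicon_id[i]]]
    pos <- catalog$position[i]
    if (catalog$strand[i] == "+") {
      if (pos - W + 1L < 1L) return(NULL)
      s <- as.character(Biostrings::subseq(chr, pos - W + 1L, pos))
    } else {
      if (pos + W - 1L > length(chr)) return(NULL)
      s <- .revcomp(as.character(Biostrings::subseq(chr, pos, pos + W - 1L)))
    }
    if (grepl("N", s, fixed = TRUE)) return(NULL)
    data.frame(tss_id = catalog$site_id[i], window = s,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped) {
    warning(skipped, " TSS window(s) skipped (out of range or containing N)")
  }
  res <- do.call(rbind, out)
  res %||% data.frame(tss_id = character(), window = character(),
                      stringsAsFactors = FALSE)
}

#' Build the full flexible promoter model
#'
#' Pipeline: malign over the -10 offset range implied by the discriminator
#' search range; sequences with non-positive Ri(-10) are dropped; a
#' preliminary -35 profile is built at the default spacer-implied positions
#' and optimized with template-seeded malign passes; multiscan with
#' gap-surprisal penalties finalizes the -35 placements and the model.
#'
#' @param windows data.frame from [extract_promoter_windows()] (or a
#'   character vector of windows).
#' @param disc_range Discriminator (TSS to -10) search range (default 3:12
#'   nt).
#' @param spacer_range -35/-10 spacer search range (default 12:22 nt).
#' @param seed RNG seed for the malign heuristic.
#' @param default_spacer Spacer used to seed the preliminary -35 profile
#'   (default 17).
#' @param tol,max_passes malign convergence controls.
#' @param min_sequences Minimum surviving sequences (default 10).
#' @param drop_nonconforming Passed to [multiscan()].
#' @return A `promoter_model`.
#' @export
build_promoter_model <- function(windows, disc_range = 3:12,
                                 spacer_range = 12:22, seed = 1,
                                 default_spacer = 17, tol = 0.01,
                                 max_passes = 100, min_sequences = 10,
                                 drop_nonconforming = TRUE) {
  if (is.data.frame(windows)) {
    tss_ids <- windows$tss_id
    seqs <- windows$window
  } else {
    seqs <- windows
    tss_ids <- sprintf("seq_%04d", seq_along(seqs))
  }
  W <- unique(nchar(seqs))
  if (length(W) != 1) stop("windows must have equal width")
  W <- as.integer(W)
  o10_range <- sort(W - 6L - as.integer(disc_range))
  m10_fit <- malign(seqs, width = 6, offset_range = o10_range, seed = seed,
                    tol = tol, max_passes = max_passes)
  ri10 <- individual_information(
    m10_fit$matrix,
    substr(seqs, m10_fit$offsets, m10_fit$offsets + 5L))
  keep <- ri10 > 0
  if (sum(keep) < min_sequences) {
    stop("too few sequences conform to the -10 model (",
         sum(keep), " < ", min_sequences, ")")
  }
  dropped_minus10 <- tss_ids[!keep]
  seqs <- seqs[keep]
  tss_ids <- tss_ids[keep]
  o10 <- m10_fit$offsets[keep]
  off35_ranges <- lapply(seq_along(seqs), function(i) {
    o <- o10[i] - 6L - spacer_range
    o[o >= 1L]
  })
  init35 <- pmax(1L, o10 - 6L - as.integer(default_spacer))
  init35 <- vapply(seq_along(init35), function(i) {
    r <- off35_ranges[[i]]
    r[which.min(abs(r - init35[i]))]
  }, integer(1))
  m35_fit <- malign(seqs, width = 6, offset_range = off35_ranges,
                    seed = seed, tol = tol, max_passes = max_passes,
                    init_offsets = init35)
  model <- multiscan(seqs, o10, m35_fit$matrix, spacer_range = spacer_range,
                     drop_nonconforming = drop_nonconforming,
                     tss_ids = tss_ids)
  model$dropped <- c(dropped_minus10, model$dropped)
  model
}

#' Write a position frequency matrix as logo-ready text
#'
#' @param x An `information_matrix` or a 4 x width frequency/count matrix
#'   with rows A, C, G, T.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(x, path) {
  m <- if (inherits(x, "information_matrix")) x$freq else x
  df <- data.frame(position = seq_len(ncol(m)), t(m))
  colnames(df) <- c("position", .BASES)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
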