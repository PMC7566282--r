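# TSS calling: prefilters, the NB exceedance test, adjacent-site resolution,
# condition merging, refinement, coalescing and reference validation.

test_that("prefilter keeps replicate-averaged treated counts at the 95th pct", {
  # 100 positions with averaged treated counts 1..100: the type-7 percentile
  # of 1..100 at 95 is 95.05, so positions 96..100 pass
  L <- 100L
  mk <- function(id, rep, kind, counts) {
    make_track(data.frame(replicon = "chr", strand = "+", pos = 1:L,
                          count = counts), c(chr = L), id, "c1", rep, kind)
  }
  tr <- list(mk("t1", "rep1", "tss_treated", 1:100),
             mk("t2", "rep2", "tss_treated", 1:100))
  un <- list(mk("u1", "rep1", "tss_untreated", rep(1, 100)),
             mk("u2", "rep2", "tss_untreated", rep(1, 100)))
  cand <- prefilter_positions(tr, un)
  expect_identical(sort(cand$pos), 96:100)
  # a position nonzero only in untreated survives the zero filter but still
  # needs the treated average to clear the cutoff
  un2 <- list(mk("u1", "rep1", "tss_untreated", c(50, rep(0, 99))),
              mk("u2", "rep2", "tss_untreated", c(50, rep(0, 99))))
  tr2 <- list(mk("t1", "rep1", "tss_treated", c(0, 0, 1:98)),
              mk("t2", "rep2", "tss_treated", c(0, 0, 1:98)))
  cand2 <- prefilter_positions(tr2, un2)
  expect_false(1L %in% cand2$pos)
  # all-zero tracks give an empty candidate set with a warning
  z <- list(mk("t1", "rep1", "tss_treated", rep(0, 100)),
            mk("t2", "rep2", "tss_treated", rep(0, 100)))
  zu <- list(mk("u1", "rep1", "tss_untreated", rep(0, 100)),
             mk("u2", "rep2", "tss_untreated", rep(0, 100)))
  expect_warning(c0 <- prefilter_positions(z, zu), "nonzero")
  expect_identical(nrow(c0), 0L)
})

test_that("size factors recover proportional library scaling", {
  set.seed(4)
  base <- matrix(stats::rpois(400, 10), ncol = 4)
  mat <- cbind(base[, 1:2], 2 * base[, 1])
  sf <- estimate_size_factors(mat)
  expect_equal(sf[3] / sf[1], 2, tolerance = 1e-8)
  mat0 <- cbind(base, lib_dead = 0)
  expect_error(estimate_size_factors(mat0), "lib_dead")
})

test_that("compiled NB Wald test matches the glm reference fit", {
  set.seed(3)
  X <- cbind(intercept = 1, treat = rep(c(1, 0), each = 3))
  sf <- c(1, 1.2, 0.9, 1.1, 0.8, 1)
  Y <- matrix(stats::rnbinom(240, mu = 20, size = 10), ncol = 6)
  res <- tuatlas:::.nb_wald_matrix(Y, X, sf, 0.1)
  for (i in seq_len(nrow(Y))) {
    ref <- tuatlas:::.nb_wald_glm(Y[i, ], X, sf, 0.1)
    expect_equal(res$p[i], ref$p, tolerance = 1e-4)
    expect_equal(res$lfc[i], ref$lfc, tolerance = 1e-4)
  }
})

test_that("exceedance testing is calibrated on null data and powered on planted signal", {
  # null: treated and untreated drawn from the same distribution
  libs <- make_tss_libs(L = 1500L, rate = 2, seed = 21)
  cand <- prefilter_positions(libs$treated, libs$untreated)
  exc <- test_end_exceedance(cand, libs$treated, libs$untreated)
  calls <- call_tss_for_condition(exc, "c1")
  expect_lt(nrow(calls) / nrow(cand), 0.02)
  # power: planted position with treated mean 200 vs untreated mean 2
  hits <- vapply(1:40, function(s) {
    planted <- data.frame(pos = 700L, strand = "+", treated_mean = 200,
                          untreated_mean = 2)
    libs <- make_tss_libs(L = 1500L, rate = 2, seed = 500 + s,
                          planted = planted)
    cand <- prefilter_positions(libs$treated, libs$untreated)
    calls <- call_tss_for_condition(
      test_end_exceedance(cand, libs$treated, libs$untreated), "c1")
    any(calls$position == 700L & calls$strand == "+")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("exceedance direction and significance agree with DESeq2 on a planted fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  n <- 120
  mu <- stats::rexp(n, 1 / 20) + 1
  Y <- cbind(matrix(stats::rnbinom(3 * n, mu = mu, size = 10), ncol = 3),
             matrix(stats::rnbinom(3 * n, mu = mu, size = 10), ncol = 3))
  Y[1, 1:3] <- stats::rpois(3, 400)  # planted treated-specific signal
  colnames(Y) <- paste0("s", 1:6)
  cand <- data.frame(replicon = "chr", strand = "+", pos = seq_len(n),
                     mean_treated = rowMeans(Y[, 1:3]))
  own <- tuatlas:::.nb_wald_matrix(Y, cbind(intercept = 1,
                                            treat = rep(c(1, 0), each = 3)),
                                   rep(1, 6), 0.1)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      Y, S4Vectors::DataFrame(cond = factor(rep(c("t", "u"), each = 3),
                                            levels = c("u", "t"))), ~cond)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, altHypothesis = "greater")
  })
  # the planted row is the clear top hit in both engines
  expect_identical(which.min(own$p), 1L)
  expect_identical(as.integer(which.min(res$pvalue)), 1L)
  expect_lt(own$p[1], 1e-6)
  # and log fold-change direction agrees on well-measured rows
  well <- rowSums(Y) > 60
  expect_gt(stats::cor(own$lfc[well], res$log2FoldChange[well]), 0.8)
})

test_that("TSS calls require FDR below threshold in either design plus positive fold", {
  exc <- data.frame(replicon = "chr", strand = "+", pos = 1:4,
                    mean_treated = 10, log2_fold = c(2, 2, 2, -1),
                    p_value_paired = 0.001, p_value_unpaired = 0.001,
                    fdr_paired = c(0.01, 0.2, 0.2, 0.01),
                    fdr_unpaired = c(0.2, 0.2, 0.01, 0.01),
                    mean_treated_norm = 10)
  calls <- call_tss_for_condition(exc, "c1")
  expect_setequal(calls$position, c(1L, 3L))  # either/or; direction gate
})

test_that("adjacent TSS runs resolve to the highest-coverage primary", {
  cat1 <- site_calls("chr", c(100L, 101L, 102L, 300L), rep("+", 4),
                     "tss_primary", mean_signal = c(10, 40, 12, 7))
  res <- resolve_adjacent_tss(cat1)
  expect_identical(res$site_kind[res$position == 101], "tss_primary")
  expect_setequal(res$position[res$site_kind == "tss_secondary"],
                  c(100L, 102L))
  expect_identical(res$site_kind[res$position == 300], "tss_primary")
  # ties go to the strand-aware upstream-most position
  tie_p <- resolve_adjacent_tss(site_calls("chr", c(50L, 51L), c("+", "+"),
                                           "tss_primary", mean_signal = 40))
  expect_identical(tie_p$site_kind[tie_p$position == 50], "tss_primary")
  tie_m <- resolve_adjacent_tss(site_calls("chr", c(50L, 51L), c("-", "-"),
                                           "tss_primary", mean_signal = 40))
  expect_identical(tie_m$site_kind[tie_m$position == 51], "tss_primary")
  # property: no two adjacent primaries on random catalogs
  for (s in 1:20) {
    res <- resolve_adjacent_tss(random_catalog(30, L = 60, seed = s))
    prim <- res[res$site_kind == "tss_primary", ]
    for (st in c("+", "-")) {
      p <- sort(prim$position[prim$strand == st])
      if (length(p) > 1) expect_true(all(diff(p) > 1))
    }
  }
})

test_that("condition merging drops secondaries and counts detections", {
  c1 <- resolve_adjacent_tss(site_calls("chr", c(100L, 101L), c("+", "+"),
                                        "tss_primary",
                                        mean_signal = c(40, 10),
                                        conditions_detected = "A"))
  c2 <- resolve_adjacent_tss(site_calls("chr", c(100L, 250L), c("+", "+"),
                                        "tss_primary", mean_signal = 25,
                                        conditions_detected = "B"))
  c3 <- resolve_adjacent_tss(site_calls("chr", 101L, "+", "tss_primary",
                                        mean_signal = 60,
                                        conditions_detected = "C"))
  merged <- merge_conditions(list(c1, c2, c3))
  # 100 was primary in A and B -> n = 2; 101 was secondary in A (dropped
  # there) but primary in C -> kept with n = 1
  expect_identical(merged$n_conditions[merged$position == 100], 2L)
  expect_identical(merged$n_conditions[merged$position == 101], 1L)
  expect_identical(merged$n_conditions[merged$position == 250], 1L)
  # mean_signal maximized over conditions of detection
  expect_identical(merged$mean_signal[merged$position == 100], 40)
  # disjoint catalogs just concatenate
  d1 <- resolve_adjacent_tss(site_calls("chr", c(10L, 30L), "+",
                                        "tss_primary", mean_signal = 1))
  d2 <- resolve_adjacent_tss(site_calls("chr", c(60L, 90L), "+",
                                        "tss_primary", mean_signal = 1))
  expect_identical(nrow(merge_conditions(list(d1, d2))), 4L)
})

test_that("15-bp refinement keeps most-condition sites, ties upstream-most", {
  mk <- function(pos, strand, nc) {
    site_calls("chr", pos, strand, "tss_primary", mean_signal = 1,
               n_conditions = nc)
  }
  r1 <- refine_for_promoter_model(mk(c(100L, 110L, 130L), "+", c(3L, 1L, 2L)))
  expect_setequal(r1$position, c(100L, 130L))
  r2 <- refine_for_promoter_model(mk(c(100L, 112L), "+", c(2L, 2L)))
  expect_identical(r2$position, 100L)
  r2m <- refine_for_promoter_model(mk(c(100L, 112L), "-", c(2L, 2L)))
  expect_identical(r2m$position, 112L)
  # exhaustive-subset oracle agreement on random instances with <= 12 sites
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:10, 1)
    cat <- site_calls("chr", sample.int(80, n),
                      sample(c("+", "-"), n, TRUE), "tss_primary",
                      mean_signal = 1, n_conditions = sample(1:6, n, TRUE))
    got <- sort(match(refine_for_promoter_model(cat)$site_id, cat$site_id))
    expect_identical(got, refine_oracle(cat))
  }
  # no two retained same-strand sites within 15 bp, ever
  for (s in 26:35) {
    ref <- refine_for_promoter_model(random_catalog(25, L = 200, seed = s))
    for (st in c("+", "-")) {
      p <- sort(ref$position[ref$strand == st])
      if (length(p) > 1) expect_true(all(diff(p) > 15))
    }
  }
})

test_that("coalescing clusters TSSs to the max-count position and is idempotent", {
  cat1 <- site_calls("chr", c(200L, 208L), c("+", "+"), "tss_primary",
                     mean_signal = c(50, 9))
  co <- coalesce_tss(cat1)
  expect_identical(co$position, 200L)
  expect_identical(co$n_sites, 2L)
  cat2 <- site_calls("chr", c(200L, 211L), c("+", "+"), "tss_primary",
                     mean_signal = c(50, 9))
  expect_identical(nrow(coalesce_tss(cat2)), 2L)
  for (s in 1:15) {
    x <- coalesce_tss(random_catalog(40, L = 150, seed = s))
    y <- coalesce_tss(x[, names(x) != "n_sites"])
    expect_identical(y$position, x$position)
  }
})

test_that("reference validation measures distances against a rotated control", {
  cat1 <- site_calls("chr", c(100L, 500L, 900L), "+", "tss_primary",
                     mean_signal = 1)
  ref_same <- data.frame(replicon_id = "chr", position = c(100L, 500L, 900L))
  v <- validate_against_reference(cat1, ref_same, "distance",
                                  c(chr = 1000L))
  expect_identical(v$median_real, 0)
  v2 <- validate_against_reference(
    cat1, data.frame(replicon_id = "chr", position = 513L), "distance",
    c(chr = 1000L))
  expect_identical(v2$median_real, 13)
  expect_error(validate_against_reference(cat1[0, ], ref_same, "distance",
                                          c(chr = 1000L)), "empty")
  # a catalog enriched at the references beats its rotation
  set.seed(42)
  refs <- data.frame(replicon_id = "chr",
                     position = sort(sample.int(99000, 50)))
  catalog <- site_calls("chr",
                        refs$position + sample(-5:5, 50, TRUE),
                        "+", "tss_primary", mean_signal = 1)
  v3 <- validate_against_reference(catalog, refs, "distance",
                                   c(chr = 100000L))
  expect_lt(v3$p_value, 0.01)
  expect_lt(v3$median_real, v3$median_rotated)
})
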