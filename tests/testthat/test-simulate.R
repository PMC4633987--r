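# Synthetic-data generator: determinism, configured truth recovery, and the
# statistical structure of the simulated observables.

test_that("the genome echoes the configuration and rejects bad lengths", {
  cfg <- sim_config(chrom_lengths = c(chrA = 5000000L, chrB = 5000000L))
  g <- simulate_genome(cfg)
  expect_equal(names(g), c("chrA", "chrB"))
  expect_equal(unname(g), c(5000000L, 5000000L))
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  expect_error(sim_config(chrom_lengths = c(chr1 = 0L)), "positive")
  expect_error(sim_config(chrom_lengths = c(1000L, 1000L)), "names")
})

test_that("truth simulation is byte-deterministic under a fixed seed", {
  cfg <- fast_config(seed = 42)
  g <- simulate_genome(cfg)
  t1 <- simulate_truth(g, cfg)
  t2 <- simulate_truth(g, cfg)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  c1 <- simulate_chip_counts(t1, g, "K27ac", cfg$stages[1], cfg)
  c2 <- simulate_chip_counts(t2, g, "K27ac", cfg$stages[1], cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_equal(t1$meta$seed, 42)
})

test_that("degenerate transition chains behave as configured", {
  id4 <- diag(4)
  dimnames(id4) <- dimnames(default_transitions())
  cfg <- fast_config(seed = 3, transitions = id4)
  tr <- simulate_truth(simulate_genome(cfg), cfg)
  st <- tr$enhancers
  expect_equal(st$state_ProB, st$state_HSC)
  expect_equal(st$state_MatB, st$state_HSC)

  pa <- default_transitions()
  pa["primed", ] <- c(1, 0, 0, 0)  # primed -> active surely
  cfg2 <- fast_config(seed = 4, transitions = pa)
  tr2 <- simulate_truth(simulate_genome(cfg2), cfg2)
  primed1 <- tr2$enhancers$state_HSC == "primed"
  expect_true(all(tr2$enhancers$state_ProB[primed1] == "active"))
})

test_that("configured transition probabilities are recovered in the truth", {
  cfg <- sim_config(seed = 5)  # default: 500 enhancers, primed->active 0.04
  tr <- simulate_truth(simulate_genome(cfg), cfg)
  primed1 <- tr$enhancers$state_HSC == "primed"
  n <- sum(primed1)
  frac <- mean(tr$enhancers$state_ProB[primed1] == "active")
  tol <- 3 * sqrt(0.04 * 0.96 / n)
  expect_lt(abs(frac - 0.04), tol)
})

test_that("enhancer placement respects TSS distance and promoter overlap", {
  cfg <- fast_config(seed = 6)
  tr <- simulate_truth(simulate_genome(cfg), cfg)
  ov <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(tr$enhancers$chrom,
                           IRanges::IRanges(tr$enhancers$start + 1,
                                            tr$enhancers$end)),
    GenomicRanges::GRanges(tr$promoters$chrom,
                           IRanges::IRanges(tr$promoters$start + 1,
                                            tr$promoters$end)))
  expect_true(all(ov == 0))
  # >= 2 kb from every TSS
  for (i in seq_len(nrow(tr$enhancers))) {
    same <- tr$genes$chrom == tr$enhancers$chrom[i]
    tss <- ifelse(tr$genes$strand[same] == "+", tr$genes$tx_start[same],
                  tr$genes$tx_end[same])
    d <- pmax(0, pmax(tr$enhancers$start[i] - tss,
                      tss - tr$enhancers$end[i]))
    expect_gte(min(d), 2000)
  }
})

test_that("background windows have near-zero mean enrichment at fold 1", {
  # all-closed enhancers => every window is background
  cfg <- fast_config(seed = 8,
                     state_probs = c(active = 0, primed = 0, poised = 0,
                                     closed = 1))
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg)
  sc <- simulate_chip_counts(tr, g, "K27ac", "HSC", cfg)
  joint <- normalize_libraries(count_matrix(
    sc$grid, cbind(sc$chip$counts, sc$input$counts),
    c(sc$chip$totals, sc$input$totals)))
  e <- enrichment(rowMeans(joint$counts[, 1:2]),
                  rowMeans(joint$counts[, 3:4]))
  # exclude promoter-free check: K27ac carries no promoter signal
  expect_gt(length(e), 1000)
  expect_lt(abs(mean(e)), 0.1)
})

test_that("marked windows match the closed-form expected enrichment", {
  cfg <- fast_config(seed = 9, state_probs = c(active = 1, primed = 0,
                                               poised = 0, closed = 0))
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg)
  sc <- simulate_chip_counts(tr, g, "K27ac", "HSC", cfg)
  # windows fully inside active enhancers: raw chip mean 160 (fold 8 x
  # background 20), raw input mean 20
  enh <- tr$enhancers
  gr_win <- GenomicRanges::GRanges(sc$grid$chrom,
                                   IRanges::IRanges(sc$grid$start + 1,
                                                    sc$grid$end))
  gr_enh <- GenomicRanges::GRanges(enh$chrom,
                                   IRanges::IRanges(enh$start + 1, enh$end))
  inside <- IRanges::overlapsAny(gr_win, gr_enh, type = "within")
  e <- enrichment(rowMeans(sc$chip$counts[inside, , drop = FALSE]),
                  rowMeans(sc$input$counts[inside, , drop = FALSE]))
  expected <- log2((20 * 8 + 8) / (20 + 8))
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - expected), max(3 * se, 0.05))
})

test_that("doubling one replicate's depth is undone by normalization", {
  cfg <- fast_config(seed = 10)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg)
  base <- simulate_chip_counts(tr, g, "K4me1", "HSC", cfg)
  deep <- simulate_chip_counts(tr, g, "K4me1", "HSC", cfg,
                               depth_factors = c(2, 1))
  mean_track <- function(sc) {
    joint <- normalize_libraries(count_matrix(
      sc$grid, cbind(sc$chip$counts, sc$input$counts),
      c(sc$chip$totals, sc$input$totals)))
    nc <- ncol(sc$chip$counts)
    enrichment(rowMeans(joint$counts[, 1:nc, drop = FALSE]),
               rowMeans(joint$counts[, -(1:nc), drop = FALSE]))
  }
  e_base <- mean_track(base)
  e_deep <- mean_track(deep)
  # same expectation: mean difference over all windows is ~0
  expect_lt(abs(mean(e_deep) - mean(e_base)), 0.02)
  expect_gt(cor(e_base, e_deep), 0.9)
})

test_that("unknown marks and stages are rejected", {
  cfg <- fast_config(seed = 1)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg)
  expect_error(simulate_chip_counts(tr, g, "K9me3", "HSC", cfg),
               "unknown mark")
  expect_error(simulate_chip_counts(tr, g, "K4me1", "LSK", cfg),
               "unknown stage")
})

test_that("the K9me2 track obeys its degenerate and chain limits", {
  cfg <- fast_config(seed = 12, k9_stay = 1)
  g <- simulate_genome(cfg)
  k9 <- simulate_k9me2_track(g, cfg)
  # stay-probability 1: one state per chromosome, so <= 1 domain each
  expect_lte(nrow(k9$domains), length(g))
  for (ch in unique(k9$track$chrom)) {
    expect_equal(length(unique(k9$states[k9$track$chrom == ch])), 1)
  }

  # near-zero SD: emissions equal their state mean
  cfg2 <- fast_config(seed = 13, k9_sd = 1e-9)
  k92 <- simulate_k9me2_track(simulate_genome(cfg2), cfg2)
  expect_equal(k92$track$score, cfg2$k9_means[k92$states],
               tolerance = 1e-6)
  expect_error(fast_config(k9_sd = 0), "positive")

  # stay frequency within 3 binomial SDs at stay = 0.99
  cfg3 <- sim_config(seed = 14, k9_stay = 0.99,
                     chrom_lengths = c(chr1 = 10000000L))
  k93 <- simulate_k9me2_track(simulate_genome(cfg3), cfg3)
  s <- k93$states
  n <- length(s) - 1
  expect_gt(n, 1500)
  stay_freq <- mean(s[-1] == s[-length(s)])
  expect_lt(abs(stay_freq - 0.99), 3 * sqrt(0.99 * 0.01 / n))
})

test_that("RNA counts scale with length and active-enhancer count", {
  cfg <- sim_config(seed = 15)
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg)
  rna <- simulate_rnaseq(tr, cfg, "HSC")
  ex <- tr$expression$HSC

  # silent-only genome: total counts below 1% of configured depth
  cfg_s <- fast_config(seed = 16, expr_base_prob = 0,
                       state_probs = c(active = 0, primed = 0, poised = 0,
                                       closed = 1))
  tr_s <- simulate_truth(simulate_genome(cfg_s), cfg_s)
  expect_true(all(tr_s$expression$HSC$class == "silent"))
  rna_s <- simulate_rnaseq(tr_s, cfg_s, "HSC")
  expect_lt(sum(rna_s$count), 0.01 * cfg_s$rna_depth)

  # expressed genes with active enhancers outexpress those without
  expressed <- ex$class == "expressed"
  with_act <- expressed & ex$n_active >= 1
  without <- expressed & ex$n_active == 0
  len_norm <- rna$count / rna$exonic_length
  expect_gt(mean(len_norm[with_act]), mean(len_norm[without]))
})
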