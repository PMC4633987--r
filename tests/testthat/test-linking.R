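# Expression quantification/binarization and two-pass enhancer-promoter
# assignment.

test_that("exonic union length handles overlap and matches the oracle", {
  expect_equal(exonic_union_length(c(0, 50), c(100, 150)), 150)
  expect_equal(exonic_union_length(c(0, 200), c(100, 300)), 200)
  expect_error(exonic_union_length(integer(0), integer(0)), "no exons")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:20, 1)
    s <- sample(0:2000, n)
    e <- s + sample(50:400, n, replace = TRUE)
    expect_equal(exonic_union_length(s, e), oracle_exonic_length(s, e))
  }
})

test_that("expression normalization scales by depth and exonic length", {
  # equal counts, lengths 1000 vs 2000 -> normalized ratio 2:1
  q <- quantify_expression(c(100, 100), c(1000, 2000))
  expect_equal(q$norm_sample1[1] / q$norm_sample1[2], 2)
  # single sample at mean depth: library factor 1, only length scaling
  expect_equal(q$norm_sample1[1], 100 * mean(c(1000, 2000)) / 1000)
  # doubling all counts and depth leaves two-sample values unchanged
  m <- cbind(a = c(100, 50), b = c(200, 100))
  q1 <- quantify_expression(m, c(1000, 1000))
  q2 <- quantify_expression(2 * m, c(1000, 1000))
  # sample b is at double depth: normalization equalizes a and b
  expect_equal(q1$norm_a, q1$norm_b)
  expect_equal(q2$norm_a / 2, q1$norm_a)
  expect_error(quantify_expression(c(1, 2), c(0, 100)), "positive")
})

test_that("binarization thresholds inclusively and finds the antimode", {
  v <- c(0, 0.5, 10, 200)
  cls <- binarize_expression(v, threshold = 0)
  expect_equal(as.character(cls), rep("expressed", 4))
  expect_equal(as.character(binarize_expression(v, threshold = 1000)),
               rep("silent", 4))
  expect_equal(as.character(binarize_expression(v, threshold = 10)),
               c("silent", "silent", "expressed", "expressed"))

  # bimodal synthetic distribution: antimode separates the populations
  set.seed(30)
  low <- exp(rnorm(200, 0, 0.5))
  high <- exp(rnorm(200, 6, 0.5))
  cls2 <- binarize_expression(c(low, high))
  expect_equal(as.character(cls2),
               rep(c("silent", "expressed"), each = 200))
})

test_that("binarization agrees with truth classes on synthetic data", {
  cfg <- fast_config(seed = 31)
  tr <- simulate_truth(simulate_genome(cfg), cfg)
  rna <- simulate_rnaseq(tr, cfg, "HSC")
  q <- quantify_expression(rna$count, rna$exonic_length, rna$gene)
  cls <- binarize_expression(q$norm_sample1)
  agree <- mean(cls == tr$expression$HSC$class)
  expect_gte(agree, 0.95)
})

test_that("two-pass assignment honours distance cap and active exclusion", {
  prom <- data.frame(chrom = "chr1", start = 99000, end = 101000,
                     gene = "g1", strand = "+", tss = 100000,
                     stringsAsFactors = FALSE)
  # enhancer midpoint 600 kb away -> unassigned
  far <- data.frame(id = "e1", chrom = "chr1", start = 699000, end = 701000,
                    state = "active", stringsAsFactors = FALSE)
  expect_equal(nrow(assign_enhancers(far, prom)), 0)

  # active at 10 kb and primed at 20 kb from the sole promoter:
  # active linked, primed left unassigned (promoter consumed)
  both <- data.frame(id = c("a", "p"), chrom = "chr1",
                     start = c(109000, 119000), end = c(111000, 121000),
                     state = c("active", "primed"), stringsAsFactors = FALSE)
  links <- assign_enhancers(both, prom)
  expect_equal(links$enhancer, "a")
  expect_equal(links$gene, "g1")
  expect_equal(links$distance, 10000)
})

test_that("assignment equals the exhaustive two-pass oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    n_e <- sample(1:30, 1)
    n_p <- sample(1:30, 1)
    enh <- data.frame(
      id = sprintf("e%02d", 1:n_e),
      chrom = sample(c("chr1", "chr2"), n_e, replace = TRUE),
      start = sample(seq(0, 900000, 1000), n_e),
      state = sample(c("active", "primed", "poised"), n_e, replace = TRUE),
      stringsAsFactors = FALSE)
    enh$end <- enh$start + 2000
    tss <- sample(seq(0, 900000, 500), n_p)
    prom <- data.frame(chrom = sample(c("chr1", "chr2"), n_p,
                                      replace = TRUE),
                       start = tss - 1000, end = tss + 1000,
                       gene = sprintf("g%02d", 1:n_p), strand = "+",
                       tss = tss, stringsAsFactors = FALSE)
    got <- assign_enhancers(enh, prom, max_distance = 300000)
    exp <- oracle_assign(enh, prom, max_distance = 300000)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp)
    # invariants: cap respected, partial function, active-first exclusion
    expect_true(all(got$distance <= 300000))
    expect_lte(max(table(got$enhancer), 0), 1)
    act_genes <- got$gene[got$state == "active"]
    expect_equal(intersect(act_genes, got$gene[got$state != "active"]),
                 character(0))
  }
})

test_that("expression summaries group by best class and active count", {
  expr <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     value = c(100, 50, 10, 1), stringsAsFactors = FALSE)
  links <- data.frame(enhancer = c("e1", "e2", "e3", "e4"),
                      gene = c("g1", "g1", "g2", "g3"),
                      distance = 1, state = c("active", "active", "primed",
                                              "poised"),
                      stringsAsFactors = FALSE)
  by_cls <- expression_by_class(links, expr)
  expect_equal(by_cls$n, c(1, 1, 1, 1))
  expect_equal(by_cls$median, c(100, 50, 10, 1))
  by_cnt <- expression_by_active_count(links, expr)
  expect_equal(by_cnt$n, c(3, 0, 1, 0))  # g1 has 2 actives, rest 0
  expect_equal(by_cnt$median[by_cnt$n_active == "2"], 100)

  none <- expression_by_class(links[0, ], expr)
  expect_equal(none$n, c(0, 0, 0, 4))
})

test_that("synthetic expression is ordered by linked enhancer class", {
  b <- default_bundle()
  st <- "HSC"
  by_cls <- b$expr_by_class[[st]]
  med <- setNames(by_cls$median, by_cls$class)
  expect_gt(med["active"], med["primed"])
  expect_gt(med["primed"], med["none"])
  # median expression non-decreasing in the number of active enhancers
  by_cnt <- expression_by_active_count(b$links[[st]], b$expression[[st]])
  meds <- by_cnt$median[by_cnt$n > 5]
  expect_true(all(diff(meds) >= 0))
})
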