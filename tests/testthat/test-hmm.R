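# Two-state Gaussian HMM: model validation, EM behaviour, Viterbi
# exactness, domain construction and overlap statistics.

test_that("model construction validates stochasticity and variances", {
  m <- k9_init_model()
  expect_equal(m$init, c(0, 1))
  expect_equal(m$trans, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE))
  expect_equal(m$means, c(-1, 1))
  expect_equal(m$vars, c(0.5, 0.5))
  expect_error(hmm_model(c(0.5, 0.6), m$trans, m$means, m$vars),
               "probability")
  expect_error(hmm_model(m$init, matrix(c(0.5, 0.6, 0.1, 0.9), 2, 2),
                         m$means, m$vars), "probability")
  expect_error(hmm_model(m$init, m$trans, m$means, c(0.5, 0)), "positive")
})

test_that("Viterbi decodes degenerate evidence as expected", {
  m <- k9_init_model()
  expect_equal(viterbi(m, rep(1, 20)), rep(2L, 20))
  # the standard initialization forces an enriched start (pi = (0, 1));
  # with a symmetric start, uniform evidence gives uniform paths
  sym <- hmm_model(c(0.5, 0.5), m$trans, m$means, m$vars)
  expect_equal(viterbi(sym, rep(-1, 20)), rep(1L, 20))
  expect_equal(viterbi(m, rep(-1, 20)), c(2L, rep(1L, 19)))
  expect_error(viterbi(m, numeric(0)), "empty")
})

test_that("Viterbi equals exhaustive enumeration over all 2^n paths", {
  m <- k9_init_model()
  # also try an asymmetric model to exercise the transition terms
  m2 <- hmm_model(c(0.3, 0.7), matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2,
                                      byrow = TRUE),
                  means = c(-0.5, 1.5), vars = c(0.3, 1.2))
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(2:12, 1)
    v <- rnorm(n, 0, 1.5)
    mod <- if (seed %% 2 == 0) m else m2
    expect_equal(viterbi(mod, v), oracle_viterbi(mod, v))
  }
})

test_that("EM log-likelihood is non-decreasing and rows stay stochastic", {
  set.seed(50)
  cfg <- fast_config(seed = 50)
  k9 <- simulate_k9me2_track(simulate_genome(cfg), cfg)
  v <- k9$track$score[k9$track$chrom == "chr1"]
  fit <- em_fit(v)
  expect_gte(length(fit$loglik), 2)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_equal(rowSums(fit$trans), c(1, 1))
  expect_true(all(fit$vars >= 1e-3))
  # state identity: state 2 is the enriched (larger-mean) state
  expect_gt(fit$means[2], fit$means[1])
})

test_that("EM recovers the generating parameters at n = 5000", {
  # data generated from the standard initialization itself
  set.seed(51)
  n <- 5000
  stay <- 0.9
  states <- integer(n)
  states[1] <- 2L
  for (t in 2:n) {
    states[t] <- if (runif(1) < stay) states[t - 1] else 3L - states[t - 1]
  }
  v <- rnorm(n, mean = c(-1, 1)[states], sd = sqrt(0.5))
  fit <- em_fit(v)
  expect_lt(abs(fit$means[1] - (-1)), 0.1)
  expect_lt(abs(fit$means[2] - 1), 0.1)
  expect_lt(abs(fit$trans[1, 1] - 0.9), 0.05)
  expect_lt(abs(fit$trans[2, 2] - 0.9), 0.05)
})

test_that("EM stopping rules and degenerate input behave as documented", {
  set.seed(52)
  v <- rnorm(100)
  one <- em_fit(v, tol = Inf)
  expect_equal(length(one$loglik), 1)
  expect_equal(rowSums(one$trans), c(1, 1))
  expect_error(em_fit(rnorm(5)), "at least 10")
  expect_warning(fit_d <- em_fit(rep(1.0, 50)), "degenerate")
  expect_equal(fit_d$vars, c(1e-3, 1e-3))
})

test_that("retained windows require a read in any sample of any stage", {
  grid <- make_windows(tiny_genome(20000), 5000, 5000)
  cm1 <- count_matrix(grid, cbind(k9 = c(0, 3, 0, 0), inp = c(0, 0, 0, 2)))
  cm2 <- count_matrix(grid, cbind(k9 = c(0, 0, 1, 0), inp = c(0, 0, 0, 0)))
  keep <- retain_covered_windows(list(cm1, cm2))
  expect_equal(keep, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(retain_covered_windows(list(count_matrix(
    grid, cbind(a = rep(1, 4))))), rep(TRUE, 4))
  bad <- count_matrix(make_windows(tiny_genome(10000), 5000, 5000),
                      cbind(a = c(1, 1)))
  expect_error(retain_covered_windows(list(cm1, bad)), "grid")
})

test_that("state runs become domains, bridging gaps in retained windows", {
  grid <- make_windows(tiny_genome(20000), 5000, 5000)
  d <- states_to_domains(c(2L, 2L, 1L, 2L), grid)
  expect_equal(d$start, c(0, 15000))
  expect_equal(d$end, c(10000, 20000))
  expect_equal(d$n_windows, c(2, 1))
  expect_equal(nrow(states_to_domains(rep(1L, 4), grid)), 0)

  # a dropped (unretained) window between two enriched runs is bridged
  gapped <- grid[c(1, 2, 4), ]  # window [10k,15k) not retained
  d2 <- states_to_domains(c(2L, 2L, 2L), gapped)
  expect_equal(nrow(d2), 1)
  expect_equal(c(d2$start, d2$end), c(0, 20000))
  # but not when the flanks are in different states
  d3 <- states_to_domains(c(2L, 2L, 1L), gapped)
  expect_equal(c(d3$start, d3$end), c(0, 10000))
})

test_that("genome fraction matches the chain's stationary value", {
  expect_equal(genome_fraction(rep(2L, 10)), 1.0)
  expect_equal(genome_fraction(c(2L, 1L, 2L, 1L)), 0.5)
  expect_error(genome_fraction(integer(0)), "retained")
  # symmetric stay-0.9 chain is stationary at 0.5
  b <- default_bundle()
  path <- b$k9$HSC$path
  n <- length(path)
  # 3 SDs with the Markov-chain variance inflation (1+rho)/(1-rho), rho=0.8
  sd3 <- 3 * sqrt(0.25 * (1 + 0.8) / (1 - 0.8) / n)
  expect_lt(abs(genome_fraction(path) - 0.5), sd3)
})

test_that("the domain Venn partition matches a per-base oracle exactly", {
  for (seed in 1:15) {
    set.seed(seed)
    sets <- lapply(1:3, function(i) {
      s <- sort(sample(seq(0, 95000, 5000), sample(2:6, 1)))
      regions_df("chr1", s, s + 5000 * sample(1:3, length(s),
                                              replace = TRUE))
    })
    names(sets) <- c("A", "B", "C")
    venn <- domain_overlap(sets)
    # oracle: per-base membership bitmask
    span <- 200000
    masks <- vapply(sets, function(d) {
      m <- logical(span)
      for (i in seq_len(nrow(d))) m[(d$start[i] + 1):min(d$end[i], span)] <- TRUE
      m
    }, logical(span))
    any_mask <- rowSums(masks) > 0
    expect_equal(sum(venn$bases), sum(any_mask))  # partition = union
    for (r in seq_len(nrow(venn))) {
      sel <- rep(TRUE, span)
      for (nm in c("A", "B", "C")) {
        sel <- sel & (masks[, nm] == venn[[nm]][r])
      }
      expect_equal(venn$bases[r], sum(sel))
    }
  }
  ident <- domain_overlap(list(a = regions_df("chr1", 0, 1000),
                               b = regions_df("chr1", 0, 1000)))
  expect_equal(nrow(ident), 1)
  expect_true(ident$a[1] && ident$b[1])
})

test_that("track correlation matches the shared-domain closed form", {
  expect_equal(correlate_tracks(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1.0)
  expect_equal(correlate_tracks(c(1, 2, 3, 4), -c(1, 2, 3, 4)), -1.0)
  expect_error(correlate_tracks(c(1, 1, 1), c(1, 2, 3)), "variance")

  # two stages sharing true domains with independent N(0, 0.5) noise:
  # rho = Var(state)/(Var(state) + 0.5) = 1/1.5 = 2/3
  b <- default_bundle()
  r <- correlate_tracks(b$k9$HSC$track, b$k9$ProB$track)
  expect_gt(nrow(b$k9$HSC$track), 2000)
  expect_lt(abs(r - 2 / 3), 0.05)
})

test_that("region-domain overlap is base-sensitive at the boundary", {
  dom <- regions_df("chr1", 10000, 20000)
  inside <- enhancer_domain_overlap(regions_df("chr1", 12000, 14000), dom)
  expect_equal(inside$fraction_overlapping, 1)
  outside <- enhancer_domain_overlap(regions_df("chr1", 8000, 10000), dom)
  expect_equal(outside$fraction_overlapping, 0)  # book-ended, no base shared
  one_bp <- enhancer_domain_overlap(regions_df("chr1", 8000, 10001), dom)
  expect_equal(one_bp$fraction_overlapping, 1)
})
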