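test_that("pwm construction normalizes columns after the pseudocount", {
  m <- pwm(matrix(c(1, 0, 0, 0), 4, 3), pseudocount = 0.0005)
  expect_equal(colSums(unclass(m)), rep(1, 3))
  expect_true(all(unclass(m) > 0))
  expect_equal(pwm_consensus(m), "AAA")
  rc <- pwm_revcomp(m)
  expect_equal(pwm_consensus(rc), "TTT")
})

test_that("JASPAR PFM text is parsed in both common layouts", {
  dir <- withr::local_tempdir()
  bracketed <- c(">MA0001.1 TEST",
                 "A [ 10  2  0 ]",
                 "C [  0  1  0 ]",
                 "G [  0  5 12 ]",
                 "T [  2  4  0 ]")
  plain <- c(">plainTF", "10 2 0", "0 1 0", "0 5 12", "2 4 0")
  for (lines in list(bracketed, plain)) {
    path <- file.path(dir, "m.pfm")
    writeLines(lines, path)
    m <- read_jaspar_pfm(path)
    expect_equal(ncol(m), 3L)
    expect_equal(pwm_consensus(m), "AGG")
  }
})

test_that("uniform PWM scores near zero against an i.i.d. context", {
  up <- pwm(matrix(0.25, 4, 6), pseudocount = 0)
  ctx <- simulate_genome(c(x = 20000), seed = 31)[[1]]
  s <- tfbs_score("ACGTAC", up, ctx)
  expect_lt(abs(s), 0.1)
})

test_that("single-position PWM gives the one-term log ratio", {
  eps <- 0.01
  m <- pwm(matrix(c(1 - 3 * eps, eps, eps, eps), 4, 1), pseudocount = 0)
  ctx <- simulate_genome(c(x = 50000), seed = 32)[[1]]
  expect_equal(tfbs_score("A", m, ctx), log((1 - 3 * eps) / 0.25),
               tolerance = 0.05)
})

test_that("tfbs_score equals the brute-force product oracle", {
  set.seed(33)
  m <- test_pwm(8)
  ctx <- substr(simulate_genome(c(x = 1000), gc = 0.42, seed = 34)[[1]],
                1, 500)
  for (i in 1:20) {
    win <- paste(sample(BASES, 8, replace = TRUE), collapse = "")
    expect_equal(tfbs_score(win, m, ctx),
                 oracle_tfbs_score(win, unclass(m), ctx),
                 tolerance = 1e-10)
  }
  expect_true(is.na(tfbs_score("ACGTNCGT", m, ctx)))
})

test_that("scan matches the all-window oracle and respects top_n", {
  g <- simulate_genome(c(chrA = 3000), seed = 35, gc = 0.45)
  m <- test_pwm(7)
  hits <- scan_genome(g, m, top_n = Inf)
  expect_equal(nrow(hits), 2 * (3000 - 7 + 1))
  idx <- sample(nrow(hits), 40)
  for (i in idx)
    expect_equal(hits$tfbs_score[i],
                 oracle_scan_score(g, hits$chrom[i], hits$start[i],
                                   hits$strand[i], unclass(m)),
                 tolerance = 1e-9)
  expect_false(is.unsorted(-hits$tfbs_score))
  top <- scan_genome(g, m, top_n = 100)
  expect_equal(top$tfbs_score, hits$tfbs_score[seq_len(nrow(top))])
  expect_gte(nrow(top), 100)                # ties at the cutoff retained
  all_back <- scan_genome(g, m, top_n = 1e9)
  expect_equal(nrow(all_back), nrow(hits))
})

test_that("a planted consensus match is the top hit on clean background", {
  m <- test_pwm(10, strong = 100)
  pl <- plant_sites(simulate_genome(c(chr1 = 20000), seed = 36), m,
                    n_bound = 1, n_unbound = 0, seed = 37)
  hit <- scan_genome(pl$genome, m, top_n = 1)
  expect_equal(hit$start[1], pl$sites$start[1])
  expect_equal(hit$strand[1], pl$sites$strand[1])
})

test_that("palindromic PWMs score both strands of a locus alike", {
  half <- matrix(c(8, 1, 1, 1, 1, 8, 1, 1, 1, 1, 8, 1), 4, 3)
  pal <- pwm(cbind(half, half[4:1, 3:1]))   # self-reverse-complement
  g <- simulate_genome(c(chrA = 4000), seed = 38)
  hits <- scan_genome(g, pal, top_n = Inf)
  sp <- hits[hits$strand == "+", c("start", "tfbs_score")]
  sm <- hits[hits$strand == "-", c("start", "tfbs_score")]
  mm <- merge(sp, sm, by = "start")
  # equality up to edge effects of the local Markov window
  expect_lt(max(abs(mm$tfbs_score.x - mm$tfbs_score.y)), 0.05)
})

test_that("larger pseudocounts shrink scores toward zero", {
  ctx <- simulate_genome(c(x = 5000), seed = 39)[[1]]
  set.seed(40)
  for (i in 1:10) {
    raw <- matrix(rexp(4 * 6), 4, 6)
    win <- paste(sample(BASES, 6, replace = TRUE), collapse = "")
    s_small <- tfbs_score(win, pwm(raw, pseudocount = 0.0005), ctx)
    s_large <- tfbs_score(win, pwm(raw, pseudocount = 0.25), ctx)
    expect_lte(abs(s_large), abs(s_small) + 1e-12)
  }
})

test_that("block-shared backgrounds approximate the per-position scan", {
  g <- simulate_genome(c(chrA = 5000), seed = 41)
  m <- test_pwm(8)
  full <- scan_genome(g, m, top_n = Inf)
  block <- scan_genome(g, m, top_n = Inf, block_size = 100)
  j <- merge(full, block, by = c("chrom", "start", "strand"))
  expect_gt(cor(j$tfbs_score.x, j$tfbs_score.y), 0.999)
})

test_that("empirical p value is calibrated, deterministic, and guarded", {
  m <- test_pwm(8, strong = 30)
  ctx <- simulate_genome(c(x = 10000), seed = 42)[[1]]
  neg_model <- markov_background(ctx)
  expect_error(empirical_pvalue(m, neg_model, 0, n_samples = 100,
                                fpr_grid = c(1e-3)),
               "n_samples")
  set.seed(43)
  r1 <- empirical_pvalue(m, neg_model, observed_min_score = 5,
                         n_samples = 5000, fpr_grid = 10^-(1:2))
  set.seed(43)
  r2 <- empirical_pvalue(m, neg_model, observed_min_score = 5,
                         n_samples = 5000, fpr_grid = 10^-(1:2))
  expect_identical(r1, r2)
  # null calibration: fraction of fresh negative scores above the
  # reported cutoffs matches the nominal FPR within a factor of 2
  set.seed(44)
  fresh <- sample_markov_sequences(neg_model, 5000, 8)
  # fixed-background score identical to empirical_pvalue's
  fresh_scores <- vapply(fresh, function(s) {
    codes <- footprintr:::.encode_dna(s)
    footprintr:::.pwm_logprob_codes(codes, m) -
      footprintr:::.markov_logprob_codes(codes, neg_model)
  }, numeric(1), USE.NAMES = FALSE)
  for (i in seq_len(nrow(r1$grid))) {
    obs <- mean(fresh_scores > r1$grid$cutoff[i])
    expect_lt(obs, 2.5 * r1$grid$fpr[i] + 2 / 5000)
  }
  # a strongly informative PWM separates positives far above negatives
  set.seed(45)
  pos <- sample_pwm_sequences(m, 200)
  pos_scores <- vapply(pos, function(s) {
    codes <- footprintr:::.encode_dna(s)
    footprintr:::.pwm_logprob_codes(codes, m) -
      footprintr:::.markov_logprob_codes(codes, neg_model)
  }, numeric(1), USE.NAMES = FALSE)
  r3 <- empirical_pvalue(m, neg_model, observed_min_score = min(pos_scores),
                         n_samples = 2e4, fpr_grid = 10^-(1:3))
  expect_lte(r3$empirical_p, 1e-2)
})
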