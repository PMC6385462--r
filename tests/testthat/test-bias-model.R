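test_that("uniform cuts over every gap give propensities near 1", {
  g <- simulate_genome(c(chr1 = 5e4), seed = 10)
  lens <- c(chr1 = 5e4L)
  tr <- cut_track(lens)
  tr$plus$chr1[] <- 1L                      # one cut at every gap,
  tr$minus$chr1[] <- 1L                     # both strands
  tab <- estimate_kmer_bias(tr, g)
  # cut-centered k-mers enumerate the genome's own (strand-symmetrized)
  # k-mer content, so every propensity sits near 1 up to edge effects
  # and the pseudo-count
  expect_true(all(abs(log10(tab$propensity)) < 0.1))
  expect_lt(sd(log10(tab$propensity)), 0.02)
})

test_that("cuts concentrated on one k-mer recover the ratio definition", {
  # genome with a unique AAAAAA run in random background
  set.seed(11)
  g <- c(chr1 = paste0(simulate_genome(c(x = 20000), gc = 0.6, seed = 11)[[1]],
                       "AAAAAA",
                       simulate_genome(c(x = 20000), gc = 0.6, seed = 12)[[1]]))
  pos <- regexpr("AAAAAA", g[[1]])
  tr <- cut_track(c(chr1 = nchar(g[[1]])))
  # plus cut whose gap is centered in that k-mer: gap = pos-1+3 (0-based)
  tr$plus$chr1[pos - 1 + 3 + 1] <- 50L
  tab <- suppressWarnings(estimate_kmer_bias(tr, g))
  expect_equal(which.max(tab$propensity), which(names(tab$propensity) == "AAAAAA"),
               ignore_attr = TRUE)
  ora <- oracle_kmer_bias(tr, g)
  expect_equal(unname(tab$propensity["AAAAAA"]), unname(ora[["AAAAAA"]]),
               tolerance = 1e-12)
})

test_that("bias estimation equals the brute-force enumeration oracle", {
  g <- simulate_genome(c(chr1 = 6000, chr2 = 4000), seed = 13)
  lens <- c(chr1 = 6000L, chr2 = 4000L)
  set.seed(14)
  tr <- cut_track(lens)
  for (chrom in names(lens)) for (s in c("plus", "minus")) {
    at <- sample(10:(lens[[chrom]] - 10), 25)
    tr[[s]][[chrom]][at + 1L] <- sample(1:3, 25, replace = TRUE)
  }
  tab <- suppressWarnings(estimate_kmer_bias(tr, g))
  ora <- oracle_kmer_bias(tr, g)
  expect_equal(unname(tab$propensity), unname(ora), tolerance = 1e-10)
})

test_that("mirrored cuts on a palindromic genome give identical strand tables", {
  # genome = S + revcomp(S); every plus cut at gap p in S is mirrored by
  # a minus cut at gap 2n - p, whose minus-strand k-mer is identical
  s <- simulate_genome(c(x = 3000), seed = 15)[[1]]
  g <- c(chr1 = paste0(s, revcomp(s)))
  n <- 3000L
  set.seed(16)
  gaps <- sample(10:(n - 10), 200)
  tr <- cut_track(c(chr1 = 2L * n))
  tr$plus$chr1[gaps + 1L] <- 1L                 # plus cut at gap p: base p
  tr$minus$chr1[(2L * n - gaps - 1L) + 1L] <- 1L  # minus cut at gap 2n-p
  rep <- suppressWarnings(strand_symmetry_report(tr, g))
  expect_equal(rep$correlation, 1.0, tolerance = 1e-12)
  expect_equal(rep$plus_table$propensity, rep$minus_table$propensity)
})

test_that("independently sampled strands from one table agree at high depth", {
  g <- simulate_genome(c(chr1 = 1e6), seed = 17)
  tab <- simulate_bias_table(seed = 18)
  tr <- simulate_naked_cuts(g, tab, 1e6, seed = 19)
  rep <- strand_symmetry_report(tr, g)
  expect_gte(rep$correlation, 0.95)
  # at two orders of magnitude lower depth, per-strand sampling noise
  # (~12 cuts per k-mer) dominates and the correlation drops
  tr_lo <- simulate_naked_cuts(g, tab, 1e4, seed = 20)
  expect_lt(strand_symmetry_report(tr_lo, g)$correlation,
            rep$correlation)
})

test_that("unrelated plus-only and minus-only cuts decorrelate the tables", {
  g <- simulate_genome(c(chr1 = 5e4), seed = 21)
  lens <- c(chr1 = 5e4L)
  set.seed(22)
  tr <- cut_track(lens)
  tr$plus$chr1[sample(10:(5e4 - 10), 2000) + 1L] <- 1L
  tr$minus$chr1[sample(10:(5e4 - 10), 2000) + 1L] <- 1L
  rep <- strand_symmetry_report(tr, g)
  expect_lt(abs(rep$correlation), 0.25)
})

test_that("a strand without cuts is rejected by name", {
  g <- simulate_genome(c(chr1 = 2000), seed = 23)
  tr <- cut_track(c(chr1 = 2000L))
  tr$plus$chr1[100] <- 5L
  expect_error(strand_symmetry_report(tr, g), "minus")
})

test_that("expected cut profile follows the k-mer propensities", {
  tab1 <- uniform_bias_table()
  seq <- simulate_genome(c(x = 1000), seed = 24)[[1]]
  W <- 40
  sub <- substr(seq, 1, W + 6)
  prof <- expected_cut_profile(sub, tab1)
  expect_equal(prof, rep(1 / W, W), ignore_attr = TRUE)
  expect_false(attr(prof, "flagged"))

  # single elevated k-mer present once: closed-form peak weight
  tab <- uniform_bias_table()
  center_kmer <- substr(sub, 11, 16)        # k-mer centered on gap 10
  tab$propensity[center_kmer] <- 5
  if (sum(gregexpr(center_kmer, sub)[[1]] > 0) == 1) {
    prof2 <- expected_cut_profile(sub, tab)
    expect_equal(max(prof2), 5 / (5 + (W - 1)), tolerance = 1e-12)
    expect_equal(which.max(prof2), 11L)
  }

  # random table matches the slicing oracle, and scaling is irrelevant
  tab3 <- simulate_bias_table(seed = 25)
  prof3 <- expected_cut_profile(sub, tab3)
  expect_equal(as.numeric(prof3), oracle_expected_profile(sub, tab3),
               tolerance = 1e-12)
  expect_equal(sum(prof3), 1)
  tab3$propensity <- tab3$propensity * 7.3
  expect_equal(as.numeric(expected_cut_profile(sub, tab3)),
               as.numeric(prof3), tolerance = 1e-12)
})

test_that("ambiguous bases are flagged and given the geometric mean", {
  tab <- simulate_bias_table(seed = 26)
  seq <- paste0(strrep("ACGT", 5), "NN", strrep("TGCA", 5))
  prof <- expected_cut_profile(seq, tab)
  expect_true(attr(prof, "flagged"))
  expect_equal(sum(prof), 1)
})

test_that("average site propensity is the within-site k-mer mean", {
  tab1 <- uniform_bias_table()
  expect_equal(average_site_propensity("ACGTACGTAC", tab1), 1.0)
  tab <- uniform_bias_table()
  tab$propensity["ACGTAC"] <- 2.5
  expect_equal(average_site_propensity("ACGTAC", tab), 2.5)
  # linearity in the table and brute-force equality
  seq <- simulate_genome(c(x = 1000), seed = 27)[[1]]
  site <- substr(seq, 101, 130)
  tab2 <- simulate_bias_table(seed = 28)
  manual <- mean(sapply(1:(30 - 5), function(j)
    tab2$propensity[[substr(site, j, j + 5)]]))
  expect_equal(average_site_propensity(site, tab2), manual)
  tab2b <- tab2; tab2b$propensity <- tab2b$propensity * 3
  expect_equal(average_site_propensity(site, tab2b),
               3 * average_site_propensity(site, tab2))
  expect_error(average_site_propensity("ACG", tab2), "shorter")
})

test_that("bias tables round-trip through TSV and pool geometrically", {
  tab <- simulate_bias_table(seed = 29, protocol = "DNase",
                             symmetric = FALSE)
  path <- file.path(withr::local_tempdir(), "bias.tsv")
  write_bias_table(tab, path)
  back <- read_bias_table(path)
  expect_equal(back$k, 6L)
  expect_equal(back$protocol, "DNase")
  expect_equal(back$propensity, tab$propensity, tolerance = 1e-12)

  tab2 <- simulate_bias_table(seed = 30, symmetric = FALSE)
  pooled <- pool_bias_tables(list(tab, tab2), weights = c(3, 1))
  expect_equal(unname(pooled$propensity[1]),
               unname(exp(0.75 * log(tab$propensity[1]) +
                            0.25 * log(tab2$propensity[1]))))
})
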