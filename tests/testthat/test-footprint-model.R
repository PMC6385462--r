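make_track_with_counts <- function(lens, counts_by_pos) {
  tr <- cut_track(lens)
  for (p in names(counts_by_pos))
    tr$plus$chr1[as.integer(p) + 1L] <- counts_by_pos[[p]]
  tr
}

test_that("site matrices slice strand-summed counts in motif orientation", {
  lens <- c(chr1 = 400L)
  tr <- cut_track(lens)
  tr$plus$chr1[] <- 1L
  sites <- data.frame(chrom = "chr1", start = 100L, end = 110L,
                      strand = "+")
  mat <- build_site_matrix(tr, sites, pad = 25L)
  expect_equal(dim(mat), c(1L, 60L))
  expect_true(all(mat == 1L))

  # identical loci on opposite strands are reverses of each other
  set.seed(50)
  tr$plus$chr1 <- as.integer(rpois(400, 2))
  tr$minus$chr1 <- as.integer(rpois(400, 1))
  sites2 <- data.frame(chrom = "chr1", start = c(200L, 200L),
                       end = c(210L, 210L), strand = c("+", "-"))
  mat2 <- build_site_matrix(tr, sites2)
  expect_equal(mat2[2, ], rev(mat2[1, ]))
  # direct slicing oracle
  pooled <- tr$plus$chr1 + tr$minus$chr1
  expect_equal(mat2[1, ], pooled[(200 - 25 + 1):(210 + 25)])

  # sites too close to an edge are dropped with a warning
  sites3 <- rbind(sites2, data.frame(chrom = "chr1", start = 5L,
                                     end = 15L, strand = "+"))
  expect_warning(mat3 <- build_site_matrix(tr, sites3), "dropped")
  expect_equal(attr(mat3, "kept"), c(1L, 2L))
})

test_that("footprint initialization aggregates ChIP-positive sites", {
  mat <- rbind(c(0, 4, 0, 4), c(9, 9, 9, 9))
  init <- initialize_footprint(mat, c(TRUE, FALSE), pseudocount = 0.5)
  expect_equal(init, (c(0, 4, 0, 4) + 0.5) / sum(c(0, 4, 0, 4) + 0.5))
  init_all <- initialize_footprint(mat, c(TRUE, TRUE), pseudocount = 0.5)
  expect_equal(init_all, (colSums(mat) + 0.5) / sum(colSums(mat) + 0.5))
  expect_warning(fallback <- initialize_footprint(mat, c(FALSE, FALSE)),
                 "no positive labels")
  expect_equal(fallback, init_all)
})

test_that("initialization recovers a planted shape from labeled sites", {
  set.seed(51)
  shape <- footprint_shape(10, preset = "dnase")
  counts <- t(rmultinom(500, 50, shape))
  init <- initialize_footprint(counts, rep(TRUE, 500))
  expect_lt(0.5 * sum(abs(init - shape)), 0.05)
})

test_that("backgrounds are uniform or bias-derived per mode", {
  g <- simulate_genome(c(chr1 = 5000), seed = 52)
  sites <- data.frame(chrom = "chr1", start = c(100L, 300L),
                      end = c(109L, 309L), strand = c("+", "-"))
  W <- 9 + 50
  u <- build_backgrounds(sites, mode = "uniform")
  expect_equal(u, matrix(1 / W, 2, W))
  b1 <- build_backgrounds(sites, g, "bias", uniform_bias_table())
  expect_equal(b1, u)
  tab <- simulate_bias_table(seed = 53)
  b2 <- build_backgrounds(sites, g, "bias", tab)
  seq1 <- substr(g[[1]], 100 - 25 - 3 + 1, 109 + 25 + 3)
  expect_equal(b2[1, ], oracle_expected_profile(seq1, tab),
               tolerance = 1e-12)
  seq2 <- oracle_revcomp(substr(g[[1]], 300 - 25 - 3 + 1, 309 + 25 + 3))
  expect_equal(b2[2, ], oracle_expected_profile(seq2, tab),
               tolerance = 1e-12)
  expect_error(build_backgrounds(sites, g, "bias"), "table")
})

test_that("EM recovers planted mixture parameters with monotone likelihood", {
  W <- 61
  f <- footprint_shape(11, preset = "dnase")
  b <- rep(1 / W, W)
  sim <- simulate_mixture_counts(2000, 50, f, b, pi = 0.4, seed = 54)
  init <- initialize_footprint(sim$counts, sim$bound)
  model <- fit_em(sim$counts, init, matrix(b, 2000, W, byrow = TRUE))
  expect_true(all(diff(model$loglik) >= -1e-6 * abs(model$loglik[1])))
  expect_lt(0.5 * sum(abs(model$footprint - f)), 0.02)
  expect_lt(abs(model$pi - 0.4), 0.05)
  expect_equal(model$backgrounds[1, ], b)   # fixed background untouched
})

test_that("EM drives pi to zero on background-only data", {
  W <- 61
  f <- footprint_shape(11, preset = "dnase")
  b <- rep(1 / W, W)
  sim <- simulate_mixture_counts(1500, 50, f, b, pi = 0, seed = 55)
  init <- initialize_footprint(sim$counts, NULL)
  init <- 0.7 * f + 0.3 * init              # start near the footprint
  model <- fit_em(sim$counts, init / sum(init),
                  matrix(b, 1500, W, byrow = TRUE),
                  tol = 1e-10, max_iter = 2000L)
  expect_lt(model$pi, 0.05)
})

test_that("EM is at a fixed point when initialized at the truth", {
  W <- 30
  f <- footprint_shape(10, pad = 10, preset = "dnase")
  b <- rep(1 / W, W)
  d <- 5000
  x <- rbind(matrix(rep(d * f, 300), 300, W, byrow = TRUE),
             matrix(rep(d * b, 300), 300, W, byrow = TRUE))
  model <- fit_em(x, f, matrix(b, 600, W, byrow = TRUE), max_iter = 1L,
                  pi_init = 0.5, pseudocount = 0.5)
  expect_lt(max(abs(model$footprint - f)), 1e-3)
  expect_lt(abs(model$pi - 0.5), 0.01)
})

test_that("FLR matches its closed forms and the brute-force oracle", {
  W <- 20
  f <- (1:W) / sum(1:W)
  model_eq <- list(footprint = f, backgrounds = matrix(f, 1, W), pi = 0.5)
  class(model_eq) <- "footprint_model"
  set.seed(56)
  x <- rpois(W, 3)
  expect_equal(flr(x, model_eq), 0)

  b <- rep(1 / W, W)
  model <- list(footprint = f, backgrounds = matrix(b, 1, W), pi = 0.5)
  class(model) <- "footprint_model"
  j <- which.max(f / b)
  conc <- integer(W); conc[j] <- 7L
  expect_equal(flr(conc, model), 7 * log(f[j] / b[j]))

  for (i in 1:100) {
    fi <- rexp(W); fi <- fi / sum(fi)
    bi <- rexp(W); bi <- bi / sum(bi)
    xi <- rpois(W, 2)
    mi <- list(footprint = fi, backgrounds = matrix(bi, 1, W), pi = 0.5)
    class(mi) <- "footprint_model"
    expect_equal(flr(xi, mi), oracle_flr(xi, fi, bi), tolerance = 1e-9)
  }
  # prior-odds variant shifts every score by the same constant
  expect_equal(flr(conc, model, include_prior_odds = TRUE),
               flr(conc, model) + log(0.5 / 0.5))
})

test_that("FLR is invariant to permuting background-identical positions", {
  W <- 40
  f <- rep(c(0.4, 0.6) / (W / 2), each = W / 2)  # duplicated values
  b <- rep(1 / W, W)
  model <- list(footprint = f, backgrounds = matrix(b, 1, W), pi = 0.5)
  class(model) <- "footprint_model"
  set.seed(57)
  x <- rpois(W, 4)
  perm <- c(sample(1:(W / 2)), sample((W / 2 + 1):W))  # within blocks
  expect_equal(flr(x, model), flr(x[perm], model), tolerance = 1e-12)
})

test_that("fitted widths reproduce the wide-ATAC vs narrow-DNase contrast", {
  g <- simulate_genome(c(chr1 = 3e5), seed = 58)
  motif <- test_pwm(10)
  tab <- simulate_bias_table(seed = 59)
  pl <- plant_sites(g, motif, 400, 400, seed = 60)
  widths <- sapply(c("dnase", "atac"), function(preset) {
    shape <- footprint_shape(10, preset = preset)
    mats <- simulate_site_counts(pl$sites, pl$genome, shape, tab,
                                 depth = 80, spurious_frac = 0,
                                 seed = 61)
    bg <- build_backgrounds(pl$sites, pl$genome, "bias", tab)
    model <- fit_em(mats[[1]], initialize_footprint(mats[[1]],
                                                    pl$sites$bound), bg)
    footprint_width(model$footprint)
  })
  expect_gt(widths[["atac"]], widths[["dnase"]])
})

test_that("non-fixed background re-estimates a single shared profile", {
  W <- 30
  f <- footprint_shape(10, pad = 10, preset = "dnase")
  b_true <- (1:W) / sum(1:W)
  sim <- simulate_mixture_counts(800, 60, f, b_true, pi = 0.4, seed = 62)
  model <- fit_em(sim$counts, initialize_footprint(sim$counts, sim$bound),
                  matrix(1 / W, 800, W, byrow = TRUE),
                  fixed_background = FALSE)
  expect_true(all(diff(model$loglik) >= -1e-6 * abs(model$loglik[1])))
  expect_lt(0.5 * sum(abs(model$backgrounds[1, ] - b_true)), 0.1)
})

test_that("model serialization writes a readable plain-text summary", {
  W <- 20
  f <- rep(1 / W, W)
  model <- list(footprint = f, backgrounds = matrix(f, 2, W, byrow = TRUE),
                pi = 0.3, n_iter = 5L, converged = TRUE)
  class(model) <- "footprint_model"
  path <- file.path(withr::local_tempdir(), "model.tsv")
  write_footprint_model(model, path)
  lines <- readLines(path)
  expect_true(any(grepl("^#pi\t0.3", lines)))
  tab <- read.table(path, sep = "\t", skip = 4)
  expect_equal(nrow(tab), W)
})
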