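## Irreproducible discovery rate over two replicates' score rankings:
## a two-component Gaussian copula mixture (one correlated "reproducible"
## component with mean mu, variance sigma2, correlation rho; one
## independent standard-normal "irreproducible" component) fitted by
## pseudo-likelihood EM on rank-derived pseudo-values.

# bivariate normal density with common mean/variance and correlation rho
.dbinorm <- function(z1, z2, mu, sigma2, rho) {
  q <- ((z1 - mu)^2 - 2 * rho * (z1 - mu) * (z2 - mu) + (z2 - mu)^2) /
    (sigma2 * (1 - rho^2))
  exp(-q / 2) / (2 * pi * sigma2 * sqrt(1 - rho^2))
}

# pseudo-values: map empirical quantiles u through the inverse CDF of the
# current mixture marginal G(z) = p N(mu, sigma2) + (1-p) N(0, 1)
.pseudo_values <- function(u, p, mu, sigma2, rho) {
  sd1 <- sqrt(sigma2)
  lo <- min(stats::qnorm(min(u), mu, sd1), stats::qnorm(min(u))) - 1
  hi <- max(stats::qnorm(max(u), mu, sd1), stats::qnorm(max(u))) + 1
  grid <- seq(lo, hi, length.out = 2048L)
  G <- p * stats::pnorm(grid, mu, sd1) + (1 - p) * stats::pnorm(grid)
  stats::approx(G, grid, xout = u, rule = 2, ties = "ordered")$y
}

#' Fit the copula mixture IDR model to two replicates' scores
#'
#' Scores are reduced to ranks (average for ties), mapped to empirical
#' quantiles and then to pseudo-values under the current marginal; EM
#' alternates posterior computation for the reproducible component with
#' moment updates of (p, mu, sigma2, rho). The local idr of an item is
#' the posterior probability of the irreproducible component; the global
#' IDR of an item is the running mean of sorted local idr values up to
#' it (the expected irreproducible fraction among all items called at or
#' before that point).
#'
#' @param score_rep1,score_rep2 numeric score vectors over the same items
#'   (higher = stronger). At least ~50 items are recommended.
#' @param max_iter,tol EM iteration cap and relative pseudo-log-likelihood
#'   tolerance.
#' @param init named list overriding starting values `p`, `mu`, `sigma2`,
#'   `rho`.
#' @return an `idr_result`: list with `local_idr`, `global_idr` (both in
#'   input order), `order` (item indices sorted by increasing local idr),
#'   `params` (p = reproducible fraction, mu, sigma2, rho), `loglik`,
#'   `converged`, and `n_pass` (function of threshold; see
#'   [idr_npass()]).
#' @export
idr_fit <- function(score_rep1, score_rep2, max_iter = 500L, tol = 1e-6,
                    init = list()) {
  n <- length(score_rep1)
  if (length(score_rep2) != n) stop("replicate score vectors differ in length")
  if (n < 10L) stop("too few items for IDR estimation")
  if (stats::sd(score_rep1) == 0 || stats::sd(score_rep2) == 0)
    stop("constant scores in a replicate; ranks undefined")
  u1 <- rank(score_rep1, ties.method = "average") / (n + 1)
  u2 <- rank(score_rep2, ties.method = "average") / (n + 1)
  p <- init$p %||% 0.5
  mu <- init$mu %||% 1
  sigma2 <- init$sigma2 %||% 1
  rho <- init$rho %||% 0.5
  converged <- FALSE
  ll <- -Inf
  par_old <- c(p, mu, sigma2, rho)
  for (outer in seq_len(100L)) {
    z1 <- .pseudo_values(u1, p, mu, sigma2, rho)
    z2 <- .pseudo_values(u2, p, mu, sigma2, rho)
    # inner EM on the pseudo-data at fixed pseudo-values
    ll_inner <- -Inf
    for (em in seq_len(max_iter)) {
      d1 <- p * .dbinorm(z1, z2, mu, sigma2, rho)
      d0 <- (1 - p) * stats::dnorm(z1) * stats::dnorm(z2)
      ll <- sum(log(d1 + d0))
      e <- d1 / (d1 + d0)
      se <- sum(e)
      # weak parsimony prior on p: at the null the two components
      # coincide and p is unidentified (a likelihood ridge); shrinking
      # the reproducible fraction by ~2% resolves the ridge toward the
      # parsimonious solution while leaving separable fits essentially
      # unbiased
      p <- min(max(se / (n + 0.02 * n), 1e-4), 1 - 1e-4)
      mu <- sum(e * (z1 + z2)) / (2 * se)
      mu <- max(mu, 0)
      sigma2 <- sum(e * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * se)
      # floor well above zero: the reproducible component describes the
      # whole signal spread on the pseudo-value scale, and letting its
      # variance collapse onto a micro-cluster of near-duplicate ranks
      # is the usual Gaussian-mixture degeneracy
      sigma2 <- max(sigma2, 0.3)
      rho <- sum(e * (z1 - mu) * (z2 - mu)) / (se * sigma2)
      rho <- min(max(rho, 0), 0.999)
      if (is.finite(ll_inner) && abs(ll - ll_inner) < tol * abs(ll_inner))
        break
      ll_inner <- ll
    }
    par_new <- c(p, mu, sigma2, rho)
    if (outer > 1L && max(abs(par_new - par_old)) < 1e-3) {
      converged <- TRUE
      break
    }
    par_old <- par_new
  }
  if (!converged)
    warning("IDR EM did not reach tolerance; results may be unstable")
  d1 <- p * .dbinorm(z1, z2, mu, sigma2, rho)
  d0 <- (1 - p) * stats::dnorm(z1) * stats::dnorm(z2)
  local_idr <- d0 / (d1 + d0)
  ord <- order(local_idr)
  global_sorted <- cumsum(local_idr[ord]) / seq_len(n)
  global_idr <- numeric(n)
  global_idr[ord] <- global_sorted
  structure(list(local_idr = local_idr, global_idr = global_idr,
                 order = ord,
                 params = list(p = p, mu = mu, sigma2 = sigma2, rho = rho),
                 loglik = ll, converged = converged, n = n),
            class = "idr_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.idr_result <- function(x, ...) {
  cat(sprintf(
    "idr_result: n=%d, reproducible fraction %.3f, rho=%.3f, n_pass(0.01)=%d\n",
    x$n, x$params$p, x$params$rho, idr_npass(x, 0.01)))
  invisible(x)
}

#' Number of items passing a global IDR threshold
#'
#' @param result an `idr_result` from [idr_fit()].
#' @param threshold global IDR cutoff (default 0.01).
#' @return integer count; monotone non-decreasing in the threshold.
#' @export
idr_npass <- function(result, threshold = 0.01) {
  sum(result$global_idr <= threshold)
}

#' Select reproducible footprints from two replicates' FLR scores
#'
#' Sites with a positive FLR in both replicates are ranked by FLR, IDR is
#' fitted on the pair of rankings, the number of sites passing the global
#' IDR threshold is noted, and the positive sites re-ranked by the
#' average FLR of the two replicates are truncated to that number.
#'
#' @param flr_rep1,flr_rep2 named numeric vectors of FLR per site (same
#'   site universe; names identify sites).
#' @param threshold global IDR threshold (default 0.01).
#' @param min_sites minimum number of doubly-positive sites required to
#'   attempt IDR (default 50); below it an empty selection is returned
#'   with a warning.
#' @return data frame of selected sites (site, flr_rep1, flr_rep2,
#'   mean_flr) ranked by mean FLR, with attributes `n_pass` and
#'   `idr_result`.
#' @export
flr_idr_select <- function(flr_rep1, flr_rep2, threshold = 0.01,
                           min_sites = 50L) {
  if (is.null(names(flr_rep1)) || is.null(names(flr_rep2)))
    stop("FLR vectors must be named by site id")
  common <- intersect(names(flr_rep1), names(flr_rep2))
  if (length(common) != length(flr_rep1) ||
      length(common) != length(flr_rep2))
    stop("replicates must share the same site universe")
  f1 <- flr_rep1[common]; f2 <- flr_rep2[common]
  pos <- f1 > 0 & f2 > 0
  empty <- data.frame(site = character(), flr_rep1 = numeric(),
                      flr_rep2 = numeric(), mean_flr = numeric())
  if (sum(pos) < min_sites) {
    warning("fewer than ", min_sites,
            " sites with positive FLR in both replicates; IDR skipped")
    attr(empty, "n_pass") <- 0L
    return(empty)
  }
  res <- idr_fit(f1[pos], f2[pos])
  n_pass <- idr_npass(res, threshold)
  out <- data.frame(site = common[pos], flr_rep1 = f1[pos],
                    flr_rep2 = f2[pos],
                    mean_flr = (f1[pos] + f2[pos]) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_flr), , drop = FALSE]
  out <- utils::head(out, n_pass)
  rownames(out) <- NULL
  attr(out, "n_pass") <- n_pass
  attr(out, "idr_result") <- res
  out
}

.check_intervals <- function(x, what) {
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("malformed intervals in ", what, " (start >= end) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(x)
}

#' Overlap two interval sets
#'
#' Reports which intervals of `a` overlap any interval of `b` by at least
#' `min_overlap_bp`, and the counts in both directions. Intervals are
#' 0-based half-open data frames (chrom, start, end).
#'
#' @param a,b interval data frames.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return list with `a_hits` (logical per row of a), `b_hits`, `pairs`
#'   (data frame of overlapping index pairs), `n_a`, `n_b`.
#' @export
overlap_sets <- function(a, b, min_overlap_bp = 1L) {
  .check_intervals(a, "a"); .check_intervals(b, "b")
  gr <- function(x) GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end))  # to 1-based closed
  ov <- GenomicRanges::findOverlaps(gr(a), gr(b),
                                    minoverlap = min_overlap_bp)
  qa <- S4Vectors::queryHits(ov); sb <- S4Vectors::subjectHits(ov)
  list(a_hits = seq_len(nrow(a)) %in% qa,
       b_hits = seq_len(nrow(b)) %in% sb,
       pairs = data.frame(a = qa, b = sb),
       n_a = length(unique(qa)), n_b = length(unique(sb)))
}

#' Truncate a jointly-called ranked list at the IDR-derived count
#'
#' @param joint_items data frame sorted descending by score.
#' @param n_pass number of items to keep (from [idr_npass()]).
#' @return the top `n_pass` rows; the full list with a warning if
#'   `n_pass` exceeds its length.
#' @export
truncate_joint_list <- function(joint_items, n_pass) {
  if (n_pass > nrow(joint_items)) {
    warning("n_pass exceeds the list length; returning the full list")
    return(joint_items)
  }
  utils::head(joint_items, n_pass)
}

#' Odds ratio and Fisher test for a 2x2 overlap table
#'
#' @param n11 items overlapping in both sets; `n10`, `n01` in one only;
#'   `n00` in neither (background universe).
#' @param n10,n01,n00 see `n11`.
#' @return list with `odds_ratio` ((n11 n00)/(n10 n01)) and `p_value`
#'   from [stats::fisher.test()].
#' @export
overlap_fisher <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n10, n01, n00), 2, 2)
  list(odds_ratio = (n11 * n00) / (n10 * n01),
       p_value = stats::fisher.test(tab)$p.value)
}
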