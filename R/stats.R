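#' One-tailed Wilcoxon test
#'
#' Paired data use the signed-rank statistic (zero differences dropped, count
#' reported via a message), unpaired the rank-sum statistic. Exact p-values
#' where available, normal approximation with ties.
#'
#' @param x,y numeric samples.
#' @param paired logical; requires equal lengths when TRUE.
#' @param alternative `"greater"` (x tends larger) or `"less"`.
#' @return one-sided p-value.
#' @export
wilcoxon_one_tail <- function(x, y, paired = FALSE,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (paired) {
    if (length(x) != length(y)) stop("paired test requires equal lengths")
    dz <- x - y
    nz <- sum(dz == 0)
    if (nz == length(dz)) {
      warning("all differences are zero; p = 1")
      return(1)
    }
    if (nz > 0) message(nz, " zero difference(s) dropped")
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, alternative = alternative,
                       exact = NULL)$p.value)
  unname(p)
}

#' Category permutation test on a benchmark battery
#'
#' Compares two categories of models (e.g. predicted-integrated vs
#' random-integrated), each summarized by a per-model battery of test values.
#' The total benchmark statistic is, by default, the sum over tests of the
#' directed difference of category medians standardized by the pooled
#' standard deviation of that test (`statistic = "standardized"`); the
#' coarser directional win count, ties counting 0.5, is available as
#' `statistic = "wins"`. The win count saturates at the number of tests, so
#' its permutation tail cannot resolve small p-values; the standardized sum
#' can. Models are shuffled between the categories `n_perm` times and the
#' p-value is `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @param a,b matrices, models x tests (same test columns).
#' @param directions character vector per test, `"lower_better"` or
#'   `"higher_better"`.
#' @param n_perm number of permutations (default 10000; must be >= 1).
#' @param statistic `"standardized"` (default) or `"wins"`.
#' @param seed integer seed.
#' @return list with `p`, `observed`, `n_perm`, `statistic`.
#' @export
category_permutation_test <- function(a, b, directions, n_perm = 10000L,
                                      statistic = c("standardized", "wins"),
                                      seed = 1L) {
  statistic <- match.arg(statistic)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b) || ncol(a) == 0L) {
    stop("categories must share a nonempty test battery")
  }
  if (length(directions) != ncol(a)) stop("one direction per test required")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  sgn <- ifelse(directions == "lower_better", -1, 1)
  pooled_sd <- apply(rbind(a, b), 2, stats::sd)
  pooled_sd[pooled_sd == 0] <- Inf  # constant test contributes 0
  stat <- function(ma, mb) {
    d <- (apply(ma, 2, stats::median) - apply(mb, 2, stats::median)) * sgn
    if (statistic == "wins") {
      sum(d > 0) + 0.5 * sum(d == 0)
    } else {
      sum(d / pooled_sd)
    }
  }
  obs <- stat(a, b)
  pool <- rbind(a, b)
  na <- nrow(a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(nrow(pool), na)
      stat(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE]) >= obs
    }, logical(1)))
  })
  list(p = (1 + exceed) / (n_perm + 1), observed = obs, n_perm = n_perm,
       statistic = statistic)
}

#' Minimal sparseness reproducing the complete-data result
#'
#' For each test, the smallest sampling fraction such that it and every larger
#' fraction are statistically indistinguishable from the complete dataset
#' (two-tailed rank-sum test at `alpha`).
#'
#' @param results_by_fraction named list (names = fractions, e.g. `"0.05"`),
#'   each a models x tests matrix of benchmark values.
#' @param full_results models x tests matrix for the complete dataset.
#' @param alpha significance level (default 0.01).
#' @return named numeric vector: minimal fraction per test. When
#'   `results_by_fraction` includes the full set itself, that fraction always
#'   qualifies, so the result is well defined.
#' @export
minimal_sparseness <- function(results_by_fraction, full_results,
                               alpha = 0.01) {
  fr <- as.numeric(names(results_by_fraction))
  if (anyNA(fr)) stop("list names must be numeric fractions")
  o <- order(fr)
  fr <- fr[o]
  results_by_fraction <- results_by_fraction[o]
  full_results <- as.matrix(full_results)
  tests <- colnames(full_results)
  if (is.null(tests)) tests <- as.character(seq_len(ncol(full_results)))
  ok <- vapply(results_by_fraction, function(m) {
    m <- as.matrix(m)
    vapply(seq_len(ncol(m)), function(t) {
      p <- suppressWarnings(stats::wilcox.test(
        m[, t], full_results[, t], alternative = "two.sided")$p.value)
      is.na(p) || p >= alpha
    }, logical(1))
  }, logical(ncol(full_results)))
  ok <- matrix(ok, nrow = ncol(full_results))  # tests x fractions
  out <- vapply(seq_len(nrow(ok)), function(t) {
    run <- rev(cumprod(rev(ok[t, ]))) > 0  # TRUE where all larger also ok
    fr[which(run)[1]]
  }, numeric(1))
  stats::setNames(out, tests)
}
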