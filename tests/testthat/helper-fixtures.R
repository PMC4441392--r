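# Shared fixtures, memoized per test run. Worlds are deterministic per seed,
# so caching only saves wall time.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_world <- function() memo("tiny", synthetic_world("tiny", seed = 11))
small_world <- function() memo("small", synthetic_world("small", seed = 42))

small_truth_map <- function() {
  memo("small_dm", truth_distance_map(small_world()$truth))
}

# a small fixed layout used by unit tests: 2 chromosomes x 5 beads @ 10 kbp
unit_layout <- function(centromeres = c(chrA = 25000, chrB = 25000)) {
  genome_layout(c(chrA = 50000, chrB = 50000), 10000L, centromeres)
}

# deterministic pseudo-random model on a given layout
unit_model <- function(layout = unit_layout(), seed = 1, scale = 300) {
  n <- n_beads(layout)
  set.seed(seed)
  coords <- matrix(stats::rnorm(3 * n, 0, scale), n, 3)
  model3d(layout, coords)
}

# random codon frequency vector
rand_profile <- function() {
  g <- stats::rgamma(64, 0.7)
  g / sum(g)
}

# independent exhaustive enumeration of the one-sided signed-rank p-value
# P(W+ >= w_obs) over all 2^n sign patterns (no ties/zeros assumed)
exact_signed_rank_p <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs)
}

# exhaustive one-sided rank-sum p-value: P(W_x >= observed) over all
# assignments of the pooled ranks to group x
exact_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  idx <- utils::combn(length(pooled), length(x))
  w_all <- colSums(matrix(r[idx], nrow = length(x)))
  mean(w_all >= w_obs)
}
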