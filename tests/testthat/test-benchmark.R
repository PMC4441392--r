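test_that("nsd detects planted structure and degenerate cases", {
  w <- tiny_world()
  # coincident beads -> 0
  gl <- genome_layout(c(a = 1e5), 10000L)
  X <- matrix(rnorm(30, 0, 200), 10, 3)
  X[1:3, ] <- 0
  m <- model3d(gl, X)
  expect_equal(nsd(m, 1:3, n_random = 20, seed = 1), 0)
  # whole-universe set ~ 1
  expect_equal(nsd(m, 1:10, n_random = 50, seed = 1), 1, tolerance = 1e-6)
  # planted compact set on the synthetic truth is clearly co-localized
  expect_lt(nsd(w$truth, w$sets$planted_compact, seed = 3), 0.8)
})

test_that("nsd matches a direct two-stage computation", {
  gl <- genome_layout(c(a = 1e5), 10000L)
  set.seed(8)
  m <- model3d(gl, matrix(rnorm(30, 0, 300), 10, 3))
  beads <- c(2L, 5L, 9L)
  val <- nsd(m, beads, n_random = 2000, seed = 5)
  obs <- mean(dist(m$coords[beads, ]))
  # expectation over random triples, computed exhaustively
  trips <- t(combn(10, 3))
  expd <- mean(apply(trips, 1, function(tr) mean(dist(m$coords[tr, ]))))
  expect_equal(val, obs / expd, tolerance = 0.05)
})

test_that("partitioned sets average their subset NSDs", {
  gl <- genome_layout(c(a = 1e5), 10000L)
  set.seed(2)
  m <- model3d(gl, matrix(rnorm(30, 0, 300), 10, 3))
  bt <- bead_table(gl)
  memb <- data.frame(chrom = "a", start_bp = bt$start_bp[c(1, 2, 7, 8)],
                     end_bp = bt$end_bp[c(1, 2, 7, 8)],
                     subset = c("s1", "s1", "s2", "s2"))
  whole <- nsd(m, locus_set("x", memb), n_random = 500, seed = 7)
  part1 <- nsd(m, c(1L, 2L), n_random = 500, seed = 7)
  part2 <- nsd(m, c(7L, 8L), n_random = 500, seed = 7)
  expect_equal(whole, mean(c(part1, part2)), tolerance = 0.1)
})

test_that("telomere_radius is the mean telomere norm", {
  gl <- genome_layout(c(a = 20000, b = 20000), 10000L)
  X <- rbind(c(800, 0, 0), c(0, 800, 0), c(0, 0, 600), c(0, 0, -1000))
  m <- model3d(gl, X)
  expect_equal(telomere_radius(m), mean(c(800, 800, 600, 1000)))
  # oracle on a random model
  m2 <- unit_model(seed = 5)
  tb <- telomere_beads(m2$layout)
  expect_equal(telomere_radius(m2),
               mean(sqrt(rowSums(m2$coords[tb, ]^2))))
})

test_that("arm_ratios: compact far-apart territories give cis_vs_trans << 1", {
  gl <- genome_layout(c(a = 50000, b = 50000), 10000L,
                      c(a = 25000, b = 25000))
  X <- matrix(0, 10, 3)
  X[1:5, 1] <- c(-20, -10, 0, 10, 20) + 800   # chrom a at x ~ +800
  X[6:10, 1] <- c(-20, -10, 0, 10, 20) - 800  # chrom b at x ~ -800
  m <- model3d(gl, X)
  ar <- arm_ratios(m)
  expect_lt(ar$cis_vs_trans, 0.1)
  expect_lt(ar$self_vs_else, 0.1)
})

test_that("arm_ratios equal brute-force means on a random model", {
  gl <- genome_layout(c(a = 70000, b = 70000), 10000L,
                      c(a = 35000, b = 35000))
  set.seed(12)
  m <- model3d(gl, matrix(rnorm(42, 0, 400), 14, 3))
  ar <- arm_ratios(m)
  D <- as.matrix(dist(m$coords))
  arms <- list(a_l = 1:3, a_r = 5:7, b_l = 8:10, b_r = 12:14)
  bmean <- function(u, v) mean(D[arms[[u]], arms[[v]]])
  cis_a <- bmean("a_l", "a_r") /
    mean(c(bmean("a_l", "b_l"), bmean("a_l", "b_r"),
           bmean("a_r", "b_l"), bmean("a_r", "b_r")))
  cis_b <- bmean("b_l", "b_r") /
    mean(c(bmean("b_l", "a_l"), bmean("b_l", "a_r"),
           bmean("b_r", "a_l"), bmean("b_r", "a_r")))
  expect_equal(ar$cis_vs_trans, mean(c(cis_a, cis_b)))
  # self-vs-else oracle
  sve <- mean(vapply(names(arms), function(u) {
    self <- mean(dist(m$coords[arms[[u]], ]))
    other <- mean(vapply(setdiff(names(arms), u),
                         function(v) bmean(u, v), numeric(1)))
    self / other
  }, numeric(1)))
  expect_equal(ar$self_vs_else, sve)
  # all arms are 30 kbp (< 250 kbp): short/long ratio undefined
  expect_true(is.na(ar$short_vs_long))
})

test_that("model_similarity is 1 for congruent models and matches oracle", {
  m <- unit_model(seed = 3)
  expect_equal(model_similarity(list(m, m)), 1)
  # mirror image: distances invariant
  mm <- model3d(m$layout, m$coords %*% diag(c(-1, 1, 1)))
  expect_equal(model_similarity(list(m, mm)), 1, tolerance = 1e-6)
  set.seed(10)
  ms <- lapply(1:3, function(k) unit_model(seed = k + 20))
  got <- model_similarity(ms)
  dv <- lapply(ms, function(x) as.numeric(model_distances(x)))
  oracle <- mean(c(cor(dv[[1]], dv[[2]], method = "spearman"),
                   cor(dv[[1]], dv[[3]], method = "spearman"),
                   cor(dv[[2]], dv[[3]], method = "spearman")))
  expect_equal(got, oracle)
})

test_that("binned_spearman reduces to plain Spearman and handles edges", {
  set.seed(7)
  d <- runif(100, 10, 900)
  cv <- d + rnorm(100, 0, 50)
  expect_equal(suppressMessages(binned_spearman(d, cv, n_bins = 100)),
               cor(d, cv, method = "spearman"))
  expect_equal(suppressMessages(binned_spearman(d, d, n_bins = 50)), 1)
  expect_warning(out <- binned_spearman(d, rep(1, 100)), "constant")
  expect_true(is.na(out))
  # n_bins = 2 on 4 pairs: hand computation
  d4 <- c(5, 1, 8, 2); c4 <- c(10, 20, 30, 40)
  got <- binned_spearman(d4, c4, n_bins = 2)
  # bins by covariate: {10,20} -> mean d 3, {30,40} -> mean d 5
  expect_equal(got, cor(c(15, 35), c(3, 5), method = "spearman"))
})

test_that("binned_spearman is near zero for independent covariates", {
  set.seed(15)
  rhos <- replicate(50, {
    d <- runif(400); cv <- runif(400)
    binned_spearman(d, cv, n_bins = 20)
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("pa_distance follows 2|p-q|/(p+q)", {
  expect_equal(pa_distance(3, 3), 0)
  expect_equal(pa_distance(3, 1), 1)
  expect_true(is.na(pa_distance(0, 0)))
  set.seed(4)
  p <- runif(50, 0, 10); q <- runif(50, 0, 10)
  expect_equal(pa_distance(p, q), 2 * abs(p - q) / (p + q))
})

test_that("ppi_pair_distance matches BFS with the 255 sentinel", {
  edges <- data.frame(a = c("g1", "g2", "g4"), b = c("g2", "g3", "g5"))
  pairs <- data.frame(gene_a = c("g1", "g1", "g1", "g9"),
                      gene_b = c("g2", "g3", "g4", "g1"))
  d <- ppi_pair_distance(edges, pairs)
  expect_equal(d, c(1, 2, 255, 255))
  # random graph against an independent BFS
  set.seed(18)
  nodes <- paste0("n", 1:12)
  e <- data.frame(a = sample(nodes, 15, TRUE), b = sample(nodes, 15, TRUE))
  e <- e[e$a != e$b, ]
  qp <- data.frame(gene_a = sample(nodes, 20, TRUE),
                   gene_b = sample(nodes, 20, TRUE))
  got <- ppi_pair_distance(e, qp)
  adj <- lapply(stats::setNames(nodes, nodes), function(x)
    unique(c(e$b[e$a == x], e$a[e$b == x])))
  bfs <- function(s, t) {
    if (s == t) return(0)
    seen <- s; frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      if (t %in% nxt) return(depth)
      seen <- c(seen, nxt); frontier <- nxt
    }
    255
  }
  oracle <- mapply(bfs, qp$gene_a, qp$gene_b)
  expect_equal(got, unname(oracle))
})

test_that("telomere_cluster merges closest telomeres first", {
  gl <- genome_layout(c(a = 20000, b = 20000), 10000L)
  # telomeres are all 4 beads; place three clustered configurations
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(10.5, 0, 0))
  m <- model3d(gl, X)
  tc <- telomere_cluster(list(m))
  expect_equal(unname(tc$dist_matrix),
               unname(as.matrix(dist(X))))
  # first merge is the closest pair (beads 3, 4 at distance 0.5)
  expect_setequal(abs(tc$tree$merge[1, ]), c(3, 4))
  # averaging across models
  m2 <- model3d(gl, X + 1)  # translated copy, same distances
  tc2 <- telomere_cluster(list(m, m2))
  expect_equal(tc2$dist_matrix, tc$dist_matrix)
})

test_that("benchmark values are invariant to rotation and mirror", {
  w <- tiny_world()
  m <- w$truth
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, -1))  # rotation + mirror
  mt <- model3d(m$layout, m$coords %*% R)
  expect_equal(nsd(mt, w$sets$planted_compact, n_random = 50, seed = 2),
               nsd(m, w$sets$planted_compact, n_random = 50, seed = 2))
  expect_equal(telomere_radius(mt), telomere_radius(m))
  art <- arm_ratios(mt); ar <- arm_ratios(m)
  expect_equal(art$cis_vs_trans, ar$cis_vs_trans)
  expect_equal(model_similarity(list(m, mt)), 1, tolerance = 1e-4)
})

test_that("run_benchmark assembles a directional report", {
  w <- tiny_world()
  rep <- run_benchmark(w$truth, sets = w$sets, genes = w$genes,
                       n_random = 30, seed = 2)
  expect_true(all(c("nsd_centromeres", "nsd_planted_compact",
                    "telomere_radius", "cis_vs_trans") %in% rep$test))
  expect_true(all(rep$direction %in% c("lower_better", "higher_better")))
  expect_false(anyNA(rep$value))
})
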