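#' Normalized set distance (NSD) of a locus set in a model
#'
#' Mean pairwise 3D distance within the set, divided by the mean of the same
#' statistic over `n_random` random sets of equal size drawn from the
#' universe: the annotated gene list for gene sets, the uniform bead grid for
#' interval sets. Values below 1 indicate co-localization, above 1 dispersion.
#' For partitioned sets the NSD is computed per subset and averaged.
#'
#' @param model a `model3d`.
#' @param set a `locus_set`, or an integer vector of bead indices.
#' @param genes gene annotation (required for gene sets).
#' @param universe `"genes"` or `"grid"`; defaults to the set type.
#' @param n_random number of random reference sets (default 100).
#' @param seed integer seed for the random draws.
#' @return numeric NSD.
#' @export
nsd <- function(model, set, genes = NULL, universe = NULL, n_random = 100L,
                seed = 1L) {
  if (inherits(set, "locus_set")) {
    sb <- set_beads(set, model$layout, genes)
    if (is.null(universe)) {
      universe <- if (set$type == "genes") "genes" else "grid"
    }
    groups <- split(sb$bead, sb$subset, drop = TRUE)
    if (!length(groups)) groups <- list(sb$bead)
  } else {
    groups <- list(as.integer(set))
    if (is.null(universe)) universe <- "grid"
  }
  pool <- if (universe == "genes") {
    if (is.null(genes)) stop("genes universe requires an annotation")
    unname(gene_beads(genes, model$layout))
  } else {
    seq_len(n_beads(model$layout))
  }
  seeds <- derive_seeds(seed, length(groups))
  vals <- mapply(function(beads, s) {
    if (length(beads) < 2L) stop("set size must be >= 2")
    obs <- mean_pairwise(model$coords, beads)
    expd <- with_seed(s, mean(vapply(seq_len(n_random), function(k) {
      mean_pairwise(model$coords, sample(pool, length(beads)))
    }, numeric(1))))
    obs / expd
  }, groups, seeds)
  mean(vals)
}

mean_pairwise <- function(coords, beads) {
  mean(stats::dist(coords[beads, , drop = FALSE]))
}

#' Mean telomere distance from the nucleus center
#'
#' @param model a `model3d` in the nucleus-centered frame.
#' @return mean Euclidean norm (nm) of the telomere beads.
#' @export
telomere_radius <- function(model) {
  tb <- telomere_beads(model$layout)
  mean(sqrt(rowSums(model$coords[tb, , drop = FALSE]^2)))
}

#' Chromosome-arm distance ratios
#'
#' Arms are the bead runs on either side of the centromere bead (which belongs
#' to neither arm), sampled at model resolution. Three ratios quantify
#' chromosome territories:
#' \describe{
#'   \item{cis_vs_trans}{mean distance between the two arms of a chromosome
#'     over mean distance to all other chromosomes' arms, averaged over
#'     chromosomes.}
#'   \item{short_vs_long}{mean distance among short arms (< 250 kbp) over mean
#'     distance among long arms (>= 250 kbp).}
#'   \item{self_vs_else}{mean distance within an arm over mean distance from
#'     that arm to all other arms, averaged over arms.}
#' }
#' Chromosomes without a centromere are skipped with a message.
#'
#' @param model a `model3d` whose layout has centromeres.
#' @param short_arm_bp threshold separating short from long arms (250 kbp).
#' @return named list with the three ratios (NA when undefined).
#' @export
arm_ratios <- function(model, short_arm_bp = 250000) {
  layout <- model$layout
  X <- model$coords
  ch <- layout$chrom
  cen <- centromere_beads(layout)
  skipped <- setdiff(ch$name, names(cen))
  if (length(skipped)) {
    message("no centromere for: ", paste(skipped, collapse = ", "))
  }
  arms <- list()   # per arm: beads, chrom, length_bp
  for (nm in names(cen)) {
    k <- match(nm, ch$name)
    first <- ch$offset[k] + 1L
    last <- ch$offset[k] + ch$n_beads[k]
    cb <- cen[[nm]]
    left <- if (cb > first) first:(cb - 1L) else integer(0)
    right <- if (cb < last) (cb + 1L):last else integer(0)
    for (a in list(left, right)) {
      if (length(a) >= 1L) {
        arms[[length(arms) + 1L]] <- list(
          beads = a, chrom = k,
          length_bp = length(a) * layout$resolution_bp)
      }
    }
  }
  if (length(arms) < 2L) {
    return(list(cis_vs_trans = NA_real_, short_vs_long = NA_real_,
                self_vs_else = NA_real_))
  }
  D <- as.matrix(stats::dist(X))
  between <- function(a, b) mean(D[a$beads, b$beads])
  nA <- length(arms)
  chrom_of <- vapply(arms, `[[`, 0, "chrom")

  # cis-vs-trans per chromosome with two arms
  cvt <- c()
  for (k in unique(chrom_of)) {
    own <- which(chrom_of == k)
    oth <- which(chrom_of != k)
    if (length(own) == 2L && length(oth)) {
      cis <- between(arms[[own[1]]], arms[[own[2]]])
      trans <- mean(vapply(own, function(a)
        mean(vapply(oth, function(b)
          between(arms[[a]], arms[[b]]), numeric(1))), numeric(1)))
      cvt <- c(cvt, cis / trans)
    }
  }

  # short-vs-long: mean pairwise distance among short arms / among long arms
  lens <- vapply(arms, `[[`, 0, "length_bp")
  short <- which(lens < short_arm_bp)
  long <- which(lens >= short_arm_bp)
  pair_mean <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    pr <- utils::combn(idx, 2)
    mean(vapply(seq_len(ncol(pr)), function(q)
      between(arms[[pr[1, q]]], arms[[pr[2, q]]]), numeric(1)))
  }
  svl <- pair_mean(short) / pair_mean(long)

  # self-vs-else per arm
  sve <- vapply(seq_len(nA), function(a) {
    self <- if (length(arms[[a]]$beads) > 1L) {
      mean(stats::dist(X[arms[[a]]$beads, , drop = FALSE]))
    } else NA_real_
    oth <- setdiff(seq_len(nA), a)
    els <- mean(vapply(oth, function(b) between(arms[[a]], arms[[b]]),
                       numeric(1)))
    self / els
  }, numeric(1))

  list(cis_vs_trans = if (length(cvt)) mean(cvt) else NA_real_,
       short_vs_long = svl,
       self_vs_else = mean(sve, na.rm = TRUE))
}

#' Mean inter-model similarity (Spearman over pairwise distances)
#'
#' For every pair of models, Spearman's rank correlation between their full
#' vectors of bead-pair distances; the reported similarity is the mean over
#' model pairs. Distances are rigid-motion and mirror invariant, so congruent
#' models score 1.
#'
#' @param models list of >= 2 `model3d` on the same layout.
#' @return mean Spearman rho.
#' @export
model_similarity <- function(models) {
  if (length(models) < 2L) stop("need >= 2 models")
  nb <- vapply(models, function(m) n_beads(m$layout), integer(1))
  if (length(unique(nb)) != 1L) stop("models on mismatched layouts")
  dv <- lapply(models, function(m) as.numeric(model_distances(m)))
  pr <- utils::combn(length(models), 2)
  mean(vapply(seq_len(ncol(pr)), function(k)
    stats::cor(dv[[pr[1, k]]], dv[[pr[2, k]]], method = "spearman"),
    numeric(1)))
}

#' Binned Spearman correlation between model distances and a covariate
#'
#' Gene pairs are sorted by the covariate and cut into `n_bins` equal-count
#' bins; Spearman's rho is computed between the per-bin mean covariate and the
#' per-bin mean 3D distance. With as many bins as pairs this reduces to plain
#' Spearman on the pairs.
#'
#' @param model_dist numeric vector of 3D distances per gene pair.
#' @param covariate numeric vector, parallel to `model_dist`.
#' @param n_bins number of bins (default 2000; reduced with a message when
#'   there are fewer pairs).
#' @return Spearman rho (NA with a warning for a constant covariate).
#' @export
binned_spearman <- function(model_dist, covariate, n_bins = 2000L) {
  stopifnot(length(model_dist) == length(covariate))
  ok <- is.finite(model_dist) & is.finite(covariate)
  model_dist <- model_dist[ok]; covariate <- covariate[ok]
  n <- length(model_dist)
  if (stats::sd(covariate) == 0) {
    warning("constant covariate; correlation undefined")
    return(NA_real_)
  }
  if (n < n_bins) {
    message("reducing bins from ", n_bins, " to ", n)
    n_bins <- n
  }
  o <- order(covariate)
  grp <- ceiling(seq_len(n) / (n / n_bins))
  grp[grp > n_bins] <- n_bins
  mx <- as.numeric(rowsum(covariate[o], grp) / tabulate(grp, n_bins))
  my <- as.numeric(rowsum(model_dist[o], grp) / tabulate(grp, n_bins))
  stats::cor(mx, my, method = "spearman")
}

#' Normalized protein-abundance distance between two genes
#'
#' `2 |p - q| / (p + q)`, in `[0, 2)`. Pairs with `p + q == 0` are undefined
#' and return NA.
#'
#' @param p,q nonnegative abundances (vectorized).
#' @return numeric vector.
#' @export
pa_distance <- function(p, q) {
  out <- 2 * abs(p - q) / (p + q)
  out[p + q == 0] <- NA_real_
  out
}

#' Shortest-path distances between gene pairs on a PPI graph
#'
#' Unweighted shortest paths; disconnected pairs and genes absent from the
#' graph are assigned the finite sentinel 255.
#'
#' @param edges data.frame with two columns of gene ids (one edge per row).
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param disconnected sentinel for unreachable pairs (default 255).
#' @return numeric vector of hop counts, parallel to `pairs`.
#' @export
ppi_pair_distance <- function(edges, pairs, disconnected = 255) {
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  vn <- igraph::V(g)$name
  known_a <- pairs$gene_a %in% vn
  known_b <- pairs$gene_b %in% vn
  out <- rep(disconnected, nrow(pairs))
  ok <- known_a & known_b
  if (any(ok)) {
    froms <- unique(pairs$gene_a[ok])
    D <- igraph::distances(g, v = froms, to = vn)
    d <- D[cbind(match(pairs$gene_a[ok], froms),
                 match(pairs$gene_b[ok], vn))]
    d[!is.finite(d)] <- disconnected
    out[ok] <- d
  }
  out
}

#' Average-linkage clustering of telomeres across models
#'
#' Builds the telomere-telomere distance matrix averaged across models, runs
#' agglomerative clustering with average linkage, and returns the tree plus
#' the matrix reordered by the dendrogram for heat-map rendering.
#'
#' @param models nonempty list of `model3d` on the same layout.
#' @return list with `dist_matrix` (labelled, original order), `tree`
#'   (an `hclust`), `order` (leaf order), `ordered_matrix`.
#' @export
telomere_cluster <- function(models) {
  if (!length(models)) stop("need >= 1 model")
  layout <- models[[1]]$layout
  tb <- telomere_beads(layout)
  M <- Reduce(`+`, lapply(models, function(m)
    as.matrix(stats::dist(m$coords[tb, , drop = FALSE])))) / length(models)
  bt <- bead_table(layout)
  lab <- sprintf("%s:%s", bt$chrom_name[tb],
                 ifelse(bt$bin[tb] == 1L, "L", "R"))
  dimnames(M) <- list(lab, lab)
  tree <- stats::hclust(stats::as.dist(M), method = "average")
  list(dist_matrix = M, tree = tree, order = tree$order,
       ordered_matrix = M[tree$order, tree$order])
}

#' Run a benchmark battery over one model
#'
#' Computes the configured tests and records each value with its improvement
#' direction (whether lower or higher values indicate a stronger signal), so
#' category comparisons know which tail to test.
#'
#' @param model a `model3d`.
#' @param sets named list of `locus_set` objects (NSD tests; lower better).
#' @param genes gene annotation, required when gene sets or covariates are
#'   given.
#' @param covariates optional named list; each element a data.frame with
#'   columns `gene_a`, `gene_b`, `value` of per-gene-pair covariates, plus an
#'   optional `direction` attribute (`"lower_better"`/`"higher_better"`) for
#'   the resulting correlation's improvement direction.
#' @param n_random,seed NSD randomization parameters.
#' @return data.frame with columns `test`, `value`, `direction`.
#' @export
run_benchmark <- function(model, sets = list(), genes = NULL,
                          covariates = list(), n_random = 100L, seed = 1L) {
  rows <- list()
  add <- function(test, value, direction) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, value = value, direction = direction,
      stringsAsFactors = FALSE)
  }
  for (nm in names(sets)) {
    add(paste0("nsd_", nm),
        nsd(model, sets[[nm]], genes = genes, n_random = n_random,
            seed = seed),
        "lower_better")
  }
  add("telomere_radius", telomere_radius(model), "higher_better")
  ar <- arm_ratios(model)
  if (!is.na(ar$cis_vs_trans)) {
    add("cis_vs_trans", ar$cis_vs_trans, "lower_better")
  }
  if (length(covariates)) {
    gb <- gene_beads(genes, model$layout)
    for (nm in names(covariates)) {
      cv <- covariates[[nm]]
      bi <- gb[cv$gene_a]; bj <- gb[cv$gene_b]
      dd <- sqrt(rowSums((model$coords[bi, , drop = FALSE] -
                            model$coords[bj, , drop = FALSE])^2))
      rho <- binned_spearman(dd, cv$value)
      dir <- attr(cv, "direction")
      if (is.null(dir)) dir <- "higher_better"
      add(paste0("cor_", nm), rho, dir)
    }
  }
  do.call(rbind, rows)
}

#' Per-model similarity to the other models of a category
#'
#' For each model, the mean Spearman correlation of its bead-pair distance
#' vector with every other model in the list; [model_similarity()] is the
#' mean of these values' pairwise form. Useful as a per-model benchmark value
#' in paired category comparisons.
#'
#' @param models list of >= 2 `model3d` on the same layout.
#' @return numeric vector, one value per model.
#' @export
per_model_similarity <- function(models) {
  if (length(models) < 2L) stop("need >= 2 models")
  dv <- vapply(models, function(m) as.numeric(model_distances(m)),
               numeric(length(model_distances(models[[1]]))))
  rho <- stats::cor(dv, method = "spearman")
  (colSums(rho) - 1) / (ncol(rho) - 1)
}
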