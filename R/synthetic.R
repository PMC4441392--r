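#' Generate a synthetic genome layout with a ground-truth 3D structure
#'
#' Emulates the nuclear organization the reconstruction method is tested
#' against: each chromosome is a confined random walk grown from its
#' centromere; centromeres are tethered inside a small cap near the nuclear
#' envelope (Rabl-like clustering); telomere-proximal beads drift outward so
#' chromosome ends sit near the periphery (radius > 0.8 R). The walk is then
#' relaxed so the structure satisfies the reconstruction constraint classes
#' (nucleus confinement, adjacency bound, minimal separation) with zero
#' violation.
#'
#' @param n_chrom number of chromosomes (default 3).
#' @param beads_per_chrom beads per chromosome, recycled (default 50).
#' @param config a `recon_config` whose constraints the truth must satisfy.
#' @param seed integer seed; the generator is fully deterministic per seed.
#' @return list with `layout` (a `genome_layout`, centromeres at the middle
#'   bead) and `truth` (a `model3d`).
#' @export
make_genome <- function(n_chrom = 3L, beads_per_chrom = 50L,
                        config = recon_config(), seed = 1L) {
  beads_per_chrom <- rep_len(beads_per_chrom, n_chrom)
  if (any(beads_per_chrom < 2L)) stop("need >= 2 beads per chromosome")
  res <- 10000L
  lens <- beads_per_chrom * res
  names(lens) <- sprintf("chr%02d", seq_len(n_chrom))
  cen_bin <- floor(beads_per_chrom / 2)        # middle bead
  cen_bp <- (cen_bin + 0.5) * res
  layout <- genome_layout(lens, res, stats::setNames(cen_bp, names(lens)))

  R <- config$nucleus_radius_nm
  bound <- adjacent_bound_nm(layout, config)
  step <- 0.8 * bound
  msep <- config$min_separation_nm
  cap_center <- c(0, 0, 0.7 * R)

  coords <- with_seed(seed, {
    X <- matrix(0, n_beads(layout), 3)
    for (ci in seq_len(n_chrom)) {
      off <- layout$chrom$offset[ci]
      nb <- layout$chrom$n_beads[ci]
      cb <- cen_bin[ci] + 1L            # centromere bead (local)
      # centromere tethered in a small cap
      repeat {
        p0 <- cap_center + stats::rnorm(3, 0, 60)
        if (sum(p0^2) < (0.95 * R)^2) break
      }
      X[off + cb, ] <- p0
      # per-chromosome territory axis: spread azimuths, pointing away from
      # the centromere cap so arms occupy distinct angular sectors
      phi <- 2 * pi * (ci - 1) / n_chrom + stats::rnorm(1, 0, 0.2)
      psi <- 2.0  # ~115 degrees from +z
      axis <- c(cos(phi) * sin(psi), sin(phi) * sin(psi), cos(psi))
      grow <- function(from, idx) {
        p <- X[off + from, ]
        n_arm <- length(idx)
        for (t in seq_along(idx)) {
          drift <- (t / n_arm)^2 * 0.9    # telomeres pushed outward
          ok <- FALSE
          for (try in 1:60) {
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2))
            pull <- 0.5 * axis + 0.5 * p / max(sqrt(sum(p^2)), 1)
            pull <- pull / sqrt(sum(pull^2))
            dir <- (1 - drift) * u + drift * pull
            dir <- dir / sqrt(sum(dir^2))
            cand <- p + dir * step
            if (sum(cand^2) < (0.97 * R)^2) { ok <- TRUE; break }
          }
          if (!ok) cand <- p - p / sqrt(sum(p^2)) * step  # fall inward
          p <- cand
          X[off + idx[t], ] <<- p
        }
      }
      if (cb > 1L) grow(cb, (cb - 1L):1L)
      if (cb < nb) grow(cb, (cb + 1L):nb)
    }
    X
  })

  coords <- relax_structure(coords, layout, R, bound, msep)
  list(layout = layout, truth = model3d(layout, coords))
}

# push apart non-adjacent beads closer than msep, keeping adjacency and the
# nucleus bound; small margins so the final structure is strictly feasible
relax_structure <- function(X, layout, R, bound, msep, n_iter = 200L) {
  bt <- bead_table(layout)
  chrom0 <- bt$chrom - 1L
  for (it in seq_len(n_iter)) {
    v <- violations_cpp(as.numeric(t(X)), chrom0, R * 0.999, bound * 0.98,
                        msep * 1.05)
    if (max(v) <= 0) break
    D <- as.matrix(stats::dist(X))
    N <- nrow(X)
    close <- which(D < msep * 1.05 & upper.tri(D), arr.ind = TRUE)
    if (nrow(close)) {
      adj <- chrom0[close[, 1]] == chrom0[close[, 2]] &
        abs(close[, 1] - close[, 2]) == 1L
      close <- close[!adj, , drop = FALSE]
    }
    for (k in seq_len(nrow(close))) {
      a <- close[k, 1]; b <- close[k, 2]
      dv <- X[a, ] - X[b, ]
      d <- sqrt(sum(dv^2))
      if (d < 1e-9) dv <- c(1, 0, 0) else dv <- dv / d
      push <- (msep * 1.05 - d) / 2 + 0.5
      X[a, ] <- X[a, ] + dv * push
      X[b, ] <- X[b, ] - dv * push
    }
    # re-impose nucleus bound
    r <- sqrt(rowSums(X^2))
    out <- r > R * 0.999
    if (any(out)) X[out, ] <- X[out, ] * (R * 0.999) / r[out]
    # re-impose adjacency bound by pulling stretched neighbors together
    for (ci in seq_len(nrow(layout$chrom))) {
      off <- layout$chrom$offset[ci]
      nb <- layout$chrom$n_beads[ci]
      for (k in seq_len(nb - 1L)) {
        a <- off + k; b <- off + k + 1L
        dv <- X[b, ] - X[a, ]
        d <- sqrt(sum(dv^2))
        if (d > bound * 0.98) {
          mid <- (X[a, ] + X[b, ]) / 2
          X[a, ] <- mid - dv / d * (bound * 0.98) / 2
          X[b, ] <- mid + dv / d * (bound * 0.98) / 2
        }
      }
    }
  }
  X
}

#' Constraint violations of a model under a configuration
#'
#' @param model a `model3d`.
#' @param config a `recon_config`.
#' @return named numeric vector of maximal violations (nm):
#'   `nucleus`, `adjacency`, `separation`.
#' @export
constraint_violations <- function(model, config = recon_config()) {
  bt <- bead_table(model$layout)
  v <- violations_cpp(as.numeric(t(model$coords)), bt$chrom - 1L,
                      config$nucleus_radius_nm,
                      adjacent_bound_nm(model$layout, config),
                      config$min_separation_nm)
  stats::setNames(v, c("nucleus", "adjacency", "separation"))
}

#' Place genes uniformly along a synthetic genome
#'
#' @param layout a `genome_layout`.
#' @param n_genes total gene count (default 2 per bead).
#' @param gene_length_bp CDS footprint per gene (default 1200).
#' @param seed integer seed.
#' @return annotation data.frame `gene`, `chrom`, `start_bp`, `end_bp`.
#' @export
make_genes <- function(layout, n_genes = 2L * n_beads(layout),
                       gene_length_bp = 1200, seed = 1L) {
  bt <- bead_table(layout)
  with_seed(seed, {
    bead <- sort(sample(rep(seq_len(nrow(bt)), length.out = n_genes)))
    start <- bt$start_bp[bead] +
      floor(stats::runif(n_genes, 0,
                         pmax(1, bt$end_bp[bead] - bt$start_bp[bead] -
                                gene_length_bp)))
    data.frame(gene = sprintf("g%04d", seq_len(n_genes)),
               chrom = bt$chrom_name[bead],
               start_bp = start, end_bp = start + gene_length_bp,
               stringsAsFactors = FALSE)
  })
}

#' Plant a spatially compact locus set in a truth structure
#'
#' Picks a random anchor bead and takes its `size` nearest beads in 3D; the
#' corresponding bins form a co-localized interval set with true NSD well
#' below 1.
#'
#' @param truth a `model3d`.
#' @param size set size (default 15).
#' @param seed integer seed.
#' @return a `locus_set` of bin intervals named `"planted_compact"`.
#' @export
make_planted_set <- function(truth, size = 15L, seed = 1L) {
  X <- truth$coords
  anchor <- with_seed(seed, sample.int(nrow(X), 1L))
  d <- sqrt(rowSums(sweep(X, 2, X[anchor, ])^2))
  beads <- order(d)[seq_len(size)]
  bt <- bead_table(truth$layout)
  locus_set("planted_compact",
            data.frame(chrom = bt$chrom_name[beads],
                       start_bp = bt$start_bp[beads],
                       end_bp = bt$end_bp[beads],
                       stringsAsFactors = FALSE))
}

#' Simulate fragment-level Hi-C contacts from a truth structure
#'
#' Contact counts between bead pairs are Poisson with rate proportional to
#' `d^(-alpha)` (spatial distance d in nm), scaled so the expected total is
#' `reads`. Records are emitted at random bp positions inside the bins.
#'
#' @param truth a `model3d`.
#' @param reads expected total read count (default 400,000).
#' @param alpha decay exponent (> 0, default 1).
#' @param seed integer seed.
#' @return data.frame `chrom_i`, `pos_i`, `chrom_j`, `pos_j`, `count`
#'   (pairs with zero sampled count omitted).
#' @export
simulate_contacts <- function(truth, reads = 4e5, alpha = 1, seed = 1L) {
  stopifnot(alpha > 0)
  if (reads <= 0) {
    return(data.frame(chrom_i = character(0), pos_i = numeric(0),
                      chrom_j = character(0), pos_j = numeric(0),
                      count = numeric(0)))
  }
  bt <- bead_table(truth$layout)
  D <- stats::dist(truth$coords)
  N <- nrow(truth$coords)
  pr <- utils::combn(N, 2)
  rate <- as.numeric(D)^(-alpha)
  lambda <- reads * rate / sum(rate)
  with_seed(seed, {
    cnt <- stats::rpois(length(lambda), lambda)
    keep <- cnt > 0
    i <- pr[1, keep]; j <- pr[2, keep]
    data.frame(
      chrom_i = bt$chrom_name[i],
      pos_i = floor(stats::runif(sum(keep), bt$start_bp[i], bt$end_bp[i])),
      chrom_j = bt$chrom_name[j],
      pos_j = floor(stats::runif(sum(keep), bt$start_bp[j], bt$end_bp[j])),
      count = cnt[keep], stringsAsFactors = FALSE)
  })
}

#' Synthesize coding sequences whose codon usage tracks 3D position
#'
#' Genes are k-means clustered by the 3D position of their bead; each spatial
#' cluster receives a distinct codon-frequency center (Dirichlet draw), and
#' each gene's codon distribution is the cluster center mixed with a
#' gene-specific random component weighted by `noise` (0 = pure cluster
#' signal, 1 = no spatial signal). CDS are sampled codon by codon, giving a
#' positive codon-usage/3D-distance correlation by construction when noise is
#' low.
#'
#' @param truth a `model3d`.
#' @param genes annotation data.frame from [make_genes()].
#' @param k_clusters number of spatial clusters (default 20).
#' @param noise mixing weight in `[0, 1]` (default 0.1).
#' @param n_codons codons per CDS (default 600, a typical ORF length).
#' @param tau archetype mixing length scale in nm (default 300).
#' @param seed integer seed.
#' @return named character vector of CDS (names = gene ids), lengths
#'   divisible by 3.
#' @export
make_cds <- function(truth, genes, k_clusters = 20L, noise = 0.1,
                     n_codons = 600L, tau = 300, seed = 1L) {
  stopifnot(noise >= 0, noise <= 1)
  gb <- gene_beads(genes, truth$layout)
  pos <- truth$coords[gb, , drop = FALSE]
  with_seed(seed, {
    km <- stats::kmeans(pos, centers = k_clusters, nstart = 5)
    cl <- km$cluster
    rdirichlet <- function(a) { g <- stats::rgamma(64, a); g / sum(g) }
    # codon usage varies smoothly with nuclear position: each cluster's
    # center profile is a distance-weighted mixture of Dirichlet archetypes
    # placed at random anchor points, so CUFS distance between clusters
    # tracks their spatial separation rather than being iid
    n_arch <- 4L
    anchors <- pos[sample.int(nrow(pos), n_arch), , drop = FALSE]
    arch <- t(vapply(seq_len(n_arch), function(j) rdirichlet(0.5),
                     numeric(64)))
    centers <- lapply(seq_len(k_clusters), function(k) {
      d <- sqrt(rowSums(sweep(anchors, 2, km$centers[k, ])^2))
      wgt <- exp(-d / tau)
      p <- colSums(arch * wgt / sum(wgt))
      p / sum(p)
    })
    vapply(seq_len(nrow(genes)), function(g) {
      p <- (1 - noise) * centers[[cl[g]]] + noise * rdirichlet(1)
      paste(sample(CODONS, n_codons, replace = TRUE, prob = p),
            collapse = "")
    }, character(1)) |> stats::setNames(genes$gene)
  })
}

#' Write CDS to FASTA
#' @param cds named character vector of sequences.
#' @param path output file.
#' @export
write_cds <- function(cds, path) {
  x <- Biostrings::DNAStringSet(cds)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Derive a jittered "organism B" with an ortholog map
#'
#' Organism B shares the layout of the truth; its structure is the truth with
#' isotropic Gaussian coordinate jitter, modeling partial conservation of 3D
#' organization. A fraction `ortho_coverage` of genes get orthologs, mostly
#' 1:1, with a `one_to_many` fraction receiving a second (duplicated) B gene.
#' The organism-B distance map is the exact pairwise bead distances of the
#' jittered structure.
#'
#' @param truth a `model3d`.
#' @param genes organism-A annotation.
#' @param jitter_nm jitter standard deviation per axis (default 50).
#' @param ortho_coverage fraction of A genes with >= 1 ortholog (default 0.9).
#' @param one_to_many fraction of covered genes with 2 orthologs (default 0.1).
#' @param seed integer seed.
#' @return list with `model_b`, `genes_b`, `orthologs` (an `ortholog_table`),
#'   `dist_b` (bead-level `distance_map`).
#' @export
make_organism_b <- function(truth, genes, jitter_nm = 50,
                            ortho_coverage = 0.9, one_to_many = 0.1,
                            seed = 1L) {
  stopifnot(jitter_nm >= 0)
  layout <- truth$layout
  with_seed(seed, {
    coords_b <- truth$coords +
      matrix(stats::rnorm(length(truth$coords), 0, jitter_nm),
             ncol = 3)
    model_b <- model3d(layout, coords_b)
    genes_b <- genes
    genes_b$gene <- paste0("b_", genes$gene)
    covered <- sort(sample.int(nrow(genes), round(ortho_coverage *
                                                    nrow(genes))))
    pairs <- data.frame(gene_a = genes$gene[covered],
                        gene_b = genes_b$gene[covered],
                        stringsAsFactors = FALSE)
    n2 <- round(one_to_many * length(covered))
    if (n2 > 0) {
      dup <- sample(covered, n2)
      extra_b <- genes[dup, ]
      extra_b$gene <- paste0("b2_", genes$gene[dup])
      genes_b <- rbind(genes_b, extra_b)
      pairs <- rbind(pairs, data.frame(gene_a = genes$gene[dup],
                                       gene_b = extra_b$gene,
                                       stringsAsFactors = FALSE))
    }
    N <- nrow(coords_b)
    pr <- utils::combn(N, 2)
    dist_b <- distance_map(layout, pr[1, ], pr[2, ],
                           as.numeric(stats::dist(coords_b)))
    list(model_b = model_b, genes_b = genes_b,
         orthologs = ortholog_table(pairs), dist_b = dist_b)
  })
}

#' Build a complete synthetic test world
#'
#' Bundles the generators into the fixture used throughout the test battery:
#' a 3-chromosome genome with ground-truth structure, gene annotation,
#' simulated contacts, CDS with spatial codon-usage signal, a jittered
#' organism B with orthologs, and planted locus sets (centromeres plus a
#' spatially compact set).
#'
#' @param preset `"small"` (3 chromosomes x 50 beads, ~300 genes) or
#'   `"tiny"` (2 x 12 beads, 48 genes) for fast unit tests.
#' @param seed integer seed.
#' @param config a `recon_config`.
#' @return list with components `layout`, `truth`, `genes`, `contacts`,
#'   `cds`, `organism_b`, `sets` (named list of `locus_set`), `config`,
#'   `seed`.
#' @export
synthetic_world <- function(preset = c("small", "tiny"), seed = 1L,
                            config = recon_config()) {
  preset <- match.arg(preset)
  dims <- switch(preset,
                 small = list(nc = 3L, bpc = c(70L, 50L, 30L), reads = 4e5),
                 tiny = list(nc = 2L, bpc = c(14L, 10L), reads = 4e4))
  seeds <- derive_seeds(seed, 6)
  g <- make_genome(dims$nc, dims$bpc, config, seeds[1])
  genes <- make_genes(g$layout, seed = seeds[2])
  contacts <- simulate_contacts(g$truth, reads = dims$reads,
                                seed = seeds[3])
  cds <- make_cds(g$truth, genes, seed = seeds[4])
  orgb <- make_organism_b(g$truth, genes, seed = seeds[5])
  ch <- g$layout$chrom
  cen_set <- locus_set("centromeres",
                       data.frame(chrom = ch$name,
                                  start_bp = ch$centromere_bp,
                                  end_bp = ch$centromere_bp + 1,
                                  stringsAsFactors = FALSE))
  planted <- make_planted_set(g$truth, seed = seeds[6])
  list(layout = g$layout, truth = g$truth, genes = genes,
       contacts = contacts, cds = cds, organism_b = orgb,
       sets = list(centromeres = cen_set, planted_compact = planted),
       config = config, seed = seed)
}

#' Exact truth distance map (all bead pairs) of a model
#' @param model a `model3d`.
#' @return a dense `distance_map`.
#' @export
truth_distance_map <- function(model) {
  N <- nrow(model$coords)
  pr <- utils::combn(N, 2)
  X <- model$coords
  # same arithmetic as objective(), so exact targets give an exact zero
  d <- sqrt(rowSums((X[pr[1, ], , drop = FALSE] -
                       X[pr[2, ], , drop = FALSE])^2))
  distance_map(model$layout, pr[1, ], pr[2, ], d)
}
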