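#' Ortholog table: many-to-many gene families between two organisms
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (one row per
#'   ortholog pair; many-to-many allowed).
#' @return object of class `ortholog_table`; `$families` maps each organism-A
#'   gene to its set of organism-B orthologs.
#' @export
ortholog_table <- function(pairs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs <- unique(pairs[c("gene_a", "gene_b")])
  if (!nrow(pairs)) stop("empty ortholog table")
  structure(list(pairs = pairs,
                 families = split(pairs$gene_b, pairs$gene_a)),
            class = "ortholog_table")
}

#' Read an ortholog table from TSV (columns: gene_a, gene_b)
#' @param path file path.
#' @return an `ortholog_table`.
#' @export
read_orthologs <- function(path) {
  ortholog_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Gene-pair spatial distances from a bead-level distance map
#'
#' Each gene maps to the bin containing its midpoint; a gene pair is assigned
#' the distance of the nearest measured bin pair (smallest combined bin offset
#' from the two midpoints, searching each gene's own chromosome; ties resolve
#' to the lower bin index). Genes with no measured bin on their chromosome are
#' skipped.
#'
#' @param map a `distance_map` for the organism.
#' @param genes annotation data.frame (`gene`, `chrom`, `start_bp`, `end_bp`).
#' @param max_offset search radius in bins around each midpoint (default 10).
#' @return data.frame `gene_a`, `gene_b`, `d` (one row per measurable pair,
#'   `gene_a < gene_b` lexicographically by position in `genes`).
#' @export
gene_pair_distances <- function(map, genes, max_offset = 10L) {
  layout <- map$layout
  N <- n_beads(layout)
  D <- as_dense(map)
  D[D == 0] <- NA
  bt <- bead_table(layout)
  gb <- gene_beads(genes, layout)
  # beads on the same chromosome with any measurement, per gene candidate list
  measured <- rowSums(!is.na(D)) > 0
  cand <- lapply(seq_along(gb), function(g) {
    b <- gb[g]
    offs <- 0:max_offset
    # interleave +/- offsets, lower index first on ties
    cc <- unique(as.integer(rbind(b - offs, b + offs)))
    cc <- cc[cc >= 1 & cc <= N]
    cc <- cc[bt$chrom[cc] == bt$chrom[b]]
    cc[measured[cc]]
  })
  ng <- length(gb)
  pr <- utils::combn(ng, 2)
  ai <- pr[1, ]; bi <- pr[2, ]
  # fast path: both midpoint bins measured against each other
  d <- D[cbind(gb[ai], gb[bi])]
  miss <- which(is.na(d))
  for (k in miss) {
    ca <- cand[[ai[k]]]; cb <- cand[[bi[k]]]
    if (!length(ca) || !length(cb)) next
    sub <- D[ca, cb, drop = FALSE]
    if (all(is.na(sub))) next
    # combined genomic offset of each candidate pair
    off <- outer(abs(ca - gb[ai[k]]), abs(cb - gb[bi[k]]), "+")
    off[is.na(sub)] <- NA
    # ties: lower bin indices (candidates are ordered low-first per offset)
    d[k] <- sub[which(off == min(off, na.rm = TRUE))[1]]
  }
  ok <- !is.na(d)
  data.frame(gene_a = genes$gene[ai[ok]], gene_b = genes$gene[bi[ok]],
             d = d[ok], stringsAsFactors = FALSE)
}

#' Project gene-pair distances through orthologs into organism A
#'
#' The projected distance of an organism-A gene pair (i, j) is the mean of the
#' measured distances over all ortholog pairs (k, l), k in O_i, l in O_j.
#' Pairs with no measurable ortholog pair are omitted.
#'
#' @param dist_b data.frame `gene_a`, `gene_b`, `d` of organism-B gene-pair
#'   distances (as from [gene_pair_distances()]).
#' @param orthologs an `ortholog_table` (A gene -> B genes).
#' @return data.frame `gene_a`, `gene_b`, `d` in organism-A gene ids.
#' @export
project_orthologous <- function(dist_b, orthologs) {
  # symmetric dense lookup over the B genes that appear anywhere
  gb_ids <- sort(unique(c(dist_b$gene_a, dist_b$gene_b,
                          orthologs$pairs$gene_b)))
  M <- matrix(NA_real_, length(gb_ids), length(gb_ids))
  ia <- match(dist_b$gene_a, gb_ids)
  ib <- match(dist_b$gene_b, gb_ids)
  M[cbind(ia, ib)] <- dist_b$d
  M[cbind(ib, ia)] <- dist_b$d
  fam <- lapply(orthologs$families, match, gb_ids)
  genes_a <- names(fam)
  n <- length(genes_a)
  if (n < 2L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      d = numeric(0), stringsAsFactors = FALSE))
  }
  pr <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pr)), function(k) {
    sub <- M[fam[[pr[1, k]]], fam[[pr[2, k]]], drop = FALSE]
    mean(sub[!is.na(sub)])  # NaN when no measurable ortholog pair
  }, numeric(1))
  ok <- is.finite(d)
  data.frame(gene_a = genes_a[pr[1, ok]], gene_b = genes_a[pr[2, ok]],
             d = d[ok], stringsAsFactors = FALSE)
}

#' Scale distances so their median matches a reference distance set
#'
#' Accounts for different nuclear dimensions between organisms (and for the
#' arbitrary scale of codon-usage distances): all values are multiplied by
#' `median(reference) / median(dist)`.
#'
#' @param d numeric vector of distances, or a data.frame with a `d` column.
#' @param reference a `distance_map` or numeric vector of reference distances.
#' @return the rescaled input (same shape).
#' @export
scale_to_median <- function(d, reference) {
  ref <- if (inherits(reference, "distance_map")) reference$d else reference
  vals <- if (is.data.frame(d)) d$d else d
  if (!length(vals) || !length(ref)) stop("empty input to scale_to_median")
  m <- stats::median(vals)
  if (m == 0) stop("zero median; cannot scale")
  f <- stats::median(ref) / m
  if (is.data.frame(d)) { d$d <- d$d * f; d } else d * f
}

#' Keep the extreme quantile bands of a distance set
#'
#' Retains values at or below the `low_q` quantile and at or above the
#' `1 - high_q` quantile. Presets used in integration: orthologous
#' `(0.05, 0)` (short, reliable distances), codon-usage `(0.10, 0.10)`,
#' orthologous-into-complete-map `(0.50, 0)`.
#'
#' @param d numeric vector, or data.frame with a `d` column.
#' @param low_q,high_q band sizes in `[0, 1]`, `low_q + high_q <= 1`.
#' @return the filtered input (same shape).
#' @export
select_quantile_band <- function(d, low_q = 0.05, high_q = 0) {
  stopifnot(low_q >= 0, high_q >= 0, low_q + high_q <= 1)
  vals <- if (is.data.frame(d)) d$d else d
  keep <- rep(FALSE, length(vals))
  if (low_q > 0) keep <- keep | vals <= stats::quantile(vals, low_q)
  if (high_q > 0) keep <- keep | vals >= stats::quantile(vals, 1 - high_q)
  if (low_q + high_q >= 1) keep <- rep(TRUE, length(vals))
  if (is.data.frame(d)) d[keep, , drop = FALSE] else vals[keep]
}

# the 64 codons in Biostrings' lexicographic order
CODONS <- as.character(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3))

#' Codon frequency profile of a coding sequence
#'
#' Counts in-frame codons (all 64, stops included) and normalizes to sum 1.
#' Codons containing non-ACGT characters are skipped with a message.
#'
#' @param cds a character string, or `DNAString`, of coding sequence; length
#'   must be divisible by 3.
#' @return named numeric vector of 64 codon frequencies summing to 1.
#' @export
codon_frequencies <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) == 0L || nchar(s) %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3")
  }
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(gsub("U", "T", s)), width = 3L, step = 3L)
  cnt <- cnt[CODONS]
  skipped <- nchar(s) / 3 - sum(cnt)
  if (skipped > 0) message(skipped, " ambiguous codon(s) skipped")
  if (sum(cnt) == 0) stop("no unambiguous codons in CDS")
  cnt / sum(cnt)
}

#' Codon-usage distance between two genes (Endres-Schindelin form)
#'
#' With codon frequency vectors `p`, `q` and `m = (p + q)/2`, the distance is
#' `d_KL(p, m) + d_KL(q, m)` where `d_KL` is the Kullback-Leibler divergence
#' with the convention `0 log 0 = 0`. The original metric takes the square
#' root of this quantity (`sqrt = TRUE`); both variants are rank-equivalent.
#'
#' @param p,q codon frequency vectors (each summing to 1).
#' @param sqrt take the square root (the metric proper; default FALSE).
#' @param base logarithm base (default `exp(1)`).
#' @return nonnegative scalar; 0 iff `p == q`; at most `2 log 2` (before the
#'   square root) for disjoint supports.
#' @export
cufs_distance <- function(p, q, sqrt = FALSE, base = exp(1)) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i], base = base))
  }
  d <- kl(p) + kl(q)
  d <- max(d, 0)  # guard tiny negative rounding
  if (sqrt) base::sqrt(d) else d
}

#' All-pairs codon-usage distances for a set of genes
#'
#' @param profiles named list of codon frequency vectors (names = gene ids),
#'   or a genes-by-64 matrix with rownames.
#' @param sqrt,base passed to [cufs_distance()].
#' @return data.frame `gene_a`, `gene_b`, `d` over all unordered pairs.
#' @export
cufs_matrix <- function(profiles, sqrt = FALSE, base = exp(1)) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 profiles")
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pr <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pr)), function(k)
    cufs_distance(profiles[pr[1, k], ], profiles[pr[2, k], ],
                  sqrt = sqrt, base = base), numeric(1))
  data.frame(gene_a = ids[pr[1, ]], gene_b = ids[pr[2, ]], d = d,
             stringsAsFactors = FALSE)
}

#' Bin gene-pair distances into bead-pair model coordinates
#'
#' Gene pairs whose midpoints fall in the same bead pair are averaged. Pairs
#' mapping to the same bead on both sides (same bin) are dropped, since a
#' self-distance carries no reconstruction information.
#'
#' @param gene_dist data.frame `gene_a`, `gene_b`, `d`.
#' @param layout a `genome_layout`.
#' @param genes gene annotation data.frame.
#' @return a `distance_map`.
#' @export
gene_pairs_to_bins <- function(gene_dist, layout, genes) {
  gb <- gene_beads(genes, layout)
  bi <- gb[gene_dist$gene_a]
  bj <- gb[gene_dist$gene_b]
  if (anyNA(bi) || anyNA(bj)) stop("gene id missing from annotation")
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  keep <- lo != hi
  lo <- lo[keep]; hi <- hi[keep]; d <- gene_dist$d[keep]
  key <- paste(lo, hi)
  agg <- rowsum(cbind(d, 1), key)
  parts <- strsplit(rownames(agg), " ")
  distance_map(layout,
               as.integer(vapply(parts, `[`, "", 1)),
               as.integer(vapply(parts, `[`, "", 2)),
               agg[, 1] / agg[, 2])
}

#' Read CDS sequences from FASTA
#' @param path FASTA file; record ids must match gene ids.
#' @return named character vector of sequences.
#' @export
read_cds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Codon profiles for a named set of CDS
#' @param cds named character vector of coding sequences.
#' @return genes-by-64 matrix of codon frequencies.
#' @export
codon_profile_matrix <- function(cds) {
  t(vapply(cds, codon_frequencies, numeric(64)))
}

#' Build an integration candidate map from an orthologous organism
#'
#' Full pipeline: organism-B gene-pair distances from its distance map,
#' ortholog projection into organism A, median scaling against the organism-A
#' Hi-C distances, quantile-band filtering (default: bottom 5%, the more
#' reliable short distances), and binning into model coordinates.
#'
#' @param dist_b organism-B bead-level `distance_map`.
#' @param genes_b organism-B gene annotation.
#' @param orthologs an `ortholog_table` (A -> B).
#' @param genes_a organism-A gene annotation.
#' @param layout_a organism-A `genome_layout`.
#' @param reference organism-A Hi-C `distance_map` used for median scaling.
#' @param low_q,high_q quantile band (default 0.05, 0).
#' @return a `distance_map` of candidate predicted distances in organism A.
#' @export
ortho_candidates <- function(dist_b, genes_b, orthologs, genes_a, layout_a,
                             reference, low_q = 0.05, high_q = 0) {
  gpd <- gene_pair_distances(dist_b, genes_b)
  proj <- project_orthologous(gpd, orthologs)
  proj <- scale_to_median(proj, reference)
  band <- select_quantile_band(proj, low_q, high_q)
  gene_pairs_to_bins(band, layout_a, genes_a)
}

#' Build an integration candidate map from codon usage similarity
#'
#' Full pipeline: codon profiles from CDS, all-pairs codon-usage distances,
#' median scaling against the Hi-C distances, quantile-band filtering
#' (default: top and bottom 10%), and binning into model coordinates.
#'
#' @param cds named character vector of coding sequences.
#' @param genes gene annotation.
#' @param layout a `genome_layout`.
#' @param reference Hi-C `distance_map` used for median scaling.
#' @param low_q,high_q quantile band (default 0.10, 0.10).
#' @param sqrt,base passed to [cufs_distance()].
#' @return a `distance_map` of candidate predicted distances.
#' @export
cufs_candidates <- function(cds, genes, layout, reference,
                            low_q = 0.10, high_q = 0.10,
                            sqrt = FALSE, base = exp(1)) {
  prof <- codon_profile_matrix(cds)
  cm <- cufs_matrix(prof, sqrt = sqrt, base = base)
  cm <- scale_to_median(cm, reference)
  band <- select_quantile_band(cm, low_q, high_q)
  gene_pairs_to_bins(band, layout, genes)
}
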