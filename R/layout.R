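#' Genome layout: chromosomes discretized into fixed-size beads
#'
#' A `genome_layout` describes an ordered set of chromosomes, a bin resolution,
#' and optional centromere positions. Each chromosome is discretized into beads
#' of `resolution_bp` base pairs; bead `k` (1-based) of a chromosome covers the
#' half-open interval `[(k-1)*res, k*res)` in 0-based genomic coordinates, with
#' the last bead truncated at the chromosome end. Beads are indexed globally
#' `1..n_beads(layout)` in chromosome order.
#'
#' @param chromosomes data.frame with columns `name` and `length_bp`, or a
#'   named numeric vector of chromosome lengths in bp.
#' @param resolution_bp bin size in bp (default 10,000, the model resolution).
#' @param centromeres optional named vector/list mapping chromosome name to
#'   centromere position in bp (0-based).
#' @return An object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(c(chrI = 30000, chrII = 20000), resolution_bp = 10000)
#' n_beads(gl)
#' @export
genome_layout <- function(chromosomes, resolution_bp = 10000L,
                          centromeres = NULL) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length_bp = as.numeric(chromosomes),
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L) stop("layout must contain >= 1 chromosome")
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (any(chromosomes$length_bp <= 0)) stop("chromosome lengths must be > 0")
  resolution_bp <- as.integer(resolution_bp)
  if (resolution_bp <= 0L) stop("resolution_bp must be positive")

  nb <- as.integer(ceiling(chromosomes$length_bp / resolution_bp))
  offset <- c(0L, cumsum(nb))[seq_len(nrow(chromosomes))]
  cen <- rep(NA_real_, nrow(chromosomes))
  if (!is.null(centromeres)) {
    idx <- match(names(centromeres), chromosomes$name)
    if (anyNA(idx)) stop("centromere for unknown chromosome")
    cen[idx] <- as.numeric(unlist(centromeres))
    bad <- !is.na(cen) & (cen < 0 | cen >= chromosomes$length_bp)
    if (any(bad)) stop("centromere position outside chromosome")
  }
  structure(list(
    chrom = data.frame(name = as.character(chromosomes$name),
                       length_bp = as.numeric(chromosomes$length_bp),
                       n_beads = nb, offset = offset,
                       centromere_bp = cen, stringsAsFactors = FALSE),
    resolution_bp = resolution_bp
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %d beads @ %d bp\n",
              nrow(x$chrom), n_beads(x), x$resolution_bp))
  invisible(x)
}

#' Total number of beads in a layout
#' @param layout a `genome_layout`.
#' @return integer bead count.
#' @export
n_beads <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$chrom$n_beads)
}

chrom_index <- function(layout, chrom) {
  idx <- match(as.character(chrom), layout$chrom$name)
  if (anyNA(idx)) {
    stop("unknown chromosome: ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Map genomic positions to global bead indices
#'
#' Positions are 0-based; bins are half-open, so position `k*res` belongs to
#' bead `k+1` of its chromosome. Bead indices are global and 1-based.
#'
#' @param layout a `genome_layout`.
#' @param chrom chromosome name(s), recycled against `pos_bp`.
#' @param pos_bp 0-based genomic position(s) in bp.
#' @return integer vector of global bead indices.
#' @export
bead_of <- function(layout, chrom, pos_bp) {
  ci <- chrom_index(layout, chrom)
  pos_bp <- as.numeric(pos_bp)
  if (any(pos_bp < 0 | pos_bp >= layout$chrom$length_bp[ci])) {
    stop("position out of chromosome range")
  }
  as.integer(layout$chrom$offset[ci] + pos_bp %/% layout$resolution_bp + 1)
}

#' Chromosome and local bin of each global bead
#'
#' @param layout a `genome_layout`.
#' @return data.frame with one row per bead: `bead`, `chrom` (integer
#'   chromosome index), `chrom_name`, `bin` (1-based within chromosome),
#'   `start_bp`, `end_bp` (0-based half-open), `mid_bp`.
#' @export
bead_table <- function(layout) {
  ch <- layout$chrom
  chrom <- rep(seq_len(nrow(ch)), ch$n_beads)
  bin <- unlist(lapply(ch$n_beads, seq_len), use.names = FALSE)
  start <- (bin - 1) * layout$resolution_bp
  end <- pmin(bin * layout$resolution_bp, ch$length_bp[chrom])
  data.frame(bead = seq_along(chrom), chrom = chrom,
             chrom_name = ch$name[chrom], bin = bin,
             start_bp = start, end_bp = end, mid_bp = (start + end) / 2,
             stringsAsFactors = FALSE)
}

#' Telomere beads: first and last bead of every chromosome
#'
#' Single-bead chromosomes contribute one bead.
#'
#' @param layout a `genome_layout`.
#' @return sorted integer vector of global bead indices.
#' @export
telomere_beads <- function(layout) {
  ch <- layout$chrom
  sort(unique(c(ch$offset + 1L, ch$offset + ch$n_beads)))
}

#' Centromere beads for chromosomes with an annotated centromere
#'
#' @param layout a `genome_layout`.
#' @return named integer vector (names are chromosome names); chromosomes
#'   without a centromere are omitted.
#' @export
centromere_beads <- function(layout) {
  ch <- layout$chrom
  has <- !is.na(ch$centromere_bp)
  if (!any(has)) return(integer(0))
  b <- bead_of(layout, ch$name[has], ch$centromere_bp[has])
  names(b) <- ch$name[has]
  b
}

#' A 3D chromosome model: one coordinate triple per bead
#'
#' Coordinates are in nanometers in a nucleus-centered frame (origin at the
#' nucleus center).
#'
#' @param layout a `genome_layout`.
#' @param coords numeric matrix, `n_beads(layout)` rows by 3 columns.
#' @return object of class `model3d`.
#' @export
model3d <- function(layout, coords) {
  stopifnot(inherits(layout, "genome_layout"))
  coords <- as.matrix(coords)
  if (nrow(coords) != n_beads(layout) || ncol(coords) != 3L) {
    stop("coords must be n_beads x 3")
  }
  if (!all(is.finite(coords))) stop("coords must be finite")
  dimnames(coords) <- NULL
  structure(list(layout = layout, coords = coords), class = "model3d")
}

#' @export
print.model3d <- function(x, ...) {
  cat(sprintf("model3d: %d beads, %d chromosome(s), radius range %.0f-%.0f nm\n",
              nrow(x$coords), nrow(x$layout$chrom),
              min(sqrt(rowSums(x$coords^2))),
              max(sqrt(rowSums(x$coords^2)))))
  invisible(x)
}

#' All pairwise bead distances of a model
#' @param model a `model3d`.
#' @return a `dist` object over beads (nm).
#' @export
model_distances <- function(model) stats::dist(model$coords)

#' A named set of genomic loci or genes, optionally partitioned into subsets
#'
#' @param name set name.
#' @param members either a data.frame with columns `chrom`, `start_bp`,
#'   `end_bp` (BED-style, 0-based half-open) and optional `subset`, or a
#'   character vector of gene ids (with optional `subset` argument).
#' @param subset optional subset labels parallel to `members` when `members`
#'   is a gene-id vector.
#' @return object of class `locus_set`.
#' @export
locus_set <- function(name, members, subset = NULL) {
  if (is.character(members)) {
    members <- data.frame(gene = members, stringsAsFactors = FALSE)
    if (!is.null(subset)) members$subset <- as.character(subset)
  }
  stopifnot(is.data.frame(members))
  structure(list(name = name, members = members,
                 type = if ("gene" %in% names(members)) "genes" else "loci"),
            class = "locus_set")
}

#' Resolve a locus set to bead indices
#'
#' Interval members map to the bin containing their midpoint; gene members are
#' looked up in `genes` (an annotation data.frame with `gene`, `chrom`,
#' `start_bp`, `end_bp`) and likewise mapped at their midpoint.
#'
#' @param set a `locus_set`.
#' @param layout a `genome_layout`.
#' @param genes gene annotation data.frame (required for gene sets).
#' @return data.frame with columns `bead` and `subset` (NA when unpartitioned).
#' @export
set_beads <- function(set, layout, genes = NULL) {
  m <- set$members
  if (set$type == "genes") {
    if (is.null(genes)) stop("gene set requires a gene annotation")
    idx <- match(m$gene, genes$gene)
    if (anyNA(idx)) stop("unknown gene id(s) in set '", set$name, "'")
    chrom <- genes$chrom[idx]
    mid <- (genes$start_bp[idx] + genes$end_bp[idx] - 1) / 2
  } else {
    chrom <- m$chrom
    mid <- (m$start_bp + m$end_bp - 1) / 2
  }
  data.frame(bead = bead_of(layout, chrom, floor(mid)),
             subset = if ("subset" %in% names(m)) as.character(m$subset)
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' Midpoint bead of every gene in an annotation
#' @param genes annotation data.frame with `gene`, `chrom`, `start_bp`, `end_bp`.
#' @param layout a `genome_layout`.
#' @return named integer vector of beads, names are gene ids.
#' @export
gene_beads <- function(genes, layout) {
  mid <- floor((genes$start_bp + genes$end_bp - 1) / 2)
  b <- bead_of(layout, genes$chrom, mid)
  names(b) <- genes$gene
  b
}

# ---- file formats ----------------------------------------------------------

#' Read a genome layout from TSV (columns: name, length_bp, optional
#' centromere_bp)
#' @param path file path.
#' @param resolution_bp bin size in bp.
#' @return a `genome_layout`.
#' @export
read_layout <- function(path, resolution_bp = 10000L) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  cen <- NULL
  if ("centromere_bp" %in% names(d)) {
    keep <- !is.na(d$centromere_bp)
    cen <- stats::setNames(d$centromere_bp[keep], d$name[keep])
  }
  genome_layout(d[c("name", "length_bp")], resolution_bp, cen)
}

#' Write a genome layout to TSV
#' @param layout a `genome_layout`.
#' @param path file path.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(
    data.frame(name = layout$chrom$name, length_bp = layout$chrom$length_bp,
               centromere_bp = layout$chrom$centromere_bp),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus set from BED (0-based half-open; optional 4th column = subset)
#' @param path BED file path.
#' @param name set name; defaults to the file name.
#' @return a `locus_set`.
#' @export
read_bed_set <- function(path, name = basename(path)) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start_bp", "end_bp")
  if (ncol(d) >= 4L) names(d)[4] <- "subset"
  locus_set(name, d[, intersect(names(d),
                                c("chrom", "start_bp", "end_bp", "subset"))])
}

#' Export a 3D model to XYZ or PDB
#'
#' XYZ: one record per bead carrying `<chrom>:<bin>` and coordinates in nm to
#' 3 decimals. PDB: one CA atom per bead, one chain per chromosome (chain ids
#' cycle through A-Z, a-z, 0-9); coordinate fields hold nanometers to 2
#' decimals (noted in a REMARK header), since nucleus-scale models overflow
#' the fixed-width fields in Angstrom.
#'
#' @param model a `model3d`.
#' @param path output file.
#' @param format `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  bt <- bead_table(model$layout)
  xyz <- model$coords
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    writeLines(c(sprintf("%d", nrow(xyz)),
                 "genome3d model; columns: chrom:bin x y z (nm)"), con)
    writeLines(sprintf("%s:%d %.3f %.3f %.3f", bt$chrom_name, bt$bin,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  } else {
    chains <- c(LETTERS, letters, 0:9)
    cid <- chains[(bt$chrom - 1L) %% length(chains) + 1L]
    writeLines("REMARK   scale: coordinate fields are in nanometers", con)
    writeLines(sprintf(
      "ATOM  %5d  CA  BED %s%4d    %8.2f%8.2f%8.2f  1.00  0.00",
      seq_len(nrow(xyz)) %% 100000L, cid, bt$bin %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("END", con)
  }
  invisible(path)
}

#' Import a model written by [export_model()]
#' @param path file path.
#' @param layout the `genome_layout` the model was built on.
#' @param format `"xyz"` or `"pdb"`.
#' @return a `model3d`.
#' @export
import_model <- function(path, layout, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "xyz") {
    n <- as.integer(lines[1])
    rec <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  } else {
    atom <- grep("^ATOM", lines, value = TRUE)
    xyz <- cbind(as.numeric(substr(atom, 31, 38)),
                 as.numeric(substr(atom, 39, 46)),
                 as.numeric(substr(atom, 47, 54)))
  }
  model3d(layout, xyz)
}

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# derive a stream of sub-seeds from one base seed, kept within 32-bit range
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
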