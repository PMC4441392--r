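#' Sparse symmetric contact map over layout beads
#'
#' Entries are stored once with `i <= j`; duplicate and mirrored records are
#' summed. Counts must be nonnegative.
#'
#' @param layout a `genome_layout`.
#' @param i,j global bead indices.
#' @param count contact counts.
#' @return object of class `contact_map` with fields `layout`, `i`, `j`,
#'   `count`.
#' @export
contact_map <- function(layout, i, j, count) {
  N <- n_beads(layout)
  i <- as.integer(i); j <- as.integer(j); count <- as.numeric(count)
  stopifnot(length(i) == length(j), length(i) == length(count))
  if (length(i) && (min(i, j) < 1L || max(i, j) > N)) {
    stop("bead index out of range")
  }
  if (any(count < 0)) stop("counts must be nonnegative")
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * N + hi
  agg <- rowsum(count, key)
  k <- as.numeric(rownames(agg))
  structure(list(layout = layout,
                 i = as.integer((k - 1) %/% N + 1),
                 j = as.integer((k - 1) %% N + 1),
                 count = as.numeric(agg[, 1])),
            class = "contact_map")
}

#' Sparse symmetric map of target spatial distances (nm)
#'
#' The reconstruction's input: each entry is an expected distance between two
#' beads. Distances must be positive and the diagonal is excluded.
#'
#' @param layout a `genome_layout`.
#' @param i,j global bead indices (`i != j`).
#' @param d distances in nm.
#' @return object of class `distance_map`.
#' @export
distance_map <- function(layout, i, j, d) {
  N <- n_beads(layout)
  i <- as.integer(i); j <- as.integer(j); d <- as.numeric(d)
  stopifnot(length(i) == length(j), length(i) == length(d))
  if (length(i) && (min(i, j) < 1L || max(i, j) > N)) {
    stop("bead index out of range")
  }
  if (any(i == j)) stop("self distances are not allowed")
  if (any(d <= 0)) stop("distances must be positive")
  lo <- pmin(i, j); hi <- pmax(i, j)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; d <- d[o]
  dup <- duplicated(cbind(lo, hi))
  if (any(dup)) { lo <- lo[!dup]; hi <- hi[!dup]; d <- d[!dup] }
  structure(list(layout = layout, i = lo, j = hi, d = d),
            class = "distance_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d entries, total count %.0f, %d beads\n",
              length(x$i), sum(x$count), n_beads(x$layout)))
  invisible(x)
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("distance_map: %d entries, median %.1f nm, %d beads\n",
              length(x$i), stats::median(x$d), n_beads(x$layout)))
  invisible(x)
}

#' Number of stored entries in a contact or distance map
#' @param map a `contact_map` or `distance_map`.
#' @return integer.
#' @export
map_size <- function(map) length(map$i)

# dense symmetric matrix view (small maps only)
as_dense <- function(map) {
  N <- n_beads(map$layout)
  M <- matrix(0, N, N)
  v <- if (inherits(map, "contact_map")) map$count else map$d
  M[cbind(map$i, map$j)] <- v
  M[cbind(map$j, map$i)] <- v
  M
}

#' Bin raw bp-level contact records into a bead-resolution contact map
#'
#' Records whose coordinates fall outside the layout are rejected with a
#' warning. Counts landing on the same (unordered) bead pair are summed.
#'
#' @param records data.frame with columns `chrom_i`, `pos_i`, `chrom_j`,
#'   `pos_j`, `count` (positions 0-based bp).
#' @param layout a `genome_layout`.
#' @return a `contact_map`.
#' @export
bin_contacts <- function(records, layout) {
  ok <- records$chrom_i %in% layout$chrom$name &
    records$chrom_j %in% layout$chrom$name
  len_i <- layout$chrom$length_bp[match(records$chrom_i, layout$chrom$name)]
  len_j <- layout$chrom$length_bp[match(records$chrom_j, layout$chrom$name)]
  ok <- ok & !is.na(len_i) & !is.na(len_j) &
    records$pos_i >= 0 & records$pos_i < len_i &
    records$pos_j >= 0 & records$pos_j < len_j
  if (any(!ok)) {
    warning(sum(!ok), " contact record(s) outside layout were dropped")
    records <- records[ok, , drop = FALSE]
  }
  contact_map(layout,
              bead_of(layout, records$chrom_i, records$pos_i),
              bead_of(layout, records$chrom_j, records$pos_j),
              records$count)
}

#' Iterative correction (matrix balancing) of a contact map
#'
#' Removes multiplicative per-bin biases by iteratively equalizing the total
#' contact of every covered bin (bins with zero coverage are untouched). The
#' overall sum is rescaled to the input total, so only relative values change.
#'
#' @param map a `contact_map` with at least one nonzero entry.
#' @param max_iter maximum balancing iterations.
#' @param tol relative tolerance on the coverage spread (coefficient of
#'   variation of per-bin totals over covered bins).
#' @return the corrected `contact_map`.
#' @export
ice_correct <- function(map, max_iter = 200L, tol = 1e-8) {
  if (!length(map$i) || all(map$count == 0)) stop("map has no contacts")
  w <- map$count
  diag_entry <- map$i == map$j
  covered <- sort(unique(c(map$i, map$j)))
  for (iter in seq_len(max_iter)) {
    cov <- rowsum(c(w, w[!diag_entry]),
                  c(map$i, map$j[!diag_entry]))
    s <- as.numeric(cov[, 1])
    names(s) <- rownames(cov)
    s <- s[match(as.character(covered), names(s))]
    s[is.na(s) | s == 0] <- 1
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv) || cv < tol) break
    b <- s / mean(s)
    bi <- b[match(map$i, covered)]
    bj <- b[match(map$j, covered)]
    w <- w / (bi * bj)
  }
  if (iter == max_iter && !is.na(cv) && cv >= tol) {
    warning("iterative correction did not converge; returning best iterate")
  }
  w <- w * sum(map$count) / sum(w)
  out <- map
  out$count <- w
  out
}

#' Fit a contact-frequency vs genomic-separation profile
#'
#' All intra-chromosomal bead pairs (unobserved pairs counting as frequency
#' zero) are grouped into `n_bins` equal-count bins of genomic separation
#' (|bin distance| x resolution); per bin the mean contact frequency and mean
#' separation are recorded. Frequencies are then forced
#' monotone non-increasing in separation by isotonic (pool-adjacent-violators)
#' regression, and pooled levels collapse to single knots so the profile is
#' invertible.
#'
#' @param map a `contact_map` containing intra-chromosomal entries.
#' @param n_bins number of profile bins (default 100; reduced with a message
#'   when fewer distinct separations are available).
#' @param packing_bp_per_nm chromatin packing ratio used downstream to convert
#'   bp to nm (default 130).
#' @return object of class `distance_profile`: data.frame `knots` with columns
#'   `freq` (strictly decreasing) and `sep_bp`, plus the packing constant.
#' @export
fit_distance_profile <- function(map, n_bins = 100L, packing_bp_per_nm = 130) {
  bt <- bead_table(map$layout)
  same <- bt$chrom[map$i] == bt$chrom[map$j] & map$i != map$j
  if (!any(same)) stop("no intra-chromosomal contacts; cannot fit profile")
  # all intra-chromosomal bead pairs; unobserved pairs carry frequency 0,
  # so far-separation bins average down to realistically small frequencies
  ch <- map$layout$chrom
  N <- n_beads(map$layout)
  sep_list <- lapply(seq_len(nrow(ch)), function(k) {
    nb <- ch$n_beads[k]
    if (nb < 2L) return(NULL)
    pr <- utils::combn(nb, 2)
    cbind(ch$offset[k] + pr[1, ], ch$offset[k] + pr[2, ])
  })
  allpr <- do.call(rbind, sep_list)
  sep <- (allpr[, 2] - allpr[, 1]) * map$layout$resolution_bp
  freq <- numeric(nrow(allpr))
  idx <- match((map$i[same] - 1) * N + map$j[same],
               (allpr[, 1] - 1) * N + allpr[, 2])
  freq[idx] <- map$count[same]
  nsep <- length(unique(sep))
  if (nsep < n_bins) {
    message("reducing profile bins from ", n_bins, " to ", nsep)
    n_bins <- nsep
  }
  o <- order(sep)
  sep <- sep[o]; freq <- freq[o]
  grp <- ceiling(seq_along(sep) / (length(sep) / n_bins))
  grp[grp > n_bins] <- n_bins
  mfreq <- as.numeric(rowsum(freq, grp) / tabulate(grp, n_bins))
  msep <- as.numeric(rowsum(sep, grp) / tabulate(grp, n_bins))
  nwt <- tabulate(grp, n_bins)
  # monotone non-increasing frequency in separation (PAVA on -freq)
  iso <- pava_nondecreasing(-mfreq, nwt)
  f <- -iso
  # collapse pooled (equal-frequency) runs into single knots
  run <- cumsum(c(TRUE, abs(diff(f)) > 0))
  kf <- as.numeric(rowsum(f * nwt, run) / rowsum(nwt, run))
  ks <- as.numeric(rowsum(msep * nwt, run) / rowsum(nwt, run))
  structure(list(knots = data.frame(freq = kf, sep_bp = ks),
                 packing_bp_per_nm = packing_bp_per_nm),
            class = "distance_profile")
}

# weighted pool-adjacent-violators, nondecreasing fit
pava_nondecreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- rep(1L, n)
  m <- 0L
  for (k in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[k]; wt[m] <- w[k]; idx[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tot <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tot
      wt[m - 1L] <- tot
      idx[m - 1L] <- idx[m - 1L] + idx[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], idx[seq_len(m)])
}

#' Invert a distance profile: contact frequency to genomic separation (bp)
#'
#' Linear interpolation between profile knots on the frequency axis.
#' Frequencies above the largest knot clamp to the smallest separation;
#' frequencies below the smallest knot clamp to the largest separation.
#'
#' @param profile a `distance_profile`.
#' @param freq numeric vector of contact frequencies.
#' @return separations in bp.
#' @export
profile_invert <- function(profile, freq) {
  k <- profile$knots
  if (nrow(k) == 1L) return(rep(k$sep_bp, length(freq)))
  k <- k[order(k$freq), ]  # approx needs increasing x
  out <- stats::approx(x = k$freq, y = k$sep_bp, xout = freq,
                       rule = 1, ties = "ordered")$y
  out[freq >= max(k$freq)] <- k$sep_bp[which.max(k$freq)]
  out[freq <= min(k$freq)] <- k$sep_bp[which.min(k$freq)]
  out
}

#' Convert a contact map to a target distance map via a fitted profile
#'
#' Every nonzero off-diagonal contact is mapped to an equivalent genomic
#' separation by inverse interpolation of the profile, then to nanometers by
#' the packing constant (bp / packing). Self-bin contacts are excluded.
#'
#' @param map a `contact_map`.
#' @param profile a `distance_profile` from [fit_distance_profile()].
#' @return a `distance_map` in nm.
#' @export
contacts_to_distances <- function(map, profile) {
  keep <- map$i != map$j & map$count > 0
  sep <- profile_invert(profile, map$count[keep])
  distance_map(map$layout, map$i[keep], map$j[keep],
               sep / profile$packing_bp_per_nm)
}

#' Damp a fragment-level contact table to simulate a smaller experiment
#'
#' Per fragment pair: divide the read count by `factor`; drop pairs falling
#' below 1 (detection threshold); round to the nearest integer (half away
#' from zero); then sum the surviving reads per bead pair.
#'
#' @param records fragment-level data.frame as in [bin_contacts()].
#' @param factor damping factor (>= 1).
#' @param layout a `genome_layout`.
#' @return a damped `contact_map`.
#' @export
damp_contacts <- function(records, factor, layout) {
  if (factor < 1) stop("damping factor must be >= 1")
  x <- records$count / factor
  keep <- x >= 1
  records <- records[keep, , drop = FALSE]
  records$count <- round_half_away(x[keep])
  bin_contacts(records, layout)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a damped map to distances by rank matching
#'
#' Damped entries sorted by descending count receive the ascending-sorted
#' distance values of `reference` positionally (highest contact frequency gets
#' the smallest reference distance) until the damped map is exhausted. Count
#' ties are broken by a seeded random permutation.
#'
#' @param damped a `contact_map` (diagonal entries are dropped).
#' @param reference a `distance_map` supplying the distance distribution.
#' @param seed integer seed for tie-breaking.
#' @return a `distance_map`.
#' @export
damped_to_distances <- function(damped, reference, seed = 1L) {
  keep <- damped$i != damped$j & damped$count > 0
  i <- damped$i[keep]; j <- damped$j[keep]; cnt <- damped$count[keep]
  if (length(i) > length(reference$d)) {
    stop("damped map has more entries (", length(i),
         ") than reference distances (", length(reference$d), ")")
  }
  o <- with_seed(seed, {
    tie <- sample.int(length(cnt))
    order(-cnt, tie)
  })
  dsorted <- sort(reference$d)[seq_along(cnt)]
  d <- numeric(length(cnt))
  d[o] <- dsorted
  distance_map(damped$layout, i, j, d)
}

# ---- TSV I/O ---------------------------------------------------------------

#' Read bp-level contact records from TSV
#'
#' Expected columns: `chrom_i`, `pos_i`, `chrom_j`, `pos_j`, `count`.
#' @param path file path.
#' @return data.frame of records.
#' @export
read_contacts <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Write bp-level contact records to TSV
#' @param records data.frame of records.
#' @param path file path.
#' @export
write_contacts <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a distance map from TSV (columns: bead_i, bead_j, nm)
#' @param path file path.
#' @param layout a `genome_layout`.
#' @return a `distance_map`.
#' @export
read_distance_map <- function(path, layout) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  distance_map(layout, d$bead_i, d$bead_j, d$nm)
}

#' Write a distance map to TSV
#' @param map a `distance_map`.
#' @param path file path.
#' @export
write_distance_map <- function(map, path) {
  utils::write.table(data.frame(bead_i = map$i, bead_j = map$j, nm = map$d),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
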