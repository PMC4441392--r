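#' Uniformly sample a fraction of a distance map's entries
#'
#' Keeps `round(fraction * n)` entries drawn uniformly without replacement;
#' deterministic per seed.
#'
#' @param map a nonempty `distance_map`.
#' @param fraction in (0, 1].
#' @param seed integer seed.
#' @return a `distance_map`.
#' @export
uniform_sample <- function(map, fraction, seed = 1L) {
  n <- length(map$i)
  if (!n) stop("empty map")
  stopifnot(fraction > 0, fraction <= 1)
  k <- max(1L, round(fraction * n))
  keep <- if (k >= n) seq_len(n) else with_seed(seed, sample.int(n, k))
  distance_map(map$layout, map$i[keep], map$j[keep], map$d[keep])
}

#' Permute the coordinates of a distance map (random model input)
#'
#' A single permutation of bead indices is applied to both axes, preserving
#' symmetry and the multiset of distances exactly. Downstream co-localization
#' analyses keep loci at their original positions.
#'
#' @param map a nonempty `distance_map`.
#' @param seed integer seed.
#' @return a `distance_map` with relabeled bead indices.
#' @export
permute_coordinates <- function(map, seed = 1L) {
  if (!length(map$i)) stop("empty map")
  N <- n_beads(map$layout)
  p <- with_seed(seed, sample.int(N))
  distance_map(map$layout, p[map$i], p[map$j], map$d)
}

#' Per-bead interaction degrees of a distance map
#'
#' Degree of a bead is its number of distinct interaction partners; isolated
#' beads get 0.5 for numerical stability of inverse-degree weights.
#'
#' @param map a `distance_map`.
#' @return numeric vector of length `n_beads(layout)`, every entry >= 0.5.
#' @export
node_degrees <- function(map) {
  N <- n_beads(map$layout)
  deg <- tabulate(c(map$i, map$j), N)
  pmax(0.5, deg)
}

#' Merge predicted distances into a base map by poor-get-richer sampling
#'
#' Candidate entries that overlap the base map (distance already known) are
#' removed. Then `n` candidates are drawn sequentially without replacement,
#' each with probability proportional to `1/(d_i * d_j)` under the current
#' degrees; both endpoints' degrees are updated after every accepted draw, so
#' poorly covered beads keep attracting interactions.
#'
#' @param base a `distance_map` (never altered).
#' @param candidates a `distance_map` of predicted distances.
#' @param n number of entries to add; must not exceed the candidate count
#'   after overlap exclusion.
#' @param seed integer seed.
#' @return a `distance_map` with exactly `length(base) + n` entries.
#' @export
poor_get_richer_merge <- function(base, candidates, n, seed = 1L) {
  N <- n_beads(base$layout)
  bkey <- (pmin(base$i, base$j) - 1) * N + pmax(base$i, base$j)
  ckey <- (pmin(candidates$i, candidates$j) - 1) * N +
    pmax(candidates$i, candidates$j)
  avail <- !(ckey %in% bkey)
  ci <- candidates$i[avail]; cj <- candidates$j[avail]
  cd <- candidates$d[avail]
  if (n > length(ci)) {
    stop("requested ", n, " additions but only ", length(ci),
         " non-overlapping candidates are available")
  }
  counts <- tabulate(c(base$i, base$j), N)
  deg <- function(k) pmax(0.5, counts[k])
  picked <- integer(n)
  alive <- seq_along(ci)
  with_seed(seed, {
    for (t in seq_len(n)) {
      w <- 1 / (deg(ci[alive]) * deg(cj[alive]))
      sel <- alive[sample.int(length(alive), 1L, prob = w)]
      picked[t] <- sel
      counts[ci[sel]] <- counts[ci[sel]] + 1L
      counts[cj[sel]] <- counts[cj[sel]] + 1L
      alive <- alive[alive != sel]
    }
  })
  distance_map(base$layout, c(base$i, ci[picked]), c(base$j, cj[picked]),
               c(base$d, cd[picked]))
}

#' Merge by uniform candidate sampling (reference for poor-get-richer)
#'
#' Same exclusion and bookkeeping as [poor_get_richer_merge()] but candidates
#' are drawn uniformly; used as the comparison arm for degree-variance
#' analyses.
#'
#' @inheritParams poor_get_richer_merge
#' @return a `distance_map`.
#' @export
uniform_merge <- function(base, candidates, n, seed = 1L) {
  N <- n_beads(base$layout)
  bkey <- (pmin(base$i, base$j) - 1) * N + pmax(base$i, base$j)
  ckey <- (pmin(candidates$i, candidates$j) - 1) * N +
    pmax(candidates$i, candidates$j)
  avail <- which(!(ckey %in% bkey))
  if (n > length(avail)) stop("not enough non-overlapping candidates")
  sel <- with_seed(seed, sample(avail, n))
  distance_map(base$layout,
               c(base$i, candidates$i[sel]), c(base$j, candidates$j[sel]),
               c(base$d, candidates$d[sel]))
}
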