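#' Reconstruction configuration
#'
#' Constraint classes of the beads-on-a-string model: nucleus confinement,
#' bounded elasticity between adjacent beads, minimal separation between
#' non-adjacent beads, an optional nucleolus exclusion sphere, and optional
#' beads fixed at known coordinates. Values are configurable defaults: the
#' method defines the constraint classes, not particular numbers.
#'
#' @param nucleus_radius_nm nucleus radius (default 1000 nm).
#' @param adjacent_max_stretch multiplier on `resolution/packing` bounding the
#'   distance between adjacent beads (default 1.5).
#' @param min_separation_nm minimal distance between non-adjacent beads,
#'   enforced as a short-range repulsive penalty (default 30 nm).
#' @param packing_bp_per_nm chromatin packing (default 130 bp/nm).
#' @param nucleolus optional list(center = xyz nm, radius_nm, inside = beads
#'   confined inside; all other beads are kept outside).
#' @param fixed_beads optional named list / matrix: bead index -> coordinate
#'   triple held fixed during optimization.
#' @param n_starts random restarts; the best model is selected (default 4).
#' @param max_iter optimizer iteration cap per start (default 2000).
#' @param tol feasibility tolerance on the maximal constraint violation, nm
#'   (default 5).
#' @param seed base seed for random initialization.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(nucleus_radius_nm = 1000, adjacent_max_stretch = 1.5,
                         min_separation_nm = 30, packing_bp_per_nm = 130,
                         nucleolus = NULL, fixed_beads = NULL,
                         n_starts = 4L, max_iter = 2000L, tol = 5,
                         seed = 1L) {
  stopifnot(nucleus_radius_nm > 0, adjacent_max_stretch >= 1,
            min_separation_nm < 2 * nucleus_radius_nm, n_starts >= 1)
  structure(list(nucleus_radius_nm = nucleus_radius_nm,
                 adjacent_max_stretch = adjacent_max_stretch,
                 min_separation_nm = min_separation_nm,
                 packing_bp_per_nm = packing_bp_per_nm,
                 nucleolus = nucleolus, fixed_beads = fixed_beads,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "recon_config")
}

adjacent_bound_nm <- function(layout, config) {
  config$adjacent_max_stretch * layout$resolution_bp / config$packing_bp_per_nm
}

#' Sum of squared errors of a model against target distances
#'
#' The reconstruction objective: `sum_t (||p_i - q_i|| - delta_t)^2` over the
#' entries of the target distance map (nm^2).
#'
#' @param model a `model3d`.
#' @param targets a `distance_map` on the same layout.
#' @return numeric scalar (nm^2).
#' @export
objective <- function(model, targets) {
  p <- model$coords[targets$i, , drop = FALSE]
  q <- model$coords[targets$j, , drop = FALSE]
  d <- sqrt(rowSums((p - q)^2))
  sum((d - targets$d)^2)
}

#' Random initial configuration of the chromosomes
#'
#' Each chromosome is laid out as a random walk from a random interior point
#' with steps bounded by the adjacency constraint; positions leaving the
#' nucleus are reflected back inside the sphere. Deterministic per seed.
#'
#' @param layout a `genome_layout`.
#' @param config a `recon_config`.
#' @param seed integer seed.
#' @return a `model3d`.
#' @export
random_init <- function(layout, config, seed = config$seed) {
  R <- config$nucleus_radius_nm
  step <- adjacent_bound_nm(layout, config)
  # crude feasibility check: total bead volume at min separation vs nucleus
  if (n_beads(layout) * (config$min_separation_nm / 2)^3 > R^3) {
    stop("nucleus too small for bead count at the requested separation")
  }
  reflect <- function(p) {
    r <- sqrt(sum(p^2))
    while (r > R) {
      p <- p * (2 * R - r) / r
      r <- abs(2 * R - r)
    }
    p
  }
  with_seed(seed, {
    coords <- matrix(0, n_beads(layout), 3)
    for (ci in seq_len(nrow(layout$chrom))) {
      nb <- layout$chrom$n_beads[ci]
      off <- layout$chrom$offset[ci]
      p <- stats::runif(3, -R / 2, R / 2)
      coords[off + 1L, ] <- p
      if (nb > 1L) for (k in 2:nb) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2)) * stats::runif(1, 0.5, 1) * step
        p <- reflect(p + u)
        coords[off + k, ] <- p
      }
    }
    model3d(layout, coords)
  })
}

# nucleolus penalty value + gradient (per-bead sphere membership), in R:
# beads listed in `inside` must lie within the sphere, all others outside.
nucleolus_penalty <- function(x, nucleolus, w) {
  N <- length(x) / 3
  X <- matrix(x, ncol = 3, byrow = TRUE)
  ctr <- nucleolus$center
  rad <- nucleolus$radius_nm
  D <- sweep(X, 2, ctr)
  r <- sqrt(rowSums(D^2)) + 1e-12
  inside <- rep(FALSE, N)
  inside[nucleolus$inside] <- TRUE
  v <- ifelse(inside, pmax(0, r - rad), pmax(0, rad - r))
  sgn <- ifelse(inside, 1, -1)
  g <- D * (2 * w * v * sgn / r)
  list(value = w * sum(v^2), grad = as.numeric(t(g)), max_violation = max(v))
}

#' Reconstruct a 3D genome model from target distances
#'
#' Minimizes the sum of squared distance errors subject to the configured
#' constraint classes, via a quadratic-penalty scheme over an L-BFGS-B core
#' with analytic gradients. Penalty weights escalate until the maximal
#' constraint violation falls below `config$tol` (or a round cap is hit).
#' `config$n_starts` random initializations are run and the best result is
#' returned (see [select_best()]); per-start results are attached.
#'
#' @param targets a nonempty `distance_map`.
#' @param layout a `genome_layout` (defaults to the targets' layout).
#' @param config a `recon_config`.
#' @return object of class `recon_result`: fields `model`, `objective` (nm^2),
#'   `constraint_violation` (nm), `n_iterations`, `seed_used`, `converged`,
#'   `starts` (list of all per-start results).
#' @export
reconstruct <- function(targets, layout = targets$layout,
                        config = recon_config()) {
  if (!length(targets$i)) stop("targets must be nonempty")
  seeds <- derive_seeds(config$seed, config$n_starts)
  starts <- lapply(seeds, function(s)
    reconstruct_once(targets, layout, config, s))
  best <- select_best(starts)
  best$starts <- starts
  best
}

reconstruct_once <- function(targets, layout, config, seed) {
  bt <- bead_table(layout)
  chrom0 <- bt$chrom - 1L
  ti <- targets$i - 1L
  tj <- targets$j - 1L
  delta <- targets$d
  R <- config$nucleus_radius_nm
  bound <- adjacent_bound_nm(layout, config)
  msep <- config$min_separation_nm
  nuo <- config$nucleolus

  init <- random_init(layout, config, seed)
  x <- as.numeric(t(init$coords))

  lower <- rep(-2 * R, length(x))
  upper <- rep(2 * R, length(x))
  if (!is.null(config$fixed_beads)) {
    fb <- config$fixed_beads
    for (b in names(fb)) {
      k <- as.integer(b)
      pos <- 3L * (k - 1L) + 1:3
      x[pos] <- as.numeric(fb[[b]])
      lower[pos] <- upper[pos] <- x[pos]
    }
  }

  # penalty weight relative to the data term so constraints keep their bite
  w0 <- max(1, length(delta) / max(1, n_beads(layout)))
  total_it <- 0L
  for (round in 1:4) {
    w <- w0 * 10^round
    fn <- function(p) {
      o <- obj_grad_cpp(p, ti, tj, delta, chrom0, R, bound, msep, w, w, w)
      v <- o$value
      if (!is.null(nuo)) v <- v + nucleolus_penalty(p, nuo, w)$value
      v
    }
    gr <- function(p) {
      o <- obj_grad_cpp(p, ti, tj, delta, chrom0, R, bound, msep, w, w, w)
      g <- o$grad
      if (!is.null(nuo)) g <- g + nucleolus_penalty(p, nuo, w)$grad
      g
    }
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = config$max_iter,
                                       factr = 1e7))
    x <- opt$par
    total_it <- total_it + opt$counts[1]
    viol <- max(violations_cpp(x, chrom0, R, bound, msep))
    if (!is.null(nuo)) {
      viol <- max(viol, nucleolus_penalty(x, nuo, 1)$max_violation)
    }
    if (viol <= config$tol) break
  }
  model <- model3d(layout, matrix(x, ncol = 3, byrow = TRUE))
  structure(list(model = model,
                 objective = objective(model, targets),
                 constraint_violation = viol,
                 n_iterations = as.integer(total_it),
                 seed_used = seed,
                 converged = viol <= config$tol),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "recon_result: objective %.3g nm^2, max violation %.2f nm, %d iters%s\n",
    x$objective, x$constraint_violation, x$n_iterations,
    if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Select the best reconstruction among restarts
#'
#' Feasible results (violation within the feasibility tolerance) are preferred
#' over infeasible ones; within each class the smallest objective wins
#' (lexicographic on thresholded violation, then objective).
#'
#' @param results nonempty list of `recon_result`.
#' @param tol feasibility tolerance in nm (default: the largest tolerance
#'   implied by the results' own `converged` flags, i.e. 5).
#' @return the selected `recon_result`.
#' @export
select_best <- function(results, tol = 5) {
  if (!length(results)) stop("no results to select from")
  infeas <- vapply(results, function(r)
    max(0, r$constraint_violation - tol), numeric(1))
  obj <- vapply(results, function(r) r$objective, numeric(1))
  results[[order(infeas, obj)[1]]]
}

#' Objective normalized by the mean objective of random models
#'
#' Random models are reconstructions of coordinate-permuted maps with the same
#' number of interactions. Values below 1 indicate a better-than-random fit.
#'
#' @param result a `recon_result`.
#' @param random_results nonempty list of `recon_result` from permuted maps.
#' @return numeric ratio.
#' @export
normalized_objective <- function(result, random_results) {
  if (!length(random_results)) stop("need at least one random result")
  result$objective /
    mean(vapply(random_results, function(r) r$objective, numeric(1)))
}
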