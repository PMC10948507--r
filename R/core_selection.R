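#' Gower distance matrix for a trait table
#'
#' For all-numeric interval traits Gower's coefficient reduces to the
#' range-normalized Manhattan distance: d(i,k) = mean over traits of
#' |x_ij - x_kj| / range_j, so all entries lie in \[0, 1\]. Traits with zero
#' range carry no information and are dropped with a warning.
#'
#' @param table A [trait_table()] (or a plain numeric matrix).
#' @return Symmetric matrix with zero diagonal, dimnames = genotype ids.
#' @export
gower_matrix <- function(table) {
  x <- if (inherits(table, "trait_table")) trait_values(table)
       else as.matrix(table)
  if (nrow(x) < 2L) stop("need >= 2 genotypes")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    gid <- if (is.null(rownames(x))) as.character(bad[1L]) else rownames(x)[bad[1L]]
    tr <- if (is.null(colnames(x))) as.character(bad[2L]) else colnames(x)[bad[2L]]
    stop(sprintf("non-finite trait value at genotype '%s', trait '%s'",
                 gid, tr))
  }
  rng <- apply(x, 2L, function(v) diff(range(v)))
  if (any(rng == 0)) {
    warning("dropping zero-range trait(s): ",
            paste(colnames(x)[rng == 0], collapse = ", "))
    x <- x[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  if (ncol(x) == 0L) stop("no trait with positive range")
  z <- sweep(x, 2L, rng, "/")
  n <- nrow(z)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(ncol(z))) d <- d + abs(outer(z[, j], z[, j], "-"))
  d / ncol(z)
}

#' Entry-to-nearest-entry and accession-to-nearest-entry objectives
#'
#' E-NE is the mean, over selected core entries, of the distance to the
#' nearest *other* selected entry (maximized to spread the core); A-NE is
#' the mean, over *all* accessions, of the distance to the nearest selected
#' entry (zero for selected accessions; minimized so the core covers the
#' collection). The combined objective is `w_E * E_NE - w_A * A_NE`, with
#' equal weights 0.5/0.5 by default, evaluated on the raw Gower scale.
#'
#' @param dist Square distance matrix.
#' @param subset Integer indices of the selected entries (>= 2 of them).
#' @param weights Numeric `c(w_E, w_A)`, default `c(0.5, 0.5)`.
#' @return List with `E_NE`, `A_NE`, `combined`.
#' @export
core_objectives <- function(dist, subset, weights = c(0.5, 0.5)) {
  subset <- sort(unique(as.integer(subset)))
  n <- nrow(dist)
  if (length(subset) < 2L) stop("E-NE undefined: need >= 2 selected entries")
  if (any(subset < 1L) || any(subset > n)) stop("subset index out of range")
  ds <- dist[, subset, drop = FALSE]
  e_block <- ds[subset, , drop = FALSE]
  diag(e_block) <- Inf
  e_ne <- mean(apply(e_block, 1L, min))
  nearest <- apply(ds, 1L, min)  # 0 for selected rows
  a_ne <- mean(nearest)
  list(E_NE = e_ne, A_NE = a_ne,
       combined = weights[1L] * e_ne - weights[2L] * a_ne)
}

#' Exhaustive optimal core subset
#'
#' Enumerates every k-subset of the collection and returns the one
#' maximizing the combined E-NE/A-NE objective; ties go to the
#' lexicographically smallest index set. A test oracle for the stochastic
#' search; refuses instances with more than `max_subsets` subsets.
#'
#' @param dist Square distance matrix.
#' @param k Core size (>= 2).
#' @param weights Objective weights as in [core_objectives()].
#' @param max_subsets Enumeration budget, default 1e6.
#' @return List with `selected` (sorted indices), `E_NE`, `A_NE`,
#'   `combined`.
#' @export
exhaustive_core <- function(dist, k, weights = c(0.5, 0.5),
                            max_subsets = 1e6) {
  n <- nrow(dist)
  if (k < 2L || k > n) stop("k must be in [2, N]")
  n_sub <- choose(n, k)
  if (n_sub > max_subsets)
    stop(sprintf("combinatorial budget exceeded: C(%d,%d) = %g subsets",
                 n, k, n_sub))
  best <- NULL
  utils::combn(n, k, function(s) {
    obj <- core_objectives(dist, s, weights)
    # strict > keeps the lexicographically first argmax (combn enumerates
    # subsets in lexicographic order)
    if (is.null(best) || obj$combined > best$combined + 1e-15)
      best <<- c(list(selected = as.integer(s)), obj)
    0
  })
  best
}

#' Select a core subset by parallel-tempering search
#'
#' Seeded stochastic search for a core of `round(fraction * N)` entries
#' maximizing the combined E-NE/A-NE objective over a Gower distance
#' matrix. Several replicas run in parallel at a geometric temperature
#' ladder; each move swaps one selected with one unselected genotype and is
#' accepted by the Metropolis rule on the combined objective; adjacent
#' replicas periodically exchange states. The search stops after `patience`
#' consecutive moves without improving the best objective found -- a
#' deterministic surrogate for a wall-clock stopping rule -- and is
#' bit-reproducible given the seed.
#'
#' @param dist Square distance matrix (e.g. from [gower_matrix()]).
#' @param fraction Core fraction of the collection, default 0.20; the core
#'   size is `round(fraction * N)` (round-half-up, so 318 x 0.20 -> 64).
#' @param weights Objective weights as in [core_objectives()].
#' @param seed Integer RNG seed.
#' @param replicas Number of tempering replicas, default 4.
#' @param t_min,t_max Temperature ladder endpoints (geometric spacing).
#' @param patience Moves without improvement before stopping, default 5000.
#' @param exchange_every Moves between adjacent-replica exchange attempts.
#' @return Object of class `core_selection`: list with `selected` (sorted
#'   indices), `genotype_ids` (when `dist` has dimnames), `E_NE`, `A_NE`,
#'   `combined`, `fraction`, `weights`, `seed` and `trace` (improvement
#'   history: move number and best objective).
#' @export
select_core <- function(dist, fraction = 0.20, weights = c(0.5, 0.5),
                        seed = 1L, replicas = 4L, t_min = 1e-4,
                        t_max = 5e-2, patience = 5000L,
                        exchange_every = 50L) {
  n <- nrow(dist)
  k <- as.integer(floor(fraction * n + 0.5))  # round-half-up
  if (k < 2L || k > n)
    stop(sprintf("infeasible core size %d for N = %d (fraction %.3f)",
                 k, n, fraction))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  if (k == n) {
    obj <- core_objectives(dist, seq_len(n), weights)
    return(structure(list(selected = seq_len(n),
                          genotype_ids = rownames(dist),
                          E_NE = obj$E_NE, A_NE = obj$A_NE,
                          combined = obj$combined, fraction = fraction,
                          core_size = k, n = n, weights = weights,
                          seed = seed,
                          trace = data.frame(move = 0L,
                                             combined = obj$combined)),
                     class = "core_selection"))
  }

  temps <- if (replicas == 1L) t_min
           else exp(seq(log(t_min), log(t_max), length.out = replicas))
  state <- lapply(seq_len(replicas), function(r) {
    s <- sort(sample.int(n, k))
    list(sel = s, obj = core_objectives(dist, s, weights)$combined)
  })
  best <- state[[which.max(vapply(state, `[[`, numeric(1), "obj"))]]
  trace <- list(list(move = 0L, combined = best$obj))
  since_improve <- 0L
  move <- 0L

  while (since_improve < patience) {
    move <- move + 1L
    for (r in seq_len(replicas)) {
      st <- state[[r]]
      out_i <- st$sel[sample.int(k, 1L)]
      pool <- setdiff(seq_len(n), st$sel)
      in_i <- pool[sample.int(length(pool), 1L)]
      cand <- sort(c(setdiff(st$sel, out_i), in_i))
      obj <- core_objectives(dist, cand, weights)$combined
      if (obj >= st$obj ||
          stats::runif(1) < exp((obj - st$obj) / temps[r])) {
        state[[r]] <- list(sel = cand, obj = obj)
        if (obj > best$obj + 1e-15) {
          best <- state[[r]]
          trace[[length(trace) + 1L]] <- list(move = move, combined = obj)
          since_improve <- -1L  # reset below (counted once per sweep)
        }
      }
    }
    since_improve <- since_improve + 1L
    if (replicas > 1L && move %% exchange_every == 0L) {
      for (r in seq_len(replicas - 1L)) {
        d_obj <- state[[r + 1L]]$obj - state[[r]]$obj
        d_beta <- 1 / temps[r] - 1 / temps[r + 1L]
        if (stats::runif(1) < exp(min(0, d_beta * d_obj))) {
          tmp <- state[[r]]
          state[[r]] <- state[[r + 1L]]
          state[[r + 1L]] <- tmp
        }
      }
    }
  }
  final <- core_objectives(dist, best$sel, weights)
  structure(list(selected = best$sel,
                 genotype_ids = if (!is.null(rownames(dist)))
                   rownames(dist)[best$sel] else NULL,
                 E_NE = final$E_NE, A_NE = final$A_NE,
                 combined = final$combined, fraction = fraction,
                 core_size = k, n = n, weights = weights, seed = seed,
                 trace = do.call(rbind, lapply(trace, as.data.frame))),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("<core_selection> %d of %d entries (fraction %.2f)\n",
              x$core_size, x$n, x$fraction))
  cat(sprintf("  E-NE = %.4f  A-NE = %.4f  combined = %.4f (seed %d)\n",
              x$E_NE, x$A_NE, x$combined, x$seed))
  invisible(x)
}
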