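#' Connectance
#'
#' Realized proportion of possible plant-bird links: the number of nonzero
#' cells divided by I*J. 1 means every bird was seen at flowers of every
#' plant.
#'
#' @param m an \code{\link{interaction_matrix}} (no empty margins).
#' @return A number in [0, 1].
#' @export
connectance <- function(m) {
  x <- metric_input(m)
  sum(x > 0) / length(x)
}

metric_input <- function(m) {
  x <- unclass_matrix(as_interaction_matrix(m))
  if (sum(x) == 0) stop("empty network")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("matrix has empty margins; call drop_empty_margins() first")
  x
}

#' Weighted NODF nestedness
#'
#' Weighted nestedness of a quantitative matrix, 0 (no nesting) to 100
#' (perfectly nested). Rows and columns are first ordered by decreasing
#' marginal totals (stable, original order breaking ties). For an ordered
#' column pair (u left of v) with strictly larger total in u, the pair
#' scores 100 times the fraction of v's nonzero cells that are strictly
#' smaller than the corresponding cell in u; ties in marginal totals score
#' 0. Row pairs are scored analogously, and WNODF is the mean over all
#' column and row pairs. With a single row (or column), only the pairs of
#' the other level are averaged.
#'
#' @param m an \code{\link{interaction_matrix}} with no empty margins and
#'   at least two species on one level.
#' @return WNODF in [0, 100].
#' @export
wnodf <- function(m) {
  x <- metric_input(m)
  if (nrow(x) < 2L && ncol(x) < 2L)
    stop("WNODF undefined for a 1 x 1 network")
  xs <- x[order(-rowSums(x)), order(-colSums(x)), drop = FALSE]
  scores <- c(if (ncol(xs) >= 2L) wnodf_pair_scores(t(xs)),
              if (nrow(xs) >= 2L) wnodf_pair_scores(xs))
  mean(scores)
}

# pair scores between rows of `x` (already sorted by decreasing totals):
# row u above row v, strict total inequality required.
wnodf_pair_scores <- function(x) {
  n <- nrow(x)
  tot <- rowSums(x)
  out <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (u in seq_len(n - 1L)) {
    xu <- x[u, ]
    for (v in (u + 1L):n) {
      k <- k + 1L
      if (tot[u] > tot[v]) {
        xv <- x[v, ]
        nz <- xv > 0
        out[k] <- 100 * sum(nz & xv < xu) / sum(nz)
      }
    }
  }
  out
}

#' Shannon interaction evenness
#'
#' Evenness of the visit-count distribution over the network's cells,
#' \eqn{-\sum p_{ij} \log p_{ij} / \log(IJ)} with \eqn{p_{ij} = a_{ij}/N}.
#' 1 for a perfectly uniform matrix, approaching 0 as visits concentrate in
#' a single cell. The denominator convention is configurable: \code{"cells"}
#' (\eqn{\log IJ}, the default) or \code{"links"} (\eqn{\log} of the number
#' of nonzero cells).
#'
#' @param m an \code{\link{interaction_matrix}} with N > 0.
#' @param denominator \code{"cells"} or \code{"links"}.
#' @return Evenness in [0, 1].
#' @export
interaction_evenness <- function(m, denominator = c("cells", "links")) {
  denominator <- match.arg(denominator)
  x <- unclass_matrix(as_interaction_matrix(m))
  N <- sum(x)
  if (N == 0) stop("empty network")
  p <- x[x > 0] / N
  H <- -sum(p * log(p))
  den <- if (denominator == "cells") log(length(x)) else log(sum(x > 0))
  if (den == 0) return(if (H == 0) 1 else 0)  # 1x1 network
  H / den
}

#' H2' network-level specialization
#'
#' Standardized two-dimensional Shannon entropy of the interaction
#' frequencies: \eqn{H2' = (H2_{max} - H2) / (H2_{max} - H2_{min})}, where
#' the extremes are the largest and smallest entropies attainable with the
#' observed row and column totals. 0 means the observed matrix is as even
#' as the margins allow (no specialization beyond abundance); 1 means
#' maximal specialization.
#'
#' The maximum is the entropy of the real-valued independence product of
#' the margins (the exact real-valued maximizer, and the fixed point of
#' iterative proportional fitting). The minimum is found by a greedy
#' integer allocation: repeatedly place \code{min(remaining row, remaining
#' column)} visits into the cell whose row and column have the largest
#' remaining totals. The result is clamped to [0, 1].
#'
#' @param m an \code{\link{interaction_matrix}} with at least two species
#'   on each level and N > 0.
#' @return H2' in [0, 1].
#' @export
h2prime <- function(m) {
  x <- metric_input(m)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("H2' undefined with a single species on one level")
  N <- sum(x)
  H2 <- shannon_entropy(x / N)
  H2max <- shannon_entropy(rowSums(x) / N) + shannon_entropy(colSums(x) / N)
  H2min <- shannon_entropy(h2min_allocation(rowSums(x), colSums(x)) / N)
  if (H2max - H2min < 1e-12) {
    warning("degenerate margins: H2max == H2min; returning 0")
    return(0)
  }
  min(max((H2max - H2) / (H2max - H2min), 0), 1)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Minimum-entropy integer allocation with fixed margins (minimum-entropy
# transportation is a concave minimization, so the optimum is a vertex of
# the transportation polytope but greedy construction alone can stall in a
# local vertex). Strategy: several greedy starts, each polished by a 2x2
# cycle descent that jumps to the better extreme of every cycle through two
# occupied cells; keep the lowest-entropy result. Exhaustive enumeration on
# small matrices guards this heuristic in the tests.
h2min_allocation <- function(rt, ct) {
  out <- if (sum(rt) <= 16 && length(rt) <= 5 && length(ct) <= 5) {
    h2min_exact(rt, ct)   # small problems: branch-and-bound, exact
  } else {
    starts <- list(greedy_largest_margins(rt, ct),
                   greedy_largest_block(rt, ct, prefer_exact = TRUE),
                   greedy_largest_block(rt, ct, prefer_exact = FALSE))
    polished <- lapply(starts, cycle_descent)
    ents <- vapply(polished, function(x) shannon_entropy(x / sum(x)),
                   numeric(1L))
    polished[[which.min(ents)]]
  }
  stopifnot(all(rowSums(out) == rt), all(colSums(out) == ct))
  out
}

# exact minimum-entropy allocation: depth-first search over row
# compositions, maximizing sum(v log v), pruned by the optimistic bound of
# fully concentrating every remaining row (and, symmetrically, column)
h2min_exact <- function(rt, ct) {
  I <- length(rt); J <- length(ct)
  ord <- order(rt, decreasing = TRUE)   # big rows first prune harder
  rts <- rt[ord]
  plogp_sum <- function(v) {
    v <- v[v > 0]
    sum(v * log(v))
  }
  best_val <- -Inf
  best_mat <- NULL
  mat <- matrix(0, I, J)
  dfs <- function(row, ctrem, acc) {
    if (row > I) {
      if (acc > best_val) {
        best_val <<- acc
        best_mat <<- mat
      }
      return(invisible())
    }
    bound <- min(plogp_sum(rts[row:I]), plogp_sum(ctrem))
    if (acc + bound <= best_val + 1e-12) return(invisible())
    comp <- function(j, left, vec) {
      if (j == J) {
        if (left <= ctrem[J]) {
          v <- c(vec, left)
          mat[row, ] <<- v
          dfs(row + 1L, ctrem - v, acc + plogp_sum(v))
          mat[row, ] <<- 0
        }
        return(invisible())
      }
      for (val in min(left, ctrem[j]):0) comp(j + 1L, left - val,
                                              c(vec, val))
    }
    comp(1L, rts[row], numeric(0))
    invisible()
  }
  dfs(1L, ct, 0)
  out <- matrix(0, I, J)
  out[ord, ] <- best_mat
  out
}

# place min(remaining row, remaining column) at the largest remaining
# row x largest remaining column
greedy_largest_margins <- function(rt, ct) {
  out <- matrix(0, length(rt), length(ct))
  while (sum(rt) > 0) {
    i <- which.max(rt)
    j <- which.max(ct)
    put <- min(rt[i], ct[j])
    out[i, j] <- out[i, j] + put
    rt[i] <- rt[i] - put
    ct[j] <- ct[j] - put
  }
  out
}

# place the largest feasible single block each step; prefer_exact breaks
# ties toward cells whose row and column remainders match exactly
greedy_largest_block <- function(rt, ct, prefer_exact = TRUE) {
  out <- matrix(0, length(rt), length(ct))
  while (sum(rt) > 0) {
    blk <- outer(rt, ct, pmin)
    best <- max(blk)
    cand <- which(blk == best, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      waste <- abs(rt[cand[, 1L]] - ct[cand[, 2L]])
      pick <- if (prefer_exact) which.min(waste) else which.max(waste)
      cand <- cand[pick, , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    out[i, j] <- out[i, j] + best
    rt[i] <- rt[i] - best
    ct[j] <- ct[j] - best
  }
  out
}

# steepest 2x2 cycle descent: entropy is concave along any cycle
# direction, so on each cycle through two occupied cells the minimum sits
# at one of the two extreme steps; repeatedly apply the best improving
# extreme move (vectorized over all occupied-cell pairs) until none helps
cycle_descent <- function(out) {
  pl <- function(x) ifelse(x > 0, x * log(x), 0)
  repeat {
    nz <- which(out > 0, arr.ind = TRUE)  # a vertex has few occupied cells
    k <- nrow(nz)
    if (k < 2L) break
    idx <- expand.grid(p = seq_len(k), q = seq_len(k))
    a <- nz[idx$p, 1L]; v <- nz[idx$p, 2L]
    b <- nz[idx$q, 1L]; u <- nz[idx$q, 2L]
    keep <- a != b & u != v
    if (!any(keep)) break
    a <- a[keep]; v <- v[keep]; b <- b[keep]; u <- u[keep]
    au <- out[cbind(a, u)]; av <- out[cbind(a, v)]
    bu <- out[cbind(b, u)]; bv <- out[cbind(b, v)]
    cur <- pl(au) + pl(av) + pl(bu) + pl(bv)
    # cycle direction: (a,u)+t (a,v)-t (b,u)-t (b,v)+t, extreme both ways
    t1 <- pmin(av, bu)
    alt1 <- pl(au + t1) + pl(av - t1) + pl(bu - t1) + pl(bv + t1)
    t2 <- -pmin(au, bv)
    alt2 <- pl(au + t2) + pl(av - t2) + pl(bu - t2) + pl(bv + t2)
    gain <- pmax(alt1, alt2) - cur   # larger sum(v log v) = lower entropy
    i <- which.max(gain)
    if (gain[i] <= 1e-12) break
    t <- if (alt1[i] >= alt2[i]) t1[i] else t2[i]
    out[cbind(c(a[i], a[i], b[i], b[i]), c(u[i], v[i], u[i], v[i]))] <-
      c(au[i] + t, av[i] - t, bu[i] - t, bv[i] + t)
  }
  out
}

#' Dependence asymmetry per network level
#'
#' The dependence of plant i on bird j is \eqn{a_{ij}} over plant i's row
#' total; the dependence of bird j on plant i is \eqn{a_{ij}} over bird j's
#' column total. For each bird, asymmetry is the mean over its realized
#' links of (own dependence - partner dependence) / (larger of the two);
#' for each plant the sign is flipped. The level value is the unweighted
#' mean across that level's species; values run from -1 to 1, larger
#' magnitudes meaning more skewed mutual dependences. Transposing the
#' matrix swaps and negates the two values.
#'
#' @param m an \code{\link{interaction_matrix}} with no empty margins.
#' @return Named numeric vector \code{c(plants = , birds = )}.
#' @export
level_asymmetry <- function(m) {
  x <- metric_input(m)
  dP <- x / rowSums(x)               # plant's dependence on each bird
  dB <- sweep(x, 2L, colSums(x), "/")  # bird's dependence on each plant
  hi <- pmax(dP, dB)
  rel <- ifelse(x > 0, (dB - dP) / hi, NA)  # + favours the bird
  birds <- colMeans(rel, na.rm = TRUE)
  plants <- rowMeans(-rel, na.rm = TRUE)
  c(plants = mean(plants), birds = mean(birds))
}

#' All network-description metrics at once
#'
#' @param m an \code{\link{interaction_matrix}} with no empty margins.
#' @param evenness_denominator passed to
#'   \code{\link{interaction_evenness}}.
#' @return A \code{metric_set}: named list with \code{connectance},
#'   \code{wnodf}, \code{interaction_evenness}, \code{h2prime},
#'   \code{asymmetry_plants} and \code{asymmetry_birds}.
#' @export
network_metrics <- function(m, evenness_denominator = "cells") {
  m <- as_interaction_matrix(m)
  asym <- level_asymmetry(m)
  structure(list(connectance = connectance(m),
                 wnodf = wnodf(m),
                 interaction_evenness =
                   interaction_evenness(m, evenness_denominator),
                 h2prime = h2prime(m),
                 asymmetry_plants = unname(asym["plants"]),
                 asymmetry_birds = unname(asym["birds"])),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  cat("network metrics:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, format(round(x[[nm]], digits))))
  invisible(x)
}

#' Chao2 sampling completeness of the interaction inventory
#'
#' Bias-corrected incidence-based Chao2 richness estimate of the number of
#' distinct interactions, \eqn{S_{est} = S_{obs} + \frac{m-1}{m}
#' \frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}}, where \eqn{Q_1}/\eqn{Q_2} are the
#' numbers of interactions detected in exactly one / two sampling units,
#' and completeness is \eqn{100 S_{obs} / S_{est}} percent.
#'
#' @param inc an \code{\link{incidence_table}} with at least two sampling
#'   units.
#' @return List with \code{S_obs}, \code{Q1}, \code{Q2}, \code{S_est} and
#'   \code{completeness_pct}.
#' @export
chao2_completeness <- function(inc) {
  if (!inherits(inc, "incidence_table")) inc <- incidence_table(inc)
  if (inc$m < 2L) stop("Chao2 requires at least 2 sampling units")
  freq <- rowSums(inc$detections)
  S_obs <- length(freq)
  Q1 <- sum(freq == 1)
  Q2 <- sum(freq == 2)
  S_est <- S_obs + ((inc$m - 1) / inc$m) * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  list(S_obs = S_obs, Q1 = Q1, Q2 = Q2, S_est = S_est,
       completeness_pct = 100 * S_obs / S_est)
}

#' Sorenson dissimilarity between two species lists
#'
#' \eqn{1 - 2|A \cap B| / (|A| + |B|)}: 0 for identical composition, 1 for
#' completely distinct communities.
#'
#' @param a,b character vectors of species names (nonempty; duplicates
#'   ignored).
#' @return Dissimilarity in [0, 1].
#' @export
sorenson_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("species lists must be nonempty")
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}
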