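# Independent brute-force oracles, coded as literal re-enumerations of the
# published definitions, deliberately separate from the package internals.

# weighted-NODF oracle: sort by decreasing marginal totals (stable), score
# every ordered pair of columns and of rows, strict total inequality
# required, average everything.
oracle_wnodf <- function(x) {
  x <- unclass(as.matrix(x))
  x <- x[order(rowSums(x), decreasing = TRUE), , drop = FALSE]
  x <- x[, order(colSums(x), decreasing = TRUE), drop = FALSE]
  scores <- c()
  J <- ncol(x); I <- nrow(x)
  if (J >= 2) for (u in 1:(J - 1)) for (v in (u + 1):J) {
    if (sum(x[, u]) > sum(x[, v])) {
      filled <- which(x[, v] > 0)
      scores <- c(scores, 100 * mean(x[filled, v] < x[filled, u]))
    } else scores <- c(scores, 0)
  }
  if (I >= 2) for (u in 1:(I - 1)) for (v in (u + 1):I) {
    if (sum(x[u, ]) > sum(x[v, ])) {
      filled <- which(x[v, ] > 0)
      scores <- c(scores, 100 * mean(x[v, filled] < x[u, filled]))
    } else scores <- c(scores, 0)
  }
  mean(scores)
}

# enumerate every nonnegative integer matrix with the given margins
enum_fixed_margins <- function(rt, ct) {
  I <- length(rt); J <- length(ct)
  out <- list()
  rec <- function(row, ctrem, acc) {
    if (row > I) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    comp <- function(j, left, cur) {
      if (j == J) {
        if (left <= ctrem[J]) {
          r <- c(cur, left)
          rec(row + 1L, ctrem - r, rbind(acc, r))
        }
        return(invisible())
      }
      for (v in 0:min(left, ctrem[j])) comp(j + 1L, left - v, c(cur, v))
    }
    comp(1L, rt[row], numeric(0))
  }
  rec(1L, ct, NULL)
  out
}

oracle_entropy <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# enumerate all 2x2 outcomes of a multinomial(N, p) and their probability
# computed with plain factorials
oracle_multinom_outcomes <- function(N, p) {
  stopifnot(length(p) == 4)
  out <- list()
  for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
    d <- N - a - b - cc
    cnt <- c(a, b, cc, d)
    pr <- factorial(N) / prod(factorial(cnt)) * prod(p^cnt)
    out[[length(out) + 1L]] <- list(counts = cnt, prob = pr)
  }
  out
}

# random interaction matrix without empty margins
random_network <- function(I, J, N) {
  repeat {
    x <- matrix(tabulate(sample.int(I * J, N, replace = TRUE), I * J), I, J)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0))
      return(interaction_matrix(x))
  }
}

# plain matrix with only dim/dimnames attributes, for identical() checks
bare <- function(m) {
  a <- as.matrix(m)
  attributes(a) <- attributes(a)[c("dim", "dimnames")]
  a
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "pollinet")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", name)
  p
}

# small deterministic community used across probability-model tests
tiny_community <- function() {
  pp <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1))
  bp <- rbind(c(1, 1, 1, 0), c(0, 1, 1, 1))
  pa <- pp * c(10, 40, 5)
  ba <- bp * c(2, 1)
  dimnames(pp) <- list(paste0("plant_", 1:3), paste0("month_", 1:4))
  dimnames(bp) <- list(paste0("bird_", 1:2), paste0("month_", 1:4))
  dimnames(pa) <- dimnames(pp); dimnames(ba) <- dimnames(bp)
  community_tables(pp, bp, pa, ba)
}

tiny_traits <- function() {
  trait_table(
    birds = data.frame(species = c("bird_1", "bird_2"),
                       bill_lo = c(15, 7.5), bill_hi = c(18.75, 9),
                       tongue_fraction = 1 / 3,
                       legitimacy = c("legitimate", "robber")),
    plants = data.frame(species = paste0("plant_", 1:3),
                        corolla_lo = c(18, 30, 5),
                        corolla_hi = c(25, 40, 9),
                        corolla_width = c(5, 6, 3),
                        wide_flower = c(FALSE, FALSE, FALSE)))
}
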