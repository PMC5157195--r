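test_that("connectance counts realized links", {
  expect_equal(connectance(interaction_matrix(rbind(c(1, 0), c(0, 2)))), 0.5)
  expect_equal(connectance(interaction_matrix(matrix(2, 3, 4))), 1)
  expect_error(connectance(rbind(c(1, 0), c(1, 0))), "empty margins")
})

test_that("wnodf matches its published examples and the enumeration oracle", {
  expect_equal(wnodf(interaction_matrix(rbind(c(3, 2, 1), c(2, 1, 0),
                                              c(1, 0, 0)))), 100)
  expect_equal(wnodf(interaction_matrix(diag(2))), 0)  # tied totals
  set.seed(42)
  for (i in 1:60) {
    m <- random_network(sample(2:4, 1), sample(2:4, 1), sample(4:12, 1))
    expect_equal(wnodf(m), oracle_wnodf(m))
  }
})

test_that("interaction evenness follows the Shannon definition", {
  expect_equal(interaction_evenness(interaction_matrix(matrix(3, 2, 3))), 1)
  one <- matrix(0, 2, 2); one[1, 1] <- 5
  expect_equal(interaction_evenness(interaction_matrix(one)), 0)
  expect_equal(interaction_evenness(interaction_matrix(rbind(c(2, 1),
                                                             c(1, 0)))),
               1.0397208 / log(4), tolerance = 1e-6)
  # links denominator: only realized cells enter the maximum
  m <- interaction_matrix(rbind(c(2, 2), c(2, 0)))
  expect_equal(interaction_evenness(m, "links"), 1)
})

test_that("h2prime hits its boundary identities", {
  expect_equal(h2prime(interaction_matrix(diag(3) * 4)), 1)
  expect_equal(h2prime(interaction_matrix(matrix(1, 2, 2))), 0)
  expect_error(h2prime(interaction_matrix(matrix(1:3, 3, 1))), "single")
})

test_that("h2prime extrema bracket the exhaustive fixed-margin enumeration", {
  check_margins <- function(rt, ct) {
    ents <- vapply(enum_fixed_margins(rt, ct), oracle_entropy, numeric(1))
    hmin <- oracle_entropy(pollinet:::h2min_allocation(rt, ct))
    hmax <- oracle_entropy(rt / sum(rt)) + oracle_entropy(ct / sum(ct))
    expect_lte(hmin, min(ents) + 1e-9)
    expect_gte(hmax, max(ents) - 1e-9)
  }
  check_margins(c(4, 3, 2), c(4, 3, 2))
  set.seed(99)
  for (i in 1:12) {
    m <- random_network(sample(2:4, 1), sample(2:4, 1), sample(4:10, 1))
    check_margins(rowSums(m), colSums(m))
  }
})

test_that("level asymmetry matches hand cases and the transpose identity", {
  expect_equal(unname(level_asymmetry(interaction_matrix(matrix(1)))),
               c(0, 0))
  a <- level_asymmetry(interaction_matrix(matrix(c(1, 1), 1, 2)))
  expect_equal(unname(a), c(-0.5, 0.5))
  set.seed(5)
  for (i in 1:20) {
    m <- random_network(sample(2:5, 1), sample(2:5, 1), sample(6:25, 1))
    # transposing exchanges the two roles: each level's per-link term
    # changes sign and the levels swap, so the pair of values swaps
    fwd <- level_asymmetry(m)
    rev <- level_asymmetry(interaction_matrix(t(as.matrix(m))))
    expect_equal(unname(fwd[c("plants", "birds")]),
                 unname(rev[c("birds", "plants")]))
  }
})

test_that("all metrics stay inside their stated bounds and are invariant to
           label permutation and (where stated) transposition", {
  set.seed(2024)
  for (i in 1:400) {
    m <- random_network(sample(2:6, 1), sample(2:6, 1), sample(6:40, 1))
    ms <- network_metrics(m)
    expect_gte(ms$connectance, 0); expect_lte(ms$connectance, 1)
    expect_gte(ms$wnodf, 0); expect_lte(ms$wnodf, 100)
    expect_gte(ms$interaction_evenness, 0)
    expect_lte(ms$interaction_evenness, 1)
    expect_gte(ms$h2prime, 0); expect_lte(ms$h2prime, 1)
    expect_gte(ms$asymmetry_plants, -1); expect_lte(ms$asymmetry_plants, 1)
    expect_gte(ms$asymmetry_birds, -1); expect_lte(ms$asymmetry_birds, 1)
    if (i <= 40) {
      x <- as.matrix(m)
      perm <- interaction_matrix(
        x[sample(nrow(x)), sample(ncol(x)), drop = FALSE])
      expect_equal(unlist(network_metrics(perm)), unlist(ms))
      tr <- interaction_matrix(t(x))
      expect_equal(connectance(tr), ms$connectance)
      expect_equal(wnodf(tr), ms$wnodf)
      expect_equal(interaction_evenness(tr), ms$interaction_evenness)
    }
  }
})

test_that("chao2 completeness follows the bias-corrected estimator", {
  # all interactions seen twice or more: inventory judged complete
  inc <- incidence_table(matrix(1, 4, 3))
  got <- chao2_completeness(inc)
  expect_equal(got$S_est, 4)
  expect_equal(got$completeness_pct, 100)

  # hand-computed: S_obs=10, Q1=4, Q2=1, m=50
  det <- matrix(0, 10, 50)
  det[1:4, 1] <- 1                 # four uniques
  det[5, 1:2] <- 1                 # one duplicate
  for (i in 6:10) det[i, 1:3] <- 1
  got <- chao2_completeness(incidence_table(det))
  expect_equal(got$Q1, 4); expect_equal(got$Q2, 1)
  expect_equal(got$S_est, 10 + (49 / 50) * 12 / 4)
  expect_equal(got$completeness_pct, 100 * 10 / 12.94, tolerance = 1e-3)

  expect_error(chao2_completeness(incidence_table(cbind(c(1, 1)))),
               "at least 2")
})

test_that("chao2 behaves sanely when half the interaction pool is seen", {
  set.seed(31)
  vals <- replicate(100, {
    pool <- 40
    seen <- sample.int(pool, 20)
    det <- matrix(rbinom(20 * 30, 1, 0.12), 20, 30)
    det <- det[rowSums(det) > 0, , drop = FALSE]
    chao2_completeness(incidence_table(det))$completeness_pct
  })
  expect_true(all(vals >= 30 & vals <= 100))
})

test_that("sorenson dissimilarity", {
  expect_equal(sorenson_dissimilarity(c("a", "b"), c("a", "b")), 0)
  expect_equal(sorenson_dissimilarity(c("a", "b"), c("c", "d")), 1)
  expect_equal(sorenson_dissimilarity(c("a", "b", "c", "d"),
                                      c("a", "b", "c", "e")), 0.25)
  expect_error(sorenson_dissimilarity(character(), "a"), "nonempty")
})
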