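test_that("phenology matrix is the normalized temporal-overlap product", {
  pp <- rbind(c(1, 1, 0), c(0, 1, 1))
  bp <- rbind(c(1, 0, 0), c(1, 1, 1))
  ct <- community_tables(pp, bp)
  pm <- build_phen(ct)
  expect_equal(unname(bare(pm)),
               rbind(c(0.2, 0.4), c(0, 0.4)))
  expect_identical(provenance_label(pm), "Phen")

  # everyone present every month: uniform, equals the null matrix
  ct2 <- community_tables(matrix(1, 3, 4), matrix(1, 2, 4))
  expect_equal(bare(build_phen(ct2)),
               bare(null_matrix(3, 2)),
               ignore_attr = TRUE)

  # no co-occurrence at all
  ct3 <- community_tables(rbind(c(1, 0)), rbind(c(0, 1)))
  expect_error(build_phen(ct3), "co-occurrence")
})

test_that("abundance matrix aligns months and is scale invariant", {
  ct <- community_tables(rbind(1, 1), rbind(1, 1),
                         rbind(10, 30), rbind(1, 1))
  pm <- build_ab(ct)
  expect_equal(unname(bare(pm)),
               rbind(c(0.125, 0.125), c(0.375, 0.375)))

  ct2 <- community_tables(rbind(1, 1), rbind(1, 1),
                          rbind(10, 30) * 7, rbind(1, 1) * 3)
  expect_equal(bare(build_ab(ct2)),
               bare(pm), ignore_attr = TRUE)

  # monthly alignment matters: species never present together contribute 0
  ct3 <- tiny_community()
  pm3 <- build_ab(ct3)
  expect_equal(sum(pm3), 1)
  # plant_1 is present months 1-2, bird_2 months 2-4: only month 2 counts
  agg <- build_ab(ct3, monthly = FALSE)
  expect_false(isTRUE(all.equal(bare(pm3),
                                bare(agg))))

  ctz <- community_tables(rbind(1, 1), rbind(1),
                          rbind(1, 1), rbind(0))
  expect_error(build_ab(ctz), "zero")
})

test_that("phen and ab matrices are invariant to month permutation", {
  ct <- tiny_community()
  perm <- sample(ncol(ct$plant_phenology))
  ct2 <- community_tables(ct$plant_phenology[, perm],
                          ct$bird_phenology[, perm],
                          ct$plant_abundance[, perm],
                          ct$bird_abundance[, perm])
  expect_equal(bare(build_phen(ct2)),
               bare(build_phen(ct)), ignore_attr = TRUE)
  expect_equal(bare(build_ab(ct2)),
               bare(build_ab(ct)), ignore_attr = TRUE)
})

test_that("morphology matrix implements the range-overlap rules", {
  # the second plant always scores 1, so the ratio of normalized cells
  # recovers the first plant's raw (pre-normalization) score
  raw <- function(bill, flower, wide = FALSE, tf = 0) {
    tt <- trait_table(
      birds = data.frame(species = "b", bill_lo = bill[1],
                         bill_hi = bill[2], tongue_fraction = tf),
      plants = data.frame(species = c("p", "q"),
                          corolla_lo = c(flower[1], 1),
                          corolla_hi = c(flower[2], 2),
                          wide_flower = c(wide, FALSE)))
    m <- bare(build_mor(tt))
    m["p", "b"] / m["q", "b"]   # q scores 1, so this is p's raw score
  }
  expect_equal(raw(c(20, 25), c(18, 30)), 1)        # reaches past f_lo
  expect_equal(raw(c(10, 20), c(15, 30)), 0.5)      # proportional overlap
  expect_equal(raw(c(10, 12), c(15, 30)), 0)        # forbidden
  expect_equal(raw(c(10, 12), c(15, 30), wide = TRUE), 1)  # wide flower
  # tongue correction scales the bill range by 1 + fraction
  expect_equal(raw(c(12, 15), c(16, 30), tf = 1 / 3), 1)

  # forbidden-but-observed cell gets the 1e-8 epsilon
  tt <- trait_table(
    birds = data.frame(species = c("b1", "b2"), bill_lo = c(10, 20),
                       bill_hi = c(12, 25), tongue_fraction = 0),
    plants = data.frame(species = c("p1", "p2"),
                        corolla_lo = c(15, 8), corolla_hi = c(30, 12)))
  obs <- interaction_matrix(rbind(c(3, 1), c(2, 2)),
                            plants = c("p1", "p2"), birds = c("b1", "b2"))
  expect_warning(pm <- build_mor(tt, observed = obs), "epsilon")
  eps <- attr(pm, "epsilon_cells")
  expect_identical(nrow(eps), 1L)
  x <- bare(pm)
  expect_gt(x["p1", "b1"], 0)
  expect_lt(x["p1", "b1"], 1e-7)
  expect_equal(sum(x), 1)

  # missing trait for a network species is an error naming it
  obs2 <- interaction_matrix(rbind(c(1, 1), c(1, 1)),
                             plants = c("p1", "pX"), birds = c("b1", "b2"))
  expect_error(build_mor(tt, observed = obs2), "pX")
})

test_that("raising the bill upper limit never lowers a cell's raw score", {
  f_lo <- 15; f_hi <- 30
  score <- function(b_hi) {
    b_lo <- 10
    if (b_lo >= f_lo) 1
    else if (b_hi < f_lo) 0
    else (b_hi - f_lo) / (b_hi - b_lo)
  }
  his <- seq(11, 40, by = 0.5)
  vals <- vapply(his, score, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  # and the package agrees with the reference rule at a few points
  for (b_hi in c(12, 16, 20, 35)) {
    tt <- trait_table(
      birds = data.frame(species = "b", bill_lo = 10, bill_hi = b_hi,
                         tongue_fraction = 0),
      plants = data.frame(species = c("p", "q"), corolla_lo = c(f_lo, 1),
                          corolla_hi = c(f_hi, 2)))
    m <- bare(build_mor(tt))
    expect_equal(m["p", "b"] / m["q", "b"], score(b_hi))
  }
})

test_that("null matrix is uniform and combining with it changes nothing", {
  nm <- null_matrix(27, 17)
  expect_equal(unique(as.vector(bare(nm))), 1 / 459)
  expect_equal(sum(null_matrix(5, 3)), 1)
  expect_equal(unname(bare(null_matrix(1, 1))),
               matrix(1, 1, 1))

  ct <- tiny_community()
  phen <- build_phen(ct)
  nm2 <- null_matrix(3, 2, like = phen)
  comb <- combine_probs(phen, nm2)
  expect_equal(bare(comb), bare(phen),
               ignore_attr = TRUE)
  expect_identical(provenance_label(comb), "Phen")
})

test_that("combine is order invariant, normalized, and unions provenance", {
  ct <- tiny_community()
  phen <- build_phen(ct)
  ab <- build_ab(ct)
  tt <- trait_table(
    birds = data.frame(species = paste0("bird_", 1:2),
                       bill_lo = c(15, 8), bill_hi = c(20, 12)),
    plants = data.frame(species = paste0("plant_", 1:3),
                        corolla_lo = c(10, 14, 6),
                        corolla_hi = c(16, 22, 10)))
  mor <- build_mor(tt)
  abc <- combine_probs(phen, ab, mor)
  bca <- combine_probs(mor, phen, ab)
  expect_equal(bare(abc), bare(bca),
               ignore_attr = TRUE)
  expect_equal(sum(abc), 1)
  expect_setequal(attr(abc, "provenance"), c("Phen", "Ab", "Mor"))
  expect_error(combine_probs(phen), "at least two")
})

test_that("epsilon repair fixes any zero cell under a positive count", {
  pm <- probability_matrix(rbind(c(0.5, 0.5), c(0, 0)), "Phen",
                           normalize = TRUE)
  obs <- interaction_matrix(rbind(c(1, 1), c(2, 0)))
  expect_error(multinomial_loglik(obs, pm), "repair_epsilon")
  expect_warning(fixed <- repair_epsilon(pm, obs), "1 forbidden")
  expect_equal(sum(fixed), 1)
  expect_silent(ll <- multinomial_loglik(obs, fixed))
  expect_true(is.finite(ll))
})
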