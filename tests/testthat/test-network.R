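# Community-level network metrics: construction, Rao redundancy,
# UPGMA complementarity and mean-degree generalization.

toy_visits <- function() {
  data.frame(site = "s1", year = "2013", round = 1,
             plant = c("pA", "pA", "pB", "pB"),
             pollinator = c("b1", "b1", "b1", "b2"),
             count = c(3, 2, 1, 4), stringsAsFactors = FALSE)
}

test_that("network construction aggregates duplicates and drops empties", {
  net <- build_network(toy_visits(), "s1", "2013", 1)
  expect_equal(net$weights["pA", "b1"], 5)   # duplicated rows summed
  expect_equal(net$weights["pB", "b2"], 4)
  expect_equal(net$weights["pA", "b2"], 0)
  expect_equal(dim(net$weights), c(2, 2))
  # single record -> 1x1 matrix
  one <- build_network(data.frame(site = "s", year = "y", round = 1,
                                  plant = "pA", pollinator = "b1", count = 3),
                       "s", "y", 1)
  expect_equal(unname(one$weights[1, 1]), 3)
  expect_message(expect_null(build_network(toy_visits(), "nope", "2013", 1)),
                 "no records")
})

test_that("network matrix equals an independent group-by-sum tabulation", {
  set.seed(41)
  v <- data.frame(site = "s", year = "y",
                  round = sample(1:2, 60, TRUE),
                  plant = sample(sprintf("p%d", 1:5), 60, TRUE),
                  pollinator = sample(sprintf("b%d", 1:6), 60, TRUE),
                  count = sample(1:4, 60, TRUE))
  net <- build_network(v, "s", "y")
  agg <- aggregate(count ~ plant + pollinator, v, sum)
  for (i in seq_len(nrow(agg)))
    expect_equal(net$weights[agg$plant[i], agg$pollinator[i]], agg$count[i])
  expect_equal(sum(net$weights), sum(v$count))
})

test_that("Rao quadratic entropy formula and its Simpson identity", {
  # d = 1 off-diagonal collapses Q to Gini-Simpson
  p <- c(0.5, 0.3, 0.2)
  d1 <- 1 - diag(3)
  expect_equal(rao_quadratic_entropy(p, d1), 1 - sum(p^2))
  expect_equal(rao_quadratic_entropy(p, matrix(0, 3, 3)), 0)
  d <- matrix(c(0, 0.4, 0.4, 0), 2)
  expect_equal(rao_quadratic_entropy(c(0.5, 0.5), d), 0.2)
  expect_error(rao_quadratic_entropy(c(0.5, 0.5), d * 4), "\\[0, 1\\]")
})

test_that("redundancy: identical profiles share everything, disjoint share nothing", {
  # two pollinators, identical profiles and equal totals
  same <- as_net(matrix(c(2, 1, 2, 1), 2,
                        dimnames = list(c("pA", "pB"), c("b1", "b2"))))
  fr <- functional_redundancy(same, "pollinator")
  expect_equal(fr$rao_Q, 0)
  expect_equal(fr$simpson_D, 0.5)
  expect_equal(fr$redundancy, 0.5)
  # disjoint binary partner sets: fully complementary, no redundancy
  disj <- as_net(diag(c(1, 1, 1)) |>
                   `dimnames<-`(list(c("pA", "pB", "pC"), c("b1", "b2", "b3"))))
  fr2 <- functional_redundancy(disj, "pollinator")
  expect_equal(fr2$redundancy, 0)
  expect_equal(fr2$rao_Q, fr2$simpson_D)
  # single species level: all zero by convention
  solo <- as_net(matrix(c(2, 3), 2, 1,
                        dimnames = list(c("pA", "pB"), "b1")))
  expect_equal(functional_redundancy(solo, "pollinator"),
               list(redundancy = 0, simpson_D = 0, rao_Q = 0))
})

test_that("redundancy identity R = D - Q holds with R in [0, D] on random networks", {
  set.seed(101)
  for (i in 1:300) {
    w <- random_net(sample(2:7, 1), sample(2:7, 1))
    for (lev in c("plant", "pollinator")) {
      fr <- functional_redundancy(as_net(w), lev)
      expect_equal(fr$redundancy, fr$simpson_D - fr$rao_Q, tolerance = 1e-12)
      expect_gte(fr$redundancy, -1e-10)
      expect_lte(fr$redundancy, fr$simpson_D + 1e-10)
    }
  }
})

test_that("complementarity: two-species closed form and identical profiles", {
  two <- as_net(matrix(c(1, 0, 0, 1), 2,
                       dimnames = list(c("pA", "pB"), c("b1", "b2"))))
  # profiles (1,0), (0,1): distance sqrt(2), two branches of full height
  expect_equal(functional_complementarity(two, "pollinator"), 2 * sqrt(2))
  same <- as_net(matrix(c(2, 1, 2, 1), 2,
                        dimnames = list(c("pA", "pB"), c("b1", "b2"))))
  expect_equal(functional_complementarity(same, "pollinator"), 0)
  solo <- as_net(matrix(1, 1, 1, dimnames = list("pA", "b1")))
  expect_equal(functional_complementarity(solo, "plant"), 0)
})

test_that("complementarity equals the exhaustive UPGMA oracle", {
  set.seed(55)
  for (i in 1:60) {
    w <- random_net(sample(2:6, 1), sample(2:6, 1))
    net <- as_net(w)
    expect_equal(functional_complementarity(net, "pollinator"),
                 oracle_upgma_branch_length(t(w)), tolerance = 1e-9)
    expect_equal(functional_complementarity(net, "plant"),
                 oracle_upgma_branch_length(w), tolerance = 1e-9)
  }
})

test_that("complementarity is invariant to species order", {
  set.seed(66)
  w <- random_net(5, 6)
  net <- as_net(w)
  perm <- as_net(w[sample(5), sample(6)])
  for (lev in c("plant", "pollinator"))
    expect_equal(functional_complementarity(perm, lev),
                 functional_complementarity(net, lev), tolerance = 1e-10)
})

test_that("generalization counts distinct partners and conserves links", {
  full <- as_net(matrix(1, 3, 4, dimnames = list(paste0("p", 1:3),
                                                 paste0("b", 1:4))))
  expect_equal(generalization(full, "plant"), 4)
  expect_equal(generalization(full, "pollinator"), 3)
  onetoone <- as_net(diag(4) |>
                       `dimnames<-`(list(paste0("p", 1:4), paste0("b", 1:4))))
  expect_equal(generalization(onetoone, "plant"), 1)
  expect_equal(generalization(onetoone, "pollinator"), 1)
  set.seed(77)
  for (i in 1:50) {
    w <- random_net(sample(2:6, 1), sample(2:6, 1))
    net <- as_net(w)
    links <- sum(w > 0)
    # conservation: mean degree x level richness = realized links, both sides
    expect_equal(generalization(net, "plant") * nrow(w), links)
    expect_equal(generalization(net, "pollinator") * ncol(w), links)
    # doubling weights leaves degree untouched
    expect_equal(generalization(as_net(w * 2), "plant"),
                 generalization(net, "plant"))
  }
})

test_that("metrics_table has one row per network x level x metric", {
  d <- gen_dataset(small_params(seed = 31))
  mt <- metrics_table(d$visits)
  nets <- unique(d$visits[, c("site", "year", "round")])
  expect_lte(nrow(mt), nrow(nets) * 2 * 4)
  expect_setequal(unique(mt$metric),
                  c("redundancy", "complementarity", "generalization",
                    "richness"))
  # spot-check one network against direct recomputation
  k <- nets[1, ]
  net <- build_network(d$visits, k$site, k$year, k$round)
  sub <- mt[mt$site == k$site & mt$year == k$year & mt$round == k$round &
              mt$level == "pollinator", ]
  expect_equal(sub$value[sub$metric == "generalization"],
               generalization(net, "pollinator"))
  expect_equal(sub$value[sub$metric == "redundancy"],
               functional_redundancy(net, "pollinator")$redundancy)
})
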