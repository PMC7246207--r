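# Species-level role metrics, the niche PCA, and the flexibility measures.

star_net <- function(n_leaves = 5) {
  # hub pollinator shares a plant with every leaf; leaves share nothing
  # plants: one per leaf, hub visits all of them
  np <- n_leaves
  w <- matrix(0, np, n_leaves + 1,
              dimnames = list(sprintf("p%d", 1:np),
                              c("hub", sprintf("leaf%d", 1:n_leaves))))
  w[, "hub"] <- 1
  for (i in 1:n_leaves) w[i, i + 1] <- 1
  as_net(w)
}

test_that("betweenness: star closed form and brute-force oracle", {
  st <- star_net(5)
  bt <- pollinator_betweenness(st)
  expect_equal(unname(bt["hub"]), 1)       # all leaf pairs route through hub
  expect_equal(unname(bt["leaf1"]), 0)
  set.seed(91)
  for (i in 1:40) {
    w <- random_net(sample(2:6, 1), sample(3:8, 1), fill = 0.35)
    net <- as_net(w)
    adj <- crossprod(w > 0) > 0; diag(adj) <- FALSE
    expect_equal(unname(pollinator_betweenness(net)),
                 oracle_betweenness(adj), tolerance = 1e-12)
  }
})

test_that("closeness: harmonic convention matches brute force", {
  # complete projection: all pollinators share one plant
  comp <- as_net(matrix(1, 1, 4, dimnames = list("pA", paste0("b", 1:4))))
  expect_equal(unname(pollinator_closeness(comp)), rep(1, 4))
  set.seed(92)
  for (i in 1:40) {
    w <- random_net(sample(2:6, 1), sample(3:8, 1), fill = 0.35)
    net <- as_net(w)
    adj <- crossprod(w > 0) > 0; diag(adj) <- FALSE
    expect_equal(unname(pollinator_closeness(net)),
                 oracle_harmonic_closeness(adj), tolerance = 1e-12)
  }
  # isolated pollinator scores 0
  w <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
              dimnames = list(paste0("p", 1:3), c("b1", "b2")))
  expect_equal(unname(pollinator_closeness(as_net(w))["b2"]), 0)
})

test_that("Chao2 rarefied degree: formula cases and the S_obs floor", {
  # S_obs = 10, m = 5, Q1 = 3, Q2 = 2 -> 10 + (4/5) * 6/6 = 10.8
  inc <- matrix(0, 10, 5)
  inc[1:5, ] <- 1                       # 5 plants in all samples
  inc[6:7, 1:2] <- 1                    # Q2 = 2
  inc[8, 1] <- 1; inc[9, 2] <- 1; inc[10, 3] <- 1   # Q1 = 3
  expect_equal(chao2_rarefied_degree(inc), 10.8)
  # Q1 = 0 -> S_obs
  all_seen <- matrix(1, 7, 3)
  expect_equal(chao2_rarefied_degree(all_seen), 7)
  set.seed(93)
  for (i in 1:300) {
    m <- sample(1:6, 1)
    inc <- matrix(rbinom(8 * m, 1, 0.4), 8, m)
    inc <- inc[rowSums(inc) > 0, , drop = FALSE]
    if (nrow(inc) == 0) next
    est <- chao2_rarefied_degree(inc)
    expect_gte(est, nrow(inc))
    if (sum(rowSums(inc) == 1) == 0) expect_equal(est, nrow(inc))
  }
})

test_that("Chao-Sorensen similarity: limits and a hand-frozen example", {
  expect_equal(chao_sorensen(c(3, 2, 1), c(3, 2, 1)), 1)
  expect_equal(chao_sorensen(c(3, 0, 1), c(0, 5, 0)), 0)
  # hand computation from the published estimator, x = (4,1,0), y = (2,1,3):
  # shared = {1,2}; n = 5, m = 6
  # U: sum x_shared/n = 1; capped at 1 -> U = 1
  # V: sum y_shared/m = 3/6; y-side correction uses x singletons among shared:
  #    f1 = 1 (species 2 has x = 1), f2 = 0 -> f1(f1-1)/2 = 0
  #    V = 0.5
  # similarity = 2 * 1 * 0.5 / 1.5 = 2/3
  expect_equal(chao_sorensen(c(4, 1, 0), c(2, 1, 3)), 2 / 3)
  # symmetry and bounds on random profiles
  set.seed(94)
  for (i in 1:100) {
    x <- rpois(6, 2); y <- rpois(6, 2)
    if (sum(x) == 0 || sum(y) == 0) next
    s <- chao_sorensen(x, y)
    expect_equal(s, chao_sorensen(y, x))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("d': perfect partition is 1, availability-tracking is 0", {
  w <- matrix(c(5, 0, 0, 5), 2, dimnames = list(c("pA", "pB"), c("b1", "b2")))
  net <- as_net(w)
  expect_equal(bluethgen_dprime(net, "b1"), 1)
  expect_equal(bluethgen_dprime(net, "b2"), 1)
  # use proportional to availability -> 0
  w2 <- matrix(c(6, 2, 3, 1), 2, dimnames = list(c("pA", "pB"), c("b1", "b2")))
  expect_equal(bluethgen_dprime(as_net(w2), "b1"), 0)
  set.seed(95)
  for (i in 1:100) {
    w <- random_net(sample(2:6, 1), sample(2:6, 1))
    net <- as_net(w)
    for (b in colnames(w)) {
      d <- bluethgen_dprime(net, b)
      expect_gte(d, 0); expect_lte(d, 1)
    }
  }
})

test_that("species strength sums plant dependencies and is conserved", {
  w <- matrix(c(2, 0, 1, 1), 2, dimnames = list(c("pA", "pB"), c("b1", "b2")))
  st <- species_strength(as_net(w))
  expect_equal(unname(st), c(2 / 3, 4 / 3))
  # sole pollinator: strength = number of plants
  solo <- as_net(matrix(c(2, 5, 1), 3, 1,
                        dimnames = list(paste0("p", 1:3), "b1")))
  expect_equal(unname(species_strength(solo)), 3)
  set.seed(96)
  for (i in 1:200) {
    w <- random_net(sample(2:7, 1), sample(2:7, 1))
    expect_equal(sum(species_strength(as_net(w))), nrow(w), tolerance = 1e-12)
  }
})

test_that("niche PCA matches an eigendecomposition oracle and is order-invariant", {
  set.seed(97)
  roles <- data.frame(
    pollinator = rep(sprintf("b%d", 1:5), 2),
    site = rep(c("s1", "s2"), each = 5), year = "2013",
    betweenness = runif(10), closeness = runif(10),
    rarefied_degree = runif(10, 1, 8), niche_overlap = runif(10),
    dprime = runif(10), strength = runif(10, 0, 3))
  pca <- niche_pca(roles)
  # oracle: eigendecomposition of the covariance of the centered matrix
  x <- scale(as.matrix(roles[, 4:9]), center = TRUE, scale = FALSE)
  eig <- eigen(cov(x))
  v1 <- eig$vectors[, 1]
  if (v1[6] > 0) v1 <- -v1       # same sign convention: strength non-positive
  expect_equal(unname(pca$loadings), v1, tolerance = 1e-8)
  expect_equal(unname(pca$var_share[1]), eig$values[1] / sum(eig$values),
               tolerance = 1e-8)
  expect_equal(sum(pca$var_share), 1)
  expect_lte(pca$loadings[["strength"]], 0)
  # permuting row order leaves loadings identical
  perm <- roles[sample(nrow(roles)), ]
  expect_equal(niche_pca(perm)$loadings, pca$loadings, tolerance = 1e-10)
  # two perfectly correlated metrics -> PC1 explains everything
  r2 <- roles; r2[, 4:9] <- matrix(rep(runif(10), 6), ncol = 6) *
    rep(c(1, 2, 3, 1, 2, 3), each = 10)
  expect_equal(unname(niche_pca(r2)$var_share[1]), 1, tolerance = 1e-10)
})

test_that("niche variability: CV closed forms and scale invariance", {
  sc <- data.frame(pollinator = rep("b1", 2), site = c("s1", "s2"),
                   year = "2013", pc1 = c(1, 3))
  nv <- niche_variability(sc, "2013")
  expect_equal(nv$cv_pc1, sqrt(2) / 2)    # sample SD convention
  expect_equal(nv$mean_pc1, 2)
  sc$pc1 <- sc$pc1 * 7                     # scaling leaves CV unchanged
  expect_equal(niche_variability(sc, "2013")$cv_pc1, sqrt(2) / 2)
  same <- data.frame(pollinator = "b2", site = c("s1", "s2", "s3"),
                     year = "2013", pc1 = rep(1.3, 3))
  expect_equal(niche_variability(same, "2013")$cv_pc1, 0)
  one <- data.frame(pollinator = "b3", site = "s1", year = "2013", pc1 = 2)
  expect_true(is.na(niche_variability(one, "2013")$cv_pc1))
})

test_that("interaction beta-diversity matches dispersion geometry", {
  # identical profiles at all samples -> 0
  v <- data.frame(site = rep(c("s1", "s2", "s3"), each = 2), year = "2013",
                  round = 1, plant = rep(c("pA", "pB"), 3),
                  pollinator = "b1", count = rep(c(2, 1), 3))
  expect_equal(interaction_beta_diversity(v, "b1", "2013"), 0)
  # two samples at Bray-Curtis dissimilarity d -> each is d/2 from centroid
  v2 <- data.frame(site = c("s1", "s1", "s2", "s2"), year = "2013", round = 1,
                   plant = c("pA", "pB", "pA", "pB"), pollinator = "b1",
                   count = c(3, 1, 1, 3))
  rel <- rbind(c(0.75, 0.25), c(0.25, 0.75))
  d <- as.numeric(vegan::vegdist(rel, "bray"))
  expect_equal(interaction_beta_diversity(v2, "b1", "2013"), d / 2)
  # <= 5-sample toys match the direct dissimilarity-matrix oracle
  set.seed(98)
  for (i in 1:40) {
    ns <- sample(3:5, 1)
    v3 <- do.call(rbind, lapply(1:ns, function(s) {
      k <- sample(2:4, 1)
      data.frame(site = paste0("s", s), year = "2013", round = 1,
                 plant = sample(paste0("p", 1:4), k), pollinator = "b1",
                 count = sample(1:5, k, TRUE))
    }))
    got <- suppressWarnings(interaction_beta_diversity(v3, "b1", "2013"))
    prof <- tapply(v3$count, list(v3$site, v3$plant), sum, default = 0)
    prof <- prof / rowSums(prof)
    expect_equal(got, oracle_dispersion(vegan::vegdist(prof, "bray")),
                 tolerance = 1e-8)
  }
  # single sample -> NA (excluded from flexibility analyses)
  v4 <- v2[1:2, ]
  expect_true(is.na(interaction_beta_diversity(v4, "b1", "2013")))
})

test_that("beta-diversity is invariant to scaling a species' counts", {
  set.seed(99)
  v <- do.call(rbind, lapply(1:4, function(s)
    data.frame(site = paste0("s", s), year = "2013", round = 1,
               plant = paste0("p", 1:3), pollinator = "b1",
               count = sample(1:6, 3, TRUE))))
  b1 <- interaction_beta_diversity(v, "b1", "2013")
  v$count <- v$count * 5
  expect_equal(interaction_beta_diversity(v, "b1", "2013"), b1,
               tolerance = 1e-10)
})

test_that("role metrics respect their bounds on many random networks", {
  set.seed(100)
  for (i in 1:150) {
    w <- random_net(sample(2:6, 1), sample(2:6, 1))
    net <- as_net(w)
    bt <- pollinator_betweenness(net)
    cl <- pollinator_closeness(net)
    expect_true(all(bt >= 0 & bt <= 1))
    expect_true(all(cl >= 0 & cl <= 1))
    for (b in colnames(w)) {
      expect_true(bluethgen_dprime(net, b) >= 0 &&
                    bluethgen_dprime(net, b) <= 1)
      if (ncol(w) > 1) {
        ov <- chao_niche_overlap(net, b)
        expect_true(ov >= 0 && ov <= 1)
      }
    }
  }
})

test_that("role metrics table covers pollinator x site x year with valid rows", {
  d <- gen_dataset(small_params(seed = 37))
  rm <- role_metrics(d$visits)
  expect_true(all(rm$rarefied_degree >= 0))
  expect_true(all(rm$betweenness >= 0 & rm$betweenness <= 1))
  expect_true(all(rm$dprime >= 0 & rm$dprime <= 1, na.rm = TRUE))
  expect_false(anyDuplicated(rm[, c("pollinator", "site", "year")]) > 0)
  # rarefied degree >= observed partner count at that site-year
  k <- rm[17, ]
  net <- build_network(d$visits, k$site, k$year)
  expect_gte(k$rarefied_degree, sum(net$weights[, k$pollinator] > 0))
})
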