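# Species-level network roles for pollinators: centralities on the one-mode
# projection, Chao2 rarefied degree, Chao abundance-based niche overlap,
# Bluethgen d' specialization and species strength; a PCA that fuses them
# into a single network-niche score; and the two flexibility measures
# (interaction beta-diversity across the landscape and the CV of the niche
# score across sites).

# unweighted one-mode pollinator projection: pollinators linked when they
# share at least one plant
.pollinator_projection <- function(net) {
  b <- net$weights > 0
  adj <- crossprod(b) > 0
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Betweenness centrality of a pollinator
#'
#' Fraction of shortest paths between other pollinator pairs that pass
#' through the focal species, on the unweighted one-mode projection
#' (pollinators linked when sharing at least one plant), normalized to
#' \[0, 1\]. Projections with fewer than three nodes give 0.
#'
#' @param net an `interaction_network`.
#' @param species pollinator label, or `NULL` for all pollinators.
#' @return named numeric vector in `[0, 1]`.
#' @export
pollinator_betweenness <- function(net, species = NULL) {
  g <- .pollinator_projection(net)
  n <- igraph::vcount(g)
  bt <- if (n < 3) stats::setNames(rep(0, n), igraph::V(g)$name) else
    igraph::betweenness(g, normalized = TRUE)
  if (is.null(species)) bt else bt[species]
}

#' Harmonic closeness centrality of a pollinator
#'
#' Sum of inverse shortest-path distances to all other pollinators on the
#' one-mode projection, divided by `n - 1` (the harmonic form handles
#' disconnected projections: unreachable nodes contribute 0, an isolated
#' pollinator scores 0, a complete projection scores 1).
#'
#' @inheritParams pollinator_betweenness
#' @return named numeric vector in `[0, 1]`.
#' @export
pollinator_closeness <- function(net, species = NULL) {
  g <- .pollinator_projection(net)
  n <- igraph::vcount(g)
  cl <- if (n < 2) stats::setNames(rep(0, n), igraph::V(g)$name) else
    igraph::harmonic_centrality(g, normalized = TRUE)
  if (is.null(species)) cl else cl[species]
}

#' Chao2 rarefied degree
#'
#' Bias-corrected Chao2 estimate of the number of plant species a pollinator
#' would be seen visiting given more sampling:
#' `S_obs + ((m - 1) / m) * Q1 (Q1 - 1) / (2 (Q2 + 1))`, where incidence
#' samples are the surveys in which the pollinator was caught, and Q1/Q2
#' count plants seen in exactly one/two of those samples. Always at least
#' `S_obs`, with equality when Q1 is 0 or 1.
#'
#' @param incidence logical or 0/1 matrix, plants x samples, for the focal
#'   pollinator.
#' @return the Chao2 estimate.
#' @export
chao2_rarefied_degree <- function(incidence) {
  incidence <- as.matrix(incidence) > 0
  m <- ncol(incidence)
  if (m < 1) stop("Chao2 undefined with zero incidence samples")
  seen <- rowSums(incidence)
  s_obs <- sum(seen > 0)
  q1 <- sum(seen == 1)
  q2 <- sum(seen == 2)
  s_obs + ((m - 1) / m) * q1 * (q1 - 1) / (2 * (q2 + 1))
}

#' Chao abundance-based similarity (Sorensen form) of two count profiles
#'
#' The Chao–Sorensen estimator adjusts the proportions of shared individuals
#' (`U`, `V`) for unseen shared species using the singletons/doubletons of
#' the opposite profile, then combines them as `2UV / (U + V)`. Identical
#' profiles give 1; disjoint partner sets give 0.
#'
#' @param x,y non-negative count vectors over a common partner roster.
#' @return similarity in `[0, 1]`.
#' @export
chao_sorensen <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- sum(x); m <- sum(y)
  if (n == 0 || m == 0) return(0)
  shared <- x > 0 & y > 0
  if (!any(shared)) return(0)
  u_hat <- function(a, b, tot_a, tot_b) {
    # proportion of a's individuals in shared species, corrected for shared
    # species present in b but unseen there
    f1 <- sum(shared & b == 1)
    f2 <- sum(shared & b == 2)
    corr <- if (f2 > 0) f1 / (2 * f2) else f1 * (f1 - 1) / (2 * (f2 + 1))
    u <- sum(a[shared]) / tot_a +
      ((tot_b - 1) / tot_b) * corr * sum(a[shared & b == 1]) / tot_a
    min(u, 1)
  }
  U <- u_hat(x, y, n, m)
  V <- u_hat(y, x, m, n)
  if (U + V == 0) return(0)
  2 * U * V / (U + V)
}

#' Interaction niche overlap of a pollinator
#'
#' Mean Chao abundance-based similarity between the focal pollinator's plant
#' visit-count profile and every other pollinator's in the same network.
#'
#' @param net an `interaction_network`.
#' @param species focal pollinator label.
#' @return overlap in `[0, 1]`.
#' @export
chao_niche_overlap <- function(net, species) {
  w <- net$weights
  others <- setdiff(colnames(w), species)
  if (length(others) == 0) stop("niche overlap needs at least one other pollinator")
  mean(vapply(others, function(o) chao_sorensen(w[, species], w[, o]),
              numeric(1)))
}

#' Bluethgen d' specialization of a pollinator
#'
#' Kullback–Leibler divergence of the pollinator's partner-use distribution
#' from partner availability (the network's plant marginals), normalized to
#' \[0, 1\] by its attainable bounds: 0 when use tracks availability exactly
#' and `ln(1 / q_min)` when all use falls on the rarest partner.
#'
#' @param net an `interaction_network`.
#' @param species focal pollinator label.
#' @return d' in `[0, 1]`.
#' @export
bluethgen_dprime <- function(net, species) {
  w <- net$weights
  use <- w[, species]
  if (sum(use) == 0) stop("species has no interactions")
  p <- use / sum(use)
  q <- rowSums(w) / sum(w)
  d <- sum(p[p > 0] * log(p[p > 0] / q[p > 0]))
  dmax <- log(1 / min(q))
  if (dmax <= 0) return(0)        # single available partner: no choice to specialize
  min(max(d / dmax, 0), 1)
}

#' Species strength of a pollinator
#'
#' Sum over plants of each plant's proportional dependence on the focal
#' pollinator (`a_ij / sum_j a_ij`); strengths over all pollinators sum to
#' the number of plant species.
#'
#' @param net an `interaction_network`.
#' @param species pollinator label, or `NULL` for all pollinators.
#' @return named numeric vector (>= 0).
#' @export
species_strength <- function(net, species = NULL) {
  dep <- net$weights / rowSums(net$weights)
  st <- colSums(dep)
  if (is.null(species)) st else st[species]
}

#' Species-level role metrics for every pollinator x site x year
#'
#' Computes the six role metrics on site-year aggregated networks (survey
#' rounds pooled so each species has one score per site per year): normalized
#' betweenness and harmonic closeness on the one-mode projection, Chao2
#' rarefied degree (incidence samples = the site-year's survey rounds), mean
#' Chao niche overlap, Bluethgen d' and species strength.
#'
#' @param visits visitation table.
#' @return data.frame: `pollinator`, `site`, `year`, `betweenness`,
#'   `closeness`, `rarefied_degree`, `niche_overlap`, `dprime`, `strength`.
#' @export
role_metrics <- function(visits) {
  keys <- unique(visits[, c("site", "year")])
  keys <- keys[order(keys$site, keys$year), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    s <- keys$site[i]; y <- keys$year[i]
    net <- build_network(visits, s, y)
    if (is.null(net)) next
    polls <- colnames(net$weights)
    bt <- pollinator_betweenness(net)
    cl <- pollinator_closeness(net)
    sub <- visits[visits$site == s & visits$year == y & visits$count > 0, ]
    for (b in polls) {
      bsub <- sub[sub$pollinator == b, ]
      inc <- table(bsub$plant, bsub$round) > 0
      overlap <- if (length(polls) > 1) chao_niche_overlap(net, b) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        pollinator = b, site = s, year = y,
        betweenness = unname(bt[b]), closeness = unname(cl[b]),
        rarefied_degree = chao2_rarefied_degree(inc),
        niche_overlap = overlap,
        dprime = bluethgen_dprime(net, b),
        strength = unname(species_strength(net, b)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Network-niche PCA over role metrics
#'
#' Centers each metric within year (across species and sites), fits one PCA
#' on the pooled centered rows, and returns PC1 as the network-niche score.
#' For a reproducible orientation the PC1 loading of species strength is
#' forced non-positive. Rows with missing metrics are dropped.
#'
#' @param roles data.frame from [role_metrics()].
#' @param metrics character vector of metric columns to use.
#' @return list with `scores` (pollinator, site, year, pc1), `loadings`
#'   (named PC1 loadings), `var_share` (per-component variance fractions),
#'   and the fitted `prcomp` object.
#' @export
niche_pca <- function(roles, metrics = c("betweenness", "closeness",
                                         "rarefied_degree", "niche_overlap",
                                         "dprime", "strength")) {
  keep <- stats::complete.cases(roles[, metrics])
  r <- roles[keep, , drop = FALSE]
  if (nrow(r) < 2) stop("PCA needs at least two complete rows")
  x <- as.matrix(r[, metrics])
  for (y in unique(r$year)) {
    sel <- r$year == y
    x[sel, ] <- scale(x[sel, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate PCA: all metrics have zero variance")
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  if (fit$rotation["strength", 1] > 0) {
    fit$rotation[, 1] <- -fit$rotation[, 1]
    fit$x[, 1] <- -fit$x[, 1]
  }
  var_share <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = data.frame(pollinator = r$pollinator, site = r$site,
                           year = r$year, pc1 = fit$x[, 1],
                           stringsAsFactors = FALSE),
       loadings = fit$rotation[, 1],
       var_share = var_share,
       fit = fit)
}

#' Network-niche variability (CV of PC1 across the landscape)
#'
#' For each pollinator, the coefficient of variation (sample SD over absolute
#' mean) of its PC1 scores across sites in the pre-drought year, plus the
#' landscape mean PC1. Species scored at fewer than two sites get `NA`; a
#' zero mean leaves the CV undefined (`NA`, flagged with a warning).
#'
#' @param scores data.frame from [niche_pca()]'s `scores`.
#' @param pre_drought_year year label of the pre-extreme-drought season.
#' @return data.frame: `pollinator`, `mean_pc1`, `cv_pc1`, `n_sites`.
#' @export
niche_variability <- function(scores, pre_drought_year) {
  pre <- scores[scores$year == pre_drought_year, , drop = FALSE]
  out <- lapply(split(pre, pre$pollinator), function(d) {
    m <- mean(d$pc1)
    cv <- if (nrow(d) < 2) NA_real_
    else if (m == 0) { warning("CV undefined for zero mean PC1"); NA_real_ }
    else stats::sd(d$pc1) / abs(m)
    data.frame(pollinator = d$pollinator[1], mean_pc1 = m, cv_pc1 = cv,
               n_sites = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interaction beta-diversity of one pollinator
#'
#' Partner flexibility as multivariate dispersion: Bray–Curtis
#' dissimilarities among the pollinator's relative (row-normalized) partner
#' profiles over the site x survey samples of one year, embedded by principal
#' coordinates (negative eigenvalues handled by the standard imaginary-axis
#' correction), returning the mean distance to the group centroid. Species
#' present in fewer than two samples return `NA`.
#'
#' @param visits visitation table.
#' @param species focal pollinator.
#' @param year year label.
#' @return mean distance to centroid (>= 0), or `NA`.
#' @export
interaction_beta_diversity <- function(visits, species, year) {
  sub <- visits[visits$pollinator == species & visits$year == year &
                  visits$count > 0, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  sample_id <- paste(sub$site, sub$round, sep = "|")
  prof <- tapply(sub$count, list(sample_id, sub$plant), sum, default = 0)
  prof <- matrix(as.numeric(prof), nrow = nrow(prof), dimnames = dimnames(prof))
  if (nrow(prof) < 2) return(NA_real_)
  rel <- prof / rowSums(prof)
  d <- vegan::vegdist(rel, method = "bray")
  if (all(d == 0)) return(0)
  bd <- vegan::betadisper(d, group = factor(rep("all", nrow(rel))),
                          type = "centroid")
  mean(bd$distances)
}

#' Niche summary per pollinator
#'
#' Combines partner flexibility (interaction beta-diversity in the
#' pre-drought year), niche flexibility (CV of PC1 across sites in the
#' pre-drought year) and the mean network niche into one table.
#'
#' @param visits visitation table.
#' @param pre_drought_year year label of the pre-extreme-drought season.
#' @param roles optional precomputed [role_metrics()] table.
#' @return data.frame: `pollinator`, `mean_pc1`, `cv_pc1`, `partner_beta`,
#'   plus the PCA (`attr(x, "pca")`).
#' @export
niche_summary <- function(visits, pre_drought_year, roles = NULL) {
  if (is.null(roles)) roles <- role_metrics(visits)
  pca <- niche_pca(roles)
  nv <- niche_variability(pca$scores, pre_drought_year)
  nv$partner_beta <- vapply(nv$pollinator, function(b)
    interaction_beta_diversity(visits, b, pre_drought_year), numeric(1))
  attr(nv, "pca") <- pca
  nv
}
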