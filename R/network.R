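# Weighted bipartite plant x pollinator networks and their community-level
# structure: Rao functional redundancy (Simpson diversity minus Rao quadratic
# entropy of interaction-profile dissimilarities), dendrogram-based functional
# complementarity, and mean-degree generalization.

#' Build a weighted interaction network from visitation records
#'
#' Sums visit counts per plant x pollinator cell for one site/year (and
#' optionally one survey round); duplicated records aggregate. Species with
#' no interactions in the subset are absent from the matrix.
#'
#' @param visits visitation table (`site`, `year`, `round`, `plant`,
#'   `pollinator`, `count`).
#' @param site,year,round subset keys; `round = NULL` pools all rounds of the
#'   site-year into one aggregate network.
#' @return object of class `interaction_network` (list with `weights`: plants
#'   x pollinators integer matrix, plus the keys), or `NULL` if no records
#'   match (logged via `message`).
#' @export
build_network <- function(visits, site, year, round = NULL) {
  sel <- visits$site == site & visits$year == year
  if (!is.null(round)) sel <- sel & visits$round == round
  sub <- visits[sel & visits$count > 0, , drop = FALSE]
  if (nrow(sub) == 0) {
    message("build_network: no records for ", site, "/", year,
            if (!is.null(round)) paste0("/round ", round), "; skipped")
    return(NULL)
  }
  w <- tapply(sub$count, list(plant = sub$plant, pollinator = sub$pollinator),
              sum, default = 0)
  w <- matrix(as.numeric(w), nrow = nrow(w), dimnames = dimnames(w))
  w <- w[rowSums(w) > 0, colSums(w) > 0, drop = FALSE]
  structure(list(weights = w, site = site, year = year, round = round),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$weights), "plants x", ncol(x$weights),
      "pollinators at", x$site, "/", x$year,
      if (!is.null(x$round)) paste("/ round", x$round) else "(rounds pooled)",
      "\n")
  invisible(x)
}

# species-by-partner profile matrix for one trophic level
.level_profiles <- function(net, level = c("pollinator", "plant")) {
  level <- match.arg(level)
  if (level == "pollinator") t(net$weights) else net$weights
}

#' Rao quadratic entropy
#'
#' `Q = sum_ij d_ij p_i p_j` for relative abundances `p` and a symmetric
#' dissimilarity matrix `d` bounded in \[0, 1\] (the bound keeps the
#' redundancy identity `R = D - Q` on the Simpson scale). With `d = 1` off the
#' diagonal, Q equals Gini–Simpson diversity.
#'
#' @param p relative abundances summing to 1.
#' @param d symmetric dissimilarity matrix, zero diagonal, values in \[0, 1\].
#' @return Q, a number in `[0, 1]`.
#' @export
rao_quadratic_entropy <- function(p, d) {
  d <- as.matrix(d)
  if (abs(sum(p) - 1) > 1e-8) stop("abundances p must sum to 1")
  if (nrow(d) != length(p) || ncol(d) != length(p))
    stop("dissimilarity matrix does not match length of p")
  if (any(abs(d - t(d)) > 1e-12) || any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with a zero diagonal")
  if (any(d < -1e-12) || any(d > 1 + 1e-12))
    stop("dissimilarities must lie in [0, 1] (required for the redundancy identity)")
  as.numeric(t(p) %*% d %*% p)
}

#' Functional redundancy of one trophic level
#'
#' Redundancy is Simpson diversity minus Rao quadratic entropy, with the
#' interaction network as the trait matrix: each species' "traits" are its
#' interaction partners. Abundances are the species' marginal interaction
#' totals; dissimilarities are Bray–Curtis distances between relative
#' interaction profiles (bounded in \[0, 1\], as the identity requires).
#' If diversity and trait diversity coincide, species partition partners
#' completely and redundancy is 0; a single-species level has D = Q = R = 0.
#'
#' @param net an `interaction_network`.
#' @param level `"pollinator"` (overlap in plant use) or `"plant"` (overlap in
#'   pollinator use).
#' @param dissim `"bray"` (default) or `"jaccard"` (binary profiles).
#' @return list with `redundancy`, `simpson_D`, `rao_Q`.
#' @export
functional_redundancy <- function(net, level = c("pollinator", "plant"),
                                  dissim = c("bray", "jaccard")) {
  dissim <- match.arg(dissim)
  prof <- .level_profiles(net, level)
  p <- rowSums(prof) / sum(prof)
  D <- 1 - sum(p^2)
  if (nrow(prof) < 2)
    return(list(redundancy = 0, simpson_D = D, rao_Q = 0))
  d <- if (dissim == "bray") {
    vegan::vegdist(prof / rowSums(prof), method = "bray")
  } else {
    vegan::vegdist(prof > 0, method = "jaccard")
  }
  Q <- rao_quadratic_entropy(p, d)
  list(redundancy = D - Q, simpson_D = D, rao_Q = Q)
}

# total branch length of an hclust tree under the convention: node height =
# merge distance, leaf height = 0, edge length = parent minus child height
.hclust_branch_length <- function(hc) {
  node_h <- numeric(nrow(hc$merge))
  total <- 0
  for (k in seq_len(nrow(hc$merge))) {
    h <- hc$height[k]
    for (child in hc$merge[k, ]) {
      ch <- if (child < 0) 0 else node_h[child]
      total <- total + (h - ch)
    }
    node_h[k] <- h
  }
  total
}

#' Functional complementarity of one trophic level
#'
#' Total branch length of a UPGMA (average-linkage) dendrogram clustering the
#' level's species by Euclidean distance between their raw weighted
#' interaction profiles: species sharing partners sit on short branches,
#' species partitioning partners on long ones. Levels with fewer than two
#' species return 0 by convention.
#'
#' @param net an `interaction_network`.
#' @param level `"pollinator"` or `"plant"`.
#' @return total branch length (>= 0).
#' @export
functional_complementarity <- function(net, level = c("pollinator", "plant")) {
  prof <- .level_profiles(net, level)
  if (nrow(prof) < 2) return(0)
  hc <- stats::hclust(stats::dist(prof), method = "average")
  .hclust_branch_length(hc)
}

#' Generalization (mean degree) of one trophic level
#'
#' Mean number of distinct interaction partners per species, counted on
#' presence (a partner is a partner however many visits it received).
#'
#' @param net an `interaction_network`.
#' @param level `"pollinator"` or `"plant"`.
#' @return mean degree (>= 1 for any constructed network).
#' @export
generalization <- function(net, level = c("pollinator", "plant")) {
  prof <- .level_profiles(net, level)
  mean(rowSums(prof > 0))
}

#' Community network metrics for every survey network
#'
#' Builds the per site x year x round networks and returns redundancy,
#' complementarity, generalization and species richness for both trophic
#' levels in long format. Empty surveys contribute no rows.
#'
#' @param visits visitation table.
#' @return data.frame: `site`, `year`, `round`, `level`, `metric`, `value`.
#' @export
metrics_table <- function(visits) {
  keys <- unique(visits[, c("site", "year", "round")])
  keys <- keys[order(keys$site, keys$year, keys$round), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    net <- build_network(visits, keys$site[i], keys$year[i], keys$round[i])
    if (is.null(net)) next
    for (lev in c("plant", "pollinator")) {
      fr <- functional_redundancy(net, lev)
      vals <- c(redundancy = fr$redundancy,
                complementarity = functional_complementarity(net, lev),
                generalization = generalization(net, lev),
                richness = nrow(.level_profiles(net, lev)))
      out[[length(out) + 1L]] <-
        data.frame(site = keys$site[i], year = keys$year[i],
                   round = keys$round[i], level = lev,
                   metric = names(vals), value = unname(vals),
                   stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(site = character(0), year = character(0), round = integer(0),
               level = character(0), metric = character(0), value = numeric(0))
  rownames(res) <- NULL
  res
}
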