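# Co-extinction cascade simulation: plants are removed from lowest to highest
# pre-drought bloom abundance; a pollinator goes extinct when its last
# remaining partner is removed. Robustness is the normalized area under the
# survival curve, computed for the observed network and for a "potential"
# network that adds every plant-pollinator link ever observed anywhere in the
# landscape (a re-wiring proxy).

#' Potential (re-wired) network for a focal site-year
#'
#' Links every plant-pollinator pair observed interacting in any survey
#' anywhere in the dataset, restricted to the plants and pollinators recorded
#' at the focal site in the focal year, so its link set always contains the
#' observed network's.
#'
#' @param visits full visitation table (all sites and years).
#' @param site,year focal keys.
#' @return binary plants x pollinators matrix, or `NULL` if the focal
#'   site-year has no records.
#' @export
potential_network <- function(visits, site, year) {
  net <- build_network(visits, site, year)
  if (is.null(net)) return(NULL)
  plants <- rownames(net$weights)
  polls <- colnames(net$weights)
  all_pairs <- unique(visits[visits$count > 0, c("plant", "pollinator")])
  all_pairs <- all_pairs[all_pairs$plant %in% plants &
                           all_pairs$pollinator %in% polls, , drop = FALSE]
  m <- matrix(0L, length(plants), length(polls), dimnames = list(plants, polls))
  m[cbind(all_pairs$plant, all_pairs$pollinator)] <- 1L
  m
}

#' Abundance-based plant removal order
#'
#' Plants ordered by ascending total bloom count at the site in the
#' pre-drought year (the least abundant are assumed most likely to be lost
#' first); ties break alphabetically. Plants in the network but absent from
#' the floral table are treated as abundance 0 (removed first) with a
#' warning.
#'
#' @param floral floral survey table (`site`, `year`, `round`, `plant`,
#'   `count`).
#' @param site focal site.
#' @param plants plant labels that must be covered by the order.
#' @param pre_drought_year year label whose abundances order the removals.
#' @return character vector: `plants` in removal order.
#' @export
abundance_removal_order <- function(floral, site, plants, pre_drought_year) {
  sub <- floral[floral$site == site & floral$year == pre_drought_year, ,
                drop = FALSE]
  tot <- tapply(sub$count, sub$plant, sum)
  ab <- stats::setNames(rep(0, length(plants)), plants)
  seen <- intersect(plants, names(tot))
  ab[seen] <- tot[seen]
  missing <- setdiff(plants, names(tot))
  if (length(missing))
    warning("plants absent from floral table treated as abundance 0: ",
            paste(missing, collapse = ", "))
  plants[order(ab, plants)]
}

#' Simulate a plant-extinction cascade
#'
#' Removes plants one at a time in the given order; a pollinator goes extinct
#' when its last remaining partner is removed. Returns the extinction curve:
#' fraction of plants removed vs. fraction of pollinators surviving, from
#' (0, 1) to (1, 0).
#'
#' @param net binary (or weighted, used as binary) plants x pollinators
#'   matrix.
#' @param order character vector covering every plant in `net`.
#' @return data.frame of class `extinction_curve` with `removed_frac`,
#'   `surviving_frac`.
#' @export
simulate_cascade <- function(net, order) {
  b <- as.matrix(net) > 0
  plants <- rownames(b)
  if (!setequal(order, plants) || length(order) != length(plants))
    stop("removal order must cover each plant in the network exactly once")
  np <- length(plants)
  nb <- ncol(b)
  alive <- rep(TRUE, np)
  names(alive) <- plants
  surviving <- numeric(np + 1)
  surviving[1] <- 1
  for (k in seq_len(np)) {
    alive[order[k]] <- FALSE
    surviving[k + 1] <- sum(colSums(b[alive, , drop = FALSE]) > 0) / nb
  }
  structure(data.frame(removed_frac = (0:np) / np, surviving_frac = surviving),
            class = c("extinction_curve", "data.frame"))
}

#' Robustness: area under the extinction curve
#'
#' Trapezoidal area under (fraction removed, fraction surviving), already on
#' the unit square so no further normalization is needed. 1 is maximal
#' resistance (survival until almost all plants are gone); values near 0 mean
#' pollinators are lost after the first removals.
#'
#' @param curve an `extinction_curve` (or data.frame with `removed_frac`,
#'   `surviving_frac`).
#' @return robustness in `[0, 1]`.
#' @export
robustness <- function(curve) {
  x <- curve$removed_frac
  y <- curve$surviving_frac
  if (is.unsorted(x, strictly = TRUE)) stop("curve x must be strictly increasing")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Robustness of observed and potential networks per site-year
#'
#' For each site-year aggregate network (rounds pooled), simulates the
#' abundance-ordered cascade on the observed binary network and on the
#' potential (re-wired) network, using the same removal order for both.
#'
#' @param visits visitation table.
#' @param floral floral survey table.
#' @param pre_drought_year year label whose bloom abundances set the removal
#'   order.
#' @return data.frame: `site`, `year`, `kind` (observed/potential),
#'   `robustness`, `n_plants`, `n_pollinators`.
#' @export
robustness_table <- function(visits, floral, pre_drought_year) {
  keys <- unique(visits[, c("site", "year")])
  keys <- keys[order(keys$site, keys$year), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    s <- keys$site[i]; y <- keys$year[i]
    net <- build_network(visits, s, y)
    if (is.null(net)) next
    obs <- (net$weights > 0) * 1L
    pot <- potential_network(visits, s, y)
    ord <- abundance_removal_order(floral, s, rownames(obs), pre_drought_year)
    for (kind in c("observed", "potential")) {
      m <- if (kind == "observed") obs else pot
      r <- robustness(simulate_cascade(m, ord))
      out[[length(out) + 1L]] <- data.frame(
        site = s, year = y, kind = kind, robustness = r,
        n_plants = nrow(m), n_pollinators = ncol(m),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
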