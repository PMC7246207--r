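# Pyrodiversity: every raster cell gets a fire-history category (the exact
# sequence of fires it experienced and the severity of each), and a site's
# pyrodiversity is Simpson's diversity of those categories among the cells
# whose centres fall inside a buffer around the site.

#' Classify a continuous burn-ratio grid into severity classes
#'
#' Burned cells are binned by ascending breakpoints: the class index is one
#' plus the number of thresholds strictly below the cell value, so values up
#' to and including the first threshold land in class 1. Unburned (`NA`)
#' cells stay `NA`. With no thresholds every burned cell is class 1.
#'
#' @param raw_grid numeric matrix of continuous burn-ratio values (`NA` =
#'   unburned).
#' @param thresholds strictly ascending numeric breakpoints.
#' @return integer matrix of severity classes.
#' @export
classify_severity <- function(raw_grid, thresholds = numeric(0)) {
  if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
    stop("severity thresholds must be strictly ascending")
  out <- raw_grid
  burned <- !is.na(raw_grid)
  if (length(thresholds) == 0) {
    out[burned] <- 1
  } else {
    v <- raw_grid[burned]
    out[burned] <- 1 + rowSums(outer(v, thresholds, ">"))
  }
  out
}

#' Assign a unique fire-history category to every cell
#'
#' Two cells share a category iff their full per-fire (fire, severity)
#' sequences are identical — cells burned in the same fires but at different
#' severities get different categories. Cells never burned in any layer all
#' share the reserved category 0. Non-zero ids are assigned in lexicographic
#' order of the severity sequences, so ids are reproducible and invariant to
#' cell traversal order.
#'
#' @param stack a [fire_raster_stack()].
#' @return list of class `fire_history_map` with `category_id` (integer
#'   matrix) and `n_categories` (distinct ids present, including 0 when
#'   never-burned cells exist).
#' @export
assign_fire_histories <- function(stack) {
  if (!inherits(stack, "fire_raster_stack")) stop("expected a fire_raster_stack")
  nr <- stack$nrow; nc <- stack$ncol
  if (length(stack$layers) == 0) {
    ids <- matrix(0L, nrow = max(nr, 0L), ncol = max(nc, 0L))
    return(structure(list(category_id = ids,
                          n_categories = if (length(ids)) 1L else 0L,
                          history_keys = c("0" = "")),
                     class = "fire_history_map"))
  }
  # per-cell key: fixed-width severity codes so string sort == sequence sort
  codes <- lapply(stack$layers, function(l) {
    v <- as.vector(l)
    v[is.na(v)] <- 0
    sprintf("%02d", v)
  })
  key <- do.call(paste, c(codes, sep = "."))
  never <- paste(rep("00", length(stack$layers)), collapse = ".")
  uniq <- sort(unique(key))
  burned_keys <- setdiff(uniq, never)
  id_of <- stats::setNames(seq_along(burned_keys), burned_keys)
  ids <- integer(length(key))
  ids[key != never] <- id_of[key[key != never]]
  id_mat <- matrix(as.integer(ids), nrow = nr, ncol = nc)
  structure(list(category_id = id_mat,
                 n_categories = length(uniq),
                 history_keys = stats::setNames(
                   c(if (never %in% uniq) never else NULL, burned_keys),
                   c(if (never %in% uniq) "0" else NULL, as.character(seq_along(burned_keys))))),
            class = "fire_history_map")
}

#' @export
print.fire_history_map <- function(x, ...) {
  cat("fire_history_map:", x$n_categories, "distinct fire-history categories over",
      nrow(x$category_id), "x", ncol(x$category_id), "cells\n")
  invisible(x)
}

#' Count fire-history categories within a site buffer
#'
#' A cell belongs to the buffer when its centre lies within `radius_m` of the
#' site centre (cell-centre-in-circle rule). Cells outside the raster extent
#' are simply absent from the counts.
#'
#' @param history a `fire_history_map`.
#' @param center_xy numeric length-2 site centre `(x, y)`.
#' @param radius_m buffer radius in metres (study default 150).
#' @param geometry a `fire_raster_stack` (or compatible list) supplying the
#'   grid geometry.
#' @return named integer vector: cell count per category id present.
#' @export
buffer_cell_counts <- function(history, center_xy, radius_m = 150, geometry) {
  if (radius_m <= 0) stop("radius_m must be > 0")
  cc <- cell_centers(geometry)
  d2 <- (cc$x - center_xy[1])^2 + (cc$y - center_xy[2])^2
  inside <- d2 <= radius_m^2
  if (!any(inside))
    stop("buffer contains no raster cells (site outside grid?)")
  ids <- as.vector(history$category_id)[inside]
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Gini–Simpson diversity of category counts
#'
#' Returns `1 - sum(p^2)` with `p` the category proportions: 0 for a single
#' category, approaching 1 as many categories share the cells evenly
#' (`1 - 1/k` for k equal categories).
#'
#' @param counts non-negative counts per category (at least one positive).
#' @return diversity in `[0, 1)`.
#' @export
simpson_diversity <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("Simpson diversity undefined for all-zero counts")
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Pyrodiversity score for each monitoring site
#'
#' Composes severity-classified fire layers -> per-cell fire-history
#' categories -> buffer category counts -> Gini–Simpson diversity, one score
#' per site. An empty stack (no fires in the record) gives every site the
#' single never-burned category and a score of 0.
#'
#' @param stack a [fire_raster_stack()].
#' @param sites data.frame with columns `site`, `x`, `y`.
#' @param radius_m buffer radius in metres.
#' @return data.frame with columns `site`, `pyrodiversity`.
#' @export
site_pyrodiversity <- function(stack, sites, radius_m = 150) {
  for (k in c("site", "x", "y"))
    if (!k %in% names(sites)) stop("sites table missing column: ", k)
  if (length(stack$layers) == 0)
    return(data.frame(site = sites$site, pyrodiversity = 0,
                      stringsAsFactors = FALSE))
  history <- assign_fire_histories(stack)
  score <- vapply(seq_len(nrow(sites)), function(i) {
    counts <- buffer_cell_counts(history, c(sites$x[i], sites$y[i]),
                                 radius_m, stack)
    simpson_diversity(counts)
  }, numeric(1))
  data.frame(site = sites$site, pyrodiversity = score, stringsAsFactors = FALSE)
}
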