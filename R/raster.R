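#' Fire raster stack
#'
#' A stack of aligned burn-severity grids, one layer per fire, ordered by fire
#' date. Each layer is a numeric matrix with `NA` marking cells unburned in
#' that fire and integer severity classes `1..severity_classes` elsewhere.
#' Row 1 is the northernmost row (the ESRI ASCII grid convention); the cell
#' centre of `[row, col]` is at
#' `x = xll + (col - 0.5) * cell_size`, `y = yll + (nrow - row + 0.5) * cell_size`.
#'
#' @param layers list of numeric matrices, all with identical dimensions.
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param cell_size_m cell edge length in metres (30 m in the study design).
#' @param severity_classes number of within-fire severity categories.
#' @param fire_ids optional character labels, one per layer.
#' @return An object of class `fire_raster_stack`.
#' @export
fire_raster_stack <- function(layers, xll = 0, yll = 0, cell_size_m = 30,
                              severity_classes = 4, fire_ids = NULL) {
  stopifnot(is.list(layers))
  if (length(layers) > 0) {
    dims <- vapply(layers, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all layers must share identical geometry (dimensions differ)")
    for (l in layers) {
      v <- l[!is.na(l)]
      if (length(v) && (any(v < 1) || any(v > severity_classes) || any(v != round(v))))
        stop("severity values must be NA (unburned) or integers in 1..severity_classes")
    }
    nr <- dims[1, 1]; nc <- dims[2, 1]
  } else {
    nr <- 0L; nc <- 0L
  }
  if (is.null(fire_ids)) fire_ids <- if (length(layers)) sprintf("fire_%02d", seq_along(layers)) else character(0)
  structure(list(layers = layers, xll = xll, yll = yll,
                 cell_size_m = cell_size_m, nrow = nr, ncol = nc,
                 severity_classes = severity_classes, fire_ids = fire_ids),
            class = "fire_raster_stack")
}

#' @export
print.fire_raster_stack <- function(x, ...) {
  cat("fire_raster_stack:", length(x$layers), "fire layer(s),",
      x$nrow, "x", x$ncol, "cells of", x$cell_size_m, "m,",
      x$severity_classes, "severity classes\n")
  invisible(x)
}

#' Cell-centre coordinates of a raster grid
#'
#' @param stack a `fire_raster_stack` (or any list with `xll`, `yll`,
#'   `cell_size_m`, `nrow`, `ncol`).
#' @return data.frame with `row`, `col`, `x`, `y` for every cell, in
#'   column-major cell order (matching `as.vector` on a layer matrix).
#' @export
cell_centers <- function(stack) {
  nr <- stack$nrow; nc <- stack$ncol; cs <- stack$cell_size_m
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(row = row, col = col,
             x = stack$xll + (col - 0.5) * cs,
             y = stack$yll + (nr - row + 0.5) * cs)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange format: a six-line header followed by rows of
#' values, first row northernmost. `NA` is written as the NODATA value.
#'
#' @param mat numeric matrix (row 1 = north).
#' @param path output file path.
#' @param xll,yll lower-left corner coordinates.
#' @param cell_size_m cell size.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_ascii_grid <- function(mat, path, xll = 0, yll = 0, cell_size_m = 30,
                             nodata = -9999) {
  m <- mat
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(mat)),
           paste("nrows", nrow(mat)),
           paste("xllcorner", format(xll, scientific = FALSE)),
           paste("yllcorner", format(yll, scientific = FALSE)),
           paste("cellsize", format(cell_size_m, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `mat` (numeric matrix, NODATA as `NA`), `xll`, `yll`,
#'   `cell_size_m`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing field: ", k)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  list(mat = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cell_size_m = hdr$cellsize)
}

#' Write a fire raster stack to disk with a manifest
#'
#' One ASCII grid per fire plus `manifest.csv` (`fire_id,date,path`) naming the
#' layers in fire-date order.
#'
#' @param stack a `fire_raster_stack`.
#' @param dir output directory (created if absent).
#' @param dates optional fire dates (character), one per layer; defaults to a
#'   synthetic ascending sequence.
#' @return path of the manifest file.
#' @export
write_raster_stack <- function(stack, dir, dates = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(stack$layers)
  if (is.null(dates)) dates <- sprintf("%04d-01-01", 1984 + seq_len(n))
  paths <- file.path(dir, paste0(stack$fire_ids, ".asc"))
  for (k in seq_len(n))
    write_ascii_grid(stack$layers[[k]], paths[k], stack$xll, stack$yll,
                     stack$cell_size_m)
  manifest <- data.frame(fire_id = stack$fire_ids, date = dates,
                         path = basename(paths), stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' Read a fire raster stack from a manifest
#'
#' @param manifest_path path to a CSV with columns `fire_id,date,path`
#'   (paths relative to the manifest's directory, or absolute). Layers are
#'   ordered by `date`.
#' @param severity_classes declared number of severity categories.
#' @return a `fire_raster_stack`.
#' @export
read_raster_stack <- function(manifest_path, severity_classes = 4) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  for (k in c("fire_id", "date", "path"))
    if (!k %in% names(man)) stop("raster manifest missing column: ", k)
  man <- man[order(man$date, man$fire_id), , drop = FALSE]
  base <- dirname(manifest_path)
  grids <- lapply(man$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    read_ascii_grid(fp)
  })
  if (length(grids) > 1) {
    g0 <- grids[[1]]
    for (g in grids[-1])
      if (g$xll != g0$xll || g$yll != g0$yll || g$cell_size_m != g0$cell_size_m ||
          !identical(dim(g$mat), dim(g0$mat)))
        stop("raster layers are not aligned on a common grid")
  }
  if (length(grids) == 0)
    return(fire_raster_stack(list(), severity_classes = severity_classes))
  fire_raster_stack(lapply(grids, `[[`, "mat"),
                    xll = grids[[1]]$xll, yll = grids[[1]]$yll,
                    cell_size_m = grids[[1]]$cell_size_m,
                    severity_classes = severity_classes,
                    fire_ids = man$fire_id)
}
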