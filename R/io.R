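# Table readers/writers with schema validation, and the flat key = value
# configuration format used by the command-line driver.

.check_schema <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

.check_counts <- function(df, path) {
  bad <- which(is.na(suppressWarnings(as.numeric(df$count))))
  if (length(bad))
    stop("non-numeric count in ", path, " at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$count <- as.numeric(df$count)
  if (any(df$count < 0)) stop("negative counts in ", path)
  df
}

# aggregate duplicated key rows (summing counts) with a warning
.aggregate_dups <- function(df, keys, path) {
  key <- do.call(paste, c(df[keys], sep = "\r"))
  if (anyDuplicated(key)) {
    warning("duplicated rows in ", path, " aggregated by summing counts")
    agg <- stats::aggregate(df["count"], df[keys], sum)
    df <- agg[do.call(order, agg[keys]), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a visitation table
#'
#' CSV with columns `site`, `year`, `round`, `plant`, `pollinator`, `count`.
#' Duplicated key rows are aggregated by summing with a warning.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_visits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(year = "character"))
  .check_schema(df, c("site", "year", "round", "plant", "pollinator", "count"),
                path)
  df <- .check_counts(df, path)
  .aggregate_dups(df, c("site", "year", "round", "plant", "pollinator"), path)
}

#' Read a floral survey table
#'
#' CSV with columns `site`, `year`, `round`, `plant`, `count`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_floral <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(year = "character"))
  .check_schema(df, c("site", "year", "round", "plant", "count"), path)
  df <- .check_counts(df, path)
  .aggregate_dups(df, c("site", "year", "round", "plant"), path)
}

#' Read a site table
#'
#' CSV with columns `site`, `x`, `y`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("site", "x", "y"), path)
  if (any(is.na(df$x)) || any(is.na(df$y))) stop("non-numeric coordinates in ", path)
  df
}

#' Read a flat key = value configuration file
#'
#' A minimal TOML-dialect reader: one `key = value` per line, `#` comments,
#' double-quoted strings, bare numbers, `true`/`false`. Section headers are
#' not supported (all keys are top-level).
#'
#' @param path config file path.
#' @return named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("config line without '=': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else if (grepl("^-?[0-9.eE+]+$", val)) as.numeric(val)
      else val
  }
  out
}

#' Write a flat key = value configuration file
#'
#' @param config named list of scalar values.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    vs <- if (is.character(v)) paste0('"', v, '"')
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, scientific = FALSE)
    paste(k, "=", vs)
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

# sim_params from a config list (unknown keys for other stages are ignored)
.params_from_config <- function(cfg) {
  args <- list()
  for (k in c("n_sites", "n_rounds_per_year", "grid_size", "cell_size_m",
              "n_fires", "n_severity_classes", "n_plants", "n_pollinators",
              "richness_slope", "drought_bloom_factor", "beta_interaction",
              "noise_sd", "base_occupancy", "visit_rate", "bloom_rate",
              "pref_conc", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  if (!is.null(cfg$severe_year) && !is.null(cfg$extreme_year))
    args$years <- c(severe = as.character(cfg$severe_year),
                    extreme = as.character(cfg$extreme_year))
  do.call(sim_params, args)
}
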