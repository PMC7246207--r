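# Model assembly and fitting: population log-ratio resistance, centered
# model tables, random-intercept linear mixed models (REML, Satterthwaite
# denominator df via lmerTest), variance inflation factors, and the
# end-to-end analysis driver.

#' Population log-ratio of abundance between years
#'
#' Natural log of (total specimens in the extreme year / total in the severe
#' year) for one species at one site, specimens summed across survey rounds.
#' Only species present at the site in both years are defined (zero abundance
#' in either year returns `NA`, and such species are excluded from the
#' resistance table).
#'
#' @param visits visitation table.
#' @param site,species focal keys.
#' @param years character pair `(severe, extreme)`.
#' @return log-ratio, or `NA` if not present both years.
#' @export
population_log_ratio <- function(visits, site, species, years) {
  sub <- visits[visits$site == site & visits$pollinator == species, ]
  a1 <- sum(sub$count[sub$year == years[1]])
  a2 <- sum(sub$count[sub$year == years[2]])
  if (a1 == 0 || a2 == 0) return(NA_real_)
  log(a2 / a1)
}

#' Site-level floral log-ratio covariate
#'
#' Mean over plant species (present at the site in both years) of the log
#' bloom-count ratio between the extreme and severe years.
#'
#' @param floral floral survey table.
#' @param years character pair `(severe, extreme)`.
#' @return data.frame: `site`, `floral_log_ratio`.
#' @export
floral_log_ratio <- function(floral, years) {
  out <- lapply(split(floral, floral$site), function(d) {
    t1 <- tapply(d$count[d$year == years[1]], d$plant[d$year == years[1]], sum)
    t2 <- tapply(d$count[d$year == years[2]], d$plant[d$year == years[2]], sum)
    common <- intersect(names(t1), names(t2))
    lr <- if (length(common)) mean(log(t2[common] / t1[common])) else NA_real_
    data.frame(site = d$site[1], floral_log_ratio = lr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# mean-center numeric columns, recording the centers
.center_cols <- function(df, cols) {
  for (k in cols) df[[paste0(k, "_c")]] <- df[[k]] - mean(df[[k]], na.rm = TRUE)
  df
}

#' Assemble the community-resistance model table
#'
#' Joins per-survey network metrics (long format) to site pyrodiversity,
#' codes drought year as a factor (severe-year reference) and mean-centers
#' the continuous predictors.
#'
#' @param metrics long table from [metrics_table()].
#' @param pyrodiv data.frame `site`, `pyrodiversity`.
#' @param years character pair `(severe, extreme)`.
#' @return wide data.frame, one row per network x level, with columns per
#'   metric plus `pyrodiversity_c`, `drought`, `richness_c`.
#' @export
assemble_metrics_table <- function(metrics, pyrodiv, years) {
  wide <- stats::reshape(metrics, idvar = c("site", "year", "round", "level"),
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (!all(wide$site %in% pyrodiv$site))
    stop("sites missing from pyrodiversity table: ",
         paste(setdiff(wide$site, pyrodiv$site), collapse = ", "))
  wide$pyrodiversity <- pyrodiv$pyrodiversity[match(wide$site, pyrodiv$site)]
  wide$drought <- factor(ifelse(wide$year == years[2], "extreme", "severe"),
                         levels = c("severe", "extreme"))
  wide <- .center_cols(wide, c("pyrodiversity", "richness"))
  rownames(wide) <- NULL
  wide
}

#' Assemble the population-resistance model table
#'
#' One row per pollinator x site for species present both years: the
#' abundance log-ratio, site pyrodiversity, the species' partner flexibility
#' (interaction beta-diversity) and niche flexibility (CV of PC1), its mean
#' network niche, and the site's floral log-ratio. Continuous predictors are
#' mean-centered over the included rows.
#'
#' @param visits visitation table.
#' @param floral floral survey table.
#' @param pyrodiv data.frame `site`, `pyrodiversity`.
#' @param niche data.frame from [niche_summary()].
#' @param years character pair `(severe, extreme)`.
#' @return data.frame with raw and `_c`-suffixed centered columns.
#' @export
assemble_resistance_table <- function(visits, floral, pyrodiv, niche, years) {
  combos <- unique(visits[visits$count > 0, c("site", "pollinator")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    lr <- population_log_ratio(visits, combos$site[i], combos$pollinator[i],
                               years)
    if (is.na(lr)) return(NULL)
    data.frame(pollinator = combos$pollinator[i], site = combos$site[i],
               log_ratio = lr, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) stop("no species present at any site in both years")
  miss <- setdiff(tab$site, pyrodiv$site)
  if (length(miss)) stop("sites missing from pyrodiversity table: ",
                         paste(miss, collapse = ", "))
  tab$pyrodiversity <- pyrodiv$pyrodiversity[match(tab$site, pyrodiv$site)]
  idx <- match(tab$pollinator, niche$pollinator)
  tab$partner_beta <- niche$partner_beta[idx]
  tab$cv_pc1 <- niche$cv_pc1[idx]
  tab$mean_pc1 <- niche$mean_pc1[idx]
  flr <- floral_log_ratio(floral, years)
  tab$floral_lr <- flr$floral_log_ratio[match(tab$site, flr$site)]
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  tab <- .center_cols(tab, c("pyrodiversity", "partner_beta", "cv_pc1",
                             "mean_pc1", "floral_lr"))
  rownames(tab) <- NULL
  tab
}

#' Fit a random-intercept linear mixed model
#'
#' REML fit with a single random intercept; fixed-effect tests use
#' Satterthwaite-approximated denominator degrees of freedom. When the
#' between-group variance is estimated at the zero boundary (singular fit) a
#' warning is attached and the fixed effects coincide with ordinary least
#' squares.
#'
#' @param formula fixed-effects formula (response and fixed terms only).
#' @param data model table.
#' @param group name of the random-intercept grouping column.
#' @return object of class `lmm_fit`: list with `coefficients` (term,
#'   estimate, se, t, df, p), `varcor` (variance components), `singular`,
#'   `group`, and the underlying `merMod` in `$model`.
#' @export
fit_lmm <- function(formula, data, group) {
  if (!group %in% names(data)) stop("grouping column not in data: ", group)
  if (length(unique(data[[group]])) < 2)
    stop("random effect needs at least two groups")
  full <- stats::as.formula(paste(deparse(formula, width.cutoff = 500),
                                  "+ (1 |", group, ")"))
  fit <- suppressMessages(lmerTest::lmer(full, data = data, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: random-intercept variance estimated at 0")
  ct <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = data.frame(term = rownames(ct),
                              estimate = ct[, "Estimate"],
                              se = ct[, "Std. Error"],
                              t = ct[, "t value"],
                              df = ct[, "df"],
                              p = ct[, "Pr(>|t|)"],
                              row.names = NULL, stringsAsFactors = FALSE),
    varcor = vc[, c("grp", "vcov")],
    singular = singular, group = group, model = fit),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (REML, Satterthwaite df); random intercept:",
      x$group, if (x$singular) "[singular]" else "", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Variance inflation factors
#'
#' `1 / (1 - R^2_k)` for each predictor regressed on all the others. Perfect
#' collinearity yields `Inf`.
#'
#' @param x numeric model matrix of predictors (no intercept column).
#' @return named numeric vector of VIF scores.
#' @export
vif_scores <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("VIF needs at least two predictors")
  vapply(seq_len(ncol(x)), function(k) {
    r2 <- summary(stats::lm(x[, k] ~ x[, -k, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(x))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a dataset, then runs pyrodiversity, per-survey
#' network metrics, site-year species roles and flexibility, co-extinction
#' robustness, and the mixed models: each network metric ~ centered
#' pyrodiversity x drought (site random intercept) and ~ centered richness;
#' robustness ~ pyrodiversity x drought; and population log-ratio ~
#' pyrodiversity x partner flexibility + pyrodiversity x niche flexibility +
#' mean niche + floral log-ratio (species random intercept). VIF of each
#' model's fixed-effect matrix is checked against the < 2 collinearity
#' guideline.
#'
#' @param params a [sim_params()]; ignored when `data` is supplied.
#' @param data optional precomputed dataset (as from [gen_dataset()], or a
#'   list with `visits`, `floral`, `pyrodiv`).
#' @param radius_m pyrodiversity buffer radius.
#' @return list of class `pyronet_results`: tables (`pyrodiv`, `metrics`,
#'   `roles`, `niche`, `robustness`, `resistance`), fitted models
#'   (`metric_models`, `richness_models`, `robustness_models`,
#'   `resistance_model`), `vif` (per model), and `log` (character).
#' @export
run_full_analysis <- function(params = sim_params(), data = NULL,
                              radius_m = 150) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  if (is.null(data)) {
    note("stage: simulate (seed ", params$seed, ")")
    data <- gen_dataset(params, radius_m)
  }
  years <- if (!is.null(params$years)) unname(params$years)
  else sort(unique(data$visits$year))
  pyro <- data$pyrodiv
  note("stage: network metrics")
  met <- metrics_table(data$visits)
  met_tab <- assemble_metrics_table(met, pyro, years)
  note("stage: species roles")
  niche <- niche_summary(data$visits, years[1])
  note("stage: coextinction")
  rob <- robustness_table(data$visits, data$floral, years[1])
  rob$pyrodiversity <- pyro$pyrodiversity[match(rob$site, pyro$site)]
  rob$drought <- factor(ifelse(rob$year == years[2], "extreme", "severe"),
                        levels = c("severe", "extreme"))
  rob <- .center_cols(rob, "pyrodiversity")
  note("stage: resistance table")
  res_tab <- assemble_resistance_table(data$visits, data$floral, pyro, niche,
                                       years)
  note("stage: models")
  metric_models <- list(); richness_models <- list(); vifs <- list()
  for (lev in c("plant", "pollinator")) {
    sub <- met_tab[met_tab$level == lev, , drop = FALSE]
    for (m in c("redundancy", "complementarity", "generalization")) {
      f <- stats::as.formula(paste(m, "~ pyrodiversity_c * drought"))
      key <- paste(lev, m, sep = ".")
      metric_models[[key]] <- fit_lmm(f, sub, "site")
      mm <- stats::model.matrix(metric_models[[key]]$model)[, -1, drop = FALSE]
      vifs[[key]] <- vif_scores(mm)
      richness_models[[key]] <-
        fit_lmm(stats::as.formula(paste(m, "~ richness_c")), sub, "site")
    }
  }
  robustness_models <- lapply(c(observed = "observed", potential = "potential"),
                              function(kind) {
    fit_lmm(robustness ~ pyrodiversity_c * drought,
            rob[rob$kind == kind, , drop = FALSE], "site")
  })
  for (kind in names(robustness_models)) {
    mm <- stats::model.matrix(robustness_models[[kind]]$model)[, -1, drop = FALSE]
    vifs[[paste0("robustness.", kind)]] <- vif_scores(mm)
  }
  resistance_model <- fit_lmm(
    log_ratio ~ pyrodiversity_c * partner_beta_c + pyrodiversity_c * cv_pc1_c +
      mean_pc1_c + floral_lr_c,
    res_tab, "pollinator")
  mm <- stats::model.matrix(resistance_model$model)[, -1, drop = FALSE]
  vifs[["resistance"]] <- vif_scores(mm)
  max_vif <- max(unlist(vifs))
  note("VIF check: max finite VIF = ", format(max_vif, digits = 4),
       if (max_vif < 2) " (< 2, passes collinearity guideline)" else
         " (>= 2: collinearity flag)")
  structure(list(pyrodiv = pyro, metrics = met, metrics_wide = met_tab,
                 niche = niche, robustness = rob, resistance = res_tab,
                 metric_models = metric_models,
                 richness_models = richness_models,
                 robustness_models = robustness_models,
                 resistance_model = resistance_model,
                 vif = vifs, log = log),
            class = "pyronet_results")
}

#' @export
print.pyronet_results <- function(x, ...) {
  cat("pyronet results:", nrow(x$pyrodiv), "sites;",
      nrow(x$resistance), "species x site resistance rows\n")
  cat("pyrodiversity x partner-flexibility interaction:\n")
  cf <- x$resistance_model$coefficients
  print(cf[grepl(":", cf$term), ], digits = 4)
  invisible(x)
}
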