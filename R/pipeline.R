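#' Partition sites into forested and developed land-cover groups
#'
#' The `n_per_group` sites with the highest PC1 scores form the forested
#' group, the `n_per_group` lowest form the developed group, and sites with
#' intermediate scores are excluded so the two groups represent the most
#' characteristic ends of the gradient. Boundary ties are broken towards the
#' lexicographically smaller site id.
#'
#' @param scores A `"landcover_scores"` object or its `scores` data.frame.
#' @param n_per_group Sites per group (default 8, i.e. 8/8/8 at 24 sites).
#' @return A `data.frame` with `site` and `group`
#'   (`forested`/`developed`/`excluded`).
#' @export
assign_groups <- function(scores, n_per_group = 8L) {
  sc <- if (inherits(scores, "landcover_scores")) scores$scores else scores
  n <- nrow(sc)
  if (n < 2 * n_per_group)
    stop("configuration error: need at least ", 2 * n_per_group, " sites",
         call. = FALSE)
  group <- rep("excluded", n)
  ord_hi <- order(-sc$PC1, sc$site)
  ord_lo <- order(sc$PC1, sc$site)
  group[ord_hi[seq_len(n_per_group)]] <- "forested"
  group[ord_lo[seq_len(n_per_group)]] <- "developed"
  data.frame(site = sc$site, group = group, stringsAsFactors = FALSE)
}

#' Species shared between land-cover groups above a total-count filter
#'
#' A species is retained if it occurs (count >= 1) in both groups and its
#' combined total count exceeds `min_total` (or meets it when
#' `strict = FALSE`).
#'
#' @param group_agg Group-level aggregated activity from
#'   [aggregate_activity()] with groups `forested` and `developed`.
#' @param min_total Total-count filter (default 100).
#' @param strict If `TRUE` (default) require total > `min_total`, else
#'   >= `min_total`.
#' @return Character vector of retained species ids (possibly empty, with a
#'   message).
#' @export
filter_shared_species <- function(group_agg, min_total = 100L,
                                  strict = TRUE) {
  tot <- tapply(group_agg$count,
                list(group_agg$species, group_agg$group), sum)
  tot[is.na(tot)] <- 0
  if (!all(c("forested", "developed") %in% colnames(tot)))
    stop("group_agg must contain groups 'forested' and 'developed'",
         call. = FALSE)
  shared <- tot[, "forested"] > 0 & tot[, "developed"] > 0
  comb <- rowSums(tot[, c("forested", "developed"), drop = FALSE])
  pass <- if (strict) comb > min_total else comb >= min_total
  keep <- rownames(tot)[shared & pass]
  if (!length(keep))
    message("no species retained by the shared-species filter")
  sort(keep)
}

#' Between-group comparison of species-level seasonality
#'
#' For every retained species, rarefies its forested and developed series to
#' the smaller of the two totals, fits the seasonal-trend-remainder model to
#' each replicate, and averages the relative seasonality variance per group.
#' The paired per-species values are compared with a Wilcoxon signed-rank
#' test (after a Shapiro-Wilk normality check on the differences), and
#' community synchrony is computed per status class and group from the
#' species' fitted seasonal components (and from the raw rarefied series).
#' Standardized seasonal curves (seasonal component / species total) and
#' their per-group means are returned for visual comparison of temporal
#' mismatch.
#'
#' @param table Station-level activity table (thresholding is applied
#'   internally with `cap`).
#' @param scores A `"landcover_scores"` object.
#' @param species_status `data.frame` with `species` and `status` columns.
#' @param n_per_group Sites per land-cover group.
#' @param min_total,strict Passed to [filter_shared_species()].
#' @param cap Threshold for [apply_threshold()].
#' @param n_rep Rarefaction replicates per species.
#' @param m Periods per annual cycle.
#' @param seed Optional integer seed.
#' @return Object of class `"group_comparison"`: list with `groups` (site
#'   partition), `species` (retained species with status and per-group
#'   relative seasonality variance), `wilcoxon` (from [paired_tests()], or
#'   `NULL` if too few species), `synchrony` (data.frame: status, group,
#'   phi on seasonal components, phi_raw on raw series, n_species),
#'   `standardized_curves` (list per group: species x period matrix) and
#'   `mean_curves` (list per group: mean standardized curve).
#' @export
run_group_comparison <- function(table, scores, species_status,
                                 n_per_group = 8L, min_total = 100L,
                                 strict = TRUE, cap = 500L, n_rep = 100L,
                                 m = 26L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- assign_groups(scores, n_per_group)
  gmap <- stats::setNames(ifelse(groups$group == "excluded", NA,
                                 groups$group), groups$site)
  tab <- apply_threshold(table, cap)
  gagg <- aggregate_activity(tab, level = "group", group_map = gmap)
  keep <- filter_shared_species(gagg, min_total = min_total,
                                strict = strict)
  status <- stats::setNames(species_status$status, species_status$species)
  periods <- sort(unique(gagg$period))
  gmat <- series_matrices(gagg)

  res <- lapply(keep, function(sp) {
    x_f <- gmat$forested[sp, ]
    x_d <- gmat$developed[sp, ]
    rr <- rarefy_between_groups(x_f, x_d, n_rep = n_rep)
    per_group <- lapply(rr[c("a", "b")], function(Rm) {
      rels <- numeric(nrow(Rm))
      seas_sum <- numeric(ncol(Rm))
      for (r in seq_len(nrow(Rm))) {
        d <- fit_tslm(Rm[r, ], m = m)
        rels[r] <- component_variances(d)$relative["seasonal"]
        seas_sum <- seas_sum + d$seasonal
      }
      list(rel_seasonality = mean(rels), seasonal = seas_sum / nrow(Rm))
    })
    list(species = sp,
         rel_forested = per_group$a$rel_seasonality,
         rel_developed = per_group$b$rel_seasonality,
         seasonal_forested = per_group$a$seasonal,
         seasonal_developed = per_group$b$seasonal,
         total = rr$target)
  })
  sp_tab <- data.frame(
    species = keep,
    status = unname(status[keep]),
    rel_seasonality_forested = vapply(res, `[[`, 0, "rel_forested"),
    rel_seasonality_developed = vapply(res, `[[`, 0, "rel_developed"),
    total_rarefied = vapply(res, `[[`, 0, "total"),
    stringsAsFactors = FALSE)

  wil <- if (nrow(sp_tab) >= 5) {
    tryCatch(paired_tests(sp_tab$rel_seasonality_forested,
                          sp_tab$rel_seasonality_developed),
             error = function(e) NULL)
  } else NULL

  curves <- list(
    forested = t(vapply(res, function(r)
      r$seasonal_forested / r$total, numeric(length(periods)))),
    developed = t(vapply(res, function(r)
      r$seasonal_developed / r$total, numeric(length(periods)))))
  for (g in names(curves)) rownames(curves[[g]]) <- keep
  mean_curves <- lapply(curves, colMeans)

  sync <- do.call(rbind, lapply(c("native", "alien", "uncertain"),
                                function(st) {
    sp_st <- keep[status[keep] == st]
    out <- data.frame(status = st,
                      group = c("forested", "developed"),
                      phi = NA_real_, phi_raw = NA_real_,
                      n_species = length(sp_st),
                      stringsAsFactors = FALSE)
    if (length(sp_st) >= 2) {
      seas_f <- t(vapply(res[match(sp_st, keep)], `[[`,
                         numeric(length(periods)), "seasonal_forested"))
      seas_d <- t(vapply(res[match(sp_st, keep)], `[[`,
                         numeric(length(periods)), "seasonal_developed"))
      out$phi <- c(loreau_synchrony(seas_f)$phi,
                   loreau_synchrony(seas_d)$phi)
      out$phi_raw <- c(
        loreau_synchrony(gmat$forested[sp_st, , drop = FALSE])$phi,
        loreau_synchrony(gmat$developed[sp_st, , drop = FALSE])$phi)
    }
    out
  }))

  structure(list(groups = groups, species = sp_tab, wilcoxon = wil,
                 synchrony = sync, standardized_curves = curves,
                 mean_curves = mean_curves),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Between-group seasonality comparison:", nrow(x$species),
      "retained species\n")
  print(table(x$species$status))
  if (!is.null(x$wilcoxon))
    cat(sprintf("Wilcoxon signed-rank: V = %.1f, p = %.4g\n",
                x$wilcoxon$statistic, x$wilcoxon$p_value))
  invisible(x)
}

#' Run the full site-level and group-level analysis
#'
#' End-to-end orchestration: land-cover ordination; thresholding and
#' station-to-site aggregation; individual-based rarefaction of every site
#' to the minimum site total; per-site variability metrics (CV, temporal
#' beta diversity with SCBD, richness, time-series component variances)
#' averaged over rarefied replicates; OLS + AICc regressions of each
#' response on PC1/PC2 with Moran's I permutation diagnostics on the
#' selected model's residuals; and the between-group species-level
#' seasonality comparison. Total activity is modelled on its natural log
#' before rarefaction; variability metrics are computed after rarefaction.
#'
#' @param counts Station-level activity table (`site`, `station`,
#'   `species`, `period`, `count`).
#' @param meta Site metadata with coordinates and land-cover proportions.
#' @param species_status `data.frame` with `species` and `status`.
#' @param cap Count threshold per species, station and period.
#' @param n_rep Rarefaction replicates.
#' @param m Periods per annual cycle.
#' @param n_per_group,min_total,strict Group-comparison settings.
#' @param n_perm Permutations for the Moran's I test.
#' @param seed Integer seed controlling rarefaction and permutations.
#' @return Object of class `"seasonvar_result"`: list with `scores`,
#'   `site_metrics` (one row per site), `regressions` (list of
#'   `"lc_regression"` per response), `moran` (list of `"moran_test"` per
#'   response), `group_comparison`, `rarefaction_target`, `seed`.
#' @export
run_full_analysis <- function(counts, meta, species_status,
                              cap = 500L, n_rep = 100L, m = 26L,
                              n_per_group = 8L, min_total = 100L,
                              strict = TRUE, n_perm = 999L, seed = 1L) {
  set.seed(seed)
  scores <- landcover_scores(meta)
  tab <- apply_threshold(counts, cap)
  sagg <- aggregate_activity(tab, level = "site")
  mats <- series_matrices(sagg)
  site_order <- scores$scores$site
  mats <- mats[site_order]
  totals <- vapply(mats, sum, numeric(1))
  target <- min(totals)
  status <- stats::setNames(species_status$status, species_status$species)

  sv <- lapply(mats, site_variability, target = target, n_rep = n_rep,
               status = status, m = m)
  site_metrics <- data.frame(
    site = site_order,
    total_activity = unname(totals),
    log_total_activity = log(unname(totals)),
    cv = vapply(sv, `[[`, 0, "cv"),
    bd_total = vapply(sv, `[[`, 0, "bd_total"),
    var_seasonal = vapply(sv, function(s) s$variance_absolute["seasonal"],
                          0),
    var_trend = vapply(sv, function(s) s$variance_absolute["trend"], 0),
    var_remainder = vapply(sv, function(s)
      s$variance_absolute["remainder"], 0),
    rel_seasonal = vapply(sv, function(s) s$variance_relative["seasonal"],
                          0),
    rel_trend = vapply(sv, function(s) s$variance_relative["trend"], 0),
    rel_remainder = vapply(sv, function(s)
      s$variance_relative["remainder"], 0),
    richness_observed = vapply(sv, function(s) s$richness$observed, 0),
    richness_rarefied = vapply(sv, function(s) s$richness$rarefied, 0),
    richness_extrapolated = vapply(sv, function(s)
      s$richness$extrapolated, 0),
    scbd_native = vapply(sv, function(s) s$scbd_by_status["native"], 0),
    scbd_alien = vapply(sv, function(s) s$scbd_by_status["alien"], 0),
    scbd_uncertain = vapply(sv, function(s) s$scbd_by_status["uncertain"],
                            0),
    stringsAsFactors = FALSE)
  for (st in c("native", "alien", "uncertain")) {
    for (variant in c("observed", "rarefied", "extrapolated")) {
      site_metrics[[paste("richness", st, variant, sep = "_")]] <-
        vapply(sv, function(s) s$richness_by_status[[st]][[variant]],
               numeric(1))
    }
  }
  rownames(site_metrics) <- NULL

  responses <- c("log_total_activity", "cv", "bd_total",
                 "var_seasonal", "var_trend", "var_remainder",
                 "rel_seasonal", "rel_trend", "rel_remainder",
                 "richness_observed", "richness_rarefied",
                 "richness_extrapolated",
                 "scbd_native", "scbd_alien", "scbd_uncertain",
                 paste("richness",
                       rep(c("native", "alien", "uncertain"), each = 3),
                       c("observed", "rarefied", "extrapolated"),
                       sep = "_"))
  W <- spatial_weights(meta[match(site_order, meta$site), c("x", "y")])
  regressions <- list()
  moran <- list()
  for (resp in responses) {
    y <- site_metrics[[resp]]
    if (anyNA(y) || stats::var(y) == 0) next
    reg <- fit_ols_aicc(y, scores, response = resp)
    regressions[[resp]] <- reg
    moran[[resp]] <- morans_i_permutation(stats::residuals(reg$fit),
                                          W = W, n_perm = n_perm)
  }

  gc_res <- run_group_comparison(counts, scores, species_status,
                                 n_per_group = n_per_group,
                                 min_total = min_total, strict = strict,
                                 cap = cap, n_rep = n_rep, m = m)

  structure(list(scores = scores, site_metrics = site_metrics,
                 regressions = regressions, moran = moran,
                 group_comparison = gc_res,
                 rarefaction_target = target, seed = seed),
            class = "seasonvar_result")
}

#' @export
print.seasonvar_result <- function(x, ...) {
  cat("seasonvar full analysis:", nrow(x$site_metrics), "sites, ",
      "rarefaction target", x$rarefaction_target, "\n")
  cat("Selected models (response: predictors, R^2):\n")
  for (r in names(x$regressions))
    cat(sprintf("  %-22s %-8s R^2 = %.3f\n", r, x$regressions[[r]]$selected,
                x$regressions[[r]]$r_squared))
  invisible(x)
}

#' Write the result bundle as tidy CSV tables plus a run manifest
#'
#' Writes `site_metrics.csv`, `regressions.csv` (one row per response x
#' candidate model), `selected_models.csv`, `moran.csv`,
#' `group_species.csv`, `synchrony.csv`, `mean_curves.csv` and
#' `manifest.txt` (seed, package version, rarefaction target, config hash).
#'
#' @param result A `"seasonvar_result"` object.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE)
  w(result$site_metrics, "site_metrics.csv")
  reg_tab <- do.call(rbind, lapply(names(result$regressions), function(r) {
    tb <- result$regressions[[r]]$table
    tb$response <- r
    tb
  }))
  w(reg_tab, "regressions.csv")
  sel <- do.call(rbind, lapply(names(result$regressions), function(r) {
    reg <- result$regressions[[r]]
    data.frame(response = r, selected = reg$selected,
               r_squared = reg$r_squared,
               p_PC1 = if ("PC1" %in% names(reg$p_values))
                 reg$p_values[["PC1"]] else NA,
               p_PC2 = if ("PC2" %in% names(reg$p_values))
                 reg$p_values[["PC2"]] else NA,
               moran_I = result$moran[[r]]$I,
               moran_p = result$moran[[r]]$p_value,
               stringsAsFactors = FALSE)
  }))
  w(sel, "selected_models.csv")
  gc_res <- result$group_comparison
  w(gc_res$species, "group_species.csv")
  w(gc_res$synchrony, "synchrony.csv")
  mc <- data.frame(period = seq_along(gc_res$mean_curves$forested),
                   forested = gc_res$mean_curves$forested,
                   developed = gc_res$mean_curves$developed)
  w(mc, "mean_curves.csv")
  manifest <- c(
    paste("package_version:", as.character(utils::packageVersion("seasonvar"))),
    paste("seed:", result$seed),
    paste("rarefaction_target:", result$rarefaction_target),
    paste("sites:", nrow(result$site_metrics)),
    paste("site_metrics_md5:",
          unname(tools::md5sum(file.path(dir, "site_metrics.csv")))))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
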