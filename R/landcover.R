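#' Arcsine square-root transformation of proportions
#'
#' Variance-stabilising transform used on land-cover proportions before PCA.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return `asin(sqrt(p))`, in radians (0 maps to 0, 1 to `pi/2`).
#' @examples
#' arcsine_sqrt(c(0, 0.5, 1))
#' @export
arcsine_sqrt <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("domain error: proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Score sites on the anthropogenic land-cover gradient
#'
#' Runs an unscaled (covariance) principal component analysis on the
#' arcsine-square-root transformed land-cover proportions and returns the
#' first two axes. Proportions are first renormalised over the seven land
#' classes, so sites whose original buffers included ocean are handled
#' consistently. Axis signs are fixed by convention: PC1 is oriented so the
#' forest loading is positive (high PC1 = forested, low PC1 = developed);
#' PC2 so that the summed grass + agriculture loading is positive (high PC2 =
#' rural, low PC2 = urban).
#'
#' @param meta Site metadata `data.frame` with a `site` column and the seven
#'   land-cover proportion columns (`forest`, `agriculture`, `urban`,
#'   `grass`, `sand`, `freshwater`, `misc`).
#' @return An object of class `"landcover_scores"`: a list with `scores`
#'   (data.frame `site`, `PC1`, `PC2`), `loadings` (7 x 2 matrix),
#'   `variance_explained` (length-2 fractions), `center` (column means of the
#'   transformed matrix) and `full` (the complete `prcomp` fit).
#' @export
landcover_scores <- function(meta) {
  if (!all(land_classes %in% names(meta)))
    stop("meta must contain the 7 land-cover proportion columns",
         call. = FALSE)
  if (nrow(meta) < 3)
    stop("need at least 3 sites for a land-cover ordination", call. = FALSE)
  P <- as.matrix(meta[, land_classes])
  P <- P / rowSums(P)
  X <- arcsine_sqrt(P)
  if (sum(apply(X, 2, stats::var)) < 1e-12)
    stop("degenerate input: land-cover matrix has no variance across sites",
         call. = FALSE)
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  # sign conventions so regression slopes are comparable across runs
  if (fit$rotation["forest", 1] < 0) {
    fit$rotation[, 1] <- -fit$rotation[, 1]
    fit$x[, 1] <- -fit$x[, 1]
  }
  if (ncol(fit$rotation) >= 2 &&
      sum(fit$rotation[c("grass", "agriculture"), 2]) < 0) {
    fit$rotation[, 2] <- -fit$rotation[, 2]
    fit$x[, 2] <- -fit$x[, 2]
  }
  n_axes <- min(2L, ncol(fit$x))
  scores <- data.frame(site = meta$site,
                       PC1 = fit$x[, 1],
                       PC2 = if (n_axes >= 2) fit$x[, 2] else 0,
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 loadings = fit$rotation[, seq_len(n_axes), drop = FALSE],
                 variance_explained = ve[seq_len(n_axes)],
                 center = fit$center,
                 full = fit),
            class = "landcover_scores")
}

#' @export
print.landcover_scores <- function(x, ...) {
  cat("Land-cover gradient scores (", nrow(x$scores), " sites)\n", sep = "")
  cat(sprintf("  variance explained: PC1 = %.1f%%, PC2 = %.1f%%\n",
              100 * x$variance_explained[1],
              100 * ifelse(length(x$variance_explained) > 1,
                           x$variance_explained[2], 0)))
  invisible(x)
}

#' Append PC1/PC2 scores to a site metadata table
#'
#' @param meta Site metadata `data.frame`.
#' @param scores A `"landcover_scores"` object; computed from `meta` if
#'   missing.
#' @return `meta` with `PC1` and `PC2` columns appended.
#' @export
add_landcover_scores <- function(meta, scores = landcover_scores(meta)) {
  idx <- match(meta$site, scores$scores$site)
  meta$PC1 <- scores$scores$PC1[idx]
  meta$PC2 <- scores$scores$PC2[idx]
  meta
}
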