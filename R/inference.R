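#' OLS regression on land-cover scores with AICc model selection
#'
#' Fits the candidate models `y ~ 1`, `y ~ PC1`, `y ~ PC2` and
#' `y ~ PC1 + PC2` by ordinary least squares and selects the one with the
#' lowest AICc, `AIC + 2k(k+1)/(n - k - 1)`, where `k` counts all estimated
#' parameters including the residual variance. With two dozen sites the
#' small-sample correction matters; it vanishes as `n` grows.
#'
#' @param y Numeric response vector, one value per site (no missing values).
#' @param scores A `"landcover_scores"` object, or a `data.frame` with
#'   `site`, `PC1`, `PC2` columns aligned with `y`.
#' @param response Optional response name carried into the result.
#' @return Object of class `"lc_regression"`: list with `response`,
#'   `selected` (name of the chosen candidate), `fit` (its `lm` object),
#'   `coefficients`, `r_squared`, `p_values` (per coefficient),
#'   `table` (data.frame of candidate, k, AICc, r_squared), `n`.
#' @export
fit_ols_aicc <- function(y, scores, response = deparse(substitute(y))) {
  sc <- if (inherits(scores, "landcover_scores")) scores$scores else scores
  n <- length(y)
  if (n != nrow(sc))
    stop("response and scores must cover the same sites", call. = FALSE)
  if (anyNA(y))
    stop("missing responses are not allowed", call. = FALSE)
  if (n < 6)
    stop("need at least 6 sites", call. = FALSE)
  dat <- data.frame(y = y, PC1 = sc$PC1, PC2 = sc$PC2)
  candidates <- list(`1` = y ~ 1, PC1 = y ~ PC1, PC2 = y ~ PC2,
                     `PC1+PC2` = y ~ PC1 + PC2)
  rows <- lapply(names(candidates), function(nm) {
    fit <- stats::lm(candidates[[nm]], data = dat)
    k <- attr(stats::logLik(fit), "df")  # slopes + intercept + sigma^2
    if (n - k - 1 <= 0) {
      warning("skipping candidate '", nm, "': n - k - 1 <= 0")
      return(NULL)
    }
    aicc <- stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
    list(candidate = nm, fit = fit, k = k, aicc = aicc,
         r2 = summary(fit)$r.squared)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no admissible candidate model", call. = FALSE)
  tab <- data.frame(candidate = vapply(rows, `[[`, "", "candidate"),
                    k = vapply(rows, `[[`, 0, "k"),
                    AICc = vapply(rows, `[[`, 0, "aicc"),
                    r_squared = vapply(rows, `[[`, 0, "r2"),
                    stringsAsFactors = FALSE)
  best <- rows[[which.min(tab$AICc)]]
  coefs <- summary(best$fit)$coefficients
  structure(list(response = response,
                 selected = best$candidate,
                 fit = best$fit,
                 coefficients = stats::coef(best$fit),
                 r_squared = best$r2,
                 p_values = coefs[, "Pr(>|t|)"],
                 table = tab,
                 n = n),
            class = "lc_regression")
}

#' @export
print.lc_regression <- function(x, ...) {
  cat("Land-cover regression:", x$response, "\n")
  cat("  selected:", x$selected, sprintf(" (R^2 = %.3f)\n", x$r_squared))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Spatial weight matrix from site coordinates
#'
#' Row-standardized inverse Euclidean distance weights by default; the
#' k-nearest-neighbour alternative gives each site equal weight over its
#' `k` nearest sites. Duplicate coordinates receive the smallest nonzero
#' inter-site distance as a floor (with a warning) so inverse distances stay
#' finite.
#'
#' @param coords Two-column matrix/data.frame of projected x/y (metres).
#' @param scheme `"idw"` or `"knn"`.
#' @param k Number of neighbours for `scheme = "knn"`.
#' @param row_standardize Scale each row to sum to 1.
#' @return An `n x n` weight matrix with zero diagonal.
#' @export
spatial_weights <- function(coords, scheme = c("idw", "knn"), k = 4,
                            row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    floor_d <- if (any(off > 0)) min(off[off > 0]) else 1
    warning("duplicate coordinates: applying minimum-distance floor ",
            signif(floor_d, 3))
    D[D == 0] <- floor_d
  }
  if (scheme == "idw") {
    W <- 1 / D
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(min(k, n - 1))]
      W[i, setdiff(seq_len(n), i)[nb]] <- 1
    }
  }
  diag(W) <- 0
  if (row_standardize) W <- W / rowSums(W)
  W
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / W_sum) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`. Under spatial randomness its expectation is
#' `-1/(n - 1)`.
#'
#' @param x Numeric vector (typically regression residuals), one per site.
#' @param coords Site coordinates (projected plane), or `NULL` when `W` is
#'   supplied.
#' @param W Optional precomputed weight matrix from [spatial_weights()].
#' @param ... Passed to [spatial_weights()].
#' @return The Moran's I statistic (scalar).
#' @export
morans_i <- function(x, coords = NULL, W = NULL, ...) {
  n <- length(x)
  if (n < 4) stop("need at least 4 sites", call. = FALSE)
  if (is.null(W)) W <- spatial_weights(coords, ...)
  z <- x - mean(x)
  s2 <- sum(z^2)
  if (s2 == 0)
    stop("zero-variance input: Moran's I undefined", call. = FALSE)
  (n / sum(W)) * as.numeric(z %*% W %*% z) / s2
}

#' Permutation test of Moran's I
#'
#' Recomputes Moran's I over random permutations of `x` across sites and
#' returns a two-sided permutation p-value centred on the null expectation
#' `E[I] = -1/(n - 1)`:
#' `p = (1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (n_perm + 1)`.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed.
#' @return Object of class `"moran_test"`: list with `I`, `expected`,
#'   `p_value`, `n_perm`, `perm_I` (the permutation distribution).
#' @export
morans_i_permutation <- function(x, coords = NULL, n_perm = 999L,
                                 seed = NULL, W = NULL, ...) {
  if (n_perm < 99)
    stop("configuration error: n_perm must be >= 99", call. = FALSE)
  n <- length(x)
  if (is.null(W)) W <- spatial_weights(coords, ...)
  if (!is.null(seed)) set.seed(seed)
  i_obs <- morans_i(x, W = W)
  z <- x - mean(x)
  s2 <- sum(z^2)
  scale_f <- n / sum(W)
  # all permutations at once: I = (n/W_sum) * z'Wz / z'z for permuted z
  P <- vapply(seq_len(n_perm), function(r) z[sample.int(n)], numeric(n))
  i_perm <- scale_f * colSums(P * (W %*% P)) / s2
  e_i <- -1 / (n - 1)
  p <- (1 + sum(abs(i_perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)
  structure(list(I = i_obs, expected = e_i, p_value = p, n_perm = n_perm,
                 perm_I = i_perm),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4f (%d perms)\n",
              x$I, x$expected, x$p_value, x$n_perm))
  invisible(x)
}

#' Paired comparison with a normality check
#'
#' Runs a Shapiro-Wilk test on the paired differences to flag
#' non-normality, then a two-sided Wilcoxon signed-rank test (zero
#' differences dropped, mid-ranks for ties; exact null distribution for
#' <= 25 non-zero untied differences, otherwise normal approximation with
#' continuity correction).
#'
#' @param x_a,x_b Equal-length paired numeric vectors (e.g. one value per
#'   species in each of two land-cover groups).
#' @return List with `n_pairs`, `n_nonzero`, `shapiro_p`,
#'   `normal` (logical flag at the 0.05 level), `statistic` (Wilcoxon V),
#'   `p_value`, `exact` (whether the exact distribution was used),
#'   `median_difference`.
#' @export
paired_tests <- function(x_a, x_b) {
  if (length(x_a) != length(x_b))
    stop("paired vectors must have equal length", call. = FALSE)
  d <- x_a - x_b
  nz <- d[d != 0]
  if (length(nz) < 5)
    stop("degenerate input: need >= 5 non-zero differences", call. = FALSE)
  sh <- stats::shapiro.test(d)
  exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(x_a, x_b, paired = TRUE, exact = exact,
                       correct = TRUE))
  list(n_pairs = length(d), n_nonzero = length(nz),
       shapiro_p = sh$p.value, normal = sh$p.value > 0.05,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact, median_difference = stats::median(d))
}
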