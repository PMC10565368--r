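#' Decompose a count series into trend, seasonal and remainder components
#'
#' Fits the time-series linear model
#' `y(t) = b0 + b1 * t + gs * sin(2*pi*t/m) + gc * cos(2*pi*t/m) + e(t)`
#' by ordinary least squares, i.e. a linear trend plus an annual Fourier
#' term of order K = 1, which models seasonality as a sine wave of arbitrary
#' phase. Short series sampled at fine resolution do not support richer
#' seasonal shapes, which is why the minimal harmonic is used. The series is
#' decomposed additively: `trend(t) = b0 + b1 * t` (the intercept is folded
#' into the trend, where it cannot affect any variance),
#' `seasonal(t) = gs * sin(2*pi*t/m) + gc * cos(2*pi*t/m)`, and
#' `remainder(t) = y(t) - trend(t) - seasonal(t)`. Missing values are
#' excluded from the fit; trend and seasonal components are still evaluated
#' at those times.
#'
#' @param y Numeric series indexed by sampling period `t = 1..length(y)`
#'   (may contain `NA`).
#' @param m Periods per annual cycle (26 for biweekly sampling).
#' @param K Harmonic order; only the default `K = 1` is supported by the
#'   downstream variance interpretation, higher orders add further Fourier
#'   pairs.
#' @return Object of class `"tslm_decomp"`: list with `coefficients`
#'   (`b0`, `b1`, `gs`, `gc`, and further pairs if `K > 1`), `trend`,
#'   `seasonal`, `remainder`, `fitted` (vectors over `t`), `m`, `K`.
#' @examples
#' t <- 1:52
#' d <- fit_tslm(sin(2 * pi * t / 26), m = 26)
#' round(d$coefficients, 8)
#' @export
fit_tslm <- function(y, m = 26L, K = 1L) {
  t_idx <- seq_along(y)
  obs <- !is.na(y)
  if (sum(obs) < 2 * K + 3)
    stop("fit error: need at least ", 2 * K + 3, " non-missing points",
         call. = FALSE)
  if (diff(range(t_idx[obs])) < m)
    stop("fit error: series must span more than one annual cycle",
         call. = FALSE)
  Xs <- sapply(seq_len(K), function(k) sin(2 * pi * k * t_idx / m))
  Xc <- sapply(seq_len(K), function(k) cos(2 * pi * k * t_idx / m))
  X <- cbind(1, t_idx, Xs, Xc)
  colnames(X) <- c("b0", "b1", paste0("gs", seq_len(K)),
                   paste0("gc", seq_len(K)))
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  if (fit$rank < ncol(X))
    stop("fit error: rank-deficient design", call. = FALSE)
  beta <- fit$coefficients
  trend <- beta["b0"] + beta["b1"] * t_idx
  seasonal <- as.vector(cbind(Xs, Xc) %*%
                          beta[c(paste0("gs", seq_len(K)),
                                 paste0("gc", seq_len(K)))])
  fitted <- trend + seasonal
  remainder <- y - fitted
  if (K == 1) names(beta) <- c("b0", "b1", "gs", "gc")
  structure(list(coefficients = beta, trend = trend, seasonal = seasonal,
                 remainder = remainder, fitted = fitted, y = y,
                 m = m, K = K),
            class = "tslm_decomp")
}

#' @export
print.tslm_decomp <- function(x, ...) {
  cat("Time-series linear model decomposition (m =", x$m, ", K =", x$K,
      ")\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Absolute and relative variances of the temporal components
#'
#' The absolute variance of each component (seasonal, trend, remainder) is
#' its population variance (denominator `n`) over the non-missing periods,
#' so that a pure sinusoid of amplitude `A` observed over whole cycles has
#' seasonal variance exactly `A^2/2`; the relative variance is each
#' component's share of the summed component variances and is identical
#' under either variance convention. Relative variances describe what *kind*
#' of variability a series has (cyclic, directional or stochastic)
#' independent of its magnitude.
#'
#' @param d A `"tslm_decomp"` object.
#' @return List with `absolute` (named vector `seasonal`, `trend`,
#'   `remainder`), `relative` (same names, summing to 1), and `degenerate`
#'   (`TRUE` when all component variances are zero, in which case the
#'   relative variances are `NA`).
#' @export
component_variances <- function(d) {
  stopifnot(inherits(d, "tslm_decomp"))
  obs <- !is.na(d$y)
  pvar <- function(x) mean((x - mean(x))^2)
  v <- c(seasonal = pvar(d$seasonal[obs]),
         trend = pvar(d$trend[obs]),
         remainder = pvar(d$remainder[obs]))
  tot <- sum(v)
  # all-flat decompositions leave only floating-point dust in the components
  degenerate <- tot <= 1e-12 * max(1, mean(d$y[obs])^2)
  rel <- if (degenerate) stats::setNames(rep(NA_real_, 3), names(v))
         else v / tot
  list(absolute = v, relative = rel, degenerate = degenerate)
}

#' Community synchrony (Loreau & de Mazancourt)
#'
#' `phi = var(sum_i x_i(t)) / (sum_i sd(x_i(t)))^2`, bounded in `[0, 1]`:
#' 1 when all species fluctuate in perfect proportion, 0 under perfect
#' compensation (the community total is constant).
#'
#' @param X Species x period matrix of series.
#' @return List with `phi` and `degenerate` (`TRUE` when every series is
#'   constant, leaving the statistic undefined as `NA`).
#' @export
loreau_synchrony <- function(X) {
  if (is.null(dim(X)) || nrow(X) < 2)
    stop("need at least 2 species series", call. = FALSE)
  sds <- apply(X, 1, stats::sd)
  denom <- sum(sds)^2
  if (denom == 0)
    return(list(phi = NA_real_, degenerate = TRUE))
  list(phi = stats::var(colSums(X)) / denom, degenerate = FALSE)
}

#' Standardize a seasonal component by total activity
#'
#' Scales a species' fitted seasonal curve by its total count so that curves
#' of abundant and rare species are comparable; the group-mean curve is the
#' average of the standardized curves across species.
#'
#' @param d A `"tslm_decomp"` object.
#' @param total The species' total count (> 0).
#' @return Numeric vector `seasonal(t) / total`.
#' @export
standardize_seasonal <- function(d, total) {
  stopifnot(inherits(d, "tslm_decomp"))
  if (!is.numeric(total) || length(total) != 1 || total <= 0)
    stop("total must be a positive scalar", call. = FALSE)
  d$seasonal / total
}
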