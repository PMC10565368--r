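#' Functional temporal variability (coefficient of variation)
#'
#' Variability of community activity at the aggregate scale: the sample
#' standard deviation of the summed counts over time divided by their mean.
#'
#' @param totals Numeric vector of community-total counts per period.
#' @param na.rm Drop missing periods before computing.
#' @return The dimensionless CV (>= 0).
#' @export
functional_cv <- function(totals, na.rm = TRUE) {
  if (na.rm) totals <- totals[!is.na(totals)]
  if (length(totals) < 2)
    stop("need at least 2 time points for a CV", call. = FALSE)
  m <- mean(totals)
  if (m == 0)
    stop("undefined CV: series mean is zero", call. = FALSE)
  stats::sd(totals) / m
}

#' Compositional temporal variability (Hellinger temporal beta diversity)
#'
#' Total variance of the community composition across time. Each time step's
#' composition is Hellinger-transformed (square root of within-step relative
#' abundances), columns are centred, and the total beta diversity is the
#' total sum of squares divided by `T - 1`. Species contributions to beta
#' diversity (SCBD) are each species' share of the total sum of squares; they
#' sum to 1.
#'
#' @param M Species x period count matrix.
#' @return List with `BD_total`, `SCBD` (named per species), and
#'   `n_steps_used` (time steps with nonzero totals retained).
#' @export
temporal_beta_diversity <- function(M) {
  if (is.null(dim(M)) || nrow(M) < 1)
    stop("M must be a species x period matrix", call. = FALSE)
  Y <- t(M)  # rows = time steps
  tot <- rowSums(Y)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " time step(s) with zero total")
    Y <- Y[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (nrow(Y) < 2)
    stop("need at least 2 time steps with nonzero totals", call. = FALSE)
  H <- sqrt(Y / tot)
  D <- scale(H, center = TRUE, scale = FALSE)
  ss_species <- colSums(D^2)
  ss_total <- sum(ss_species)
  bd <- ss_total / (nrow(Y) - 1)
  scbd <- if (ss_total > 0) ss_species / ss_total else
    rep(NA_real_, ncol(Y))
  names(scbd) <- colnames(Y)
  list(BD_total = bd, SCBD = scbd, n_steps_used = nrow(Y))
}

# Chao1-type estimate of undetected species from singletons/doubletons.
chao_f0 <- function(f1, f2, n) {
  if (f1 == 0) return(0)
  if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
  else ((n - 1) / n) * f1 * (f1 - 1) / 2
}

#' Observed, rarefied and extrapolated species richness
#'
#' Observed richness counts species with at least one individual; rarefied
#' richness is the mean observed richness over individual-based rarefaction
#' replicates; extrapolated richness is the Hill-number (q = 0) estimate at
#' an extended sample of `2n` individuals,
#' `S_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^n)`, where `f0` is the
#' Chao1-type estimate of undetected species from the singleton and
#' doubleton frequencies `f1`, `f2`.
#'
#' @param M Species x period count matrix of integer abundances.
#' @param target Rarefaction total (defaults to `sum(M)`, i.e. no
#'   subsampling).
#' @param n_rep Rarefaction replicates.
#' @param seed Optional integer seed for rarefaction.
#' @return List with `observed`, `rarefied`, `extrapolated`, `f1`, `f2`.
#' @export
richness_summary <- function(M, target = sum(M), n_rep = 100L, seed = NULL) {
  if (is.null(dim(M)) || length(M) == 0 || sum(M) == 0)
    stop("empty abundance matrix", call. = FALSE)
  abund <- rowSums(M)
  n <- sum(abund)
  s_obs <- sum(abund > 0)
  f1 <- sum(abund == 1)
  f2 <- sum(abund == 2)
  f0 <- chao_f0(f1, f2, n)
  extrap <- if (f0 == 0) s_obs else
    s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^n)
  if (target < n) {
    reps <- rarefy_matrix(M, target, n_rep = n_rep, seed = seed)
    rar <- mean(vapply(reps, function(R) sum(rowSums(R) > 0), numeric(1)))
  } else {
    rar <- s_obs
  }
  list(observed = s_obs, rarefied = rar, extrapolated = extrap,
       f1 = f1, f2 = f2)
}

#' Per-site variability summary over rarefied replicates
#'
#' Computes functional and compositional variability and richness for one
#' site: metrics are computed on each rarefied replicate of the site's
#' species x period matrix and then averaged, so all sites are compared at
#' equal total counts.
#'
#' @param M Species x period count matrix for the site.
#' @param target Rarefaction total (the minimum site total across the study).
#' @param n_rep Number of rarefaction replicates.
#' @param status Optional named character vector (species -> status class)
#'   used to sum SCBD and count richness per class.
#' @param m Periods per annual cycle; when supplied, the community-total
#'   series of each replicate is also decomposed with [fit_tslm()] and the
#'   absolute and relative component variances are averaged across
#'   replicates.
#' @param seed Optional integer seed.
#' @return List with `cv`, `bd_total`, `scbd` (mean per-species SCBD),
#'   `richness` (observed/rarefied/extrapolated), optionally
#'   `variance_absolute` and `variance_relative` (mean component variances),
#'   and, when `status` is given, `scbd_by_status` and `richness_by_status`
#'   (observed, extrapolated and rarefied per class).
#' @export
site_variability <- function(M, target, n_rep = 100L, status = NULL,
                             m = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- rarefy_matrix(M, target, n_rep = n_rep)
  cvs <- numeric(n_rep)
  bds <- numeric(n_rep)
  scbds <- matrix(0, nrow = n_rep, ncol = nrow(M),
                  dimnames = list(NULL, rownames(M)))
  rar_rich <- numeric(n_rep)
  vab <- vre <- matrix(NA_real_, nrow = n_rep, ncol = 3,
                       dimnames = list(NULL,
                                       c("seasonal", "trend", "remainder")))
  for (r in seq_len(n_rep)) {
    R <- reps[[r]]
    cvs[r] <- functional_cv(colSums(R))
    tb <- temporal_beta_diversity(R)
    bds[r] <- tb$BD_total
    scbds[r, names(tb$SCBD)] <- tb$SCBD
    rar_rich[r] <- sum(rowSums(R) > 0)
    if (!is.null(m)) {
      cv_r <- component_variances(fit_tslm(colSums(R), m = m))
      vab[r, ] <- cv_r$absolute
      vre[r, ] <- cv_r$relative
    }
  }
  rich <- richness_summary(M)  # observed/extrapolated on unrarefied counts
  out <- list(cv = mean(cvs), bd_total = mean(bds),
              scbd = colMeans(scbds),
              richness = list(observed = rich$observed,
                              rarefied = mean(rar_rich),
                              extrapolated = rich$extrapolated))
  if (!is.null(m)) {
    out$variance_absolute <- colMeans(vab)
    out$variance_relative <- colMeans(vre)
  }
  if (!is.null(status)) {
    st <- status[rownames(M)]
    classes <- c("native", "alien", "uncertain")
    out$scbd_by_status <- vapply(classes, function(k)
      sum(out$scbd[which(st == k)]), numeric(1))
    out$richness_by_status <- lapply(classes, function(k) {
      rows <- which(st == k)
      if (!length(rows))
        return(list(observed = 0, rarefied = 0, extrapolated = 0))
      Mk <- M[rows, , drop = FALSE]
      obs <- sum(rowSums(Mk) > 0)
      rar <- mean(vapply(reps, function(R)
        sum(rowSums(R[rows, , drop = FALSE]) > 0), numeric(1)))
      ext <- if (sum(Mk) > 0) richness_summary(Mk)$extrapolated else 0
      list(observed = obs, rarefied = rar, extrapolated = ext)
    })
    names(out$richness_by_status) <- classes
  }
  out
}
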