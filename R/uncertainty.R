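## Variability estimation, pooling transform, lognormal machinery and the
## shared/unshared uncertainty budget.

#' Relative RMSD of dose-factor realizations about the population-mean value
#'
#' The variability of a segment's dose factor is measured as the root mean
#' square deviation of `n` randomly generated realizations about the dose
#' factor of the population-mean model (not about the sample mean), divided
#' by that population-mean value.
#'
#' @param df_true dose factor of the population-mean model (> 0).
#' @param df_samples numeric vector of realizations (length >= 2).
#' @return relative RMSD (fraction).
#' @examples
#' variabilityRmsd(1, c(0.8, 1.2))  # 0.2
#' @export
variabilityRmsd <- function(df_true, df_samples) {
  if (length(df_samples) < 2L) stop("need at least 2 realizations")
  if (df_true <= 0) stop("df_true must be positive")
  sqrt(mean((df_true - df_samples)^2)) / df_true
}

#' Linear standardization for pooling dose factors across segments
#'
#' Segment-specific dose factors differ by up to an order of magnitude, so
#' realizations are standardized before pooling:
#' `DF~ = (df_true - sample) / sigma_var`. A pooled set across segments has
#' mean ~0 and SD ~1.
#'
#' @param df_samples realizations for one segment.
#' @param df_true the segment's population-mean dose factor.
#' @param sigma_var the segment's variability in absolute RMSD terms (> 0).
#' @return standardized values.
#' @export
poolTransform <- function(df_samples, df_true, sigma_var) {
  if (sigma_var <= 0) stop("sigma_var must be positive")
  (df_true - df_samples) / sigma_var
}

#' Lognormal distribution from arithmetic mean and CV
#'
#' Moment matching: `mu = ln(mean / sqrt(cv^2 + 1))`,
#' `s = sqrt(ln(cv^2 + 1))`. `cv = 0` degenerates to a point mass at the
#' mean (all quantiles equal the mean).
#'
#' @param mean arithmetic mean (> 0).
#' @param cv coefficient of variation (>= 0).
#' @return a [LognormalDF-class].
#' @export
lognormalFromMeanCv <- function(mean, cv) {
  if (mean <= 0) stop("mean must be positive")
  if (cv < 0) stop("cv must be nonnegative")
  s <- sqrt(log(cv^2 + 1))
  mu <- log(mean) - s^2 / 2
  new("LognormalDF", mu = mu, s = s, mean = mean, cv = cv)
}

#' Quantiles of a mean/CV-parameterized lognormal
#'
#' @param ln a [LognormalDF-class].
#' @param p probability vector.
#' @return quantiles `exp(mu + z_p * s)`.
#' @examples
#' ln <- lognormalFromMeanCv(1.54, 0.38)
#' lnQuantile(ln, c(0.05, 0.95))  # ~0.79, ~2.63
#' @export
lnQuantile <- function(ln, p) {
  if (ln@s == 0) return(rep(ln@mean, length(p)))
  exp(ln@mu + stats::qnorm(p) * ln@s)
}

#' Fit normal and shifted (3-parameter) lognormal to pooled values
#'
#' Standardized pooled dose factors look symmetric but are better described
#' by a 3-parameter lognormal (a shift accommodates the negative values)
#' than by a Gaussian. Both are fit by maximum likelihood (the shift by
#' profile likelihood) and compared; the lognormal is fit in both
#' orientations (right- and left-skewed, i.e. on `x` and on `-x`) and the
#' better one is kept, since the pooling transform reflects the sign of the
#' underlying dose-factor skew.
#'
#' @param x pooled standardized values.
#' @return list with `loglik_normal`, `loglik_lognormal3`, `shift`,
#'   `orientation` (`"right"` or `"left"`), `preferred` (the
#'   larger-likelihood family).
#' @export
fitPooledDistribution <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 pooled values")
  ll_norm <- sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n),
                              log = TRUE))
  fitOne <- function(y) {
    profile <- function(theta) {
      w <- y - theta
      if (any(w <= 0)) return(-Inf)
      lw <- log(w)
      mu <- mean(lw); s <- stats::sd(lw) * sqrt((n - 1) / n)
      if (s == 0) return(-Inf)
      sum(stats::dlnorm(w, mu, s, log = TRUE))
    }
    lo <- min(y) - 10 * stats::sd(y)
    opt <- stats::optimize(function(t) -profile(t),
                           interval = c(lo, min(y) - 1e-8))
    list(ll = -opt$objective, shift = opt$minimum)
  }
  right <- fitOne(x)
  left <- fitOne(-x)
  use <- if (left$ll > right$ll) left else right
  list(loglik_normal = ll_norm, loglik_lognormal3 = use$ll,
       shift = use$shift,
       orientation = if (left$ll > right$ll) "left" else "right",
       preferred = if (use$ll > ll_norm) "lognormal3" else "normal")
}

#' Combine classified budget components in quadrature
#'
#' Components classified `shared` (introduced by the modeling approach,
#' common to a population) and `unshared` (individual variability) are each
#' combined in quadrature within their class; the overall relative
#' uncertainty is the quadrature of the two class totals.
#'
#' @param components data.frame with numeric `delta` (fractions) and
#'   character `classification` (`"shared"` or `"unshared"`).
#' @return list with `delta_shared`, `delta_unshared`, `delta_overall`.
#' @examples
#' composeBudget(data.frame(delta = c(0.11, 0.36),
#'                          classification = c("shared", "unshared")))
#' @export
composeBudget <- function(components) {
  if (!all(c("delta", "classification") %in% names(components)))
    stop("components need 'delta' and 'classification' columns")
  if (!all(components$classification %in% c("shared", "unshared")))
    stop("every component must be classified as shared or unshared")
  if (any(components$delta < 0)) stop("delta must be nonnegative")
  sh <- sqrt(sum(components$delta[components$classification == "shared"]^2))
  un <- sqrt(sum(components$delta[components$classification == "unshared"]^2))
  list(delta_shared = sh, delta_unshared = un,
       delta_overall = sqrt(sh^2 + un^2))
}

## stylization uncertainty by size class (fractions); the largest classes
## are insensitive to shape and the component is neglected
.DELTA_GEOM <- c(TBV1 = 0, TBV2 = 0.15, TBV3 = 0.13, TBV4 = 0.07,
                 CBV1 = 0, CBV2 = 0.15, CBV3 = 0.10, CBV4 = 0.14,
                 CBV5 = 0.09, CBV6 = 0.04)

#' Uncertainty-budget components applicable to a size class and source
#'
#' Returns the component set with default deltas: shape stylization by size
#' class (neglected for the largest classes), voxelization 1 %, restricted
#' geometry 5 % when the crossfire adjustment is applied (trabecular source
#' of small segments), cortical-thickness uniformity 7 % (cortical source),
#' chemical composition 4 %, bone density 4 % (large segments,
#' trabecular)/6 % (small, trabecular)/13 % (small, cortical)/neglected
#' (large, cortical), and micro/macro-architecture variability (20 % on
#' average; override with the segment's own variability RMSD).
#'
#' @param size_class `"TBV1"`-`"TBV4"` or `"CBV1"`-`"CBV6"` (source is
#'   implied by the class prefix).
#' @param restricted is the restricted-geometry adjustment in use?
#' @param delta_var segment-specific micro/macro variability (fraction).
#' @return data.frame with `component`, `delta`, `classification`.
#' @export
budgetLookup <- function(size_class, restricted = FALSE, delta_var = 0.20) {
  if (!size_class %in% names(.DELTA_GEOM))
    stop("unknown size class '", size_class, "'")
  source <- substr(size_class, 1, 3)
  large <- size_class %in% c("TBV1", "CBV1", "CBV2", "CBV3")
  density <- if (source == "TBV") {
    if (large) 0.04 else 0.06
  } else {
    if (large) 0 else 0.13
  }
  data.frame(
    component = c("shape_stylization", "voxelization", "model_restriction",
                  "cortical_uniformity", "microarchitecture_variability",
                  "chemical_composition", "bone_density"),
    delta = c(.DELTA_GEOM[[size_class]],
              0.01,
              if (source == "TBV" && restricted) 0.05 else 0,
              if (source == "CBV") 0.07 else 0,
              delta_var,
              0.04,
              density),
    classification = c("shared", "shared", "shared", "shared",
                       "unshared", "unshared", "unshared"),
    stringsAsFactors = FALSE)
}

#' Bootstrap minimum sample size for variability estimation
#'
#' The relative variance of the variance estimator (VOV) measures how stable
#' the variability estimate is at sample size `n`. For each `n`, the dose
#' factor set is resampled with replacement `n_boot` times; each replicate's
#' variance about the population-mean dose factor is computed, and
#' `VOV(n) = Var(v) / E(v)^2`. The minimum suitable sample size is the
#' smallest `n` with `VOV(n)` below the threshold (0.15).
#'
#' @param df_samples dose-factor realizations (>= 20 unless `n_max` smaller).
#' @param df_true population-mean dose factor.
#' @param n_max largest sample size examined (default: number of samples).
#' @param n_boot bootstrap replicates per sample size.
#' @param threshold VOV acceptance threshold.
#' @param n_min_allowed smallest admissible answer (returned for degenerate,
#'   e.g. constant, inputs).
#' @param seed RNG seed for the bootstrap.
#' @return list with `n_min` and `vov_curve` (data.frame of `n`, `vov`).
#' @export
minSampleSize <- function(df_samples, df_true, n_max = length(df_samples),
                          n_boot = 1000L, threshold = 0.15,
                          n_min_allowed = 5L, seed = 1L) {
  if (n_max > length(df_samples))
    stop("requested n exceeds the number of available realizations")
  dev2 <- (df_true - df_samples)^2
  if (max(dev2) == 0) {
    ns <- seq.int(n_min_allowed, n_max)
    return(list(n_min = n_min_allowed,
                vov_curve = data.frame(n = ns, vov = rep(0, length(ns)))))
  }
  ns <- seq.int(max(2L, n_min_allowed), n_max)
  vov <- withSeed(seed, vapply(ns, function(n) {
    v <- vapply(seq_len(n_boot), function(b)
      mean(dev2[sample.int(length(dev2), n, replace = TRUE)]), numeric(1))
    stats::var(v) / mean(v)^2
  }, numeric(1)))
  idx <- which(vov < threshold)
  n_min <- if (length(idx)) ns[idx[1]] else NA_integer_
  list(n_min = n_min, vov_curve = data.frame(n = ns, vov = vov))
}
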