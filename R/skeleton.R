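## Segment -> site -> skeleton averaging with active-marrow weights,
## correlated uncertainty propagation and the two-dimensional (shared/
## unshared) Monte Carlo.

#' Create an active-marrow distribution
#'
#' Fractions are renormalized to sum to 1.
#'
#' @param site site names.
#' @param fraction site AM fractions (any positive weights).
#' @param cv per-site coefficient of variation; sites with `NA` receive the
#'   population-average variability of 0.39.
#' @param provenance `"measured"` or `"propagated"` per site (recycled).
#' @return an [AMDistribution-class].
#' @export
AMDistribution <- function(site, fraction, cv, provenance = "measured") {
  cv[is.na(cv)] <- 0.39
  new("AMDistribution", site = as.character(site),
      fraction = fraction / sum(fraction), cv = as.numeric(cv),
      provenance = rep(as.character(provenance), length.out = length(site)))
}

#' Site-average dose factor from segment dose factors
#'
#' Segments of one hematopoietic site are averaged with weights equal to the
#' normalized segment bone-marrow masses:
#' `DF_i = sum_j w_ij DF_ij`, `w_ij = m_BM,ij / sum_j m_BM,ij`.
#'
#' @param df segment dose factors (numeric).
#' @param marrow_mass segment bone-marrow masses (g, > 0).
#' @return site-average dose factor.
#' @examples
#' siteAverage(c(2, 4), c(1, 3))  # 3.5
#' @export
siteAverage <- function(df, marrow_mass) {
  if (length(df) < 1L) stop("need at least one segment")
  if (length(df) != length(marrow_mass))
    stop("df and marrow_mass lengths differ")
  if (any(marrow_mass <= 0) || sum(marrow_mass) <= 0)
    stop("marrow masses must be positive")
  sum(df * marrow_mass) / sum(marrow_mass)
}

#' Skeletal-average dose factor from site dose factors
#'
#' Weighted average with normalized site AM fractions:
#' `DF = sum_i W_i DF_i`. Unnormalized weights are renormalized first.
#'
#' @param df site dose factors.
#' @param am an [AMDistribution-class] or a numeric weight vector.
#' @return skeletal-average dose factor.
#' @export
skeletalAverage <- function(df, am) {
  w <- if (is(am, "AMDistribution")) am@fraction else am
  if (length(df) != length(w)) stop("sites and weights do not align")
  sum(df * w / sum(w))
}

#' Correlated propagation of site uncertainties to the skeletal average
#'
#' Site contributions carry both the weight uncertainty and the dose-factor
#' uncertainty: `sigma_i = DF_i W_i sqrt(delta_w_i^2 + delta_DF_i^2)`. Site
#' dose factors are correlated (linear dimensions and masses of skeletal
#' bones correlate across sites), so cross terms
#' `sum_{i != l} rho sigma_i sigma_l` are added. The relative uncertainty is
#' the square root of the total variance divided by `sum_i DF_i W_i`.
#'
#' @param df site dose factors.
#' @param delta_df per-site relative uncertainties of the dose factors.
#' @param am an [AMDistribution-class] (weights and their CVs), or a numeric
#'   weight vector when `delta_w` is supplied.
#' @param delta_w per-site relative weight uncertainties (taken from `am`
#'   when it is an [AMDistribution-class]).
#' @param rho inter-site correlation coefficient in `[0, 1)` (default 0.5).
#' @return relative standard uncertainty of the skeletal-average DF.
#' @export
propagateSkeletalUncertainty <- function(df, delta_df, am, delta_w = NULL,
                                         rho = 0.5) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (is(am, "AMDistribution")) {
    W <- am@fraction
    if (is.null(delta_w)) delta_w <- am@cv
  } else {
    W <- am / sum(am)
    if (is.null(delta_w)) stop("delta_w required with plain weights")
  }
  n <- length(df)
  if (length(delta_df) != n || length(W) != n || length(delta_w) != n)
    stop("site vectors do not align")
  sigma <- df * W * sqrt(delta_w^2 + delta_df^2)
  total_var <- sum(sigma^2) + rho * (sum(sigma)^2 - sum(sigma^2))
  sqrt(total_var) / sum(df * W)
}

#' Shared/unshared split of the skeletal-average uncertainty
#'
#' The correlated propagation is run twice: once on the shared (introduced)
#' per-site components with no weight uncertainty, and once on the unshared
#' (variability) components including the AM-fraction CVs. Shared components
#' arise from modeling simplifications (stylization, voxelization,
#' restriction, cortical uniformity) and are common to every individual;
#' unshared components reflect individual anatomy.
#'
#' @param df site dose factors.
#' @param delta_shared,delta_unshared per-site relative uncertainties by
#'   class (e.g. from [composeBudget()] per site).
#' @param am an [AMDistribution-class].
#' @param rho inter-site correlation.
#' @return list with `delta_shared`, `delta_unshared`, `delta_overall`.
#' @export
splitSharedUnshared <- function(df, delta_shared, delta_unshared, am,
                                rho = 0.5) {
  sh <- propagateSkeletalUncertainty(df, delta_shared, am,
                                     delta_w = rep(0, length(df)), rho = rho)
  un <- propagateSkeletalUncertainty(df, delta_unshared, am, rho = rho)
  list(delta_shared = sh, delta_unshared = un,
       delta_overall = sqrt(sh^2 + un^2))
}

#' Two-dimensional Monte Carlo over shared and unshared uncertainty
#'
#' Outer loop: one multiplicative shared perturbation per population
#' realization, normal with mean 1 and SD `delta_shared` (truncated at 0;
#' the sub-zero mass is negligible for the shared levels in use). Inner
#' loop: individual dose factors drawn from the lognormal with mean
#' `mean * shared draw` and CV `delta_unshared`. Returns all realizations,
#' their empirical CV and the empirical 90 % interval.
#'
#' @param mean skeletal-average dose factor (1e-11 scale).
#' @param delta_shared,delta_unshared relative uncertainties (fractions).
#' @param n_outer,n_inner loop sizes (>= 1).
#' @param seed RNG seed (local to the call).
#' @return list with `realizations` (length `n_outer * n_inner`), `cv`,
#'   `ci90` (5th and 95th percentiles) and `mean`.
#' @export
twoDimMC <- function(mean, delta_shared, delta_unshared,
                     n_outer = 400L, n_inner = 250L, seed = 1L) {
  if (n_outer < 1L || n_inner < 1L) stop("n_outer and n_inner must be >= 1")
  if (mean <= 0) stop("mean must be positive")
  withSeed(seed, {
    shared <- stats::rnorm(n_outer, 1, delta_shared)
    while (any(shared <= 0))
      shared[shared <= 0] <- stats::rnorm(sum(shared <= 0), 1, delta_shared)
    s <- sqrt(log(delta_unshared^2 + 1))
    z <- stats::rnorm(n_outer * n_inner)
    mu <- rep(log(mean * shared) - s^2 / 2, each = n_inner)
    x <- exp(mu + s * z)
    list(realizations = x,
         cv = stats::sd(x) / base::mean(x),
         ci90 = unname(stats::quantile(x, c(0.05, 0.95))),
         mean = base::mean(x))
  })
}

#' Skeletal-average dose factor with full uncertainty bookkeeping
#'
#' Aggregates a segment table (site, segment DF values and uncertainties by
#' class, marrow masses) to site averages, then to the skeletal average;
#' propagates shared and unshared uncertainty separately and attaches the
#' lognormal 90 % interval for the overall CV.
#'
#' @param segments data.frame with columns `site`, `df`, `marrow_mass`,
#'   `delta_shared`, `delta_unshared`.
#' @param am an [AMDistribution-class]; sites absent from it are dropped
#'   (with a warning) and the remaining weights renormalized.
#' @param nuclide,source tags stored in the result.
#' @param rho inter-site correlation.
#' @return a [SkeletalDF-class].
#' @export
skeletalDoseFactor <- function(segments, am, nuclide = "Sr90",
                               source = "TBV", rho = 0.5) {
  need <- c("site", "df", "marrow_mass", "delta_shared", "delta_unshared")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  keep <- segments$site %in% am@site
  if (!all(keep)) {
    warning("dropping segments of sites absent from the AM distribution: ",
            paste(unique(segments$site[!keep]), collapse = ", "))
    segments <- segments[keep, , drop = FALSE]
  }
  sites <- intersect(am@site, unique(segments$site))
  ## site DF is the marrow-mass-weighted mean; site-level relative
  ## uncertainty combines segment contributions in quadrature on the
  ## absolute scale, then renormalizes by the site DF
  agg <- do.call(rbind, lapply(sites, function(s) {
    seg <- segments[segments$site == s, , drop = FALSE]
    w <- seg$marrow_mass / sum(seg$marrow_mass)
    site_df <- sum(w * seg$df)
    data.frame(
      site = s, df = site_df,
      delta_shared = sqrt(sum((w * seg$df * seg$delta_shared)^2)) / site_df,
      delta_unshared = sqrt(sum((w * seg$df * seg$delta_unshared)^2)) / site_df)
  }))
  idx <- match(agg$site, am@site)
  amSub <- AMDistribution(agg$site, am@fraction[idx], am@cv[idx],
                          am@provenance[idx])
  mean_df <- skeletalAverage(agg$df, amSub)
  split <- splitSharedUnshared(agg$df, agg$delta_shared, agg$delta_unshared,
                               amSub, rho = rho)
  ln <- lognormalFromMeanCv(mean_df, split$delta_overall)
  new("SkeletalDF", mean = mean_df,
      delta_shared = split$delta_shared,
      delta_unshared = split$delta_unshared,
      delta_overall = split$delta_overall,
      ci90 = lnQuantile(ln, c(0.05, 0.95)),
      nuclide = nuclide, source = source)
}
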