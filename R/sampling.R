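## Stochastic sampling of individual-variability realizations of segment
## macro and micro parameters: Gaussian-copula correlated draws, truncated
## to the central confidence mass of each marginal, mapped through normal
## (macro) and lognormal (micro) quantile functions.

# Cholesky draw of correlated standard normals with an equicorrelated
# macro block and a 2x2 micro block
copulaDraw <- function(n_macro, macro_cor, micro_cor) {
  k <- n_macro + 2L
  R <- diag(k)
  if (n_macro > 1L)
    R[seq_len(n_macro), seq_len(n_macro)] <-
      macro_cor + (1 - macro_cor) * diag(n_macro)
  R[n_macro + 1L, n_macro + 2L] <- micro_cor
  R[n_macro + 2L, n_macro + 1L] <- micro_cor
  L <- chol(R)
  drop(stats::rnorm(k) %*% L)
}

# implied BV/TV surrogate for a parameter realization: quantized
# three-family rod-lattice bone fraction, scaled so the population-mean
# parameters reproduce the population-mean BV/TV. Captures both the
# (Tb.Th/(Tb.Th+Tb.Sp))^2 micro dependence and the rod-count quantization
# induced by linear-dimension variability in small segments.
latticeBvtvRaw <- function(tb_th, tb_sp, edges) {
  d <- tb_th + tb_sp
  n <- pmax(1, round(edges / d))
  a <- pi / 4 * tb_th^2
  p12 <- a * n[1] * n[2] / (edges[1] * edges[2])
  p23 <- a * n[2] * n[3] / (edges[2] * edges[3])
  p13 <- a * n[1] * n[3] / (edges[1] * edges[3])
  1 - (1 - p12) * (1 - p23) * (1 - p13)
}

impliedBvtv <- function(spec, dims, ct_th, tb_th, tb_sp) {
  # spongiosa bounding box approximated by the shape box minus the shell
  box0 <- shapeMetrics(spec@shape)$box
  scale0 <- box0 / max(box0)
  boxOf <- function(dd, ct) {
    b <- shapeMetrics(ShapeSpec(spec@shape@kind, dd))$box
    pmax(b - 2 * ct, b * 0.2)
  }
  raw0 <- latticeBvtvRaw(spec@micro@tb_th, spec@micro@tb_sp,
                         boxOf(spec@shape@dims, spec@ct_th))
  raw1 <- latticeBvtvRaw(tb_th, tb_sp, boxOf(dims, ct_th))
  spec@micro@bvtv * raw1 / raw0
}

#' Sample individual-variability realizations of a segment
#'
#' Draws `n` parameter realizations of a segment: linear dimensions and
#' cortical thickness from correlated truncated normal marginals (positive
#' equicorrelation), trabecular thickness and separation from negatively
#' correlated truncated lognormal marginals. The correlation structure is a
#' Gaussian copula; draws outside the central `truncation` confidence mass
#' of any varying marginal are rejected and redrawn (inverse-transform
#' construction). Each realization's implied BV/TV (quantized rod-lattice
#' surrogate, scaled to the population-mean BV/TV) must fall inside
#' `bvtv_range`; realizations violating it are resampled up to
#' `max_attempts` times before an explicit failure naming the segment.
#'
#' With all CVs zero every realization equals the population means.
#'
#' @param spec a [SegmentSpec-class].
#' @param n number of realizations (>= 1).
#' @param seed integer RNG seed (draws are local to the call).
#' @param max_attempts resampling cap per realization.
#' @return list of `n` [SegmentSpec-class] realizations; each carries its
#'   implied BV/TV in `micro@bvtv` and zeroed CVs (a realization is a fixed
#'   individual, not a population).
#' @export
sampleSegmentParams <- function(spec, n, seed, max_attempts = 1000L) {
  stopifnot(n >= 1)
  validObject(spec)
  v <- spec@variability
  dims0 <- spec@shape@dims
  n_dims <- length(dims0)
  n_macro <- n_dims + 1L  # linear dimensions + cortical thickness
  macro_cv <- rep(v@macro_cv, length.out = n_dims)
  zmax <- if (v@truncation < 1) {
    stats::qnorm((1 + v@truncation) / 2)
  } else Inf
  cvs <- c(macro_cv, v@ct_th_cv, v@tb_th_cv, v@tb_sp_cv)
  lnTh <- lnormParams(spec@micro@tb_th,
                      max(v@tb_th_cv * spec@micro@tb_th, 1e-300))
  lnSp <- lnormParams(spec@micro@tb_sp,
                      max(v@tb_sp_cv * spec@micro@tb_sp, 1e-300))
  fixed <- rep(FALSE, n_macro + 2L)
  fixed[cvs == 0] <- TRUE
  withSeed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        z <- copulaDraw(n_macro, v@macro_cor, v@micro_cor)
        if (any(abs(z[!fixed]) > zmax)) next  # outside central mass: redraw
        dims <- dims0 * (1 + macro_cv * z[seq_len(n_dims)])
        ct <- spec@ct_th * (1 + v@ct_th_cv * z[n_macro])
        if (any(dims <= 0) || ct < 0) next
        tb_th <- if (fixed[n_macro + 1L]) spec@micro@tb_th
                 else exp(lnTh$mu + lnTh$s * z[n_macro + 1L])
        tb_sp <- if (fixed[n_macro + 2L]) spec@micro@tb_sp
                 else exp(lnSp$mu + lnSp$s * z[n_macro + 2L])
        b <- impliedBvtv(spec, dims, ct, tb_th, tb_sp)
        if (b < spec@micro@bvtv_range[1] || b > spec@micro@bvtv_range[2]) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("bvtv_range unsatisfiable for segment ", spec@segment_id,
             " after ", max_attempts, " attempts")
      out[[i]] <- new("SegmentSpec",
        site_id = spec@site_id, segment_id = spec@segment_id,
        shape = ShapeSpec(spec@shape@kind, dims),
        ct_th = ct, cortical_coverage = spec@cortical_coverage,
        micro = new("MicroSpec", tb_th = tb_th, tb_th_sd = spec@micro@tb_th_sd,
                    tb_sp = tb_sp, tb_sp_sd = spec@micro@tb_sp_sd,
                    bvtv = b, bvtv_range = spec@micro@bvtv_range),
        marrow_mass = spec@marrow_mass,
        variability = new("VariabilityModel", macro_cv = 0, ct_th_cv = 0,
                          tb_th_cv = 0, tb_sp_cv = 0,
                          macro_cor = v@macro_cor, micro_cor = v@micro_cor,
                          truncation = 1))
    }
    out
  })
}
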