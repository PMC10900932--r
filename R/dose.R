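## Analytic dose-factor surrogates for 90Sr(+90Y) and 89Sr, size-class
## logic and the restricted-geometry (crossfire) adjustment.
##
## All dose factors are on the 1e-11 Gy s^-1 per Bq g^-1 (of parent nuclide)
## scale used throughout; dfToSI() converts at I/O boundaries.

# registry of nuclide constants for the analytic surrogates:
#  a_tbv, b_tbv: DF(AM<-TBV) = a_tbv * (1 - exp(-b_tbv * BV/TV))
#  a_f, b_f:     energy ratio E(BM<-CBV)/E(BM<-TBV) = a_f * exp(-b_f * Ct.Th)
.NUCLIDES <- list(
  Sr90 = list(a_tbv = 28,   b_tbv = 0.897, a_f = 0.435, b_f = 4.98),
  Sr89 = list(a_tbv = 13.9, b_tbv = 1.06,  a_f = 0.431, b_f = 6.915))

# fit intervals of the surrogates
.BVTV_INTERVAL <- c(0.01, 0.52)
.CTTH_INTERVAL <- c(0.01, 0.41)

# residual-uncertainty law of the TBV fit (delta as a fraction, DF on the
# 1e-11 scale): delta = 0.063 + 0.1 * exp(-0.373 * DF)
.DELTA_TBV <- function(df) 0.063 + 0.1 * exp(-0.373 * df)

# average residual uncertainty of the energy-ratio fit (at Ct.Th = 0.21 cm);
# configurable constant used in the CBV quadrature
.DELTA_ENERGY_RATIO <- 0.10

#' Read-only registry of nuclide surrogate constants
#'
#' @param path optional file; when given, the registry is also serialized to
#'   JSON at that path.
#' @return named list of constants per nuclide (`Sr90` is the combined
#'   90Sr+90Y spectrum in secular equilibrium, normalized per parent decay).
#' @export
nuclideRegistry <- function(path = NULL) {
  if (!is.null(path))
    jsonlite::write_json(.NUCLIDES, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  .NUCLIDES
}

checkNuclide <- function(nuclide) {
  if (!nuclide %in% names(.NUCLIDES))
    stop("unknown nuclide '", nuclide, "'; use one of ",
         paste(names(.NUCLIDES), collapse = ", "))
  .NUCLIDES[[nuclide]]
}

#' Mean and maximum electron pathlength in spongiosa
#'
#' Continuous-slowing-down-approximation pathlengths of the beta spectra in
#' spongiosa as a function of its bone volume fraction:
#' `lambda = 0.112 + 0.099 * exp(-1.526 * BV/TV)` (cm); the maximum
#' pathlength is `5 * lambda` and never exceeds 1.1 cm.
#'
#' @param bvtv bone volume fraction(s) of spongiosa, in `[0, 1]`.
#' @return pathlength(s) in cm.
#' @examples
#' meanFreePath(0)     # 0.211
#' maxPathlength(0)    # 1.055
#' @export
meanFreePath <- function(bvtv) {
  if (any(bvtv < 0 | bvtv > 1)) stop("bvtv must be within [0, 1]")
  0.112 + 0.099 * exp(-1.526 * bvtv)
}

#' @rdname meanFreePath
#' @export
maxPathlength <- function(bvtv) 5 * meanFreePath(bvtv)

makeDoseFactor <- function(value, nuclide, source, delta) {
  ln <- lognormalFromMeanCv(max(value, .Machine$double.xmin), delta)
  new("DoseFactor", value = value, nuclide = nuclide, source = source,
      delta = delta, mu = ln@mu, s = ln@s)
}

#' Analytic dose factor for a trabecular-bone source
#'
#' Surrogate for the Monte Carlo transport result, valid for segments with
#' all spongiosa dimensions above two mean electron pathlengths (~0.46 cm):
#' `DF(AM<-TBV) = a * (1 - exp(-b * BV/TV))` on the 1e-11 Gy/s per Bq/g
#' scale, with the relative residual uncertainty
#' `delta = 0.063 + 0.1 * exp(-0.373 * DF)`. The fit is defined on
#' BV/TV in \[0.01, 0.52\]; outside, the function extrapolates with a
#' warning.
#'
#' @param bvtv bone volume fraction of spongiosa.
#' @param nuclide `"Sr90"` or `"Sr89"`.
#' @return a [DoseFactor-class].
#' @examples
#' dfTbvAnalytic(0.265, "Sr90")  # 5.92e-11 scale units, delta 7.4 %
#' @export
dfTbvAnalytic <- function(bvtv, nuclide = "Sr90") {
  k <- checkNuclide(nuclide)
  if (bvtv < 0) stop("bvtv must be nonnegative")
  if (bvtv < .BVTV_INTERVAL[1] || bvtv > .BVTV_INTERVAL[2])
    warning(sprintf("BV/TV = %.3g outside the fit interval [%.2f, %.2f]; extrapolating",
                    bvtv, .BVTV_INTERVAL[1], .BVTV_INTERVAL[2]))
  value <- k$a_tbv * (1 - exp(-k$b_tbv * bvtv))
  makeDoseFactor(value, nuclide, "TBV", dfTbvUncertainty(value))
}

#' Residual uncertainty of the trabecular-source surrogate
#'
#' @param df_value DF(AM<-TBV) on the 1e-11 scale.
#' @return relative standard uncertainty (fraction).
#' @export
dfTbvUncertainty <- function(df_value) {
  if (any(df_value < 0)) stop("df_value must be nonnegative")
  .DELTA_TBV(df_value)
}

#' Cortical-to-trabecular energy-deposition ratio
#'
#' `Fc(Ct.Th) = a_F * exp(-b_F * Ct.Th)`: the ratio of marrow energy
#' deposition per decay in cortical bone to that per decay in trabecular
#' bone, driven by self-attenuation in the cortical shell. Defined on
#' Ct.Th in \[0.01, 0.41\] cm; extrapolates with a warning outside.
#'
#' @param ct_th cortical thickness (cm).
#' @param nuclide `"Sr90"` or `"Sr89"`.
#' @return dimensionless ratio.
#' @export
energyRatio <- function(ct_th, nuclide = "Sr90") {
  k <- checkNuclide(nuclide)
  if (ct_th < 0) stop("ct_th must be >= 0")
  if (ct_th < .CTTH_INTERVAL[1] || ct_th > .CTTH_INTERVAL[2])
    warning(sprintf("Ct.Th = %.3g outside the fit interval [%.2f, %.2f] cm; extrapolating",
                    ct_th, .CTTH_INTERVAL[1], .CTTH_INTERVAL[2]))
  k$a_f * exp(-k$b_f * ct_th)
}

#' Analytic dose factor for a cortical-bone source
#'
#' Composition of the trabecular surrogate, the energy-deposition ratio and
#' the source-volume ratio:
#' `DF(AM<-CBV) = DF(AM<-TBV) * Fc(Ct.Th) * V_CBV / V_TBV`.
#' The uncertainty combines the energy-ratio residual (10 % on average) with
#' the trabecular residual in quadrature.
#'
#' @param bvtv bone volume fraction of spongiosa.
#' @param ct_th cortical thickness (cm).
#' @param v_cbv,v_tbv cortical and trabecular bone volumes (cm^3).
#' @param nuclide `"Sr90"` or `"Sr89"`.
#' @param delta_energy_ratio residual uncertainty of the energy-ratio fit.
#' @return a [DoseFactor-class].
#' @export
dfCbvAnalytic <- function(bvtv, ct_th, v_cbv, v_tbv, nuclide = "Sr90",
                          delta_energy_ratio = .DELTA_ENERGY_RATIO) {
  if (v_tbv <= 0) stop("v_tbv must be positive")
  if (v_cbv < 0) stop("v_cbv must be nonnegative")
  tbv <- dfTbvAnalytic(bvtv, nuclide)
  value <- tbv@value * energyRatio(ct_th, nuclide) * v_cbv / v_tbv
  delta <- sqrt(delta_energy_ratio^2 + tbv@delta^2)
  makeDoseFactor(value, nuclide, "CBV", delta)
}

#' Dose factor from an externally computed mean absorbed energy
#'
#' Converts a mean energy absorbed in bone marrow per decay of the source
#' nuclide into a dose factor. An activity concentration of 1 Bq per gram of
#' source tissue gives `m_source` decays per second, depositing
#' `E * m_source` MeV s^-1 in the marrow; dividing by the marrow mass (in kg)
#' and converting MeV to J yields the dose rate. The mass dependence enters
#' only through the `m_source / m_marrow` ratio, so the dose factor is an
#' intensive quantity, insensitive to a common tissue-mass error.
#'
#' @param E mean absorbed energy in marrow per decay (MeV).
#' @param m_source source-tissue mass (g).
#' @param m_marrow bone-marrow mass (g).
#' @return DF value on the 1e-11 Gy s^-1 per Bq g^-1 scale.
#' @export
dfFromEnergy <- function(E, m_source, m_marrow) {
  if (m_source <= 0 || m_marrow <= 0) stop("masses must be positive")
  if (E < 0) stop("E must be nonnegative")
  mev_to_j <- 1.602176634e-13
  # Bq/g of source * m_s = decays/s; energy rate in marrow = E * decays/s;
  # dose rate = that / (m_BM in kg)
  gy_per_s <- E * mev_to_j * m_source / (m_marrow * 1e-3)
  gy_per_s / 1e-11
}

#' Convert a dose factor from the 1e-11 package scale to SI
#'
#' @param df_value value on the 1e-11 Gy s^-1 per Bq g^-1 scale.
#' @return Gy s^-1 per Bq g^-1.
#' @export
dfToSI <- function(df_value) df_value * 1e-11

#' Size classification of a segment for stylization-uncertainty lookup
#'
#' Classifies a segment by its circumscribed-box edges and spongiosa volume
#' into one trabecular-source class (TBV1-TBV4) and one cortical-source
#' class (CBV1-CBV6). Rules are evaluated top-down, first match wins, with
#' the small-volume rows dominating (a segment with spongiosa volume below
#' 1.1 cm^3 is TBV4 regardless of its edges; below 0.2 cm^3 it is CBV6).
#'
#' @param geom a [DerivedGeometry-class].
#' @return list with `tbv` and `cbv` class labels.
#' @export
classifySegment <- function(geom) {
  e <- geom@circumscribed_box
  vs <- geom@V_s
  nSmall <- sum(e < 1.1)
  tbv <-
    if (vs < 1.1) "TBV4"
    else if (all(e > 1.1)) "TBV1"
    else if (nSmall == 1L) "TBV2"
    else "TBV3"
  cbv <-
    if (vs < 0.2) "CBV6"
    else if (all(e > 2.8)) "CBV1"
    else if (all(e > 1.5)) "CBV2"
    else if (all(e > 1.1)) "CBV3"
    else if (vs > 1.6) "CBV4"
    else "CBV5"
  list(tbv = tbv, cbv = cbv)
}

#' Restricted-geometry (crossfire) adjustment for small segments
#'
#' Segmenting a bone restricts the spongiosa available for electron
#' crossfire and underestimates marrow energy deposition. When the spongiosa
#' surface area exceeds 6 cm^2 the effect is negligible (multiplier 1, no
#' uncertainty); otherwise every linear dimension of the spongiosa is
#' extended by two mean electron pathlengths and the trabecular dose factor
#' is increased by `(SS_ext / SS)^0.28`, with a 5 % relative standard
#' uncertainty on the adjustment coefficient.
#'
#' @param geom a [DerivedGeometry-class] (needs `SS` > 0).
#' @param bvtv bone volume fraction (sets the pathlength).
#' @param spongiosa_shape the spongiosa [ShapeSpec-class]; when omitted, the
#'   extension is applied to an equivalent box with the circumscribed-box
#'   aspect ratio scaled to the spongiosa volume.
#' @return list with `multiplier` and `delta`.
#' @export
restrictedGeometryAdjustment <- function(geom, bvtv, spongiosa_shape = NULL) {
  if (geom@SS <= 0) stop("SS must be positive")
  if (geom@SS > 6) return(list(multiplier = 1.0, delta = 0.0))
  ext <- 2 * meanFreePath(bvtv)
  if (is.null(spongiosa_shape)) {
    edges <- geom@circumscribed_box * (geom@V_s / prod(geom@circumscribed_box))^(1 / 3)
    ss <- 2 * (edges[1] * edges[2] + edges[2] * edges[3] + edges[1] * edges[3])
    e2 <- edges + ext
    ss_ext <- 2 * (e2[1] * e2[2] + e2[2] * e2[3] + e2[1] * e2[3])
    # scale the analytic SS by the box-model ratio
    ratio <- ss_ext / ss
  } else {
    ss <- buildSolid(spongiosa_shape)@surface_area
    ss_ext <- buildSolid(extendShape(spongiosa_shape, ext))@surface_area
    ratio <- ss_ext / ss
  }
  list(multiplier = ratio^0.28, delta = 0.05)
}

#' Segment-level dose factor via the analytic pathway
#'
#' Full segment bookkeeping: analytic surrogate for the requested source,
#' restricted-geometry adjustment for small trabecular sources, returning a
#' [DoseFactor-class] whose uncertainty is the surrogate residual combined
#' in quadrature with the adjustment uncertainty.
#'
#' @param geom a [DerivedGeometry-class].
#' @param ct_th mean cortical thickness (cm) (cortical source only).
#' @param nuclide `"Sr90"` or `"Sr89"`.
#' @param source `"TBV"` or `"CBV"`.
#' @param adjust apply the restricted-geometry adjustment (TBV source).
#' @param spongiosa_shape optional spongiosa [ShapeSpec-class] for the exact
#'   surface-extension construction.
#' @return a [DoseFactor-class].
#' @export
segmentDoseFactor <- function(geom, ct_th = NULL, nuclide = "Sr90",
                              source = c("TBV", "CBV"), adjust = TRUE,
                              spongiosa_shape = NULL) {
  source <- match.arg(source)
  if (source == "TBV") {
    df <- dfTbvAnalytic(geom@bvtv, nuclide)
    if (adjust) {
      adj <- restrictedGeometryAdjustment(geom, geom@bvtv, spongiosa_shape)
      makeDoseFactor(df@value * adj$multiplier, nuclide, "TBV",
                     sqrt(df@delta^2 + adj$delta^2))
    } else df
  } else {
    if (is.null(ct_th)) stop("ct_th is required for a CBV source")
    dfCbvAnalytic(geom@bvtv, ct_th, geom@V_CBV, geom@V_TBV, nuclide)
  }
}
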