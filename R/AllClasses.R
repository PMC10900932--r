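#' @import methods
NULL

SHAPE_KINDS <- c("box", "elliptic_cylinder", "deformed_cylinder",
                 "ellipsoid", "triangular_pyramid", "tube")

## number of distinct outer surfaces per shape kind (the unit a cortical
## coverage mask addresses)
SHAPE_SURFACES <- c(
  box                = 6L,  # x-, x+, y-, y+, z-, z+
  elliptic_cylinder  = 3L,  # lateral, base z-, base z+
  deformed_cylinder  = 3L,
  ellipsoid          = 1L,
  triangular_pyramid = 4L,  # base, face x=0, face y=0, slanted face
  tube               = 4L   # outer lateral, inner lateral, base z-, base z+
)

SHAPE_NDIMS <- c(
  box                = 3L,  # three edges
  elliptic_cylinder  = 3L,  # a x b x H (full axes of the elliptic base)
  deformed_cylinder  = 5L,  # a x b x c x d x H
  ellipsoid          = 3L,  # l x m x n (full axes)
  triangular_pyramid = 3L,  # base legs a, b and height H
  tube               = 3L   # inner radius, outer radius, H
)

#' Stylized shape description of a bone segment
#'
#' Dimensions follow the full-axis convention: `a x b x H` for elliptic
#' cylinders (`a`, `b` are full axes of the elliptic base), `a x b x c x d x H`
#' for deformed cylinders (base 1 has major axis `a` along x and minor axis
#' `b` along y; base 2 has major axis `c` along y and minor axis `d` along x,
#' so the major axes of the two bases lie in perpendicular planes),
#' `l x m x n` full axes for ellipsoids, three edges for boxes, base legs and
#' height for triangular pyramids, and inner radius / outer radius / height
#' for tubes. All lengths in cm.
#'
#' @slot kind shape kind, one of `box`, `elliptic_cylinder`,
#'   `deformed_cylinder`, `ellipsoid`, `triangular_pyramid`, `tube`.
#' @slot dims numeric vector of lengths (cm).
#' @export
setClass("ShapeSpec", representation(kind = "character", dims = "numeric"))

setValidity("ShapeSpec", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% SHAPE_KINDS)
    return(sprintf("unknown shape kind '%s'", paste(object@kind, collapse = ",")))
  nd <- SHAPE_NDIMS[[object@kind]]
  if (length(object@dims) != nd)
    return(sprintf("shape '%s' requires %d dims, got %d",
                   object@kind, nd, length(object@dims)))
  if (any(!is.finite(object@dims)) || any(object@dims <= 0))
    return("all dims must be positive and finite")
  if (object@kind == "tube" && object@dims[1] >= object@dims[2])
    return("tube inner radius must be smaller than outer radius")
  TRUE
})

#' Trabecular microarchitecture of spongiosa
#'
#' @slot tb_th mean trabecular thickness (cm).
#' @slot tb_th_sd intra-specimen SD of trabecular thickness (cm).
#' @slot tb_sp mean trabecular separation (cm).
#' @slot tb_sp_sd intra-specimen SD of trabecular separation (cm).
#' @slot bvtv target bone volume fraction of spongiosa (dimensionless).
#' @slot bvtv_range length-2 numeric, admissible (min, max) for realized BV/TV.
#' @export
setClass("MicroSpec", representation(
  tb_th = "numeric", tb_th_sd = "numeric",
  tb_sp = "numeric", tb_sp_sd = "numeric",
  bvtv = "numeric", bvtv_range = "numeric"))

setValidity("MicroSpec", function(object) {
  if (object@tb_th <= 0 || object@tb_sp <= 0)
    return("tb_th and tb_sp must be positive")
  if (object@tb_th_sd < 0 || object@tb_sp_sd < 0)
    return("SDs must be nonnegative")
  if (object@bvtv < 0 || object@bvtv >= 1)
    return("bvtv must be in [0, 1)")  # 0 is the rod-free degenerate
  if (length(object@bvtv_range) != 2L || diff(object@bvtv_range) < 0)
    return("bvtv_range must be (min, max)")
  if (object@bvtv < object@bvtv_range[1] || object@bvtv > object@bvtv_range[2])
    return("bvtv_range must contain bvtv")
  TRUE
})

#' Individual-variability model for a bone segment
#'
#' Macro parameters (linear dimensions, cortical thickness) vary normally;
#' micro parameters (Tb.Th, Tb.Sp) vary lognormally. Macro parameters are
#' positively correlated with each other, Tb.Th and Tb.Sp negatively
#' (separation grows as trabeculae thin). Draws are truncated to the central
#' `truncation` confidence mass of each marginal (default 0.90: the 10 %
#' tail mass is treated as outliers and resampled).
#'
#' @slot macro_cv per-dimension coefficient of variation (recycled).
#' @slot ct_th_cv CV of cortical thickness.
#' @slot tb_th_cv lognormal CV of trabecular thickness.
#' @slot tb_sp_cv lognormal CV of trabecular separation.
#' @slot macro_cor pairwise correlation among macro parameters (positive).
#' @slot micro_cor Tb.Th-Tb.Sp correlation (negative).
#' @slot truncation central confidence mass retained, in (0, 1].
#' @export
setClass("VariabilityModel", representation(
  macro_cv = "numeric", ct_th_cv = "numeric",
  tb_th_cv = "numeric", tb_sp_cv = "numeric",
  macro_cor = "numeric", micro_cor = "numeric",
  truncation = "numeric"))

setValidity("VariabilityModel", function(object) {
  cvs <- c(object@macro_cv, object@ct_th_cv, object@tb_th_cv, object@tb_sp_cv)
  if (any(cvs < 0)) return("CVs must be nonnegative")
  if (abs(object@macro_cor) >= 1 || abs(object@micro_cor) >= 1)
    return("|correlations| must be < 1")
  if (object@truncation <= 0 || object@truncation > 1)
    return("truncation must be in (0, 1]")
  TRUE
})

#' One bone segment: shape, cortical shell, microarchitecture, variability
#'
#' @slot site_id hematopoietic site identifier.
#' @slot segment_id segment identifier.
#' @slot shape a [ShapeSpec-class].
#' @slot ct_th mean cortical thickness (cm).
#' @slot cortical_coverage logical mask, one entry per outer surface of the
#'   shape (see [surfaceCount()]), `TRUE` where the cortical shell is present.
#' @slot micro a [MicroSpec-class].
#' @slot marrow_mass bone-marrow mass of the segment (g).
#' @slot variability a [VariabilityModel-class].
#' @export
setClass("SegmentSpec", representation(
  site_id = "character", segment_id = "character",
  shape = "ShapeSpec", ct_th = "numeric", cortical_coverage = "logical",
  micro = "MicroSpec", marrow_mass = "numeric",
  variability = "VariabilityModel"))

setValidity("SegmentSpec", function(object) {
  if (object@ct_th < 0) return("ct_th must be >= 0")
  if (object@marrow_mass <= 0) return("marrow_mass must be > 0")
  ns <- SHAPE_SURFACES[[object@shape@kind]]
  if (length(object@cortical_coverage) != ns)
    return(sprintf("coverage mask must have %d entries for shape '%s'",
                   ns, object@shape@kind))
  TRUE
})

#' Simulated medium (bone or marrow)
#'
#' Element mass fractions should sum to 1; a tolerance of 0.02 is accepted
#' because published composition tables are rounded.
#'
#' @slot name medium name.
#' @slot density mass density (g cm^-3).
#' @slot element_mass_fractions named numeric, element symbol -> mass fraction.
#' @export
setClass("Media", representation(
  name = "character", density = "numeric",
  element_mass_fractions = "numeric"))

setValidity("Media", function(object) {
  if (object@density <= 0) return("density must be positive")
  s <- sum(object@element_mass_fractions)
  if (abs(s - 1) > 0.02)
    return(sprintf("element mass fractions sum to %.4f (expected 1)", s))
  if (is.null(names(object@element_mass_fractions)))
    return("element_mass_fractions must be named by element")
  TRUE
})

#' Analytic stylized solid
#'
#' A closed solid with a vectorized point-membership predicate and analytic
#' volume and surface area. Solids are centered at the origin with the height
#' axis along z (pyramids have their base corner at the origin).
#'
#' @slot shape the generating [ShapeSpec-class].
#' @slot volume analytic volume (cm^3).
#' @slot surface_area total analytic boundary area (cm^2).
#' @slot contains function(x, y, z) -> logical, vectorized.
#' @slot box circumscribed-box edges (cm), length 3.
#' @slot origin lower corner of the circumscribed box in solid coordinates.
#' @export
setClass("StylizedSolid", representation(
  shape = "ShapeSpec", volume = "numeric", surface_area = "numeric",
  contains = "function", box = "numeric", origin = "numeric"))

#' A stylized solid partitioned into cortical shell and spongiosa
#'
#' @slot outer the full [StylizedSolid-class].
#' @slot spongiosa the inner (spongiosa) [StylizedSolid-class].
#' @slot ct_th per-surface cortical thicknesses (cm; 0 where uncovered).
#' @slot coverage logical per-surface coverage mask.
#' @export
setClass("PartitionedSolid", representation(
  outer = "StylizedSolid", spongiosa = "StylizedSolid",
  ct_th = "numeric", coverage = "logical"))

#' Rod-like trabecular lattice inscribed in a spongiosa region
#'
#' Three orthogonal families of cylindrical rods at jittered grid positions;
#' rod diameters are lognormal with mean `tb_th`. A uniform thickness scale
#' (calibrated at generation time) lands the realized BV/TV inside the
#' admissible range of the microarchitecture spec.
#'
#' @slot rods list with elements `x`, `y`, `z`; each a data.frame of rod line
#'   coordinates `u`, `v` (cm, in the plane perpendicular to the family axis)
#'   and `r` (rod radius, cm).
#' @slot micro the generating [MicroSpec-class].
#' @slot scale calibrated uniform thickness scale applied to rod radii.
#' @slot bvtv_target calibration target (the spec's BV/TV).
#' @slot bvtv_calibrated point-sampled BV/TV estimate after calibration.
#' @slot seed RNG seed used.
#' @export
setClass("TrabecularLattice", representation(
  rods = "list", micro = "MicroSpec", scale = "numeric",
  bvtv_target = "numeric", bvtv_calibrated = "numeric", seed = "numeric"))

#' Labeled voxel phantom of a bone segment
#'
#' Integer labels: 0 outside, 1 cortical bone, 2 trabecular bone, 3 marrow.
#'
#' @slot resolution voxel edge (cm).
#' @slot grid 3-D integer array of labels.
#' @slot seed RNG seed of the trabecular lattice (NA when no lattice).
#' @slot source_id identifier of the generating segment/spec.
#' @export
setClass("VoxelPhantom", representation(
  resolution = "numeric", grid = "array", seed = "numeric",
  source_id = "character"))

setValidity("VoxelPhantom", function(object) {
  if (object@resolution <= 0) return("resolution must be positive")
  if (length(dim(object@grid)) != 3L) return("grid must be a 3-D array")
  if (!all(object@grid %in% 0:3)) return("labels must be in 0:3")
  TRUE
})

#' Derived volumes, surfaces and masses of a partitioned segment
#'
#' @slot V_s spongiosa volume (cm^3).
#' @slot SS spongiosa boundary surface area (cm^2).
#' @slot V_TBV,V_BMV,V_CBV trabecular bone, marrow and cortical bone
#'   volumes (cm^3); `V_s = V_TBV + V_BMV`.
#' @slot m_TBV,m_BMV,m_CBV corresponding masses (g).
#' @slot bvtv realized bone volume fraction of spongiosa.
#' @slot circumscribed_box three edges of the circumscribed box (cm).
#' @export
setClass("DerivedGeometry", representation(
  V_s = "numeric", SS = "numeric",
  V_TBV = "numeric", V_BMV = "numeric", V_CBV = "numeric",
  m_TBV = "numeric", m_BMV = "numeric", m_CBV = "numeric",
  bvtv = "numeric", circumscribed_box = "numeric"))

setValidity("DerivedGeometry", function(object) {
  vols <- c(object@V_s, object@V_TBV, object@V_BMV, object@V_CBV)
  if (any(vols < 0)) return("volumes must be nonnegative")
  if (abs(object@V_s - (object@V_TBV + object@V_BMV)) >
      1e-6 * max(object@V_s, 1e-12))
    return("V_s must equal V_TBV + V_BMV")
  TRUE
})

#' A dose factor with uncertainty and lognormal parameterization
#'
#' Value in units of 1e-11 Gy s^-1 per Bq g^-1 of parent nuclide (the scale
#' used throughout the package). The lognormal parameters (mu, s) are the
#' moment-matched log-space mean and SD for the stated value and relative
#' uncertainty delta.
#'
#' @slot value dose factor on the 1e-11 scale.
#' @slot nuclide `"Sr90"` (with Y90 in equilibrium, per parent decay) or `"Sr89"`.
#' @slot source `"TBV"` or `"CBV"`.
#' @slot delta relative standard uncertainty (fraction).
#' @slot mu,s lognormal log-space parameters.
#' @export
setClass("DoseFactor", representation(
  value = "numeric", nuclide = "character", source = "character",
  delta = "numeric", mu = "numeric", s = "numeric"))

setValidity("DoseFactor", function(object) {
  if (object@value < 0) return("value must be nonnegative")
  if (object@delta < 0) return("delta must be nonnegative")
  if (!object@nuclide %in% c("Sr90", "Sr89")) return("unknown nuclide")
  if (!object@source %in% c("TBV", "CBV")) return("source must be TBV or CBV")
  if (object@value > 0) {
    m <- exp(object@mu + object@s^2 / 2)
    if (abs(m - object@value) > 1e-8 * object@value)
      return("(mu, s) inconsistent with (value, delta)")
  }
  TRUE
})

#' Lognormal distribution parameterized by arithmetic mean and CV
#'
#' @slot mu,s log-space mean and SD.
#' @slot mean,cv arithmetic mean and coefficient of variation.
#' @export
setClass("LognormalDF", representation(
  mu = "numeric", s = "numeric", mean = "numeric", cv = "numeric"))

#' Active-marrow distribution over hematopoietic sites
#'
#' @slot site site names.
#' @slot fraction normalized AM fractions (sum to 1).
#' @slot cv per-site coefficient of variation of the fraction.
#' @slot provenance `"measured"` or `"propagated"` per site.
#' @export
setClass("AMDistribution", representation(
  site = "character", fraction = "numeric", cv = "numeric",
  provenance = "character"))

setValidity("AMDistribution", function(object) {
  n <- length(object@site)
  if (length(object@fraction) != n || length(object@cv) != n)
    return("site, fraction and cv lengths must agree")
  if (abs(sum(object@fraction) - 1) > 1e-6)
    return("fractions must be normalized to 1")
  if (any(object@cv < 0)) return("cv must be nonnegative")
  TRUE
})

#' Skeletal-average dose factor with shared/unshared uncertainty split
#'
#' @slot mean skeletal-average DF (1e-11 scale).
#' @slot delta_shared,delta_unshared,delta_overall relative uncertainties;
#'   overall is the quadrature of the two parts.
#' @slot ci90 5th and 95th percentiles of the DF distribution.
#' @slot nuclide,source nuclide and source-region tags.
#' @export
setClass("SkeletalDF", representation(
  mean = "numeric", delta_shared = "numeric", delta_unshared = "numeric",
  delta_overall = "numeric", ci90 = "numeric",
  nuclide = "character", source = "character"))

setValidity("SkeletalDF", function(object) {
  q <- sqrt(object@delta_shared^2 + object@delta_unshared^2)
  if (abs(q - object@delta_overall) > 1e-6)
    return("delta_overall must be the quadrature of shared and unshared")
  if (length(object@ci90) != 2L || diff(object@ci90) < 0)
    return("ci90 must be (low, high)")
  TRUE
})
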