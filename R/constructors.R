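#' Create a shape specification
#'
#' @param kind shape kind; see [ShapeSpec-class] for the dims convention.
#' @param dims numeric vector of lengths (cm).
#' @return a [ShapeSpec-class] object.
#' @examples
#' ShapeSpec("box", c(1.1, 0.6, 3))
#' ShapeSpec("elliptic_cylinder", c(0.6, 0.6, 3))
#' @export
ShapeSpec <- function(kind, dims) {
  new("ShapeSpec", kind = kind, dims = as.numeric(dims))
}

#' Create a microarchitecture specification
#'
#' @param tb_th,tb_sp mean trabecular thickness / separation (cm).
#' @param bvtv target bone volume fraction of spongiosa.
#' @param tb_th_sd,tb_sp_sd intra-specimen SDs (cm); default 10 % of the mean.
#' @param bvtv_range admissible (min, max) of realized BV/TV; default
#'   `bvtv * c(0.85, 1.15)`.
#' @return a [MicroSpec-class] object.
#' @export
MicroSpec <- function(tb_th, tb_sp, bvtv,
                      tb_th_sd = 0.1 * tb_th, tb_sp_sd = 0.1 * tb_sp,
                      bvtv_range = bvtv * c(0.85, 1.15)) {
  new("MicroSpec", tb_th = tb_th, tb_th_sd = tb_th_sd,
      tb_sp = tb_sp, tb_sp_sd = tb_sp_sd,
      bvtv = bvtv, bvtv_range = as.numeric(bvtv_range))
}

#' Create an individual-variability model
#'
#' Defaults follow the variability regime used for adult bone segments:
#' micro parameters within 4 %, linear dimensions within 16 %, cortical
#' thickness within 42 %, positive macro-macro correlation 0.5, negative
#' Tb.Th-Tb.Sp correlation -0.5, central 90 % truncation.
#'
#' @param macro_cv per-dimension CV of linear dimensions.
#' @param ct_th_cv CV of cortical thickness.
#' @param tb_th_cv,tb_sp_cv lognormal CVs of Tb.Th and Tb.Sp.
#' @param macro_cor,micro_cor correlation coefficients (macro positive,
#'   micro negative).
#' @param truncation central confidence mass retained.
#' @return a [VariabilityModel-class] object.
#' @export
VariabilityModel <- function(macro_cv = 0.16, ct_th_cv = 0.42,
                             tb_th_cv = 0.04, tb_sp_cv = 0.04,
                             macro_cor = 0.5, micro_cor = -0.5,
                             truncation = 0.90) {
  new("VariabilityModel", macro_cv = macro_cv, ct_th_cv = ct_th_cv,
      tb_th_cv = tb_th_cv, tb_sp_cv = tb_sp_cv,
      macro_cor = macro_cor, micro_cor = micro_cor, truncation = truncation)
}

#' Create a segment specification
#'
#' @param site_id,segment_id identifiers.
#' @param shape a [ShapeSpec-class].
#' @param ct_th mean cortical thickness (cm).
#' @param micro a [MicroSpec-class].
#' @param marrow_mass bone-marrow mass (g).
#' @param cortical_coverage logical per-surface mask; default full coverage.
#' @param variability a [VariabilityModel-class]; default
#'   `VariabilityModel()`.
#' @return a [SegmentSpec-class] object.
#' @export
SegmentSpec <- function(site_id, segment_id, shape, ct_th, micro, marrow_mass,
                        cortical_coverage = rep(TRUE, surfaceCount(shape)),
                        variability = VariabilityModel()) {
  new("SegmentSpec", site_id = site_id, segment_id = segment_id,
      shape = shape, ct_th = ct_th,
      cortical_coverage = as.logical(cortical_coverage),
      micro = micro, marrow_mass = marrow_mass, variability = variability)
}

#' Create a medium definition
#'
#' @param name medium name.
#' @param density mass density (g cm^-3).
#' @param element_mass_fractions named numeric vector of mass fractions.
#' @return a [Media-class] object.
#' @export
Media <- function(name, density, element_mass_fractions) {
  new("Media", name = name, density = density,
      element_mass_fractions = element_mass_fractions)
}

#' Number of distinct outer surfaces of a shape
#'
#' The unit addressed by a cortical coverage mask: 6 faces for a box; lateral
#' surface plus two bases for (deformed) cylinders; a single surface for an
#' ellipsoid; base plus three lateral faces for a triangular pyramid; outer
#' lateral, inner lateral and two bases for a tube.
#'
#' @param shape a [ShapeSpec-class] (or shape kind string).
#' @return integer surface count.
#' @export
surfaceCount <- function(shape) {
  kind <- if (is(shape, "ShapeSpec")) shape@kind else shape
  SHAPE_SURFACES[[kind]]
}

setMethod("show", "ShapeSpec", function(object) {
  cat(sprintf("ShapeSpec: %s [%s] cm\n", object@kind,
              paste(signif(object@dims, 4), collapse = " x ")))
})

setMethod("show", "SegmentSpec", function(object) {
  cat(sprintf("SegmentSpec %s/%s: %s [%s] cm, Ct.Th %.3g cm, BV/TV %.3g, marrow %.3g g\n",
              object@site_id, object@segment_id, object@shape@kind,
              paste(signif(object@shape@dims, 3), collapse = " x "),
              object@ct_th, object@micro@bvtv, object@marrow_mass))
})

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@grid)
  counts <- tabulate(object@grid + 1L, nbins = 4L)
  cat(sprintf("VoxelPhantom %s: %d x %d x %d voxels @ %.4g cm\n",
              object@source_id, d[1], d[2], d[3], object@resolution))
  cat(sprintf("  outside %d | cortical %d | trabecular %d | marrow %d\n",
              counts[1], counts[2], counts[3], counts[4]))
})

setMethod("show", "DoseFactor", function(object) {
  cat(sprintf("DoseFactor %s DF(AM<-%s) = %.4g x 1e-11 Gy/s per Bq/g (delta %.1f%%)\n",
              object@nuclide, object@source, object@value, 100 * object@delta))
})

setMethod("show", "DerivedGeometry", function(object) {
  cat(sprintf("DerivedGeometry: V_s %.4g cm^3, SS %.4g cm^2, BV/TV %.3g\n",
              object@V_s, object@SS, object@bvtv))
  cat(sprintf("  V_TBV %.4g | V_BMV %.4g | V_CBV %.4g cm^3; box %s cm\n",
              object@V_TBV, object@V_BMV, object@V_CBV,
              paste(signif(object@circumscribed_box, 3), collapse = " x ")))
})

setMethod("show", "SkeletalDF", function(object) {
  cat(sprintf("SkeletalDF %s DF(AM<-%s): mean %.3g [%.2g-%.2g] x 1e-11 Gy/s per Bq/g\n",
              object@nuclide, object@source, object@mean,
              object@ci90[1], object@ci90[2]))
  cat(sprintf("  shared %.1f%% | unshared %.1f%% | overall %.1f%%\n",
              100 * object@delta_shared, 100 * object@delta_unshared,
              100 * object@delta_overall))
})

## simple accessors -----------------------------------------------------------

#' Accessors for dose-factor and geometry objects
#'
#' `dfValue()`, `dfDelta()` extract the value and relative uncertainty of a
#' [DoseFactor-class]; `spongiosaVolume()`, `spongiosaSurface()` the spongiosa
#' volume and surface of a [DerivedGeometry-class]; `circumscribedBox()` its
#' circumscribed-box edges.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
dfValue <- function(x) x@value

#' @rdname accessors
#' @export
dfDelta <- function(x) x@delta

#' @rdname accessors
#' @export
spongiosaVolume <- function(x) x@V_s

#' @rdname accessors
#' @export
spongiosaSurface <- function(x) x@SS

#' @rdname accessors
#' @export
circumscribedBox <- function(x) x@circumscribed_box
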