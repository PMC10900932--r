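# shared model builders for the test suite

# the reference box segment used for variability studies:
# 1.1 x 0.6 x 3 cm, Ct.Th 0.08, Tb.Th 0.009, Tb.Sp 0.09, BV/TV 0.09
referenceBoxSegment <- function(truncation = 0.9, macro_cv = 0.16,
                                macro_cor = 0.5, micro_cor = -0.5,
                                bvtv_range = 0.09 * c(0.4, 1.9)) {
  SegmentSpec(
    site_id = "test", segment_id = "reference_box",
    shape = ShapeSpec("box", c(1.1, 0.6, 3)), ct_th = 0.08,
    micro = MicroSpec(0.009, 0.09, 0.09, tb_th_sd = 0.1 * 0.009,
                      tb_sp_sd = 0.1 * 0.09, bvtv_range = bvtv_range),
    marrow_mass = 10,
    variability = VariabilityModel(macro_cv = macro_cv, ct_th_cv = 0.42,
                                   tb_th_cv = 0.04, tb_sp_cv = 0.04,
                                   macro_cor = macro_cor,
                                   micro_cor = micro_cor,
                                   truncation = truncation))
}

pullDims <- function(reals, i) vapply(reals, function(s) s@shape@dims[i], numeric(1))
pullMicro <- function(reals, slot) vapply(reals, function(s) methods::slot(s@micro, slot), numeric(1))

# lognormal population with arithmetic mean 1 and a given CV
rlnormMeanCv <- function(n, cv) {
  s <- sqrt(log(cv^2 + 1))
  stats::rlnorm(n, -s^2 / 2, s)
}
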