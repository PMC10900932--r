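# analytic dose-factor surrogates, size classes and the crossfire adjustment

test_that("electron pathlengths follow the spongiosa attenuation law", {
  expect_equal(meanFreePath(0), 0.211)
  expect_equal(maxPathlength(0), 1.055)
  # typical spongiosa: lambda between 0.15 and 0.21 cm
  l <- meanFreePath(seq(0.05, 0.5, by = 0.01))
  expect_true(all(l > 0.15 & l < 0.21))
  # the maximum pathlength never exceeds 1.1 cm anywhere on [0, 1]
  expect_lte(max(maxPathlength(seq(0, 1, by = 1e-3))), 1.1)
  expect_error(meanFreePath(1.2), "within")
})

test_that("trabecular-source surrogate and its residual law", {
  df <- dfTbvAnalytic(0.265, "Sr90")
  expect_equal(df@value, 28 * (1 - exp(-0.897 * 0.265)), tolerance = 1e-12)
  expect_equal(df@delta, 0.074, tolerance = 0.001)  # 7.4 % at BV/TV 0.265
  expect_equal(dfTbvAnalytic(0.52, "Sr90")@delta, 0.065, tolerance = 0.001)
  # lower end of the fit interval: 15.4 %, printed as 15 %
  expect_equal(suppressWarnings(dfTbvAnalytic(0.01, "Sr90"))@delta, 0.154,
               tolerance = 0.005)
  # asymptote of the law
  expect_equal(dfTbvUncertainty(1e9), 0.063, tolerance = 1e-9)
  # DF -> 0 as BV/TV -> 0 and strict monotonicity in BV/TV
  expect_lt(suppressWarnings(dfTbvAnalytic(1e-9, "Sr90"))@value, 1e-6)
  b <- seq(0.01, 0.52, by = 0.01)
  v <- vapply(b, function(x) dfTbvAnalytic(x, "Sr90")@value, numeric(1))
  expect_true(all(diff(v) > 0))
  # Sr89 runs about half of Sr90 (per parent decay) across the fit range
  ratio <- vapply(seq(0.1, 0.5, by = 0.05), function(x)
    dfTbvAnalytic(x, "Sr89")@value / dfTbvAnalytic(x, "Sr90")@value,
    numeric(1))
  expect_true(all(ratio > 0.4 & ratio < 0.6))
  expect_warning(dfTbvAnalytic(0.6, "Sr90"), "extrapolating")
})

test_that("energy ratio and the composed cortical-source closed form", {
  expect_equal(suppressWarnings(energyRatio(0, "Sr90")), 0.435)
  # composed leading coefficients reproduce the printed closed form
  expect_equal(28 * suppressWarnings(energyRatio(0, "Sr90")), 12.2,
               tolerance = 0.002)           # 12.18, printed 12.2
  expect_equal(13.9 * suppressWarnings(energyRatio(0, "Sr89")), 6,
               tolerance = 0.01)            # 5.99, printed 6
  # composition equals the closed form with printed coefficients to <= 1 %
  for (ct in c(0.05, 0.15, 0.3)) for (b in c(0.1, 0.3, 0.5)) {
    comp <- dfCbvAnalytic(b, ct, 1, 1, "Sr90")@value
    closed <- 12.2 * exp(-4.98 * ct) * (1 - exp(-0.897 * b))
    expect_lt(abs(comp / closed - 1), 0.01)
  }
  # zero cortical volume: no dose
  expect_equal(dfCbvAnalytic(0.2, 0.1, 0, 1, "Sr90")@value, 0)
  # monotone decreasing in cortical thickness
  v <- vapply(seq(0.02, 0.4, by = 0.02), function(ct)
    dfCbvAnalytic(0.2, ct, 1, 1, "Sr90")@value, numeric(1))
  expect_true(all(diff(v) < 0))
  # combined uncertainty at the average operating point stays below 13 %
  d <- dfCbvAnalytic(0.265, 0.21, 1, 1, "Sr90")@delta
  expect_equal(d, sqrt(0.10^2 + 0.074^2), tolerance = 0.001)
  expect_lte(d, 0.13)
})

test_that("energy-to-dose conversion is intensive and unit-correct", {
  expect_equal(dfFromEnergy(0, 1, 1), 0)
  # E = 0.1 MeV, equal 1 g masses: 0.1 * 1.602e-13 J / 1e-3 kg = 1.602e-11 Gy/s
  expect_equal(dfFromEnergy(0.1, 1, 1) * 1e-11, 0.1 * 1.602176634e-13 / 1e-3,
               tolerance = 1e-9)
  # doubling both masses leaves the dose factor unchanged
  expect_equal(dfFromEnergy(0.3, 2, 4), dfFromEnergy(0.3, 4, 8))
  expect_error(dfFromEnergy(0.1, 0, 1), "positive")
  expect_equal(dfToSI(5.92), 5.92e-11)
})

test_that("size classification follows the grouping rules, volume rules first", {
  g <- function(edges, vs) new("DerivedGeometry", V_s = vs, SS = 10,
                               V_TBV = vs * 0.2, V_BMV = vs * 0.8, V_CBV = 1,
                               m_TBV = 1, m_BMV = 1, m_CBV = 1, bvtv = 0.2,
                               circumscribed_box = edges)
  expect_equal(classifySegment(g(c(3, 3, 3), 5)), list(tbv = "TBV1", cbv = "CBV1"))
  expect_equal(classifySegment(g(c(2, 2, 2), 5))$cbv, "CBV2")
  expect_equal(classifySegment(g(c(1.3, 1.3, 1.3), 2))$cbv, "CBV3")
  expect_equal(classifySegment(g(c(0.9, 3, 3), 2)), list(tbv = "TBV2", cbv = "CBV4"))
  expect_equal(classifySegment(g(c(0.9, 0.9, 3), 1.2))$tbv, "TBV3")
  expect_equal(classifySegment(g(c(0.9, 3, 3), 1.0))$cbv, "CBV5")
  # the spongiosa-volume rules dominate the edge rules
  expect_equal(classifySegment(g(c(1.2, 1.2, 1.2), 1.0))$tbv, "TBV4")
  expect_equal(classifySegment(g(c(3, 3, 3), 0.1))$cbv, "CBV6")
})

test_that("restricted-geometry adjustment triggers only for small spongiosa", {
  gBig <- new("DerivedGeometry", V_s = 3, SS = 6.5, V_TBV = 0.6, V_BMV = 2.4,
              V_CBV = 1, m_TBV = 1, m_BMV = 1, m_CBV = 1, bvtv = 0.2,
              circumscribed_box = c(2, 2, 2))
  expect_equal(restrictedGeometryAdjustment(gBig, 0.2),
               list(multiplier = 1.0, delta = 0))
  # small cube spongiosa: multiplier via the exact shape extension
  sh <- ShapeSpec("box", c(0.8, 0.8, 0.8))
  gSmall <- deriveGeometry(addCorticalShell(buildSolid(ShapeSpec("box", c(0.9, 0.9, 0.9))), 0.05),
                           bvtv = 0.2)
  adj <- restrictedGeometryAdjustment(gSmall, 0.2, spongiosa_shape = sh)
  lam <- meanFreePath(0.2)
  expect_equal(adj$multiplier, ((0.8 + 2 * lam)^2 / 0.8^2)^0.28,
               tolerance = 1e-10)
  expect_equal(adj$delta, 0.05)
  expect_gte(adj$multiplier, 1)
  # a doubled surface sits at the upper edge of the reported 1.03-1.21
  # adjustment envelope
  expect_equal(2^0.28, 1.214, tolerance = 1e-3)
})

test_that("segment pipeline composes surrogate, adjustment and budget inputs", {
  tab <- loadFixture("synthetic_segments_adult")
  segs <- segmentsFromTable(tab[c(1, 5, 20), ])
  for (s in segs) {
    geom <- segmentGeometry(s)
    tbv <- suppressWarnings(segmentDoseFactor(geom, nuclide = "Sr90",
                                              source = "TBV",
                                              spongiosa_shape = NULL))
    cbv <- suppressWarnings(segmentDoseFactor(geom, ct_th = s@ct_th,
                                              nuclide = "Sr90", source = "CBV"))
    expect_gte(tbv@value, 0)
    expect_gte(cbv@value, 0)
    expect_true(tbv@delta >= 0 && tbv@delta <= 1)
    expect_true(cbv@delta >= 0 && cbv@delta <= 1)
    # lognormal parameters are consistent with value/delta
    expect_equal(exp(tbv@mu + tbv@s^2 / 2), tbv@value, tolerance = 1e-8)
  }
  expect_error(segmentDoseFactor(segmentGeometry(segs[[1]]), nuclide = "Sr90",
                                 source = "CBV"), "ct_th")
})

test_that("nuclide registry exposes the fixed surrogate constants", {
  reg <- nuclideRegistry()
  expect_equal(reg$Sr90[c("a_tbv", "b_tbv", "a_f", "b_f")],
               list(a_tbv = 28, b_tbv = 0.897, a_f = 0.435, b_f = 4.98))
  expect_equal(reg$Sr89[c("a_tbv", "b_tbv", "a_f", "b_f")],
               list(a_tbv = 13.9, b_tbv = 1.06, a_f = 0.431, b_f = 6.915))
  tf <- tempfile(fileext = ".json")
  nuclideRegistry(tf)
  expect_equal(jsonlite::read_json(tf, simplifyVector = TRUE)$Sr90$a_tbv, 28)
  expect_error(dfTbvAnalytic(0.2, "Cs137"), "unknown nuclide")
})
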