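# segment -> site -> skeleton aggregation, correlated propagation and the
# two-dimensional Monte Carlo

test_that("site and skeletal averaging use normalized mass/AM weights", {
  expect_equal(siteAverage(5, 2), 5)
  expect_equal(siteAverage(c(2, 4), c(1, 1)), 3)
  expect_equal(siteAverage(c(2, 4), c(1, 3)), 3.5)
  expect_error(siteAverage(c(1, 2), c(1, 0)), "positive")
  expect_equal(skeletalAverage(c(3, 3, 3), c(0.2, 0.3, 0.5)), 3)
  expect_equal(skeletalAverage(c(1, 2), c(0.25, 0.75)), 1.75)
  # unnormalized weights are renormalized
  expect_equal(skeletalAverage(c(1, 2), c(1, 3)), 1.75)
  expect_error(skeletalAverage(c(1, 2), c(0.5, 0.3, 0.2)), "align")
  # affine: scaling dose factors scales the mean
  expect_equal(skeletalAverage(10 * c(1, 2), c(0.25, 0.75)), 17.5)
})

test_that("correlated propagation equals the covariance-matrix quadratic form", {
  covOracle <- function(df, ddf, W, dw, rho) {
    sigma <- df * W * sqrt(dw^2 + ddf^2)
    R <- matrix(rho, length(df), length(df)); diag(R) <- 1
    sqrt(drop(t(sigma) %*% R %*% sigma)) / sum(df * W)
  }
  # single site collapses to the component quadrature
  expect_equal(propagateSkeletalUncertainty(2, 0.2, 1, delta_w = 0.39),
               sqrt(0.39^2 + 0.2^2))
  # 12-site uniform skeleton against the matrix oracle
  df <- rep(2, 12); ddf <- rep(0.2, 12); dw <- rep(0.39, 12)
  W <- rep(1 / 12, 12)
  expect_equal(propagateSkeletalUncertainty(df, ddf, W, delta_w = dw, rho = 0.5),
               covOracle(df, ddf, W, dw, 0.5), tolerance = 1e-10)
  # random skeletons, property-style
  set.seed(4)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    df <- runif(n, 0.5, 8); ddf <- runif(n, 0.05, 0.5)
    W <- runif(n); W <- W / sum(W); dw <- runif(n, 0, 0.6)
    rho <- runif(1, 0, 0.9)
    expect_equal(propagateSkeletalUncertainty(df, ddf, W, delta_w = dw, rho = rho),
                 covOracle(df, ddf, W, dw, rho), tolerance = 1e-10)
  }
  # positive cross-correlation inflates the uncertainty
  expect_gt(propagateSkeletalUncertainty(df, ddf, W, delta_w = dw, rho = 0.5),
            propagateSkeletalUncertainty(df, ddf, W, delta_w = dw, rho = 0))
  # scaling all dose factors leaves the relative uncertainty unchanged
  expect_equal(propagateSkeletalUncertainty(3 * df, ddf, W, delta_w = dw, rho = 0.3),
               propagateSkeletalUncertainty(df, ddf, W, delta_w = dw, rho = 0.3))
})

test_that("shared/unshared split runs the propagation per component class", {
  am <- AMDistribution(paste0("s", 1:3), c(0.3, 0.3, 0.4), rep(0.39, 3))
  df <- c(2, 3, 4)
  sp <- splitSharedUnshared(df, delta_shared = rep(0, 3),
                            delta_unshared = rep(0.2, 3), am = am)
  expect_equal(sp$delta_shared, 0)
  expect_equal(sp$delta_overall, sp$delta_unshared)
  sp2 <- splitSharedUnshared(df, delta_shared = rep(0.1, 3),
                             delta_unshared = rep(0.2, 3), am = am)
  expect_equal(sp2$delta_overall,
               sqrt(sp2$delta_shared^2 + sp2$delta_unshared^2))
  # AM-fraction variability belongs to the unshared part only
  expect_lt(sp2$delta_shared, sp2$delta_unshared)
})

test_that("adult skeletal pipeline keeps the shared component within bounds", {
  tab <- loadFixture("synthetic_segments_adult")
  am <- adultAMDistribution()
  segs <- segmentsFromTable(tab)
  rows <- do.call(rbind, lapply(segs, function(s) {
    g <- segmentGeometry(s)
    cls <- classifySegment(g)
    for (src in c("TBV", "CBV")) {
      budget <- budgetLookup(if (src == "TBV") cls$tbv else cls$cbv,
                             restricted = src == "TBV" && g@SS <= 6)
      comp <- composeBudget(budget)
      df <- if (src == "TBV")
        suppressWarnings(segmentDoseFactor(g, nuclide = "Sr90", source = "TBV"))
      else
        suppressWarnings(segmentDoseFactor(g, ct_th = s@ct_th,
                                           nuclide = "Sr90", source = "CBV"))
      row <- data.frame(site = s@site_id, source = src, df = df@value,
                        marrow_mass = s@marrow_mass,
                        delta_shared = comp$delta_shared,
                        delta_unshared = comp$delta_unshared)
      if (src == "TBV") out <- row else out <- rbind(out, row)
    }
    out
  }))
  for (src in c("TBV", "CBV")) {
    sk <- skeletalDoseFactor(rows[rows$source == src, ], am,
                             nuclide = "Sr90", source = src)
    # introduced (shared) uncertainty never exceeds 16 %
    expect_lte(sk@delta_shared, 0.16)
    # unshared dominated by AM-distribution variability (~40 %) stays larger
    expect_gt(sk@delta_unshared, sk@delta_shared)
    expect_equal(sk@delta_overall,
                 sqrt(sk@delta_shared^2 + sk@delta_unshared^2),
                 tolerance = 1e-9)
    expect_gt(sk@mean, 0)
    expect_true(sk@ci90[1] < sk@mean && sk@mean < sk@ci90[2])
  }
})

test_that("sites missing from the AM distribution are dropped with warning", {
  am <- AMDistribution(c("a", "b"), c(0.6, 0.4), c(0.3, 0.3))
  segs <- data.frame(site = c("a", "b", "zz"), df = c(1, 2, 9),
                     marrow_mass = c(1, 1, 1),
                     delta_shared = 0.1, delta_unshared = 0.2)
  expect_warning(sk <- skeletalDoseFactor(segs, am), "zz")
  expect_equal(sk@mean, 0.6 * 1 + 0.4 * 2)
})

test_that("two-dimensional Monte Carlo reproduces the moment algebra", {
  # no shared part: plain lognormal with CV = unshared
  mc0 <- twoDimMC(1, 0, 0.25, n_outer = 1, n_inner = 1e5, seed = 3)
  se_cv <- 0.25 / sqrt(2 * 1e5)
  expect_lt(abs(mc0$cv - 0.25), 5 * se_cv)
  expect_true(all(mc0$realizations > 0))
  # overall CV of the normal x lognormal product:
  # cv^2 = (1 + sh^2)(1 + un^2) - 1
  mc <- twoDimMC(2, 0.1, 0.3, n_outer = 500, n_inner = 200, seed = 6)
  cv_expect <- sqrt((1 + 0.1^2) * (1 + 0.3^2) - 1)
  expect_lt(abs(mc$cv - cv_expect), 0.02)
  expect_lt(abs(mc$mean - 2), 3 * 2 * mc$cv / sqrt(500))
  # seeded determinism
  mc2 <- twoDimMC(2, 0.1, 0.3, n_outer = 500, n_inner = 200, seed = 6)
  expect_identical(mc$realizations, mc2$realizations)
  # tabulated cortical skeletal row: mean 0.74, shared 9 %, unshared 37 %
  # gives an empirical 90 % interval of about [0.4, 1.3]
  mcT <- twoDimMC(0.74, 0.09, 0.37, n_outer = 800, n_inner = 150, seed = 12)
  expect_equal(round(mcT$ci90, 1), c(0.4, 1.3))
  expect_error(twoDimMC(1, 0.1, 0.2, n_outer = 0), ">= 1")
})
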