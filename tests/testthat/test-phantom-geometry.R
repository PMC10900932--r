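# stylized solids, cortical shells, trabecular lattices, voxelization and
# derived geometry

test_that("closed-form volumes of all shape kinds are correct", {
  expect_equal(buildSolid(ShapeSpec("box", c(1.1, 0.6, 3)))@volume, 1.98)
  # circular cylinder, full axes a = b = 1, H = 2
  expect_equal(buildSolid(ShapeSpec("elliptic_cylinder", c(1, 1, 2)))@volume,
               pi / 4 * 2, tolerance = 1e-12)
  # sphere as the symmetric ellipsoid
  expect_equal(buildSolid(ShapeSpec("ellipsoid", c(1, 1, 1)))@volume, pi / 6,
               tolerance = 1e-12)
  # deformed cylinder degenerates to a cone frustum when both bases are circles
  fr <- buildSolid(ShapeSpec("deformed_cylinder", c(1, 1, 0.6, 0.6, 2)))
  expect_equal(fr@volume, pi * 2 / 12 * (1 + 0.6 + 0.36), tolerance = 1e-12)
  expect_equal(buildSolid(ShapeSpec("triangular_pyramid", c(1, 2, 3)))@volume,
               1 * 2 * 3 / 6)
  expect_equal(buildSolid(ShapeSpec("tube", c(0.3, 0.5, 2)))@volume,
               pi * (0.25 - 0.09) * 2, tolerance = 1e-12)
  expect_error(ShapeSpec("box", c(1, -1, 1)))
})

test_that("membership predicates are consistent with analytic volumes", {
  shapes <- list(
    ShapeSpec("elliptic_cylinder", c(0.8, 0.5, 1.2)),
    ShapeSpec("deformed_cylinder", c(1.7, 0.6, 0.8, 0.9, 1.3)),
    ShapeSpec("ellipsoid", c(0.9, 0.6, 1.4)),
    ShapeSpec("triangular_pyramid", c(1, 0.7, 1.1)),
    ShapeSpec("tube", c(0.2, 0.45, 1)))
  set.seed(77)
  for (sh in shapes) {
    s <- buildSolid(sh)
    n <- 2e5
    x <- runif(n, s@origin[1], s@origin[1] + s@box[1])
    y <- runif(n, s@origin[2], s@origin[2] + s@box[2])
    z <- runif(n, s@origin[3], s@origin[3] + s@box[3])
    mc <- mean(s@contains(x, y, z)) * prod(s@box)
    expect_lt(abs(mc / s@volume - 1), 0.01)
  }
})

test_that("cortical shell volume matches the closed-form shell and ct=0 is empty", {
  cube <- buildSolid(ShapeSpec("box", c(2.1, 2.1, 2.1)))
  p <- addCorticalShell(cube, 0.035)
  expect_equal(cube@volume - p@spongiosa@volume, 2.1^3 - (2.1 - 0.07)^3,
               tolerance = 1e-12)  # 0.895573
  p0 <- addCorticalShell(cube, 0)
  expect_equal(p0@spongiosa@volume, cube@volume)
  expect_error(addCorticalShell(cube, 1.1), "no spongiosa")
})

test_that("per-face thickness randomization renormalizes to the requested mean", {
  faces <- loadFixture("cortical_faces_example")
  cube <- buildSolid(ShapeSpec("box", c(2.1, 2.1, 2.1)))
  # model 7 of the randomization example: mean must equal the basic 0.035 cm
  t7 <- as.numeric(faces[faces$model == 7, c("f1", "f2", "f3", "f4", "f5", "f6")]) * 1e-2
  expect_equal(mean(t7), 0.035, tolerance = 1e-12)
  p <- addCorticalShell(cube, t7, mean_ct_th = 0.035)
  expect_equal(mean(p@ct_th), 0.035, tolerance = 1e-12)
  # a deliberately unnormalized draw is rescaled to the same mean
  p2 <- addCorticalShell(cube, t7 * 1.7, mean_ct_th = 0.035)
  expect_equal(mean(p2@ct_th), 0.035, tolerance = 1e-12)
  # asymmetric shells shift the spongiosa but conserve its volume bookkeeping
  expect_equal(p@outer@volume - p@spongiosa@volume,
               2.1^3 - prod(2.1 - (t7[c(1, 3, 5)] + t7[c(2, 4, 6)]) *
                              0.035 / mean(t7)),
               tolerance = 1e-9)
})

test_that("trabecular lattice hits the BV/TV window and rod statistics", {
  # zero target: all-marrow spongiosa
  p <- addCorticalShell(buildSolid(ShapeSpec("box", c(1, 1, 1))), 0.05)
  mi0 <- new("MicroSpec", tb_th = 0.01, tb_th_sd = 0.001, tb_sp = 0.03,
             tb_sp_sd = 0.003, bvtv = 0, bvtv_range = c(0, 0))
  lat0 <- generateTrabecularLattice(p@spongiosa, mi0, seed = 1)
  expect_equal(lat0@bvtv_calibrated, 0)
  ph0 <- voxelize(p, 0.02, lat0)
  expect_equal(sum(ph0@grid == 2L), 0)
  # microarchitecture of a printed small phantom: Tb.Th 0.01, Tb.Sp 0.036,
  # BV/TV 0.28
  p3 <- addCorticalShell(buildSolid(ShapeSpec("elliptic_cylinder", c(0.6, 0.6, 3))),
                         0.13, coverage = c(TRUE, FALSE, FALSE))
  mi <- MicroSpec(0.01, 0.036, 0.28, bvtv_range = 0.28 * c(0.9, 1.1))
  lat <- generateTrabecularLattice(p3@spongiosa, mi, seed = 7)
  expect_gte(lat@bvtv_calibrated, 0.28 * 0.9)
  expect_lte(lat@bvtv_calibrated, 0.28 * 1.1)
  # voxelized realization stays inside the window too
  ph <- voxelize(p3, 0.0075, lat)
  g <- deriveGeometry(ph)
  expect_gt(g@bvtv, 0.28 * 0.85)
  expect_lt(g@bvtv, 0.28 * 1.15)
  # mean realized rod diameter tracks Tb.Th (the calibration scale is a
  # thickness adjustment, so compare against scale x Tb.Th)
  rr <- unlist(lapply(lat@rods, function(f) f$R))
  expect_gt(length(rr), 100)
  se <- sd(2 * rr) / sqrt(length(rr))
  expect_lt(abs(mean(2 * rr) - 0.01), 2 * se + 1e-4)
  # identical seed, identical lattice
  lat2 <- generateTrabecularLattice(p3@spongiosa, mi, seed = 7)
  expect_identical(lat@scale, lat2@scale)
  expect_identical(lat@rods$z$R, lat2@rods$z$R)
})

test_that("unreachable BV/TV window fails after bounded retries", {
  p <- addCorticalShell(buildSolid(ShapeSpec("box", c(1, 1, 1))), 0.05)
  mi <- new("MicroSpec", tb_th = 0.01, tb_th_sd = 0.001, tb_sp = 0.03,
            tb_sp_sd = 0.003, bvtv = 0.97, bvtv_range = c(0.96, 0.98))
  expect_error(
    generateTrabecularLattice(p@spongiosa, mi, seed = 3, max_iter = 4,
                              segment_id = "impossible_seg"),
    "impossible_seg")
})

test_that("aligned voxelization is exact and shell error shrinks with resolution", {
  # box with a grid dividing the edges exactly: marrow count reproduces the
  # volume to machine precision
  p <- addCorticalShell(buildSolid(ShapeSpec("box", c(1, 0.8, 0.6))), 0)
  ph <- voxelize(p, 0.05)
  v <- phantomVolumes(ph)
  expect_equal(v$volume[v$label == "marrow"], 1 * 0.8 * 0.6,
               tolerance = 1e-12)
  expect_equal(v$count[v$label == "outside"] + v$count[v$label == "cortical"] +
                 v$count[v$label == "trabecular"] + v$count[v$label == "marrow"],
               prod(dim(ph@grid)))
  # cube with a 0.1 shell: cortex volume error decreases monotonically
  cube <- addCorticalShell(buildSolid(ShapeSpec("box", c(1, 1, 1))), 0.1)
  trueShell <- 1 - 0.8^3
  errAt <- function(res) {
    v <- phantomVolumes(voxelize(cube, res))
    abs(v$volume[v$label == "cortical"] - trueShell)
  }
  e <- vapply(c(0.05, 0.02, 0.01), errAt, numeric(1))
  expect_true(all(diff(e) <= 0))
})

test_that("voxel resolution rule warns above 0.75 x Tb.Th and not below", {
  p <- addCorticalShell(buildSolid(ShapeSpec("box", c(0.5, 0.5, 0.5))), 0.03)
  mi <- MicroSpec(0.02, 0.06, 0.15, bvtv_range = c(0.1, 0.2))
  lat <- generateTrabecularLattice(p@spongiosa, mi, seed = 2)
  expect_silent(voxelize(p, 0.015, lat))   # 0.75 x 0.02 exactly
  expect_warning(voxelize(p, 0.02, lat), "0.75 x Tb.Th")
  expect_error(voxelize(p, 0.001, lat, voxel_budget = 1e4), "budget")
})

test_that("derived geometry reproduces closed forms and printed spongiosa volumes", {
  # unit-cube spongiosa: V_s = 1, SS = 6
  p <- addCorticalShell(buildSolid(ShapeSpec("box", c(2, 2, 2))), 0.5)
  g <- deriveGeometry(p, bvtv = 0)
  expect_equal(g@V_s, 1)
  expect_equal(g@SS, 6)
  expect_equal(g@V_s, g@V_TBV + g@V_BMV)
  # masses follow the media densities
  g2 <- deriveGeometry(p, bvtv = 0.2)
  expect_equal(g2@m_TBV, 0.2 * 1 * 1.9)
  expect_equal(g2@m_BMV, 0.8 * 1 * 0.98)
  expect_equal(g2@m_CBV, 7 * 1.9)
  # printed small phantom (elliptic cylinder 1.12 x 1.12 x 3, Ct.Th 0.23,
  # lateral shell): printed TBV + BMV = 0.226 + 0.804 = 1.03 cm^3
  tab <- loadFixture("small_phantoms")
  r5 <- tab[tab$n == 5, ]
  p5 <- addCorticalShell(
    buildSolid(ShapeSpec(r5$shape, as.numeric(strsplit(r5$dims, ";")[[1]]))),
    r5$ct_th,
    coverage = as.logical(as.integer(strsplit(r5$coverage, ";")[[1]])))
  g5 <- deriveGeometry(p5, bvtv = r5$bvtv)
  expect_lt(abs(g5@V_s / (r5$tbv + r5$bmv) - 1), 0.05)
  expect_lt(abs(g5@V_CBV / r5$cbv - 1), 0.05)
})

test_that("every printed small phantom reproduces its printed volume partition", {
  tab <- loadFixture("small_phantoms")
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    p <- addCorticalShell(
      buildSolid(ShapeSpec(r$shape, as.numeric(strsplit(r$dims, ";")[[1]]))),
      r$ct_th,
      coverage = as.logical(as.integer(strsplit(r$coverage, ";")[[1]])))
    g <- deriveGeometry(p, bvtv = r$bvtv)
    expect_lt(abs(g@V_s / (r$tbv + r$bmv) - 1), 0.05)
    expect_lt(abs(g@V_CBV / r$cbv - 1), 0.06)
    expect_lt(abs(g@V_TBV / r$tbv - 1), 0.07)
  }
})

test_that("voxel-face surface estimate matches a sphere within 10 %", {
  sph <- addCorticalShell(buildSolid(ShapeSpec("ellipsoid", c(1, 1, 1))), 0)
  ph <- voxelize(sph, 1 / 50)
  g <- deriveGeometry(ph)
  expect_lt(abs(g@SS / pi - 1), 0.10)  # true surface pi d^2 = pi
  # voxel volumes converge too
  expect_lt(abs(g@V_s / (pi / 6) - 1), 0.02)
})
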