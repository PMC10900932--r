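## Analytic stylized solids: membership predicates, volumes, surface areas.
## All solids are centered at the origin (height axis along z); the
## triangular pyramid has its base corner at the origin and apex on the z axis
## image at (0, 0, H).

# Ramanujan's second approximation to the ellipse perimeter (semi-axes A, B)
ellipsePerimeter <- function(A, B) {
  h <- ((A - B) / (A + B))^2
  pi * (A + B) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Thomsen approximation to the ellipsoid surface (semi-axes)
ellipsoidSurface <- function(A, B, C) {
  p <- 1.6075
  4 * pi * ((A^p * B^p + A^p * C^p + B^p * C^p) / 3)^(1 / p)
}

# lateral area of the ruled solid between two parallel ellipses whose major
# axes lie in perpendicular planes; numerical quadrature over the ruling
deformedLateralArea <- function(a, b, c, d, H, n_theta = 360L, n_u = 60L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  u <- (seq_len(n_u) - 0.5) / n_u
  du <- 1 / n_u
  dth <- 2 * pi / n_theta
  area <- 0
  ct <- cos(theta); st <- sin(theta)
  for (ui in u) {
    Ax <- ((1 - ui) * a + ui * d) / 2
    Ay <- ((1 - ui) * b + ui * c) / 2
    dAx <- (d - a) / 2
    dAy <- (c - b) / 2
    # P(theta, u) = (Ax ct, Ay st, u H); cross product of partials
    e1x <- -Ax * st; e1y <- Ay * ct            # d/dtheta
    e2x <- dAx * ct; e2y <- dAy * st; e2z <- H # d/du
    cx <- e1y * e2z
    cy <- -e1x * e2z
    cz <- e1x * e2y - e1y * e2x
    area <- area + sum(sqrt(cx^2 + cy^2 + cz^2)) * dth * du
  }
  area
}

pyramidFaceAreas <- function(a, b, H) {
  c(base = a * b / 2,
    x0 = b * H / 2,
    y0 = a * H / 2,
    slant = 0.5 * sqrt(b^2 * H^2 + a^2 * H^2 + a^2 * b^2))
}

# analytic volume, total surface area and circumscribed box for a ShapeSpec
shapeMetrics <- function(shape) {
  d <- shape@dims
  switch(shape@kind,
    box = list(
      volume = prod(d),
      surface = 2 * (d[1] * d[2] + d[2] * d[3] + d[1] * d[3]),
      box = d, origin = -d / 2),
    elliptic_cylinder = {
      A <- d[1] / 2; B <- d[2] / 2; H <- d[3]
      list(volume = pi * A * B * H,
           surface = ellipsePerimeter(A, B) * H + 2 * pi * A * B,
           box = c(d[1], d[2], H), origin = c(-A, -B, -H / 2))
    },
    deformed_cylinder = {
      a <- d[1]; b <- d[2]; cc <- d[3]; dd <- d[4]; H <- d[5]
      vol <- (pi * H / 24) * (2 * a * b + a * cc + dd * b + 2 * dd * cc)
      surf <- deformedLateralArea(a, b, cc, dd, H) +
        pi / 4 * a * b + pi / 4 * dd * cc
      bx <- max(a, dd); by <- max(b, cc)
      list(volume = vol, surface = surf,
           box = c(bx, by, H), origin = c(-bx / 2, -by / 2, -H / 2))
    },
    ellipsoid = {
      A <- d[1] / 2; B <- d[2] / 2; C <- d[3] / 2
      list(volume = pi / 6 * d[1] * d[2] * d[3],
           surface = ellipsoidSurface(A, B, C),
           box = d, origin = -d / 2)
    },
    triangular_pyramid = {
      a <- d[1]; b <- d[2]; H <- d[3]
      list(volume = a * b * H / 6,
           surface = sum(pyramidFaceAreas(a, b, H)),
           box = c(a, b, H), origin = c(0, 0, 0))
    },
    tube = {
      ri <- d[1]; ro <- d[2]; H <- d[3]
      list(volume = pi * (ro^2 - ri^2) * H,
           surface = 2 * pi * (ro + ri) * H + 2 * pi * (ro^2 - ri^2),
           box = c(2 * ro, 2 * ro, H), origin = c(-ro, -ro, -H / 2))
    },
    stop("unknown shape kind: ", shape@kind))
}

# membership predicate in the solid's own frame, optionally translated by
# `center` (used for shrunken spongiosa solids)
shapeContains <- function(shape, center = c(0, 0, 0)) {
  d <- shape@dims
  force(center)
  switch(shape@kind,
    box = {
      h <- d / 2
      function(x, y, z) {
        abs(x - center[1]) <= h[1] & abs(y - center[2]) <= h[2] &
          abs(z - center[3]) <= h[3]
      }
    },
    elliptic_cylinder = {
      A <- d[1] / 2; B <- d[2] / 2; H <- d[3]
      function(x, y, z) {
        ((x - center[1]) / A)^2 + ((y - center[2]) / B)^2 <= 1 &
          abs(z - center[3]) <= H / 2
      }
    },
    deformed_cylinder = {
      a <- d[1]; b <- d[2]; cc <- d[3]; dd <- d[4]; H <- d[5]
      function(x, y, z) {
        zz <- z - center[3]
        u <- (zz + H / 2) / H
        Ax <- ((1 - u) * a + u * dd) / 2
        Ay <- ((1 - u) * b + u * cc) / 2
        ok <- u >= 0 & u <= 1
        ok & ((x - center[1]) / Ax)^2 + ((y - center[2]) / Ay)^2 <= 1
      }
    },
    ellipsoid = {
      A <- d[1] / 2; B <- d[2] / 2; C <- d[3] / 2
      function(x, y, z) {
        ((x - center[1]) / A)^2 + ((y - center[2]) / B)^2 +
          ((z - center[3]) / C)^2 <= 1
      }
    },
    triangular_pyramid = {
      a <- d[1]; b <- d[2]; H <- d[3]
      function(x, y, z) {
        xx <- x - center[1]; yy <- y - center[2]; zz <- z - center[3]
        s <- 1 - zz / H
        zz >= 0 & zz <= H & xx >= 0 & yy >= 0 &
          xx * b + yy * a <= a * b * s
      }
    },
    tube = {
      ri <- d[1]; ro <- d[2]; H <- d[3]
      function(x, y, z) {
        r2 <- (x - center[1])^2 + (y - center[2])^2
        r2 >= ri^2 & r2 <= ro^2 & abs(z - center[3]) <= H / 2
      }
    })
}

#' Build an analytic stylized solid from a shape specification
#'
#' Returns a [StylizedSolid-class] holding a vectorized point-membership
#' predicate together with the closed-form volume, total boundary surface
#' area and circumscribed box. The deformed cylinder is the ruled solid
#' between two parallel ellipses whose major axes lie in perpendicular
#' planes (a truncated cone is the circular special case); its lateral area
#' is evaluated by quadrature over the ruling.
#'
#' @param shape a [ShapeSpec-class].
#' @return a [StylizedSolid-class].
#' @examples
#' s <- buildSolid(ShapeSpec("box", c(1.1, 0.6, 3)))
#' s@volume  # 1.98
#' @export
buildSolid <- function(shape) {
  validObject(shape)
  m <- shapeMetrics(shape)
  new("StylizedSolid", shape = shape, volume = m$volume,
      surface_area = m$surface, contains = shapeContains(shape),
      box = m$box, origin = m$origin)
}

# Shrink a shape inward by per-surface cortical thicknesses, returning the
# spongiosa StylizedSolid expressed in the parent solid's frame.
shrinkSolid <- function(shape, t) {
  d <- shape@dims
  kind <- shape@kind
  fail <- function() stop("cortical thickness leaves no spongiosa in shape '",
                          kind, "'", call. = FALSE)
  if (kind == "box") {
    lo <- -d / 2 + t[c(1, 3, 5)]
    hi <- d / 2 - t[c(2, 4, 6)]
    nd <- hi - lo
    if (any(nd <= 0)) fail()
    sp <- ShapeSpec("box", nd)
    center <- (hi + lo) / 2
  } else if (kind == "elliptic_cylinder") {
    nd <- c(d[1] - 2 * t[1], d[2] - 2 * t[1], d[3] - t[2] - t[3])
    if (any(nd <= 0)) fail()
    sp <- ShapeSpec("elliptic_cylinder", nd)
    center <- c(0, 0, (t[2] - t[3]) / 2)
  } else if (kind == "deformed_cylinder") {
    nd <- c(d[1:4] - 2 * t[1], d[5] - t[2] - t[3])
    if (any(nd <= 0)) fail()
    sp <- ShapeSpec("deformed_cylinder", nd)
    center <- c(0, 0, (t[2] - t[3]) / 2)
  } else if (kind == "ellipsoid") {
    nd <- d - 2 * t[1]
    if (any(nd <= 0)) fail()
    sp <- ShapeSpec("ellipsoid", nd)
    center <- c(0, 0, 0)
  } else if (kind == "triangular_pyramid") {
    # uniform inward offset of a tetrahedron: similar solid scaled about the
    # incenter by (r - t)/r, r = 3V/(total face area)
    if (length(unique(t[t > 0])) > 1L)
      stop("triangular_pyramid supports a single uniform cortical thickness",
           call. = FALSE)
    tt <- max(t)
    a <- d[1]; b <- d[2]; H <- d[3]
    A <- pyramidFaceAreas(a, b, H)
    r <- 3 * (a * b * H / 6) / sum(A)
    if (tt >= r) fail()
    k <- (r - tt) / r
    I <- (A[["x0"]] * c(a, 0, 0) + A[["y0"]] * c(0, b, 0) +
            A[["base"]] * c(0, 0, H)) / sum(A)
    sp <- ShapeSpec("triangular_pyramid", d * k)
    # inner pyramid = scale about incenter; its base corner maps to
    center <- I * (1 - k)
  } else if (kind == "tube") {
    nd <- c(d[1] + t[2], d[2] - t[1], d[3] - t[3] - t[4])
    if (any(nd <= 0) || nd[1] >= nd[2]) fail()
    sp <- ShapeSpec("tube", nd)
    center <- c(0, 0, (t[3] - t[4]) / 2)
  } else stop("unknown shape kind")
  m <- shapeMetrics(sp)
  new("StylizedSolid", shape = sp, volume = m$volume, surface_area = m$surface,
      contains = shapeContains(sp, center = center),
      box = m$box, origin = m$origin + center)
}

#' Partition a stylized solid into cortical shell and spongiosa
#'
#' The cortical shell occupies the region within the given thickness of each
#' covered outer surface, measured inward; the spongiosa is the same shape
#' family shrunk accordingly (axes reduced by twice the lateral thickness,
#' height trimmed at covered bases). A per-surface thickness vector is
#' accepted for boxes; per-surface values are renormalized so their mean over
#' covered faces equals the requested mean thickness.
#'
#' @param solid a [StylizedSolid-class] from [buildSolid()].
#' @param ct_th mean cortical thickness (cm), or for boxes a per-face vector.
#' @param coverage logical per-surface mask (default: all covered). Surfaces
#'   are ordered x-, x+, y-, y+, z-, z+ for boxes; lateral, bottom, top for
#'   cylinders; outer, inner, bottom, top for tubes.
#' @param mean_ct_th optional target mean thickness; when a per-face vector is
#'   given, the face values are rescaled so their mean over covered faces
#'   equals this target.
#' @return a [PartitionedSolid-class].
#' @examples
#' cube <- buildSolid(ShapeSpec("box", c(2.1, 2.1, 2.1)))
#' p <- addCorticalShell(cube, 0.035)
#' cube@volume - p@spongiosa@volume  # closed-form shell volume
#' @export
addCorticalShell <- function(solid, ct_th,
                             coverage = rep(TRUE, surfaceCount(solid@shape)),
                             mean_ct_th = NULL) {
  ns <- surfaceCount(solid@shape)
  coverage <- as.logical(coverage)
  if (length(coverage) != ns)
    stop("coverage mask must have ", ns, " entries")
  if (any(ct_th < 0)) stop("ct_th must be >= 0")
  if (length(ct_th) == 1L) {
    t <- ifelse(coverage, ct_th, 0)
  } else {
    if (solid@shape@kind != "box")
      stop("per-surface cortical thickness is only supported for boxes")
    if (length(ct_th) != ns)
      stop("per-surface ct_th must have ", ns, " entries")
    t <- ifelse(coverage, ct_th, 0)
    if (!is.null(mean_ct_th) && any(coverage) && mean(t[coverage]) > 0)
      t[coverage] <- t[coverage] * mean_ct_th / mean(t[coverage])
  }
  if (all(t == 0)) {
    sp <- solid  # no shell: spongiosa fills the solid
  } else {
    sp <- shrinkSolid(solid@shape, t)
  }
  new("PartitionedSolid", outer = solid, spongiosa = sp,
      ct_th = t, coverage = coverage)
}

# Extend every linear dimension of a shape by `ext` (used for the
# restricted-geometry SS_ext construction). For tubes the outer radius grows
# by ext/2 and the inner radius is kept.
extendShape <- function(shape, ext) {
  d <- shape@dims
  nd <- switch(shape@kind,
    box = d + ext,
    elliptic_cylinder = d + ext,
    deformed_cylinder = d + ext,
    ellipsoid = d + ext,
    triangular_pyramid = d + ext,
    tube = c(d[1], d[2] + ext / 2, d[3] + ext))
  ShapeSpec(shape@kind, nd)
}
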