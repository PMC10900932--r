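## Rod-like trabecular lattice generation and calibration.

# evaluate `expr` under a local RNG seed without disturbing the caller's state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

# lognormal meanlog/sdlog from arithmetic mean and SD
lnormParams <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  list(mu = log(mean / sqrt(cv2 + 1)), s = sqrt(log(cv2 + 1)))
}

# one rod family: jittered grid of rod lines along `axis`, perpendicular
# plane coordinates (u, v) spanning [u_lo, u_hi] x [v_lo, v_hi]
makeRodFamily <- function(u_rng, v_rng, micro) {
  d <- micro@tb_sp + micro@tb_th
  gridSeq <- function(rng) {
    if (rng[1] + d / 2 > rng[2]) numeric(0)
    else seq(rng[1] + d / 2, rng[2], by = d)
  }
  us <- gridSeq(u_rng)
  vs <- gridSeq(v_rng)
  nu <- length(us); nv <- length(vs)
  if (nu == 0L || nv == 0L)
    return(list(u0 = u_rng[1] + d / 2, v0 = v_rng[1] + d / 2, d = d,
                U = matrix(numeric(0), 0, 0), V = matrix(numeric(0), 0, 0),
                R = matrix(numeric(0), 0, 0)))
  U <- matrix(us, nu, nv) + matrix(stats::rnorm(nu * nv, 0, micro@tb_sp_sd), nu, nv)
  V <- matrix(vs, nu, nv, byrow = TRUE) +
    matrix(stats::rnorm(nu * nv, 0, micro@tb_sp_sd), nu, nv)
  lp <- lnormParams(micro@tb_th, max(micro@tb_th_sd, 1e-12))
  R <- matrix(stats::rlnorm(nu * nv, lp$mu, lp$s) / 2, nu, nv)
  list(u0 = us[1], v0 = vs[1], d = d, U = U, V = V, R = R)
}

# vectorized membership of points (u, v) in the discs of a rod family,
# radii scaled by `scale`; only the 3x3 grid neighborhood is examined
# (positional jitter is small relative to the spacing)
familyHit <- function(fam, u, v, scale) {
  nu <- nrow(fam$U); nv <- ncol(fam$U)
  if (nu == 0L || nv == 0L) return(rep(FALSE, length(u)))
  iu <- round((u - fam$u0) / fam$d) + 1L
  jv <- round((v - fam$v0) / fam$d) + 1L
  hit <- rep(FALSE, length(u))
  for (di in -1:1) for (dj in -1:1) {
    ii <- pmin(pmax(iu + di, 1L), nu)
    jj <- pmin(pmax(jv + dj, 1L), nv)
    idx <- (jj - 1L) * nu + ii
    hit <- hit | ((u - fam$U[idx])^2 + (v - fam$V[idx])^2 <=
                    (scale * fam$R[idx])^2)
  }
  hit
}

# bone membership of 3-D points under a lattice (x/y/z rod families)
latticeHit <- function(rods, x, y, z, scale) {
  # z-family: rods along z, plane (x, y); x-family: along x, plane (y, z);
  # y-family: along y, plane (x, z)
  familyHit(rods$z, x, y, scale) |
    familyHit(rods$x, y, z, scale) |
    familyHit(rods$y, x, z, scale)
}

#' Generate a rod-like trabecular lattice inside a spongiosa region
#'
#' Three orthogonal families of cylindrical rods are laid on grids with
#' spacing `tb_sp + tb_th`, positions jittered with SD `tb_sp_sd`, and rod
#' diameters drawn lognormally with mean `tb_th` and SD `tb_th_sd`. A final
#' uniform thickness scale is calibrated (by point sampling inside the
#' spongiosa) so the realized bone volume fraction lands inside
#' `micro@bvtv_range`; if the range cannot be reached within the retry
#' budget the function fails naming the segment.
#'
#' A target `bvtv = 0` with range `c(0, 0)` yields an all-marrow spongiosa
#' (no rods).
#'
#' @param spongiosa a [StylizedSolid-class] spongiosa region (e.g.
#'   `addCorticalShell(...)@spongiosa`).
#' @param micro a [MicroSpec-class].
#' @param seed integer RNG seed (draws are local; global RNG state is left
#'   untouched).
#' @param n_points number of calibration sample points inside the spongiosa.
#' @param max_iter calibration iterations before giving up.
#' @param segment_id label used in error messages.
#' @return a [TrabecularLattice-class].
#' @export
generateTrabecularLattice <- function(spongiosa, micro, seed,
                                      n_points = 8000L, max_iter = 30L,
                                      segment_id = "segment") {
  if (micro@bvtv_range[2] == 0) {
    return(new("TrabecularLattice",
               rods = list(x = makeRodFamily(c(0, -1), c(0, -1), micro),
                           y = makeRodFamily(c(0, -1), c(0, -1), micro),
                           z = makeRodFamily(c(0, -1), c(0, -1), micro)),
               micro = micro, scale = 0, bvtv_target = 0,
               bvtv_calibrated = 0, seed = seed))
  }
  validObject(micro)
  o <- spongiosa@origin; b <- spongiosa@box
  withSeed(seed, {
    rods <- list(
      z = makeRodFamily(c(o[1], o[1] + b[1]), c(o[2], o[2] + b[2]), micro),
      x = makeRodFamily(c(o[2], o[2] + b[2]), c(o[3], o[3] + b[3]), micro),
      y = makeRodFamily(c(o[1], o[1] + b[1]), c(o[3], o[3] + b[3]), micro))
    # quasi-uniform points inside the spongiosa (rejection from the box)
    pts <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(pts) < n_points && tries < 50L) {
      m <- stats::runif(3L * n_points)
      cand <- cbind(o[1] + b[1] * m[seq_len(n_points)],
                    o[2] + b[2] * m[n_points + seq_len(n_points)],
                    o[3] + b[3] * m[2L * n_points + seq_len(n_points)])
      keep <- spongiosa@contains(cand[, 1], cand[, 2], cand[, 3])
      pts <- rbind(pts, cand[keep, , drop = FALSE])
      tries <- tries + 1L
    }
    if (nrow(pts) < 100L)
      stop("could not sample points inside spongiosa of ", segment_id)
    pts <- pts[seq_len(min(nrow(pts), n_points)), , drop = FALSE]
    bvtvAt <- function(s)
      mean(latticeHit(rods, pts[, 1], pts[, 2], pts[, 3], s))
    target <- micro@bvtv
    # thin-rod initialization: coverage scales ~ scale^2
    p1 <- bvtvAt(1)
    scale <- if (p1 > 0) sqrt(target / p1) else 1
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      p <- bvtvAt(scale)
      if (p >= micro@bvtv_range[1] && p <= micro@bvtv_range[2]) {
        ok <- TRUE
        break
      }
      if (p <= 0) scale <- scale * 2
      else scale <- scale * sqrt(target / p)
    }
    if (!ok)
      stop("bvtv_range [", micro@bvtv_range[1], ", ", micro@bvtv_range[2],
           "] unreachable for ", segment_id,
           " (last realized BV/TV = ", signif(p, 3), ")")
    new("TrabecularLattice", rods = rods, micro = micro, scale = scale,
        bvtv_target = target, bvtv_calibrated = p, seed = seed)
  })
}

#' Mean realized rod diameter of a lattice
#'
#' @param lattice a [TrabecularLattice-class].
#' @return mean rod diameter (cm) after the calibration scale.
#' @export
meanRodDiameter <- function(lattice) {
  r <- unlist(lapply(lattice@rods, function(f) f$R))
  if (length(r) == 0) return(0)
  2 * lattice@scale * mean(r)
}
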