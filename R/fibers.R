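#' Harmonic transmural coordinate
#'
#' Solves the Laplace problem on the wall with Dirichlet data e = 0 on the
#' epicardium and e = 1 on the endocardium, the standard rule-based
#' realization of a transmural interpolation coordinate. The discrete field
#' is clamped to [0, 1] (quadratic elements can overshoot the continuous
#' maximum principle by a discretization-level amount).
#'
#' @param mesh an `lv_mesh` with labeled `endo` and `epi` facets.
#' @return numeric vector of nodal values e in [0, 1].
#' @export
solve_transmural_coordinate <- function(mesh) {
  if (is.null(mesh$faces$endo) || is.null(mesh$faces$epi) ||
      nrow(mesh$faces$endo) == 0 || nrow(mesh$faces$epi) == 0)
    stop_lv("mesh must carry labeled endo and epi facets")
  K <- tet10_laplace(mesh$nodes, mesh$elems - 1L)
  n <- nrow(mesh$nodes)
  Ksp <- Matrix::sparseMatrix(i = K$i, j = K$j, x = K$x, dims = c(n, n))
  endo_n <- unique(as.vector(mesh$faces$endo))
  epi_n <- unique(as.vector(mesh$faces$epi))
  e <- numeric(n)
  e[endo_n] <- 1
  fixed <- union(endo_n, epi_n)
  free <- setdiff(seq_len(n), fixed)
  rhs <- -Ksp[free, fixed, drop = FALSE] %*% e[fixed]
  e[free] <- as.numeric(Matrix::solve(Ksp[free, free], rhs))
  pmin(pmax(e, 0), 1)
}

#' Local circumferential/longitudinal/transmural frames at quadrature points
#'
#' Builds per-quadrature-point orthonormal triads (c, l, t): t is the
#' transmural direction (endocardium to epicardium, i.e. minus the normalized
#' gradient of the transmural coordinate), l the projection of the global
#' apex-to-base axis (+z) orthogonal to t, and c = l x t the circumferential
#' direction. Quadrature points where the projection degenerates (the apex
#' region, a cap of configurable height) inherit the frame of the nearest
#' regular point.
#'
#' @param mesh an `lv_mesh`.
#' @param e nodal transmural coordinate from [solve_transmural_coordinate()].
#' @param apex_cap_frac apex cap height as a fraction of cavity length
#'   (default 0.02); points within the cap are regularized.
#' @return object of class `lv_frames`: list with `c`, `l`, `t` (nq x 3),
#'   `e_qp`, `x_qp`, `w_qp` and the degenerate-point index.
#' @export
build_local_frames <- function(mesh, e, apex_cap_frac = 0.02) {
  qp <- tet10_scalar_qp(mesh$nodes, mesh$elems - 1L, e)
  qp$value <- as.numeric(qp$value)
  qp$wref <- as.numeric(qp$wref)
  g <- qp$grad
  gn <- sqrt(rowSums(g^2))
  tdir <- -g / pmax(gn, 1e-300)
  lz <- cbind(-tdir[, 3] * tdir[, 1], -tdir[, 3] * tdir[, 2], 1 - tdir[, 3]^2)
  ln <- sqrt(rowSums(lz^2))
  cav_len <- mesh$spec$cavity_length %||% diff(range(mesh$nodes[, 3]))
  z_apex <- min(qp$x[, 3])
  bad <- gn < 1e-8 | ln < 1e-6 | qp$x[, 3] < z_apex + apex_cap_frac * cav_len
  if (all(bad)) stop_lv("degenerate transmural gradient region covers the whole mesh")
  if (mean(bad) > 0.2)
    stop_lv("zero-gradient/apex region exceeds the declared apex cap (%.0f%% of points)",
            100 * mean(bad))
  lv <- lz / pmax(ln, 1e-300)
  # c = l x t
  cv <- cbind(lv[, 2] * tdir[, 3] - lv[, 3] * tdir[, 2],
              lv[, 3] * tdir[, 1] - lv[, 1] * tdir[, 3],
              lv[, 1] * tdir[, 2] - lv[, 2] * tdir[, 1])
  cv <- cv / pmax(sqrt(rowSums(cv^2)), 1e-300)
  if (any(bad)) {
    good <- which(!bad)
    for (i in which(bad)) {
      d2 <- (qp$x[good, 1] - qp$x[i, 1])^2 + (qp$x[good, 2] - qp$x[i, 2])^2 +
        (qp$x[good, 3] - qp$x[i, 3])^2
      j <- good[which.min(d2)]
      tdir[i, ] <- tdir[j, ]; lv[i, ] <- lv[j, ]; cv[i, ] <- cv[j, ]
    }
  }
  structure(list(c = cv, l = lv, t = tdir, e_qp = qp$value, x_qp = qp$x,
                 w_qp = qp$wref, degenerate = which(bad)),
            class = "lv_frames")
}

#' Helix-angle configuration
#'
#' A transmural helix profile is defined by the transmural-averaged helix
#' angle `tau_bar` and the epicardial-to-endocardial difference `tau_diff`:
#' the epicardial fiber angle is `tau_bar - tau_diff/2` and the endocardial
#' angle `tau_bar + tau_diff/2`, varying linearly across the wall.
#'
#' @param tau_bar transmural-averaged helix angle, degrees.
#' @param tau_diff epicardial-to-endocardial helix angle difference, degrees.
#' @return object of class `helix_config`.
#' @export
helix_config <- function(tau_bar, tau_diff) {
  if (!is.finite(tau_bar) || !is.finite(tau_diff))
    stop_lv("helix configuration must be finite")
  if (tau_bar < -90 || tau_bar > 180 || tau_diff < -90 || tau_diff > 180)
    warning("helix configuration outside the swept range [-90, 180] degrees")
  structure(list(tau_bar = tau_bar, tau_diff = tau_diff), class = "helix_config")
}

#' Helix angle at a transmural coordinate
#' @param e transmural coordinate in [0,1] (0 epicardium, 1 endocardium).
#' @param config a [helix_config()].
#' @return helix angle alpha in degrees, linear in e.
#' @export
helix_angle <- function(e, config) {
  config$tau_bar + (e - 0.5) * config$tau_diff
}

#' Assign a rule-based helix fiber field
#'
#' Fiber direction f = cos(alpha) c + sin(alpha) l rotates from the local
#' circumferential direction toward the apex-to-base longitudinal direction
#' by the helix angle alpha(e) = tau_bar + (e - 1/2) tau_diff (degrees),
#' linear across the wall; the sheet direction s is the transmural direction
#' t (transverse angle 0) and n = f x s.
#'
#' @param mesh an `lv_mesh`.
#' @param frames [build_local_frames()] output.
#' @param config a [helix_config()].
#' @return object of class `lv_fibers`: `f`, `s`, `n` (nq x 3), `alpha`
#'   (degrees), `e_qp`, and a `frames_mat` (nq x 9) column-block (f|s|n)
#'   matrix as consumed by the FE kernels.
#' @export
assign_helix_field <- function(mesh, frames, config) {
  a <- helix_angle(frames$e_qp, config) * pi / 180
  f <- cos(a) * frames$c + sin(a) * frames$l
  s <- frames$t
  n <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
             f[, 3] * s[, 1] - f[, 1] * s[, 3],
             f[, 1] * s[, 2] - f[, 2] * s[, 1])
  structure(list(f = f, s = s, n = n, alpha = a * 180 / pi,
                 e_qp = frames$e_qp, x_qp = frames$x_qp, w_qp = frames$w_qp,
                 config = config, frames_mat = cbind(f, s, n),
                 cl = list(c = frames$c, l = frames$l, t = frames$t)),
            class = "lv_fibers")
}

# convenience: transmural coordinate + frames + fibers in one call
#' Build the complete fiber field for a mesh and helix configuration
#' @inheritParams assign_helix_field
#' @param e optional precomputed nodal transmural coordinate.
#' @param apex_cap_frac passed to [build_local_frames()].
#' @export
build_fiber_field <- function(mesh, config, e = NULL, apex_cap_frac = 0.02) {
  e <- e %||% solve_transmural_coordinate(mesh)
  fr <- build_local_frames(mesh, e, apex_cap_frac)
  fib <- assign_helix_field(mesh, fr, config)
  fib$e_nodal <- e
  fib
}
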