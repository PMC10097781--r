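#' Idealized LV geometry specification
#'
#' Builds the dimensional specification of an idealized left-ventricular (LV)
#' geometry: a half-prolate (or oblate/hemispherical) ellipsoidal cavity with
#' a uniform-offset outer wall, truncated by a flat base plane at z = 0 with
#' the apex pointing toward negative z. The fetal reference family is built
#' around the "symmetric" shape (cavity length 16.00 mm, basal cavity width
#' 13.40 mm, 3 mm wall); the alternative shapes (hypertrophic, long,
#' hemisphere, wide) are volume-matched to the symmetric cavity in closed
#' form. The "regular" shape is the symmetric-family prolate at physiological
#' 32-week dimensions (18.75 x 15.40 mm) with a medially leaning apex, and
#' "adult_regular" is a size-scaled adult prolate (85 x 45 x 9 mm).
#'
#' @param shape one of "symmetric", "hypertrophic", "long", "hemisphere",
#'   "wide", "regular", "adult_regular".
#' @param wall_thickness wall thickness in mm (default per shape).
#' @param cavity_length cavity long-axis length in mm (base plane to endo
#'   apex; default per shape).
#' @param basal_cavity_width cavity diameter at the base in mm (default per
#'   shape; for volume-matched shapes derived in closed form).
#' @param target_cavity_volume cavity volume in ml that volume-matched shapes
#'   must reproduce (default: the symmetric reference volume).
#' @param septal_lean_amplitude apex lean in mm toward +x (asymmetry; 0 for
#'   the symmetric family, default 2 mm for "regular").
#' @return an object of class `lv_geometry_spec`.
#' @export
lv_geometry_spec <- function(shape = c("symmetric", "hypertrophic", "long",
                                       "hemisphere", "wide", "regular",
                                       "adult_regular"),
                             wall_thickness = NULL, cavity_length = NULL,
                             basal_cavity_width = NULL,
                             target_cavity_volume = NULL,
                             septal_lean_amplitude = NULL) {
  shape <- match.arg(shape)
  # symmetric fetal reference: half prolate, a = 16.00, b = 13.40/2
  a_sym <- 16.00; b_sym <- 13.40 / 2
  v_sym <- (2 / 3) * pi * a_sym * b_sym^2 / 1000  # ml
  vt <- target_cavity_volume %||% v_sym
  vmm <- vt * 1000
  lean <- septal_lean_amplitude %||% (if (shape == "regular") 2.0 else 0.0)
  tw <- wall_thickness %||% (if (shape == "hypertrophic") 6.0
                             else if (shape == "adult_regular") 9.0 else 3.0)
  if (shape %in% c("symmetric", "hypertrophic")) {
    L <- cavity_length %||% a_sym
    W <- basal_cavity_width %||% (2 * b_sym)
  } else if (shape == "long") {
    L <- cavity_length %||% (1.5 * a_sym)
    # free radius from (2/3) pi L b^2 = V
    W <- basal_cavity_width %||% (2 * sqrt(vmm / ((2 / 3) * pi * L)))
  } else if (shape == "hemisphere") {
    r <- (vmm / ((2 / 3) * pi))^(1 / 3)
    L <- cavity_length %||% r
    W <- basal_cavity_width %||% (2 * r)
  } else if (shape == "wide") {
    # oblate: aspect ratio (length/radius) is the reciprocal arrangement of
    # the symmetric prolate; radius solved so the cavity volume matches
    k <- b_sym / a_sym
    b <- (vmm / ((2 / 3) * pi * k))^(1 / 3)
    L <- cavity_length %||% (k * b)
    W <- basal_cavity_width %||% (2 * b)
  } else if (shape == "regular") {
    L <- cavity_length %||% 18.75
    W <- basal_cavity_width %||% 15.40
  } else {  # adult_regular
    L <- cavity_length %||% 85
    W <- basal_cavity_width %||% 45
  }
  spec <- structure(list(shape = shape, wall_thickness = tw,
                         cavity_length = L, basal_cavity_width = W,
                         target_cavity_volume = vt,
                         septal_lean_amplitude = lean),
                    class = "lv_geometry_spec")
  validate_geometry_spec(spec)
  spec
}

validate_geometry_spec <- function(spec) {
  with(spec, {
    if (any(c(wall_thickness, cavity_length, basal_cavity_width) <= 0))
      stop_lv("geometry spec: all dimensions must be positive")
    if (wall_thickness >= basal_cavity_width / 2)
      stop_lv("geometry spec (%s): wall_thickness %.3g must be < basal_cavity_width/2 = %.3g",
              shape, wall_thickness, basal_cavity_width / 2)
    if (shape == "hemisphere" &&
        abs(cavity_length - basal_cavity_width / 2) > 1e-6 * cavity_length)
      stop_lv("hemisphere spec requires cavity_length = basal_cavity_width/2")
  })
  invisible(spec)
}

#' @export
print.lv_geometry_spec <- function(x, ...) {
  cat(sprintf("LV geometry spec [%s]: cavity length %.2f mm, basal width %.2f mm, wall %.2f mm\n",
              x$shape, x$cavity_length, x$basal_cavity_width, x$wall_thickness))
  cat(sprintf("  analytic cavity volume %.4f ml, septal lean %.2f mm\n",
              analytic_cavity_volume(x), x$septal_lean_amplitude))
  invisible(x)
}

#' Closed-form cavity volume (ml) of an idealized geometry spec
#' @param spec an `lv_geometry_spec`.
#' @export
analytic_cavity_volume <- function(spec) {
  b <- spec$basal_cavity_width / 2
  (2 / 3) * pi * spec$cavity_length * b^2 / 1000
}

# parametric map of the wall: e in [0,1] (0 = epicardium, 1 = endocardium),
# v in [0, pi/2] (0 = base, pi/2 = apex), theta azimuth.
param_to_xyz <- function(e, v, theta, spec) {
  a_en <- spec$cavity_length
  b_en <- spec$basal_cavity_width / 2
  tw <- spec$wall_thickness
  surf <- function(a, b) cbind(b * cos(v) * cos(theta),
                               b * cos(v) * sin(theta),
                               -a * sin(v))
  (1 - e) * surf(a_en + tw, b_en + tw) + e * surf(a_en, b_en)
}

# Dompierre et al. indexed prism-to-tetrahedra split: conforming across
# shared quad faces because every face diagonal passes through the face's
# smallest global vertex id.
split_prism <- function(v) {
  rot_bot <- function(v) v[c(2, 3, 1, 5, 6, 4)]
  flip <- function(v) v[c(4, 6, 5, 1, 3, 2)]
  if (which.min(v) > 3) v <- flip(v)
  while (which.min(v) != 1) v <- rot_bot(v)
  if (min(v[2], v[6]) < min(v[3], v[5])) {
    rbind(v[c(1, 2, 3, 6)], v[c(1, 2, 6, 5)], v[c(1, 5, 6, 4)])
  } else {
    rbind(v[c(1, 2, 3, 5)], v[c(1, 5, 3, 6)], v[c(1, 5, 6, 4)])
  }
}

#' Generate an idealized LV wall mesh of 10-node quadratic tetrahedra
#'
#' Meshes the half-ellipsoidal wall between the endocardial and epicardial
#' surfaces of an [lv_geometry_spec()] with quadratic (10-node) tetrahedra,
#' curved by placing midside nodes through the parametric surface map.
#' Boundary facets are labeled `endo`, `epi` and `base`. With default
#' resolution the mesh has at least 2500 elements; the structured counts can
#' be overridden (e.g. for fast tests) via `n_trans`, `n_long`, `n_circ`.
#'
#' @param spec an [lv_geometry_spec()].
#' @param resolution target element size in mm (ignored when explicit counts
#'   are given).
#' @param n_trans,n_long,n_circ optional structured cell counts across the
#'   wall, along the meridian, and around the circumference.
#' @return an object of class `lv_mesh` with fields `nodes` (N x 3 mm),
#'   `elems` (E x 10 connectivity), `faces` (list of labeled TRI6 facet
#'   matrices), `param` (per-node parametric coordinates) and `spec`.
#' @export
generate_idealized_lv <- function(spec, resolution = 2.0, n_trans = NULL,
                                  n_long = NULL, n_circ = NULL) {
  validate_geometry_spec(spec)
  b_mid <- spec$basal_cavity_width / 2 + spec$wall_thickness / 2
  a_mid <- spec$cavity_length + spec$wall_thickness / 2
  meridian <- (pi / 2) * sqrt((a_mid^2 + b_mid^2) / 2)
  n_e <- n_trans %||% max(1L, round(spec$wall_thickness / resolution))
  n_v <- n_long %||% max(4L, ceiling(meridian / resolution))
  n_t <- n_circ %||% max(8L, ceiling(2 * pi * b_mid / resolution))
  mesh <- lv_mesh_prolate(spec, n_e, n_v, n_t)
  if (spec$septal_lean_amplitude != 0)
    mesh <- make_asymmetric_fixture(mesh, spec$septal_lean_amplitude)
  mesh
}

lv_mesh_prolate <- function(spec, n_e, n_v, n_t) {
  layer_size <- n_v * n_t + 1L
  node_id <- function(i, j, k) {  # 1-based; j in 0..n_v-1, k in 0..n_t-1
    i * layer_size + j * n_t + (k %% n_t) + 1L
  }
  apex_id <- function(i) i * layer_size + n_v * n_t + 1L
  n_nodes <- (n_e + 1L) * layer_size
  par_e <- par_v <- par_t <- numeric(n_nodes)
  for (i in 0:n_e) {
    base <- i * layer_size
    jj <- rep(0:(n_v - 1L), each = n_t)
    kk <- rep(0:(n_t - 1L), n_v)
    idx <- base + seq_len(n_v * n_t)
    par_e[idx] <- i / n_e
    par_v[idx] <- jj / n_v * (pi / 2)
    par_t[idx] <- kk / n_t * 2 * pi
    par_e[base + layer_size] <- i / n_e
    par_v[base + layer_size] <- pi / 2
    par_t[base + layer_size] <- NA_real_
  }

  # surface triangulation of one (j,k) grid layer, as local (j,k) ids
  tris <- list()
  for (j in 0:(n_v - 2L)) for (k in 0:(n_t - 1L)) {
    A <- c(j, k); B <- c(j, k + 1L); C <- c(j + 1L, k + 1L); D <- c(j + 1L, k)
    if ((j + k) %% 2L == 0L) {
      tris[[length(tris) + 1L]] <- rbind(A, B, C)
      tris[[length(tris) + 1L]] <- rbind(A, C, D)
    } else {
      tris[[length(tris) + 1L]] <- rbind(A, B, D)
      tris[[length(tris) + 1L]] <- rbind(B, C, D)
    }
  }
  tets <- vector("list", 0)
  add_prism <- function(bot, top) split_prism(c(bot, top))
  for (i in 0:(n_e - 1L)) {
    for (tr in tris) {
      bot <- node_id(i, tr[, 1], tr[, 2])
      top <- node_id(i + 1L, tr[, 1], tr[, 2])
      tets[[length(tets) + 1L]] <- add_prism(bot, top)
    }
    for (k in 0:(n_t - 1L)) {
      bot <- c(node_id(i, n_v - 1L, k), node_id(i, n_v - 1L, k + 1L), apex_id(i))
      top <- c(node_id(i + 1L, n_v - 1L, k), node_id(i + 1L, n_v - 1L, k + 1L), apex_id(i + 1L))
      tets[[length(tets) + 1L]] <- add_prism(bot, top)
    }
  }
  tets <- do.call(rbind, tets)

  nodes <- param_to_xyz(par_e, par_v, ifelse(is.na(par_t), 0, par_t), spec)

  # orient tets to positive volume
  v6 <- tet_signed_volume(nodes, tets)
  neg <- v6 < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  if (any(abs(v6) < 1e-12)) stop_lv("degenerate tetrahedron in structured mesh")

  # quadratic midside nodes via parametric averaging (curved elements)
  edge_pairs <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  e1 <- tets[, edge_pairs[, 1]]; e2 <- tets[, edge_pairs[, 2]]
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  key <- paste(lo, hi)
  ukey <- !duplicated(key)
  mid_of <- match(key, key[ukey])
  ulo <- lo[ukey]; uhi <- hi[ukey]
  em <- (par_e[ulo] + par_e[uhi]) / 2
  vm <- (par_v[ulo] + par_v[uhi]) / 2
  t1 <- par_t[ulo]; t2 <- par_t[uhi]
  tm <- ifelse(is.na(t1), t2, ifelse(is.na(t2), t1, {
    d <- ((t2 - t1 + pi) %% (2 * pi)) - pi
    t1 + d / 2
  }))
  tm[is.na(tm)] <- 0
  mid_nodes <- param_to_xyz(em, vm, tm, spec)
  n0 <- nrow(nodes)
  nodes <- rbind(nodes, mid_nodes)
  par_e <- c(par_e, em); par_v <- c(par_v, vm)
  par_t <- c(par_t, ifelse(is.na(t1) & is.na(t2), NA_real_, tm))
  elems <- cbind(tets, matrix(n0 + mid_of, nrow = nrow(tets), ncol = 6))
  storage.mode(elems) <- "integer"
  dimnames(elems) <- NULL

  mesh <- structure(list(nodes = nodes, elems = elems,
                         param = data.frame(e = par_e, v = par_v, theta = par_t),
                         spec = spec,
                         counts = c(n_trans = n_e, n_long = n_v, n_circ = n_t)),
                    class = "lv_mesh")
  mesh$faces <- label_boundary_faces(mesh)
  jmin <- tet10_min_jacobian(mesh$nodes, mesh$elems - 1L)
  if (any(jmin <= 0)) stop_lv("mesh has non-positive element Jacobians")
  # orient endocardial faces so the enclosed cavity volume is positive
  v <- cavity_volume_grad(mesh$nodes, mesh$faces$endo - 1L,
                          numeric(3 * nrow(mesh$nodes)), FALSE)$volume
  if (v < 0) mesh$faces$endo <- mesh$faces$endo[, c(1, 3, 2, 6, 5, 4), drop = FALSE]
  mesh
}

tet_signed_volume <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE]
  c_ <- nodes[tets[, 3], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# extract boundary TRI6 faces of a TET10 mesh and label them endo/epi/base
# using per-node parametric coordinates (or, for meshes without parametric
# data, geometric classification against the spec surfaces).
label_boundary_faces <- function(mesh) {
  elems <- mesh$elems
  # local faces (corners + their midside nodes), ordered so the normal points
  # out of the tet
  lf <- rbind(c(1, 3, 2, 7, 6, 5),
              c(1, 2, 4, 5, 9, 8),
              c(2, 3, 4, 6, 10, 9),
              c(1, 4, 3, 8, 10, 7))
  faces <- do.call(rbind, lapply(1:4, function(s) elems[, lf[s, ], drop = FALSE]))
  key <- apply(faces[, 1:3, drop = FALSE], 1, function(r) paste(sort(r), collapse = " "))
  cnt <- table(key)
  bnd <- faces[cnt[key] == 1L, , drop = FALSE]
  pe <- mesh$param$e; pv <- mesh$param$v
  tol <- 1e-9
  on_endo <- matrix(pe[bnd] > 1 - tol, nrow = nrow(bnd))
  on_epi <- matrix(pe[bnd] < tol, nrow = nrow(bnd))
  on_base <- matrix(pv[bnd] < tol, nrow = nrow(bnd))
  lab <- rep(NA_character_, nrow(bnd))
  lab[rowSums(on_endo) == 6L] <- "endo"
  lab[rowSums(on_epi) == 6L] <- "epi"
  lab[rowSums(on_base) == 6L] <- "base"
  if (anyNA(lab)) stop_lv("unclassified boundary facet (mesh labeling failed)")
  list(endo = bnd[lab == "endo", , drop = FALSE],
       epi = bnd[lab == "epi", , drop = FALSE],
       base = bnd[lab == "base", , drop = FALSE])
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV mesh [%s]: %d nodes, %d quadratic tetrahedra\n",
              x$spec$shape %||% "custom", nrow(x$nodes), nrow(x$elems)))
  cat(sprintf("  facets: endo %d, epi %d, base %d; cavity volume %.4f ml\n",
              nrow(x$faces$endo), nrow(x$faces$epi), nrow(x$faces$base),
              compute_cavity_volume(x)))
  invisible(x)
}

#' Cavity volume of an LV mesh by the divergence theorem
#'
#' Integrates the flux of x/3 over the (curved quadratic) endocardial surface;
#' the flat basal cap at z = 0 contributes nothing to the flux, so the
#' endocardial surface plus the implicit cap encloses the cavity. Errors if
#' the endocardial surface is not closed against the base plane.
#'
#' @param mesh an `lv_mesh`.
#' @param U optional nodal displacement vector (3N, mm) for a deformed state.
#' @return cavity volume in ml.
#' @export
compute_cavity_volume <- function(mesh, U = NULL) {
  if (is.null(mesh$faces$endo) || nrow(mesh$faces$endo) == 0)
    stop_lv("mesh has no labeled endocardial facets")
  check_endo_closed(mesh, U)
  U <- U %||% numeric(3 * nrow(mesh$nodes))
  v <- cavity_volume_grad(mesh$nodes, mesh$faces$endo - 1L, U, FALSE)$volume
  if (v <= 0) stop_lv("non-positive cavity volume (check facet orientation)")
  v / 1000
}

check_endo_closed <- function(mesh, U = NULL) {
  f <- mesh$faces$endo
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  open_edges <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  if (nrow(open_edges) == 0) return(invisible(TRUE))
  z <- mesh$nodes[unique(as.vector(open_edges)), 3]
  if (!is.null(U)) z <- z + U[3 * unique(as.vector(open_edges))]
  if (any(abs(z) > 1e-6 * max(1, mesh$spec$cavity_length %||% 1)))
    stop_lv("endocardial surface is open away from the base plane; cavity is not enclosed")
  invisible(TRUE)
}

#' Apply a smooth medial apex lean to an LV mesh
#'
#' Shears the wall in +x as a smooth quadratic function of depth below the
#' base, so the apex leans toward one side (emulating the straight-septum
#' asymmetry of patient-like geometries). The map is a pure shear (unit
#' Jacobian), so wall volume is preserved exactly; facet labels are kept.
#'
#' @param mesh an `lv_mesh`.
#' @param lean apex displacement in mm (0 returns the mesh unchanged).
#' @return the deformed `lv_mesh`.
#' @export
make_asymmetric_fixture <- function(mesh, lean) {
  if (lean == 0) return(mesh)
  z <- mesh$nodes[, 3]
  z_apex <- min(z)
  if (abs(lean) > 0.5 * (mesh$spec$basal_cavity_width %||% (4 * abs(lean))))
    stop_lv("lean amplitude too large relative to cavity width")
  mesh$nodes[, 1] <- mesh$nodes[, 1] + lean * (z / z_apex)^2
  jmin <- tet10_min_jacobian(mesh$nodes, mesh$elems - 1L)
  if (any(jmin <= 0)) stop_lv("lean caused element inversion")
  mesh
}
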