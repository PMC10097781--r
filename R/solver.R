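#' Solver configuration for the quasi-static FE mechanics
#'
#' @param steps_per_cycle time steps per cardiac cycle (>= 20).
#' @param newton_atol absolute residual tolerance (mN).
#' @param newton_rtol relative residual tolerance (vs. the step's initial
#'   residual).
#' @param max_iter maximum Newton iterations per solve.
#' @param epi_spring epicardial Robin spring stiffness, kPa/mm.
#' @param max_substeps maximum load-substep halvings on non-convergence.
#' @param volume_rtol relative cavity-volume tolerance of the
#'   volume-constrained solves.
#' @param apex_cap_frac apex regularization cap for local frames.
#' @export
solver_config <- function(steps_per_cycle = 50, newton_atol = 1e-6,
                          newton_rtol = 1e-9, max_iter = 30,
                          epi_spring = 0.05, max_substeps = 6,
                          volume_rtol = 1e-6, apex_cap_frac = 0.02) {
  if (steps_per_cycle < 20) stop_lv("steps_per_cycle must be >= 20")
  if (newton_atol <= 0 || newton_rtol <= 0 || volume_rtol <= 0)
    stop_lv("tolerances must be positive")
  structure(list(steps_per_cycle = as.integer(steps_per_cycle),
                 newton_atol = newton_atol, newton_rtol = newton_rtol,
                 max_iter = max_iter, epi_spring = epi_spring,
                 max_substeps = max_substeps, volume_rtol = volume_rtol,
                 apex_cap_frac = apex_cap_frac),
            class = "solver_config")
}

#' Assemble an FE model of the LV wall
#'
#' Bundles mesh, fiber field, material and solver settings, precomputing the
#' basal boundary conditions (longitudinal displacement fixed on the base
#' plane, in-plane free), the epicardial Robin spring matrix, and the
#' endocardial facet set used for the follower pressure load and cavity
#' volume.
#'
#' @param mesh an `lv_mesh`.
#' @param fibers an `lv_fibers` field on the same mesh.
#' @param passive [passive_params()].
#' @param active [active_params()] or NULL for passive-only models.
#' @param cfg [solver_config()].
#' @return an object of class `fe_model`.
#' @export
fe_model <- function(mesh, fibers, passive = passive_params(),
                     active = NULL, cfg = solver_config()) {
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  base_nodes <- which(abs(mesh$nodes[, 3]) < 1e-8)
  fixed <- 3L * base_nodes  # z dofs (1-based: dof 3i is z of node i)
  free <- setdiff(seq_len(ndof), fixed)
  ms <- tri6_mass(mesh$nodes, mesh$faces$epi - 1L)
  k <- cfg$epi_spring
  ii <- c(3 * ms$i - 2, 3 * ms$i - 1, 3 * ms$i)
  jj <- c(3 * ms$j - 2, 3 * ms$j - 1, 3 * ms$j)
  xx <- rep(k * ms$x, 3)
  Ks <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  structure(list(mesh = mesh, fibers = fibers, passive = passive,
                 active = active, cfg = cfg, Ks = Ks, free = free,
                 fixed = fixed, ndof = ndof,
                 endo0 = mesh$faces$endo - 1L),
            class = "fe_model")
}

# residual, tangent and diagnostics at (U, cavity pressure p_kpa, time t ms)
fe_assemble_state <- function(model, U, p_kpa, t = -1, want_tangent = TRUE) {
  act <- if (!is.null(model$active)) pact_vec(model$active, t) else pact_vec(active_params(T0_LV = 0), -1)
  a <- fe_assemble(model$mesh$nodes, model$mesh$elems - 1L, U,
                   model$fibers$frames_mat, pmat_vec(model$passive), act,
                   want_tangent)
  cv <- cavity_volume_grad(model$mesh$nodes, model$endo0, U, TRUE)
  gV <- as.numeric(cv$grad)
  R <- as.numeric(a$residual) + as.numeric(model$Ks %*% U) - p_kpa * gV
  out <- list(R = R, V = cv$volume, gV = gV, detF = as.numeric(a$detF),
              W = as.numeric(a$W), wref = as.numeric(a$wref),
              energy = a$energy)
  if (want_tangent) {
    n <- model$ndof
    K <- Matrix::sparseMatrix(i = a$Ki, j = a$Kj, x = a$Kx, dims = c(n, n)) + model$Ks
    if (p_kpa != 0) {
      hv <- cavity_volume_hess(model$mesh$nodes, model$endo0, U)
      K <- K - p_kpa * Matrix::sparseMatrix(i = hv$i, j = hv$j, x = hv$x,
                                            dims = c(n, n))
    }
    out$K <- K
  }
  out
}

# sparse symmetric solve: Cholesky with LU fallback (near limit points the
# tangent can be indefinite)
solve_sym <- function(K, B) {
  res <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE)
    as.matrix(Matrix::solve(ch, B))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res)) res <- as.matrix(Matrix::solve(K, B))
  res
}

# Newton solve at prescribed cavity pressure (kPa). Returns U or errors.
newton_pressure <- function(model, U, p_kpa, t = -1) {
  cfg <- model$cfg
  free <- model$free
  st <- fe_assemble_state(model, U, p_kpa, t)
  r0 <- max(abs(st$R[free]))
  tol <- max(cfg$newton_atol, cfg$newton_rtol * r0)
  hist <- r0
  for (it in seq_len(cfg$max_iter)) {
    if (max(abs(st$R[free])) < tol) return(structure(U, iters = it - 1L))
    dU <- numeric(model$ndof)
    dU[free] <- -solve_sym(st$K[free, free], st$R[free])[, 1]
    # backtracking line search on the residual norm (residual-only probes)
    alpha <- 1
    rprev <- max(abs(st$R[free]))
    repeat {
      Utry <- U + alpha * dU
      sttry <- tryCatch(fe_assemble_state(model, Utry, p_kpa, t,
                                          want_tangent = FALSE),
                        error = function(e) NULL)
      ok <- !is.null(sttry) &&
        (max(abs(sttry$R[free])) < rprev ||
           (alpha <= 1 / 16 && max(abs(sttry$R[free])) < 2 * rprev))
      if (ok) {
        U <- Utry
        break
      }
      alpha <- alpha / 2
      if (alpha < 1 / 128)
        stop_lv("Newton line search stalled at residual %.3g (history: %s)",
                rprev, paste(signif(hist, 3), collapse = ", "))
    }
    st <- fe_assemble_state(model, U, p_kpa, t)
    hist <- c(hist, max(abs(st$R[free])))
  }
  if (max(abs(st$R[free])) < tol) return(structure(U, iters = cfg$max_iter))
  stop_lv("Newton did not converge: residual history %s",
          paste(signif(hist, 3), collapse = ", "))
}

#' Inflate the model to a prescribed cavity pressure
#'
#' Ramps the endocardial (follower) pressure load in substeps and solves the
#' quasi-static equilibrium at each level.
#'
#' @param model an [fe_model()].
#' @param p_mmhg target cavity pressure, mmHg.
#' @param U0 initial displacement guess (default zero).
#' @param nsteps number of pressure substeps.
#' @param t activation time within the cycle in ms, or -1 for passive.
#' @return displacement vector U (3N, mm) with attribute `volume` (ml).
#' @export
inflate_to_pressure <- function(model, p_mmhg, U0 = NULL, nsteps = 5, t = -1) {
  U <- U0 %||% numeric(model$ndof)
  p_target <- p_mmhg * MMHG_TO_KPA
  done <- 0
  step <- 1 / nsteps
  nsub <- 0
  while (done < 1 - 1e-12) {
    frac <- min(1, done + step)
    res <- tryCatch(newton_pressure(model, U, frac * p_target, t),
                    error = function(e) e)
    if (inherits(res, "error")) {
      step <- step / 2
      nsub <- nsub + 1
      if (nsub > model$cfg$max_substeps)
        stop_lv("pressure inflation failed at load fraction %.3g: %s",
                frac, conditionMessage(res))
    } else {
      U <- res
      done <- frac
    }
  }
  v <- cavity_volume_grad(model$mesh$nodes, model$endo0, U, FALSE)$volume
  structure(as.numeric(U), volume = v / 1000)
}

# Bordered Newton: solve equilibrium with the cavity pressure as a Lagrange
# multiplier enforcing V(U) = V_target (mm^3). Returns list(U, p_kpa, V).
solve_volume_kpa <- function(model, U, p_kpa, V_target, t = -1) {
  cfg <- model$cfg
  free <- model$free
  merit <- function(st) {
    gscale <- max(max(abs(st$gV)), 1e-12)
    sqrt(max(abs(st$R[free]))^2 + (gscale * (st$V - V_target) /
                                     max(abs(V_target), 1e-9))^2)
  }
  st <- fe_assemble_state(model, U, p_kpa, t)
  tol <- max(cfg$newton_atol, cfg$newton_rtol * max(abs(st$R[free])))
  cav <- max(abs(model$mesh$nodes))
  for (it in seq_len(cfg$max_iter)) {
    rnorm <- max(abs(st$R[free]))
    verr <- abs(st$V - V_target) / max(abs(V_target), 1e-9)
    if (rnorm < tol && verr < cfg$volume_rtol)
      return(list(U = U, p_kpa = p_kpa, V = st$V, iters = it - 1L))
    rhs <- cbind(st$R[free], st$gV[free])
    sol <- solve_sym(st$K[free, free], rhs)
    a <- as.numeric(sol[, 1]); b <- as.numeric(sol[, 2])
    g <- st$gV[free]
    gb <- sum(g * b)
    if (abs(gb) < 1e-300) stop_lv("volume constraint is singular (gV.K^-1.gV ~ 0)")
    dp <- ((V_target - st$V) + sum(g * a)) / gb
    dU <- numeric(model$ndof)
    dU[free] <- -a + dp * b
    # cap the displacement increment, then backtrack on the augmented residual
    alpha <- min(1, 0.1 * cav / max(max(abs(dU)), 1e-12))
    m0 <- merit(st)
    repeat {
      sttry <- tryCatch(fe_assemble_state(model, U + alpha * dU,
                                          p_kpa + alpha * dp,
                                          t, want_tangent = FALSE),
                        error = function(e) NULL)
      ok <- !is.null(sttry) &&
        (merit(sttry) < m0 || (alpha <= 1 / 16 && merit(sttry) < 2 * m0))
      if (ok) break
      alpha <- alpha / 2
      if (alpha < 1 / 128)
        stop_lv("volume-constrained line search stalled (residual %.3g, volume error %.3g)",
                rnorm, verr)
    }
    U <- U + alpha * dU
    p_kpa <- p_kpa + alpha * dp
    st <- fe_assemble_state(model, U, p_kpa, t)
  }
  stop_lv("volume-constrained Newton did not converge (last residual %.3g, volume error %.3g)",
          rnorm, verr)
}

#' Solve for the cavity pressure that produces a target volume
#'
#' The cavity pressure acts as a Lagrange multiplier on the enclosed-volume
#' constraint: the bordered Newton system is solved for displacement and
#' pressure simultaneously, with substepping in volume on non-convergence.
#'
#' @param model an [fe_model()].
#' @param V_target_ml target cavity volume, ml.
#' @param U0,p0 initial guesses (displacement, pressure in mmHg).
#' @param t activation time in ms (-1 passive).
#' @return list with `U`, `p` (mmHg), `V` (ml), `detF` range.
#' @export
inflate_to_volume <- function(model, V_target_ml, U0 = NULL, p0 = 0, t = -1) {
  U <- U0 %||% numeric(model$ndof)
  p <- p0 * MMHG_TO_KPA
  V_start <- cavity_volume_grad(model$mesh$nodes, model$endo0, U, FALSE)$volume
  V_target <- V_target_ml * 1000
  done <- 0; step <- 1; nsub <- 0
  while (done < 1 - 1e-12) {
    frac <- min(1, done + step)
    Vt <- V_start + frac * (V_target - V_start)
    res <- tryCatch(solve_volume_kpa(model, U, p, Vt, t), error = function(e) e)
    if (inherits(res, "error")) {
      step <- step / 2; nsub <- nsub + 1
      if (nsub > model$cfg$max_substeps)
        stop_lv("volume-constrained solve failed at fraction %.3g: %s", frac,
                conditionMessage(res))
    } else {
      U <- res$U; p <- res$p_kpa; done <- frac
    }
  }
  st <- fe_assemble_state(model, U, p, t, want_tangent = FALSE)
  list(U = U, p = p * KPA_TO_MMHG, V = st$V / 1000,
       detF_range = range(st$detF))
}

#' Estimate the zero-pressure unloaded state by backward displacement
#'
#' Fixed-point (inverse displacement) iteration: the current unloaded-state
#' guess is inflated to the end-diastolic pressure, the mismatch with the
#' input (loaded) geometry is subtracted from the guess, and the fiber field
#' is rebuilt on the updated guess. On convergence, inflating the returned
#' unloaded geometry to EDP reproduces the input geometry.
#'
#' @param mesh the loaded (e.g. end-diastolic) `lv_mesh`.
#' @param config [helix_config()] used to rebuild fibers on each iterate.
#' @param EDP end-diastolic pressure, mmHg.
#' @param passive [passive_params()].
#' @param cfg [solver_config()].
#' @param EDV target end-diastolic volume in ml (default: the input mesh's
#'   cavity volume; used for the round-trip check).
#' @param max_iter,tol_frac iteration cap and nodal RMS tolerance as a
#'   fraction of the cavity length.
#' @return list with the unloaded `mesh`, `U_inflate` (displacement that
#'   reloads it to EDP), `iterations`, `rms_residual` (mm), `V_roundtrip`
#'   (ml) and `EDV`.
#' @export
find_unloaded_state <- function(mesh, config, EDP, passive = passive_params(),
                                cfg = solver_config(), EDV = NULL,
                                max_iter = 12, tol_frac = 5e-4) {
  if (EDP < 0) stop_lv("EDP must be >= 0")
  EDV <- EDV %||% compute_cavity_volume(mesh)
  X_target <- mesh$nodes
  cav_len <- mesh$spec$cavity_length %||% diff(range(X_target[, 3]))
  e0 <- solve_transmural_coordinate(mesh)
  mesh_u <- mesh
  if (EDP == 0)
    return(list(mesh = mesh_u, U_inflate = numeric(3 * nrow(X_target)),
                iterations = 0L, rms_residual = 0, V_roundtrip = EDV, EDV = EDV))
  U <- NULL
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    fib <- build_fiber_field(mesh_u, config, e = e0,
                             apex_cap_frac = cfg$apex_cap_frac)
    model <- fe_model(mesh_u, fib, passive, active = NULL, cfg = cfg)
    U <- inflate_to_pressure(model, EDP, nsteps = 4)
    x_loaded <- mesh_u$nodes + matrix(U, ncol = 3, byrow = TRUE)
    err <- x_loaded - X_target
    rms <- sqrt(mean(rowSums(err^2)))
    hist <- c(hist, rms)
    mesh_u$nodes <- mesh_u$nodes - err
    if (rms < tol_frac * cav_len) break
  }
  if (rms >= tol_frac * cav_len && it == max_iter)
    warning(sprintf("unloaded-state iteration reached max_iter with RMS %.3g mm (history: %s)",
                    rms, paste(signif(hist, 3), collapse = ", ")))
  jmin <- tet10_min_jacobian(mesh_u$nodes, mesh_u$elems - 1L)
  if (any(jmin <= 0)) stop_lv("unloaded-state estimate has inverted elements")
  fib <- build_fiber_field(mesh_u, config, e = e0, apex_cap_frac = cfg$apex_cap_frac)
  model <- fe_model(mesh_u, fib, passive, active = NULL, cfg = cfg)
  U_check <- inflate_to_pressure(model, EDP, nsteps = 4)
  list(mesh = mesh_u, U_inflate = as.numeric(U_check), iterations = it,
       rms_residual = rms, V_roundtrip = attr(U_check, "volume"), EDV = EDV,
       e_nodal = e0)
}
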