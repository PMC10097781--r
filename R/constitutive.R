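#' Passive myocardial material parameters (Fung transversely isotropic)
#'
#' Strain-energy function W = C/2 (exp(Q) - 1) with
#' Q = b_ff E_ff^2 + b_xx (E_ss^2 + E_nn^2 + E_sn^2 + E_ns^2)
#'   + b_fx (E_fn^2 + E_nf^2 + E_fs^2 + E_sf^2),
#' where E is the Green-Lagrange strain in the fiber/sheet/normal frame.
#' The shipped defaults are a documented surrogate set from the
#' Guccione-family literature, placeholders until subject-calibrated values
#' are supplied; every value is overridable. `bulk_modulus` is the
#' volumetric penalty enforcing near-incompressibility and `Q_cap` the
#' overflow guard on the exponent.
#'
#' @param C stiffness scale, kPa.
#' @param b_ff,b_xx,b_fx dimensionless exponents (fiber, transverse, shear).
#' @param bulk_modulus volumetric penalty modulus, kPa.
#' @param Q_cap overflow cap on the Fung exponent.
#' @export
passive_params <- function(C = 2.0, b_ff = 8.0, b_xx = 2.0, b_fx = 4.0,
                           bulk_modulus = 2000, Q_cap = 50) {
  if (C <= 0) stop_lv("C must be positive")
  if (any(c(b_ff, b_xx, b_fx) < 0)) stop_lv("Fung exponents must be >= 0")
  if (bulk_modulus <= 0) stop_lv("bulk_modulus must be positive")
  structure(list(C = C, b_ff = b_ff, b_xx = b_xx, b_fx = b_fx,
                 bulk_modulus = bulk_modulus, Q_cap = Q_cap),
            class = "passive_params")
}

# pack for the C++ kernels
pmat_vec <- function(p) c(p$C, p$b_ff, p$b_xx, p$b_fx, p$bulk_modulus, p$Q_cap)

as_strain_matrix <- function(E) {
  if (is.matrix(E)) {
    stopifnot(all(dim(E) == c(3, 3)))
    return(E)
  }
  # named components E_ff, E_ss, ... (unnamed default 0)
  m <- matrix(0, 3, 3, dimnames = list(c("f", "s", "n"), c("f", "s", "n")))
  for (nm in names(E)) {
    ij <- sub("^E_", "", nm)
    m[substr(ij, 1, 1), substr(ij, 2, 2)] <- E[[nm]]
  }
  m
}

fung_Q <- function(Em, p) {
  B <- matrix(c(p$b_ff, p$b_fx, p$b_fx,
                p$b_fx, p$b_xx, p$b_xx,
                p$b_fx, p$b_xx, p$b_xx), 3, 3, byrow = TRUE)
  sum(B * Em^2)
}

#' Passive strain-energy density
#'
#' @param E Green-Lagrange strain in the fiber frame: a 3x3 matrix or a named
#'   list/vector of components (`E_ff`, `E_ss`, `E_nn`, `E_fs`, ...);
#'   components not given are zero.
#' @param p [passive_params()].
#' @return energy density W in kPa.
#' @export
passive_energy <- function(E, p = passive_params()) {
  Em <- as_strain_matrix(E)
  if (max(abs(Em - t(Em))) > 1e-9)
    stop_lv("strain tensor must be symmetric")
  Q <- fung_Q(Em, p)
  if (Q > p$Q_cap)
    stop_lv("Fung exponent Q = %.3g exceeds cap %.3g (strain state too severe)", Q, p$Q_cap)
  0.5 * p$C * (exp(Q) - 1)
}

#' Passive second Piola-Kirchhoff stress (fiber frame)
#'
#' Analytic derivative of [passive_energy()] with respect to the full strain
#' tensor: S_ij = C exp(Q) B_ij E_ij (no sum), with B the exponent
#' coefficient matrix.
#'
#' @inheritParams passive_energy
#' @return 3x3 stress matrix in kPa, fiber frame.
#' @export
passive_stress <- function(E, p = passive_params()) {
  Em <- as_strain_matrix(E)
  if (max(abs(Em - t(Em))) > 1e-9)
    stop_lv("strain tensor must be symmetric")
  Q <- fung_Q(Em, p)
  if (Q > p$Q_cap)
    stop_lv("Fung exponent Q = %.3g exceeds cap %.3g (strain state too severe)", Q, p$Q_cap)
  B <- matrix(c(p$b_ff, p$b_fx, p$b_fx,
                p$b_fx, p$b_xx, p$b_xx,
                p$b_fx, p$b_xx, p$b_xx), 3, 3, byrow = TRUE)
  p$C * exp(Q) * B * Em
}

#' Active-tension model parameters (calcium activation)
#'
#' Length- and time-dependent active fiber tension
#' P_act = T0_LV Ca0^2 / (Ca0^2 + ECa50(l)^2) Ct(t, l), with
#' Ct = (1 - cos omega)/2 rising over [0, t0), falling over [0, t0 + t_r) and
#' zero after, t_r = m l + b_time, and calcium sensitivity
#' ECa50 = Ca0_max / sqrt(exp(B_len (l - l0)) - 1). Sarcomere length l is the
#' reference length times the fiber stretch. Fetal defaults: t0 = 140.5 ms
#' for a 400 ms cycle; T0_LV defaults inside the reported fetal range
#' (23.9-59.2 kPa); calcium constants and the relaxation line (m, b_time) are
#' documented surrogates scaled to the fetal cycle duration.
#'
#' @param T0_LV maximum tension, kPa.
#' @param Ca0 peak intracellular calcium, uM.
#' @param Ca0_max,B_len,l0 calcium-sensitivity constants (uM, 1/um, um).
#' @param l_ref reference sarcomere length at unit fiber stretch, um.
#' @param t0 time to peak tension, ms.
#' @param m,b_time relaxation-duration line t_r = m l + b_time (ms/um, ms).
#' @param cycle_length cardiac cycle duration, ms.
#' @export
active_params <- function(T0_LV = 40, Ca0 = 4.35, Ca0_max = 4.35,
                          B_len = 4.75, l0 = 1.58, l_ref = 1.85,
                          t0 = 140.5, m = 87.5, b_time = -75,
                          cycle_length = 400) {
  if (T0_LV < 0) stop_lv("T0_LV must be >= 0")
  if (t0 <= 0 || t0 >= cycle_length)
    stop_lv("t0 must lie in (0, cycle_length)")
  structure(list(T0_LV = T0_LV, Ca0 = Ca0, Ca0_max = Ca0_max, B_len = B_len,
                 l0 = l0, l_ref = l_ref, t0 = t0, m = m, b_time = b_time,
                 cycle_length = cycle_length),
            class = "active_params")
}

# pack for the C++ kernels; t in ms within the cycle (t < 0 disables)
pact_vec <- function(p, t) {
  c(p$T0_LV, p$Ca0, p$Ca0_max, p$B_len, p$l0, p$l_ref, t, p$t0, p$m, p$b_time)
}

#' Calcium-activation time course
#'
#' @param t time within the cycle, ms (0 <= t < cycle_length).
#' @param l sarcomere length, um.
#' @param p [active_params()].
#' @return list with `omega` (rad), `Ct` in [0,1], `t_r` (ms) and `ECa50`.
#' @export
activation_timecourse <- function(t, l, p = active_params()) {
  if (any(t < 0) || any(t >= p$cycle_length))
    stop_lv("t must satisfy 0 <= t < cycle_length")
  t_r <- p$m * l + p$b_time
  if (any(t_r <= 0)) stop_lv("relaxation duration t_r = m*l + b_time <= 0")
  arg <- exp(p$B_len * (l - p$l0)) - 1
  if (any(arg <= 0))
    stop_lv("ECa50 undefined: sarcomere length %.3g um at or below law domain l0 = %.3g", min(l), p$l0)
  ECa50 <- p$Ca0_max / sqrt(arg)
  omega <- ifelse(t < p$t0, pi * t / p$t0,
                  ifelse(t < p$t0 + t_r, pi * (t - p$t0 + t_r) / t_r, 0))
  list(omega = omega, Ct = 0.5 * (1 - cos(omega)), t_r = t_r, ECa50 = ECa50)
}

#' Active fiber tension
#'
#' @inheritParams activation_timecourse
#' @return active tension P_act in kPa (applied along f x f in the solver).
#' @export
active_stress <- function(t, l, p = active_params()) {
  act <- activation_timecourse(t, l, p)
  p$T0_LV * p$Ca0^2 / (p$Ca0^2 + act$ECa50^2) * act$Ct
}
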