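#' Stroke work of a PV loop
#'
#' Shoelace area of the closed (volume, pressure) polygon, converted from
#' mmHg.ml to mJ. The loop must close (first and last points coincide); a
#' clockwise traversal yields a negative raw area, which is reported as its
#' absolute value with an orientation warning.
#'
#' @param pv a `pv_loop` data.frame (time ms, pressure mmHg, volume ml).
#' @return stroke work in mJ.
#' @export
compute_stroke_work <- function(pv) {
  v <- pv$volume; p <- pv$pressure
  n <- length(v)
  vtol <- 0.02 * max(diff(range(v)), 1e-12)
  ptol <- 0.02 * max(diff(range(p)), 1e-12)
  if (abs(v[1] - v[n]) > vtol || abs(p[1] - p[n]) > ptol)
    stop_lv("PV loop is not closed (first/last points differ beyond 2%% of range)")
  # shoelace over the polygon closed from the last point back to the first
  v <- c(v, v[1]); p <- c(p, p[1]); n <- n + 1L
  a <- 0.5 * sum(v[-n] * p[-1] - v[-1] * p[-n])
  if (a < -1e-12 * max(abs(v)) * max(abs(p)))
    warning("PV loop traversed clockwise; reporting |area|")
  abs(a) * MMHGML_TO_MJ
}

# per-step field summaries of a cycle: volume-averaged passive strain-energy
# density (reference-volume weights) and volume-averaged fiber-direction
# Cauchy stress (current-volume weights)
cycle_step_fields <- function(cycle, i) {
  m <- cycle$model
  T <- m$active$cycle_length
  fe_fields(m$mesh$nodes, m$mesh$elems - 1L, cycle$U[, i],
            m$fibers$frames_mat, pmat_vec(m$passive),
            pact_vec(m$active, cycle$times[i] %% T))
}

#' Temporal peak of the volume-averaged myofiber stress
#'
#' At every step of the cycle, the Cauchy stress is projected on the
#' deformed, normalized fiber direction and averaged over the wall with
#' current-volume weights; the temporal maximum is returned.
#'
#' @param cycle an `lv_cycle`.
#' @return peak volume-averaged myofiber stress, kPa.
#' @export
compute_peak_myofiber_stress <- function(cycle) {
  n <- ncol(cycle$U)
  vals <- vapply(seq_len(n), function(i) {
    fl <- cycle_step_fields(cycle, i)
    w <- fl$wref * fl$detF
    sum(w * fl$sigma_ff) / sum(w)
  }, numeric(1))
  max(vals)
}

#' Deformational strain-energy burden
#'
#' Absolute change of the volume-averaged passive (Fung) strain-energy
#' density between end-diastole and end-systole, both measured against the
#' unloaded reference; reference-volume weights.
#'
#' @param cycle an `lv_cycle`.
#' @return burden amplitude in kPa.
#' @export
compute_deformational_burden <- function(cycle) {
  wbar <- function(i) {
    fl <- cycle_step_fields(cycle, i)
    sum(fl$wref * fl$W) / sum(fl$wref)
  }
  abs(wbar(cycle$i_es) - wbar(cycle$i_ed))
}

#' Transmural variance of fiber-direction strain at mid-ventricle
#'
#' Fiber-direction Green-Lagrange strain of end-systole with end-diastole as
#' reference, sampled at quadrature points within a slab around the
#' mid-ventricular transverse plane; the unweighted variance is returned.
#'
#' @param cycle an `lv_cycle`.
#' @param plane_frac plane position as a fraction of cavity length below the
#'   base (default 0.5, mid-ventricle).
#' @param slab_frac slab half-width as a fraction of cavity length.
#' @return dimensionless strain variance.
#' @export
compute_transmural_strain_variance <- function(cycle, plane_frac = 0.5,
                                               slab_frac = 0.05) {
  m <- cycle$model
  ed <- cycle_step_fields(cycle, cycle$i_ed)
  es <- cycle_step_fields(cycle, cycle$i_es)
  Erel <- rel_strain_cpp(ed$F, es$F)
  f <- m$fibers$f
  fdef <- push_forward(ed$F, f)
  ef <- quad_form_rows(Erel, fdef)
  cav_len <- m$mesh$spec$cavity_length %||% diff(range(m$mesh$nodes[, 3]))
  z0 <- -plane_frac * cav_len
  sel <- abs(m$fibers$x_qp[, 3] - z0) < slab_frac * cav_len
  if (!any(sel)) stop_lv("mid-ventricular slab contains no quadrature points")
  var(ef[sel])
}

# normalized push-forward of reference direction d by per-row F
push_forward <- function(Fm, d) {
  out <- cbind(Fm[, 1] * d[, 1] + Fm[, 4] * d[, 2] + Fm[, 7] * d[, 3],
               Fm[, 2] * d[, 1] + Fm[, 5] * d[, 2] + Fm[, 8] * d[, 3],
               Fm[, 3] * d[, 1] + Fm[, 6] * d[, 2] + Fm[, 9] * d[, 3])
  out / pmax(sqrt(rowSums(out^2)), 1e-300)
}

# d' M d per row for flattened 3x3 rows M and unit rows d
quad_form_rows <- function(Mm, d) {
  Mm[, 1] * d[, 1]^2 + Mm[, 5] * d[, 2]^2 + Mm[, 9] * d[, 3]^2 +
    (Mm[, 2] + Mm[, 4]) * d[, 1] * d[, 2] +
    (Mm[, 3] + Mm[, 7]) * d[, 1] * d[, 3] +
    (Mm[, 6] + Mm[, 8]) * d[, 2] * d[, 3]
}

#' Global longitudinal and circumferential strains (ES vs ED)
#'
#' Volume-weighted wall averages of the end-systolic Green-Lagrange strain
#' with end-diastole as the reference, projected on the (push-forwarded)
#' local longitudinal and circumferential directions.
#'
#' @param cycle an `lv_cycle`.
#' @return a [strain_summary()].
#' @export
compute_global_strains <- function(cycle) {
  m <- cycle$model
  ed <- cycle_step_fields(cycle, cycle$i_ed)
  es <- cycle_step_fields(cycle, cycle$i_es)
  Erel <- rel_strain_cpp(ed$F, es$F)
  cl <- m$fibers$cl
  ldef <- push_forward(ed$F, cl$l)
  cdef <- push_forward(ed$F, cl$c)
  w <- ed$wref * ed$detF
  eps_long <- sum(w * quad_form_rows(Erel, ldef)) / sum(w)
  eps_circ <- sum(w * quad_form_rows(Erel, cdef)) / sum(w)
  strain_summary(eps_long, eps_circ, source = "FE")
}

#' FE-versus-image strain error
#'
#' ER = (eps_long_FE - eps_long_echo)^2 + (eps_circ_FE - eps_circ_echo)^2,
#' with both summaries as fractions.
#'
#' @param fe,echo [strain_summary()] objects.
#' @return nonnegative scalar ER.
#' @export
strain_error <- function(fe, echo) {
  mags <- c(abs(fe$eps_long), abs(fe$eps_circ), abs(echo$eps_long), abs(echo$eps_circ))
  if (max(mags) > 1.5 && min(mags[mags > 0]) < 0.5)
    stop_lv("strain unit mismatch: summaries appear to mix fractions and percent")
  (fe$eps_long - echo$eps_long)^2 + (fe$eps_circ - echo$eps_circ)^2
}

#' All four optimality metrics of a cycle
#' @param cycle an `lv_cycle`.
#' @return named list: stroke_work (mJ), peak_myofiber_stress (kPa),
#'   deform_burden (kPa), strain_variance, plus peak pressure (mmHg), stroke
#'   volume (ml) and the global strains.
#' @export
compute_biomech_metrics <- function(cycle) {
  gs <- compute_global_strains(cycle)
  list(stroke_work = compute_stroke_work(cycle$pv),
       peak_myofiber_stress = compute_peak_myofiber_stress(cycle),
       deform_burden = compute_deformational_burden(cycle),
       strain_variance = compute_transmural_strain_variance(cycle),
       peak_pressure = max(cycle$pv$pressure),
       stroke_volume = max(cycle$pv$volume) - min(cycle$pv$volume),
       eps_long = gs$eps_long, eps_circ = gs$eps_circ)
}
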