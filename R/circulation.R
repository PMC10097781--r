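#' Lumped-parameter fetal circulation parameters
#'
#' Closed-loop network of the fetal circulation in the Pennati-model family:
#' four elastance chambers (LV, LA, RV, RA), compliant vascular compartments
#' (ascending aorta AA, descending aorta DAO, pulmonary artery PA, pulmonary
#' veins PV, systemic veins SV, placenta PL, lungs LU), ideal-diode valves
#' with small forward resistances, the ductus arteriosus (PA to DAO) and the
#' foramen ovale (RA to LA, one-way). The numeric defaults are a documented
#' surrogate set, chosen to give physiological late-gestation fetal pressures and outputs
#' at a 400 ms cycle; every value is overridable, and the whole set can be
#' recalibrated by the resistance/compliance scale factors.
#'
#' Units: pressures mmHg, volumes ml, time s; resistances mmHg.s/ml,
#' compliances ml/mmHg, elastances mmHg/ml.
#'
#' @param ... named overrides of any default component value.
#' @param k_R,k_C resistance and compliance scale factors applied by
#'   [apply_scale_factors()].
#' @export
circulation_params <- function(..., k_R = 1, k_C = 1) {
  p <- list(
    cycle_length = 0.4,
    # valves (diodes with forward resistance)
    R_mv = 0.12, R_av = 0.18, R_tv = 0.12, R_pval = 0.18, R_fo = 0.55,
    # arterial / venous / organ resistances
    R_arch = 0.45, R_da = 0.25, R_ub = 22, R_lb = 34, R_pl_a = 14,
    R_uv = 1.8, R_lung = 40, R_pulm_ven = 2.5, R_pv_la = 0.6, R_sv = 0.35,
    # compliances
    C_aa = 0.04, C_dao = 0.06, C_pa = 0.05, C_pv = 0.25, C_sv = 1.4,
    C_pl = 0.7, C_lu = 0.22,
    # unstressed volumes (ml)
    V0_aa = 0.5, V0_dao = 0.8, V0_pa = 0.55, V0_pv = 0.9, V0_sv = 6,
    V0_pl = 3, V0_lu = 0.8,
    # elastance chambers: E(t) = Emin + (Emax - Emin) act(t)
    LV = list(Emax = 42, Emin = 2.6, V0 = 0.35, t_peak = 0.1405, t_relax = 0.11, onset = 0),
    RV = list(Emax = 40, Emin = 2.4, V0 = 0.42, t_peak = 0.1405, t_relax = 0.11, onset = 0),
    LA = list(Emax = 4.5, Emin = 1.6, V0 = 0.25, t_peak = 0.05, t_relax = 0.05, onset = -0.06),
    RA = list(Emax = 4.5, Emin = 1.5, V0 = 0.3, t_peak = 0.05, t_relax = 0.05, onset = -0.06),
    k_R = k_R, k_C = k_C)
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(p)) stop_lv("unknown circulation parameter '%s'", nm)
    p[[nm]] <- if (is.list(p[[nm]])) modifyList(p[[nm]], ov[[nm]]) else ov[[nm]]
  }
  bad <- vapply(p[grep("^R_|^C_", names(p))], function(x) x <= 0, TRUE)
  if (any(bad)) stop_lv("resistances and compliances must be positive")
  structure(p, class = "circulation_params")
}

#' Apply resistance/compliance scale factors
#'
#' Multiplies every resistance by `k_R` and every compliance by `k_C`,
#' leaving all other components untouched (the recalibration mechanism of
#' the circulation model).
#'
#' @param p [circulation_params()].
#' @param k_R,k_C positive scale factors.
#' @export
apply_scale_factors <- function(p, k_R = 1, k_C = 1) {
  if (k_R <= 0 || k_C <= 0) stop_lv("scale factors must be positive")
  for (nm in grep("^R_", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * k_R
  for (nm in grep("^C_", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * k_C
  p$k_R <- p$k_R * k_R
  p$k_C <- p$k_C * k_C
  p
}

# raised-cosine activation pulse for elastance chambers; t in s within cycle
chamber_activation <- function(t, ch, T) {
  tt <- (t - ch$onset) %% T
  dur <- ch$t_peak + ch$t_relax
  ifelse(tt < ch$t_peak, 0.5 * (1 - cos(pi * tt / ch$t_peak)),
         ifelse(tt < dur, 0.5 * (1 + cos(pi * (tt - ch$t_peak) / ch$t_relax)), 0))
}

diode <- function(dp, R) pmax(dp, 0) / R

# state vector ordering (volumes, ml)
CIRC_STATES <- c("LV", "LA", "RV", "RA", "AA", "DAO", "PA", "PV", "SV", "PL", "LU")

circ_pressures <- function(v, p, t, lv_pressure = NULL) {
  T <- p$cycle_length
  pr <- c(
    LV = if (is.null(lv_pressure)) {
      ch <- p$LV; (ch$Emin + (ch$Emax - ch$Emin) * chamber_activation(t, ch, T)) * (v[["LV"]] - ch$V0)
    } else lv_pressure,
    LA = { ch <- p$LA; (ch$Emin + (ch$Emax - ch$Emin) * chamber_activation(t, ch, T)) * (v[["LA"]] - ch$V0) },
    RV = { ch <- p$RV; (ch$Emin + (ch$Emax - ch$Emin) * chamber_activation(t, ch, T)) * (v[["RV"]] - ch$V0) },
    RA = { ch <- p$RA; (ch$Emin + (ch$Emax - ch$Emin) * chamber_activation(t, ch, T)) * (v[["RA"]] - ch$V0) },
    AA = (v[["AA"]] - p$V0_aa) / p$C_aa,
    DAO = (v[["DAO"]] - p$V0_dao) / p$C_dao,
    PA = (v[["PA"]] - p$V0_pa) / p$C_pa,
    PV = (v[["PV"]] - p$V0_pv) / p$C_pv,
    SV = (v[["SV"]] - p$V0_sv) / p$C_sv,
    PL = (v[["PL"]] - p$V0_pl) / p$C_pl,
    LU = (v[["LU"]] - p$V0_lu) / p$C_lu)
  pr
}

circ_flows <- function(pr, p) {
  c(mv = diode(pr[["LA"]] - pr[["LV"]], p$R_mv),
    av = diode(pr[["LV"]] - pr[["AA"]], p$R_av),
    tv = diode(pr[["RA"]] - pr[["RV"]], p$R_tv),
    pval = diode(pr[["RV"]] - pr[["PA"]], p$R_pval),
    fo = diode(pr[["RA"]] - pr[["LA"]], p$R_fo),
    arch = (pr[["AA"]] - pr[["DAO"]]) / p$R_arch,
    da = (pr[["PA"]] - pr[["DAO"]]) / p$R_da,
    ub = (pr[["AA"]] - pr[["SV"]]) / p$R_ub,
    lb = (pr[["DAO"]] - pr[["SV"]]) / p$R_lb,
    pl_a = (pr[["DAO"]] - pr[["PL"]]) / p$R_pl_a,
    uv = (pr[["PL"]] - pr[["SV"]]) / p$R_uv,
    lung = (pr[["PA"]] - pr[["LU"]]) / p$R_lung,
    pulm_ven = (pr[["LU"]] - pr[["PV"]]) / p$R_pulm_ven,
    pv_la = (pr[["PV"]] - pr[["LA"]]) / p$R_pv_la,
    sv_ra = (pr[["SV"]] - pr[["RA"]]) / p$R_sv)
}

# dV/dt for all compartments; flows computed once so total volume is
# conserved exactly by construction of the vector field
circ_deriv <- function(t, v, p, lv_pressure = NULL) {
  pr <- circ_pressures(v, p, t, lv_pressure)
  q <- circ_flows(pr, p)
  dv <- c(LV = q[["mv"]] - q[["av"]],
          LA = q[["pv_la"]] + q[["fo"]] - q[["mv"]],
          RV = q[["tv"]] - q[["pval"]],
          RA = q[["sv_ra"]] - q[["tv"]] - q[["fo"]],
          AA = q[["av"]] - q[["arch"]] - q[["ub"]],
          DAO = q[["arch"]] + q[["da"]] - q[["lb"]] - q[["pl_a"]],
          PA = q[["pval"]] - q[["da"]] - q[["lung"]],
          PV = q[["pulm_ven"]] - q[["pv_la"]],
          SV = q[["ub"]] + q[["lb"]] + q[["uv"]] - q[["sv_ra"]],
          PL = q[["pl_a"]] - q[["uv"]],
          LU = q[["lung"]] - q[["pulm_ven"]])
  list(dv, pr, q)
}

circ_initial_volumes <- function(p, p_art = 45, p_ven = 3.5, p_plac = 10) {
  c(LV = p$LV$V0 + p_ven / p$LV$Emin, LA = p$LA$V0 + p_ven / p$LA$Emin,
    RV = p$RV$V0 + p_ven / p$RV$Emin, RA = p$RA$V0 + p_ven / p$RA$Emin,
    AA = p$V0_aa + p_art * p$C_aa, DAO = p$V0_dao + p_art * p$C_dao,
    PA = p$V0_pa + p_art * p$C_pa, PV = p$V0_pv + p_ven * p$C_pv,
    SV = p$V0_sv + p_ven * p$C_sv, PL = p$V0_pl + p_plac * p$C_pl,
    LU = p$V0_lu + p_ven * p$C_lu)
}

#' Simulate the closed-loop fetal circulation
#'
#' Integrates the compartment-volume ODEs of the closed loop with an
#' elastance left ventricle for `n_cycles` cardiac cycles (12 by default,
#' enough to reach periodic steady state). Pressures are derived from
#' volumes algebraically, and valve diodes admit forward flow only.
#'
#' @param p [circulation_params()].
#' @param n_cycles number of cycles to integrate.
#' @param samples_per_cycle output sampling density.
#' @param v0 optional initial volume vector (named as the compartments).
#' @param rtol,atol integrator tolerances.
#' @return data.frame (class `circulation_series`) with time (s), cycle
#'   index, compartment volumes `V_*`, pressures `p_*` and valve/branch
#'   flows `Q_*`.
#' @export
simulate_circulation <- function(p = circulation_params(), n_cycles = 12,
                                 samples_per_cycle = 200, v0 = NULL,
                                 rtol = 1e-9, atol = 1e-9) {
  T <- p$cycle_length
  v0 <- v0 %||% circ_initial_volumes(p)
  times <- seq(0, n_cycles * T, length.out = n_cycles * samples_per_cycle + 1)
  sol <- deSolve::ode(y = v0, times = times,
                      func = function(t, y, parms) circ_deriv(t, y, parms)[1],
                      parms = p, method = "lsoda", rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  vol <- as.matrix(out[, CIRC_STATES])
  pr <- t(vapply(seq_len(nrow(out)),
                 function(i) circ_pressures(vol[i, ], p, out$time[i]),
                 numeric(length(CIRC_STATES))))
  qf <- t(vapply(seq_len(nrow(pr)), function(i) circ_flows(pr[i, ], p),
                 numeric(15)))
  res <- data.frame(time = out$time, cycle = pmin(floor(out$time / T) + 1, n_cycles))
  for (s in CIRC_STATES) res[[paste0("V_", s)]] <- out[[s]]
  for (s in colnames(pr)) res[[paste0("p_", s)]] <- pr[, s]
  for (s in colnames(qf)) res[[paste0("Q_", s)]] <- qf[, s]
  res$V_total <- rowSums(vol)
  class(res) <- c("circulation_series", "data.frame")
  res
}

#' Cycle-to-cycle steady-state summary of a circulation run
#'
#' End-diastolic volume of each chamber per cycle and the relative change in
#' the final cycle, plus total-volume drift per cycle.
#' @param series a `circulation_series`.
#' @param p the [circulation_params()] used.
#' @export
circulation_steady_state <- function(series, p) {
  T <- p$cycle_length
  ncyc <- max(series$cycle)
  chambers <- c("LV", "LA", "RV", "RA")
  edv <- sapply(chambers, function(ch) {
    sapply(seq_len(ncyc), function(k) {
      idx <- abs(series$time - (k - 1) * T) < 1e-9
      series[[paste0("V_", ch)]][which(idx)[1]]
    })
  })
  last_change <- abs(edv[ncyc, ] - edv[ncyc - 1, ]) / pmax(abs(edv[ncyc - 1, ]), 1e-12)
  drift <- abs(series$V_total[nrow(series)] - series$V_total[1]) /
    series$V_total[1] / ncyc
  list(edv = edv, edv_rel_change = last_change, volume_drift_per_cycle = drift)
}

#' Extract a left-ventricular PV loop from a circulation series
#' @param series a `circulation_series`.
#' @param p the [circulation_params()] used.
#' @param cycle which cycle to extract (default the last).
#' @return data.frame with `time` (ms), `pressure` (mmHg), `volume` (ml),
#'   class `pv_loop`.
#' @export
pv_loop_from_circulation <- function(series, p, cycle = max(series$cycle)) {
  T <- p$cycle_length
  sel <- series$time >= (cycle - 1) * T - 1e-12 & series$time <= cycle * T + 1e-12
  out <- data.frame(time = (series$time[sel] - (cycle - 1) * T) * 1000,
                    pressure = series$p_LV[sel], volume = series$V_LV[sel])
  class(out) <- c("pv_loop", "data.frame")
  out
}

# advance the circulation one macro step with the LV as an external pressure
# source (FE coupling port): LV volume evolves from the valve flows at the
# prescribed LV pressure. Returns the new volume state.
circ_step_lv_pressure <- function(v, p, t0, dt, p_lv, rtol = 1e-8, atol = 1e-8) {
  sol <- deSolve::ode(y = v, times = c(t0, t0 + dt),
                      func = function(t, y, parms) circ_deriv(t, y, parms, lv_pressure = p_lv)[1],
                      parms = p, method = "lsoda", rtol = rtol, atol = atol)
  v1 <- sol[nrow(sol), -1]
  names(v1) <- names(v)
  v1
}

#' Analytic single-compartment RC discharge (integrator check)
#'
#' Discharges one capacitor through one resistor with the package's ODE
#' machinery; the analytic solution is p0 exp(-t/(RC)).
#' @param p0 initial pressure (mmHg), R resistance, C compliance.
#' @param R,C element values.
#' @param times output times (s).
#' @export
rc_discharge <- function(p0, R, C, times) {
  sol <- deSolve::ode(y = c(V = p0 * C), times = times,
                      func = function(t, y, parms) list(-(y[["V"]] / C) / R),
                      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  data.frame(time = sol[, 1], pressure = sol[, 2] / C)
}
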