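#' Run a volume-constrained cardiac cycle
#'
#' Prescribes the cavity volume over time from a smoothed waveform and
#' solves, at each step, the quasi-static equilibrium with the cavity
#' pressure as the volume-constraint multiplier. The input mesh is taken as
#' the unloaded reference, assumed to be the geometry at one third of the
#' diastolic duration (the pressure minimum), where the simulation starts
#' and ends after one full cycle.
#'
#' @param mesh unloaded `lv_mesh`.
#' @param fibers `lv_fibers` on the mesh.
#' @param passive,active [passive_params()], [active_params()].
#' @param waveform a `volume_waveform` whose cycle length matches the active
#'   model.
#' @param cfg [solver_config()].
#' @return object of class `lv_cycle`: the PV loop (`pv`: time ms, pressure
#'   mmHg, volume ml), per-step displacement matrix `U` (ndof x nsteps+1),
#'   step times, ED/ES step indices, and the model.
#' @export
run_volume_constrained_cycle <- function(mesh, fibers, passive, active,
                                         waveform, cfg = solver_config()) {
  spec <- attr(waveform, "spec")
  if (abs(spec$cycle_length - active$cycle_length) > 1e-9)
    stop_lv("waveform and activation cycle lengths differ")
  vol_fun <- attr(waveform, "fun")
  T <- spec$cycle_length
  model <- fe_model(mesh, fibers, passive, active, cfg)
  t_u <- waveform_unload_time(waveform)
  n <- cfg$steps_per_cycle
  times <- t_u + (0:n) * T / n
  U <- numeric(model$ndof)
  p <- 0
  Us <- matrix(0, model$ndof, n + 1)
  ps <- vs <- numeric(n + 1)
  t_prev <- times[1]
  for (i in seq_along(times)) {
    res <- advance_time_step(model, U, p, t_prev, times[i],
                             function(tt) vol_fun(tt), T)
    U <- res$U; p <- res$p
    Us[, i] <- U; ps[i] <- p; vs[i] <- res$V
    t_prev <- times[i]
    if (max(abs(res$detF_range - 1)) > 0.05)
      warning(sprintf("det(F) deviates from 1 by %.1f%% at step %d",
                      100 * max(abs(res$detF_range - 1)), i))
  }
  pv <- data.frame(time = times %% T, pressure = ps, volume = vs)
  class(pv) <- c("pv_loop", "data.frame")
  structure(list(pv = pv, U = Us, times = times, model = model,
                 i_ed = which.max(vs[-1]) + 1L, i_es = which.min(vs[-1]) + 1L,
                 waveform = waveform, driver = "volume_constrained"),
            class = "lv_cycle")
}

# advance the FE state from cycle time t_from to t_to with target volumes
# given by vol_at(t); if the solve fails (activation can change sharply
# within a step, e.g. during rapid relaxation), the time interval is split
# recursively so activation and volume ramp together.
advance_time_step <- function(model, U, p, t_from, t_to, vol_at, T,
                              max_splits = 4, depth = 0) {
  res <- tryCatch(inflate_to_volume(model, vol_at(t_to), U0 = U, p0 = p,
                                    t = t_to %% T),
                  error = function(e) e)
  if (!inherits(res, "error")) return(res)
  if (depth >= max_splits)
    stop_lv("time step %.1f -> %.1f ms failed after %d splits: %s", t_from,
            t_to, depth, conditionMessage(res))
  tm <- (t_from + t_to) / 2
  mid <- advance_time_step(model, U, p, t_from, tm, vol_at, T, max_splits,
                           depth + 1)
  advance_time_step(model, mid$U, mid$p, tm, t_to, vol_at, T, max_splits,
                    depth + 1)
}

#' Run a circulation-coupled cardiac cycle
#'
#' Warm-starts the closed-loop circulation with an elastance LV to periodic
#' steady state, then replaces the LV by the FE model: each macro time step
#' the circulation is advanced at the current FE pressure to produce the new
#' LV volume, and the FE volume-constrained solve returns the new pressure
#' (one exchange per step, with optional fixed-point sub-iterations).
#'
#' @inheritParams run_volume_constrained_cycle
#' @param circ [circulation_params()].
#' @param warmup_cycles elastance-LV cycles before coupling (default 11).
#' @param coupled_cycles coupled cycles to run (the last is reported).
#' @param sub_iterations fixed-point pressure/volume exchanges per step.
#' @param unload if TRUE, estimate the unloaded state by backward
#'   displacement from the warm-start EDP before coupling; if FALSE the
#'   input mesh is used as the unloaded reference directly.
#' @return an `lv_cycle` with the coupled PV loop, the circulation state
#'   series of the coupled cycles, and valve-phase annotations.
#' @export
run_coupled_cycle <- function(mesh, fibers, passive, active, circ,
                              cfg = solver_config(), warmup_cycles = 11,
                              coupled_cycles = 2, sub_iterations = 2,
                              unload = FALSE) {
  T_ms <- active$cycle_length
  if (abs(circ$cycle_length * 1000 - T_ms) > 1e-6)
    stop_lv("circulation and activation cycle lengths differ")
  warm <- simulate_circulation(circ, n_cycles = warmup_cycles)
  v <- as.numeric(warm[nrow(warm), paste0("V_", CIRC_STATES)])
  names(v) <- CIRC_STATES
  model0 <- fe_model(mesh, fibers, passive, active, cfg)
  if (unload) {
    edp <- tail(warm$p_LV[warm$Q_mv > 0], 1)
    unl <- find_unloaded_state(mesh, fibers$config, EDP = edp, passive = passive,
                               cfg = cfg)
    mesh <- unl$mesh
    fibers <- build_fiber_field(mesh, fibers$config, e = unl$e_nodal,
                                apex_cap_frac = cfg$apex_cap_frac)
    model0 <- fe_model(mesh, fibers, passive, active, cfg)
  }
  model <- model0
  n <- cfg$steps_per_cycle
  dt <- circ$cycle_length / n
  # initialize FE at the warm-start LV volume
  U <- numeric(model$ndof); p_fe <- 0
  res <- inflate_to_volume(model, v[["LV"]], U0 = U, p0 = 2, t = 0)
  U <- res$U; p_fe <- res$p
  nt <- coupled_cycles * n
  times <- (0:nt) * dt * 1000
  Us <- matrix(0, model$ndof, nt + 1)
  ps <- vs <- numeric(nt + 1)
  Us[, 1] <- U; ps[1] <- p_fe; vs[1] <- res$V
  series <- list()
  v_exch_in <- v_exch_fe <- numeric(0)
  V_fe <- res$V
  for (i in seq_len(nt)) {
    t0 <- (i - 1) * dt
    p_try <- p_fe
    for (s in seq_len(max(1, sub_iterations))) {
      v_new <- circ_step_lv_pressure(v, circ, t0, dt, p_lv = p_try)
      res <- advance_time_step(
        model, U, p_try, t0 * 1000, (t0 + dt) * 1000,
        function(tt) V_fe + (v_new[["LV"]] - V_fe) *
          (tt - t0 * 1000) / (dt * 1000),
        T_ms)
      p_next <- res$p
      if (abs(p_next - p_try) < 0.05) { p_try <- p_next; break }
      p_try <- 0.5 * (p_try + p_next)
    }
    V_fe <- res$V
    v <- v_new
    v_exch_in <- c(v_exch_in, v[["LV"]])
    U <- res$U; p_fe <- p_try
    v_exch_fe <- c(v_exch_fe, res$V)
    Us[, i + 1] <- U; ps[i + 1] <- p_fe; vs[i + 1] <- res$V
    pr <- circ_pressures(v, circ, (t0 + dt) %% circ$cycle_length, lv_pressure = p_fe)
    series[[i]] <- c(time = (t0 + dt) * 1000, pr, v)
  }
  series <- as.data.frame(do.call(rbind, series))
  i0 <- nt - n + 1L  # last coupled cycle
  pv <- data.frame(time = times[i0:(nt + 1)] %% T_ms, pressure = ps[i0:(nt + 1)],
                   volume = vs[i0:(nt + 1)])
  class(pv) <- c("pv_loop", "data.frame")
  structure(list(pv = pv, U = Us[, i0:(nt + 1), drop = FALSE],
                 times = times[i0:(nt + 1)], model = model,
                 i_ed = which.max(vs[i0:(nt + 1)][-1]) + 1L,
                 i_es = which.min(vs[i0:(nt + 1)][-1]) + 1L,
                 circulation = series, warm = warm,
                 volume_exchange = data.frame(circ = v_exch_in, fe = v_exch_fe),
                 driver = "coupled"),
            class = "lv_cycle")
}

#' @export
print.lv_cycle <- function(x, ...) {
  sv <- max(x$pv$volume) - min(x$pv$volume)
  cat(sprintf("LV cycle [%s]: %d steps, EDV %.3f ml, ESV %.3f ml, SV %.3f ml\n",
              x$driver, nrow(x$pv) - 1, max(x$pv$volume), min(x$pv$volume), sv))
  cat(sprintf("  peak pressure %.2f mmHg, stroke work %.4f mJ\n",
              max(x$pv$pressure), compute_stroke_work(x$pv)))
  invisible(x)
}

#' Calibrate maximum active tension to a target peak pressure
#'
#' Monotone root find of T0_LV such that the peak systolic LV pressure of a
#' supplied simulation matches a measured target, over the fetal literature
#' bracket by default (23.9-59.2 kPa).
#'
#' @param peak_pressure_fn function T0_LV (kPa) -> peak pressure (mmHg).
#' @param target_peak target peak systolic pressure, mmHg.
#' @param bounds bracket for T0_LV, kPa.
#' @param tol acceptance tolerance on the achieved peak, mmHg.
#' @return list with `T0_LV`, `achieved_peak`, and the bracket evaluations.
#' @export
calibrate_t0lv <- function(peak_pressure_fn, target_peak,
                           bounds = c(23.9, 59.2), tol = 0.5) {
  lo <- peak_pressure_fn(bounds[1])
  hi <- peak_pressure_fn(bounds[2])
  if (hi <= lo) stop_lv("peak pressure is not increasing over the bracket")
  if (target_peak < lo - tol || target_peak > hi + tol)
    stop_lv("target %.2f mmHg outside achievable range [%.2f, %.2f] over bounds",
            target_peak, lo, hi)
  if (abs(lo - target_peak) <= tol)
    return(list(T0_LV = bounds[1], achieved_peak = lo, bracket = c(lo, hi)))
  if (abs(hi - target_peak) <= tol)
    return(list(T0_LV = bounds[2], achieved_peak = hi, bracket = c(lo, hi)))
  f <- function(T0) peak_pressure_fn(T0) - target_peak
  root <- uniroot(f, interval = bounds, f.lower = lo - target_peak,
                  f.upper = hi - target_peak, tol = 0.05)
  achieved <- root$f.root + target_peak
  if (abs(achieved - target_peak) > tol)
    stop_lv("calibration stopped %.2f mmHg from target", achieved - target_peak)
  list(T0_LV = root$root, achieved_peak = achieved, bracket = c(lo, hi))
}
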