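#' Specification of a smoothed periodic LV volume waveform
#'
#' Emulates temporally smoothed echo-derived volume-over-time curves: a
#' raised-cosine ejection from EDV to ESV followed by a biphasic (early/late
#' filling) raised-cosine return to EDV, C1-continuous and periodic with no
#' isovolumetric plateaus. Fetal defaults: EDV 2.2 ml, 400 ms cycle, stroke
#' volume about 1 ml; the adult preset uses EDV 132 ml and stroke volume
#' 81.8 ml over an 800 ms cycle.
#'
#' @param EDV,ESV end-diastolic and end-systolic volumes, ml.
#' @param cycle_length cycle duration, ms.
#' @param systolic_fraction fraction of the cycle spent ejecting.
#' @param early_fraction share of filling carried by the early (E) wave; the
#'   remainder is the late atrial (A) wave (fetal filling is A-dominant).
#' @param samples samples per cycle.
#' @export
waveform_spec <- function(EDV = 2.2, ESV = 1.2, cycle_length = 400,
                          systolic_fraction = 0.4, early_fraction = 0.45,
                          samples = 200) {
  if (!(EDV > ESV && ESV > 0)) stop_lv("need EDV > ESV > 0")
  if (systolic_fraction <= 0 || systolic_fraction >= 1 ||
      early_fraction <= 0 || early_fraction >= 1)
    stop_lv("fractions must lie in (0,1)")
  structure(list(EDV = EDV, ESV = ESV, cycle_length = cycle_length,
                 systolic_fraction = systolic_fraction,
                 early_fraction = early_fraction, samples = samples),
            class = "waveform_spec")
}

#' Adult LV waveform preset
#' @param ... overrides passed to [waveform_spec()].
#' @export
waveform_spec_adult <- function(...) {
  waveform_spec(EDV = 132, ESV = 132 - 81.8, cycle_length = 800, ...)
}

smoothstep <- function(s) 0.5 * (1 - cos(pi * pmin(pmax(s, 0), 1)))

#' Generate a smooth periodic volume waveform
#'
#' @param spec a [waveform_spec()].
#' @return object of class `volume_waveform`: data.frame (`time` ms,
#'   `volume` ml) with attributes `spec`, `fun` (a periodic interpolating
#'   function of time in ms) and `t_eject` (end of ejection, ms).
#' @export
generate_volume_waveform <- function(spec) {
  T <- spec$cycle_length
  Te <- spec$systolic_fraction * T
  SV <- spec$EDV - spec$ESV
  vol_fun <- function(t) {
    t <- t %% T
    v <- numeric(length(t))
    ej <- t < Te
    v[ej] <- spec$ESV + SV * 0.5 * (1 + cos(pi * t[ej] / Te))
    s <- (t[!ej] - Te) / (T - Te)
    # E wave over s in [0, 0.5], A wave over s in [0.5, 1]
    w <- spec$early_fraction * smoothstep(s / 0.5) +
      (1 - spec$early_fraction) * smoothstep((s - 0.5) / 0.5)
    v[!ej] <- spec$ESV + SV * w
    v
  }
  tt <- seq(0, T, length.out = spec$samples + 1)
  out <- data.frame(time = tt, volume = vol_fun(tt))
  structure(out, class = c("volume_waveform", "data.frame"), spec = spec,
            fun = vol_fun, t_eject = Te)
}

#' Build a periodic volume waveform from a sampled series
#'
#' Wraps a measured or simulated volume-over-time series (e.g. an
#' echo-derived curve read from CSV, or the volume trace of a coupled
#' simulation) as a periodic interpolating waveform usable by the
#' volume-constrained driver. The cycle is assumed to start at end-diastole;
#' a small first/last mismatch (up to 2% of the excursion) is closed onto
#' the first sample.
#'
#' @param time sample times in ms, starting at 0, spanning one cycle.
#' @param volume volumes in ml.
#' @param cycle_length cycle duration in ms (default: the last sample time).
#' @return a `volume_waveform`.
#' @export
waveform_from_series <- function(time, volume, cycle_length = NULL) {
  if (abs(volume[length(volume)] - volume[1]) >
      0.02 * max(diff(range(volume)), 1e-12))
    stop_lv("series is not periodic (first/last volumes differ beyond 2%)")
  o <- order(time)
  time <- time[o]; volume <- volume[o]
  T <- cycle_length %||% max(time)
  keep <- !duplicated(time)
  time <- time[keep]; volume <- volume[keep]
  if (abs(max(time) - T) > 1e-9) { time <- c(time, T); volume <- c(volume, volume[1]) }
  volume[length(volume)] <- volume[1]
  sf <- splinefun(time, volume, method = "periodic")
  vol_fun <- function(t) sf(t %% T)
  spec <- waveform_spec(EDV = max(volume), ESV = min(volume), cycle_length = T,
                        systolic_fraction = max(time[which.min(volume)], 1e-6) / T)
  out <- data.frame(time = time, volume = volume)
  structure(out, class = c("volume_waveform", "data.frame"), spec = spec,
            fun = vol_fun, t_eject = time[which.min(volume)])
}

#' Time of the assumed unloaded state of a waveform
#'
#' One third of the way through diastole (filling), where LV pressure is at
#' its minimum.
#' @param wf a `volume_waveform`.
#' @export
waveform_unload_time <- function(wf) {
  spec <- attr(wf, "spec")
  Te <- attr(wf, "t_eject")
  Te + (spec$cycle_length - Te) / 3
}

#' Synthetic image-derived global strains
#'
#' Stand-in for echo motion-tracked strains: true end-systolic global
#' longitudinal/circumferential Green-Lagrange strains (end-diastolic
#' reference) plus i.i.d. Gaussian noise, reproducible by seed.
#'
#' @param eps_long,eps_circ true strains (fractions).
#' @param sd noise standard deviation (fraction).
#' @param seed RNG seed.
#' @return a `strain_summary` (see [strain_summary()]).
#' @export
generate_synthetic_echo_strains <- function(eps_long, eps_circ, sd = 0,
                                            seed = 1) {
  if (sd < 0) stop_lv("noise sd must be >= 0")
  noise <- withr::with_seed(seed, rnorm(2, 0, sd))
  if (sd == 0) noise <- c(0, 0)
  strain_summary(eps_long + noise[1], eps_circ + noise[2], source = "synthetic echo")
}

#' Global strain summary
#' @param eps_long,eps_circ global end-systolic Green-Lagrange strains with
#'   end-diastolic reference, as fractions.
#' @param source provenance label.
#' @export
strain_summary <- function(eps_long, eps_circ, source = "FE") {
  if (!is.finite(eps_long) || !is.finite(eps_circ))
    stop_lv("strains must be finite")
  structure(list(eps_long = eps_long, eps_circ = eps_circ, source = source),
            class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("global strains [%s]: longitudinal %.2f%%, circumferential %.2f%%\n",
              x$source, 100 * x$eps_long, 100 * x$eps_circ))
  invisible(x)
}
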