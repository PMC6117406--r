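# One simulated beat: passive inflation to EDP, isovolumic contraction,
# ejection against a two-element Windkessel afterload, end systole at valve
# closure (zero outflow).

#' Two-element Windkessel afterload
#'
#' @param open_mmHg aortic valve opening pressure (and initial arterial
#'   pressure), mmHg.
#' @param R arterial resistance (mmHg s / ml).
#' @param C arterial compliance (ml / mmHg).
#' @return afterload parameter list.
#' @export
afterload_params <- function(open_mmHg = 80, R = 1.2, C = 2.5) {
  stopifnot(open_mmHg > 0, R > 0, C > 0)
  list(open_mmHg = open_mmHg, R = R, C = C)
}

# advance to a target cavity pressure with bisection cutbacks
advance_pressure <- function(model, state, p_target_mmHg, depth = 0) {
  ns <- solve_state(model, state, control_pressure(p_target_mmHg), time = -1)
  if (ns$converged) return(ns)
  if (depth >= 8)
    stop(sprintf("inflation failed to converge at %.3f mmHg", p_target_mmHg))
  mid <- (MPa_to_mmHg(state$p) + p_target_mmHg) / 2
  s1 <- advance_pressure(model, state, mid, depth + 1)
  advance_pressure(model, s1, p_target_mmHg, depth + 1)
}

#' Passive inflation to end-diastolic pressure
#'
#' Inflates the unloaded model quasi-statically through a staircase of
#' cavity pressures up to EDP, recording the pressure-volume curve.
#'
#' @param model an `lv_model` (passive; contractility ignored since time < 0).
#' @param edp_mmHg target end-diastolic pressure (mmHg).
#' @param pressures optional explicit pressure staircase (mmHg); default 8
#'   evenly spaced steps in `(0, edp]`.
#' @param warmup prepend small unrecorded sub-steps before the first target
#'   pressure (the near-reference wall is very soft, so the first load
#'   increment otherwise needs repeated Newton cutbacks).
#' @return list with the ED `state`, a `pv` data frame (pressure_mmHg,
#'   volume_ml) including the unloaded point, and `V0`.
#' @export
inflate_to_edp <- function(model, edp_mmHg, pressures = NULL, warmup = TRUE) {
  if (is.null(pressures)) {
    stopifnot(edp_mmHg >= 0)
    pressures <- if (edp_mmHg == 0) numeric(0) else edp_mmHg * (1:8) / 8
  }
  state <- new_state(model)
  pv <- data.frame(pressure_mmHg = 0, volume_ml = state$V)
  if (warmup && length(pressures)) {
    for (pw in pressures[1] * c(0.125, 0.25, 0.5))
      state <- advance_pressure(model, state, pw)
  }
  for (pt in pressures) {
    state <- advance_pressure(model, state, pt)
    pv <- rbind(pv, data.frame(pressure_mmHg = pt, volume_ml = state$V))
  }
  list(state = state, pv = pv, V0 = pv$volume_ml[1])
}

# cavity volumes at a set of pressures; NULL on solver failure
inflate_volumes <- function(model, pressures_mmHg) {
  out <- tryCatch({
    r <- inflate_to_edp(model, edp_mmHg = max(pressures_mmHg),
                        pressures = pressures_mmHg)
    r$pv$volume_ml[-1]
  }, error = function(e) NULL)
  out
}

advance_iso <- function(model, state, V_target, t_target, depth = 0) {
  ns <- solve_state(model, state, control_volume(V_target), time = t_target)
  if (ns$converged) return(ns)
  if (depth >= 8)
    stop(sprintf("isovolumic step failed at t=%.4f s", t_target))
  mid <- (state$time + t_target) / 2
  s1 <- advance_iso(model, state, V_target, mid, depth + 1)
  advance_iso(model, s1, V_target, t_target, depth + 1)
}

advance_wk <- function(model, state, p_art, V_prev, dt, t_start, Rw, Cw,
                       depth = 0) {
  ctrl <- control_windkessel(p_art, V_prev, dt, Rw, Cw)
  ns <- solve_state(model, state, ctrl, time = t_start + dt)
  if (ns$converged) { ns$time <- t_start + dt; return(ns) }
  if (depth >= 8)
    stop(sprintf("ejection step failed at t=%.4f s", t_start + dt))
  s1 <- advance_wk(model, state, p_art, V_prev, dt / 2, t_start, Rw, Cw,
                   depth + 1)
  advance_wk(model, s1, s1$p, s1$V, dt / 2, t_start + dt / 2, Rw, Cw,
             depth + 1)
}

#' Simulate one beat from the end-diastolic state
#'
#' Activation starts at `t = 0` from the supplied ED state. The cavity volume
#' is held at EDV (isovolumic contraction, pressure as unknown) until the
#' cavity pressure reaches the valve opening pressure; ejection then couples
#' the cavity to the two-element Windkessel until the outflow returns to
#' zero, which defines end systole. If the peak isovolumic pressure never
#' reaches the opening pressure the beat is flagged `no_ejection` and
#' ESV = EDV.
#'
#' @param model an `lv_model` with the scenario's contractility.
#' @param ed_state converged ED state from [inflate_to_edp()].
#' @param afterload an [afterload_params()] list.
#' @param dt activation time increment (s).
#' @param t_end simulation horizon (s).
#' @param warm optional environment reused across beats of a calibration
#'   run: converged states of the previous beat at matching time steps serve
#'   as Newton starting iterates (results are unchanged; only iteration
#'   counts drop).
#' @return object of class `lv_beat`: time/pressure/volume traces, `edv`,
#'   `esv`, `esp_mmHg`, `ef`, `ed_state`, `es_state`, `no_ejection`.
#' @export
run_beat <- function(model, ed_state, afterload = afterload_params(),
                     dt = 0.01, t_end = 0.8, warm = NULL) {
  stopifnot(ed_state$converged)
  edv <- ed_state$V
  Rw <- afterload$R * MMHG_TO_MPA        # MPa s / ml
  Cw <- afterload$C / MMHG_TO_MPA        # ml / MPa
  p_open <- mmHg_to_MPa(afterload$open_mmHg)
  t0 <- model$ap$t0

  state <- ed_state
  state$time <- 0
  times <- 0; pres <- MPa_to_mmHg(ed_state$p); vols <- edv
  p_peak <- state$p
  peak_state <- state
  opened <- FALSE
  u_prev <- NULL
  step_idx <- 0L

  # predictor: previous beat's state at the same step if available,
  # otherwise linear extrapolation of the previous two converged states
  predict_from <- function(state, u_prev) {
    if (!is.null(warm) && length(warm$states) > step_idx &&
        !is.null(warm$states[[step_idx + 1L]])) {
      g <- state
      ws <- warm$states[[step_idx + 1L]]
      g$u <- ws$u
      g$p <- ws$p
      return(g)
    }
    if (is.null(u_prev)) return(state)
    g <- state
    g$u <- 2 * state$u - u_prev
    g
  }
  remember <- function(state) {
    step_idx <<- step_idx + 1L
    if (!is.null(warm)) {
      if (is.null(warm$states)) warm$states <- list()
      warm$states[[step_idx]] <- list(u = state$u, p = state$p)
    }
  }

  # isovolumic contraction; the opening instant is located by bisection so
  # ejection always starts at the valve opening pressure (within ~0.1 mmHg)
  # rather than at a step-dependent overshoot
  t <- 0
  t_prev <- 0
  while (t < t_end) {
    t <- t + dt
    ns <- solve_state(model, predict_from(state, u_prev),
                      control_volume(edv), time = t)
    if (!ns$converged) ns <- advance_iso(model, state, edv, t)
    if (ns$p >= p_open) {
      lo_t <- t_prev; hi_t <- t
      lo_state <- state
      for (k in 1:8) {
        if (abs(ns$p - p_open) <= mmHg_to_MPa(0.1)) break
        mid <- (lo_t + hi_t) / 2
        ms <- advance_iso(model, lo_state, edv, mid)
        if (ms$p >= p_open) { hi_t <- mid; ns <- ms }
        else { lo_t <- mid; lo_state <- ms; lo_state$time <- mid }
      }
      state <- ns
      state$time <- hi_t
      t <- hi_t
      times <- c(times, t); pres <- c(pres, MPa_to_mmHg(state$p))
      vols <- c(vols, state$V)
      opened <- TRUE
      break
    }
    u_prev <- state$u
    state <- ns
    remember(state)
    state$time <- t
    t_prev <- t
    times <- c(times, t); pres <- c(pres, MPa_to_mmHg(state$p))
    vols <- c(vols, state$V)
    if (state$p > p_peak) { p_peak <- state$p; peak_state <- state }
    if (t > t0 && state$p < 0.995 * p_peak) break   # tension waning, no opening
  }

  if (!opened) {
    ef <- ejection_fraction(edv, edv)
    beat <- list(times = times, pressures_mmHg = pres, volumes_ml = vols,
                 edv = edv, esv = edv, esp_mmHg = MPa_to_mmHg(p_peak),
                 ef = ef, ed_state = ed_state, es_state = peak_state,
                 no_ejection = TRUE, es_time = peak_state$time)
    class(beat) <- "lv_beat"
    return(beat)
  }

  # ejection
  p_art <- state$p
  V_prev <- state$V
  es_state <- state

  # once the outflow reverses inside a step, bisect the time increment to
  # locate valve closure, so ESV varies smoothly with contractility instead
  # of being quantized by dt
  refine_es <- function(state, dt_loc, t_loc, depth) {
    if (depth > 4) return(state)
    ns <- tryCatch(advance_wk(model, state, state$p, state$V, dt_loc / 2,
                              t_loc, Rw, Cw),
                   error = function(e) NULL)
    if (is.null(ns)) return(state)
    if ((state$V - ns$V) / (dt_loc / 2) >= 0)
      refine_es(ns, dt_loc / 2, t_loc + dt_loc / 2, depth + 1)
    else refine_es(state, dt_loc / 2, t_loc, depth + 1)
  }

  closed <- FALSE
  while (t < t_end) {
    ctrl <- control_windkessel(p_art, V_prev, dt, Rw, Cw)
    ns <- solve_state(model, predict_from(state, u_prev), ctrl, time = t + dt)
    if (ns$converged) ns$time <- t + dt
    else ns <- advance_wk(model, state, p_art, V_prev, dt, t, Rw, Cw)
    Q <- (V_prev - ns$V) / dt
    if (Q < 0) { closed <- TRUE; break }  # flow reversal inside this step
    t <- t + dt
    u_prev <- state$u
    state <- ns
    remember(state)
    p_art <- state$p
    V_prev <- state$V
    es_state <- state
    times <- c(times, t); pres <- c(pres, MPa_to_mmHg(state$p))
    vols <- c(vols, state$V)
  }
  if (closed) {
    es_state <- refine_es(es_state, dt, t, 1)
    times <- c(times, es_state$time); pres <- c(pres, MPa_to_mmHg(es_state$p))
    vols <- c(vols, es_state$V)
  }

  esv <- es_state$V
  beat <- list(times = times, pressures_mmHg = pres, volumes_ml = vols,
               edv = edv, esv = esv, esp_mmHg = MPa_to_mmHg(es_state$p),
               ef = ejection_fraction(edv, esv), ed_state = ed_state,
               es_state = es_state, no_ejection = FALSE,
               es_time = es_state$time)
  class(beat) <- "lv_beat"
  beat
}

#' @export
print.lv_beat <- function(x, ...) {
  cat(sprintf("LV beat: EDV %.1f ml, ESV %.1f ml, EF %.1f%%, ESP %.1f mmHg%s\n",
              x$edv, x$esv, x$ef, x$esp_mmHg,
              if (x$no_ejection) " [no ejection]" else ""))
  invisible(x)
}
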