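# Calibration: passive stiffness to the single-point end-diastolic PV
# relation, and contractility to a measured end-systolic volume.

#' Single-point end-diastolic pressure-volume curve
#'
#' Normalized empirical EDPVR reconstructed from one measured (volume,
#' pressure) point: `P(V) = An * Vn^Bn` with
#' `Vn = (V - V0) / (V30 - V0)`, `An = 28.2` mmHg, `Bn = 2.79`, and
#' `V30 = V0 + (Vm - V0) / (Pm/An)^(1/Bn)` so the curve interpolates the
#' measured point exactly. `V0` defaults to the single-point unloading
#' regression [klotz_unloaded_volume()].
#'
#' @param vm,pm measured end-diastolic volume (ml) and pressure (mmHg).
#' @param v0 unloaded volume (ml); estimated from `vm`, `pm` if omitted.
#' @param an,bn curve constants.
#' @return object of class `klotz_curve`.
#' @export
klotz_curve <- function(vm, pm, v0 = NULL, an = 28.2, bn = 2.79) {
  if (is.null(v0)) v0 <- klotz_unloaded_volume(vm, pm)
  stopifnot(vm > v0, pm > 0)
  v30 <- v0 + (vm - v0) / (pm / an)^(1 / bn)
  k <- list(v0 = v0, v30 = v30, an = an, bn = bn, vm = vm, pm = pm)
  class(k) <- "klotz_curve"
  k
}

#' Evaluate the single-point EDPVR
#'
#' @param curve a [klotz_curve()].
#' @param v volume (ml); volumes at or below `v0` return 0 pressure.
#' @return pressure (mmHg).
#' @export
klotz_pressure <- function(curve, v) {
  vn <- pmax(v - curve$v0, 0) / (curve$v30 - curve$v0)
  curve$an * vn^curve$bn
}

#' @rdname klotz_pressure
#' @param p pressure (mmHg, >= 0).
#' @return `klotz_volume`: volume (ml).
#' @export
klotz_volume <- function(curve, p) {
  stopifnot(all(p >= 0))
  curve$v0 + (curve$v30 - curve$v0) * (p / curve$an)^(1 / curve$bn)
}

#' Fit passive stiffness to the EDPVR
#'
#' Minimizes the sum of squared differences between model and EDPVR cavity
#' volumes at `n_pressures` evenly spaced pressures in `(0, EDP]` over the
#' eight passive constants within box bounds. Two stages: (1) a secant
#' iteration on a common multiplier of the four stiffness scales, which fixes
#' the overall compliance cheaply, then (2) box-constrained quasi-Newton
#' refinement of all eight parameters (stiffness scales on a log scale) from
#' that start. The best parameter set seen is returned; the eight-parameter
#' problem is non-unique, so the fit is judged by curve mismatch, never by
#' parameter values.
#'
#' @param model an `lv_model` built on the unloaded geometry (the fit mesh).
#' @param curve a [klotz_curve()].
#' @param edp_mmHg end-diastolic pressure (mmHg).
#' @param init starting `lv_material`.
#' @param n_pressures number of matched pressures.
#' @param maxit quasi-Newton iteration cap for the refinement stage
#'   (0 skips it).
#' @param lower_a,upper_a bounds on stiffness scales (MPa).
#' @param lower_b,upper_b bounds on exponents.
#' @return list with `params` (fitted `lv_material`), `rms_ml`,
#'   `rms_frac_edv`, `volumes`, `targets`, `pressures`, `value`, `counts`,
#'   `n_eval`, `convergence`, `warning_flag`.
#' @export
fit_passive_params <- function(model, curve, edp_mmHg,
                               init = material_params(), n_pressures = 8,
                               maxit = 3,
                               lower_a = 1e-6, upper_a = 1e-1,
                               lower_b = 0.1, upper_b = 30) {
  pressures <- edp_mmHg * seq_len(n_pressures) / n_pressures
  targets <- klotz_volume(curve, pressures)
  K <- init$K

  pack <- function(mp) c(log(c(mp$a, mp$a_f, mp$a_s, mp$a_fs)),
                         c(mp$b, mp$b_f, mp$b_s, mp$b_fs))
  unpack <- function(x) material_params(
    a = exp(x[1]), a_f = exp(x[2]), a_s = exp(x[3]), a_fs = exp(x[4]),
    b = x[5], b_f = x[6], b_s = x[7], b_fs = x[8], K = K)

  n_eval <- 0L
  best <- list(val = Inf, mp = init, vols = NULL)
  # warm-started staircase: each pressure step starts from the converged
  # state of the previous objective evaluation at the same pressure (the
  # parameter perturbations of the optimizer are small, so one or two Newton
  # iterations usually suffice); falls back to cold sequential stepping
  cache <- new.env(parent = emptyenv())
  vols_warm <- function(mod2) {
    prev <- cache$states
    newst <- vector("list", length(pressures))
    out <- numeric(length(pressures))
    st <- new_state(mod2)
    for (i in seq_along(pressures)) {
      ns <- NULL
      if (!is.null(prev) && !is.null(prev[[i]])) {
        g <- st; g$u <- prev[[i]]$u; g$p <- prev[[i]]$p
        ns <- solve_state(mod2, g, control_pressure(pressures[i]))
        if (!ns$converged) ns <- NULL
      }
      if (is.null(ns))
        ns <- tryCatch(advance_pressure(mod2, st, pressures[i]),
                       error = function(e) NULL)
      if (is.null(ns)) return(NULL)
      st <- ns; newst[[i]] <- ns; out[i] <- ns$V
    }
    cache$states <- newst
    out
  }
  obj <- function(x) {
    mp <- unpack(x)
    vols <- vols_warm(set_material(model, mp))
    n_eval <<- n_eval + 1L
    if (is.null(vols)) return(1e8)
    v <- sum((vols - targets)^2)
    if (v < best$val) best <<- list(val = v, mp = mp, vols = vols)
    v
  }

  # stage 1: common stiffness multiplier (secant on V at EDP)
  pol <- rescale_stiffness_to_edv(set_material(model, init), edp_mmHg,
                                  curve$vm, tol_ml = 0.1)
  start <- pack(pol$params)
  obj(start)

  # stage 2: all eight parameters free within bounds
  opt <- list(counts = c(0L, 0L), convergence = 0L)
  if (maxit > 0) {
    lower <- c(rep(log(lower_a), 4), rep(lower_b, 4))
    upper <- c(rep(log(upper_a), 4), rep(upper_b, 4))
    opt <- optim(start, obj, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 1e10,
                                parscale = c(rep(1, 4), rep(5, 4))))
  }
  mp <- best$mp
  vols <- best$vols
  if (is.null(vols)) vols <- inflate_volumes(set_material(model, mp), pressures)
  rms <- sqrt(mean((vols - targets)^2))
  list(params = mp, rms_ml = rms, rms_frac_edv = rms / curve$vm,
       volumes = vols, targets = targets, pressures = pressures,
       value = best$val, counts = opt$counts, n_eval = n_eval,
       convergence = opt$convergence, warning_flag = opt$convergence != 0)
}

#' Rescale passive stiffness so the model EDV matches a target
#'
#' One-dimensional polish applied after the multi-parameter fit (typically on
#' a finer production mesh): all four stiffness scales are multiplied by a
#' common factor, found by secant iteration in log space, so the model cavity
#' volume at EDP matches the measured EDV.
#'
#' @param model an `lv_model`.
#' @param edp_mmHg end-diastolic pressure (mmHg).
#' @param target_edv measured EDV (ml).
#' @param tol_ml volume tolerance (ml).
#' @param max_iter secant iteration cap.
#' @return list with the rescaled `params`, the `scale` factor and achieved
#'   `edv`.
#' @export
rescale_stiffness_to_edv <- function(model, edp_mmHg, target_edv,
                                     tol_ml = 0.05, max_iter = 8) {
  mp0 <- model$mp
  scaled <- function(s) material_params(
    a = s * mp0$a, a_f = s * mp0$a_f, a_s = s * mp0$a_s, a_fs = s * mp0$a_fs,
    b = mp0$b, b_f = mp0$b_f, b_s = mp0$b_s, b_fs = mp0$b_fs, K = mp0$K)
  # warm start: after the first full inflation, successive scale evaluations
  # re-solve directly from the previous converged ED state (the parameter
  # change between secant iterates is small)
  cache <- new.env(parent = emptyenv())
  vol_at <- function(s) {
    mod2 <- set_material(model, scaled(s))
    if (!is.null(cache$state)) {
      ns <- solve_state(mod2, cache$state, control_pressure(edp_mmHg))
      if (ns$converged) { cache$state <- ns; return(ns$V) }
    }
    r <- tryCatch(inflate_to_edp(mod2, edp_mmHg), error = function(e) NULL)
    if (is.null(r)) stop("inflation failed during stiffness rescale")
    cache$state <- r$state
    r$state$V
  }
  s1 <- 1; v1 <- vol_at(s1)
  if (abs(v1 - target_edv) <= tol_ml)
    return(list(params = scaled(1), scale = 1, edv = v1))
  # stiffer wall -> smaller volume; initial guess from local power-law slope
  s2 <- if (v1 > target_edv) 1.3 else 0.75
  v2 <- vol_at(s2)
  for (k in seq_len(max_iter)) {
    if (abs(v2 - target_edv) <= tol_ml) break
    ds <- (log(s2) - log(s1)) / (v2 - v1)
    s_new <- exp(log(s2) + ds * (target_edv - v2))
    s_new <- min(max(s_new, s2 / 3), s2 * 3)
    s1 <- s2; v1 <- v2
    s2 <- s_new; v2 <- vol_at(s2)
  }
  list(params = scaled(s2), scale = s2, edv = v2)
}

# bracketed secant (false position) on a monotone-decreasing ESV(tmax) map.
# The length-dependent activation makes ESV(tmax) saturate: tension vanishes
# as sarcomeres shorten toward l0, so arbitrarily large tmax cannot shrink
# the cavity below a floor. If the target lies under that floor the search
# either errors (`on_unreachable = "error"`) or returns the best-achieving
# point flagged `saturated = TRUE` (`"best"`).
root_esv <- function(esv_of, lo, hi, target, tol_ml = 0.15, max_eval = 15,
                     hi_cap = 0.5, on_unreachable = c("error", "best")) {
  on_unreachable <- match.arg(on_unreachable)
  n <- 0
  ev <- function(x) { n <<- n + 1; esv_of(x) }
  rlo <- ev(lo)
  while (rlo$esv < target && lo > 1e-4) {     # lo already ejects too much
    hi <- lo; rhi <- rlo
    lo <- lo / 2
    rlo <- ev(lo)
  }
  if (rlo$esv - target <= tol_ml && rlo$esv >= target - tol_ml)
    return(list(tmax = lo, beat = rlo$beat, n_beats = n))
  rhi <- ev(hi)
  while (rhi$esv > target) {
    # flat tail: the ESV gain of a 1.6x tension increase is a small fraction
    # of the remaining gap, so the target sits below the reachable floor
    saturated <- hi >= hi_cap ||
      (hi > lo && rhi$esv - target > 10 * (rlo$esv - rhi$esv))
    if (saturated) {
      if (on_unreachable == "best") {
        best <- if (rhi$esv <= rlo$esv) list(t = hi, r = rhi)
                else list(t = lo, r = rlo)
        warning(sprintf(
          "target ESV %.2f ml unreachable (floor %.2f ml at t_max %.3f MPa)",
          target, best$r$esv, best$t))
        return(list(tmax = best$t, beat = best$r$beat, n_beats = n,
                    saturated = TRUE))
      }
      stop(sprintf("target ESV unreachable with t_max in [0, %.2f] MPa",
                   hi_cap))
    }
    lo <- hi; rlo <- rhi
    hi <- min(hi * 1.6, hi_cap)
    rhi <- ev(hi)
  }
  # false position with the Illinois modification (a retained endpoint has
  # its residual halved, which prevents one-sided stagnation on the convex,
  # flattening ESV curve) and a bisection safeguard
  flo <- rlo$esv - target; fhi <- rhi$esv - target
  side <- 0L
  for (k in seq_len(max_eval)) {
    if (abs(flo) <= tol_ml)
      return(list(tmax = lo, beat = rlo$beat, n_beats = n))
    if (abs(fhi) <= tol_ml)
      return(list(tmax = hi, beat = rhi$beat, n_beats = n))
    xm <- hi - fhi * (hi - lo) / (fhi - flo)
    if (!is.finite(xm) || xm <= lo || xm >= hi) xm <- (lo + hi) / 2
    rm <- ev(xm); fm <- rm$esv - target
    if (abs(fm) <= tol_ml)
      return(list(tmax = xm, beat = rm$beat, n_beats = n))
    if (fm > 0) {
      lo <- xm; rlo <- rm; flo <- fm
      if (side == 1L) fhi <- fhi / 2
      side <- 1L
    } else {
      hi <- xm; rhi <- rm; fhi <- fm
      if (side == -1L) flo <- flo / 2
      side <- -1L
    }
  }
  stop("contractility calibration did not converge to the ESV tolerance")
}

#' Calibrate uniform contractility to a target end-systolic volume
#'
#' Root-finds the single `t_max` applied to all layers so the simulated ESV
#' matches the measured target within `tol_ml`. ESV decreases monotonically
#' with `t_max` over the bracket, so a bracketed false-position iteration is
#' used.
#'
#' @param model an `lv_model` (passive parameters already set).
#' @param ed_state ED state from [inflate_to_edp()].
#' @param afterload an [afterload_params()].
#' @param target_esv measured ESV (ml).
#' @param lo,hi initial bracket for `t_max` (MPa).
#' @param tol_ml ESV tolerance (ml).
#' @param dt activation time increment (s).
#' @param warm optional warm-start environment shared across calibration
#'   rounds (see [run_beat()]).
#' @return list with `tmax` (MPa), the calibrated `beat`, `n_beats`.
#' @export
calibrate_tmax_uniform <- function(model, ed_state, afterload, target_esv,
                                   lo = 0.12, hi = 0.24, tol_ml = 0.15,
                                   dt = 0.01, warm = NULL) {
  if (target_esv >= ed_state$V - tol_ml)
    return(list(tmax = 0, beat = NULL, n_beats = 0))
  if (is.null(warm)) warm <- new.env(parent = emptyenv())
  esv_of <- function(tm) {
    b <- run_beat(set_tmax(model, tm), ed_state, afterload, dt = dt,
                  warm = warm)
    list(esv = b$esv, beat = b)
  }
  root_esv(esv_of, lo, hi, target_esv, tol_ml)
}

#' Calibrate subepicardial contractility with a silent subendocardium
#'
#' With subendocardial `t_max = 0` and midmyocardial `t_max` at the baseline
#' value, root-finds the subepicardial `t_max` that restores the target ESV.
#'
#' @inheritParams calibrate_tmax_uniform
#' @param baseline_tmax calibrated uniform baseline `t_max` (MPa).
#' @return list with `tmax` (subepicardial, MPa), `beat`, `n_beats`, and
#'   `saturated = TRUE` if the target ESV lies below the reachable floor
#'   (length-dependent activation bounds achievable ejection), in which case
#'   `tmax` is the smallest value attaining the floor.
#' @export
calibrate_tmax_subepi <- function(model, ed_state, afterload, baseline_tmax,
                                  target_esv, tol_ml = 0.15, dt = 0.01) {
  warm <- new.env(parent = emptyenv())
  beat2 <- NULL
  esv_of <- function(tm) {
    m2 <- set_tmax(model, c(subendo = 0, mid = baseline_tmax, subepi = tm))
    b <- run_beat(m2, ed_state, afterload, dt = dt, warm = warm)
    # the first bracket point doubles as the silent-subendocardium scenario
    if (tm == baseline_tmax) beat2 <<- b
    list(esv = b$esv, beat = b)
  }
  out <- root_esv(esv_of, baseline_tmax, baseline_tmax * 2, target_esv,
                  tol_ml, hi_cap = max(0.5, 6 * baseline_tmax),
                  on_unreachable = "best")
  out$beat2 <- beat2
  out
}

#' Calibrate afterload resistance and baseline contractility jointly
#'
#' Calibrates uniform `t_max` to the target ESV, then rescales the arterial
#' resistance so the baseline end-systolic pressure approaches the target
#' ESP, re-calibrating `t_max` after each resistance update (at most
#' `max_rounds` rounds). The afterload is then frozen for all scenarios.
#'
#' @inheritParams calibrate_tmax_uniform
#' @param target_esp_mmHg baseline end-systolic pressure target (mmHg).
#' @param esp_tol_mmHg acceptance band on ESP (mmHg).
#' @param max_rounds resistance update rounds.
#' @return list with `tmax`, `afterload`, `beat`, `n_beats`.
#' @export
calibrate_baseline <- function(model, ed_state, afterload, target_esv,
                               target_esp_mmHg = 88.9, esp_tol_mmHg = 2,
                               max_rounds = 2, tol_ml = 0.15, dt = 0.01) {
  total <- 0
  warm <- new.env(parent = emptyenv())
  cal <- calibrate_tmax_uniform(model, ed_state, afterload, target_esv,
                                tol_ml = tol_ml, dt = dt, warm = warm)
  total <- total + cal$n_beats
  for (k in seq_len(max_rounds)) {
    esp <- cal$beat$esp_mmHg
    if (abs(esp - target_esp_mmHg) <= esp_tol_mmHg) break
    afterload$R <- afterload$R * (target_esp_mmHg / esp)
    # the resistance update moves ESV(t_max) only slightly, and in a known
    # direction: a stiffer afterload raises ESV at fixed t_max, a softer one
    # lowers it, so the previous root brackets the new one from one side
    br <- if (target_esp_mmHg > esp) c(cal$tmax, cal$tmax * 1.2)
          else c(cal$tmax * 0.85, cal$tmax)
    cal <- calibrate_tmax_uniform(model, ed_state, afterload, target_esv,
                                  lo = br[1], hi = br[2],
                                  tol_ml = tol_ml, dt = dt, warm = warm)
    total <- total + cal$n_beats
  }
  list(tmax = cal$tmax, afterload = afterload, beat = cal$beat,
       n_beats = total)
}
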