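# Synthetic echo-style patient measurements.
#
# Every downstream stage (geometry, calibration, scenarios) is seeded from a
# small record of echocardiographic scalars. A fixed reference subject is
# provided, and random plausible normal subjects can be drawn for pipeline
# exercising.

#' Patient measurement record
#'
#' Constructs a validated set of echocardiography-derived measurements: LV
#' end-diastolic volume, E/e' ratio, end-diastolic pressure (estimated from
#' E/e' when not given), end-systolic volume, internal diameter and wall
#' thicknesses at end diastole.
#'
#' @param edv end-diastolic volume (ml).
#' @param esv end-systolic volume (ml), must be smaller than `edv`.
#' @param e_over_eprime mitral E/e' ratio (dimensionless).
#' @param edp end-diastolic pressure (mmHg). If `NULL`, estimated from
#'   `e_over_eprime` via [estimate_edp_nagueh()].
#' @param lv_internal_diameter_ed LV internal diameter at end diastole (cm).
#' @param posterior_wall_thickness_ed,septal_wall_thickness_ed wall
#'   thicknesses at end diastole (cm).
#' @return an object of class `lv_patient` (a named list).
#' @export
patient_measurements <- function(edv, esv, e_over_eprime = NULL, edp = NULL,
                                 lv_internal_diameter_ed = 4.6,
                                 posterior_wall_thickness_ed = 0.9,
                                 septal_wall_thickness_ed = 0.9) {
  if (is.null(edp)) {
    if (is.null(e_over_eprime))
      stop("provide either `edp` or `e_over_eprime`")
    edp <- estimate_edp_nagueh(e_over_eprime)
  }
  p <- list(edv = edv, esv = esv,
            e_over_eprime = if (is.null(e_over_eprime)) NA_real_ else e_over_eprime,
            edp = edp,
            lv_internal_diameter_ed = lv_internal_diameter_ed,
            posterior_wall_thickness_ed = posterior_wall_thickness_ed,
            septal_wall_thickness_ed = septal_wall_thickness_ed)
  stopifnot(p$edv > 0, p$esv > 0, p$edv > p$esv, p$edp > 0,
            p$lv_internal_diameter_ed > 0,
            p$posterior_wall_thickness_ed > 0,
            p$septal_wall_thickness_ed > 0)
  class(p) <- "lv_patient"
  p
}

#' Reference subject
#'
#' The fixed single-subject record used throughout the package: EDV 53 ml,
#' EDP 14.3 mmHg (equivalently E/e' = 10 under the linear estimator), measured
#' ESV 24.8 ml. Diameter and wall thicknesses are normal-adult textbook
#' defaults (4.6 cm internal diameter, 0.9 cm posterior and septal walls),
#' exposed as arguments.
#'
#' @param lv_internal_diameter_ed,posterior_wall_thickness_ed,septal_wall_thickness_ed
#'   geometry defaults (cm), override to explore sensitivity.
#' @return an `lv_patient` record.
#' @export
paper_patient <- function(lv_internal_diameter_ed = 4.6,
                          posterior_wall_thickness_ed = 0.9,
                          septal_wall_thickness_ed = 0.9) {
  patient_measurements(edv = 53, esv = 24.8, e_over_eprime = 10,
                       edp = 14.3,
                       lv_internal_diameter_ed = lv_internal_diameter_ed,
                       posterior_wall_thickness_ed = posterior_wall_thickness_ed,
                       septal_wall_thickness_ed = septal_wall_thickness_ed)
}

#' Estimate LV end-diastolic pressure from E/e'
#'
#' Linear single-point estimator of LV filling pressure from the mitral E/e'
#' ratio, `EDP = 1.9 + 1.24 * E/e'` (mmHg). E/e' of 10 gives 14.3 mmHg.
#'
#' @param e_over_eprime E/e' ratio, must be positive.
#' @return estimated end-diastolic pressure (mmHg).
#' @export
estimate_edp_nagueh <- function(e_over_eprime) {
  if (any(!is.finite(e_over_eprime)) || any(e_over_eprime <= 0))
    stop("`e_over_eprime` must be positive")
  1.9 + 1.24 * e_over_eprime
}

# one-at-a-time truncated-normal draw (rejection sampling, deterministic
# under a fixed RNG state)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Distribution defaults for sampled normal subjects
#'
#' Mean/sd and physiological truncation bounds for each sampled measurement.
#' @return a named list of `c(mean, sd, lo, hi)` vectors.
#' @export
patient_distributions <- function() {
  list(edv = c(mean = 53, sd = 8, lo = 35, hi = 80),
       e_over_eprime = c(mean = 8, sd = 2, lo = 4, hi = 14),
       ef_fraction = c(mean = 0.55, sd = 0.05, lo = 0.40, hi = 0.70),
       lvidd = c(mean = 4.6, sd = 0.3, lo = 3.8, hi = 5.6),
       wall = c(mean = 0.9, sd = 0.1, lo = 0.6, hi = 1.2))
}

#' Draw a plausible normal subject
#'
#' Samples EDV, E/e', ejection fraction (hence ESV), diameter and wall
#' thicknesses from truncated normal distributions of normal adults
#' ([patient_distributions()]); EDP is derived from E/e' by
#' [estimate_edp_nagueh()]. Deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param dist distribution set, see [patient_distributions()].
#' @return an `lv_patient` record.
#' @export
sample_patient <- function(seed, dist = patient_distributions()) {
  set.seed(as.integer(seed))
  draw <- function(d) rtruncnorm1(1, d["mean"], d["sd"], d["lo"], d["hi"])
  edv <- draw(dist$edv)
  ee <- draw(dist$e_over_eprime)
  ef <- draw(dist$ef_fraction)
  lvidd <- draw(dist$lvidd)
  pw <- draw(dist$wall)
  sw <- draw(dist$wall)
  patient_measurements(edv = edv, esv = edv * (1 - ef), e_over_eprime = ee,
                       lv_internal_diameter_ed = lvidd,
                       posterior_wall_thickness_ed = pw,
                       septal_wall_thickness_ed = sw)
}

#' Read or write a patient record as JSON
#'
#' @param p an `lv_patient` record.
#' @param path file path.
#' @return `read_patient` returns an `lv_patient`; `write_patient` the path,
#'   invisibly.
#' @export
write_patient <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patient
#' @export
read_patient <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_measurements(edv = x$edv, esv = x$esv,
                       e_over_eprime = x$e_over_eprime, edp = x$edp,
                       lv_internal_diameter_ed = x$lv_internal_diameter_ed,
                       posterior_wall_thickness_ed = x$posterior_wall_thickness_ed,
                       septal_wall_thickness_ed = x$septal_wall_thickness_ed)
}

#' @export
print.lv_patient <- function(x, ...) {
  cat("LV patient record\n")
  cat(sprintf("  EDV %.1f ml, ESV %.1f ml, EDP %.1f mmHg (E/e' %.1f)\n",
              x$edv, x$esv, x$edp, x$e_over_eprime))
  cat(sprintf("  LVIDd %.2f cm, PW %.2f cm, SW %.2f cm\n",
              x$lv_internal_diameter_ed, x$posterior_wall_thickness_ed,
              x$septal_wall_thickness_ed))
  invisible(x)
}
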