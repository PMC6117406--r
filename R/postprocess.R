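# Outcome measures: ejection fraction, normalized torsion, global strains,
# sphericity, transmural fiber strain/stress profiles.

#' Ejection fraction
#'
#' `EF = 100 (EDV - ESV) / EDV` (percent). A negative EF (ESV above EDV) is
#' returned with a warning as a diagnostic.
#'
#' @param edv,esv end-diastolic and end-systolic volumes (ml).
#' @return ejection fraction (%).
#' @export
ejection_fraction <- function(edv, esv) {
  stopifnot(edv > 0)
  if (esv > edv) warning("ESV exceeds EDV: negative ejection fraction")
  100 * (edv - esv) / edv
}

#' Size-normalized torsion from ring rotations
#'
#' `tau = (phi_apex - phi_base) * (rho_apex + rho_base) / (2 D)`, with ring
#' rotations in degrees, radii and apex-base distance in consistent length
#' units. The normalization makes torsion comparable across heart sizes.
#'
#' @param phi_apex,phi_base ring rotations (degrees, positive
#'   counterclockwise when viewed from the apex).
#' @param rho_apex,rho_base deformed ring radii (cm).
#' @param D deformed apex-base distance (cm).
#' @return normalized torsion (degrees).
#' @export
torsion_formula <- function(phi_apex, phi_base, rho_apex, rho_base, D) {
  (phi_apex - phi_base) * (rho_apex + rho_base) / (2 * D)
}

# mean rotation of a node ring about the long axis, positive counterclockwise
# when viewed from the apex (the apex sits at -z, so this is the negative of
# the rotation about +z)
ring_rotation_deg <- function(mesh, u, ring) {
  X <- mesh$nodes[ring, , drop = FALSE]
  ux <- u[3 * (ring - 1) + 1]; uy <- u[3 * (ring - 1) + 2]
  th0 <- atan2(X[, 2], X[, 1])
  th1 <- atan2(X[, 2] + uy, X[, 1] + ux)
  dth <- th1 - th0
  dth <- atan2(sin(dth), cos(dth))       # wrap to (-pi, pi]
  -mean(dth) * 180 / pi
}

ring_radius <- function(mesh, u, ring) {
  X <- mesh$nodes[ring, , drop = FALSE]
  ux <- u[3 * (ring - 1) + 1]; uy <- u[3 * (ring - 1) + 2]
  mean(sqrt((X[, 1] + ux)^2 + (X[, 2] + uy)^2))
}

ring_z <- function(mesh, u, ring) {
  mean(mesh$nodes[ring, 3] + u[3 * (ring - 1) + 3])
}

#' Normalized LV torsion of a deformed state
#'
#' Ring rotations are evaluated on the most apical complete endocardial node
#' ring (the pole itself is singular) and on the endocardial annulus; radii
#' and the apex-base distance are measured in the deformed configuration.
#'
#' @param mesh an `lv_mesh`.
#' @param u nodal displacement vector.
#' @return normalized torsion (degrees).
#' @export
torsion <- function(mesh, u) {
  apex <- mesh$apical_ring
  base <- mesh$annulus_nodes
  D <- abs(ring_z(mesh, u, base) - ring_z(mesh, u, apex))
  torsion_formula(ring_rotation_deg(mesh, u, apex),
                  ring_rotation_deg(mesh, u, base),
                  ring_radius(mesh, u, apex),
                  ring_radius(mesh, u, base), D)
}

#' Global longitudinal, circumferential and radial strains
#'
#' Volume-weighted mean Green-Lagrange strain components of the ES state
#' relative to the ED configuration, projected on the element-local
#' (longitudinal, circumferential, radial) directions, in percent. For each
#' element `F_rel = F_es F_ed^-1` and
#' `E = (F_rel' F_rel - I)/2` is projected on the reference local basis.
#'
#' @param model an `lv_model` (provides the local basis).
#' @param ed_state,es_state converged states.
#' @return named vector `c(e_l, e_c, e_r)` in percent.
#' @export
global_strains <- function(model, ed_state, es_state) {
  fed <- element_fields(model, ed_state$u)
  fes <- element_fields(model, es_state$u)
  ne <- nrow(model$mesh$conn)
  bas <- model$fibers$basis
  w <- fed$vol
  el <- ec <- er <- numeric(ne)
  for (e in seq_len(ne)) {
    Fed <- matrix(fed$F[e, ], 3, 3)
    Fes <- matrix(fes$F[e, ], 3, 3)
    Frel <- Fes %*% solve(Fed)
    E <- (crossprod(Frel) - diag(3)) / 2
    el[e] <- bas$e_l[e, ] %*% E %*% bas$e_l[e, ]
    ec[e] <- bas$e_c[e, ] %*% E %*% bas$e_c[e, ]
    er[e] <- bas$e_r[e, ] %*% E %*% bas$e_r[e, ]
  }
  100 * c(e_l = sum(el * w) / sum(w), e_c = sum(ec * w) / sum(w),
          e_r = sum(er * w) / sum(w))
}

#' End-systolic sphericity index
#'
#' Ratio of the deformed cavity long-axis length (basal cap center to apical
#' endocardial ring centroid) to the maximal deformed endocardial short-axis
#' diameter. Lower values mean a more spherical ventricle.
#'
#' @param mesh an `lv_mesh`.
#' @param u nodal displacement vector.
#' @return dimensionless sphericity index.
#' @export
sphericity_index <- function(mesh, u) {
  base_c <- colMeans(deformed_ring(mesh, u, mesh$annulus_nodes))
  apex_c <- colMeans(deformed_ring(mesh, u, mesh$apical_ring))
  long_axis <- sqrt(sum((base_c - apex_c)^2))
  short <- 2 * max(vapply(mesh$endo_rings, function(r) ring_radius(mesh, u, r),
                          numeric(1)))
  long_axis / short
}

deformed_ring <- function(mesh, u, ring) {
  mesh$nodes[ring, , drop = FALSE] +
    cbind(u[3 * (ring - 1) + 1], u[3 * (ring - 1) + 2], u[3 * (ring - 1) + 3])
}

#' Transmural fiber strain and stress profile at end systole
#'
#' Volume-weighted layer means (8 layers, depth 0 at the endocardium) of the
#' end-systolic fiber strain and total Cauchy fiber stress. Fiber strain is
#' reported both relative to the ED configuration (`eff_ed`, the clinical
#' convention used for interpretation) and relative to the unloaded reference
#' (`eff_ref`).
#'
#' @param model an `lv_model` carrying the scenario's contractility.
#' @param ed_state,es_state converged states.
#' @param time_es activation time of the ES state (s), used for the active
#'   stress contribution.
#' @return data frame with `layer`, `depth`, `eff_ed`, `eff_ref`,
#'   `sigma_f_mpa`.
#' @export
transmural_profile <- function(model, ed_state, es_state, time_es) {
  fed <- element_fields(model, ed_state$u)
  fes <- element_fields(model, es_state$u, time = time_es)
  ne <- nrow(model$mesh$conn)
  f0 <- model$fibers$f0
  eff_ed <- numeric(ne)
  for (e in seq_len(ne)) {
    Fed <- matrix(fed$F[e, ], 3, 3)
    Fes <- matrix(fes$F[e, ], 3, 3)
    Frel <- Fes %*% solve(Fed)
    fd <- Fed %*% f0[e, ]
    fd <- fd / sqrt(sum(fd^2))
    eff_ed[e] <- (drop(t(fd) %*% crossprod(Frel) %*% fd) - 1) / 2
  }
  w <- fed$vol
  lay <- model$mesh$layer
  agg <- function(x) as.numeric(tapply(x * w, lay, sum) / tapply(w, lay, sum))
  data.frame(layer = 1:8, depth = (1:8 - 0.5) / 8,
             eff_ed = agg(eff_ed), eff_ref = agg(fes$Eff),
             sigma_f_mpa = agg(fes$sigma_f))
}

#' Full metric set for one scenario beat
#'
#' @param model the scenario's `lv_model`.
#' @param beat an `lv_beat`.
#' @return one-row data frame of Table-style metrics plus the transmural
#'   profile as an attribute.
#' @export
scenario_metrics <- function(model, beat) {
  mesh <- model$mesh
  strains <- global_strains(model, beat$ed_state, beat$es_state)
  prof <- transmural_profile(model, beat$ed_state, beat$es_state,
                             beat$es_time)
  out <- data.frame(
    ef = beat$ef, esv = beat$esv, esp_mmHg = beat$esp_mmHg,
    torsion_deg = torsion(mesh, beat$es_state$u) -
      torsion(mesh, beat$ed_state$u),
    e_l = strains[["e_l"]], e_c = strains[["e_c"]], e_r = strains[["e_r"]],
    sphericity_es = sphericity_index(mesh, beat$es_state$u),
    no_ejection = beat$no_ejection)
  attr(out, "profile") <- prof
  out
}
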