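# Material-point constitutive interface.
#
# Passive myocardium: Holzapfel-Ogden orthotropic hyperelasticity with an
# isochoric/volumetric split. The deviatoric energy uses the isochoric
# invariants (J^{-2/3}-scaled), the volumetric penalty is
# (1/D)((J^2-1)/2 - ln J) with D = 2/K. The anisotropic fiber and sheet
# exponentials contribute only in tension (I4 > 1).
#
# Active contraction: time-varying tension along the fiber with
# length-dependent calcium sensitivity; the active second Piola-Kirchhoff
# stress is T0(t, Eff) f0 (x) f0 / I4f, added to the passive stress.

#' Passive material parameters
#'
#' The eight Holzapfel-Ogden constants plus the bulk modulus `K` of the
#' volumetric penalty (`D = 2/K`). Defaults are the package's reference human
#' parameter set, obtained by fitting the end-diastolic pressure-volume
#' behavior of a normal adult LV to the single-point Klotz curve.
#'
#' @param a,a_f,a_s,a_fs stress-like stiffness scales (MPa).
#' @param b,b_f,b_s,b_fs dimensionless exponents.
#' @param K bulk modulus of the volumetric penalty (MPa).
#' @return object of class `lv_material` (named list, includes `Dpar = 2/K`).
#' @export
material_params <- function(a = 6.832e-4, b = 7.541,
                            a_f = 2.252e-3, b_f = 14.471,
                            a_s = 3.127e-4, b_s = 12.548,
                            a_fs = 1.837e-4, b_fs = 3.088,
                            K = 1) {
  stopifnot(a >= 0, a_f >= 0, a_s >= 0, a_fs >= 0,
            b >= 0, b_f >= 0, b_s >= 0, b_fs >= 0, K > 0)
  m <- list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
            a_fs = a_fs, b_fs = b_fs, K = K, Dpar = 2 / K)
  class(m) <- "lv_material"
  m
}

#' Active contraction parameters
#'
#' Constants of the time-varying active tension law. `t_max` is the isometric
#' tension at the longest sarcomere length and highest calcium concentration;
#' it is the contractility dial varied across scenarios and is supplied
#' per-region at the model level. The remaining constants are the
#' cross-bridge-lineage defaults: peak calcium `ca0` and its maximum
#' `ca0_max` (uM), sarcomere-length sensitivity `b_len` (1/um), zero-tension
#' length `l0` (um), stress-free length `lR` (um), relaxation-shape constants
#' `m_relax` (s/um) and `b_relax` (s), and time to peak tension `t0` (s).
#'
#' @param ca0,ca0_max,b_len,l0,lR,m_relax,b_relax,t0 see description.
#' @return object of class `lv_active`.
#' @export
active_params <- function(ca0 = 4.35, ca0_max = 4.35, b_len = 4.75,
                          l0 = 1.58, lR = 1.85, m_relax = 1.0489,
                          b_relax = -1.429, t0 = 0.2) {
  stopifnot(lR >= l0, l0 > 0, t0 > 0, ca0 > 0, ca0_max > 0, b_len > 0)
  a <- list(ca0 = ca0, ca0_max = ca0_max, b_len = b_len, l0 = l0, lR = lR,
            m_relax = m_relax, b_relax = b_relax, t0 = t0)
  class(a) <- "lv_active"
  a
}

#' Kinematic invariants of a deformation gradient
#'
#' Computes `I1 = tr(C)`, `I4f = f0.C.f0`, `I4s = s0.C.s0`,
#' `I8fs = f0.C.s0`, `J = det F` and the fiber Green-Lagrange strain
#' `Eff = (I4f - 1)/2`, with `C = F'F`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param f0,s0 unit, mutually orthogonal fiber and sheet directions.
#' @return named list of invariants.
#' @export
compute_invariants <- function(F, f0, s0) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("inverted element: det F <= 0")
  C <- crossprod(F)
  I4f <- drop(f0 %*% C %*% f0)
  list(I1 = sum(diag(C)), I4f = I4f,
       I4s = drop(s0 %*% C %*% s0),
       I8fs = drop(f0 %*% C %*% s0),
       J = J, Eff = (I4f - 1) / 2)
}

#' Passive second Piola-Kirchhoff stress
#'
#' Stress `S = 2 dPsi/dC` of the passive law (isochoric deviatoric part plus
#' volumetric penalty). Zero at the reference configuration.
#'
#' @param F 3x3 deformation gradient.
#' @param f0,s0 fiber and sheet unit vectors.
#' @param mp an `lv_material`.
#' @return symmetric 3x3 stress tensor (MPa).
#' @export
passive_pk2_stress <- function(F, f0, s0, mp = material_params()) {
  compute_invariants(F, f0, s0)   # validates det F > 0
  out <- .ho_point_cpp(F, f0, s0, unclass(mp), 0, unclass(active_params()), -1)
  if (!out$ok) stop("constitutive evaluation failed (extreme state)")
  matrix(out$S, 3, 3)
}

#' Strain energy density
#'
#' @inheritParams passive_pk2_stress
#' @return energy density (MPa), zero at the reference configuration.
#' @export
strain_energy <- function(F, f0, s0, mp = material_params()) {
  out <- .ho_point_cpp(F, f0, s0, unclass(mp), 0, unclass(active_params()), -1)
  if (!out$ok) stop("constitutive evaluation failed (extreme state)")
  out$psi
}

#' Active fiber tension
#'
#' Scalar active tension `T0(t, Eff)` (MPa): peak isometric tension scaled by
#' a calcium-activation factor with length-dependent half-activation
#' calcium, and a cosine time course that peaks at `t0` and relaxes over a
#' sarcomere-length-dependent duration. Returns 0 before activation, after
#' relaxation, and at or below the zero-tension sarcomere length.
#'
#' @param t time since activation onset (s, >= 0).
#' @param Eff fiber Green-Lagrange strain (relative to the stress-free
#'   configuration); requires `2*Eff + 1 > 0`.
#' @param t_max isometric tension scale (MPa).
#' @param ap an `lv_active`.
#' @return tension (MPa, >= 0).
#' @export
active_tension <- function(t, Eff, t_max, ap = active_params()) {
  stopifnot(t >= 0)
  if (2 * Eff + 1 <= 0) stop("invalid fiber strain: 2*Eff + 1 <= 0")
  .active_T0_cpp(t, Eff, t_max, unclass(ap))
}

#' Total second Piola-Kirchhoff stress (passive + active)
#'
#' `S = S_passive + T0(t, Eff) f0 (x) f0 / I4f`.
#'
#' @inheritParams passive_pk2_stress
#' @param t_max isometric tension scale (MPa).
#' @param ap an `lv_active`.
#' @param t time since activation onset (s).
#' @return symmetric 3x3 stress tensor (MPa).
#' @export
total_stress <- function(F, f0, s0, mp = material_params(), t_max = 0,
                         ap = active_params(), t = 0) {
  compute_invariants(F, f0, s0)
  out <- .ho_point_cpp(F, f0, s0, unclass(mp), t_max, unclass(ap), t)
  if (!out$ok) stop("constitutive evaluation failed (extreme state)")
  matrix(out$S, 3, 3)
}
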