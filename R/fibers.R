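# Rule-based myofiber architecture.
#
# A local orthonormal triad (circumferential, longitudinal, radial) is built
# at each element centroid from the structured mesh, and the fiber direction
# is rotated in the (circumferential, longitudinal) tangent plane by a helix
# angle that varies linearly through the wall: +60 deg at the endocardium to
# -60 deg at the epicardium (measured from the local circumferential
# direction, by convention).

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Per-element local orthonormal basis
#'
#' Builds the local triad at each element: `e_r` the outward transmural
#' direction, `e_l` the apex-to-base tangent (orthogonalized against `e_r`),
#' and `e_c = e_l x e_r` the circumferential direction. The triad is
#' right-handed with `det[e_c e_l e_r] = +1`.
#'
#' @param mesh an `lv_mesh`.
#' @return list of three `ne x 3` matrices `e_c`, `e_l`, `e_r`.
#' @export
local_basis <- function(mesh) {
  conn <- mesh$conn
  X <- mesh$nodes
  facemean <- function(cols) {
    (X[conn[, cols[1]], , drop = FALSE] + X[conn[, cols[2]], , drop = FALSE] +
     X[conn[, cols[3]], , drop = FALSE] + X[conn[, cols[4]], , drop = FALSE]) / 4
  }
  er_raw <- facemean(5:8) - facemean(1:4)              # inner -> outer
  el_raw <- facemean(c(4, 3, 8, 7)) - facemean(c(1, 2, 6, 5))  # apex -> base
  e_r <- normalize_rows(er_raw)
  el_p <- el_raw - rowSums(el_raw * e_r) * e_r
  e_l <- normalize_rows(el_p)
  e_c <- cbind(e_l[, 2] * e_r[, 3] - e_l[, 3] * e_r[, 2],
               e_l[, 3] * e_r[, 1] - e_l[, 1] * e_r[, 3],
               e_l[, 1] * e_r[, 2] - e_l[, 2] * e_r[, 1])
  list(e_c = e_c, e_l = e_l, e_r = e_r)
}

#' Helix angle rule
#'
#' Linear transmural interpolation of the fiber helix angle:
#' `angle(d) = endo_angle + (epi_angle - endo_angle) * d` with transmural
#' depth `d = 0` at the endocardium and `d = 1` at the epicardium. Defaults
#' give `+60 - 120 d` degrees.
#'
#' @param d transmural depth in `[0, 1]`.
#' @param endo_angle,epi_angle surface helix angles (degrees).
#' @return helix angle (degrees).
#' @export
helix_angle <- function(d, endo_angle = 60, epi_angle = -60) {
  endo_angle + (epi_angle - endo_angle) * d
}

#' Assign rule-based fiber and sheet directions
#'
#' Fiber direction `f0 = cos(a) e_c + sin(a) e_l` with helix angle `a` from
#' [helix_angle()] evaluated at the element-centroid transmural depth
#' (layer midpoints, `d = (layer - 0.5)/8`). The sheet direction `s0` is the
#' outward transmural direction orthogonalized against `f0` (transmural
#' sheets), so the sheet and fiber-sheet coupling terms of the passive law
#' act across the wall.
#'
#' @param mesh an `lv_mesh`.
#' @param endo_angle,epi_angle surface helix angles (degrees).
#' @return object of class `lv_fibers`: `f0`, `s0` (`ne x 3` unit rows),
#'   `depth`, `helix_angle` (degrees) and the local `basis`.
#' @export
assign_fibers <- function(mesh, endo_angle = 60, epi_angle = -60) {
  basis <- local_basis(mesh)
  d <- mesh$depth
  ang <- helix_angle(d, endo_angle, epi_angle) * pi / 180
  f0 <- cos(ang) * basis$e_c + sin(ang) * basis$e_l
  f0 <- normalize_rows(f0)
  s0 <- basis$e_r - rowSums(basis$e_r * f0) * f0
  s0 <- normalize_rows(s0)
  out <- list(f0 = f0, s0 = s0, depth = d,
              helix_angle = helix_angle(d, endo_angle, epi_angle),
              basis = basis,
              endo_angle = endo_angle, epi_angle = epi_angle)
  class(out) <- "lv_fibers"
  out
}
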