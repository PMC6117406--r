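# Truncated-ellipsoid LV geometry and structured hexahedral meshing.
#
# Conventions: the long axis is z, the apex is at the -z pole, the basal
# (truncation) plane sits at z = truncation_height > 0 above the equator.
# Lengths cm, volumes ml.

#' Analytic volume of a truncated ellipsoid of revolution
#'
#' Volume enclosed by the surface with short semi-axis `a` (x and y), long
#' semi-axis `c` (z), cut by the plane `z = zb` (apex at `z = -c`,
#' `0 <= zb < c`).
#'
#' @param a short semi-axis (cm).
#' @param c_ax long semi-axis (cm).
#' @param zb truncation plane height above the equator (cm).
#' @return volume (ml).
#' @export
trunc_ellipsoid_volume <- function(a, c_ax, zb) {
  stopifnot(a > 0, c_ax > 0, zb >= 0, zb < c_ax)
  pi * a^2 * (zb + c_ax - (zb^3 + c_ax^3) / (3 * c_ax^2))
}

#' Back-calculate end-diastolic endo/epi ellipsoid surfaces
#'
#' Builds truncated-ellipsoid endocardial and epicardial surfaces from the
#' echo measurements: the endocardial short-axis diameter equals the measured
#' internal diameter, the equatorial wall thickness equals the mean of the
#' posterior and septal thicknesses, and the endocardial long semi-axis is
#' solved so the cavity volume equals the measured EDV. The basal plane is
#' placed at `trunc_ratio * c_endo` above the equator.
#'
#' @param meas an `lv_patient` record.
#' @param trunc_ratio truncation height as a fraction of the endocardial long
#'   semi-axis (default 0.4).
#' @return an object of class `lv_geometry`.
#' @export
build_ed_surfaces <- function(meas, trunc_ratio = 0.4) {
  stopifnot(inherits(meas, "lv_patient"), trunc_ratio > 0, trunc_ratio < 1)
  a_endo <- meas$lv_internal_diameter_ed / 2
  tbar <- mean(c(meas$posterior_wall_thickness_ed,
                 meas$septal_wall_thickness_ed))
  if (tbar <= 0 || tbar >= a_endo)
    stop("wall thickness is infeasible for the measured internal diameter")
  # V = pi a^2 c f(kappa) with f = (1 + k) - (1 + k^3)/3
  f <- (1 + trunc_ratio) - (1 + trunc_ratio^3) / 3
  c_endo <- meas$edv / (pi * a_endo^2 * f)
  zb <- trunc_ratio * c_endo
  a_epi <- a_endo + tbar
  c_epi <- c_endo + tbar
  if (c_epi <= zb)
    stop("epicardial surface does not reach the basal plane")
  cav <- trunc_ellipsoid_volume(a_endo, c_endo, zb)
  wall <- trunc_ellipsoid_volume(a_epi, c_epi, zb) - cav
  g <- list(endo_semi_axis_long = c_endo, endo_semi_axis_short = a_endo,
            epi_semi_axis_long = c_epi, epi_semi_axis_short = a_epi,
            truncation_height = zb, cavity_volume = cav, wall_volume = wall)
  class(g) <- "lv_geometry"
  g
}

#' Unloaded cavity volume from the single-point regression
#'
#' Linear regression estimate of the unloaded (zero-pressure) LV cavity
#' volume from one measured end-diastolic point:
#' `V0 = EDV * (0.6 - 0.006 * EDP)`.
#'
#' @param edv end-diastolic volume (ml).
#' @param edp end-diastolic pressure (mmHg), `0 <= edp < 100`.
#' @return unloaded volume V0 (ml).
#' @export
klotz_unloaded_volume <- function(edv, edp) {
  if (any(edp < 0) || any(edp >= 100))
    stop("`edp` must be in [0, 100) mmHg for the unloading regression")
  edv * (0.6 - 0.006 * edp)
}

#' Rescale the ED geometry to its unloaded volume, preserving wall mass
#'
#' The endocardial surface (and truncation plane) is scaled affinely so the
#' cavity volume equals `v0`; the epicardial surface is then scaled by its own
#' factor, found by root finding, so that the myocardial wall volume of the
#' ED configuration is preserved.
#'
#' @param geom an `lv_geometry` (end-diastolic).
#' @param v0 target unloaded cavity volume (ml), `0 < v0 <= cavity_volume`.
#' @return a rescaled `lv_geometry`.
#' @export
scale_to_unloaded <- function(geom, v0) {
  stopifnot(inherits(geom, "lv_geometry"))
  if (v0 <= 0 || v0 > geom$cavity_volume)
    stop("`v0` must lie in (0, cavity_volume]")
  s <- (v0 / geom$cavity_volume)^(1 / 3)
  a_en <- s * geom$endo_semi_axis_short
  c_en <- s * geom$endo_semi_axis_long
  zb <- s * geom$truncation_height
  wall_target <- geom$wall_volume
  wall_of <- function(se) {
    trunc_ellipsoid_volume(se * geom$epi_semi_axis_short,
                           se * geom$epi_semi_axis_long, zb) - v0
  }
  se <- uniroot(function(x) wall_of(x) - wall_target,
                lower = s * 0.5, upper = 1.5, tol = 1e-12)$root
  g <- list(endo_semi_axis_long = c_en, endo_semi_axis_short = a_en,
            epi_semi_axis_long = se * geom$epi_semi_axis_long,
            epi_semi_axis_short = se * geom$epi_semi_axis_short,
            truncation_height = zb,
            cavity_volume = trunc_ellipsoid_volume(a_en, c_en, zb),
            wall_volume = wall_of(se))
  stopifnot(g$epi_semi_axis_short > g$endo_semi_axis_short,
            g$epi_semi_axis_long > g$endo_semi_axis_long)
  class(g) <- "lv_geometry"
  g
}

# balanced triangulation of a closed polygon (indices in CCW order): splits
# recursively instead of fanning from one vertex, keeping vertex degrees low
# so the pressure-load stiffness stays cheap to factorize
triangulate_polygon <- function(idx) {
  n <- length(idx)
  if (n < 3) return(matrix(integer(0), 0, 3))
  if (n == 3) return(matrix(idx, 1, 3))
  mid <- (n + 2) %/% 2
  rbind(matrix(c(idx[1], idx[mid], idx[n]), 1, 3),
        triangulate_polygon(idx[1:mid]),
        triangulate_polygon(idx[mid:n]))
}

# parametric point on a truncated ellipsoid surface; phi = 0 at the apex
# (-z pole), phi_max at the basal plane
ellipsoid_point <- function(a, c_ax, phi, theta) {
  cbind(a * sin(phi) * cos(theta),
        a * sin(phi) * sin(theta),
        -c_ax * cos(phi))
}

#' Structured hexahedral mesh of the LV wall
#'
#' Meshes the wall between the endo- and epicardial truncated ellipsoids with
#' a structured grid: exactly 8 transmural layers (layer 1 innermost),
#' `n_circ` circumferential and `n_long` longitudinal elements, i.e.
#' `8 * n_circ * n_long` trilinear hexahedra. Layers 1-3, 4-5 and 6-8 are
#' labeled subendocardium, midmyocardium and subepicardium. The apical pole
#' cannot be meshed with positive-Jacobian hexahedra, so the mesh has a small
#' apical opening that shrinks under longitudinal refinement; the cavity
#' surface is closed by flat basal and apical caps for volume tracking.
#'
#' @param geom an `lv_geometry` (typically the unloaded configuration).
#' @param n_circ circumferential element count (>= 8).
#' @param n_long longitudinal element count (>= 6).
#' @return an object of class `lv_mesh` with fields `nodes` (n x 3, cm),
#'   `conn` (ne x 8, 1-based), `layer` (1-8), `region` (character),
#'   `depth` (element transmural depth in `[0, 1]`), node/face sets, oriented
#'   `endo_faces` quads and `cavity_tris` triangles.
#' @export
mesh_lv <- function(geom, n_circ = 16, n_long = 10) {
  stopifnot(inherits(geom, "lv_geometry"))
  if (n_circ < 8) stop("`n_circ` must be at least 8")
  if (n_long < 6) stop("`n_long` must be at least 6")
  if (geom$epi_semi_axis_short <= geom$endo_semi_axis_short)
    stop("non-positive wall thickness; cannot mesh")

  nlay <- 8L
  theta <- 2 * pi * (0:(n_circ - 1)) / n_circ
  # one virtual apex ring is skipped: phi_j = phi_max * (j+1)/(n_long+1)
  frac <- (1:(n_long + 1)) / (n_long + 1)
  phi_en <- acos(-geom$truncation_height / geom$endo_semi_axis_long) * frac
  phi_ep <- acos(-geom$truncation_height / geom$epi_semi_axis_long) * frac

  nid <- function(i, j, k) {
    # i circumferential 0..n_circ-1 (wrapped), j longitudinal 0..n_long,
    # k transmural surface 0..8
    1L + (i %% n_circ) + n_circ * (j + (n_long + 1L) * k)
  }
  nnode <- n_circ * (n_long + 1L) * (nlay + 1L)
  nodes <- matrix(0, nnode, 3)
  for (k in 0:nlay) {
    xi <- k / nlay
    for (j in 0:n_long) {
      pen <- ellipsoid_point(geom$endo_semi_axis_short,
                             geom$endo_semi_axis_long, phi_en[j + 1], theta)
      pep <- ellipsoid_point(geom$epi_semi_axis_short,
                             geom$epi_semi_axis_long, phi_ep[j + 1], theta)
      nodes[nid(0:(n_circ - 1), j, k), ] <- (1 - xi) * pen + xi * pep
    }
  }

  ne <- nlay * n_circ * n_long
  conn <- matrix(0L, ne, 8)
  layer <- integer(ne)
  e <- 0L
  for (k in 0:(nlay - 1L)) {
    for (j in 0:(n_long - 1L)) {
      for (i in 0:(n_circ - 1L)) {
        e <- e + 1L
        conn[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k),
                       nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                       nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                       nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
        layer[e] <- k + 1L
      }
    }
  }
  region <- c("subendocardium", "subendocardium", "subendocardium",
              "midmyocardium", "midmyocardium",
              "subepicardium", "subepicardium", "subepicardium")[layer]

  # node sets
  basal_nodes <- sort(unique(as.integer(outer(0:(n_circ - 1), 0:nlay,
    function(i, k) nid(i, n_long, k)))))
  annulus_nodes <- as.integer(nid(0:(n_circ - 1), n_long, 0))
  apical_ring <- as.integer(nid(0:(n_circ - 1), 0, 0))
  endo_rings <- lapply(0:n_long, function(j) as.integer(nid(0:(n_circ - 1), j, 0)))

  # endocardial faces of layer-1 elements, oriented so t_theta x t_phi points
  # out of the cavity (into the wall)
  endo_el <- which(layer == 1L)
  endo_faces <- conn[endo_el, 1:4, drop = FALSE]

  # closed cavity surface triangulation: endo quads split along a diagonal,
  # plus apical and basal cap fans (normals outward from the cavity)
  qt <- rbind(endo_faces[, c(1, 2, 3)], endo_faces[, c(1, 3, 4)])
  cap_a <- triangulate_polygon(rev(apical_ring))   # outward normal -z
  cap_b <- triangulate_polygon(annulus_nodes)      # outward normal +z
  tris <- rbind(qt, cap_a, cap_b)
  # basal-cap fan excluded from the load-stiffness pattern: its Hessian is
  # identically zero on the free dofs (triangles coplanar with the reference
  # point; longitudinal annulus dofs are fixed)
  n_wall_tris <- nrow(qt) + nrow(cap_a)

  mesh <- list(nodes = nodes, conn = conn, layer = layer, region = region,
               depth = (layer - 0.5) / 8,
               n_circ = as.integer(n_circ), n_long = as.integer(n_long),
               basal_nodes = basal_nodes, annulus_nodes = annulus_nodes,
               apical_ring = apical_ring, endo_rings = endo_rings,
               endo_faces = endo_faces, cavity_tris = tris,
               n_wall_tris = n_wall_tris,
               ref_point = c(0, 0, geom$truncation_height),
               geom = geom)
  class(mesh) <- "lv_mesh"

  mj <- .hex_min_jac_cpp(mesh$nodes, mesh$conn)
  if (any(mj <= 0)) stop("mesh has non-positive hexahedral Jacobians")
  raw0 <- .cavity_volume_cpp(mesh$nodes, mesh$cavity_tris,
                             numeric(3 * nnode), mesh$ref_point)
  if (raw0 <= 0) stop("mesh cavity volume is non-positive; orientation error")
  # the faceted surface systematically underestimates the continuum cavity;
  # volumes are reported in continuum units via this fixed reference-state
  # correction (cancels exactly in EF and converges to 1 under refinement)
  mesh$vol_scale <- geom$cavity_volume / raw0
  mesh
}

#' Cavity volume of a (possibly deformed) mesh
#'
#' Signed-volume integral over the closed, triangulated endocardial surface
#' (endocardial faces plus basal and apical caps). By default the raw
#' faceted-surface volume is rescaled by the fixed reference-configuration
#' correction factor (`vol_scale`) so that volumes are reported in continuum
#' units; the factor cancels in ejection fraction and tends to 1 under mesh
#' refinement.
#'
#' @param mesh an `lv_mesh`.
#' @param u nodal displacement vector (length `3 * nnodes`), zero if omitted.
#' @param corrected apply the reference-state correction factor.
#' @return cavity volume (ml).
#' @export
mesh_cavity_volume <- function(mesh, u = NULL, corrected = TRUE) {
  if (is.null(u)) u <- numeric(3 * nrow(mesh$nodes))
  v <- .cavity_volume_cpp(mesh$nodes, mesh$cavity_tris, u, mesh$ref_point)
  if (corrected) v * mesh$vol_scale else v
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf(
    "LV truncated-ellipsoid geometry: endo a=%.3f c=%.3f cm, epi a=%.3f c=%.3f cm\n",
    x$endo_semi_axis_short, x$endo_semi_axis_long,
    x$epi_semi_axis_short, x$epi_semi_axis_long))
  cat(sprintf("  basal plane z=%.3f cm; cavity %.2f ml; wall %.2f ml\n",
              x$truncation_height, x$cavity_volume, x$wall_volume))
  invisible(x)
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV hex mesh: %d nodes, %d elements (8 x %d x %d), cavity %.2f ml\n",
              nrow(x$nodes), nrow(x$conn), x$n_circ, x$n_long,
              mesh_cavity_volume(x)))
  invisible(x)
}
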