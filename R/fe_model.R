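# Finite-element model container and fast sparse assembly.
#
# The global quasi-static system is solved for z = [u_free; lambda(3); p]:
#   R_u      = f_int(u) - p * Phi(u) + A' lambda   (equilibrium, follower load)
#   R_lambda = A u                                 (annulus mean-motion MPCs)
#   R_ctrl   = control equation                    (pressure / volume / afterload)
# Basal nodes are fixed longitudinally by elimination. The Jacobian sparsity
# pattern is precomputed once per mesh; per-iteration assembly only
# accumulates numeric values into the fixed compressed-column structure.

#' Build a finite-element LV model
#'
#' Combines mesh, fibers, passive material, active constants and per-region
#' contractility into a solvable model. Boundary conditions follow the
#' standard idealized-LV setup: basal nodes fixed longitudinally, and the
#' mean in-plane translation and mean long-axis rotation of the endocardial
#' annulus tied to the fixed base center (three multipoint constraints),
#' which removes rigid-body motion while letting the annulus dilate and
#' contract.
#'
#' @param mesh an `lv_mesh`.
#' @param fibers an `lv_fibers` for the same mesh.
#' @param mp an `lv_material`.
#' @param ap an `lv_active`.
#' @param tmax contractility (MPa): scalar, or named region vector
#'   `c(subendo=, mid=, subepi=)`, or per-element vector.
#' @param k_pen penalty stiffness enforcing the three annulus mean-motion
#'   constraints.
#' @return object of class `lv_model`.
#' @export
lv_model <- function(mesh, fibers, mp = material_params(),
                     ap = active_params(), tmax = 0, k_pen = 1e5) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(fibers, "lv_fibers"))
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn

  fixed <- 3L * (mesh$basal_nodes - 1L) + 3L   # longitudinal dof of base
  free <- setdiff(seq_len(ndof), fixed)
  nfree <- length(free)
  fmap <- integer(ndof)
  fmap[free] <- seq_len(nfree)

  # annulus mean-motion constraints (x/y dofs are all free), enforced by a
  # quadratic penalty: rows of A are mean u_x, mean u_y, and the normalized
  # mean rotation about the long axis
  ann <- mesh$annulus_nodes
  na <- length(ann)
  xy <- mesh$nodes[ann, 1:2, drop = FALSE]
  mpc_i <- c(rep(1L, na), rep(2L, na), rep(3L, na), rep(3L, na))
  mpc_dof <- c(3L * (ann - 1L) + 1L,            # mean u_x
               3L * (ann - 1L) + 2L,            # mean u_y
               3L * (ann - 1L) + 1L,            # rotation: -y u_x + x u_y
               3L * (ann - 1L) + 2L)
  rbar <- mean(sqrt(rowSums(xy^2)))
  mpc_v <- c(rep(1 / na, 2L * na), -xy[, 2] / (na * rbar), xy[, 1] / (na * rbar))
  mpc_j <- fmap[mpc_dof]
  stopifnot(all(mpc_j > 0))
  mpc <- list(i = mpc_i, j = mpc_j, v = mpc_v, n = 3L, k_pen = k_pen)

  # constant penalty tangent triplets k * A'A (free-dof indexing)
  pi_ <- pj_ <- integer(0); pv_ <- numeric(0)
  for (r in 1:3) {
    sel <- mpc_i == r
    jj <- mpc_j[sel]; vv <- mpc_v[sel]
    op <- outer(vv, vv) * k_pen
    pi_ <- c(pi_, rep(jj, each = length(jj)))
    pj_ <- c(pj_, rep(jj, times = length(jj)))
    pv_ <- c(pv_, as.numeric(op))
  }
  mpc$pen_i <- pi_; mpc$pen_j <- pj_; mpc$pen_v <- pv_

  pat_k <- .lv_pattern_cpp(mesh$conn, nn)
  # load stiffness over wall + apical-cap triangles; the basal-cap Hessian
  # vanishes on the free dofs and is omitted from the pattern
  wall_tris <- mesh$cavity_tris[seq_len(mesh$n_wall_tris), , drop = FALSE]
  pat_h <- .cavity_hess_pattern_cpp(wall_tris, nn)

  model <- list(mesh = mesh, fibers = fibers, mp = mp, ap = ap,
                tmax_el = resolve_tmax(tmax, mesh),
                fixed = fixed, free = free, nfree = nfree, fmap = fmap,
                mpc = mpc, pat_k = pat_k, pat_h = pat_h)
  class(model) <- "lv_model"
  model$assembly <- build_assembly_plan(model)
  # shared cache for the CHOLMOD symbolic factorization (pattern-invariant)
  model$cache <- new.env(parent = emptyenv())
  model
}

# map a scalar / region-named / per-element tmax spec to a per-element vector
resolve_tmax <- function(tmax, mesh) {
  ne <- nrow(mesh$conn)
  if (length(tmax) == 1L && is.null(names(tmax))) return(rep(as.numeric(tmax), ne))
  if (!is.null(names(tmax))) {
    need <- c("subendo", "mid", "subepi")
    stopifnot(all(need %in% names(tmax)))
    out <- numeric(ne)
    out[mesh$region == "subendocardium"] <- tmax[["subendo"]]
    out[mesh$region == "midmyocardium"] <- tmax[["mid"]]
    out[mesh$region == "subepicardium"] <- tmax[["subepi"]]
    return(out)
  }
  stopifnot(length(tmax) == ne)
  as.numeric(tmax)
}

#' Swap contractility or passive material without rebuilding patterns
#'
#' @param model an `lv_model`.
#' @param tmax contractility spec as in [lv_model()].
#' @param mp an `lv_material`.
#' @return the modified model.
#' @export
set_tmax <- function(model, tmax) {
  model$tmax_el <- resolve_tmax(tmax, model$mesh)
  model
}

#' @rdname set_tmax
#' @export
set_material <- function(model, mp) {
  stopifnot(inherits(mp, "lv_material"))
  model$mp <- mp
  model
}

# ---------------------------------------------------------------------------
# assembly plan for the sparse stiffness block over the free displacement
# dofs (element tangents + follower-load stiffness + constant annulus
# penalty), fixed triplet ordering [elem K | face K | penalty]. The single
# cavity-pressure unknown is eliminated by a rank-one Schur complement in the
# solver, which keeps the dense pressure/volume couplings out of the sparse
# factorization.

build_assembly_plan <- function(model) {
  mesh <- model$mesh
  nfree <- model$nfree
  fmap <- model$fmap
  nz <- nfree

  map_pair <- function(gi, gj) {
    # global dof pairs -> system indices; 0 = dropped (fixed dof)
    ii <- fmap[gi]; jj <- fmap[gj]
    keep <- ii > 0L & jj > 0L
    list(i = ifelse(keep, ii, 0L), j = ifelse(keep, jj, 0L))
  }

  kk <- map_pair(model$pat_k$i, model$pat_k$j)
  hh <- map_pair(model$pat_h$i, model$pat_h$j)

  ti <- c(kk$i, hh$i, model$mpc$pen_i)
  tj <- c(kk$j, hh$j, model$mpc$pen_j)
  drop0 <- ti == 0L | tj == 0L
  ti[drop0] <- 1L; tj[drop0] <- 1L    # park dropped entries at (1,1) with 0 value

  # symmetrized upper-triangle storage: a lower triplet (i > j) accumulates
  # onto its mirror position; off-diagonal slots then hold K_ij + K_ji and
  # are halved after accumulation, which both symmetrizes (averaging the
  # tiny follower-load asymmetry) and matches dsCMatrix storage
  swap <- ti > tj
  tiu <- ifelse(swap, tj, ti)
  tju <- ifelse(swap, ti, tj)

  key <- (as.double(tju) - 1) * nz + as.double(tiu)
  ukey <- sort(unique(key))
  pos <- match(key, ukey)
  pos[drop0] <- 0L                    # accumulator skips these

  u_i <- as.integer((ukey - 1) %% nz) + 1L
  u_j <- as.integer((ukey - 1) %/% nz) + 1L
  colcount <- tabulate(u_j, nbins = nz)

  # dense pressure column / control row supports (global dof indexing)
  fnodes <- sort(unique(as.integer(mesh$endo_faces)))
  fdofs <- as.integer(t(outer(3L * (fnodes - 1L), 1:3, `+`)))
  cnodes <- sort(unique(as.integer(mesh$cavity_tris)))
  cdofs <- as.integer(t(outer(3L * (cnodes - 1L), 1:3, `+`)))

  list(nz = nz, nnz = length(ukey),
       pos = as.integer(pos),
       xscale = ifelse(u_i == u_j, 1, 0.5),
       diag_pos = which(u_i == u_j),
       csc_i = u_i - 1L, csc_p = c(0L, cumsum(colcount)),
       fdofs = fdofs, cdofs = cdofs)
}

# accumulate triplet values (fixed order) into the symmetric CSC value slot
accumulate_csc <- function(plan, vals) {
  .accum_pos_cpp(plan$pos, vals, plan$nnz) * plan$xscale
}

make_sparse_sym <- function(plan, x) {
  new("dsCMatrix", i = plan$csc_i, p = plan$csc_p, x = x,
      uplo = "U", Dim = c(plan$nz, plan$nz))
}

#' @export
print.lv_model <- function(x, ...) {
  cat(sprintf("LV FE model: %d elements, %d free dofs; tmax range %.3f-%.3f MPa\n",
              nrow(x$mesh$conn), x$nfree, min(x$tmax_el), max(x$tmax_el)))
  invisible(x)
}
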