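# Viscous finite-element mechanics.
#
# Every rod segment of every edge carries the constant tension of its edge
# and pulls its two end nodes together; the cytoplasm of each cell grounds
# each of the cell's boundary nodes through two orthogonal dashpots.  One
# time step solves
#
#     [ (1/dt) C   G^T ] [ du     ]   [ f ]
#     [    G        0  ] [ lambda ] = [ r ]
#
# where f is the assembled tension force vector, C the (diagonal) viscous
# matrix, G the per-cell area gradients (shoelace derivatives) and r the
# area restoration term A0 - A.  Because the dashpots are grounded, C is
# positive definite and rigid-body modes are damped without extra anchoring.
# The multipliers are reported as cell pressures (medium pressure = 0).

#' Collect all rod segments of a tissue
#' @return list with integer vectors `i`, `j` (node ids of segment ends),
#'   numeric `gamma`, and `edge` (owning edge id).
#' @keywords internal
collect_segments <- function(ts) .pc_segments(ts$edges)

#' Total boundary energy: sum over edges of tension times polyline length
#'
#' The assembled nodal tension forces are exactly minus the gradient of this
#' quantity with respect to the node positions.
#' @param ts a tissue.
#' @return scalar energy.
#' @export
boundary_energy <- function(ts) {
  s <- collect_segments(ts)
  d <- ts$pos[s$j, , drop = FALSE] - ts$pos[s$i, , drop = FALSE]
  sum(s$gamma * sqrt(d[, 1L]^2 + d[, 2L]^2))
}

#' Assemble nodal interfacial-tension forces
#'
#' The force on a node is the vector sum over its incident segments of the
#' segment tension directed from the node toward the segment's far end --
#' i.e. minus the gradient of [boundary_energy()].
#'
#' @param ts a tissue.
#' @return numeric matrix, one row per node slot (inactive slots zero),
#'   columns x and y.
#' @export
assemble_tension_forces <- function(ts) {
  s <- collect_segments(ts)
  d <- ts$pos[s$j, , drop = FALSE] - ts$pos[s$i, , drop = FALSE]
  len <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  if (any(len <= 0)) stop("zero-length segment in force assembly")
  u <- d / len
  contrib <- rbind(s$gamma * u, -s$gamma * u)
  idx <- c(s$i, s$j)
  agg <- rowsum(contrib, idx)
  f <- matrix(0, nrow(ts$pos), 2L)
  f[as.integer(rownames(agg)), ] <- agg
  f
}

#' Effective node count of a cell for dashpot calibration
#'
#' The number of triple-junction nodes on the cell's boundary plus half the
#' number of its intermediate nodes; intermediate nodes carry half weight.
#' @param ts a tissue. @param ci cell id.
#' @return effective node count.
#' @export
cell_n_eff <- function(ts, ci) {
  nodes <- cell_loop_nodes(ts, ci)
  sum(ts$kind[nodes] == 1L) + 0.5 * sum(ts$kind[nodes] == 2L)
}

#' Per-step geometry cache: boundary loops and areas of all active cells
#' @return list(cells, loops, areas).
#' @keywords internal
cell_loops <- function(ts) {
  cells <- active_cells(ts)
  loops <- .pc_loop_nodes(ts$edges, lapply(ts$cells[cells], `[[`, "loop"))
  areas <- .pc_shoelace(ts$pos, loops)
  list(cells = cells, loops = loops, areas = areas)
}

#' Assemble the diagonal of the global viscous (dashpot) matrix
#'
#' Each cell grounds each of its boundary nodes through two orthogonal
#' dashpots of coefficient k = mu * A / n_eff, where n_eff counts junction
#' nodes fully and intermediate nodes at half weight.  Contributions from
#' cells sharing a node add.  Because the dashpots are isotropic and
#' grounded, the global matrix C is diagonal (hence symmetric positive
#' definite); this function returns its per-node coefficient, which applies
#' to both the x and y degree of freedom of the node.
#'
#' @param ts a tissue.
#' @param lc optional precomputed [cell_loops()] cache.
#' @return numeric vector, one entry per node slot (inactive slots zero).
#' @export
assemble_viscous_matrix <- function(ts, lc = NULL) {
  if (is.null(lc)) lc <- cell_loops(ts)
  coef <- numeric(nrow(ts$pos))
  for (k in seq_along(lc$cells)) {
    a <- lc$areas[k]
    if (a <= 0) stop("cell ", lc$cells[k], " has non-positive area")
    nodes <- lc$loops[[k]]
    kd <- ts$kind[nodes]
    neff <- sum(kd == 1L) + 0.5 * sum(kd == 2L)
    kk <- ts$cells[[lc$cells[k]]]$mu * a / neff
    coef[nodes] <- coef[nodes] + kk
  }
  coef
}

#' Per-cell area gradient triplets (shoelace derivatives)
#'
#' For a CCW loop v1..vm, dA/dx_i = (y_{i+1} - y_{i-1}) / 2 and
#' dA/dy_i = (x_{i-1} - x_{i+1}) / 2.
#' @return list of per-cell lists(nodes, gx, gy) named by cell id.
#' @keywords internal
area_gradients <- function(ts, lc = NULL) {
  if (is.null(lc)) lc <- cell_loops(ts)
  out <- list()
  for (k in seq_along(lc$cells)) {
    v <- lc$loops[[k]]
    p <- ts$pos[v, , drop = FALSE]
    m <- length(v)
    nxt <- c(2:m, 1L); prv <- c(m, 1:(m - 1L))
    out[[as.character(lc$cells[k])]] <- list(
      nodes = v,
      gx = (p[nxt, 2L] - p[prv, 2L]) / 2,
      gy = (p[prv, 1L] - p[nxt, 1L]) / 2
    )
  }
  out
}

#' Advance the tissue by one viscous time step
#'
#' Solves the saddle-point system coupling the dashpot matrix with the
#' per-cell area constraints, using a Schur complement on the (diagonal)
#' viscous block, and moves the nodes by the resulting increments.  The area
#' right-hand side restores each cell toward its target area, so constraint
#' drift is corrected every step.  A deterministic step-length clamp scales
#' the whole increment if any node would move more than
#' `clamp_frac * seg_min_frac * D` in one step, which keeps the explicit
#' geometry update stable through fast transients.
#'
#' @param ts a tissue.
#' @param config a [sim_config()]; a `NULL` `dt` selects the adaptive
#'   per-step stable increment (see [sim_config()]).
#' @param D optional mean cell diameter (recomputed when missing; constant
#'   for practical purposes because areas are constrained to their targets).
#' @return list with elements `tissue` (updated), `displacements` (node
#'   increment matrix), `forces` (assembled tension forces), `pressures`
#'   (named per-cell pressure, medium = 0 reference), and `max_disp`
#'   (largest nodal displacement this step), and `dt` (the increment used).
#' @export
advance_step <- function(ts, config, D = NULL) {
  if (!inherits(config, "polycell_config")) config <- do.call(sim_config, config)
  s <- collect_segments(ts)
  d <- ts$pos[s$j, , drop = FALSE] - ts$pos[s$i, , drop = FALSE]
  len <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  if (any(len <= 0)) stop("zero-length segment in force assembly")
  u <- d / len
  contrib <- rbind(s$gamma * u, -s$gamma * u)
  agg <- rowsum(contrib, c(s$i, s$j))
  f <- matrix(0, nrow(ts$pos), 2L)
  f[as.integer(rownames(agg)), ] <- agg
  if (!all(is.finite(f))) stop("non-finite geometry in force assembly")
  lc <- cell_loops(ts)
  if (is.null(D)) D <- mean(2 * sqrt(abs(lc$areas) / pi))
  coef <- assemble_viscous_matrix(ts, lc)
  dt <- config$dt
  if (is.null(dt)) {
    # per-step stability bound: the stiffest transverse mode of a segment of
    # length L and tension gamma damped by its end nodes' dashpots k obeys
    # dt < k L / gamma; take the worst segment with a safety factor
    act <- s$gamma > 0
    if (!any(act)) stop("all tensions are zero; supply dt explicitly")
    kend <- pmin(coef[s$i[act]], coef[s$j[act]])
    dt <- config$dt_safety * min(kend * len[act] / s$gamma[act])
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  n <- nrow(ts$pos)
  dinv <- ifelse(coef > 0, dt / coef, 0)   # inverse of (1/dt) C
  dinv2 <- c(dinv, dinv)                   # x dofs then y dofs
  fvec <- c(f[, 1L], f[, 2L])
  ustar <- dinv2 * fvec

  ag <- .pc_area_grad(ts$pos, lc$loops)
  cids <- lc$cells
  m <- length(cids)
  ii <- rep(seq_len(m), times = ag$len)
  G <- Matrix::sparseMatrix(i = c(ii, ii), j = c(ag$nodes, ag$nodes + n),
                            x = c(ag$gx, ag$gy), dims = c(m, 2L * n))

  r <- vapply(seq_len(m), function(k)
    ts$cells[[cids[k]]]$target_area - lc$areas[k], numeric(1L))

  S <- Matrix::tcrossprod(G %*% Matrix::Diagonal(x = dinv2), G)
  rhs <- as.numeric(G %*% ustar) - r
  lam <- tryCatch(as.numeric(Matrix::solve(S, rhs)),
                  error = function(e) stop("singular constraint block: ",
                                           conditionMessage(e)))
  du <- ustar - dinv2 * as.numeric(Matrix::crossprod(G, lam))
  dun <- sqrt(du[seq_len(n)]^2 + du[n + seq_len(n)]^2)
  maxd <- max(dun)
  clamp <- config$clamp_frac * config$seg_min_frac * D
  if (maxd > clamp) {
    du <- du * (clamp / maxd)
    maxd <- clamp
  }
  ts$pos[, 1L] <- ts$pos[, 1L] + du[seq_len(n)]
  ts$pos[, 2L] <- ts$pos[, 2L] + du[n + seq_len(n)]
  list(tissue = ts,
       displacements = cbind(du[seq_len(n)], du[n + seq_len(n)]),
       forces = f,
       pressures = stats::setNames(-lam, cids),
       max_disp = maxd, dt = dt)
}

#' Equivalent transverse shear carried to a straight edge's ends
#'
#' A straight cell edge loaded by the pressure difference across it behaves
#' like a beam and transfers half the total transverse load to each end:
#' V = (1/2) * delta_p * length.  This diagnostic explains why monoline
#' junctions arrest: the shear adds to the tension balance at the junction.
#'
#' @param delta_p pressure difference across the edge.
#' @param length edge (or segment) length, >= 0.
#' @return shear force V.
#' @export
equivalent_shear <- function(delta_p, length) {
  stopifnot(all(length >= 0))
  0.5 * delta_p * length
}
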