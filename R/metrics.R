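# Quantitative comparison measures: circular-arc fits to polyline edges,
# theoretical Young angles at triple junctions and the RMS error of the
# observed angles against them, interface curvature and length series,
# centroid displacement, dimensionless time, and the discrepancy
# percentage used to compare matched monoline/polyline runs.

#' Least-squares circular arc fit (Taubin's algebraic method)
#'
#' Fits the circle `A(x^2+y^2) + Bx + Cy + D = 0` minimizing Taubin's
#' gradient-weighted algebraic distance, which is accurate for the short
#' low-noise arcs a polyline edge provides.  Near-collinear chains (best
#' circle radius enormous relative to the chord) are reported as straight:
#' infinite radius, zero curvature.  With exactly two points the segment is
#' straight by definition.
#'
#' The curvature sign convention: positive when the centre of curvature
#' lies to the left of the chain direction (first to last point), so that
#' for an edge with left region `l` and right region `r`,
#' `kappa = (p_l - p_r) / gamma` is the Young-Laplace relation (the arc
#' bulges toward the lower-pressure side).
#'
#' @param points n x 2 matrix of chain coordinates (n >= 2).
#' @return object of class `polycell_arcfit`: list with `center`, `radius`
#'   (`Inf` for straight), `signed_curvature`, `rms_residual`.
#' @export
fit_circular_arc <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  chord <- sqrt(sum((points[n, ] - points[1L, ])^2))
  straight <- function() structure(
    list(center = c(NA_real_, NA_real_), radius = Inf,
         signed_curvature = 0, rms_residual = line_rms(points)),
    class = "polycell_arcfit")
  if (n == 2L) return(straight())
  ctr <- colMeans(points)
  x <- points[, 1L] - ctr[1L]; y <- points[, 2L] - ctr[2L]
  z <- x^2 + y^2
  zm <- mean(z)
  if (zm < 1e-300) return(straight())
  z0 <- (z - zm) / (2 * sqrt(zm))
  sv <- svd(cbind(z0, x, y))
  v <- sv$v[, 3L]
  A <- v[1L] / (2 * sqrt(zm)); B <- v[2L]; C <- v[3L]; D <- -zm * A
  if (abs(A) * max(chord, 1e-12) < 1e-9) return(straight())
  cx <- -B / (2 * A); cy <- -C / (2 * A)
  R <- sqrt(max(B^2 + C^2 - 4 * A * D, 0)) / (2 * abs(A))
  if (!is.finite(R) || R > 1e6 * max(chord, 1e-12)) return(straight())
  center <- c(cx + ctr[1L], cy + ctr[2L])
  d <- sqrt((points[, 1L] - center[1L])^2 + (points[, 2L] - center[2L])^2)
  rms <- sqrt(mean((d - R)^2))
  # side of the chain the centre lies on: cross(last-first, center-first)
  u <- points[n, ] - points[1L, ]
  w <- center - points[1L, ]
  s <- sign(u[1L] * w[2L] - u[2L] * w[1L])
  if (s == 0) s <- 1
  structure(list(center = center, radius = R,
                 signed_curvature = s / R, rms_residual = rms),
            class = "polycell_arcfit")
}

#' @keywords internal
line_rms <- function(points) {
  n <- nrow(points)
  if (n <= 2L) return(0)
  ctr <- colMeans(points)
  m <- sweep(points, 2L, ctr)
  sv <- svd(m)
  sqrt(mean((m %*% sv$v[, 2L])^2))
}

#' @export
print.polycell_arcfit <- function(x, ...) {
  if (is.infinite(x$radius)) cat("arc fit: straight (curvature 0)\n")
  else cat("arc fit: radius", signif(x$radius, 6L), "curvature",
           signif(x$signed_curvature, 6L), "rms residual",
           signif(x$rms_residual, 3L), "\n")
  invisible(x)
}

#' Theoretical Young angles at a triple junction
#'
#' The unique planar force-balance angles for three interfaces carrying
#' tensions `g1, g2, g3`: the angle between the interfaces carrying `g_i`
#' and `g_j` is `acos((g_k^2 - g_i^2 - g_j^2) / (2 g_i g_j))`.  Element `k`
#' of the returned vector is the angle between the two interfaces *other*
#' than `k` (the wedge pierced by interface `k`'s opposite region).  The
#' three angles always sum to 2*pi and are invariant under uniform
#' rescaling of the tensions.
#'
#' @param g1,g2,g3 positive tensions satisfying the triangle inequality
#'   (each strictly less than the sum of the other two; otherwise no
#'   equilibrium junction exists and an error is thrown).
#' @return numeric length-3 vector of angles in radians.
#' @export
young_angles <- function(g1, g2, g3) {
  g <- c(g1, g2, g3)
  if (any(!is.finite(g)) || any(g <= 0)) stop("tensions must be positive")
  if (any(g >= c(g2 + g3, g1 + g3, g1 + g2)))
    stop("triangle inequality violated: no equilibrium junction for tensions ",
         paste(signif(g, 6L), collapse = ", "))
  ang <- function(i, j, k)
    acos(pmin(1, pmax(-1, (g[k]^2 - g[i]^2 - g[j]^2) / (2 * g[i] * g[j]))))
  c(ang(2L, 3L, 1L), ang(1L, 3L, 2L), ang(1L, 2L, 3L))
}

#' Observed interface direction at a junction for one incident edge
#' @keywords internal
edge_direction_at <- function(ts, ei, nid, method) {
  e <- ts$edges[[ei]]
  ch <- e$chain
  if (ch[1L] == nid) pts <- ts$pos[ch, , drop = FALSE]
  else pts <- ts$pos[rev(ch), , drop = FALSE]
  v_seg <- pts[2L, ] - pts[1L, ]
  if (method == "nearest_segment" || nrow(pts) == 2L)
    return(v_seg / sqrt(sum(v_seg^2)))
  fit <- fit_circular_arc(pts)
  if (is.infinite(fit$radius)) {
    u <- pts[nrow(pts), ] - pts[1L, ]
    return(u / sqrt(sum(u^2)))
  }
  r <- pts[1L, ] - fit$center
  t1 <- c(-r[2L], r[1L])
  if (sum(t1 * v_seg) < 0) t1 <- -t1
  t1 / sqrt(sum(t1^2))
}

#' Young-angle errors at the triple junctions of a tissue
#'
#' For every 3-valent junction the three observed angles between adjacent
#' interface directions are compared with the theoretical Young angles
#' implied by the three edge tensions, pairing angles by interface identity
#' (each angle is opposite a known tension, so there is no matching
#' ambiguity).  Observed directions come either from the tangent of the
#' least-squares circular arc fitted to each edge's node chain
#' (`"arc_tangent"`) or from the polyline segment nearest the junction
#' (`"nearest_segment"`; the only option meaningful for straight monoline
#' edges, for which both methods coincide).
#'
#' Junctions incident to a rosette-split connector edge are excluded (the
#' artificial pair of closely spaced triple junctions does not carry
#' physical contact angles), and junctions whose tensions violate the
#' triangle inequality are skipped and flagged.
#'
#' @param ts a tissue.
#' @param method `"arc_tangent"` or `"nearest_segment"`.
#' @param interior_only score only junctions whose three regions are all
#'   cells (no medium interface).
#' @return data.frame with one row per scored junction: `junction`,
#'   observed angles `obs1..obs3` (radians), Young angles `young1..young3`,
#'   `rms_error` in degrees, `interior`, `flagged`.
#' @export
junction_angle_errors <- function(ts, method = c("arc_tangent",
                                                 "nearest_segment"),
                                  interior_only = FALSE) {
  method <- match.arg(method)
  inc <- junction_incidence(ts)
  val <- table(inc$node)
  jids <- as.integer(names(val)[val == 3L])
  rows <- list()
  for (nid in jids) {
    es <- node_edges(ts, nid)
    if (length(es) != 3L) next
    if (any(vapply(ts$edges[es], function(e) isTRUE(e$connector),
                   logical(1L)))) next
    fan <- node_fan(ts, nid)
    regions <- unique(c(fan$left_away, fan$right_away))
    interior <- !(MEDIUM %in% regions)
    if (interior_only && !interior) next
    gam <- vapply(fan$edge, function(ei) ts$edges[[ei]]$tension, numeric(1L))
    dirs <- t(vapply(fan$edge, function(ei)
      edge_direction_at(ts, ei, nid, method), numeric(2L)))
    # observed wedge angles CCW between consecutive directions (fan is
    # already sorted by first-segment angle; use measured directions)
    obs <- vapply(1:3, function(i) {
      j <- if (i == 3L) 1L else i + 1L
      ccw_angle(dirs[i, ], dirs[j, ])
    }, numeric(1L))
    yng <- tryCatch({
      # wedge between edges i and j is opposite the third edge k
      vapply(1:3, function(i) {
        j <- if (i == 3L) 1L else i + 1L
        k <- setdiff(1:3, c(i, j))
        young_angles(gam[1L], gam[2L], gam[3L])[k]
      }, numeric(1L))
    }, error = function(e) rep(NA_real_, 3L))
    flagged <- anyNA(yng)
    rms <- if (flagged) NA_real_
           else sqrt(mean(((obs - yng) * 180 / pi)^2))
    rows[[length(rows) + 1L]] <- data.frame(
      junction = nid, obs1 = obs[1L], obs2 = obs[2L], obs3 = obs[3L],
      young1 = yng[1L], young2 = yng[2L], young3 = yng[3L],
      rms_error = rms, interior = interior, flagged = flagged)
  }
  if (length(rows) == 0L)
    return(data.frame(junction = integer(0L), obs1 = numeric(0L),
                      obs2 = numeric(0L), obs3 = numeric(0L),
                      young1 = numeric(0L), young2 = numeric(0L),
                      young3 = numeric(0L), rms_error = numeric(0L),
                      interior = logical(0L), flagged = logical(0L)))
  do.call(rbind, rows)
}

#' Percentage discrepancy between paired values
#'
#' The absolute difference divided by the pair mean, times 100.  Returns 0
#' where both values are 0.
#' @param a,b numeric vectors.
#' @return percentage discrepancies.
#' @export
discrepancy_percent <- function(a, b) {
  m <- (a + b) / 2
  out <- ifelse(abs(m) < 1e-300, 0, abs(a - b) / m * 100)
  abs(out)
}

#' Edges of a tissue matching an interface class
#' @keywords internal
edges_of_class <- function(ts, class_label) {
  want <- paste(sort(trimws(strsplit(class_label, "|", fixed = TRUE)[[1L]])),
                collapse = "|")
  eids <- active_edges(ts)
  eids[vapply(eids, function(ei)
    paste(interface_class(ts, ei), collapse = "|") == want, logical(1L))]
}

#' Reference scales of a trajectory (from its initial snapshot)
#' @keywords internal
trajectory_scales <- function(traj) {
  ts0 <- traj$snapshots[[1L]]
  eids <- active_edges(ts0)
  gamma_ref <- mean(vapply(ts0$edges[eids], function(e) e$tension,
                           numeric(1L)))
  mu_ref <- mean(vapply(active_cells(ts0), function(ci) ts0$cells[[ci]]$mu,
                        numeric(1L)))
  D0 <- mean_cell_diameter(ts0)
  list(gamma_ref = gamma_ref, mu_ref = mu_ref, D0 = D0)
}

#' Time-series comparison metrics along a trajectory
#'
#' For every saved snapshot computes: dimensionless time
#' `t* = t * gamma_ref / (mu * D)` (with `gamma_ref` the mean initial
#' tension -- a choice that only scales the abscissa), the median and mean
#' per-junction RMS Young-angle error, the mean absolute edge curvature of
#' the requested interface class normalized by the radius of the circle
#' with the average cell's area, the total class boundary length normalized
#' to its initial value, and the mean centroid displacement of tracked
#' cells normalized to the mean cell diameter.
#'
#' @param traj a trajectory.
#' @param interface_class interface whose curvature/length is followed,
#'   e.g. `"green|yellow"`; defaults to all cell-cell interfaces when `NA`.
#' @param tracked_cells cell ids whose displacement is followed (default:
#'   all cells present in the first snapshot).
#' @param displacement `"euclidean"` or `"x"` (signed horizontal component,
#'   as used for invasion).
#' @param angle_method passed to [junction_angle_errors()].
#' @return data.frame with columns `step`, `t_star`,
#'   `median_rms_angle_err_deg`, `mean_rms_angle_err_deg`,
#'   `mean_abs_curv_norm`, `boundary_len_norm`, `displacement_norm`.
#' @export
aggregate_metrics <- function(traj, interface_class = NA,
                              tracked_cells = NULL,
                              displacement = c("euclidean", "x"),
                              angle_method = "arc_tangent") {
  displacement <- match.arg(displacement)
  stopifnot(length(traj$snapshots) >= 1L)
  sc <- trajectory_scales(traj)
  ts0 <- traj$snapshots[[1L]]
  if (is.null(tracked_cells)) tracked_cells <- active_cells(ts0)
  cen0 <- t(vapply(tracked_cells, function(ci)
    polygon_centroid(cell_vertices(ts0, ci)), numeric(2L)))
  class_edges0 <- if (is.na(interface_class)) cellcell_edges(ts0)
                  else edges_of_class(ts0, interface_class)
  len0 <- sum(vapply(class_edges0, function(ei) edge_length(ts0, ei),
                     numeric(1L)))
  rows <- lapply(seq_along(traj$snapshots), function(k) {
    ts <- traj$snapshots[[k]]
    errs <- junction_angle_errors(ts, method = angle_method)
    errs <- errs$rms_error[!errs$flagged]
    eids <- if (is.na(interface_class)) cellcell_edges(ts)
            else edges_of_class(ts, interface_class)
    curv <- if (length(eids) == 0L) NA_real_ else {
      abar <- mean(vapply(active_cells(ts), function(ci)
        polygon_area(ts, ci), numeric(1L)))
      rnorm_ <- sqrt(abar / pi)
      mean(vapply(eids, function(ei) {
        f <- fit_circular_arc(ts$pos[ts$edges[[ei]]$chain, , drop = FALSE])
        abs(f$signed_curvature)
      }, numeric(1L))) * rnorm_
    }
    blen <- if (len0 > 0 && length(eids) > 0L)
      sum(vapply(eids, function(ei) edge_length(ts, ei), numeric(1L))) / len0
    else NA_real_
    alive <- tracked_cells[vapply(tracked_cells, function(ci)
      !is.null(ts$cells[[ci]]), logical(1L))]
    disp <- if (length(alive) == 0L) NA_real_ else {
      cen <- t(vapply(alive, function(ci)
        polygon_centroid(cell_vertices(ts, ci)), numeric(2L)))
      d0 <- cen0[match(alive, tracked_cells), , drop = FALSE]
      if (displacement == "euclidean")
        mean(sqrt(rowSums((cen - d0)^2))) / sc$D0
      else mean(cen[, 1L] - d0[, 1L]) / sc$D0
    }
    data.frame(step = traj$snapshot_steps[k],
               t_star = traj$times[k] * sc$gamma_ref / (sc$mu_ref * sc$D0),
               median_rms_angle_err_deg =
                 if (length(errs)) stats::median(errs) else NA_real_,
               mean_rms_angle_err_deg =
                 if (length(errs)) mean(errs) else NA_real_,
               mean_abs_curv_norm = curv,
               boundary_len_norm = blen,
               displacement_norm = disp)
  })
  do.call(rbind, rows)
}

#' @keywords internal
cellcell_edges <- function(ts) {
  eids <- active_edges(ts)
  eids[vapply(ts$edges[eids], function(e)
    e$rl != MEDIUM && e$rr != MEDIUM, logical(1L))]
}

#' Total boundary length of an interface class
#' @param ts a tissue. @param class_label e.g. `"green|medium"`.
#' @return summed polyline length over matching edges.
#' @export
interface_length <- function(ts, class_label) {
  eids <- edges_of_class(ts, class_label)
  if (length(eids) == 0L) return(0)
  sum(vapply(eids, function(ei) edge_length(ts, ei), numeric(1L)))
}

#' Fig-3-style discrepancy report between matched runs
#'
#' Compares a monoline and a polyline trajectory of the same scenario and
#' seed.  Angle error, boundary length and displacement discrepancies are
#' time-averaged (trapezoidal integral of the instantaneous percentage
#' discrepancy over the overlapping dimensionless-time range, divided by
#' its span); curvature is evaluated at the terminal configurations only,
#' because straight monoline edges carry zero curvature throughout, and is
#' reported as the difference of the terminal normalized mean absolute
#' curvatures rather than a percentage.
#'
#' @param mono,poly trajectories from [run_pair()].
#' @param interface_class interface followed for curvature and length.
#' @param ... further arguments passed to [aggregate_metrics()].
#' @return one-row data.frame: `angle_error_pct`, `boundary_length_pct`,
#'   `displacement_pct`, `curvature_terminal_diff`.
#' @export
compare_trajectories <- function(mono, poly, interface_class = NA, ...) {
  if (!identical(mono$scenario, poly$scenario))
    stop("trajectories come from different scenarios: ",
         mono$scenario, " vs ", poly$scenario)
  if (!identical(mono$config$seed, poly$config$seed))
    stop("trajectories were run with different seeds")
  meth <- function(tr) if (tr$config$mode == "monoline") "nearest_segment"
                       else "arc_tangent"
  mm <- aggregate_metrics(mono, interface_class, angle_method = meth(mono), ...)
  pm <- aggregate_metrics(poly, interface_class, angle_method = meth(poly), ...)
  t_hi <- min(max(mm$t_star), max(pm$t_star))
  grid <- sort(unique(c(mm$t_star, pm$t_star)))
  grid <- grid[grid <= t_hi]
  tavg <- function(col) {
    a <- stats::approx(mm$t_star, mm[[col]], grid, rule = 2L)$y
    b <- stats::approx(pm$t_star, pm[[col]], grid, rule = 2L)$y
    d <- discrepancy_percent(a, b)
    ok <- is.finite(d)
    if (sum(ok) < 2L) return(NA_real_)
    g <- grid[ok]; d <- d[ok]
    sum(diff(g) * (utils::head(d, -1L) + utils::tail(d, -1L)) / 2) /
      (max(g) - min(g))
  }
  data.frame(
    angle_error_pct = tavg("median_rms_angle_err_deg"),
    boundary_length_pct = tavg("boundary_len_norm"),
    displacement_pct = tavg("displacement_norm"),
    curvature_terminal_diff =
      pm$mean_abs_curv_norm[nrow(pm)] - mm$mean_abs_curv_norm[nrow(mm)])
}
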