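# The six cell-interaction scenarios: interfacial tension tables satisfying
# each scenario's defining inequality, a seeded initial tessellation, and a
# configuration; plus matched monoline/polyline runs from identical initial
# meshes.
#
# Only the tension *inequalities* define the regimes; the default magnitudes
# are chosen with comfortable margin and are fully overridable.

#' Interfacial tension table
#'
#' Maps unordered pairs of region type labels (cell types and the medium) to
#' interfacial tensions.  Pair names use `"a|b"`; the order within a name is
#' irrelevant.
#'
#' @param ... named tensions, e.g. `"yellow|medium" = 3, "green|yellow" = 1`,
#'   or a single named numeric vector.
#' @param medium_label the label that denotes the medium.
#' @return an object of class `polycell_tension_table`.
#' @export
tension_table <- function(..., medium_label = "medium") {
  vals <- c(...)
  if (is.null(names(vals)) || any(names(vals) == ""))
    stop("all tensions must be named 'a|b'")
  if (any(vals < 0)) stop("tensions must be non-negative")
  key <- vapply(strsplit(names(vals), "|", fixed = TRUE), function(p) {
    if (length(p) != 2L) stop("tension names must be 'a|b' pairs")
    paste(sort(trimws(p)), collapse = "|")
  }, character(1L))
  dup <- duplicated(key)
  if (any(dup & vals[dup] != vals[match(key[dup], key)]))
    stop("conflicting tensions for pair ", key[dup][1L])
  structure(stats::setNames(as.numeric(vals[!dup]), key[!dup]),
            medium_label = medium_label, class = "polycell_tension_table")
}

#' Look up the tension of an interface
#' @param tt a [tension_table()].
#' @param a,b region type labels (cell types or the medium label).
#' @return tension gamma.
#' @export
get_tension <- function(tt, a, b) {
  key <- paste(sort(c(a, b)), collapse = "|")
  v <- unclass(tt)
  i <- match(key, names(v))
  if (is.na(i)) stop("no tension for interface ", key)
  unname(v[i])
}

#' @export
print.polycell_tension_table <- function(x, ...) {
  cat("polycell tension table (medium:", attr(x, "medium_label"), ")\n")
  for (k in names(unclass(x))) cat("  ", k, "=", unclass(x)[[k]], "\n")
  invisible(x)
}

#' Assign edge tensions from a tension table by interface class
#' @param ts a tissue. @param tt a [tension_table()].
#' @return tissue with every active edge's tension set.
#' @export
set_tensions <- function(ts, tt) {
  for (ei in active_edges(ts)) {
    lab <- interface_class(ts, ei)
    ts$edges[[ei]]$tension <- get_tension(tt, lab[1L], lab[2L])
  }
  ts
}

#' @keywords internal
require_inequality <- function(ok, text) {
  if (!ok) stop("scenario tension table violates its defining inequality: ",
                text)
}

#' Build one of the six study scenarios
#'
#' Returns the initial tissue (seeded Voronoi tessellation with the
#' scenario's cell types), its tension table (defaults satisfy each
#' scenario's defining inequality with margin, checked at construction) and
#' a simulation configuration.
#'
#' Scenarios and their defining conditions:
#' \describe{
#'   \item{annealing}{one cell type with intentional size variation; every
#'     interface (including the medium) carries the same tension.}
#'   \item{cell_engulfment}{two cells, yellow and green; engulfment of the
#'     yellow cell by the green one requires
#'     `gamma_gm + gamma_gy < gamma_ym`.}
#'   \item{tissue_engulfment}{two abutting multicellular masses; the same
#'     spreading inequality holds and the green-green tension is high
#'     enough that single green cells can be drawn away from their mass
#'     (`gamma_gg > gamma_gy`); the T1 embargo timer is enabled.}
#'   \item{sorting}{200 cells of two randomly assigned types; heterotypic
#'     interfaces are penalized (`gamma_gy` above the homotypic mean) so
#'     the types sort, and the medium tensions order the engulfment
#'     (`gamma_ym > gamma_gm`).}
#'   \item{invasion}{a small group of yellow cells abutting a green mass;
#'     heterotypic interfaces are energetically preferred
#'     (`gamma_gy < (gamma_gg + gamma_yy)/2`) with high green-green
#'     tension, so yellow cells are drawn in between the green ones.  The
#'     embargo timer is enabled: freshly created high-tension green-green
#'     edges would otherwise shorten and exchange straight back.}
#'   \item{checkerboard}{two mixed types with heterotypic tension far below
#'     both homotypic ones.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed for the tessellation and type assignment.
#' @param n_cells optional cell-count override.
#' @param tensions optional [tension_table()] override (still checked
#'   against the scenario inequality).
#' @param size_variation optional jitter override for the tessellation.
#' @param ... configuration overrides passed to [sim_config()].
#' @return an object of class `polycell_scenario`: list with `name`,
#'   `tissue`, `tensions`, `config`.
#' @export
build_scenario <- function(name = c("annealing", "cell_engulfment",
                                    "tissue_engulfment", "sorting",
                                    "invasion", "checkerboard"),
                           seed = 1L, n_cells = NULL, tensions = NULL,
                           size_variation = NULL, ...) {
  name <- match.arg(name)
  cfg_args <- list(...)
  defaults <- switch(name,
    annealing = list(n = 50L, sv = 0.5, embargo = 0L),
    cell_engulfment = list(n = 2L, sv = 0, embargo = 0L),
    tissue_engulfment = list(n = 30L, sv = 0.2, embargo = 20L),
    sorting = list(n = 200L, sv = 0.2, embargo = 0L),
    invasion = list(n = 46L, sv = 0.2, embargo = 20L),
    checkerboard = list(n = 60L, sv = 0.2, embargo = 20L))
  n <- if (is.null(n_cells)) defaults$n else as.integer(n_cells)
  sv <- if (is.null(size_variation)) defaults$sv else size_variation
  if (is.null(cfg_args$embargo_steps)) cfg_args$embargo_steps <- defaults$embargo
  if (is.null(cfg_args$seed)) cfg_args$seed <- seed
  config <- do.call(sim_config, cfg_args)

  if (name == "annealing") {
    ts <- voronoi_tissue(n, seed = seed, size_variation = sv, types = "cell")
    tt <- if (is.null(tensions))
      tension_table("cell|cell" = 1, "cell|medium" = 1) else tensions
    gs <- unclass(tt)
    require_inequality(length(unique(round(gs, 12L))) == 1L,
                       "annealing requires one uniform tension on all edges")
  } else if (name == "cell_engulfment") {
    ts <- voronoi_tissue(n, seed = seed, size_variation = sv,
                         types = c("yellow", "green"))
    tt <- if (is.null(tensions))
      tension_table("green|yellow" = 1, "green|medium" = 1,
                    "yellow|medium" = 3) else tensions
    require_inequality(
      get_tension(tt, "green", "medium") + get_tension(tt, "green", "yellow") <
        get_tension(tt, "yellow", "medium"),
      "gamma_gm + gamma_gy < gamma_ym")
  } else if (name == "tissue_engulfment") {
    ts <- voronoi_tissue(n, seed = seed, size_variation = sv)
    ts <- assign_types_by_x(ts, frac_left = 0.5, left = "yellow",
                            right = "green")
    tt <- if (is.null(tensions))
      tension_table("yellow|yellow" = 1, "green|green" = 1.6,
                    "green|yellow" = 0.8, "yellow|medium" = 3,
                    "green|medium" = 0.6) else tensions
    require_inequality(
      get_tension(tt, "green", "medium") + get_tension(tt, "green", "yellow") <
        get_tension(tt, "yellow", "medium"),
      "gamma_gm + gamma_gy < gamma_ym")
    require_inequality(
      get_tension(tt, "green", "green") > get_tension(tt, "green", "yellow"),
      "gamma_gg > gamma_gy (green cells must be extractable)")
  } else if (name == "sorting") {
    ts <- voronoi_tissue(n, seed = seed, size_variation = sv)
    ts <- assign_types_random(ts, c("yellow", "green"), seed + 1000L)
    tt <- if (is.null(tensions))
      tension_table("yellow|yellow" = 1, "green|green" = 1,
                    "green|yellow" = 1.6, "green|medium" = 1.2,
                    "yellow|medium" = 2.2) else tensions
    require_inequality(
      get_tension(tt, "green", "yellow") >
        (get_tension(tt, "green", "green") +
           get_tension(tt, "yellow", "yellow")) / 2,
      "gamma_gy > (gamma_gg + gamma_yy)/2 (sorting regime)")
  } else if (name == "invasion") {
    ts <- voronoi_tissue(n, seed = seed, size_variation = sv)
    ts <- assign_types_by_x(ts, n_left = max(2L, round(n * 0.13)),
                            left = "yellow", right = "green")
    tt <- if (is.null(tensions))
      tension_table("green|green" = 1.6, "yellow|yellow" = 0.8,
                    "green|yellow" = 0.7, "green|medium" = 1.2,
                    "yellow|medium" = 1.2) else tensions
    require_inequality(
      get_tension(tt, "green", "yellow") <
        (get_tension(tt, "green", "green") +
           get_tension(tt, "yellow", "yellow")) / 2,
      "gamma_gy < (gamma_gg + gamma_yy)/2 (heterotypic preferred)")
  } else { # checkerboard
    ts <- voronoi_tissue(n, seed = seed, size_variation = sv)
    ts <- assign_types_random(ts, c("yellow", "green"), seed + 1000L)
    tt <- if (is.null(tensions))
      tension_table("yellow|yellow" = 1, "green|green" = 1,
                    "green|yellow" = 0.2, "green|medium" = 1.5,
                    "yellow|medium" = 1.5) else tensions
    require_inequality(
      get_tension(tt, "green", "yellow") <
        get_tension(tt, "green", "green") &&
        get_tension(tt, "green", "yellow") <
          get_tension(tt, "yellow", "yellow"),
      "gamma_gy far below both homotypic tensions")
  }
  ts <- set_tensions(ts, tt)
  structure(list(name = name, tissue = ts, tensions = tt, config = config),
            class = "polycell_scenario")
}

#' Assign cell types by centroid abscissa
#' @keywords internal
assign_types_by_x <- function(ts, frac_left = NULL, n_left = NULL,
                              left = "yellow", right = "green") {
  ids <- active_cells(ts)
  cx <- vapply(ids, function(ci) polygon_centroid(cell_vertices(ts, ci))[1L],
               numeric(1L))
  if (is.null(n_left)) n_left <- round(length(ids) * frac_left)
  lefties <- ids[order(cx)][seq_len(n_left)]
  for (ci in ids)
    ts$cells[[ci]]$type <- if (ci %in% lefties) left else right
  ts
}

#' Randomly assign two cell types (about 50/50, seeded)
#' @keywords internal
assign_types_random <- function(ts, types, seed) {
  ids <- active_cells(ts)
  lab <- with_seed(seed, sample(rep_len(types, length(ids))))
  for (k in seq_along(ids)) ts$cells[[ids[k]]]$type <- lab[k]
  ts
}

#' @export
print.polycell_scenario <- function(x, ...) {
  cat("polycell scenario:", x$name, "\n")
  print(x$tissue)
  print(x$tensions)
  invisible(x)
}

#' Run matched monoline and polyline simulations of one scenario
#'
#' Both runs start from the identical initial mesh and seed and differ only
#' in the edge-representation mode, so every difference between the two
#' trajectories is attributable to the straight-edge constraint.
#'
#' @param scenario a [build_scenario()] result.
#' @return list with elements `monoline` and `polyline`, each a trajectory.
#' @export
run_pair <- function(scenario) {
  stopifnot(inherits(scenario, "polycell_scenario"))
  out <- lapply(c("monoline", "polyline"), function(md) {
    cfg <- scenario$config
    cfg$mode <- md
    tr <- run_simulation(scenario$tissue, cfg, scenario$tensions)
    tr$scenario <- scenario$name
    tr
  })
  stats::setNames(out, c("monoline", "polyline"))
}

#' Segment-length fraction that yields a target mean segments-per-edge
#'
#' The bisection refinement rule leaves segment lengths roughly uniform
#' between half the maximum and the maximum (mean about 0.72 of the
#' maximum), so an edge of length L carries about L / (0.72 * seg_max)
#' segments.  Inverting this for the tissue's current mean edge length
#' gives the `seg_max_frac` to request a desired average segment count.
#'
#' @param ts a tissue.
#' @param segments_per_edge desired mean number of segments per edge.
#' @return suggested `seg_max_frac` (fraction of the mean cell diameter).
#' @export
tune_segment_fraction <- function(ts, segments_per_edge) {
  stopifnot(segments_per_edge >= 1)
  D <- mean_cell_diameter(ts)
  lbar <- mean(vapply(active_edges(ts), function(ei) edge_length(ts, ei),
                      numeric(1L)))
  (lbar / D) / (0.72 * segments_per_edge)
}

#' Mean number of segments per edge of a tissue
#' @param ts a tissue.
#' @param cell_cell_only count only cell-cell edges.
#' @return mean segment count.
#' @export
mean_segments_per_edge <- function(ts, cell_cell_only = FALSE) {
  eids <- active_edges(ts)
  if (cell_cell_only)
    eids <- eids[vapply(ts$edges[eids], function(e)
      e$rl != MEDIUM && e$rr != MEDIUM, logical(1L))]
  mean(vapply(ts$edges[eids], function(e) length(e$chain) - 1L, numeric(1L)))
}
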