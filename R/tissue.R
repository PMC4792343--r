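# The mesh data model.
#
# A tissue is a planar aggregate of polygonal cells surrounded by medium.
# Nodes live in a growing position table and are never renumbered: slots of
# removed nodes are simply deactivated, so node identity is stable across
# topological events and trajectory analysis can track entities over time.
#
# Edges are polylines: an ordered chain of node ids whose first and last
# entries are junction nodes and whose interior entries are intermediate
# nodes.  Each edge stores the two regions it separates as the region on the
# LEFT and on the RIGHT of the chain direction (cell id, or 0 for the
# medium), plus the interfacial tension carried by all of its rod segments.
#
# Cells store an ordered, signed edge loop: +e means edge e is traversed in
# chain order (cell on the left), -e means it is traversed reversed.  The
# loop is oriented counter-clockwise.

MEDIUM <- 0L

#' Construct a tissue from node, edge and cell tables
#'
#' This is the low-level constructor; most users will start from
#' [voronoi_tissue()] or [build_scenario()].  Cell boundary loops are derived
#' from the edges' left/right region labels, so only node positions, edge
#' chains and cell attributes need to be supplied.
#'
#' @param pos numeric matrix with two columns, one row per node.  Lengths are
#'   dimensionless; by convention the mean cell diameter is near 1.
#' @param kind integer vector: 1 for junction nodes, 2 for intermediate nodes.
#' @param edges list of edges, each a list with elements `chain` (integer node
#'   ids), `rl` and `rr` (cell id to the left/right of the chain direction, 0
#'   for medium) and `tension` (gamma >= 0).
#' @param cells list of cells, each a list with `type` (character label),
#'   `target_area` (positive) and `mu` (cytoplasm viscosity, positive).
#' @param medium_label label used for the medium in tension tables and
#'   reports.
#' @return an object of class `polycell_tissue`.
#' @export
new_tissue <- function(pos, kind, edges, cells, medium_label = "medium") {
  stopifnot(is.matrix(pos), ncol(pos) == 2L, length(kind) == nrow(pos))
  dimnames(pos) <- NULL
  edges <- lapply(edges, function(e) {
    e$chain <- as.integer(e$chain)
    e$rl <- as.integer(e$rl); e$rr <- as.integer(e$rr)
    if (is.null(e$tension)) e$tension <- 0
    if (is.null(e$embargo)) e$embargo <- -1L
    if (is.null(e$connector)) e$connector <- FALSE
    e
  })
  cells <- lapply(cells, function(cl) {
    if (is.null(cl$mu)) cl$mu <- 1
    cl
  })
  ts <- structure(list(
    pos = pos, kind = as.integer(kind),
    edges = edges, cells = cells,
    medium_label = medium_label
  ), class = "polycell_tissue")
  ts <- rebuild_cell_loops(ts)
  for (ci in active_cells(ts)) {
    if (is.null(ts$cells[[ci]]$target_area) || is.na(ts$cells[[ci]]$target_area))
      ts$cells[[ci]]$target_area <- polygon_area(ts, ci)
  }
  ts
}

#' @keywords internal
active_edges <- function(ts) which(!vapply(ts$edges, is.null, logical(1L)))

#' @keywords internal
active_cells <- function(ts) which(!vapply(ts$cells, is.null, logical(1L)))

#' @keywords internal
active_nodes <- function(ts) which(!is.na(ts$kind))

#' Rebuild the boundary loop of one cell (or all cells) from edge topology
#'
#' Walks the cycle of edges bordering the cell, orienting each so the cell is
#' on its left; the resulting loop is counter-clockwise by construction.
#' @keywords internal
rebuild_cell_loops <- function(ts, which_cells = NULL) {
  if (is.null(which_cells)) which_cells <- active_cells(ts)
  eids <- active_edges(ts)
  rl <- vapply(ts$edges[eids], function(e) e$rl, integer(1L))
  rr <- vapply(ts$edges[eids], function(e) e$rr, integer(1L))
  for (ci in which_cells) {
    mine <- eids[rl == ci | rr == ci]
    if (length(mine) == 0L)
      stop("cell ", ci, " has no boundary edges")
    starts <- integer(length(mine)); ends <- integer(length(mine))
    sgn <- integer(length(mine))
    for (k in seq_along(mine)) {
      e <- ts$edges[[mine[k]]]
      if (e$rl == ci) {            # forward traversal
        starts[k] <- e$chain[1L]; ends[k] <- e$chain[length(e$chain)]
        sgn[k] <- 1L
      } else {
        starts[k] <- e$chain[length(e$chain)]; ends[k] <- e$chain[1L]
        sgn[k] <- -1L
      }
    }
    loop <- integer(length(mine))
    used <- logical(length(mine))
    cur <- 1L
    loop[1L] <- sgn[1L] * mine[1L]
    used[1L] <- TRUE
    for (k in seq_along(mine)[-1L]) {
      nxt <- which(!used & starts == ends[cur])
      if (length(nxt) == 0L)
        stop("boundary of cell ", ci, " does not close")
      nxt <- nxt[1L]
      loop[k] <- sgn[nxt] * mine[nxt]
      used[nxt] <- TRUE
      cur <- nxt
    }
    if (starts[abs(loop[1L]) == mine][1L] != ends[cur])
      stop("boundary of cell ", ci, " does not close")
    ts$cells[[ci]]$loop <- loop
  }
  ts
}

#' Ordered boundary node ids of a cell (CCW, first node not repeated)
#' @keywords internal
cell_loop_nodes <- function(ts, ci) {
  loop <- ts$cells[[ci]]$loop
  unlist(lapply(loop, function(se) {
    ch <- ts$edges[[abs(se)]]$chain
    n <- length(ch)
    if (se < 0L) ch[n:2L] else ch[-n]
  }), use.names = FALSE)
}

#' Cell boundary vertex coordinates (CCW)
#' @param ts a tissue. @param ci cell id.
#' @return two-column matrix of boundary vertices.
#' @export
cell_vertices <- function(ts, ci) ts$pos[cell_loop_nodes(ts, ci), , drop = FALSE]

#' Signed area of a cell polygon
#'
#' Shoelace area of the node chain around the cell; positive for the
#' counter-clockwise orientation all valid cells carry.
#'
#' @param ts a tissue.
#' @param ci cell id.
#' @return signed area.
#' @export
polygon_area <- function(ts, ci) {
  if (is.null(ts$cells[[ci]])) stop("cell ", ci, " is not active")
  shoelace_area(cell_vertices(ts, ci))
}

#' Mean cell diameter of a tissue
#'
#' The diameter of the circle with the same area as each cell, averaged over
#' cells: mean of 2*sqrt(A/pi).  Topological thresholds (T1 length delta,
#' segment length bounds) are expressed as fractions of this quantity.
#'
#' @param ts a tissue.
#' @return mean equal-area-circle diameter.
#' @export
mean_cell_diameter <- function(ts) {
  cs <- active_cells(ts)
  if (length(cs) == 0L) stop("tissue has no cells")
  mean(vapply(cs, function(ci) 2 * sqrt(abs(polygon_area(ts, ci)) / pi),
              numeric(1L)))
}

#' Interface class of an edge: sorted pair of region type labels
#' @keywords internal
interface_class <- function(ts, ei) {
  e <- ts$edges[[ei]]
  lab <- function(r) if (r == MEDIUM) ts$medium_label else ts$cells[[r]]$type
  sort(c(lab(e$rl), lab(e$rr)))
}

#' Endpoint (junction) incidence table: one row per edge endpoint
#' @return data.frame with columns edge, node.
#' @keywords internal
junction_incidence <- function(ts) {
  eids <- active_edges(ts)
  n1 <- vapply(ts$edges[eids], function(e) e$chain[1L], integer(1L))
  n2 <- vapply(ts$edges[eids], function(e) e$chain[length(e$chain)], integer(1L))
  data.frame(edge = c(eids, eids), node = c(n1, n2))
}

#' Edges incident to a junction node
#' @keywords internal
node_edges <- function(ts, nid) {
  eids <- active_edges(ts)
  eids[vapply(ts$edges[eids], function(e)
    e$chain[1L] == nid || e$chain[length(e$chain)] == nid, logical(1L))]
}

#' Length of an edge's polyline
#' @keywords internal
edge_length <- function(ts, ei)
  chain_length(ts$pos[ts$edges[[ei]]$chain, , drop = FALSE])

#' Append a node, returning the updated tissue and the fresh id
#' @keywords internal
add_node <- function(ts, p, kind) {
  ts$pos <- rbind(ts$pos, unname(p), deparse.level = 0L)
  ts$kind <- c(ts$kind, as.integer(kind))
  list(ts = ts, id = nrow(ts$pos))
}

#' Append an edge, returning the updated tissue and the fresh id
#' @keywords internal
add_edge <- function(ts, chain, rl, rr, tension, embargo = -1L,
                     connector = FALSE) {
  ts$edges[[length(ts$edges) + 1L]] <-
    list(chain = as.integer(chain), rl = as.integer(rl), rr = as.integer(rr),
         tension = tension, embargo = as.integer(embargo),
         connector = connector)
  list(ts = ts, id = length(ts$edges))
}

#' Validate the topological invariants of a tissue
#'
#' Checks that intermediate nodes have exactly two incident segments of one
#' edge, that junction nodes join at least two edges, that every edge
#' separates two distinct regions and has a strictly positive chain, that
#' cell loops close with positive (CCW) area, that no junction exceeds
#' valence 3, and that the mesh is edge-connected.
#'
#' @param ts a tissue.
#' @return a data.frame of violations with columns `entity`, `id`, `rule`;
#'   zero rows when the tissue is valid.
#' @export
validate_topology <- function(ts) {
  bad <- list()
  note <- function(entity, id, rule)
    bad[[length(bad) + 1L]] <<- data.frame(entity = entity, id = id, rule = rule)

  eids <- active_edges(ts)
  # per-node incidence counting chain interior occurrences
  n_nodes <- nrow(ts$pos)
  inc_seg <- integer(n_nodes)       # incident segments
  inc_edge_end <- integer(n_nodes)  # incidences as an edge endpoint
  interior_of <- integer(n_nodes)   # edges owning a node as interior
  for (ei in eids) {
    ch <- ts$edges[[ei]]$chain
    if (anyNA(ts$kind[ch])) note("edge", ei, "chain references inactive node")
    if (any(ch[-1L] == ch[-length(ch)]))
      note("edge", ei, "consecutive chain nodes repeat")
    segl <- chain_seg_lengths(ts$pos[ch, , drop = FALSE])
    if (any(segl <= 0)) note("edge", ei, "non-positive segment length")
    inc_seg[ch[1L]] <- inc_seg[ch[1L]] + 1L
    inc_seg[ch[length(ch)]] <- inc_seg[ch[length(ch)]] + 1L
    if (length(ch) > 2L) {
      mid <- ch[-c(1L, length(ch))]
      inc_seg[mid] <- inc_seg[mid] + 2L
      interior_of[mid] <- interior_of[mid] + 1L
    }
    inc_edge_end[ch[1L]] <- inc_edge_end[ch[1L]] + 1L
    inc_edge_end[ch[length(ch)]] <- inc_edge_end[ch[length(ch)]] + 1L
    e <- ts$edges[[ei]]
    if (e$rl == e$rr) note("edge", ei, "same region on both sides")
    for (r in c(e$rl, e$rr))
      if (r != MEDIUM && is.null(ts$cells[[r]]))
        note("edge", ei, "references inactive cell")
  }
  for (nid in active_nodes(ts)) {
    if (ts$kind[nid] == 2L) {
      if (inc_seg[nid] != 2L || interior_of[nid] != 1L || inc_edge_end[nid] != 0L)
        note("node", nid, "intermediate node must have exactly 2 incident segments of one edge")
    } else {
      if (inc_edge_end[nid] < 2L)
        note("node", nid, "junction node must join at least 2 edges")
      if (inc_edge_end[nid] > 3L)
        note("node", nid, "junction valence exceeds 3 (quad/rosette not normalized)")
      if (interior_of[nid] > 0L)
        note("node", nid, "junction node appears inside an edge chain")
    }
  }
  for (ci in active_cells(ts)) {
    ok <- tryCatch({
      a <- polygon_area(ts, ci)
      if (a <= 0) note("cell", ci, "non-positive or clockwise area")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) note("cell", ci, "boundary loop does not close")
  }
  # connectivity across shared junctions
  if (length(eids) > 1L) {
    inc <- junction_incidence(ts)
    comp <- stats::setNames(seq_along(eids), eids)
    repeat {
      changed <- FALSE
      for (nid in unique(inc$node)) {
        es <- as.character(inc$edge[inc$node == nid])
        m <- min(comp[es])
        if (any(comp[es] != m)) { comp[es] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    if (length(unique(comp)) > 1L)
      note("tissue", NA_integer_, "mesh is not connected")
  }
  if (length(bad) == 0L)
    data.frame(entity = character(0L), id = integer(0L), rule = character(0L))
  else do.call(rbind, bad)
}

#' @export
print.polycell_tissue <- function(x, ...) {
  nc <- length(active_cells(x)); ne <- length(active_edges(x))
  nn <- active_nodes(x)
  nj <- sum(x$kind[nn] == 1L); ni <- sum(x$kind[nn] == 2L)
  cat("polycell tissue:", nc, "cells,", ne, "edges,",
      nj, "junction +", ni, "intermediate nodes\n")
  cat("  cell types:", paste(sort(unique(vapply(active_cells(x),
      function(ci) x$cells[[ci]]$type, character(1L)))), collapse = ", "),
      "| medium:", x$medium_label, "\n")
  cat("  mean cell diameter:", signif(mean_cell_diameter(x), 4L), "\n")
  invisible(x)
}

#' Node table of a tissue
#' @param ts a tissue.
#' @return data.frame with columns id, x, y, kind ("junction"/"intermediate").
#' @export
tissue_nodes <- function(ts) {
  ids <- active_nodes(ts)
  data.frame(id = ids, x = ts$pos[ids, 1L], y = ts$pos[ids, 2L],
             kind = c("junction", "intermediate")[ts$kind[ids]])
}

#' Edge table of a tissue
#' @param ts a tissue.
#' @return data.frame with columns id, left, right (region ids, 0 = medium),
#'   class (interface label pair), tension, length, n_segments, embargo.
#' @export
tissue_edges <- function(ts) {
  ids <- active_edges(ts)
  data.frame(
    id = ids,
    left = vapply(ts$edges[ids], function(e) e$rl, integer(1L)),
    right = vapply(ts$edges[ids], function(e) e$rr, integer(1L)),
    class = vapply(ids, function(ei) paste(interface_class(ts, ei),
                                           collapse = "|"), character(1L)),
    tension = vapply(ts$edges[ids], function(e) e$tension, numeric(1L)),
    length = vapply(ids, function(ei) edge_length(ts, ei), numeric(1L)),
    n_segments = vapply(ts$edges[ids], function(e) length(e$chain) - 1L,
                        integer(1L)),
    embargo = vapply(ts$edges[ids], function(e) e$embargo, integer(1L))
  )
}

#' Cell table of a tissue
#' @param ts a tissue.
#' @return data.frame with columns id, type, area, target_area, mu,
#'   n_boundary_edges.
#' @export
tissue_cells <- function(ts) {
  ids <- active_cells(ts)
  data.frame(
    id = ids,
    type = vapply(ts$cells[ids], function(cl) cl$type, character(1L)),
    area = vapply(ids, function(ci) polygon_area(ts, ci), numeric(1L)),
    target_area = vapply(ts$cells[ids], function(cl) cl$target_area, numeric(1L)),
    mu = vapply(ts$cells[ids], function(cl) cl$mu, numeric(1L)),
    n_boundary_edges = vapply(ts$cells[ids], function(cl) length(cl$loop),
                              integer(1L))
  )
}
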