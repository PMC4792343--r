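# Discrete mesh events: T1 neighbour exchanges, polyline segment refinement
# and coarsening, and normalization of quad junctions / rosettes into chains
# of closely spaced triple junctions.
#
# Event ordering within a time step (run_simulation): coarsen -> T1 ->
# refine -> viscous solve.  T1 is defined on intermediate-free short edges,
# so coarsening runs first; refining last hands the solver a compliant mesh.

empty_events <- function() {
  data.frame(step = integer(0L), kind = character(0L),
             entities = character(0L), pre_length = numeric(0L),
             post_length = numeric(0L))
}

# rbind a list of event rows, or return NULL when there are none (the run
# loop treats NULL as "no events" to avoid per-step data.frame overhead)
bind_events <- function(events)
  if (length(events)) do.call(rbind, events) else NULL

event_row <- function(step, kind, entities, pre_length = NA_real_,
                      post_length = NA_real_) {
  data.frame(step = step, kind = kind,
             entities = paste(entities, collapse = ","),
             pre_length = pre_length, post_length = post_length)
}

#' Effective maximum segment length for one edge
#'
#' In polyline mode every edge is subject to the configured maximum.  In
#' monoline mode cell-cell edges are kept as single straight rods (their
#' maximum is infinite) while cell-medium edges may still carry intermediate
#' nodes, so the aggregate surface can curve in both modes.
#' @keywords internal
edge_seg_max <- function(ts, ei, config, D) {
  e <- ts$edges[[ei]]
  if (config$mode == "monoline" && e$rl != MEDIUM && e$rr != MEDIUM) return(Inf)
  config$seg_max_frac * D
}

#' Refine and coarsen polyline segments
#'
#' Any segment longer than its edge's maximum is bisected with a new
#' intermediate node at its midpoint, repeatedly until compliant.  Any
#' segment shorter than `seg_min_frac * D` is collapsed: two intermediate
#' ends merge into a single fresh intermediate node at the segment midpoint;
#' an intermediate end merges into its junction neighbour (the junction
#' keeps its position); a short junction-junction edge is left to the T1
#' machinery.
#'
#' @param ts a tissue.
#' @param config a [sim_config()].
#' @param step integer step index used for event logging.
#' @param refine,coarsen logical switches so the run loop can order the two
#'   phases around the T1 scan.
#' @return list with elements `tissue` and `events`.
#' @export
refine_and_coarsen <- function(ts, config, step = 0L,
                               refine = TRUE, coarsen = TRUE, D = NULL) {
  if (is.null(D)) D <- mean_cell_diameter(ts)
  seg_min <- config$seg_min_frac * D
  events <- list()
  # fast screen over the pooled segment list: only edges with an
  # out-of-range segment (or a connector flag to refresh) need any work
  s <- collect_segments(ts)
  eids <- unique(s$edge)
  seglen <- sqrt((ts$pos[s$j, 1L] - ts$pos[s$i, 1L])^2 +
                 (ts$pos[s$j, 2L] - ts$pos[s$i, 2L])^2)
  gid <- match(s$edge, eids)
  nseg <- tabulate(gid, length(eids))
  eds <- ts$edges[eids]
  smax_e <- if (config$mode == "monoline") {
    internal <- vapply(eds, function(e) e$rl != MEDIUM && e$rr != MEDIUM,
                       logical(1L))
    ifelse(internal, Inf, config$seg_max_frac * D)
  } else rep(config$seg_max_frac * D, length(eids))
  too_short <- as.logical(rowsum((seglen < seg_min) * 1L, gid)) & nseg > 1L
  too_long <- as.logical(rowsum((seglen > smax_e[gid]) * 1L, gid))
  conn <- vapply(eds, function(e) isTRUE(e$connector), logical(1L))
  need <- (coarsen & too_short) | (refine & too_long) | conn
  for (ei in eids[need]) {
    ch <- ts$edges[[ei]]$chain
    if (coarsen) {
      repeat {
        if (length(ch) < 3L) break
        lens <- chain_seg_lengths(ts$pos[ch, , drop = FALSE])
        k <- which(lens < seg_min)
        if (length(k) == 0L) break
        k <- k[1L]
        a <- ch[k]; b <- ch[k + 1L]
        ka <- ts$kind[a]; kb <- ts$kind[b]
        if (ka == 2L && kb == 2L) {
          mid <- (ts$pos[a, ] + ts$pos[b, ]) / 2
          res <- add_node(ts, mid, 2L)
          ts <- res$ts
          ts$kind[c(a, b)] <- NA_integer_
          ch <- c(ch[seq_len(k - 1L)], res$id, ch[seq(k + 2L, length(ch))])
          events[[length(events) + 1L]] <-
            event_row(step, "merge", c(ei, a, b, res$id), lens[k])
        } else if (ka == 2L || kb == 2L) {
          drop <- if (ka == 2L) k else k + 1L
          ts$kind[ch[drop]] <- NA_integer_
          events[[length(events) + 1L]] <-
            event_row(step, "merge", c(ei, ch[drop]), lens[k])
          ch <- ch[-drop]
        } else {
          break  # junction-junction: neighbour-change criterion governs
        }
      }
    }
    if (refine) {
      smax <- edge_seg_max(ts, ei, config, D)
      if (is.finite(smax)) {
        repeat {
          lens <- chain_seg_lengths(ts$pos[ch, , drop = FALSE])
          k <- which(lens > smax)
          if (length(k) == 0L) break
          newch <- integer(0L)
          for (s in seq_along(lens)) {
            newch <- c(newch, ch[s])
            if (lens[s] > smax) {
              mid <- (ts$pos[ch[s], ] + ts$pos[ch[s + 1L], ]) / 2
              res <- add_node(ts, mid, 2L)
              ts <- res$ts
              newch <- c(newch, res$id)
              events[[length(events) + 1L]] <-
                event_row(step, "split", c(ei, ch[s], ch[s + 1L], res$id),
                          lens[s], lens[s] / 2)
            }
          }
          ch <- c(newch, ch[length(ch)])
        }
      }
    }
    ts$edges[[ei]]$chain <- ch
    # a fresh connector that has grown past the post-T1 length becomes a
    # regular edge again (eligible for future exchanges)
    if (isTRUE(ts$edges[[ei]]$connector) &&
        edge_length(ts, ei) > config$post_t1_length_frac * D)
      ts$edges[[ei]]$connector <- FALSE
  }
  list(tissue = ts, events = bind_events(events))
}

#' Regions of an edge as a length-2 integer vector
#' @keywords internal
edge_regions <- function(ts, ei) c(ts$edges[[ei]]$rl, ts$edges[[ei]]$rr)

#' The region flanking junction `nid` of edge `ei`, i.e. the region shared by
#' the two other edges meeting there.  Returns NA when ill-defined.
#' @keywords internal
flanking_region <- function(ts, nid, ei) {
  others <- setdiff(node_edges(ts, nid), ei)
  if (length(others) != 2L) return(NA_integer_)
  ab <- edge_regions(ts, ei)
  shared <- intersect(edge_regions(ts, others[1L]), edge_regions(ts, others[2L]))
  shared <- setdiff(shared, ab)
  if (length(shared) != 1L) return(NA_integer_)
  shared
}

#' Apply T1 neighbour exchanges to all qualifying short edges
#'
#' Every junction-junction edge shorter than `t1_threshold_frac * D` with no
#' active embargo is replaced: the two regions that flanked its endpoints
#' become neighbours across a new edge of length `post_t1_length_frac * D`,
#' perpendicular to the eliminated edge and centred on its midpoint.  The
#' new edge's tension is looked up from the tension table by its new
#' interface class and it receives an embargo of `embargo_steps` steps so a
#' freshly created high-tension edge cannot immediately exchange back.
#' Edges bordering the medium are exchanged by the same rewiring whenever
#' the two flanking regions differ (equivalent to merging the junctions and
#' splitting the resulting quad junction across the flanking diagonal);
#' when both flanking regions are the same cell -- the engulfment pinch-off
#' configuration -- the event is skipped and logged.
#'
#' Candidates are processed shortest first; a candidate whose local
#' neighbourhood was already modified this step is deferred to the next
#' step.  Exchanges that would leave a cell with fewer than three boundary
#' edges are skipped and logged.
#'
#' @param ts a tissue.
#' @param config a [sim_config()].
#' @param step integer step index (embargo bookkeeping and event log).
#' @param tensions a [tension_table()] used to look up new-edge tensions.
#' @return list with elements `tissue` and `events`.
#' @export
apply_t1_exchanges <- function(ts, config, step = 0L, tensions = NULL,
                               D = NULL) {
  if (is.null(D)) D <- mean_cell_diameter(ts)
  delta <- config$t1_threshold_frac * D
  events <- list()
  eids <- active_edges(ts)
  jj <- eids[vapply(ts$edges[eids], function(e) length(e$chain) == 2L,
                    logical(1L))]
  if (length(jj) == 0L)
    return(list(tissue = ts, events = NULL))
  n1v <- vapply(ts$edges[jj], function(e) e$chain[1L], integer(1L))
  n2v <- vapply(ts$edges[jj], function(e) e$chain[2L], integer(1L))
  lens <- sqrt((ts$pos[n2v, 1L] - ts$pos[n1v, 1L])^2 +
               (ts$pos[n2v, 2L] - ts$pos[n1v, 2L])^2)
  if (all(lens >= delta))
    return(list(tissue = ts, events = NULL))
  ord <- order(lens)
  touched <- integer(0L)
  for (k in ord) {
    ei <- jj[k]
    if (lens[k] >= delta) next
    e <- ts$edges[[ei]]
    if (is.null(e)) next
    if (isTRUE(e$connector)) next
    if (e$embargo >= 0L && step < e$embargo) next
    n1 <- e$chain[1L]; n2 <- e$chain[2L]
    if (n1 %in% touched || n2 %in% touched) next
    a <- e$rl; b <- e$rr
    cc <- flanking_region(ts, n1, ei)
    dd <- flanking_region(ts, n2, ei)
    skip <- function(why) {
      events[[length(events) + 1L]] <<-
        event_row(step, "t1_skipped", c(ei, why), lens[k])
    }
    if (is.na(cc) || is.na(dd)) { skip("irregular junction"); next }
    if (cc == dd) { skip("flanking regions identical"); next }
    if (cc == MEDIUM && dd == MEDIUM) { skip("medium on both flanks"); next }
    too_small <- FALSE
    for (r in c(a, b)) if (r != MEDIUM && length(ts$cells[[r]]$loop) < 4L)
      too_small <- TRUE
    if (too_small) { skip("would create two-edged cell"); next }

    p1 <- ts$pos[n1, ]; p2 <- ts$pos[n2, ]
    mid <- (p1 + p2) / 2
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    perp <- c(-u[2L], u[1L])          # left normal: points into region a
    lnew <- config$post_t1_length_frac * D
    res <- add_node(ts, mid + perp * lnew / 2, 1L); ts <- res$ts; ma <- res$id
    res <- add_node(ts, mid - perp * lnew / 2, 1L); ts <- res$ts; mb <- res$id

    rewired <- setdiff(c(node_edges(ts, n1), node_edges(ts, n2)), ei)
    old <- ts
    ok <- tryCatch({
      for (oi in rewired) {
        oe <- ts$edges[[oi]]
        tgt <- if (a %in% c(oe$rl, oe$rr)) ma else mb
        if (oe$chain[1L] %in% c(n1, n2)) oe$chain[1L] <- tgt
        if (oe$chain[length(oe$chain)] %in% c(n1, n2))
          oe$chain[length(oe$chain)] <- tgt
        ts$edges[[oi]] <- oe
      }
      ts$edges[ei] <- list(NULL)   # deactivate; keep list indices stable
      ts$kind[c(n1, n2)] <- NA_integer_
      gam <- if (is.null(tensions)) e$tension
             else get_tension(tensions, region_label(ts, cc), region_label(ts, dd))
      res <- add_edge(ts, c(ma, mb), rl = dd, rr = cc, tension = gam,
                      embargo = step + config$embargo_steps)
      ts <- res$ts
      ts <- rebuild_cell_loops(ts, setdiff(unique(c(a, b, cc, dd)), MEDIUM))
      TRUE
    }, error = function(err) FALSE)
    if (!ok) {
      ts <- old
      ts$kind[c(ma, mb)] <- NA_integer_
      skip("would disconnect mesh")
      next
    }
    touched <- c(touched, n1, n2, ma, mb,
                 unlist(lapply(ts$edges[rewired], `[[`, "chain")))
    events[[length(events) + 1L]] <-
      event_row(step, "t1", c(ei, a, b, "->", cc, dd), lens[k], lnew)
  }
  list(tissue = ts, events = bind_events(events))
}

#' Type label of a region id (cell type, or the medium label)
#' @keywords internal
region_label <- function(ts, r) {
  if (r == MEDIUM) ts$medium_label else ts$cells[[r]]$type
}

#' Incident edges of a node with their away-from-node geometry
#' @return data.frame: edge, angle, left_away, right_away (regions seen when
#'   travelling away from the node), ordered counter-clockwise.
#' @keywords internal
node_fan <- function(ts, nid) {
  es <- node_edges(ts, nid)
  rows <- lapply(es, function(ei) {
    e <- ts$edges[[ei]]
    if (e$chain[1L] == nid) {
      second <- e$chain[2L]; la <- e$rl; ra <- e$rr
    } else {
      second <- e$chain[length(e$chain) - 1L]; la <- e$rr; ra <- e$rl
    }
    v <- ts$pos[second, ] - ts$pos[nid, ]
    data.frame(edge = ei, angle = vec_angle(v), left_away = la,
               right_away = ra)
  })
  fan <- do.call(rbind, rows)
  fan[order(fan$angle), , drop = FALSE]
}

#' Split a quad junction or rosette into closely spaced triple junctions
#'
#' A node with four or more incident edges is replaced by a chain of
#' 3-valent nodes joined by short connector edges of length `epsilon`,
#' preserving the cyclic order of the incident edges.  Each connector lies
#' on the interface separating the two regions left exposed by the pair of
#' edges split off, and takes that interface's tension (from `tensions` when
#' given, otherwise from an existing edge of the same class or the local
#' mean).  Called on a node of valence three or less this is a no-op.
#'
#' @param ts a tissue.
#' @param node_id node to split.
#' @param epsilon connector edge length; defaults to
#'   `seg_min_frac * mean_cell_diameter(ts)` with `seg_min_frac = 0.025`.
#' @param tensions optional [tension_table()].
#' @return updated tissue.
#' @export
split_higher_order_junction <- function(ts, node_id, epsilon = NULL,
                                        tensions = NULL) {
  if (is.null(epsilon)) epsilon <- 0.025 * mean_cell_diameter(ts)
  repeat {
    fan <- node_fan(ts, node_id)
    v <- nrow(fan)
    if (v <= 3L) return(ts)
    # pick the first cyclically adjacent pair whose exposed flank regions
    # differ (those become the connector's two sides)
    pick <- NULL
    for (i in seq_len(v)) {
      j <- if (i == v) 1L else i + 1L
      rA <- fan$left_away[j]    # wedge beyond the pair
      rB <- fan$right_away[i]   # wedge before the pair
      if (rA != rB) { pick <- c(i, j, rA, rB); break }
    }
    if (is.null(pick)) {
      warning("cannot split junction ", node_id,
              ": all flank pairs identical")
      return(ts)
    }
    i <- pick[1L]; j <- pick[2L]; rA <- pick[3L]; rB <- pick[4L]
    e1 <- fan$edge[i]; e2 <- fan$edge[j]
    a1 <- fan$angle[i]; a2 <- fan$angle[j]
    if (a2 < a1) a2 <- a2 + 2 * pi
    bis <- (a1 + a2) / 2
    newp <- ts$pos[node_id, ] + epsilon * c(cos(bis), sin(bis))
    res <- add_node(ts, newp, 1L); ts <- res$ts; m1 <- res$id
    for (ei in c(e1, e2)) {
      oe <- ts$edges[[ei]]
      if (oe$chain[1L] == node_id) oe$chain[1L] <- m1
      if (oe$chain[length(oe$chain)] == node_id)
        oe$chain[length(oe$chain)] <- m1
      ts$edges[[ei]] <- oe
    }
    gam <- connector_tension(ts, rA, rB, c(fan$edge), tensions)
    # travelling m1 -> node_id the region before the pair (rB) lies left
    res <- add_edge(ts, c(m1, node_id), rl = rB, rr = rA, tension = gam,
                    connector = TRUE)
    ts <- res$ts
    affected <- setdiff(unique(c(fan$left_away, fan$right_away)), MEDIUM)
    ts <- rebuild_cell_loops(ts, affected)
  }
}

#' @keywords internal
connector_tension <- function(ts, rA, rB, local_edges, tensions) {
  if (!is.null(tensions))
    return(get_tension(tensions, region_label(ts, rA), region_label(ts, rB)))
  want <- sort(c(rA, rB))
  for (ei in active_edges(ts)) {
    e <- ts$edges[[ei]]
    if (identical(sort(c(e$rl, e$rr)), want)) return(e$tension)
  }
  mean(vapply(local_edges, function(ei) ts$edges[[ei]]$tension, numeric(1L)))
}

#' Numerical guard at the engulfment pinch-off singularity
#'
#' A junction-junction edge that qualifies for elimination but cannot be
#' exchanged (e.g. both flanking regions are the same cell) keeps shrinking
#' without an equilibrium; to keep segment lengths strictly positive -- and
#' the adaptive time step from collapsing with them -- its two junctions are
#' pushed back apart to a floor of half the T1 threshold about the edge
#' midpoint.  Silent numerical maintenance, not a topological event.
#' @keywords internal
apply_pinch_guard <- function(ts, config, step, D = NULL) {
  if (is.null(D)) D <- mean_cell_diameter(ts)
  floor_len <- 0.5 * config$t1_threshold_frac * D
  for (ei in active_edges(ts)) {
    e <- ts$edges[[ei]]
    if (length(e$chain) != 2L) next
    p1 <- ts$pos[e$chain[1L], ]; p2 <- ts$pos[e$chain[2L], ]
    len <- sqrt(sum((p2 - p1)^2))
    if (len >= floor_len) next
    mid <- (p1 + p2) / 2
    u <- if (len > 1e-300) (p2 - p1) / len else c(1, 0)
    ts$pos[e$chain[1L], ] <- mid - u * floor_len / 2
    ts$pos[e$chain[2L], ] <- mid + u * floor_len / 2
  }
  list(tissue = ts, events = NULL)
}
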