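# Seeded Voronoi tessellation initial conditions.
#
# Generator points are sampled in a disc, optionally Lloyd-relaxed toward
# uniformity and then jittered to create intentional cell-size variation
# (so pressure differences exist between neighbours).  Cell polygons are
# computed by half-plane intersection -- each cell is the clip of the
# aggregate hull by the perpendicular bisectors against all other points --
# which is O(n^2) overall and entirely adequate for the few hundred cells
# these models use.  The shared-vertex mesh is then assembled by snapping
# coincident polygon vertices, classifying junction versus path vertices,
# and walking maximal constant-interface paths into polyline edges.

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Voronoi / Laguerre cell polygons by half-plane intersection
#'
#' Unweighted generators give the ordinary Voronoi diagram; per-generator
#' weights give the Laguerre (power) diagram, whose dividing lines are the
#' radical axes -- still straight, so the same convex clipping applies with
#' a weight-shifted offset.
#' @param pts n x 2 generator points. @param hull CCW convex clip polygon.
#' @param w optional power-diagram weights (length n).
#' @return list of CCW polygon matrices (possibly empty for dominated
#'   weighted generators).
#' @keywords internal
voronoi_polygons <- function(pts, hull, w = NULL) {
  n <- nrow(pts)
  wmax <- if (is.null(w)) 0 else max(abs(w))
  lapply(seq_len(n), function(i) {
    pi_ <- pts[i, ]
    d2 <- (pts[, 1L] - pi_[1L])^2 + (pts[, 2L] - pi_[2L])^2
    ord <- order(d2)
    poly <- hull
    for (j in ord) {
      if (j == i) next
      if (nrow(poly) == 0L) break
      # early exit: no further dividing line can cut the current polygon
      rmax2 <- max((poly[, 1L] - pi_[1L])^2 + (poly[, 2L] - pi_[2L])^2)
      if (d2[j] > 4 * rmax2 + 4 * wmax) break
      a <- pts[j, ] - pi_
      b <- sum(a * (pts[j, ] + pi_)) / 2
      if (!is.null(w)) b <- b + (w[i] - w[j]) / 2
      poly <- clip_halfplane(poly, a, b)
    }
    poly
  })
}

#' Snap near-coincident vertices to shared ids
#' @param coords m x 2 matrix of raw vertices.
#' @return list(ids = integer vector mapping rows to vertex ids,
#'   pos = k x 2 matrix of unique positions).
#' @keywords internal
snap_vertices <- function(coords, tol = 1e-6) {
  gx <- round(coords[, 1L] / tol); gy <- round(coords[, 2L] / tol)
  ids <- integer(nrow(coords))
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  pos <- matrix(0, 0L, 2L)
  for (r in seq_len(nrow(coords))) {
    found <- 0L
    for (dx in -1L:1L) {
      for (dy in -1L:1L) {
        key <- paste(gx[r] + dx, gy[r] + dy)
        hit <- lookup[[key]]
        if (!is.null(hit) &&
            sum((pos[hit, ] - coords[r, ])^2) < (2 * tol)^2) {
          found <- hit; break
        }
      }
      if (found > 0L) break
    }
    if (found == 0L) {
      pos <- rbind(pos, coords[r, ])
      found <- nrow(pos)
      lookup[[paste(gx[r], gy[r])]] <- found
    }
    ids[r] <- found
  }
  list(ids = ids, pos = pos)
}

#' Assemble a tissue from a list of cell polygons
#'
#' @param polys list of CCW polygons (one per cell).
#' @param types character vector of cell type labels (recycled).
#' @param mu cytoplasm viscosity (recycled).
#' @param medium_label medium label.
#' @return a `polycell_tissue`.
#' @keywords internal
tissue_from_polygons <- function(polys, types = "cell", mu = 1,
                                 medium_label = "medium", snap_tol = 1e-6) {
  ncell <- length(polys)
  types <- rep_len(types, ncell)
  mu <- rep_len(mu, ncell)
  raw <- do.call(rbind, polys)
  sv <- snap_vertices(raw, snap_tol)
  offs <- c(0L, cumsum(vapply(polys, nrow, integer(1L))))
  cell_vids <- lapply(seq_len(ncell), function(i) {
    v <- sv$ids[(offs[i] + 1L):offs[i + 1L]]
    v <- v[c(TRUE, v[-1L] != v[-length(v)])]          # drop snapped repeats
    if (length(v) > 1L && v[1L] == v[length(v)]) v <- v[-length(v)]
    v
  })
  # undirected segment table with left/right cell (0 = medium)
  seg_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(ncell)) {
    v <- cell_vids[[i]]
    m <- length(v)
    for (k in seq_len(m)) {
      u <- v[k]; w <- v[if (k == m) 1L else k + 1L]
      key <- if (u < w) paste(u, w) else paste(w, u)
      rec <- seg_env[[key]]
      if (is.null(rec)) rec <- c(0L, 0L)   # left (u<w dir), right
      if (u < w) rec[1L] <- i else rec[2L] <- i
      seg_env[[key]] <- rec
    }
  }
  keys <- ls(seg_env)
  segs <- do.call(rbind, lapply(keys, function(k) {
    uv <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
    rec <- seg_env[[k]]
    c(uv, rec)
  }))
  colnames(segs) <- c("u", "v", "left", "right")
  nvert <- nrow(sv$pos)
  valence <- tabulate(c(segs[, "u"], segs[, "v"]), nvert)
  is_junction <- valence >= 3L
  # a cell none of whose vertices is a junction (an isolated cell bordered
  # entirely by medium) gets three of its vertices promoted so its boundary
  # can be expressed as junction-terminated edges
  for (i in seq_len(ncell)) {
    v <- cell_vids[[i]]
    if (!any(is_junction[v]) && length(v) >= 3L) {
      pick <- v[unique(round(seq(1L, length(v), length.out = 4L))[1:3])]
      is_junction[pick] <- TRUE
    }
  }
  # walk maximal paths between junctions through valence-2 vertices
  adj <- vector("list", nvert)
  for (s in seq_len(nrow(segs))) {
    adj[[segs[s, "u"]]] <- c(adj[[segs[s, "u"]]], s)
    adj[[segs[s, "v"]]] <- c(adj[[segs[s, "v"]]], s)
  }
  used <- logical(nrow(segs))
  edges <- list()
  for (s in seq_len(nrow(segs))) {
    if (used[s]) next
    ends <- segs[s, c("u", "v")]
    if (!is_junction[ends[1L]] && !is_junction[ends[2L]]) next
    start <- ends[if (is_junction[ends[1L]]) 1L else 2L]
    chain <- start
    cur_seg <- s
    cur <- start
    rl <- NA_integer_; rr <- NA_integer_
    repeat {
      used[cur_seg] <- TRUE
      u <- segs[cur_seg, "u"]; v <- segs[cur_seg, "v"]
      nxt <- if (cur == u) v else u
      if (cur == u) { l <- segs[cur_seg, "left"]; r <- segs[cur_seg, "right"] }
      else { l <- segs[cur_seg, "right"]; r <- segs[cur_seg, "left"] }
      if (is.na(rl)) { rl <- l; rr <- r }
      chain <- c(chain, nxt)
      if (is_junction[nxt]) break
      cand <- setdiff(adj[[nxt]], cur_seg)
      cand <- cand[!used[cand]]
      if (length(cand) != 1L)
        stop("inconsistent path at vertex ", nxt)
      cur_seg <- cand
      cur <- nxt
    }
    edges[[length(edges) + 1L]] <-
      list(chain = chain, rl = rl, rr = rr, tension = 0)
  }
  kind <- ifelse(is_junction, 1L, 2L)
  cells <- lapply(seq_len(ncell), function(i)
    list(type = types[i], target_area = NA_real_, mu = mu[i]))
  new_tissue(sv$pos, kind, edges, cells, medium_label)
}

#' Seeded Voronoi tessellation tissue
#'
#' Generates a finite isolated aggregate of `n_cells` polygonal cells
#' surrounded by medium, sized so the mean cell diameter is close to 1.
#' With `size_variation = 0` generator points are sampled uniformly in a
#' disc and Lloyd-relaxed `lloyd_iters` times, giving a well-annealed,
#' near-monodisperse tessellation.  With `size_variation > 0` cell sizes
#' are varied intentionally: each cell is assigned a target area from a
#' lognormal distribution with log-sd `size_variation` and the generators
#' are placed by non-overlapping disc dart-throwing (largest first), the
#' classical construction for polydisperse foams; the resulting area
#' spread creates the intracellular pressure differences that bulge edges
#' under uniform tension.  Quad junctions arising from degenerate vertices
#' are normalized into closely spaced triple junctions.  Target areas are
#' set to the initial polygon areas.
#'
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; the same seed always returns the same mesh.
#' @param size_variation lognormal log-sd of prescribed cell areas; 0 gives
#'   a well-annealed tessellation, 0.5 a strongly polydisperse one (area
#'   coefficient of variation above 0.2).
#' @param lloyd_iters Lloyd relaxation iterations (used when
#'   `size_variation = 0`; relaxation would erase prescribed sizes).
#' @param types cell type labels (recycled across cells).
#' @param mu cytoplasm viscosity (recycled).
#' @param medium_label medium label.
#' @return a `polycell_tissue`.
#' @export
voronoi_tissue <- function(n_cells, seed = 1L, size_variation = 0.3,
                           lloyd_iters = 2L, types = "cell", mu = 1,
                           medium_label = "medium") {
  stopifnot(n_cells >= 1L)
  a_target <- pi / 4                      # unit mean cell diameter
  R <- sqrt(n_cells * a_target / pi)
  hull <- regular_ngon(64L, R * 1.05)
  gen <- with_seed(seed, {
    if (n_cells == 1L) list(p = matrix(0, 1L, 2L), w = NULL)
    else if (size_variation > 0) {
      areas <- stats::rlnorm(n_cells, sdlog = size_variation)
      areas <- areas / mean(areas) * a_target
      rad <- sqrt(0.7 * areas / pi)        # packing head-room
      ord <- order(rad, decreasing = TRUE)
      p <- matrix(NA_real_, n_cells, 2L)
      f <- 0.95
      for (i in ord) {
        placed <- FALSE
        while (!placed) {
          for (try in 1:200) {
            rr <- max(R - 0.8 * rad[i], 0) * sqrt(stats::runif(1L))
            th <- 2 * pi * stats::runif(1L)
            cand <- c(rr * cos(th), rr * sin(th))
            done <- !is.na(p[, 1L])
            if (!any(done) ||
                all(sqrt((p[done, 1L] - cand[1L])^2 +
                         (p[done, 2L] - cand[2L])^2) >=
                    f * (rad[done] + rad[i]))) {
              p[i, ] <- cand; placed <- TRUE; break
            }
          }
          if (!placed) f <- f * 0.95       # relax spacing until it fits
        }
      }
      list(p = p, w = rad^2 / 0.7)   # Laguerre weights realize the areas
    } else {
      for (attempt in 1:10) {
        r <- R * sqrt(stats::runif(n_cells))
        th <- 2 * pi * stats::runif(n_cells)
        p <- cbind(r * cos(th), r * sin(th))
        for (it in seq_len(lloyd_iters)) {
          polys <- voronoi_polygons(p, hull)
          p <- t(vapply(polys, polygon_centroid, numeric(2L)))
        }
        dmin <- min(stats::dist(p))
        if (dmin > 1e-5) break
        warning("degenerate generator set; regenerating with perturbation")
      }
      list(p = p, w = NULL)
    }
  })
  w <- gen$w
  repeat {
    polys <- voronoi_polygons(gen$p, hull, w)
    keep <- vapply(polys, function(q) nrow(q) >= 3L &&
                     abs(shoelace_area(q)) > 1e-9, logical(1L))
    if (all(keep) || is.null(w) || max(abs(w)) < 1e-10) break
    w <- w * 0.7                 # damp weights until no cell is dominated
  }
  polys <- polys[keep]
  ts <- tissue_from_polygons(polys, types = types, mu = mu,
                             medium_label = medium_label)
  # normalize any higher-order junctions from degenerate Voronoi vertices
  eps <- 0.025 * mean_cell_diameter(ts)
  inc <- junction_incidence(ts)
  val <- table(inc$node)
  for (nid in as.integer(names(val)[val >= 4L]))
    ts <- split_higher_order_junction(ts, nid, eps)
  ts
}
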