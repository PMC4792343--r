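# T1 exchanges, segment refinement/coarsening, junction splitting.

cc_adjacent <- function(ts) {
  e <- tissue_edges(ts)
  e <- e[e$left != 0L & e$right != 0L, ]
  unique(t(apply(cbind(e$left, e$right), 1L, sort)))
}

has_pair <- function(adj, a, b)
  any(adj[, 1L] == min(a, b) & adj[, 2L] == max(a, b))

test_that("long segments are bisected at their midpoints, recursively", {
  ts <- square_tissue(1)                 # D = 2/sqrt(pi), sides 1
  D <- mean_cell_diameter(ts)
  cfg <- sim_config(seg_max_frac = 0.3 / D * 1.001, seg_min_frac = 0.01)
  out <- refine_and_coarsen(ts, cfg)
  ts2 <- out$tissue
  lens <- tissue_edges(ts2)$length       # edge lengths unchanged
  expect_equal(lens, rep(1, 4L))
  segs <- polycell:::collect_segments(ts2)
  sl <- sqrt(rowSums((ts2$pos[segs$j, ] - ts2$pos[segs$i, ])^2))
  expect_true(all(sl <= 0.3 * 1.001 + 1e-12))
  expect_true(all(sl >= 0.2))            # equal halves of halves: 0.25 each
  expect_identical(nrow(validate_topology(ts2)), 0L)
  # a 0.30 D segment over a 0.25 D maximum splits once into 0.15 D halves
  ts3 <- square_tissue(1)
  res <- polycell:::add_node(ts3, c(0.3 * D, 0), 2L)
  ts3 <- res$ts; ts3$edges[[1L]]$chain <- c(1L, res$id, 2L)
  cfg3 <- sim_config(seg_max_frac = 0.25, seg_min_frac = 0.01)
  ts4 <- refine_and_coarsen(ts3, cfg3)$tissue
  ch <- ts4$edges[[1L]]$chain
  expect_equal(ts4$pos[ch[2L], ], c(0.15 * D, 0), tolerance = 1e-12)
  expect_equal(ts4$pos[ch[3L], ], c(0.3 * D, 0), tolerance = 1e-12)
  sl4 <- polycell:::chain_seg_lengths(ts4$pos[ch, ])
  expect_true(all(sl4 <= 0.25 * D + 1e-12))
})

test_that("short segments collapse by the stated merge rules", {
  # two intermediate nodes 0.01 D apart merge to a single midpoint node
  ts <- square_tissue(1)
  D <- mean_cell_diameter(ts)
  r1 <- polycell:::add_node(ts, c(0.5 - 0.005 * D, 0), 2L); ts <- r1$ts
  r2 <- polycell:::add_node(ts, c(0.5 + 0.005 * D, 0), 2L); ts <- r2$ts
  ts$edges[[1L]]$chain <- c(1L, r1$id, r2$id, 2L)
  cfg <- sim_config(seg_min_frac = 0.025, seg_max_frac = 10)
  out <- refine_and_coarsen(ts, cfg)
  ch <- out$tissue$edges[[1L]]$chain
  expect_identical(length(ch), 3L)
  newmid <- ch[2L]
  expect_gt(newmid, r2$id)               # fresh id
  expect_equal(out$tissue$pos[newmid, ], c(0.5, 0), tolerance = 1e-12)
  expect_true(all(is.na(out$tissue$kind[c(r1$id, r2$id)])))

  # an intermediate node 0.01 D from a junction is removed; junction stays
  ts2 <- square_tissue(1)
  r3 <- polycell:::add_node(ts2, c(0.01 * D, 0), 2L); ts2 <- r3$ts
  ts2$edges[[1L]]$chain <- c(1L, r3$id, 2L)
  out2 <- refine_and_coarsen(ts2, cfg)
  expect_identical(out2$tissue$edges[[1L]]$chain, c(1L, 2L))
  expect_equal(out2$tissue$pos[1L, ], c(0, 0))
  expect_identical(out2$events$kind, "merge")
})

test_that("a T1 exchange swaps the adjacent and separated cell pairs", {
  ts <- quartet_tissue(eps = 0.02)
  expect_identical(nrow(validate_topology(ts)), 0L)
  tt <- uniform_tensions()
  adj0 <- cc_adjacent(ts)
  expect_true(has_pair(adj0, 1L, 3L))
  expect_false(has_pair(adj0, 2L, 4L))
  cfg <- sim_config()
  out <- apply_t1_exchanges(ts, cfg, step = 1L, tensions = tt)
  ts2 <- out$tissue
  expect_identical(out$events$kind, "t1")
  adj1 <- cc_adjacent(ts2)
  expect_false(has_pair(adj1, 1L, 3L))
  expect_true(has_pair(adj1, 2L, 4L))
  expect_identical(nrow(validate_topology(ts2)), 0L)
  # cell count preserved; new edge has the post-T1 length and an embargo stamp
  expect_identical(nrow(tissue_cells(ts2)), 4L)
  enew <- tissue_edges(ts2)
  enew <- enew[enew$left %in% c(2L, 4L) & enew$right %in% c(2L, 4L), ]
  D <- mean_cell_diameter(ts)
  expect_equal(enew$length, cfg$post_t1_length_frac * D, tolerance = 1e-9)
})

test_that("embargoed and long-enough edges are left alone", {
  ts <- quartet_tissue(eps = 0.02)
  tt <- uniform_tensions()
  ei <- tissue_edges(ts)
  central <- ei$id[(ei$left == 1L & ei$right == 3L) |
                     (ei$left == 3L & ei$right == 1L)]
  ts$edges[[central]]$embargo <- 10L
  out <- apply_t1_exchanges(ts, sim_config(), step = 1L, tensions = tt)
  expect_null(out$events)
  expect_identical(out$tissue$edges[[central]]$chain,
                   ts$edges[[central]]$chain)
  # after expiry the exchange goes ahead
  out2 <- apply_t1_exchanges(ts, sim_config(), step = 10L, tensions = tt)
  expect_identical(out2$events$kind, "t1")
  # no short edge at all: nothing happens
  wide <- quartet_tissue(eps = 0.5)
  out3 <- apply_t1_exchanges(wide, sim_config(), step = 1L, tensions = tt)
  expect_null(out3$events)
  expect_identical(wide$pos, out3$tissue$pos)
})

test_that("T1 that would create a two-edged cell is skipped and logged", {
  # a triangular cell: its three edges include one short one; exchanging it
  # would leave the triangle with two edges
  ts <- quartet_tissue(eps = 0.02)
  # shrink cell 1's loop to 3 edges by merging its west corner edges is
  # involved; instead forbid via loop-length guard directly: temporarily
  # pretend cell 1 has only 3 boundary edges
  ts$cells[[1L]]$loop <- ts$cells[[1L]]$loop[1:3]
  out <- apply_t1_exchanges(ts, sim_config(), step = 1L,
                            tensions = uniform_tensions())
  expect_true(any(out$events$kind == "t1_skipped"))
  expect_match(out$events$entities[out$events$kind == "t1_skipped"],
               "two-edged")
})

test_that("quad junctions and rosettes split into triple-junction chains", {
  # 4 wedge cells around one central vertex (a quad junction)
  wedge <- function(a1, a2) rbind(c(0, 0), c(cos(a1), sin(a1)),
                                  c(cos(a2), sin(a2)))
  polys <- lapply(0:3, function(k)
    wedge(k * pi / 2, (k + 1) * pi / 2))
  ts <- polycell:::tissue_from_polygons(polys, types = "cell")
  ts <- set_tensions(ts, uniform_tensions())
  centre <- which(apply(ts$pos, 1L, function(p) all(abs(p) < 1e-9)))
  expect_identical(length(polycell:::node_edges(ts, centre)), 4L)
  ts2 <- split_higher_order_junction(ts, centre, epsilon = 0.01)
  inc <- polycell:::junction_incidence(ts2)
  val <- table(inc$node)
  expect_true(all(val <= 3L))
  expect_identical(nrow(validate_topology(ts2)), 0L)
  adj0 <- cc_adjacent(ts)
  adj1 <- cc_adjacent(ts2)
  for (r in seq_len(nrow(adj0)))     # all original adjacencies preserved
    expect_true(has_pair(adj1, adj0[r, 1L], adj0[r, 2L]))
  # edge and cell counts: one connector added, cells unchanged
  expect_identical(nrow(tissue_cells(ts2)), nrow(tissue_cells(ts)))
  expect_identical(nrow(tissue_edges(ts2)), nrow(tissue_edges(ts)) + 1L)

  # 5-valent rosette -> chain of two connectors, three triple junctions
  polys5 <- lapply(0:4, function(k)
    wedge(k * 2 * pi / 5, (k + 1) * 2 * pi / 5))
  t5 <- polycell:::tissue_from_polygons(polys5, types = "cell")
  t5 <- set_tensions(t5, uniform_tensions())
  centre5 <- which(apply(t5$pos, 1L, function(p) all(abs(p) < 1e-9)))
  t5b <- split_higher_order_junction(t5, centre5, epsilon = 0.01)
  expect_identical(nrow(tissue_edges(t5b)), nrow(tissue_edges(t5)) + 2L)
  inc5 <- polycell:::junction_incidence(t5b)
  expect_true(all(table(inc5$node) <= 3L))
  adjA <- cc_adjacent(t5); adjB <- cc_adjacent(t5b)
  for (r in seq_len(nrow(adjA)))
    expect_true(has_pair(adjB, adjA[r, 1L], adjA[r, 2L]))
  # a 3-valent node is a no-op
  j3 <- as.integer(names(which(table(inc5$node) == 3L)))[1L]
  expect_identical(split_higher_order_junction(t5b, j3), t5b)
})

test_that("segment lengths stay within bounds along a running simulation", {
  ts <- voronoi_tissue(12L, seed = 8L, size_variation = 0.4)
  tt <- uniform_tensions()
  ts <- set_tensions(ts, tt)
  cfg <- sim_config(n_steps = 400L, snapshot_stride = 200L, dt_safety = 0.5)
  tr <- run_simulation(ts, cfg, tt)
  term <- terminal_tissue(tr)
  D <- mean_cell_diameter(term)
  ed <- tissue_edges(term)
  segs <- polycell:::collect_segments(term)
  sl <- sqrt(rowSums((term$pos[segs$j, ] - term$pos[segs$i, ])^2))
  multi <- segs$edge %in% ed$id[ed$n_segments > 1L]
  expect_true(all(sl[multi] >= cfg$seg_min_frac * D * 0.9))
  expect_true(all(sl <= cfg$seg_max_frac * D * 1.1))
  expect_identical(nrow(validate_topology(term)), 0L)
})

test_that("a fresh edge cannot reverse its exchange while embargoed", {
  ts <- quartet_tissue(eps = 0.02)
  tt <- uniform_tensions()
  cfg <- sim_config(embargo_steps = 20L)
  out <- apply_t1_exchanges(ts, cfg, step = 1L, tensions = tt)
  ts2 <- out$tissue
  enew_id <- max(tissue_edges(ts2)$id)
  expect_identical(ts2$edges[[enew_id]]$embargo, 21L)
  # squeeze the new edge back below threshold: embargo must hold it
  ch <- ts2$edges[[enew_id]]$chain
  mid <- colMeans(ts2$pos[ch, ])
  u <- ts2$pos[ch[2L], ] - ts2$pos[ch[1L], ]; u <- u / sqrt(sum(u^2))
  D <- mean_cell_diameter(ts2)
  ts2$pos[ch[1L], ] <- mid - u * 0.005 * D
  ts2$pos[ch[2L], ] <- mid + u * 0.005 * D
  out2 <- apply_t1_exchanges(ts2, cfg, step = 2L, tensions = tt)
  expect_null(out2$events)
  out3 <- apply_t1_exchanges(ts2, cfg, step = 21L, tensions = tt)
  expect_identical(out3$events$kind, "t1")
})
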