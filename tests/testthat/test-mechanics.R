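# Force assembly, viscous matrix, constrained time stepping.

test_that("tension forces cancel on collinear segments and add at corners", {
  ts <- square_tissue()
  res <- polycell:::add_node(ts, c(0.5, 0), 2L)
  ts <- res$ts
  ts$edges[[1L]]$chain <- c(1L, res$id, 2L)   # bottom edge gets a midpoint
  f <- assemble_tension_forces(ts)
  expect_equal(f[res$id, ], c(0, 0), tolerance = 1e-14)   # collinear pulls cancel
  # corner (0,0): unit pulls along +x and +y
  expect_equal(f[1L, ], c(1, 1), tolerance = 1e-14)
  expect_equal(sqrt(sum(f[1L, ]^2)), sqrt(2), tolerance = 1e-14)
})

test_that("assembled forces equal minus the numerical energy gradient", {
  ts <- voronoi_tissue(20L, seed = 11L, size_variation = 0.4)
  ts <- set_tensions(ts, uniform_tensions(1.3))
  # refine so intermediate nodes participate too
  ts <- refine_and_coarsen(ts, sim_config(seg_max_frac = 0.2))$tissue
  f <- assemble_tension_forces(ts)
  h <- 1e-6
  ids <- polycell:::active_nodes(ts)
  set.seed(1); ids <- sample(ids, 40L)     # spot-check a random subset
  for (nid in ids) {
    for (d in 1:2) {
      tp <- ts; tp$pos[nid, d] <- tp$pos[nid, d] + h
      tm <- ts; tm$pos[nid, d] <- tm$pos[nid, d] - h
      g <- (boundary_energy(tp) - boundary_energy(tm)) / (2 * h)
      expect_equal(f[nid, d], -g, tolerance = 1e-6)
    }
  }
})

test_that("total tension load on an isolated aggregate is momentum-free", {
  ts <- voronoi_tissue(15L, seed = 4L, size_variation = 0.3)
  ts <- set_tensions(ts, uniform_tensions())
  f <- assemble_tension_forces(ts)
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("dashpot denominator counts junctions fully, intermediates half", {
  hexa <- ngon_cell(6L, area = pi / 4)
  expect_equal(cell_n_eff(hexa, 1L), 6)
  # bisect every side: 6 junctions + 6 intermediate nodes -> n_eff = 9
  refined <- refine_and_coarsen(hexa,
    sim_config(seg_max_frac = 0.45, seg_min_frac = 0.01))$tissue
  expect_equal(sum(refined$kind[polycell:::active_nodes(refined)] == 2L), 6L)
  expect_equal(cell_n_eff(refined, 1L), 9)
  # coefficient: mu * A / n_eff on every boundary node
  coef <- assemble_viscous_matrix(refined)
  a <- polygon_area(refined, 1L)
  expect_equal(unique(round(coef[coef > 0] / (a / 9), 12L)), 1)
})

test_that("advance_step leaves a zero-tension tissue at target areas untouched", {
  ts <- square_tissue(tension = 0)
  sol <- advance_step(ts, sim_config(dt = 0.01))
  expect_lt(sol$max_disp, 1e-14)
  expect_equal(sol$tissue$pos, ts$pos)
})

test_that("area constraints hold to high precision over many steps", {
  ts <- voronoi_tissue(12L, seed = 6L, size_variation = 0.5)
  ts <- set_tensions(ts, uniform_tensions())
  cfg <- sim_config(n_steps = 300L, snapshot_stride = 100L, dt_safety = 0.5)
  tr <- run_simulation(ts, cfg, uniform_tensions())
  term <- terminal_tissue(tr)
  cells <- tissue_cells(term)
  expect_lt(max(abs(cells$area - cells$target_area) / cells$target_area),
            1e-3 * 0.1)   # well under 0.1% drift
})

test_that("a single cell relaxes to a circle obeying the pressure-vessel law", {
  ts <- ngon_cell(12L, area = pi / 4, tension = 1)
  tt <- tension_table("cell|medium" = 1, "cell|cell" = 1)
  # ~60+ segments are needed before a regular polygon's isoperimetric ratio
  # pi/n / tan(pi/n) can exceed 0.999
  cfg <- sim_config(n_steps = 20000L, snapshot_stride = 2000L,
                    dt_safety = 0.5, seg_max_frac = 0.05,
                    seg_min_frac = 0.02)
  tr <- run_simulation(ts, cfg, tt)
  expect_identical(tr$status, "stationary")
  term <- terminal_tissue(tr)
  a <- polygon_area(term, 1L)
  per <- sum(tissue_edges(term)$length)
  expect_gt(4 * pi * a / per^2, 0.999)            # isoperimetric ratio
  sol <- advance_step(term, sim_config(dt = 1e-4))
  r <- sqrt(a / pi)
  expect_equal(unname(sol$pressures["1"]), 1 / r, tolerance = 0.02)
})

test_that("a two-cell doublet satisfies Young-Laplace at its interface", {
  # unequal target areas force a pressure difference across the interface
  ts <- doublet_square_tissue()
  ts$cells[[2L]]$target_area <- 0.55
  tt <- tension_table("a|a" = 1, "b|b" = 1, "a|b" = 1,
                      "a|medium" = 1, "b|medium" = 1)
  ts <- set_tensions(ts, tt)
  cfg <- sim_config(n_steps = 6000L, snapshot_stride = 500L, dt_safety = 0.5,
                    seg_max_frac = 0.1)
  tr <- run_simulation(ts, cfg, tt)
  expect_identical(tr$status, "stationary")
  term <- terminal_tissue(tr)
  sol <- advance_step(term, sim_config(dt = 1e-4))
  dp <- sol$pressures["1"] - sol$pressures["2"]
  iface <- tissue_edges(term)
  ei <- iface$id[iface$left != 0L & iface$right != 0L]
  fit <- fit_circular_arc(term$pos[term$edges[[ei]]$chain, ])
  # sign convention: kappa = (p_left - p_right) / gamma
  e <- term$edges[[ei]]
  dp_lr <- sol$pressures[as.character(e$rl)] - sol$pressures[as.character(e$rr)]
  expect_equal(fit$signed_curvature, unname(dp_lr) / e$tension,
               tolerance = 0.02)
  expect_equal(abs(fit$signed_curvature), abs(unname(dp)) / e$tension,
               tolerance = 0.02)
})

test_that("equivalent shear follows V = dp * L / 2", {
  expect_identical(equivalent_shear(0, 17.3), 0)
  expect_identical(equivalent_shear(2, 3), 3)
  expect_equal(equivalent_shear(1.4, 5) / equivalent_shear(1.4, 10), 0.5)
  expect_error(equivalent_shear(1, -1))
})

test_that("interior junctions of a symmetric hexagonal patch sit at rest", {
  # 7 regular hexagons (centre + ring): the central cell's junctions are
  # interior, symmetric, and carry balanced 120-degree tensions
  s <- 0.6
  hex <- function(cx, cy) {
    th <- pi / 6 + seq(0, 2 * pi, length.out = 7L)[-7L]
    cbind(cx + s * cos(th), cy + s * sin(th))
  }
  centers <- rbind(c(0, 0), t(vapply(0:5, function(k) {
    a <- pi / 3 * k         # neighbour centres sit along the edge normals
    c(sqrt(3) * s * cos(a), sqrt(3) * s * sin(a))
  }, numeric(2L))))
  polys <- lapply(seq_len(nrow(centers)), function(i)
    hex(centers[i, 1L], centers[i, 2L]))
  ts <- polycell:::tissue_from_polygons(polys, types = "cell")
  ts <- set_tensions(ts, uniform_tensions())
  expect_identical(nrow(validate_topology(ts)), 0L)
  f <- assemble_tension_forces(ts)
  inner <- polycell:::cell_loop_nodes(ts, 1L)
  expect_lt(max(abs(f[inner, ])), 1e-12)
  je <- junction_angle_errors(ts, "nearest_segment", interior_only = TRUE)
  expect_true(all(je$rms_error[!je$flagged] < 0.1))
})
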