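# Arc fits, Young angles, junction errors, series metrics, discrepancies.

test_that("circular arc fits recover exact circles and straight lines", {
  th <- seq(0.2, 1.4, length.out = 5L)
  pts <- cbind(1 + 2 * cos(th), -0.5 + 2 * sin(th))
  fit <- fit_circular_arc(pts)
  expect_equal(fit$radius, 2, tolerance = 1e-9)
  expect_equal(fit$center, c(1, -0.5), tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-10)
  expect_equal(abs(fit$signed_curvature), 0.5, tolerance = 1e-9)

  line <- cbind(seq(0, 1, length.out = 7L), seq(0, 2, length.out = 7L))
  lf <- fit_circular_arc(line)
  expect_identical(lf$radius, Inf)
  expect_identical(lf$signed_curvature, 0)

  expect_identical(fit_circular_arc(rbind(c(0, 0), c(1, 1)))$radius, Inf)
  expect_error(fit_circular_arc(rbind(c(0, 0))))
})

test_that("arc fit matches a brute-force geometric least-squares oracle", {
  set.seed(13)
  for (rep in 1:5) {
    R <- runif(1L, 0.5, 3)
    c0 <- runif(2L, -1, 1)
    th <- sort(runif(10L, 0, 1.8))
    pts <- cbind(c0[1L] + R * cos(th), c0[2L] + R * sin(th)) +
      matrix(rnorm(20L, sd = 0.005 * R), ncol = 2L)
    fit <- fit_circular_arc(pts)
    obj <- function(p) sum((sqrt((pts[, 1L] - p[1L])^2 +
                                   (pts[, 2L] - p[2L])^2) - p[3L])^2)
    # oracle: direct geometric minimization from a crude centroid start
    start <- c(colMeans(pts) - c(0, R), R)
    best <- optim(start, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000L, reltol = 1e-14))
    best <- optim(best$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000L, reltol = 1e-14))
    expect_equal(fit$radius, best$par[3L], tolerance = 1e-3)
  }
})

test_that("arc curvature sign follows the left-of-chain convention", {
  th <- seq(-0.5, 0.5, length.out = 6L)
  # arc around a centre on the LEFT of the chain direction
  up <- cbind(sin(th), 1 - cos(th))      # centre (0,1), travelling +x
  expect_gt(fit_circular_arc(up)$signed_curvature, 0)
  expect_lt(fit_circular_arc(up[rev(seq_len(6L)), ])$signed_curvature, 0)
})

test_that("young_angles reproduces closed forms and a force-balance oracle", {
  expect_equal(young_angles(1, 1, 1), rep(2 * pi / 3, 3L), tolerance = 1e-12)

  g <- c(1, 1, sqrt(2))
  ya <- young_angles(g[1L], g[2L], g[3L])
  # numerical oracle: directions t1 = 0, t2, t3 balancing the tensions
  obj <- function(p) {
    v <- c(g[1L] + g[2L] * cos(p[1L]) + g[3L] * cos(p[2L]),
           g[2L] * sin(p[1L]) + g[3L] * sin(p[2L]))
    sum(v^2)
  }
  sol <- optim(c(2.5, 4.0), obj, method = "BFGS",
               control = list(reltol = 1e-15))
  th2 <- sol$par[1L]; th3 <- sol$par[2L] %% (2 * pi)
  # wedge angles: between interfaces 2 and 3 (opposite tension 1), etc.
  w23 <- abs(th3 - th2); w12 <- th2; w13 <- 2 * pi - th3
  expect_equal(sort(ya), sort(c(w23, w12, w13)), tolerance = 1e-6)
  expect_equal(ya[3L], pi / 2, tolerance = 1e-12)   # between the two g=1 arms
  expect_equal(ya[1L], 3 * pi / 4, tolerance = 1e-12)

  expect_error(young_angles(3, 1, 1), "triangle")
  expect_error(young_angles(0, 1, 1))
})

test_that("young angles sum to 2*pi and are scale invariant", {
  set.seed(99)
  n_ok <- 0L
  while (n_ok < 20L) {
    g <- runif(3L, 0.2, 2)
    if (any(g >= c(g[2L] + g[3L], g[1L] + g[3L], g[1L] + g[2L]))) next
    ya <- young_angles(g[1L], g[2L], g[3L])
    expect_equal(sum(ya), 2 * pi, tolerance = 1e-12)
    expect_equal(ya, young_angles(7.3 * g[1L], 7.3 * g[2L], 7.3 * g[3L]),
                 tolerance = 1e-12)
    n_ok <- n_ok + 1L
  }
})

test_that("junction scoring skips tension triples without equilibrium", {
  ts <- quartet_tissue(eps = 0.4)
  # give one edge at a junction an unbalanceable tension
  ed <- tissue_edges(ts)
  central <- ed$id[(ed$left == 1L & ed$right == 3L) |
                     (ed$left == 3L & ed$right == 1L)]
  ts$edges[[central]]$tension <- 10
  je <- junction_angle_errors(ts, "nearest_segment")
  touched <- ts$edges[[central]]$chain
  expect_true(all(je$flagged[je$junction %in% touched]))
  expect_false(any(je$flagged[!je$junction %in% touched]))
})

test_that("discrepancy percentage behaves at zero and for identical series", {
  expect_identical(discrepancy_percent(0, 0), 0)
  expect_equal(discrepancy_percent(1, 1), 0)
  expect_equal(discrepancy_percent(1, 3), 100)
  expect_equal(discrepancy_percent(c(2, 4), c(2, 4)), c(0, 0))
})

test_that("aggregate_metrics reports exact trivials on short runs", {
  ts <- voronoi_tissue(10L, seed = 21L, size_variation = 0.4)
  tt <- uniform_tensions()
  ts <- set_tensions(ts, tt)
  cfg <- sim_config(n_steps = 60L, snapshot_stride = 20L,
                    mode = "monoline", dt_safety = 0.5)
  tr <- run_simulation(ts, cfg, tt)
  am <- aggregate_metrics(tr, interface_class = "cell|cell",
                          angle_method = "nearest_segment")
  expect_equal(am$boundary_len_norm[1L], 1.0)
  expect_equal(am$displacement_norm[1L], 0)
  expect_identical(am$t_star[1L], 0)
  # straight monoline cell-cell edges carry exactly zero curvature
  expect_true(all(am$mean_abs_curv_norm == 0))
  expect_true(all(diff(am$t_star) > 0))
})

test_that("nearest-segment angles approach arc-tangent angles under refinement", {
  ts <- voronoi_tissue(12L, seed = 31L, size_variation = 0.5)
  tt <- uniform_tensions()
  ts <- set_tensions(ts, tt)
  gap <- numeric(0L)
  for (smax in c(0.25, 0.08)) {
    cfg <- sim_config(n_steps = 4000L, seg_max_frac = smax,
                      seg_min_frac = smax / 10, snapshot_stride = 1000L,
                      dt_safety = 0.5)
    tr <- run_simulation(ts, cfg, tt)
    term <- terminal_tissue(tr)
    ns <- junction_angle_errors(term, "nearest_segment")
    at <- junction_angle_errors(term, "arc_tangent")
    gap <- c(gap, abs(median(ns$rms_error[!ns$flagged]) -
                        median(at$rms_error[!at$flagged])))
  }
  expect_lt(gap[2L], gap[1L])
})
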